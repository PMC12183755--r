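## Synthetic systems and independent oracles: a sinc-DVR eigensolver
## (1D/2D), Gauss-Hermite quadrature for matrix elements, steepest-descent
## model reaction paths, and a pseudo-triatomic molecular test bed for the
## projection operators.

#' Sinc-DVR eigenvalues of -1/2 Laplacian + V (1D or 2D)
#'
#' Colbert-Miller sinc discrete variable representation on a uniform grid;
#' coordinates are pre-mass-weighted (unit mass). Convergence can be
#' verified by doubling `n_points`.
#'
#' @param pes_callable function of a coordinate vector returning the
#'   potential energy, or an `sbg_provider`.
#' @param grid_min,grid_max per-dimension grid bounds (a.u.); must bracket
#'   the classical turning points of the requested states.
#' @param n_points grid points per dimension (>= 32).
#' @param n_states number of eigenvalues returned.
#' @return ascending numeric eigenvalues (hartree).
#' @export
dvr_eigenvalues <- function(pes_callable, grid_min, grid_max, n_points = 101,
                            n_states = 4) {
  ndim <- length(grid_min)
  if (ndim > 2) stop("sinc-DVR oracle supports 1D and 2D only")
  if (any(n_points < 32)) stop("n_points must be >= 32")
  n_points <- rep_len(n_points, ndim)
  f <- if (inherits(pes_callable, "sbg_provider"))
    function(q) pes_callable$eval_fn(q, FALSE)$energy else pes_callable
  kin1 <- function(n, dx) {
    i <- matrix(seq_len(n), n, n); j <- t(i)
    t1 <- (-1)^(i - j) / dx^2
    diag(t1) <- pi^2 / 3 / dx^2
    off <- i != j
    t1[off] <- t1[off] * 2 / (i[off] - j[off])^2
    t1 / 2
  }
  if (ndim == 1) {
    q <- seq(grid_min, grid_max, length.out = n_points)
    h <- kin1(n_points, q[2] - q[1]) + diag(vapply(q, f, numeric(1)))
    ev <- eigen(h, symmetric = TRUE, only.values = TRUE)$values
    return(sort(ev)[seq_len(n_states)])
  }
  q1 <- seq(grid_min[1], grid_max[1], length.out = n_points[1])
  q2 <- seq(grid_min[2], grid_max[2], length.out = n_points[2])
  t1 <- kin1(n_points[1], q1[2] - q1[1])
  t2 <- kin1(n_points[2], q2[2] - q2[1])
  n1 <- n_points[1]; n2 <- n_points[2]
  vg <- outer(seq_len(n1), seq_len(n2),
              Vectorize(function(i, j) f(c(q1[i], q2[j]))))
  h <- kronecker(t1, diag(n2)) + kronecker(diag(n1), t2) + diag(as.numeric(t(vg)))
  ev <- eigen(h, symmetric = TRUE, only.values = TRUE)$values
  sort(ev)[seq_len(n_states)]
}

#' Gauss-Hermite quadrature oracle for Gaussian matrix elements
#'
#' Numerically integrates overlap, momentum-moment, exact-potential or
#' local-harmonic integrands between two Gaussian bases (D <= 3). The
#' quadrature frame is a reference Gaussian twice as broad as the pair
#' product, centred between the two centres; the oracle shares no algebra
#' with the closed forms it checks beyond the width sum used for that frame
#' and the integrand definitions themselves.
#'
#' @param operator_tag one of `"overlap"`, `"kinetic_ab"` (returns the full
#'   D x D momentum-moment matrix), `"potential_exact"`, `"potential_lha"`.
#' @param g1,g2 `sbg_basis` objects (dimension <= 3).
#' @param pes provider (required for the potential tags).
#' @param n_nodes Gauss-Hermite nodes per dimension.
#' @return scalar, or a matrix for `"kinetic_ab"`.
#' @export
quadrature_matrix_element <- function(operator_tag, g1, g2, pes = NULL,
                                      n_nodes = 40) {
  d <- length(g1$center)
  if (d > 3) stop("quadrature oracle supports D <= 3")
  gh <- pracma::gaussHermite(n_nodes)
  # anisotropic reference frame: eigenvectors of the width sum, scaled to be
  # twice as broad as the product Gaussian, centred between the two centres
  ed <- eigen(g1$width + g2$width, symmetric = TRUE)
  scale <- sqrt(2 / ed$values)
  center <- (g1$center + g2$center) / 2
  grids <- rep(list(seq_len(n_nodes)), d)
  idx <- as.matrix(expand.grid(grids))
  u <- sweep(matrix(gh$x[idx], ncol = d), 2, scale, `*`)
  pts <- sweep(u %*% t(ed$vectors), 2, center, `+`)
  logw <- matrix(log(gh$w)[idx], ncol = d)
  w <- exp(rowSums(logw) + rowSums(matrix(gh$x[idx], ncol = d)^2)) *
    prod(scale)
  gv1 <- basis_value(g1, pts)
  gv2 <- basis_value(g2, pts)
  if (operator_tag == "overlap") return(sum(w * gv1 * gv2))
  if (operator_tag == "kinetic_ab") {
    # M_ab = integral of (d_a G1)(d_b G2)
    d1 <- -2 * (sweep(pts, 2, g1$center) %*% g1$width) * gv1
    d2 <- -2 * (sweep(pts, 2, g2$center) %*% g2$width) * gv2
    m <- crossprod(d1 * w, d2)
    return((m + t(m)) / 2)
  }
  if (operator_tag == "potential_exact") {
    v <- apply(pts, 1, function(q) pes$eval_fn(q, FALSE)$energy)
    return(sum(w * gv1 * v * gv2))
  }
  if (operator_tag == "potential_lha") {
    qm <- gauss_midpoint(g1, g2)
    info <- pes$eval_fn(qm, TRUE)
    dq <- sweep(pts, 2, qm)
    vloc <- info$energy + rowSums((dq %*% info$hessian) * dq) / 2
    return(sum(w * gv1 * vloc * gv2))
  }
  stop("unknown operator_tag: ", operator_tag)
}

#' Steepest-descent reaction path of a model potential
#'
#' Integrates the two downhill branches from the saddle point (displaced by
#' `1e-4` along the negative-curvature eigenvector), using
#' normalized-gradient Euler steps of size `step`, finishing each branch
#' with Newton iterations onto the minimum (gradient norm below `g_tol`).
#' Branches are concatenated minimum-to-minimum.
#'
#' @param provider model provider exposing `$saddle` (e.g.
#'   [pes_double_well()]).
#' @param step Euler step length (mass-weighted a.u.).
#' @param max_points per-branch step limit.
#' @param g_tol terminal gradient-norm tolerance.
#' @return an `sbg_path` with per-point energies.
#' @export
synthetic_irc <- function(provider, step = 0.25, max_points = 2000,
                          g_tol = 1e-8) {
  if (is.null(provider$saddle)) stop("provider does not expose a saddle point")
  q0 <- provider$saddle
  info0 <- provider$eval_fn(q0, TRUE)
  ed <- eigen(info0$hessian, symmetric = TRUE)
  if (sum(ed$values < -1e-12) != 1)
    stop("starting point is not a first-order saddle")
  down <- ed$vectors[, which.min(ed$values)]
  # fix the arbitrary eigenvector sign so branch ordering is deterministic
  imax <- which.max(abs(down))
  if (down[imax] < 0) down <- -down
  branch <- function(dir_sign) {
    q <- q0 + dir_sign * 1e-4 * down
    pts <- list(); en <- numeric(0)
    for (k in seq_len(max_points)) {
      info <- provider$eval_fn(q, FALSE)
      # fixed-size normalized steps overshoot once the minimum basin floor
      # is reached; stop descending there and let Newton finish
      if (length(en) && info$energy >= en[length(en)]) break
      pts[[length(pts) + 1L]] <- q; en <- c(en, info$energy)
      g <- info$gradient
      gn <- sqrt(sum(g^2))
      if (gn < g_tol) break
      q <- q - step * g / gn
    }
    q <- pts[[length(pts)]]
    # Newton polish onto the minimum
    for (k in 1:50) {
      info <- provider$eval_fn(q, TRUE)
      if (sqrt(sum(info$gradient^2)) < g_tol) break
      q <- q - solve(info$hessian, info$gradient)
    }
    if (sqrt(sum((q - pts[[length(pts)]])^2)) > 1e-10) {
      pts[[length(pts) + 1L]] <- q
      en <- c(en, provider$eval_fn(q, FALSE)$energy)
    } else {
      pts[[length(pts)]] <- q
      en[length(en)] <- provider$eval_fn(q, FALSE)$energy
    }
    list(pts = do.call(rbind, pts), en = en)
  }
  b1 <- branch(-1); b2 <- branch(+1)
  pts <- rbind(b1$pts[rev(seq_len(nrow(b1$pts))), , drop = FALSE],
               q0, b2$pts)
  en <- c(rev(b1$en), info0$energy, b2$en)
  sbg_path(pts, energies = en)
}

#' Pseudo-triatomic molecular fixture for projection tests
#'
#' A bent three-atom "molecule" with a potential quadratic in internal
#' displacements (two bonds and the bend), mapped to mass-weighted
#' Cartesians through the Wilson B matrix at equilibrium:
#' `V = 1/2 dQ' H0 dQ` with `H0 = B' K B`. `H0` has exactly 6 zero
#' eigenvalues (rigid translations and infinitesimal rotations), making the
#' energy invariant under rigid translations exactly and under rotations to
#' first order.
#'
#' @param k_bond stretch force constant (hartree/bohr^2).
#' @param k_bend bend force constant (hartree/rad^2).
#' @return list with `molecule`, `provider`, the equilibrium mass-weighted
#'   vector `q0`, `h0`, and the three internal vibrational frequencies
#'   `omega` (a.u.).
#' @export
pseudo_triatomic <- function(k_bond = 0.35, k_bend = 0.08) {
  # bent water-like geometry (Angstrom), centred at the centre of mass so
  # the projection-operator precondition holds
  raw <- rbind(c(0, 0, 0),
               c(0.9572, 0, 0),
               c(-0.2400, 0.9266, 0))
  masses <- unname(.isotope_masses[c("O", "H", "H")])
  com <- colSums(raw * masses) / sum(masses)
  mol <- molecule(c("O", "H", "H"), sweep(raw, 2, com), masses)
  q0 <- to_mass_weighted(mol)
  m_au <- mol$masses * sbg_units[["amu_to_me"]]
  x <- matrix(q0, ncol = 3, byrow = TRUE) / sqrt(m_au)   # bohr
  # internal coordinates: r12, r13, theta(2-1-3); B matrix in mass-weighted
  # coordinates by finite differences of the exact internal-coordinate maps
  internals <- function(q) {
    xx <- matrix(q, ncol = 3, byrow = TRUE) / sqrt(m_au)
    v1 <- xx[2, ] - xx[1, ]; v2 <- xx[3, ] - xx[1, ]
    c(sqrt(sum(v1^2)), sqrt(sum(v2^2)),
      acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))
  }
  d <- length(q0)
  b <- matrix(0, 3, d)
  hstep <- 1e-6
  for (j in seq_len(d)) {
    e <- numeric(d); e[j] <- hstep
    b[, j] <- (internals(q0 + e) - internals(q0 - e)) / (2 * hstep)
  }
  kdiag <- c(k_bond, k_bond, k_bend)
  h0 <- t(b) %*% (kdiag * b)
  h0 <- (h0 + t(h0)) / 2
  provider <- pes_quadratic(h0, center = q0)
  # internal frequencies: nonzero eigenvalues of H0
  ev <- sort(eigen(h0, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)[1:3]
  list(molecule = mol, provider = provider, q0 = q0, h0 = h0,
       omega = sqrt(ev))
}

#' Default double-well study fixture
#'
#' The standard synthetic system used throughout the tests and examples: a
#' quartic double well (barrier `1.6e-2` hartree, minima at `+/- 25`
#' mass-weighted a.u.) with optionally one transverse harmonic mode of
#' `4e-3` a.u. (about 878 cm^-1) and a weak quadratic coupling that bends
#' the path, placing the ground doublet splitting at a few percent of the
#' well frequency (the tunneling-dominated regime).
#'
#' @param ndim 1 for the bare double well, 2 to include the transverse mode.
#' @param coupling path-bending coupling constant (2D only).
#' @return an `sbg_provider`.
#' @export
fixture_double_well <- function(ndim = 1, coupling = 8e-4) {
  if (ndim == 1) pes_double_well(1.6e-2, 25)
  else pes_double_well(1.6e-2, 25, omega_t = 4e-3, coupling = coupling)
}
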