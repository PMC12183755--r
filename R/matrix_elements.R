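## Closed-form matrix elements between anisotropic Gaussians: overlap,
## momentum second moments (kinetic), and local-harmonic potential
## elements at the width-weighted pair midpoint.
##
## With A = alpha1 + alpha2 and d = Q1 - Q2 the product of two normalized
## Gaussians is again a Gaussian with centre Qm = A^-1 (alpha1 Q1 +
## alpha2 Q2), precision 2A (covariance A^-1/2), and total weight
##   S12 = exp(z1 + z2) * pi^(D/2) det(A)^(-1/2)
##         * exp(-d' alpha1 A^-1 alpha2 d).
## All further elements are Gaussian moments against that product measure.

.pair_geometry <- function(g1, g2) {
  d <- length(g1$center)
  if (length(g2$center) != d) stop("basis dimension mismatch")
  a_sum <- g1$width + g2$width
  ed <- eigen(a_sum, symmetric = TRUE)
  a_inv <- ed$vectors %*% (t(ed$vectors) / ed$values)
  dd <- g1$center - g2$center
  b <- g1$width %*% a_inv %*% g2$width        # symmetric: (a1^-1 + a2^-1)^-1
  b <- (b + t(b)) / 2
  log_s <- g1$log_norm + g2$log_norm + d / 2 * log(pi) -
    sum(log(ed$values)) / 2 - sum(dd * (b %*% dd))
  list(dim = d, a_sum = a_sum, a_inv = a_inv, b = b, dd = dd,
       s = exp(log_s),
       midpoint = as.numeric(a_inv %*% (g1$width %*% g1$center +
                                        g2$width %*% g2$center)))
}

#' Overlap integral of two Gaussian bases
#'
#' @param g1,g2 `sbg_basis` objects of equal dimension.
#' @return scalar in (0, 1] for normalized bases.
#' @export
gauss_overlap <- function(g1, g2) .pair_geometry(g1, g2)$s

#' Width-weighted midpoint of a basis pair
#'
#' The peak position of the product `G1 G2`:
#' `(alpha1 + alpha2)^-1 (alpha1 Q1 + alpha2 Q2)`. Potential information
#' for the local harmonic approximation is evaluated here.
#'
#' @param g1,g2 `sbg_basis` objects.
#' @return mass-weighted midpoint vector (a.u.).
#' @export
gauss_midpoint <- function(g1, g2) .pair_geometry(g1, g2)$midpoint

#' Momentum second-moment matrix of a basis pair
#'
#' `M[a,b] = <G1| P_a P_b |G2> = -<G1| d^2/dQ_a dQ_b |G2>` (hbar = 1);
#' symmetric. The total kinetic element is `Tr(M)/2` and projected kinetic
#' elements are `Tr(O M)/2`.
#'
#' @param g1,g2 `sbg_basis` objects.
#' @return D x D symmetric matrix.
#' @export
momentum_moments <- function(g1, g2) {
  pg <- .pair_geometry(g1, g2)
  bd <- pg$b %*% pg$dd
  m <- (2 * pg$b - 4 * tcrossprod(bd)) * pg$s
  (m + t(m)) / 2
}

#' Vibrational (projected) kinetic matrix element
#'
#' `T_vib = T_total - T_tra - T_rot = Tr[(1 - o_tra - o_rot) M] / 2`. For
#' abstract systems (`proj = NULL`) there is nothing to project out and the
#' element is `Tr(M) / 2`.
#'
#' @param g1,g2 `sbg_basis` objects.
#' @param proj optional projection operators from [projection_operators()].
#' @return scalar (hartree).
#' @export
kinetic_vib <- function(g1, g2, proj = NULL) {
  m <- momentum_moments(g1, g2)
  if (is.null(proj)) return(sum(diag(m)) / 2)
  sum(proj$o_vib * m) / 2           # Tr(O M) for symmetric O, M
}

#' Local-harmonic potential matrix element
#'
#' `{ V(Qm) + Tr[(alpha1 + alpha2)^-1 V''(Qm)] / 4 } * <G1|G2>` with the
#' raw (unregularized) Hessian at the pair midpoint `Qm`. Exact whenever
#' the potential is at most quadratic.
#'
#' @param g1,g2 `sbg_basis` objects.
#' @param info an `sbg_potinfo` evaluated at [gauss_midpoint()] of the pair.
#' @return scalar (hartree).
#' @export
potential_lha <- function(g1, g2, info) {
  stopifnot(inherits(info, "sbg_potinfo"))
  if (is.null(info$hessian))
    stop("potential info must carry a Hessian for the LHA element")
  pg <- .pair_geometry(g1, g2)
  (info$energy + sum(pg$a_inv * info$hessian) / 4) * pg$s
}

# deterministic point IDs: centres "c<i>", midpoints "m<i>_<j>" (i <= j)
.point_id <- function(i, j = NULL)
  if (is.null(j)) sprintf("c%d", i) else sprintf("m%d_%d", min(i, j), max(i, j))

#' Assemble overlap, kinetic and potential matrices
#'
#' Fills `S` and `T_vib` from the closed forms and `V` from the local
#' harmonic approximation, taking midpoint potential information from
#' `source` (a provider or a GPR source from [gpr_source()]). Diagonal
#' entries use the basis centre itself. When a symmetry operation is
#' supplied, point requests that are images of already-evaluated points are
#' served by [symmetry_expand()] instead of new provider calls, and
#' `evaluation_log` records only the unique underlying evaluations.
#'
#' @param bases list of `sbg_basis`.
#' @param source an `sbg_provider` or `sbg_gpr_source`.
#' @param proj optional projection operators (molecular systems).
#' @param symmetry optional `sbg_symop` used to deduplicate evaluations.
#' @param sym_tol coordinate tolerance when matching symmetry images.
#' @return list of class `sbg_hmat`: `overlap`, `kinetic_vib`, `potential`
#'   (L x L symmetric), `evaluation_log` (IDs of unique evaluations) and
#'   `midpoint_info` (per-pair `sbg_potinfo`).
#' @export
assemble_hamiltonian <- function(bases, source, proj = NULL, symmetry = NULL,
                                 sym_tol = 1e-6) {
  l <- length(bases)
  if (l < 1) stop("need at least one basis")
  d <- length(bases[[1]]$center)
  s_mat <- t_mat <- v_mat <- matrix(0, l, l)
  seen_pts <- list()   # id -> list(point, info)
  log_ids <- character(0)
  fetch <- function(id, point) {
    if (!is.null(seen_pts[[id]])) return(seen_pts[[id]]$info)
    if (!is.null(symmetry)) {
      img <- as.numeric(symmetry$matrix %*% point)
      for (rec in seen_pts) {
        if (max(abs(rec$point - img)) <= sym_tol) {
          info <- symmetry_expand(rec$info, .sym_inverse(symmetry))
          seen_pts[[id]] <<- list(point = point, info = info)
          return(info)
        }
      }
    }
    info <- .source_eval(source, point)
    seen_pts[[id]] <<- list(point = point, info = info)
    log_ids <<- c(log_ids, id)
    info
  }
  for (i in seq_len(l)) for (j in i:l) {
    g1 <- bases[[i]]; g2 <- bases[[j]]
    pg <- .pair_geometry(g1, g2)
    s_mat[i, j] <- s_mat[j, i] <- pg$s
    tv <- if (is.null(proj)) sum(diag(momentum_moments(g1, g2))) / 2
          else sum(proj$o_vib * momentum_moments(g1, g2)) / 2
    t_mat[i, j] <- t_mat[j, i] <- tv
    info <- fetch(.point_id(i, if (i != j) j), pg$midpoint)
    v_mat[i, j] <- v_mat[j, i] <- (info$energy +
      sum(pg$a_inv * info$hessian) / 4) * pg$s
  }
  structure(list(overlap = s_mat, kinetic_vib = t_mat, potential = v_mat,
                 evaluation_log = log_ids, n_bases = l, dim = d),
            class = "sbg_hmat")
}

# inverse of an orthogonal symmetry operation (M' = M^-1)
.sym_inverse <- function(op) symmetry_op(t(op$matrix), op$order)

# uniform evaluation across providers and GPR sources
.source_eval <- function(source, point) {
  if (inherits(source, "sbg_provider"))
    pes_evaluate(source, point, need_hessian = TRUE)
  else if (inherits(source, "sbg_gpr_source"))
    source$eval_fn(point)
  else stop("source must be an sbg_provider or sbg_gpr_source")
}

#' @export
print.sbg_hmat <- function(x, ...) {
  cat("<sbg_hmat> L = ", x$n_bases, ", dim ", x$dim, ", ",
      length(x$evaluation_log), " unique potential evaluations\n", sep = "")
  invisible(x)
}
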