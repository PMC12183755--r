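## Potential-information providers: a uniform contract for energies,
## gradients and mass-weighted Hessians, analytic model potentials with
## exact derivatives, a tabulated JSON store, and symmetry expansion.

#' Bundle of potential information at a point
#'
#' @param energy potential energy (hartree).
#' @param gradient optional D-vector (hartree per mass-weighted a.u.).
#' @param hessian optional D x D symmetric matrix (a.u.; eigenvalues are
#'   squared angular frequencies omega^2).
#' @return object of class `sbg_potinfo`.
#' @export
potential_info <- function(energy, gradient = NULL, hessian = NULL) {
  if (!is.finite(energy)) stop("energy must be finite")
  if (!is.null(hessian)) {
    hessian <- as.matrix(hessian)
    asym <- max(abs(hessian - t(hessian)))
    if (asym > 1e-10 * max(1, max(abs(hessian))))
      stop("hessian asymmetric beyond tolerance: ", format(asym))
    hessian <- (hessian + t(hessian)) / 2
  }
  structure(list(energy = as.numeric(energy), gradient = gradient,
                 hessian = hessian),
            class = "sbg_potinfo")
}

.new_provider <- function(dim, capabilities, eval_fn, extra = list()) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  p <- c(list(dim = dim, capabilities = capabilities, eval_fn = eval_fn,
              counter = counter), extra)
  class(p) <- "sbg_provider"
  p
}

#' @export
print.sbg_provider <- function(x, ...) {
  cat("<sbg_provider> dim ", x$dim, ", capabilities: ",
      paste(x$capabilities, collapse = "/"),
      ", evaluations: ", x$counter$n, "\n", sep = "")
  invisible(x)
}

#' Evaluate a potential provider at a point
#'
#' @param provider an `sbg_provider`.
#' @param point mass-weighted coordinate vector (a.u.).
#' @param need_hessian request the Hessian as well as the energy.
#' @param fd_fallback if `TRUE`, a provider lacking Hessians is completed by
#'   [fd_hessian()] (explicit opt-in: costs O(D^2) energy calls).
#' @return an `sbg_potinfo`.
#' @export
pes_evaluate <- function(provider, point, need_hessian = TRUE,
                         fd_fallback = FALSE) {
  stopifnot(inherits(provider, "sbg_provider"))
  if (length(point) != provider$dim)
    stop("point dimension ", length(point), " != provider dimension ",
         provider$dim)
  if (need_hessian && !("hessian" %in% provider$capabilities)) {
    if (!fd_fallback)
      stop("provider does not supply Hessians (enable fd_fallback to use ",
           "finite differences)")
    return(fd_hessian(provider, point))
  }
  provider$counter$n <- provider$counter$n + 1L
  provider$eval_fn(point, need_hessian)
}

#' Number of provider evaluations so far
#' @param provider an `sbg_provider`.
#' @export
pes_eval_count <- function(provider) provider$counter$n

#' Reset the provider evaluation counter
#' @param provider an `sbg_provider`.
#' @export
pes_reset_count <- function(provider) {
  provider$counter$n <- 0L
  invisible(provider)
}

#' Harmonic model potential
#'
#' `V(Q) = 1/2 sum_k omega_k^2 (Q_k - c_k)^2` on an abstract D-dimensional
#' mass-weighted space.
#'
#' @param omega vector of angular frequencies (a.u.).
#' @param center optional minimum position (default origin).
#' @export
pes_harmonic <- function(omega, center = NULL) {
  d <- length(omega)
  if (any(omega <= 0)) stop("frequencies must be positive")
  if (is.null(center)) center <- numeric(d)
  h <- diag(omega^2, d)
  .new_provider(d, c("energy", "gradient", "hessian"),
    function(q, need_hessian) {
      dq <- q - center
      potential_info(sum(omega^2 * dq^2) / 2, gradient = omega^2 * dq,
                     hessian = if (need_hessian) h else NULL)
    },
    extra = list(minima = list(center)))
}

#' Quartic double-well model potential with transverse harmonic modes
#'
#' `V(Q) = V0 (Q1^2 - a^2)^2 / a^4 + sum_k 1/2 omega_k^2 (Q_k + c_k Q1^2)^2`
#' for k = 2..D: a symmetric double well along the first coordinate with
#' optional bilinear-in-`Q1^2` coupling that bends the reaction path off the
#' `Q1` axis (the umbrella-inversion-like test system). Analytic gradient
#' and Hessian; minima at `Q1 = +/- a` (for `c = 0`), one saddle at the
#' origin with exactly one negative Hessian eigenvalue.
#'
#' @param v0 barrier height (hartree), > 0.
#' @param a half-separation of the wells (mass-weighted a.u.), > 0.
#' @param omega_t transverse angular frequencies (a.u.), one per extra mode.
#' @param coupling coupling constants `c_k` (same length as `omega_t`).
#' @export
pes_double_well <- function(v0 = 1.6e-2, a = 25, omega_t = numeric(0),
                            coupling = 0) {
  if (v0 <= 0 || a <= 0) stop("v0 and a must be positive")
  if (length(omega_t) && any(omega_t <= 0)) stop("omega_t must be positive")
  nk <- length(omega_t)
  ck <- rep_len(coupling, nk)
  d <- 1L + nk
  eval_fn <- function(q, need_hessian) {
    q1 <- q[1]
    e <- v0 * (q1^2 - a^2)^2 / a^4
    g <- numeric(d)
    g[1] <- 4 * v0 * q1 * (q1^2 - a^2) / a^4
    h <- matrix(0, d, d)
    h[1, 1] <- 4 * v0 * (3 * q1^2 - a^2) / a^4
    if (nk) {
      u <- q[-1] + ck * q1^2
      e <- e + sum(omega_t^2 * u^2) / 2
      g[1] <- g[1] + sum(omega_t^2 * u * 2 * ck * q1)
      g[-1] <- omega_t^2 * u
      h[1, 1] <- h[1, 1] + sum(omega_t^2 * (4 * ck^2 * q1^2 + 2 * ck * u))
      h[1, -1] <- h[-1, 1] <- omega_t^2 * 2 * ck * q1
      diag(h)[-1] <- omega_t^2
    }
    potential_info(e, gradient = g, hessian = if (need_hessian) h else NULL)
  }
  min1 <- c(-a, if (nk) -ck * a^2 else NULL)
  min2 <- c(a, if (nk) -ck * a^2 else NULL)
  .new_provider(d, c("energy", "gradient", "hessian"), eval_fn,
                extra = list(v0 = v0, a = a, omega_t = omega_t, coupling = ck,
                             saddle = numeric(d), minima = list(min1, min2)))
}

#' Quadratic model potential with an arbitrary Hessian
#'
#' `V(Q) = e0 + 1/2 (Q - c)' H (Q - c)`; the local harmonic approximation is
#' exact for this provider, which makes it the reference for closed-form
#' checks.
#'
#' @param hessian D x D symmetric matrix (a.u.).
#' @param center minimum position (default origin).
#' @param e0 energy offset (hartree).
#' @export
pes_quadratic <- function(hessian, center = NULL, e0 = 0) {
  hessian <- as.matrix(hessian)
  d <- nrow(hessian)
  if (is.null(center)) center <- numeric(d)
  .new_provider(d, c("energy", "gradient", "hessian"),
    function(q, need_hessian) {
      dq <- q - center
      potential_info(e0 + sum(dq * (hessian %*% dq)) / 2,
                     gradient = as.numeric(hessian %*% dq),
                     hessian = if (need_hessian) hessian else NULL)
    },
    extra = list(minima = list(center)))
}

#' Orthogonal symmetry operation in mass-weighted space
#'
#' @param matrix D x D orthogonal matrix (e.g. a reflection).
#' @param order smallest positive integer with `matrix^order = identity`.
#' @export
symmetry_op <- function(matrix, order = 2L) {
  matrix <- as.matrix(matrix)
  d <- nrow(matrix)
  if (max(abs(crossprod(matrix) - diag(d))) > 1e-12)
    stop("symmetry matrix is not orthogonal to 1e-12")
  p <- diag(d)
  for (k in seq_len(order)) p <- p %*% matrix
  if (max(abs(p - diag(d))) > 1e-10)
    stop("matrix^order is not the identity")
  structure(list(matrix = matrix, order = as.integer(order)),
            class = "sbg_symop")
}

#' Transport potential information through a symmetry operation
#'
#' Given info at `Q`, returns the info at `M Q`: the energy is unchanged,
#' the gradient maps to `M g` and the Hessian to `M H M'`.
#'
#' @param info an `sbg_potinfo`.
#' @param op an `sbg_symop`.
#' @export
symmetry_expand <- function(info, op) {
  stopifnot(inherits(info, "sbg_potinfo"), inherits(op, "sbg_symop"))
  m <- op$matrix
  if (!is.null(info$hessian) && nrow(info$hessian) != nrow(m))
    stop("dimension mismatch between info and symmetry operation")
  potential_info(info$energy,
                 gradient = if (!is.null(info$gradient)) as.numeric(m %*% info$gradient),
                 hessian = if (!is.null(info$hessian)) m %*% info$hessian %*% t(m))
}

#' Central-difference Hessian from an energy-only provider
#'
#' @param provider an `sbg_provider` supporting at least energies.
#' @param point evaluation point (a.u.).
#' @param step finite-difference step (mass-weighted a.u.).
#' @export
fd_hessian <- function(provider, point, step = 1e-3) {
  d <- provider$dim
  en <- function(q) {
    provider$counter$n <- provider$counter$n + 1L
    provider$eval_fn(q, FALSE)$energy
  }
  e0 <- en(point)
  h <- matrix(0, d, d)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- step
    h[i, i] <- (en(point + ei) - 2 * e0 + en(point - ei)) / step^2
    if (i < d) for (j in (i + 1L):d) {
      ej <- numeric(d); ej[j] <- step
      hij <- (en(point + ei + ej) - en(point + ei - ej) -
              en(point - ei + ej) + en(point - ei - ej)) / (4 * step^2)
      h[i, j] <- h[j, i] <- hij
    }
  }
  potential_info(e0, hessian = (h + t(h)) / 2)
}

## ---- tabulated potential store (JSON, schema "sbg-pes-1") -------------

#' Create an empty tabulated potential store
#'
#' Records are keyed by caller-assigned point IDs (the basis builder assigns
#' them deterministically); coordinates are stored alongside for validation.
#'
#' @param dim dimension of the stored points.
#' @export
pes_store <- function(dim) {
  e <- new.env(parent = emptyenv())
  e$dim <- as.integer(dim)
  e$records <- list()
  class(e) <- "sbg_store"
  e
}

#' Insert a record into a potential store
#'
#' @param store an `sbg_store`.
#' @param id character point ID.
#' @param point coordinates (a.u.).
#' @param info an `sbg_potinfo`.
#' @export
store_put <- function(store, id, point, info) {
  stopifnot(inherits(store, "sbg_store"), length(point) == store$dim)
  store$records[[id]] <- list(point = as.numeric(point), info = info)
  invisible(store)
}

#' Fetch a record (or `NULL`) from a potential store
#' @param store an `sbg_store`.
#' @param id character point ID.
#' @export
store_get <- function(store, id) {
  r <- store$records[[id]]
  if (is.null(r)) NULL else r$info
}

#' @rdname store_get
#' @export
store_ids <- function(store) names(store$records)

#' Serialize a potential store to JSON
#'
#' Schema `"sbg-pes-1"`: one object per point ID holding coordinates, the
#' energy, and (when present) gradient and Hessian.
#'
#' @param store an `sbg_store`.
#' @param file output path.
#' @export
store_save <- function(store, file) {
  recs <- lapply(store$records, function(r) {
    out <- list(coords = r$point, energy = r$info$energy)
    if (!is.null(r$info$gradient)) out$gradient <- as.numeric(r$info$gradient)
    if (!is.null(r$info$hessian)) out$hessian <- r$info$hessian
    out
  })
  # 17 significant digits keeps the double round-trip bit-exact
  jsonlite::write_json(list(schema = "sbg-pes-1", dim = store$dim,
                            points = recs),
                       file, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(file)
}

#' Load a potential store from JSON
#' @param file path written by [store_save()].
#' @export
store_load <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(obj$schema, "sbg-pes-1"))
    stop("not an sbg-pes-1 store: ", file)
  st <- pes_store(obj$dim)
  for (id in names(obj$points)) {
    r <- obj$points[[id]]
    hess <- if (!is.null(r$hessian)) matrix(unlist(r$hessian), obj$dim, obj$dim)
    grad <- if (!is.null(r$gradient)) as.numeric(r$gradient)
    store_put(st, id, as.numeric(r$coords),
              potential_info(r$energy, gradient = grad, hessian = hess))
  }
  st
}

#' Wrap a potential store as a provider
#'
#' The resulting provider answers only at registered points (matched by
#' coordinates within `tol`); anywhere else it raises a capability error.
#'
#' @param store an `sbg_store`.
#' @param tol coordinate matching tolerance (a.u.).
#' @export
store_provider <- function(store, tol = 1e-8) {
  .new_provider(store$dim, c("energy", "hessian"),
    function(q, need_hessian) {
      for (r in store$records) {
        if (max(abs(r$point - q)) <= tol) return(r$info)
      }
      stop("point not registered in the tabulated store")
    })
}
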