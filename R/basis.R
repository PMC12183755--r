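## Gaussian basis functions G(Q) = exp[-(Q - Qc)' alpha (Q - Qc) + zeta]
## with width matrices alpha = 1/2 sqrt(V'') from positive-definitized
## local Hessians.

#' Positive-definitize a mass-weighted Hessian
#'
#' Eigenvalues with magnitude below `zero_tol` (the translational/rotational
#' null space, and accidental zeros) are replaced by `omega_c^2` with
#' `omega_c` the angular frequency corresponding to `v_const_wavenumber`;
#' negative eigenvalues have their signs flipped so the width still reflects
#' the steep local shape in regions of negative curvature. Eigenvectors are
#' kept.
#'
#' @param hessian D x D symmetric matrix (a.u.).
#' @param v_const_wavenumber replacement frequency for near-zero modes
#'   (cm^-1); pick it somewhat below the harmonic frequency of the mode of
#'   interest.
#' @param zero_tol magnitude below which an eigenvalue counts as zero
#'   (a.u. of omega^2); default corresponds to 10 cm^-1.
#' @param proj optional projection operators from [projection_operators()];
#'   when supplied, the Hessian is first projected with the vibrational
#'   complement `o_vib`, which identifies the rigid-body null space more
#'   robustly than the magnitude test alone.
#' @return list of class `sbg_reghess`: `matrix` (symmetric PD),
#'   `flipped_count`, `replaced_count`, `v_const` (omega_c^2, a.u.).
#' @export
regularize_hessian <- function(hessian, v_const_wavenumber = 1500,
                               zero_tol = cm_to_hartree(10)^2,
                               proj = NULL) {
  hessian <- as.matrix(hessian)
  if (v_const_wavenumber <= 0) stop("v_const_wavenumber must be positive")
  asym <- max(abs(hessian - t(hessian)))
  if (asym > 1e-8 * max(1, max(abs(hessian))))
    stop("hessian asymmetric beyond tolerance")
  hessian <- (hessian + t(hessian)) / 2
  if (!is.null(proj))
    hessian <- proj$o_vib %*% hessian %*% proj$o_vib
  wc2 <- cm_to_hartree(v_const_wavenumber)^2
  ed <- eigen(hessian, symmetric = TRUE)
  lam <- ed$values
  near_zero <- abs(lam) < zero_tol
  negative <- !near_zero & lam < 0
  lam[near_zero] <- wc2
  lam[negative] <- abs(lam[negative])
  structure(list(matrix = ed$vectors %*% (lam * t(ed$vectors)),
                 flipped_count = sum(negative),
                 replaced_count = sum(near_zero),
                 v_const = wc2),
            class = "sbg_reghess")
}

#' Width matrix from a regularized Hessian
#'
#' `alpha = 1/2 sqrt(V'')` (principal matrix square root, hbar = 1): the
#' exponent of the local-harmonic ground-state Gaussian.
#'
#' @param reg an `sbg_reghess` (or a symmetric PD matrix).
#' @return symmetric positive-definite width matrix (a.u.).
#' @export
width_from_hessian <- function(reg) {
  m <- if (inherits(reg, "sbg_reghess")) reg$matrix else as.matrix(reg)
  ed <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (any(ed$values <= 0)) stop("regularized Hessian must be positive definite")
  a <- ed$vectors %*% (sqrt(ed$values) * t(ed$vectors)) / 2
  (a + t(a)) / 2
}

#' Construct a normalized Gaussian basis function
#'
#' @param center mass-weighted centre (a.u.).
#' @param width D x D symmetric PD width matrix; alternatively supply
#'   `hessian` and let the width be derived via [regularize_hessian()] and
#'   [width_from_hessian()].
#' @param hessian raw local Hessian (used when `width` is missing).
#' @param v_const_wavenumber,zero_tol,proj passed to [regularize_hessian()].
#' @param point_id identifier linking the centre to the potential store.
#' @return object of class `sbg_basis` with fields `center`, `width`,
#'   `log_norm` (zeta such that the self-overlap is 1) and `point_id`.
#' @export
make_basis <- function(center, width = NULL, hessian = NULL,
                       v_const_wavenumber = 1500,
                       zero_tol = cm_to_hartree(10)^2,
                       proj = NULL, point_id = NA_character_) {
  center <- as.numeric(center)
  d <- length(center)
  if (is.null(width)) {
    if (is.null(hessian)) stop("supply either width or hessian")
    width <- width_from_hessian(
      regularize_hessian(hessian, v_const_wavenumber, zero_tol, proj))
  }
  width <- as.matrix(width)
  if (!all(dim(width) == d)) stop("width dimension mismatch")
  ev <- eigen((width + t(width)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("width matrix must be positive definite")
  # <G|G> = exp(2 zeta) (pi^D / det(2 alpha))^(1/2) = 1
  log_norm <- sum(log(2 * ev / pi)) / 4
  structure(list(center = center, width = (width + t(width)) / 2,
                 log_norm = log_norm, point_id = point_id),
            class = "sbg_basis")
}

#' @export
print.sbg_basis <- function(x, ...) {
  cat("<sbg_basis> dim ", length(x$center), ", id ", x$point_id, "\n", sep = "")
  invisible(x)
}

#' Evaluate Gaussian basis functions on points
#'
#' @param basis an `sbg_basis`.
#' @param points matrix with one mass-weighted point per row (or a vector).
#' @return numeric vector of basis values.
#' @export
basis_value <- function(basis, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  dq <- sweep(points, 2, basis$center)
  expo <- -rowSums((dq %*% basis$width) * dq) + basis$log_norm
  exp(expo)
}
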