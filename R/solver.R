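## Generalized eigenproblem S^-1 (T_vib + V) c = E c via canonical
## orthogonalization, spectrum post-processing, and wavefunction evaluation.

#' Solve the generalized vibrational eigenproblem
#'
#' Eigendecomposes the overlap matrix, drops eigenvalues below
#' `s_tol * max`, transforms the Hamiltonian into the retained subspace,
#' solves the symmetric problem there and back-transforms the coefficients
#' (canonical orthogonalization).
#'
#' @param h an `sbg_hmat` from [assemble_hamiltonian()].
#' @param s_tol relative overlap-eigenvalue cutoff. The default (1e-3) is
#'   deliberately coarse: local-harmonic potential elements carry a small
#'   inconsistency relative to the exact operator, and overlap eigenvalues
#'   smaller than that inconsistency amplify it non-variationally. Lower it
#'   only for exactly quadratic potentials.
#' @return object of class `sbg_spectrum`: ascending `energies` (hartree),
#'   `energies_cm`, `zpe`, `levels_rel_cm` (relative to the ground state),
#'   S-orthonormal `coefficients` (L x M), `kept_rank`, `s_condition`
#'   (smallest retained overlap eigenvalue).
#' @export
solve_spectrum <- function(h, s_tol = 1e-3) {
  stopifnot(inherits(h, "sbg_hmat"))
  es <- eigen((h$overlap + t(h$overlap)) / 2, symmetric = TRUE)
  keep <- es$values > s_tol * max(es$values)
  if (!any(keep)) stop("degenerate basis: all overlap eigenvalues below cutoff")
  x <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  hvib <- h$kinetic_vib + h$potential
  ht <- t(x) %*% ((hvib + t(hvib)) / 2) %*% x
  eh <- eigen((ht + t(ht)) / 2, symmetric = TRUE)
  ord <- order(eh$values)
  energies <- eh$values[ord]
  coeff <- x %*% eh$vectors[, ord, drop = FALSE]
  structure(list(energies = energies,
                 energies_cm = hartree_to_cm(energies),
                 zpe = energies[1],
                 levels_rel_cm = hartree_to_cm(energies - energies[1]),
                 coefficients = coeff,
                 kept_rank = sum(keep),
                 s_condition = min(es$values[keep])),
            class = "sbg_spectrum")
}

#' @export
print.sbg_spectrum <- function(x, ...) {
  cat("<sbg_spectrum> rank ", x$kept_rank, ", ZPE ",
      format(hartree_to_cm(x$zpe), digits = 8), " cm^-1\n", sep = "")
  lv <- utils::head(x$levels_rel_cm, 8)
  cat("levels (cm^-1, rel. ground): ",
      paste(format(lv, digits = 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Spectrum report: ZPE, relative levels, tunnel splittings, parity, RMSE
#'
#' Consecutive levels are labelled a tunneling doublet when their gap is
#' smaller than `doublet_gap_factor` times the gap to the next level. When
#' `bases` and a `symmetry` operation are supplied, parity labels are
#' computed from the sign of `<chi | sigma | chi>` via the overlap of
#' mirrored coefficients.
#'
#' @param res an `sbg_spectrum`.
#' @param reference_levels optional reference levels (cm^-1, relative to the
#'   ground state, same ordering) for the RMSE.
#' @param bases,symmetry optional: basis list and `sbg_symop` for parity.
#' @param n_states number of states to report.
#' @param doublet_gap_factor doublet labelling threshold (default 0.2).
#' @return list of class `sbg_report` with a `table` data frame (index,
#'   E_hartree, E_rel_cm1, parity, assignment), `zpe_cm`, `splittings_cm`
#'   and `rmse_cm`.
#' @export
spectrum_report <- function(res, reference_levels = NULL, bases = NULL,
                            symmetry = NULL, n_states = NULL,
                            doublet_gap_factor = 0.2) {
  stopifnot(inherits(res, "sbg_spectrum"))
  m <- length(res$energies)
  if (is.null(n_states)) n_states <- m
  n_states <- min(n_states, m)
  lev <- res$levels_rel_cm[seq_len(n_states)]
  parity <- rep(NA_character_, n_states)
  if (!is.null(bases) && !is.null(symmetry)) {
    for (k in seq_len(n_states))
      parity[k] <- if (wavefunction_parity(bases, res$coefficients[, k],
                                           symmetry) >= 0) "+" else "-"
  }
  assignment <- rep("", n_states)
  splittings <- numeric(0)
  k <- 1L
  while (k < n_states) {
    gap <- lev[k + 1] - lev[k]
    nxt <- if (k + 2 <= n_states) lev[k + 2] - lev[k + 1] else Inf
    if (gap < doublet_gap_factor * nxt) {
      assignment[k] <- assignment[k + 1] <- sprintf("doublet%d",
                                                    length(splittings) + 1L)
      splittings <- c(splittings, gap)
      k <- k + 2L
    } else k <- k + 1L
  }
  rmse <- NA_real_
  if (!is.null(reference_levels)) {
    # references are excited levels relative to the ground state, paired
    # with the calculated levels in order (the ground level is 0 for both)
    if (length(reference_levels) > n_states - 1)
      stop("more reference levels than calculated excited states")
    idx <- 1 + seq_along(reference_levels)
    rmse <- sqrt(mean((lev[idx] - reference_levels)^2))
  }
  structure(list(table = data.frame(index = seq_len(n_states) - 1L,
                                    E_hartree = res$energies[seq_len(n_states)],
                                    E_rel_cm1 = lev,
                                    parity = parity,
                                    assignment = assignment),
                 zpe_cm = hartree_to_cm(res$zpe),
                 splittings_cm = splittings,
                 rmse_cm = rmse),
            class = "sbg_report")
}

#' @export
print.sbg_report <- function(x, ...) {
  cat("ZPE: ", format(x$zpe_cm, digits = 8), " cm^-1\n", sep = "")
  print(x$table, row.names = FALSE)
  if (length(x$splittings_cm))
    cat("tunnel splittings (cm^-1): ",
        paste(format(x$splittings_cm, digits = 6), collapse = ", "), "\n",
        sep = "")
  if (is.finite(x$rmse_cm))
    cat("RMSE vs reference: ", format(x$rmse_cm, digits = 6), " cm^-1\n",
        sep = "")
  invisible(x)
}

#' Write a spectrum report as CSV and JSON
#'
#' @param report an `sbg_report`.
#' @param csv,json optional output paths.
#' @export
write_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(report$table, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(zpe_cm = report$zpe_cm,
                              levels = report$table,
                              splittings_cm = report$splittings_cm,
                              rmse_cm = report$rmse_cm),
                         json, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(report)
}

#' Evaluate an expanded wavefunction on points
#'
#' `chi(Q) = sum_i c_i G_i(Q)`.
#'
#' @param bases list of `sbg_basis`.
#' @param coeffs coefficient vector (length L).
#' @param points matrix of mass-weighted points (rows), or a vector.
#' @return numeric vector of wavefunction values.
#' @export
evaluate_wavefunction <- function(bases, coeffs, points) {
  if (length(coeffs) != length(bases))
    stop("coefficient length must equal the number of bases")
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  vals <- numeric(nrow(points))
  for (i in seq_along(bases))
    vals <- vals + coeffs[i] * basis_value(bases[[i]], points)
  vals
}

#' Parity of a wavefunction under a symmetry operation
#'
#' `<chi| sigma |chi>` computed in closed form: mirroring every basis
#' (centre `M Q_i`, width `M alpha_i M'`) and contracting the cross overlap
#' matrix with the coefficients. +1/-1 for even/odd states of a symmetric
#' double well.
#'
#' @param bases list of `sbg_basis`.
#' @param coeffs eigenvector (S-normalized).
#' @param symmetry an `sbg_symop`.
#' @return scalar expectation value.
#' @export
wavefunction_parity <- function(bases, coeffs, symmetry) {
  m <- symmetry$matrix
  mirrored <- lapply(bases, function(g)
    make_basis(as.numeric(m %*% g$center), width = m %*% g$width %*% t(m)))
  acc <- 0
  for (i in seq_along(bases)) for (j in seq_along(bases))
    acc <- acc + coeffs[i] * coeffs[j] * gauss_overlap(bases[[i]], mirrored[[j]])
  acc
}
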