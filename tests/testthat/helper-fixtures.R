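# Shared fixture builders for the test suite. Everything is generated in
# code; the double-well parameters are the package's standard study
# conditions (see fixture_double_well()).

# bases with widths from the local Hessian at given 1D centres
dw_bases_1d <- function(provider, centers) {
  lapply(seq_along(centers), function(i) {
    info <- pes_evaluate(provider, centers[i], need_hessian = TRUE)
    make_basis(centers[i], hessian = info$hessian,
               point_id = sprintf("c%d", i))
  })
}

# a store holding centre info for a basis list
centre_store <- function(provider, bases) {
  d <- length(bases[[1]]$center)
  st <- pes_store(d)
  for (g in bases)
    store_put(st, g$point_id, g$center,
              pes_evaluate(provider, g$center, need_hessian = TRUE))
  st
}

# reflection of the first coordinate in d dimensions
reflect_q1 <- function(d) {
  m <- diag(d)
  m[1, 1] <- -1
  symmetry_op(m, 2L)
}

# random symmetric positive-definite width matrix
random_width <- function(d, scale = 40) {
  crossprod(matrix(stats::rnorm(d * d), d)) / scale + diag(0.01, d)
}

# reference sinc-DVR levels of the standard 1D double well (301 points is
# converged to ~1e-10 hartree for the lowest doublet; verified by doubling)
dw1_dvr_levels <- function(n_states = 4) {
  dw <- fixture_double_well(1)
  dvr_eigenvalues(function(q) dw$eval_fn(q, FALSE)$energy,
                  -60, 60, 301, n_states)
}
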