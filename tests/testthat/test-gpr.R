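test_that("the squared-exponential kernel has its defining properties", {
  expect_equal(gpr_kernel(c(1, 2), c(1, 2), tau = 1.5, beta = 3), 1.5^2)
  # at distance beta the kernel is tau^2 exp(-1/2)
  expect_equal(gpr_kernel(0, 3, tau = 2, beta = 3), 4 * exp(-0.5),
               tolerance = 1e-14)
  set.seed(71)
  for (k in 1:5) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(gpr_kernel(a, b, 1.2, 0.8), gpr_kernel(b, a, 1.2, 0.8))
  }
  km <- gpr_kernel(matrix(rnorm(10), 5), matrix(rnorm(10), 5), 1, 1)
  expect_equal(dim(km), c(5, 5))
  expect_error(gpr_kernel(0, 1, tau = -1, beta = 1), "positive")
})

test_that("predictions interpolate training data as sigma vanishes", {
  dw <- fixture_double_well(1)
  x <- matrix(seq(-30, 30, length.out = 7), ncol = 1)
  infos <- lapply(x, function(q) pes_evaluate(dw, q))
  fit <- gpr_fit(x, infos, sigma2_rel = 1e-14)
  for (i in seq_len(nrow(x))) {
    p <- gpr_predict(fit, x[i, ])
    expect_equal(p$energy, infos[[i]]$energy,
                 tolerance = 1e-8)
    expect_equal(p$hessian, infos[[i]]$hessian, tolerance = 1e-6)
  }
  # predicted Hessians are exactly symmetric by construction
  pm <- gpr_predict(fit, 3.3)
  expect_identical(pm$hessian, t(pm$hessian))
  # far from all data the centred prediction decays to the target mean
  far <- gpr_predict(fit, 1e4)
  expect_equal(far$energy, mean(vapply(infos, `[[`, numeric(1), "energy")),
               tolerance = 1e-10)
  expect_error(gpr_predict(fit, c(1, 2)), "dimension")
  expect_error(gpr_fit(x[1:2, , drop = FALSE], infos[1:2]), "at least 3")
})

test_that("prediction is linear in the training targets", {
  set.seed(72)
  x <- matrix(runif(8, -5, 5), ncol = 1)
  mk_infos <- function(f) lapply(x, function(q)
    potential_info(f(q), hessian = matrix(f(q) / 3 + 0.2)))
  i1 <- mk_infos(function(q) sin(q))
  i2 <- mk_infos(function(q) 0.1 * q^2)
  i12 <- lapply(seq_len(nrow(x)), function(k)
    potential_info(i1[[k]]$energy + i2[[k]]$energy,
                   hessian = i1[[k]]$hessian + i2[[k]]$hessian))
  # same hyperparameters for all three (linearity is a fixed-kernel
  # property); a well-conditioned Gram keeps roundoff below the tolerance
  f1 <- gpr_fit(x, i1, tau_grid = 1, beta_grid = 2, sigma2_rel = 1e-4)
  f2 <- gpr_fit(x, i2, tau_grid = 1, beta_grid = 2, sigma2_rel = 1e-4)
  f12 <- gpr_fit(x, i12, tau_grid = 1, beta_grid = 2, sigma2_rel = 1e-4)
  qs <- c(-3.7, 0.4, 2.2)
  for (q in qs) {
    expect_equal(gpr_predict(f12, q)$energy,
                 gpr_predict(f1, q)$energy + gpr_predict(f2, q)$energy,
                 tolerance = 1e-10)
  }
})

test_that("closed-form LOO residuals equal explicit refits", {
  set.seed(73)
  n <- 10   # N <= 12
  x <- matrix(sort(runif(n, -20, 20)), ncol = 1)
  dw <- fixture_double_well(1)
  infos <- lapply(x, function(q) pes_evaluate(dw, q))
  tau <- 1.3; beta <- 6; s2r <- 1e-6
  loo <- gpr_loo_residuals(x, infos, tau, beta, s2r)

  # oracle: n explicit refits on n-1 points, in the same fixed scaled space
  y_raw <- cbind(vapply(infos, `[[`, numeric(1), "energy"),
                 vapply(infos, function(i) i$hessian[1, 1], numeric(1)))
  mu <- colMeans(y_raw)
  sc <- apply(y_raw, 2, sd)
  y <- sweep(sweep(y_raw, 2, mu), 2, sc, `/`)
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]
    km <- gpr_kernel(xi, xi, tau, beta) + diag(s2r * tau^2, n - 1)
    kv <- gpr_kernel(xi, x[i, , drop = FALSE], tau, beta)
    pred <- as.numeric(crossprod(kv, solve(km, y[-i, ])))
    resid_phys <- (y[i, ] - pred) * sc
    expect_equal(unname(loo[i, ]), unname(resid_phys), tolerance = 1e-8)
  }
})

test_that("grid search recovers planted kernel hyperparameters", {
  set.seed(20250607)
  n <- 14
  d <- 1
  x <- matrix(seq(-10, 10, length.out = n), ncol = 1)
  tau_true <- 1; beta_true <- 4
  km <- gpr_kernel(x, x, tau_true, beta_true) + diag(1e-10, n)
  l <- t(chol(km))
  draw <- function() as.numeric(l %*% rnorm(n))
  ys <- cbind(draw(), draw())    # energy + one Hessian column, same GP
  infos <- lapply(seq_len(n), function(i)
    potential_info(ys[i, 1], hessian = matrix(ys[i, 2])))
  beta_grid <- c(0.5, 1, 2, 4, 8, 16)
  fit <- gpr_fit(x, infos, tau_grid = c(0.5, 1, 2), beta_grid = beta_grid,
                 sigma2_rel = 1e-8)
  # the selected length scale is the grid point nearest the truth
  expect_equal(fit$beta, beta_grid[which.min(abs(log(beta_grid / beta_true)))])

  # LOO objective at the optimum beats both grid extremes
  obj <- fit$grid
  o_best <- min(obj$objective, na.rm = TRUE)
  o_lo <- min(obj$objective[obj$beta == min(obj$beta)], na.rm = TRUE)
  o_hi <- min(obj$objective[obj$beta == max(obj$beta)], na.rm = TRUE)
  expect_lt(o_best, o_lo)
  expect_lte(o_best, o_hi)
})

test_that("symmetry augmentation adds transported image rows", {
  dw2 <- fixture_double_well(2)
  refl <- reflect_q1(2)
  x <- rbind(c(-20, 1), c(-10, 0.5), c(0, 0.2))
  infos <- lapply(seq_len(3), function(i) pes_evaluate(dw2, x[i, ]))
  aug <- symmetry_augment_training(x, infos, refl)
  # the origin-row image coincides with itself; the two others are new
  expect_equal(nrow(aug$x), 5)
  expect_equal(aug$x[4, ], c(20, 1))
  expect_equal(aug$infos[[4]]$energy, infos[[1]]$energy)
  expect_equal(aug$infos[[4]]$hessian,
               pes_evaluate(dw2, c(20, 1))$hessian, tolerance = 1e-12)
})

test_that("the GPR source routes centres to the store and logs requests", {
  dw <- fixture_double_well(1)
  bases <- dw_bases_1d(dw, seq(-30, 30, length.out = 5))
  store <- centre_store(dw, bases)
  infos <- lapply(bases, function(g) store_get(store, g$point_id))
  fit <- gpr_fit(do.call(rbind, lapply(bases, `[[`, "center")), infos,
                 lapply(bases, `[[`, "width"))
  src <- gpr_source(fit, store)
  # a registered centre comes back bit-exact from the store
  got <- src$eval_fn(bases[[2]]$center)
  expect_identical(got$energy, infos[[2]]$energy)
  expect_identical(got$hessian, infos[[2]]$hessian)
  # a midpoint goes through the GPR path
  mid <- gauss_midpoint(bases[[1]], bases[[2]])
  src$eval_fn(mid)
  expect_equal(src$log$routes, c("store:c2", "gpr"))
})

test_that("estimation reports quantify interpolation error in cm^-1", {
  dw <- fixture_double_well(1)
  bases <- dw_bases_1d(dw, seq(-35, 35, length.out = 9))
  store <- centre_store(dw, bases)
  infos <- lapply(bases, function(g) store_get(store, g$point_id))
  x <- do.call(rbind, lapply(bases, `[[`, "center"))
  fit <- gpr_fit(x, infos, lapply(bases, `[[`, "width"),
                 sigma2_rel = 1e-12, symmetry = reflect_q1(1))
  # at the training points the error is numerically negligible relative to
  # the 6500 cm^-1 span of the training energies
  rep0 <- gpr_estimation_report(fit, dw, x)
  expect_lt(rep0$rmse_energy_cm, 1)
  # at pair midpoints it is finite and reported on the wavenumber scale
  mids <- do.call(rbind, lapply(1:8, function(i)
    gauss_midpoint(bases[[i]], bases[[i + 1]])))
  weights <- lapply(1:8, function(i)
    solve(bases[[i]]$width + bases[[i + 1]]$width))
  rep1 <- gpr_estimation_report(fit, dw, mids, weights)
  expect_gt(rep1$rmse_energy_cm, 0)
  expect_lt(rep1$rmse_energy_cm, 500)
  expect_true(is.finite(rep1$rmse_trace_cm))
})
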