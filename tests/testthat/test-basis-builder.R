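test_that("IRC placement spans the path with overlapping bases", {
  dw <- fixture_double_well(1)
  path <- synthetic_irc(dw)
  irc <- place_on_irc(path, dw, build_config(n_irc_bases = 5))
  centers <- vapply(irc$bases, function(g) g$center[1], numeric(1))
  expect_equal(centers[1], -25, tolerance = 1e-5)
  expect_equal(centers[5], 25, tolerance = 1e-5)
  expect_equal(diff(centers), rep(12.5, 4), tolerance = 1e-3)
  # adjacent overlaps sit in the useful window around 0.7
  expect_true(all(irc$adjacent_overlaps > 0.55 &
                  irc$adjacent_overlaps < 0.85))

  # n = 2: just the two endpoints (the minima)
  irc2 <- place_on_irc(path, dw, build_config(n_irc_bases = 2))
  expect_equal(vapply(irc2$bases, function(g) g$center[1], numeric(1)),
               c(-25, 25), tolerance = 1e-5)

  # straight path through a harmonic valley: equal overlaps by symmetry
  hp <- pes_harmonic(c(0.01, 0.01))
  line <- sbg_path(cbind(seq(-5, 5, length.out = 40), 0))
  irc3 <- place_on_irc(line, hp, build_config(n_irc_bases = 4))
  expect_equal(diff(irc3$adjacent_overlaps), rep(0, 2), tolerance = 1e-10)
})

test_that("path PCA recovers planted directions and variance structure", {
  # collinear path: PC1 = +/- u, lambda_1 = sum (t - tbar)^2, rest zero
  set.seed(61)
  u <- rnorm(4); u <- u / sqrt(sum(u^2))
  tl <- seq(-2, 2, length.out = 37)
  path <- sbg_path(outer(tl, u))
  pca <- pca_of_path(path)
  expect_gt(abs(sum(pca$components[, 1] * u)), 0.999)
  expect_equal(pca$variances[1], sum((tl - mean(tl))^2), tolerance = 1e-10)
  expect_lt(pca$ratios[2], 1e-12)

  # planar arc: exactly two nonzero variances
  v <- rnorm(4); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
  arc <- outer(cos(tl), u) + outer(sin(tl), v)
  pca2 <- pca_of_path(sbg_path(arc))
  expect_gt(pca2$ratios[2], 1e-6)
  expect_lt(pca2$ratios[3], 1e-12)

  # orthonormal components; variances sum to the covariance trace
  expect_equal(crossprod(pca2$components), diag(4), tolerance = 1e-10)
  xc <- sweep(arc, 2, colMeans(arc))
  expect_equal(sum(pca2$variances), sum(xc^2), tolerance = 1e-8)

  expect_error(sbg_path(matrix(0, 1, 3)), "at least 2")
})

test_that("component selection thresholds on the variance ratio", {
  pca <- structure(list(ratios = c(1, 1.3e-2, 1e-10, 1e-12)),
                   class = "sbg_pca")
  expect_equal(select_components(pca, 1e-3), c(1L, 2L))
  expect_equal(select_components(pca, 1.0), 1L)
  expect_equal(select_components(pca, 1e-15), 1:4)
  expect_error(select_components(pca, 0), "in \\(0, 1\\]")
})

test_that("shift distances match the equal-width closed form", {
  g <- make_basis(0, width = matrix(1))
  d <- shift_distance(g, 1, 0.75)
  expect_equal(d, sqrt(-2 * log(0.75)), tolerance = 1e-9)
  expect_equal(d, 0.75853, tolerance = 1e-4)

  # target -> 1 gives d -> 0
  expect_lt(shift_distance(g, 1, 0.999999), 2e-3)

  # anisotropic width: stiff axis needs a smaller shift than the soft axis
  ga <- make_basis(c(0, 0), width = diag(c(1, 0.04)))
  d_stiff <- shift_distance(ga, c(1, 0), 0.75)
  d_soft <- shift_distance(ga, c(0, 1), 0.75)
  expect_lt(d_stiff, d_soft)
  # closed form d = sqrt(-2 log t / (u' alpha u)) for the equal-width pair
  expect_equal(d_soft, sqrt(-2 * log(0.75) / 0.04), tolerance = 1e-8)

  expect_error(shift_distance(g, 2, 0.75), "unit-norm")
  expect_error(shift_distance(g, 1, 1.5), "target")
})

test_that("shift generation enumerates first and second order candidates", {
  g <- make_basis(c(0, 0, 0), width = diag(0.3, 3))
  pca <- structure(list(components = diag(3), ratios = c(1, 0.5, 1e-9)),
                   class = "sbg_pca")
  cfg <- build_config()
  # 1 centre, 2 selected PCs: 4 first-order + 4 second-order
  cand <- generate_shifted_centers(list(bases = list(g)), pca, c(1, 2), cfg)
  expect_equal(nrow(cand$centers), 8)
  # 1 centre, 1 PC: just the 2 first-order shifts
  cand1 <- generate_shifted_centers(list(bases = list(g)), pca, 1, cfg)
  expect_equal(nrow(cand1$centers), 2)
  # 5 centres, 2 PCs: 40 candidates before pruning
  gs <- lapply(seq(-2, 2), function(c1)
    make_basis(c(c1, 0, 0), width = diag(0.3, 3)))
  cand5 <- generate_shifted_centers(list(bases = gs), pca, c(1, 2), cfg)
  expect_equal(nrow(cand5$centers), 40)
  # deterministic order and distances given by shift_distance
  d1 <- shift_distance(g, c(1, 0, 0), cfg$target_overlap)
  expect_equal(cand$centers[1, ], c(d1, 0, 0), tolerance = 1e-9)
  expect_equal(cand$centers[2, ], c(-d1, 0, 0), tolerance = 1e-9)

  # tangent orthogonalization removes the path-parallel part
  cfg2 <- build_config(orthogonalize_to_tangent = TRUE)
  tang <- matrix(c(1, 0, 0), 1, 3)
  cand_o <- generate_shifted_centers(list(bases = list(g)), pca, c(1, 2),
                                     cfg2, tangents = tang)
  # PC1 is parallel to the tangent here and drops out; PC2 remains
  expect_equal(nrow(cand_o$centers), 2)
  expect_equal(abs(cand_o$centers[1, 2]) > 0, TRUE)
})

test_that("pruning recomputes widths and enforces the overlap ceiling", {
  dw <- fixture_double_well(1)
  path <- synthetic_irc(dw)
  cfg <- build_config(n_irc_bases = 5, prune_overlap_max = 0.9)
  irc <- place_on_irc(path, dw, cfg)

  # candidate identical to an IRC basis is dropped as a duplicate
  cand <- list(centers = matrix(irc$bases[[1]]$center, 1),
               origin = "dup")
  res <- prune_and_finalize(cand, irc, dw, cfg)
  expect_length(res$bases, 5)

  # far-away candidate is kept, near-duplicate (overlap > max) pruned
  cand2 <- list(centers = rbind(-34, -25.5), origin = c("far", "near"))
  res2 <- prune_and_finalize(cand2, irc, dw, cfg)
  expect_equal(res2$kept, "far")
  expect_equal(res2$pruned, "near")
  # kept basis got its own width, not the IRC one
  gnew <- res2$bases[[6]]
  info <- pes_evaluate(dw, gnew$center)
  expect_equal(gnew$width,
               width_from_hessian(regularize_hessian(info$hessian, 1500)),
               tolerance = 1e-12)

  # final sets respect the ceiling pairwise
  built <- build_basis_set(path, dw, cfg)
  l <- length(built$bases)
  for (i in seq_len(l - 1)) for (j in (i + 1):l)
    expect_lte(gauss_overlap(built$bases[[i]], built$bases[[j]]),
               0.9 + 1e-9)
})

test_that("pair and centre orbit counting matches brute force", {
  dw <- fixture_double_well(1)
  bases <- dw_bases_1d(dw, seq(-25, 25, length.out = 5))
  refl <- reflect_q1(1)
  # identity symmetry: L(L+1)/2 pairs, L centres
  expect_equal(count_unique_evaluations(bases), 15L)
  expect_equal(count_unique_evaluations(bases, mode = "centers"), 5L)
  expect_equal(count_unique_evaluations(bases[1]), 1L)
  # reflection i -> 6 - i: 9 pair orbits, 3 centre orbits
  expect_equal(count_unique_evaluations(bases, refl), 9L)
  expect_equal(count_unique_evaluations(bases, refl, mode = "centers"), 3L)
  # brute-force centre orbits for the same permutation
  perm <- 5:1
  expect_equal(length(unique(lapply(1:5, function(i) sort(c(i, perm[i]))))),
               3L)
  # symmetry that does not permute the centres is rejected
  shifted <- dw_bases_1d(dw, seq(-25, 25, length.out = 5) + 3)
  expect_error(count_unique_evaluations(shifted, refl), "permute")
})

test_that("local normal mode shifts follow the Hessian eigenvectors", {
  hp <- pes_harmonic(c(0.01, 0.02))
  line <- sbg_path(cbind(seq(-3, 3, length.out = 30), 0))
  cfg <- build_config(n_irc_bases = 1)
  irc <- place_on_irc(line, hp, cfg)
  cand <- local_normal_mode_shifts(irc, cfg)
  # 2 modes: 4 first-order + 4 second-order candidates
  expect_equal(nrow(cand$centers), 8)
  # diagonal Hessian: first-order shifts are axis-aligned about the centre
  disp <- sweep(cand$centers[1:4, ], 2, irc$bases[[1]]$center)
  expect_equal(sum(abs(disp[, 1]) > 1e-9 & abs(disp[, 2]) > 1e-9), 0)
  expect_true(all(rowSums(abs(disp) > 1e-9) == 1))

  # combinatorics for m modes: 2m + 4 C(m,2)
  hp3 <- pes_harmonic(c(0.01, 0.02, 0.03))
  line3 <- sbg_path(cbind(seq(-3, 3, length.out = 30), 0, 0))
  irc3 <- place_on_irc(line3, hp3, build_config(n_irc_bases = 1))
  cand3 <- local_normal_mode_shifts(irc3, build_config(n_irc_bases = 1))
  expect_equal(nrow(cand3$centers), 2 * 3 + 4 * choose(3, 2))
})

test_that("the end-to-end build extends the set past the path endpoints", {
  dw <- fixture_double_well(1)
  path <- synthetic_irc(dw)
  cfg <- build_config(n_irc_bases = 5, pc_ratio_threshold = 1e-3)
  irc_only <- place_on_irc(path, dw, cfg)
  built <- build_basis_set(path, dw, cfg)
  # the dominant component is the path direction itself, so the surviving
  # shifted bases sit in the extended regions beyond the two minima
  expect_gt(length(built$bases), length(irc_only$bases))
  centers <- vapply(built$bases, function(g) g$center[1], numeric(1))
  expect_gt(max(centers), 25 + 1)
  expect_lt(min(centers), -25 - 1)
  # identical rebuild is deterministic
  built2 <- build_basis_set(path, dw, cfg)
  expect_equal(do.call(rbind, lapply(built2$bases, `[[`, "center")),
               do.call(rbind, lapply(built$bases, `[[`, "center")),
               tolerance = 1e-14)
  # and the build's own spectrum lands on the physical scale (ZPE within
  # the documented local-harmonic envelope of the oracle value)
  dvr <- dw1_dvr_levels(1)
  sp <- solve_spectrum(assemble_hamiltonian(built$bases, dw))
  expect_equal(sp$zpe, dvr[1], tolerance = 0.3)
})
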