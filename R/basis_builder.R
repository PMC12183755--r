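## Automatic basis-set construction along a reaction path: equally spaced
## placement on the IRC, PCA of the path, component selection, first- and
## second-order shifted candidate centres, width recomputation with overlap
## pruning, and symmetry-orbit accounting of potential evaluations.

#' Build configuration for the automatic basis constructor
#'
#' @param n_irc_bases number of bases equally spaced (in arc length) on the
#'   IRC, endpoints included.
#' @param target_overlap desired overlap between an IRC basis and its
#'   first-order shifted neighbours (the useful window is about 0.7-0.8).
#' @param pc_ratio_threshold keep principal components with variance ratio
#'   `lambda_n / lambda_1 >=` this threshold.
#' @param prune_overlap_max candidates whose maximum overlap with any kept
#'   basis exceeds this are discarded.
#' @param second_order add shifts `+/- (d_n PCn +/- d_n' PCn')` for distinct
#'   component pairs.
#' @param orthogonalize_to_tangent Gram-Schmidt each selected component
#'   against the local path tangent before shifting.
#' @param v_const_wavenumber,zero_tol Hessian regularization settings.
#' @param symmetry optional `sbg_symop` used for evaluation accounting.
#' @param resample_factor the path is resampled to at least
#'   `resample_factor * n_irc_bases` uniformly spaced structures before PCA.
#' @return list of class `sbg_build_config`.
#' @export
build_config <- function(n_irc_bases = 5, target_overlap = 0.75,
                         pc_ratio_threshold = 1e-3, prune_overlap_max = 0.9,
                         second_order = TRUE, orthogonalize_to_tangent = FALSE,
                         v_const_wavenumber = 1500,
                         zero_tol = cm_to_hartree(10)^2,
                         symmetry = NULL, resample_factor = 20) {
  if (!(target_overlap > 0 && target_overlap < prune_overlap_max &&
        prune_overlap_max < 1))
    stop("need 0 < target_overlap < prune_overlap_max < 1")
  structure(list(n_irc_bases = n_irc_bases, target_overlap = target_overlap,
                 pc_ratio_threshold = pc_ratio_threshold,
                 prune_overlap_max = prune_overlap_max,
                 second_order = second_order,
                 orthogonalize_to_tangent = orthogonalize_to_tangent,
                 v_const_wavenumber = v_const_wavenumber,
                 zero_tol = zero_tol, symmetry = symmetry,
                 resample_factor = resample_factor),
            class = "sbg_build_config")
}

# linear interpolation of a path to n points uniform in arc length
.resample_path <- function(path, n) {
  s <- seq(0, max(path$arc), length.out = n)
  pts <- apply(path$points, 2, function(col)
    stats::approx(path$arc, col, xout = s)$y)
  sbg_path(pts, molecule = path$molecule)
}

#' Place Gaussian bases equally spaced on a reaction path
#'
#' Centres at `n_irc_bases` arc-length-uniform positions including both
#' endpoints; widths from the provider Hessians at those centres via
#' [make_basis()]. Point IDs `c1..cL` are assigned in path order.
#'
#' @param path an `sbg_path`.
#' @param provider potential provider (must supply Hessians).
#' @param config an `sbg_build_config`.
#' @param proj optional projection operators for zero-mode identification.
#' @return list with `bases`, `adjacent_overlaps`, and `store` (an
#'   `sbg_store` holding the evaluated centre information).
#' @export
place_on_irc <- function(path, provider, config = build_config(),
                         proj = NULL) {
  if (nrow(path$points) < 2) stop("path needs at least 2 points")
  n <- config$n_irc_bases
  s <- seq(0, max(path$arc), length.out = n)
  centers <- apply(path$points, 2, function(col)
    stats::approx(path$arc, col, xout = s)$y)
  centers <- matrix(centers, nrow = n)
  store <- pes_store(ncol(centers))
  bases <- vector("list", n)
  for (i in seq_len(n)) {
    info <- pes_evaluate(provider, centers[i, ], need_hessian = TRUE)
    id <- .point_id(i)
    store_put(store, id, centers[i, ], info)
    bases[[i]] <- make_basis(centers[i, ], hessian = info$hessian,
                             v_const_wavenumber = config$v_const_wavenumber,
                             zero_tol = config$zero_tol, proj = proj,
                             point_id = id)
  }
  adj <- vapply(seq_len(n - 1), function(i)
    gauss_overlap(bases[[i]], bases[[i + 1]]), numeric(1))
  list(bases = bases, adjacent_overlaps = adj, store = store)
}

#' Principal component analysis of a reaction path
#'
#' Diagonalizes the covariance of the mean-centred structures, accumulated
#' as the plain (unnormalized) sum of outer products. Only variance ratios
#' are used downstream, so the normalization is immaterial. The path is
#' resampled to uniform arc length first so that the variances do not
#' depend on the sampling density of the input.
#'
#' @param path an `sbg_path` with at least 2 points.
#' @param n_resample number of uniformly spaced structures to resample to
#'   (default: keep the input sampling).
#' @return list of class `sbg_pca`: `mean`, `components` (columns,
#'   orthonormal), `variances` (descending), `ratios` (`lambda_n/lambda_1`).
#' @export
pca_of_path <- function(path, n_resample = NULL) {
  if (nrow(path$points) < 2) stop("path needs at least 2 points")
  pts <- if (is.null(n_resample)) path$points
         else .resample_path(path, n_resample)$points
  mu <- colMeans(pts)
  xc <- sweep(pts, 2, mu)
  cov <- crossprod(xc)                       # sum_l (Q_l - mean)(Q_l - mean)'
  ed <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  structure(list(mean = mu, components = ed$vectors,
                 variances = ed$values,
                 ratios = ed$values / ed$values[1]),
            class = "sbg_pca")
}

#' @export
print.sbg_pca <- function(x, ...) {
  k <- min(6, length(x$variances))
  cat("<sbg_pca> variance ratios lambda_n/lambda_1:\n")
  print(stats::setNames(signif(x$ratios[seq_len(k)], 3),
                        paste0("PC", seq_len(k))))
  invisible(x)
}

#' Select principal components by variance ratio
#'
#' @param pca an `sbg_pca`.
#' @param ratio_threshold keep components with `lambda_n/lambda_1 >=`
#'   threshold (in (0, 1]).
#' @return integer indices in descending-variance order.
#' @export
select_components <- function(pca, ratio_threshold = 1e-3) {
  if (!(ratio_threshold > 0 && ratio_threshold <= 1))
    stop("ratio_threshold must be in (0, 1]")
  which(pca$ratios >= ratio_threshold)
}

#' Shift distance along a direction for a target overlap
#'
#' The unique `d > 0` such that a basis shifted by `d * direction`, with
#' the same width matrix as the original (the tentative equal-width
#' assumption of the construction), overlaps the original by `target`.
#' For equal widths the overlap is `exp(-u' alpha u d^2 / 2)` with `u` the
#' unit direction, giving the closed form
#' `d = sqrt(-2 log(target) / (u' alpha u))`; the implementation solves by
#' bisection and is cross-checked against that closed form in the tests.
#'
#' @param basis an `sbg_basis`.
#' @param direction unit vector.
#' @param target target overlap in (0, 1).
#' @param tol bisection tolerance on the overlap.
#' @return scalar distance (mass-weighted a.u.).
#' @export
shift_distance <- function(basis, direction, target, tol = 1e-10) {
  nd <- sqrt(sum(direction^2))
  if (abs(nd - 1) > 1e-8) stop("direction must be unit-norm")
  if (!(target > 0 && target < 1)) stop("target must be in (0, 1)")
  ov <- function(d) {
    shifted <- make_basis(basis$center + d * direction, width = basis$width)
    gauss_overlap(basis, shifted)
  }
  lo <- 0
  hi <- 1
  while (ov(hi) > target) hi <- hi * 2
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (ov(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate first- and second-order shifted candidate centres
#'
#' For every IRC basis centre `Q_i` and selected component `PCn`:
#' first-order candidates `Q_i +/- d_{i,n} PCn`; for every unordered pair
#' `n < n'` of selected components, second-order candidates
#' `Q_i +/- (d_{i,n} PCn +/- d_{i,n'} PCn')` (four sign combinations).
#' With `orthogonalize_to_tangent`, each component is first orthogonalized
#' against the local path tangent at `Q_i`.
#'
#' @param irc list returned by [place_on_irc()] (or a bare list of bases).
#' @param pca an `sbg_pca`.
#' @param selected indices of selected components.
#' @param config an `sbg_build_config`.
#' @param tangents optional matrix of per-centre unit tangents (rows),
#'   required for `orthogonalize_to_tangent`.
#' @return data frame-like list: matrix `centers` (candidates in rows) and
#'   character `origin` tags ordered deterministically (centre index, then
#'   component order, then sign pattern).
#' @export
generate_shifted_centers <- function(irc, pca, selected,
                                     config = build_config(),
                                     tangents = NULL) {
  bases <- if (!is.null(irc$bases)) irc$bases else irc
  if (!length(selected)) stop("no components selected")
  d <- length(bases[[1]]$center)
  cand <- matrix(numeric(0), ncol = d)
  origin <- character(0)
  for (i in seq_along(bases)) {
    g <- bases[[i]]
    dirs <- list()
    for (n in selected) {
      u <- pca$components[, n]
      if (config$orthogonalize_to_tangent) {
        if (is.null(tangents)) stop("tangents required for orthogonalization")
        tg <- tangents[i, ] / sqrt(sum(tangents[i, ]^2))
        u <- u - sum(u * tg) * tg
        nu <- sqrt(sum(u^2))
        if (nu < 1e-10) next   # component parallel to the path here
        u <- u / nu
      }
      dirs[[as.character(n)]] <- u
    }
    dist <- lapply(dirs, function(u)
      shift_distance(g, u, config$target_overlap))
    keys <- names(dirs)
    for (k in keys) {
      for (sgn in c(1, -1)) {
        cand <- rbind(cand, g$center + sgn * dist[[k]] * dirs[[k]])
        origin <- c(origin, sprintf("i%d_pc%s_%+d", i, k, sgn))
      }
    }
    if (config$second_order && length(keys) >= 2) {
      for (a in seq_along(keys)[-length(keys)]) for (b in (a + 1):length(keys)) {
        ka <- keys[a]; kb <- keys[b]
        for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
          shift <- s1 * (dist[[ka]] * dirs[[ka]] + s2 * dist[[kb]] * dirs[[kb]])
          cand <- rbind(cand, g$center + shift)
          origin <- c(origin, sprintf("i%d_pc%s%+dpc%s%+d", i, ka, s1, kb, s2))
        }
      }
    }
  }
  list(centers = cand, origin = origin)
}

#' Recompute widths at candidate centres and prune by overlap
#'
#' Duplicate candidates (centre distance < `dup_tol`) are removed first.
#' Candidates are then visited in generation order; each gets its width
#' recomputed from the provider Hessian at its own centre, and is kept iff
#' its maximum overlap with all IRC bases and all previously kept
#' candidates is at most `prune_overlap_max`.
#'
#' @param candidates output of [generate_shifted_centers()].
#' @param irc output of [place_on_irc()].
#' @param provider potential provider.
#' @param config an `sbg_build_config`.
#' @param proj optional projection operators.
#' @param dup_tol duplicate-centre tolerance (a.u.).
#' @return list with `bases` (IRC bases followed by kept candidates),
#'   `store` (centre info incl. new evaluations), `kept`, `pruned`
#'   (origin tags) and `n_candidates`.
#' @export
prune_and_finalize <- function(candidates, irc, provider,
                               config = build_config(), proj = NULL,
                               dup_tol = 1e-8) {
  bases <- irc$bases
  store <- irc$store
  centers <- candidates$centers
  origin <- candidates$origin
  # drop duplicates among candidates and against IRC centres
  keep_rows <- rep(TRUE, nrow(centers))
  seen <- do.call(rbind, lapply(bases, `[[`, "center"))
  for (r in seq_len(nrow(centers))) {
    if (any(sqrt(rowSums(sweep(seen, 2, centers[r, ])^2)) < dup_tol)) {
      keep_rows[r] <- FALSE
    } else seen <- rbind(seen, centers[r, ])
  }
  centers <- centers[keep_rows, , drop = FALSE]
  origin <- origin[keep_rows]
  kept <- list(); kept_tags <- character(0); pruned_tags <- character(0)
  idx0 <- length(bases)
  for (r in seq_len(nrow(centers))) {
    info <- pes_evaluate(provider, centers[r, ], need_hessian = TRUE)
    g <- make_basis(centers[r, ], hessian = info$hessian,
                    v_const_wavenumber = config$v_const_wavenumber,
                    zero_tol = config$zero_tol, proj = proj)
    ov <- vapply(c(bases, kept), function(b) gauss_overlap(b, g), numeric(1))
    if (max(ov) <= config$prune_overlap_max) {
      id <- .point_id(idx0 + length(kept) + 1L)
      g$point_id <- id
      store_put(store, id, centers[r, ], info)
      kept[[length(kept) + 1L]] <- g
      kept_tags <- c(kept_tags, origin[r])
    } else pruned_tags <- c(pruned_tags, origin[r])
  }
  list(bases = c(bases, kept), store = store, kept = kept_tags,
       pruned = pruned_tags, n_candidates = nrow(centers))
}

#' Shift candidates along local normal modes ("all vibrations" reference)
#'
#' Same shift scheme as [generate_shifted_centers()], but the directions at
#' each IRC centre are the eigenvectors of its own regularized Hessian
#' (local normal modes; translational/rotational directions excluded via
#' the projection operators when supplied).
#'
#' @param irc output of [place_on_irc()].
#' @param config an `sbg_build_config`.
#' @param proj optional projection operators; modes with eigenvalue equal
#'   to the regularization constant are dropped as rigid-body directions.
#' @return candidate list as in [generate_shifted_centers()].
#' @export
local_normal_mode_shifts <- function(irc, config = build_config(),
                                     proj = NULL) {
  bases <- irc$bases
  store <- irc$store
  d <- length(bases[[1]]$center)
  cand <- matrix(numeric(0), ncol = d)
  origin <- character(0)
  for (i in seq_along(bases)) {
    g <- bases[[i]]
    info <- store_get(store, g$point_id)
    reg <- regularize_hessian(info$hessian, config$v_const_wavenumber,
                              config$zero_tol, proj)
    ed <- eigen(reg$matrix, symmetric = TRUE)
    mode_ok <- rep(TRUE, d)
    if (!is.null(proj)) {
      # rigid-body directions live in the projected-out space
      ovib <- proj$o_vib
      mode_ok <- vapply(seq_len(d), function(k)
        sum((ovib %*% ed$vectors[, k])^2) > 0.5, logical(1))
    }
    modes <- which(mode_ok)
    dist <- lapply(modes, function(k)
      shift_distance(g, ed$vectors[, k], config$target_overlap))
    names(dist) <- as.character(modes)
    for (mi in seq_along(modes)) {
      k <- modes[mi]
      for (sgn in c(1, -1)) {
        cand <- rbind(cand, g$center + sgn * dist[[mi]] * ed$vectors[, k])
        origin <- c(origin, sprintf("i%d_nm%d_%+d", i, k, sgn))
      }
    }
    if (config$second_order && length(modes) >= 2) {
      for (a in seq_along(modes)[-length(modes)]) for (b in (a + 1):length(modes)) {
        for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
          shift <- s1 * (dist[[a]] * ed$vectors[, modes[a]] +
                         s2 * dist[[b]] * ed$vectors[, modes[b]])
          cand <- rbind(cand, g$center + shift)
          origin <- c(origin,
                      sprintf("i%d_nm%d%+dnm%d%+d", i, modes[a], s1, modes[b], s2))
        }
      }
    }
  }
  list(centers = cand, origin = origin)
}

#' Count symmetry-unique potential evaluations
#'
#' Without GPR the assembled Hamiltonian needs potential information at all
#' unordered basis pairs (`L (L + 1) / 2` points including the diagonal
#' centres); with GPR only at the `L` centres. A symmetry operation that
#' permutes the basis centres identifies pairs (or centres) lying on the
#' same orbit, which then cost a single evaluation.
#'
#' @param bases list of `sbg_basis` (or a matrix of centres in rows).
#' @param symmetry optional `sbg_symop`; must map the centre set onto
#'   itself within `tol`.
#' @param mode `"pairs"` (no GPR) or `"centers"` (GPR).
#' @param tol centre matching tolerance.
#' @return integer number of orbit representatives.
#' @export
count_unique_evaluations <- function(bases, symmetry = NULL,
                                     mode = c("pairs", "centers"),
                                     tol = 1e-6) {
  mode <- match.arg(mode)
  centers <- if (is.matrix(bases)) bases
             else do.call(rbind, lapply(bases, `[[`, "center"))
  l <- nrow(centers)
  perm <- seq_len(l)
  if (!is.null(symmetry)) {
    img <- centers %*% t(symmetry$matrix)
    for (i in seq_len(l)) {
      dist <- sqrt(rowSums(sweep(centers, 2, img[i, ])^2))
      j <- which.min(dist)
      if (dist[j] > tol)
        stop("symmetry operation does not permute the basis centres ",
             "(centre ", i, " maps ", format(min(dist), digits = 3),
             " a.u. away from any centre)")
      perm[i] <- j
    }
    if (anyDuplicated(perm)) stop("symmetry-induced map is not a permutation")
  }
  if (mode == "centers") {
    seen <- rep(FALSE, l); n <- 0L
    for (i in seq_len(l)) {
      if (seen[i]) next
      n <- n + 1L
      j <- i
      repeat { seen[j] <- TRUE; j <- perm[j]; if (seen[j]) break }
    }
    return(n)
  }
  key <- function(i, j) paste0(min(i, j), "_", max(i, j))
  seen <- new.env(parent = emptyenv()); n <- 0L
  for (i in seq_len(l)) for (j in i:l) {
    if (!is.null(seen[[key(i, j)]])) next
    n <- n + 1L
    a <- i; b <- j
    repeat {
      seen[[key(a, b)]] <- TRUE
      ab <- c(perm[a], perm[b]); a <- min(ab); b <- max(ab)
      if (!is.null(seen[[key(a, b)]])) break
    }
  }
  n
}

#' Build a complete basis set from a path
#'
#' End-to-end constructor: IRC placement, PCA, component selection, shift
#' generation, and width-recomputing overlap pruning.
#'
#' @param path an `sbg_path`.
#' @param provider potential provider.
#' @param config an `sbg_build_config`.
#' @param proj optional projection operators.
#' @return list with `bases`, `store`, `pca`, `selected`, `irc`,
#'   `candidates`, `prune` (pruning log) and `report` (stage counts).
#' @export
build_basis_set <- function(path, provider, config = build_config(),
                            proj = NULL) {
  irc <- place_on_irc(path, provider, config, proj)
  n_res <- max(config$resample_factor * config$n_irc_bases,
               nrow(path$points))
  pca <- pca_of_path(path, n_resample = n_res)
  selected <- select_components(pca, config$pc_ratio_threshold)
  cand <- generate_shifted_centers(irc, pca, selected, config,
                                   tangents = .irc_tangents(path, config))
  pruned <- prune_and_finalize(cand, irc, provider, config, proj)
  list(bases = pruned$bases, store = pruned$store, pca = pca,
       selected = selected, irc = irc, candidates = cand, prune = pruned,
       report = list(n_irc = length(irc$bases),
                     n_candidates = nrow(cand$centers),
                     n_kept = length(pruned$kept),
                     n_total = length(pruned$bases),
                     adjacent_overlaps = irc$adjacent_overlaps))
}

# tangents at the IRC basis positions (arc-length interpolation)
.irc_tangents <- function(path, config) {
  s <- seq(0, max(path$arc), length.out = config$n_irc_bases)
  tg <- apply(path$tangent, 2, function(col)
    stats::approx(path$arc, col, xout = s)$y)
  matrix(tg, nrow = config$n_irc_bases)
}
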