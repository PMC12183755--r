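## Gaussian process regression of potential energies and Hessian elements
## at basis-pair midpoints, with grid-search hyperparameter selection by
## closed-form leave-one-out cross-validation.

#' Squared-exponential kernel
#'
#' `k(q, q') = tau^2 exp(-||q - q'||^2 / (2 beta^2))`.
#'
#' @param q1,q2 points (vectors) or matrices of points in rows.
#' @param tau kernel amplitude (> 0).
#' @param beta length scale in mass-weighted a.u. (> 0).
#' @return scalar or cross-kernel matrix.
#' @export
gpr_kernel <- function(q1, q2, tau, beta) {
  if (tau <= 0 || beta <= 0) stop("tau and beta must be positive")
  if (is.null(dim(q1)) && is.null(dim(q2)))
    return(tau^2 * exp(-sum((q1 - q2)^2) / (2 * beta^2)))
  q1 <- if (is.null(dim(q1))) matrix(q1, nrow = 1) else as.matrix(q1)
  q2 <- if (is.null(dim(q2))) matrix(q2, nrow = 1) else as.matrix(q2)
  d2 <- outer(rowSums(q1^2), rowSums(q2^2), `+`) - 2 * tcrossprod(q1, q2)
  tau^2 * exp(-pmax(d2, 0) / (2 * beta^2))
}

# flatten energy + upper-triangle Hessian into a target row
.info_to_targets <- function(info) {
  h <- info$hessian
  c(info$energy, h[upper.tri(h, diag = TRUE)])
}

# closed-form leave-one-out residuals y_i - yhat_{-i} from the inverse-Gram
# identity: residual_i = [K^-1 y]_i / [K^-1]_ii, per target column
.loo_residuals <- function(kinv, alpha) alpha / diag(kinv)

#' Closed-form leave-one-out residuals of a GPR configuration
#'
#' For fixed hyperparameters, returns the matrix of leave-one-out
#' residuals `y_i - yhat_{-i}(Q_i)` (training rows by target columns, in
#' physical units) computed from the inverse-Gram identity without any
#' refitting. This is the quantity the grid search in [gpr_fit()]
#' minimizes; it equals what explicit n-fold refitting produces.
#'
#' @param x matrix of training points (rows).
#' @param infos list of `sbg_potinfo` aligned with `x`.
#' @param tau,beta kernel hyperparameters.
#' @param sigma2_rel Gram regularization: `sigma^2 = sigma2_rel * tau^2`.
#' @return numeric matrix, rows = training points, columns = energy then
#'   upper-triangle Hessian elements.
#' @export
gpr_loo_residuals <- function(x, infos, tau, beta, sigma2_rel = 1e-8) {
  x <- as.matrix(x)
  n <- nrow(x)
  y_raw <- t(vapply(infos, .info_to_targets,
                    numeric(1 + ncol(x) * (ncol(x) + 1) / 2)))
  mu <- colMeans(y_raw)
  sc <- apply(y_raw, 2, stats::sd)
  sc[sc < 1e-300] <- 1
  y <- sweep(sweep(y_raw, 2, mu), 2, sc, `/`)
  kmat <- gpr_kernel(x, x, tau, beta) + diag(sigma2_rel * tau^2, n)
  kinv <- chol2inv(chol(kmat))
  sweep(.loo_residuals(kinv, kinv %*% y), 2, sc, `*`)
}

# weights of each target column in the scalar V + Tr(W H)/4 (off-diagonal
# upper-triangle elements count twice in the trace)
.objective_weights <- function(w_mat) {
  d <- nrow(w_mat)
  mult <- matrix(2, d, d); diag(mult) <- 1
  c(1, (w_mat * mult)[upper.tri(w_mat, diag = TRUE)] / 4)
}

#' Augment GPR training data by a symmetry operation
#'
#' Adds image points `M Q_i` with energies unchanged and Hessians
#' transported as `M H M'`, skipping images that coincide with existing
#' training points. Image rows cost no provider calls.
#'
#' @param x matrix of training points (rows).
#' @param infos list of `sbg_potinfo` aligned with the rows of `x`.
#' @param op an `sbg_symop`.
#' @param tol duplicate-point tolerance (a.u.).
#' @return list with augmented `x` and `infos`.
#' @export
symmetry_augment_training <- function(x, infos, op, tol = 1e-8) {
  x <- as.matrix(x)
  for (i in seq_len(nrow(x))) {
    img <- as.numeric(op$matrix %*% x[i, ])
    if (min(sqrt(rowSums(sweep(x, 2, img)^2))) > tol) {
      x <- rbind(x, img)
      infos[[length(infos) + 1L]] <- symmetry_expand(infos[[i]], op)
    }
  }
  list(x = x, infos = infos)
}

#' Fit a GPR model for potential energies and Hessian elements
#'
#' Targets are the energy plus the upper triangle of the Hessian (one
#' multi-output model, `1 + D(D+1)/2` columns), centred and scaled per
#' column. One shared `(tau, beta)` pair is selected on a grid by
#' minimizing the summed squared leave-one-out error of the scalar
#' `V(Q_i) + Tr[(2 alpha_i)^-1 V''(Q_i)] / 4` (the local-harmonic diagonal
#' bracket), reconstructed from the per-column closed-form LOO residuals.
#' When no widths are supplied the objective falls back to the energy
#' column alone.
#'
#' @param x matrix of training points (rows; basis centres).
#' @param infos list of `sbg_potinfo` with Hessians, aligned with `x`.
#' @param widths optional list of width matrices `alpha_i` (for the LOO
#'   objective weights).
#' @param tau_grid amplitudes to scan, in units of the scaled targets
#'   (default `c(0.3, 1, 3)`).
#' @param beta_grid length scales to scan (default: the 10/25/50/75/90th
#'   percentiles of the pairwise training distances).
#' @param sigma2_rel Gram regularization: `sigma^2 = sigma2_rel * tau^2`.
#' @param symmetry optional `sbg_symop`: training rows for image points are
#'   generated by [symmetry_augment_training()] before fitting.
#' @return object of class `sbg_gpr` with the fitted hyperparameters, the
#'   cached Gram factorization and the LOO objective per grid point.
#' @export
gpr_fit <- function(x, infos, widths = NULL, tau_grid = c(0.3, 1, 3),
                    beta_grid = NULL, sigma2_rel = 1e-8, symmetry = NULL) {
  x <- as.matrix(x)
  if (!is.null(symmetry)) {
    aug <- symmetry_augment_training(x, infos, symmetry)
    if (!is.null(widths)) {
      # image widths transported like Hessians
      extra <- nrow(aug$x) - nrow(x)
      if (extra > 0) {
        m <- symmetry$matrix
        have <- vapply(seq_len(nrow(x)), function(i) {
          img <- as.numeric(m %*% x[i, ])
          min(sqrt(rowSums(sweep(x, 2, img)^2))) > 1e-8
        }, logical(1))
        for (i in which(have))
          widths[[length(widths) + 1L]] <- m %*% widths[[i]] %*% t(m)
      }
    }
    x <- aug$x; infos <- aug$infos
  }
  n <- nrow(x)
  if (n < 3) stop("need at least 3 training points")
  y_raw <- t(vapply(infos, .info_to_targets,
                    numeric(1 + ncol(x) * (ncol(x) + 1) / 2)))
  mu <- colMeans(y_raw)
  sc <- apply(y_raw, 2, stats::sd)
  sc[sc < 1e-300] <- 1
  y <- sweep(sweep(y_raw, 2, mu), 2, sc, `/`)
  if (is.null(beta_grid)) {
    pd <- stats::dist(x)
    beta_grid <- unname(stats::quantile(pd, c(0.1, 0.25, 0.5, 0.75, 0.9)))
    beta_grid <- unique(beta_grid[beta_grid > 0])
  }
  w_cols <- if (is.null(widths)) {
    wv <- numeric(ncol(y)); wv[1] <- 1
    matrix(wv, n, ncol(y), byrow = TRUE)
  } else {
    t(vapply(widths, function(a) .objective_weights(solve(2 * a)),
             numeric(ncol(y))))
  }
  grid <- expand.grid(tau = tau_grid, beta = beta_grid)
  grid$objective <- NA_real_
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    tau <- grid$tau[g]; beta <- grid$beta[g]
    kmat <- gpr_kernel(x, x, tau, beta) + diag(sigma2_rel * tau^2, n)
    ch <- tryCatch(chol(kmat), error = function(e) NULL)
    if (is.null(ch)) next
    kinv <- chol2inv(ch)
    alpha <- kinv %*% y                      # per-column K^-1 y
    loo <- .loo_residuals(kinv, alpha)
    loo_phys <- sweep(loo, 2, sc, `*`)       # de-scale (means cancel)
    obj <- sum(rowSums(loo_phys * w_cols)^2)
    grid$objective[g] <- obj
    if (is.null(best) || obj < best$objective)
      best <- list(tau = tau, beta = beta, objective = obj,
                   chol = ch, alpha = alpha)
  }
  if (is.null(best)) stop("Gram matrix singular for every grid point")
  structure(list(train_x = x, train_y = y, y_mean = mu, y_scale = sc,
                 tau = best$tau, beta = best$beta,
                 sigma2 = sigma2_rel * best$tau^2,
                 alpha = best$alpha, chol = best$chol,
                 dim = ncol(x), grid = grid,
                 objective = best$objective),
            class = "sbg_gpr")
}

#' @export
print.sbg_gpr <- function(x, ...) {
  cat("<sbg_gpr> ", nrow(x$train_x), " training points, dim ", x$dim,
      ", tau = ", format(x$tau, digits = 4),
      ", beta = ", format(x$beta, digits = 4),
      ", LOO objective = ", format(x$objective, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict potential information at a point
#'
#' All target columns are predicted with the single cached factorization
#' and one kernel vector; the Hessian is reassembled symmetric and the
#' prediction is de-scaled to physical units.
#'
#' @param model an `sbg_gpr`.
#' @param q_star query point (a.u.).
#' @return an `sbg_potinfo`.
#' @export
gpr_predict <- function(model, q_star) {
  if (length(q_star) != model$dim) stop("dimension mismatch")
  kvec <- gpr_kernel(model$train_x, matrix(q_star, nrow = 1),
                     model$tau, model$beta)
  ys <- as.numeric(crossprod(kvec, model$alpha))
  y <- ys * model$y_scale + model$y_mean
  d <- model$dim
  h <- matrix(0, d, d)
  h[upper.tri(h, diag = TRUE)] <- y[-1]
  h <- h + t(h) - diag(diag(h), d)
  potential_info(y[1], hessian = h)
}

#' Wrap a GPR model and a centre store as a potential-information source
#'
#' Requests at registered centre coordinates are answered bit-exactly from
#' the store; anywhere else (the basis-pair midpoints) the GPR prediction
#' is returned. Each request is logged with the path that served it.
#'
#' @param model an `sbg_gpr`.
#' @param store an `sbg_store` holding the centre information.
#' @param tol coordinate matching tolerance (a.u.).
#' @return object of class `sbg_gpr_source` with fields `eval_fn` and the
#'   request `log` environment (`log$routes`).
#' @export
gpr_source <- function(model, store, tol = 1e-8) {
  log <- new.env(parent = emptyenv())
  log$routes <- character(0)
  eval_fn <- function(point) {
    for (id in store_ids(store)) {
      rec <- store$records[[id]]
      if (max(abs(rec$point - point)) <= tol) {
        log$routes <- c(log$routes, paste0("store:", id))
        return(rec$info)
      }
    }
    log$routes <- c(log$routes, "gpr")
    gpr_predict(model, point)
  }
  structure(list(eval_fn = eval_fn, model = model, store = store, log = log),
            class = "sbg_gpr_source")
}

#' Interpolation-error report for a GPR model
#'
#' Compares predicted and true potential energies and local-harmonic
#' Hessian-trace terms `Tr[W V''] / 4` at a set of points, and reports both
#' RMSEs in cm^-1.
#'
#' @param model an `sbg_gpr`.
#' @param truth an `sbg_provider` able to evaluate all points.
#' @param points matrix of evaluation points (rows).
#' @param weights list of D x D matrices `W = (alpha_i + alpha_i')^-1`, one
#'   per point (identity if omitted).
#' @return list with a per-point `table` and `rmse_energy_cm`,
#'   `rmse_trace_cm`.
#' @export
gpr_estimation_report <- function(model, truth, points, weights = NULL) {
  points <- as.matrix(points)
  np <- nrow(points)
  if (is.null(weights)) weights <- rep(list(diag(model$dim)), np)
  e_pred <- e_true <- t_pred <- t_true <- numeric(np)
  for (i in seq_len(np)) {
    pr <- gpr_predict(model, points[i, ])
    tr <- pes_evaluate(truth, points[i, ], need_hessian = TRUE)
    w <- weights[[i]]
    e_pred[i] <- pr$energy; e_true[i] <- tr$energy
    t_pred[i] <- sum(w * pr$hessian) / 4
    t_true[i] <- sum(w * tr$hessian) / 4
  }
  list(table = data.frame(energy_pred = e_pred, energy_true = e_true,
                          trace_pred = t_pred, trace_true = t_true),
       rmse_energy_cm = hartree_to_cm(sqrt(mean((e_pred - e_true)^2))),
       rmse_trace_cm = hartree_to_cm(sqrt(mean((t_pred - t_true)^2))))
}
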