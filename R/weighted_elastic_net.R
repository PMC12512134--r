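# Weighted elastic net: unnormalized residual sum of squares plus a
# per-feature-weighted penalty,
#   ||y - X beta||^2 + lambda * [alpha * sum(w |beta|) +
#                                (1 - alpha)/2 * sum(w beta^2)],
# trained federatively by FedAvg over full-batch subgradient updates, with
# an exact proximal coordinate-descent solver as the centralized reference.

#' Weighted elastic net model container
#'
#' @param beta Length-`P` coefficient vector.
#' @param intercept Unpenalized intercept.
#' @param lam Regularization strength `lambda` (positive).
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (1 = pure lasso).
#' @param weights Length-`P` per-feature penalty weights in `[0, 1]`.
#' @param group Optional target-group tag this model was trained for.
#' @param provenance Optional list of free-form provenance fields.
#' @return An object of class `wen_model`.
#' @export
wen_model <- function(beta, intercept = 0, lam = 1, alpha = 0.8,
                      weights = rep(1, length(beta)), group = NULL,
                      provenance = list()) {
  beta <- as.numeric(beta)
  if (any(!is.finite(beta)) || !is.finite(intercept)) {
    stop_config("wen_model: coefficients must be finite")
  }
  if (lam < 0) stop_config("wen_model: lam must be nonnegative")
  if (alpha < 0 || alpha > 1) stop_config("wen_model: alpha must be in [0, 1]")
  if (length(weights) != length(beta)) stop_config("wen_model: weights length mismatch")
  structure(list(beta = beta, intercept = intercept, lam = lam, alpha = alpha,
                 weights = as.numeric(weights), group = group,
                 provenance = provenance),
            class = "wen_model")
}

#' @export
print.wen_model <- function(x, ...) {
  cat(sprintf("<wen_model: P=%d, nonzero=%d, lambda=%.4g, alpha=%.2f%s>\n",
              length(x$beta), sum(x$beta != 0), x$lam, x$alpha,
              if (is.null(x$group)) "" else paste0(", group=", x$group)))
  invisible(x)
}

wen_penalty <- function(beta, weights, alpha) {
  alpha * sum(weights * abs(beta)) + 0.5 * (1 - alpha) * sum(weights * beta^2)
}

#' Weighted elastic net objective
#'
#' Unnormalized residual sum of squares plus the weighted penalty, exactly
#' as the model definition states (no division by the sample count; the
#' meaning of `lambda` therefore scales with `n`).
#'
#' @param model A [wen_model()].
#' @param X Design matrix (n x P).
#' @param y Response vector.
#' @return Scalar objective value.
#' @export
wen_objective <- function(model, X, y) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$beta) || nrow(X) != length(y)) {
    stop_config("wen_objective: shape mismatch")
  }
  r <- y - drop(X %*% model$beta) - model$intercept
  sum(r^2) + model$lam * wen_penalty(model$beta, model$weights, model$alpha)
}

#' Predict from a weighted elastic net model
#'
#' @param object A [wen_model()].
#' @param X Design matrix with matching feature count.
#' @param ... Unused.
#' @return Numeric vector `X %*% beta + intercept`.
#' @export
predict.wen_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$beta)) stop_config("predict.wen_model: shape mismatch")
  drop(X %*% object$beta) + object$intercept
}

#' FedAvg training schedule
#'
#' @param global_rounds Number of global aggregation rounds (default 100).
#' @param local_epochs Full-batch local steps per round (default 20).
#' @param lr_start,lr_end Exponentially decayed learning rate: round `r`
#'   (0-based) uses `lr_start * (lr_end / lr_start)^(r / (global_rounds - 1))`.
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(global_rounds = 100, local_epochs = 20,
                              lr_start = 1e-4, lr_end = 1e-5) {
  if (global_rounds < 1 || local_epochs < 1) {
    stop_config("training_schedule: rounds and epochs must be positive")
  }
  if (lr_end > lr_start || lr_start <= 0) {
    stop_config("training_schedule: need 0 < lr_end <= lr_start")
  }
  structure(list(global_rounds = as.integer(global_rounds),
                 local_epochs = as.integer(local_epochs),
                 lr_start = lr_start, lr_end = lr_end),
            class = "training_schedule")
}

schedule_lr <- function(schedule, round) {
  if (schedule$global_rounds == 1) return(schedule$lr_start)
  schedule$lr_start *
    (schedule$lr_end / schedule$lr_start)^(round / (schedule$global_rounds - 1))
}

# Sufficient statistics reused across local epochs.
wen_suffstats <- function(X, y) {
  list(XtX = crossprod(X), Xty = drop(crossprod(X, y)), sx = colSums(X),
       sy = sum(y), yty = sum(y^2), n = length(y))
}

wen_local_objective <- function(ss, beta, b, lam, alpha, w, scale) {
  rss <- ss$yty - 2 * sum(beta * ss$Xty) - 2 * b * ss$sy +
    drop(crossprod(beta, ss$XtX %*% beta)) + 2 * b * sum(ss$sx * beta) +
    ss$n * b^2
  scale * rss + lam * wen_penalty(beta, w, alpha)
}

#' Local full-batch proximal-gradient training slice
#'
#' Runs `epochs` full-batch proximal gradient steps on the client's share of
#' the global objective: a gradient step on the smooth part (residuals plus
#' the weighted L2 penalty) followed by soft-thresholding at
#' `lr * lambda * alpha * w` for the weighted L1 part. The proximal step is
#' monotone at stable learning rates, unlike a plain L1 subgradient, which
#' oscillates around zero once coefficients reach the threshold. The local
#' residual term is scaled by `n_total / n_i`, so that the sample-size-
#' weighted FedAvg of local updates matches the pooled objective's geometry
#' regardless of how data are partitioned. If the local objective increases
#' over the slice, the learning rate is halved and the slice retried (up to
#' 5 times) before raising a training error.
#'
#' @param model Starting [wen_model()] (carries `lam`, `alpha`, `weights`).
#' @param X,y Local design matrix and response.
#' @param epochs Number of full-batch steps.
#' @param lr Learning rate for this slice.
#' @param n_total Pooled source sample count (defaults to `nrow(X)`).
#' @return Updated [wen_model()].
#' @export
local_train <- function(model, X, y, epochs, lr, n_total = nrow(X)) {
  if (lr <= 0) stop_config("local_train: lr must be positive")
  local_train_ss(model, wen_suffstats(as.matrix(X), y), epochs, lr, n_total)
}

# Slice on precomputed sufficient statistics (hot path of FedAvg training).
local_train_ss <- function(model, ss, epochs, lr, n_total = ss$n) {
  scale <- n_total / ss$n
  lam <- model$lam; alpha <- model$alpha; w <- model$weights
  beta0 <- model$beta; b0 <- model$intercept
  obj0 <- wen_local_objective(ss, beta0, b0, lam, alpha, w, scale)
  l1 <- lam * alpha * w
  for (attempt in 0:5) {
    beta <- beta0; b <- b0
    for (e in seq_len(epochs)) {
      xtr <- ss$Xty - drop(ss$XtX %*% beta) - b * ss$sx   # X'(y - X beta - b)
      sr <- ss$sy - sum(ss$sx * beta) - ss$n * b          # sum of residuals
      g_smooth <- scale * (-2 * xtr) + lam * (1 - alpha) * w * beta
      beta <- soft_threshold(beta - lr * g_smooth, lr * l1)
      b <- b + lr * scale * 2 * sr
    }
    obj1 <- wen_local_objective(ss, beta, b, lam, alpha, w, scale)
    if (is.finite(obj1) && obj1 <= obj0 + 1e-10 * (1 + abs(obj0))) {
      return(wen_model(beta, b, lam, alpha, w, model$group, model$provenance))
    }
    lr <- lr / 2
  }
  stop_numerical("local_train: objective increased despite learning-rate halving")
}

same_provenance <- function(a, b) {
  identical(a$lam, b$lam) && identical(a$alpha, b$alpha) &&
    identical(a$weights, b$weights)
}

#' Sample-size-weighted FedAvg aggregation
#'
#' Averages client models coefficientwise with weights `n_i / sum(n_j)`,
#' computed through [secure_sum()] so the aggregator never observes an
#' individual client's update. All clients must share identical
#' `(lambda, alpha, weights)` provenance.
#'
#' @param models Named list (client -> [wen_model()]).
#' @param n_i Named vector of client sample sizes.
#' @param codec An [fp_codec()].
#' @param pairwise_seeds Pairwise mask seeds; derived from `seed` if `NULL`.
#' @param round_id Aggregation round.
#' @param seed Fallback seed for mask derivation.
#' @return The aggregated [wen_model()].
#' @export
fedavg_aggregate <- function(models, n_i, codec = fp_codec(),
                             pairwise_seeds = NULL, round_id = 0, seed = 1) {
  ids <- names(models)
  if (is.null(ids)) stop_protocol("fedavg_aggregate: models must be named by client")
  if (!all(vapply(models, same_provenance, logical(1), b = models[[1]]))) {
    stop_protocol("fedavg_aggregate: (lambda, alpha, weights) provenance differs")
  }
  if (is.null(pairwise_seeds)) pairwise_seeds <- derive_pairwise_seeds(ids, seed)
  n_tot <- sum(n_i[ids])
  vals <- stats::setNames(lapply(ids, function(p) {
    n_i[[p]] * c(models[[p]]$beta, models[[p]]$intercept)
  }), ids)
  tot <- secure_sum(vals, codec, round_id = round_id, pairwise_seeds = pairwise_seeds)
  m1 <- models[[1]]
  wen_model(tot[-length(tot)] / n_tot, tot[length(tot)] / n_tot,
            m1$lam, m1$alpha, m1$weights, m1$group, m1$provenance)
}

#' Federated weighted elastic net training (FedAvg)
#'
#' Alternates local full-batch subgradient slices and secure sample-size-
#' weighted aggregation for `schedule$global_rounds` rounds with an
#' exponentially decaying learning rate. Deterministic given the seed and
#' the (sorted) client order; the final model is broadcast to all roles.
#'
#' @param clients List of labeled [domain_dataset()] objects.
#' @param weights Length-`P` penalty weight vector (or a
#'   `feature_weight_vector`).
#' @param lam,alpha Regularization strength and mixing parameter.
#' @param schedule A [training_schedule()].
#' @param init Optional starting [wen_model()] (default zeros).
#' @param codec An [fp_codec()].
#' @param seed Seed for the aggregation mask streams.
#' @param group Group tag recorded on the returned model.
#' @param transcript Optional transcript environment for message recording.
#' @return The trained global [wen_model()].
#' @export
train_federated_wen <- function(clients, weights, lam, alpha = 0.8,
                                schedule = training_schedule(), init = NULL,
                                codec = fp_codec(), seed = 1, group = NULL,
                                transcript = NULL) {
  clients <- clients[order(vapply(clients, function(s) s$domain_id, character(1)))]
  ids <- vapply(clients, function(s) s$domain_id, character(1))
  names(clients) <- ids
  if (inherits(weights, "feature_weight_vector")) weights <- weights$values
  P <- ncol(clients[[1]]$X)
  if (length(weights) != P) stop_config("train_federated_wen: weights length != P")
  n_i <- vapply(clients, function(s) nrow(s$X), numeric(1))
  n_total <- sum(n_i)
  suffstats <- lapply(clients, function(s) wen_suffstats(s$X, s$y))
  pairwise_seeds <- derive_pairwise_seeds(ids, mix_seed(seed, "fedavg"))
  global <- init %||% wen_model(numeric(P), 0, lam, alpha, weights, group)
  global <- wen_model(global$beta, global$intercept, lam, alpha, weights, group)
  for (r in seq_len(schedule$global_rounds) - 1L) {
    lr <- schedule_lr(schedule, r)
    locals <- stats::setNames(lapply(ids, function(p) {
      local_train_ss(global, suffstats[[p]], schedule$local_epochs, lr, n_total)
    }), ids)
    if (!is.null(transcript)) {
      for (p in ids) record_message(transcript, r, p, "aggregator",
                                    "masked_model_update", locals[[p]]$beta,
                                    masked = TRUE)
    }
    global <- fedavg_aggregate(locals, n_i, codec,
                               pairwise_seeds = pairwise_seeds, round_id = r)
  }
  if (!is.null(transcript)) {
    record_message(transcript, schedule$global_rounds, "aggregator", "target",
                   "final_model", global$beta)
  }
  global
}

soft_threshold <- function(z, t) {
  a <- abs(z) - t
  a[a < 0] <- 0
  sign(z) * a
}

#' Exact centralized weighted elastic net (reference solver)
#'
#' Proximal coordinate descent with exact soft-thresholding on the pooled
#' objective; the unpenalized intercept is handled by centering. Iterates to
#' a coordinate-change tolerance tight enough that KKT residuals reach
#' numerical precision. Serves as the equivalence oracle for federated
#' training and as the non-federated (WENDA-style) solution path.
#'
#' @param X Pooled design matrix.
#' @param y Pooled response.
#' @param weights Per-feature penalty weights.
#' @param lam,alpha Regularization strength and mixing parameter.
#' @param max_iter Maximum number of full coordinate sweeps.
#' @param tol Convergence tolerance on the largest coordinate change.
#' @return A [wen_model()] at the optimum.
#' @export
centralized_wen_oracle <- function(X, y, weights = rep(1, ncol(X)), lam, alpha = 0.8,
                                   max_iter = 50000, tol = 1e-13) {
  X <- as.matrix(X)
  if (inherits(weights, "feature_weight_vector")) weights <- weights$values
  P <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  G <- crossprod(Xc)
  c0 <- drop(crossprod(Xc, yc))
  dG <- diag(G)
  beta <- numeric(P)
  l1 <- lam * alpha * weights
  l2 <- lam * (1 - alpha) * weights
  for (it in seq_len(max_iter)) {
    delta_max <- 0
    for (j in seq_len(P)) {
      rho <- c0[j] - sum(G[, j] * beta) + dG[j] * beta[j]
      denom <- 2 * dG[j] + l2[j]
      bj <- if (denom > 0) soft_threshold(2 * rho, l1[j]) / denom else 0
      delta_max <- max(delta_max, abs(bj - beta[j]))
      beta[j] <- bj
    }
    if (delta_max < tol * (1 + max(abs(beta)))) break
  }
  if (it == max_iter && delta_max >= tol * (1 + max(abs(beta)))) {
    stop_numerical("centralized_wen_oracle: coordinate descent did not converge")
  }
  wen_model(beta, ym - sum(xm * beta), lam, alpha, weights,
            provenance = list(solver = "coordinate_descent", sweeps = it))
}

#' KKT residual of a weighted elastic net solution
#'
#' Largest violation of the subgradient optimality conditions of the pooled
#' objective: zero at an exact optimum.
#'
#' @param model A [wen_model()].
#' @param X,y Pooled data.
#' @return Scalar maximum KKT residual.
#' @export
kkt_residual <- function(model, X, y) {
  X <- as.matrix(X)
  r <- y - drop(X %*% model$beta) - model$intercept
  g <- -2 * drop(crossprod(X, r)) +
    model$lam * (1 - model$alpha) * model$weights * model$beta
  l1 <- model$lam * model$alpha * model$weights
  resid <- ifelse(model$beta != 0,
                  abs(g + l1 * sign(model$beta)),
                  pmax(abs(g) - l1, 0))
  max(c(resid, abs(-2 * sum(r))))
}

#' Non-adaptive elastic-net + least-squares baseline
#'
#' Fits a standard (unweighted) elastic net with `lambda` chosen by internal
#' 10-fold cross-validation, then refits ordinary least squares on the
#' selected support. With an empty support the model falls back to the
#' intercept-only mean predictor; a singular restricted design falls back to
#' a lightly ridge-stabilized solve.
#'
#' @param X Pooled source design matrix.
#' @param y Pooled source response.
#' @param lam_grid Optional lambda grid for [glmnet::cv.glmnet()] (its own
#'   scale); default lets glmnet build its path.
#' @param alpha Elastic-net mixing parameter (default 0.8).
#' @param nfolds Number of CV folds (default 10).
#' @param seed Seed for the CV fold assignment.
#' @return A [wen_model()] with uniform (unit) penalty weights.
#' @export
en_ls_baseline <- function(X, y, lam_grid = NULL, alpha = 0.8, nfolds = 10,
                           seed = 1) {
  X <- as.matrix(X)
  cv <- with_seed(seed, glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = nfolds,
                                          lambda = lam_grid,
                                          standardize = FALSE))
  cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
  support <- which(cf[-1] != 0)
  P <- ncol(X)
  if (!length(support)) {
    return(wen_model(numeric(P), mean(y), cv$lambda.min, alpha,
                     provenance = list(method = "en-ls", support = integer(0))))
  }
  Z <- cbind(1, X[, support, drop = FALSE])
  fit <- tryCatch({
    qr_z <- qr(Z)
    if (qr_z$rank < ncol(Z)) stop("rank deficient")
    qr.coef(qr_z, y)
  }, error = function(e) {
    drop(solve(crossprod(Z) + diag(1e-8, ncol(Z)), crossprod(Z, y)))
  })
  beta <- numeric(P)
  beta[support] <- fit[-1]
  wen_model(beta, fit[1], cv$lambda.min, alpha,
            provenance = list(method = "en-ls", support = support))
}
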