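# Per-feature Gaussian-process feature models with a linear kernel:
# one GPR per feature f regresses that feature on all remaining features,
# trained on source data that stays distributed. Hyper-parameters are
# optimized locally and securely averaged; the kernel blocks and the
# predictive mean reach the target client only through masked protocols.

#' GPR hyper-parameters
#'
#' @param sigma_k2 Prior (kernel) variance of the linear kernel; positive.
#' @param sigma_eps2 Additive Gaussian noise variance; positive.
#' @return An object of class `gpr_hyperparams`.
#' @export
gpr_hyperparams <- function(sigma_k2, sigma_eps2) {
  if (!is.finite(sigma_k2) || !is.finite(sigma_eps2) ||
      sigma_k2 <= 0 || sigma_eps2 <= 0) {
    stop_config("gpr_hyperparams: variances must be strictly positive and finite")
  }
  structure(list(sigma_k2 = sigma_k2, sigma_eps2 = sigma_eps2),
            class = "gpr_hyperparams")
}

# Cholesky with an escalating jitter ladder: 1e-8 * mean(diag), x10, up to
# 3 escalations. Errors if K stays non-PD.
chol_jitter <- function(K) {
  jitter <- 0
  base <- 1e-8 * mean(diag(K))
  for (attempt in 0:3) {
    R <- tryCatch(chol(K + diag(jitter, nrow(K))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jitter <- if (jitter == 0) base else jitter * 10
  }
  stop_numerical("kernel matrix not positive definite after jitter escalation")
}

#' Negative log marginal likelihood of a linear-kernel GPR
#'
#' For `K = sigma_k2 * X_nf X_nf' + sigma_eps2 * I`, returns
#' `0.5 * (x_f' K^-1 x_f + log|K| + n log 2pi)`, evaluated through a
#' jittered Cholesky factorization.
#'
#' @param X_nf Numeric matrix (n x (P-1)): all features except the modeled one.
#' @param x_f Numeric vector (length n): the modeled feature.
#' @param hyper A [gpr_hyperparams()].
#' @return Scalar negative log marginal likelihood.
#' @export
neg_log_marginal_likelihood <- function(X_nf, x_f, hyper) {
  X_nf <- as.matrix(X_nf)
  n <- length(x_f)
  if (nrow(X_nf) != n) stop_config("neg_log_marginal_likelihood: shape mismatch")
  if (anyNA(X_nf) || anyNA(x_f)) stop_config("non-finite inputs")
  K <- hyper$sigma_k2 * tcrossprod(X_nf) + diag(hyper$sigma_eps2, n)
  R <- chol_jitter(K)
  alpha <- backsolve(R, forwardsolve(t(R), x_f))
  0.5 * (sum(x_f * alpha) + 2 * sum(log(diag(R))) + n * log(2 * pi))
}

# Eigen-decomposition form of the NLML used inside the optimizer: with
# G = X_nf X_nf' = U diag(d) U' and u = U' x_f,
# NLML = 0.5 * sum(u^2 / s + log s) + n/2 log 2pi, s = sigma_k2 * d + sigma_eps2.
nlml_eigen_parts <- function(X_nf, x_f) {
  eg <- eigen(tcrossprod(as.matrix(X_nf)), symmetric = TRUE)
  list(d = pmax(eg$values, 0), u2 = drop(crossprod(eg$vectors, x_f))^2,
       n = length(x_f))
}

nlml_from_parts <- function(parts, sigma_k2, sigma_eps2) {
  s <- sigma_k2 * parts$d + sigma_eps2
  0.5 * (sum(parts$u2 / s) + sum(log(s)) + parts$n * log(2 * pi))
}

#' Optimize GPR hyper-parameters on local data
#'
#' Maximizes the marginal likelihood over `(sigma_k2, sigma_eps2)` by
#' box-constrained quasi-Newton descent in log-parameter space, using the
#' one-off eigendecomposition of the local Gram matrix so that each
#' objective evaluation is O(n). Returns the best point seen; never worse
#' than `init`.
#'
#' @inheritParams neg_log_marginal_likelihood
#' @param init Starting [gpr_hyperparams()] (default `(1, 1)`).
#' @param bounds Length-2 box `[lower, upper]` applied to both parameters.
#' @param restarts Number of additional random restarts (default 0).
#' @param restart_seed Seed for restart draws.
#' @return A [gpr_hyperparams()] within bounds.
#' @export
optimize_local_hyperparams <- function(X_nf, x_f, init = gpr_hyperparams(1, 1),
                                       bounds = c(1e-6, 1e6), restarts = 0,
                                       restart_seed = 1) {
  if (length(x_f) < 2) stop_config("optimize_local_hyperparams: need n >= 2")
  parts <- nlml_eigen_parts(X_nf, x_f)
  lb <- log(bounds[1]); ub <- log(bounds[2])
  obj <- function(th) nlml_from_parts(parts, exp(th[1]), exp(th[2]))
  grad <- function(th) {
    k2 <- exp(th[1]); e2 <- exp(th[2])
    s <- k2 * parts$d + e2
    common <- 1 / s - parts$u2 / s^2
    0.5 * c(k2 * sum(parts$d * common), e2 * sum(common))
  }
  starts <- list(log(c(init$sigma_k2, init$sigma_eps2)))
  if (restarts > 0) {
    extra <- with_seed(restart_seed, replicate(restarts, stats::runif(2, -2, 2),
                                               simplify = FALSE))
    starts <- c(starts, extra)
  }
  best <- list(par = starts[[1]], value = obj(starts[[1]]))
  for (st in starts) {
    st <- pmin(pmax(st, lb), ub)
    fit <- tryCatch(
      stats::optim(st, obj, grad, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (!fit$convergence %in% c(0L, 1L)) {
      warning("hyper-parameter optimizer did not converge; keeping best-seen point")
    }
    if (fit$value < best$value) best <- fit[c("par", "value")]
  }
  gpr_hyperparams(exp(best$par[1]), exp(best$par[2]))
}

#' Securely average per-client hyper-parameters
#'
#' Computes the componentwise mean of client hyper-parameters through
#' [secure_sum()], so the aggregator sees only masked contributions. An
#' optional sample-size-weighted mean is available via `weights`.
#'
#' @param per_client Named list (client -> [gpr_hyperparams()]).
#' @param codec An [fp_codec()].
#' @param pairwise_seeds Pairwise mask seeds (see [derive_zero_sum_masks()]);
#'   derived from `seed` when `NULL`.
#' @param round_id Aggregation round (advances the mask streams).
#' @param weights Optional positive per-client weights (e.g. sample sizes).
#' @param seed Seed used to derive `pairwise_seeds` when absent.
#' @return A [gpr_hyperparams()] holding the (weighted) mean.
#' @export
aggregate_hyperparams <- function(per_client, codec = fp_codec(),
                                  pairwise_seeds = NULL, round_id = 0,
                                  weights = NULL, seed = 1) {
  if (!length(per_client)) stop_protocol("aggregate_hyperparams: empty client map")
  ids <- names(per_client) %||% as.character(seq_along(per_client))
  names(per_client) <- ids
  if (is.null(pairwise_seeds)) pairwise_seeds <- derive_pairwise_seeds(ids, seed)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(ids)), ids)
  vals <- lapply(ids, function(p) {
    weights[[p]] * c(per_client[[p]]$sigma_k2, per_client[[p]]$sigma_eps2)
  })
  names(vals) <- ids
  tot <- secure_sum(vals, codec, round_id = round_id, pairwise_seeds = pairwise_seeds)
  wsum <- sum(unlist(weights[ids]))
  gpr_hyperparams(tot[1] / wsum, tot[2] / wsum)
}

#' Derive pairwise mask seeds for a set of parties
#'
#' Simulation stand-in for a pairwise key exchange: expands a run seed into
#' one deterministic seed per unordered party pair.
#'
#' @param party_ids Character vector of party identifiers.
#' @param seed Run seed.
#' @return Named list of pair seeds keyed `"<p>|<q>"`.
#' @export
derive_pairwise_seeds <- function(party_ids, seed) {
  out <- list()
  for (i in seq_along(party_ids)) {
    for (j in seq_along(party_ids)) {
      if (i >= j) next
      key <- pair_key(party_ids[i], party_ids[j])
      out[[key]] <- mix_seed(seed, "pairseed", key)
    }
  }
  out
}

#' Assemble GPR kernel blocks from Gram matrices
#'
#' `K = sigma_k2 * G_ss + sigma_eps2 * I`, `K* = sigma_k2 * G_ts`
#' (target x source), `K** = sigma_k2 * G_tt` (noise-free latent variance).
#'
#' @param gram_ss Source-source Gram matrix (n_S x n_S, symmetric).
#' @param gram_ts Target-source Gram matrix (n_t x n_S).
#' @param gram_tt Target-target Gram matrix (n_t x n_t, symmetric).
#' @param hyper A [gpr_hyperparams()].
#' @return List with elements `K`, `K_star`, `K_star_star`.
#' @export
assemble_kernel_matrices <- function(gram_ss, gram_ts, gram_tt, hyper) {
  check_sym <- function(G, label) {
    tol <- 1e-8 * max(1, max(abs(G)))
    if (max(abs(G - t(G))) > tol) {
      stop_protocol("assemble_kernel_matrices: ", label, " is not symmetric")
    }
  }
  check_sym(gram_ss, "gram_ss")
  check_sym(gram_tt, "gram_tt")
  if (ncol(gram_ts) != nrow(gram_ss) || nrow(gram_ts) != nrow(gram_tt)) {
    stop_protocol("assemble_kernel_matrices: Gram blocks are not conformable")
  }
  list(K = hyper$sigma_k2 * gram_ss + diag(hyper$sigma_eps2, nrow(gram_ss)),
       K_star = hyper$sigma_k2 * gram_ts,
       K_star_star = hyper$sigma_k2 * gram_tt)
}

#' Masked predicted-mean protocol
#'
#' The aggregator computes `A = K* K^-1`, masks it as `C A`, and sends each
#' source client its column block; clients multiply by their private feature
#' column and send the n_t-vectors to the target, which sums them and
#' removes the mask with `C^-1`. In exact arithmetic the result equals
#' `K* K^-1 X_f^S`, while no party ever observes another party's feature
#' column and source clients see only masked rows.
#'
#' @param K_star,K Kernel blocks from [assemble_kernel_matrices()].
#' @param feature_columns Named list (client -> numeric vector): each source
#'   client's private column for the modeled feature.
#' @param row_mask A [make_row_mask()] of dimension `n_t`.
#' @param client_row_slices Named list (client -> integer indices) giving each
#'   client's rows inside the pooled source ordering; must partition
#'   `1..n_S` in client order.
#' @return Numeric vector of length `n_t`: the predictive mean.
#' @export
predicted_mean_protocol <- function(K_star, K, feature_columns, row_mask,
                                    client_row_slices) {
  n_S <- nrow(K)
  ids <- names(feature_columns)
  if (!identical(sort(unlist(client_row_slices[ids], use.names = FALSE)), seq_len(n_S))) {
    stop_protocol("predicted_mean_protocol: row slices do not partition 1..n_S")
  }
  for (p in ids) {
    if (length(feature_columns[[p]]) != length(client_row_slices[[p]])) {
      stop_protocol("predicted_mean_protocol: feature column length mismatch for ", p)
    }
  }
  R <- chol_jitter(K)
  A <- t(backsolve(R, forwardsolve(t(R), t(K_star))))  # K* K^-1, n_t x n_S
  B_masked <- apply_row_mask(row_mask, A)
  v <- 0
  for (p in ids) {
    v <- v + B_masked[, client_row_slices[[p]], drop = FALSE] %*% feature_columns[[p]]
  }
  unmask_vector(row_mask, v)
}

#' Predictive variance of the feature model
#'
#' Diagonal of the Schur complement `K** - K* K^-1 K*'`, clipped at zero.
#' Only this diagonal is released to the target role.
#'
#' @inheritParams predicted_mean_protocol
#' @param K_star_star Target-target kernel block.
#' @return Numeric vector of length `n_t` of nonnegative variances.
#' @export
predicted_variance <- function(K_star_star, K_star, K) {
  R <- chol_jitter(K)
  TT <- backsolve(R, forwardsolve(t(R), t(K_star)))  # K^-1 K*', n_S x n_t
  v <- diag(K_star_star) - colSums(t(K_star) * TT)
  if (min(v) < -1e-6) {
    stop_numerical("predicted_variance: strongly negative variance ", min(v))
  }
  pmax(v, 0)
}

#' Centralized GPR closed form (reference path)
#'
#' Direct pooled evaluation of the predictive distribution, used as the
#' equivalence oracle for the masked protocols and as the non-federated
#' reference pipeline.
#'
#' @param X_source Pooled source matrix with the modeled feature removed.
#' @param x_f Pooled source vector of the modeled feature.
#' @param X_target Target matrix with the modeled feature removed.
#' @param hyper A [gpr_hyperparams()].
#' @return List with `mean` and `variance` vectors of length `n_t`.
#' @export
centralized_gpr_oracle <- function(X_source, x_f, X_target, hyper) {
  X_source <- as.matrix(X_source); X_target <- as.matrix(X_target)
  km <- assemble_kernel_matrices(tcrossprod(X_source),
                                 X_target %*% t(X_source),
                                 tcrossprod(X_target), hyper)
  R <- chol_jitter(km$K)
  alpha <- backsolve(R, forwardsolve(t(R), x_f))
  list(mean = drop(km$K_star %*% alpha),
       variance = predicted_variance(km$K_star_star, km$K_star, km$K))
}

#' Train all per-feature models federatively (phase 1)
#'
#' For every modeled feature: optimize hyper-parameters on each source
#' client, securely average them, compute all kernel blocks from
#' randomized-encoded data, and run the masked predicted-mean protocol plus
#' the predictive-variance computation. The target client ends up with one
#' predictive distribution per feature; the aggregator sees only encoded
#' matrices and masked intermediates.
#'
#' @param sources List of labeled [domain_dataset()] source clients.
#' @param target Unlabeled target [domain_dataset()].
#' @param features Integer subset of features to model (default all).
#' @param d Encoding dimension for the mask bundle (default `(P - 1) + 10`).
#' @param seed Run seed driving all mask material.
#' @param codec An [fp_codec()] for secure aggregation.
#' @param hyper_bounds Box bounds for the hyper-parameter search.
#' @param weighted_hyper_mean If `TRUE`, average hyper-parameters weighted by
#'   client sample sizes instead of uniformly.
#' @param fixed_hyper Optional [gpr_hyperparams()] to use for every feature,
#'   skipping local optimization (protocol-equivalence studies).
#' @param transcript Optional transcript environment (see
#'   [new_transcript()]); cross-party messages are recorded when supplied.
#' @return List of class `feature_model_set`: one record per feature with
#'   fields `feature`, `hyper`, `mean`, `variance`.
#' @export
federated_feature_models <- function(sources, target, features = NULL,
                                     d = NULL, seed = 1, codec = fp_codec(),
                                     hyper_bounds = c(1e-6, 1e6),
                                     weighted_hyper_mean = FALSE,
                                     fixed_hyper = NULL, transcript = NULL) {
  sources <- sources[order(vapply(sources, function(s) s$domain_id, character(1)))]
  ids <- vapply(sources, function(s) s$domain_id, character(1))
  names(sources) <- ids
  P <- ncol(target$X)
  stopifnot(all(vapply(sources, function(s) ncol(s$X), integer(1)) == P))
  features <- features %||% seq_len(P)
  if (is.null(d)) d <- (P - 1L) + 10L
  n_t <- nrow(target$X)
  n_i <- vapply(sources, function(s) nrow(s$X), integer(1))
  n_S <- sum(n_i)
  slice_end <- cumsum(n_i)
  slices <- stats::setNames(lapply(seq_along(ids), function(i) {
    (slice_end[i] - n_i[i] + 1L):slice_end[i]
  }), ids)

  bundle <- generate_shared_mask(mix_seed(seed, "bundle"), P - 1L, d,
                                 party_ids = c(ids, "target"))
  pair_seeds <- derive_pairwise_seeds(ids, mix_seed(seed, "hyperagg"))

  results <- vector("list", length(features))
  for (fi in seq_along(features)) {
    f <- features[fi]
    if (is.null(fixed_hyper)) {
      per_client <- lapply(sources, function(s) {
        optimize_local_hyperparams(s$X[, -f, drop = FALSE], s$X[, f],
                                   bounds = hyper_bounds)
      })
      if (!is.null(transcript)) {
        for (p in ids) record_message(transcript, f, p, "aggregator",
                                      "masked_hyperparams", per_client[[p]],
                                      masked = TRUE)
      }
      hyper <- aggregate_hyperparams(per_client, codec, pairwise_seeds = pair_seeds,
                                     round_id = f,
                                     weights = if (weighted_hyper_mean) n_i else NULL)
    } else {
      hyper <- fixed_hyper
    }

    enc <- lapply(ids, function(p) {
      encode_matrix(sources[[p]]$X[, -f, drop = FALSE], bundle, p)
    })
    names(enc) <- ids
    enc_t <- encode_matrix(target$X[, -f, drop = FALSE], bundle, "target")
    if (!is.null(transcript)) {
      for (p in ids) record_message(transcript, f, p, "aggregator",
                                    "encoded_matrix", enc[[p]]$values)
      record_message(transcript, f, "target", "aggregator", "encoded_matrix",
                     enc_t$values)
    }

    # aggregator: pairwise Gram blocks from encoded data only
    gram_ss <- matrix(0, n_S, n_S)
    for (p in ids) {
      for (q in ids) {
        gram_ss[slices[[p]], slices[[q]]] <- gram_from_encoded(enc[[p]], enc[[q]])
      }
    }
    gram_ss <- (gram_ss + t(gram_ss)) / 2
    gram_ts <- do.call(cbind, lapply(ids, function(q) gram_from_encoded(enc_t, enc[[q]])))
    gram_tt <- gram_from_encoded(enc_t, enc_t)
    gram_tt <- (gram_tt + t(gram_tt)) / 2
    km <- assemble_kernel_matrices(gram_ss, gram_ts, gram_tt, hyper)

    rmask <- make_row_mask(n_t, mix_seed(seed, "rowmask", f))
    cols <- lapply(sources, function(s) s$X[, f])
    mu <- predicted_mean_protocol(km$K_star, km$K, cols, rmask, slices)
    vr <- predicted_variance(km$K_star_star, km$K_star, km$K)
    if (!is.null(transcript)) {
      R <- chol_jitter(km$K)
      A <- t(backsolve(R, forwardsolve(t(R), t(km$K_star))))
      Bm <- apply_row_mask(rmask, A)
      for (p in ids) record_message(transcript, f, "aggregator", p,
                                    "masked_mean_block",
                                    Bm[, slices[[p]], drop = FALSE], masked = TRUE)
      record_message(transcript, f, "aggregator", "target", "row_mask_inverse",
                     rmask$C_inv, masked = TRUE)
      for (p in ids) record_message(transcript, f, p, "target",
                                    "masked_mean_contribution",
                                    Bm[, slices[[p]], drop = FALSE] %*% cols[[p]],
                                    masked = TRUE)
      record_message(transcript, f, "aggregator", "target",
                     "predictive_variance", vr)
    }

    results[[fi]] <- structure(list(feature = f, hyper = hyper, mean = mu,
                                    variance = vr),
                               class = "feature_model_result")
  }
  structure(results, class = "feature_model_set",
            features = features, n_t = n_t)
}

#' Centralized per-feature models (reference path)
#'
#' Same mathematics as [federated_feature_models()] evaluated on pooled
#' plaintext data: hyper-parameters are optimized per client and averaged
#' (identically to the secure path, at codec resolution), then the pooled
#' closed form is evaluated directly.
#'
#' @inheritParams federated_feature_models
#' @return A `feature_model_set`.
#' @export
centralized_feature_models <- function(sources, target, features = NULL,
                                       codec = fp_codec(),
                                       hyper_bounds = c(1e-6, 1e6),
                                       weighted_hyper_mean = FALSE,
                                       fixed_hyper = NULL) {
  sources <- sources[order(vapply(sources, function(s) s$domain_id, character(1)))]
  X_pool <- do.call(rbind, lapply(sources, function(s) s$X))
  n_i <- vapply(sources, function(s) nrow(s$X), integer(1))
  P <- ncol(target$X)
  features <- features %||% seq_len(P)
  results <- lapply(seq_along(features), function(fi) {
    f <- features[fi]
    if (is.null(fixed_hyper)) {
      per_client <- lapply(sources, function(s) {
        optimize_local_hyperparams(s$X[, -f, drop = FALSE], s$X[, f],
                                   bounds = hyper_bounds)
      })
      names(per_client) <- vapply(sources, function(s) s$domain_id, character(1))
      hyper <- aggregate_hyperparams(per_client, codec, round_id = f,
                                     weights = if (weighted_hyper_mean) n_i else NULL)
    } else {
      hyper <- fixed_hyper
    }
    orc <- centralized_gpr_oracle(X_pool[, -f, drop = FALSE], X_pool[, f],
                                  target$X[, -f, drop = FALSE], hyper)
    structure(list(feature = f, hyper = hyper, mean = orc$mean,
                   variance = orc$variance),
              class = "feature_model_result")
  })
  structure(results, class = "feature_model_set",
            features = features, n_t = nrow(target$X))
}

#' Serialize / load a feature-model set as JSON lines
#'
#' One JSON record per feature, for resumable runs.
#'
#' @param models A `feature_model_set`.
#' @param path File path.
#' @export
write_feature_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    writeLines(jsonlite::toJSON(list(feature = m$feature,
                                     sigma_k2 = m$hyper$sigma_k2,
                                     sigma_eps2 = m$hyper$sigma_eps2,
                                     mean = m$mean, variance = m$variance),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_feature_models
#' @export
read_feature_models <- function(path) {
  lines <- readLines(path)
  results <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    structure(list(feature = rec$feature,
                   hyper = gpr_hyperparams(rec$sigma_k2, rec$sigma_eps2),
                   mean = rec$mean, variance = rec$variance),
              class = "feature_model_result")
  })
  structure(results, class = "feature_model_set",
            features = vapply(results, function(m) m$feature, numeric(1)),
            n_t = length(results[[1]]$mean))
}
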