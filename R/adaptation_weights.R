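# Confidence scores and elastic-net penalty weights: each feature model's
# predictive distribution on the target samples is turned into a two-sided
# tail probability, averaged per target group (tissue), and mapped to a
# penalty weight (1 - c)^k. Features whose dependency structure transfers
# poorly get low confidence and hence a high penalty.

#' Two-sided tail confidence of an observed value
#'
#' `2 * Phi(-|x_obs - mu| / sigma)`: the probability of observing a value at
#' least as extreme as `x_obs` under the predictive normal `N(mu, sigma^2)`.
#' Equals 1 at `x_obs == mu`, decreases strictly in the standardized
#' deviation, and lies in `[0, 1]`. The standard deviation is floored at
#' 1e-12 for degenerate (zero-variance) predictions, so an exact match still
#' scores 1 while any deviation from a degenerate prediction scores 0.
#'
#' @param x_obs Observed value(s).
#' @param mu Predictive mean(s).
#' @param sigma Predictive standard deviation(s), `>= 0`.
#' @return Confidence value(s) in `[0, 1]`.
#' @export
confidence_score <- function(x_obs, mu, sigma) {
  if (any(!is.finite(x_obs)) || any(!is.finite(mu)) || any(!is.finite(sigma))) {
    stop_config("confidence_score: inputs must be finite")
  }
  if (any(sigma < 0)) stop_config("confidence_score: sigma must be >= 0")
  z <- abs(x_obs - mu) / pmax(sigma, 1e-12)
  2 * stats::pnorm(-z)
}

#' Average per-sample confidences within groups
#'
#' @param per_sample Numeric vector of per-sample confidences.
#' @param group_labels Group (tissue) label per sample; use a single constant
#'   label to average over the whole target domain.
#' @return Named numeric vector (group -> mean confidence).
#' @export
aggregate_confidence <- function(per_sample, group_labels) {
  if (!length(per_sample)) stop_config("aggregate_confidence: empty input")
  if (length(group_labels) != length(per_sample)) {
    stop_config("aggregate_confidence: label length mismatch")
  }
  groups <- unique(as.character(group_labels))
  out <- vapply(groups, function(g) mean(per_sample[group_labels == g]), numeric(1))
  if (anyNA(out)) stop_config("aggregate_confidence: empty group")
  out
}

#' Confidence vector for one target group
#'
#' @param group Group identifier.
#' @param values Length-`P` confidences in `[0, 1]`.
#' @return An object of class `confidence_vector`.
#' @export
confidence_vector <- function(group, values) {
  values <- as.numeric(values)
  if (any(values < 0 | values > 1)) {
    stop_config("confidence_vector: values must lie in [0, 1]")
  }
  structure(list(group = as.character(group), values = values),
            class = "confidence_vector")
}

#' Map confidences to elastic-net penalty weights
#'
#' `w_f = (1 - c_f)^k`: features the source-trained models explain well in
#' the target domain (high confidence) are penalized lightly; discrepant
#' features heavily. Larger `k` sharpens the contrast.
#'
#' @param conf A [confidence_vector()].
#' @param k Positive weighting exponent (default 3).
#' @return An object of class `feature_weight_vector` with fields `group`,
#'   `values`, `k`.
#' @export
compute_feature_weights <- function(conf, k = 3) {
  stopifnot(inherits(conf, "confidence_vector"))
  if (!is.finite(k) || k <= 0) stop_config("compute_feature_weights: k must be > 0")
  structure(list(group = conf$group, values = (1 - conf$values)^k, k = k),
            class = "feature_weight_vector")
}

#' Per-group confidences and weights from trained feature models (phase 2)
#'
#' For every feature model, scores each target sample's observed value
#' against the predictive distribution, averages confidences within each
#' target group, and converts them to penalty weights.
#'
#' @param models A `feature_model_set` (see [federated_feature_models()]).
#' @param target The target [domain_dataset()] (group tags required unless
#'   `groups` is supplied).
#' @param k Weighting exponent passed to [compute_feature_weights()].
#' @param groups Optional explicit per-sample group labels.
#' @return Named list (group -> list with `confidence` and `weights`),
#'   each holding vectors indexed by the modeled features.
#' @export
compute_group_weights <- function(models, target, k = 3, groups = NULL) {
  groups <- groups %||% target$groups %||% rep("all", nrow(target$X))
  feats <- vapply(models, function(m) m$feature, numeric(1))
  group_names <- unique(groups)
  conf <- matrix(NA_real_, length(group_names), length(feats),
                 dimnames = list(group_names, paste0("f", feats)))
  for (i in seq_along(models)) {
    m <- models[[i]]
    cs <- confidence_score(target$X[, m$feature], m$mean, sqrt(m$variance))
    conf[, i] <- aggregate_confidence(cs, groups)[group_names]
  }
  out <- lapply(group_names, function(g) {
    cv <- confidence_vector(g, conf[g, ])
    wv <- compute_feature_weights(cv, k)
    list(confidence = stats::setNames(cv$values, colnames(conf)),
         weights = stats::setNames(wv$values, colnames(conf)), k = k)
  })
  stats::setNames(out, group_names)
}

#' Write per-group weights as CSV
#'
#' One file per call: columns `group`, `feature`, `confidence`, `weight`.
#'
#' @param group_weights Output of [compute_group_weights()].
#' @param path File path.
#' @export
write_group_weights <- function(group_weights, path) {
  rows <- do.call(rbind, lapply(names(group_weights), function(g) {
    gw <- group_weights[[g]]
    data.frame(group = g, feature = names(gw$weights),
               confidence = unname(gw$confidence), weight = unname(gw$weights),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
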