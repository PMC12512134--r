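# Orchestration of the three roles (source clients, target client,
# aggregator) in one process: the four-phase pipeline, a protocol transcript
# of every cross-party message, and an information-flow audit over it.

#' Protocol transcript
#'
#' Append-only record of cross-party messages. Each entry stores the round,
#' sender and receiver roles, a payload tag, the payload shape, an MD5
#' digest of the payload, and whether the payload is masked. Raw payloads
#' are never stored.
#'
#' @return A transcript environment.
#' @export
new_transcript <- function() {
  env <- new.env(parent = emptyenv())
  env$messages <- list()
  class(env) <- "protocol_transcript"
  env
}

#' @rdname new_transcript
#' @param transcript A transcript environment.
#' @param round Integer round / feature counter.
#' @param sender,receiver Role identifiers.
#' @param tag Payload tag (e.g. `"encoded_matrix"`).
#' @param payload The payload object (digested, not stored).
#' @param masked Whether the payload is masked/encoded material.
#' @export
record_message <- function(transcript, round, sender, receiver, tag, payload,
                           masked = FALSE) {
  stopifnot(inherits(transcript, "protocol_transcript"))
  transcript$messages[[length(transcript$messages) + 1L]] <-
    list(round = round, sender = sender, receiver = receiver, tag = tag,
         shape = paste(dim(payload) %||% length(payload), collapse = "x"),
         digest = payload_digest(payload), masked = masked)
  invisible(transcript)
}

#' @rdname new_transcript
#' @export
transcript_to_frame <- function(transcript) {
  msgs <- transcript$messages
  if (!length(msgs)) {
    return(data.frame(round = integer(), sender = character(),
                      receiver = character(), tag = character(),
                      shape = character(), digest = character(),
                      masked = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(msgs, function(m) {
    data.frame(round = m$round, sender = m$sender, receiver = m$receiver,
               tag = m$tag, shape = m$shape, digest = m$digest,
               masked = m$masked, stringsAsFactors = FALSE)
  }))
}

#' Digests of every private payload in a run
#'
#' Raw data matrices, label vectors, and every single feature column of
#' every source client, plus the target's raw matrix; appearing in any
#' cross-party message, these digests constitute a privacy violation.
#'
#' @param sources List of source [domain_dataset()]s.
#' @param target Target [domain_dataset()] (optional).
#' @return Character vector of MD5 digests.
#' @export
collect_private_digests <- function(sources, target = NULL) {
  digs <- character(0)
  for (s in sources) {
    digs <- c(digs, payload_digest(s$X), payload_digest(s$y))
    for (j in seq_len(ncol(s$X))) digs <- c(digs, payload_digest(s$X[, j]))
  }
  if (!is.null(target)) digs <- c(digs, payload_digest(target$X))
  unique(digs)
}

#' Audit a protocol transcript for information-flow violations
#'
#' PASS iff no cross-party message carries a payload whose digest matches a
#' private payload, and no mask-material digest reaches the aggregator.
#' Masked/encoded payloads are permitted and are reported as such.
#'
#' @param transcript A [new_transcript()] environment (or its data frame).
#' @param private_digests Digests from [collect_private_digests()].
#' @param mask_digests Optional digests of mask seeds/material that must
#'   never reach the aggregator.
#' @return List with `pass` (logical), `violations` (data frame),
#'   `n_messages`, and `n_masked`.
#' @export
audit_transcript <- function(transcript, private_digests,
                             mask_digests = character(0)) {
  df <- if (inherits(transcript, "protocol_transcript")) {
    transcript_to_frame(transcript)
  } else {
    as.data.frame(transcript)
  }
  leak <- df$digest %in% private_digests
  mask_to_agg <- df$receiver == "aggregator" &
    (df$digest %in% mask_digests | df$tag == "mask_seed")
  violations <- df[leak | mask_to_agg, , drop = FALSE]
  if (nrow(violations)) {
    violations$rule <- ifelse(violations$digest %in% private_digests,
                              "raw_private_payload", "mask_material_to_aggregator")
  } else {
    violations$rule <- character(0)
  }
  list(pass = nrow(violations) == 0L, violations = violations,
       n_messages = nrow(df), n_masked = sum(df$masked))
}

#' Run configuration
#'
#' Validated bundle of all parameters that, together with the input files,
#' fully determine a run.
#'
#' @param n_sources Number of source clients.
#' @param proportions Client share vector or `"uniform"`.
#' @param k Confidence-weighting exponent (default 3).
#' @param alpha Elastic-net mixing parameter (default 0.8).
#' @param lambda_mode `"prior_knowledge"` (similarity-based prediction) or
#'   `"cv"` (source-side cross-validation).
#' @param grid Lambda grid (default [lambda_grid()]).
#' @param schedule FedAvg [training_schedule()].
#' @param d_offset Encoding dimension exceeds the feature count by this much.
#' @param frac_bits Fixed-point fractional bits for secure aggregation.
#' @param seed Master run seed.
#' @param feature_subset Optional integer subset of features to model.
#' @param fit_groups Target groups whose labels anchor the lambda selection
#'   (default: the three alphabetically first groups, mirroring the
#'   three-tissue fit combinations of the evaluation protocol).
#' @param cv_folds Folds for `lambda_mode = "cv"`.
#' @param adult_age Adult-age threshold of the age transform.
#' @param record_transcript Whether to record the protocol transcript.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_sources = 4, proportions = "uniform", k = 3,
                       alpha = 0.8, lambda_mode = c("prior_knowledge", "cv"),
                       grid = lambda_grid(), schedule = training_schedule(),
                       d_offset = 10, frac_bits = 32, seed = 1,
                       feature_subset = NULL, fit_groups = NULL, cv_folds = 5,
                       adult_age = 20, record_transcript = TRUE) {
  lambda_mode <- match.arg(lambda_mode)
  if (n_sources < 1) stop_config("run_config: n_sources must be >= 1")
  if (k <= 0) stop_config("run_config: k must be > 0")
  if (alpha < 0 || alpha > 1) stop_config("run_config: alpha must be in [0, 1]")
  if (!length(grid) || any(grid <= 0)) stop_config("run_config: invalid lambda grid")
  structure(list(n_sources = as.integer(n_sources), proportions = proportions,
                 k = k, alpha = alpha, lambda_mode = lambda_mode,
                 grid = sort(grid), schedule = schedule,
                 d_offset = as.integer(d_offset),
                 frac_bits = as.integer(frac_bits), seed = as.integer(seed),
                 feature_subset = feature_subset, fit_groups = fit_groups,
                 cv_folds = cv_folds, adult_age = adult_age,
                 record_transcript = isTRUE(record_transcript)),
            class = "run_config")
}

pick_fit_groups <- function(config, target) {
  groups <- sort(unique(target$groups))
  fit_groups <- config$fit_groups %||% groups[seq_len(min(3L, length(groups)))]
  missing <- setdiff(fit_groups, groups)
  if (length(missing)) {
    stop_config("fit_groups not present in target: ", paste(missing, collapse = ", "))
  }
  fit_groups
}

subset_features <- function(data, features) {
  domain_dataset(data$X[, features, drop = FALSE], y = data$y,
                 groups = data$groups, domain_id = data$domain_id)
}

# Shared phases 2-4, used by both the federated and the centralized path.
# `train_fun(weights, lam, group)` must return a wen_model; feature-model
# results arrive via `models`.
run_adaptation_phases <- function(config, models, sources, target, similarity,
                                  fit_labels, truth, train_fun) {
  features <- attr(models, "features")
  groups <- sort(unique(target$groups))
  gw <- compute_group_weights(models, target, k = config$k)

  sources_f <- lapply(sources, subset_features, features = features)
  target_f <- subset_features(target, features)
  grid <- config$grid
  grange <- range(grid)

  fit_groups <- pick_fit_groups(config, target)
  lambda_rows <- list()
  if (config$lambda_mode == "prior_knowledge") {
    if (is.null(similarity)) {
      stop_config("prior-knowledge lambda mode requires a similarity table")
    }
    if (is.null(fit_labels)) {
      stop_config("prior-knowledge lambda mode requires labels for the fit groups")
    }
    sim <- stats::setNames(similarity$similarity, similarity$group)
    if (!all(groups %in% names(sim))) {
      stop_config("similarity table missing groups: ",
                  paste(setdiff(groups, names(sim)), collapse = ", "))
    }
    sel <- list()
    for (g in fit_groups) {
      idx <- target$groups == g
      mods <- stats::setNames(lapply(grid, function(lam) {
        train_fun(gw[[g]]$weights, lam, g)
      }), as.character(grid))
      sel[[g]] <- select_best_lambda(mods, target_f$X[idx, , drop = FALSE],
                                     fit_labels[idx], config$adult_age)
    }
    simlam <- fit_similarity_lambda_model(
      data.frame(similarity = unname(sim[fit_groups]),
                 lambda = unlist(sel[fit_groups])))
    lam_by_group <- stats::setNames(lapply(groups, function(g) {
      if (g %in% fit_groups) {
        list(lambda = sel[[g]], how = "selected")
      } else {
        list(lambda = predict_lambda(simlam, sim[[g]], grange), how = "predicted")
      }
    }), groups)
  } else {
    simlam <- NULL
    lam_by_group <- stats::setNames(lapply(groups, function(g) {
      list(lambda = cv_select_lambda(sources_f, gw[[g]]$weights, grid,
                                     folds = config$cv_folds,
                                     alpha = config$alpha,
                                     adult_age = config$adult_age,
                                     seed = mix_seed(config$seed, "cv", g)),
           how = "cv")
    }), groups)
  }

  # phase 4: one final model per target group, trained on all source data
  # with that group's weights and lambda
  final_models <- list()
  predictions <- numeric(nrow(target$X))
  for (g in groups) {
    lam_g <- lam_by_group[[g]]$lambda
    m <- train_fun(gw[[g]]$weights, lam_g, g)
    final_models[[g]] <- m
    idx <- target$groups == g
    predictions[idx] <- predict(m, target_f$X[idx, , drop = FALSE])
    lambda_rows[[g]] <- data.frame(group = g, lambda = unname(lam_g),
                                   how = lam_by_group[[g]]$how,
                                   stringsAsFactors = FALSE)
  }

  mae <- NULL
  if (!is.null(truth)) {
    y_t <- truth$y_target
    per_group <- vapply(groups, function(g) {
      idx <- target$groups == g
      mae_years(predictions[idx], y_t[idx], config$adult_age)
    }, numeric(1))
    eval_groups <- setdiff(groups, fit_groups)
    mae <- list(per_group = per_group,
                overall = mae_years(predictions, y_t, config$adult_age),
                eval_groups = if (length(eval_groups)) {
                  idx <- target$groups %in% eval_groups
                  mae_years(predictions[idx], y_t[idx], config$adult_age)
                } else {
                  NA_real_
                })
  }

  list(weights = gw, lambda_report = do.call(rbind, lambda_rows),
       similarity_model = simlam, wen_models = final_models,
       predictions = predictions,
       predictions_years = horvath_inverse(
         clip_to_transform_range(predictions, config$adult_age),
         config$adult_age),
       fit_groups = fit_groups, mae = mae)
}

#' Run the full federated pipeline
#'
#' Executes the four phases against simulated roles: (1) federated
#' per-feature GPR models through the masked protocols, (2) per-group
#' confidences and penalty weights on the target, (3) lambda selection
#' (similarity-predicted or CV), (4) final per-group weighted elastic nets
#' trained by FedAvg, with target predictions. Every cross-party message is
#' recorded in the transcript and audited.
#'
#' @param config A [run_config()].
#' @param inputs List with `sources` (list of labeled [domain_dataset()]s),
#'   `target` (unlabeled, with groups), `similarity` (data frame
#'   `group`/`similarity`; required for the prior-knowledge mode),
#'   `fit_labels` (full-length target label vector, used only on fit
#'   groups), and optional `truth` (ground-truth record for MAE reporting).
#' @return A run report: feature models, weights, lambda report, per-group
#'   models, predictions (transformed and years), MAE summaries (when truth
#'   is supplied), the protocol transcript, the audit result, and per-phase
#'   timings.
#' @export
run_freda <- function(config, inputs) {
  stopifnot(inherits(config, "run_config"))
  sources <- inputs$sources
  target <- inputs$target
  if (!length(sources) || is.null(target)) {
    stop_config("run_freda: inputs must contain sources and target")
  }
  transcript <- if (config$record_transcript) new_transcript() else NULL
  codec <- fp_codec(config$frac_bits)
  timings <- c()
  tic <- function() Sys.time()
  t0 <- tic()

  models <- federated_feature_models(
    sources, target, features = config$feature_subset,
    d = ncol(target$X) - 1L + config$d_offset,
    seed = config$seed, codec = codec, transcript = transcript)
  timings["phase1_feature_models"] <- as.numeric(tic() - t0, units = "secs")

  t0 <- tic()
  train_fun <- function(weights, lam, group) {
    train_federated_wen(sources_features(sources, attr(models, "features")),
                        weights, lam, config$alpha, config$schedule,
                        codec = codec,
                        seed = mix_seed(config$seed, "wen", group, lam),
                        group = group)
  }
  phases <- run_adaptation_phases(config, models, sources, target,
                                  inputs$similarity, inputs$fit_labels,
                                  inputs$truth, train_fun)
  timings["phases2_4_adaptation"] <- as.numeric(tic() - t0, units = "secs")

  audit <- NULL
  if (!is.null(transcript)) {
    audit <- audit_transcript(transcript,
                              collect_private_digests(sources, target),
                              mask_digests = mask_material_digests(config))
  }
  c(list(feature_models = models, transcript = transcript, audit = audit,
         config = config, timings = timings,
         digest = payload_digest(list(phases$predictions,
                                      phases$lambda_report$lambda,
                                      lapply(phases$wen_models, function(m) m$beta)))),
    phases)
}

sources_features <- function(sources, features) {
  lapply(sources, subset_features, features = features)
}

mask_material_digests <- function(config) {
  c(payload_digest(mix_seed(config$seed, "bundle")),
    payload_digest(config$seed))
}

#' Run the centralized (non-federated) reference pipeline
#'
#' Identical mathematics on pooled plaintext data: pooled closed-form GPR
#' feature models, the same weight computation, and the same gradient
#' training driven as a single-client federation. Serves as the
#' non-federated reference path and as the equivalence oracle for
#' [run_freda()].
#'
#' @inheritParams run_freda
#' @return A run report (no transcript or audit).
#' @export
run_centralized <- function(config, inputs) {
  stopifnot(inherits(config, "run_config"))
  sources <- inputs$sources
  target <- inputs$target
  codec <- fp_codec(config$frac_bits)
  t0 <- Sys.time()
  models <- centralized_feature_models(sources, target,
                                       features = config$feature_subset,
                                       codec = codec)
  timings <- c(phase1_feature_models = as.numeric(Sys.time() - t0, units = "secs"))
  pooled <- domain_dataset(do.call(rbind, lapply(sources, function(s) s$X)),
                           y = unlist(lapply(sources, function(s) s$y),
                                      use.names = FALSE),
                           domain_id = "source_pooled")
  t0 <- Sys.time()
  train_fun <- function(weights, lam, group) {
    train_federated_wen(list(subset_features(pooled, attr(models, "features"))),
                        weights, lam, config$alpha, config$schedule,
                        codec = codec,
                        seed = mix_seed(config$seed, "wen", group, lam),
                        group = group)
  }
  phases <- run_adaptation_phases(config, models, sources, target,
                                  inputs$similarity, inputs$fit_labels,
                                  inputs$truth, train_fun)
  timings["phases2_4_adaptation"] <- as.numeric(Sys.time() - t0, units = "secs")
  c(list(feature_models = models, transcript = NULL, audit = NULL,
         config = config, timings = timings,
         digest = payload_digest(list(phases$predictions,
                                      phases$lambda_report$lambda,
                                      lapply(phases$wen_models, function(m) m$beta)))),
    phases)
}

#' Write a run report to a directory
#'
#' Models and the lambda report as JSON, weights and predictions as CSV,
#' the transcript as JSON lines, and the audit as JSON.
#'
#' @param report A [run_freda()] report.
#' @param dir Output directory (created if needed).
#' @param target Optional target dataset (adds groups to the predictions CSV).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir, target = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    lapply(report$wen_models, function(m) {
      list(group = m$group, beta = m$beta, intercept = m$intercept,
           lambda = m$lam, alpha = m$alpha)
    }),
    file.path(dir, "models.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$lambda_report, file.path(dir, "lambda_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_group_weights(report$weights, file.path(dir, "weights.csv"))
  preds <- data.frame(prediction = report$predictions,
                      prediction_years = report$predictions_years)
  if (!is.null(target) && !is.null(target$groups)) preds$group <- target$groups
  utils::write.csv(preds, file.path(dir, "predictions.csv"), row.names = FALSE)
  if (!is.null(report$transcript)) {
    df <- transcript_to_frame(report$transcript)
    con <- file(file.path(dir, "transcript.jsonl"), "w")
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE), con)
    }
    close(con)
  }
  if (!is.null(report$audit)) {
    jsonlite::write_json(list(pass = report$audit$pass,
                              n_messages = report$audit$n_messages,
                              n_masked = report$audit$n_masked,
                              violations = report$audit$violations),
                         file.path(dir, "audit.json"), auto_unbox = TRUE)
  }
  if (!is.null(report$mae)) {
    jsonlite::write_json(report$mae, file.path(dir, "mae.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
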