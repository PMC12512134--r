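small_cfg <- function(seed = 1, n_sources = 2, ...) {
  run_config(n_sources = n_sources, grid = lambda_grid(4, c(1e-2, 10)),
             schedule = training_schedule(15, 10, 1e-4, 1e-5),
             fit_groups = c("g1", "g2"), seed = seed, ...)
}

test_that("a full run is deterministic given config and seed", {
  sim <- tiny_sim(seed = 8)
  cfg <- small_cfg(seed = 8)
  a <- run_freda(cfg, default_inputs(sim))
  b <- run_freda(cfg, default_inputs(sim))
  expect_identical(a$digest, b$digest)
  expect_identical(a$predictions, b$predictions)
  expect_s3_class(a$wen_models$g1, "wen_model")
  expect_named(a$mae, c("per_group", "overall", "eval_groups"))
  expect_true(all(is.finite(a$predictions_years)))
  expect_equal(nrow(a$lambda_report), 3L)
  expect_true(all(a$lambda_report$lambda >= 1e-2 - 1e-12 &
                    a$lambda_report$lambda <= 10 + 1e-12))
})

test_that("a feature subset models only the requested features but keeps all regressors", {
  sim <- tiny_sim(seed = 13)
  cfg <- small_cfg(seed = 13, feature_subset = c(2L, 5L, 7L, 9L))
  rep <- run_freda(cfg, default_inputs(sim))
  expect_length(rep$weights$g1$weights, 4L)
  expect_length(rep$wen_models$g1$beta, 4L)
  expect_length(rep$predictions, nrow(sim$target$X))
  expect_true(all(is.finite(rep$predictions)))
})

test_that("the transcript audits clean and no private payload reaches any party", {
  sim <- tiny_sim(seed = 9)
  cfg <- small_cfg(seed = 9)
  rep <- run_freda(cfg, default_inputs(sim))
  expect_true(rep$audit$pass)
  expect_gt(rep$audit$n_messages, 0)
  expect_gt(rep$audit$n_masked, 0)
  df <- transcript_to_frame(rep$transcript)
  # role isolation: raw matrices, columns, and labels never cross parties
  priv <- collect_private_digests(sim$sources, sim$target)
  expect_false(any(df$digest %in% priv))
  # the aggregator never receives mask seed material
  expect_false(any(df$tag == "mask_seed"))
  agg_in <- df[df$receiver == "aggregator", ]
  expect_false(any(agg_in$digest %in% freda:::mask_material_digests(cfg)))
})

test_that("a planted raw-data leak fails the audit; masked payloads are permitted", {
  sim <- tiny_sim(seed = 10)
  priv <- collect_private_digests(sim$sources, sim$target)
  tr <- new_transcript()
  record_message(tr, 1, "source_pooled_1", "aggregator", "encoded_matrix",
                 sim$sources[[1]]$X * 2, masked = TRUE)  # benign masked payload
  expect_true(audit_transcript(tr, priv)$pass)
  record_message(tr, 2, "source_pooled_1", "aggregator", "debug_dump",
                 sim$sources[[1]]$X)                      # planted leak
  res <- audit_transcript(tr, priv)
  expect_false(res$pass)
  expect_equal(res$violations$rule, "raw_private_payload")
  # mask seed routed to the aggregator is also flagged
  tr2 <- new_transcript()
  record_message(tr2, 1, "target", "aggregator", "mask_seed", 1234)
  expect_false(audit_transcript(tr2, priv)$pass)
})

test_that("configuration validation rejects inconsistent requests", {
  expect_error(run_config(n_sources = 0), "n_sources")
  expect_error(run_config(k = 0), "k must be")
  expect_error(run_config(alpha = 1.5), "alpha")
  sim <- tiny_sim(seed = 11)
  cfg <- small_cfg(seed = 11)
  inputs <- default_inputs(sim)
  inputs$similarity <- NULL
  expect_error(run_freda(cfg, inputs), "similarity")
  inputs2 <- default_inputs(sim)
  inputs2$fit_labels <- NULL
  expect_error(run_freda(cfg, inputs2), "labels")
  cfg_bad <- small_cfg(seed = 11)
  cfg_bad$fit_groups <- c("g1", "missing")
  expect_error(run_freda(cfg_bad, default_inputs(sim)), "fit_groups")
})

test_that("run reports serialize to disk", {
  sim <- tiny_sim(seed = 12)
  rep <- run_freda(small_cfg(seed = 12), default_inputs(sim))
  dir <- tempfile("runout")
  write_run_report(rep, dir, target = sim$target)
  expect_true(all(file.exists(file.path(dir, c("models.json", "weights.csv",
                                               "predictions.csv",
                                               "lambda_report.json",
                                               "transcript.jsonl",
                                               "audit.json", "mae.json")))))
  models <- jsonlite::fromJSON(file.path(dir, "models.json"),
                               simplifyVector = FALSE)
  expect_equal(length(models), 3L)
  unlink(dir, recursive = TRUE)
})

test_that("the CLI drives simulate/run/audit/report end to end", {
  expect_equal(freda_cli_main("--help"), 0L)
  expect_equal(freda_cli_main(character(0)), 2L)
  expect_equal(freda_cli_main(c("unknown-cmd")), 2L)
  expect_equal(freda_cli_main(c("run", "--config", "does-not-exist.json")), 2L)

  dir <- tempfile("clidata")
  status <- freda_cli_main(c("simulate-data", "--out", dir, "--seed", "3",
                             "--P", "10", "--n-sources", "2",
                             "--n-source", "40", "--n-target", "18"))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(dir, "source_2.csv")))

  cfg <- list(seed = 3,
              data = list(sources = c("source_1.csv", "source_2.csv"),
                          target = "target.csv", similarity = "similarity.csv",
                          truth = "truth.json"),
              params = list(k = 3, alpha = 0.8,
                            lambda_mode = "prior_knowledge",
                            grid = list(n = 3, min = 0.01, max = 10),
                            schedule = list(global_rounds = 10,
                                            local_epochs = 5,
                                            lr_start = 1e-4, lr_end = 1e-5),
                            fit_groups = c("g1", "g2")))
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE)
  out <- file.path(dir, "run")
  expect_equal(suppressMessages(freda_cli_main(c("run", "--config", cfg_path,
                                                 "--out", out))), 0L)
  expect_true(file.exists(file.path(out, "predictions.csv")))
  expect_equal(suppressMessages(freda_cli_main(c("audit", "--run", out))), 0L)
  expect_equal(suppressMessages(freda_cli_main(c("report", "--run", out))), 0L)
  expect_equal(suppressMessages(freda_cli_main(c("audit", "--run",
                                                 file.path(dir, "nope")))), 2L)
  # the installed entry script exists and is a thin wrapper
  script <- system.file("cli", "freda.R", package = "freda")
  expect_true(nzchar(script))
  unlink(dir, recursive = TRUE)
})
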