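test_that("objective evaluates the weighted penalty exactly", {
  X <- matrix(c(1, 2), 2, 1); y <- c(1, 2)
  null <- wen_model(0, 0, lam = 1, alpha = 0.8, weights = 1)
  expect_equal(wen_objective(null, X, y), sum(y^2))
  nolam <- wen_model(0.5, 0.1, lam = 0, alpha = 0.8, weights = 1)
  r <- y - 0.5 * drop(X) - 0.1
  expect_equal(wen_objective(nolam, X, y), sum(r^2))
  # perfect fit: objective is the penalty alone, 0.8*1 + 0.1*1 = 0.9
  m <- wen_model(1, 0, lam = 1, alpha = 0.8, weights = 1)
  expect_equal(wen_objective(m, X, y), 0.9)
})

test_that("prediction is the affine map X beta + intercept", {
  m <- wen_model(c(0, 0), 2.5, lam = 1, alpha = 0.8)
  expect_equal(predict(m, matrix(rnorm(6), 3, 2)), rep(2.5, 3))
  m2 <- wen_model(c(1.5, -2), 0, lam = 1, alpha = 0.8)
  expect_equal(predict(m2, diag(2)), c(1.5, -2))
  X <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  expect_equal(predict(wen_model(c(2, -1), 0.5, 1, 0.8), X),
               c(2 * 1 - 4 + 0.5, 2 * 2 - 5 + 0.5, 2 * 3 - 6 + 0.5))
})

test_that("a local slice leaves a stationary point unchanged and shrinks under huge lambda", {
  set.seed(7)
  X <- matrix(rnorm(40 * 3), 40, 3); y <- drop(X %*% c(1, -2, 0.5)) + rnorm(40)
  ols <- lm.fit(cbind(1, X), y)$coefficients
  m <- wen_model(ols[-1], ols[1], lam = 0, alpha = 0.8, weights = rep(0, 3))
  out <- local_train(m, X, y, epochs = 5, lr = 1e-3)
  expect_equal(out$beta, m$beta, tolerance = 1e-8)
  expect_equal(out$intercept, m$intercept, tolerance = 1e-8)

  m2 <- wen_model(c(1, -2, 0.5), 0, lam = 1e6, alpha = 0.8, weights = rep(1, 3))
  norms <- numeric(6)
  cur <- m2
  for (i in 1:6) {
    cur <- local_train(cur, X, y, epochs = 1, lr = 1e-4)
    norms[i] <- max(abs(cur$beta))
  }
  expect_true(all(diff(c(max(abs(m2$beta)), norms)) <= 1e-12))
  expect_lt(norms[6], 1e-3)
})

test_that("single-client gradient training approaches the exact optimum", {
  set.seed(8)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- drop(X %*% c(2, -1, 0, 0, 1, 0, 0.5, 0)) + rnorm(60)
  w <- runif(8)
  opt <- centralized_wen_oracle(X, y, w, lam = 2, alpha = 0.8)
  jopt <- wen_objective(opt, X, y)
  ds <- domain_dataset(X, y, domain_id = "solo")
  fed <- train_federated_wen(list(ds), w, lam = 2, alpha = 0.8,
                             schedule = training_schedule(400, 10, 2e-3, 2e-3))
  expect_lt((wen_objective(fed, X, y) - jopt) / jopt, 1e-4)
})

test_that("FedAvg aggregation is the secure sample-size-weighted mean", {
  mk <- function(b, int = 0) wen_model(b, int, lam = 1, alpha = 0.8, weights = 1)
  same <- list(a = mk(0.7, 0.2), b = mk(0.7, 0.2))
  agg <- fedavg_aggregate(same, c(a = 5, b = 5))
  expect_equal(agg$beta, 0.7, tolerance = 1e-9)
  agg2 <- fedavg_aggregate(list(a = mk(0), b = mk(2)), c(a = 1, b = 3))
  expect_equal(agg2$beta, 1.5, tolerance = 1e-9)
  set.seed(9)
  models <- setNames(lapply(1:5, function(i) {
    wen_model(rnorm(4), rnorm(1), lam = 1, alpha = 0.8, weights = rep(1, 4))
  }), paste0("c", 1:5))
  n_i <- setNames(sample(10:100, 5), names(models))
  agg3 <- fedavg_aggregate(models, n_i)
  plain <- Reduce(`+`, Map(function(m, n) n * c(m$beta, m$intercept),
                           models, n_i)) / sum(n_i)
  expect_equal(c(agg3$beta, agg3$intercept), plain, tolerance = 1e-7)
  # permutation invariance
  agg3p <- fedavg_aggregate(rev(models), n_i)
  expect_equal(agg3$beta, agg3p$beta, tolerance = 1e-9)
  bad <- list(a = mk(1), b = wen_model(1, 0, lam = 2, alpha = 0.8, weights = 1))
  expect_error(fedavg_aggregate(bad, c(a = 1, b = 1)), "provenance")
})

test_that("unpenalized federated training converges to least squares", {
  set.seed(10)
  X <- matrix(rnorm(100 * 10), 100, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(100)
  pooled <- domain_dataset(X, y, domain_id = "s")
  parts <- partition_source(pooled, 2, seed = 4)
  fed <- train_federated_wen(parts, rep(1, 10), lam = 0, alpha = 0.8)
  rss_fed <- wen_objective(fed, X, y)
  rss_ols <- sum(lm.fit(cbind(1, X), y)$residuals^2)
  expect_lt((rss_fed - rss_ols) / rss_ols, 1e-3)
})

test_that("one-client federation reproduces the centralized gradient trajectory", {
  set.seed(11)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(50)
  w <- runif(6)
  sched <- training_schedule(30, 5, 1e-3, 1e-4)
  fed <- train_federated_wen(list(domain_dataset(X, y, domain_id = "s")),
                             w, lam = 1, alpha = 0.8, schedule = sched)
  # test-side plain gradient trajectory with the same schedule
  ref <- wen_model(numeric(6), 0, lam = 1, alpha = 0.8, weights = w)
  for (r in seq_len(sched$global_rounds) - 1L) {
    lr <- sched$lr_start * (sched$lr_end / sched$lr_start)^(r / (sched$global_rounds - 1))
    ref <- local_train(ref, X, y, sched$local_epochs, lr)
  }
  expect_lt(max(abs(fed$beta - ref$beta)), 1e-7)
  expect_lt(abs(fed$intercept - ref$intercept), 1e-7)
})

test_that("the exact solver matches closed forms, OLS limits, and glmnet", {
  set.seed(12)
  X <- matrix(rnorm(50 * 5), 50, 5)
  y <- drop(X %*% c(1, 0, -2, 0.5, 0)) + rnorm(50)
  # w = 0: unpenalized => OLS
  m0 <- centralized_wen_oracle(X, y, rep(0, 5), lam = 3, alpha = 0.8)
  ols <- lm.fit(cbind(1, X), y)$coefficients
  expect_equal(m0$beta, unname(ols[-1]), tolerance = 1e-8)
  expect_equal(m0$intercept, unname(ols[1]), tolerance = 1e-8)

  # orthonormal zero-mean design: per-coordinate soft-threshold closed form
  Q <- qr.Q(qr(scale(matrix(rnorm(40 * 4), 40, 4), scale = FALSE)))
  yq <- drop(Q %*% c(2, -1, 0.05, 0.6)) + 0.1 * rnorm(40)
  lam <- 0.8; alpha <- 0.7
  mq <- centralized_wen_oracle(Q, yq, rep(1, 4), lam = lam, alpha = alpha)
  rho <- drop(crossprod(Q, yq - mean(yq)))
  closed <- sign(rho) * pmax(2 * abs(rho) - lam * alpha, 0) / (2 + lam * (1 - alpha))
  expect_equal(mq$beta, closed, tolerance = 1e-9)

  # glmnet cross-check: its objective is 1/(2n) RSS + lambda * penalty, and
  # it standardizes y internally (rescaling the ridge term), so compare on a
  # unit-variance response where the mapping lambda_glmnet = lambda/(2n) is
  # exact
  ys <- y / sqrt(mean((y - mean(y))^2))
  lam_pkg <- 20
  mg <- centralized_wen_oracle(X, ys, rep(1, 5), lam = lam_pkg, alpha = 0.8)
  gfit <- glmnet::glmnet(X, ys, alpha = 0.8, lambda = lam_pkg / (2 * nrow(X)),
                         standardize = FALSE, thresh = 1e-14)
  expect_equal(mg$beta, as.numeric(gfit$beta), tolerance = 1e-6)
})

test_that("the exact solver satisfies KKT conditions on random instances", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(20:60, 1); p <- sample(3:12, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p)) + rnorm(n)
    w <- runif(p)
    lam <- 10^runif(1, -2, 1.5)
    m <- centralized_wen_oracle(X, y, w, lam = lam, alpha = 0.8)
    expect_lt(kkt_residual(m, X, y), 1e-8)
  }
})

test_that("raising one feature's penalty weight weakly shrinks its coefficient", {
  set.seed(14)
  for (rep in 1:5) {
    X <- matrix(rnorm(60 * 6), 60, 6)
    y <- drop(X %*% rnorm(6)) + rnorm(60)
    w <- runif(6, 0.2, 0.8)
    j <- sample(6, 1)
    m1 <- centralized_wen_oracle(X, y, w, lam = 8, alpha = 0.8)
    w2 <- w; w2[j] <- w[j] * 3
    m2 <- centralized_wen_oracle(X, y, w2, lam = 8, alpha = 0.8)
    expect_lte(abs(m2$beta[j]), abs(m1$beta[j]) + 1e-10)
  }
})

test_that("en-ls equals OLS on a full support and the mean on an empty one", {
  set.seed(15)
  X <- matrix(rnorm(80 * 4), 80, 4)
  y <- drop(X %*% c(3, -2, 1.5, 2.5)) + 0.2 * rnorm(80)
  m <- en_ls_baseline(X, y, lam_grid = c(2e-4, 1e-4), seed = 2)
  ols <- lm.fit(cbind(1, X), y)$coefficients
  expect_equal(length(m$provenance$support), 4L)
  expect_equal(m$beta, unname(ols[-1]), tolerance = 1e-6)
  m2 <- en_ls_baseline(X, y, lam_grid = c(1e6, 1e5), seed = 2)
  expect_equal(m2$beta, rep(0, 4))
  expect_equal(m2$intercept, mean(y))
  expect_equal(predict(m2, X), rep(mean(y), 80))
})
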