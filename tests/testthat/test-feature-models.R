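test_that("negative log marginal likelihood matches closed forms and oracles", {
  # scalar case: K = 1 => NLML = x^2/2 + log(2*pi)/2
  h <- gpr_hyperparams(1, 1)
  expect_equal(neg_log_marginal_likelihood(matrix(0, 1, 1), 0.7, h),
               0.5 * 0.7^2 + 0.5 * log(2 * pi), tolerance = 1e-12)
  # zero response: only the determinant and constant terms remain
  X <- matrix(c(0.5, -0.2, 0.3, 0.8, -0.7, 0.1), 3, 2, byrow = TRUE)
  K <- tcrossprod(X) + diag(3)
  expect_equal(neg_log_marginal_likelihood(X, rep(0, 3), h),
               0.5 * (determinant(K)$modulus + 3 * log(2 * pi)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # direct solve/determinant oracle on random instances
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(3:30, 1); p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n, p); xf <- rnorm(n)
    k2 <- runif(1, 0.1, 3); e2 <- runif(1, 0.1, 3)
    expect_equal(neg_log_marginal_likelihood(X, xf, gpr_hyperparams(k2, e2)),
                 nlml_direct(X, xf, k2, e2), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("marginal likelihood agrees with an external GP library (frozen values)", {
  X <- matrix(c(0.5, -0.2, 0.3, 0.8, -0.7, 0.1, 0.9, -0.4), 4, 2, byrow = TRUE)
  y <- c(0.2, -0.4, 0.9, 0.35)
  expect_equal(neg_log_marginal_likelihood(X, y, gpr_hyperparams(1.3, 0.7)),
               4.783529522312581, tolerance = 1e-6)
  X2 <- matrix(c(1.0, 0.0, 0.5, 0.2, -1.1, 0.3, -0.6, 0.4, -0.2,
                 0.1, 0.9, 1.2, 0.7, -0.3, -0.8), 5, 3, byrow = TRUE)
  y2 <- c(1.1, -0.2, 0.4, -0.9, 0.6)
  expect_equal(neg_log_marginal_likelihood(X2, y2, gpr_hyperparams(0.4, 1.6)),
               7.073543831428911, tolerance = 1e-6)
})

test_that("hyper-parameter optimizer descends and respects its box", {
  set.seed(9)
  X <- matrix(rnorm(40 * 5), 40, 5)
  xf <- drop(X %*% rnorm(5)) + rnorm(40)
  init <- gpr_hyperparams(1, 1)
  opt <- optimize_local_hyperparams(X, xf, init = init)
  expect_lte(neg_log_marginal_likelihood(X, xf, opt),
             neg_log_marginal_likelihood(X, xf, init) + 1e-8)
  # adversarial response forces the noise variance against the box
  huge <- rep(c(1e6, -1e6), 20)
  opt2 <- optimize_local_hyperparams(X, huge, bounds = c(1e-6, 1e6))
  expect_gte(opt2$sigma_k2, 1e-6); expect_lte(opt2$sigma_k2, 1e6)
  expect_gte(opt2$sigma_eps2, 1e-6); expect_lte(opt2$sigma_eps2, 1e6)
  expect_error(optimize_local_hyperparams(matrix(0, 1, 1), 1), "n >= 2")
})

test_that("secure hyper-parameter averaging equals the plain mean", {
  same <- list(a = gpr_hyperparams(2, 0.5), b = gpr_hyperparams(2, 0.5))
  agg <- aggregate_hyperparams(same)
  expect_equal(c(agg$sigma_k2, agg$sigma_eps2), c(2, 0.5), tolerance = 1e-9)
  two <- list(a = gpr_hyperparams(1, 1), b = gpr_hyperparams(3, 3))
  agg2 <- aggregate_hyperparams(two)
  expect_equal(c(agg2$sigma_k2, agg2$sigma_eps2), c(2, 2), tolerance = 1e-9)
  set.seed(3)
  eight <- setNames(lapply(1:8, function(i) {
    gpr_hyperparams(runif(1, 0.1, 5), runif(1, 0.1, 5))
  }), paste0("c", 1:8))
  agg8 <- aggregate_hyperparams(eight)
  expect_equal(agg8$sigma_k2, mean(vapply(eight, `[[`, 1, "sigma_k2")),
               tolerance = 1e-7)
  # permutation invariance across clients
  aggp <- aggregate_hyperparams(rev(eight))
  expect_equal(agg8$sigma_k2, aggp$sigma_k2, tolerance = 1e-9)
  expect_error(aggregate_hyperparams(list()), "empty")
  # weighted variant
  aggw <- aggregate_hyperparams(two, weights = c(a = 1, b = 3))
  expect_equal(aggw$sigma_k2, 2.5, tolerance = 1e-7)
})

test_that("kernel blocks assemble as scaled Gram matrices plus noise", {
  h <- gpr_hyperparams(1, 1)
  km <- assemble_kernel_matrices(diag(3), matrix(0.5, 2, 3), diag(2), h)
  expect_equal(km$K, 2 * diag(3))
  h2 <- gpr_hyperparams(1e-6, 1)
  km2 <- assemble_kernel_matrices(diag(3), matrix(1, 2, 3), diag(2), h2)
  expect_equal(km2$K_star, matrix(1e-6, 2, 3))
  expect_equal(km2$K_star_star, 1e-6 * diag(2))  # no noise term in K**
  bad <- diag(3); bad[1, 2] <- 1
  expect_error(assemble_kernel_matrices(bad, matrix(0, 2, 3), diag(2), h),
               "symmetric")
})

test_that("masked mean protocol reproduces the closed form", {
  h <- gpr_hyperparams(1, 1)
  # scalar case: K = 2, K* = 1, mean = 1 * (1/2) * 2 = 1, var = 1 - 1/2
  km <- assemble_kernel_matrices(matrix(1), matrix(1), matrix(1), h)
  ident <- structure(list(C = diag(1), C_inv = diag(1)), class = "row_mask")
  mu <- predicted_mean_protocol(km$K_star, km$K, list(c1 = 2), ident,
                                list(c1 = 1L))
  expect_equal(mu, 1.0, tolerance = 1e-12)
  expect_equal(predicted_variance(km$K_star_star, km$K_star, km$K), 0.5,
               tolerance = 1e-12)

  # identity mask equals the direct product; random mask agrees with it
  set.seed(21)
  Xs <- matrix(rnorm(12 * 4), 12, 4); Xt <- matrix(rnorm(5 * 4), 5, 4)
  xf <- rnorm(12)
  km <- assemble_kernel_matrices(tcrossprod(Xs), Xt %*% t(Xs), tcrossprod(Xt),
                                 gpr_hyperparams(1.5, 0.3))
  direct <- drop(km$K_star %*% solve(km$K, xf))
  slices <- list(a = 1:7, b = 8:12)
  cols <- list(a = xf[1:7], b = xf[8:12])
  identity5 <- structure(list(C = diag(5), C_inv = diag(5)), class = "row_mask")
  expect_equal(predicted_mean_protocol(km$K_star, km$K, cols, identity5, slices),
               direct, tolerance = 1e-9)
  rmask <- make_row_mask(5, seed = 3)
  expect_equal(predicted_mean_protocol(km$K_star, km$K, cols, rmask, slices),
               direct, tolerance = 1e-8)
  expect_error(predicted_mean_protocol(km$K_star, km$K,
                                       list(a = xf[1:6], b = xf[8:12]),
                                       rmask, slices), "length mismatch")
})

test_that("predictive variance is a nonnegative Schur complement", {
  set.seed(6)
  for (rep in 1:100) {
    n <- sample(3:20, 1); p <- sample(2:6, 1); m <- sample(1:6, 1)
    Xs <- matrix(rnorm(n * p), n, p); Xt <- matrix(rnorm(m * p), m, p)
    km <- assemble_kernel_matrices(tcrossprod(Xs), Xt %*% t(Xs),
                                   tcrossprod(Xt),
                                   gpr_hyperparams(runif(1, 0.1, 2),
                                                   runif(1, 0.1, 2)))
    v <- predicted_variance(km$K_star_star, km$K_star, km$K)
    expect_gte(min(v), 0)
  }
  # interpolation limit: a test point equal to a training row, tiny noise
  Xs <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  km <- assemble_kernel_matrices(tcrossprod(Xs), Xs[1, , drop = FALSE] %*% t(Xs),
                                 tcrossprod(Xs[1, , drop = FALSE]),
                                 gpr_hyperparams(1, 1e-8))
  expect_lt(predicted_variance(km$K_star_star, km$K_star, km$K), 1e-6)
})

test_that("variance shrinks as training data accumulate", {
  set.seed(14)
  p <- 4
  Xbig <- matrix(rnorm(40 * p), 40, p)
  Xt <- matrix(rnorm(6 * p), 6, p)
  h <- gpr_hyperparams(1, 0.5)
  v_small <- centralized_gpr_oracle(Xbig[1:10, ], rnorm(10), Xt, h)$variance
  v_large <- centralized_gpr_oracle(Xbig, rnorm(40), Xt, h)$variance
  expect_true(all(v_large <= v_small + 1e-10))
})

test_that("federated feature models equal the pooled oracle across splits", {
  sim <- tiny_sim(seed = 2, n_sources = 1, P = 10, n_source = 40, n_target = 12)
  pooled <- sim$sources[[1]]
  for (m in c(2, 4)) {
    parts <- partition_source(pooled, m, seed = 5)
    fed <- federated_feature_models(parts, sim$target, seed = 9)
    cen <- centralized_feature_models(parts, sim$target)
    for (i in seq_along(fed)) {
      expect_lt(max(abs(fed[[i]]$mean - cen[[i]]$mean)), 1e-6)
      expect_lt(max(abs(fed[[i]]$variance - cen[[i]]$variance)), 1e-6)
    }
  }
  # pooled oracle itself is invariant to client ordering
  parts <- partition_source(pooled, 2, seed = 5)
  a <- centralized_feature_models(parts, sim$target, fixed_hyper = gpr_hyperparams(1, 1))
  b <- centralized_feature_models(rev(parts), sim$target, fixed_hyper = gpr_hyperparams(1, 1))
  expect_equal(a[[1]]$mean, b[[1]]$mean, tolerance = 1e-12)
})

test_that("federated feature models are deterministic given the seed", {
  sim <- tiny_sim(seed = 4, n_sources = 2, P = 8, n_source = 30, n_target = 10)
  a <- federated_feature_models(sim$sources, sim$target, seed = 13)
  b <- federated_feature_models(sim$sources, sim$target, seed = 13)
  expect_identical(lapply(a, `[[`, "mean"), lapply(b, `[[`, "mean"))
})

test_that("feature-model sets round-trip through JSON lines", {
  sim <- tiny_sim(seed = 4, n_sources = 1, P = 6, n_source = 20, n_target = 8)
  models <- centralized_feature_models(sim$sources, sim$target,
                                       fixed_hyper = gpr_hyperparams(1.2, 0.4))
  f <- tempfile(fileext = ".jsonl")
  write_feature_models(models, f)
  back <- read_feature_models(f)
  expect_equal(back[[3]]$mean, models[[3]]$mean, tolerance = 1e-12)
  expect_equal(back[[3]]$hyper$sigma_k2, 1.2)
  unlink(f)
})
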