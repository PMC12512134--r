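# Shared fixtures and independent oracles for the test suite.

# Small multi-domain simulation for fast structural tests.
tiny_sim <- function(seed = 1, n_sources = 2, P = 12, n_source = 60,
                     n_target = 24, n_groups = 3, shift_strength = 2) {
  spec <- shift_spec(P = P, n_source = n_source, n_target = n_target,
                     latent_rank = 3, perturbed_features = seq_len(min(3, P)),
                     n_groups = n_groups, shift_strength = shift_strength,
                     seed = seed)
  generate_multidomain_dataset(spec, n_sources = n_sources)
}

# Direct-formula NLML oracle (solve + determinant), independent of the
# package's Cholesky/eigen code paths.
nlml_direct <- function(X_nf, x_f, sigma_k2, sigma_eps2) {
  n <- length(x_f)
  K <- sigma_k2 * tcrossprod(as.matrix(X_nf)) + diag(sigma_eps2, n)
  0.5 * (drop(t(x_f) %*% solve(K, x_f)) +
           determinant(K, logarithm = TRUE)$modulus + n * log(2 * pi))
}

# Two-sample energy statistic and permutation test.
energy_stat <- function(D, idx_x, idx_y) {
  2 * mean(D[idx_x, idx_y]) - mean(D[idx_x, idx_x]) - mean(D[idx_y, idx_y])
}

energy_perm_test <- function(X, Y, n_perm = 199, seed = 1) {
  Z <- rbind(X, Y)
  D <- as.matrix(stats::dist(Z))
  nx <- nrow(X); n <- nrow(Z)
  obs <- energy_stat(D, seq_len(nx), (nx + 1):n)
  set.seed(seed)
  perm <- replicate(n_perm, {
    p <- sample.int(n)
    energy_stat(D, p[seq_len(nx)], p[(nx + 1):n])
  })
  (1 + sum(perm >= obs)) / (n_perm + 1)
}

# Pool a list of source datasets.
pool_sources <- function(sources) {
  list(X = do.call(rbind, lapply(sources, function(s) s$X)),
       y = unlist(lapply(sources, function(s) s$y), use.names = FALSE))
}

default_inputs <- function(sim) {
  list(sources = sim$sources, target = sim$target,
       similarity = sim$truth$similarity,
       fit_labels = sim$truth$y_target, truth = sim$truth)
}
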