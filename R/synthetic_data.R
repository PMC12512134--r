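#' One party's dataset
#'
#' Container for a single party's samples-by-features matrix, with optional
#' labels (source parties) and per-sample group tags such as tissue of origin
#' (target party). All domains participating in one run must share the same
#' feature count and feature order.
#'
#' @param X Numeric matrix, `n` samples by `P` features (no missing values).
#' @param y Optional numeric label vector of length `n` (transformed ages for
#'   the age-prediction task).
#' @param groups Optional character/factor vector of length `n` with group
#'   (tissue) identifiers.
#' @param domain_id Identifier for this party's domain.
#' @return An object of class `domain_dataset` with fields `X`, `y`,
#'   `groups`, `domain_id`.
#' @export
domain_dataset <- function(X, y = NULL, groups = NULL, domain_id = "domain") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) {
    stop_config("domain_dataset: X contains missing or non-finite values")
  }
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != nrow(X)) stop_config("domain_dataset: length(y) != nrow(X)")
    if (anyNA(y)) stop_config("domain_dataset: y contains missing values")
  }
  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (length(groups) != nrow(X)) stop_config("domain_dataset: length(groups) != nrow(X)")
  }
  structure(list(X = X, y = y, groups = groups, domain_id = as.character(domain_id)),
            class = "domain_dataset")
}

#' @export
print.domain_dataset <- function(x, ...) {
  cat(sprintf("<domain_dataset '%s': %d samples x %d features%s%s>\n",
              x$domain_id, nrow(x$X), ncol(x$X),
              if (is.null(x$y)) ", unlabeled" else ", labeled",
              if (is.null(x$groups)) "" else sprintf(", %d groups", length(unique(x$groups)))))
  invisible(x)
}

#' Specification for the synthetic multi-domain generator
#'
#' Describes a family of related regression domains built from a shared
#' latent-factor model `X = Z W + eps`, with a linear label model
#' `y = b0 + X beta + noise`, and a target domain whose dependency structure
#' is perturbed for a chosen subset of features (covariate shift). Target
#' groups emulate tissues: each group carries its own shift severity, and a
#' similarity score (decreasing in severity) is emitted for the
#' regularization-selection phase.
#'
#' @param P Number of features.
#' @param n_source Total number of pooled source samples (split across
#'   clients by [partition_source()]).
#' @param n_target Number of target samples.
#' @param latent_rank Number of shared latent factors (must be `< P`).
#' @param perturbed_features Integer indices (in `1..P`) of features whose
#'   latent loadings are rotated in the target domain.
#' @param shift_strength Nonnegative rotation magnitude; 0 means the target
#'   is drawn from the source law.
#' @param noise_sd Standard deviation of the label noise.
#' @param beta_true Length-`P` coefficient vector of the label model, or
#'   `NULL` to use the default: coefficients on a block of unperturbed
#'   features so that adaptation has room to help.
#' @param feature_noise_sd Standard deviation of the per-feature idiosyncratic
#'   noise `eps`.
#' @param n_groups Number of target groups ("tissues").
#' @param group_severity Length-`n_groups` multipliers applied to
#'   `shift_strength` per group (default ramps from mild to strong).
#' @param intercept Intercept `b0` of the label model, on the transformed-age
#'   scale.
#' @param adult_age Adult-age threshold of the age transform used when
#'   reporting labels as chronological ages.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return An object of class `shift_spec`.
#' @export
shift_spec <- function(P = 50, n_source = 200, n_target = 60, latent_rank = 5,
                       perturbed_features = 1:10, shift_strength = 2,
                       noise_sd = 0.15, beta_true = NULL,
                       feature_noise_sd = 0.3, n_groups = 4,
                       group_severity = NULL, intercept = 0.5,
                       adult_age = 20, seed = 1) {
  if (P < 2) stop_config("shift_spec: P must be >= 2")
  if (latent_rank >= P) stop_config("shift_spec: latent_rank must be < P")
  if (latent_rank < 1) stop_config("shift_spec: latent_rank must be >= 1")
  if (n_source < 2 || n_target < 1) stop_config("shift_spec: empty domains")
  perturbed_features <- sort(unique(as.integer(perturbed_features)))
  if (length(perturbed_features) &&
      (min(perturbed_features) < 1 || max(perturbed_features) > P)) {
    stop_config("shift_spec: perturbed_features must lie in 1..P")
  }
  if (shift_strength < 0) stop_config("shift_spec: shift_strength must be >= 0")
  if (noise_sd <= 0 || feature_noise_sd <= 0) {
    stop_config("shift_spec: noise standard deviations must be positive")
  }
  if (is.null(beta_true)) {
    beta_true <- numeric(P)
    stable <- setdiff(seq_len(P), perturbed_features)
    support <- stable[seq_len(min(10L, length(stable)))]
    beta_true[support] <- 0.2 * rep_len(c(1, -1, 1, 1, -1), length(support))
  }
  beta_true <- as.numeric(beta_true)
  if (length(beta_true) != P) stop_config("shift_spec: beta_true must have length P")
  if (is.null(group_severity)) {
    group_severity <- seq(0.25, 1, length.out = n_groups)
  }
  if (length(group_severity) != n_groups) {
    stop_config("shift_spec: group_severity must have length n_groups")
  }
  structure(list(P = as.integer(P), n_source = as.integer(n_source),
                 n_target = as.integer(n_target),
                 latent_rank = as.integer(latent_rank),
                 perturbed_features = perturbed_features,
                 shift_strength = shift_strength, noise_sd = noise_sd,
                 beta_true = beta_true, feature_noise_sd = feature_noise_sd,
                 n_groups = as.integer(n_groups),
                 group_severity = as.numeric(group_severity),
                 intercept = intercept, adult_age = adult_age,
                 seed = as.integer(seed)),
            class = "shift_spec")
}

# Draw one domain from latent factors Z and loadings W (latent_rank x P).
draw_domain <- function(n, W, feature_noise_sd) {
  r <- nrow(W)
  Z <- matrix(stats::rnorm(n * r), n, r)
  Z %*% W + feature_noise_sd * matrix(stats::rnorm(n * ncol(W)), n, ncol(W))
}

# Rotate the perturbed loading columns: w -> (w + s u) / sqrt(1 + s^2) with a
# fresh unit direction u, preserving the column norm (marginal feature
# variance) while changing its dependence on the latent factors.
rotate_loadings <- function(W, cols, s) {
  if (s == 0 || !length(cols)) return(W)
  for (j in cols) {
    w <- W[, j]
    u <- stats::rnorm(length(w))
    u <- u / sqrt(sum(u^2)) * sqrt(sum(w^2))
    W[, j] <- (w + s * u) / sqrt(1 + s^2)
  }
  W
}

#' Generate a multi-domain dataset with planted covariate shift
#'
#' Builds labeled source-party datasets and one unlabeled target dataset from
#' a shared latent-factor feature model. All source parties share the same
#' loadings; the target re-draws the loading directions of
#' `spec$perturbed_features`, per group, with severity
#' `shift_strength * group_severity[g]`. Labels follow the same linear model
#' in every domain; the target labels are returned only inside the ground
#' truth record so unsupervised pipeline stages cannot touch them.
#'
#' @param spec A [shift_spec()].
#' @param n_sources Number of source clients to split the pooled source data
#'   into.
#' @param proportions Client share vector summing to 1, or `"uniform"`.
#' @return A list with elements
#'   * `sources`: list of labeled [domain_dataset()] objects,
#'   * `target`: unlabeled [domain_dataset()] with group tags,
#'   * `truth`: ground-truth record (`y_target`, `age_target`, `beta_true`,
#'     `intercept`, `W`, per-group target loadings, `perturbed_features`,
#'     `similarity` table, `spec`).
#' @export
generate_multidomain_dataset <- function(spec, n_sources = 4,
                                         proportions = "uniform") {
  stopifnot(inherits(spec, "shift_spec"))
  if (n_sources < 1) stop_config("generate_multidomain_dataset: n_sources must be >= 1")
  if (n_sources > spec$n_source) stop_config("more source clients than source samples")
  with_seed(spec$seed, {
    W <- matrix(stats::rnorm(spec$latent_rank * spec$P), spec$latent_rank, spec$P)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")  # unit-norm loading columns

    Xs <- draw_domain(spec$n_source, W, spec$feature_noise_sd)
    ys <- spec$intercept + drop(Xs %*% spec$beta_true) +
      spec$noise_sd * stats::rnorm(spec$n_source)
    colnames(Xs) <- paste0("f", seq_len(spec$P))

    # target groups: contiguous blocks, sizes by largest-remainder rounding
    gsize <- round_shares(spec$n_target, rep(1 / spec$n_groups, spec$n_groups))
    group_names <- paste0("g", seq_len(spec$n_groups))
    Xt <- matrix(0, spec$n_target, spec$P)
    groups <- character(spec$n_target)
    W_target <- vector("list", spec$n_groups)
    names(W_target) <- group_names
    offset <- 0L
    severities <- spec$shift_strength * spec$group_severity
    for (g in seq_len(spec$n_groups)) {
      Wg <- rotate_loadings(W, spec$perturbed_features, severities[g])
      W_target[[g]] <- Wg
      idx <- offset + seq_len(gsize[g])
      Xt[idx, ] <- draw_domain(gsize[g], Wg, spec$feature_noise_sd)
      groups[idx] <- group_names[g]
      offset <- offset + gsize[g]
    }
    colnames(Xt) <- colnames(Xs)
    yt <- spec$intercept + drop(Xt %*% spec$beta_true) +
      spec$noise_sd * stats::rnorm(spec$n_target)

    pooled <- domain_dataset(Xs, y = ys, domain_id = "source_pooled")
    sources <- partition_source(pooled, n_sources, proportions,
                                seed = mix_seed(spec$seed, "partition"))
    target <- domain_dataset(Xt, y = NULL, groups = groups, domain_id = "target")

    similarity <- data.frame(group = group_names,
                             similarity = 1 / (1 + severities),
                             stringsAsFactors = FALSE)
    truth <- list(y_target = yt,
                  age_target = horvath_inverse(clip_to_transform_range(yt, spec$adult_age),
                                               spec$adult_age),
                  beta_true = spec$beta_true, intercept = spec$intercept,
                  W = W, W_target = W_target,
                  perturbed_features = spec$perturbed_features,
                  group_sizes = stats::setNames(gsize, group_names),
                  similarity = similarity, spec = spec)
    list(sources = sources, target = target, truth = truth)
  })
}

#' Age transform for epigenetic-clock labels
#'
#' Logarithmic below the adult-age threshold and linear above it:
#' `log((age + 1) / (adult_age + 1))` for `age <= adult_age`, else
#' `(age - adult_age) / (adult_age + 1)`. Strictly increasing and continuous
#' (both branches are 0 at `age == adult_age`); accounts for the nonlinear
#' dynamics of methylation during development.
#'
#' @param age Nonnegative chronological age(s) in years.
#' @param adult_age Positive adult-age threshold (default 20).
#' @return Transformed age(s).
#' @seealso [horvath_inverse()]
#' @export
horvath_transform <- function(age, adult_age = 20) {
  if (any(!is.finite(age)) || any(age < 0)) {
    stop_config("horvath_transform: age must be finite and >= 0")
  }
  if (adult_age <= 0) stop_config("horvath_transform: adult_age must be positive")
  ifelse(age <= adult_age,
         log((age + 1) / (adult_age + 1)),
         (age - adult_age) / (adult_age + 1))
}

#' Inverse age transform
#'
#' Maps transformed ages back to chronological years; exact inverse of
#' [horvath_transform()] on its image `[-log(adult_age + 1), Inf)`.
#'
#' @param t Transformed age(s).
#' @param adult_age Positive adult-age threshold (default 20).
#' @return Chronological age(s) in years.
#' @export
horvath_inverse <- function(t, adult_age = 20) {
  if (any(!is.finite(t))) stop_config("horvath_inverse: t must be finite")
  lo <- -log(adult_age + 1)
  if (any(t < lo - 1e-12)) {
    stop_config("horvath_inverse: t below the image of the transform")
  }
  ifelse(t <= 0, exp(pmin(t, 0)) * (adult_age + 1) - 1,
         t * (adult_age + 1) + adult_age)
}

# Clamp transformed-age values into the image of the transform so that model
# predictions can always be mapped back to years.
clip_to_transform_range <- function(t, adult_age = 20) {
  pmax(t, -log(adult_age + 1))
}

# Largest-remainder rounding of n into shares `proportions`.
round_shares <- function(n, proportions) {
  raw <- n * proportions
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_frac <- order(raw - sizes, decreasing = TRUE)
    sizes[order_frac[seq_len(rem)]] <- sizes[order_frac[seq_len(rem)]] + 1
  }
  as.integer(sizes)
}

#' Split one source dataset across clients
#'
#' Randomly assigns samples to `n_clients` disjoint, exhaustive parts with
#' sizes given by largest-remainder rounding of the requested proportions.
#' Group tags are ignored when splitting (clients may end up with unbalanced
#' tissue composition, as in realistic federations).
#'
#' @param data A labeled [domain_dataset()].
#' @param n_clients Number of clients.
#' @param proportions Numeric vector of client shares summing to 1, or
#'   `"uniform"`.
#' @param seed Integer seed controlling the random assignment.
#' @return List of `n_clients` [domain_dataset()] objects with ids
#'   `<domain_id>_1`, ...
#' @export
partition_source <- function(data, n_clients, proportions = "uniform", seed = 1) {
  stopifnot(inherits(data, "domain_dataset"))
  n <- nrow(data$X)
  if (identical(proportions, "uniform")) {
    proportions <- rep(1 / n_clients, n_clients)
  }
  proportions <- as.numeric(proportions)
  if (length(proportions) != n_clients) {
    stop_config("partition_source: n_clients must equal length(proportions)")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop_config("partition_source: proportions must sum to 1")
  }
  if (n_clients > n) stop_config("partition_source: more clients than samples")
  sizes <- round_shares(n, proportions)
  perm <- with_seed(seed, sample.int(n))
  out <- vector("list", n_clients)
  offset <- 0L
  for (i in seq_len(n_clients)) {
    idx <- perm[offset + seq_len(sizes[i])]
    out[[i]] <- domain_dataset(data$X[idx, , drop = FALSE],
                               y = if (!is.null(data$y)) data$y[idx],
                               groups = if (!is.null(data$groups)) data$groups[idx],
                               domain_id = sprintf("%s_%d", data$domain_id, i))
    offset <- offset + sizes[i]
  }
  out
}

#' Write / read a domain dataset as CSV
#'
#' The header row holds feature names; labels and group tags travel in the
#' reserved `__label__` and `__group__` columns.
#'
#' @param data A [domain_dataset()].
#' @param path File path.
#' @return `write_domain_dataset` returns `path` invisibly;
#'   `read_domain_dataset` returns a [domain_dataset()].
#' @export
write_domain_dataset <- function(data, path) {
  stopifnot(inherits(data, "domain_dataset"))
  df <- as.data.frame(data$X)
  if (!is.null(data$y)) df[["__label__"]] <- data$y
  if (!is.null(data$groups)) df[["__group__"]] <- data$groups
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_domain_dataset
#' @param domain_id Identifier for the loaded dataset.
#' @export
read_domain_dataset <- function(path, domain_id = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  y <- df[["__label__"]]
  groups <- df[["__group__"]]
  df[["__label__"]] <- NULL
  df[["__group__"]] <- NULL
  domain_dataset(as.matrix(df), y = y, groups = groups, domain_id = domain_id)
}
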