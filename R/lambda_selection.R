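# Regularization-strength selection: weighted elastic nets are trained over
# a lambda grid for target groups with known labels, the best lambda per
# group is chosen by MAE in chronological years, and a linear model of
# log10(lambda) on domain similarity predicts lambda for held-out groups.
# A similarity-free cross-validation fallback selects lambda on the source
# side.

#' Default logarithmic lambda grid
#'
#' @param n Number of grid points (default 15).
#' @param range Length-2 positive range (default `c(1e-3, 1e2)`).
#' @return Increasing numeric vector of lambda values.
#' @export
lambda_grid <- function(n = 15, range = c(1e-3, 1e2)) {
  if (n < 1 || any(range <= 0) || range[2] < range[1]) {
    stop_config("lambda_grid: invalid grid request")
  }
  10^seq(log10(range[1]), log10(range[2]), length.out = n)
}

#' Mean absolute error in chronological years
#'
#' Maps transformed-age predictions and labels back through the inverse age
#' transform (clamping into its image) and returns the MAE in years, the
#' unit used for every selection and report in the pipeline.
#'
#' @param pred,truth Transformed-age vectors.
#' @param adult_age Adult-age threshold of the transform.
#' @return Scalar MAE in years.
#' @export
mae_years <- function(pred, truth, adult_age = 20) {
  mean(abs(horvath_inverse(clip_to_transform_range(pred, adult_age), adult_age) -
           horvath_inverse(clip_to_transform_range(truth, adult_age), adult_age)))
}

#' Split the target domain into a labeled fit subset and a holdout
#'
#' Samples belonging to `fit_groups` form the labeled subset used to select
#' lambda (labels for these groups are assumed available and supplied via
#' `labels`); the remainder stays label-free. Disjoint and exhaustive.
#'
#' @param target Target [domain_dataset()] with group tags.
#' @param fit_groups Nonempty character vector of groups present in the
#'   target.
#' @param labels Full-length label vector aligned with the target rows
#'   (only the `fit_groups` entries are ever attached).
#' @return List with labeled `fit` and unlabeled `holdout`
#'   [domain_dataset()]s.
#' @export
split_target <- function(target, fit_groups, labels = NULL) {
  stopifnot(inherits(target, "domain_dataset"))
  if (is.null(target$groups)) stop_config("split_target: target has no group tags")
  fit_groups <- as.character(fit_groups)
  if (!length(fit_groups)) stop_config("split_target: fit_groups is empty")
  missing <- setdiff(fit_groups, unique(target$groups))
  if (length(missing)) {
    stop_config("split_target: groups not present in target: ",
                paste(missing, collapse = ", "))
  }
  in_fit <- target$groups %in% fit_groups
  if (!is.null(labels) && length(labels) != nrow(target$X)) {
    stop_config("split_target: labels must align with target rows")
  }
  fit <- domain_dataset(target$X[in_fit, , drop = FALSE],
                        y = if (!is.null(labels)) labels[in_fit],
                        groups = target$groups[in_fit],
                        domain_id = paste0(target$domain_id, "_fit"))
  holdout <- domain_dataset(target$X[!in_fit, , drop = FALSE],
                            groups = target$groups[!in_fit],
                            domain_id = paste0(target$domain_id, "_holdout"))
  list(fit = fit, holdout = holdout)
}

#' Enumerate candidate fit-group combinations
#'
#' All size-`k` combinations of groups that individually contain at least
#' `min_n` samples; used to iterate similarity-fit/evaluation splits.
#'
#' @param groups Per-sample group labels.
#' @param min_n Minimum group size for eligibility (default 20).
#' @param k Combination size (default 3).
#' @return List of character vectors, each one combination.
#' @export
enumerate_fit_group_combinations <- function(groups, min_n = 20, k = 3) {
  sizes <- table(groups)
  eligible <- names(sizes)[sizes >= min_n]
  if (length(eligible) < k) return(list())
  combos <- utils::combn(sort(eligible), k, simplify = FALSE)
  combos
}

#' Select the best lambda on a labeled subset
#'
#' Argmin over the grid of the MAE (in chronological years) on the labeled
#' samples; ties resolve to the smaller lambda.
#'
#' @param models_per_lambda Named list (lambda value as name ->
#'   [wen_model()]).
#' @param X Labeled subset design matrix.
#' @param y Labels (transformed ages) for the subset.
#' @param adult_age Adult-age threshold for the year-space MAE.
#' @return The selected lambda (numeric).
#' @export
select_best_lambda <- function(models_per_lambda, X, y, adult_age = 20) {
  if (!length(models_per_lambda)) stop_config("select_best_lambda: empty grid")
  if (!length(y)) stop_config("select_best_lambda: empty labeled set")
  lams <- as.numeric(names(models_per_lambda))
  ord <- order(lams)
  maes <- vapply(ord, function(i) {
    mae_years(predict(models_per_lambda[[i]], X), y, adult_age)
  }, numeric(1))
  lams[ord][which.min(maes)]  # which.min takes the first: smaller lambda on ties
}

#' Fit the similarity -> lambda linear model
#'
#' Least-squares line of `log10(lambda)` on the domain-similarity score.
#' Lambda spans orders of magnitude, so the fit lives on the log scale.
#'
#' @param points Data frame (or list of pairs) with columns `similarity` and
#'   `lambda`; at least two distinct similarity values required.
#' @return An object of class `lambda_similarity_model` with `slope`,
#'   `intercept`, and `scale = "log10-lambda"`.
#' @export
fit_similarity_lambda_model <- function(points) {
  points <- as.data.frame(points)
  if (nrow(points) < 2) stop_config("fit_similarity_lambda_model: need >= 2 points")
  if (length(unique(points$similarity)) < 2) {
    stop_config("fit_similarity_lambda_model: degenerate similarity values")
  }
  fit <- stats::lm(log10(lambda) ~ similarity, data = points)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 scale = "log10-lambda"),
            class = "lambda_similarity_model")
}

#' Predict lambda from a similarity score
#'
#' `10^(slope * similarity + intercept)`, clipped into the configured grid
#' range so downstream training always sees a lambda the grid was built for.
#'
#' @param model A [fit_similarity_lambda_model()].
#' @param similarity Finite similarity score(s).
#' @param grid_range Length-2 clipping range (default the [lambda_grid()]
#'   default range).
#' @return Positive lambda value(s).
#' @export
predict_lambda <- function(model, similarity, grid_range = c(1e-3, 1e2)) {
  if (any(!is.finite(similarity))) stop_config("predict_lambda: non-finite similarity")
  lam <- 10^(model$slope * similarity + model$intercept)
  pmin(pmax(lam, grid_range[1]), grid_range[2])
}

#' Cross-validation lambda selection (similarity-free fallback)
#'
#' Selects the lambda minimizing the mean source-side CV MAE (in years) of
#' the weighted elastic net, with folds stratified within clients so every
#' fold mirrors the federation's composition. Ties resolve to the smaller
#' lambda. Fits use the exact centralized solver.
#'
#' @param sources List of labeled source [domain_dataset()]s.
#' @param weights Per-feature penalty weights.
#' @param grid Lambda grid (see [lambda_grid()]).
#' @param folds Number of folds (>= 2).
#' @param alpha Elastic-net mixing parameter.
#' @param adult_age Adult-age threshold for year-space MAE.
#' @param seed Seed for the fold assignment.
#' @return The selected lambda.
#' @export
cv_select_lambda <- function(sources, weights, grid = lambda_grid(), folds = 5,
                             alpha = 0.8, adult_age = 20, seed = 1) {
  if (folds < 2) stop_config("cv_select_lambda: folds must be >= 2")
  if (inherits(weights, "feature_weight_vector")) weights <- weights$values
  X <- do.call(rbind, lapply(sources, function(s) s$X))
  y <- unlist(lapply(sources, function(s) s$y), use.names = FALSE)
  fold_id <- unlist(lapply(seq_along(sources), function(i) {
    n <- nrow(sources[[i]]$X)
    if (n < folds) stop_config("cv_select_lambda: client ", i, " has fewer samples than folds")
    with_seed(mix_seed(seed, "cvfold", i), sample(rep_len(seq_len(folds), n)))
  }), use.names = FALSE)
  grid <- sort(grid)
  cv_mae <- vapply(grid, function(lam) {
    errs <- vapply(seq_len(folds), function(fd) {
      tr <- fold_id != fd
      fit <- centralized_wen_oracle(X[tr, , drop = FALSE], y[tr], weights,
                                    lam = lam, alpha = alpha)
      mae_years(predict(fit, X[!tr, , drop = FALSE]), y[!tr], adult_age)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  grid[which.min(cv_mae)]
}
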