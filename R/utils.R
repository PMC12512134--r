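# Internal helpers shared across modules.

#' Evaluate an expression with a private RNG state
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state afterwards, so that library calls never perturb user-level
#' reproducibility.
#'
#' @param seed Integer seed (must be below 2^31).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministically mix a base seed with one or more stream labels into a
# 32-bit seed. Cheap LCG-style mixing; collisions across the handful of
# streams used in one run are checked in tests.
mix_seed <- function(seed, ...) {
  parts <- list(seed, ...)
  acc <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
    acc <- (acc * 69069 + v * 99991 + 12345) %% 2147483629
  }
  as.integer(acc)
}

# MD5 digest of an arbitrary R payload (used by the protocol transcript and
# the privacy audit). Serialization is version-pinned so digests are stable
# across sessions.
payload_digest <- function(x) {
  f <- tempfile(fileext = ".bin")
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 3L), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("freda_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_protocol <- function(...) {
  stop(structure(class = c("freda_protocol_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_numerical <- function(...) {
  stop(structure(class = c("freda_numerical_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
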