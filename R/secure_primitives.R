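# Privacy mechanisms: zero-sum-mask secure aggregation over a fixed-point
# ring, the randomized-encoding masked matrix-product scheme, and the
# row-mask/unmask pair used by the predicted-mean protocol.
#
# Fixed-point values live in Z_{2^64}, represented exactly in R as two
# 32-bit limbs stored in doubles (every intermediate stays below 2^53, so
# all limb arithmetic is exact and mask cancellation is bit-exact).

TWO32 <- 4294967296  # 2^32

#' Fixed-point codec for secure aggregation
#'
#' Real values are scaled by `2^frac_bits`, rounded, and embedded into the
#' ring of integers modulo 2^64 (two's complement for negatives). Sums of
#' masked residues decode exactly whenever the true sum is representable,
#' which makes zero-sum mask cancellation exact rather than approximate.
#'
#' @param frac_bits Number of fractional bits (default 32).
#' @return An object of class `fp_codec`.
#' @export
fp_codec <- function(frac_bits = 32) {
  if (frac_bits < 1 || frac_bits > 52) stop_config("fp_codec: frac_bits must be in 1..52")
  structure(list(frac_bits = as.integer(frac_bits), modulus_log2 = 64L),
            class = "fp_codec")
}

# --- limb arithmetic (internal) ---------------------------------------------

fp_zero <- function(n) list(hi = numeric(n), lo = numeric(n))

fp_from_integerish <- function(v) {
  # v: vector of integers with |v| < 2^52, exact in doubles
  a <- abs(v)
  hi <- floor(a / TWO32)
  lo <- a - hi * TWO32
  out <- list(hi = hi, lo = lo)
  idx <- which(v < 0)
  if (length(idx)) {
    neg <- fp_neg(list(hi = hi[idx], lo = lo[idx]))
    out$hi[idx] <- neg$hi
    out$lo[idx] <- neg$lo
  }
  out
}

fp_neg <- function(a) {
  nonzero <- a$lo > 0
  list(hi = (TWO32 - a$hi - nonzero) %% TWO32,
       lo = (TWO32 - a$lo) * nonzero)
}

fp_add <- function(a, b) {
  lo <- a$lo + b$lo
  carry <- as.numeric(lo >= TWO32)
  lo <- lo - carry * TWO32
  hi <- a$hi + b$hi + carry
  hi <- hi - (hi >= TWO32) * TWO32
  list(hi = hi, lo = lo)
}

fp_random <- function(n) {
  list(hi = floor(stats::runif(n) * TWO32), lo = floor(stats::runif(n) * TWO32))
}

fp_encode_values <- function(codec, x, n_parties = 1) {
  scale <- 2^codec$frac_bits
  limit <- 2^62 / scale / max(1, n_parties)
  if (any(abs(x) >= limit)) {
    stop_protocol("fixed-point overflow: |value| must be < 2^62 / 2^frac_bits / n_parties")
  }
  fp_from_integerish(round(x * scale))
}

fp_decode_values <- function(codec, a) {
  signed_hi <- ifelse(a$hi >= TWO32 / 2, a$hi - TWO32, a$hi)
  (signed_hi * TWO32 + a$lo) / 2^codec$frac_bits
}

# --- zero-sum masks ----------------------------------------------------------

pair_key <- function(p, q) paste(sort(c(p, q)), collapse = "|")

#' Derive pairwise zero-sum masks
#'
#' Every unordered party pair expands a shared seed into a stream of uniform
#' 64-bit residues for the given round; the lexicographically smaller party
#' adds the stream, the larger subtracts it. The elementwise modular sum of
#' all parties' masks is therefore exactly zero, so masked contributions
#' reveal only their total.
#'
#' @param party_ids Character vector of party identifiers.
#' @param shape Integer vector giving the tensor shape to mask.
#' @param round_id Integer round counter; masks differ across rounds.
#' @param pairwise_seeds Named list of integer seeds, one per unordered pair,
#'   with names `"<p>|<q>"` for sorted `p < q`.
#' @return Named list mapping each party to its mask (limb representation).
#' @export
derive_zero_sum_masks <- function(party_ids, shape, round_id, pairwise_seeds) {
  n <- prod(shape)
  masks <- stats::setNames(lapply(party_ids, function(p) fp_zero(n)), party_ids)
  if (length(party_ids) < 2) return(masks)
  for (i in seq_along(party_ids)) {
    for (j in seq_along(party_ids)) {
      if (i >= j) next
      p <- party_ids[i]; q <- party_ids[j]
      key <- pair_key(p, q)
      seed <- pairwise_seeds[[key]]
      if (is.null(seed)) stop_protocol("missing pairwise seed for ", key)
      r <- with_seed(mix_seed(seed, "round", round_id), fp_random(n))
      small <- if (p < q) p else q
      big <- if (p < q) q else p
      masks[[small]] <- fp_add(masks[[small]], r)
      masks[[big]] <- fp_add(masks[[big]], fp_neg(r))
    }
  }
  masks
}

#' Secure summation of per-party tensors
#'
#' Each party encodes its tensor in fixed point, adds its zero-sum mask, and
#' releases only the masked residues; the aggregator folds the residues and
#' decodes the total. Because mask cancellation is exact in the ring, the
#' result equals the plain sum of the fixed-point-rounded inputs.
#'
#' @param local_values Named list (party -> numeric array), all same shape.
#' @param codec An [fp_codec()].
#' @param masks Masks from [derive_zero_sum_masks()], or `NULL` to derive
#'   them from `pairwise_seeds`.
#' @param round_id,pairwise_seeds Used only when `masks` is `NULL`.
#' @return Numeric array of the same shape as the inputs.
#' @export
secure_sum <- function(local_values, codec, masks = NULL, round_id = 0,
                       pairwise_seeds = NULL) {
  if (!length(local_values)) stop_protocol("secure_sum: no parties")
  shapes <- lapply(local_values, function(v) dim(v) %||% length(v))
  if (length(unique(vapply(shapes, paste, character(1), collapse = "x"))) != 1) {
    stop_protocol("secure_sum: tensors differ in shape")
  }
  template <- local_values[[1]]
  party_ids <- names(local_values)
  if (is.null(masks)) {
    if (is.null(pairwise_seeds)) {
      stop_protocol("secure_sum: need masks or pairwise_seeds")
    }
    masks <- derive_zero_sum_masks(party_ids, length(template), round_id,
                                   pairwise_seeds)
  }
  n_parties <- length(local_values)
  acc <- fp_zero(length(template))
  for (p in party_ids) {
    enc <- fp_encode_values(codec, as.numeric(local_values[[p]]), n_parties)
    acc <- fp_add(acc, fp_add(enc, masks[[p]]))
  }
  out <- fp_decode_values(codec, acc)
  if (!is.null(dim(template))) dim(out) <- dim(template)
  out
}

# --- randomized-encoding masked matrix products ------------------------------

#' Generate the shared randomized-encoding mask bundle
#'
#' All parties expand a common seed into a full-column-rank mask matrix
#' `M` (d x P, `d > P`), its symmetric PSD square-root factor
#' `S = (M M')^(1/2)`, and per-party left inverses `L_p` with `L_p M = I_P`.
#' A party encodes its data as `X L_p S`; pairwise products of encoded
#' matrices then collapse to plaintext Gram matrices because
#' `L_p M M' L_q' = I`.
#'
#' @param seed Shared integer seed.
#' @param P Number of data columns to be encoded.
#' @param d Encoding dimension (`> P`; default `P + 10`). The encoded data
#'   lives in a higher-dimensional space, hiding the true dimensionality.
#' @param party_ids Character vector of participating parties.
#' @param randomize_left_inverse If `TRUE`, each party adds a private
#'   null-space component to its left inverse (still satisfying
#'   `L_p M = I_P`).
#' @return An object of class `mask_bundle`.
#' @export
generate_shared_mask <- function(seed, P, d = P + 10, party_ids,
                                 randomize_left_inverse = FALSE) {
  if (d <= P) stop_config("generate_shared_mask: d must exceed P")
  M <- NULL
  with_seed(mix_seed(seed, "mask_matrix"), {
    for (try in 1:5) {
      cand <- matrix(stats::rnorm(d * P), d, P)
      if (qr(cand)$rank == P) { M <- cand; break }
    }
  })
  if (is.null(M)) stop_numerical("mask matrix rank-deficient after retries")
  eg <- eigen(tcrossprod(M), symmetric = TRUE)
  S <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  L <- solve(crossprod(M), t(M))  # Moore-Penrose left inverse, (M'M)^-1 M'
  proj_null <- diag(d) - M %*% L  # projector onto the null space of M'
  left_inverses <- stats::setNames(lapply(party_ids, function(p) {
    if (!randomize_left_inverse) return(L)
    R <- with_seed(mix_seed(seed, "null_component", p),
                   matrix(stats::rnorm(P * d), P, d))
    L + R %*% proj_null
  }), party_ids)
  structure(list(seed = seed, P = as.integer(P), d = as.integer(d), M = M,
                 S = S, left_inverses = left_inverses,
                 bundle_id = payload_digest(list(seed, P, d, randomize_left_inverse))),
            class = "mask_bundle")
}

#' Encode a data matrix under the shared mask
#'
#' Computes `X L_p S` (an n x d matrix); only this encoding ever leaves the
#' party. Reconstructing `X` from it without the mask material is
#' underdetermined.
#'
#' @param X Numeric matrix with `P` columns matching the bundle.
#' @param bundle A [generate_shared_mask()] bundle.
#' @param party Party identifier (selects the left inverse).
#' @return An object of class `encoded_matrix`.
#' @export
encode_matrix <- function(X, bundle, party) {
  stopifnot(inherits(bundle, "mask_bundle"))
  X <- as.matrix(X)
  if (ncol(X) != bundle$P) {
    stop_config("encode_matrix: X has ", ncol(X), " columns, bundle expects ", bundle$P)
  }
  L <- bundle$left_inverses[[party]]
  if (is.null(L)) stop_protocol("encode_matrix: unknown party ", party)
  structure(list(values = X %*% L %*% bundle$S, party = party,
                 d = bundle$d, bundle_id = bundle$bundle_id),
            class = "encoded_matrix")
}

#' Gram matrix from two encoded matrices
#'
#' For encodings produced under the same bundle, the masks cancel and the
#' product of encoded matrices equals the plaintext cross-Gram `X_p X_q'`.
#'
#' @param A,B [encode_matrix()] outputs sharing a bundle.
#' @return Numeric matrix `X_p %*% t(X_q)`.
#' @export
gram_from_encoded <- function(A, B) {
  stopifnot(inherits(A, "encoded_matrix"), inherits(B, "encoded_matrix"))
  if (A$d != B$d || !identical(A$bundle_id, B$bundle_id)) {
    stop_protocol("gram_from_encoded: encodings come from different bundles")
  }
  tcrossprod(A$values, B$values)
}

# --- row mask for the predicted-mean protocol --------------------------------

#' Invertible row mask
#'
#' A random, well-conditioned `n_t x n_t` matrix `C` and its inverse. The
#' aggregator releases only `C %*% B` to source clients; the target removes
#' the mask with `C^-1` after summing their contributions.
#'
#' @param n_t Number of target samples (mask dimension).
#' @param seed Integer seed; identical seeds give identical masks.
#' @param max_condition Resample threshold on the condition number.
#' @return An object of class `row_mask` with fields `C` and `C_inv`.
#' @export
make_row_mask <- function(n_t, seed, max_condition = 1e8) {
  C <- with_seed(mix_seed(seed, "row_mask"), {
    ok <- NULL
    for (try in 1:5) {
      cand <- matrix(stats::rnorm(n_t * n_t), n_t, n_t)
      sv <- svd(cand, nu = 0, nv = 0)$d
      if (min(sv) > 0 && max(sv) / min(sv) < max_condition) {
        ok <- cand
        break
      }
    }
    ok
  })
  if (is.null(C)) stop_numerical("row mask singular after retries")
  structure(list(C = C, C_inv = solve(C)), class = "row_mask")
}

#' @rdname make_row_mask
#' @param mask A `row_mask`.
#' @param B Matrix with `n_t` rows to be masked.
#' @export
apply_row_mask <- function(mask, B) {
  stopifnot(inherits(mask, "row_mask"))
  mask$C %*% B
}

#' @rdname make_row_mask
#' @param C_inv Inverse mask matrix (or a `row_mask`, whose `C_inv` is used).
#' @param v Masked vector to unmask.
#' @export
unmask_vector <- function(C_inv, v) {
  if (inherits(C_inv, "row_mask")) C_inv <- C_inv$C_inv
  drop(C_inv %*% v)
}
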