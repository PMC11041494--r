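# Additive secret sharing over a fixed-point ring.
#
# Reals are encoded as integers v = round(x * scale) and masked in the ring
# Z_M with M = 2^(16 * n_limbs) (default 2^256). Ring elements are stored as
# base-2^16 limb matrices (n_limbs x N, little-endian), so all arithmetic is
# exact: float masking of raw doubles loses bits, integer masking does not.
# Signed values use two's-complement convention: x < 0 maps to M - |v|.

#' Fixed-point codec for secure aggregation
#'
#' @param scale positive power of ten; one unit in the last place is
#'   `1/scale`. Default 1e10, which keeps end-to-end quantization drift of a
#'   federated fit far below 1e-6 per weight.
#' @param n_limbs number of 16-bit limbs of the ring; the modulus is
#'   `2^(16 * n_limbs)` (default 16 limbs = 2^256).
#' @return an object of class `fp_codec`.
#' @export
fp_codec <- function(scale = 1e10, n_limbs = 16L) {
  if (scale <= 0 || log10(scale) %% 1 != 0) {
    stop_invalid("scale must be a positive power of ten")
  }
  if (n_limbs < 4L) stop_invalid("need at least 4 limbs")
  structure(list(scale = scale, n_limbs = as.integer(n_limbs)),
            class = "fp_codec")
}

BASE <- 65536

# Exact double -> limb matrix for nonnegative integers < 2^53.
to_limbs <- function(v, n_limbs) {
  L <- matrix(0, n_limbs, length(v))
  for (k in seq_len(n_limbs)) {
    r <- v %% BASE
    L[k, ] <- r
    v <- (v - r) / BASE
    if (all(v == 0)) break
  }
  L
}

# Modular addition in Z_(2^(16*n_limbs)): limb-wise add with carry; the
# final carry wraps (drops) naturally.
mod_add <- function(A, B) {
  n <- nrow(A)
  C <- matrix(0, n, ncol(A))
  carry <- 0
  for (k in seq_len(n)) {
    s <- A[k, ] + B[k, ] + carry
    carry <- s %/% BASE
    C[k, ] <- s %% BASE
  }
  C
}

# Two's-complement negation: complement limbs, add 1.
mod_neg <- function(A) {
  n <- nrow(A)
  C <- (BASE - 1) - A
  carry <- 1
  for (k in seq_len(n)) {
    s <- C[k, ] + carry
    carry <- s %/% BASE
    C[k, ] <- s %% BASE
    if (all(carry == 0)) break
  }
  C
}

#' Encode reals as fixed-point ring elements
#'
#' @param x numeric vector/array.
#' @param codec an [fp_codec()].
#' @return limb matrix (`n_limbs` x `length(x)`) representing
#'   `round(x * scale) mod 2^(16 * n_limbs)`.
#' @export
fp_encode <- function(x, codec = fp_codec()) {
  v <- round(as.numeric(x) * codec$scale)
  if (any(abs(v) >= 2^53)) {
    stop_protocol("fixed-point overflow: |value| ",
                  format(max(abs(v) / codec$scale)),
                  " exceeds the exactly encodable range at scale ",
                  format(codec$scale))
  }
  L <- to_limbs(abs(v), codec$n_limbs)
  neg <- v < 0
  if (any(neg)) L[, neg] <- mod_neg(L[, neg, drop = FALSE])
  L
}

#' Decode fixed-point ring elements back to reals
#'
#' @param L limb matrix as produced by [fp_encode()] or summed shards.
#' @param codec the matching [fp_codec()].
#' @return numeric vector; within `1/scale` of the encoded reals.
#' @export
fp_decode <- function(L, codec = fp_codec()) {
  n <- nrow(L)
  neg <- L[n, ] >= BASE / 2
  if (any(neg)) L[, neg] <- mod_neg(L[, neg, drop = FALSE])
  if (n > 4L && any(L[5:n, ] != 0)) {
    stop_protocol("fixed-point overflow on decode: aggregate magnitude ",
                  "exceeds the exactly representable range")
  }
  v <- L[1, ] + L[2, ] * BASE + L[3, ] * BASE^2 + L[4, ] * BASE^3
  v[neg] <- -v[neg]
  v / codec$scale
}

#' Split a ring element into additive shards
#'
#' The first `n - 1` shards are uniform over the ring; the last is chosen so
#' the modular sum of all `n` shards equals the value. Any `n - 1` shards are
#' jointly uniform, so no proper subset reveals the value.
#'
#' @param L limb matrix (encoded values; columns are independent entries).
#' @param n number of shards = number of participating clients.
#' @return list of `n` limb matrices whose modular sum is `L`.
#' @export
make_shards <- function(L, n) {
  if (n < 1L) stop_invalid("number of shards must be >= 1")
  if (n == 1L) return(list(L))
  shards <- vector("list", n)
  acc <- NULL
  for (k in seq_len(n - 1L)) {
    R <- matrix(sample.int(BASE, nrow(L) * ncol(L), replace = TRUE) - 1,
                nrow(L), ncol(L))
    shards[[k]] <- R
    acc <- if (is.null(acc)) R else mod_add(acc, R)
  }
  shards[[n]] <- mod_add(L, mod_neg(acc))
  shards
}

#' Secure sum of per-client tensors
#'
#' Simulates one round of additive-secret-sharing aggregation: each client
#' splits each entry of its tensor into `n` shards, shard k is routed to
#' client k, each client sums the shards it received, and the aggregator sums
#' the `n` per-client partial sums and decodes. Only shards and partial sums
#' ever reach the aggregator; no client's cleartext value does. Communication
#' is `n^2` shard messages per tensor.
#'
#' @param client_values list of numeric tensors of identical shape, one per
#'   client.
#' @param codec an [fp_codec()].
#' @return the elementwise sum (same shape as the inputs), exact up to one
#'   rounding of each input at `1/scale`, with attribute `messages` counting
#'   shard messages.
#' @export
secure_sum <- function(client_values, codec = fp_codec()) {
  n <- length(client_values)
  if (n < 1L) stop_invalid("need at least one client value")
  shp <- dim(client_values[[1L]]) %||% length(client_values[[1L]])
  for (v in client_values) {
    if (!identical(dim(v) %||% length(v), shp)) {
      stop_protocol("secure_sum: client tensors differ in shape")
    }
  }
  # mailboxes[[k]]: modular sum of the shards addressed to client k
  mailboxes <- vector("list", n)
  for (i in seq_len(n)) {
    shards <- make_shards(fp_encode(client_values[[i]], codec), n)
    for (k in seq_len(n)) {
      mailboxes[[k]] <- if (is.null(mailboxes[[k]])) shards[[k]] else
        mod_add(mailboxes[[k]], shards[[k]])
    }
  }
  total <- Reduce(mod_add, mailboxes)
  out <- fp_decode(total, codec)
  if (!is.null(dim(client_values[[1L]]))) dim(out) <- dim(client_values[[1L]])
  attr(out, "messages") <- n * n
  out
}
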