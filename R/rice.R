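#' @title Golomb-Rice residual coding
#' @description
#' Residuals are mapped to non-negative integers with the zigzag bijection,
#' then each value `u` is split by `2^m` into a unary-coded quotient
#' `q = floor(u / 2^m)` (q one-bits and a zero terminator) and an m-bit
#' binary remainder written most-significant-bit first, for a codeword of
#' exactly `m + q + 1` bits. Rice codes are near-optimal when the input is
#' geometrically distributed, which prediction residuals of slowly varying
#' signals are to a good approximation.
#'
#' A guarded escape path bounds pathological expansion: when `q > 47` the
#' value is emitted as 48 one-bits followed by the raw 32-bit value
#' (80 bits total) instead of a potentially enormous unary run.
#' @name rice
NULL

RICE_ESCAPE_Q <- 48L       # q > 47 triggers the escape
RICE_ESCAPE_BITS <- 48L + 32L

#' Zigzag mapping between signed and unsigned integers
#'
#' `zigzag()` interleaves signed values as 0, -1, 1, -2, 2, ... ->
#' 0, 1, 2, 3, 4, ... (`u = 2e` for `e >= 0`, `-2e - 1` otherwise), so small
#' magnitudes get small codes regardless of sign; `unzigzag()` inverts it.
#'
#' @param e integer vector (|e| <= 2^31 - 1).
#' @return non-negative integer vector (as doubles; values may exceed
#'   .Machine$integer.max).
#' @examples
#' zigzag(c(0, -1, 1, -3, 3))  # 0 1 2 5 6
#' @export
zigzag <- function(e) {
  e <- as.numeric(e)
  ifelse(e >= 0, 2 * e, -2 * e - 1)
}

#' @rdname zigzag
#' @param u non-negative integer vector.
#' @export
unzigzag <- function(u) {
  u <- as.numeric(u)
  ifelse(u %% 2 == 0, u / 2, -(u + 1) / 2)
}

#' Rice-encode a vector of non-negative integers
#'
#' @param u non-negative integers.
#' @param m Rice order, `0 <= m <= 30`.
#' @return list with `bits` (integer 0/1 vector, append order) and
#'   `lengths` (bits per codeword; `m + q + 1`, or 80 on the escape path).
#' @export
rice_encode <- function(u, m) {
  stopifnot(length(m) == 1, m >= 0, m <= 30)
  m <- as.integer(m)
  u <- as.numeric(u)
  if (any(u < 0)) stop("rice_encode requires non-negative values")
  q <- u %/% 2^m
  r <- u - q * 2^m
  esc <- q >= RICE_ESCAPE_Q
  lens <- ifelse(esc, RICE_ESCAPE_BITS, m + q + 1)
  pieces <- vector("list", length(u))
  rem_pows <- if (m > 0) 2^((m - 1):0) else numeric(0)
  esc_pows <- 2^(31:0)
  for (i in seq_along(u)) {
    if (esc[i]) {
      pieces[[i]] <- c(rep(1L, RICE_ESCAPE_Q),
                       as.integer((u[i] %/% esc_pows) %% 2))
    } else {
      rem <- if (m > 0) as.integer((r[i] %/% rem_pows) %% 2) else integer(0)
      pieces[[i]] <- c(rep(1L, q[i]), 0L, rem)
    }
  }
  bits <- unlist(pieces, use.names = FALSE)
  if (is.null(bits)) bits <- integer(0)
  # codelength law: emitted size must equal the closed form when no escape fires
  stopifnot(length(bits) == sum(lens))
  list(bits = bits, lengths = lens)
}

#' Decode `n` Rice codewords from a bit vector
#'
#' Exact inverse of [rice_encode()], including the escape path (a run of 48
#' one-bits is an escape marker followed by the raw 32-bit value).
#'
#' @param bits integer 0/1 vector.
#' @param m Rice order used to encode.
#' @param n number of codewords to read.
#' @return list with `values` (non-negative integers) and `bits_used`.
#' @export
rice_decode <- function(bits, m, n) {
  stopifnot(length(m) == 1, m >= 0, m <= 30)
  m <- as.integer(m); n <- as.integer(n)
  out <- numeric(n)
  if (n == 0L) return(list(values = out, bits_used = 0L))
  zpos <- which(bits == 0L)
  zi <- 1L     # next candidate terminator
  idx <- 1L    # next unread bit
  nb <- length(bits)
  esc_pows <- 2^(31:0)
  rem_pows <- if (m > 0) 2^((m - 1):0) else numeric(0)
  for (k in seq_len(n)) {
    # escape: 48 consecutive ones starting at idx
    if (idx + RICE_ESCAPE_Q + 31L <= nb + 1L &&
        idx + RICE_ESCAPE_Q - 1L <= nb &&
        all(bits[idx:(idx + RICE_ESCAPE_Q - 1L)] == 1L)) {
      lo <- idx + RICE_ESCAPE_Q
      hi <- lo + 31L
      if (hi > nb) stop("truncated Rice stream (escape payload)")
      out[k] <- sum(bits[lo:hi] * esc_pows)
      idx <- hi + 1L
      next
    }
    while (zi <= length(zpos) && zpos[zi] < idx) zi <- zi + 1L
    if (zi > length(zpos)) stop("truncated Rice stream (no terminator)")
    term <- zpos[zi]
    q <- term - idx
    idx <- term + 1L
    if (m > 0) {
      if (idx + m - 1L > nb) stop("truncated Rice stream (remainder)")
      r <- sum(bits[idx:(idx + m - 1L)] * rem_pows)
      idx <- idx + m
    } else r <- 0
    out[k] <- q * 2^m + r
  }
  list(values = out, bits_used = idx - 1L)
}

#' Select the Rice order for a block of residuals
#'
#' Exhaustively evaluates the total encoded size
#' `sum(m + floor(u / 2^m) + 1)` over `m = 0..15` on the zigzag-mapped
#' residuals and returns the minimizer, ties broken toward the smaller
#' order. A streaming heuristic (`mode = "streaming"`) instead takes
#' `m = floor(log2(max(1, mean(u))))` — cheaper, one pass, but not
#' guaranteed optimal; the exhaustive two-pass search is the default
#' because the codec's block structure already requires buffering.
#'
#' @param residuals signed integer residuals (non-empty).
#' @param mode `"exhaustive"` (default) or `"streaming"`.
#' @return Rice order m in 0..15.
#' @export
select_rice_order <- function(residuals, mode = c("exhaustive", "streaming")) {
  mode <- match.arg(mode)
  if (length(residuals) == 0) return(0L)
  u <- zigzag(residuals)
  if (mode == "streaming") {
    return(as.integer(min(15, floor(log2(max(1, mean(u)))))))
  }
  costs <- vapply(0:15, function(m) sum(m + u %/% 2^m + 1), numeric(1))
  as.integer(which.min(costs) - 1L)
}

#' Pack a bit vector into bytes / unpack bytes into bits
#'
#' Bytes are filled most-significant-bit first and the final byte is
#' zero-padded; this layout is part of the container format contract.
#'
#' @param bits integer 0/1 vector.
#' @return `bits_to_raw()`: a raw vector; `raw_to_bits()`: integer 0/1
#'   vector of length `8 * length(raw)` (padding included).
#' @export
bits_to_raw <- function(bits) {
  if (length(bits) == 0) return(raw(0))
  pad <- (-length(bits)) %% 8
  bits <- c(as.integer(bits), integer(pad))
  mat <- matrix(bits, nrow = 8)        # column = one byte, row 1 = MSB
  packBits(as.logical(mat[8:1, ]), type = "raw")
}

#' @rdname bits_to_raw
#' @param bytes raw vector.
#' @export
raw_to_bits <- function(bytes) {
  if (length(bytes) == 0) return(integer(0))
  bits <- as.integer(rawToBits(bytes))       # LSB-first within each byte
  mat <- matrix(bits, nrow = 8)
  as.integer(mat[8:1, ])
}
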