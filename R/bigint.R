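# Exact signed big-integer arithmetic in plain R (base-1e6 limbs in doubles).
# This is the arithmetic behind the plaintext reference pipeline and the
# exact rational-comparison oracle. It deliberately shares no code with the
# compiled ring kernel so that secure-vs-plaintext agreement is a genuine
# dual-route check, and it is exact where doubles are not: the integer-fraction
# statistics reach ~2^56 at 1080 donors and the cross-multiplied comparisons
# ~2^80.

BI_BASE <- 1e6

bi_trim <- function(mag) {
  n <- length(mag)
  while (n > 1 && mag[n] == 0) n <- n - 1
  mag[seq_len(n)]
}

bi_carry <- function(mag) {
  repeat {
    c <- floor(mag / BI_BASE)
    if (all(c == 0)) break
    mag <- mag - c * BI_BASE
    mag <- c(mag, 0)[seq_len(length(mag) + 1)]
    mag[-1] <- mag[-1] + c
  }
  bi_trim(mag)
}

# construct from a double holding an exact integer (|x| < 2^53)
bi <- function(x) {
  stopifnot(length(x) == 1, x == floor(x), abs(x) < 2^53)
  sign <- if (x > 0) 1L else if (x < 0) -1L else 0L
  x <- abs(x)
  mag <- numeric(0)
  repeat {
    mag <- c(mag, x %% BI_BASE)
    x <- x %/% BI_BASE
    if (x == 0) break
  }
  structure(list(sign = sign, mag = mag), class = "bigint")
}

bi_is_zero <- function(a) a$sign == 0L

# compare magnitudes: -1, 0, 1
bi_mag_cmp <- function(a, b) {
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}

bi_mag_add <- function(a, b) {
  n <- max(length(a), length(b))
  bi_carry(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

# requires |a| >= |b|
bi_mag_sub <- function(a, b) {
  n <- length(a)
  r <- a - c(b, numeric(n - length(b)))
  # borrow propagation
  for (i in seq_len(n - 1)) {
    if (r[i] < 0) { r[i] <- r[i] + BI_BASE; r[i + 1] <- r[i + 1] - 1 }
  }
  stopifnot(r[n] >= 0)
  bi_trim(r)
}

bi_add <- function(a, b) {
  if (bi_is_zero(a)) return(b)
  if (bi_is_zero(b)) return(a)
  if (a$sign == b$sign) {
    structure(list(sign = a$sign, mag = bi_mag_add(a$mag, b$mag)),
              class = "bigint")
  } else {
    cmp <- bi_mag_cmp(a$mag, b$mag)
    if (cmp == 0) return(bi(0))
    if (cmp > 0) {
      structure(list(sign = a$sign, mag = bi_mag_sub(a$mag, b$mag)),
                class = "bigint")
    } else {
      structure(list(sign = b$sign, mag = bi_mag_sub(b$mag, a$mag)),
                class = "bigint")
    }
  }
}

bi_neg <- function(a) structure(list(sign = -a$sign, mag = a$mag),
                                class = "bigint")

bi_sub <- function(a, b) bi_add(a, bi_neg(b))

bi_mul <- function(a, b) {
  if (bi_is_zero(a) || bi_is_zero(b)) return(bi(0))
  la <- length(a$mag); lb <- length(b$mag)
  acc <- numeric(la + lb)
  for (i in seq_len(la)) {
    idx <- i:(i + lb - 1)
    acc[idx] <- acc[idx] + a$mag[i] * b$mag
    # keep partial sums inside exact-double range
    if (i %% 8 == 0) acc <- c(bi_carry(acc), numeric(la + lb))[seq_len(la + lb)]
  }
  structure(list(sign = a$sign * b$sign, mag = bi_carry(acc)),
            class = "bigint")
}

# signed comparison: -1, 0, 1
bi_cmp <- function(a, b) {
  if (a$sign != b$sign) return(sign(a$sign - b$sign))
  if (a$sign == 0) return(0)
  a$sign * bi_mag_cmp(a$mag, b$mag)
}

bi_to_str <- function(a) {
  if (bi_is_zero(a)) return("0")
  digits <- paste0(rev(sprintf("%06d", a$mag)), collapse = "")
  digits <- sub("^0+", "", digits)
  paste0(if (a$sign < 0) "-" else "", digits)
}

bi_to_num <- function(a) {
  v <- sum(a$mag * BI_BASE^(seq_along(a$mag) - 1))
  a$sign * v
}

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint>", bi_to_str(x), "\n")
  invisible(x)
}
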