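#' Ring configuration for secret sharing
#'
#' All secure values live on the ring of integers modulo `2^k`. Shares and
#' intermediate products are represented as base-2^32 limb matrices handled by
#' compiled code; `k` is configurable because the integer-fraction test
#' statistics overflow narrow rings (see [ring_width_check()]).
#'
#' @param k Bit width of the ring modulus (modulus is `2^k`). Production runs
#'   use k >= 8 (default 128); tiny rings (k >= 4) are allowed for exhaustive
#'   verification.
#' @return An object of class `ring_config` with fields `k` and `L`
#'   (the number of 32-bit limbs).
#' @export
ring_config <- function(k = 128L) {
  k <- as.integer(k)
  if (is.na(k) || k < 4L) stop("ring width k must be an integer >= 4")
  structure(list(k = k, L = rl_nlimbs(k)), class = "ring_config")
}

#' @export
print.ring_config <- function(x, ...) {
  cat(sprintf("<ring_config> Z_{2^%d} (%d limbs)\n", x$k, x$L))
  invisible(x)
}

# limb matrix holding 2^e on a k-bit ring (e < k)
ring_pow2 <- function(e, k) {
  L <- rl_nlimbs(k)
  m <- matrix(0, L, 1)
  m[e %/% 32 + 1L, 1L] <- 2^(e %% 32)
  m
}

# limb matrix from a numeric vector (|x| < 2^53)
ring_from_num <- function(x, k) rl_from_num(as.numeric(x), k)
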