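#' Simulated three-host secure computation session
#'
#' Creates the in-process simulation of three data hosts plus a trusted dealer:
#' 3-out-of-3 additive secret sharing over `Z_{2^k}`, local homomorphic
#' addition, Beaver-triple secure multiplication, dealer-assisted secure
#' comparison and audited opening of values. The three hosts are actors
#' exchanging messages through a recorded message bus; the bus counters are the
#' test surface for the communication-discipline properties (local operations
#' send nothing; interactive protocols send a number of messages that depends
#' only on operand shapes, never on the data). The model is honest-but-curious:
#' parties follow the protocol but may inspect what they see, which is why
#' every value that crosses the bus is uniformly masked.
#'
#' One root seed is split into independent randomness streams for secret
#' sharing, Beaver triples and comparison masks, so a run is reproducible from
#' `(inputs, seed)` alone.
#'
#' @param k Ring bit width (default 128; see [ring_width_check()]).
#' @param seed Integer root seed for all randomness in the session.
#' @return An environment of class `mpc_session`.
#' @export
mpc_session <- function(k = 128L, seed = 1L) {
  ring <- ring_config(k)
  s <- new.env(parent = emptyenv())
  s$ring <- ring
  s$k <- ring$k
  s$seed <- as.integer(seed)
  base <- as.integer(abs(seed) %% 2147480000)
  s$streams <- list(
    sharing = .capture_rng_state(base + 11L),
    triples = .capture_rng_state(base + 37L),
    masks   = .capture_rng_state(base + 59L)
  )
  s$ntriples <- 0
  s$bus <- new.env(parent = emptyenv())  # per-op message counters
  s$audit <- list()                      # one entry per open_value() call
  class(s) <- "mpc_session"
  s
}

#' @export
print.mpc_session <- function(x, ...) {
  cat(sprintf("<mpc_session> ring Z_{2^%d}, seed %d, %d Beaver triples issued, %d opened values\n",
              x$k, x$seed, x$ntriples, length(x$audit)))
  invisible(x)
}

# -- seeded independent RNG streams (saved .Random.seed states) ---------------

.capture_rng_state <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  st <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  st
}

with_stream <- function(session, name, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", session$streams[[name]], envir = globalenv())
  on.exit({
    session$streams[[name]] <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# -- message bus --------------------------------------------------------------

bus_record <- function(session, op, n_messages) {
  cur <- get0(op, envir = session$bus, inherits = FALSE)
  if (is.null(cur)) cur <- c(calls = 0, messages = 0)
  assign(op, cur + c(1, n_messages), envir = session$bus)
  invisible(NULL)
}

#' Message-bus counters of a session
#'
#' @param session An [mpc_session()].
#' @return A data frame with one row per operation type: number of protocol
#'   invocations and total host-to-host messages.
#' @export
bus_counts <- function(session) {
  ops <- sort(ls(session$bus))
  if (length(ops) == 0)
    return(data.frame(op = character(), calls = numeric(), messages = numeric()))
  m <- t(vapply(ops, function(o) get(o, envir = session$bus), numeric(2)))
  data.frame(op = ops, calls = m[, 1], messages = m[, 2], row.names = NULL)
}

# -- shared vectors -----------------------------------------------------------

new_shared_vector <- function(shares, k, n, bit = FALSE) {
  structure(list(shares = shares, k = k, n = n, bit = bit),
            class = "shared_vector")
}

#' @export
print.shared_vector <- function(x, ...) {
  cat(sprintf("<shared_vector> %d element(s) on Z_{2^%d}%s (shares withheld)\n",
              x$n, x$k, if (isTRUE(x$bit)) ", bit-valued" else ""))
  invisible(x)
}

#' @export
length.shared_vector <- function(x) x$n

check_same_ring <- function(a, b) {
  if (a$k != b$k) stop("protocol error: operands on different rings")
}

#' Secret-share a vector of integers
#'
#' Splits each value into three additive shares over `Z_{2^k}`: shares for
#' hosts 0 and 1 are drawn uniformly from the session's sharing stream and host
#' 2 receives the difference, so the shares sum to the secret mod `2^k` while
#' any single share — and any pair of shares — is marginally uniform on the
#' ring. Signed inputs are mapped to two's complement.
#'
#' @param x Numeric vector of integers with `|x| < 2^53`, or a limb matrix.
#' @param session An [mpc_session()].
#' @param bit Mark the result as bit-valued (caller asserts secrets in {0,1}).
#' @return A `shared_vector`.
#' @export
share_secret <- function(x, session, bit = FALSE) {
  k <- session$k
  if (!is.matrix(x) && any(x >= 2^k | x <= -2^(k - 1)))
    stop("range error: value outside ring")
  v <- if (is.matrix(x)) x else ring_from_num(x, k)
  n <- ncol(v)
  shares <- with_stream(session, "sharing", rl_share(v, k))
  new_shared_vector(shares, k, n, bit = bit)
}

# sharing helper using an arbitrary stream (dealer randomness for triples/masks)
.share_with_stream <- function(v, session, stream) {
  k <- session$k
  n <- ncol(v)
  shares <- with_stream(session, stream, rl_share(v, k))
  new_shared_vector(shares, k, n)
}

# trivial (non-random) sharing of a public constant vector
shared_constant <- function(x, session, bit = FALSE) {
  k <- session$k
  v <- if (is.matrix(x)) x else ring_from_num(x, k)
  zero <- matrix(0, nrow(v), ncol(v))
  new_shared_vector(list(v, zero, zero), k, ncol(v), bit = bit)
}

#' Reconstruct secret-shared values
#'
#' Sums the three shares mod `2^k`. This is a test/verification utility and is
#' also the final step of [open_value()]; the secure pipeline itself only ever
#' opens decision bits.
#'
#' @param v A `shared_vector`.
#' @param signed Interpret the result as a two's-complement signed value.
#' @return Numeric vector (closest double; use [reconstruct_str()] for exact
#'   values beyond 2^53).
#' @export
reconstruct <- function(v, signed = FALSE) {
  stopifnot(inherits(v, "shared_vector"))
  if (length(v$shares) != 3) stop("protocol error: missing share")
  tot <- rl_add(rl_add(v$shares[[1]], v$shares[[2]], v$k), v$shares[[3]], v$k)
  rl_to_num(tot, v$k, signed)
}

#' @rdname reconstruct
#' @export
reconstruct_str <- function(v) {
  tot <- rl_add(rl_add(v$shares[[1]], v$shares[[2]], v$k), v$shares[[3]], v$k)
  rl_to_str(tot)
}

# -- local (communication-free) operations ------------------------------------

#' Homomorphic operations on shared values
#'
#' `add_shared`, `sub_shared`, `add_public` and `mul_public` are local: each
#' host operates on its own share and no messages cross the bus. Public
#' constants may be scalars or per-element vectors; `add_public` adds the
#' constant to host 0's share only.
#'
#' @param a,b `shared_vector`s on a common ring (length-1 operands recycle).
#' @param c Public integer constant(s) (numeric vector or limb matrix).
#' @return A `shared_vector`.
#' @export
add_shared <- function(a, b) {
  check_same_ring(a, b)
  k <- a$k
  new_shared_vector(
    lapply(1:3, function(i) rl_add(a$shares[[i]], b$shares[[i]], k)),
    k, max(a$n, b$n))
}

#' @rdname add_shared
#' @export
sub_shared <- function(a, b) {
  check_same_ring(a, b)
  k <- a$k
  new_shared_vector(
    lapply(1:3, function(i) rl_sub(a$shares[[i]], b$shares[[i]], k)),
    k, max(a$n, b$n))
}

#' @rdname add_shared
#' @export
add_public <- function(a, c) {
  k <- a$k
  cv <- if (is.matrix(c)) c else ring_from_num(c, k)
  s0 <- rl_add(a$shares[[1]], cv, k)
  n <- max(a$n, ncol(cv))
  if (ncol(s0) > ncol(a$shares[[2]])) {
    # broadcasting against a length-1 shared value: replicate other shares
    idx <- rep(1L, ncol(s0))
    new_shared_vector(list(s0, a$shares[[2]][, idx, drop = FALSE],
                           a$shares[[3]][, idx, drop = FALSE]), k, n)
  } else {
    new_shared_vector(list(s0, a$shares[[2]], a$shares[[3]]), k, n)
  }
}

#' @rdname add_shared
#' @export
mul_public <- function(a, c) {
  k <- a$k
  cv <- if (is.matrix(c)) c else ring_from_num(c, k)
  new_shared_vector(
    lapply(a$shares, function(s) rl_mul(s, cv, k)),
    k, max(a$n, ncol(cv)))
}

# negate: 0 - a (local)
neg_shared <- function(a) {
  k <- a$k
  zero <- matrix(0, rl_nlimbs(k), 1)
  new_shared_vector(lapply(a$shares, function(s) rl_sub(zero, s, k)), k, a$n)
}

# -- interactive protocols ----------------------------------------------------

# open a masked/protocol-internal value: counts bus messages (each host
# broadcasts its share to the two others) but is NOT an audited release --
# everything opened this way is uniformly distributed by construction.
open_internal <- function(v, session, op) {
  bus_record(session, op, 6 * v$n)
  rl_add(rl_add(v$shares[[1]], v$shares[[2]], v$k), v$shares[[3]], v$k)
}

#' Secure multiplication of shared values
#'
#' Beaver-triple multiplication: the trusted dealer supplies a fresh shared
#' triple `(alpha, beta, gamma = alpha*beta)` from the session's dealer
#' stream (triples are never reused); the hosts open only the masked
#' differences `a - alpha` and `b - beta`, which are uniform on the ring and
#' leak nothing, then combine them locally.
#'
#' @param a,b `shared_vector`s (length-1 operands recycle against the other).
#' @param session An [mpc_session()].
#' @return A `shared_vector` reconstructing to `a*b mod 2^k`.
#' @export
mul_shared <- function(a, b, session) {
  check_same_ring(a, b)
  k <- a$k
  n <- max(a$n, b$n)
  shares <- with_stream(session, "triples", rl_mul_shared(a$shares, b$shares, k))
  session$ntriples <- session$ntriples + n
  bus_record(session, "mul_shared", 12 * n)  # two masked openings of width n
  new_shared_vector(shares, k, n)
}

#' Secure greater-or-equal comparison
#'
#' Dealer-assisted comparison of non-negative shared integers. Both operands
#' must be below `2^(k-2)` (the caller's obligation, enforced at pipeline
#' configuration by [ring_width_check()]); then `d = a - b + 2^(k-2)` lies in
#' `[0, 2^(k-1))` and `a >= b` iff bit `k-2` of `d` is set. The hosts open
#' `c = d + r` for a dealer-drawn uniform mask `r` (uniform, leaks nothing);
#' the dealer shares the bits of `r`, and the bits of `d = c - r` are
#' recovered through a borrow-propagation chain over the shared mask bits and
#' the public bits of `c`, costing one secure multiplication per bit.
#'
#' @param a,b `shared_vector`s of non-negative secrets below `2^(k-2)`.
#' @param session An [mpc_session()].
#' @return A bit-valued `shared_vector` reconstructing to 1 iff `a >= b`.
#' @export
secure_geq <- function(a, b, session) {
  check_same_ring(a, b)
  k <- a$k
  n <- max(a$n, b$n)
  d <- add_public(sub_shared(a, b), ring_pow2(k - 2L, k))

  r <- with_stream(session, "masks", rl_rand(n, k))
  rbits <- rl_bits(r, k)                       # dealer-side plaintext bits
  r_sh <- .share_with_stream(r, session, "masks")
  # dealer shares each needed bit plane of r
  bit_sh <- vector("list", k - 1L)
  for (j in seq_len(k - 1L)) {                 # positions 0 .. k-2
    bv <- ring_from_num(rbits[j, ], k)
    bit_sh[[j]] <- .share_with_stream(bv, session, "masks")
  }

  c_pub <- open_internal(add_shared(d, r_sh), session, "secure_geq")
  cbits <- rl_bits(c_pub, k)                   # public

  # borrow chain for d = c - r over positions 0 .. k-3
  bor <- shared_constant(numeric(n), session)
  one_minus_2 <- function(cj) 1 - 2 * cj
  if (k >= 3L) for (j in seq_len(k - 2L)) {    # position j-1
    cj <- cbits[j, ]
    t <- mul_shared(bit_sh[[j]], bor, session)
    # next borrow = t + (1-c)*(r + bor - 2t)
    lin <- sub_shared(add_shared(bit_sh[[j]], bor), mul_public(t, 2))
    bor <- add_shared(t, mul_public(lin, 1 - cj))
  }

  # bit k-2 of d = c_{k-2} XOR r_{k-2} XOR borrow
  rb <- bit_sh[[k - 1L]]
  t <- mul_shared(rb, bor, session)
  x <- sub_shared(add_shared(rb, bor), mul_public(t, 2))
  ctop <- cbits[k - 1L, ]
  out <- add_public(mul_public(x, 1 - 2 * ctop), ctop)
  out$bit <- TRUE
  out
}

#' Open a shared value to all parties
#'
#' The controlled release point of the engine: all three hosts agree to
#' disclose their shares, the value becomes public, and an audit record of
#' what was opened is appended to the session. The secure GWAS pipeline calls
#' this only for per-SNP decision bits (and the Benjamini-Hochberg rejection
#' count); the audit log makes that checkable.
#'
#' @param v A `shared_vector`.
#' @param session An [mpc_session()].
#' @param what Short label recorded in the audit log.
#' @param signed Two's-complement interpretation of the released value.
#' @return Numeric vector of the released values.
#' @export
open_value <- function(v, session, what = "value", signed = FALSE) {
  bus_record(session, "open", 6 * v$n)
  out <- reconstruct(v, signed = signed)
  session$audit <- c(session$audit,
                     list(list(what = what, n = v$n, values = out)))
  out
}

#' Audit log of opened values
#'
#' @param session An [mpc_session()].
#' @return List of audit records (label, length, released values).
#' @export
audit_log <- function(session) session$audit

# -- shape utilities (local share manipulation, no communication) -------------

sv_index <- function(v, idx) {
  new_shared_vector(lapply(v$shares, function(s) s[, idx, drop = FALSE]),
                    v$k, length(idx), bit = v$bit)
}

sv_tile <- function(v, times) {
  idx <- rep(seq_len(v$n), times = times)
  sv_index(v, idx)
}

sv_concat <- function(lst) {
  k <- lst[[1]]$k
  shares <- lapply(1:3, function(i)
    do.call(cbind, lapply(lst, function(v) v$shares[[i]])))
  new_shared_vector(shares, k, sum(vapply(lst, function(v) v$n, 0L)))
}

# local summation of elements by group (for secure dot products)
sv_sum_groups <- function(v, group, ngroups) {
  k <- v$k
  new_shared_vector(
    lapply(v$shares, function(s)
      rl_sum_groups(s, k, as.integer(group), as.integer(ngroups))),
    k, as.integer(ngroups))
}

sv_sum <- function(v) sv_sum_groups(v, rep(1L, v$n), 1L)
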