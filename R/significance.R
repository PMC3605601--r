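#' Rational approximation of the chi-square critical value
#'
#' Significance decisions never touch floating point on shares: the upper-alpha
#' critical value `t(alpha)` of the chi-square distribution with 1 df is
#' approximated publicly by the integer fraction `p/q` with
#' `p = floor(t(alpha) * q)`, so `p/q <= t(alpha) < (p+1)/q`. Flooring errs
#' toward declaring significance by at most `1/q`; the disagreement band with
#' the floating-point decision shrinks as `1/q`.
#'
#' @param alpha Nominal significance level in (0, 1).
#' @param q_precision Public denominator `q` (default `1e6`, minimum `1e3`).
#' @return A `rational_threshold` with fields `p`, `q`, `alpha`, `t`.
#' @export
chi2_critical_rational <- function(alpha, q_precision = 1e6) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (q_precision < 1e3) stop("q_precision must be at least 1e3")
  t <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  structure(list(p = floor(t * q_precision), q = q_precision,
                 alpha = alpha, t = t),
            class = "rational_threshold")
}

#' @export
print.rational_threshold <- function(x, ...) {
  cat(sprintf("<rational_threshold> p/q = %.0f/%.0f ~ chi^2(1) upper-%g critical value %.6f\n",
              x$p, x$q, x$alpha, x$t))
  invisible(x)
}

#' Bonferroni-corrected rational threshold
#'
#' Builds the threshold at level `alpha / n_tests` — the conservative
#' family-wise correction for a genome-wide scan.
#'
#' @param alpha Family-wise level.
#' @param n_tests Number of tests (SNPs).
#' @param q_precision Public denominator.
#' @return A `rational_threshold`.
#' @export
bonferroni <- function(alpha, n_tests, q_precision = 1e6) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  chi2_critical_rational(alpha / n_tests, q_precision)
}

#' Ring-width overflow check
#'
#' The secure comparison contract requires every compared operand below
#' `2^(k-2)`. The largest operands in the pipeline are `m*q` and `p*n`; with
#' `N` donors every count is at most `2N`, so `16*(2N)^5*q` bounds the
#' worst case over all four tests. The check is pure and public.
#'
#' @param k Ring width.
#' @param n_donors Donor count `N`.
#' @param q_precision Threshold denominator `q`.
#' @return List with `ok`, the minimal safe width `k_min`, and the bound's
#'   base-2 logarithm.
#' @export
ring_width_check <- function(k, n_donors, q_precision = 1e6) {
  lb <- 4 + 5 * log2(2 * n_donors) + log2(q_precision)  # log2 of 16 (2N)^5 q
  k_min <- floor(lb) + 3  # smallest k with bound < 2^(k-2)
  list(ok = (k - 2) > lb, k_min = as.integer(k_min), bound_log2 = lb)
}

#' Decide per-SNP significance from shared fractions
#'
#' `m/n >= p/q` is decided as the integer comparison `m*q >= p*n` (the `>=`
#' convention holds at the boundary): both products are computed locally from
#' public `p`, `q`, the secure comparison produces a shared bit, and only the
#' decision bits — plus the public undefined-statistic flags for SNPs with
#' `n = 0` — are opened. Undefined statistics decide 0.
#'
#' @param stat A `rational_stat` (vectorized over SNPs).
#' @param threshold A `rational_threshold`.
#' @param session An [mpc_session()].
#' @return A `decision_vector`: data frame columns `snp_id`, `test`,
#'   `decision`, `undefined`.
#' @export
decide <- function(stat, threshold, session) {
  chk <- ring_width_check_stat(stat, threshold, session)
  mq <- mul_public(stat$m, threshold$q)
  pn <- mul_public(stat$n, threshold$p)
  bit <- secure_geq(mq, pn, session)
  defined <- secure_geq(stat$n, shared_constant(rep(1, stat$n$n), session),
                        session)
  dec <- mul_shared(bit, defined, session)
  decision <- open_value(dec, session, what = sprintf("%s decision bits", stat$test))
  defined_pub <- open_value(defined, session,
                            what = sprintf("%s undefined-statistic flags", stat$test))
  structure(data.frame(snp_id = stat$snp_ids, test = stat$test,
                       decision = as.integer(decision),
                       undefined = 1L - as.integer(defined_pub),
                       stringsAsFactors = FALSE),
            class = c("decision_vector", "data.frame"))
}

# configuration-time guard: refuse silent wraparound
ring_width_check_stat <- function(stat, threshold, session) {
  k <- session$k
  # conservative public bound: q and p are public; m, n are below 2^(k-2)/q by
  # the pipeline-level ring_width_check, which callers run at configuration.
  if (log2(max(threshold$p, threshold$q)) + 2 > k - 2)
    stop("configuration error: threshold exceeds ring capacity; increase k")
  invisible(TRUE)
}

#' Oblivious Benjamini-Hochberg procedure on shared statistics
#'
#' Step-up false-discovery-rate control without revealing statistics or their
#' order: the shared fractions are sorted in descending order by a Batcher
#' odd-even merge sorting network (data-independent shape; comparator =
#' cross-multiplied secure comparison with oblivious swap); the rank-`i`
#' statistic is compared against the public rational threshold for level
#' `alpha*i/M` (the p-value condition `p_(i) <= alpha*i/M` mapped into
#' statistic space through the monotone chi-square quantile); the largest
#' qualifying rank `j*` — which equals the rejection count, obtained by a
#' secure suffix-OR — is released, and each SNP's decision is then the audited
#' comparison of its own statistic against the public rank-`j*` threshold.
#' That set provably equals the top-`j*` ranks. Undefined statistics
#' (`n = 0`) are obliviously mapped to the fraction `0/1` first and can never
#' be rejected.
#'
#' @param stat A `rational_stat` over `M` SNPs.
#' @param alpha FDR level.
#' @param session An [mpc_session()].
#' @param q_precision Public denominator for the per-rank thresholds.
#' @return A `decision_vector` with attribute `n_rejected`.
#' @export
secure_bh <- function(stat, alpha, session, q_precision = 1e6) {
  M <- stat$n_snps
  # oblivious defined-statistic normalization: m' = m*def, n' = n + (1-def)
  def <- secure_geq(stat$n, shared_constant(rep(1, M), session), session)
  m_sh <- mul_shared(stat$m, def, session)
  n_sh <- add_shared(stat$n, add_public(neg_shared(def), 1))

  # pad to a power of two with minimal sentinels 0/1
  P <- 2^ceiling(log2(max(M, 2)))
  if (P > M) {
    pad_m <- shared_constant(numeric(P - M), session)
    pad_n <- shared_constant(rep(1, P - M), session)
    m_sh <- sv_concat(list(m_sh, pad_m))
    n_sh <- sv_concat(list(n_sh, pad_n))
  }

  stages <- batcher_stages(P)
  for (st in stages) {
    I <- st[, 1]; J <- st[, 2]
    am <- sv_index(m_sh, I); an <- sv_index(n_sh, I)
    bm <- sv_index(m_sh, J); bn <- sv_index(n_sh, J)
    g <- secure_geq(mul_shared(am, bn, session),
                    mul_shared(bm, an, session), session)
    hi_m <- add_shared(bm, mul_shared(g, sub_shared(am, bm), session))
    hi_n <- add_shared(bn, mul_shared(g, sub_shared(an, bn), session))
    lo_m <- sub_shared(add_shared(am, bm), hi_m)
    lo_n <- sub_shared(add_shared(an, bn), hi_n)
    for (h in 1:3) {
      m_sh$shares[[h]][, I] <- hi_m$shares[[h]]
      m_sh$shares[[h]][, J] <- lo_m$shares[[h]]
      n_sh$shares[[h]][, I] <- hi_n$shares[[h]]
      n_sh$shares[[h]][, J] <- lo_n$shares[[h]]
    }
  }

  # public per-rank thresholds (alpha, M, ranks are public)
  ranks <- seq_len(M)
  th <- lapply(ranks, function(i)
    chi2_critical_rational(alpha * i / M, q_precision))
  pvec <- vapply(th, function(x) x$p, 0)
  sorted_m <- sv_index(m_sh, ranks)
  sorted_n <- sv_index(n_sh, ranks)
  g <- secure_geq(mul_public(sorted_m, q_precision),
                  mul_public(sorted_n, pvec), session)

  # suffix OR, then the rejection count j* = sum_i h_i is released
  h <- sv_index(g, M)
  hsum <- h
  if (M > 1) for (i in (M - 1):1) {
    gi <- sv_index(g, i)
    h <- sub_shared(add_shared(gi, h), mul_shared(gi, h, session))
    hsum <- add_shared(hsum, h)
  }
  j_star <- open_value(sv_index(hsum, 1), session,
                       what = "BH rejection count")

  if (j_star >= 1) {
    th_j <- th[[j_star]]
    m_adj <- mul_shared(stat$m, def, session)
    n_adj <- add_shared(stat$n, add_public(neg_shared(def), 1))
    bit <- secure_geq(mul_public(m_adj, th_j$q),
                      mul_public(n_adj, th_j$p), session)
    dec <- mul_shared(bit, def, session)
    decision <- open_value(dec, session, what = sprintf("%s BH decision bits", stat$test))
  } else {
    decision <- numeric(M)
    open_value(shared_constant(decision, session), session,
               what = sprintf("%s BH decision bits", stat$test))
  }
  defined_pub <- open_value(def, session,
                            what = sprintf("%s undefined-statistic flags", stat$test))
  out <- structure(data.frame(snp_id = stat$snp_ids, test = stat$test,
                              decision = as.integer(decision),
                              undefined = 1L - as.integer(defined_pub),
                              stringsAsFactors = FALSE),
                   class = c("decision_vector", "data.frame"))
  attr(out, "n_rejected") <- as.integer(j_star)
  out
}

# ---------------------------------------------------------------------------
# Batcher odd-even mergesort comparator schedule for n a power of two,
# grouped into stages of disjoint comparators (classic recursive
# construction; greedy layering preserves dependency order).
# ---------------------------------------------------------------------------
batcher_comparators <- function(n) {
  out <- list()
  merge_rng <- function(lo, len, r) {
    step <- 2 * r
    if (step < len) {
      merge_rng(lo, len, step)
      merge_rng(lo + r, len, step)
      i <- seq(lo + r, lo + len - 1 - r, by = step)
      out[[length(out) + 1]] <<- cbind(i, i + r)
    } else {
      out[[length(out) + 1]] <<- cbind(lo, lo + r)
    }
  }
  sort_rng <- function(lo, len) {
    if (len > 1) {
      mid <- len / 2
      sort_rng(lo, mid)
      sort_rng(lo + mid, mid)
      merge_rng(lo, len, 1)
    }
  }
  sort_rng(1, n)
  do.call(rbind, out)
}

batcher_stages <- function(n) {
  if (n < 2) return(list())
  comp <- batcher_comparators(n)
  last <- integer(n)   # last stage each wire was touched
  stage_of <- integer(nrow(comp))
  for (r in seq_len(nrow(comp))) {
    i <- comp[r, 1]; j <- comp[r, 2]
    s <- max(last[i], last[j]) + 1L
    stage_of[r] <- s
    last[i] <- s; last[j] <- s
  }
  lapply(seq_len(max(stage_of)), function(s)
    comp[stage_of == s, , drop = FALSE])
}

#' Write decision output
#'
#' Persists the released decisions as a TSV (`snp_id`, `test`, `decision`,
#' `undefined`) plus a JSON run-metadata file (level, correction, `p/q`, ring
#' width, seeds, operation counts).
#'
#' @param decisions A `decision_vector`.
#' @param path Output TSV path.
#' @param metadata Named list written alongside as `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path, metadata = list()) {
  utils::write.table(decisions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(metadata) > 0)
    jsonlite::write_json(metadata, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
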