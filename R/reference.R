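# ---------------------------------------------------------------------------
# Plaintext reference pipeline: the same tables, statistics and decisions as
# the secure path, computed on cleartext with exact big-integer arithmetic.
# Used for verification (the secure pipeline must match it bit for bit) and
# as the CLI's `decide-only` backend. It shares no code with the ring kernel.
# ---------------------------------------------------------------------------

#' Plaintext contingency tables
#'
#' Reference tabulations of the reconstructed-equivalent counts from cleartext
#' calls: allele 2x2 table, genotype 2x3 table with margins, and TDT
#' transmission counts, vectorized over SNPs.
#'
#' @param m A [genotype_matrix()].
#' @param case_idx,ctrl_idx Donor column indices of the two groups.
#' @return A data frame of per-SNP counts.
#' @export
plaintext_allele_table <- function(m, case_idx, ctrl_idx) {
  fa <- matrix(c(AA = 2, AB = 1, BB = 0, NN = 0)[m$calls], nrow(m$calls))
  fb <- matrix(c(AA = 0, AB = 1, BB = 2, NN = 0)[m$calls], nrow(m$calls))
  data.frame(snp_id = m$snp_ids,
             a = rowSums(fa[, case_idx, drop = FALSE]),
             c = rowSums(fb[, case_idx, drop = FALSE]),
             b = rowSums(fa[, ctrl_idx, drop = FALSE]),
             d = rowSums(fb[, ctrl_idx, drop = FALSE]),
             stringsAsFactors = FALSE)
}

#' @rdname plaintext_allele_table
#' @export
plaintext_genotype_table <- function(m, case_idx, ctrl_idx) {
  cnt <- function(idx, g) rowSums(m$calls[, idx, drop = FALSE] == g)
  t <- data.frame(snp_id = m$snp_ids,
                  r0 = cnt(case_idx, "AA"), r1 = cnt(case_idx, "AB"),
                  r2 = cnt(case_idx, "BB"),
                  s0 = cnt(ctrl_idx, "AA"), s1 = cnt(ctrl_idx, "AB"),
                  s2 = cnt(ctrl_idx, "BB"),
                  stringsAsFactors = FALSE)
  t$m1 <- t$r0 + t$r1 + t$r2
  t$m2 <- t$s0 + t$s1 + t$s2
  t$n0 <- t$r0 + t$s0; t$n1 <- t$r1 + t$s1; t$n2 <- t$r2 + t$s2
  t$N <- t$m1 + t$m2
  t
}

#' @rdname plaintext_allele_table
#' @param trios A [trio_structure()].
#' @export
plaintext_tdt_counts <- function(m, trios) {
  informative <- m$calls[, trios$mother, drop = FALSE] == "AB" &
    m$calls[, trios$father, drop = FALSE] == "AB"
  child <- m$calls[, trios$child, drop = FALSE]
  data.frame(snp_id = m$snp_ids,
             u = rowSums(informative & child == "AA"),
             v = rowSums(informative & child == "BB"),
             stringsAsFactors = FALSE)
}

# exact integer fraction (bigint pair) of one statistic
ref_fraction <- function(test, row, weights = c(0, 1, 2)) {
  switch(test,
    chi2 = {
      with(row, {
        N <- bi(a + b + c + d)
        diff <- bi_sub(bi_mul(bi(a), bi(d)), bi_mul(bi(b), bi(c)))
        m <- bi_mul(N, bi_mul(diff, diff))
        n <- bi_mul(bi_mul(bi(a + b), bi(c + d)),
                    bi_mul(bi(a + c), bi(b + d)))
        list(m = m, n = n)
      })
    },
    chi2prop = {
      with(row, {
        n1 <- a + c; n2 <- b + d
        N <- bi(n1 + n2)
        diff <- bi_sub(bi_mul(bi(a), bi(n2)), bi_mul(bi(b), bi(n1)))
        m <- bi_mul(N, bi_mul(diff, diff))
        n <- bi_mul(bi_mul(bi(n1), bi(n2)), bi_mul(bi(a + b), bi(c + d)))
        list(m = m, n = n)
      })
    },
    catt = {
      w <- weights
      with(row, {
        acc <- bi(w[1] * (m2 * r0 - m1 * s0) + w[2] * (m2 * r1 - m1 * s1) +
                  w[3] * (m2 * r2 - m1 * s2))
        m <- bi_mul(bi(N), bi_mul(acc, acc))
        swn2 <- w[1]^2 * n0 + w[2]^2 * n1 + w[3]^2 * n2
        swn <- w[1] * n0 + w[2] * n1 + w[3] * n2
        var_term <- bi_sub(bi_mul(bi(N), bi(swn2)), bi_mul(bi(swn), bi(swn)))
        n <- bi_mul(bi_mul(bi(m1), bi(m2)), var_term)
        list(m = m, n = n)
      })
    },
    tdt = {
      with(row, {
        diff <- bi(u - v)
        list(m = bi_mul(diff, diff), n = bi(u + v))
      })
    },
    stop("unknown test")
  )
}

#' Plaintext statistics as exact integer fractions
#'
#' @param test One of `"chi2"`, `"chi2prop"`, `"catt"`, `"tdt"`.
#' @param tab Per-SNP count table from the matching `plaintext_*` function.
#' @param weights Trend weights (CATT only).
#' @return Data frame with exact decimal strings `m`, `n` and the floating
#'   value `m/n` (`NA` where undefined).
#' @export
plaintext_stat_fractions <- function(test, tab, weights = c(0, 1, 2)) {
  frs <- lapply(seq_len(nrow(tab)), function(i)
    ref_fraction(test, tab[i, , drop = FALSE], weights))
  m <- vapply(frs, function(f) bi_to_str(f$m), "")
  n <- vapply(frs, function(f) bi_to_str(f$n), "")
  mv <- vapply(frs, function(f) bi_to_num(f$m), 0)
  nv <- vapply(frs, function(f) bi_to_num(f$n), 0)
  data.frame(snp_id = tab$snp_id, m = m, n = n,
             value = ifelse(nv == 0, NA_real_, mv / nv),
             stringsAsFactors = FALSE)
}

# exact decision m/n >= p/q via big-integer cross-multiplication
ref_decide_fraction <- function(m_str, n_str, p, q) {
  m <- bi_from_str(m_str); n <- bi_from_str(n_str)
  defined <- bi_cmp(n, bi(0)) > 0
  dec <- defined && bi_cmp(bi_mul(m, bi(q)), bi_mul(n, bi(p))) >= 0
  c(decision = as.integer(dec), undefined = as.integer(!defined))
}

bi_from_str <- function(s) {
  sign <- 1L
  if (startsWith(s, "-")) { sign <- -1L; s <- substring(s, 2) }
  n <- nchar(s)
  ends <- seq(n, 1, by = -6)  # rightmost chunk first -> little-endian limbs
  mag <- bi_trim(vapply(ends, function(e)
    as.numeric(substr(s, max(1, e - 5), e)), 0))
  if (length(mag) == 1 && mag[1] == 0) sign <- 0L
  structure(list(sign = sign, mag = mag), class = "bigint")
}

#' Plaintext significance decisions
#'
#' Exact rational comparison of each `m/n` against the public `p/q` threshold
#' (Bonferroni built in via the threshold), or the plaintext counterpart of
#' the oblivious Benjamini-Hochberg step-up in statistic space.
#'
#' @param stats Data frame from [plaintext_stat_fractions()].
#' @param threshold A `rational_threshold`.
#' @return A decision data frame (`decision`, `undefined` per SNP).
#' @export
plaintext_decide <- function(stats, threshold) {
  out <- t(vapply(seq_len(nrow(stats)), function(i)
    ref_decide_fraction(stats$m[i], stats$n[i], threshold$p, threshold$q),
    c(decision = 0L, undefined = 0L)))
  data.frame(snp_id = stats$snp_id, decision = out[, "decision"],
             undefined = out[, "undefined"], stringsAsFactors = FALSE)
}

#' @rdname plaintext_decide
#' @param alpha FDR level.
#' @param q_precision Denominator of the per-rank rational thresholds.
#' @return For `plaintext_bh`, a decision data frame with attribute
#'   `n_rejected`.
#' @export
plaintext_bh <- function(stats, alpha, q_precision = 1e6) {
  M <- nrow(stats)
  val <- ifelse(is.na(stats$value), -1, stats$value)
  ord <- order(val, decreasing = TRUE)
  th <- lapply(seq_len(M), function(i)
    chi2_critical_rational(alpha * i / M, q_precision))
  g <- vapply(seq_len(M), function(i) {
    j <- ord[i]
    if (is.na(stats$value[j])) return(0L)
    unname(ref_decide_fraction(stats$m[j], stats$n[j],
                               th[[i]]$p, th[[i]]$q)["decision"])
  }, 0L)
  j_star <- if (any(g == 1)) max(which(g == 1)) else 0L
  if (j_star >= 1) {
    dec <- plaintext_decide(stats, th[[j_star]])
  } else {
    dec <- data.frame(snp_id = stats$snp_id, decision = 0L,
                      undefined = as.integer(is.na(stats$value)),
                      stringsAsFactors = FALSE)
  }
  attr(dec, "n_rejected") <- as.integer(j_star)
  dec
}
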