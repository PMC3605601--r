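#' Association test statistics as exact shared integer fractions
#'
#' Every statistic is held as a non-negative integer fraction `m/n` on shares:
#' `m/n` equals the real-valued statistic exactly, so significance can later be
#' decided with integer-only secure comparison against a rational threshold and
#' no floating point ever touches the shares. Signed intermediate values
#' (`ad - bc`, `m2*r_j - m1*s_j`, `u - v`) live in two's complement on the ring
#' and are squared before any comparison, so `m` and `n` reconstruct to
#' non-negative integers. A denominator that reconstructs to 0 (monomorphic
#' SNP, empty group, no informative trios) marks the statistic undefined; the
#' significance layer maps undefined to "not significant" rather than aborting
#' a genome-wide run.
#'
#' @name rational_stat
NULL

new_rational_stat <- function(m, n, test, n_snps, snp_ids) {
  structure(list(m = m, n = n, test = test, n_snps = n_snps,
                 snp_ids = snp_ids),
            class = "rational_stat")
}

#' @export
print.rational_stat <- function(x, ...) {
  cat(sprintf("<rational_stat> %s for %d SNP(s), held as shared m/n\n",
              x$test, x$n_snps))
  invisible(x)
}

#' Pearson chi-square test of allele-group independence
#'
#' For the 2x2 allele table with cases `(a, c)` and controls `(b, d)`:
#' `m = (a+b+c+d) * (ad - bc)^2`, `n = (a+b)(c+d)(a+c)(b+d)` — the exact
#' integer fraction equal to the Pearson chi-square statistic (1 df for
#' reasonable sample sizes).
#'
#' @param t An [allele_table()].
#' @param session An [mpc_session()].
#' @return A `rational_stat`.
#' @export
chi2_independence <- function(t, session) {
  N <- add_shared(add_shared(t$a, t$b), add_shared(t$c, t$d))
  ad <- mul_shared(t$a, t$d, session)
  bc <- mul_shared(t$b, t$c, session)
  diff <- sub_shared(ad, bc)
  m <- mul_shared(N, mul_shared(diff, diff, session), session)
  n <- mul_shared(mul_shared(add_shared(t$a, t$b), add_shared(t$c, t$d), session),
                  mul_shared(add_shared(t$a, t$c), add_shared(t$b, t$d), session),
                  session)
  new_rational_stat(m, n, "chi2", t$n_snps, t$snp_ids)
}

#' Chi-square test of equal allele-A proportion in the two groups
#'
#' The pooled two-proportion z^2 statistic computed as an exact fraction via
#' its own route (`p1 = a/(a+c)`, `p2 = b/(b+d)`, pooled variance):
#' `m = N * (a*(b+d) - b*(a+c))^2`, `n = (a+c)(b+d)(a+b)(c+d)`. On 2x2 tables
#' this is algebraically the same value as [chi2_independence()]; both are
#' provided and their observed equivalence is verified, not assumed.
#'
#' @inheritParams chi2_independence
#' @return A `rational_stat`.
#' @export
chi2_proportion <- function(t, session) {
  n1 <- add_shared(t$a, t$c)   # case allele total
  n2 <- add_shared(t$b, t$d)   # control allele total
  N <- add_shared(n1, n2)
  diff <- sub_shared(mul_shared(t$a, n2, session),
                     mul_shared(t$b, n1, session))
  m <- mul_shared(N, mul_shared(diff, diff, session), session)
  n <- mul_shared(mul_shared(n1, n2, session),
                  mul_shared(add_shared(t$a, t$b), add_shared(t$c, t$d), session),
                  session)
  new_rational_stat(m, n, "chi2prop", t$n_snps, t$snp_ids)
}

#' Cochran-Armitage trend test
#'
#' Trend across the genotype classes AA/AB/BB with public integer weights
#' `(w0, w1, w2)` chosen for the suspected influence mechanism (default the
#' additive `(0, 1, 2)`):
#' `m = N * (sum_j w_j (m2*r_j - m1*s_j))^2`,
#' `n = m1*m2*(N * sum_j w_j^2 n_j - (sum_j w_j n_j)^2)`.
#' Equals the standard trend statistic exactly; does not assume
#' Hardy-Weinberg equilibrium.
#'
#' @param t A [genotype_table()].
#' @param weights Public integer weights, not all equal; default `c(0, 1, 2)`.
#' @param session An [mpc_session()].
#' @return A `rational_stat`.
#' @export
cochran_armitage <- function(t, session, weights = c(0, 1, 2)) {
  w <- as.numeric(weights)
  if (length(w) != 3 || any(w != floor(w)) || length(unique(w)) == 1)
    stop("trend weights must be three integers, not all equal")
  rs <- list(t$r0, t$r1, t$r2); ss <- list(t$s0, t$s1, t$s2)
  ns <- list(t$n0, t$n1, t$n2)
  # sum_j w_j (m2 r_j - m1 s_j)
  acc <- NULL
  for (j in 1:3) {
    term <- sub_shared(mul_shared(t$m2, rs[[j]], session),
                       mul_shared(t$m1, ss[[j]], session))
    term <- mul_public(term, w[j])
    acc <- if (is.null(acc)) term else add_shared(acc, term)
  }
  m <- mul_shared(t$N, mul_shared(acc, acc, session), session)
  # N sum w^2 n_j - (sum w n_j)^2
  swn2 <- NULL; swn <- NULL
  for (j in 1:3) {
    swn2 <- if (is.null(swn2)) mul_public(ns[[j]], w[j]^2) else
      add_shared(swn2, mul_public(ns[[j]], w[j]^2))
    swn <- if (is.null(swn)) mul_public(ns[[j]], w[j]) else
      add_shared(swn, mul_public(ns[[j]], w[j]))
  }
  var_term <- sub_shared(mul_shared(t$N, swn2, session),
                         mul_shared(swn, swn, session))
  n <- mul_shared(mul_shared(t$m1, t$m2, session), var_term, session)
  new_rational_stat(m, n, "catt", t$n_snps, t$snp_ids)
}

#' Transmission disequilibrium test
#'
#' Among children of double-heterozygous parents, with `u` AA children and `v`
#' BB children: `m = (u - v)^2`, `n = u + v` (the McNemar form).
#'
#' @param t A [tdt_counts()].
#' @param session An [mpc_session()].
#' @return A `rational_stat`.
#' @export
tdt_stat <- function(t, session) {
  diff <- sub_shared(t$u, t$v)
  m <- mul_shared(diff, diff, session)
  n <- add_shared(t$u, t$v)
  new_rational_stat(m, n, "tdt", t$n_snps, t$snp_ids)
}

#' Reconstruct a rational statistic (verification only)
#'
#' Opens nothing through the session: directly reconstructs `m` and `n` as
#' exact decimal strings plus the floating value `m/n`. Intended for tests and
#' the verification mode of the pipeline; a production run releases only
#' decision bits.
#'
#' @param stat A `rational_stat`.
#' @return Data frame with columns `m`, `n` (exact decimal strings) and
#'   `value` (double, `NA` where `n = 0`).
#' @export
reconstruct_stat <- function(stat) {
  m <- reconstruct_str(stat$m)
  n <- reconstruct_str(stat$n)
  mv <- reconstruct(stat$m)
  nv <- reconstruct(stat$n)
  data.frame(snp_id = stat$snp_ids, m = m, n = n,
             value = ifelse(nv == 0, NA_real_, mv / nv),
             stringsAsFactors = FALSE)
}
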