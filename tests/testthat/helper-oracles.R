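# Independent floating-point statistic oracles (base R stats functions and
# direct formulas; no shared code with either package pipeline).

chi2_float_oracle <- function(a, b, c, d) {
  suppressWarnings(
    unname(stats::chisq.test(matrix(c(a, b, c, d), 2), correct = FALSE)$statistic))
}

catt_float_oracle <- function(r, s, w = c(0, 1, 2)) {
  # prop.trend.test: events r_j out of n_j with scores w
  suppressWarnings(
    unname(stats::prop.trend.test(r, r + s, score = w)$statistic))
}

tdt_float_oracle <- function(u, v) {
  suppressWarnings(
    unname(stats::mcnemar.test(matrix(c(0, u, v, 0), 2), correct = FALSE)$statistic))
}

# simple loop-based tabulation oracle for allele counts
tabulate_alleles_oracle <- function(calls, case_idx, ctrl_idx) {
  fa <- c(AA = 2, AB = 1, BB = 0, NN = 0)
  fb <- c(AA = 0, AB = 1, BB = 2, NN = 0)
  t(apply(calls, 1, function(row) c(
    a = sum(fa[row[case_idx]]), c = sum(fb[row[case_idx]]),
    b = sum(fa[row[ctrl_idx]]), d = sum(fb[row[ctrl_idx]]))))
}

tabulate_genotypes_oracle <- function(calls, case_idx, ctrl_idx) {
  t(apply(calls, 1, function(row) c(
    r0 = sum(row[case_idx] == "AA"), r1 = sum(row[case_idx] == "AB"),
    r2 = sum(row[case_idx] == "BB"),
    s0 = sum(row[ctrl_idx] == "AA"), s1 = sum(row[ctrl_idx] == "AB"),
    s2 = sum(row[ctrl_idx] == "BB"))))
}

tdt_counts_oracle <- function(calls, trios) {
  u <- 0; v <- 0
  uu <- numeric(nrow(calls)); vv <- numeric(nrow(calls))
  for (s in seq_len(nrow(calls))) {
    inf <- calls[s, trios$mother] == "AB" & calls[s, trios$father] == "AB"
    uu[s] <- sum(inf & calls[s, trios$child] == "AA")
    vv[s] <- sum(inf & calls[s, trios$child] == "BB")
  }
  cbind(u = uu, v = vv)
}

# build a rational_stat directly from plaintext (m, n) vectors
make_stat <- function(mv, nv, session, test = "chi2") {
  ppgwas:::new_rational_stat(
    share_secret(mv, session), share_secret(nv, session),
    test, length(mv), paste0("s", seq_along(mv)))
}

# tiny VCF fixture text
toy_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\td1\td2\td3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0|1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t1/0\t0/.",
    "1\t300\trs3\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1")
}
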