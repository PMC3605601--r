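# Rational thresholds, integer-only decisions, overflow bounds, Bonferroni
# and the oblivious Benjamini-Hochberg procedure.

test_that("rational chi-square thresholds bracket the critical value from below", {
  th <- chi2_critical_rational(0.05, 1000)
  expect_equal(th$p, 3841)  # floor(3.841459... * 1000)
  th2 <- chi2_critical_rational(0.5, 1000)
  expect_equal(th2$p, 454)  # floor(0.454936... * 1000)
  expect_true(chi2_critical_rational(0.01, 1000)$p > th$p)
  for (a in c(0.001, 0.05, 0.3)) {
    t <- chi2_critical_rational(a, 1e6)
    expect_true(t$p / t$q <= t$t && t$t < (t$p + 1) / t$q)
  }
  expect_error(chi2_critical_rational(1.2), "alpha")
  expect_error(chi2_critical_rational(0.05, 10), "q_precision")
})

test_that("Bonferroni thresholds are the corrected quantiles", {
  expect_equal(bonferroni(0.05, 1, 1000)$p, chi2_critical_rational(0.05, 1000)$p)
  bg <- bonferroni(0.05, 262264, 1e6)
  expect_equal(bg$alpha, 0.05 / 262264)
  expect_equal(bg$p, floor(stats::qchisq(0.05 / 262264, 1, lower.tail = FALSE) * 1e6))
  expect_true(bg$p > chi2_critical_rational(0.05, 1e6)$p)
})

test_that("ring-width overflow check: stated cases and monotonicity", {
  expect_true(ring_width_check(128, 1080, 1e6)$ok)
  expect_false(ring_width_check(32, 1080, 1e6)$ok)
  k1 <- ring_width_check(128, 270, 1e6)$k_min
  k2 <- ring_width_check(128, 1080, 1e6)$k_min
  expect_true(k2 >= k1)
  # the minimal k really is safe and one less is not
  chk <- ring_width_check(128, 500, 1e6)
  expect_true(ring_width_check(chk$k_min, 500, 1e6)$ok)
  expect_false(ring_width_check(chk$k_min - 1, 500, 1e6)$ok)
})

test_that("decide: stated examples, boundary convention and undefined statistics", {
  ses <- mpc_session(k = 128, seed = 3)
  th <- chi2_critical_rational(0.05, 1000)  # p/q = 3841/1000
  d1 <- decide(make_stat(10, 1, ses), th, ses)
  expect_equal(d1$decision, 1L)
  d0 <- decide(make_stat(0, 5, ses), th, ses)
  expect_equal(d0$decision, 0L)
  # boundary m*q = p*n decides significant (>= convention)
  db <- decide(make_stat(3841, 1000, ses), th, ses)
  expect_equal(db$decision, 1L)
  # monomorphic SNP: n = 0 -> not significant, flagged
  du <- decide(make_stat(4, 0, ses), th, ses)
  expect_equal(du$decision, 0L)
  expect_equal(du$undefined, 1L)
})

test_that("decide agrees with the exact big-integer rational comparison on random instances", {
  ses <- mpc_session(k = 128, seed = 5)
  th <- chi2_critical_rational(0.05, 1e6)
  set.seed(17)
  mv <- sample(0:10^7, 300, replace = TRUE)
  nv <- sample(1:10^6, 300, replace = TRUE)
  got <- decide(make_stat(mv, nv, ses), th, ses)$decision
  oracle <- vapply(seq_along(mv), function(i) {
    ppgwas:::bi_cmp(ppgwas:::bi_mul(ppgwas:::bi(mv[i]), ppgwas:::bi(th$q)),
                    ppgwas:::bi_mul(ppgwas:::bi(nv[i]), ppgwas:::bi(th$p))) >= 0
  }, NA)
  expect_equal(got, as.integer(oracle))
})

test_that("the Batcher network sorts shared fractions into descending order", {
  ses <- mpc_session(k = 64, seed = 7)
  set.seed(19)
  mv <- sample(0:5000, 37, replace = TRUE)   # statistics m/n all below 5
  nv <- rep(1000, 37)
  stat <- make_stat(mv, nv, ses)
  # exercise the sort through secure_bh at alpha so low nothing is rejected,
  # then check the released count is 0 and decisions match plaintext
  dec <- secure_bh(stat, 1e-12, ses, 1e6)
  expect_equal(attr(dec, "n_rejected"), 0L)
  expect_true(all(dec$decision == 0))
  # comparator schedule covers every wire and is made of disjoint stages
  stages <- ppgwas:::batcher_stages(16)
  expect_true(all(sort(unique(unlist(stages))) == 1:16))
  for (st in stages) expect_false(anyDuplicated(as.vector(st)) > 0)
  # the schedule really sorts: apply it to plaintext values
  v <- sample(100, 16)
  for (st in stages) for (r in seq_len(nrow(st))) {
    i <- st[r, 1]; j <- st[r, 2]
    if (v[i] < v[j]) { t <- v[i]; v[i] <- v[j]; v[j] <- t }
  }
  expect_equal(v, sort(v, decreasing = TRUE))
})

test_that("secure BH equals plaintext BH: degenerate, spiked and random instances", {
  ses <- mpc_session(k = 64, seed = 9)
  # all statistics zero: no rejections
  z <- make_stat(rep(0, 20), rep(1, 20), ses)
  dz <- secure_bh(z, 0.05, ses, 1e6)
  expect_equal(attr(dz, "n_rejected"), 0L)

  # one huge statistic among nulls is rejected
  mv <- c(rep(1, 99), 500000); nv <- rep(1000, 100)
  sp <- make_stat(mv, nv, ses)
  dsp <- secure_bh(sp, 0.05, ses, 1e6)
  expect_equal(attr(dsp, "n_rejected"), 1L)
  expect_equal(dsp$decision, c(rep(0L, 99), 1L))

  # random instance vs the plaintext reference and p.adjust
  set.seed(23)
  mv <- round(stats::rchisq(120, 1) * 1e5)
  mv[sample(120, 10)] <- round(stats::rchisq(10, 1, ncp = 30) * 1e5)
  nv <- rep(1e5, 120)
  st <- make_stat(mv, nv, ses)
  got <- secure_bh(st, 0.1, ses, 1e6)
  ref_df <- data.frame(snp_id = paste0("s", 1:120), m = as.character(mv),
                       n = as.character(nv), value = mv / nv,
                       stringsAsFactors = FALSE)
  ref <- plaintext_bh(ref_df, 0.1, 1e6)
  expect_equal(got$decision, ref$decision)
  expect_equal(attr(got, "n_rejected"), attr(ref, "n_rejected"))
  padj <- stats::p.adjust(stats::pchisq(mv / nv, 1, lower.tail = FALSE), "BH")
  expect_equal(got$decision, as.integer(padj <= 0.1))

  # undefined statistics can never be rejected
  mv2 <- c(900000, 0); nv2 <- c(1000, 0)
  d2 <- secure_bh(make_stat(mv2, nv2, ses), 0.05, ses, 1e6)
  expect_equal(d2$decision, c(1L, 0L))
  expect_equal(d2$undefined, c(0L, 1L))
})

test_that("BH comparison count depends only on the instance size", {
  run <- function(mv, seed) {
    ses <- mpc_session(k = 64, seed = seed)
    invisible(secure_bh(make_stat(mv, rep(1000, length(mv)), ses), 0.05, ses, 1e6))
    bc <- bus_counts(ses)
    bc$messages[bc$op == "secure_geq"]
  }
  set.seed(29)
  a <- run(sample(0:9999, 50), 1)
  b <- run(sample(0:9999, 50), 2)
  expect_equal(a, b)
})

test_that("decision output files round-trip", {
  ses <- mpc_session(k = 128, seed = 11)
  dec <- decide(make_stat(c(10, 0), c(1, 1), ses),
                chi2_critical_rational(0.05, 1e6), ses)
  path <- tempfile(fileext = ".tsv")
  write_decisions(dec, path, metadata = list(alpha = 0.05, k = 128))
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$decision, c(1L, 0L))
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  expect_equal(meta$alpha, 0.05)
})
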