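# Test statistics as exact shared integer fractions, against independent
# floating-point oracles and each other.

stat_value <- function(stat) reconstruct_stat(stat)$value

test_that("chi-square independence: stated examples and random tables to 12 digits", {
  ses <- mpc_session(k = 128, seed = 3)
  tab <- list(a = share_secret(10, ses), b = share_secret(10, ses),
              c = share_secret(10, ses), d = share_secret(10, ses),
              n_snps = 1L, snp_ids = "s1")
  expect_equal(stat_value(chi2_independence(tab, ses)), 0)

  tab2 <- list(a = share_secret(20, ses), b = share_secret(10, ses),
               c = share_secret(10, ses), d = share_secret(20, ses),
               n_snps = 1L, snp_ids = "s1")
  st <- reconstruct_stat(chi2_independence(tab2, ses))
  expect_equal(st$value, 20 / 3, tolerance = 1e-12)
  expect_equal(st$value, chi2_float_oracle(20, 10, 10, 20), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:40) {
    cc <- sample(5:200, 4)
    tabr <- list(a = share_secret(cc[1], ses), b = share_secret(cc[2], ses),
                 c = share_secret(cc[3], ses), d = share_secret(cc[4], ses),
                 n_snps = 1L, snp_ids = "s1")
    expect_equal(stat_value(chi2_independence(tabr, ses)),
                 chi2_float_oracle(cc[1], cc[2], cc[3], cc[4]),
                 tolerance = 1e-12)
  }
})

test_that("two-proportion chi-square equals the independence statistic as a rational", {
  ses <- mpc_session(k = 128, seed = 5)
  set.seed(11)
  for (i in 1:40) {
    cc <- sample(1:150, 4)
    tab <- list(a = share_secret(cc[1], ses), b = share_secret(cc[2], ses),
                c = share_secret(cc[3], ses), d = share_secret(cc[4], ses),
                n_snps = 1L, snp_ids = "s1")
    s1 <- reconstruct_stat(chi2_independence(tab, ses))
    s2 <- reconstruct_stat(chi2_proportion(tab, ses))
    # exact cross-multiplied equality m1*n2 == m2*n1
    lhs <- ppgwas:::bi_mul(ppgwas:::bi_from_str(s1$m), ppgwas:::bi_from_str(s2$n))
    rhs <- ppgwas:::bi_mul(ppgwas:::bi_from_str(s2$m), ppgwas:::bi_from_str(s1$n))
    expect_equal(ppgwas:::bi_cmp(lhs, rhs), 0)
  }
  # equal proportions give 0
  tab0 <- list(a = share_secret(30, ses), b = share_secret(15, ses),
               c = share_secret(50, ses), d = share_secret(25, ses),
               n_snps = 1L, snp_ids = "s1")
  expect_equal(stat_value(chi2_proportion(tab0, ses)), 0)
})

test_that("Cochran-Armitage: oracle agreement, no-trend zero, weight scale invariance", {
  ses <- mpc_session(k = 128, seed = 7)
  mk_tab <- function(r, s) {
    cells <- list(r0 = r[1], r1 = r[2], r2 = r[3],
                  s0 = s[1], s1 = s[2], s2 = s[3])
    cells <- lapply(cells, share_secret, session = ses)
    cells$m1 <- add_shared(add_shared(cells$r0, cells$r1), cells$r2)
    cells$m2 <- add_shared(add_shared(cells$s0, cells$s1), cells$s2)
    cells$n0 <- add_shared(cells$r0, cells$s0)
    cells$n1 <- add_shared(cells$r1, cells$s1)
    cells$n2 <- add_shared(cells$r2, cells$s2)
    cells$N <- add_shared(cells$m1, cells$m2)
    c(cells, list(n_snps = 1L, snp_ids = "s1"))
  }
  t1 <- mk_tab(c(10, 20, 30), c(30, 20, 10))
  expect_equal(stat_value(cochran_armitage(t1, ses)),
               catt_float_oracle(c(10, 20, 30), c(30, 20, 10)),
               tolerance = 1e-12)
  # identical genotype distributions: no trend
  t0 <- mk_tab(c(12, 24, 8), c(12, 24, 8))
  expect_equal(stat_value(cochran_armitage(t0, ses)), 0)
  # doubling the weights leaves the ratio unchanged
  s_a <- stat_value(cochran_armitage(t1, ses, weights = c(0, 1, 2)))
  s_b <- stat_value(cochran_armitage(t1, ses, weights = c(0, 2, 4)))
  expect_equal(s_a, s_b, tolerance = 1e-12)
  set.seed(13)
  for (i in 1:25) {
    r <- sample(0:80, 3); s <- sample(0:80, 3)
    if (sum(r) == 0 || sum(s) == 0) next
    v <- stat_value(cochran_armitage(mk_tab(r, s), ses))
    o <- catt_float_oracle(r, s)
    if (is.finite(o)) expect_equal(v, o, tolerance = 1e-10)
  }
  expect_error(cochran_armitage(t1, ses, weights = c(1, 1, 1)), "not all equal")
})

test_that("TDT statistic: stated examples and the McNemar oracle", {
  ses <- mpc_session(k = 128, seed = 9)
  mk <- function(u, v) list(u = share_secret(u, ses), v = share_secret(v, ses),
                            n_snps = length(u), snp_ids = paste0("s", seq_along(u)))
  expect_equal(stat_value(tdt_stat(mk(15, 15), ses)), 0)
  expect_equal(stat_value(tdt_stat(mk(30, 10), ses)), 10)
  expect_equal(stat_value(tdt_stat(mk(1, 0), ses)), 1)
  expect_equal(stat_value(tdt_stat(mk(30, 10), ses)),
               tdt_float_oracle(30, 10), tolerance = 1e-12)
  # undefined when no informative trios
  st <- reconstruct_stat(tdt_stat(mk(0, 0), ses))
  expect_true(is.na(st$value))
})

test_that("signed intermediates square correctly regardless of sign (b > a cases)", {
  ses <- mpc_session(k = 128, seed = 11)
  tab <- list(a = share_secret(5, ses), b = share_secret(50, ses),
              c = share_secret(45, ses), d = share_secret(10, ses),
              n_snps = 1L, snp_ids = "s1")
  expect_equal(stat_value(chi2_independence(tab, ses)),
               chi2_float_oracle(5, 50, 45, 10), tolerance = 1e-12)
  mk <- function(u, v) list(u = share_secret(u, ses), v = share_secret(v, ses),
                            n_snps = 1L, snp_ids = "s1")
  expect_equal(stat_value(tdt_stat(mk(10, 30), ses)), 10)  # v > u
})
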