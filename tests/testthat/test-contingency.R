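# Secure contingency assembly: dot products, allele and genotype tables,
# heterozygous-parent detection and TDT counts.

shared_db_from_calls <- function(calls, ses, ...) {
  share_genotype_db(genotype_matrix(calls, ...), ses)
}

test_that("secure_dot matches the plaintext dot product", {
  ses <- mpc_session(k = 64, seed = 3)
  x <- share_secret(c(1, 0, 1), ses)
  g <- share_secret(c(2, 1, 0), ses)
  expect_equal(reconstruct(secure_dot(x, g, ses)), 2)
  z <- share_secret(c(0, 0, 0), ses)
  expect_equal(reconstruct(secure_dot(z, g, ses)), 0)
  set.seed(9)
  xv <- sample(0:1, 50, TRUE); gv <- sample(0:2, 50, TRUE)
  expect_equal(reconstruct(secure_dot(share_secret(xv, ses),
                                      share_secret(gv, ses), ses)),
               sum(xv * gv))
  expect_error(secure_dot(x, share_secret(1:2, ses), ses), "length mismatch")
})

test_that("allele tables: stated examples and a random cohort vs the tabulation oracle", {
  ses <- mpc_session(k = 64, seed = 5)
  db <- shared_db_from_calls(matrix(c("AA", "BB"), 1), ses,
                             donor_ids = c("case1", "ctrl1"))
  x <- index_from_plaintext("case1", db$donor_ids, ses)
  y <- complement(x)
  tab <- allele_table(x, y, db, ses)
  expect_equal(c(reconstruct(tab$a), reconstruct(tab$c),
                 reconstruct(tab$b), reconstruct(tab$d)), c(2, 0, 0, 2))

  # empty case group
  x0 <- index_from_plaintext(character(0), db$donor_ids, ses)
  tab0 <- allele_table(x0, complement(x0), db, ses)
  expect_equal(reconstruct(tab0$a), 0)
  expect_equal(reconstruct(tab0$c), 0)

  set.seed(17)
  calls <- matrix(sample(c("AA", "AB", "BB", "NN"), 8 * 100, TRUE,
                         prob = c(.3, .35, .3, .05)), 8, 100)
  db2 <- shared_db_from_calls(calls, ses)
  case_idx <- sort(sample(1:100, 45))
  x2 <- share_secret(as.integer(1:100 %in% case_idx), ses, bit = TRUE)
  y2 <- complement(x2)
  tab2 <- allele_table(x2, y2, db2, ses)
  oracle <- tabulate_alleles_oracle(calls, case_idx, setdiff(1:100, case_idx))
  expect_equal(reconstruct(tab2$a), unname(oracle[, "a"]))
  expect_equal(reconstruct(tab2$b), unname(oracle[, "b"]))
  expect_equal(reconstruct(tab2$c), unname(oracle[, "c"]))
  expect_equal(reconstruct(tab2$d), unname(oracle[, "d"]))
  # a + c = 2 * number of non-NN case donors, per SNP
  nonNN <- vapply(1:8, function(s) sum(calls[s, case_idx] != "NN"), 0)
  expect_equal(reconstruct(tab2$a) + reconstruct(tab2$c), 2 * nonNN)
})

test_that("genotype indicators select exactly one class for every valid encoding", {
  ses <- mpc_session(k = 64, seed = 7)
  db <- shared_db_from_calls(matrix(c("AA", "AB", "BB", "NN"), 1), ses)
  ind <- genotype_indicators(db, ses)
  expect_equal(reconstruct(ind$iAA), c(1, 0, 0, 0))
  expect_equal(reconstruct(ind$iAB), c(0, 1, 0, 0))
  expect_equal(reconstruct(ind$iBB), c(0, 0, 1, 0))
  expect_equal(reconstruct(ind$iNN), c(0, 0, 0, 1))
})

test_that("genotype tables: stated example, all-missing SNPs, random cohorts, margins", {
  ses <- mpc_session(k = 64, seed = 9)
  db <- shared_db_from_calls(matrix(c("AA", "AB", "BB"), 1), ses,
                             donor_ids = c("c1", "c2", "k1"))
  x <- index_from_plaintext(c("c1", "c2"), db$donor_ids, ses)
  tab <- genotype_table(x, complement(x), db, ses)
  expect_equal(vapply(tab[c("r0", "r1", "r2", "s0", "s1", "s2", "N")],
                      reconstruct, 0),
               c(r0 = 1, r1 = 1, r2 = 0, s0 = 0, s1 = 0, s2 = 1, N = 3))

  dbNN <- shared_db_from_calls(matrix("NN", 2, 3), ses)
  xN <- share_secret(c(1L, 1L, 0L), ses, bit = TRUE)
  tabN <- genotype_table(xN, complement(xN), dbNN, ses)
  for (cell in c("r0", "r1", "r2", "s0", "s1", "s2", "N"))
    expect_equal(reconstruct(tabN[[cell]]), c(0, 0), info = cell)

  set.seed(23)
  calls <- matrix(sample(c("AA", "AB", "BB", "NN"), 6 * 60, TRUE), 6, 60)
  db2 <- shared_db_from_calls(calls, ses)
  case_idx <- sort(sample(1:60, 25))
  x2 <- share_secret(as.integer(1:60 %in% case_idx), ses, bit = TRUE)
  tab2 <- genotype_table(x2, complement(x2), db2, ses)
  oracle <- tabulate_genotypes_oracle(calls, case_idx, setdiff(1:60, case_idx))
  for (cell in colnames(oracle))
    expect_equal(reconstruct(tab2[[cell]]), unname(oracle[, cell]), info = cell)
  # Table margin identities after reconstruction
  expect_equal(reconstruct(tab2$m1),
               reconstruct(tab2$r0) + reconstruct(tab2$r1) + reconstruct(tab2$r2))
  expect_equal(reconstruct(tab2$N), reconstruct(tab2$m1) + reconstruct(tab2$m2))
  expect_equal(reconstruct(tab2$n1), reconstruct(tab2$r1) + reconstruct(tab2$s1))
})

test_that("heterozygous-parent indicator over all 16 parent genotype pairs", {
  ses <- mpc_session(k = 64, seed = 11)
  gts <- c("AA", "AB", "BB", "NN")
  pairs <- expand.grid(mother = gts, father = gts, stringsAsFactors = FALSE)
  nt <- nrow(pairs)
  calls <- matrix(c(rep("AB", nt), pairs$mother, pairs$father), 1)  # 1 SNP
  db <- shared_db_from_calls(calls, ses)
  trios <- trio_structure(1:nt, nt + 1:nt, 2 * nt + 1:nt, 3 * nt)
  z <- heterozygous_parent_vector(db, trios, ses)
  expect_equal(reconstruct(z),
               as.numeric(pairs$mother == "AB" & pairs$father == "AB"))
})

test_that("TDT counts: stated example, no informative trios, random trios vs oracle", {
  ses <- mpc_session(k = 64, seed = 13)
  # 3 informative trios with children AA, AA, BB
  calls <- matrix(c("AA", "AA", "BB", rep("AB", 6)), 1)
  db <- shared_db_from_calls(calls, ses)
  trios <- trio_structure(1:3, 4:6, 7:9, 9)
  cnt <- tdt_counts(db, trios, ses)
  expect_equal(reconstruct(cnt$u), 2)
  expect_equal(reconstruct(cnt$v), 1)

  # homozygous parents everywhere: nothing is informative
  calls2 <- matrix(c("AA", "BB", "AA", "AA", "BB", "BB"), 1)
  db2 <- shared_db_from_calls(calls2, ses)
  trios2 <- trio_structure(1:2, 3:4, 5:6, 6)
  cnt2 <- tdt_counts(db2, trios2, ses)
  expect_equal(reconstruct(cnt2$u), 0)
  expect_equal(reconstruct(cnt2$v), 0)

  sim <- simulate_trios(40, 5, maf = c(0.2, 0.5), tau = 0.6, seed = 31)
  ses2 <- mpc_session(k = 64, seed = 17)
  db3 <- share_genotype_db(sim$genotypes, ses2)
  cnt3 <- tdt_counts(db3, sim$trios, ses2)
  oracle <- tdt_counts_oracle(sim$genotypes$calls, sim$trios)
  expect_equal(reconstruct(cnt3$u), unname(oracle[, "u"]))
  expect_equal(reconstruct(cnt3$v), unname(oracle[, "v"]))
})
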