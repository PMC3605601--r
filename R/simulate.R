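# evaluate expr under a private, restored RNG state (generators are
# deterministic given seed and never disturb the caller's RNG)
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

draw_maf <- function(n_snps, maf) {
  if (length(maf) == 1) rep(maf, n_snps)
  else stats::runif(n_snps, maf[1], maf[2])
}

calls_from_freq <- function(f, n_donors, missing_rate) {
  n_snps <- length(f)
  u <- matrix(stats::runif(n_snps * n_donors), n_snps, n_donors)
  pAA <- f^2; pAB <- 2 * f * (1 - f)
  calls <- matrix("BB", n_snps, n_donors)
  calls[u < pAA + pAB] <- "AB"
  calls[u < pAA] <- "AA"
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n_snps * n_donors) < missing_rate,
                   n_snps, n_donors)
    calls[miss] <- "NN"
  }
  calls
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Emulates a HapMap-style biallelic genotype panel: per SNP an allele-A
#' frequency `f` is drawn (fixed value, or uniform on a range), and each
#' donor's genotype is sampled under Hardy-Weinberg equilibrium —
#' `P(AA) = f^2`, `P(AB) = 2f(1-f)`, `P(BB) = (1-f)^2` — with independent
#' missingness. No linkage disequilibrium or population structure is modeled.
#'
#' @param n_donors,n_snps Panel dimensions.
#' @param maf Allele-A frequency: a single value or a `c(lo, hi)` uniform
#'   range (default `c(0.05, 0.5)`).
#' @param missing_rate Per-call probability of `NN`.
#' @param seed Seed; the generator is deterministic given `(config, seed)`.
#' @return A [genotype_matrix()] with attribute `freqs` (the per-SNP
#'   frequencies used).
#' @export
simulate_genotypes <- function(n_donors, n_snps, maf = c(0.05, 0.5),
                               missing_rate = 0, seed = 1) {
  with_seed(seed, {
    f <- draw_maf(n_snps, maf)
    m <- genotype_matrix(calls_from_freq(f, n_donors, missing_rate))
    attr(m, "freqs") <- f
    m
  })
}

#' Plant case-control allele-frequency differences
#'
#' Regenerates the selected SNPs with allele-A frequency `f_case` in the case
#' columns and `f_ctrl` elsewhere (still Hardy-Weinberg within group); all
#' other SNPs are untouched.
#'
#' @param m A [genotype_matrix()].
#' @param snp_index Indices of SNPs to plant.
#' @param case_ids Donor IDs of the case group.
#' @param f_case,f_ctrl Group allele-A frequencies.
#' @param missing_rate Per-call probability of `NN` in regenerated entries.
#' @param seed Seed.
#' @return The modified [genotype_matrix()].
#' @export
plant_association <- function(m, snp_index, case_ids, f_case, f_ctrl,
                              missing_rate = 0, seed = 1) {
  stopifnot(all(snp_index >= 1), all(snp_index <= nrow(m$calls)))
  is_case <- m$donor_ids %in% case_ids
  with_seed(seed, {
    for (s in snp_index) {
      m$calls[s, is_case] <-
        calls_from_freq(rep(f_case, 1), sum(is_case), missing_rate)
      m$calls[s, !is_case] <-
        calls_from_freq(rep(f_ctrl, 1), sum(!is_case), missing_rate)
    }
    m
  })
}

#' Simulate parent-child trios with transmission distortion
#'
#' Parents are drawn under Hardy-Weinberg equilibrium; each child allele is
#' inherited Mendelianly, except that a heterozygous parent transmits allele A
#' with probability `tau` (`tau = 0.5` is the transmission-disequilibrium
#' null; `tau > 0.5` over-transmits A). Donor columns are laid out children
#' first, then mothers, then fathers.
#'
#' @param n_trios,n_snps Panel dimensions.
#' @param maf Allele-A frequency (value or uniform range).
#' @param tau Probability that a heterozygous parent transmits allele A.
#' @param missing_rate Per-call probability of `NN` (applied to all members).
#' @param seed Seed.
#' @return List with `genotypes` (a [genotype_matrix()] over `3*n_trios`
#'   donors) and `trios` (a [trio_structure()]).
#' @export
simulate_trios <- function(n_trios, n_snps, maf = c(0.05, 0.5), tau = 0.5,
                           missing_rate = 0, seed = 1) {
  stopifnot(tau >= 0, tau <= 1)
  with_seed(seed, {
    f <- draw_maf(n_snps, maf)
    mother <- calls_from_freq(f, n_trios, 0)
    father <- calls_from_freq(f, n_trios, 0)
    transmit <- function(par) {
      # allele transmitted by each parent: 1 = A, 0 = B
      out <- matrix(0L, n_snps, n_trios)
      out[par == "AA"] <- 1L
      het <- par == "AB"
      out[het] <- as.integer(stats::runif(sum(het)) < tau)
      out
    }
    child_fa <- transmit(mother) + transmit(father)
    child <- matrix("BB", n_snps, n_trios)
    child[child_fa == 1] <- "AB"
    child[child_fa == 2] <- "AA"
    calls <- cbind(child, mother, father)
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(length(calls)) < missing_rate,
                     nrow(calls), ncol(calls))
      calls[miss] <- "NN"
    }
    ids <- c(paste0("c", seq_len(n_trios)), paste0("m", seq_len(n_trios)),
             paste0("f", seq_len(n_trios)))
    g <- genotype_matrix(calls, donor_ids = ids)
    attr(g, "freqs") <- f
    list(genotypes = g,
         trios = trio_structure(seq_len(n_trios),
                                n_trios + seq_len(n_trios),
                                2 * n_trios + seq_len(n_trios),
                                3 * n_trios))
  })
}

#' Simulate a phenotype table
#'
#' Boolean `has_disease` flag with the given prevalence plus an integer `age`
#' uniform on 30..79. The construction guarantees that the documented
#' criterion `"has_disease"` recovers the intended case set exactly.
#'
#' @param n_donors Donor count.
#' @param case_fraction Disease prevalence.
#' @param donor_ids Donor IDs (default `d1..dN`).
#' @param seed Seed.
#' @return Data frame with columns `donor_id`, `has_disease`, `age`; attribute
#'   `case_ids` holds the intended case set.
#' @export
simulate_phenotypes <- function(n_donors, case_fraction,
                                donor_ids = paste0("d", seq_len(n_donors)),
                                seed = 1) {
  with_seed(seed, {
    flag <- as.integer(stats::runif(n_donors) < case_fraction)
    t <- data.frame(donor_id = donor_ids, has_disease = flag,
                    age = sample(30:79, n_donors, replace = TRUE),
                    stringsAsFactors = FALSE)
    attr(t, "case_ids") <- donor_ids[flag == 1]
    t
  })
}
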