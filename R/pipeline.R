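#' End-to-end secure GWAS run
#'
#' Wires the whole pipeline on one simulated three-host session: share the
#' genotype (and, for scenario 2, phenotype) database, form case/control index
#' vectors — from plaintext member lists (scenario 1: the analyst knows the
#' cohort) or obliviously from an inclusion criterion (scenario 2) — assemble
#' the contingency tables by secure dot products, compute the test statistic
#' as a shared integer fraction and release only the per-SNP decision bits
#' (plus, for Benjamini-Hochberg, the rejection count).
#'
#' @param genotypes A [genotype_matrix()] or `shared_genotype_db`.
#' @param test One of `"chi2"`, `"chi2prop"`, `"catt"`, `"tdt"`.
#' @param cases,controls Scenario 1: donor-ID vectors. `controls = NULL` takes
#'   the complement of the case group.
#' @param phenotypes,criterion Scenario 2: a phenotype data frame plus an
#'   inclusion-criterion string; controls are the complement.
#' @param trios A [trio_structure()] (TDT only).
#' @param alpha Significance level.
#' @param correction `"none"`, `"bonferroni"` or `"bh"`.
#' @param n_tests Test count for Bonferroni (default: the panel's SNP count;
#'   set it to the full scan size when the panel is a subset).
#' @param q_precision Rational-threshold denominator.
#' @param weights Trend weights (CATT).
#' @param k Ring width; must pass [ring_width_check()] for the donor count.
#' @param seed Root seed for all session randomness.
#' @param session Optionally, an existing [mpc_session()] holding the shared
#'   database.
#' @param return_stats Verification mode: additionally reconstruct the per-SNP
#'   `(m, n)` fractions. Never enabled in a production run — it bypasses the
#'   release discipline (and is not an audited open).
#' @return List with `decisions` (data frame), `n_rejected`, `threshold`,
#'   `session` (for audit/bus inspection), `metadata`, and `stats` when
#'   `return_stats = TRUE`.
#' @export
run_secure_gwas <- function(genotypes, test = c("chi2", "chi2prop", "catt", "tdt"),
                            cases = NULL, controls = NULL,
                            phenotypes = NULL, criterion = NULL,
                            trios = NULL,
                            alpha = 0.05,
                            correction = c("bonferroni", "none", "bh"),
                            n_tests = NULL, q_precision = 1e6,
                            weights = c(0, 1, 2),
                            k = 128L, seed = 1L,
                            session = NULL, return_stats = FALSE) {
  test <- match.arg(test)
  correction <- match.arg(correction)

  if (inherits(genotypes, "shared_genotype_db")) {
    if (is.null(session))
      stop("a session must accompany an already-shared database")
    db <- genotypes
  } else {
    if (is.null(session)) session <- mpc_session(k = k, seed = seed)
    db <- share_genotype_db(genotypes, session)
  }
  k <- session$k
  chk <- ring_width_check(k, db$n_donors, q_precision)
  if (!chk$ok)
    stop(sprintf("configuration error: ring width %d unsafe for %d donors at q=%g (need k >= %d)",
                 k, db$n_donors, q_precision, chk$k_min))

  if (test == "tdt") {
    if (is.null(trios)) stop("TDT needs a trio structure")
    stat <- tdt_stat(tdt_counts(db, trios, session), session)
  } else {
    if (!is.null(criterion)) {
      if (is.null(phenotypes)) stop("scenario 2 needs a phenotype table")
      pdb <- share_phenotype_db(phenotypes, session)
      x <- evaluate_criterion(pdb, criterion, session)
    } else {
      if (is.null(cases)) stop("provide cases (scenario 1) or a criterion (scenario 2)")
      x <- index_from_plaintext(cases, db$donor_ids, session)
    }
    y <- if (is.null(controls)) complement(x)
         else index_from_plaintext(controls, db$donor_ids, session)
    if (test %in% c("chi2", "chi2prop")) {
      tab <- allele_table(x, y, db, session)
      stat <- if (test == "chi2") chi2_independence(tab, session)
              else chi2_proportion(tab, session)
    } else {
      tab <- genotype_table(x, y, db, session)
      stat <- cochran_armitage(tab, session, weights = weights)
    }
  }

  if (correction == "bh") {
    decisions <- secure_bh(stat, alpha, session, q_precision)
    threshold <- NULL
    n_rejected <- attr(decisions, "n_rejected")
  } else {
    nt <- if (correction == "bonferroni") {
      if (is.null(n_tests)) db$n_snps else n_tests
    } else 1
    threshold <- bonferroni(alpha, nt, q_precision)
    decisions <- decide(stat, threshold, session)
    n_rejected <- sum(decisions$decision)
  }

  out <- list(
    decisions = decisions, n_rejected = n_rejected, threshold = threshold,
    session = session,
    metadata = list(test = test, alpha = alpha, correction = correction,
                    n_tests = if (correction == "bonferroni") nt else NA,
                    q_precision = q_precision, k = k, seed = session$seed,
                    n_snps = db$n_snps, n_donors = db$n_donors))
  if (return_stats) out$stats <- reconstruct_stat(stat)
  out
}

#' End-to-end plaintext reference run
#'
#' The cleartext mirror of [run_secure_gwas()] with the same interface and
#' exact big-integer arithmetic; a secure run must reproduce its `(m, n)`
#' fractions and decision bits identically.
#'
#' @inheritParams run_secure_gwas
#' @return List with `decisions`, `stats`, `n_rejected`, `threshold`.
#' @export
run_plaintext_gwas <- function(genotypes, test = c("chi2", "chi2prop", "catt", "tdt"),
                               cases = NULL, controls = NULL,
                               phenotypes = NULL, criterion = NULL,
                               trios = NULL,
                               alpha = 0.05,
                               correction = c("bonferroni", "none", "bh"),
                               n_tests = NULL, q_precision = 1e6,
                               weights = c(0, 1, 2)) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  m <- genotypes

  if (test == "tdt") {
    if (is.null(trios)) stop("TDT needs a trio structure")
    tab <- plaintext_tdt_counts(m, trios)
  } else {
    if (!is.null(criterion)) {
      member <- evaluate_criterion_plaintext(phenotypes, criterion)
      case_idx <- which(member == 1)
    } else {
      case_idx <- match(cases, m$donor_ids)
    }
    ctrl_idx <- if (is.null(controls)) setdiff(seq_along(m$donor_ids), case_idx)
                else match(controls, m$donor_ids)
    tab <- if (test %in% c("chi2", "chi2prop"))
      plaintext_allele_table(m, case_idx, ctrl_idx)
    else plaintext_genotype_table(m, case_idx, ctrl_idx)
  }
  stats <- plaintext_stat_fractions(test, tab, weights)

  if (correction == "bh") {
    dec <- plaintext_bh(stats, alpha, q_precision)
    dec$test <- test
    list(decisions = dec[, c("snp_id", "test", "decision", "undefined")],
         stats = stats, n_rejected = attr(dec, "n_rejected"), threshold = NULL)
  } else {
    nt <- if (correction == "bonferroni") {
      if (is.null(n_tests)) nrow(stats) else n_tests
    } else 1
    threshold <- bonferroni(alpha, nt, q_precision)
    dec <- plaintext_decide(stats, threshold)
    dec$test <- test
    list(decisions = dec[, c("snp_id", "test", "decision", "undefined")],
         stats = stats, n_rejected = sum(dec$decision), threshold = threshold)
  }
}
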