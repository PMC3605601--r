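#' Secure inner product
#'
#' Reconstructs to `sum_i x_i * g_i mod 2^k`: one batched secure
#' multiplication followed by local share summation. This is the workhorse of
#' contingency-table assembly.
#'
#' @param x,g `shared_vector`s of equal length.
#' @param session An [mpc_session()].
#' @return A length-1 `shared_vector`.
#' @export
secure_dot <- function(x, g, session) {
  if (x$n != g$n) stop("length mismatch in secure_dot")
  sv_sum(mul_shared(x, g, session))
}

# batched dot of one donor-length vector against every SNP row of a flat
# SNP-major shared matrix: returns one shared value per SNP
dot_rows <- function(x, flat, n_snps, n_donors, session) {
  if (flat$n != n_snps * n_donors) stop("length mismatch in dot_rows")
  xt <- sv_tile(x, n_snps)
  prods <- mul_shared(xt, flat, session)
  sv_sum_groups(prods, rep(seq_len(n_snps), each = n_donors), n_snps)
}

#' Secure allele contingency tables (2x2), vectorized over SNPs
#'
#' Assembles, for every SNP, the case/control x allele-A/allele-B table from
#' index vectors and the shared allele-count rows: `a = x.fA`, `c = x.fB`
#' (cases), `b = y.fA`, `d = y.fB` (controls). Each count is a secure dot
#' product; nothing is opened.
#'
#' @param x,y Case and control index vectors (bit-valued `shared_vector`s of
#'   donor length).
#' @param db A `shared_genotype_db`.
#' @param session An [mpc_session()].
#' @return An `allele_table`: shared count vectors `a`, `b`, `c`, `d`, one
#'   element per SNP.
#' @export
allele_table <- function(x, y, db, session) {
  if (x$n != db$n_donors || y$n != db$n_donors)
    stop("length mismatch: index vectors must have one entry per donor")
  structure(list(
    a = dot_rows(x, db$fA, db$n_snps, db$n_donors, session),
    c = dot_rows(x, db$fB, db$n_snps, db$n_donors, session),
    b = dot_rows(y, db$fA, db$n_snps, db$n_donors, session),
    d = dot_rows(y, db$fB, db$n_snps, db$n_donors, session),
    n_snps = db$n_snps, snp_ids = db$snp_ids
  ), class = "allele_table")
}

#' Secure genotype-class indicators
#'
#' Per donor and SNP, shared 0/1 indicators of the four genotype classes.
#' `iAB = fA*fB` follows from the encoding algebra (it is 1 exactly for the
#' (1,1) pair); `iAA` and `iBB` are the redundant flag rows shared at import
#' time, and `iNN = 1 - iAA - iBB - iAB`. With valid encodings exactly one
#' indicator reconstructs to 1. Degree stays <= 2 and no secure comparisons
#' are needed.
#'
#' @param db A `shared_genotype_db`.
#' @param session An [mpc_session()].
#' @return List of four flat bit-valued `shared_vector`s
#'   (`iAA`, `iAB`, `iBB`, `iNN`).
#' @export
genotype_indicators <- function(db, session) {
  iAB <- mul_shared(db$fA, db$fB, session)
  iNN <- add_public(neg_shared(add_shared(add_shared(db$hAA, db$hBB), iAB)), 1)
  iAB$bit <- TRUE; iNN$bit <- TRUE
  list(iAA = db$hAA, iAB = iAB, iBB = db$hBB, iNN = iNN)
}

#' Secure genotype contingency tables (2x3), vectorized over SNPs
#'
#' Case/control counts of the AA, AB and BB genotype classes with margins:
#' `r_j = x.i_j`, `s_j = y.i_j`, `n_j = r_j + s_j`, `m1 = r0+r1+r2`,
#' `m2 = s0+s1+s2`, `N = m1+m2`. Donors with missing calls carry all-zero
#' indicators for the three called classes and so drop out of every count and
#' margin.
#'
#' @inheritParams allele_table
#' @return A `genotype_table`: shared vectors `r0,r1,r2,m1,s0,s1,s2,m2,
#'   n0,n1,n2,N`, one element per SNP.
#' @export
genotype_table <- function(x, y, db, session) {
  ind <- genotype_indicators(db, session)
  S <- db$n_snps; D <- db$n_donors
  r0 <- dot_rows(x, ind$iAA, S, D, session)
  r1 <- dot_rows(x, ind$iAB, S, D, session)
  r2 <- dot_rows(x, ind$iBB, S, D, session)
  s0 <- dot_rows(y, ind$iAA, S, D, session)
  s1 <- dot_rows(y, ind$iAB, S, D, session)
  s2 <- dot_rows(y, ind$iBB, S, D, session)
  m1 <- add_shared(add_shared(r0, r1), r2)
  m2 <- add_shared(add_shared(s0, s1), s2)
  structure(list(r0 = r0, r1 = r1, r2 = r2, m1 = m1,
                 s0 = s0, s1 = s1, s2 = s2, m2 = m2,
                 n0 = add_shared(r0, s0), n1 = add_shared(r1, s1),
                 n2 = add_shared(r2, s2), N = add_shared(m1, m2),
                 n_snps = S, snp_ids = db$snp_ids),
            class = "genotype_table")
}

#' Trio structure
#'
#' @param child,mother,father Donor column indices (1-based), one entry per
#'   trio; all indices distinct within a trio and in range.
#' @param n_donors Total donor count (for range validation).
#' @return A data frame of class `trio_structure`.
#' @export
trio_structure <- function(child, mother, father, n_donors) {
  t <- data.frame(child = as.integer(child), mother = as.integer(mother),
                  father = as.integer(father))
  if (any(t < 1) || any(t > n_donors)) stop("trio index out of range")
  if (any(t$child == t$mother | t$child == t$father | t$mother == t$father))
    stop("trio indices must be distinct")
  class(t) <- c("trio_structure", "data.frame")
  t
}

# flat positions of a donor-index vector across all SNPs (SNP-major layout)
trio_positions <- function(db, donors) {
  as.vector(outer(donors, (seq_len(db$n_snps) - 1L) * db$n_donors, `+`))
}

#' Secure heterozygous-parent indicator for trios
#'
#' Per trio and SNP, `z = (mother_fA * mother_fB) * (father_fA * father_fB)`:
#' 1 iff both parents are heterozygous (AB); 0 if at least one parent is
#' homozygous or missing, since `fA*fB = 0` for homozygous and missing
#' encodings. Trios where `z = 0` contribute nothing downstream, so the
#' informative-trio selection never has to be revealed.
#'
#' @param db A `shared_genotype_db` whose columns include the trio members.
#' @param trios A [trio_structure()].
#' @param session An [mpc_session()].
#' @return A flat bit-valued `shared_vector` (trio-major per SNP).
#' @export
heterozygous_parent_vector <- function(db, trios, session) {
  mpos <- trio_positions(db, trios$mother)
  fpos <- trio_positions(db, trios$father)
  mz <- mul_shared(sv_index(db$fA, mpos), sv_index(db$fB, mpos), session)
  fz <- mul_shared(sv_index(db$fA, fpos), sv_index(db$fB, fpos), session)
  z <- mul_shared(mz, fz, session)
  z$bit <- TRUE
  z
}

#' Secure TDT transmission counts, vectorized over SNPs
#'
#' Among trios with two heterozygous parents, `u` counts AA children and `v`
#' counts BB children: `u = z.child_iAA`, `v = z.child_iBB`, with `z` from
#' [heterozygous_parent_vector()] and the child genotype flags from the
#' redundant shared flag rows.
#'
#' @inheritParams heterozygous_parent_vector
#' @return A `tdt_counts`: shared vectors `u` and `v`, one element per SNP.
#' @export
tdt_counts <- function(db, trios, session) {
  z <- heterozygous_parent_vector(db, trios, session)
  cpos <- trio_positions(db, trios$child)
  nt <- nrow(trios)
  grp <- rep(seq_len(db$n_snps), each = nt)
  u <- sv_sum_groups(mul_shared(z, sv_index(db$hAA, cpos), session),
                     grp, db$n_snps)
  v <- sv_sum_groups(mul_shared(z, sv_index(db$hBB, cpos), session),
                     grp, db$n_snps)
  structure(list(u = u, v = v, n_trios = nt, n_snps = db$n_snps,
                 snp_ids = db$snp_ids),
            class = "tdt_counts")
}
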