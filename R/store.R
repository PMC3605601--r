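#' Genotype call encoding
#'
#' Each biallelic SNP call is stored as the pair of allele counts
#' `(fA, fB)`: `AA -> (2,0)`, `AB -> (1,1)`, `BB -> (0,2)` and missing
#' `NN -> (0,0)`. Counting alleles then becomes integer arithmetic — no string
#' comparisons are ever needed on shares.
#'
#' @param call Character vector of calls (`AA`, `AB`, `BB`, `NN`).
#' @return For `encode_genotype`, a two-column integer matrix with columns
#'   `fA`, `fB`; for `decode_genotype`, a character vector of calls.
#' @export
encode_genotype <- function(call) {
  fa <- c(AA = 2L, AB = 1L, BB = 0L, NN = 0L)[call]
  fb <- c(AA = 0L, AB = 1L, BB = 2L, NN = 0L)[call]
  if (anyNA(fa)) {
    bad <- which(is.na(fa))[1]
    stop(sprintf("import error: unknown genotype call '%s' at position %d",
                 call[bad], bad))
  }
  cbind(fA = unname(fa), fB = unname(fb))
}

#' @rdname encode_genotype
#' @param fA,fB Integer allele counts per the encoding above.
#' @export
decode_genotype <- function(fA, fB) {
  key <- paste(fA, fB)
  out <- c("2 0" = "AA", "1 1" = "AB", "0 2" = "BB", "0 0" = "NN")[key]
  if (anyNA(out)) stop("invalid allele-count pair")
  unname(out)
}

#' Plaintext genotype matrix (staging container)
#'
#' @param calls Character matrix, one row per SNP, one column per donor.
#' @param snp_ids,donor_ids Row/column identifiers (donor IDs must be unique).
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snp_ids = rownames(calls),
                            donor_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(calls)))
  if (is.null(donor_ids)) donor_ids <- paste0("d", seq_len(ncol(calls)))
  if (anyDuplicated(donor_ids)) stop("import error: duplicate donor IDs")
  if (length(snp_ids) != nrow(calls) || length(donor_ids) != ncol(calls))
    stop("id/dimension mismatch")
  bad <- !(calls %in% c("AA", "AB", "BB", "NN"))
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("import error: unknown call '%s' (SNP %s, donor %s)",
                 calls[i], snp_ids[(i - 1) %% nrow(calls) + 1],
                 donor_ids[(i - 1) %/% nrow(calls) + 1]))
  }
  dimnames(calls) <- list(snp_ids, donor_ids)
  structure(list(calls = calls, snp_ids = snp_ids, donor_ids = donor_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d SNPs x %d donors\n",
              nrow(x$calls), ncol(x$calls)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Import and export the genotype TSV dialect
#'
#' The TSV dialect: a header row `snp_id<TAB>donor1<TAB>donor2...`, then one
#' row per SNP with `AA`/`AB`/`BB`/`NN` calls.
#'
#' @param path File path.
#' @return A [genotype_matrix()].
#' @export
import_genotype_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("import error: empty genotype file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  donor_ids <- header[-1]
  body <- parts[-1]
  width <- lengths(body)
  if (any(width != length(header)))
    stop(sprintf("import error: ragged row at line %d",
                 which(width != length(header))[1] + 1))
  snp_ids <- vapply(body, `[`, "", 1)
  calls <- do.call(rbind, lapply(body, `[`, -1))
  genotype_matrix(calls, snp_ids, donor_ids)
}

#' @rdname import_genotype_tsv
#' @param m A [genotype_matrix()].
#' @export
export_genotype_tsv <- function(m, path) {
  header <- paste(c("snp_id", m$donor_ids), collapse = "\t")
  rows <- apply(cbind(m$snp_ids, m$calls), 1, paste, collapse = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Import biallelic genotypes from a VCF file
#'
#' Reads GT fields of biallelic sites: `0/0 -> AA`, `0/1`, `1/0` (and phased
#' variants) `-> AB`, `1/1 -> BB`; any call containing `.` becomes `NN`
#' (conservative missing-data handling). The REF allele maps to allele A and
#' the first ALT to allele B. Multi-allelic sites are skipped with a warning.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @return A [genotype_matrix()].
#' @export
import_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required for VCF import")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic site(s)", sum(multi)))
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  snp_ids <- rownames(gt)
  if (is.null(snp_ids) || anyNA(snp_ids))
    snp_ids <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))
  calls <- gt_to_call(gt)
  genotype_matrix(calls, snp_ids, colnames(gt))
}

gt_to_call <- function(gt) {
  out <- matrix("NN", nrow(gt), ncol(gt))
  norm <- gsub("|", "/", gt, fixed = TRUE)
  out[!is.na(norm) & norm == "0/0"] <- "AA"
  out[!is.na(norm) & (norm == "0/1" | norm == "1/0")] <- "AB"
  out[!is.na(norm) & norm == "1/1"] <- "BB"
  unknown <- !is.na(norm) & !(norm %in% c("0/0", "0/1", "1/0", "1/1")) &
    !grepl(".", norm, fixed = TRUE)
  if (any(unknown))
    stop(sprintf("import error: malformed GT '%s'", gt[which(unknown)[1]]))
  out
}

#' Secret-share a genotype database
#'
#' Converts calls to the allele-count encoding and secret-shares the database
#' in the layout of the secure store: per SNP a row of `fA` counts and a row of
#' `fB` counts, one column per donor. Two redundant 0/1 flag rows `hAA`
#' (call == AA) and `hBB` (call == BB) are shared alongside, which makes every
#' genotype-table and TDT count a pure secure dot product (no secure
#' comparisons on the hot path).
#'
#' Elements are stored flat in SNP-major order: SNP `i`, donor `j` sits at
#' position `(i-1)*n_donors + j`.
#'
#' @param m A [genotype_matrix()].
#' @param session An [mpc_session()].
#' @return A `shared_genotype_db`.
#' @export
share_genotype_db <- function(m, session) {
  enc <- encode_genotype(t(m$calls))      # donor-major per SNP row
  fa <- enc[, "fA"]; fb <- enc[, "fB"]
  haa <- as.integer(t(m$calls) == "AA")
  hbb <- as.integer(t(m$calls) == "BB")
  structure(list(
    fA = share_secret(fa, session),
    fB = share_secret(fb, session),
    hAA = share_secret(haa, session, bit = TRUE),
    hBB = share_secret(hbb, session, bit = TRUE),
    snp_ids = m$snp_ids, donor_ids = m$donor_ids,
    n_snps = nrow(m$calls), n_donors = ncol(m$calls), k = session$k
  ), class = "shared_genotype_db")
}

#' @export
print.shared_genotype_db <- function(x, ...) {
  cat(sprintf("<shared_genotype_db> %d SNPs x %d donors on Z_{2^%d}\n",
              x$n_snps, x$n_donors, x$k))
  invisible(x)
}

#' Reconstruct a shared genotype database (verification only)
#'
#' @param db A `shared_genotype_db`.
#' @return A [genotype_matrix()].
#' @export
reconstruct_genotype_db <- function(db) {
  fa <- reconstruct(db$fA); fb <- reconstruct(db$fB)
  calls <- matrix(decode_genotype(fa, fb), db$n_snps, db$n_donors, byrow = TRUE)
  genotype_matrix(calls, db$snp_ids, db$donor_ids)
}

# flat SNP-major positions of one SNP's (or donor subset's) entries
db_positions <- function(db, snp, donors = seq_len(db$n_donors)) {
  (snp - 1L) * db$n_donors + donors
}

#' Phenotype tables and their shared form
#'
#' A phenotype table is a data frame with a `donor_id` column plus boolean
#' attributes (stored 0/1) and non-negative integer attributes. The shared form
#' holds each attribute as a secret-shared vector.
#'
#' @param path CSV file path.
#' @return `import_phenotype_csv`: a data frame; `share_phenotype_db`: a
#'   `shared_phenotype_db`.
#' @export
import_phenotype_csv <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"donor_id" %in% names(t)) stop("import error: no donor_id column")
  for (nm in setdiff(names(t), "donor_id")) {
    if (is.logical(t[[nm]])) t[[nm]] <- as.integer(t[[nm]])
    if (!is.numeric(t[[nm]]) || any(t[[nm]] != floor(t[[nm]])) ||
        any(t[[nm]] < 0))
      stop(sprintf("import error: attribute '%s' is not boolean/non-negative integer", nm))
  }
  t
}

#' @rdname import_phenotype_csv
#' @param t Phenotype data frame (see above).
#' @param session An [mpc_session()].
#' @export
share_phenotype_db <- function(t, session) {
  attrs <- setdiff(names(t), "donor_id")
  shared <- lapply(attrs, function(nm) {
    v <- as.integer(t[[nm]])
    share_secret(v, session, bit = all(v %in% c(0L, 1L)))
  })
  names(shared) <- attrs
  structure(list(attributes = shared, donor_ids = as.character(t$donor_id),
                 n_donors = nrow(t), k = session$k),
            class = "shared_phenotype_db")
}

#' @export
print.shared_phenotype_db <- function(x, ...) {
  cat(sprintf("<shared_phenotype_db> %d donors, attributes: %s\n",
              x$n_donors, paste(names(x$attributes), collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Host share stores: one store per host holding that host's share of every
# database row. Header carries format version, ring width, dimensions and row
# labels; values are row-major limb data. Two dialects, both bit-exact:
# "jsonl" (one JSON object per line) and "binary" (packed doubles).
# ---------------------------------------------------------------------------

STORE_VERSION <- 2L  # version 2 adds the redundant hAA/hBB flag rows

#' Write and read per-host share stores
#'
#' `write_share_stores` persists each host's share of a shared genotype
#' database into its own directory; any single directory (or pair) is
#' uniform-looking on its own, and `read_share_stores` needs all three to
#' rebuild the shared database (3-out-of-3).
#'
#' @param db A `shared_genotype_db`.
#' @param dirs Character vector of three host directories.
#' @param dialect `"jsonl"` or `"binary"`.
#' @return `write_share_stores` returns `dirs` invisibly; `read_share_stores`
#'   returns a `shared_genotype_db`.
#' @export
write_share_stores <- function(db, dirs, dialect = c("jsonl", "binary")) {
  dialect <- match.arg(dialect)
  stopifnot(length(dirs) == 3)
  rows <- c("fA", "fB", "hAA", "hBB")
  for (h in 1:3) {
    dir.create(dirs[h], recursive = TRUE, showWarnings = FALSE)
    header <- list(format = "ppgwas-share-store", version = STORE_VERSION,
                   dialect = dialect, host = h - 1L, k = db$k,
                   n_snps = db$n_snps, n_donors = db$n_donors,
                   rows = rows, snp_ids = db$snp_ids,
                   donor_ids = db$donor_ids)
    if (dialect == "jsonl") {
      path <- file.path(dirs[h], "store.jsonl")
      con <- file(path, "w")
      writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
      for (r in rows) {
        limbs <- db[[r]]$shares[[h]]
        writeLines(jsonlite::toJSON(
          list(row = r, limbs = as.vector(limbs), L = nrow(limbs)),
          auto_unbox = TRUE, digits = NA), con)
      }
      close(con)
    } else {
      path <- file.path(dirs[h], "store.bin")
      con <- file(path, "wb")
      hjson <- as.character(jsonlite::toJSON(header, auto_unbox = TRUE,
                                             digits = NA))
      writeBin(c("ppgwas-share-store-bin", hjson), con)
      for (r in rows) {
        limbs <- db[[r]]$shares[[h]]
        writeBin(as.integer(dim(limbs)), con)
        writeBin(as.vector(limbs), con)
      }
      close(con)
    }
  }
  invisible(dirs)
}

read_host_store <- function(dir) {
  jl <- file.path(dir, "store.jsonl")
  bn <- file.path(dir, "store.bin")
  if (file.exists(jl)) {
    lines <- readLines(jl)
    header <- jsonlite::fromJSON(lines[1])
    shares <- list()
    for (ln in lines[-1]) {
      obj <- jsonlite::fromJSON(ln)
      shares[[obj$row]] <- matrix(obj$limbs, nrow = obj$L)
    }
    list(header = header, shares = shares)
  } else if (file.exists(bn)) {
    con <- file(bn, "rb")
    on.exit(close(con))
    magic <- readBin(con, "character", 1)
    if (!identical(magic, "ppgwas-share-store-bin"))
      stop("not a ppgwas binary share store")
    header <- jsonlite::fromJSON(readBin(con, "character", 1))
    shares <- list()
    for (r in header$rows) {
      d <- readBin(con, "integer", 2)
      shares[[r]] <- matrix(readBin(con, "double", d[1] * d[2]), nrow = d[1])
    }
    list(header = header, shares = shares)
  } else {
    stop(sprintf("no share store found in '%s' (3-out-of-3 reconstruction needs all hosts)", dir))
  }
}

#' @rdname write_share_stores
#' @export
read_share_stores <- function(dirs) {
  stopifnot(length(dirs) == 3)
  hosts <- lapply(dirs, read_host_store)
  hd <- hosts[[1]]$header
  for (h in 2:3) {
    h2 <- hosts[[h]]$header
    if (!identical(h2$k, hd$k) || !identical(h2$n_snps, hd$n_snps) ||
        !identical(h2$n_donors, hd$n_donors))
      stop("protocol error: host stores disagree on header")
  }
  mk <- function(r) {
    shares <- lapply(hosts, function(x) x$shares[[r]])
    new_shared_vector(shares, as.integer(hd$k), ncol(shares[[1]]),
                      bit = r %in% c("hAA", "hBB"))
  }
  structure(list(fA = mk("fA"), fB = mk("fB"), hAA = mk("hAA"),
                 hBB = mk("hBB"),
                 snp_ids = as.character(hd$snp_ids),
                 donor_ids = as.character(hd$donor_ids),
                 n_snps = as.integer(hd$n_snps),
                 n_donors = as.integer(hd$n_donors),
                 k = as.integer(hd$k)),
            class = "shared_genotype_db")
}
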