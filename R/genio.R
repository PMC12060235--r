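# Genotype containers, VCF / call-code I/O and per-locus QC summaries.
#
# Genotypes are stored as an integer matrix of alternate-allele dosages
# (samples in rows, loci in columns): 0 = hom ref, 1 = het, 2 = hom alt,
# NA = missing. NA is a distinct sentinel and is never conflated with 0.

#' Construct a genotype matrix
#'
#' Validates and returns a samples-by-loci matrix of alternate-allele
#' dosages in \{0, 1, 2, NA\}. Row names are sample ids, column names locus
#' ids; both must be unique.
#'
#' @param calls integer (or coercible) matrix with dimnames.
#' @return An integer matrix of class `geno_matrix`.
#' @export
geno_matrix <- function(calls) {
  if (!is.matrix(calls)) abort("`calls` must be a matrix.")
  if ((nrow(calls) > 0 && is.null(rownames(calls))) ||
      (ncol(calls) > 0 && is.null(colnames(calls))))
    abort("genotype matrix needs sample ids (rownames) and locus ids (colnames).")
  if (anyDuplicated(rownames(calls))) abort("duplicated sample ids.")
  if (anyDuplicated(colnames(calls))) abort("duplicated locus ids.")
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) abort("genotype calls must be 0, 1, 2 or NA.")
  class(calls) <- c("geno_matrix", class(unclass(calls)))
  calls
}

assert_geno <- function(g) {
  if (!is.matrix(g) || nrow(g) == 0L || ncol(g) == 0L)
    abort("expected a non-empty samples x loci genotype matrix.")
  invisible(g)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d loci (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Read diploid biallelic genotypes from a VCF file
#'
#' Parses the GT field only. `0/0` maps to dosage 0, `0/1` and `1/0` to 1,
#' `1/1` to 2, and `./.` (or `.`) to NA. Phased separators `|` are treated
#' as `/`. Sample and record order are preserved.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param drop_multiallelic drop records with >1 ALT allele (with a message)
#'   instead of erroring. Default `FALSE`: the intended substrate is a
#'   biallelic array.
#' @return A [geno_matrix()] (samples x loci).
#' @export
read_vcf <- function(path, drop_multiallelic = FALSE) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    if (drop_multiallelic) {
      inform(sprintf("dropped %d multiallelic record(s).", sum(multi)))
      v <- v[!multi, ]
      ids <- ids[!multi]
    } else {
      abort(sprintf("multiallelic record at %s:%s (%s); set drop_multiallelic = TRUE to drop.",
                    fix[multi, "CHROM"][1], fix[multi, "POS"][1], ids[multi][1]))
    }
  }
  samples <- colnames(v@gt)[-1]
  if (nrow(v@fix) == 0L) {
    empty <- matrix(NA_integer_, nrow = length(samples), ncol = 0,
                    dimnames = list(samples, character()))
    return(geno_matrix(empty))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) abort("VCF has no GT field.")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = 1, dimnames = list(ids, names(gt)))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[is.na(gt)] <- "./."
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "./." = NA_integer_, "." = NA_integer_, "./0" = NA_integer_,
           "0/." = NA_integer_, "./1" = NA_integer_, "1/." = NA_integer_)
  unknown <- matrix(!(gt %in% names(map)), nrow = nrow(gt))
  if (any(unknown)) {
    i <- which(unknown, arr.ind = TRUE)[1, ]
    abort(sprintf("unsupported GT value '%s' at record %s, sample %s (haploid or >2 alleles?).",
                  gt[unknown][1], ids[i[1]], colnames(gt)[i[2]]))
  }
  calls <- matrix(map[gt], nrow = nrow(gt),
                  dimnames = list(ids, colnames(gt)))
  geno_matrix(t(calls))
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Minimal VCF 4.2 with GT only; missing calls written as `./.`. REF/ALT
#' are written as A/C placeholders unless supplied.
#'
#' @param g genotype matrix.
#' @param path output path.
#' @param ref,alt optional per-locus REF/ALT allele characters.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, ref = NULL, alt = NULL) {
  assert_geno(g)
  L <- ncol(g)
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("C", L)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  cells <- matrix("./.", nrow = L, ncol = nrow(g))
  known <- !is.na(t(g))
  cells[known] <- gt_code[as.character(t(g)[known])]
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  body <- paste("1", seq_len(L), colnames(g), ref, alt, ".", ".", ".", "GT",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read Axiom-style call codes (AA/AB/BB/NoCall)
#'
#' Expects a tab-separated table with sample ids in the first column and one
#' column per locus; cells in \{AA, AB, BB, NoCall\}. Under the default
#' mapping A is the reference allele, so AA -> 0, AB -> 1, BB -> 2,
#' NoCall -> NA. Loci whose B allele is the reference can be listed in
#' `b_is_ref` to flip the coding.
#'
#' @param path TSV path.
#' @param b_is_ref character vector of locus ids with swapped A/B mapping.
#' @return A [geno_matrix()].
#' @export
read_callcodes <- function(path, b_is_ref = character()) {
  if (!file.exists(path)) abort(sprintf("call-code table not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  map <- c(AA = 0L, AB = 1L, BB = 2L, NoCall = NA_integer_)
  unknown <- !(m %in% names(map)) & !is.na(m)
  if (any(unknown)) {
    i <- which(unknown, arr.ind = TRUE)[1, ]
    abort(sprintf("unknown call code '%s' at sample %s, locus %s.",
                  m[unknown][1], rownames(m)[i[1]], colnames(m)[i[2]]))
  }
  calls <- matrix(map[m], nrow = nrow(m), dimnames = dimnames(m))
  flip <- colnames(calls) %in% b_is_ref
  calls[, flip] <- 2L - calls[, flip]
  geno_matrix(calls)
}

#' Write a genotype matrix as an Axiom-style call-code table
#'
#' Inverse of [read_callcodes()] under the default A = ref mapping.
#'
#' @param g genotype matrix.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_callcodes <- function(g, path) {
  assert_geno(g)
  code <- c(`0` = "AA", `1` = "AB", `2` = "BB")
  cells <- matrix("NoCall", nrow = nrow(g), ncol = ncol(g),
                  dimnames = dimnames(g))
  known <- !is.na(g)
  cells[known] <- code[as.character(g[known])]
  out <- tibble::as_tibble(cells, rownames = "sample_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Genotype completeness per locus and per sample
#'
#' Fraction of non-missing calls along each axis of the genotype matrix.
#'
#' @param g genotype matrix.
#' @return A list with tibbles `locus` (locus_id, completeness) and
#'   `sample` (sample_id, completeness).
#' @export
completeness <- function(g) {
  assert_geno(g)
  ok <- !is.na(g)
  list(
    locus  = tibble(locus_id = colnames(g),
                    completeness = unname(colMeans(ok))),
    sample = tibble(sample_id = rownames(g),
                    completeness = unname(rowMeans(ok)))
  )
}

#' Per-locus allele-frequency and heterozygosity summaries
#'
#' For each locus, over its non-missing samples of size n: the ALT allele
#' frequency `p_alt` (mean dosage / 2), minor allele frequency
#' `maf = min(p, 1 - p)`, observed heterozygosity `ho` (frequency of
#' dosage 1), and unbiased expected heterozygosity (gene diversity)
#' `hs = 2n/(2n - 1) * (1 - p^2 - (1-p)^2)` with Nei's small-sample
#' correction. Loci with zero non-missing calls get NA statistics (flagged
#' by `n = 0`), never a silent 0.
#'
#' @param g genotype matrix.
#' @return A tibble with one row per locus: locus_id, n, completeness,
#'   p_alt, maf, ho, hs.
#' @export
locus_stats <- function(g) {
  assert_geno(g)
  ok <- !is.na(g)
  n <- colSums(ok)
  p <- ifelse(n > 0, colSums(g, na.rm = TRUE) / (2 * n), NA_real_)
  ho <- ifelse(n > 0, colSums(g == 1L, na.rm = TRUE) / n, NA_real_)
  hs <- ifelse(n > 0, (2 * n / pmax(2 * n - 1, 1)) * (1 - p^2 - (1 - p)^2),
               NA_real_)
  tibble(
    locus_id = colnames(g),
    n = as.integer(unname(n)),
    completeness = unname(n) / nrow(g),
    p_alt = unname(p),
    maf = unname(pmin(p, 1 - p)),
    ho = unname(ho),
    hs = unname(hs)
  )
}

# Mean-dosage imputation of missing calls; the convention used before
# distance and relationship computations. Loci with no observed calls are
# rejected (no defensible mean exists).
impute_mean <- function(g) {
  assert_geno(g)
  m <- unclass(g)
  storage.mode(m) <- "double"
  n_ok <- colSums(!is.na(m))
  if (any(n_ok == 0L))
    abort(sprintf("%d locus/loci have no observed calls; drop them first.",
                  sum(n_ok == 0L)))
  mu <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- mu[idx[, 2]]
  m
}
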