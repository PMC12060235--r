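# Genomic relationship matrix (VanRaden method 1), inbreeding from its
# diagonal, F_IS per group, and relatedness-network edges.

#' Compute a genomic relationship matrix (VanRaden method 1)
#'
#' Missing calls are mean-imputed per locus, dosages are centered on twice
#' the ALT allele frequency, and G = ZZ' / (2 * sum_l p_l (1 - p_l)).
#' With in-sample frequencies each row of G sums to zero and the diagonal
#' has mean 1 + f, f the mean inbreeding coefficient relative to the
#' sample. Loci with maf <= `min_maf` (monomorphic ones at the default 0)
#' are dropped with a message.
#'
#' @param g genotype matrix (typically clone consensus genotypes, one row
#'   per clone).
#' @param freqs optional external per-locus ALT frequencies (named or in
#'   column order); default uses in-sample frequencies.
#' @param min_maf drop loci with minor allele frequency <= this value.
#' @param ibs if `TRUE`, return instead the plain mean identity-by-state
#'   similarity matrix (mean over loci of the fraction of shared alleles);
#'   provided for comparison only.
#' @return list of class `grm`: `values` (symmetric matrix), `clone_ids`,
#'   `allele_freqs_used`, `loci_used`, `n_dropped`.
#' @export
compute_grm <- function(g, freqs = NULL, min_maf = 0, ibs = FALSE) {
  assert_geno(g)
  if (nrow(g) < 2) abort("need at least 2 samples.")
  M <- impute_mean(g)
  p <- if (is.null(freqs)) colMeans(M) / 2 else {
    if (!is.null(names(freqs))) freqs[colnames(g)] else freqs
  }
  if (length(p) != ncol(g)) abort("`freqs` length must match loci.")
  maf <- pmin(p, 1 - p)
  keep <- maf > min_maf
  if (!any(keep)) abort("zero denominator: all loci monomorphic (maf <= min_maf).")
  if (any(!keep))
    inform(sprintf("dropped %d locus/loci with maf <= %g.", sum(!keep), min_maf))
  M <- M[, keep, drop = FALSE]; p <- p[keep]
  if (ibs) {
    # mean probability of identity by state: share = 1 - |mi - mj| / 2
    D <- as.matrix(dist(M, method = "manhattan")) / ncol(M)
    V <- 1 - D / 2
  } else {
    Z <- sweep(M, 2, 2 * p)
    V <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  }
  dimnames(V) <- list(rownames(g), rownames(g))
  structure(list(values = V, clone_ids = rownames(g),
                 allele_freqs_used = p, loci_used = colnames(M),
                 n_dropped = sum(!keep), ibs = ibs),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d clones, %d loci used; mean diagonal %.3f\n",
              length(x$clone_ids), length(x$loci_used),
              mean(diag(x$values))))
  invisible(x)
}

#' @export
as.matrix.grm <- function(x, ...) x$values

#' Group-level inbreeding and relatedness summaries from a GRM
#'
#' Per group: mean GRM diagonal minus 1 (`f_grm`, the realised inbreeding
#' coefficient) with SD; mean off-diagonal relationship within the group
#' (`ibd_within`, SD) and against all other groups (`ibd_between`, SD).
#' Singleton groups have no within-group pairs and get NA there.
#'
#' @param grm a [compute_grm()] result (or plain symmetric matrix).
#' @param groups named character vector or factor mapping clone ids to
#'   group labels (e.g. provenance regions).
#' @return tibble: group, n1, f_grm, f_grm_sd, ibd_within, ibd_within_sd,
#'   n2, ibd_between, ibd_between_sd.
#' @export
inbreeding_from_grm <- function(grm, groups) {
  G <- if (inherits(grm, "grm")) grm$values else grm
  ids <- rownames(G)
  if (is.null(names(groups))) names(groups) <- ids
  gr <- as.character(groups[ids])
  purrr::map_dfr(sort(unique(gr)), function(lab) {
    inside <- which(gr == lab); outside <- which(gr != lab)
    dg <- diag(G)[inside]
    within <- G[inside, inside, drop = FALSE]
    wvals <- within[upper.tri(within)]
    bet <- as.vector(G[inside, outside, drop = FALSE])
    tibble(group = lab, n1 = length(inside),
           f_grm = mean(dg) - 1, f_grm_sd = sd(dg),
           ibd_within = if (length(wvals)) mean(wvals) else NA_real_,
           ibd_within_sd = if (length(wvals) > 1) sd(wvals) else NA_real_,
           n2 = length(outside),
           ibd_between = if (length(bet)) mean(bet) else NA_real_,
           ibd_between_sd = if (length(bet) > 1) sd(bet) else NA_real_)
  })
}

#' Within-group inbreeding coefficient F_IS with bootstrap CI
#'
#' Per group, observed (Ho) and unbiased expected (Hs) heterozygosity are
#' averaged over the group's polymorphic loci and F_IS = 1 - Ho/Hs. The
#' confidence interval is a seeded percentile bootstrap over loci.
#'
#' @param g genotype matrix.
#' @param groups named character vector/factor mapping sample ids to groups.
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return tibble: group, n, n_loci, ho, hs, fis, ci_lo, ci_hi. Groups with
#'   no polymorphic locus get NA fis (flagged by n_loci = 0).
#' @export
fis <- function(g, groups, n_boot = 1000, conf = 0.95, seed = 1) {
  assert_geno(g)
  if (is.null(names(groups))) names(groups) <- rownames(g)
  gr <- as.character(groups[rownames(g)])
  set.seed(seed)
  purrr::map_dfr(sort(unique(gr)), function(lab) {
    sub <- g[gr == lab, , drop = FALSE]
    st <- locus_stats(geno_matrix(unclass(sub)))
    st <- st %>% filter(.data$n > 0, .data$maf > 0, !is.na(.data$hs),
                        .data$hs > 0)
    if (nrow(st) == 0)
      return(tibble(group = lab, n = sum(gr == lab), n_loci = 0L,
                    ho = NA_real_, hs = NA_real_, fis = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_))
    f_of <- function(idx) 1 - mean(st$ho[idx]) / mean(st$hs[idx])
    fhat <- f_of(seq_len(nrow(st)))
    boots <- vapply(seq_len(n_boot), function(b)
      f_of(sample.int(nrow(st), replace = TRUE)), numeric(1))
    qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    tibble(group = lab, n = nrow(sub), n_loci = nrow(st),
           ho = mean(st$ho), hs = mean(st$hs), fis = fhat,
           ci_lo = qs[1], ci_hi = qs[2])
  })
}

#' Relatedness-network edges from a GRM
#'
#' Undirected edges (i, j, weight = G_ij) for every off-diagonal pair whose
#' relationship exceeds `relatedness_factor`. If `groups` is supplied a
#' per-node degree report (with group label) is returned alongside.
#'
#' @param grm a [compute_grm()] result or symmetric matrix.
#' @param relatedness_factor edge inclusion threshold (default 0.0001).
#' @param groups optional named group labels per clone.
#' @return list: `edges` (tibble: from, to, weight) and `degrees` (tibble:
#'   clone_id, group, degree).
#' @export
ibd_network_edges <- function(grm, relatedness_factor = 1e-4, groups = NULL) {
  G <- if (inherits(grm, "grm")) grm$values else grm
  ids <- rownames(G)
  ut <- which(upper.tri(G) & G > relatedness_factor, arr.ind = TRUE)
  edges <- tibble(from = ids[ut[, 1]], to = ids[ut[, 2]],
                  weight = G[ut])
  deg <- table(factor(c(edges$from, edges$to), levels = ids))
  degrees <- tibble(clone_id = ids, degree = as.integer(deg))
  if (!is.null(groups)) {
    if (is.null(names(groups))) names(groups) <- ids
    degrees$group <- as.character(groups[ids])
  }
  list(edges = edges, degrees = degrees)
}
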