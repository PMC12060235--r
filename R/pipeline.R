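# End-to-end orchestration: genotypes + metadata + phenotypes ->
# verification, lineage collapsing, GRM/inbreeding, clonal BLUPs,
# cross-validated genomic prediction and selection gains.

#' Parameters for a full pipeline run
#'
#' @param error_threshold per-sample error-rate exclusion threshold.
#' @param mlg_cutoff `"auto"` or a numeric similarity threshold.
#' @param min_maf GRM locus filter.
#' @param k cross-validation folds.
#' @param n_permutations permutation-null replicates (0 disables).
#' @param top_fraction selection fraction for gain reporting.
#' @param seed root seed for folds and permutations.
#' @return named list of class `pipeline_params`.
#' @export
pipeline_params <- function(error_threshold = 0.025, mlg_cutoff = "auto",
                            min_maf = 0, k = 9, n_permutations = 200,
                            top_fraction = 0.10, seed = 1) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full clonal-breeding analysis pipeline
#'
#' Stages: ramet verification against clone consensus genotypes -> per-SNP
#' error rates -> multilocus-lineage collapsing (auto cutoff) -> GRM on the
#' verified clone consensus genotypes -> group inbreeding and F_IS ->
#' phenotype correction and clonal BLUPs per site and trait -> broad-sense
#' heritability -> GBLUP cross-validation (+ permutation null) ->
#' selection gains. Inputs may be in-memory objects or file paths (VCF /
#' TSV). If `outdir` is given, every table is written as TSV/JSON together
#' with a manifest carrying the parameter hash and seed.
#'
#' @param genotypes ramet [geno_matrix()] or path to a VCF.
#' @param meta sample metadata tibble (sample_id, clone_id, region,
#'   registered) or TSV path.
#' @param phenotypes phenotype tibble (site, clone_id, ramet_id, year, age,
#'   nc, mcw, dag) or TSV path.
#' @param params a [pipeline_params()] list.
#' @param outdir optional output directory.
#' @return list of class `pipeline_report` with all stage results and a
#'   `manifest`.
#' @export
run_pipeline <- function(genotypes, meta, phenotypes,
                         params = pipeline_params(), outdir = NULL) {
  if (is.character(genotypes)) {
    if (!file.exists(genotypes)) abort(sprintf("genotype file not found: %s", genotypes))
    genotypes <- read_vcf(genotypes)
  }
  if (is.character(meta)) {
    if (!file.exists(meta)) abort(sprintf("metadata file not found: %s", meta))
    meta <- readr::read_tsv(meta, show_col_types = FALSE, progress = FALSE)
  }
  if (is.character(phenotypes)) {
    if (!file.exists(phenotypes)) abort(sprintf("phenotype file not found: %s", phenotypes))
    phenotypes <- readr::read_tsv(phenotypes, show_col_types = FALSE,
                                  progress = FALSE)
  }
  assert_geno(genotypes); assert_pheno(phenotypes)

  verification <- verify_ramets(genotypes, meta,
                                error_threshold = params$error_threshold)
  snp_errors <- snp_error_rates(genotypes, verification)
  clone_summary <- clone_error_summary(verification, genotypes, meta)

  retained <- verification$reports %>% filter(!.data$excluded)
  dmat <- nei_distance_matrix(genotypes)
  mlg <- collapse_mlg(dmat, threshold = params$mlg_cutoff)

  cons <- verification$consensus
  all_missing <- colSums(!is.na(unclass(cons))) == 0
  if (any(all_missing)) cons <- geno_matrix(unclass(cons)[, !all_missing, drop = FALSE])
  grm <- compute_grm(cons, min_maf = params$min_maf)
  clone_groups <- meta %>% distinct(.data$clone_id, .data$region)
  groups <- setNames(clone_groups$region, clone_groups$clone_id)
  inbreeding <- inbreeding_from_grm(grm, groups)
  fis_tbl <- fis(cons, groups, seed = params$seed)
  network <- ibd_network_edges(grm, groups = groups)

  sites <- sort(unique(phenotypes$site))
  registered_ids <- if ("registered" %in% names(meta))
    unique(meta$clone_id[meta$registered]) else character()
  blups <- list(); h2 <- list(); cv <- list(); perms <- list(); gains <- list()
  for (s in sites) {
    for (trait in c("nc", "mcw")) {
      rv <- tryCatch({
        if (trait == "mcw") ramet_blup_mcw(phenotypes, s)
        else accumulate_nc(phenotypes, s)
      }, error = function(e) NULL)
      if (is.null(rv)) next
      cb <- clonal_blups(rv, use_nyears = (trait == "nc"))
      key <- paste(s, trait, sep = ".")
      blups[[key]] <- cb
      h2[[key]] <- tibble(site = s, trait = trait, H2 = cb$H2)
      yv <- cb$blups %>% filter(.data$clone_id %in% rownames(grm$values))
      if (nrow(yv) >= params$k * 2) {
        cvr <- cross_validate(yv %>% select("clone_id", "value"), grm,
                              k = params$k, seed = params$seed)
        cv[[key]] <- glance(cvr) %>% mutate(site = s, trait = trait)
        if (params$n_permutations > 0) {
          pn <- permutation_null(yv %>% select("clone_id", "value"), grm,
                                 B = params$n_permutations, k = params$k,
                                 seed = params$seed)
          perms[[key]] <- tibble(site = s, trait = trait,
                                 observed_r_y = pn$observed,
                                 p_value = pn$p_value, B = pn$B)
        }
      }
      gain_rows <- selection_gain(cb, top_fraction = params$top_fraction) %>%
        mutate(site = s, trait = trait)
      if (length(registered_ids)) {
        gain_rows <- bind_rows(
          gain_rows,
          selection_gain(cb, subset_ids = registered_ids) %>%
            mutate(site = s, trait = trait, subset = "registered"))
      }
      gains[[key]] <- gain_rows
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("clonalpred")),
    seed = params$seed,
    params_hash = rlang::hash(unclass(params)),
    n_samples = nrow(genotypes), n_loci = ncol(genotypes),
    n_clones = n_distinct(meta$clone_id),
    n_excluded = sum(verification$reports$excluded),
    n_lineages = mlg$n_lineages,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  report <- structure(list(
    params = params, manifest = manifest,
    verification = verification, clone_summary = clone_summary,
    snp_errors = snp_errors, mlg = mlg, grm = grm,
    inbreeding = inbreeding, fis = fis_tbl, network = network,
    blups = blups, h2 = bind_rows(h2), cv = bind_rows(cv),
    permutations = bind_rows(perms), gains = bind_rows(gains)
  ), class = "pipeline_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0(
    "<pipeline_report> %d samples / %d clones / %d loci\n",
    "  excluded ramets: %d; lineages: %d; params hash %s\n"),
    m$n_samples, m$n_clones, m$n_loci, m$n_excluded, m$n_lineages,
    m$params_hash))
  if (nrow(x$cv)) {
    cat("  predictive ability:\n")
    for (i in seq_len(nrow(x$cv)))
      cat(sprintf("    %s %s: r_y = %.3f +- %.3f\n", x$cv$site[i],
                  x$cv$trait[i], x$cv$r_y[i], x$cv$sd[i]))
  }
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tb, name) readr::write_tsv(tb, file.path(outdir, name),
                                           progress = FALSE)
  w(report$verification$reports, "mismatch_reports.tsv")
  w(report$clone_summary, "clone_error_summary.tsv")
  w(report$snp_errors, "snp_error_rates.tsv")
  w(report$mlg$assignment, "lineage_assignment.tsv")
  gm <- as_tibble(report$grm$values, rownames = "clone_id")
  w(gm, "grm.tsv")
  w(report$network$edges, "ibd_network_edges.tsv")
  w(report$inbreeding, "inbreeding_summary.tsv")
  w(report$fis, "fis_summary.tsv")
  w(report$h2, "heritability.tsv")
  if (nrow(report$cv)) w(report$cv, "predictive_ability.tsv")
  if (nrow(report$permutations)) w(report$permutations, "permutation_tests.tsv")
  if (nrow(report$gains)) w(report$gains, "selection_gains.tsv")
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
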