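# Synthetic clone/ramet cohort generator.
#
# Emulates a clonal breeding-programme dataset: ~99 clones from 4
# differentiated provenance regions genotyped at ~2,245 biallelic SNPs,
# registered clones sampled with 4-11 ramets each, per-genotype call error
# ~0.5%, ~1% missingness, ~10% of registered-clone ramets mislabelled, and
# repeated-measure cone phenotypes (NC counts with masting years, MCW
# weights) across 3 clonal test sites. A truth record accompanies every
# draw so downstream estimators can be validated against known parameters.
#
# All randomness flows from one root seed; each stage derives its own
# sub-seed (seed + fixed offset) so stages can be re-run independently and
# reproducibly.

#' Configuration for the synthetic cohort generator
#'
#' Defaults are calibrated to a Spanish stone-pine breeding cohort: 99
#' clones in 4 provenance regions, 2,245 SNPs, 15 registered clones with
#' 4-11 ramets each, 0.5% per-genotype error, 1% missingness, 10%
#' mislabelled ramets, and broad-sense heritabilities inside 0.2-0.5.
#'
#' @param n_loci number of biallelic SNPs.
#' @param regions named integer vector: clones per provenance region.
#' @param fst differentiation among regions (Balding-Nichols F), in [0, 1);
#'   either one value for all regions or a named per-region vector (a larger
#'   F gives a more drifted, internally related region).
#' @param region_selfing named per-region inbreeding coefficient in [0, 1],
#'   applied to genotype probabilities (P(het) = 2p(1-p)(1-F)).
#' @param n_registered number of registered clones (multi-ramet sampling).
#' @param ramets_registered integer range of ramets per registered clone.
#' @param ramets_unregistered ramets per unregistered clone.
#' @param geno_error_rate probability each called genotype is flipped to a
#'   different valid genotype.
#' @param missing_rate probability a call is set missing.
#' @param mislabel_rate fraction of registered-clone ramets whose clone
#'   label is reassigned to a different registered clone.
#' @param h2_nc,h2_mcw broad-sense heritabilities, strictly inside (0, 1).
#'   For NC the value applies on the latent log scale.
#' @param n_sites number of clonal test sites (site 1 hosts all clones).
#' @param years calendar years measured.
#' @param masting_sd SD of the random calendar-year (masting) effect on the
#'   NC log scale.
#' @param mcw_year_sd SD of the calendar-year effect on MCW (g).
#' @param nc_mean baseline yearly cone count at the reference diameter.
#' @param nc_dispersion negative-binomial size parameter for NC counts.
#' @param pheno_ramets grafted ramets per clone per site in the trials.
#' @param drop_rate fraction of ramet-year records dropped at random.
#' @param seed root integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 2245,
                       regions = c(ES1 = 31L, ES2 = 19L, ES3 = 21L, ES6 = 28L),
                       fst = 0.2,
                       region_selfing = c(ES1 = 0.02, ES2 = 0.2,
                                          ES3 = 0.15, ES6 = 0.5),
                       n_registered = 15L,
                       ramets_registered = 4:11,
                       ramets_unregistered = 1L,
                       geno_error_rate = 0.005,
                       missing_rate = 0.01,
                       mislabel_rate = 0.10,
                       h2_nc = 0.45,
                       h2_mcw = 0.35,
                       n_sites = 3L,
                       years = 2005:2014,
                       masting_sd = 0.6,
                       mcw_year_sd = 15,
                       nc_mean = 1.5,
                       nc_dispersion = 2,
                       pheno_ramets = 5L,
                       drop_rate = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_clones <- sum(regions)
  probs <- c(geno_error_rate = geno_error_rate,
             missing_rate = missing_rate, mislabel_rate = mislabel_rate,
             drop_rate = drop_rate, region_selfing, fst)
  if (any(probs < 0 | probs > 1)) abort("all rates must lie in [0, 1].")
  if (any(fst >= 1)) abort("fst must be < 1.")
  if (length(fst) > 1 && !all(names(regions) %in% names(fst)))
    abort("per-region `fst` must be named and cover every region.")
  if (n_loci < 1) abort("n_loci must be >= 1.")
  if (any(regions < 1)) abort("every region needs at least 1 clone.")
  if (is.null(names(regions))) abort("`regions` must be named.")
  if (!all(names(regions) %in% names(region_selfing)))
    abort("`region_selfing` must cover every region.")
  if (h2_nc <= 0 || h2_nc >= 1 || h2_mcw <= 0 || h2_mcw >= 1)
    abort("heritabilities must lie strictly inside (0, 1).")
  if (n_registered > cfg$n_clones)
    abort("n_registered exceeds number of clones.")
  if (mislabel_rate > 0 && n_registered < 2)
    abort("mislabelling needs at least 2 registered clones.")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d clones (%s), %d loci, fst %s, error %.3f, missing %.3f, mislabel %.2f, seed %d\n",
    x$n_clones, paste(names(x$regions), x$regions, sep = ":", collapse = " "),
    x$n_loci, paste(format(x$fst, digits = 2), collapse = "/"),
    x$geno_error_rate, x$missing_rate, x$mislabel_rate, x$seed))
  invisible(x)
}

#' Simulate per-region founder allele frequencies
#'
#' Ancestral frequencies p0 ~ Uniform(0.05, 0.95) per locus; each region's
#' frequencies follow the Balding-Nichols model,
#' Beta(p0 (1-F)/F, (1-p0)(1-F)/F) with F = `cfg$fst`. With `fst = 0` all
#' regions share p0 exactly.
#'
#' @param cfg a [sim_config()].
#' @return A regions x loci matrix of ALT allele frequencies in (0, 1),
#'   with the ancestral `p0` attached as attribute `"p0"`.
#' @export
simulate_founder_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 101L)
  p0 <- runif(cfg$n_loci, 0.05, 0.95)
  R <- length(cfg$regions)
  f_r <- if (length(cfg$fst) > 1) cfg$fst[names(cfg$regions)]
         else rep(cfg$fst, R)
  freqs <- t(vapply(seq_len(R), function(i) {
    if (f_r[i] == 0) return(p0)
    k <- (1 - f_r[i]) / f_r[i]
    # keep frequencies strictly inside (0,1) so no locus is degenerate
    pmin(pmax(rbeta(cfg$n_loci, p0 * k, (1 - p0) * k), 1e-6), 1 - 1e-6)
  }, numeric(cfg$n_loci)))
  dimnames(freqs) <- list(names(cfg$regions), sprintf("snp%04d", seq_len(cfg$n_loci)))
  attr(freqs, "p0") <- p0
  freqs
}

#' Simulate true clone genotypes
#'
#' Each clone's genotype is drawn per locus from inbreeding-adjusted
#' genotype probabilities for its region: P(het) = 2p(1-p)(1-F),
#' P(hom alt) = p^2 + F p (1-p), with F the region's selfing/inbreeding
#' level. With `region_selfing = 1` a region produces no heterozygotes.
#'
#' @param cfg a [sim_config()].
#' @param freqs output of [simulate_founder_frequencies()].
#' @return list with `genotypes` (a clones x loci [geno_matrix()]) and
#'   `clone_meta` (tibble: clone_id, region, registered).
#' @export
simulate_clones <- function(cfg, freqs) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 202L)
  regions <- rep(names(cfg$regions), cfg$regions)
  clone_id <- sprintf("c%03d", seq_len(cfg$n_clones))
  registered <- seq_len(cfg$n_clones) %in%
    sort(sample.int(cfg$n_clones, cfg$n_registered))
  G <- matrix(0L, nrow = cfg$n_clones, ncol = cfg$n_loci,
              dimnames = list(clone_id, colnames(freqs)))
  for (i in seq_len(cfg$n_clones)) {
    p <- freqs[regions[i], ]
    f <- cfg$region_selfing[[regions[i]]]
    p2 <- p^2 + f * p * (1 - p)
    p1 <- 2 * p * (1 - p) * (1 - f)
    u <- runif(cfg$n_loci)
    G[i, ] <- ifelse(u < p2, 2L, ifelse(u < p2 + p1, 1L, 0L))
  }
  list(genotypes = geno_matrix(G),
       clone_meta = tibble(clone_id = clone_id, region = regions,
                           registered = registered))
}

#' Simulate genotyped ramets with error, missingness and mislabels
#'
#' Each ramet copies its clone's genotype exactly, then each call is flipped
#' to a different random valid genotype with probability
#' `cfg$geno_error_rate` and set missing with probability
#' `cfg$missing_rate`. Registered clones contribute a random 4-11 ramets
#' (per `cfg$ramets_registered`), unregistered clones 1. A
#' `cfg$mislabel_rate` fraction of registered-clone ramets have their clone
#' label reassigned to a different random registered clone, emulating
#' grafting mix-ups in the clonal bank; the truth record lists every
#' injection.
#'
#' @param clones output of [simulate_clones()].
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (ramets x loci [geno_matrix()]), `meta`
#'   (tibble: sample_id, clone_id (label), region, registered) and `truth`
#'   (list: true_clone per sample, mislabelled_samples tibble,
#'   injected_error_positions tibble, n_missing_injected).
#' @export
simulate_ramets <- function(clones, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 303L)
  cm <- clones$clone_meta
  reg_draw <- if (length(cfg$ramets_registered) > 1)
    sample(cfg$ramets_registered, nrow(cm), replace = TRUE)
  else rep(cfg$ramets_registered, nrow(cm))
  n_r <- ifelse(cm$registered, reg_draw, cfg$ramets_unregistered)
  row_of <- rep(seq_len(nrow(cm)), n_r)
  ramet_no <- sequence(n_r)
  sample_id <- sprintf("%s_r%02d", cm$clone_id[row_of], ramet_no)
  M <- unclass(clones$genotypes)[row_of, , drop = FALSE]
  rownames(M) <- sample_id

  # genotype-call errors: flip to one of the two other dosages
  err <- runif(length(M)) < cfg$geno_error_rate
  if (any(err)) {
    shift <- sample(1:2, sum(err), replace = TRUE)
    M[err] <- (M[err] + shift) %% 3L
  }
  err_idx <- which(matrix(err, nrow = nrow(M)), arr.ind = TRUE)
  injected_errors <- tibble(sample_id = sample_id[err_idx[, 1]],
                            locus_id = colnames(M)[err_idx[, 2]])

  miss <- runif(length(M)) < cfg$missing_rate
  M[miss] <- NA_integer_

  # clone-label swaps among registered clones
  true_clone <- cm$clone_id[row_of]
  label <- true_clone
  reg_ids <- cm$clone_id[cm$registered]
  eligible <- which(true_clone %in% reg_ids)
  swap <- eligible[runif(length(eligible)) < cfg$mislabel_rate]
  for (i in swap) {
    label[i] <- sample(setdiff(reg_ids, true_clone[i]), 1L)
  }
  meta <- tibble(sample_id = sample_id, clone_id = label) %>%
    left_join(cm, by = "clone_id") %>%
    select("sample_id", "clone_id", "region", "registered")
  truth <- list(
    true_clone = setNames(true_clone, sample_id),
    mislabelled_samples = tibble(sample_id = sample_id[swap],
                                 true_clone_id = true_clone[swap],
                                 labelled_clone_id = label[swap]),
    injected_error_positions = injected_errors,
    n_missing_injected = sum(miss)
  )
  list(genotypes = geno_matrix(M), meta = meta, truth = truth)
}

#' Simulate repeated-measure cone phenotypes
#'
#' Clonal genetic values per trait are sums of per-locus additive effects
#' over the true clone dosages, standardised to unit variance. Mean cone
#' weight (MCW, g) is Gaussian: overall mean + site + calendar-year effect
#' + genetic value + permanent ramet effect + record noise, truncated at 0.
#' `h2_mcw` is the broad-sense heritability at the corrected-ramet level:
#' var(genetic) / (var(genetic) + var(ramet)) with year and record noise
#' marginalised out, matching what [broad_sense_h2()] estimates after year
#' correction.
#' Cone number (NC) is negative-binomial with log link: site + masting year
#' effect (SD `masting_sd`) + allometric log-diameter term + genetic +
#' permanent ramet effect; `h2_nc` applies on the latent scale. Diameter
#' (DAG, cm) grows linearly with age. A `drop_rate` fraction of ramet-years
#' is dropped, and MCW is absent whenever no cones were produced.
#'
#' @param clones output of [simulate_clones()].
#' @param cfg a [sim_config()].
#' @return list with `phenotypes` (tibble: site, clone_id, ramet_id, year,
#'   age, nc, mcw, dag) and `truth` (tibble of true clonal genetic values
#'   plus the per-trait heritabilities and snp effects).
#' @export
simulate_phenotypes <- function(clones, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 404L)
  cm <- clones$clone_meta
  M <- impute_mean(clones$genotypes)  # no missing here, but centers types
  std_gv <- function(beta) {
    gv <- drop(M %*% beta)
    s <- sd(gv)
    if (s < 1e-12) gv * 0 else (gv - mean(gv)) / s
  }
  beta_nc <- rnorm(cfg$n_loci, 0, 1 / sqrt(cfg$n_loci))
  beta_mcw <- rnorm(cfg$n_loci, 0, 1 / sqrt(cfg$n_loci))
  g_nc <- std_gv(beta_nc)
  g_mcw <- std_gv(beta_mcw)

  sites <- paste0("S", seq_len(cfg$n_sites))
  plant_year <- setNames(min(cfg$years) - seq(12, 4, length.out = cfg$n_sites),
                         sites)
  site_eff_mcw <- setNames(rnorm(cfg$n_sites, 0, 8), sites)
  site_eff_nc <- setNames(rnorm(cfg$n_sites, 0, 0.3), sites)
  year_mast <- setNames(rnorm(length(cfg$years), 0, cfg$masting_sd),
                        cfg$years)
  year_mcw <- setNames(rnorm(length(cfg$years), 0, cfg$mcw_year_sd),
                       cfg$years)

  # phenotypic scales: MCW ramet-level SD 30 g split genetic vs permanent
  # ramet; 15 g record-to-record measurement noise on top
  sp_mcw <- 30
  sg_mcw <- sqrt(cfg$h2_mcw) * sp_mcw
  sr_mcw <- sqrt(1 - cfg$h2_mcw) * sp_mcw
  se_mcw <- 15
  # NC latent scale: total non-year latent SD 0.5 split genetic vs ramet
  sl_nc <- 0.5
  sg_nc <- sqrt(cfg$h2_nc) * sl_nc
  sr_nc <- sqrt(1 - cfg$h2_nc) * sl_nc

  recs <- list()
  for (s in sites) {
    clone_idx <- if (s == sites[1]) seq_len(nrow(cm)) else
      sort(sample.int(nrow(cm), round(0.62 * nrow(cm))))
    n_cl <- length(clone_idx)
    n_ram <- cfg$pheno_ramets
    base <- tidyr::expand_grid(ci = clone_idx, ramet = seq_len(n_ram),
                               year = cfg$years)
    dag0 <- rnorm(n_cl * n_ram, 4, 0.8)  # diameter intercept per ramet
    growth <- rnorm(n_cl * n_ram, 1.3, 0.15)
    ramet_key <- (match(base$ci, clone_idx) - 1L) * n_ram + base$ramet
    age <- base$year - plant_year[[s]]
    dag <- pmax(dag0[ramet_key] + growth[ramet_key] * age, 1)
    ramet_eff_nc <- rnorm(n_cl * n_ram, 0, sr_nc)
    ramet_eff_mcw <- rnorm(n_cl * n_ram, 0, sr_mcw)
    eta <- log(cfg$nc_mean) + site_eff_nc[[s]] + year_mast[as.character(base$year)] +
      0.8 * log(dag / 20) + sg_nc * g_nc[base$ci] + ramet_eff_nc[ramet_key]
    nc <- rnbinom(nrow(base), size = cfg$nc_dispersion, mu = exp(eta))
    mcw <- 268 + site_eff_mcw[[s]] + year_mcw[as.character(base$year)] +
      sg_mcw * g_mcw[base$ci] + ramet_eff_mcw[ramet_key] +
      rnorm(nrow(base), 0, se_mcw)
    mcw <- pmax(mcw, 0)
    mcw[nc == 0] <- NA_real_  # no unspoiled cones, no weight
    recs[[s]] <- tibble(site = s,
                        clone_id = cm$clone_id[base$ci],
                        ramet_id = sprintf("t%02d", base$ramet),
                        year = base$year, age = as.numeric(age),
                        nc = as.integer(nc), mcw = mcw, dag = dag)
  }
  pheno <- bind_rows(recs)
  keep <- runif(nrow(pheno)) >= cfg$drop_rate
  pheno <- pheno[keep, ]
  truth <- list(
    true_clonal_values = tibble(clone_id = cm$clone_id,
                                gv_nc = sg_nc * g_nc, gv_mcw = sg_mcw * g_mcw),
    true_snp_effects = tibble(locus_id = colnames(M),
                              beta_nc = beta_nc, beta_mcw = beta_mcw),
    true_h2 = c(nc = cfg$h2_nc, mcw = cfg$h2_mcw),
    sigma_g = c(nc = sg_nc, mcw = sg_mcw),
    sigma_ramet = c(nc = sr_nc, mcw = sr_mcw),
    sigma_record_mcw = se_mcw
  )
  list(phenotypes = pheno, truth = truth)
}

#' Simulate a complete clone/ramet cohort
#'
#' Runs the four generator stages (founder frequencies, clone genotypes,
#' ramet genotypes, phenotypes) from one configuration and returns all
#' pieces plus the merged truth record. Identical configurations (including
#' seed) give bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return list: `config`, `ramet_genotypes`, `sample_meta`,
#'   `clone_genotypes`, `clone_meta`, `phenotypes`, `truth`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  freqs <- simulate_founder_frequencies(cfg)
  clones <- simulate_clones(cfg, freqs)
  ramets <- simulate_ramets(clones, cfg)
  pheno <- simulate_phenotypes(clones, cfg)
  list(config = cfg,
       founder_freqs = freqs,
       clone_genotypes = clones$genotypes,
       clone_meta = clones$clone_meta,
       ramet_genotypes = ramets$genotypes,
       sample_meta = ramets$meta,
       phenotypes = pheno$phenotypes,
       truth = c(ramets$truth, pheno$truth))
}

#' Write a simulated cohort to disk
#'
#' Ramet genotypes as plain-text VCF and Axiom-style call-code TSV, sample
#' metadata and phenotypes as TSV, truth as JSON.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort$ramet_genotypes, file.path(dir, "ramets.vcf"))
  write_callcodes(cohort$ramet_genotypes, file.path(dir, "ramets_callcodes.tsv"))
  readr::write_tsv(cohort$sample_meta, file.path(dir, "sample_meta.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                   progress = FALSE)
  truth <- cohort$truth
  truth$true_clone <- as.list(truth$true_clone)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
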