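# Identity verification: mismatch counting, consensus building, exclusion,
# per-SNP error rates, Nei distances, lineage collapsing, cutoff prediction.

test_that("mismatch_count handles missing data and both counting modes", {
  a <- c(0, 1, 2, NA, 2)
  b <- c(0, 2, 2, 1, 0)
  mm <- mismatch_count(a, b)
  expect_equal(mm$mismatches, 2L)
  expect_equal(mm$compared, 4L)
  expect_equal(mm$error_rate, 0.5)
  # identical vectors: zero mismatches over the non-missing loci
  mm2 <- mismatch_count(a, a)
  expect_equal(mm2$mismatches, 0L)
  expect_equal(mm2$compared, 4L)
  # one vector all missing: empty comparison, undefined rate
  mm3 <- mismatch_count(rep(NA_integer_, 5), b)
  expect_equal(mm3$compared, 0L)
  expect_true(is.na(mm3$error_rate))
  # allele mode counts |dosage difference|: 0 vs 2 counts twice
  mm4 <- mismatch_count(c(0, 1), c(2, 1), mode = "allele")
  expect_equal(mm4$mismatches, 2L)
  expect_error(mismatch_count(1:3, 1:4), "length")
})

test_that("consensus is per-locus majority with conservative tie handling", {
  g <- toy_geno(c(1, 0, 0, 2,
                  1, 0, 2, 2,
                  1, 2, 0, NA,
                  2, 2, 2, NA), 4)
  cons <- build_consensus(g, rownames(g))
  # L1: (1,1,1,2) -> 1; L2: (0,0,2,2) -> tie -> NA; L3: (0,2,0,2) -> NA;
  # L4: (2,2,NA,NA) -> 2
  expect_identical(as.integer(cons), c(1L, NA, NA, 2L))
  expect_equal(attr(cons, "support"), c(3L, 2L, 2L, 2L))
  # single member: consensus equals that member
  single <- build_consensus(g, "s01")
  expect_identical(as.integer(single), as.integer(unclass(g)["s01", ]))
  # all-missing locus -> NA
  gm <- toy_geno(c(NA, 0, NA, 1), 2)
  expect_true(is.na(build_consensus(gm, rownames(gm))[1]))
  expect_error(build_consensus(g, "nope"), "unknown member")
})

test_that("verify_ramets excludes at the threshold edge and is idempotent", {
  # clone of 5 ramets at 40 loci; one ramet gets 2 discordant loci
  # (rate 0.05 > 0.025) and must go; another gets 1 (0.025, retained)
  base <- rep(c(0L, 1L, 2L, 1L), 10)
  m <- matrix(rep(base, 5), nrow = 5, byrow = TRUE,
              dimnames = list(sprintf("r%d", 1:5), sprintf("L%02d", 1:40)))
  m[2, 1:2] <- c(2L, 0L)   # rate 2/40 = 0.05 -> excluded
  m[3, 3] <- 2L            # rate 1/40 = 0.025 -> retained (not > threshold)
  g <- geno_matrix(m)
  meta <- tibble::tibble(sample_id = rownames(m), clone_id = "K")
  v <- verify_ramets(g, meta)
  rep2 <- v$reports[order(v$reports$sample_id), ]
  expect_identical(rep2$excluded, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(rep2$error_rate[2], 0.05)
  # ramet identical to consensus: rate 0
  expect_equal(rep2$error_rate[1], 0)
  # idempotence: a second pass on retained samples excludes nobody
  kept <- rep2$sample_id[!rep2$excluded]
  v2 <- verify_ramets(geno_matrix(m[kept, , drop = FALSE]),
                      meta[meta$sample_id %in% kept, ])
  expect_false(any(v2$reports$excluded))
})

test_that("truth-based confusion matrix: mislabels caught, genuine ramets kept", {
  detected <- numeric(20); false_rate <- numeric(20)
  for (s in 1:20) {
    cfg <- sim_config(seed = 400 + s)
    coh <- simulate_cohort(cfg)
    v <- verify_ramets(coh$ramet_genotypes, coh$sample_meta)
    tr <- coh$truth$mislabelled_samples$sample_id
    checked <- v$reports$sample_id  # only multi-ramet clones get reports
    ex <- v$reports$sample_id[v$reports$excluded]
    detected[s] <- if (length(intersect(tr, checked)))
      mean(intersect(tr, checked) %in% ex) else NA
    genuine <- setdiff(checked, tr)
    false_rate[s] <- mean(genuine %in% ex)
  }
  expect_gte(mean(detected, na.rm = TRUE), 0.95)
  expect_lte(mean(false_rate), 0.02)
})

test_that("per-SNP error rates recover the injected rate and hand counts", {
  # constructed 3-ramet clone with 1 discordant call at locus L2
  m <- matrix(rep(c(0L, 1L, 2L), 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("r1", "r2", "r3"), c("L1", "L2", "L3")))
  m[2, 2] <- 2L
  v <- verify_ramets(geno_matrix(m),
                     tibble::tibble(sample_id = rownames(m), clone_id = "K"),
                     error_threshold = 0.5)
  se <- snp_error_rates(geno_matrix(m), v)
  expect_equal(se$error_rate, c(0, 1 / 3, 0))
  # noise-free cohort: all zero
  cfg0 <- sim_config(n_loci = 200, regions = c(A = 5L),
                     region_selfing = c(A = 0), n_registered = 5L,
                     geno_error_rate = 0, missing_rate = 0, mislabel_rate = 0,
                     seed = 31)
  coh0 <- simulate_cohort(cfg0)
  v0 <- verify_ramets(coh0$ramet_genotypes, coh0$sample_meta)
  se0 <- snp_error_rates(coh0$ramet_genotypes, v0)
  expect_true(all(se0$error_rate == 0, na.rm = TRUE))
})

test_that("Nei distances match the from-first-principles formula", {
  set.seed(6)
  m <- matrix(sample(0:2, 12, replace = TRUE), nrow = 4,
              dimnames = list(sprintf("s%d", 1:4), sprintf("L%d", 1:3)))
  g <- geno_matrix(m)
  D <- nei_distance_matrix(g)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(D[i, j], nei_pair(m[i, ], m[j, ]), tolerance = 1e-12)
    expect_equal(D[i, j], D[j, i])
  }
  expect_true(all(diag(D) == 0))
  # identical individuals at distance 0
  m2 <- rbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L))
  colnames(m2) <- sprintf("L%d", 1:3)
  expect_equal(nei_distance_matrix(geno_matrix(m2))["a", "b"], 0)
  # missing replaced by average allele counts before the computation
  m3 <- rbind(a = c(0L, 1L, 2L), b = c(NA, 1L, 2L), c = c(2L, 1L, 2L))
  colnames(m3) <- sprintf("L%d", 1:3)
  D3 <- nei_distance_matrix(geno_matrix(m3))
  imput <- m3; imput[1, 1] <- 0; imput[2, 1] <- 1; imput[3, 1] <- 2
  expect_equal(D3["a", "b"], nei_pair(c(0, 1, 2), c(1, 1, 2)),
               tolerance = 1e-12)
})

test_that("complete-linkage lineage collapsing matches a naive oracle", {
  # two tight triplets
  set.seed(8)
  d <- matrix(0.3 + runif(36, 0, 0.1), 6, 6)
  d <- (d + t(d)) / 2
  within <- matrix(runif(9, 0, 0.01), 3, 3); within <- (within + t(within)) / 2
  d[1:3, 1:3] <- within
  within2 <- matrix(runif(9, 0, 0.01), 3, 3); within2 <- (within2 + t(within2)) / 2
  d[4:6, 4:6] <- within2
  diag(d) <- 0
  dimnames(d) <- list(sprintf("s%d", 1:6), sprintf("s%d", 1:6))
  res <- collapse_mlg(d, threshold = 0.05)
  expect_equal(res$n_lineages, 2L)
  oracle <- naive_complete_linkage(d, 0.05)
  expect_true(same_partition(res$assignment$lineage, oracle))
  # random matrices: agreement with the oracle and monotonicity in threshold
  for (rep in 1:5) {
    set.seed(100 + rep)
    dd <- matrix(runif(64), 8, 8); dd <- (dd + t(dd)) / 2; diag(dd) <- 0
    dimnames(dd) <- list(sprintf("x%d", 1:8), sprintf("x%d", 1:8))
    prev <- Inf
    for (th in c(0.1, 0.3, 0.5, 0.9)) {
      r <- collapse_mlg(dd, th)
      expect_true(same_partition(r$assignment$lineage,
                                 naive_complete_linkage(dd, th)))
      expect_lte(r$n_lineages, prev)
      prev <- r$n_lineages
    }
  }
  # threshold extremes
  expect_equal(collapse_mlg(d, 0)$n_lineages, 6L)
  expect_equal(collapse_mlg(d, max(d) + 1)$n_lineages, 1L)
  expect_error(collapse_mlg(d, -0.1), "non-negative")
})

test_that("cutoff prediction finds the largest gap", {
  expect_equal(predict_cutoff(c(0.01, 0.02, 0.03, 0.40, 0.41)), 0.215)
  expect_equal(predict_cutoff(c(0.1, 0.9)), 0.5)
  expect_equal(predict_cutoff(c(0.1, 0.9), f = 0.25), 0.3)
  expect_error(predict_cutoff(rep(0.2, 5)), "no gap")
})

test_that("predicted cutoff separates within-clone from between-clone distances", {
  ok <- logical(20)
  for (s in 1:20) {
    cfg <- sim_config(n_loci = 800, regions = c(A = 10L, B = 10L),
                      region_selfing = c(A = 0, B = 0), n_registered = 20L,
                      ramets_registered = 4, mislabel_rate = 0,
                      seed = 600 + s)
    coh <- simulate_cohort(cfg)
    D <- nei_distance_matrix(coh$ramet_genotypes)
    res <- collapse_mlg(D, threshold = "auto")
    tc <- coh$truth$true_clone[rownames(D)]
    same <- outer(tc, tc, "==")
    ut <- upper.tri(D)
    ok[s] <- max(D[ut & same]) < res$threshold &&
      res$threshold < min(D[ut & !same])
  }
  expect_gte(mean(ok), 0.9)
})

test_that("full identity stage maps every true clone to exactly one lineage", {
  cfg <- sim_config(seed = 77)
  coh <- simulate_cohort(cfg)
  D <- nei_distance_matrix(coh$ramet_genotypes)
  res <- collapse_mlg(D, threshold = "auto")
  truth_map <- coh$truth$true_clone[res$assignment$sample_id]
  tab <- table(truth_map, res$assignment$lineage)
  # each true clone occupies exactly one lineage, and lineages never mix clones
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  # and the verification stage flags the truth-mislabelled ramets
  v <- verify_ramets(coh$ramet_genotypes, coh$sample_meta)
  tr <- intersect(coh$truth$mislabelled_samples$sample_id,
                  v$reports$sample_id)
  expect_true(all(tr %in% v$reports$sample_id[v$reports$excluded]))
})
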