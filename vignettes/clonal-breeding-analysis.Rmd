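---
title: "Clonal identity verification and genomic prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal identity verification and genomic prediction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalpred)
```

`clonalpred` implements the analysis chain used in low-input breeding of
clonally propagated trees such as Mediterranean stone pine (*Pinus pinea*):
SNP-array genotypes of grafted ramets are checked against their clone of
record, genotyping error rates are estimated from the clonal replicates, a
genomic relationship matrix (GRM) summarises relatedness and inbreeding
among clones, repeated cone-production measurements are corrected into
clonal values, and a GBLUP model predicts clonal performance with
cross-validated predictive ability. This vignette documents the models,
the tunable parameters, and the design decisions behind each stage.

## Clonal identity and genotyping error

Each clone's reference genotype is the per-locus majority call across its
labelled ramets (`build_consensus()`). Ties and all-missing loci yield a
missing consensus call rather than an invented one; this is deliberately
conservative, since a wrong consensus call would charge an error to every
ramet of the clone. A ramet's error rate is the number of mismatching loci
divided by the number of loci non-missing in both the ramet and the
consensus. Mismatches are counted at the genotype level by default — any
dosage difference is one mismatch, so a hom–hom discordance (0 vs 2) counts
once. An allele-level mode (counting `|dosage difference|`) is available
because the convention is genuinely ambiguous in practice; published
per-clone mismatch tables do not settle it, and the default follows the
"number of mismatching markers" reading.

`verify_ramets()` is a two-pass procedure: consensus from all members,
exclusion of members whose error rate exceeds the threshold (default 2.5%,
a configuration value rather than a constant), then a rebuild of the
consensus from retained members and a final recomputation of everyone's
rate against the cleaned reference. The second pass matters: a mislabelled
ramet distorts the first-pass consensus at tie loci, and rates reported
against the cleaned consensus are the ones a registry would publish. The
procedure is a fixed point in practice — re-running it on the retained set
excludes nobody — which the test suite checks on simulated cohorts.

Per-SNP error rates (`snp_error_rates()`) divide mismatches by non-missing
paired calls per locus, pooled over retained ramets of multi-ramet clones.
Only clones with replicates carry information about error rates; reports
for single-ramet clones are trivially zero and must be excluded from any
rate summary (the pipeline does this).

## Multilocus lineages

Distinct multilocus genotypes that differ only by genotyping error are
collapsed into lineages by complete-linkage (farthest-neighbour)
clustering on Nei's (1972) standard genetic distance between individuals,
after replacing missing calls with the locus mean dosage. Each individual
is treated as a two-allele frequency vector per locus (dosage/2 and its
complement). Complete linkage guarantees the interpretable contract that
two samples share a lineage only if *every* pairwise distance within the
cluster is at or below the threshold.

The threshold can be predicted from the data (`predict_cutoff()`): with
clonal replicates the merge-height distribution is strongly bimodal
(within-clone error-scale distances versus between-clone distances), and
the predictor returns the midpoint (fraction `f = 0.5`) of the largest gap
between consecutive distinct merge heights. The predicted value is
data-dependent; a reference stone-pine cohort yielded 0.0399, while the
package's synthetic cohorts typically yield values near 0.1 because the
synthetic between-clone distances are set by the Balding–Nichols
differentiation rather than by a shared pedigree.

## Genomic relationships and inbreeding

`compute_grm()` uses VanRaden's method 1: missing calls are mean-imputed,
dosages centered on twice the ALT allele frequency, and
`G = ZZ' / (2 * sum p(1-p))` over the retained (polymorphic) loci. With
in-sample frequencies every row sums to zero and the diagonal averages
`1 + f`. A plain mean identity-by-state similarity matrix is available
behind the `ibs` flag because "probability of identity by state" can also
be read literally; VanRaden method 1 is the default as the canonical
`A.mat`-style estimator used in genomic prediction, and the two diverge
mainly in scale, not ranking. Group summaries report `f` from the
diagonal, mean within-group and between-group relationships
(`inbreeding_from_grm()`), and `F_IS = 1 - Ho/Hs` with a seeded percentile
bootstrap over loci (`fis()`; 1,000 replicates by default — the bootstrap
method is our choice, as published CIs rarely state theirs). GRM-derived
`f` and `F_IS` measure different things (identity by descent relative to
the sample versus departure from Hardy–Weinberg within groups) and agree
in sign but not magnitude, which the test suite asserts in exactly that
weak form.

## Phenotype correction

Cone production in stone pine is dominated by masting: calendar year is
the largest variance component. Two traits are handled differently,
following the structure of the repeated measurements:

- **MCW** (mean cone weight, g) is a repeated measure of the same
  underlying quantity, so `ramet_blup_mcw()` fits
  `mcw ~ (1 | year) + (1 | ramet)` by REML (lme4) and takes the fitted
  mean plus the ramet BLUP as the single corrected value per ramet.
- **NC** (number of unspoiled cones) accumulates: `accumulate_nc()` first
  removes calendar-year and tree-size effects record by record with
  `nc ~ factor(year) + log(dag)` — the log-diameter term is the allometric
  default, linear is a flag — keeping the fitted grand mean plus residual
  (so records stay on the count scale), then sums per ramet. Negative
  corrected totals are floored at zero with a logged count, since a
  negative cone total is not interpretable. Diameter at the year of
  measurement is used, not final diameter.

Clonal BLUPs (`clonal_blups()`) come from `value ~ (1 | clone)` on the
ramet values, with the number of measured years as a fixed covariate for
NC only (ramets measured longer accumulate more cones; MCW needs no such
correction). Broad-sense heritability is
`H2 = sigma2_clone / (sigma2_clone + sigma2_residual)` at the ramet level,
i.e. after the year variance has been removed upstream. A clonal-mean
variant (dividing the residual by the harmonic-mean ramet count) was
considered and not adopted as a default because the ramet-level form is
the one whose recovery the synthetic tests validate.

## GBLUP and predictive ability

The prediction model is `y = Xb + a + e` at clone level, with
`a ~ N(0, G sigma2_g)` and iid residuals. `reml_fit()` eigendecomposes G
once and maximises the restricted likelihood over the variance ratio
`gamma = sigma2_g / sigma2_e` by bounded one-dimensional optimisation
(bounds 1e-9 to 1e9, tolerance 1e-8 on log gamma); variance estimates at
a bound indicate a degenerate fit and are reported as such, not hidden.
The spectral parameterisation is exact for a single random effect and
costs one `eigen()` per fit, which is what makes permutation testing
affordable. Fixed effects default to the intercept only. GEBVs for
unphenotyped clones use the genomic cross-covariance
`a_new = sigma2_g G[new, train] V^{-1} (y - Xb)`, the joint-BLUP solution;
tests verify exact agreement with a dense joint solve.

`cross_validate()` partitions clones into k seeded folds (default k = 9),
refits per fold, and reports the predictive ability `r_y` as the mean
(with SD) over folds of the Pearson correlation between observed clonal
BLUPs and GEBVs of the held-out clones, plus a pooled correlation over all
held-out predictions. The SD is over folds; whether published ± values are
fold SDs or repeat SDs is usually unstated, so the label is explicit here.
Fold assignment is simple random; regional stratification is deliberately
not the default (it changes the estimand). Folds with fewer than 2 clones
are an error, 2-clone folds warn — a correlation over two points is a coin
flip, but small exhaustive-permutation fixtures need them.

The permutation test (`permutation_null()`) permutes clonal values across
clones with folds held fixed, recomputing `r_y` each time, and reports the
one-sided add-one p-value `(1 + #{null >= observed}) / (B + 1)`. Per-fold
eigendecompositions are cached, so B = 1,000 costs seconds at n ≈ 100.
With 8 or fewer clones the full permutation set can be enumerated, which
the test suite uses as an oracle. If the GRM carries no information about
a held-out fold (constant GEBVs), that fold's correlation is undefined and
reported as NA rather than coerced to zero.

`selection_gain()` reports the percentage gain of the mean value of the
top decile (or an explicit subset, e.g. the registered clones) over the
cohort mean, rounded to the nearest integer as such gains are reported in
practice; an error is raised on a non-positive baseline where relative
gain is meaningless.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the estimators assume, with a
truth record for every injected artefact. Defaults describe a reference
cohort: 99 clones in 4 provenance regions (31/19/21/28), 2,245 biallelic
SNPs, 15 registered clones sampled with 4–11 ramets each and 1 ramet for
the rest, 0.5% per-call genotyping error, 1% missingness, 10% of
registered-clone ramets mislabelled, three trial sites (site 1 hosting all
clones, the others ~62%), ten measurement years, and heritabilities of
0.45 (NC, latent scale) and 0.35 (MCW) — inside the 0.2–0.5 range typical
of clonal cone-production trials.

Design choices worth stating:

- **Balding–Nichols** region frequencies (`Beta(p0(1-F)/F, (1-p0)(1-F)/F)`
  around ancestral `p0 ~ U(0.05, 0.95)`): the standard one-parameter
  differentiation model; empirical Weir–Cockerham F_ST on simulated
  diploids recovers the nominal F (tested at F = 0.2 ± 0.05). `fst` may be
  per-region, which is how a strongly drifted, internally related region
  is emulated.
- **Genotype errors are flips to a different valid dosage** (uniform over
  the other two), missingness is applied after error injection, and
  **mislabels are label swaps among registered clones' ramets** — the
  actual failure mode of grafting mix-ups in a clonal bank. Swapping onto
  single-ramet unregistered clones would create two-member "clones" whose
  consensus is undefined at every discordant locus, which is not the
  phenomenon of interest.
- **NC is negative-binomial** with log link (counts are overdispersed and
  zero-rich in masting species; the distributional family is our default,
  not an established convention), with site, masting-year, allometric
  log-diameter, genetic and permanent-ramet terms. `h2_nc` applies on the
  latent scale; NB sampling adds non-genetic noise, so realized ramet-level
  H2 for NC sits below nominal. Parameter-recovery tests therefore target
  MCW, whose Gaussian generator (genetic + permanent ramet + 15 g record
  noise, year and site effects on top) is built so that ramet-level H2
  equals `h2_mcw` by construction; recovery is tested to ±0.1 across an
  H2 grid of 0.1–0.6.
- **MCW is missing whenever a ramet-year produced no cones**, tying the
  two traits' missingness realistically.
- All randomness flows from one root seed; each stage derives a fixed
  offset sub-seed so stages can be re-run independently with identical
  results.

What the generator does **not** emulate: linkage and recombination (loci
are independent), pedigree relationships within regions, somatic mutation,
selection, spatial/block field structure, pest-damage dynamics beyond
random record dropping, and genotype-calling artefacts upstream of the
dosage matrix. Passing recovery tests on these cohorts therefore shows the
estimators are correct under the stated model, not that real cohorts meet
the model.

## Numerical conventions and problem sizes

Missing dosages are mean-imputed only where a method requires a complete
matrix (distances, GRM, PCA); QC statistics and mismatch counts always use
observed calls only, and MISSING is never conflated with dosage 0.
Consensus ties are missing; undefined rates (zero compared loci, zero
denominators) are NA with a flag, never silent zeros. GRM computation
drops monomorphic loci (maf ≤ `min_maf`, default 0) with a logged count and
errors if nothing remains. REML fits clip tiny negative eigenvalues to
zero and reject matrices that are materially non-PSD.

The test suite exercises the full reference scale (99 clones × 2,245 SNPs)
for the identity stage across 20 seeds, heritability recovery on 5 grid
points × 4 seeds, REML recovery on 20 cohorts of 200 clones, and null
calibration with 50 permutation runs of B = 199 at 60 clones; the complete
suite runs in a few minutes on one core. The acceptance script
(`scripts/acceptance.R`) re-runs the whole pipeline on one freshly
simulated reference-scale cohort plus the bundled registered-clone
reference tables.

## Known limitations

- Single-site, single-trait GBLUP only: no multi-trait models, no
  genotype-by-environment joint modelling, no marker-effect (Bayesian
  alphabet) models, no cross-generation prediction.
- No dominance or epistatic relationship matrices; clones are ideal for
  estimating non-additive components, but that is out of scope here.
- The clone-level two-stage approach (clonal BLUPs, then GBLUP) ignores
  uncertainty in the first-stage BLUPs.
- `F_IS` confidence intervals bootstrap loci, not individuals, so they
  reflect marker sampling rather than cohort sampling.
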