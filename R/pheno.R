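# Phenotype correction: repeated ramet-year measurements -> corrected
# ramet values -> clonal BLUPs -> broad-sense heritability.
#
# Expected long-format table columns: site, clone_id, ramet_id, year, age,
# nc (cone count), mcw (mean cone weight, g; NA when no unspoiled cones),
# dag (diameter, cm). Mixed models are Gaussian REML fits via lme4.

assert_pheno <- function(tbl) {
  need <- c("site", "clone_id", "ramet_id", "year")
  if (!all(need %in% names(tbl)))
    abort(sprintf("phenotype table needs columns: %s.",
                  paste(need, collapse = ", ")))
  invisible(tbl)
}

#' Ramet BLUPs for mean cone weight, corrected for calendar year
#'
#' Fits `mcw ~ (1 | year) + (1 | ramet)` by REML at one site and returns
#' one corrected value per ramet: the fitted overall mean plus the ramet's
#' BLUP. The random calendar-year term absorbs masting variation; with zero
#' year variance the values reduce to shrunken ramet means.
#'
#' @param tbl phenotype table.
#' @param site site label to analyse.
#' @return tibble: site, clone_id, ramet_id, value, n_years. Attributes
#'   `varcomp` (named variance components) and `mean` (fitted intercept).
#' @export
ramet_blup_mcw <- function(tbl, site) {
  assert_pheno(tbl)
  d <- tbl %>% filter(.data$site == !!site, !is.na(.data$mcw))
  if (nrow(d) == 0) abort(sprintf("no MCW records at site %s.", site))
  if (n_distinct(d$year) < 2)
    abort("need at least 2 years with data for year correction.")
  d$ramet_uid <- paste(d$clone_id, d$ramet_id, sep = "/")
  d$year_f <- factor(d$year)
  fit <- suppress_singular(
    lme4::lmer(mcw ~ 1 + (1 | year_f) + (1 | ramet_uid), data = d,
               REML = TRUE))
  mu <- unname(lme4::fixef(fit)[1])
  re <- lme4::ranef(fit)$ramet_uid
  blup <- setNames(re[, 1], rownames(re))
  yrs <- d %>% group_by(.data$clone_id, .data$ramet_id) %>%
    summarise(n_years = n_distinct(.data$year), .groups = "drop")
  out <- yrs %>%
    mutate(site = !!site,
           value = mu + unname(blup[paste(.data$clone_id, .data$ramet_id,
                                          sep = "/")])) %>%
    select("site", "clone_id", "ramet_id", "value", "n_years")
  vc <- as.data.frame(lme4::VarCorr(fit))
  nm <- vc$grp; nm[nm == "Residual"] <- "residual"
  varcomp <- setNames(vc$vcov, nm)
  attr(out, "varcomp") <- varcomp
  attr(out, "mean") <- mu
  out
}

suppress_singular <- function(expr) {
  withCallingHandlers(expr, message = function(m) {
    if (grepl("boundary \\(singular\\)", conditionMessage(m)))
      invokeRestart("muffleMessage")
  })
}

#' Accumulated cone number per ramet, corrected for year and allometry
#'
#' Per-record correction before summation: fits
#' `nc ~ factor(year) + log(dag)` across all ramets at the site, keeps the
#' fitted grand mean + residual per record (removing year and tree-size
#' effects while preserving the count scale), then sums the corrected
#' records per ramet and counts the years measured.
#' Negative corrected totals are floored at 0 with a logged count. Records
#' with missing nc or dag are dropped with a logged count.
#'
#' @param tbl phenotype table.
#' @param site site label to analyse.
#' @param dag_transform `"log"` (default, allometric) or `"linear"`.
#' @return tibble: site, clone_id, ramet_id, value (corrected total NC),
#'   n_years.
#' @export
accumulate_nc <- function(tbl, site, dag_transform = c("log", "linear")) {
  assert_pheno(tbl)
  dag_transform <- match.arg(dag_transform)
  d <- tbl %>% filter(.data$site == !!site)
  drop <- is.na(d$nc) | is.na(d$dag) | d$dag <= 0
  if (any(drop))
    inform(sprintf("dropped %d record(s) with missing nc or dag.", sum(drop)))
  d <- d[!drop, ]
  if (nrow(d) == 0) abort(sprintf("no usable NC records at site %s.", site))
  d$fdag <- if (dag_transform == "log") log(d$dag) else d$dag
  d$year_f <- factor(d$year)
  m <- if (nlevels(d$year_f) > 1) lm(nc ~ year_f + fdag, data = d)
       else lm(nc ~ fdag, data = d)
  corrected <- mean(d$nc) + resid(m)
  out <- d %>%
    mutate(corrected = corrected) %>%
    group_by(.data$clone_id, .data$ramet_id) %>%
    summarise(value = sum(.data$corrected),
              n_years = n_distinct(.data$year), .groups = "drop") %>%
    mutate(site = !!site) %>%
    select("site", "clone_id", "ramet_id", "value", "n_years")
  neg <- out$value < 0
  if (any(neg)) {
    inform(sprintf("floored %d negative corrected total(s) at 0.", sum(neg)))
    out$value[neg] <- 0
  }
  out
}

#' Clonal BLUPs from ramet-level corrected values
#'
#' Fits `value ~ 1 [+ n_years] + (1 | clone)` by REML. The number of years
#' measured enters as a fixed covariate only when requested (appropriate
#' for accumulated cone counts, where ramets measured longer accumulate
#' more). Returns shrunken clone BLUPs, predicted clone values (fitted mean
#' + BLUP) and the variance components needed for broad-sense heritability.
#'
#' @param ramet_values tibble from [ramet_blup_mcw()] or [accumulate_nc()]
#'   (columns clone_id, value and, if `use_nyears`, n_years).
#' @param use_nyears include n_years as a fixed covariate.
#' @return object of class `clonal_blups`: `blups` tibble (clone_id,
#'   n_ramets, blup, value, low_support), `varcomp` (sigma2_clone,
#'   sigma2_residual), `mean`, `H2`.
#' @export
clonal_blups <- function(ramet_values, use_nyears = FALSE) {
  if (!all(c("clone_id", "value") %in% names(ramet_values)))
    abort("`ramet_values` needs columns clone_id and value.")
  d <- ramet_values
  form <- if (use_nyears) value ~ n_years + (1 | clone_id)
          else value ~ 1 + (1 | clone_id)
  fit <- suppress_singular(lme4::lmer(form, data = d, REML = TRUE))
  re <- lme4::ranef(fit)$clone_id
  blup <- setNames(re[, 1], rownames(re))
  fe <- lme4::fixef(fit)
  mu <- unname(fe[1]) +
    if (use_nyears) unname(fe["n_years"]) * mean(d$n_years) else 0
  counts <- d %>% count(.data$clone_id, name = "n_ramets")
  blups <- counts %>%
    mutate(blup = unname(blup[.data$clone_id]),
           value = mu + .data$blup,
           low_support = .data$n_ramets < 2)
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- c(sigma2_clone = vc$vcov[vc$grp == "clone_id"],
               sigma2_residual = vc$vcov[vc$grp == "Residual"])
  structure(list(blups = blups, varcomp = varcomp, mean = mu,
                 H2 = broad_sense_h2(varcomp), use_nyears = use_nyears),
            class = "clonal_blups")
}

#' @export
print.clonal_blups <- function(x, ...) {
  cat(sprintf(
    "<clonal_blups> %d clones; sigma2_clone %.3g, sigma2_residual %.3g, H2 %.3f\n",
    nrow(x$blups), x$varcomp[["sigma2_clone"]],
    x$varcomp[["sigma2_residual"]], x$H2))
  invisible(x)
}

#' @export
tidy.clonal_blups <- function(x, ...) x$blups

#' @export
glance.clonal_blups <- function(x, ...) {
  tibble(sigma2_clone = x$varcomp[["sigma2_clone"]],
         sigma2_residual = x$varcomp[["sigma2_residual"]],
         H2 = x$H2, mean = x$mean, n_clones = nrow(x$blups))
}

#' Broad-sense heritability from clonal variance components
#'
#' H2 = sigma2_clone / (sigma2_clone + sigma2_residual) on ramet-level
#' corrected values (calendar-year variance having been removed upstream).
#' Returns NA with a warning when both components are zero.
#'
#' @param x a `clonal_blups` object or a named numeric vector with
#'   `sigma2_clone` and `sigma2_residual`.
#' @return scalar H2 in [0, 1], or NA if undefined.
#' @export
broad_sense_h2 <- function(x) {
  vc <- if (inherits(x, "clonal_blups")) x$varcomp else x
  sc <- vc[["sigma2_clone"]]; se <- vc[["sigma2_residual"]]
  if (sc < 0 || se < 0) abort("variance components must be non-negative.")
  if (sc + se == 0) {
    warn("both variance components are zero; H2 undefined.")
    return(NA_real_)
  }
  sc / (sc + se)
}
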