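# GBLUP genomic prediction: single-kernel spectral REML, genomic estimated
# breeding values, k-fold cross-validated predictive ability, permutation
# significance, and selection-gain reporting.
#
# Model: y = X b + a + e with a ~ N(0, G sigma2_g), e ~ N(0, I sigma2_e),
# one observation per clone (clonal BLUPs from the pheno stage). The
# restricted likelihood is profiled over the variance ratio
# gamma = sigma2_g / sigma2_e after a single eigendecomposition of G, so a
# fit costs one eigen plus a bounded 1-D optimisation.

coerce_y <- function(y) {
  if (is.data.frame(y)) {
    if (!all(c("clone_id", "value") %in% names(y)))
      abort("data-frame response needs columns clone_id and value.")
    setNames(y$value, y$clone_id)
  } else {
    if (is.null(names(y))) abort("response vector must be named by clone id.")
    y
  }
}

# Profiled restricted log-likelihood pieces on the rotated scale.
# ytil = U'y, Xtil = U'X, d = eigenvalues of G. Returns the REML criterion
# and GLS quantities for a given gamma.
reml_eval <- function(gamma, ytil, Xtil, d) {
  n <- length(ytil); p <- ncol(Xtil)
  w <- 1 / (gamma * d + 1)
  XtWX <- crossprod(Xtil, w * Xtil)
  b <- solve(XtWX, crossprod(Xtil, w * ytil))
  r <- ytil - Xtil %*% b
  rss <- sum(w * r^2)
  s2e <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(s2e) + sum(log(gamma * d + 1)) +
                  determinant(XtWX, logarithm = TRUE)$modulus[1] + (n - p))
  list(ll = ll, b = drop(b), s2e = s2e, wr = w * drop(r))
}

reml_core <- function(ytil, Xtil, d, bounds = c(1e-9, 1e9), tol = 1e-8) {
  obj <- function(lg) -reml_eval(exp(lg), ytil, Xtil, d)$ll
  opt <- optimize(obj, interval = log(bounds), tol = tol)
  gamma <- exp(opt$minimum)
  # compare against the boundaries: a monotone likelihood should sit there
  for (b in bounds) if (-obj(log(b)) > -opt$objective) gamma <- b
  ev <- reml_eval(gamma, ytil, Xtil, d)
  list(gamma = gamma, b = ev$b, s2e = ev$s2e, wr = ev$wr, loglik = ev$ll)
}

#' Fit a GBLUP model by restricted maximum likelihood
#'
#' Single random genetic effect with covariance `G * sigma2_g` plus iid
#' residual. G is eigendecomposed once and the restricted log-likelihood is
#' maximised over the variance ratio gamma = sigma2_g/sigma2_e by bounded
#' one-dimensional optimisation (default bounds 1e-9..1e9, tolerance 1e-8
#' on log gamma). Fixed effects default to an intercept.
#'
#' @param y named numeric vector (names = clone ids) or tibble with
#'   clone_id and value columns; one record per clone.
#' @param G genomic relationship matrix (a [compute_grm()] result or a
#'   symmetric PSD matrix with matching clone ids).
#' @param X optional fixed-effect design matrix (default intercept only).
#' @param bounds,tol optimisation bounds and tolerance on the ratio.
#' @return object of class `gblup_fit`: sigma2_g, sigma2_e, gamma, h2, b,
#'   a (named BLUPs), loglik, clone_ids, and internals used for prediction.
#' @export
reml_fit <- function(y, G, X = NULL, bounds = c(1e-9, 1e9), tol = 1e-8) {
  y <- coerce_y(y)
  Gm <- if (inherits(G, "grm")) G$values else G
  ids <- names(y)
  if (!all(ids %in% rownames(Gm)))
    abort("all phenotyped clones must be present in G.")
  Gm <- Gm[ids, ids]
  n <- length(y)
  if (var(y) == 0) abort("degenerate response: zero phenotypic variance.")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  if (qr(X)$rank < ncol(X)) abort("X must have full column rank.")
  if (n < ncol(X) + 2) abort("too few observations for REML.")
  eg <- eigen(Gm, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    abort("G is not positive semidefinite within tolerance.")
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ytil <- drop(crossprod(U, y))
  Xtil <- crossprod(U, X)
  core <- reml_core(ytil, Xtil, d, bounds, tol)
  # a_hat = sigma2_g G V^{-1}(y - Xb) = gamma G U (w * rtil)
  u_wr <- drop(U %*% core$wr)
  a <- drop(core$gamma * Gm %*% u_wr)
  names(a) <- ids
  structure(list(
    clone_ids = ids, y = y, X = X,
    sigma2_g = core$gamma * core$s2e, sigma2_e = core$s2e,
    gamma = core$gamma,
    h2 = core$gamma / (core$gamma + 1),
    b = core$b, a = a, u_wr = u_wr, loglik = core$loglik, n = n
  ), class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf(
    "<gblup_fit> n = %d; sigma2_g %.4g, sigma2_e %.4g, h2 %.3f, REML loglik %.3f\n",
    x$n, x$sigma2_g, x$sigma2_e, x$h2, x$loglik))
  invisible(x)
}

#' @export
tidy.gblup_fit <- function(x, ...) {
  tibble(clone_id = x$clone_ids, gebv = unname(x$a))
}

#' @export
glance.gblup_fit <- function(x, ...) {
  tibble(sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e, h2 = x$h2,
         loglik = x$loglik, n = x$n)
}

#' Genomic estimated breeding values for target clones
#'
#' For clones in the training set this returns the fitted BLUPs exactly;
#' for new clones it uses the genomic cross-covariance,
#' a_new = sigma2_g * G[new, train] V^{-1} (y - Xb), the joint-BLUP
#' solution for unphenotyped individuals.
#'
#' @param fit a [reml_fit()] object.
#' @param G the full GRM containing both training and target clones.
#' @param clones target clone ids (default: all clones in G).
#' @return named numeric vector of GEBVs.
#' @export
gebv_predict <- function(fit, G, clones = NULL) {
  Gm <- if (inherits(G, "grm")) G$values else G
  if (is.null(clones)) clones <- rownames(Gm)
  missing_ids <- setdiff(clones, rownames(Gm))
  if (length(missing_ids))
    abort(sprintf("target clone(s) absent from G: %s",
                  paste(head(missing_ids, 3), collapse = ", ")))
  Gct <- Gm[clones, fit$clone_ids, drop = FALSE]
  setNames(drop(fit$gamma * Gct %*% fit$u_wr), clones)
}

make_folds <- function(ids, k, seed, n_repeats = 1) {
  n <- length(ids)
  if (k < 2 || k > n) abort("k must be between 2 and the number of clones.")
  set.seed(seed)
  lapply(seq_len(n_repeats), function(r) {
    f <- sample(rep(seq_len(k), length.out = n))
    sizes <- tabulate(f, k)
    if (any(sizes < 2)) abort("fold too small: every fold needs >= 2 clones.")
    if (any(sizes < 3))
      warn("fold with < 3 clones: per-fold correlations are unstable.")
    split(ids, f)
  })
}

# Precompute per-fold spectral pieces so many responses (observed +
# permuted) can be scored against identical folds cheaply.
fold_contexts <- function(ids, Gm, folds) {
  lapply(folds, function(test_ids) {
    train <- setdiff(ids, test_ids)
    Gtt <- Gm[train, train]
    eg <- eigen(Gtt, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    U <- eg$vectors
    list(train = train, test = test_ids, d = d, U = U,
         Xtil = crossprod(U, matrix(1, length(train), 1)),
         R = Gm[test_ids, train, drop = FALSE] %*% U)
  })
}

cv_engine <- function(yvec, ctxs, tol = 1e-8) {
  vapply(ctxs, function(cx) {
    ytr <- yvec[cx$train]
    core <- reml_core(drop(crossprod(cx$U, ytr)), cx$Xtil, cx$d, tol = tol)
    pred <- drop(core$gamma * cx$R %*% core$wr)
    # a fold whose GEBVs are constant (e.g. G carries no information about
    # the held-out clones) has no defined correlation
    if (sd(pred) < 1e-12 || sd(yvec[cx$test]) < 1e-12) return(NA_real_)
    cor(yvec[cx$test], pred)
  }, numeric(1))
}

#' Cross-validated predictive ability of GBLUP
#'
#' Clones are partitioned into k seeded folds; for each fold the model is
#' refit by REML on the training clones and GEBVs are predicted for the
#' held-out clones. Predictive ability per fold is the Pearson correlation
#' between observed clonal values and GEBVs over the held-out clones; `r_y`
#' is the mean over folds (and repeats) with the SD over folds, and a
#' pooled correlation across all held-out predictions is also reported.
#'
#' @param y named clonal values (or tibble clone_id/value).
#' @param G GRM covering all clones in `y`.
#' @param k number of folds (default 9).
#' @param n_repeats independent repetitions of the fold split.
#' @param seed fold-assignment seed.
#' @return object of class `cv_result`: `folds` tibble (repeat, fold,
#'   n_test, r), `r_y`, `sd`, `pooled_r`, `k`, `seed`.
#' @export
cross_validate <- function(y, G, k = 9, n_repeats = 1, seed = 1) {
  y <- coerce_y(y)
  Gm <- if (inherits(G, "grm")) G$values else G
  ids <- names(y)
  if (!all(ids %in% rownames(Gm))) abort("all clones must be present in G.")
  Gm <- Gm[ids, ids]
  reps <- make_folds(ids, k, seed, n_repeats)
  rows <- list(); preds <- list()
  for (r in seq_along(reps)) {
    ctxs <- fold_contexts(ids, Gm, reps[[r]])
    rs <- cv_engine(y, ctxs)
    rows[[r]] <- tibble(rep = r, fold = seq_along(rs),
                        n_test = vapply(reps[[r]], length, integer(1)),
                        r = rs)
    preds[[r]] <- tibble(
      clone_id = unlist(lapply(ctxs, `[[`, "test")),
      observed = y[unlist(lapply(ctxs, `[[`, "test"))],
      gebv = unlist(lapply(ctxs, function(cx) {
        core <- reml_core(drop(crossprod(cx$U, y[cx$train])), cx$Xtil, cx$d)
        drop(core$gamma * cx$R %*% core$wr)
      })))
  }
  folds <- bind_rows(rows)
  pr <- bind_rows(preds)
  pooled <- if (sd(pr$gebv) < 1e-12) NA_real_ else cor(pr$observed, pr$gebv)
  structure(list(folds = folds,
                 r_y = mean(folds$r, na.rm = TRUE),
                 sd = sd(folds$r, na.rm = TRUE),
                 pooled_r = pooled,
                 predictions = pr, k = k, seed = seed,
                 n_clones = length(ids)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d clones, %d-fold: r_y = %.3f +- %.3f (pooled %.3f)\n",
              x$n_clones, x$k, x$r_y, x$sd, x$pooled_r))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @export
glance.cv_result <- function(x, ...) {
  tibble(r_y = x$r_y, sd = x$sd, pooled_r = x$pooled_r, k = x$k,
         n_clones = x$n_clones)
}

# all permutations of 1..n (n <= 8), deterministic order
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Permutation null distribution for predictive ability
#'
#' Permutes the clonal values across clones B times, recomputes the
#' cross-validated r_y with identical folds each time, and reports the
#' one-sided add-one p-value P = (1 + #\{null >= observed\}) / (B + 1).
#' With `exhaustive = TRUE` (n <= 8 clones) all n! permutations are
#' enumerated instead, making the p-value seed-independent.
#'
#' @param y named clonal values (or tibble clone_id/value).
#' @param G GRM covering all clones.
#' @param B number of permutations (default 1000; a warning is issued
#'   below 20).
#' @param k folds, as in [cross_validate()].
#' @param seed seed for folds and permutations.
#' @param exhaustive enumerate all permutations (requires <= 8 clones).
#' @return object of class `perm_null`: `observed` r_y, `null` vector,
#'   `p_value`, `B`, `k`.
#' @export
permutation_null <- function(y, G, B = 1000, k = 9, seed = 1,
                             exhaustive = FALSE) {
  y <- coerce_y(y)
  Gm <- if (inherits(G, "grm")) G$values else G
  ids <- names(y)
  Gm <- Gm[ids, ids]
  if (!exhaustive && B < 20) warn("B < 20: unstable p-value.")
  folds <- make_folds(ids, k, seed)[[1]]
  ctxs <- fold_contexts(ids, Gm, folds)
  observed <- mean(cv_engine(y, ctxs), na.rm = TRUE)
  if (exhaustive) {
    n <- length(y)
    if (n > 8) abort("exhaustive enumeration limited to 8 clones.")
    P <- all_perms(n)
    null <- vapply(seq_len(nrow(P)), function(i) {
      yp <- setNames(unname(y)[P[i, ]], ids)
      mean(cv_engine(yp, ctxs), na.rm = TRUE)
    }, numeric(1))
  } else {
    set.seed(seed + 1L)
    null <- vapply(seq_len(B), function(i) {
      yp <- setNames(sample(unname(y)), ids)
      mean(cv_engine(yp, ctxs), na.rm = TRUE)
    }, numeric(1))
  }
  p <- (1 + sum(null >= observed)) / (length(null) + 1)
  structure(list(observed = observed, null = null, p_value = p,
                 B = length(null), k = k),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null> observed r_y = %.3f; p = %.4g (B = %d)\n",
              x$observed, x$p_value, x$B))
  invisible(x)
}

#' Percentage gain of a selected mean over a baseline mean
#'
#' gain% = 100 * (mean_selected - mean_all) / mean_all. Errors on a
#' non-positive baseline, where a relative gain is undefined.
#'
#' @param mean_selected,mean_all scalar means.
#' @return the percentage gain (not rounded).
#' @export
gain_percent <- function(mean_selected, mean_all) {
  if (mean_all <= 0) abort("gain undefined on non-positive baseline.")
  100 * (mean_selected - mean_all) / mean_all
}

#' Selection gain of top-ranking (or listed) clones
#'
#' Computes the percentage gain of the mean clonal value of a selected
#' subset over the mean of all clones. The subset is either the top
#' `ceiling(top_fraction * n)` clones by value, or an explicit id list
#' (e.g. the registered clones).
#'
#' @param blups tibble with clone_id and value columns, or a
#'   [clonal_blups()] object.
#' @param top_fraction fraction selected (default 0.10); needs >= 10 clones
#'   for a decile.
#' @param subset_ids explicit clone ids overriding the top-fraction rule.
#' @return tibble: subset, n_selected, mean_selected, mean_all, gain_pct,
#'   gain_pct_rounded (nearest integer, as conventionally reported).
#' @export
selection_gain <- function(blups, top_fraction = 0.10, subset_ids = NULL) {
  tb <- if (inherits(blups, "clonal_blups")) blups$blups else blups
  if (!all(c("clone_id", "value") %in% names(tb)))
    abort("`blups` needs columns clone_id and value.")
  mean_all <- mean(tb$value)
  if (is.null(subset_ids)) {
    if (nrow(tb) < 10) abort("need >= 10 clones for a top-decile selection.")
    n_sel <- ceiling(top_fraction * nrow(tb))
    sel <- tb %>% slice_max(.data$value, n = n_sel, with_ties = FALSE)
    label <- sprintf("top %d%%", round(100 * top_fraction))
  } else {
    sel <- tb %>% filter(.data$clone_id %in% subset_ids)
    if (nrow(sel) == 0) abort("no listed clone found.")
    label <- "custom subset"
  }
  g <- gain_percent(mean(sel$value), mean_all)
  tibble(subset = label, n_selected = nrow(sel),
         mean_selected = mean(sel$value), mean_all = mean_all,
         gain_pct = g, gain_pct_rounded = round(g))
}
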