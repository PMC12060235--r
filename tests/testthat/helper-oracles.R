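# Independent oracles used across the suite. Each is a deliberately naive
# implementation of the underlying definition, kept separate from the
# package's computational path.

# Weir & Cockerham (1984) theta over biallelic dosage genotypes, given a
# grouping factor. Per-locus variance components a, b, c summed over loci.
wc_fst <- function(geno, pop) {
  pop <- as.factor(pop)
  r <- nlevels(pop)
  a_sum <- 0; abc_sum <- 0
  for (l in seq_len(ncol(geno))) {
    x <- geno[, l]; ok <- !is.na(x)
    xl <- x[ok]; pl <- pop[ok]
    n_i <- tabulate(pl, r)
    if (any(n_i == 0)) next
    p_i <- tapply(xl, pl, mean) / 2
    h_i <- tapply(xl == 1, pl, mean)
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    pbar <- sum(n_i * p_i) / sum(n_i)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / sum(n_i)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
      ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    abc_sum <- abc_sum + a + b + cc
  }
  a_sum / abc_sum
}

# Unbiased gene diversity from raw allele counts at one locus.
hs_from_counts <- function(dosages) {
  x <- dosages[!is.na(dosages)]
  n <- length(x)
  n_alt <- sum(x)
  p <- n_alt / (2 * n)
  (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
}

# Nei (1972) standard distance between two individuals treated as
# two-allele frequency vectors per locus, from first principles.
nei_pair <- function(a, b) {
  xa <- rbind(a / 2, 1 - a / 2)
  xb <- rbind(b / 2, 1 - b / 2)
  jxy <- sum(xa * xb); jx <- sum(xa^2); jy <- sum(xb^2)
  -log(jxy / sqrt(jx * jy))
}

# Naive complete-linkage agglomeration: repeatedly merge the two clusters
# with the smallest maximum inter-cluster pairwise distance while that
# distance is <= threshold. O(n^3), order-deterministic.
naive_complete_linkage <- function(d, threshold) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    best <- Inf; bi <- bj <- 0
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dd <- max(d[clusters[[i]], clusters[[j]]])
      if (dd < best) { best <- dd; bi <- i; bj <- j }
    }
    if (!is.finite(best) || best > threshold) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  assign <- integer(n)
  for (i in seq_along(clusters)) assign[clusters[[i]]] <- i
  assign
}

# Dense REML criterion for y = Xb + a + e, a ~ N(0, G sg2), e ~ N(0, I se2),
# evaluated directly from V = gamma*G + I (profiling se2), no spectral trick.
dense_reml_ll <- function(gamma, y, X, G) {
  n <- length(y); p <- ncol(X)
  V0 <- gamma * G + diag(n)
  Vi <- solve(V0)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  s2e <- drop(t(r) %*% Vi %*% r) / (n - p)
  -0.5 * ((n - p) * log(s2e) + determinant(V0)$modulus[1] +
            determinant(XtViX)$modulus[1] + (n - p))
}

# Partition comparison helper: same clustering up to label permutation.
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# All permutations of 1..n, one per row (recursive enumeration).
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Small deterministic genotype matrix builder for fixtures.
toy_geno <- function(values, n_samples, ids = NULL) {
  m <- matrix(values, nrow = n_samples, byrow = TRUE)
  rownames(m) <- ids %||% sprintf("s%02d", seq_len(n_samples))
  colnames(m) <- sprintf("L%02d", seq_len(ncol(m)))
  geno_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
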