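# Shared fixtures and independent oracles used across the suite.

# Small planted cohort for fast module-level tests.
small_cohort <- function(seed = 3, n_samples = 60, n_genes = 300,
                         module_sizes = c(60, 45, 40)) {
  generate_reference_cohort(n_samples = n_samples, n_genes = n_genes,
                            module_sizes = module_sizes, seed = seed)
}

# Random symmetric [0,1] adjacency with zero diagonal.
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
  a
}

# Brute-force TOM dissimilarity via explicit loops.
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    num <- a[i, j]
    for (u in 1:n) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    d[i, j] <- 1 - num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(d) <- dimnames(a)
  d
}

# Brute-force gene-level concepts via explicit loops.
concepts_oracle <- function(a) {
  n <- nrow(a)
  k <- mar <- cc <- numeric(n)
  for (i in 1:n) {
    k[i] <- sum(a[i, -i])
    sq <- sum(a[i, -i]^2)
    mar[i] <- if (k[i] > 0) sq / k[i] else NA_real_
    num <- 0
    for (j in 1:n) for (l in 1:n)
      if (j != i && l != i && j != l) num <- num + a[i, j] * a[j, l] * a[l, i]
    den <- k[i]^2 - sq
    cc[i] <- if (den > 0) num / den else NA_real_
  }
  list(connectivity = k, mar = mar, clustering = cc)
}

# Whole-network concepts from their defining formulas.
whole_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  dens <- sum(k) / (n * (n - 1))
  cent <- n / (n - 2) * (max(k) / (n - 1) - dens)
  het <- sqrt(mean((k - mean(k))^2)) / mean(k)
  list(density = dens, centralization = cent, heterogeneity = het)
}

# Direct scalar biweight midcorrelation from the estimator definition.
bicor_oracle <- function(x, y) {
  part <- function(v) {
    med <- median(v); m <- median(abs(v - med))
    if (m == 0) return(v - mean(v))
    u <- (v - med) / (9 * m)
    (v - med) * ((1 - u^2)^2 * (abs(u) < 1))
  }
  a <- part(x); b <- part(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Memoized full-scale default reference build shared by acceptance tests.
cached_default_build <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- generate_reference_cohort(seed = 7)
      cache <<- list(ref = ref,
                     built = run_reference_build(ref$expr, params = list(seed = 7)))
    }
    cache
  }
})
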