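test_that("variable-gene selection is deterministic and drops constants", {
  set.seed(1)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:10)))
  m["g05", ] <- 3  # constant gene: minimal variance
  expect_identical(select_variable_genes(m, 20), m)
  sel <- select_variable_genes(m, 19)
  expect_false("g05" %in% rownames(sel))
  # planted structure enriches the selected set
  ref <- small_cohort(seed = 2)
  sel <- select_variable_genes(ref$expr, 100)
  lab <- setNames(ref$truth$loadings$module, ref$truth$loadings$gene_id)
  expect_gt(mean(lab[rownames(sel)] > 0), mean(lab > 0))
})

test_that("bicor matches the direct biweight estimator and handles edge cases", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(50); y <- rnorm(50)
    expect_equal(bicor(x, y), bicor_oracle(x, y), tolerance = 1e-12)
  }
  x <- rnorm(30)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)
  expect_true(is.na(bicor(rep(1, 10), rnorm(10))))
  expect_error(bicor(1:2, 1:2), "length")
  # MAD = 0 but non-constant: falls back to Pearson weighting
  v <- c(rep(0, 8), 5, -5)
  w <- rnorm(10)
  expect_equal(bicor(v, v), 1)
})

test_that("signed-hybrid adjacency truncates and powers correlations", {
  s <- seq(0, 1, length.out = 12)
  expr <- rbind(a = s, b = s, c = 1 - s, d = c(s[1:6], rev(s[1:6])))
  colnames(expr) <- sprintf("s%d", 1:12)
  net <- adjacency(expr, power = 5)
  expect_equal(net$adjacency["a", "b"], 1)       # perfect correlation
  expect_equal(net$adjacency["a", "c"], 0)       # anti-correlation truncated
  expect_true(all(diag(net$adjacency) == 0))
  expect_true(all(net$adjacency >= 0 & net$adjacency <= 1))
  expect_error(adjacency(expr, power = 0), "power")
  # 0.5^5 by hand
  expect_equal(max(0.5, 0)^5, 0.03125)
  # monotonicity of the map r -> max(r,0)^power
  r <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(pmax(r, 0)^5) >= 0))
})

test_that("topological overlap matches the loop oracle and closed forms", {
  # 2-gene network with a = 1: TOM = 1, dissimilarity 0
  a2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(topological_overlap(a2)["x", "y"], 0)
  # empty network: off-diagonal dissimilarity 1
  a0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d0 <- topological_overlap(a0)
  expect_true(all(d0[upper.tri(d0)] == 1))
  # random networks vs brute force
  for (seed in 1:5) {
    a <- random_adjacency(8, seed)
    expect_equal(topological_overlap(a), tom_oracle(a), tolerance = 1e-12)
  }
})

test_that("module detection recovers separable blocks and is permutation-equivariant", {
  # two planted blocks of 50 with tiny within-block dissimilarity
  set.seed(8)
  n <- 100
  d <- matrix(1, n, n)
  d[1:50, 1:50] <- matrix(runif(2500, 0, 0.2), 50, 50)
  d[51:100, 51:100] <- matrix(runif(2500, 0, 0.2), 50, 50)
  d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  asg <- detect_modules(d, min_size = 30)
  expect_equal(unname(asg$module_sizes), c(50L, 50L))
  expect_equal(sort(unique(asg$labels[1:50])), 1L)

  # all-1 dissimilarity: everything unassigned
  d1 <- matrix(1, 40, 40); diag(d1) <- 0
  dimnames(d1) <- list(sprintf("g%02d", 1:40), sprintf("g%02d", 1:40))
  expect_true(all(detect_modules(d1, min_size = 10)$labels == 0L))

  # permutation equivariance
  perm <- sample(n)
  asg_p <- detect_modules(d[perm, perm], min_size = 30)
  expect_identical(asg_p$labels[rownames(d)], asg$labels)

  expect_warning(detect_modules(d[1:10, 1:10], min_size = 30), "min_size")
})

test_that("eigengene has fixed orientation and reproduces rank-1 structure", {
  ref <- generate_reference_cohort(n_samples = 40, n_genes = 60,
                                   module_sizes = 25, loading_range = c(1, 1),
                                   noise_sd = 1e-10, seed = 3)
  g <- ref$truth$loadings$gene_id[ref$truth$loadings$module == 1]
  eg <- module_eigengene(ref$expr, g)
  f <- ref$truth$latent_factors[, 1]
  expect_gt(abs(cor(eg$scores$PC1, f)), 1 - 1e-8)
  expect_gt(eg$model$explained[1], 1 - 1e-8)
  # orientation: PC1 correlates non-negatively with mean standardized expression
  z <- scale(t(ref$expr[g, ]))
  expect_gte(cor(eg$scores$PC1, rowMeans(z)), 0)
  # sign convention invariant to decomposition sign flips: orientation is
  # a deterministic function of the data
  eg2 <- module_eigengene(ref$expr[, ncol(ref$expr):1], g)
  expect_equal(sort(eg2$scores$PC1), sort(eg$scores$PC1), tolerance = 1e-6)
  # module of two identical genes: PC1 explains everything
  two <- ref$expr[g[1:2], ]; two[2, ] <- two[1, ]
  rownames(two) <- c("dup1", "dup2")
  eg3 <- module_eigengene(two, c("dup1", "dup2"))
  expect_equal(eg3$model$explained[1], 1)
})

test_that("kME measures membership and flags undefined genes", {
  ref <- small_cohort(seed = 6)
  tr <- ref$truth
  g <- tr$loadings$gene_id[tr$loadings$module == 1]
  eg <- module_eigengene(ref$expr, g)
  kv <- kme(ref$expr, eg$scores)
  expect_named(kv, rownames(ref$expr))
  # top-loading gene in its own module scores high; background near zero
  expect_gt(max(kv[g]), 0.85)
  bg <- tr$loadings$gene_id[tr$loadings$module == 0]
  expect_lt(mean(abs(kv[bg])), 2 / sqrt(ncol(ref$expr)))
  # ranking follows loadings
  sp <- cor(kv[g], tr$loadings$loading[tr$loadings$module == 1],
            method = "spearman")
  expect_gt(sp, 0.9)
  # constant gene flagged NA
  expr2 <- ref$expr; expr2[1, ] <- 2
  expect_true(is.na(kme(expr2, eg$scores)[1]))
})

test_that("topological significance passes planted modules and not random sets", {
  ref <- small_cohort(seed = 12)
  built_net <- adjacency(ref$expr, power = 5)
  asg <- detect_modules(topological_overlap(built_net), min_size = 30)
  sig <- topological_significance(ref$expr, asg, n_random = 100,
                                  net = built_net, seed = 1)
  expect_true(all(sig$pass))
  # a random pseudo-module sits inside the null band
  set.seed(2)
  fake <- asg
  fake$labels[] <- 0L
  fake$labels[sample(names(fake$labels), 40)] <- 1L
  fake$module_sizes <- c("1" = 40L)
  z <- topological_significance(ref$expr, fake, n_random = 100,
                                net = built_net, seed = 3)$median_z
  expect_lt(abs(z), 3)
})

test_that("module stability is 1 for deterministic recovery and low for noise", {
  ref <- generate_reference_cohort(n_samples = 40, n_genes = 120,
                                   module_sizes = c(40, 35),
                                   loading_range = c(1.2, 1.5),
                                   noise_sd = 0.3, seed = 5)
  st <- module_stability(ref$expr, n_iter = 8, seed = 2)
  expect_true(all(st > 0.8))
  # n_iter = 1, frac = 1: self comparison
  st1 <- module_stability(ref$expr, n_iter = 1, frac = 1, seed = 2)
  expect_true(all(st1 == 1))
  # pure noise: no stable modules (usually none detected at all)
  set.seed(9)
  noise <- matrix(rnorm(120 * 40), 120, 40,
                  dimnames = list(sprintf("g%d", 1:120), sprintf("s%d", 1:40)))
  st0 <- suppressWarnings(module_stability(noise, n_iter = 5, seed = 3))
  expect_true(length(st0) == 0 || all(st0 < 0.5))
})
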