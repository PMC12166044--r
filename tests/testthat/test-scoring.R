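test_that("kME-derived gene sets follow threshold and top-n rules", {
  kv <- setNames(c(0.95, 0.92, 0.91, 0.85, 0.7, NA), sprintf("g%d", 1:6))
  thr <- derive_geneset_by_kme(kv, "sig", mode = "threshold", theta = 0.9)
  expect_equal(thr$genes, c("g1", "g2", "g3"))
  top <- derive_geneset_by_kme(kv, "top", mode = "top_n", n = 3)
  expect_equal(top$genes, c("g1", "g2", "g3"))
  # theta = -1 keeps the whole (defined) module; top_n = module size too
  expect_equal(length(derive_geneset_by_kme(kv, "all", theta = -1)$genes), 5)
  expect_equal(derive_geneset_by_kme(kv, "all", mode = "top_n", n = 99)$genes,
               derive_geneset_by_kme(kv, "all", theta = -1)$genes)
  expect_error(derive_geneset_by_kme(kv, "none", theta = 0.99), "0.95")
})

test_that("ssGSEA walk matches a hand-enumerated oracle", {
  # 6-gene universe, expression 6..1 (no ties), set {g1, g4}, exponent 0.25:
  # in-set weights 6^.25 and 3^.25; walking down the list the cumulative
  # in-set mass minus uniform out-of-set mass sums to ~1.62963.
  expr <- matrix(6:1, ncol = 1, dimnames = list(sprintf("g%d", 1:6), "s1"))
  got <- ssgsea_score(expr, c("g1", "g4"), exponent = 0.25)
  w1 <- 6^0.25; w4 <- 3^0.25; denom <- w1 + w4
  cdf_in <- cumsum(c(w1, 0, 0, w4, 0, 0)) / denom
  cdf_out <- cumsum(c(0, 1, 1, 0, 1, 1)) / 4
  expect_equal(unname(got), sum(cdf_in - cdf_out), tolerance = 1e-12)
  expect_equal(unname(got), 1.629634, tolerance = 1e-4)
})

test_that("ssGSEA sign and null behavior follow construction", {
  set.seed(3)
  expr <- matrix(rnorm(50 * 30), 50, 30,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:30)))
  top_set <- names(sort(expr[, 1], decreasing = TRUE))[1:5]
  bot_set <- names(sort(expr[, 1]))[1:5]
  expect_gt(ssgsea_score(expr, top_set)[1], 0)
  expect_lt(ssgsea_score(expr, bot_set)[1], 0)
  # null behavior: with uniform step weights (exponent 0) the walk is an
  # exchangeable two-sample ECDF difference, so random sets on random data
  # are mean-zero; a positive exponent concentrates in-set mass at the top
  # of the list, adding a small systematic positive offset that must stay
  # well below the per-sample score spread
  rand_means0 <- replicate(20, {
    mean(ssgsea_score(expr, sample(rownames(expr), 8), exponent = 0))
  })
  s_scale <- sd(ssgsea_score(expr, sample(rownames(expr), 8)))
  expect_lt(abs(mean(rand_means0)), 0.1 * s_scale)
  rand_means <- replicate(20, {
    mean(ssgsea_score(expr, sample(rownames(expr), 8), exponent = 0.25))
  })
  expect_lt(abs(mean(rand_means)), s_scale)
  # invariance under monotone per-sample transforms (rank-based)
  rand <- sample(rownames(expr), 8)
  s <- ssgsea_score(expr, rand)
  expect_equal(ssgsea_score(exp(expr), rand), s, tolerance = 1e-12)
  expect_equal(ssgsea_score(expr * 3 + 7, rand), s, tolerance = 1e-12)
  # set outside the universe errors
  expect_error(ssgsea_score(expr, c("nope", rand)), "outside")
})

test_that("GSVA scores behave under construction and sample duplication", {
  set.seed(4)
  expr <- matrix(rnorm(40 * 12), 40, 12,
                 dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:12)))
  sets <- list(up = sprintf("g%02d", 1:5), rand = sprintf("g%02d", 21:28))
  # the statistic is cross-sample relative: shifting the set genes up in
  # half the samples makes those samples' scores strongly positive and the
  # rest negative
  expr[1:5, 1:6] <- expr[1:5, 1:6] + 100
  sc <- gsva_score(expr, sets)
  expect_equal(dim(sc), c(12, 2))
  expect_true(all(sc[1:6, "up"] > 0.3))
  expect_true(all(sc[7:12, "up"] < 0))
  # duplicating every sample leaves scores unchanged
  dup <- cbind(expr, expr)
  colnames(dup) <- sprintf("d%02d", 1:24)
  sc_dup <- gsva_score(dup, sets)
  expect_equal(unname(sc_dup[1:12, ]), unname(sc), tolerance = 1e-9)
  # 16 sets score jointly into samples x 16
  sets16 <- lapply(1:16, function(i) sample(rownames(expr), 6))
  names(sets16) <- sprintf("immune%02d", 1:16)
  expect_equal(dim(gsva_score(expr, sets16)), c(12, 16))
  expect_warning(gsva_score(expr, list(tiny = "g01")), "smaller than 2")
})

test_that("mean score is linear with a deterministic median split", {
  set.seed(5)
  expr <- matrix(rnorm(20 * 10), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  # single-gene set equals that gene's expression
  ms <- mean_z_score(expr, "g03")
  expect_equal(ms$score, unname(expr["g03", ]))
  # linearity in expression
  set <- sprintf("g%02d", 1:4)
  expect_equal(mean_z_score(2 * expr, set)$score,
               2 * mean_z_score(expr, set)$score)
  # n clearly-high samples get n "high" labels; ties at the median go low
  expr2 <- expr; expr2[, 1:5] <- expr2[, 1:5] + 50
  expect_equal(sum(mean_z_score(expr2, set)$label == "high"), 5)
  const <- matrix(1, 3, 4, dimnames = list(letters[1:3], LETTERS[1:4]))
  expect_warning(msc <- mean_z_score(const, "a"), "degenerate")
  expect_true(all(msc$label == "low"))
})

test_that("over-representation uses the hypergeometric tail with BY adjustment", {
  universe <- sprintf("g%03d", 1:200)
  module <- universe[1:20]
  sets <- list(same = module, disjoint = universe[101:130],
               partial = universe[11:40])
  res <- overrepresentation_test(module, sets, universe)
  expect_equal(res$set[1], "same")
  expect_equal(res$p[res$set == "same"],
               phyper(19, 20, 180, 20, lower.tail = FALSE))
  expect_gte(res$p[res$set == "disjoint"], 0.5)
  expect_true(all(res$fdr_by >= res$p))
  # BY is monotone in p
  expect_true(all(diff(res$fdr_by[order(res$p)]) >= -1e-12))
  # empty overlap allowed, p = 1 for a set absent from the universe overlap
  res2 <- overrepresentation_test(module, list(none = universe[150:160]), universe)
  expect_equal(res2$overlap, 0)
  expect_error(overrepresentation_test(c(module, "zzz"), sets, universe),
               "universe")
})

test_that("GMT round-trip preserves gene sets", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g2"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
})
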