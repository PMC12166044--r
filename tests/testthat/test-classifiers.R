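test_that("separable scores yield a mid-gap split with perfect training accuracy", {
  set.seed(1)
  scores <- c(rnorm(5, -3, 0.3), rnorm(8, 3, 0.3))
  names(scores) <- sprintf("p%02d", 1:13)
  labels <- rep(c(FALSE, TRUE), c(5, 8))
  fit <- fit_threshold_classifier(scores, labels, seed = 1)
  expect_false(fit$degenerate)
  expect_equal(fit$direction, "greater_is_responder")
  expect_gt(fit$cutoff, max(scores[1:5]))
  expect_lt(fit$cutoff, min(scores[6:13]))
  # cutoff is the midpoint of the straddled adjacent pair
  s <- sort(scores)
  gaps <- (s[-1] + s[-13]) / 2
  expect_true(fit$cutoff %in% gaps)
  pred <- predict(fit, scores)
  expect_equal(classification_metrics(pred, labels)$accuracy, 1)
  # both leaves respect min_leaf at fit time
  expect_gte(sum(scores <= fit$cutoff), fit$min_leaf)
  expect_gte(sum(scores > fit$cutoff), fit$min_leaf)
})

test_that("prediction uses the documented tie and degenerate-model rules", {
  scores <- setNames(c(1, 2, 3, 10, 11, 12), sprintf("p%d", 1:6))
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  fit <- fit_threshold_classifier(scores, labels, min_leaf = 3, seed = 1)
  if (!fit$degenerate) {
    # exactly at the cutoff goes to the <= side
    expect_false(predict(fit, fit$cutoff))
    expect_true(predict(fit, fit$cutoff + 1e-9))
    # shifted far up: everything a responder
    expect_true(all(predict(fit, scores + 100)))
  }
  # degenerate model predicts its majority class everywhere
  set.seed(2)
  null_fit <- fit_threshold_classifier(setNames(rnorm(12), sprintf("q%d", 1:12)),
                                       rep(c(TRUE, FALSE), c(7, 5)),
                                       alpha = 1e-6, seed = 2)
  expect_true(null_fit$degenerate)
  expect_true(all(predict(null_fit, rnorm(5))))
  expect_error(predict(null_fit, c(a = 1, b = NA)), "missing score")
  expect_error(fit_threshold_classifier(scores, rep(TRUE, 6)), "both classes")
})

test_that("permutation gate controls type-I error on null data", {
  set.seed(10)
  n_sim <- 200
  labels <- rep(c(TRUE, FALSE), c(7, 6))
  splits <- vapply(seq_len(n_sim), function(i) {
    fit <- fit_threshold_classifier(setNames(rnorm(13), sprintf("p%d", 1:13)),
                                    labels, n_perm = 399, seed = i)
    !fit$degenerate
  }, TRUE)
  rate <- mean(splits)
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lte(rate, 0.05 + 3 * se)
})

test_that("metrics match direct confusion-table formulas for all n <= 6 tables", {
  for (n in 2:6) {
    grid <- expand.grid(replicate(2 * n, c(TRUE, FALSE), simplify = FALSE))
    # subsample the grid for n > 4 to keep the loop quick but varied
    idx <- if (n > 4) seq(1, nrow(grid), by = 7) else seq_len(nrow(grid))
    for (r in idx) {
      pred <- unlist(grid[r, 1:n]); truth <- unlist(grid[r, (n + 1):(2 * n)])
      if (!any(truth) && !any(!truth)) next
      m <- classification_metrics(pred, truth)
      tp <- sum(pred & truth); fp <- sum(pred & !truth)
      fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
      expect_equal(m$accuracy, (tp + tn) / n)
      denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      if (denom == 0) expect_true(is.na(m$mcc))
      else expect_equal(m$mcc, (tp * tn - fp * fn) / sqrt(denom))
      if (tp + fn == 0 || tp + fp == 0) {
        expect_true(is.na(m$f1))
      } else if (tp == 0) {
        expect_true(is.na(m$f1) || m$f1 == 0)
      } else {
        expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn))
      }
    }
  }
  # degenerate all-one-class prediction reports N/A, never 0
  m <- classification_metrics(rep(TRUE, 13), rep(c(TRUE, FALSE), c(8, 5)))
  expect_equal(m$accuracy, 8 / 13)
  expect_true(is.na(m$mcc))
})

test_that("subtype calling applies the Spearman margin rule", {
  ref <- small_cohort(seed = 2)
  cent <- generate_centroids(ref$truth, n_subtype_genes = 40, seed = 3)
  # identity: maximal correlation with own centroid
  call <- call_subtype(cent$profiles[, "BLIA"], cent)
  expect_equal(call$call, "BLIA")
  expect_equal(call$rho_BLIA, 1)
  # rank-space midpoint of two centroids: Spearman margin exactly 0 by
  # symmetry (a value-space average is not rank-symmetric), indeterminate
  mid <- rank(cent$profiles[, "BLIA"]) + rank(cent$profiles[, "BLIS"])
  call_mid <- call_subtype(mid, cent)
  expect_equal(call_mid$call, "INDETERMINATE")
  expect_lt(call_mid$margin, 0.1)
  # margin just under / over the threshold
  expect_equal(call_subtype(mid, cent, margin_threshold = 1e-6)$call ==
                 "INDETERMINATE", call_mid$margin < 1e-6)
  # monotone-transform invariance (Spearman is rank-based)
  x <- simulate_from_centroid(cent, "LAR", seed = 4)
  expect_equal(call_subtype(exp(2 * x), cent)$call, call_subtype(x, cent)$call)
  # constant sample: indeterminate with reason
  const <- setNames(rep(1, length(cent$gene_ids)), cent$gene_ids)
  cc <- call_subtype(const, cent)
  expect_equal(cc$call, "INDETERMINATE")
  expect_equal(cc$reason, "constant_sample")
})

test_that("rescue resolves exactly the indeterminate calls", {
  ref <- small_cohort(seed = 2)
  cent <- generate_centroids(ref$truth, n_subtype_genes = 40, seed = 3)
  mid <- rank(cent$profiles[, "BLIA"]) + rank(cent$profiles[, "BLIS"])
  samples <- cbind(
    det1 = simulate_from_centroid(cent, "BLIA", seed = 5),
    det2 = simulate_from_centroid(cent, "LAR", seed = 6),
    ind1 = mid, ind2 = mid + 1e-9)
  rownames(samples) <- cent$gene_ids
  calls <- call_subtype(samples, cent)
  expect_equal(calls$call[3:4], rep("INDETERMINATE", 2))
  pred <- c(ind1 = TRUE, ind2 = FALSE)
  rescued <- rescue_indeterminate(calls, pred, cent)
  expect_equal(rescued$call[3], "BLIA")   # predicted responder -> good prognosis
  expect_equal(rescued$call[4], "BLIS")   # predicted non-responder -> poor
  expect_equal(rescued$rescue_source[3:4], rep("network_classifier", 2))
  # determinate calls untouched; no indeterminates -> identity
  expect_equal(rescued$call[1:2], calls$call[1:2])
  expect_identical(rescue_indeterminate(calls[1:2, ], pred, cent), calls[1:2, ])
  expect_error(rescue_indeterminate(calls, pred[1], cent), "no prediction")
})
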