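test_that("TMM factors are scale-invariant and match edgeR on composition shifts", {
  set.seed(1)
  counts <- matrix(rnbinom(500 * 4, mu = 100, size = 5), 500, 4,
                   dimnames = list(sprintf("g%03d", 1:500), sprintf("s%d", 1:4)))
  # identical libraries: factors all 1
  same <- cbind(a = counts[, 1], b = counts[, 1], c = counts[, 1])
  expect_equal(unname(tmm_factors(same)), rep(1, 3))
  # doubling a library leaves composition unchanged
  doubled <- cbind(a = counts[, 1], b = counts[, 1] * 2, c = counts[, 2])
  f <- tmm_factors(doubled)
  expect_equal(f[["a"]], f[["b"]], tolerance = 1e-9)
  # composition shift: 10% of genes 5-fold up inflates the library, so the
  # trimmed mean of M over the unchanged majority pulls the factor below 1
  # (effective-library-size convention); verified against a direct
  # trimmed-mean evaluation and edgeR below
  shifted <- counts
  shifted[1:50, 4] <- shifted[1:50, 4] * 5
  f <- tmm_factors(shifted, ref_column = 1)
  expect_lt(f[["s4"]] / f[["s1"]], 1)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  # direct formula oracle: untrimmed-weighted mean of M for the unchanged
  # genes approximates the factor's direction and magnitude
  m_unchanged <- log2((shifted[51:500, 4] / sum(shifted[, 4])) /
                        (shifted[51:500, 1] / sum(shifted[, 1])))
  expect_lt(median(m_unchanged), 0)
  # independent oracle: edgeR with the same reference column
  skip_if_not_installed("edgeR")
  f_edger <- edgeR::calcNormFactors(shifted, method = "TMM", refColumn = 1)
  expect_equal(unname(f / f_edger), rep(1, 4), tolerance = 0.03)
})

test_that("moderated t reduces to the ordinary t when the prior df is zero", {
  set.seed(2)
  mat <- matrix(rnorm(100 * 10), 100, 10,
                dimnames = list(sprintf("f%03d", 1:100), sprintf("s%d", 1:10)))
  grp <- rep(c(FALSE, TRUE), each = 5)
  res <- moderated_t(mat, grp, prior_df = 0)
  ts <- apply(mat, 1, function(x)
    t.test(x[grp], x[!grp], var.equal = TRUE)$statistic)
  expect_equal(res$t, unname(ts), tolerance = 1e-9)
  ps <- apply(mat, 1, function(x)
    t.test(x[grp], x[!grp], var.equal = TRUE)$p.value)
  expect_equal(res$p, unname(ps), tolerance = 1e-9)
})

test_that("estimated moderation agrees with the limma empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  set.seed(3)
  mat <- matrix(rnorm(300 * 12, sd = rep(runif(300, 0.5, 2), 12)), 300, 12,
                dimnames = list(sprintf("f%03d", 1:300), sprintf("s%02d", 1:12)))
  grp <- rep(c(FALSE, TRUE), each = 6)
  mat[1:20, grp] <- mat[1:20, grp] + 3
  res <- moderated_t(mat, grp)
  design <- cbind(1, as.numeric(grp))
  fit <- limma::eBayes(limma::lmFit(mat, design))
  expect_gt(cor(res$t, fit$t[, 2]), 0.999)
  expect_equal(res$effect, unname(fit$coefficients[, 2]), tolerance = 1e-9)
  # rank agreement on the planted features
  expect_gt(mean(rank(res$p)[1:20] <= 30), 0.8)
})

test_that("null simulations keep the BH family-wise discovery rate in band", {
  set.seed(4)
  n_sim <- 200; n_feat <- 150
  grp <- rep(c(FALSE, TRUE), each = 5)
  any_hit <- vapply(seq_len(n_sim), function(i) {
    mat <- matrix(rnorm(n_feat * 10), n_feat, 10)
    res <- moderated_t(mat, grp, prior_df = 0)
    any(res$fdr < 0.05)
  }, TRUE)
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lte(mean(any_hit), 0.05 + 3 * se)
})

test_that("power: planted shifts rank near the top", {
  set.seed(5)
  mat <- matrix(rnorm(500 * 26), 500, 26,
                dimnames = list(sprintf("f%03d", 1:500), sprintf("s%02d", 1:26)))
  grp <- rep(c(FALSE, TRUE), each = 13)
  mat[1:50, grp] <- mat[1:50, grp] + 1.5
  res <- moderated_t(mat, grp)
  expect_lte(median(rank(res$p)[1:50]), 50)  # median planted rank in top decile
})

test_that("paired deltas align patients and recover planted treatment shifts", {
  ref <- small_cohort(seed = 6)
  clin <- generate_clinical_cohort(ref$truth, n_patients = 13,
                                   treatment_shift = 1, seed = 7)
  mat <- cbind(clin$bx1, clin$bx2)
  d <- paired_delta(mat, clin$clinical)
  expect_equal(ncol(d), 13)
  # Bx2 = Bx1 gives the zero matrix
  clin0 <- clin
  mat0 <- cbind(clin$bx1, clin$bx1)
  colnames(mat0) <- c(colnames(clin$bx1), colnames(clin$bx2))
  expect_true(all(paired_delta(mat0, clin$clinical) == 0))
  # planted shift on the response module appears in the mean delta
  lo <- ref$truth$loadings
  resp_genes <- lo$gene_id[lo$module == ref$truth$response_module]
  bg_genes <- lo$gene_id[lo$module == 0]
  mean_loading <- mean(lo$loading[lo$module == ref$truth$response_module])
  planted <- mean_loading * 1  # loading x shift
  expect_equal(mean(d[resp_genes, ]), planted, tolerance = 0.35)
  expect_lt(abs(mean(d[bg_genes, ])), 0.15)
  # duplicate biopsy is an error
  bad <- clin$clinical
  bad$biopsy[14] <- "Bx1"
  expect_error(paired_delta(mat, bad), "duplicate")
})

test_that("sector assignment partitions the t-plane with documented boundaries", {
  sa <- function(e, n) sector_assign(e, n)$sector
  expect_equal(sa(0, 5), 2L)       # +network axis
  expect_equal(sa(0, -5), 5L)      # -network axis
  expect_equal(sa(5, 5), 1L)       # 45 degrees: outside the 30-degree wedge
  expect_equal(sa(-5, 5), 3L)
  expect_equal(sa(5, -5), 6L)
  expect_equal(sa(-5, -5), 4L)
  expect_equal(sa(5, 0), 1L)
  expect_equal(sa(-5, 0), 3L)
  # wedge membership exactly at 30 degrees from the axis follows the tie rule
  th <- tan(60 * pi / 180)
  expect_equal(sa(1, th + 1e-9), 2L)
  expect_equal(sa(1, th - 1e-9), 1L)
  # expression-sign invariance of the network-dominant wedges
  set.seed(8)
  te <- rnorm(200); tn <- rnorm(200)
  s1 <- sector_assign(te, tn)$sector
  s2 <- sector_assign(-te, tn)$sector
  expect_equal(s1 == 2, s2 == 2)
  expect_equal(s1 == 5, s2 == 5)
  # origin unassigned
  expect_true(is.na(sa(0, 0)))
  # everything else partitioned
  expect_false(anyNA(sector_assign(te, tn)$sector))
})

test_that("planted Bx2-only effects surface in Bx2 but not Bx1 contrasts", {
  ref <- small_cohort(seed = 9)
  clin <- generate_clinical_cohort(ref$truth, n_patients = 10, effect = 2,
                                   treatment_shift = 0, seed = 10)
  lo <- ref$truth$loadings
  resp_genes <- lo$gene_id[lo$module == ref$truth$response_module]
  labels <- clin$clinical$responder[clin$clinical$biopsy == "Bx1"]
  # response-module genes differ between groups at both biopsies by
  # construction; background genes never do
  bg <- lo$gene_id[lo$module == 0]
  res_bg <- moderated_t(clin$bx1[bg, , drop = FALSE], labels)
  expect_equal(sum(res_bg$fdr < 0.05), 0)
  res_resp <- moderated_t(clin$bx1[resp_genes, , drop = FALSE], labels)
  expect_gt(sum(res_resp$fdr < 0.05), length(resp_genes) / 2)
})
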