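# Differential testing of expression and network features: TMM library
# normalization, trend-capable empirical-Bayes moderated t statistics with
# BH adjustment, paired biopsy deltas, and sector classification of genes
# into expression-driven vs wiring-driven groups.

#' TMM normalization factors
#'
#' Trimmed mean of M-values against a reference sample (the highest-depth
#' library by default): per gene, the log-ratio M and average abundance A
#' relative to the reference are computed on library-size-scaled counts,
#' the most extreme 30% of M values and 5% of A values are trimmed, and
#' the factor is 2 to the precision-weighted mean of the remaining M
#' values (weights = inverse asymptotic binomial variances). Factors are
#' rescaled to geometric mean 1. Genes zero in either library of a pair
#' are excluded from that pair's trimmed mean.
#'
#' @param counts genes x samples nonnegative matrix.
#' @param trim_m two-sided M-value trim fraction (default 0.3).
#' @param trim_a two-sided A-value trim fraction (default 0.05).
#' @param ref_column reference sample index (default: highest library size).
#' @return named per-sample normalization factor vector, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05, ref_column = NULL) {
  if (!is.matrix(counts) || any(counts < 0))
    stop("counts must be a nonnegative matrix", call. = FALSE)
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  lib <- colSums(counts)
  if (any(lib == 0)) stop("library sizes must be positive", call. = FALSE)
  if (is.null(ref_column)) ref_column <- which.max(lib)

  one_factor <- function(j) {
    if (j == ref_column) return(1)
    obs <- counts[, j]; ref <- counts[, ref_column]
    ok <- obs > 0 & ref > 0
    obs <- obs[ok]; ref <- ref[ok]
    n_o <- lib[j]; n_r <- lib[ref_column]
    m <- log2((obs / n_o) / (ref / n_r))
    a <- 0.5 * log2((obs / n_o) * (ref / n_r))
    w <- 1 / ((n_o - obs) / (n_o * obs) + (n_r - ref) / (n_r * ref))
    keep_m <- rank(m) > trim_m * length(m) & rank(m) <= (1 - trim_m) * length(m)
    keep_a <- rank(a) > trim_a * length(a) & rank(a) <= (1 - trim_a) * length(a)
    keep <- keep_m & keep_a
    if (!any(keep)) return(1)
    2^(sum(w[keep] * m[keep]) / sum(w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, 0)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# Inverse trigamma by Newton iteration (monotone decreasing target).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

# Empirical-Bayes moments for residual variances: estimates the prior df
# d0 and prior variance s0^2 (optionally an abundance trend s0^2(A)) by
# moment matching on log variances, following the standard moderated-t
# construction.
squeeze_variances <- function(s2, df, trend_x = NULL, prior_df = NULL) {
  ok <- s2 > 0
  z <- log(s2[ok])
  if (!is.null(trend_x)) {
    lo <- stats::lowess(trend_x[ok], z, f = 0.5)
    z_trend <- stats::approx(lo$x, lo$y, xout = trend_x, rule = 2, ties = mean)$y
  } else {
    z_trend <- rep(mean(z), length(s2))
  }
  e_z <- z - z_trend[ok]
  # var(log s^2) = trigamma(df/2) + trigamma(d0/2)
  excess <- stats::var(e_z) - trigamma(df / 2)
  d0 <- if (!is.null(prior_df)) prior_df
        else if (excess <= 0) Inf
        else 2 * trigamma_inverse(excess)
  if (d0 == 0)  # no moderation: ordinary variances
    return(list(post_var = s2, prior_df = 0, prior_var = NA_real_))
  # E[log s^2] = log s0^2 + digamma(df/2) - log(df/2) - (digamma(d0/2) - log(d0/2))
  bias <- digamma(df / 2) - log(df / 2)
  prior_adj <- if (is.finite(d0)) digamma(d0 / 2) - log(d0 / 2) else 0
  log_s0 <- z_trend + mean(e_z) - bias + prior_adj
  s0 <- exp(log_s0)
  post <- if (is.infinite(d0)) s0
          else (d0 * s0 + df * s2) / (d0 + df)
  list(post_var = post, prior_df = d0, prior_var = s0)
}

#' Moderated t-tests across features
#'
#' Per-feature two-group comparison (or, with `paired_ids`, a one-sample
#' test on within-pair differences) with empirical-Bayes variance
#' moderation: residual variances are shrunk toward a common prior (or an
#' abundance-trend prior when `trend = TRUE`) with prior degrees of freedom
#' estimated by moment matching on log variances. `prior_df = 0` disables
#' moderation, reproducing the ordinary t-test. P-values are BH-adjusted.
#' Rows with undefined (NA) values are excluded with a logged count.
#'
#' @param mat features x samples numeric matrix (log2 scale for
#'   expression-like input).
#' @param groups logical or two-level vector over samples (TRUE/second
#'   level = the group whose mean enters positively in the effect).
#' @param trend fit an abundance trend on the prior variance (default
#'   FALSE).
#' @param paired_ids optional pairing ids over samples: each id must occur
#'   once per group; the test is then on within-pair differences.
#' @param prior_df override the estimated prior degrees of freedom
#'   (0 = ordinary t; NULL = estimate).
#' @return data.frame (feature, effect, t, p, fdr, df_total), ordered as
#'   the input rows (excluded rows dropped).
#' @export
moderated_t <- function(mat, groups, trend = FALSE, paired_ids = NULL,
                        prior_df = NULL) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  g <- if (is.logical(groups)) groups else groups == sort(unique(groups))[2]
  if (length(g) != ncol(mat)) stop("groups length mismatch", call. = FALSE)

  drop <- apply(mat, 1, anyNA)
  if (any(drop)) {
    message(sum(drop), " feature row(s) with undefined values excluded")
    mat <- mat[!drop, , drop = FALSE]
  }
  if (!nrow(mat)) stop("no testable features", call. = FALSE)

  if (!is.null(paired_ids)) {
    ids <- unique(paired_ids)
    d <- sapply(ids, function(id) {
      i2 <- which(paired_ids == id & g); i1 <- which(paired_ids == id & !g)
      if (length(i1) != 1 || length(i2) != 1)
        stop("each pair id must occur once per group", call. = FALSE)
      mat[, i2] - mat[, i1]
    })
    if (is.null(dim(d))) d <- matrix(d, nrow = 1)
    n <- ncol(d)
    if (n < 2) stop("need >= 2 pairs", call. = FALSE)
    effect <- rowMeans(d)
    df <- n - 1
    s2 <- apply(d, 1, stats::var)
    se_unit <- sqrt(1 / n)
    a_mean <- rowMeans(mat)
  } else {
    n1 <- sum(!g); n2 <- sum(g)
    if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples", call. = FALSE)
    m1 <- rowMeans(mat[, !g, drop = FALSE]); m2 <- rowMeans(mat[, g, drop = FALSE])
    effect <- m2 - m1
    df <- n1 + n2 - 2
    ss1 <- rowSums((mat[, !g, drop = FALSE] - m1)^2)
    ss2 <- rowSums((mat[, g, drop = FALSE] - m2)^2)
    s2 <- (ss1 + ss2) / df
    se_unit <- sqrt(1 / n1 + 1 / n2)
    a_mean <- rowMeans(mat)
  }
  if (df < 1) stop("zero residual degrees of freedom", call. = FALSE)

  sq <- squeeze_variances(s2, df, trend_x = if (trend) a_mean else NULL,
                          prior_df = prior_df)
  d0 <- sq$prior_df
  df_total <- if (is.finite(d0)) df + d0 else Inf
  tstat <- effect / (sqrt(sq$post_var) * se_unit)
  p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  data.frame(feature = rownames(mat) %||% sprintf("f%d", seq_len(nrow(mat))),
             effect = effect, t = tstat, p = p,
             fdr = stats::p.adjust(p, method = "BH"),
             df_total = df_total,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-patient on-treatment minus pre-treatment differences
#'
#' Aligns the two biopsies of each patient and returns the Bx2 - Bx1
#' matrix (one column per complete pair). Patients missing either biopsy
#' are dropped with a warning; a duplicated biopsy for a patient is an
#' error.
#'
#' @param mat features x samples matrix (columns named by sample id).
#' @param clinical clinical table (sample_id, patient_id, biopsy).
#' @return features x patients matrix of paired differences.
#' @export
paired_delta <- function(mat, clinical) {
  cl <- clinical[clinical$sample_id %in% colnames(mat), ]
  if (anyDuplicated(cl[, c("patient_id", "biopsy")]))
    stop("duplicate biopsy for a patient", call. = FALSE)
  pts <- unique(cl$patient_id)
  cols <- lapply(pts, function(p) {
    s1 <- cl$sample_id[cl$patient_id == p & cl$biopsy == "Bx1"]
    s2 <- cl$sample_id[cl$patient_id == p & cl$biopsy == "Bx2"]
    if (length(s1) != 1 || length(s2) != 1) return(NULL)
    mat[, s2] - mat[, s1]
  })
  keep <- !vapply(cols, is.null, TRUE)
  if (any(!keep))
    warning(sum(!keep), " patient(s) without a complete pair dropped")
  out <- do.call(cbind, cols[keep])
  colnames(out) <- pts[keep]
  out
}

#' Assign genes to expression-vs-wiring sectors
#'
#' Places each gene in the (expression t, network-feature t) plane and
#' partitions the plane into six sectors by angle: sectors 2 and 5 are the
#' wedges within `boundary_angle` degrees of the positive and negative
#' network axes (differences attributable to wiring alone); sectors 1/3
#' flank sector 2 and sectors 4/6 flank sector 5 (mixed expression and
#' wiring). Boundary ties go to the lower-numbered sector; the origin is
#' unassigned (`NA`).
#'
#' @param t_expr,t_net per-gene t statistics (equal length, finite or NA).
#' @param boundary_angle half-width of the network-dominant wedges in
#'   degrees (default 30).
#' @return data.frame (gene, sector, t_expr, t_net); sector is NA for the
#'   origin or non-finite input.
#' @export
sector_assign <- function(t_expr, t_net, boundary_angle = 30) {
  if (length(t_expr) != length(t_net))
    stop("t_expr and t_net must have equal length", call. = FALSE)
  if (boundary_angle <= 0 || boundary_angle >= 90)
    stop("boundary_angle must be in (0, 90)", call. = FALSE)
  b <- boundary_angle
  theta <- atan2(t_net, t_expr) * 180 / pi   # (-180, 180], 90 = +t_net axis
  sector <- rep(NA_integer_, length(theta))
  ok <- is.finite(theta) & (t_expr != 0 | t_net != 0)
  th <- theta[ok]
  s <- integer(length(th))
  upper <- th >= 0
  # upper half: wedge about +90 is sector 2; flanks 1 (expression > 0 side)
  # and 3 (expression < 0 side). Ties on the wedge boundary go to sector 1.
  s[upper & th > 90 - b & th <= 90 + b] <- 2L
  s[upper & th <= 90 - b] <- 1L
  s[upper & th > 90 + b] <- 3L
  # lower half mirrors: wedge about -90 is sector 5; flanks 4 (expression
  # < 0 side) and 6 (expression > 0 side); ties go to the lower number.
  lower <- !upper
  s[lower & th <= -90 - b] <- 4L
  s[lower & th > -90 - b & th <= -90 + b] <- 5L
  s[lower & th > -90 + b] <- 6L
  sector[ok] <- s
  data.frame(gene = names(t_expr) %||% seq_along(t_expr),
             sector = sector, t_expr = t_expr, t_net = t_net,
             stringsAsFactors = FALSE, row.names = NULL)
}
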