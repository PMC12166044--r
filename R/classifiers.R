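# One-dimensional response classification and nearest-centroid subtype
# calling. The threshold classifier realizes a depth-1 conditional-inference
# tree: a permutation test on the linear statistic sum(score * label) gates
# whether any split is made at all; if it passes, the cutoff maximizing the
# standardized two-sample statistic over admissible midpoints is chosen,
# with both leaves required to hold at least `min_leaf` training samples.

perm_linear_p <- function(scores, y, n_perm, exact_limit, seed) {
  n <- length(y)
  t_obs <- sum(scores * y)
  n1 <- sum(y)
  if (n <= exact_limit) {
    combos <- utils::combn(n, n1)
    t_null <- apply(combos, 2, function(idx) sum(scores[idx]))
    center <- mean(t_null)
    mean(abs(t_null - center) >= abs(t_obs - center) - 1e-12)
  } else {
    with_seed(seed, {
      t_null <- vapply(seq_len(n_perm), function(i)
        sum(scores[sample.int(n, n1)]), 0)
      center <- mean(t_null)
      (1 + sum(abs(t_null - center) >= abs(t_obs - center) - 1e-12)) / (n_perm + 1)
    })
  }
}

#' Fit a depth-1 threshold classifier on a single score
#'
#' Global association between the score and the binary label is assessed by
#' a permutation test on the linear statistic `sum(score_i * label_i)`:
#' exact enumeration of all label assignments when `n <= exact_limit`,
#' Monte-Carlo with `n_perm` draws otherwise. If the permutation p-value is
#' below `alpha`, the cutoff maximizing the absolute standardized
#' two-sample statistic over all admissible midpoints (each leaf at least
#' `min_leaf` samples) is chosen, the cutoff being the midpoint between the
#' two adjacent observed scores. Otherwise a no-split model predicting the
#' majority class is returned with a degenerate-fit flag.
#'
#' @param scores named numeric vector, one score per sample.
#' @param labels logical (or 0/1) responder labels, same order/names.
#' @param min_leaf minimum samples per leaf (default 3).
#' @param alpha association gate (default 0.05).
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible
#'   (default 1999).
#' @param exact_limit largest n for exact enumeration (default 12).
#' @param feature name of the score, carried into reports.
#' @param seed integer seed for the Monte-Carlo branch.
#' @return `threshold_classifier` with fields cutoff, direction
#'   (`greater_is_responder` / `lesser_is_responder`), p_value, degenerate,
#'   majority (fallback class), and fit metadata. Supports [predict()].
#' @export
fit_threshold_classifier <- function(scores, labels, min_leaf = 3, alpha = 0.05,
                                     n_perm = 1999, exact_limit = 12,
                                     feature = "score", seed = 1) {
  y <- as.logical(labels)
  if (anyNA(scores) || anyNA(y)) stop("missing scores or labels", call. = FALSE)
  n <- length(y)
  if (length(scores) != n) stop("scores and labels differ in length", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  min_leaf <- check_count(min_leaf, "min_leaf")
  if (n < 2 * min_leaf)
    stop("need at least 2 * min_leaf samples", call. = FALSE)

  p <- perm_linear_p(scores, y, n_perm, exact_limit, seed)
  majority <- mean(y) >= 0.5

  base <- list(feature = feature, min_leaf = min_leaf, alpha = alpha,
               n_perm = n_perm, seed = seed, p_value = p, n = n,
               majority = majority)
  if (p >= alpha) {
    return(structure(c(base, list(cutoff = NA_real_, direction = NA_character_,
                                  degenerate = TRUE)),
                     class = "threshold_classifier"))
  }

  ord <- order(scores)
  s <- scores[ord]; yo <- y[ord]
  ybar <- mean(yo); yvar <- sum((yo - ybar)^2)
  best_stat <- -Inf; best_cut <- NA_real_
  for (i in seq(min_leaf, n - min_leaf)) {
    if (s[i] == s[i + 1]) next  # no midpoint between tied scores
    n_l <- i
    t_split <- sum(yo[seq_len(i)])
    v <- yvar * n_l * (n - n_l) / (n * (n - 1))
    if (v <= 0) next
    stat <- abs(t_split - n_l * ybar) / sqrt(v)
    if (stat > best_stat + 1e-12) {
      best_stat <- stat
      best_cut <- (s[i] + s[i + 1]) / 2
    }
  }
  if (!is.finite(best_stat)) {
    return(structure(c(base, list(cutoff = NA_real_, direction = NA_character_,
                                  degenerate = TRUE)),
                     class = "threshold_classifier"))
  }
  left_resp <- mean(y[scores <= best_cut])
  right_resp <- mean(y[scores > best_cut])
  direction <- if (right_resp >= left_resp) "greater_is_responder"
               else "lesser_is_responder"
  structure(c(base, list(cutoff = best_cut, direction = direction,
                         degenerate = FALSE)),
            class = "threshold_classifier")
}

#' @export
print.threshold_classifier <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Threshold classifier [%s]: no split (p = %.4f); predicts %s\n",
                x$feature, x$p_value,
                if (x$majority) "responder" else "non-responder"))
  } else {
    cat(sprintf("Threshold classifier [%s]: cutoff %.4f (%s), p = %.4f\n",
                x$feature, x$cutoff, x$direction, x$p_value))
  }
  invisible(x)
}

#' Predict responder labels from a threshold classifier
#'
#' Scores exactly at the cutoff go to the `<= cutoff` side (fixed tie
#' convention). A degenerate (no-split) model predicts its majority class
#' for every sample. Missing scores raise an error naming the samples.
#'
#' @param object `threshold_classifier`.
#' @param newdata numeric score vector.
#' @param ... unused.
#' @return logical vector of predicted responder labels.
#' @export
predict.threshold_classifier <- function(object, newdata, ...) {
  if (anyNA(newdata)) {
    bad <- which(is.na(newdata))
    stop("missing score for sample(s): ",
         paste(utils::head(if (is.null(names(newdata))) bad else names(newdata)[bad], 5),
               collapse = ", "), call. = FALSE)
  }
  if (object$degenerate)
    return(rep(object$majority, length(newdata)))
  le <- newdata <= object$cutoff
  if (object$direction == "greater_is_responder") !le else le
}

#' Confusion-matrix metrics with explicit N/A for degenerate cases
#'
#' Accuracy, Matthews correlation coefficient and F1 from standard
#' confusion-matrix formulas. MCC is reported as `NA` (printed "N/A")
#' whenever any marginal of the confusion matrix is zero; F1 is `NA` when
#' no true or predicted positives exist, or precision + recall is zero.
#' `NA` is an explicit value here, never silently replaced by 0.
#'
#' @param pred,truth logical vectors of equal, non-zero length
#'   (TRUE = responder).
#' @return list(accuracy, mcc, f1, confusion).
#' @export
classification_metrics <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (!length(pred) || length(pred) != length(truth))
    stop("pred and truth must be non-empty and of equal length", call. = FALSE)
  tp <- sum(pred & truth);  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  acc <- (tp + tn) / length(pred)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marg == 0)) NA_real_
         else (tp * tn - fp * fn) / sqrt(prod(marg))
  f1 <- if ((tp + fn) == 0 || (tp + fp) == 0) NA_real_ else {
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    if (prec + rec == 0) NA_real_ else 2 * prec * rec / (prec + rec)
  }
  list(accuracy = acc, mcc = mcc, f1 = f1,
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(truth = c("resp", "nonresp"),
                                          pred = c("resp", "nonresp"))))
}

#' Nearest-centroid subtype call with an indeterminate margin
#'
#' Spearman correlation between the sample's expression over the centroid
#' genes and each centroid profile; the sample is assigned to the
#' highest-correlating centroid unless the margin between the top two
#' correlations is below `margin_threshold`, in which case the call is
#' `INDETERMINATE`. A sample constant over the centroid genes has undefined
#' correlations and is `INDETERMINATE` with a reason code.
#'
#' @param expr_sample named numeric vector covering the centroid gene list,
#'   or a genes x samples matrix (each column called separately).
#' @param centroids `centroid_model`.
#' @param margin_threshold indeterminate margin (default 0.1).
#' @return data.frame with one row per sample: sample_id, call, margin,
#'   rescue_source (`"none"`), reason, and one correlation column per
#'   subtype (`rho_<subtype>`).
#' @export
call_subtype <- function(expr_sample, centroids, margin_threshold = 0.1) {
  stopifnot(inherits(centroids, "centroid_model"))
  if (is.matrix(expr_sample)) {
    out <- lapply(colnames(expr_sample), function(s) {
      r <- call_subtype(expr_sample[, s], centroids, margin_threshold)
      r$sample_id <- s
      r
    })
    return(do.call(rbind, out))
  }
  missing <- setdiff(centroids$gene_ids, names(expr_sample))
  if (length(missing))
    stop("sample does not cover the centroid genes: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  x <- expr_sample[centroids$gene_ids]
  if (stats::sd(x) == 0) {
    rhos <- rep(NA_real_, ncol(centroids$profiles))
    call <- "INDETERMINATE"; margin <- NA_real_; reason <- "constant_sample"
  } else {
    rhos <- apply(centroids$profiles, 2, function(p)
      stats::cor(x, p, method = "spearman"))
    ord <- order(rhos, decreasing = TRUE)
    margin <- rhos[ord[1]] - rhos[ord[2]]
    if (margin < margin_threshold) {
      call <- "INDETERMINATE"; reason <- "margin_below_threshold"
    } else {
      call <- colnames(centroids$profiles)[ord[1]]; reason <- ""
    }
  }
  res <- data.frame(sample_id = "sample", call = call, margin = margin,
                    rescue_source = "none", reason = reason,
                    stringsAsFactors = FALSE)
  rho_df <- as.data.frame(as.list(stats::setNames(
    rhos, paste0("rho_", colnames(centroids$profiles)))))
  cbind(res, rho_df)
}

#' Rescue indeterminate subtype calls with predicted response
#'
#' Indeterminate samples predicted as non-responders get the
#' poor-prognosis subtype; those predicted as responders get the
#' good-prognosis subtype. Determinate calls are untouched;
#' `rescue_source` records the provenance of every changed call. A missing
#' prediction for an indeterminate sample is an error.
#'
#' @param calls data.frame from [call_subtype()].
#' @param predicted_response named logical vector (TRUE = predicted
#'   responder) covering every indeterminate sample.
#' @param centroids `centroid_model` (supplies the good/poor-prognosis
#'   subtype names).
#' @return the calls data.frame with indeterminate rows resolved.
#' @export
rescue_indeterminate <- function(calls, predicted_response, centroids) {
  stopifnot(inherits(centroids, "centroid_model"))
  ind <- which(calls$call == "INDETERMINATE")
  if (!length(ind)) return(calls)
  missing <- setdiff(calls$sample_id[ind], names(predicted_response))
  if (length(missing))
    stop("no prediction for indeterminate sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  pr <- predicted_response[calls$sample_id[ind]]
  calls$call[ind] <- ifelse(pr, centroids$good_prognosis, centroids$poor_prognosis)
  calls$rescue_source[ind] <- "network_classifier"
  calls
}

#' Serialize a threshold classifier to JSON
#'
#' @param classifier `threshold_classifier`.
#' @param path output path.
#' @export
write_classifier_json <- function(classifier, path) {
  jsonlite::write_json(unclass(classifier), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
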