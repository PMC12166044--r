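# Reference-batch harmonization and projection of new cohorts onto the
# reference module axes. Correction is reference-moment matching: each
# target gene is rescaled so its batch mean and SD equal the reference
# batch's; the reference itself is never altered. Projection re-uses the
# reference gene means, SDs and eigenvectors, so a new cohort's scores are
# expressed on the reference scale with no refitting.

#' Reference-batch correction by per-gene moment matching
#'
#' Transforms the target cohort gene-by-gene so its mean and standard
#' deviation match the reference batch: `x' = (x - m_t)/s_t * s_r + m_r`.
#' Reference values are unchanged by construction (reference-batch
#' semantics). Genes present in the target but not the reference are
#' dropped with a warning; genes with zero target SD skip the scale step.
#'
#' @param target genes x samples log2 matrix to correct.
#' @param reference genes x samples log2 reference matrix.
#' @return corrected target matrix over the shared gene universe, with a
#'   `harmonization` attribute recording the method.
#' @export
reference_batch_correct <- function(target, reference) {
  check_expr(target, "target"); check_expr(reference, "reference")
  extra <- setdiff(rownames(target), rownames(reference))
  if (length(extra)) {
    warning(length(extra), " gene(s) absent from the reference were dropped")
    target <- target[setdiff(rownames(target), extra), , drop = FALSE]
  }
  genes <- rownames(target)
  ref <- reference[genes, , drop = FALSE]
  m_t <- rowMeans(target); s_t <- apply(target, 1, stats::sd)
  m_r <- rowMeans(ref);    s_r <- apply(ref, 1, stats::sd)
  scale_f <- ifelse(s_t > 0, s_r / s_t, 1)  # zero target SD: location only
  out <- (target - m_t) * scale_f + m_r
  attr(out, "scale") <- attr(target, "scale")
  attr(out, "harmonization") <- "reference_moment_matching"
  out
}

#' Fit a projection model on the reference cohort
#'
#' Stores the module's reference gene means, standard deviations and the
#' oriented PC1/PC2 eigenvectors so any harmonized cohort can be scored on
#' the reference axes. Genes with zero reference variance are excluded at
#' fit time.
#'
#' @param reference genes x samples reference matrix.
#' @param genes module gene ids.
#' @return `projection_model` (also usable with [predict()]), containing
#'   the `eigengene_model` pieces plus the reference score table.
#' @export
fit_projection <- function(reference, genes) {
  eg <- module_eigengene(reference, genes)
  structure(list(
    gene_ids = eg$model$gene_ids,
    means = eg$model$means,
    sds = eg$model$sds,
    eigenvectors = eg$model$eigenvectors,
    explained = eg$model$explained,
    reference_scores = eg$scores
  ), class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  cat("Projection model over", length(x$gene_ids), "genes; reference PC1/PC2 explain",
      sprintf("%.1f%% / %.1f%%", 100 * x$explained[1], 100 * x$explained[2]), "\n")
  invisible(x)
}

#' Project a cohort onto reference module axes
#'
#' Standardizes each model gene by the *reference* mean and SD and
#' multiplies into the stored eigenvectors; nothing is refit. Missing model
#' genes are a hard error (projection onto a partial basis silently changes
#' the score scale).
#'
#' @param model `projection_model` from [fit_projection()].
#' @param cohort genes x samples matrix (harmonized to the reference).
#' @return data.frame (sample_id, PC1, PC2).
#' @export
project_scores <- function(model, cohort) {
  stopifnot(inherits(model, "projection_model"))
  check_expr(cohort, "cohort")
  missing <- setdiff(model$gene_ids, rownames(cohort))
  if (length(missing))
    stop("cohort is missing model genes: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10),
         call. = FALSE)
  z <- (cohort[model$gene_ids, , drop = FALSE] - model$means) / model$sds
  sc <- t(z) %*% model$eigenvectors
  data.frame(sample_id = colnames(cohort), PC1 = sc[, 1], PC2 = sc[, 2],
             stringsAsFactors = FALSE)
}

#' @export
predict.projection_model <- function(object, newdata, ...) {
  project_scores(object, newdata)
}

#' Serialize a projection model to JSON
#'
#' @param model `projection_model`.
#' @param path output path.
#' @export
write_projection_json <- function(model, path) {
  payload <- list(
    gene_ids = model$gene_ids,
    means = unname(model$means),
    sds = unname(model$sds),
    pc1 = model$eigenvectors[, 1],
    pc2 = model$eigenvectors[, 2],
    explained = model$explained
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a projection model from JSON
#'
#' @param path JSON path written by [write_projection_json()].
#' @return `projection_model` (without reference scores).
#' @export
read_projection_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    gene_ids = p$gene_ids,
    means = stats::setNames(p$means, p$gene_ids),
    sds = stats::setNames(p$sds, p$gene_ids),
    eigenvectors = cbind(p$pc1, p$pc2),
    explained = p$explained,
    reference_scores = NULL
  ), class = "projection_model")
}
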