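# Signature derivation and per-sample gene-set scoring. Modules are
# distilled into portable gene sets by module membership (kME), then
# samples are scored by rank-based single-sample enrichment (no
# cross-sample rescaling), kernel-CDF GSVA, or a plain mean of set genes
# with a median split.

#' Derive a gene set from a module's kME table
#'
#' Threshold mode keeps genes with kME strictly greater than `theta`;
#' top-n mode keeps the `n` highest-kME genes. Genes are ordered by
#' descending kME, ties by gene id, so regeneration from the same table is
#' deterministic. Genes with undefined kME are excluded.
#'
#' @param kme_values named numeric vector of kME over the module's genes.
#' @param name gene-set name.
#' @param mode `"threshold"` or `"top_n"`.
#' @param theta kME cutoff (threshold mode).
#' @param n set size (top-n mode).
#' @return list with `name`, `genes` (ordered ids), `provenance`.
#' @export
derive_geneset_by_kme <- function(kme_values, name, mode = c("threshold", "top_n"),
                                  theta = 0.9, n = 3) {
  mode <- match.arg(mode)
  kv <- kme_values[!is.na(kme_values)]
  ord <- order(-kv, names(kv))
  kv <- kv[ord]
  genes <- if (mode == "threshold") names(kv)[kv > theta]
           else names(kv)[seq_len(min(n, length(kv)))]
  if (!length(genes))
    stop(sprintf("no genes selected (max kME observed: %.4f)", max(kv)),
         call. = FALSE)
  list(name = name, genes = genes,
       provenance = if (mode == "threshold")
         list(mode = "kme_threshold", theta = theta)
       else list(mode = "kme_top_n", n = n))
}

# Descending-order walk shared by the single-sample scorers: genes ordered
# by decreasing statistic, in-set steps weighted by rank_value^exponent
# (rank_value = ascending rank, so the top gene carries the largest mass),
# out-of-set steps uniform.
walk_stats <- function(stat, in_set, exponent) {
  n <- length(stat)
  r <- rank(stat)                      # ascending; average ties
  ord <- order(-stat, names(stat))     # walk from the top
  in_ord <- in_set[ord]
  w <- r[ord]^exponent
  w[!in_ord] <- 0
  denom_in <- sum(w)
  if (denom_in == 0) stop("gene set carries no rank mass", call. = FALSE)
  cdf_in <- cumsum(w) / denom_in
  cdf_out <- cumsum(!in_ord) / (n - sum(in_ord))
  cdf_in - cdf_out
}

#' Single-sample GSEA score
#'
#' For each sample, genes in the universe are ranked by expression
#' (descending, average ranks for ties) and the score is the sum over the
#' ordered list of the difference between the weighted cumulative in-set
#' rank mass (weights `rank^exponent`) and the uniform out-of-set
#' cumulative mass. No cross-sample normalization is applied, so scores are
#' comparable only within the fixed universe. Being rank-based, the score
#' is invariant to any strictly monotone per-sample transform.
#'
#' @param expr genes x samples matrix.
#' @param gene_set character vector of set genes, or the list from
#'   [derive_geneset_by_kme()].
#' @param universe gene ids forming the ranking universe (default: all rows
#'   of `expr`); the set must be contained in it.
#' @param exponent rank-weighting exponent (default 0.25).
#' @return named numeric per-sample score vector.
#' @export
ssgsea_score <- function(expr, gene_set, universe = rownames(expr),
                         exponent = 0.25) {
  check_expr(expr)
  if (is.list(gene_set)) gene_set <- gene_set$genes
  bad <- setdiff(universe, rownames(expr))
  if (length(bad))
    stop("universe genes absent from expr: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  off <- setdiff(gene_set, universe)
  if (length(off))
    stop("gene set outside the universe: ", paste(utils::head(off, 5), collapse = ", "),
         call. = FALSE)
  if (length(gene_set) >= length(universe))
    stop("gene set must be a proper subset of the universe", call. = FALSE)
  sub <- expr[universe, , drop = FALSE]
  in_set <- universe %in% gene_set
  names(in_set) <- universe
  apply(sub, 2, function(x) {
    names(x) <- universe
    sum(walk_stats(x, in_set, exponent))
  })
}

#' GSVA-style gene-set scores
#'
#' Per gene, a Gaussian-kernel cumulative density across samples (bandwidth
#' = population SD / 4) turns expression into a sample-relative statistic;
#' per sample, genes are ranked by that statistic and a Kolmogorov-Smirnov
#' random walk is run for each set with the symmetric rank weight
#' `|N/2 - rank|`. With `mx_diff = TRUE` the enrichment score is the signed
#' sum of the maximum and minimum walk deviations; otherwise the deviation
#' largest in magnitude.
#'
#' @param expr genes x samples matrix with >= 3 samples (the kernel CDF is
#'   cross-sample).
#' @param gene_sets named list of character vectors.
#' @param kcdf only `"Gaussian"` is implemented.
#' @param mx_diff logical (default TRUE).
#' @return samples x sets score matrix.
#' @export
gsva_score <- function(expr, gene_sets, kcdf = "Gaussian", mx_diff = TRUE) {
  check_expr(expr)
  kcdf <- match.arg(kcdf)
  if (ncol(expr) < 3) stop("gsva_score requires >= 3 samples", call. = FALSE)
  small <- vapply(gene_sets, length, 0L) < 2
  if (any(small))
    warning(sum(small), " gene set(s) smaller than 2 genes are still scored")
  n_genes <- nrow(expr)

  # gene-level kernel CDF statistic; population SD so sample duplication
  # leaves the statistic (and hence all scores) unchanged
  z <- t(apply(expr, 1, function(x) {
    h <- sd_pop(x) / 4
    if (h == 0) return(rep(0.5, length(x)))
    vapply(x, function(xi) mean(stats::pnorm((xi - x) / h)), 0)
  }))
  dimnames(z) <- dimnames(expr)

  scores <- sapply(gene_sets, function(set) {
    set <- intersect(set, rownames(expr))
    if (!length(set)) return(rep(NA_real_, ncol(expr)))
    in_set <- rownames(expr) %in% set
    apply(z, 2, function(col) {
      r <- rank(col)
      s <- abs(n_genes / 2 - r)                 # symmetric rank weight
      ord <- order(-col, rownames(expr))
      io <- in_set[ord]; w <- s[ord]
      w[!io] <- 0
      d <- cumsum(w) / sum(w) - cumsum(!io) / (n_genes - sum(io))
      if (mx_diff) max(d) + min(d) else d[which.max(abs(d))]
    })
  })
  rownames(scores) <- colnames(expr)
  scores
}

#' Mean expression score with median split
#'
#' Per-sample mean over the set genes; samples are labeled `"high"` or
#' `"low"` by the cohort median, with scores exactly at the median going to
#' `"low"` (deterministic tie rule). A degenerate cohort where all scores
#' are equal labels everything `"low"` with a warning. A singleton set
#' realizes a single-gene hub classifier.
#'
#' @param expr genes x samples matrix.
#' @param gene_set character vector or gene-set list.
#' @return data.frame (sample_id, score, label).
#' @export
mean_z_score <- function(expr, gene_set) {
  check_expr(expr)
  if (is.list(gene_set)) gene_set <- gene_set$genes
  missing <- setdiff(gene_set, rownames(expr))
  if (length(missing))
    stop("gene set members absent from expr: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  score <- colMeans(expr[gene_set, , drop = FALSE])
  med <- stats::median(score)
  label <- ifelse(score > med, "high", "low")
  if (all(label == "low"))
    warning("degenerate median split: all scores at or below the median")
  data.frame(sample_id = colnames(expr), score = score, label = label,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Over-representation of a module in a gene-set collection
#'
#' Hypergeometric upper-tail test of the overlap between the module and
#' each set, restricted to the stated universe, with Benjamini-Yekutieli
#' adjustment across the collection and a significance flag at
#' `fdr < 0.05`.
#'
#' @param module_genes character vector (must be contained in `universe`).
#' @param gene_sets named list of character vectors.
#' @param universe character vector of universe gene ids.
#' @param fdr_cutoff significance cutoff on the BY-adjusted p (default 0.05).
#' @return data.frame (set, overlap, k, K, p, fdr_by, significant), ordered
#'   by p.
#' @export
overrepresentation_test <- function(module_genes, gene_sets, universe,
                                    fdr_cutoff = 0.05) {
  if (length(setdiff(module_genes, universe)))
    stop("module genes must be contained in the universe", call. = FALSE)
  n_u <- length(universe)
  k <- length(module_genes)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    ov <- length(intersect(module_genes, set))
    p <- stats::phyper(ov - 1, length(set), n_u - length(set), k,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, k = k, K = length(set), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr_by <- stats::p.adjust(out$p, method = "BY")
  out$significant <- out$fdr_by < fdr_cutoff
  out[order(out$p, out$set), , drop = FALSE]
}
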