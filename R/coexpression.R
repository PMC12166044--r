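# Reference co-expression network construction and module discovery.
#
# The network is a signed-hybrid weighted network: biweight midcorrelations
# between genes are truncated at zero and raised to a soft-threshold power,
# so only positively co-expressed genes are connected. Modules are branches
# of an average-linkage tree on topological-overlap dissimilarity, validated
# by a density-based permutation gate and subsampling stability.

#' Select the most variable genes
#'
#' Keeps the `n` genes with the highest per-gene variance. Ties at the
#' cutoff are broken by higher mean, then lexicographic gene id, so the
#' selection is deterministic.
#'
#' @param expr genes x samples log2 matrix.
#' @param n number of genes to keep.
#' @return the row-subset matrix, original sample order preserved, rows
#'   ordered as in the input.
#' @export
select_variable_genes <- function(expr, n) {
  check_expr(expr)
  n <- check_count(n, "n")
  if (n > nrow(expr)) stop("n exceeds the gene count", call. = FALSE)
  v <- apply(expr, 1, stats::var)
  m <- rowMeans(expr)
  ord <- order(-v, -m, rownames(expr))
  keep <- sort(ord[seq_len(n)])
  expr[keep, , drop = FALSE]
}

# Biweight transform of one vector: returns the centered, weighted values
# whose normalized cross-products are bicor. MAD = 0 falls back to the
# Pearson transform (plain centering); a constant vector returns all zeros,
# which downstream code reports as an undefined correlation (NA).
bicor_transform <- function(x) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 == 0) {
    a <- x - mean(x)
  } else {
    u <- (x - med) / (9 * mad0)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    a <- (x - med) * w
  }
  a
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation using Tukey biweights with the standard 9-MAD outlier
#' cutoff. A vector whose median absolute deviation is zero falls back to
#' Pearson weighting for that vector; a constant vector yields `NA`
#' (undefined correlation, deliberately distinct from 0).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or `NA` if either side is constant.
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("bicor requires length >= 3", call. = FALSE)
  a <- bicor_transform(x); b <- bicor_transform(y)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  max(-1, min(1, sum(a * b) / (na * nb)))
}

# All pairwise bicors between the rows of a matrix, vectorized through one
# crossproduct of the row-wise biweight transforms.
bicor_rows <- function(mat) {
  a <- t(apply(mat, 1, bicor_transform))
  nrm <- sqrt(rowSums(a^2))
  bad <- nrm == 0
  nrm[bad] <- 1
  a <- a / nrm
  r <- tcrossprod(a)
  r[r > 1] <- 1; r[r < -1] <- -1
  if (any(bad)) { r[bad, ] <- NA_real_; r[, bad] <- NA_real_ }
  diag(r) <- ifelse(bad, NA_real_, 1)
  dimnames(r) <- list(rownames(mat), rownames(mat))
  r
}

#' Construct a weighted network object
#'
#' @param adjacency symmetric numeric matrix with entries in `[0, 1]`; the
#'   diagonal is forced to zero (self-edges carry no information in the
#'   concept statistics).
#' @param power soft-threshold power used (metadata).
#' @param flavor network flavor label.
#' @return `weighted_network` object.
#' @export
weighted_network <- function(adjacency, power = NA_real_,
                             flavor = "signed_hybrid") {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric", call. = FALSE)
  diag(adjacency) <- 0
  if (any(adjacency < 0 | adjacency > 1, na.rm = TRUE))
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  structure(list(adjacency = adjacency, gene_ids = rownames(adjacency),
                 power = power, flavor = flavor),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("Weighted network (", x$flavor, "): ", nrow(x$adjacency), " genes, power ",
      x$power, "\n", sep = "")
  invisible(x)
}

# Accept either a weighted_network or a bare adjacency matrix.
as_adjacency <- function(net) {
  if (inherits(net, "weighted_network")) net$adjacency
  else { diag(net) <- 0; net }
}

#' Signed-hybrid soft-threshold adjacency
#'
#' `a_ij = max(bicor_ij, 0) ^ power`: negative correlations are truncated to
#' zero before powering, the diagonal is zero.
#'
#' @param expr genes x samples log2 matrix with >= 3 samples.
#' @param power soft-threshold power (> 0; the reference build uses 5).
#' @param flavor only `"signed_hybrid"` is implemented.
#' @return `weighted_network`.
#' @export
adjacency <- function(expr, power = 5, flavor = "signed_hybrid") {
  check_expr(expr)
  if (ncol(expr) < 3) stop("adjacency requires >= 3 samples", call. = FALSE)
  if (!is.numeric(power) || power <= 0)
    stop("power must be positive", call. = FALSE)
  flavor <- match.arg(flavor)
  r <- bicor_rows(expr)
  a <- pmax(r, 0)^power
  a[is.na(a)] <- 0  # constant genes are unconnected
  diag(a) <- 0
  weighted_network(a, power = power, flavor = flavor)
}

#' Topological-overlap dissimilarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i` the weighted connectivity; returns `1 - TOM` with a zero diagonal.
#' High overlap means two genes share the same neighborhood in addition to
#' any direct edge.
#'
#' @param net `weighted_network` or adjacency matrix.
#' @return symmetric dissimilarity matrix in `[0, 1]`.
#' @export
topological_overlap <- function(net) {
  a <- as_adjacency(net)
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  d <- 1 - tom
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# Best Jaccard overlap of set a against a list of sets.
best_jaccard <- function(a, sets) {
  if (!length(sets)) return(0)
  max(vapply(sets, function(b)
    length(intersect(a, b)) / length(union(a, b)), 0))
}

# Recursive branch split: accept the binary split at a subtree root when
# both children can host a module and the root merge height stands clear of
# the children's internal heights. deep_split in 0..4 lowers the required
# relative gap (0.25 down to 0.05), producing progressively finer modules.
split_branch <- function(d, items, min_size, gap_frac) {
  n <- length(items)
  if (n < 2 * min_size) return(list(items))
  hc <- stats::hclust(stats::as.dist(d[items, items, drop = FALSE]), "average")
  h0 <- max(hc$height)
  if (h0 <= 0) return(list(items))
  cl <- stats::cutree(hc, k = 2)
  g1 <- items[cl == 1]; g2 <- items[cl == 2]
  if (length(g1) < min_size || length(g2) < min_size) return(list(items))
  sub_h <- function(g) {
    if (length(g) < 2) return(0)
    max(stats::hclust(stats::as.dist(d[g, g, drop = FALSE]), "average")$height)
  }
  gap <- h0 - max(sub_h(g1), sub_h(g2))
  if (gap / h0 < gap_frac) return(list(items))
  c(split_branch(d, g1, min_size, gap_frac),
    split_branch(d, g2, min_size, gap_frac))
}

#' Detect modules by dynamic branch cutting
#'
#' Average-linkage hierarchical clustering of a topological-overlap
#' dissimilarity, followed by a simplified dynamic hybrid cut: a static cut
#' at `cut_height` defines the coarse branches, each branch is recursively
#' split where a merge height stands clear of its children (the required
#' relative gap shrinks as `deep_split` grows), clusters under `min_size`
#' are dissolved to label 0, and an optional PAM-like stage reassigns
#' unlabeled genes to the module with the smallest average dissimilarity
#' (when that average is below `cut_height`). Module ids are contiguous
#' positive integers ordered by decreasing size; 0 means unassigned.
#'
#' @param dissim square symmetric dissimilarity matrix with gene dimnames.
#' @param min_size minimum module size (default 30).
#' @param deep_split split sensitivity, integer 0-4 (default 2).
#' @param cut_height static cut height (default 0.995).
#' @param pam_stage logical; run the reassignment stage (default TRUE).
#' @return `module_assignment`: labels (named integer vector),
#'   module_sizes, dendrogram_order and the parameters used.
#' @export
detect_modules <- function(dissim, min_size = 30, deep_split = 2,
                           cut_height = 0.995, pam_stage = TRUE) {
  if (!is.matrix(dissim) || nrow(dissim) != ncol(dissim))
    stop("dissim must be a square matrix", call. = FALSE)
  genes <- rownames(dissim)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(dissim)))
  dimnames(dissim) <- list(genes, genes)
  min_size <- check_count(min_size, "min_size")
  deep_split <- check_count(deep_split, "deep_split", min = 0L)
  if (deep_split > 4L) stop("deep_split must be in 0..4", call. = FALSE)
  n <- length(genes)
  labels <- stats::setNames(rep(0L, n), genes)

  if (n < min_size) {
    warning("fewer genes than min_size; everything unassigned")
    return(structure(list(labels = labels, module_sizes = integer(0),
                          dendrogram_order = seq_len(n),
                          params = list(min_size = min_size,
                                        deep_split = deep_split,
                                        cut_height = cut_height,
                                        pam_stage = pam_stage)),
                     class = "module_assignment"))
  }

  hc <- stats::hclust(stats::as.dist(dissim), "average")
  static <- stats::cutree(hc, h = cut_height)
  gap_frac <- 0.25 - 0.05 * deep_split

  clusters <- list()
  for (cl in unique(static)) {
    items <- genes[static == cl]
    if (length(items) < min_size) next
    clusters <- c(clusters, split_branch(dissim, items, min_size, gap_frac))
  }
  clusters <- Filter(function(g) length(g) >= min_size, clusters)

  if (length(clusters)) {
    # order by decreasing size, ties by first gene id for determinism
    ord <- order(-vapply(clusters, length, 0L),
                 vapply(clusters, function(g) min(g), ""))
    clusters <- clusters[ord]
    for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  }

  if (pam_stage && length(clusters)) {
    unassigned <- names(labels)[labels == 0L]
    for (g in unassigned) {
      avg <- vapply(clusters, function(set) mean(dissim[g, set]), 0)
      if (min(avg) < cut_height) labels[g] <- which.min(avg)
    }
    # relabel: PAM can change sizes
    sizes <- table(labels[labels > 0L])
    remap <- order(-as.integer(sizes), names(sizes))
    new <- stats::setNames(seq_along(remap), names(sizes)[remap])
    labels[labels > 0L] <- new[as.character(labels[labels > 0L])]
  }

  sizes <- table(factor(labels[labels > 0L]))
  structure(list(
    labels = labels,
    module_sizes = stats::setNames(as.integer(sizes), names(sizes)),
    dendrogram_order = hc$order,
    params = list(min_size = min_size, deep_split = deep_split,
                  cut_height = cut_height, pam_stage = pam_stage)
  ), class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("Module assignment:", length(x$module_sizes), "modules over",
      length(x$labels), "genes (", sum(x$labels == 0L), "unassigned )\n")
  if (length(x$module_sizes))
    print(x$module_sizes)
  invisible(x)
}

#' Gene ids belonging to one module
#'
#' @param assignment `module_assignment`.
#' @param module module id.
#' @return character vector of gene ids.
#' @export
module_genes <- function(assignment, module) {
  names(assignment$labels)[assignment$labels == module]
}

#' Module eigengene: first principal axes of a module's expression
#'
#' Genes are centered and scaled by their own mean and standard deviation;
#' the standardized samples x genes matrix is decomposed by SVD. PC1 (the
#' eigengene) is oriented so it correlates non-negatively with the module's
#' mean standardized expression, making the sign reproducible across
#' platforms and decompositions. Constant genes are dropped with a warning.
#'
#' @param expr genes x samples log2 matrix.
#' @param genes module gene ids (>= 2 usable genes required).
#' @return list with `model` (an `eigengene_model`: gene means, sds,
#'   oriented eigenvectors for PC1/PC2, explained variance fractions) and
#'   `scores`, a data.frame (sample_id, PC1, PC2).
#' @export
module_eigengene <- function(expr, genes) {
  check_expr(expr)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("genes absent from expr: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  sub <- expr[genes, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped before decomposition")
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(sub) < 2) stop("need >= 2 non-constant genes", call. = FALSE)
  if (ncol(sub) < 3) stop("need >= 3 samples", call. = FALSE)
  mus <- rowMeans(sub)
  z <- (sub - mus) / sds              # genes x samples, standardized
  sv <- svd(t(z), nu = 2, nv = 2)     # samples x genes
  ev <- sv$v[, 1:2, drop = FALSE]
  scores <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2)
  # orient PC1 toward the mean standardized expression
  avg <- colMeans(z)
  s1 <- sum(scores[, 1] * avg)
  if (s1 < 0) { ev[, 1] <- -ev[, 1]; scores[, 1] <- -scores[, 1] }
  expl <- sv$d^2 / sum(sv$d^2)
  model <- structure(list(
    gene_ids = rownames(sub), means = mus, sds = sds,
    eigenvectors = ev, explained = expl[1:2]
  ), class = "eigengene_model")
  list(model = model,
       scores = data.frame(sample_id = colnames(sub),
                           PC1 = scores[, 1], PC2 = scores[, 2],
                           stringsAsFactors = FALSE))
}

#' @export
print.eigengene_model <- function(x, ...) {
  cat("Eigengene model:", length(x$gene_ids), "genes; PC1/PC2 explain",
      sprintf("%.1f%% / %.1f%%", 100 * x$explained[1], 100 * x$explained[2]), "\n")
  invisible(x)
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's expression profile with the module
#' eigengene score vector. High kME means the gene's pattern closely mirrors
#' the module summary. Constant genes get `NA` and are excluded from
#' rankings.
#'
#' @param expr genes x samples matrix.
#' @param eigengene_scores numeric per-sample vector (PC1), or the `scores`
#'   data.frame from [module_eigengene()].
#' @return named numeric vector, one kME per gene (NA where undefined).
#' @export
kme <- function(expr, eigengene_scores) {
  check_expr(expr)
  if (is.data.frame(eigengene_scores)) {
    v <- stats::setNames(eigengene_scores$PC1, eigengene_scores$sample_id)
  } else v <- eigengene_scores
  if (!is.null(names(v))) {
    if (!all(colnames(expr) %in% names(v)))
      stop("eigengene scores missing for some samples", call. = FALSE)
    v <- v[colnames(expr)]
  } else if (length(v) != ncol(expr))
    stop("eigengene score length does not match sample count", call. = FALSE)
  sds <- apply(expr, 1, stats::sd)
  out <- rep(NA_real_, nrow(expr))
  ok <- sds > 0
  out[ok] <- as.vector(stats::cor(t(expr[ok, , drop = FALSE]), v))
  stats::setNames(out, rownames(expr))
}

# Mean off-diagonal adjacency of a gene subset (== weighted density of the
# subnetwork, since the diagonal is zero).
subnet_density <- function(a, genes) {
  s <- a[genes, genes]
  sum(s) / (length(genes) * (length(genes) - 1))
}

#' Topological-significance gate for modules
#'
#' Compares density-based statistics of each module's subnetwork (weighted
#' density and mean adjacency, which coincide for a zero-diagonal network
#' and are both reported) to `n_random` equally sized gene sets drawn
#' without replacement from the analysis universe. For each statistic,
#' `Z = (observed - mean_random) / sd_random`; a module passes when the
#' median Z across statistics is at least `z_min` (default 2).
#'
#' @param expr genes x samples matrix over the analysis universe.
#' @param assignment `module_assignment`.
#' @param n_random number of random sets per module (default 100).
#' @param power soft-threshold power used to build the network when `net`
#'   is not supplied.
#' @param z_min pass threshold on the median Z (default 2).
#' @param net optional precomputed `weighted_network` over the universe.
#' @param seed integer seed for the random sets.
#' @return data.frame (module, size, observed_density, median_z, pass).
#' @export
topological_significance <- function(expr, assignment, n_random = 100,
                                     power = 5, z_min = 2, net = NULL,
                                     seed = 1) {
  n_random <- check_count(n_random, "n_random")
  if (is.null(net)) net <- adjacency(expr, power = power)
  a <- as_adjacency(net)
  universe <- rownames(a)
  mods <- names(assignment$module_sizes)
  with_seed(seed, {
    res <- lapply(mods, function(m) {
      genes <- module_genes(assignment, as.integer(m))
      obs <- subnet_density(a, genes)
      null <- vapply(seq_len(n_random), function(i)
        subnet_density(a, sample(universe, length(genes))), 0)
      zs <- vapply(c(density = obs, mean_adjacency = obs), function(o) {
        s <- stats::sd(null)
        if (s == 0) {
          warning("zero null sd in topological significance for module ", m)
          if (o > mean(null)) Inf else -Inf
        } else (o - mean(null)) / s
      }, 0)
      data.frame(module = as.integer(m), size = length(genes),
                 observed_density = obs, median_z = stats::median(zs),
                 pass = stats::median(zs) >= z_min)
    })
    do.call(rbind, res)
  })
}

#' Module stability under sample subsampling
#'
#' Repeats module detection on random subsets of samples and scores each
#' reference module by its best Jaccard overlap with any module found in
#' each iteration; the stability score is the mean over iterations.
#' Iterations that find no module contribute overlap 0.
#'
#' @param expr genes x samples matrix.
#' @param params list of detection parameters: `power`, `min_size`,
#'   `deep_split`, `cut_height`, `pam_stage` (missing entries take the
#'   defaults of [adjacency()] / [detect_modules()]).
#' @param n_iter number of subsampling iterations (default 50).
#' @param frac fraction of samples per iteration (default 0.632).
#' @param seed integer seed.
#' @return named numeric vector: stability in `[0, 1]` per reference module.
#' @export
module_stability <- function(expr, params = list(), n_iter = 50, frac = 0.632,
                             seed = 1) {
  check_expr(expr)
  n_iter <- check_count(n_iter, "n_iter")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]", call. = FALSE)
  p <- utils::modifyList(list(power = 5, min_size = 30, deep_split = 2,
                              cut_height = 0.995, pam_stage = TRUE), params)
  detect <- function(mat) {
    net <- adjacency(mat, power = p$power)
    asg <- detect_modules(topological_overlap(net), min_size = p$min_size,
                          deep_split = p$deep_split, cut_height = p$cut_height,
                          pam_stage = p$pam_stage)
    lapply(names(asg$module_sizes), function(m) module_genes(asg, as.integer(m)))
  }
  ref_sets <- detect(expr)
  if (!length(ref_sets)) {
    warning("no modules detected on the full data")
    return(stats::setNames(numeric(0), character(0)))
  }
  n_keep <- max(3L, round(frac * ncol(expr)))
  with_seed(seed, {
    overlaps <- matrix(0, n_iter, length(ref_sets))
    for (it in seq_len(n_iter)) {
      cols <- if (n_keep >= ncol(expr)) seq_len(ncol(expr))
              else sample(ncol(expr), n_keep)
      found <- detect(expr[, cols, drop = FALSE])
      overlaps[it, ] <- vapply(ref_sets, best_jaccard, 0, sets = found)
    }
    stats::setNames(colMeans(overlaps), paste0("module", seq_along(ref_sets)))
  })
}
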