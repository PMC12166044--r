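# Patient-specific network decomposition. A single sample's network is
# estimated by linear interpolation against the reference cohort: with
# e(S) the edge function over sample set S and N the reference size,
#   edges(q) = (N + 1) * e(reference + q) - N * e(reference).
# The signed result is converted to a standard adjacency by removing
# negative edges and scaling the rest into [0, 1], after which the usual
# weighted-network concept statistics apply.

#' Single-sample network edge weights by linear interpolation
#'
#' Computes `(N + 1) * e(reference with the sample included) - N *
#' e(reference)` where `e` is the edge function applied gene-by-gene
#' (default: biweight midcorrelation, matching the reference network;
#' `"pearson"` is available, and any function mapping a genes x samples
#' matrix to a symmetric matrix may be passed). Edges involving a gene that
#' is constant in the pooled set are undefined and returned as `NA`.
#'
#' @param sample named numeric vector, same gene order as `reference`.
#' @param reference genes x samples matrix (N >= 3).
#' @param edge_function `"bicor"`, `"pearson"`, or a function.
#' @return signed symmetric genes x genes matrix with attribute `N`
#'   (the reference size used).
#' @export
lioness_edge_weights <- function(sample, reference, edge_function = "bicor") {
  check_expr(reference, "reference")
  n_ref <- ncol(reference)
  if (n_ref < 3) stop("reference must have >= 3 samples", call. = FALSE)
  if (length(sample) != nrow(reference))
    stop("sample length must match the reference gene count", call. = FALSE)
  if (!is.null(names(sample)) && !identical(names(sample), rownames(reference)))
    stop("sample gene order must match the reference", call. = FALSE)

  efun <- if (is.function(edge_function)) edge_function
  else switch(match.arg(edge_function, c("bicor", "pearson")),
              bicor = bicor_rows,
              pearson = function(m) stats::cor(t(m)))
  e_ref <- efun(reference)
  pooled <- cbind(reference, q = sample)
  e_all <- efun(pooled)
  out <- (n_ref + 1) * e_all - n_ref * e_ref
  dimnames(out) <- list(rownames(reference), rownames(reference))
  attr(out, "N") <- n_ref
  out
}

#' Convert a signed edge matrix to a standard adjacency
#'
#' Negative edges are removed (set to 0) and the remaining positive weights
#' are divided by the maximum positive weight so the result lies in
#' `[0, 1]` with a zero diagonal; the scaling constant is recorded in the
#' network's provenance. An all-nonpositive input yields the zero network
#' with a warning. The conversion is idempotent: a matrix already in
#' `[0, 1]` with maximum 1 passes through unchanged.
#'
#' @param signed symmetric numeric matrix (NA edges are treated as absent).
#' @return `weighted_network` with `conversion` provenance
#'   (negatives_removed, scale_constant, n_undefined).
#' @export
to_adjacency <- function(signed) {
  if (!isSymmetric(unname(signed), tol = 1e-8))
    stop("input must be symmetric", call. = FALSE)
  n_na <- sum(is.na(signed))
  signed[is.na(signed)] <- 0
  diag(signed) <- 0
  neg <- sum(signed < 0)
  signed[signed < 0] <- 0
  mx <- max(signed)
  if (mx <= 0) {
    warning("no positive edges; returning the zero network")
    scale_c <- 1
  } else {
    scale_c <- mx
    signed <- signed / mx
  }
  net <- weighted_network(signed, flavor = "single_sample")
  net$conversion <- list(negatives_removed = neg, scale_constant = scale_c,
                         n_undefined = n_na)
  net
}

#' Gene-level network concepts
#'
#' For each gene i of a weighted network: connectivity
#' `k_i = sum_j a_ij`; maximum adjacency ratio
#' `MAR_i = sum_j a_ij^2 / sum_j a_ij` (undefined for an isolated gene);
#' clustering coefficient
#' `C_i = sum_{j != l} a_ij a_jl a_li / (k_i^2 - sum_j a_ij^2)`
#' (undefined when the denominator is zero). Undefined values are returned
#' as `NA`, never silently as zero.
#'
#' @param net `weighted_network` or adjacency matrix with >= 3 genes.
#' @return data.frame (gene_id, connectivity, mar, clustering).
#' @export
gene_features <- function(net) {
  a <- as_adjacency(net)
  n <- nrow(a)
  if (n < 3) stop("network must have >= 3 genes", call. = FALSE)
  k <- rowSums(a)
  sq <- rowSums(a^2)
  mar <- ifelse(k > 0, sq / k, NA_real_)
  tri <- diag(a %*% a %*% a)          # sum_{j,l} a_ij a_jl a_li
  denom <- k^2 - sq
  clustering <- ifelse(denom > 0, tri / denom, NA_real_)
  data.frame(gene_id = rownames(a) %||% sprintf("g%d", seq_len(n)),
             connectivity = k, mar = mar, clustering = clustering,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Whole-network concepts
#'
#' `density = sum_i k_i / (n (n - 1))`;
#' `centralization = n/(n - 2) * (max_i k_i / (n - 1) - density)`;
#' `heterogeneity = sd(k) / mean(k)` with the population SD. Heterogeneity
#' is undefined (`NA`) for an empty network.
#'
#' @param net `weighted_network` or adjacency matrix with >= 3 genes.
#' @return list(density, centralization, heterogeneity).
#' @export
whole_network_features <- function(net) {
  a <- as_adjacency(net)
  n <- nrow(a)
  if (n < 3) stop("network must have >= 3 genes", call. = FALSE)
  k <- rowSums(a)
  density <- sum(k) / (n * (n - 1))
  centralization <- n / (n - 2) * (max(k) / (n - 1) - density)
  heterogeneity <- if (mean(k) == 0) NA_real_ else sd_pop(k) / mean(k)
  list(density = density, centralization = centralization,
       heterogeneity = heterogeneity)
}

#' Patient-specific networks for a cohort over one module
#'
#' Runs the interpolation for every cohort sample against the reference,
#' restricted to the module genes, converts each signed result to an
#' adjacency, and collects gene-level and whole-network features.
#'
#' @param cohort genes x samples matrix (harmonized to the reference).
#' @param reference genes x samples reference matrix.
#' @param genes module gene ids.
#' @param edge_function passed to [lioness_edge_weights()].
#' @return list with `networks` (named list of `weighted_network`),
#'   `gene_features` (long data.frame: sample_id, gene_id, connectivity,
#'   mar, clustering) and `network_features` (data.frame: sample_id,
#'   density, centralization, heterogeneity).
#' @export
patient_networks <- function(cohort, reference, genes,
                             edge_function = "bicor") {
  check_expr(cohort, "cohort"); check_expr(reference, "reference")
  missing <- setdiff(genes, intersect(rownames(cohort), rownames(reference)))
  if (length(missing))
    stop("module genes absent from cohort or reference: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  ref <- reference[genes, , drop = FALSE]
  nets <- lapply(colnames(cohort), function(s) {
    signed <- lioness_edge_weights(cohort[genes, s], ref,
                                   edge_function = edge_function)
    suppressWarnings(to_adjacency(signed))
  })
  names(nets) <- colnames(cohort)
  gf <- do.call(rbind, lapply(names(nets), function(s) {
    cbind(sample_id = s, gene_features(nets[[s]]))
  }))
  nf <- do.call(rbind, lapply(names(nets), function(s) {
    as.data.frame(c(sample_id = s, whole_network_features(nets[[s]])))
  }))
  list(networks = nets, gene_features = gf, network_features = nf)
}

#' Write a patient network as an edge list with a JSON sidecar
#'
#' @param net `weighted_network` from [to_adjacency()].
#' @param path TSV path (gene_a, gene_b, weight for the upper triangle);
#'   a `.json` sidecar with sample/module/N/conversion provenance is
#'   written next to it.
#' @param meta named list merged into the sidecar.
#' @export
write_network_tsv <- function(net, path, meta = list()) {
  a <- as_adjacency(net)
  idx <- which(upper.tri(a), arr.ind = TRUE)
  df <- data.frame(gene_a = rownames(a)[idx[, 1]],
                   gene_b = colnames(a)[idx[, 2]],
                   weight = a[idx], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(meta, list(conversion = net$conversion))
  jsonlite::write_json(side, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
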