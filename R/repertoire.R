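# Immune-repertoire clonotype diversity. All metrics are functions of the
# clone-size distribution only: Shannon entropy (nats), evenness (entropy /
# ln(number of clonotypes)), D50 (fewest top clones holding half the
# reads), the Gini coefficient of the count distribution, and Gini-Simpson
# (1 - sum p^2). Read-depth confounding is handled by downsampling reads
# without replacement and taking per-metric medians over repetitions.

#' Diversity metrics of one clone-size vector
#'
#' @param counts positive integer read counts, one per clonotype.
#' @return list: shannon_entropy (nats), evenness (`NA` when fewer than 2
#'   clonotypes), d50_count, d50_fraction, gini, gini_simpson,
#'   n_clonotypes, total_reads.
#' @export
diversity_metrics <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("no clonotypes with positive counts", call. = FALSE)
  n <- length(counts)
  total <- sum(counts)
  p <- counts / total
  h <- -sum(p * log(p))
  evenness <- if (n > 1) h / log(n) else NA_real_
  sorted <- sort(p, decreasing = TRUE)
  d50 <- which(cumsum(sorted) >= 0.5)[1]
  cs <- sort(counts)
  gini <- sum((2 * seq_len(n) - n - 1) * cs) / (n * total)
  list(shannon_entropy = h, evenness = evenness,
       d50_count = as.integer(d50), d50_fraction = d50 / n,
       gini = gini, gini_simpson = 1 - sum(p^2),
       n_clonotypes = n, total_reads = total)
}

# Filter a long clonotype table by chain / isotype prefix.
filter_clonotypes <- function(table, chain = NULL, isotype = NULL) {
  if (!is.null(chain)) table <- table[table$chain %in% chain, , drop = FALSE]
  if (!is.null(isotype))
    table <- table[startsWith(table$isotype, isotype), , drop = FALSE]
  table
}

#' Per-sample diversity panel from a clonotype table
#'
#' Computes [diversity_metrics()] for every sample after optional chain /
#' isotype-class filtering (e.g. `chain = "IGH", isotype = "IGHG"` for the
#' IgG class). Samples with no clonotypes left after filtering get an
#' all-`NA` metrics row (flagged undefined rather than dropped silently).
#'
#' @param table data.frame (sample_id, clonotype_id, chain, isotype, reads).
#' @param chain optional chain filter (e.g. `"IGH"`).
#' @param isotype optional isotype-class prefix filter (e.g. `"IGHG"`).
#' @return data.frame, one row per sample present in `table`.
#' @export
repertoire_diversity <- function(table, chain = NULL, isotype = NULL) {
  samples <- unique(table$sample_id)
  filtered <- filter_clonotypes(table, chain, isotype)
  rows <- lapply(samples, function(s) {
    cnt <- filtered$reads[filtered$sample_id == s]
    if (!length(cnt) || sum(cnt) == 0) {
      data.frame(sample_id = s, shannon_entropy = NA_real_, evenness = NA_real_,
                 d50_count = NA_integer_, d50_fraction = NA_real_,
                 gini = NA_real_, gini_simpson = NA_real_,
                 n_clonotypes = 0L, total_reads = 0L, stringsAsFactors = FALSE)
    } else {
      cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
            as.data.frame(diversity_metrics(cnt)))
    }
  })
  do.call(rbind, rows)
}

#' Downsampled diversity metrics (median over repetitions)
#'
#' Each repetition draws `depth` reads without replacement from the
#' sample's read multiset (multivariate hypergeometric), recomputes the
#' diversity panel, and the per-metric median over repetitions is
#' reported. Samples whose total reads fall below `depth` are excluded
#' (the comparison would otherwise confound diversity with depth).
#'
#' @param table clonotype table (long format, as above).
#' @param depth target read depth (> 0); shipped per-biopsy defaults are
#'   8500 for Bx1 and 400 for Bx2, see [biopsy_downsampling_depths()].
#' @param n_reps repetitions (default 5).
#' @param chain,isotype optional filters, as in [repertoire_diversity()].
#' @param seed integer seed.
#' @return data.frame, one row per retained sample, with `downsampled =
#'   TRUE` and the depth recorded.
#' @export
downsampled_metrics <- function(table, depth, n_reps = 5, chain = NULL,
                                isotype = NULL, seed = 1) {
  depth <- check_count(depth, "depth")
  n_reps <- check_count(n_reps, "n_reps")
  filtered <- filter_clonotypes(table, chain, isotype)
  totals <- tapply(filtered$reads, filtered$sample_id, sum)
  keep <- names(totals)[!is.na(totals) & totals >= depth]
  with_seed(seed, {
    rows <- lapply(keep, function(s) {
      sub <- filtered[filtered$sample_id == s, , drop = FALSE]
      reps <- lapply(seq_len(n_reps), function(r) {
        if (sum(sub$reads) == depth) {
          cnt <- sub$reads
        } else {
          pool <- rep.int(seq_len(nrow(sub)), sub$reads)
          drawn <- sample(pool, depth)
          cnt <- tabulate(drawn, nbins = nrow(sub))
        }
        as.data.frame(diversity_metrics(cnt))
      })
      reps <- do.call(rbind, reps)
      med <- vapply(reps, stats::median, 0)
      cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
            as.data.frame(as.list(med)),
            data.frame(downsampled = TRUE, depth = depth))
    })
    if (!length(rows)) {
      warning("no samples reach the downsampling depth")
      return(NULL)
    }
    do.call(rbind, rows)
  })
}

#' Shipped per-biopsy downsampling depths
#'
#' The configured read depths used when comparing diversity between
#' response groups: 8500 reads for pre-treatment (Bx1) and 400 for
#' on-treatment (Bx2) biopsies.
#'
#' @return named integer vector `c(Bx1 = 8500, Bx2 = 400)`.
#' @export
biopsy_downsampling_depths <- function() c(Bx1 = 8500L, Bx2 = 400L)

#' Total reads per sample and chain (or isotype class)
#'
#' Sums read counts per grouping; groupings absent from the table are
#' absent from the result (not zero-filled). Suitable for correlating
#' immunoglobulin chain abundance with module eigengene scores.
#'
#' @param table clonotype table (long format).
#' @param by `"chain"` or `"isotype"`.
#' @return data.frame (sample_id, group, reads).
#' @export
class_abundance <- function(table, by = c("chain", "isotype")) {
  by <- match.arg(by)
  if (!nrow(table))
    return(data.frame(sample_id = character(), group = character(),
                      reads = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(table$reads,
                          by = list(sample_id = table$sample_id,
                                    group = table[[by]]),
                          FUN = sum)
  names(agg)[3] <- "reads"
  agg[order(agg$sample_id, agg$group), , drop = FALSE]
}

#' Read a clonotype table from TSV
#'
#' @param path TSV with columns sample_id, clonotype_id, chain, isotype,
#'   reads.
#' @return validated data.frame.
#' @export
read_clonotype_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "clonotype_id", "chain", "isotype", "reads")
  if (!all(need %in% names(df)))
    stop("clonotype table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$reads < 1)) stop("read counts must be >= 1", call. = FALSE)
  df$isotype[is.na(df$isotype)] <- ""
  df
}
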