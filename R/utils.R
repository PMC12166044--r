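#' @keywords internal
"_PACKAGE"

# Shared input checks. All user-facing errors go through stop(call. = FALSE)
# so messages name the offending argument, not internal frames.

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_expr <- function(expr, name = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop(sprintf("'%s' must be a numeric matrix (genes x samples)", name), call. = FALSE)
  if (anyNA(expr))
    stop(sprintf("'%s' contains missing values", name), call. = FALSE)
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr)))
    stop(sprintf("'%s' must have unique gene ids as rownames", name), call. = FALSE)
  if (is.null(colnames(expr)) || anyDuplicated(colnames(expr)))
    stop(sprintf("'%s' must have unique sample ids as colnames", name), call. = FALSE)
  invisible(expr)
}

# Deterministic local RNG: every generator takes a seed and restores the
# caller's RNG state on exit, so generation never perturbs a session.
with_seed <- function(seed, code) {
  seed <- check_count(seed, "seed", min = 0L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Population (n-denominator) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Write a matrix as a tab-separated table with an id column
#'
#' Genes (or features) as rows, a leading id column, sample ids as the
#' remaining header fields. The reader [read_expression_tsv()] inverts it.
#'
#' @param mat numeric matrix with rownames and colnames.
#' @param path output file path.
#' @param id_col header name for the row-id column.
#' @export
write_expression_tsv <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes-by-samples TSV written by [write_expression_tsv()]
#'
#' @param path file path; first column is the gene id, remaining columns are
#'   numeric sample values.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  check_expr(mat, "read matrix")
  mat
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
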