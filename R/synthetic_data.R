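# Synthetic cohorts with planted co-expression structure.
#
# The generative model is latent-factor linear-Gaussian: each module m has a
# per-sample latent factor f_m ~ N(0, 1); a gene g assigned to m is
#   x_gs = mu_g + lambda_g * f_ms + eps,  eps ~ N(0, noise_sd^2)
# on the log2 scale, with lambda_g > 0 (modules are coherently oriented, so a
# signed-hybrid correlation network sees them). Background genes are
# mu_g + eps. This is the minimal structure under which eigengenes, kME and
# co-expression modules are well defined and recoverable.

#' Generate a synthetic reference cohort with planted co-expression modules
#'
#' Emulates a large reference tumor cohort restricted to its most variable
#' genes: a handful of correlated gene modules of realistic sizes planted
#' among background genes. Module genes load positively on a per-module
#' latent factor; background genes are independent noise around a
#' gene-specific baseline.
#'
#' @param n_samples number of samples (default 150).
#' @param n_genes total genes including background (default 2000).
#' @param module_sizes integer vector of planted module sizes, largest first
#'   (default `c(469, 323, 190, 48, 42)`).
#' @param loading_range range of the (positive) factor loadings, drawn
#'   uniformly per gene (default `c(0.5, 1.5)`; with the default noise this
#'   yields true module-membership correlations spanning roughly 0.7-0.95,
#'   with a minority of genes above 0.9, as seen in real kME tables).
#' @param noise_sd residual standard deviation on the log2 scale
#'   (default 0.5).
#' @param baseline_range range of gene baseline means on the log2 scale.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `expr` (genes x samples matrix, log2 scale, attribute
#'   `scale = "log2"`) and `truth`, a `synthetic_truth` object holding the
#'   latent factors, loadings table, response-module id and threshold.
#' @export
generate_reference_cohort <- function(n_samples = 150, n_genes = 2000,
                                      module_sizes = c(469, 323, 190, 48, 42),
                                      loading_range = c(0.5, 1.5),
                                      noise_sd = 0.5,
                                      baseline_range = c(4, 10),
                                      seed = 1) {
  n_samples <- check_count(n_samples, "n_samples", min = 3L)
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  module_sizes <- vapply(module_sizes, check_count, 1L, name = "module_sizes")
  if (sum(module_sizes) > n_genes)
    stop("sum(module_sizes) exceeds n_genes", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be positive", call. = FALSE)

  n_mod <- length(module_sizes)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sample_ids <- sprintf("REF%03d", seq_len(n_samples))
  module <- rep(0L, n_genes)
  module[seq_len(sum(module_sizes))] <- rep(seq_len(n_mod), module_sizes)

  with_seed(seed, {
    factors <- matrix(stats::rnorm(n_samples * n_mod), n_samples, n_mod,
                      dimnames = list(sample_ids, paste0("module", seq_len(n_mod))))
    loading <- numeric(n_genes)
    in_mod <- module > 0L
    loading[in_mod] <- stats::runif(sum(in_mod), loading_range[1], loading_range[2])
    baseline <- stats::runif(n_genes, baseline_range[1], baseline_range[2])

    expr <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                   n_genes, n_samples, dimnames = list(gene_ids, sample_ids))
    expr <- expr + baseline
    for (m in seq_len(n_mod)) {
      idx <- which(module == m)
      expr[idx, ] <- expr[idx, ] + loading[idx] %o% factors[, m]
    }
    attr(expr, "scale") <- "log2"

    truth <- structure(list(
      latent_factors = factors,
      loadings = data.frame(gene_id = gene_ids, module = module,
                            loading = loading, stringsAsFactors = FALSE),
      gene_baselines = stats::setNames(baseline, gene_ids),
      module_sizes = stats::setNames(as.integer(module_sizes),
                                     paste0("module", seq_len(n_mod))),
      response_module = min(3L, n_mod),
      response_threshold = 0,
      noise_sd = noise_sd,
      loading_range = loading_range,
      seed = seed
    ), class = "synthetic_truth")
    list(expr = expr, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic cohort truth\n")
  cat("  modules:", paste(x$module_sizes, collapse = "/"),
      "genes among", nrow(x$loadings), "\n")
  cat("  response module:", x$response_module,
      " threshold:", x$response_threshold, "\n")
  invisible(x)
}

# Expression for arbitrary factor draws under a fixed truth object.
expr_from_factors <- function(truth, factors, sample_ids, noise_sd) {
  lo <- truth$loadings
  expr <- matrix(stats::rnorm(nrow(lo) * nrow(factors), sd = noise_sd),
                 nrow(lo), nrow(factors),
                 dimnames = list(lo$gene_id, sample_ids))
  expr <- expr + truth$gene_baselines[lo$gene_id]
  for (m in seq_along(truth$module_sizes)) {
    idx <- which(lo$module == m)
    expr[idx, ] <- expr[idx, ] + lo$loading[idx] %o% factors[, m]
  }
  attr(expr, "scale") <- "log2"
  expr
}

#' Generate a paired-biopsy clinical cohort tied to the reference truth
#'
#' Draws a small cohort of patients, each with a pre-treatment (Bx1) and an
#' on-treatment (Bx2) sample, generated from the same latent-factor model as
#' the reference. Response labels derive from the response module's Bx1
#' latent factor: responders sit at least `effect/2` above the truth's
#' threshold, non-responders at least `effect/2` below, so the two classes
#' are separated by a gap of width `effect` straddling the threshold.
#' Bx2 factors are correlated with Bx1 within patient and receive an
#' additive treatment shift on selected modules. A gene-wise batch
#' location/scale perturbation emulates a cohort measured on a different
#' platform, exercising harmonization.
#'
#' @param truth `synthetic_truth` from [generate_reference_cohort()].
#' @param n_patients number of patients (>= 4; default 13).
#' @param effect width of the latent-factor gap between classes (non-zero;
#'   default 2).
#' @param label_noise probability of flipping each response label
#'   (in `[0, 0.5)`; default 0).
#' @param responder_fraction fraction of patients drawn as responders
#'   (default 8/13, giving 8 responders among 13 patients).
#' @param within_patient_cor correlation of Bx1 and Bx2 latent factors for
#'   the same patient (default 0.8; not asserted, exposed as a knob).
#' @param treatment_shift additive Bx2 offset per module; a single number is
#'   applied to the response module only (default 1).
#' @param batch_shift_sd,batch_scale_range gene-wise batch location/scale
#'   perturbation applied to both biopsy matrices.
#' @param seed integer seed.
#' @return list with `bx1`, `bx2` (genes x patients matrices), `clinical`
#'   (one row per sample: sample_id, patient_id, biopsy, tissue,
#'   best_response, responder), and `truth`: the input truth augmented with
#'   the cohort's latent factors (`clinical_factors`, rows = sample ids),
#'   true labels before noise, and recorded label flips.
#' @export
generate_clinical_cohort <- function(truth, n_patients = 13, effect = 2,
                                     label_noise = 0,
                                     responder_fraction = 8 / 13,
                                     within_patient_cor = 0.8,
                                     treatment_shift = 1,
                                     batch_shift_sd = 0.3,
                                     batch_scale_range = c(0.8, 1.25),
                                     seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n_patients <- check_count(n_patients, "n_patients", min = 1L)
  if (n_patients < 4L)
    stop("n_patients must be >= 4 to form both classes with minimum leaf size 3",
         call. = FALSE)
  if (effect == 0) stop("effect must be non-zero", call. = FALSE)
  if (label_noise < 0 || label_noise >= 0.5)
    stop("label_noise must lie in [0, 0.5)", call. = FALSE)

  n_mod <- length(truth$module_sizes)
  rm_id <- truth$response_module
  thr <- truth$response_threshold
  n_resp <- max(1L, min(n_patients - 1L, round(responder_fraction * n_patients)))
  patient_ids <- sprintf("PT%02d", seq_len(n_patients))

  shift <- rep(0, n_mod)
  if (length(treatment_shift) == 1L) shift[rm_id] <- treatment_shift
  else shift[seq_along(treatment_shift)] <- treatment_shift

  with_seed(seed, {
    true_resp <- rep(c(TRUE, FALSE), c(n_resp, n_patients - n_resp))

    f1 <- matrix(stats::rnorm(n_patients * n_mod), n_patients, n_mod)
    f_resp <- ifelse(true_resp,
                     thr + effect / 2 + abs(stats::rnorm(n_patients)),
                     thr - effect / 2 - abs(stats::rnorm(n_patients)))
    f1[, rm_id] <- f_resp

    w <- within_patient_cor
    f2 <- w * f1 + sqrt(max(0, 1 - w^2)) *
      matrix(stats::rnorm(n_patients * n_mod), n_patients, n_mod)
    f2 <- sweep(f2, 2, shift, "+")

    s1 <- paste0(patient_ids, "_Bx1")
    s2 <- paste0(patient_ids, "_Bx2")
    rownames(f1) <- s1; rownames(f2) <- s2
    colnames(f1) <- colnames(f2) <- names(truth$module_sizes)

    bx1 <- expr_from_factors(truth, f1, s1, truth$noise_sd)
    bx2 <- expr_from_factors(truth, f2, s2, truth$noise_sd)

    n_genes <- nrow(bx1)
    b_shift <- stats::rnorm(n_genes, sd = batch_shift_sd)
    b_scale <- stats::runif(n_genes, batch_scale_range[1], batch_scale_range[2])
    bx1 <- bx1 * b_scale + b_shift
    bx2 <- bx2 * b_scale + b_shift
    attr(bx1, "scale") <- attr(bx2, "scale") <- "log2"

    flips <- stats::runif(n_patients) < label_noise
    responder <- xor(true_resp, flips)
    best <- ifelse(responder,
                   rep(c("SD", "PR"), length.out = n_patients)[order(order(-f_resp))],
                   "PD")
    tissue <- sample(c("Breast", "LymphNode", "Liver", "Lung"),
                     n_patients, replace = TRUE)

    clinical <- data.frame(
      sample_id = c(s1, s2),
      patient_id = rep(patient_ids, 2),
      biopsy = rep(c("Bx1", "Bx2"), each = n_patients),
      tissue = rep(tissue, 2),
      best_response = rep(best, 2),
      responder = rep(responder, 2),
      stringsAsFactors = FALSE
    )

    clin_truth <- truth
    clin_truth$clinical_factors <- rbind(f1, f2)
    clin_truth$true_responder <- stats::setNames(true_resp, patient_ids)
    clin_truth$label_flips <- stats::setNames(flips, patient_ids)
    clin_truth$effect <- effect
    clin_truth$treatment_shift <- shift

    list(bx1 = bx1, bx2 = bx2, clinical = clinical, truth = clin_truth)
  })
}

#' Generate per-sample immune-repertoire clonotype tables
#'
#' Produces long-format clonotype counts (sample_id, clonotype_id, chain,
#' isotype, reads) for the immunoglobulin chains IGH/IGK/IGL, with IGH reads
#' split over IgG/IgM/IgA isotype classes. Per-sample total reads scale with
#' the response module's latent factor (responders, who sit high on that
#' factor, get more reads), and clone sizes follow a discrete power law with
#' exponent `clone_alpha` truncated at the read budget.
#'
#' @param clinical clinical table from [generate_clinical_cohort()].
#' @param truth the augmented truth returned by the same call (must carry
#'   `clinical_factors`).
#' @param mean_reads geometric-mean total read count per sample (>= 1).
#' @param clone_alpha power-law exponent of clone sizes (> 0; default 1.5).
#' @param n_clonotypes clonotypes drawn per (sample, chain) before empties
#'   are dropped (default 60).
#' @param abundance_scale log2-fold change in total reads per unit of the
#'   response-module factor (default 1).
#' @param seed integer seed.
#' @return data.frame with columns sample_id, clonotype_id, chain, isotype,
#'   reads (reads >= 1).
#' @export
generate_clonotype_tables <- function(clinical, truth, mean_reads = 2000,
                                      clone_alpha = 1.5, n_clonotypes = 60,
                                      abundance_scale = 1, seed = 1) {
  mean_reads <- check_count(mean_reads, "mean_reads", min = 1L)
  if (!is.numeric(clone_alpha) || clone_alpha <= 0)
    stop("clone_alpha must be positive", call. = FALSE)
  if (is.null(truth$clinical_factors))
    stop("truth must carry clinical_factors (use the truth returned by ",
         "generate_clinical_cohort)", call. = FALSE)

  f <- truth$clinical_factors[clinical$sample_id, truth$response_module]
  chains <- c(IGH = 0.6, IGK = 0.25, IGL = 0.15)
  isotypes <- c(IGHG1 = 0.4, IGHG2 = 0.2, IGHM = 0.25, IGHA1 = 0.15)

  # Discrete power-law sizes p(k) ~ k^-alpha truncated at the budget.
  draw_sizes <- function(n, alpha, kmax) {
    k <- seq_len(max(2L, min(kmax, 10000L)))
    sample(k, n, replace = TRUE, prob = k^(-alpha))
  }

  with_seed(seed, {
    out <- vector("list", nrow(clinical))
    for (i in seq_len(nrow(clinical))) {
      total <- max(10L, round(mean_reads * 2^(abundance_scale * f[i])))
      chain_reads <- stats::rmultinom(1, total, chains)[, 1]
      rows <- list()
      for (ch in names(chains)) {
        if (chain_reads[[ch]] == 0) next
        sizes <- draw_sizes(n_clonotypes, clone_alpha, chain_reads[[ch]])
        reads <- stats::rmultinom(1, chain_reads[[ch]], sizes)[, 1]
        keep <- reads > 0
        if (!any(keep)) next
        iso <- if (ch == "IGH")
          sample(names(isotypes), sum(keep), replace = TRUE, prob = isotypes)
        else rep("", sum(keep))
        rows[[ch]] <- data.frame(
          sample_id = clinical$sample_id[i],
          clonotype_id = sprintf("%s_%s_c%03d", clinical$sample_id[i], ch,
                                 seq_len(sum(keep))),
          chain = ch, isotype = iso, reads = reads[keep],
          stringsAsFactors = FALSE)
      }
      out[[i]] <- do.call(rbind, rows)
    }
    tbl <- do.call(rbind, out)
    rownames(tbl) <- NULL
    tbl
  })
}

#' Generate synthetic molecular-subtype centroids
#'
#' Builds a nearest-centroid reference: `n_subtypes` independent profiles
#' over a stated gene list, far enough apart in rank space that a sample
#' generated from one centroid correlates most with it. Subtype names follow
#' the TNBC convention (BLIA, BLIS, LAR, MES) with BLIA marked the
#' good-prognosis subtype and BLIS the poor-prognosis one, which the
#' indeterminate-rescue rule uses.
#'
#' @param truth `synthetic_truth` (supplies the gene universe).
#' @param n_subtype_genes number of centroid genes (default 77).
#' @param subtypes character vector of >= 2 subtype names.
#' @param seed integer seed.
#' @return `centroid_model`: list with `profiles` (genes x subtypes),
#'   `gene_ids`, `good_prognosis`, `poor_prognosis`.
#' @export
generate_centroids <- function(truth, n_subtype_genes = 77,
                               subtypes = c("BLIA", "BLIS", "LAR", "MES"),
                               seed = 1) {
  n_subtype_genes <- check_count(n_subtype_genes, "n_subtype_genes")
  if (length(subtypes) < 2)
    stop("at least 2 subtypes are required", call. = FALSE)
  genes <- truth$loadings$gene_id
  if (n_subtype_genes > length(genes))
    stop("n_subtype_genes exceeds the gene universe", call. = FALSE)
  with_seed(seed, {
    gene_ids <- sort(sample(genes, n_subtype_genes))
    profiles <- matrix(stats::rnorm(n_subtype_genes * length(subtypes)),
                       n_subtype_genes, length(subtypes),
                       dimnames = list(gene_ids, subtypes))
    structure(list(profiles = profiles, gene_ids = gene_ids,
                   good_prognosis = if ("BLIA" %in% subtypes) "BLIA" else subtypes[1],
                   poor_prognosis = if ("BLIS" %in% subtypes) "BLIS" else subtypes[2]),
              class = "centroid_model")
  })
}

#' @export
print.centroid_model <- function(x, ...) {
  cat("Centroid model:", ncol(x$profiles), "subtypes over",
      nrow(x$profiles), "genes\n")
  cat("  subtypes:", paste(colnames(x$profiles), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate an expression sample from a centroid
#'
#' @param model `centroid_model`.
#' @param subtype subtype name.
#' @param noise_sd Gaussian noise added to the centroid profile.
#' @param seed integer seed.
#' @return named numeric vector over the centroid genes.
#' @export
simulate_from_centroid <- function(model, subtype, noise_sd = 0.3, seed = 1) {
  stopifnot(inherits(model, "centroid_model"), subtype %in% colnames(model$profiles))
  with_seed(seed,
    model$profiles[, subtype] + stats::rnorm(nrow(model$profiles), sd = noise_sd))
}

#' Serialize a synthetic truth object to JSON
#'
#' @param truth `synthetic_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
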