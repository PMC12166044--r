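# End-to-end orchestration: a reference build fit once, then a cohort
# analysis that re-uses the frozen reference artifacts. Both stages write
# plain-text artifacts (TSV/JSON) so every report number is recomputable
# from disk, and both are deterministic for a fixed seed.

default_reference_params <- function() {
  list(n_genes = 2000, power = 5, min_size = 30, deep_split = 2,
       cut_height = 0.995, pam_stage = TRUE, n_random = 100, z_min = 2,
       seed = 1)
}

#' Build the reference co-expression network and its module artifacts
#'
#' Selects the most variable genes, builds the signed-hybrid network,
#' detects modules on topological-overlap dissimilarity, gates them by
#' topological significance, and fits an eigengene/projection model plus
#' kME table per module. Artifacts (module assignment, eigengene scores,
#' kME, significance report, projection models, resolved parameters) are
#' written under `out_dir` when given.
#'
#' @param expr genes x samples log2 reference matrix.
#' @param params named list overriding [default_reference_params()].
#' @param out_dir optional artifact directory (created if needed).
#' @return list: expr (selected universe), network, assignment,
#'   significance, projections (per module), eigengene_scores, kme_table,
#'   params.
#' @export
run_reference_build <- function(expr, params = list(), out_dir = NULL) {
  check_expr(expr)
  p <- utils::modifyList(default_reference_params(), params)
  message("reference build: ", nrow(expr), " genes x ", ncol(expr),
          " samples; params: ",
          paste(names(p), unlist(p), sep = "=", collapse = " "))

  uni <- select_variable_genes(expr, min(p$n_genes, nrow(expr)))
  net <- adjacency(uni, power = p$power)
  dissim <- topological_overlap(net)
  assignment <- detect_modules(dissim, min_size = p$min_size,
                               deep_split = p$deep_split,
                               cut_height = p$cut_height,
                               pam_stage = p$pam_stage)
  if (!length(assignment$module_sizes))
    stop("reference build found no modules", call. = FALSE)
  signif_tab <- topological_significance(uni, assignment, n_random = p$n_random,
                                         z_min = p$z_min, net = net,
                                         seed = p$seed)

  mods <- as.integer(names(assignment$module_sizes))
  projections <- lapply(mods, function(m)
    fit_projection(uni, module_genes(assignment, m)))
  names(projections) <- paste0("module", mods)

  scores <- do.call(rbind, lapply(mods, function(m) {
    sc <- projections[[paste0("module", m)]]$reference_scores
    cbind(module = m, sc)
  }))
  kme_tab <- do.call(rbind, lapply(mods, function(m) {
    pm <- projections[[paste0("module", m)]]
    kv <- kme(uni[pm$gene_ids, , drop = FALSE],
              stats::setNames(pm$reference_scores$PC1,
                              pm$reference_scores$sample_id))
    data.frame(module = m, gene_id = names(kv), kme = kv,
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  out <- list(expr = uni, network = net, assignment = assignment,
              significance = signif_tab, projections = projections,
              eigengene_scores = scores, kme_table = kme_tab, params = p)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      data.frame(gene_id = names(assignment$labels),
                 module_id = unname(assignment$labels)),
      file.path(out_dir, "module_assignment.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(scores, file.path(out_dir, "eigengene_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(kme_tab, file.path(out_dir, "kme.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(signif_tab, file.path(out_dir, "topological_significance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (m in mods)
      write_projection_json(projections[[paste0("module", m)]],
                            file.path(out_dir, sprintf("projection_module%d.json", m)))
    write_expression_tsv(uni, file.path(out_dir, "reference_universe.tsv"))
    jsonlite::write_json(p, file.path(out_dir, "reference_params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

fit_and_eval <- function(scores_bx1, scores_bx2, labels, feature, seed) {
  fit <- fit_threshold_classifier(scores_bx1, labels, feature = feature,
                                  seed = seed)
  eval_bx <- function(sc) {
    pred <- predict(fit, sc)
    m <- classification_metrics(pred, labels)
    list(pred = pred, accuracy = m$accuracy, mcc = m$mcc, f1 = m$f1)
  }
  list(fit = fit, bx1 = eval_bx(scores_bx1), bx2 = eval_bx(scores_bx2))
}

#' Analyze a paired-biopsy cohort against a fitted reference
#'
#' Harmonizes the cohort to the reference, projects eigengene scores for
#' every reference module, derives kME signatures from the
#' best-discriminating module, fits the panel of depth-1 response
#' classifiers (module eigengene, kME-threshold set and top-n set scored
#' by single-sample enrichment, single hub gene, and any supplied external
#' mean-score signatures), calls centroid subtypes with the indeterminate
#' margin and rescues no-calls with the signature classifier, decomposes
#' the modules of interest into patient-specific networks with wiring
#' statistics and differential/sector tables, and summarizes repertoire
#' diversity when clonotype tables are given.
#'
#' @param reference result of [run_reference_build()].
#' @param bx1,bx2 genes x patients matrices for the two biopsies.
#' @param clinical clinical table (sample_id, patient_id, biopsy,
#'   best_response, responder).
#' @param centroids optional `centroid_model` for subtype calling.
#' @param clonotypes optional long clonotype table.
#' @param external_sets optional named list of external gene sets scored
#'   by mean expression + median split.
#' @param kme_threshold kME cutoff for the threshold signature (default
#'   0.9); if no gene passes, the top `kme_top_fallback` genes are used.
#' @param kme_top_fallback fallback signature size (default 34).
#' @param n_top_genes size of the small top-kME set (default 3).
#' @param n_interest number of modules decomposed into patient networks
#'   (default 3, largest first).
#' @param margin_threshold indeterminate margin for subtype calls.
#' @param out_dir optional artifact directory.
#' @param seed integer seed (classifier permutation tests, downsampling).
#' @return list: classifiers (per-method fits and metrics), report
#'   (data.frame, one row per method), subtype_calls (before/after
#'   rescue), patient_networks, differential, sectors, repertoire, scores.
#' @export
run_cohort_analysis <- function(reference, bx1, bx2, clinical,
                                centroids = NULL, clonotypes = NULL,
                                external_sets = NULL,
                                kme_threshold = 0.9, kme_top_fallback = 34,
                                n_top_genes = 3, n_interest = 3,
                                margin_threshold = 0.1,
                                out_dir = NULL, seed = 1) {
  if (is.null(reference$projections))
    stop("reference artifacts missing; run run_reference_build() first",
         call. = FALSE)
  check_expr(bx1, "bx1"); check_expr(bx2, "bx2")
  ref_expr <- reference$expr
  asg <- reference$assignment

  h1 <- reference_batch_correct(bx1[rownames(ref_expr), , drop = FALSE], ref_expr)
  h2 <- reference_batch_correct(bx2[rownames(ref_expr), , drop = FALSE], ref_expr)

  pts <- clinical$patient_id[clinical$biopsy == "Bx1"]
  labels <- stats::setNames(clinical$responder[clinical$biopsy == "Bx1"], pts)
  s1_ids <- clinical$sample_id[clinical$biopsy == "Bx1"]
  s2_ids <- clinical$sample_id[clinical$biopsy == "Bx2"][
    match(pts, clinical$patient_id[clinical$biopsy == "Bx2"])]

  mods <- as.integer(names(asg$module_sizes))
  proj1 <- lapply(mods, function(m)
    project_scores(reference$projections[[paste0("module", m)]], h1))
  proj2 <- lapply(mods, function(m)
    project_scores(reference$projections[[paste0("module", m)]], h2))
  names(proj1) <- names(proj2) <- paste0("module", mods)

  # eigengene classifiers per module; the signature module is the one whose
  # eigengene separates Bx1 response best (ties to the smaller module id)
  eg_fits <- lapply(seq_along(mods), function(i) {
    sc1 <- stats::setNames(proj1[[i]]$PC1[match(s1_ids, proj1[[i]]$sample_id)], pts)
    sc2 <- stats::setNames(proj2[[i]]$PC1[match(s2_ids, proj2[[i]]$sample_id)], pts)
    fit_and_eval(sc1, sc2, labels, sprintf("eigengene_module%d", mods[i]), seed)
  })
  names(eg_fits) <- paste0("module", mods)
  acc1 <- vapply(eg_fits, function(f) f$bx1$accuracy, 0)
  sig_mod <- mods[which.max(acc1)]
  sig_key <- paste0("module", sig_mod)

  kv <- reference$kme_table
  kv <- stats::setNames(kv$kme[kv$module == sig_mod],
                        kv$gene_id[kv$module == sig_mod])
  sig_set <- tryCatch(
    derive_geneset_by_kme(kv, sprintf("module%d_kme%.2f", sig_mod, kme_threshold),
                          mode = "threshold", theta = kme_threshold),
    error = function(e) {
      message("kME threshold produced an empty set; falling back to top ",
              kme_top_fallback, " genes")
      derive_geneset_by_kme(kv, sprintf("module%d_top%d", sig_mod, kme_top_fallback),
                            mode = "top_n", n = kme_top_fallback)
    })
  top_set <- derive_geneset_by_kme(kv, sprintf("module%d_top%d", sig_mod, n_top_genes),
                                   mode = "top_n", n = n_top_genes)
  hub_gene <- top_set$genes[1]

  universe <- rownames(ref_expr)
  ss1_sig <- ssgsea_score(h1, sig_set, universe)
  ss2_sig <- ssgsea_score(h2, sig_set, universe)
  ss1_top <- ssgsea_score(h1, top_set, universe)
  ss2_top <- ssgsea_score(h2, top_set, universe)
  mz_scores <- function(h, set, ids) {
    df <- mean_z_score(h, set)
    df$score[match(ids, df$sample_id)]
  }
  hub1 <- mz_scores(h1, hub_gene, s1_ids)
  hub2 <- mz_scores(h2, hub_gene, s2_ids)

  classifiers <- list(
    eigengene = eg_fits[[sig_key]],
    kme_signature = fit_and_eval(stats::setNames(ss1_sig[s1_ids], pts),
                                 stats::setNames(ss2_sig[s2_ids], pts), labels,
                                 paste0("ssgsea_", sig_set$name), seed),
    kme_top = fit_and_eval(stats::setNames(ss1_top[s1_ids], pts),
                           stats::setNames(ss2_top[s2_ids], pts), labels,
                           paste0("ssgsea_", top_set$name), seed),
    hub_gene = fit_and_eval(stats::setNames(hub1, pts),
                            stats::setNames(hub2, pts), labels,
                            paste0("hub_", hub_gene), seed)
  )
  for (nm in names(external_sets)) {
    sc1 <- stats::setNames(mz_scores(h1, external_sets[[nm]], s1_ids), pts)
    sc2 <- stats::setNames(mz_scores(h2, external_sets[[nm]], s2_ids), pts)
    classifiers[[paste0("external_", nm)]] <-
      fit_and_eval(sc1, sc2, labels, paste0("external_", nm), seed)
  }

  # centroid subtype calls; indeterminates rescued by the kME signature
  subtype <- NULL
  if (!is.null(centroids)) {
    calls1 <- call_subtype(h1[centroids$gene_ids, , drop = FALSE], centroids,
                           margin_threshold)
    pred1 <- stats::setNames(classifiers$kme_signature$bx1$pred, pts)
    names(pred1) <- s1_ids
    rescued1 <- rescue_indeterminate(calls1, pred1, centroids)
    call_resp <- rescued1$call == centroids$good_prognosis
    m <- classification_metrics(call_resp, labels[pts])
    subtype <- list(before = calls1, after = rescued1,
                    nocall_rate_before = mean(calls1$call == "INDETERMINATE"),
                    nocall_rate_after = mean(rescued1$call == "INDETERMINATE"),
                    accuracy = m$accuracy, mcc = m$mcc, f1 = m$f1)
    classifiers$rescued_subtype <- list(
      fit = NULL,
      bx1 = list(pred = call_resp, accuracy = m$accuracy, mcc = m$mcc, f1 = m$f1),
      bx2 = list(pred = NULL, accuracy = NA_real_, mcc = NA_real_, f1 = NA_real_))
  }

  # patient-specific networks over the modules of interest
  interest <- utils::head(mods, n_interest)
  cohort_all <- cbind(h1, h2)
  pnets <- lapply(interest, function(m)
    patient_networks(cohort_all, ref_expr, module_genes(asg, m)))
  names(pnets) <- paste0("module", interest)
  n_networks <- sum(vapply(pnets, function(p) length(p$networks), 0L))

  # differential expression and wiring, Bx1 response groups, over the
  # signature module's genes; sector classification of the two t vectors
  sig_genes <- module_genes(asg, sig_mod)
  grp <- labels[pts]
  de1 <- moderated_t(h1[sig_genes, s1_ids, drop = FALSE], grp[pts])
  conn <- pnets[[sig_key]]$gene_features
  conn1 <- conn[conn$sample_id %in% s1_ids, ]
  cmat <- matrix(NA_real_, length(sig_genes), length(s1_ids),
                 dimnames = list(sig_genes, s1_ids))
  cmat[cbind(conn1$gene_id, conn1$sample_id)] <- conn1$connectivity
  dn1 <- moderated_t(log2(cmat + 1), grp[pts])
  tt <- merge(de1[, c("feature", "t")], dn1[, c("feature", "t")],
              by = "feature", suffixes = c("_expr", "_net"))
  sectors <- sector_assign(stats::setNames(tt$t_expr, tt$feature),
                           stats::setNames(tt$t_net, tt$feature))

  delta <- paired_delta(cbind(h1, h2), clinical)

  repertoire <- NULL
  if (!is.null(clonotypes)) {
    depths <- biopsy_downsampling_depths()
    bx1_samp <- clonotypes$sample_id %in% s1_ids
    repertoire <- list(
      igh = repertoire_diversity(clonotypes, chain = "IGH"),
      igg = repertoire_diversity(clonotypes, chain = "IGH", isotype = "IGHG"),
      igg_down_bx1 = downsampled_metrics(clonotypes[bx1_samp, ],
                                         depth = depths[["Bx1"]],
                                         chain = "IGH", isotype = "IGHG",
                                         seed = seed),
      igg_down_bx2 = downsampled_metrics(clonotypes[!bx1_samp, ],
                                         depth = depths[["Bx2"]],
                                         chain = "IGH", isotype = "IGHG",
                                         seed = seed),
      abundance = class_abundance(clonotypes, by = "chain"))
  }

  fmt <- function(x) ifelse(is.na(x), "N/A", sprintf("%.3f", x))
  report <- do.call(rbind, lapply(names(classifiers), function(nm) {
    cl <- classifiers[[nm]]
    data.frame(method = nm,
               bx1_accuracy = cl$bx1$accuracy, bx1_mcc = fmt(cl$bx1$mcc),
               bx1_f1 = fmt(cl$bx1$f1),
               bx2_accuracy = cl$bx2$accuracy, bx2_mcc = fmt(cl$bx2$mcc),
               bx2_f1 = fmt(cl$bx2$f1),
               stringsAsFactors = FALSE)
  }))

  out <- list(classifiers = classifiers, report = report,
              signature_module = sig_mod, signature_set = sig_set,
              top_set = top_set, hub_gene = hub_gene,
              subtype = subtype, patient_networks = pnets,
              n_patient_networks = n_networks,
              differential = list(expression_bx1 = de1, connectivity_bx1 = dn1),
              sectors = sectors, paired_delta = delta,
              repertoire = repertoire,
              scores = list(eigengene_bx1 = proj1, eigengene_bx2 = proj2,
                            ssgsea_sig_bx1 = ss1_sig, ssgsea_sig_bx2 = ss2_sig))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report, file.path(out_dir, "classifier_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sectors, file.path(out_dir, "sectors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(subtype)) {
      utils::write.table(subtype$after, file.path(out_dir, "subtype_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary_json <- list(
      signature_module = sig_mod,
      signature_set = sig_set$genes,
      top_set = top_set$genes,
      hub_gene = hub_gene,
      n_patient_networks = n_networks,
      nocall_rate_before = if (!is.null(subtype)) subtype$nocall_rate_before else NA,
      nocall_rate_after = if (!is.null(subtype)) subtype$nocall_rate_after else NA,
      methods = report$method,
      bx1_accuracy = report$bx1_accuracy,
      bx2_accuracy = report$bx2_accuracy)
    jsonlite::write_json(summary_json, file.path(out_dir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  out
}

#' Run the full pipeline on a synthetic demonstration cohort
#'
#' Generates the default synthetic study (reference cohort of 150 samples
#' by 2000 genes with planted modules of sizes 469/323/190/48/42, a
#' 13-patient paired-biopsy cohort, clonotype tables, and centroid
#' profiles), runs the reference build and the cohort analysis, and writes
#' all artifacts under `out_dir`. Deterministic for a fixed seed.
#'
#' @param seed integer seed driving every generator and stochastic step.
#' @param out_dir output directory.
#' @param reference_params overrides for the reference build.
#' @return the cohort-analysis result, invisibly; artifacts on disk.
#' @export
run_demo <- function(seed = 7, out_dir = tempfile("netstrat_demo"),
                     reference_params = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference_cohort(seed = seed)
  clin <- generate_clinical_cohort(ref$truth, seed = seed + 1)
  clono <- generate_clonotype_tables(clin$clinical, clin$truth,
                                     mean_reads = 8500, seed = seed + 2)
  centroids <- generate_centroids(ref$truth, seed = seed + 3)

  built <- run_reference_build(ref$expr,
                               params = utils::modifyList(list(seed = seed),
                                                          reference_params),
                               out_dir = file.path(out_dir, "reference"))
  # a synthetic external mean-score signature overlapping the reference
  # response module, standing in for a published B-cell signature
  kv <- built$kme_table
  resp_genes <- kv$gene_id[kv$module == ref$truth$response_module]
  ext <- list(synthetic_bcell = utils::head(resp_genes, 15))

  res <- run_cohort_analysis(built, clin$bx1, clin$bx2, clin$clinical,
                             centroids = centroids, clonotypes = clono,
                             external_sets = ext,
                             out_dir = file.path(out_dir, "cohort"),
                             seed = seed)
  invisible(res)
}
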