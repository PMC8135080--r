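#' Pipeline configuration
#'
#' All stage parameters with their published defaults: DE at raw p < 0.05,
#' enrichment at overlap >= 3 and p < 0.01, VIP > 1 candidate triage, k = 3
#' trajectory clusters, exhaustive leave-one-out panel search at probability
#' threshold 0.5. Input is either a matrix + sample sheet pair of TSV paths or
#' (when both are `NULL`) a synthetic cohort simulated from `design`. A single
#' master seed is fanned out to the stochastic stages (simulation seed,
#' seed + 1 imputation, seed + 2 clustering) so every stage is independently
#' replayable.
#'
#' @param matrix_path,samples_path input TSVs (see [read_proteome()]), or
#'   `NULL` to simulate.
#' @param gmt_path optional GMT file; enrichment is skipped when `NULL`.
#' @param out_dir output directory for the report bundle.
#' @param seed master integer seed.
#' @param design a [cohort_design()] for simulated input (its `seed` is
#'   overridden by the master seed).
#' @param de_alpha,corr_alpha raw p-value cutoffs for differential expression
#'   and MMSE correlation.
#' @param min_valid_frac per-group quantification filter (see
#'   [filter_min_valid()]).
#' @param impute_width,impute_downshift downshifted-normal imputation
#'   parameters.
#' @param vip_threshold VIP selection cutoff.
#' @param n_components PLS-DA components.
#' @param exclude protein ids excluded from the candidate list before PLS-DA
#'   (the published analysis dropped complement-pathway members here).
#' @param search_strategy `"exhaustive"` or `"greedy"`.
#' @param search_threshold probability cutoff for panel confusion matrices.
#' @param min_overlap,ora_alpha enrichment reporting rule.
#' @param max_search_candidates cap on proteins entering the exhaustive search
#'   (top-VIP candidates are kept if more pass the VIP rule).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path = NULL, samples_path = NULL,
                            gmt_path = NULL, out_dir = "plateletpanel_out",
                            seed = 1L, design = cohort_design(),
                            de_alpha = 0.05, corr_alpha = 0.05,
                            min_valid_frac = 0.7,
                            impute_width = 0.3, impute_downshift = 1.8,
                            vip_threshold = 1.0, n_components = 2,
                            exclude = NULL,
                            search_strategy = c("exhaustive", "greedy"),
                            search_threshold = 0.5,
                            min_overlap = 3, ora_alpha = 0.01,
                            max_search_candidates = 12) {
  structure(list(
    matrix_path = matrix_path, samples_path = samples_path,
    gmt_path = gmt_path, out_dir = out_dir, seed = as.integer(seed),
    design = design, de_alpha = de_alpha, corr_alpha = corr_alpha,
    min_valid_frac = min_valid_frac, impute_width = impute_width,
    impute_downshift = impute_downshift, vip_threshold = vip_threshold,
    n_components = n_components, exclude = exclude,
    search_strategy = match.arg(search_strategy),
    search_threshold = search_threshold, min_overlap = min_overlap,
    ora_alpha = ora_alpha,
    max_search_candidates = max_search_candidates
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `design` may be a
#' nested mapping of [cohort_design()] arguments. Unknown keys are an error.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$design)) {
    if (!is.null(raw$design$mmse_ranges))
      raw$design$mmse_ranges <- lapply(raw$design$mmse_ranges, as.numeric)
    raw$design <- do.call(cohort_design, raw$design)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    fail("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

.log_info <- function(fmt, ...) message(sprintf(paste0("[plateletpanel] ", fmt), ...))

#' Run the full discovery pipeline
#'
#' Executes preprocess -> differential expression -> trajectory clustering ->
#' MMSE correlation -> (optional) enrichment -> PLS-DA/VIP -> panel search,
#' writing every stage table as TSV into `config$out_dir` plus a `summary.tsv`
#' of headline numbers. Every applied threshold and seed is logged. With the
#' same config (and seed) the output bundle is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with all stage objects (`matrix`, `truth` or
#'   `NULL`, `de`, `de_summary`, `clusters`, `correlation`, `candidates`,
#'   `enrichment`, `plsda`, `vip`, `selected`, `search`, `summary`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  .log_info("seed = %d; output -> %s", config$seed, config$out_dir)

  truth <- NULL
  if (is.null(config$matrix_path)) {
    design <- config$design
    design$seed <- config$seed
    .log_info("simulating cohort: %d proteins, %d/%d/%d Ctrl/MCI/AD",
              design$n_proteins, design$n_ctrl, design$n_mci, design$n_ad)
    cohort <- generate_cohort(design)
    pm_raw <- cohort$matrix
    truth <- cohort$truth
    write_proteome(pm_raw, out("matrix_raw.tsv"), out("samples.tsv"))
    write_tsv(truth$cluster, out("truth_clusters.tsv"))
    write_tsv(data.frame(protein = truth$true_panel), out("truth_panel.tsv"))
  } else {
    .log_info("reading matrix %s + samples %s",
              config$matrix_path, config$samples_path)
    pm_raw <- read_proteome(config$matrix_path, config$samples_path)
  }

  # --- preprocess ---
  pm <- filter_min_valid(pm_raw, config$min_valid_frac)
  .log_info("quantification filter >= %.0f%% per group: %d -> %d proteins",
            100 * config$min_valid_frac, nrow(pm_raw$abundance),
            nrow(pm$abundance))
  pm <- normalize_columns(pm)
  pm <- impute_downshifted(pm, config$impute_width, config$impute_downshift,
                           seed = config$seed + 1L)
  write_proteome(pm, out("matrix_normalized.tsv"), out("samples.tsv"))

  # --- differential expression ---
  de <- run_de_contrasts(pm)
  de_summary <- summarize_de(de, alpha = config$de_alpha)
  for (nm in names(de)) write_tsv(de[[nm]], out(sprintf("de_%s.tsv", nm)))
  write_tsv(de_summary$counts, out("de_summary.tsv"))
  .log_info("DE at p < %.3g: union %d, Ctrl-referenced overlap %d",
            config$de_alpha, length(de_summary$union),
            length(de_summary$overlap_ctrl))

  # --- trajectory clustering ---
  clusters <- NULL
  if (length(de_summary$union) >= 3) {
    profiles <- compute_profiles(pm, de_summary$union)
    clusters <- cluster_k3(profiles, seed = config$seed + 2L)
    write_tsv(clusters$assignment, out("clusters.tsv"))
    write_tsv(data.frame(cluster = rownames(clusters$centroids),
                         clusters$centroids), out("cluster_centroids.tsv"))
    .log_info("trajectory clusters: %s",
              paste(sprintf("%d=%d", 1:3, clusters$sizes), collapse = " "))
  } else .log_info("fewer than 3 DE proteins; clustering skipped")

  # --- MMSE correlation ---
  corr <- pearson_vs_mmse(pm, alpha = config$corr_alpha)
  write_tsv(corr, out("correlation.tsv"))
  .log_info("MMSE correlation at p < %.3g: %d NC, %d PC", config$corr_alpha,
            sum(corr$class == "NC"), sum(corr$class == "PC"))
  candidates <- build_candidates(corr, de_summary, exclude = config$exclude)
  write_tsv(candidates, out("candidates.tsv"))
  .log_info("candidates (DE & correlated%s): %d",
            if (length(attr(candidates, "excluded_hits")) > 0)
              sprintf(", %d excluded", length(attr(candidates, "excluded_hits")))
            else "", nrow(candidates))
  if (nrow(candidates) >= 2) {
    ccm <- candidate_corr_matrix(pm, candidates$protein)
    write_tsv(corr_matrix_long(ccm), out("candidate_correlations.tsv"))
  }

  # --- enrichment (optional) ---
  enr <- NULL
  if (!is.null(config$gmt_path)) {
    collection <- read_gmt(config$gmt_path)
    enr <- ora(de_summary$union, rownames(pm$abundance), collection,
               min_overlap = config$min_overlap, alpha = config$ora_alpha)
    write_tsv(enr, out("enrichment.tsv"))
    .log_info("enrichment (overlap >= %d, p < %.3g): %d set(s)",
              config$min_overlap, config$ora_alpha, nrow(enr))
  } else .log_info("no GMT supplied; enrichment skipped")

  # --- PLS-DA / VIP ---
  plsda <- NULL; vip <- NULL; selected <- character(0); search <- NULL
  if (nrow(candidates) >= 2) {
    plsda <- fit_plsda(pm, candidates$protein,
                       n_components = config$n_components)
    vip <- vip_scores(plsda)
    write_tsv(data.frame(protein = names(vip), vip = vip), out("vip.tsv"))
    write_tsv(data.frame(sample = rownames(plsda$T_scores),
                         group = as.character(pm$group), plsda$T_scores),
              out("plsda_scores.tsv"))
    selected <- select_candidates(vip, config$vip_threshold)
    .log_info("VIP > %.2f: %d of %d candidates", config$vip_threshold,
              length(selected), length(vip))
    # --- panel search ---
    if (length(selected) >= 1) {
      if (length(selected) > config$max_search_candidates) {
        .log_info("capping search candidates at top %d by VIP",
                  config$max_search_candidates)
        selected <- selected[seq_len(config$max_search_candidates)]
      }
      search_fun <- if (config$search_strategy == "exhaustive")
        exhaustive_search else greedy_forward_search
      search <- search_fun(pm, selected, threshold = config$search_threshold)
      write_tsv(search$ranked, out("panels.tsv"))
      write_tsv(search$per_size, out("panels_per_size.tsv"))
      best_ev <- search$best_evaluation
      write_tsv(data.frame(sample = names(best_ev$probs),
                           prob_impaired = best_ev$probs,
                           impaired = best_ev$labels),
                out("best_panel_probs.tsv"))
      write_tsv(best_ev$roc, out("best_panel_roc.tsv"))
      write_tsv(best_ev$pr, out("best_panel_pr.tsv"))
      .log_info("best panel (%s search): %s", config$search_strategy,
                paste(search$best, collapse = " + "))
    }
  } else .log_info("fewer than 2 candidates; PLS-DA and panel search skipped")

  summary_df <- data.frame(
    key = c("n_proteins_input", "n_proteins_quantified", "n_de_union",
            "n_de_overlap_ctrl", "cluster_sizes", "n_nc", "n_pc",
            "n_candidates", "n_vip_selected", "best_panel",
            "best_auc_roc", "best_auc_pr", "best_accuracy", "best_f1"),
    value = c(nrow(pm_raw$abundance), nrow(pm$abundance),
              length(de_summary$union), length(de_summary$overlap_ctrl),
              if (is.null(clusters)) NA else paste(clusters$sizes, collapse = "/"),
              sum(corr$class == "NC"), sum(corr$class == "PC"),
              nrow(candidates), length(selected),
              if (is.null(search)) NA else paste(search$best, collapse = "+"),
              if (is.null(search)) NA else sprintf("%.3f", search$best_evaluation$metrics$auc_roc),
              if (is.null(search)) NA else sprintf("%.3f", search$best_evaluation$metrics$auc_pr),
              if (is.null(search)) NA else sprintf("%.3f", search$best_evaluation$metrics$accuracy),
              if (is.null(search)) NA else sprintf("%.3f", search$best_evaluation$metrics$f1))
  )
  write_tsv(summary_df, out("summary.tsv"))
  invisible(list(matrix = pm, truth = truth, de = de, de_summary = de_summary,
                 clusters = clusters, correlation = corr,
                 candidates = candidates, enrichment = enr, plsda = plsda,
                 vip = vip, selected = selected, search = search,
                 summary = summary_df))
}
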