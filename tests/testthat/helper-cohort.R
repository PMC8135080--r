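# shared fixtures: all synthetic, generated in code at test time

# scaled-down design (~1/10 the published protein count) for fast module tests;
# per-protein power is unchanged, only the protein universe shrinks
small_design <- function(seed = 42, ...) {
  args <- list(n_proteins = 300, n_cluster1 = 24, n_cluster2 = 20,
               n_cluster3 = 10, n_corr_pos = 10, n_corr_neg = 4,
               panel_size = 4, seed = seed)
  do.call(cohort_design, modifyList(args, list(...)))
}

# normalize + impute, optionally skipping the per-group completeness filter
# (recovery runs keep all planted proteins; see the methods vignette)
preprocess_cohort <- function(pm, seed = 7, filter = TRUE, min_frac = 0.7) {
  if (filter) pm <- filter_min_valid(pm, min_frac)
  impute_downshifted(normalize_columns(pm), seed = seed)
}

# proteome_matrix from a bare matrix, default 4 Ctrl / 4 MCI / 4 AD layout
quick_pm <- function(ab, group = rep(c("Ctrl", "MCI", "AD"), each = 4),
                     mmse = NULL, log2_scale = TRUE) {
  if (is.null(rownames(ab))) rownames(ab) <- sprintf("G%03d", seq_len(nrow(ab)))
  if (is.null(colnames(ab))) colnames(ab) <- sprintf("s%02d", seq_len(ncol(ab)))
  if (is.null(mmse)) {
    ranges <- list(Ctrl = 29:30, MCI = 18:23, AD = 2:17)
    mmse <- vapply(group, function(g) as.integer(ranges[[g]][1]), integer(1))
  }
  proteome_matrix(ab, group, mmse, log2_scale = log2_scale)
}

# pure-noise protein ids of a generated cohort
null_proteins <- function(cohort) {
  setdiff(rownames(cohort$matrix$abundance),
          c(cohort$truth$cluster$protein,
            cohort$truth$mmse_correlated$protein))
}

# mean silhouette of group `a` against the rest on a score matrix
silhouette_vs_rest <- function(scores, is_a) {
  d <- as.matrix(dist(scores))
  s <- vapply(which(is_a), function(i) {
    a <- mean(d[i, is_a & seq_len(nrow(d)) != i])
    b <- mean(d[i, !is_a])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
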