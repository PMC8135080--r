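#' Design of a synthetic platelet proteomics cohort
#'
#' Describes the cohort the generator emulates. Defaults mirror the published
#' study design this package targets: 9 Ctrl / 10 MCI / 9 AD subjects, ~3,000
#' quantified proteins of which 360 are planted as differential in three
#' trajectory archetypes (160 monotone-down, 135 down-then-up, 65 monotone-up
#' across Ctrl -> MCI -> AD), group MMSE ranges 29-30 / 18-23 / 2-17, a small
#' planted "true panel" separating cognitively impaired (MCI+AD) subjects from
#' controls, and a block of proteins with a planted moderate Pearson
#' correlation to MMSE.
#'
#' @param n_ctrl,n_mci,n_ad group sizes.
#' @param n_proteins total quantified proteins.
#' @param n_cluster1,n_cluster2,n_cluster3 planted trajectory-protein counts
#'   (monotone-down, down-up, monotone-up).
#' @param effect_size log2 fold-change magnitude per planted group step.
#' @param mmse_ranges named list of inclusive integer MMSE ranges per group.
#' @param panel_size number of planted true-panel proteins (taken from the
#'   monotone-down block, which they lead).
#' @param target_corr absolute expected Pearson r of planted MMSE-correlated
#'   proteins against the sampled MMSE vector.
#' @param n_corr_pos,n_corr_neg counts of positively / negatively
#'   MMSE-correlated planted proteins.
#' @param missing_rate overall fraction of missing cells in \[0, 1).
#' @param noise_sd residual log2-scale SD per cell.
#' @param seed integer seed; the full cohort is a deterministic function of the
#'   design.
#' @return A validated list of class `cohort_design`.
#' @export
cohort_design <- function(n_ctrl = 9, n_mci = 10, n_ad = 9,
                          n_proteins = 3000,
                          n_cluster1 = 160, n_cluster2 = 135, n_cluster3 = 65,
                          effect_size = 0.8,
                          mmse_ranges = list(Ctrl = c(29, 30),
                                             MCI = c(18, 23),
                                             AD = c(2, 17)),
                          panel_size = 4,
                          target_corr = 0.55,
                          n_corr_pos = 90, n_corr_neg = 30,
                          missing_rate = 0.05,
                          noise_sd = 0.5,
                          seed = 1L) {
  d <- list(n_ctrl = n_ctrl, n_mci = n_mci, n_ad = n_ad,
            n_proteins = n_proteins,
            n_cluster1 = n_cluster1, n_cluster2 = n_cluster2,
            n_cluster3 = n_cluster3,
            effect_size = effect_size, mmse_ranges = mmse_ranges,
            panel_size = panel_size, target_corr = target_corr,
            n_corr_pos = n_corr_pos, n_corr_neg = n_corr_neg,
            missing_rate = missing_rate, noise_sd = noise_sd,
            seed = as.integer(seed))
  counts <- c("n_ctrl", "n_mci", "n_ad", "n_proteins", "panel_size")
  for (f in counts)
    if (d[[f]] < 1) fail("design field '%s' must be a positive count", f)
  for (f in c("n_cluster1", "n_cluster2", "n_cluster3",
              "n_corr_pos", "n_corr_neg"))
    if (d[[f]] < 0) fail("design field '%s' must be non-negative", f)
  n_planted <- n_cluster1 + n_cluster2 + n_cluster3 + n_corr_pos + n_corr_neg
  if (n_planted > n_proteins)
    fail("planted proteins (%d) exceed n_proteins (%d)", n_planted, n_proteins)
  if (panel_size > max(n_cluster1, 1) && n_cluster1 > 0)
    fail("panel_size (%d) exceeds n_cluster1 (%d)", panel_size, n_cluster1)
  if (!all(c("Ctrl", "MCI", "AD") %in% names(mmse_ranges)))
    fail("mmse_ranges needs entries Ctrl, MCI, AD")
  for (g in c("Ctrl", "MCI", "AD")) {
    r <- mmse_ranges[[g]]
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 30)
      fail("mmse_ranges$%s must be an increasing integer pair within [0, 30]", g)
  }
  if (missing_rate < 0 || missing_rate >= 1)
    fail("missing_rate must be in [0, 1)")
  if (abs(target_corr) >= 1) fail("target_corr must have |r| < 1")
  if (noise_sd <= 0) fail("noise_sd must be positive")
  structure(d, class = "cohort_design")
}

#' Sample MMSE scores for a group
#'
#' Uniform integer draws on the group's configured inclusive range (defaults:
#' Ctrl 29-30, MCI 18-23, AD 2-17). Only the ranges are published for the
#' target cohort, so the uniform is the least-assuming generator. Draws use the
#' current RNG stream.
#'
#' @param group character vector of group labels.
#' @param design a [cohort_design()] supplying the ranges.
#' @return Integer vector of MMSE scores, one per element of `group`.
#' @export
sample_mmse <- function(group, design = cohort_design()) {
  vapply(as.character(group), function(g) {
    r <- design$mmse_ranges[[g]]
    if (is.null(r)) fail("unknown group '%s'", g)
    if (r[1] == r[2]) as.integer(r[1])
    else as.integer(sample(seq.int(r[1], r[2]), 1L))
  }, integer(1), USE.NAMES = FALSE)
}

# Trajectory archetype offsets in units of effect_size, ordered (Ctrl,MCI,AD).
# Cluster 1 steps down at each transition, cluster 2 dips at MCI, cluster 3
# steps up at each transition.
.trajectory_offsets <- list(
  `1` = c(0, -1, -2),
  `2` = c(0, -1, 0),
  `3` = c(0, 1, 2)
)

#' Generate a synthetic cohort with planted ground truth
#'
#' Builds a protein x sample reporter-abundance matrix with the statistical
#' structure the downstream pipeline assumes, plus labels for everything that
#' was planted, so that recovery can be scored exactly:
#'
#' * baseline log2 abundances per protein drawn Normal(20, 2), with residual
#'   Normal(0, `noise_sd`) per cell;
#' * three trajectory blocks whose group means step by `effect_size` along
#'   Ctrl -> MCI -> AD (down-down, down-up, up-up);
#' * a true panel: the leading `panel_size` monotone-down proteins, which
#'   separate impaired (MCI+AD) subjects from controls;
#' * MMSE-correlated blocks: a signed multiple of the standardized sampled
#'   MMSE vector is added so the expected Pearson r equals `target_corr`
#'   (beta = noise_sd * r / sqrt(1 - r^2));
#' * all remaining proteins pure noise;
#' * optional left-censored missingness concentrated in low-abundance proteins
#'   (see [inject_missing()]).
#'
#' The returned abundances are raw scale (2^log2), ready for
#' [normalize_columns()].
#'
#' @param design a [cohort_design()].
#' @return A list with elements `matrix` (a [proteome_matrix()]) and `truth`,
#'   a list of class `ground_truth` with elements `de` (planted differential
#'   protein ids per contrast), `cluster` (data frame protein/cluster),
#'   `mmse_correlated` (data frame protein/r_target), `true_panel` (ordered
#'   ids) and `design`.
#' @examples
#' cohort <- generate_cohort(cohort_design(n_proteins = 200, n_cluster1 = 16,
#'                                         n_cluster2 = 14, n_cluster3 = 6,
#'                                         n_corr_pos = 9, n_corr_neg = 3))
#' cohort$matrix
#' @export
generate_cohort <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed, {
    n_samples <- design$n_ctrl + design$n_mci + design$n_ad
    group <- factor(rep(c("Ctrl", "MCI", "AD"),
                        c(design$n_ctrl, design$n_mci, design$n_ad)),
                    levels = c("Ctrl", "MCI", "AD"))
    sample_ids <- sprintf("S%02d_%s", seq_len(n_samples), group)
    mmse <- sample_mmse(group, design)
    # standardized MMSE used to plant protein-MMSE correlations
    z_mmse <- if (sd(mmse) > 0) (mmse - mean(mmse)) / sd(mmse) else rep(0, n_samples)

    P <- design$n_proteins
    protein_ids <- sprintf("P%05d", seq_len(P))
    n_cl <- c(design$n_cluster1, design$n_cluster2, design$n_cluster3)
    cluster_of <- rep(c(1L, 2L, 3L, NA_integer_),
                      c(n_cl, P - sum(n_cl)))
    corr_start <- sum(n_cl)
    r_target <- rep(0, P)
    if (design$n_corr_pos > 0)
      r_target[corr_start + seq_len(design$n_corr_pos)] <- design$target_corr
    if (design$n_corr_neg > 0)
      r_target[corr_start + design$n_corr_pos + seq_len(design$n_corr_neg)] <-
        -design$target_corr

    base <- rnorm(P, mean = 20, sd = 2)
    log2ab <- matrix(rnorm(P * n_samples, sd = design$noise_sd), P, n_samples,
                     dimnames = list(protein_ids, sample_ids))
    log2ab <- log2ab + base
    gi <- as.integer(group)  # 1 = Ctrl, 2 = MCI, 3 = AD
    for (k in 1:3) {
      rows <- which(!is.na(cluster_of) & cluster_of == k)
      if (length(rows) > 0) {
        offs <- design$effect_size * .trajectory_offsets[[as.character(k)]][gi]
        log2ab[rows, ] <- log2ab[rows, ] + rep(offs, each = length(rows))
      }
    }
    corr_rows <- which(r_target != 0)
    if (length(corr_rows) > 0) {
      r <- design$target_corr
      beta <- design$noise_sd * r / sqrt(1 - r^2)
      slope <- sign(r_target[corr_rows]) * beta
      log2ab[corr_rows, ] <- log2ab[corr_rows, ] +
        outer(slope, z_mmse)
    }

    pm <- proteome_matrix(2^log2ab, group, mmse, log2_scale = FALSE)
    if (design$missing_rate > 0)
      pm <- inject_missing(pm, design$missing_rate)

    has_effect <- design$effect_size != 0
    ids_cl <- function(k) protein_ids[!is.na(cluster_of) & cluster_of == k]
    de <- list(
      MCI_vs_Ctrl = if (has_effect) c(ids_cl(1), ids_cl(2), ids_cl(3)) else character(0),
      AD_vs_Ctrl  = if (has_effect) c(ids_cl(1), ids_cl(3)) else character(0),
      AD_vs_MCI   = if (has_effect) c(ids_cl(1), ids_cl(2), ids_cl(3)) else character(0)
    )
    truth <- structure(list(
      de = de,
      cluster = data.frame(protein = protein_ids[!is.na(cluster_of)],
                           cluster = cluster_of[!is.na(cluster_of)]),
      mmse_correlated = data.frame(protein = protein_ids[r_target != 0],
                                   r_target = r_target[r_target != 0]),
      true_panel = if (has_effect) head(ids_cl(1), design$panel_size) else character(0),
      design = design
    ), class = "ground_truth")
    if (!has_effect) truth$cluster <- truth$cluster[0, ]
    list(matrix = pm, truth = truth)
  })
}

#' Inject left-censored missingness
#'
#' Marks cells missing with a probability that decreases linearly in the
#' cell's abundance rank and vanishes above the `censor_quantile` of all
#' cells, emulating the detection-limit mechanism that downshifted-normal
#' imputation assumes: low-intensity measurements drop out, so low-abundance
#' proteins lose the most cells, and the overall missing fraction is
#' approximately `missing_rate`. Because missingness is value-dependent
#' (missing cells really were low), imputing below the observed distribution
#' is the consistent fill-in. Draws use the current RNG stream (seeded by
#' [generate_cohort()]).
#'
#' @param pm a [proteome_matrix()] without missing values.
#' @param missing_rate overall target fraction in \[0, 1).
#' @param censor_quantile only cells below this abundance quantile can go
#'   missing (default 0.25).
#' @return The matrix with `NA` cells injected.
#' @export
inject_missing <- function(pm, missing_rate, censor_quantile = 0.25) {
  if (missing_rate < 0 || missing_rate >= 1)
    fail("missing_rate must be in [0, 1)")
  if (missing_rate == 0) return(pm)
  ab <- pm$abundance
  # u = cell's abundance rank fraction; p(u) = c * (1 - u/q) below q, 0 above,
  # with c chosen so the mean over all cells is missing_rate
  u <- (rank(ab, ties.method = "first") - 0.5) / length(ab)
  p_cell <- pmin(0.9, (2 * missing_rate / censor_quantile) *
                   pmax(0, 1 - u / censor_quantile))
  ab[runif(length(ab)) < p_cell] <- NA_real_
  proteome_matrix(ab, pm$group, pm$mmse, log2_scale = pm$log2_scale)
}
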