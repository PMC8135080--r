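#' Filter proteins by per-group quantification completeness
#'
#' Keeps proteins observed (non-missing) in at least `min_frac` of the samples
#' of every group, the usual "valid values per group" rule applied before
#' imputation and testing. The published analysis reduced 4,165 identified to
#' 2,994 proteins "effectively captured in each experimental group" without
#' stating its rule; 70% per group is the configurable default here.
#'
#' @param pm a [proteome_matrix()].
#' @param min_frac minimum observed fraction per group, in (0, 1\].
#' @return The filtered `proteome_matrix`.
#' @export
filter_min_valid <- function(pm, min_frac = 0.7) {
  if (min_frac <= 0 || min_frac > 1) fail("min_frac must be in (0, 1]")
  ok <- rep(TRUE, nrow(pm$abundance))
  for (g in levels(pm$group)) {
    cols <- pm$group == g
    if (!any(cols)) next
    frac <- rowMeans(!is.na(pm$abundance[, cols, drop = FALSE]))
    ok <- ok & frac >= min_frac
  }
  proteome_matrix(pm$abundance[ok, , drop = FALSE], pm$group, pm$mmse,
                  log2_scale = pm$log2_scale)
}

#' Median-center each sample column on the log2 scale
#'
#' Perseus-style column normalization: abundances are log2-transformed (if not
#' already) and every sample column is shifted so its median equals the global
#' median of the log2 matrix. Removes per-channel loading differences while
#' preserving within-sample structure. Idempotent on an already-centered
#' matrix.
#'
#' @param pm a [proteome_matrix()] (raw or log2 scale).
#' @return A log2-scale `proteome_matrix` with equal column medians.
#' @export
normalize_columns <- function(pm) {
  ab <- pm$abundance
  if (!pm$log2_scale) ab <- log2(ab)
  all_na <- colSums(!is.na(ab)) == 0
  if (any(all_na))
    fail("sample(s) with no observed values: %s",
         paste(colnames(ab)[all_na], collapse = ", "))
  global_med <- median(ab, na.rm = TRUE)
  col_med <- apply(ab, 2, median, na.rm = TRUE)
  ab <- sweep(ab, 2, col_med - global_med)
  proteome_matrix(ab, pm$group, pm$mmse, log2_scale = TRUE)
}

#' Impute missing values from a downshifted normal distribution
#'
#' Perseus' default "replace missing values from normal distribution": each
#' missing cell in a sample column is drawn from
#' Normal(mean - `downshift` * SD, (`width` * SD)^2), where mean and SD are the
#' column's observed log2 statistics. This models intensities missing because
#' they fell below the detection limit. Observed cells are never modified.
#'
#' @param pm a log2-scale [proteome_matrix()].
#' @param width imputation SD as a fraction of the column SD (default 0.3).
#' @param downshift distribution shift in column SDs (default 1.8).
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return A `proteome_matrix` with no missing values.
#' @export
impute_downshifted <- function(pm, width = 0.3, downshift = 1.8, seed = NULL) {
  if (!pm$log2_scale)
    fail("impute_downshifted() expects a log2-scale matrix; run normalize_columns() first")
  ab <- pm$abundance
  if (!anyNA(ab)) return(pm)
  with_seed(seed, {
    for (j in seq_len(ncol(ab))) {
      miss <- is.na(ab[, j])
      if (!any(miss)) next
      obs <- ab[!miss, j]
      if (length(obs) < 2)
        fail("column '%s' has fewer than 2 observed values", colnames(ab)[j])
      m <- mean(obs)
      s <- sd(obs)
      ab[miss, j] <- rnorm(sum(miss), mean = m - downshift * s, sd = width * s)
    }
    proteome_matrix(ab, pm$group, pm$mmse, log2_scale = TRUE)
  })
}

#' Per-protein two-sample t-test for one group contrast
#'
#' Student (pooled-variance) two-sided t-test on log2 abundances for every
#' protein, vectorized across the matrix. The contrast `c(a, b)` is reported as
#' "b vs a": `log2_fold_change = mean_b - mean_a`, direction `up` when positive.
#' Welch's unequal-variance test is available behind `var_equal = FALSE`. A
#' Benjamini-Hochberg adjusted p-value is emitted for information only; the
#' published selection rule is raw p < 0.05.
#'
#' @param pm a log2-scale [proteome_matrix()] without missing values in the
#'   tested groups (impute first).
#' @param contrast character pair `c(reference, test)`, e.g. `c("Ctrl", "MCI")`.
#' @param var_equal pooled-variance Student test if `TRUE` (default), Welch
#'   otherwise.
#' @return A data frame of class `de_comparison` with columns `protein`,
#'   `mean_a`, `mean_b`, `log2_fold_change`, `t_statistic`, `df`, `p_value`,
#'   `p_adj_bh`, `direction`, and attribute `contrast`.
#' @export
t_test_per_protein <- function(pm, contrast = c("Ctrl", "MCI"),
                               var_equal = TRUE) {
  if (length(contrast) != 2 || !all(contrast %in% levels(pm$group)))
    fail("contrast must be two of %s", paste(levels(pm$group), collapse = "/"))
  a_cols <- pm$group == contrast[1]
  b_cols <- pm$group == contrast[2]
  xa <- pm$abundance[, a_cols, drop = FALSE]
  xb <- pm$abundance[, b_cols, drop = FALSE]
  na_ <- rowSums(!is.na(xa))
  nb_ <- rowSums(!is.na(xb))
  if (any(na_ < 2 | nb_ < 2))
    fail("every protein needs >= 2 observed values per group (impute first)")
  ma <- rowMeans(xa, na.rm = TRUE)
  mb <- rowMeans(xb, na.rm = TRUE)
  va <- rowSums((xa - ma)^2, na.rm = TRUE) / (na_ - 1)
  vb <- rowSums((xb - mb)^2, na.rm = TRUE) / (nb_ - 1)
  if (var_equal) {
    sp2 <- ((na_ - 1) * va + (nb_ - 1) * vb) / (na_ + nb_ - 2)
    se <- sqrt(sp2 * (1 / na_ + 1 / nb_))
    df <- na_ + nb_ - 2
  } else {
    se <- sqrt(va / na_ + vb / nb_)
    df <- (va / na_ + vb / nb_)^2 /
      ((va / na_)^2 / (na_ - 1) + (vb / nb_)^2 / (nb_ - 1))
  }
  tstat <- (mb - ma) / se
  tstat[se == 0 & mb == ma] <- 0        # identical groups: t = 0, p = 1
  p <- 2 * pt(-abs(tstat), df)
  p[is.na(p) & se == 0] <- 1
  res <- data.frame(
    protein = rownames(pm$abundance),
    mean_a = ma, mean_b = mb,
    log2_fold_change = mb - ma,
    t_statistic = tstat, df = df,
    p_value = p,
    p_adj_bh = p.adjust(p, method = "BH"),
    direction = ifelse(mb - ma >= 0, "up", "down"),
    row.names = NULL
  )
  attr(res, "contrast") <- contrast
  class(res) <- c("de_comparison", "data.frame")
  res
}

#' Summarize differential expression across contrasts
#'
#' Counts up/down-regulated proteins at raw `p < alpha` per contrast, the
#' overlap of the two Ctrl-referenced contrasts, and the union over all
#' contrasts ("total differential proteins", the published 360-analog).
#'
#' @param comparisons named list of [t_test_per_protein()] results sharing a
#'   protein universe; names like `"MCI_vs_Ctrl"`.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @return A list of class `de_summary`: `counts` (data frame contrast /
#'   n_up / n_down / n_sig), `significant` (named list of protein id sets),
#'   `overlap_ctrl` (intersection of Ctrl-referenced contrasts), `union`
#'   (all contrasts), `alpha`.
#' @export
summarize_de <- function(comparisons, alpha = 0.05) {
  if (is.null(names(comparisons)) || any(names(comparisons) == ""))
    fail("'comparisons' must be a named list")
  universe <- comparisons[[1]]$protein
  sig <- lapply(comparisons, function(cmp) {
    if (!setequal(cmp$protein, universe))
      fail("comparisons do not share a protein universe")
    cmp$protein[cmp$p_value < alpha]
  })
  counts <- do.call(rbind, lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    s <- cmp$p_value < alpha
    data.frame(contrast = nm,
               n_up = sum(s & cmp$direction == "up"),
               n_down = sum(s & cmp$direction == "down"),
               n_sig = sum(s))
  }))
  ctrl_ref <- grep("_vs_Ctrl$", names(comparisons), value = TRUE)
  overlap <- if (length(ctrl_ref) >= 2)
    Reduce(intersect, sig[ctrl_ref]) else character(0)
  structure(list(counts = counts, significant = sig,
                 overlap_ctrl = overlap,
                 union = Reduce(union, sig), alpha = alpha),
            class = "de_summary")
}

#' @export
print.de_summary <- function(x, ...) {
  cat(sprintf("Differential expression at raw p < %.3g\n", x$alpha))
  print(x$counts, row.names = FALSE)
  cat(sprintf("Ctrl-referenced overlap: %d; union (total differential): %d\n",
              length(x$overlap_ctrl), length(x$union)))
  invisible(x)
}

#' Run the three canonical contrasts
#'
#' Convenience wrapper running MCI vs Ctrl, AD vs Ctrl and AD vs MCI, the three
#' comparison groups of the published design.
#'
#' @inheritParams t_test_per_protein
#' @return Named list of `de_comparison` data frames.
#' @export
run_de_contrasts <- function(pm, var_equal = TRUE) {
  list(
    MCI_vs_Ctrl = t_test_per_protein(pm, c("Ctrl", "MCI"), var_equal),
    AD_vs_Ctrl  = t_test_per_protein(pm, c("Ctrl", "AD"), var_equal),
    AD_vs_MCI   = t_test_per_protein(pm, c("MCI", "AD"), var_equal)
  )
}
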