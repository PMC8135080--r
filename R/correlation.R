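#' Pearson correlation of every protein with MMSE
#'
#' Product-moment correlation of each protein's (log2) abundance profile with
#' the MMSE score across all samples, with two-sided p-values from the exact t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#' Proteins are classed `PC` (positively correlated, r > 0 and p < alpha),
#' `NC` (negatively correlated) or `ns`. Zero-variance proteins cannot be
#' correlated and are flagged `excluded`.
#'
#' @param pm a [proteome_matrix()]; correlations are computed on the stored
#'   (normalized, imputed log2) abundances.
#' @param alpha significance threshold for the NC/PC split (default 0.05).
#' @return A data frame of class `correlation_table` with columns `protein`,
#'   `r`, `p_value`, `n`, `class` (`NC`/`PC`/`ns`/`excluded`).
#' @export
pearson_vs_mmse <- function(pm, alpha = 0.05) {
  ab <- pm$abundance
  if (anyNA(ab))
    fail("missing values present; normalize and impute before correlating")
  y <- pm$mmse
  n <- length(y)
  if (n < 3) fail("need at least 3 samples")
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  xc <- ab - rowMeans(ab)
  sx <- sqrt(rowSums(xc^2))
  excluded <- sx == 0 | sy == 0
  r <- as.vector(xc %*% yc) / (sx * sy)
  r[excluded] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  p[abs(r) >= 1] <- 0
  cls <- ifelse(excluded, "excluded",
                ifelse(p < alpha & r > 0, "PC",
                       ifelse(p < alpha & r < 0, "NC", "ns")))
  res <- data.frame(protein = rownames(ab), r = r, p_value = p, n = n,
                    class = cls, row.names = NULL)
  attr(res, "alpha") <- alpha
  class(res) <- c("correlation_table", "data.frame")
  res
}

#' Build the candidate set: differential and MMSE-correlated
#'
#' Intersects the MMSE-correlated proteins (p < alpha, i.e. class NC or PC)
#' with the differential-expression union, the published candidate rule
#' ("not only differentially expressed but also correlated to MMSE").
#' Candidates are ranked by |r| descending (ties broken by protein id), and an
#' optional exclusion list (e.g. complement-pathway members, removed in the
#' published analysis) is applied with annotation.
#'
#' @param corr_table a [pearson_vs_mmse()] result.
#' @param de_summary a [summarize_de()] result over the same universe.
#' @param exclude optional protein ids to drop from the candidate list.
#' @return A data frame of class `candidate_set`: columns `protein`, `r`,
#'   `p_value`, `class`, plus one logical `de_<contrast>` column per contrast.
#'   Attribute `excluded_hits` records which exclusions matched. Empty (with a
#'   warning) if the intersection is empty.
#' @export
build_candidates <- function(corr_table, de_summary, exclude = NULL) {
  sig <- corr_table[corr_table$class %in% c("NC", "PC"), , drop = FALSE]
  members <- intersect(sig$protein, de_summary$union)
  if (length(members) == 0)
    warning("no protein is both MMSE-correlated and differential")
  res <- sig[match(members, sig$protein),
             c("protein", "r", "p_value", "class"), drop = FALSE]
  for (nm in names(de_summary$significant))
    res[[paste0("de_", nm)]] <- res$protein %in% de_summary$significant[[nm]]
  excluded_hits <- intersect(exclude, res$protein)
  res <- res[!res$protein %in% excluded_hits, , drop = FALSE]
  res <- res[order(-abs(res$r), res$protein), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded_hits") <- excluded_hits
  class(res) <- c("candidate_set", "data.frame")
  res
}

#' Pairwise Pearson correlation among candidate proteins
#'
#' Symmetric unit-diagonal matrix of protein-protein correlations across
#' samples, the candidate co-regulation structure.
#'
#' @param pm a [proteome_matrix()] without missing values.
#' @param candidates at least two protein ids present in the matrix.
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
candidate_corr_matrix <- function(pm, candidates) {
  if (length(candidates) < 2) fail("need at least 2 candidates")
  pm_sub <- subset_proteins(pm, candidates)
  cc <- stats::cor(t(pm_sub$abundance))
  (cc + t(cc)) / 2
}

#' Long-format pairwise correlations
#'
#' @param corr_matrix a [candidate_corr_matrix()] result.
#' @return A data frame `protein_a`, `protein_b`, `r` over unordered pairs.
#' @export
corr_matrix_long <- function(corr_matrix) {
  idx <- which(upper.tri(corr_matrix), arr.ind = TRUE)
  data.frame(protein_a = rownames(corr_matrix)[idx[, 1]],
             protein_b = colnames(corr_matrix)[idx[, 2]],
             r = corr_matrix[idx])
}
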