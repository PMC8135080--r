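#' Read a GMT gene-set file
#'
#' Standard tab-separated gene-set exchange format: one set per line, fields
#' `name`, `description`, then member identifiers. Duplicate members within a
#' line are collapsed.
#'
#' @param path path to a GMT file.
#' @return A named list of character vectors of class `gene_set_collection`,
#'   with a `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) fail("GMT file is empty: %s", path)
  sets <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      fail("malformed GMT line %d (need name, description, >= 1 member): %s",
           i, path)
    nm <- fields[1]
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) fail("GMT line %d has no members", i)
    if (nm %in% names(sets)) fail("duplicated set name '%s' (line %d)", nm, i)
    sets[[nm]] <- members
    descriptions[nm] <- fields[2]
  }
  structure(sets, description = descriptions, class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of observing at
#' least the realized overlap `k` between the target list (size n) and the set
#' (size K within the background of size N): `p = P(X >= k)`. Stands in for the
#' Metascape/DAVID/WebGestalt style calls of the published analysis, with its
#' reporting rule: sets kept when the overlap has at least `min_overlap`
#' proteins and raw `p < alpha`. A BH-adjusted p over all tested sets is
#' emitted for information. The background should be the quantified-protein
#' universe, not the genome.
#'
#' @param target_ids protein/gene ids of interest (must all be in the
#'   background).
#' @param background_ids the tested universe.
#' @param collection a [read_gmt()] result (or named list of id vectors).
#' @param min_overlap minimum overlap to report (default 3).
#' @param alpha raw p-value cutoff for reporting (default 0.01).
#' @param filter if `FALSE`, return all sets unfiltered.
#' @return A data frame of class `enrichment_result`, sorted by p: columns
#'   `set`, `k` (overlap), `K` (set size in background), `n` (target size),
#'   `N` (background size), `p_value`, `p_adj_bh`, `overlap_ids`
#'   (comma-separated).
#' @export
ora <- function(target_ids, background_ids, collection,
                min_overlap = 3, alpha = 0.01, filter = TRUE) {
  target <- unique(target_ids)
  bg <- unique(background_ids)
  stray <- setdiff(target, bg)
  if (length(stray) > 0)
    fail("target ids not in background: %s",
         paste(head(stray, 10), collapse = ", "))
  N <- length(bg)
  n <- length(target)
  rows <- lapply(names(collection), function(nm) {
    set_bg <- intersect(unique(collection[[nm]]), bg)
    K <- length(set_bg)
    hits <- intersect(target, set_bg)
    k <- length(hits)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p_value = p,
               overlap_ids = paste(sort(hits), collapse = ","))
  })
  res <- do.call(rbind, rows)
  res$p_adj_bh <- p.adjust(res$p_value, method = "BH")
  res <- res[, c("set", "k", "K", "n", "N", "p_value", "p_adj_bh",
                 "overlap_ids")]
  if (filter)
    res <- res[res$k >= min_overlap & res$p_value < alpha, , drop = FALSE]
  res <- res[order(res$p_value, res$set), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
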