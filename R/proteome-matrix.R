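#' Construct a proteome matrix with sample metadata
#'
#' The central data container of the pipeline: a protein x sample abundance
#' matrix together with the per-sample cognition group (Ctrl, MCI, AD) and
#' MMSE score (mini-mental state examination, 0-30, lower = more impaired).
#' Raw reporter abundances are positive and possibly missing (`NA`);
#' [normalize_columns()] moves the container onto the log2 scale.
#'
#' @param abundance numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns (colnames = sample ids). May contain `NA`.
#' @param group character or factor of length `ncol(abundance)` with values in
#'   `c("Ctrl", "MCI", "AD")`.
#' @param mmse integer vector of length `ncol(abundance)`, each in 0..30.
#' @param log2_scale logical; `TRUE` if `abundance` is already log2-transformed.
#' @return An object of class `proteome_matrix`: a list with elements
#'   `abundance`, `group` (factor Ctrl < MCI < AD), `mmse`, `log2_scale`.
#' @export
proteome_matrix <- function(abundance, group, mmse, log2_scale = FALSE) {
  if (!is.matrix(abundance) || !is.numeric(abundance))
    fail("'abundance' must be a numeric matrix")
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    fail("'abundance' needs protein rownames and sample colnames")
  if (anyDuplicated(rownames(abundance)))
    fail("duplicated protein ids in abundance matrix")
  if (anyDuplicated(colnames(abundance)))
    fail("duplicated sample ids in abundance matrix")
  if (length(group) != ncol(abundance))
    fail("length(group) != number of samples")
  if (length(mmse) != ncol(abundance))
    fail("length(mmse) != number of samples")
  group <- factor(as.character(group), levels = c("Ctrl", "MCI", "AD"))
  if (anyNA(group)) fail("group labels must be Ctrl, MCI or AD")
  mmse <- as.integer(mmse)
  if (anyNA(mmse) || any(mmse < 0 | mmse > 30))
    fail("MMSE scores must be integers in [0, 30]")
  if (!log2_scale && any(abundance <= 0, na.rm = TRUE))
    fail("raw-scale abundances must be positive")
  structure(
    list(abundance = abundance, group = group, mmse = mmse,
         log2_scale = isTRUE(log2_scale)),
    class = "proteome_matrix"
  )
}

#' @export
print.proteome_matrix <- function(x, ...) {
  cat(sprintf("proteome_matrix: %d proteins x %d samples (%s scale)\n",
              nrow(x$abundance), ncol(x$abundance),
              if (x$log2_scale) "log2" else "raw"))
  cat("  groups:", paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                         collapse = " "), "\n")
  n_missing <- sum(is.na(x$abundance))
  cat(sprintf("  missing: %d cells (%.1f%%)\n", n_missing,
              100 * n_missing / length(x$abundance)))
  invisible(x)
}

#' @export
dim.proteome_matrix <- function(x) dim(x$abundance)

#' Subset a proteome matrix by protein ids
#' @param pm a [proteome_matrix()].
#' @param proteins character vector of protein ids (must all be present).
#' @return A `proteome_matrix` restricted to `proteins`.
#' @export
subset_proteins <- function(pm, proteins) {
  missing <- setdiff(proteins, rownames(pm$abundance))
  if (length(missing) > 0)
    fail("proteins not in matrix: %s", paste(head(missing, 5), collapse = ", "))
  proteome_matrix(pm$abundance[proteins, , drop = FALSE], pm$group, pm$mmse,
                  log2_scale = pm$log2_scale)
}

#' Write / read a proteome matrix as TSV files
#'
#' The matrix file has a `protein` id column followed by one column per sample;
#' the sample sheet has columns `sample_id`, `group`, `mmse`. Both are plain
#' tab-separated text, the exchange format of every pipeline stage.
#'
#' @param pm a [proteome_matrix()].
#' @param matrix_path,samples_path file paths.
#' @return `write_proteome`: invisibly, the matrix path. `read_proteome`: a
#'   `proteome_matrix`.
#' @export
write_proteome <- function(pm, matrix_path, samples_path) {
  mat <- data.frame(protein = rownames(pm$abundance), pm$abundance,
                    check.names = FALSE)
  write_tsv(mat, matrix_path)
  sheet <- data.frame(sample_id = colnames(pm$abundance),
                      group = as.character(pm$group), mmse = pm$mmse)
  write_tsv(sheet, samples_path)
  invisible(matrix_path)
}

#' @rdname write_proteome
#' @param log2_scale logical; scale of the stored abundances.
#' @export
read_proteome <- function(matrix_path, samples_path, log2_scale = FALSE) {
  mat <- read_tsv(matrix_path)
  if (colnames(mat)[1] != "protein")
    fail("matrix file must start with a 'protein' column: %s", matrix_path)
  ab <- as.matrix(mat[, -1, drop = FALSE])
  rownames(ab) <- mat$protein
  sheet <- read_tsv(samples_path)
  need <- c("sample_id", "group", "mmse")
  if (!all(need %in% colnames(sheet)))
    fail("sample sheet must have columns sample_id, group, mmse: %s",
         samples_path)
  idx <- match(colnames(ab), sheet$sample_id)
  if (anyNA(idx))
    fail("samples missing from sample sheet: %s",
         paste(colnames(ab)[is.na(idx)], collapse = ", "))
  proteome_matrix(ab, sheet$group[idx], sheet$mmse[idx],
                  log2_scale = log2_scale)
}
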