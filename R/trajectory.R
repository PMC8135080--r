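#' Group-mean trajectory profiles
#'
#' For each requested protein, the ordered triple of mean log2 abundances over
#' (Ctrl, MCI, AD) and its standardized version (mean 0, population SD 1), the
#' shape representation that trajectory clustering operates on. Flat profiles
#' (zero SD) are flagged and excluded from clustering.
#'
#' @param pm a log2-scale [proteome_matrix()].
#' @param proteins protein ids to profile (typically the DE union).
#' @return A list of class `trajectory_profiles`: `means` and `z` (matrices
#'   with columns Ctrl/MCI/AD), `flat` (logical vector).
#' @export
compute_profiles <- function(pm, proteins) {
  if (length(proteins) == 0) fail("'proteins' must be non-empty")
  missing <- setdiff(proteins, rownames(pm$abundance))
  if (length(missing) > 0)
    fail("proteins absent from matrix: %s",
         paste(head(missing, 5), collapse = ", "))
  ab <- pm$abundance[proteins, , drop = FALSE]
  means <- sapply(levels(pm$group), function(g)
    rowMeans(ab[, pm$group == g, drop = FALSE], na.rm = TRUE))
  means <- matrix(means, ncol = 3,
                  dimnames = list(proteins, levels(pm$group)))
  ctr <- means - rowMeans(means)
  sd_pop <- sqrt(rowMeans(ctr^2))      # population SD (divisor n = 3)
  flat <- sd_pop < 1e-12
  z <- ctr / ifelse(flat, 1, sd_pop)
  structure(list(means = means, z = z, flat = flat),
            class = "trajectory_profiles")
}

# standardized archetype templates, ordered (Ctrl, MCI, AD); used only for
# labeling clusters, never for fitting
.archetypes <- rbind(
  monotone_down = c(1, 0, -1) / sqrt(2 / 3),
  down_up       = c(1, -2, 1) / sqrt(2),
  monotone_up   = c(-1, 0, 1) / sqrt(2 / 3)
)

.label_centroid <- function(ctr) {
  if (ctr[1] > ctr[2] && ctr[2] > ctr[3]) return("monotone_down")
  if (ctr[1] < ctr[2] && ctr[2] < ctr[3]) return("monotone_up")
  if (ctr[2] < ctr[1] && ctr[2] < ctr[3]) return("down_up")
  NA_character_
}

#' Cluster trajectory profiles into the three archetypes
#'
#' k-means (k = 3) on standardized group-mean triples with a deterministic
#' seeded multi-start (20 starts, best within-cluster sum of squares kept).
#' Profiles are sorted by protein id before clustering, so the assignment is
#' invariant to input order. Clusters are then labeled by centroid shape:
#' cluster 1 = monotone decreasing across Ctrl -> MCI -> AD, cluster 2 =
#' minimum at MCI (V shape), cluster 3 = monotone increasing. If a centroid
#' matches no archetype the three clusters are labeled by the nearest archetype
#' template (best one-to-one matching), with a warning.
#'
#' @param profiles a [compute_profiles()] result with at least 3 non-flat
#'   profiles.
#' @param seed integer seed for the multi-start.
#' @param method `"kmeans"` (default) or `"hclust"` (average-linkage Euclidean,
#'   cut at k = 3).
#' @return A list of class `cluster_result`: `assignment` (data frame protein /
#'   cluster / archetype), `centroids` (3 x 3 matrix), `sizes`, `flat`
#'   (excluded protein ids).
#' @export
cluster_k3 <- function(profiles, seed = 1L, method = c("kmeans", "hclust")) {
  method <- match.arg(method)
  keep <- !profiles$flat
  z <- profiles$z[keep, , drop = FALSE]
  if (nrow(z) < 3) fail("need at least 3 non-flat profiles")
  z <- z[order(rownames(z)), , drop = FALSE]
  cl <- if (method == "kmeans") {
    with_seed(seed,
              kmeans(z, centers = 3, nstart = 20, iter.max = 100)$cluster)
  } else {
    cutree(hclust(dist(z), method = "average"), k = 3)
  }
  centroids <- t(sapply(1:3, function(k) colMeans(z[cl == k, , drop = FALSE])))
  colnames(centroids) <- colnames(profiles$z)

  labels <- apply(centroids, 1, .label_centroid)
  if (anyNA(labels) || anyDuplicated(labels)) {
    warning("centroid shapes do not match the three archetypes uniquely; ",
            "labeling by nearest archetype template")
    perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    cost <- function(p) sum((centroids - .archetypes[p, , drop = FALSE])^2)
    best <- perms[[which.min(vapply(perms, cost, numeric(1)))]]
    labels <- rownames(.archetypes)[best]
  }
  # renumber so cluster 1/2/3 = monotone_down/down_up/monotone_up
  new_id <- match(labels, rownames(.archetypes))
  assignment <- data.frame(
    protein = rownames(z),
    cluster = new_id[cl],
    archetype = rownames(.archetypes)[new_id[cl]],
    row.names = NULL
  )
  centroids <- centroids[order(new_id), , drop = FALSE]
  rownames(centroids) <- rownames(.archetypes)
  structure(list(assignment = assignment, centroids = centroids,
                 sizes = setNames(tabulate(assignment$cluster, 3), 1:3),
                 flat = rownames(profiles$z)[profiles$flat]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Trajectory clusters (Ctrl -> MCI -> AD):\n")
  for (k in 1:3)
    cat(sprintf("  cluster %d (%s): n = %d\n", k,
                rownames(x$centroids)[k], x$sizes[k]))
  if (length(x$flat) > 0)
    cat(sprintf("  flat profiles excluded: %d\n", length(x$flat)))
  invisible(x)
}
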