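#' Leave-one-out folds
#'
#' One fold per sample: the held-out sample is the validation set, all others
#' train. For the published 9/10/9 cohort this yields exactly 28
#' train/validate cycles.
#'
#' @param sample_ids unique sample identifiers.
#' @return A list of `n` lists with elements `train` (ids) and `test` (one id).
#' @export
loo_folds <- function(sample_ids) {
  if (anyDuplicated(sample_ids))
    fail("duplicate sample ids: %s",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(sample_ids) < 3) fail("need at least 3 samples for LOO")
  lapply(seq_along(sample_ids), function(i)
    list(train = sample_ids[-i], test = sample_ids[i]))
}

# impaired (MCI + AD) vs Ctrl binary target
.binary_labels <- function(pm, positive = c("MCI", "AD")) {
  as.character(pm$group) %in% positive
}

# pooled LOO probabilities for one panel, pure-R engine; autoscaling uses
# training-fold statistics only (no leakage)
.loo_probs_r <- function(X, y, lambda = 1, balanced = TRUE) {
  n <- nrow(X)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ctr <- colMeans(Xtr)
    scl <- apply(Xtr, 2, sd)
    scl[scl == 0] <- 1
    Xtr <- scale(Xtr, ctr, scl)
    fit <- fit_balanced_logistic(Xtr, y[-i], lambda = lambda,
                                 balanced = balanced)
    xt <- (X[i, ] - ctr) / scl
    probs[i] <- predict(fit, matrix(xt, nrow = 1))
  }
  probs
}

#' Evaluate one biomarker panel by pooled leave-one-out
#'
#' For every fold, a class-balanced ridge logistic classifier
#' ([fit_balanced_logistic()]) is fit on the training samples (features
#' autoscaled with training-fold statistics only) and the held-out sample's
#' predicted probability of being cognitively impaired (MCI or AD) is
#' recorded. The n pooled probabilities give a confusion matrix at the
#' threshold, the published metric formulas, and ROC/PR curves (trapezoidal /
#' step-rule areas, ties half-credited). Deterministic: there is no random
#' state in folds or fitting.
#'
#' @param pm a normalized, imputed log2-scale [proteome_matrix()].
#' @param panel non-empty protein id vector.
#' @param positive group labels forming the positive class (default MCI + AD).
#' @param threshold probability cutoff for the confusion matrix (default 0.5).
#' @param lambda ridge penalty (default 1).
#' @param engine `"cpp"` (compiled fast path) or `"r"` (reference
#'   implementation); both produce the same probabilities.
#' @return A list of class `panel_evaluation`: `panel`, `probs` (named pooled
#'   probabilities), `labels`, `metrics` (a [metric_set()]), `roc`, `pr`.
#' @export
evaluate_panel <- function(pm, panel, positive = c("MCI", "AD"),
                           threshold = 0.5, lambda = 1,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (length(panel) == 0) fail("panel must be non-empty")
  y <- .binary_labels(pm, positive)
  X <- t(subset_proteins(pm, panel)$abundance)
  if (anyNA(X)) fail("missing values present; impute before panel evaluation")
  probs <- if (engine == "cpp") {
    as.vector(cpp_loo_panel_probs(X, as.integer(y),
                                  list(seq_along(panel) - 1L), lambda))
  } else {
    .loo_probs_r(X, y, lambda = lambda)
  }
  names(probs) <- rownames(X)
  structure(list(panel = panel, probs = probs, labels = y,
                 metrics = metric_set(probs, y, threshold),
                 roc = roc_curve(probs, y), pr = pr_curve(probs, y)),
            class = "panel_evaluation")
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat("Panel:", paste(x$panel, collapse = " + "), "\n")
  print(x$metrics)
  invisible(x)
}

# ranking key shared by both searches: AUCROC desc, accuracy desc, size asc,
# panel string lexicographic
.rank_panels <- function(df) {
  df[order(-df$auc_roc, -df$accuracy, df$k, df$panel), , drop = FALSE]
}

.panel_metrics_df <- function(panels, probs_mat, y, threshold) {
  rows <- lapply(seq_along(panels), function(j) {
    m <- metric_set(probs_mat[, j], y, threshold)
    data.frame(panel = paste(panels[[j]], collapse = "+"),
               k = length(panels[[j]]),
               auc_roc = m$auc_roc, auc_pr = m$auc_pr,
               accuracy = m$accuracy, recall = m$recall,
               precision = m$precision, f1 = m$f1)
  })
  do.call(rbind, rows)
}

#' Exhaustive leave-one-out panel search
#'
#' Evaluates every non-empty subset of the candidate proteins (2^k - 1 panels)
#' by [evaluate_panel()] and ranks them by AUCROC descending, then accuracy
#' descending, then panel size ascending, then lexicographically. Per-size
#' winners are reported alongside the global ranking. Capped at 20 candidates
#' (use [greedy_forward_search()] beyond that).
#'
#' @inheritParams evaluate_panel
#' @param candidates candidate protein ids, between 1 and 20.
#' @return A list of class `search_result`: `ranked` (data frame of all
#'   panels with metrics), `best` (protein ids of the rank-1 panel),
#'   `best_evaluation` (full [evaluate_panel()] of the best panel),
#'   `per_size` (best panel per size), `n_panels`.
#' @export
exhaustive_search <- function(pm, candidates, positive = c("MCI", "AD"),
                              threshold = 0.5, lambda = 1,
                              engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  candidates <- unique(candidates)
  k <- length(candidates)
  if (k < 1) fail("need at least one candidate")
  if (k > 20)
    fail("%d candidates give %g panels; use greedy_forward_search()", k, 2^k - 1)
  y <- .binary_labels(pm, positive)
  X <- t(subset_proteins(pm, candidates)$abundance)
  if (anyNA(X)) fail("missing values present; impute before panel search")
  panels <- unlist(lapply(seq_len(k), function(m)
    combn(candidates, m, simplify = FALSE)), recursive = FALSE)
  idx0 <- lapply(panels, function(p) match(p, candidates) - 1L)
  probs_mat <- if (engine == "cpp") {
    cpp_loo_panel_probs(X, as.integer(y), idx0, lambda)
  } else {
    vapply(panels, function(p)
      .loo_probs_r(X[, match(p, candidates), drop = FALSE], y, lambda),
      numeric(nrow(X)))
  }
  ranked <- .rank_panels(.panel_metrics_df(panels, probs_mat, y, threshold))
  rownames(ranked) <- NULL
  per_size <- do.call(rbind, lapply(sort(unique(ranked$k)), function(m)
    ranked[ranked$k == m, , drop = FALSE][1, , drop = FALSE]))
  rownames(per_size) <- NULL
  best <- strsplit(ranked$panel[1], "+", fixed = TRUE)[[1]]
  structure(list(ranked = ranked, best = best,
                 best_evaluation = evaluate_panel(pm, best, positive,
                                                  threshold, lambda, engine),
                 per_size = per_size, n_panels = length(panels)),
            class = "search_result")
}

#' Greedy forward leave-one-out panel search
#'
#' Starts from the empty panel and repeatedly adds the candidate that
#' maximizes the ranking key (AUCROC, then accuracy, then size, then
#' lexicographic), stopping when no addition improves the AUCROC. Linear in
#' the number of candidates, so usable beyond the exhaustive-search cap; its
#' best AUCROC can never exceed the exhaustive optimum.
#'
#' @inheritParams exhaustive_search
#' @return A `search_result` (with `ranked` listing the evaluated panels along
#'   the greedy path).
#' @export
greedy_forward_search <- function(pm, candidates, positive = c("MCI", "AD"),
                                  threshold = 0.5, lambda = 1,
                                  engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  candidates <- unique(candidates)
  if (length(candidates) < 1) fail("need at least one candidate")
  y <- .binary_labels(pm, positive)
  current <- character(0)
  best_auc <- -Inf
  evaluated <- list()
  repeat {
    remaining <- setdiff(candidates, current)
    if (length(remaining) == 0) break
    trial_panels <- lapply(remaining, function(cand) c(current, cand))
    trials <- lapply(trial_panels, function(p)
      evaluate_panel(pm, p, positive, threshold, lambda, engine))
    df <- do.call(rbind, lapply(trials, function(ev)
      data.frame(panel = paste(sort(ev$panel), collapse = "+"),
                 k = length(ev$panel),
                 auc_roc = ev$metrics$auc_roc, auc_pr = ev$metrics$auc_pr,
                 accuracy = ev$metrics$accuracy, recall = ev$metrics$recall,
                 precision = ev$metrics$precision, f1 = ev$metrics$f1)))
    evaluated <- c(evaluated, list(df))
    pick <- .rank_panels(df)[1, ]
    if (pick$auc_roc <= best_auc) break
    best_auc <- pick$auc_roc
    current <- strsplit(pick$panel, "+", fixed = TRUE)[[1]]
  }
  ranked <- .rank_panels(unique(do.call(rbind, evaluated)))
  rownames(ranked) <- NULL
  per_size <- do.call(rbind, lapply(sort(unique(ranked$k)), function(m)
    ranked[ranked$k == m, , drop = FALSE][1, , drop = FALSE]))
  rownames(per_size) <- NULL
  structure(list(ranked = ranked, best = current,
                 best_evaluation = evaluate_panel(pm, current, positive,
                                                  threshold, lambda, engine),
                 per_size = per_size, n_panels = nrow(ranked)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("Panel search: %d panels evaluated\n", x$n_panels))
  cat("Best panel:", paste(x$best, collapse = " + "), "\n")
  print(x$best_evaluation$metrics)
  invisible(x)
}
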