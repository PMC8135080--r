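#' Fit a PLS-DA model by NIPALS
#'
#' Partial least squares discriminant analysis: PLS2 regression of a
#' column-centered one-hot class matrix Y on the autoscaled abundance matrix X
#' (samples x proteins), components extracted by the NIPALS algorithm with
#' deflation of X and Y. The fit is fully deterministic. Used to triage
#' candidate proteins by their variable importance in projection
#' ([vip_scores()]), replacing the SIMCA step of the published analysis.
#'
#' @param pm a log2-scale [proteome_matrix()] without missing values.
#' @param candidates protein ids used as predictors.
#' @param groups class labels, one per sample (default the matrix groups;
#'   three classes reproduce the published three-group score plot).
#' @param n_components number of components A (default 2; capped at
#'   min(N - 1, P)).
#' @param tol,max_iter NIPALS inner-loop convergence controls.
#' @return A list of class `plsda_model` with weights `W` (P x A, unit-norm
#'   columns), X-loadings `P_load`, Y-loadings `Q`, scores `T_scores` (N x A,
#'   mutually orthogonal), per-component explained-Y sums of squares `ssy`,
#'   autoscaling vectors `x_center`/`x_scale`, class `levels`, and the protein
#'   ids.
#' @export
fit_plsda <- function(pm, candidates, groups = pm$group, n_components = 2,
                      tol = 1e-12, max_iter = 500) {
  candidates <- unique(candidates)
  if (length(candidates) < 1) fail("need at least one candidate protein")
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) fail("need at least 2 classes")
  pm_sub <- subset_proteins(pm, candidates)
  X <- t(pm_sub$abundance)
  if (anyNA(X)) fail("missing values present; impute before PLS-DA")
  n <- nrow(X); p <- ncol(X)
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, sd)
  zero_var <- x_scale == 0
  if (any(zero_var))
    fail("zero-variance candidate(s): %s",
         paste(candidates[zero_var], collapse = ", "))
  X <- scale(X, center = x_center, scale = x_scale)
  lev <- levels(droplevels(groups))
  Y <- sapply(lev, function(l) as.numeric(groups == l))
  Y <- scale(Y, center = TRUE, scale = FALSE)
  A <- min(n_components, n - 1, p)

  W <- matrix(0, p, A); P_load <- matrix(0, p, A)
  Q <- matrix(0, ncol(Y), A); T_scores <- matrix(0, n, A)
  ssy <- numeric(A)
  Xa <- X; Ya <- Y
  for (a in seq_len(A)) {
    u <- Ya[, which.max(colSums(Ya^2))]
    w <- t_old <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xa, u)
      w <- w / sqrt(sum(w^2))
      t_vec <- Xa %*% w
      q <- crossprod(Ya, t_vec) / sum(t_vec^2)
      u_new <- Ya %*% q / sum(q^2)
      if (!is.null(t_old) && sum((t_vec - t_old)^2) < tol * sum(t_vec^2)) {
        u <- u_new; break
      }
      t_old <- t_vec
      u <- u_new
    }
    t_vec <- Xa %*% w
    tt <- sum(t_vec^2)
    p_vec <- crossprod(Xa, t_vec) / tt
    q <- crossprod(Ya, t_vec) / tt
    Xa <- Xa - t_vec %*% t(p_vec)
    Ya <- Ya - t_vec %*% t(q)
    W[, a] <- w; P_load[, a] <- p_vec; Q[, a] <- q; T_scores[, a] <- t_vec
    ssy[a] <- tt * sum(q^2)       # Y sum of squares explained by component a
  }
  dimnames(W) <- dimnames(P_load) <-
    list(candidates, paste0("comp", seq_len(A)))
  dimnames(T_scores) <- list(rownames(X), paste0("comp", seq_len(A)))
  dimnames(Q) <- list(lev, paste0("comp", seq_len(A)))
  structure(list(W = W, P_load = P_load, Q = Q, T_scores = T_scores,
                 ssy = ssy, x_center = x_center, x_scale = x_scale,
                 levels = lev, proteins = candidates, n_components = A),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d predictors, %d classes (%s), %d component(s)\n",
              length(x$proteins), length(x$levels),
              paste(x$levels, collapse = "/"), x$n_components))
  cat("  explained Y-SS per component:",
      paste(signif(x$ssy, 4), collapse = " "), "\n")
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' Per-predictor importance summarizing its contribution across all PLS
#' components, weighted by each component's explained Y variance:
#' `VIP_j = sqrt(P * sum_a(ssy_a * w_ja^2) / sum_a(ssy_a))` for unit-norm
#' weight columns. The mean squared VIP equals 1 by construction, so VIP > 1
#' marks an above-average contributor (the published selection rule).
#'
#' @param model a [fit_plsda()] model.
#' @return Named numeric vector of VIP scores, one per predictor.
#' @export
vip_scores <- function(model) {
  W2 <- model$W^2                       # columns already unit-norm
  p <- nrow(W2)
  vip <- sqrt(p * as.vector(W2 %*% model$ssy) / sum(model$ssy))
  names(vip) <- model$proteins
  vip
}

#' Select candidates by VIP threshold
#'
#' @param vip a [vip_scores()] vector.
#' @param threshold strict lower bound (default 1, the published VIP > 1 rule).
#' @return Protein ids with `VIP > threshold`, sorted by VIP descending.
#' @export
select_candidates <- function(vip, threshold = 1.0) {
  sel <- vip[vip > threshold]
  names(sel)[order(-sel, names(sel))]
}
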