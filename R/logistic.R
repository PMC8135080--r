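#' Class-balanced L2-penalized logistic regression
#'
#' Ridge-penalized logistic classifier with per-sample weights inversely
#' proportional to class frequency (`w_c = n / (2 * n_c)`), the "balanced"
#' scheme: minimizes
#' `sum_i s_i * [log(1 + exp(eta_i)) - y_i * eta_i] + lambda/2 * ||beta||^2`
#' by Newton's method with step halving. The intercept is unpenalized and the
#' penalty constant is the conventional unit default (`lambda = 1`). The fit
#' is deterministic. Callers are responsible for feature scaling (the LOO
#' evaluator autoscales from training-fold statistics only).
#'
#' @param x numeric matrix, samples x features.
#' @param y logical (or 0/1) labels, `TRUE` = positive class; both classes
#'   must be present.
#' @param lambda ridge penalty on the coefficients (default 1).
#' @param balanced apply balanced class weights (default `TRUE`).
#' @param max_iter,tol Newton iteration controls.
#' @return A list of class `balanced_logistic`: `intercept`, `coef` (named),
#'   `objective`, `converged`, `weights` (the per-class sample weights).
#' @export
fit_balanced_logistic <- function(x, y, lambda = 1, balanced = TRUE,
                                  max_iter = 100, tol = 1e-10) {
  x <- as.matrix(x)
  y <- as.numeric(as.logical(y))
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(y) == n)
  n_pos <- sum(y); n_neg <- n - n_pos
  if (n_pos == 0 || n_neg == 0)
    fail("both classes must be present in the training data")
  s <- if (balanced) ifelse(y == 1, n / (2 * n_pos), n / (2 * n_neg))
       else rep(1, n)
  Xd <- cbind(1, x)
  pen <- c(0, rep(lambda, p))           # intercept unpenalized
  beta <- numeric(p + 1)
  obj <- function(b) {
    eta <- as.vector(Xd %*% b)
    # numerically stable log(1 + exp(eta)) - y * eta
    ll <- ifelse(eta > 0, eta * (1 - y) + log1p(exp(-eta)),
                 -y * eta + log1p(exp(eta)))
    sum(s * ll) + sum(pen * b^2) / 2
  }
  f <- obj(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.vector(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- as.vector(crossprod(Xd, s * (mu - y))) + pen * beta
    w <- pmax(s * mu * (1 - mu), 1e-12)
    H <- crossprod(Xd, Xd * w) + diag(pen, p + 1)
    step <- solve(H, grad)
    alpha_step <- 1
    repeat {
      beta_new <- beta - alpha_step * step
      f_new <- obj(beta_new)
      if (f_new <= f + 1e-12 || alpha_step < 1e-8) break
      alpha_step <- alpha_step / 2
    }
    delta <- f - f_new
    beta <- beta_new; f <- f_new
    if (abs(delta) < tol * (abs(f) + 1)) { converged <- TRUE; break }
  }
  coef <- beta[-1]
  names(coef) <- colnames(x)
  structure(list(intercept = beta[1], coef = coef, objective = f,
                 converged = converged,
                 weights = c(negative = n / (2 * n_neg),
                             positive = n / (2 * n_pos))),
            class = "balanced_logistic")
}

#' Predict positive-class probabilities
#' @param object a [fit_balanced_logistic()] fit.
#' @param newdata matrix with the same feature columns.
#' @param ... unused.
#' @return Numeric vector of probabilities.
#' @export
predict.balanced_logistic <- function(object, newdata, ...) {
  eta <- as.vector(as.matrix(newdata) %*% object$coef) + object$intercept
  1 / (1 + exp(-eta))
}
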