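test_that("loo_folds partitions every sample exactly once", {
  ids <- sprintf("S%02d", 1:28)
  folds <- loo_folds(ids)
  expect_length(folds, 28)
  expect_setequal(vapply(folds, `[[`, "", "test"), ids)
  expect_true(all(vapply(folds, function(f) length(f$train), 0L) == 27))
  f3 <- loo_folds(c("a", "b", "c"))
  expect_length(f3, 3)
  expect_equal(f3[[1]]$train, c("b", "c"))
  expect_error(loo_folds(c("a", "a", "b")), "duplicate")
  expect_error(loo_folds(c("a", "b")), "at least 3")
})

test_that("balanced logistic solves the stated penalized objective", {
  # independent oracle: numerical optimizer of the same objective
  set.seed(111)
  x <- matrix(rnorm(20), 10, 2)
  y <- c(rep(1, 4), rep(0, 6))
  fit <- fit_balanced_logistic(x, y)
  s <- ifelse(y == 1, 10 / (2 * 4), 10 / (2 * 6))
  obj <- function(b) {
    eta <- b[1] + x %*% b[2:3]
    sum(s * (log1p(exp(eta)) - y * eta)) + 0.5 * sum(b[2:3]^2)
  }
  ref <- optim(c(0, 0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(c(fit$intercept, fit$coef)), ref$par, tolerance = 1e-4)
  expect_lte(fit$objective, ref$value + 1e-8)
  expect_true(fit$converged)

  # balanced weights reduce to uniform when classes are balanced
  xb <- matrix(rnorm(16), 8, 2)
  yb <- rep(c(0, 1), each = 4)
  f_bal <- fit_balanced_logistic(xb, yb, balanced = TRUE)
  f_unw <- fit_balanced_logistic(xb, yb, balanced = FALSE)
  expect_equal(f_bal$coef, f_unw$coef, tolerance = 1e-8)
  expect_equal(f_bal$intercept, f_unw$intercept, tolerance = 1e-8)

  expect_error(fit_balanced_logistic(xb, rep(1, 8)), "both classes")
})

test_that("separable 1-D panels classify every held-out sample correctly", {
  ab <- matrix(c(rnorm(9, 10, 0.2), rnorm(19, 14, 0.2)), 1,
               dimnames = list("sep", sprintf("S%02d", 1:28)))
  pm <- quick_pm(ab, group = rep(c("Ctrl", "MCI", "AD"), c(9, 10, 9)))
  ev <- evaluate_panel(pm, "sep")
  expect_true(all(ev$probs[ev$labels] > 0.5))
  expect_true(all(ev$probs[!ev$labels] < 0.5))
  expect_equal(ev$metrics$auc_roc, 1)
  expect_equal(ev$metrics$auc_pr, 1)
})

test_that("compiled and reference LOO engines agree", {
  ch <- generate_cohort(small_design(seed = 112))
  pm <- preprocess_cohort(ch$matrix, seed = 113, filter = FALSE)
  panel <- ch$truth$true_panel
  ev_c <- evaluate_panel(pm, panel, engine = "cpp")
  ev_r <- evaluate_panel(pm, panel, engine = "r")
  expect_equal(ev_c$probs, ev_r$probs, tolerance = 1e-8)
  sr_c <- exhaustive_search(pm, panel[1:3], engine = "cpp")
  sr_r <- exhaustive_search(pm, panel[1:3], engine = "r")
  expect_equal(sr_c$ranked$auc_roc, sr_r$ranked$auc_roc, tolerance = 1e-8)
  expect_equal(sr_c$best, sr_r$best)
})

test_that("exhaustive search enumerates, ranks, and is deterministic", {
  ch <- generate_cohort(small_design(seed = 114))
  pm <- preprocess_cohort(ch$matrix, seed = 115, filter = FALSE)
  cands <- c(ch$truth$true_panel, null_proteins(ch)[1:2])
  sr <- exhaustive_search(pm, cands)
  expect_equal(sr$n_panels, 2^6 - 1)
  expect_equal(nrow(sr$ranked), 63)
  # ranking key is respected
  expect_true(all(diff(sr$ranked$auc_roc) <= 1e-12))
  expect_equal(strsplit(sr$ranked$panel[1], "+", fixed = TRUE)[[1]], sr$best)
  # per-size winners come from the ranking
  expect_equal(nrow(sr$per_size), 6)
  expect_equal(sr$per_size$auc_roc,
               vapply(1:6, function(k)
                 max(sr$ranked$auc_roc[sr$ranked$k == k]), numeric(1)))
  # metric identities on the best evaluation
  m <- sr$best_evaluation$metrics
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
               tolerance = 1e-12)
  cm <- m$confusion
  expect_equal(cm$TP + cm$FN, 19)
  expect_equal(cm$TN + cm$FP, 9)
  # determinism
  sr2 <- exhaustive_search(pm, cands)
  expect_identical(sr$ranked, sr2$ranked)

  # single candidate and the blowup guard
  sr1 <- exhaustive_search(pm, cands[1])
  expect_equal(sr1$n_panels, 1)
  expect_equal(sr1$best, cands[1])
  expect_error(exhaustive_search(pm, sprintf("P%05d", 1:21)), "greedy")
})

test_that("greedy search picks dominant features and never beats exhaustive", {
  ch <- generate_cohort(small_design(seed = 116))
  pm <- preprocess_cohort(ch$matrix, seed = 117, filter = FALSE)
  cands <- c(ch$truth$true_panel[1:3], null_proteins(ch)[1:3])
  gr <- greedy_forward_search(pm, cands)
  sr <- exhaustive_search(pm, cands)
  expect_lte(gr$best_evaluation$metrics$auc_roc,
             sr$best_evaluation$metrics$auc_roc + 1e-12)

  # a single dominant feature is selected first
  ab <- rbind(dom = c(rnorm(9, 10, 0.2), rnorm(19, 14, 0.2)),
              matrix(rnorm(3 * 28, 20, 1), 3,
                     dimnames = list(paste0("n", 1:3), NULL)))
  colnames(ab) <- sprintf("S%02d", 1:28)
  pm2 <- quick_pm(ab, group = rep(c("Ctrl", "MCI", "AD"), c(9, 10, 9)))
  gr2 <- greedy_forward_search(pm2, rownames(ab))
  expect_true("dom" %in% gr2$best)
  expect_equal(gr2$best_evaluation$metrics$auc_roc, 1)
})
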