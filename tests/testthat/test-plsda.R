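random_fit <- function(seed, n = 12, p = 6, ncomp = 2) {
  set.seed(seed)
  ab <- matrix(rnorm(p * n, 20, 1), p, n,
               dimnames = list(sprintf("v%02d", seq_len(p)), NULL))
  pm <- quick_pm(ab, group = rep(c("Ctrl", "MCI", "AD"), length.out = n))
  fit_plsda(pm, rownames(ab), n_components = ncomp)
}

test_that("NIPALS model satisfies its structural contracts", {
  for (seed in 81:84) {
    m <- random_fit(seed, ncomp = 3)
    # scores mutually orthogonal
    G <- crossprod(m$T_scores)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
    # unit-norm weight columns
    expect_equal(unname(sqrt(colSums(m$W^2))), rep(1, m$n_components),
                 tolerance = 1e-10)
    # A capped at min(N - 1, P)
    expect_lte(m$n_components, min(nrow(m$T_scores) - 1, length(m$proteins)))
  }
})

test_that("component 1 agrees with the dominant singular direction of X'Y", {
  for (seed in 85:88) {
    set.seed(seed)
    n <- 14; p <- 7
    ab <- matrix(rnorm(p * n, 20, 1), p, n,
                 dimnames = list(sprintf("v%02d", 1:p), NULL))
    grp <- rep(c("Ctrl", "MCI", "AD"), length.out = n)
    pm <- quick_pm(ab, group = grp)
    m <- fit_plsda(pm, rownames(ab), n_components = 1)
    X <- scale(t(ab))
    Y <- scale(sapply(unique(grp), function(l) as.numeric(grp == l)),
               scale = FALSE)
    w_svd <- svd(crossprod(X, Y))$u[, 1]
    cosine <- abs(sum(w_svd * m$W[, 1]))
    expect_gt(cosine, 0.999)
  }
})

test_that("X reconstruction residual decreases with more components", {
  set.seed(89)
  ab <- matrix(rnorm(60, 20, 1), 6, 10,
               dimnames = list(sprintf("v%02d", 1:6), NULL))
  pm <- quick_pm(ab, group = rep(c("Ctrl", "MCI"), each = 5),
                 mmse = c(rep(30, 5), rep(20, 5)))
  resid <- vapply(1:4, function(a) {
    m <- fit_plsda(pm, rownames(ab), n_components = a)
    X <- scale(t(ab))
    sum((X - m$T_scores %*% t(m$P_load))^2)
  }, numeric(1))
  expect_true(all(diff(resid) < 0))
})

test_that("separable classes separate on component 1", {
  ab <- rbind(sep = c(10, 10.2, 9.9, 10.1, 14, 14.2, 13.9, 14.1, 14, 13.8, 14.1, 14.2),
              noise = rnorm(12, 20, 0.2))
  pm <- quick_pm(ab)
  m <- fit_plsda(pm, rownames(ab))
  t1 <- m$T_scores[, 1]
  ctrl <- pm$group == "Ctrl"
  expect_true(max(t1[ctrl]) < min(t1[!ctrl]) ||
                min(t1[ctrl]) > max(t1[!ctrl]))
})

test_that("VIP identity and limit cases hold", {
  # mean squared VIP = 1, i.e. sum VIP^2 = P, on every fit
  for (seed in 90:93) {
    m <- random_fit(seed, p = sample(3:9, 1))
    v <- vip_scores(m)
    expect_equal(sum(v^2), length(v), tolerance = 1e-8)
    expect_true(all(v >= 0))
  }
  # single predictor: VIP = 1 exactly
  set.seed(94)
  ab <- matrix(rnorm(12, 20, 1), 1, dimnames = list("only", NULL))
  m1 <- fit_plsda(quick_pm(ab), "only", n_components = 1)
  expect_equal(unname(vip_scores(m1)), 1, tolerance = 1e-10)
})

test_that("an informative predictor among noise gets the top VIP > 1", {
  set.seed(95)
  grp <- rep(c("Ctrl", "MCI", "AD"), c(9, 10, 9))
  signal <- c(rep(0, 9), rep(-1, 10), rep(-2, 9)) + rnorm(28, 0, 0.3)
  ab <- rbind(matrix(rnorm(9 * 28, 20, 1), 9), 20 + signal)
  rownames(ab) <- c(sprintf("noise%d", 1:9), "info")
  pm <- quick_pm(ab, group = grp)
  v <- vip_scores(fit_plsda(pm, rownames(ab)))
  expect_equal(names(which.max(v)), "info")
  expect_gt(v["info"], 1)
})

test_that("select_candidates applies the strict VIP > threshold rule", {
  v <- c(a = 1, b = 1.4, c = 0.2, d = 1.2)
  expect_equal(select_candidates(v), c("b", "d"))       # exactly 1 excluded
  expect_equal(select_candidates(v, 0), c("b", "d", "a", "c"))
  expect_equal(select_candidates(c(x = 1, y = 1)), character(0))
})

test_that("zero-variance candidates are reported by name", {
  ab <- rbind(flat = rep(5, 12), ok = rnorm(12, 20))
  expect_error(fit_plsda(quick_pm(ab), c("flat", "ok")), "flat")
})

test_that("scores separate Ctrl from impaired on planted cohorts", {
  good <- 0
  for (k in 1:20) {
    ch <- generate_cohort(small_design(seed = 700 + k))
    pm <- preprocess_cohort(ch$matrix, seed = 800 + k, filter = FALSE)
    cands <- c(ch$truth$true_panel,
               head(ch$truth$cluster$protein[ch$truth$cluster$cluster == 1], 9))
    m <- fit_plsda(pm, cands)
    sil <- silhouette_vs_rest(m$T_scores, pm$group == "Ctrl")
    good <- good + (sil > 0)
  }
  expect_gte(good / 20, 0.95)
})
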