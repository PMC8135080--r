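test_that("normalize_columns equalizes medians and is idempotent", {
  set.seed(1)
  ab <- matrix(2^rnorm(600, 20, 2), 50, 12)
  pm <- quick_pm(ab, log2_scale = FALSE)
  norm1 <- normalize_columns(pm)
  meds <- apply(norm1$abundance, 2, median)
  expect_equal(max(meds) - min(meds), 0, tolerance = 1e-12)
  expect_true(norm1$log2_scale)
  norm2 <- normalize_columns(norm1)
  expect_equal(norm2$abundance, norm1$abundance, tolerance = 1e-12)

  # a column shifted by +3 in log2 equals its reference after centering
  ab2 <- norm1$abundance
  ab2[, 2] <- ab2[, 1] + 3
  shifted <- normalize_columns(quick_pm(ab2, log2_scale = TRUE))
  expect_equal(shifted$abundance[, 2], shifted$abundance[, 1],
               ignore_attr = TRUE, tolerance = 1e-12)

  ab3 <- ab
  ab3[, 4] <- NA
  expect_error(normalize_columns(quick_pm(ab3, log2_scale = FALSE)), "s04")
})

test_that("downshifted imputation leaves observed cells and matches its target", {
  set.seed(2)
  ab <- matrix(rnorm(3000 * 10, 20, 2), 3000, 10)
  pm_full <- quick_pm(ab, group = rep(c("Ctrl", "MCI", "AD"), c(3, 4, 3)))
  expect_identical(impute_downshifted(pm_full), pm_full)

  miss <- matrix(runif(length(ab)) < 0.05, nrow(ab))
  ab_na <- ab; ab_na[miss] <- NA
  pm <- quick_pm(ab_na, group = rep(c("Ctrl", "MCI", "AD"), c(3, 4, 3)))
  imp <- impute_downshifted(pm, seed = 5)
  expect_false(anyNA(imp$abundance))
  expect_identical(imp$abundance[!miss], ab[!miss])
  expect_identical(impute_downshifted(pm, seed = 5)$abundance, imp$abundance)

  # imputed-cell mean ~ col_mean - 1.8 * col_SD within 0.1 SD (>= 1000 cells)
  expect_gt(sum(miss), 1000)
  dev <- vapply(seq_len(ncol(ab)), function(j) {
    obs <- ab[!miss[, j], j]
    (mean(imp$abundance[miss[, j], j]) - (mean(obs) - 1.8 * sd(obs))) / sd(obs)
  }, numeric(1))
  expect_lt(max(abs(dev)), 0.1)

  ab_bad <- ab_na; ab_bad[-1, 3] <- NA
  expect_error(impute_downshifted(
    quick_pm(ab_bad, group = rep(c("Ctrl", "MCI", "AD"), c(3, 4, 3)))),
    "fewer than 2")
})

test_that("filter_min_valid enforces per-group completeness", {
  ab <- matrix(20, 4, 12)
  rownames(ab) <- paste0("p", 1:4)
  ab[2, 1:2] <- NA      # Ctrl group (cols 1-4) at 50% < 70%
  ab[3, 5] <- NA        # MCI group at 3/4 = 75% >= 70%
  pm <- quick_pm(ab)
  kept <- rownames(filter_min_valid(pm, 0.7)$abundance)
  expect_setequal(kept, c("p1", "p3", "p4"))
})

test_that("per-protein t-test matches stats::t.test to 1e-10", {
  # frozen worked example: pooled-variance Student t (verified independently
  # against stats::t.test; equal-variance, df = 6)
  ab <- rbind(c(1, 2, 3, 4, 3, 4, 5, 6))
  pm <- quick_pm(matrix(ab, 1), group = rep(c("Ctrl", "MCI"), each = 4),
                 mmse = c(29, 29, 30, 30, 20, 20, 21, 21))
  res <- t_test_per_protein(pm, c("Ctrl", "MCI"))
  expect_equal(res$t_statistic, 2.19089023002066, tolerance = 1e-10)
  expect_equal(res$p_value, 0.0709876543209876, tolerance = 1e-10)
  expect_equal(res$df, 6)
  expect_equal(res$log2_fold_change, 2)
  expect_equal(res$direction, "up")

  # identical groups: t = 0, p = 1
  pm0 <- quick_pm(matrix(c(1, 2, 3, 4, 1, 2, 3, 4), 1),
                  group = rep(c("Ctrl", "AD"), each = 4),
                  mmse = c(29, 29, 30, 30, 5, 5, 6, 6))
  res0 <- t_test_per_protein(pm0, c("Ctrl", "AD"))
  expect_equal(res0$t_statistic, 0)
  expect_equal(res0$p_value, 1)

  # oracle: 100 random small inputs, Student and Welch
  set.seed(30)
  for (k in 1:100) {
    na_ <- sample(3:8, 1); nb_ <- sample(3:8, 1)
    x <- rnorm(na_); y <- rnorm(nb_, sample(c(0, 1), 1))
    pmk <- quick_pm(matrix(c(x, y), 1), group = rep(c("Ctrl", "MCI"),
                                                    c(na_, nb_)),
                    mmse = c(rep(30, na_), rep(20, nb_)))
    for (ve in c(TRUE, FALSE)) {
      got <- t_test_per_protein(pmk, c("Ctrl", "MCI"), var_equal = ve)
      ref <- t.test(y, x, var.equal = ve)
      expect_equal(got$t_statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
  expect_error(t_test_per_protein(pm, c("Ctrl", "bogus")), "contrast")
})

test_that("DE direction always agrees with the fold-change sign", {
  ch <- generate_cohort(small_design(seed = 31))
  pm <- preprocess_cohort(ch$matrix, seed = 32)
  for (cmp in run_de_contrasts(pm)) {
    expect_true(all(cmp$direction == ifelse(cmp$log2_fold_change >= 0,
                                            "up", "down")))
    expect_true(all(cmp$p_value > 0 & cmp$p_value <= 1))
  }
})

test_that("summarize_de counts, overlap and planted recovery behave", {
  ch <- generate_cohort(small_design(seed = 33))
  pm <- preprocess_cohort(ch$matrix, seed = 34)
  de <- run_de_contrasts(pm)
  s <- summarize_de(de)
  expect_equal(s$counts$n_sig, s$counts$n_up + s$counts$n_down)
  for (nm in c("MCI_vs_Ctrl", "AD_vs_Ctrl"))
    expect_true(all(s$overlap_ctrl %in% s$significant[[nm]]))
  expect_true(all(unlist(s$significant) %in% s$union))

  # recovery: >= 95% of filter-surviving planted proteins in the union
  surviving <- intersect(ch$truth$cluster$protein, rownames(pm$abundance))
  expect_gte(mean(surviving %in% s$union), 0.95)

  # with no missingness the whole planted set is recovered at >= 95%
  ch0 <- generate_cohort(small_design(seed = 35, missing_rate = 0))
  s0 <- summarize_de(run_de_contrasts(normalize_columns(ch0$matrix)))
  expect_gte(mean(ch0$truth$cluster$protein %in% s0$union), 0.95)
})
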