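test_that("pearson_vs_mmse matches the product-moment formula and cor.test", {
  # exact linear protein -> r = 1
  mmse <- c(29, 30, 29, 30, 18, 20, 22, 23, 2, 9, 13, 17)
  ab <- rbind(lin = 2 + 3 * mmse,
              anti = 50 - 2 * mmse,
              const = rep(5, 12))
  pm <- quick_pm(ab, mmse = mmse)
  ct <- pearson_vs_mmse(pm)
  expect_equal(ct$r[ct$protein == "lin"], 1)
  expect_equal(ct$r[ct$protein == "anti"], -1)
  expect_equal(ct$class[ct$protein == "const"], "excluded")
  expect_true(is.na(ct$r[ct$protein == "const"]))

  # frozen worked example: x = 1:4 vs y = (1,3,2,4) -> r = 0.8
  r <- suppressWarnings(cor(c(1, 2, 3, 4), c(1, 3, 2, 4)))
  expect_equal(r, 0.8)

  # oracle: random matrices against cor() / cor.test() to 1e-12
  set.seed(61)
  for (k in 1:20) {
    n <- sample(5:28, 1)
    abk <- matrix(rnorm(8 * n, 20, 2), 8)
    mm <- sample(0:30, n, replace = TRUE)
    grp <- rep(c("Ctrl", "MCI", "AD"), length.out = n)
    ctk <- pearson_vs_mmse(quick_pm(abk, group = grp, mmse = mm))
    for (j in 1:8) {
      ref <- cor.test(abk[j, ], mm)
      expect_equal(ctk$r[j], unname(ref$estimate), tolerance = 1e-12)
      expect_equal(ctk$p_value[j], ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("NC/PC classes partition the tested proteins", {
  ch <- generate_cohort(small_design(seed = 62))
  pm <- preprocess_cohort(ch$matrix, seed = 63)
  ct <- pearson_vs_mmse(pm)
  expect_equal(sum(ct$class %in% c("NC", "PC", "ns")) +
                 sum(ct$class == "excluded"), nrow(pm$abundance))
  expect_true(all(ct$r[ct$class == "NC"] < 0))
  expect_true(all(ct$r[ct$class == "PC"] > 0))
  expect_true(all(ct$p_value[ct$class %in% c("NC", "PC")] < 0.05))
  expect_true(all(ct$p_value[ct$class == "ns"] >= 0.05))
})

test_that("planted target_corr = 0.55 lands in [0.3, 0.75] in >= 90% of draws", {
  inb <- logical(0)
  for (k in 1:200) {
    ch <- generate_cohort(cohort_design(
      seed = 5000 + k, n_proteins = 6, n_cluster1 = 0, n_cluster2 = 0,
      n_cluster3 = 0, n_corr_pos = 2, n_corr_neg = 1, missing_rate = 0,
      panel_size = 1))
    ab <- log2(ch$matrix$abundance)
    rr <- apply(ab[ch$truth$mmse_correlated$protein, , drop = FALSE], 1,
                cor, y = ch$matrix$mmse)
    inb <- c(inb, abs(rr) >= 0.3 & abs(rr) <= 0.75)
  }
  expect_gte(mean(inb), 0.9)
})

test_that("build_candidates intersects, ranks, and applies exclusions", {
  ch <- generate_cohort(small_design(seed = 64))
  pm <- preprocess_cohort(ch$matrix, seed = 65)
  ct <- pearson_vs_mmse(pm)
  s <- summarize_de(run_de_contrasts(pm))
  cand <- build_candidates(ct, s)
  # every member is both correlated (p < 0.05) and in the DE union
  expect_true(all(cand$protein %in% s$union))
  expect_true(all(cand$p_value < 0.05))
  # ranked by |r| descending
  expect_true(all(diff(abs(cand$r)) <= 1e-12))
  # surviving planted panel members are candidates
  surviving_panel <- intersect(ch$truth$true_panel, rownames(pm$abundance))
  expect_true(all(surviving_panel %in% cand$protein))

  # exclusion list drops exactly the matched ids
  drop2 <- cand$protein[1:2]
  cand2 <- build_candidates(ct, s, exclude = c(drop2, "NOT_A_PROTEIN"))
  expect_equal(nrow(cand2), nrow(cand) - 2)
  expect_equal(attr(cand2, "excluded_hits"), drop2)

  # empty intersection warns and returns an empty set
  ct_none <- ct
  ct_none$class <- "ns"
  expect_warning(c0 <- build_candidates(ct_none, s), "no protein")
  expect_equal(nrow(c0), 0)
})

test_that("candidate correlation matrix is symmetric with unit diagonal", {
  ch <- generate_cohort(small_design(seed = 66))
  pm <- preprocess_cohort(ch$matrix, seed = 67, filter = FALSE)
  picks <- c(ch$truth$true_panel,
             ch$truth$mmse_correlated$protein[1:4])
  cc <- candidate_corr_matrix(pm, picks)
  expect_equal(unname(diag(cc)), rep(1, length(picks)))
  expect_equal(cc, t(cc), tolerance = 1e-12)
  # two proteins driven strongly by the same latent MMSE term are mutually
  # correlated (expected pairwise r = target^2 = 0.64 here)
  ch8 <- generate_cohort(small_design(seed = 68, target_corr = 0.8,
                                      missing_rate = 0))
  pm8 <- normalize_columns(ch8$matrix)
  pos <- ch8$truth$mmse_correlated$protein[
    ch8$truth$mmse_correlated$r_target > 0][1:2]
  cc8 <- candidate_corr_matrix(pm8, pos)
  expect_gt(abs(cc8[pos[1], pos[2]]), 0.5)
  long <- corr_matrix_long(cc)
  expect_equal(nrow(long), choose(length(picks), 2))
  expect_error(candidate_corr_matrix(pm, picks[1]), "at least 2")
})
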