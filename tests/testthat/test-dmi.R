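test_that("binning sorts by modulator expression and splits evenly", {
  expr <- matrix(c(5, 1, 9, 2, 8, 3, 7, 4, 6), nrow = 1,
                 dimnames = list("M", paste0("s", 1:9)))
  bins <- bin_samples_by_modulator(expr, "M", 3)
  expect_named(bins, c("low", "bin_2", "high"))
  expect_equal(sort(unlist(bins)), 1:9, ignore_attr = TRUE)
  expect_equal(unname(expr[1, bins$low]), c(1, 2, 3))
  expect_equal(unname(expr[1, bins$high]), c(7, 8, 9))
  # remainder goes to the earliest (Low) bins
  expr10 <- matrix(1:10, nrow = 1, dimnames = list("M", paste0("s", 1:10)))
  sizes <- lengths(bin_samples_by_modulator(expr10, "M", 3))
  expect_equal(unname(sizes), c(4L, 3L, 3L))
  expr100 <- matrix(rnorm(100), nrow = 1,
                    dimnames = list("M", sprintf("s%03d", 1:100)))
  expect_equal(unname(lengths(bin_samples_by_modulator(expr100, "M", 2))),
               c(50L, 50L))
})

test_that("binning validates inputs and resolves ties deterministically", {
  expr <- matrix(c(1, 1, 1, 2), nrow = 1,
                 dimnames = list("M", paste0("s", 1:4)))
  bins1 <- bin_samples_by_modulator(expr, "M", 2)
  bins2 <- bin_samples_by_modulator(expr, "M", 2)
  expect_identical(bins1, bins2)
  expect_equal(bins1$low, c(1L, 2L))  # stable on (value, sample index)
  expect_error(bin_samples_by_modulator(expr, "NOPE", 2), "not found")
  expect_error(bin_samples_by_modulator(expr, "M", 5), "fewer samples")
})

test_that("fold change is the difference of bin means on the log2 scale", {
  expr <- matrix(c(4, 4, 4, 6, 6, 6), nrow = 1,
                 dimnames = list("M", paste0("s", 1:6)))
  expect_equal(fold_change(expr, "M", low = 1:3, high = 4:6), 2)
  expect_equal(fold_change(expr, "M", low = 1:3, high = 4:6, scale = "ratio"), 1.5)
  expr2 <- matrix(c(4, 4, 4.5, 4.5), nrow = 1,
                  dimnames = list("M", paste0("s", 1:4)))
  expect_equal(fold_change(expr2, "M", low = 1:2, high = 3:4), 0.5)
  const <- matrix(rep(3, 6), nrow = 1, dimnames = list("M", paste0("s", 1:6)))
  expect_equal(fold_change(const, "M", 1:3, 4:6), 0)
})

test_that("delta information is positive when targets co-regulate in the high bin", {
  expr <- make_modulated_expr(seed = 21)
  cfg <- dmi_config(n_bins = 3, rmi = test_rmi_config())
  di <- delta_information(expr, sprintf("T%02d", 1:4), "MOD", cfg)
  expect_gt(di$delta_i, 0.3)
  expect_equal(di$delta_i, di$i_high - di$i_low)
  expect_equal(di$delta_i_norm, di$delta_i / (di$i_high + di$i_low))
  # flipping the modulator sign swaps the bins and negates delta exactly
  flipped <- make_modulated_expr(seed = 21, flip = TRUE)
  di_f <- delta_information(flipped, sprintf("T%02d", 1:4), "MOD", cfg)
  expect_equal(di_f$delta_i, -di$delta_i, tolerance = 1e-12)
  # independent targets in both bins give delta near zero
  indep <- expr
  set.seed(31)
  indep[sprintf("T%02d", 1:4), ] <- matrix(rnorm(4 * ncol(expr)), nrow = 4)
  di0 <- delta_information(indep, sprintf("T%02d", 1:4), "MOD", cfg)
  expect_lt(abs(di0$delta_i), 0.3)
})

test_that("delta information guards its preconditions", {
  expr <- make_modulated_expr(seed = 5)
  cfg <- dmi_config(rmi = test_rmi_config())
  expect_error(delta_information(expr, c("T01", "MOD"), "MOD", cfg), "confounded")
  expect_error(delta_information(expr, c("T01", "NOPE"), "MOD", cfg), "NOPE")
  expect_error(delta_information(expr, "T01", "MOD", cfg), "at least 2")
  # bins below the estimator minimum are skipped, not errors
  small <- expr[, 1:24]
  expect_message(di <- delta_information(small, sprintf("T%02d", 1:4), "MOD", cfg),
                 "skipping")
  expect_true(is.na(di$delta_i))
  expect_false(is.na(di$fold_change))
})

test_that("permutation p-values follow the exceedance-percentage definition", {
  expr <- make_modulated_expr(seed = 8)
  cfg <- dmi_config(n_bins = 3, n_permutations = 100,
                    rmi = test_rmi_config(), seed = 3)
  bins <- bin_samples_by_modulator(expr, "MOD", 3)
  set.seed(3)
  out <- permutation_pvalue(expr, observed_delta = 1e6, d = 4,
                            modulator_id = "MOD", bins = bins, config = cfg,
                            return_null = TRUE)
  expect_identical(out$p_value, 0)          # larger than every null trial
  set.seed(3)
  expect_identical(permutation_pvalue(expr, -1e6, 4, "MOD", bins, cfg), 1)
  med <- stats::median(out$null)
  set.seed(3)
  p_med <- permutation_pvalue(expr, med, 4, "MOD", bins, cfg)
  expect_lt(abs(p_med - 0.5), 0.1)
  # pseudo-count option keeps p strictly positive
  cfg_pc <- dmi_config(n_bins = 3, n_permutations = 100, p_pseudocount = TRUE,
                       rmi = test_rmi_config(), seed = 3)
  set.seed(3)
  expect_equal(permutation_pvalue(expr, 1e6, 4, "MOD", bins, cfg_pc), 1 / 101)
})

test_that("run_dmi ranks the planted modulator first and is seed-deterministic", {
  expr <- make_modulated_expr(m = 90L, seed = 13)
  cfg <- dmi_config(n_bins = 3, n_permutations = 50, fc_threshold = -Inf,
                    rmi = test_rmi_config(), seed = 7)
  cands <- c("MOD", sprintf("G%03d", 1:10))
  res1 <- run_dmi(expr, sprintf("T%02d", 1:4), cands, cfg)
  res2 <- run_dmi(expr, sprintf("T%02d", 1:4), cands, cfg)
  expect_identical(res1$p_value, res2$p_value)
  expect_identical(res1$modulator_id[res1$rank == 1], "MOD")
  expect_true(all(res1$p_adjusted >= res1$p_value, na.rm = TRUE))
  # BH-adjusted values are monotone in raw p-value order
  ord <- order(res1$p_value)
  expect_true(!is.unsorted(res1$p_adjusted[ord], na.rm = TRUE))
})

test_that("the fold-change prefilter is monotone in its threshold", {
  expr <- make_modulated_expr(seed = 17)
  cands <- c("MOD", sprintf("G%03d", 1:10))
  passed <- lapply(c(2, 0.5, -Inf), function(thr) {
    cfg <- dmi_config(n_bins = 3, n_permutations = 10, fc_threshold = thr,
                      rmi = test_rmi_config(), seed = 1)
    res <- run_dmi(expr, sprintf("T%02d", 1:4), cands, cfg)
    res$modulator_id[res$passed_filter]
  })
  expect_true(all(passed[[1]] %in% passed[[2]]))
  expect_true(all(passed[[2]] %in% passed[[3]]))
})

test_that("constant-expression candidates are all filtered with a warning", {
  expr <- make_modulated_expr(seed = 19)
  expr["G001", ] <- 5
  expr["G002", ] <- 1
  cfg <- dmi_config(n_bins = 3, n_permutations = 10,
                    rmi = test_rmi_config(), seed = 1)
  expect_warning(
    res <- run_dmi(expr, sprintf("T%02d", 1:4), c("G001", "G002"), cfg),
    "no modulator passed"
  )
  expect_true(all(!res$passed_filter))
  expect_true(all(is.na(res$rank)))
})

test_that("significance cut drops modulators with adjusted p above the cutoff", {
  expr <- make_modulated_expr(m = 90L, seed = 23)
  cfg <- dmi_config(n_bins = 3, n_permutations = 50, fc_threshold = -Inf,
                    rmi = test_rmi_config(), seed = 2)
  cands <- c("MOD", sprintf("G%03d", 1:10))
  res <- run_dmi(expr, sprintf("T%02d", 1:4), cands, cfg,
                 significant_only = TRUE)
  kept <- res[!is.na(res$rank), ]
  expect_true(all(kept$p_adjusted < cfg$alpha_significance))
  expect_true("MOD" %in% kept$modulator_id)
})
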