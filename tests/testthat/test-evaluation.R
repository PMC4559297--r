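test_that("curve counts follow the standard confusion-matrix definitions", {
  cv <- ppv_sensitivity_curve(c("a", "b", "c", "d"), truth = c("a", "b", "d"))
  expect_equal(cv$ppv, c(1, 1, 2 / 3, 3 / 4))
  expect_equal(cv$sensitivity, c(1 / 3, 2 / 3, 2 / 3, 1))
  # at every depth k: TP + FP = k and TP + FN = |truth|
  expect_equal(cv$tp + cv$fp, cv$depth)
  expect_equal(cv$tp + cv$fn, rep(3L, 4))
  expect_equal(cv$specificity, c(1, 1, 0, 0))
  expect_equal(cv$fpr, 1 - cv$specificity)
})

test_that("curve invariants hold on random rankings", {
  for (s in 1:5) {
    universe <- sprintf("g%02d", 1:40)
    truth <- withr::with_seed(s, sample(universe, 12))
    ranking <- withr::with_seed(s + 100, sample(universe))
    cv <- ppv_sensitivity_curve(ranking, truth)
    expect_equal(cv$tp + cv$fp, cv$depth)
    expect_equal(cv$tp + cv$fn, rep(12L, 40))
    expect_true(all(cv$ppv >= 0 & cv$ppv <= 1))
    expect_true(!is.unsorted(cv$sensitivity))
    expect_true(!is.unsorted(cv$fpr))
  }
})

test_that("degenerate rankings produce the expected extremes", {
  cv <- ppv_sensitivity_curve(c("x", "y", "a", "b"), truth = c("a", "b"))
  expect_equal(cv$ppv[1:2], c(0, 0))  # all negatives first
  expect_error(ppv_sensitivity_curve(character(0), "a"), "empty")
  expect_error(ppv_sensitivity_curve(c("a", "b"), character(0)), "truth")
})

test_that("11-point interpolation equals the brute-force max-suffix oracle", {
  levels <- seq(0, 1, 0.1)
  for (s in 1:5) {
    universe <- sprintf("g%02d", 1:30)
    truth <- withr::with_seed(s, sample(universe, 9))
    ranking <- withr::with_seed(s + 50, sample(universe))
    cv <- ppv_sensitivity_curve(ranking, truth)
    comp <- average_precision_11pt(cv)
    # oracle: maximum PPV over all depths with sensitivity >= r, with the
    # defined point (sens 0, ppv 1) included
    sens <- c(0, cv$sensitivity)
    ppv <- c(1, cv$ppv)
    oracle <- vapply(levels, function(r) max(ppv[sens >= r - 1e-12]), numeric(1))
    expect_equal(comp$value, oracle)
  }
})

test_that("interpolated precision starts at 1 and never increases", {
  cv <- ppv_sensitivity_curve(
    withr::with_seed(2, sample(sprintf("g%02d", 1:50))),
    truth = sprintf("g%02d", 1:10)
  )
  comp <- average_precision_11pt(cv)
  expect_equal(comp$value[1], 1)
  expect_true(all(diff(comp$value) <= 1e-12))
})

test_that("perfect ranking keeps interpolated precision at 1 everywhere", {
  cv <- ppv_sensitivity_curve(c("a", "b", "c", "x", "y"),
                              truth = c("a", "b", "c"))
  expect_equal(average_precision_11pt(cv)$value, rep(1, 11))
})

test_that("composite curves average linearly and identical inputs pass through", {
  universe <- sprintf("g%02d", 1:30)
  truth <- sprintf("g%02d", 1:8)
  cv1 <- ppv_sensitivity_curve(withr::with_seed(1, sample(universe)), truth)
  cv2 <- ppv_sensitivity_curve(withr::with_seed(2, sample(universe)), truth)
  same <- average_precision_11pt(list(cv1, cv1))
  expect_equal(same$value, average_precision_11pt(cv1)$value)
  both <- average_precision_11pt(list(cv1, cv2))
  expect_equal(both$value,
               (average_precision_11pt(cv1)$value +
                  average_precision_11pt(cv2)$value) / 2)
  roc_same <- roc_vertical_average(list(cv1, cv1))
  expect_equal(roc_same$value, roc_vertical_average(cv1)$value)
})

test_that("vertical ROC averaging matches hand linear interpolation", {
  # 5-item ranking, 2 positives at depths 2 and 4:
  # fpr grid per depth = 1/3, 1/3, 2/3, 2/3, 1; sens = 0, .5, .5, 1, 1
  cv <- ppv_sensitivity_curve(c("n1", "p1", "n2", "p2", "n3"),
                              truth = c("p1", "p2"))
  comp <- roc_vertical_average(cv)
  # piecewise-linear through (0,0), (1/3,.5), (2/3,1), (1,1)
  hand <- vapply(seq(0, 1, 0.1), function(x) {
    if (x <= 1 / 3) 0.5 * x / (1 / 3)
    else if (x <= 2 / 3) 0.5 + 0.5 * (x - 1 / 3) / (1 / 3)
    else 1
  }, numeric(1))
  expect_equal(comp$value, hand, tolerance = 1e-12)
})

test_that("a random ranker's averaged ROC sits on the diagonal", {
  universe <- sprintf("g%03d", 1:60)
  truth <- sprintf("g%03d", 1:15)
  curves <- lapply(1:200, function(s) {
    ppv_sensitivity_curve(withr::with_seed(s, sample(universe)), truth)
  })
  comp <- roc_vertical_average(curves)
  expect_lt(max(abs(comp$value - comp$level)), 0.05)
})

test_that("ppv-sensitivity area separates perfect from random rankings", {
  truth <- sprintf("g%02d", 1:10)
  universe <- c(truth, sprintf("n%02d", 1:40))
  perfect <- ppv_sensitivity_curve(universe, truth)
  expect_equal(ppv_sensitivity_auc(perfect), 1)
  rand_auc <- mean(vapply(1:50, function(s) {
    ppv_sensitivity_auc(
      ppv_sensitivity_curve(withr::with_seed(s, sample(universe)), truth)
    )
  }, numeric(1)))
  expect_lt(abs(rand_auc - 10 / 50), 0.08)
})

test_that("enrichment score matches both the direct running sum and fgsea", {
  scores <- sort(withr::with_seed(10, rnorm(50, sd = 2)), decreasing = TRUE)
  names(scores) <- sprintf("g%02d", 1:50)
  for (s in 1:5) {
    hits <- sort(withr::with_seed(s, sample(50, 5)))
    es <- dmi:::enrichment_score(scores, hits, weight = 1)
    expect_equal(es, running_sum_es(scores, hits, weight = 1), tolerance = 1e-12)
    if (requireNamespace("fgsea", quietly = TRUE)) {
      expect_equal(es, fgsea::calcGseaStat(scores, hits, gseaParam = 1),
                   tolerance = 1e-12)
    }
    # classic KS weighting
    es0 <- dmi:::enrichment_score(scores, hits, weight = 0)
    expect_equal(es0, running_sum_es(scores, hits, weight = 0), tolerance = 1e-12)
  }
})

test_that("pre-ranked enrichment finds a top-loaded set and ignores a spread one", {
  scores <- seq(5, 0.1, length.out = 40)
  names(scores) <- sprintf("g%02d", 1:40)
  sets <- list(top = sprintf("g%02d", 1:6),
               spread = sprintf("g%02d", seq(3, 38, by = 7)),
               tiny = "g01",
               absent = c("zz1", "zz2"))
  expect_warning(
    res <- preranked_enrichment(scores, sets, n_permutations = 200, seed = 1),
    NA
  )
  expect_setequal(res$set, c("top", "spread"))  # <2-member sets dropped
  expect_identical(res$p_value[res$set == "top"], 0)
  expect_gt(res$es[res$set == "top"], 0.8)
  expect_gt(res$p_value[res$set == "spread"], 0.2)
  # the p < 0.01 reporting cut keeps only the loaded set
  cut <- preranked_enrichment(scores, sets, n_permutations = 200, seed = 1,
                              p_cut = 0.01)
  expect_identical(cut$set, "top")
})

test_that("enrichment p-values are uniform under a random ranking", {
  scores <- withr::with_seed(3, rnorm(60))
  names(scores) <- sprintf("g%02d", 1:60)
  sets <- lapply(1:30, function(i) {
    withr::with_seed(i, sample(names(scores), 8))
  })
  names(sets) <- sprintf("set%02d", 1:30)
  res <- preranked_enrichment(scores, sets, n_permutations = 200, seed = 2)
  expect_gt(suppressWarnings(stats::ks.test(res$p_value, "punif")$p.value),
            0.01)
})
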