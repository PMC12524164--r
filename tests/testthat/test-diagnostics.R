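test_that("AUC equals brute-force pair counting, with ties at half", {
  r <- roc_auc(c(1, 2, 3, 4, 5, 6), c(0, 0, 1, 0, 1, 1), ci = FALSE)
  expect_equal(r$auc, 8 / 9)
  set.seed(77)
  for (i in 1:300) {
    n <- sample(6:50, 1)
    scores <- sample(1:12, n, replace = TRUE) # deliberate ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels, ci = FALSE)$auc,
                 auc_oracle(scores, labels))
  }
})

test_that("AUC respects separation, symmetry and the U identity", {
  sep <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1), ci = FALSE)
  expect_equal(sep$auc, 1.0)
  set.seed(8)
  scores <- rnorm(40) # tie-free
  labels <- rbinom(40, 1, 0.5)
  a <- roc_auc(scores, labels, ci = FALSE)$auc
  expect_equal(roc_auc(scores, 1 - labels, ci = FALSE)$auc, 1 - a)
  n1 <- sum(labels); n0 <- sum(labels == 0)
  U <- unname(wilcox.test(scores[labels == 1],
                          scores[labels == 0])$statistic)
  expect_equal(a * n1 * n0, U)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    scores <- sample(seq(0, 4, 0.25), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(roc_auc(scores, labels, ci = FALSE)$auc, ref)
  }
})

test_that("bootstrap CI brackets the point estimate deterministically", {
  set.seed(21)
  scores <- c(rnorm(30), rnorm(30, 1.2))
  labels <- rep(0:1, each = 30)
  r1 <- roc_auc(scores, labels, boot = 400, seed = 5)
  r2 <- roc_auc(scores, labels, boot = 400, seed = 5)
  expect_identical(r1, r2)
  expect_lte(r1$ci_lower, r1$auc)
  expect_gte(r1$ci_upper, r1$auc)
})

test_that("all three cutoff rules match exhaustive candidate scans", {
  expect_equal(as.numeric(cutoff_youden(c(1, 2, 3, 4), c(0, 0, 1, 1))), 3)
  # positives at 6..10, target 0.90 -> sensitivity cutoff 6
  expect_equal(as.numeric(cutoff_at_sensitivity(
    1:10, c(rep(0, 5), rep(1, 5)), 0.90
  )), 6)
  set.seed(31)
  for (i in 1:300) {
    n <- sample(8:40, 1)
    scores <- round(rnorm(n), 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    cands <- sort(unique(scores))
    stats <- t(vapply(cands, function(ct) {
      pred <- scores >= ct
      c(se = mean(pred[labels == 1]), sp = mean(!pred[labels == 0]))
    }, numeric(2)))
    j <- stats[, "se"] + stats[, "sp"] - 1
    expect_equal(as.numeric(cutoff_youden(scores, labels)),
                 cands[which(j == max(j))[1]])
    ok_se <- which(stats[, "se"] >= 0.9)
    expect_equal(as.numeric(cutoff_at_sensitivity(scores, labels, 0.9)),
                 cands[max(ok_se)])
    ok_sp <- which(stats[, "sp"] >= 0.9)
    sp_hat <- cutoff_at_specificity(scores, labels, 0.9)
    if (length(ok_sp) > 0) {
      expect_equal(as.numeric(sp_hat), cands[min(ok_sp)])
      expect_true(attr(sp_hat, "constraint_met"))
    } else {
      expect_false(attr(sp_hat, "constraint_met"))
    }
  }
})

test_that("cutoff rules behave at the degenerate and shifted edges", {
  # all scores equal: single candidate, J = 0
  ct <- cutoff_youden(rep(2, 8), c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(as.numeric(ct), 2)
  expect_equal(attr(ct, "youden"), 0)
  # shift equivariance
  set.seed(4)
  scores <- rnorm(30); labels <- rbinom(30, 1, 0.5)
  if (length(unique(labels)) >= 2) {
    c0 <- as.numeric(cutoff_youden(scores, labels))
    c1 <- as.numeric(cutoff_youden(scores + 5, labels))
    expect_equal(c1, c0 + 5)
  }
  # target 1.0 with overlap forces the minimum positive score
  scores <- c(1, 2, 3, 4, 5, 6); labels <- c(0, 1, 0, 1, 0, 1)
  expect_equal(as.numeric(cutoff_at_sensitivity(scores, labels, 1.0)), 2)
})

test_that("diagnostic metrics come straight from the 2x2 table", {
  # TP=9, FN=1, TN=8, FP=2
  scores <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
  labels <- c(rep(1, 10), rep(0, 10))
  m <- diagnostic_metrics(scores, labels, cutoff = 1)
  expect_equal(m$se, 90)
  expect_equal(m$sp, 80)
  expect_equal(round(m$ppv, 1), 81.8)
  expect_equal(round(m$npv, 1), 88.9)
  # no predicted positives: PPV undefined
  m2 <- diagnostic_metrics(c(0, 0, 0, 0), c(0, 0, 1, 1), cutoff = 1)
  expect_true(is.na(m2$ppv))
  # rank invariance: monotone transform with transformed cutoff
  m3 <- diagnostic_metrics(exp(scores), labels, cutoff = exp(1))
  expect_equal(m3$se, m$se)
  expect_equal(m3$sp, m$sp)
})

test_that("evaluate_score produces a tidy table over comparisons", {
  coh <- compute_nit_panel(generate_cohort(cohort_spec(seed = 60)))
  tab <- evaluate_score(coh, "qf", "stage", boot = 100, seed = 2)
  expect_equal(nrow(tab), 4 * 3)
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_true(all(tab$se >= 0 & tab$se <= 100, na.rm = TRUE))
  expect_setequal(unique(tab$strategy), c("youden", "se90", "sp90"))
})

test_that("spearman correlations use mid-ranks and adjust p-values", {
  res <- spearman_matrix(tibble::tibble(x = c(1, 2, 2, 3)),
                         tibble::tibble(y = c(1, 2, 3, 4)),
                         adjust = "none")
  expect_equal(round(res$rho, 4), 0.9487) # 4.5 / sqrt(4.5 * 5)
  inc <- spearman_matrix(tibble::tibble(x = 1:8),
                         tibble::tibble(up = (1:8)^2, down = -(1:8)))
  expect_equal(inc$rho[inc$col == "up"], 1)
  expect_equal(inc$rho[inc$col == "down"], -1)
  # bonferroni multiplies within the grid
  x <- tibble::tibble(a = rnorm(20), b = rnorm(20))
  set.seed(2)
  y <- tibble::tibble(c = rnorm(20), d = rnorm(20), e = rnorm(20))
  m <- spearman_matrix(x, y)
  expect_equal(m$p_adj, pmin(1, m$p * 6))
  # insufficient pairs are flagged
  short <- spearman_matrix(tibble::tibble(x = c(1, 2, NA, NA)),
                           tibble::tibble(y = c(1, 2, 3, 4)))
  expect_equal(short$flag, "insufficient")
})

test_that("group tests combine Kruskal-Wallis with Bonferroni post hoc", {
  set.seed(11)
  same <- rep(c(1, 2, 3, 4, 5), 4)
  g <- rep(1:4, each = 5)
  res <- group_tests(same, g)
  expect_gt(res$omnibus$p, 0.99)
  # two fully separated groups of 10: U = 0, p < 0.001
  v <- c(rnorm(10), rnorm(10) + 50)
  res2 <- group_tests(v, rep(c("a", "b"), each = 10))
  expect_lt(res2$pairwise$p[1], 0.001)
  expect_equal(res2$pairwise$p_bonferroni, res2$pairwise$p) # one pair
  # bonferroni multiplies by the number of pairs (5 groups -> 10)
  v5 <- rnorm(50); g5 <- rep(0:4, each = 10)
  res5 <- group_tests(v5, g5)
  expect_equal(nrow(res5$pairwise), 10)
  expect_equal(res5$pairwise$p_bonferroni,
               pmin(1, res5$pairwise$p * 10))
  expect_warning(group_tests(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "c")),
                 "dropping")
})

test_that("weighted kappa matches hand arithmetic and the chance null", {
  expect_equal(weighted_kappa(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4)), 1.0)
  # 2x2 confusion [[40,10],[10,40]]: po = 0.8, pe = 0.5 -> 0.6
  a <- rep(c(0, 0, 1, 1), c(40, 10, 10, 40))
  b <- rep(c(0, 1, 0, 1), c(40, 10, 10, 40))
  expect_equal(weighted_kappa(a, b, "linear"), 0.6)
  expect_equal(weighted_kappa(a, b, "quadratic"), 0.6) # 2 categories
  set.seed(123)
  x <- sample(0:4, 10000, TRUE); y <- sample(0:4, 10000, TRUE)
  expect_lt(abs(weighted_kappa(x, y)), 0.03)
  expect_error(weighted_kappa(1:3, 1:4), "mismatch")
})

test_that("random-forest importance recovers a planted driver", {
  set.seed(1)
  hits <- 0
  for (s in 1:50) {
    n <- 120
    X <- as.data.frame(matrix(rnorm(n * 10), n, 10))
    names(X) <- paste0("f", 1:10)
    y <- X$f1 + rnorm(n, sd = 0.1)
    imp <- rf_importance(X, y, n_trees = 150, seed = s)
    if (imp$feature[imp$rank == 1] == "f1") hits <- hits + 1
  }
  expect_gte(hits, 48)
  # determinism and null importance of pure noise
  X <- as.data.frame(matrix(rnorm(600), 60, 10))
  y <- X[[1]] + rnorm(60, sd = 0.1)
  i1 <- rf_importance(X, y, n_trees = 100, seed = 7)
  i2 <- rf_importance(X, y, n_trees = 100, seed = 7)
  expect_identical(i1, i2)
  expect_error(rf_importance(X, rep(1, 60)), "constant")
})
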