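check_binary_labels <- function(labels) {
  l <- as.integer(labels)
  if (!all(l %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(l)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  l
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' AUC is computed through the Mann-Whitney identity: the proportion of
#' positive-negative pairs in which the positive scores higher, ties
#' counted one half. The confidence interval is a class-stratified
#' percentile bootstrap.
#'
#' @param scores Numeric scores (higher = more diseased).
#' @param labels Binary labels (1 = positive class).
#' @param ci Compute a bootstrap CI (default `TRUE`).
#' @param boot Bootstrap replicates (default 2000).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return List with `auc`, `ci_lower`, `ci_upper`, `n_pos`, `n_neg`,
#'   `method`.
#' @export
roc_auc <- function(scores, labels, ci = TRUE, boot = 2000,
                    conf_level = 0.95, seed = 1L) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  auc_of <- function(s, l) {
    n1 <- sum(l == 1); n0 <- sum(l == 0)
    r <- rank(s) # mid-ranks for ties
    (sum(r[l == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  est <- auc_of(scores, labels)
  lo <- hi <- NA_real_
  if (ci) {
    ip <- which(labels == 1); ineg <- which(labels == 0)
    reps <- with_seed(seed, vapply(seq_len(boot), function(b) {
      bp <- sample(ip, length(ip), replace = TRUE)
      bn <- sample(ineg, length(ineg), replace = TRUE)
      idx <- c(bp, bn)
      auc_of(scores[idx], labels[idx])
    }, numeric(1)))
    a <- (1 - conf_level) / 2
    qs <- quantile(reps, c(a, 1 - a), names = FALSE, type = 7)
    lo <- qs[1]; hi <- qs[2]
  }
  list(auc = est, ci_lower = lo, ci_upper = hi,
       n_pos = sum(labels == 1), n_neg = sum(labels == 0),
       method = "mann-whitney; stratified percentile bootstrap")
}

se_sp_at <- function(scores, labels, cutoff) {
  pred <- scores >= cutoff
  c(se = sum(pred & labels == 1) / sum(labels == 1),
    sp = sum(!pred & labels == 0) / sum(labels == 0))
}

#' Youden-optimal cutoff
#'
#' Scans all observed score values as candidate cutoffs (positive call:
#' score >= cutoff) and returns the smallest cutoff maximizing the
#' Youden index Se + Sp - 1.
#'
#' @inheritParams roc_auc
#' @return The cutoff, with the achieved index in attribute `youden`.
#' @export
cutoff_youden <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  cands <- sort(unique(scores))
  j <- vapply(cands, function(ct) {
    m <- se_sp_at(scores, labels, ct)
    m[["se"]] + m[["sp"]] - 1
  }, numeric(1))
  best <- cands[which.max(j)] # which.max: first (smallest) maximizer
  attr(best, "youden") <- max(j)
  best
}

#' Cutoff at a fixed sensitivity
#'
#' Returns the largest observed cutoff whose sensitivity is at least
#' `target` (thereby maximizing specificity subject to the constraint).
#' The sensitivity constraint is always attainable at the minimum score.
#'
#' @inheritParams roc_auc
#' @param target Required sensitivity (default 0.90).
#' @return The cutoff, with attribute `constraint_met`.
#' @export
cutoff_at_sensitivity <- function(scores, labels, target = 0.90) {
  labels <- check_binary_labels(labels)
  cands <- sort(unique(scores), decreasing = TRUE)
  for (ct in cands) {
    if (se_sp_at(scores, labels, ct)[["se"]] >= target) {
      return(structure(ct, constraint_met = TRUE))
    }
  }
  structure(min(scores), constraint_met = TRUE)
}

#' Cutoff at a fixed specificity
#'
#' Returns the smallest observed cutoff whose specificity is at least
#' `target` (maximizing sensitivity subject to the constraint). If no
#' observed cutoff attains the target the highest-specificity cutoff is
#' returned flagged with `constraint_met = FALSE`.
#'
#' @inheritParams cutoff_at_sensitivity
#' @return The cutoff, with attribute `constraint_met`.
#' @export
cutoff_at_specificity <- function(scores, labels, target = 0.90) {
  labels <- check_binary_labels(labels)
  cands <- sort(unique(scores))
  sp <- vapply(cands, function(ct) se_sp_at(scores, labels, ct)[["sp"]],
               numeric(1))
  ok <- which(sp >= target)
  if (length(ok) > 0) {
    structure(cands[ok[1]], constraint_met = TRUE)
  } else {
    structure(cands[which.max(sp)], constraint_met = FALSE)
  }
}

#' Sensitivity, specificity, PPV and NPV at a cutoff
#'
#' From the 2x2 table at the positive call `score >= cutoff`. Predictive
#' values with an empty denominator (no predicted positives/negatives)
#' are returned `NA`.
#'
#' @inheritParams roc_auc
#' @param cutoff Decision threshold.
#' @return One-row tibble with `se`, `sp`, `ppv`, `npv` in percent and
#'   the 2x2 counts.
#' @export
diagnostic_metrics <- function(scores, labels, cutoff) {
  labels <- check_binary_labels(labels)
  stopifnot(is.finite(cutoff))
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
  tibble::tibble(
    se = 100 * tp / (tp + fn),
    sp = 100 * tn / (tn + fp),
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Stage-dichotomized diagnostic evaluation of a score
#'
#' For each fibrosis-stage dichotomy (by default F0 vs F1-4 through
#' F0-3 vs F4) computes AUC with bootstrap CI and the three cutoffs
#' (Youden, 90% sensitivity, 90% specificity) with their Se/Sp/PPV/NPV.
#'
#' @param data Tibble containing the score and stage columns.
#' @param score Column name of the score (string).
#' @param stage Column name of the ordinal stage 0-4 (string).
#' @param thresholds Integer vector: each `t` defines the comparison
#'   stage >= t (default 1:4).
#' @param boot,seed Bootstrap parameters passed to [roc_auc()].
#' @return Tidy tibble, one row per comparison x cutoff strategy.
#' @export
evaluate_score <- function(data, score, stage, thresholds = 1:4,
                           boot = 2000, seed = 1L) {
  s <- data[[score]]
  st <- as.integer(data[[stage]])
  keep <- !is.na(s) & !is.na(st)
  s <- s[keep]; st <- st[keep]
  purrr::map_dfr(thresholds, function(t) {
    lab <- as.integer(st >= t)
    roc <- roc_auc(s, lab, boot = boot, seed = derive_seed(seed, t))
    cuts <- list(
      youden = cutoff_youden(s, lab),
      se90 = cutoff_at_sensitivity(s, lab, 0.90),
      sp90 = cutoff_at_specificity(s, lab, 0.90)
    )
    purrr::map_dfr(names(cuts), function(nm) {
      ct <- cuts[[nm]]
      dplyr::bind_cols(
        tibble::tibble(
          score = score,
          comparison = sprintf("F0-%d vs F%d-4", t - 1, t),
          auc = roc$auc, auc_lo = roc$ci_lower, auc_hi = roc$ci_upper,
          strategy = nm, cutoff = as.numeric(ct),
          constraint_met = !isFALSE(attr(ct, "constraint_met"))
        ),
        diagnostic_metrics(s, lab, as.numeric(ct))[, c("se", "sp", "ppv",
                                                       "npv")]
      )
    })
  })
}

#' Spearman correlation matrix between two variable sets
#'
#' Mid-rank Spearman correlations for every pair of a column of `x` and
#' a column of `y`, with t-approximation p-values (exact permutation
#' p-values for n < 10) and optional multiplicity adjustment.
#'
#' @param x,y Tibbles of numeric columns on the same observations.
#' @param adjust Adjustment method for [stats::p.adjust()] (default
#'   `"bonferroni"`; `"none"` to skip).
#' @param min_n Minimum paired complete observations per cell
#'   (default 3); cells below it are `NA` and flagged.
#' @return Long tibble: `row` (x name), `col` (y name), `rho`, `p`,
#'   `p_adj`, `n`, `flag`.
#' @export
spearman_matrix <- function(x, y, adjust = "bonferroni", min_n = 3) {
  x <- tibble::as_tibble(x); y <- tibble::as_tibble(y)
  stopifnot(nrow(x) == nrow(y))
  grid <- expand.grid(row = names(x), col = names(y),
                      stringsAsFactors = FALSE)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    xv <- x[[grid$row[i]]]; yv <- y[[grid$col[i]]]
    ok <- is.finite(xv) & is.finite(yv)
    n <- sum(ok)
    if (n < min_n || sd(xv[ok]) == 0 || sd(yv[ok]) == 0) {
      return(tibble::tibble(row = grid$row[i], col = grid$col[i],
                            rho = NA_real_, p = NA_real_, n = n,
                            flag = "insufficient"))
    }
    ct <- suppressWarnings(cor.test(
      xv[ok], yv[ok], method = "spearman",
      exact = n < 10, alternative = "two.sided"
    ))
    tibble::tibble(row = grid$row[i], col = grid$col[i],
                   rho = unname(ct$estimate), p = ct$p.value, n = n,
                   flag = "ok")
  })
  res$p_adj <- if (adjust == "none") res$p else p.adjust(res$p, adjust)
  res[c("row", "col", "rho", "p", "p_adj", "n", "flag")]
}

#' Stage-wise distribution tests with Bonferroni post hoc
#'
#' Kruskal-Wallis omnibus test across all stages, then every pairwise
#' Mann-Whitney comparison with Bonferroni-multiplied p-values (capped
#' at 1). Groups with fewer than 2 observations are dropped with a
#' warning.
#'
#' @param values Numeric response.
#' @param groups Group labels (e.g. fibrosis stage).
#' @return List with `omnibus` (one-row tibble) and `pairwise` (tibble
#'   of comparisons).
#' @export
group_tests <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("dropping groups with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop("need >= 2 usable groups", call. = FALSE)
  kw <- kruskal.test(values, factor(groups, levels = lev))
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  pairwise <- purrr::map_dfr(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    wt <- suppressWarnings(wilcox.test(values[groups == a],
                                       values[groups == b]))
    tibble::tibble(
      group_a = a, group_b = b, statistic = unname(wt$statistic),
      p = wt$p.value, p_bonferroni = min(1, wt$p.value * m)
    )
  })
  list(
    omnibus = tibble::tibble(
      test = "kruskal-wallis", statistic = unname(kw$statistic),
      df = unname(kw$parameter), p = kw$p.value
    ),
    pairwise = pairwise
  )
}

#' Weighted kappa for ordinal agreement
#'
#' `kappa = 1 - sum(w * O) / sum(w * E)` with linear (default) or
#' quadratic disagreement weights over the ordinal categories.
#'
#' @param a,b Integer ratings on the same subjects (e.g. stages 0-4).
#' @param weights `"linear"` or `"quadratic"`.
#' @return Weighted kappa.
#' @export
weighted_kappa <- function(a, b, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  lev <- sort(unique(c(a, b)))
  k <- length(lev)
  O <- table(factor(a, lev), factor(b, lev)) / length(a)
  pa <- rowSums(O); pb <- colSums(O)
  E <- outer(pa, pb)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  w <- if (weights == "linear") d else d^2
  1 - sum(w * O) / sum(w * E)
}

#' Random-forest variable importance for a continuous target
#'
#' Fits a regression random forest and reports both permutation
#' importance (mean increase in out-of-bag MSE when the feature is
#' permuted) and total node-impurity decrease, with ranks by
#' permutation importance.
#'
#' @param X Tibble/data frame of numeric features.
#' @param y Continuous target.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return Tibble: `feature`, `mse_increase`, `node_purity`, `rank`.
#' @export
rf_importance <- function(X, y, n_trees = 500, seed = 1L) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) >= 10, ncol(X) >= 2, nrow(X) == length(y))
  if (sd(y) == 0) stop("constant target", call. = FALSE)
  fit <- with_seed(seed, randomForest::randomForest(
    x = X, y = as.numeric(y), ntree = n_trees, importance = TRUE
  ))
  imp <- randomForest::importance(fit)
  out <- tibble::tibble(
    feature = rownames(imp),
    mse_increase = unname(imp[, "%IncMSE"]),
    node_purity = unname(imp[, "IncNodePurity"])
  )
  out$rank <- rank(-out$mse_increase, ties.method = "first")
  dplyr::arrange(out, .data$rank)
}
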