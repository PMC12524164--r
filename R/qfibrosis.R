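#' Max-normalize a q-FP feature table
#'
#' Divides every feature column by its maximum over the supplied
#' (training) tables, mapping each column into \[0, 1\]. Columns whose
#' maximum is zero carry no information and are dropped with a warning.
#'
#' @param tables Tibble/data frame of q-FP values, one row per specimen
#'   (numeric columns only; bind rows of [compute_qfp_table()] outputs).
#' @return List with `features` (normalized tibble), `maxima` (named
#'   vector), `dropped` (character).
#' @export
normalize_qfp <- function(tables) {
  tables <- tibble::as_tibble(tables, .name_repair = "minimal")
  if (nrow(tables) == 0) stop("no q-FP tables supplied", call. = FALSE)
  stopifnot(all(vapply(tables, is.numeric, logical(1))))
  maxima <- vapply(tables, max, numeric(1))
  dropped <- names(maxima)[maxima <= 0]
  if (length(dropped) > 0) {
    warning("dropping zero-maximum features: ",
            paste(dropped, collapse = ", "))
  }
  keep <- names(maxima)[maxima > 0]
  feats <- tables[keep]
  for (nm in keep) feats[[nm]] <- feats[[nm]] / maxima[[nm]]
  list(features = feats, maxima = maxima[keep], dropped = dropped)
}

# Stage-stratified fold assignment, deterministic given seed.
stratified_folds <- function(stages, k, seed) {
  with_seed(seed, {
    fold <- integer(length(stages))
    for (s in unique(stages)) {
      idx <- sample(which(stages == s))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

cv_rss <- function(X, y, fold) {
  k <- max(fold)
  rss <- 0
  for (f in seq_len(k)) {
    tr <- fold != f
    df_tr <- data.frame(y = y[tr], X[tr, , drop = FALSE])
    df_te <- data.frame(X[!tr, , drop = FALSE])
    fit <- stats::lm(y ~ ., data = df_tr)
    pred <- suppressWarnings(predict(fit, newdata = df_te))
    rss <- rss + sum((y[!tr] - pred)^2)
  }
  rss
}

#' Forward sequential feature selection against fibrosis stage
#'
#' Greedy forward selection for the linear stage model: at each step the
#' candidate feature whose addition minimizes the stage-stratified
#' cross-validated residual sum of squares is added; selection stops at
#' `k_max` features or when the CV error no longer improves.
#'
#' @param X Normalized feature tibble (e.g. `normalize_qfp()$features`).
#' @param stages Numeric/ordinal stage labels (0-4), one per row.
#' @param k_max Maximum number of features (default 17).
#' @param cv_folds Number of stratified folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return Character vector of selected feature names, in selection
#'   order, with the CV-error trace in attribute `trace`.
#' @export
select_features <- function(X, stages, k_max = 17, cv_folds = 5, seed = 1L) {
  if (k_max < 1) stop("k_max must be >= 1", call. = FALSE)
  X <- tibble::as_tibble(X, .name_repair = "minimal")
  y <- as.numeric(stages)
  stopifnot(nrow(X) == length(y), nrow(X) > cv_folds, cv_folds >= 2)
  fold <- stratified_folds(y, cv_folds, seed)
  selected <- character(0)
  trace <- numeric(0)
  best_err <- Inf
  pool <- names(X)
  repeat {
    if (length(selected) >= k_max || length(pool) == 0) break
    errs <- vapply(pool, function(f) {
      cv_rss(X[c(selected, f)], y, fold)
    }, numeric(1))
    cand <- pool[which.min(errs)]
    err <- min(errs)
    if (err >= best_err - 1e-10) break
    selected <- c(selected, cand)
    trace <- c(trace, err)
    best_err <- err
    pool <- setdiff(pool, cand)
  }
  if (length(selected) == 0) { # never return an empty model
    errs <- vapply(names(X), function(f) cv_rss(X[f], y, fold), numeric(1))
    selected <- names(X)[which.min(errs)]
    trace <- min(errs)
  }
  attr(selected, "trace") <- trace
  selected
}

#' Fit the linear qFibrosis model on selected features
#'
#' Ordinary least squares of stage (treated as numeric 0-4) on the
#' selected, max-normalized features.
#'
#' @param X_selected Tibble of selected normalized features.
#' @param stages Numeric stage labels.
#' @param maxima Named vector of training maxima for the selected
#'   features (stored so new specimens are normalized with the frozen
#'   training maxima).
#' @return A `qf_model`: selected feature names, coefficients,
#'   intercept, maxima, and fit metadata.
#' @export
fit_qf_model <- function(X_selected, stages, maxima = NULL) {
  X_selected <- tibble::as_tibble(X_selected, .name_repair = "minimal")
  y <- as.numeric(stages)
  n <- nrow(X_selected); p <- ncol(X_selected)
  stopifnot(n == length(y))
  if (n <= p) stop("need more specimens than features", call. = FALSE)
  df <- data.frame(y = y, X_selected, check.names = TRUE)
  fit <- stats::lm(y ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- names(X_selected)[is.na(cf[-1])]
    stop("rank-deficient design; collinear features: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(maxima)) maxima <- setNames(rep(1, p), names(X_selected))
  stopifnot(all(names(X_selected) %in% names(maxima)))
  structure(list(
    features = names(X_selected),
    intercept = unname(cf[1]),
    coefficients = setNames(unname(cf[-1]), names(X_selected)),
    maxima = maxima[names(X_selected)],
    fitted = unname(stats::fitted(fit)),
    r_squared = summary(fit)$r.squared,
    n = n
  ), class = "qf_model")
}

#' @export
print.qf_model <- function(x, ...) {
  cat(sprintf("<qf_model> %d features, n = %d, R^2 = %.3f\n",
              length(x$features), x$n, x$r_squared))
  cat("  features:", paste(utils::head(x$features, 6), collapse = ", "),
      if (length(x$features) > 6) "..." else "", "\n")
  invisible(x)
}

#' @method tidy qf_model
#' @export
tidy.qf_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$features),
    estimate = c(x$intercept, unname(x$coefficients)),
    normalization_max = c(NA_real_, unname(x$maxima))
  )
}

#' @method glance qf_model
#' @export
glance.qf_model <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n = x$n,
                 n_features = length(x$features))
}

#' Score specimens with a fitted qFibrosis model
#'
#' Applies the frozen training maxima and linear coefficients to raw
#' q-FP tables. The score is continuous and dimensionless; it is not
#' clamped to \[0, 4\], and normalized values may exceed 1 on specimens
#' outside the training range.
#'
#' @param model A `qf_model`.
#' @param tables Raw (unnormalized) q-FP tibble, one row per specimen.
#' @return Numeric qFibrosis score per row.
#' @export
score_qf <- function(model, tables) {
  stopifnot(inherits(model, "qf_model"))
  tables <- tibble::as_tibble(tables, .name_repair = "minimal")
  missing_f <- setdiff(model$features, names(tables))
  if (length(missing_f) > 0) {
    stop("tables lack selected features: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(tables[model$features])
  Xn <- sweep(X, 2, model$maxima, "/")
  as.numeric(model$intercept + Xn %*% model$coefficients)
}

#' Fit the full qFibrosis pipeline on a training set of q-FP tables
#'
#' Convenience wrapper: max-normalization, forward CV feature selection
#' against stage, then the OLS stage model.
#'
#' @inheritParams select_features
#' @param tables Raw q-FP tibble (one row per specimen).
#' @param stages Stage labels.
#' @return A `qf_model`.
#' @export
fit_qfibrosis <- function(tables, stages, k_max = 17, cv_folds = 5,
                          seed = 1L) {
  norm <- normalize_qfp(tables)
  sel <- select_features(norm$features, stages, k_max = k_max,
                         cv_folds = cv_folds, seed = seed)
  fit_qf_model(norm$features[sel], stages, maxima = norm$maxima)
}
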