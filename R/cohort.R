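# Stage-conditional distribution parameters for the synthetic MASLD
# cohort. Variables reported as mean (SD) are normal; variables reported
# as median (IQR) are log-normal with parameters solved from the printed
# median m and quartiles (q1, q3): mu = log(m),
# sigma = (log q3 - log q1) / (2 * qnorm(0.75)). Proportions are
# Bernoulli. One row per variable x stage.
cohort_params_default <- function() {
  z75 <- 2 * qnorm(0.75)
  ln <- function(variable, m, q1, q3) {
    tibble::tibble(
      variable = variable, stage = 0:4, dist = "lognormal",
      meanlog = log(m), sdlog = (log(q3) - log(q1)) / z75
    )
  }
  nm <- function(variable, mean, sd) {
    tibble::tibble(
      variable = variable, stage = 0:4, dist = "normal",
      mean = mean, sd = sd
    )
  }
  bin <- function(variable, prob) {
    tibble::tibble(variable = variable, stage = 0:4, dist = "binomial",
                   prob = prob)
  }
  dplyr::bind_rows(
    ln("age", c(38, 37, 46, 38, 56), c(32, 29, 33, 32, 40),
       c(42, 44, 55, 59, 63)),
    bin("male", c(14 / 17, 10 / 16, 17 / 32, 14 / 28, 4 / 6)),
    ln("bmi", c(28.8, 27.1, 27.7, 28.1, 28.5), c(25.4, 25.8, 26.3, 26.0, 27.4),
       c(30.1, 29.6, 29.3, 33.8, 29.8)),
    bin("diabetes", c(3 / 17, 4 / 16, 10 / 32, 7 / 28, 4 / 6)),
    ln("alt", c(67, 73, 89, 99, 59), c(53, 44, 65, 71, 51),
       c(98, 116, 126, 125, 67)),
    ln("ast", c(39, 58, 50, 68, 51), c(33, 37, 42, 53, 41),
       c(46, 72, 89, 107, 58)),
    ln("ggt", c(38, 49, 40, 72, 96), c(31, 34, 31, 55, 70),
       c(56, 78, 69, 97, 135)),
    ln("alb_gl", c(48, 48, 47, 45, 45), c(46, 44, 45, 44, 41),
       c(49, 50, 49, 48, 49)),
    nm("plt", c(247, 281, 244, 226, 167), c(52, 69, 53, 76, 68)),
    ln("glucose", c(5.2, 5.0, 6.0, 5.5, 6.6), c(4.9, 4.5, 5.3, 5.0, 6.0),
       c(5.8, 5.6, 6.5, 6.8, 6.7)),
    ln("pdff", c(12.4, 14.1, 16.6, 15.0, 6.9), c(6.0, 10.6, 10.4, 8.9, 6.4),
       c(19.3, 16.8, 21.4, 20.7, 11.9)),
    ln("mre_lsm", c(2.44, 2.77, 2.89, 3.98, 5.13),
       c(2.17, 2.52, 2.47, 3.23, 4.88), c(2.55, 3.15, 3.26, 4.27, 5.31)),
    nm("cap", c(320, 328, 327, 332, 324), c(44, 38, 46, 31, 40)),
    ln("vcte_lsm", c(7.4, 7.7, 8.5, 12.0, 14.6), c(5.7, 6.3, 7.5, 9.9, 10.6),
       c(8.4, 10.1, 10.1, 17.8, 16.5)),
    nm("qf", c(0.94, 1.42, 2.14, 2.86, 3.78),
       c(0.38, 0.45, 0.47, 0.63, 0.60))
  )
}

#' Specification for a synthetic MASLD patient cohort
#'
#' Stage-conditional distributions default to the calibration of a
#' biopsy-staged MASLD cohort: variables reported as mean (SD) are drawn
#' normal, skewed variables reported as median (IQR) are drawn
#' log-normal with parameters solved from the printed median and
#' quartiles, and proportions are Bernoulli. Stage counts default to the
#' cohort's 17/16/32/28/6 split over F0-F4 (n = 99).
#'
#' @param stage_counts Integer vector of length 5: patients per stage
#'   F0..F4.
#' @param params Long tibble of distribution parameters (`variable`,
#'   `stage`, `dist`, and `mean`/`sd`, `meanlog`/`sdlog` or `prob`);
#'   default is the built-in calibration.
#' @param ast_uln Upper limit of normal for AST in U/L (default 40).
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(stage_counts = c(17, 16, 32, 28, 6),
                        params = cohort_params_default(),
                        ast_uln = 40, seed = 1L) {
  stopifnot(length(stage_counts) == 5, all(stage_counts >= 0),
            sum(stage_counts) >= 1)
  structure(list(
    stage_counts = as.integer(stage_counts),
    n = sum(as.integer(stage_counts)),
    params = params, ast_uln = ast_uln, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Draws one record per patient with a true fibrosis stage and
#' stage-conditional clinical variables. Negative draws of physical
#' quantities (labs, imaging values) are redrawn; the redraw count is
#' recorded in attribute `n_redraws`. The continuous qFibrosis score is
#' drawn on its calibrated normal and left untruncated (a regression
#' score may be negative).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per patient: `patient_id`, `stage`,
#'   demographics, labs, elastography and imaging values, `qf`, plus
#'   `hyperglycemia` (diabetes or fasting glucose >= 5.6 mmol/L) and
#'   `ast_uln`.
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 7))
#' dplyr::count(coh, stage)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  stages <- rep(0:4, times = spec$stage_counts)
  n <- length(stages)
  p <- spec$params
  n_redraws <- 0L
  draw <- function(variable, truncate_pos = TRUE) {
    out <- numeric(n)
    for (s in 0:4) {
      idx <- which(stages == s)
      if (length(idx) == 0) next
      row <- p[p$variable == variable & p$stage == s, ]
      if (nrow(row) != 1) stop("missing parameters for ", variable)
      gen <- switch(row$dist,
        normal = function(m) rnorm(m, row$mean, row$sd),
        lognormal = function(m) rlnorm(m, row$meanlog, row$sdlog),
        binomial = function(m) rbinom(m, 1, row$prob),
        stop("unknown distribution ", row$dist)
      )
      x <- gen(length(idx))
      if (truncate_pos && row$dist == "normal") {
        bad <- which(x <= 0)
        guard <- 0
        while (length(bad) > 0 && guard < 100) {
          n_redraws <<- n_redraws + length(bad)
          x[bad] <- gen(length(bad))
          bad <- bad[x[bad] <= 0]
          guard <- guard + 1
        }
      }
      out[idx] <- x
    }
    out
  }
  out <- with_seed(spec$seed, {
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      stage = stages,
      age = draw("age"),
      male = as.integer(draw("male")),
      bmi = draw("bmi"),
      diabetes = as.integer(draw("diabetes")),
      alt = draw("alt"),
      ast = draw("ast"),
      ggt = draw("ggt"),
      alb_gl = draw("alb_gl"),
      plt = draw("plt"),
      glucose = draw("glucose"),
      pdff = draw("pdff"),
      mre_lsm = draw("mre_lsm"),
      cap = draw("cap"),
      vcte_lsm = draw("vcte_lsm"),
      qf = draw("qf", truncate_pos = FALSE),
      ast_uln = spec$ast_uln
    )
  })
  out$hyperglycemia <- as.integer(out$diabetes == 1 | out$glucose >= 5.6)
  attr(out, "n_redraws") <- n_redraws
  out
}

#' Simulate a screening roster with planted exclusion flags
#'
#' Builds a roster of screened patients of which `n_incomplete` lack
#' complete clinical data, `n_interval` have a biopsy-imaging interval
#' longer than six months, and `n_disease` have a concomitant liver
#' disease. By default the three flagged groups are disjoint.
#'
#' @param n Total screened patients (default 126).
#' @param n_incomplete,n_interval,n_disease Patients failing each
#'   exclusion (defaults 15, 10, 2).
#' @param seed Integer seed.
#' @return Tibble with `screen_id`, `has_complete_data`,
#'   `biopsy_mri_interval_days`, `concomitant_liver_disease`.
#' @export
simulate_screening_roster <- function(n = 126, n_incomplete = 15,
                                      n_interval = 10, n_disease = 2,
                                      seed = 1L) {
  stopifnot(n_incomplete + n_interval + n_disease <= n)
  with_seed(seed, {
    ids <- sample.int(n)
    i_inc <- ids[seq_len(n_incomplete)]
    i_int <- ids[n_incomplete + seq_len(n_interval)]
    i_dis <- ids[n_incomplete + n_interval + seq_len(n_disease)]
    interval <- round(runif(n, 1, 150))
    interval[i_int] <- round(runif(n_interval, 190, 400))
    tibble::tibble(
      screen_id = sprintf("S%03d", seq_len(n)),
      has_complete_data = !(seq_len(n) %in% i_inc),
      biopsy_mri_interval_days = interval,
      concomitant_liver_disease = seq_len(n) %in% i_dis
    )
  })
}

#' Apply cohort-assembly exclusion filters to a screening roster
#'
#' Excludes, in order: records without complete clinical data, records
#' with a biopsy-imaging interval longer than `max_interval_days`, and
#' records with concomitant liver disease. A record failing several
#' criteria is counted once, under the first matching reason.
#'
#' @param roster Tibble with columns `has_complete_data` (logical),
#'   `biopsy_mri_interval_days` (numeric) and `concomitant_liver_disease`
#'   (logical).
#' @param max_interval_days Maximum biopsy-imaging interval (default 183
#'   days, i.e. six months).
#' @return The retained records, with an `exclusions` attribute: a
#'   tibble of per-reason tallies.
#' @export
apply_screening_filters <- function(roster, max_interval_days = 183) {
  need <- c("has_complete_data", "biopsy_mri_interval_days",
            "concomitant_liver_disease")
  missing_cols <- setdiff(need, names(roster))
  if (length(missing_cols) > 0) {
    stop("roster lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(roster[need])) {
    stop("roster exclusion fields contain missing values", call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(roster))
  reason[is.na(reason) & !roster$has_complete_data] <- "incomplete_data"
  reason[is.na(reason) &
           roster$biopsy_mri_interval_days > max_interval_days] <-
    "interval_gt_6mo"
  reason[is.na(reason) & roster$concomitant_liver_disease] <-
    "concomitant_disease"
  reasons <- c("incomplete_data", "interval_gt_6mo", "concomitant_disease")
  counts <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  tally <- tibble::tibble(reason = reasons, n = unname(counts))
  out <- roster[is.na(reason), , drop = FALSE]
  attr(out, "exclusions") <- tally
  out
}
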