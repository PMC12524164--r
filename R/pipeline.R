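#' Analysis parameters for the image pipeline
#'
#' Bundles every tunable of the segmentation, zonation and morphometry
#' stages with its default. Units are um / um^2 / mm^2 as named.
#'
#' @param min_tissue_area_mm2 Tissue components must exceed this area
#'   (default 0.1).
#' @param min_string_um2 Collagen noise floor (default 15).
#' @param fill_hole_px Gap-filling hole size in px (default 2).
#' @param min_lumen_um2 Minimum lumen area (default 100).
#' @param collar_width_um Collagen collar ring width (default 6).
#' @param periportal_band_um,pericentral_band_um Zone band widths
#'   (default 100).
#' @param thick_um,long_um String width/length class bounds (defaults
#'   3, 40).
#' @param close_radius_um,agg_area_um2 Aggregation closing radius and
#'   cluster area bound (defaults 5, 200).
#' @param attach_dist_um Chicken-wire attachment distance (default 10).
#' @return Named list of parameters.
#' @export
analysis_params <- function(min_tissue_area_mm2 = 0.1, min_string_um2 = 15,
                            fill_hole_px = 2, min_lumen_um2 = 100,
                            collar_width_um = 6, periportal_band_um = 100,
                            pericentral_band_um = 100, thick_um = 3,
                            long_um = 40, close_radius_um = 5,
                            agg_area_um2 = 200, attach_dist_um = 10) {
  as.list(environment())
}

#' Run segmentation, zonation and morphometry on one specimen
#'
#' The full image side of the pipeline for a single two-channel image:
#' tissue and collagen segmentation, lumen detection, landmark
#' classification, zone map construction, string decomposition and
#' the named q-FP table.
#'
#' @param img A [multiphoton_image()].
#' @param landmark_model A trained [train_landmark_classifier()] model,
#'   or `NULL` if `landmark_classes` is given.
#' @param landmark_classes Optional character vector of known lumen
#'   classes (bypasses the model; aligned with detected lumens).
#' @param params [analysis_params()] list.
#' @return List with `qfp` (one-row tibble), `strings`, `zone_map`,
#'   `lumens`, `tissue`, `collagen`.
#' @export
analyze_specimen <- function(img, landmark_model = NULL,
                             landmark_classes = NULL,
                             params = analysis_params()) {
  tissue <- segment_tissue(img, params$min_tissue_area_mm2)
  if (!any(tissue)) stop("no tissue passed the area filter", call. = FALSE)
  collagen <- segment_collagen(img, tissue, params$min_string_um2,
                               params$fill_hole_px)
  lumens <- detect_lumens(tissue, collagen, params$min_lumen_um2,
                          params$collar_width_um)
  classes <- if (!is.null(landmark_classes)) {
    stopifnot(length(landmark_classes) == nrow(lumens))
    landmark_classes
  } else if (!is.null(landmark_model) && nrow(lumens) > 0) {
    predict_landmarks(landmark_model, lumens)
  } else {
    character(0)
  }
  zone_map <- build_zone_map(
    tissue, lumens, classes, collagen,
    params$periportal_band_um, params$pericentral_band_um,
    params$collar_width_um
  )
  strings <- extract_strings(collagen, zone_map)
  strings <- classify_strings(strings, params$thick_um, params$long_um)
  strings <- classify_aggregation(strings, collagen,
                                  params$close_radius_um,
                                  params$agg_area_um2)
  strings <- assign_chickenwire(strings, zone_map, params$attach_dist_um,
                                params$thick_um)
  qfp <- compute_qfp_table(strings, zone_map)
  list(qfp = qfp, strings = strings, zone_map = zone_map, lumens = lumens,
       tissue = tissue, collagen = collagen)
}

#' Label detected lumens from phantom ground truth
#'
#' Matches detected lumens to the phantom's planted landmarks by
#' nearest centroid and returns the true class per detected lumen
#' (`other` when nothing is planted within `max_dist_um`).
#'
#' @param lumens Tibble from [detect_lumens()].
#' @param truth Phantom ground truth (`generate_phantom()$truth`).
#' @param max_dist_um Match tolerance (default 30).
#' @return Character vector of classes aligned with `lumens`.
#' @export
match_lumens_to_truth <- function(lumens, truth, max_dist_um = 30) {
  if (nrow(lumens) == 0) return(character(0))
  pitch <- attr(lumens, "pixel_pitch_um")
  gt <- truth$lumen_table
  vapply(seq_len(nrow(lumens)), function(i) {
    d <- sqrt((gt$centroid_row - lumens$centroid_row[i])^2 +
              (gt$centroid_col - lumens$centroid_col[i])^2) * pitch
    j <- which.min(d)
    if (d[j] <= max_dist_um) gt$class[j] else "other"
  }, character(1))
}

#' Configuration for a reproducible end-to-end run
#'
#' One seed fans out deterministically to every stochastic sub-step.
#' The configuration is fully JSON-serializable
#' ([write_run_config()] / [read_run_config()] round-trip).
#'
#' @param seed Top-level integer seed.
#' @param n_per_stage Phantoms per fibrosis stage (default 10).
#' @param canvas_px Phantom canvas side (default 512).
#' @param pixel_pitch_um Pixel pitch (default 0.390625).
#' @param n_portal_tracts,n_central_veins Landmarks per phantom.
#' @param params [analysis_params()] list; defaults are rescaled to the
#'   canvas when you pass your own (`min_tissue_area_mm2` must be below
#'   the canvas area to retain any tissue).
#' @param k_max,cv_folds qFibrosis fitting parameters.
#' @param boot Bootstrap replicates for AUC CIs (default 500).
#' @param cohort_stage_counts Stage counts of the synthetic cohort
#'   (default the 17/16/32/28/6 split).
#' @param write_images Write per-phantom TIFFs (default `FALSE`).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_per_stage = 10, canvas_px = 512,
                       pixel_pitch_um = 0.390625, n_portal_tracts = 2,
                       n_central_veins = 2, params = NULL, k_max = 17,
                       cv_folds = 5, boot = 500,
                       cohort_stage_counts = c(17, 16, 32, 28, 6),
                       write_images = FALSE) {
  canvas_mm2 <- (canvas_px * pixel_pitch_um)^2 / 1e6
  if (is.null(params)) {
    params <- analysis_params(
      # keep the area filter exercisable on small canvases: a quarter of
      # the canvas, capped at the standard 0.1 mm^2
      min_tissue_area_mm2 = min(0.1, canvas_mm2 / 4),
      periportal_band_um = min(100, canvas_px * pixel_pitch_um / 4),
      pericentral_band_um = min(100, canvas_px * pixel_pitch_um / 4)
    )
  }
  structure(list(
    seed = as.integer(seed), n_per_stage = as.integer(n_per_stage),
    canvas_px = as.integer(canvas_px), pixel_pitch_um = pixel_pitch_um,
    n_portal_tracts = as.integer(n_portal_tracts),
    n_central_veins = as.integer(n_central_veins),
    params = params, k_max = as.integer(k_max),
    cv_folds = as.integer(cv_folds), boot = as.integer(boot),
    cohort_stage_counts = as.integer(cohort_stage_counts),
    write_images = isTRUE(write_images),
    version = as.character(utils::packageVersion("fibroquant"))
  ), class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$params <- as.list(x$params)
  structure(x, class = "run_config")
}

#' Generate a staged phantom set and its q-FP tables
#'
#' Builds `n_per_stage` phantoms per stage, trains the landmark CART on
#' ground-truth-labelled lumens from a training subset, analyzes every
#' phantom with the trained model and returns the stacked q-FP table.
#'
#' @param config A [run_config()].
#' @param progress Print a line per stage (default `FALSE`).
#' @return List with `qfp` (tibble with `specimen`, `stage` + q-FP
#'   columns), `landmark_model`, `landmark_accuracy` (on phantoms not
#'   used for training), and `analyses` (list of per-specimen results
#'   when `config$write_images`).
#' @export
phantom_study <- function(config = run_config(), progress = FALSE) {
  stages <- rep(0:4, each = config$n_per_stage)
  specs <- lapply(seq_along(stages), function(i) {
    phantom_spec(
      stage = stages[i], canvas_px = config$canvas_px,
      pixel_pitch_um = config$pixel_pitch_um,
      n_portal_tracts = config$n_portal_tracts,
      n_central_veins = config$n_central_veins,
      periportal_band_um = config$params$periportal_band_um,
      pericentral_band_um = config$params$pericentral_band_um,
      seed = derive_seed(config$seed, i)
    )
  })
  # landmark training set: detected lumens of the first phantom of each
  # stage, labelled from ground truth
  train_idx <- which(!duplicated(stages))
  feat <- list(); labs <- character(0)
  analyses <- vector("list", length(stages))
  phantoms <- lapply(specs, generate_phantom)
  for (i in train_idx) {
    ph <- phantoms[[i]]
    tissue <- segment_tissue(ph$image, config$params$min_tissue_area_mm2)
    collagen <- segment_collagen(ph$image, tissue,
                                 config$params$min_string_um2,
                                 config$params$fill_hole_px)
    lum <- detect_lumens(tissue, collagen, config$params$min_lumen_um2,
                         config$params$collar_width_um)
    if (nrow(lum) == 0) next
    feat[[length(feat) + 1]] <- lumen_features(lum)
    labs <- c(labs, match_lumens_to_truth(lum, ph$truth))
  }
  features <- dplyr::bind_rows(feat)
  model <- if (length(unique(labs)) >= 2) {
    train_landmark_classifier(features, labs,
                              seed = derive_seed(config$seed, 9001))
  } else {
    constant_landmark_model(labs[1], n = length(labs))
  }
  rows <- vector("list", length(stages))
  correct <- 0L; total <- 0L
  for (i in seq_along(stages)) {
    ph <- phantoms[[i]]
    res <- analyze_specimen(ph$image, landmark_model = model,
                            params = config$params)
    if (!(i %in% train_idx) && nrow(res$lumens) > 0) {
      truth_cls <- match_lumens_to_truth(res$lumens, ph$truth)
      pred_cls <- predict_landmarks(model, res$lumens)
      correct <- correct + sum(pred_cls == truth_cls)
      total <- total + length(truth_cls)
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(specimen = sprintf("phantom_%03d", i),
                     stage = stages[i]),
      res$qfp
    )
    if (config$write_images) analyses[[i]] <- res
    if (progress && i %% config$n_per_stage == 0) {
      message("stage F", stages[i], " done (", i, "/", length(stages), ")")
    }
  }
  list(
    qfp = dplyr::bind_rows(rows), landmark_model = model,
    landmark_accuracy = if (total > 0) correct / total else NA_real_,
    analyses = if (config$write_images) analyses else NULL
  )
}

#' Run the full synthetic study end to end
#'
#' Orchestrates phantom generation, segmentation, zonation,
#' morphometry, qFibrosis fitting, cohort simulation, NIT scoring and
#' the diagnostic layer, writing every tabular artifact plus a summary
#' JSON into `out_dir`. Re-running with the same config reproduces the
#' outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the main results: `qf_model`,
#'   `qf_spearman`, `auc_table`, `correlations`, `importance`, `kappa`,
#'   `summary`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("fqrun")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(out_dir, "config.json"))

  study <- phantom_study(config)
  qfp <- study$qfp
  feature_cols <- setdiff(names(qfp), c("specimen", "stage"))
  write.csv(qfp, file.path(out_dir, "qfp_tables.csv"), row.names = FALSE)

  model <- fit_qfibrosis(qfp[feature_cols], qfp$stage, k_max = config$k_max,
                         cv_folds = config$cv_folds,
                         seed = derive_seed(config$seed, 2))
  qfp$qf_score <- score_qf(model, qfp[feature_cols])
  qf_spearman <- suppressWarnings(
    cor(qfp$qf_score, qfp$stage, method = "spearman")
  )
  jsonlite::write_json(
    list(features = model$features, intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         maxima = as.list(model$maxima), r_squared = model$r_squared,
         n = model$n, version = config$version),
    file.path(out_dir, "qf_model.json"), auto_unbox = TRUE, digits = NA
  )

  cohort <- generate_cohort(cohort_spec(
    stage_counts = config$cohort_stage_counts,
    seed = derive_seed(config$seed, 3)
  ))
  cohort <- compute_nit_panel(cohort)
  write.csv(cohort, file.path(out_dir, "cohort_scored.csv"),
            row.names = FALSE)

  nit_cols <- c("qf", "mre_lsm", "vcte_lsm", "mast", "fast", "fib4",
                "apri", "aar", "nfs")
  auc_table <- purrr::map_dfr(nit_cols, function(sc) {
    evaluate_score(cohort, sc, "stage", boot = config$boot,
                   seed = derive_seed(config$seed, 4))
  })
  write.csv(auc_table, file.path(out_dir, "auc_table.csv"),
            row.names = FALSE)

  # pair each patient with a stage-matched phantom q-FP table
  pair_idx <- with_seed(derive_seed(config$seed, 5), vapply(
    cohort$stage, function(s) {
      idx <- which(qfp$stage == s)
      idx[sample.int(length(idx), 1)]
    }, integer(1)
  ))
  top_qfp <- c("StrWidthPT", "StrLengthPT", "%PeriPortal",
               "StrAreaPeriPortal", "#StrPT", "%PTDis", "%SHG",
               "#ShortStrZone2", "#StrZone2", "StrLengthZone2")
  top_qfp <- intersect(top_qfp, feature_cols)
  correlations <- spearman_matrix(qfp[pair_idx, top_qfp],
                                  cohort[nit_cols])
  write.csv(correlations, file.path(out_dir, "correlations.csv"),
            row.names = FALSE)

  imp <- rf_importance(qfp[pair_idx, top_qfp], cohort$mre_lsm,
                       n_trees = 300, seed = derive_seed(config$seed, 6))
  write.csv(imp, file.path(out_dir, "importance_mre.csv"),
            row.names = FALSE)

  pred_stage <- pmin(pmax(round(qfp$qf_score[pair_idx]), 0), 4)
  kappa <- weighted_kappa(cohort$stage, pred_stage)

  summary <- list(
    n_phantoms = nrow(qfp),
    landmark_accuracy = study$landmark_accuracy,
    qf_features = model$features,
    qf_r_squared = model$r_squared,
    qf_spearman_vs_stage = qf_spearman,
    qf_median_by_stage = as.list(tapply(qfp$qf_score, qfp$stage, median)),
    auc_f3f4 = as.list(setNames(
      vapply(nit_cols, function(sc) {
        auc_table$auc[auc_table$score == sc &
                        auc_table$comparison == "F0-2 vs F3-4"][1]
      }, numeric(1)), nit_cols
    )),
    weighted_kappa = kappa
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(
    qf_model = model, qfp = qfp, cohort = cohort,
    qf_spearman = qf_spearman, auc_table = auc_table,
    correlations = correlations, importance = imp, kappa = kappa,
    summary = summary, out_dir = out_dir
  ))
}
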