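#' Per-lumen feature matrix for landmark classification
#'
#' Extracts the features used by the portal-tract / central-vein
#' classifier from a lumen table produced by [detect_lumens()]: physical
#' area, eccentricity, collagen collar fraction, boundary smoothness and
#' neighbour count. All features are finite.
#'
#' @param lumens Tibble from [detect_lumens()].
#' @return Tibble with `lumen_id` plus the five feature columns.
#' @export
lumen_features <- function(lumens) {
  out <- dplyr::select(
    tibble::as_tibble(lumens), "lumen_id", "area_um2", "eccentricity",
    "collar_fraction", "boundary_smoothness", "neighbor_lumen_count"
  )
  stopifnot(all(vapply(out[-1], function(x) all(is.finite(x)), logical(1))))
  out
}

#' Train a CART landmark classifier on labelled lumens
#'
#' Fits a depth-limited classification tree (recursive binary splits
#' minimizing Gini impurity) that predicts the anatomical class of a
#' lumen -- `portal_tract`, `central_vein` or `other` -- from its shape
#' and collagen-collar features.
#'
#' @param features Tibble from [lumen_features()] (the `lumen_id` column
#'   is ignored if present).
#' @param labels Character/factor vector of true classes, one per row.
#' @param max_depth Maximum tree depth (default 4).
#' @param seed Integer seed (tree growth is deterministic; the seed is
#'   recorded and fixes any surrogate tie-breaking).
#' @return A `landmark_model` object.
#' @export
train_landmark_classifier <- function(features, labels, max_depth = 4,
                                      seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("training labels must contain at least 2 classes", call. = FALSE)
  }
  df <- dplyr::select(tibble::as_tibble(features),
                      -dplyr::any_of("lumen_id"))
  stopifnot(nrow(df) == length(labels))
  df$.class <- factor(labels)
  fit <- with_seed(seed, rpart::rpart(
    .class ~ ., data = df, method = "class",
    control = rpart::rpart.control(
      maxdepth = max_depth, minsplit = 4, minbucket = 2, cp = 0.001,
      xval = 0
    )
  ))
  structure(list(
    tree = fit, classes = levels(df$.class),
    meta = list(n = nrow(df), class_counts = table(labels),
                max_depth = max_depth, seed = seed)
  ), class = "landmark_model")
}

#' @export
print.landmark_model <- function(x, ...) {
  cat(sprintf("<landmark_model> CART on %d lumens (%s)\n", x$meta$n,
              paste(names(x$meta$class_counts), x$meta$class_counts,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# Degenerate landmark model for single-class training sets (e.g. a
# phantom layout with no central veins): predicts its one class always.
constant_landmark_model <- function(class, n = 0) {
  structure(list(
    tree = NULL, classes = class,
    meta = list(n = n, class_counts = table(rep(class, max(n, 1))),
                max_depth = 0, seed = NA_integer_)
  ), class = "landmark_model")
}

#' Predict lumen classes with a trained landmark model
#'
#' @param model A `landmark_model`.
#' @param lumens Tibble from [detect_lumens()] (or a feature tibble).
#' @return Character vector of predicted classes.
#' @export
predict_landmarks <- function(model, lumens) {
  stopifnot(inherits(model, "landmark_model"))
  df <- dplyr::select(tibble::as_tibble(lumens),
                      -dplyr::any_of(c("lumen_id", "class")))
  if (is.null(model$tree)) {
    return(rep(model$classes[1], nrow(df)))
  }
  as.character(predict(model$tree, newdata = df, type = "class"))
}

#' Build the five-region lobular zone map
#'
#' Partitions the tissue mask into the regions `portal`, `periportal`,
#' `zone2`, `pericentral` and `central_vein`, with lumen interiors
#' labelled `lumen` and non-tissue pixels `background`. The portal
#' region is the collagen collar around portal lumens together with any
#' collagen component contiguous with it (portal stroma); the central
#' vein region is built the same way (a component touching both is
#' assigned portal). Bands extend by geodesic distance inside tissue:
#' a pixel within both bands goes to the nearer landmark region, exact
#' ties to periportal. With no classified landmark the whole parenchyma
#' is zone2.
#'
#' @param tissue Tissue mask from [segment_tissue()].
#' @param lumens Lumen tibble from [detect_lumens()] (needs the
#'   `label_image` attribute).
#' @param classes Character vector of lumen classes aligned with
#'   `lumens` rows (from [predict_landmarks()] or ground truth).
#' @param collagen Optional collagen mask; when supplied, collagen
#'   components contiguous with a landmark collar join that landmark's
#'   region.
#' @param periportal_band_um,pericentral_band_um Band widths in um
#'   (defaults 100).
#' @param collar_width_um Collar ring width around lumens (default 6).
#' @return Integer zone map (class `fq_zone_map`) with attributes
#'   `legend` (name -> code) and `bands_um`.
#' @export
build_zone_map <- function(tissue, lumens, classes, collagen = NULL,
                           periportal_band_um = 100,
                           pericentral_band_um = 100,
                           collar_width_um = 6) {
  lab <- attr(lumens, "label_image")
  pitch <- attr(tissue, "pixel_pitch_um")
  stopifnot(!is.null(lab), !is.null(pitch), nrow(lumens) == length(classes))
  nr <- nrow(tissue); nc <- ncol(tissue)
  tis <- unclass(tissue)
  lumen_mask <- lab > 0

  collar_of <- function(which_ids) {
    if (length(which_ids) == 0) return(matrix(FALSE, nr, nc))
    sel <- matrix(lab %in% which_ids, nr, nc)
    cpp_dilate_disc(sel, collar_width_um / pitch) & !lumen_mask
  }
  p_ids <- lumens$lumen_id[classes == "portal_tract"]
  c_ids <- lumens$lumen_id[classes == "central_vein"]
  p_region <- collar_of(p_ids)
  c_region <- collar_of(c_ids)

  if (!is.null(collagen) && (any(p_region) || any(c_region))) {
    cm <- unclass(collagen)
    cl <- cpp_label_components(cm, 8L)
    if (any(cl > 0)) {
      p_touch <- unique(cl[p_region & cm])
      c_touch <- unique(cl[c_region & cm])
      p_touch <- p_touch[p_touch > 0]
      c_touch <- setdiff(c_touch[c_touch > 0], p_touch) # portal priority
      if (length(p_touch)) p_region <- p_region | matrix(cl %in% p_touch, nr, nc)
      if (length(c_touch)) c_region <- c_region | matrix(cl %in% c_touch, nr, nc)
    }
  }
  c_region <- c_region & !p_region

  zone <- matrix(ZONE_CODES[["background"]], nr, nc)
  zone[tis] <- ZONE_CODES[["zone2"]]
  if (!any(p_region) && !any(c_region)) {
    message("no classified landmarks: whole parenchyma labelled zone2")
  } else {
    domain <- tis | lumen_mask | p_region | c_region
    dist_p <- if (any(p_region)) {
      cpp_geodesic_distance(domain, p_region) * pitch
    } else matrix(Inf, nr, nc)
    dist_c <- if (any(c_region)) {
      cpp_geodesic_distance(domain, c_region) * pitch
    } else matrix(Inf, nr, nc)
    in_pp <- dist_p <= periportal_band_um
    in_pc <- dist_c <= pericentral_band_um
    both <- in_pp & in_pc
    zone[tis & in_pp] <- ZONE_CODES[["periportal"]]
    zone[tis & in_pc & !in_pp] <- ZONE_CODES[["pericentral"]]
    sel <- tis & both
    zone[sel] <- ifelse(dist_p[sel] <= dist_c[sel],
                        ZONE_CODES[["periportal"]],
                        ZONE_CODES[["pericentral"]])
    zone[p_region & tis] <- ZONE_CODES[["portal"]]
    zone[c_region & tis] <- ZONE_CODES[["central_vein"]]
  }
  zone[lumen_mask] <- ZONE_CODES[["lumen"]]
  structure(zone,
    legend = ZONE_CODES,
    bands_um = c(periportal = periportal_band_um,
                 pericentral = pericentral_band_um),
    pixel_pitch_um = pitch,
    class = c("fq_zone_map", "matrix", "array")
  )
}

#' @export
print.fq_zone_map <- function(x, ...) {
  tab <- table(factor(zone_name(as.vector(x)),
                      levels = names(ZONE_CODES)))
  cat("<fq_zone_map>", nrow(x), "x", ncol(x), "px\n")
  print(tab)
  invisible(x)
}

#' Flag chicken-wire (perisinusoidal) collagen strings
#'
#' A string is flagged chicken-wire when it lies in zone 2 or the
#' pericentral band, is thin (`width_um < thick_um`), and is detached
#' from landmark-associated collagen: its minimum geodesic distance to
#' the portal / central-vein regions exceeds `attach_dist_um`.
#'
#' @param strings String tibble from [extract_strings()] (needs the
#'   `label_image` attribute).
#' @param zone_map Zone map from [build_zone_map()].
#' @param attach_dist_um Attachment distance in um (default 10).
#' @param thick_um Width threshold in um (default 3).
#' @return `strings` with a logical `is_chickenwire` column.
#' @export
assign_chickenwire <- function(strings, zone_map, attach_dist_um = 10,
                               thick_um = 3) {
  lab <- attr(strings, "label_image")
  pitch <- attr(zone_map, "pixel_pitch_um")
  stopifnot(!is.null(lab), !is.null(pitch))
  if (nrow(strings) == 0) {
    strings$is_chickenwire <- logical(0)
    return(strings)
  }
  anchored <- matrix(
    zone_map %in% ZONE_CODES[c("portal", "central_vein")],
    nrow(zone_map), ncol(zone_map)
  )
  if (any(anchored)) {
    domain <- matrix(zone_map != ZONE_CODES[["background"]],
                     nrow(zone_map), ncol(zone_map))
    dd <- cpp_geodesic_distance(domain, anchored) * pitch
    mind <- vapply(strings$string_id, function(id) {
      v <- dd[lab == id]
      if (length(v) == 0) Inf else min(v)
    }, numeric(1))
  } else {
    mind <- rep(Inf, nrow(strings))
  }
  strings$is_chickenwire <- strings$region %in% c("zone2", "pericentral") &
    mind > attach_dist_um & strings$width_um < thick_um
  strings
}
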