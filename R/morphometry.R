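# Table-style region suffixes used in q-FP names.
QFP_REGIONS <- c(
  portal = "PT", periportal = "PeriPortal", chickenwire = "ChickenWire",
  zone2 = "Zone2", central_vein = "CV", pericentral = "PeriCentral"
)

#' Decompose a collagen mask into strings
#'
#' One string per 8-connected collagen component. Length is the arc
#' length of the component's morphological skeleton (orthogonal steps 1,
#' diagonal steps sqrt(2), times the pixel pitch); width is the ribbon
#' estimate `area / length`. A component whose ribbon width would exceed
#' its length is a blob, not a ribbon: it is re-parameterised as
#' `length = width = sqrt(area)` and flagged. Each string is assigned
#' the zone holding the majority of its pixels (ties resolved in the
#' order periportal > portal > pericentral > zone2 > central_vein).
#'
#' @param collagen Collagen mask from [segment_collagen()].
#' @param zone_map Zone map from [build_zone_map()] (or phantom ground
#'   truth with the same legend).
#' @return Tibble with `string_id`, `region`, `n_px`, `area_um2`,
#'   `length_um`, `width_um`, `is_blob`; the component label image is in
#'   attribute `label_image`.
#' @export
extract_strings <- function(collagen, zone_map) {
  pitch <- attr(collagen, "pixel_pitch_um")
  if (is.null(pitch)) pitch <- attr(zone_map, "pixel_pitch_um")
  stopifnot(!is.null(pitch), all(dim(collagen) == dim(zone_map)))
  cm <- unclass(collagen)
  lab <- cpp_label_components(cm, 8L)
  k <- max(lab)
  empty <- tibble::tibble(
    string_id = integer(), region = character(), n_px = integer(),
    area_um2 = numeric(), length_um = numeric(), width_um = numeric(),
    is_blob = logical()
  )
  if (k == 0) {
    attr(empty, "label_image") <- lab
    attr(empty, "pixel_pitch_um") <- pitch
    return(empty)
  }
  skel <- cpp_skeletonize(cm)
  len_px <- cpp_skeleton_lengths(skel, lab, k)
  n_px <- tabulate(lab[lab > 0], nbins = k)
  area <- n_px * pitch^2
  length_um <- pmax(len_px, 1) * pitch
  width_um <- area / length_um
  # ribbon model breaks when "width" exceeds "length": treat as blob
  is_blob <- width_um > length_um
  length_um[is_blob] <- sqrt(area[is_blob])
  width_um[is_blob] <- sqrt(area[is_blob])

  # majority zone per component with fixed tie priority
  priority <- c("periportal", "portal", "pericentral", "zone2",
                "central_vein", "lumen", "background")
  region <- character(k)
  zl <- as.vector(zone_map)
  ll <- as.vector(lab)
  nz <- ll > 0
  tab <- table(ll[nz], zl[nz])
  zn <- zone_name(as.integer(colnames(tab)))
  for (i in seq_len(k)) {
    counts <- tab[as.character(i), ]
    best <- zn[counts == max(counts)]
    region[i] <- priority[min(match(best, priority))]
  }
  out <- tibble::tibble(
    string_id = seq_len(k), region = region, n_px = n_px,
    area_um2 = area, length_um = length_um, width_um = width_um,
    is_blob = is_blob
  )
  attr(out, "label_image") <- lab
  attr(out, "pixel_pitch_um") <- pitch
  out
}

#' Classify strings as thick/thin and long/short
#'
#' Thresholds are closed lower bounds: `is_thick` iff
#' `width_um >= thick_um`, `is_long` iff `length_um >= long_um`, so the
#' thin/thick and short/long pairs partition the strings exactly.
#'
#' @param strings Tibble from [extract_strings()].
#' @param thick_um Width threshold in um (default 3).
#' @param long_um Length threshold in um (default 40).
#' @return `strings` with logical `is_thick` and `is_long` columns.
#' @export
classify_strings <- function(strings, thick_um = 3, long_um = 40) {
  stopifnot(thick_um > 0, long_um > 0)
  strings$is_thick <- strings$width_um >= thick_um
  strings$is_long <- strings$length_um >= long_um
  attr(strings, "thresholds") <- c(thick_um = thick_um, long_um = long_um)
  strings
}

#' Classify strings as aggregated or distributed
#'
#' Morphological closing of the collagen mask at `close_radius_um` fuses
#' nearby strings into clusters; a string is aggregated iff the total
#' collagen area of its cluster reaches `agg_area_um2`.
#'
#' @param strings Tibble from [extract_strings()].
#' @param collagen The collagen mask the strings came from.
#' @param close_radius_um Closing radius in um (default 5).
#' @param agg_area_um2 Minimum cluster collagen area in um^2 (default
#'   200).
#' @return `strings` with a logical `is_aggregated` column.
#' @export
classify_aggregation <- function(strings, collagen, close_radius_um = 5,
                                 agg_area_um2 = 200) {
  stopifnot(close_radius_um > 0, agg_area_um2 > 0)
  if (nrow(strings) == 0) {
    strings$is_aggregated <- logical(0)
    return(strings)
  }
  pitch <- attr(strings, "pixel_pitch_um")
  lab <- attr(strings, "label_image")
  cm <- unclass(collagen)
  r_px <- close_radius_um / pitch
  closed <- cpp_erode_disc(cpp_dilate_disc(cm, r_px), r_px) | cm
  clu <- cpp_label_components(closed, 8L)
  # cluster id per string (strings are subsets of the closed mask)
  string_cluster <- vapply(strings$string_id, function(id) {
    v <- clu[lab == id]
    v[v > 0][1]
  }, numeric(1))
  # collagen area per cluster
  clu_area <- tapply(strings$area_um2, string_cluster, sum)
  strings$is_aggregated <-
    as.numeric(clu_area[as.character(string_cluster)]) >= agg_area_um2
  attr(strings, "aggregation") <- c(close_radius_um = close_radius_um,
                                    agg_area_um2 = agg_area_um2)
  strings
}

#' Compute the named quantitative fibrosis parameter (q-FP) table
#'
#' Emits the per-specimen q-FP vector over the naming grid
#' `<metric><region>` with metrics `#Str`, `#ShortStr`, `#LongStr`,
#' `#ThinStr`, `#ThickStr`, `StrArea`, `StrLength`, `StrWidth` and
#' percentage metrics, and regions overall (empty suffix), `PT`,
#' `PeriPortal`, `ChickenWire`, `Zone2`, `CV`, `PeriCentral`.
#' `%SHG` is total collagen area over tissue area; `%<R>` is the
#' region's collagen fraction, split additively into `%<R>Agg` and
#' `%<R>Dis`. `StrLength`/`StrWidth` are means over the region's strings
#' (0 when the region is empty; see the `region_present` attribute).
#' Counts are also emitted as densities per mm^2 of region tissue
#' (suffix `Dens`). ChickenWire is an overlay: flagged strings remain
#' counted in their zone, and its tissue denominator is the zone2 +
#' pericentral area.
#'
#' @param strings Tibble from [extract_strings()] after
#'   [classify_strings()], [classify_aggregation()] and
#'   [assign_chickenwire()].
#' @param zone_map Zone map from [build_zone_map()].
#' @return One-row tibble of named q-FPs, with attributes
#'   `region_present`, `thresholds`, `bands_um`.
#' @export
compute_qfp_table <- function(strings, zone_map) {
  pitch <- attr(zone_map, "pixel_pitch_um")
  stopifnot(!is.null(pitch))
  need <- c("is_thick", "is_long", "is_aggregated", "is_chickenwire")
  missing_f <- setdiff(need, names(strings))
  if (length(missing_f) > 0) {
    stop("strings lack flags: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  px_area <- pitch^2
  zcounts <- tabulate(as.vector(zone_map) + 1L, nbins = 7L)
  names(zcounts) <- names(ZONE_CODES)[order(ZONE_CODES)]
  tissue_area <- sum(zcounts[c("portal", "periportal", "zone2",
                               "pericentral", "central_vein")]) * px_area
  if (tissue_area <= 0) stop("zone map has no tissue", call. = FALSE)
  region_area <- function(region) {
    if (region == "chickenwire") {
      sum(zcounts[c("zone2", "pericentral")]) * px_area
    } else if (region == "overall") {
      tissue_area
    } else {
      zcounts[[region]] * px_area
    }
  }
  sel_region <- function(region) {
    if (region == "overall") rep(TRUE, nrow(strings))
    else if (region == "chickenwire") strings$is_chickenwire
    else strings$region == region
  }
  vals <- list()
  present <- logical(0)
  for (region in c("overall", names(QFP_REGIONS))) {
    suffix <- if (region == "overall") "" else QFP_REGIONS[[region]]
    s <- strings[sel_region(region), , drop = FALSE]
    ra <- region_area(region)
    present[region] <- ra > 0
    n <- nrow(s)
    area_sum <- sum(s$area_um2)
    agg_area <- sum(s$area_um2[s$is_aggregated])
    pct <- function(x) if (ra > 0) 100 * x / ra else 0
    vals[[paste0("#Str", suffix)]] <- n
    vals[[paste0("#ShortStr", suffix)]] <- sum(!s$is_long)
    vals[[paste0("#LongStr", suffix)]] <- sum(s$is_long)
    vals[[paste0("#ThinStr", suffix)]] <- sum(!s$is_thick)
    vals[[paste0("#ThickStr", suffix)]] <- sum(s$is_thick)
    vals[[paste0("StrArea", suffix)]] <- area_sum
    vals[[paste0("StrLength", suffix)]] <- if (n > 0) mean(s$length_um) else 0
    vals[[paste0("StrWidth", suffix)]] <- if (n > 0) mean(s$width_um) else 0
    pct_name <- if (region == "overall") "%Area" else paste0("%", suffix)
    vals[[pct_name]] <- pct(area_sum)
    vals[[paste0("%", suffix, "Agg")]] <- pct(agg_area)
    vals[[paste0("%", suffix, "Dis")]] <- pct(area_sum - agg_area)
    # count densities per mm^2 of region tissue
    per_mm2 <- function(x) if (ra > 0) x / (ra / 1e6) else 0
    for (cn in c("#Str", "#ShortStr", "#LongStr", "#ThinStr", "#ThickStr")) {
      vals[[paste0(cn, suffix, "Dens")]] <- per_mm2(vals[[paste0(cn, suffix)]])
    }
  }
  vals[["%SHG"]] <- 100 * sum(strings$area_um2) / tissue_area
  out <- tibble::as_tibble(vals, .name_repair = "minimal")
  attr(out, "region_present") <- present
  attr(out, "thresholds") <- c(attr(strings, "thresholds"),
                               attr(strings, "aggregation"))
  attr(out, "bands_um") <- attr(zone_map, "bands_um")
  out
}
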