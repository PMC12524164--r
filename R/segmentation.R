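#' Otsu threshold from a 256-bin intensity histogram
#'
#' Exhaustively scans all 255 candidate splits of a 256-bin histogram and
#' returns the boundary maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`. When several splits tie (e.g. an empty
#' valley between two modes), the mean of the tied boundaries is
#' returned, so a symmetric histogram yields a central threshold.
#'
#' @param counts Integer vector of 256 bin counts (bins 0..255).
#' @return Threshold on the bin scale: pixels with bin index `>=` the
#'   returned value are foreground. Divide by 256 for the \[0, 1\]
#'   intensity scale.
#' @examples
#' counts <- numeric(256)
#' counts[c(51, 201)] <- 100 # delta peaks at bins 50 and 200
#' otsu_threshold(counts)
#' @export
otsu_threshold <- function(counts) {
  if (length(counts) != 256 || any(counts < 0)) {
    stop("counts must be 256 non-negative bin counts", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) stop("empty histogram", call. = FALSE)
  if (sum(counts > 0) < 2) {
    stop("degenerate histogram: all mass in one bin", call. = FALSE)
  }
  bins <- 0:255
  w0 <- cumsum(counts)[1:255]
  w1 <- total - w0
  m0 <- cumsum(counts * bins)[1:255]
  mu_tot <- sum(counts * bins)
  mu0 <- ifelse(w0 > 0, m0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (mu_tot - m0) / w1, 0)
  score <- (w0 / total) * (w1 / total) * (mu0 - mu1)^2
  # candidate t splits bins 0..t-1 | t..255
  best <- which(score >= max(score) - 1e-12)
  mean(best)
}

# Histogram a [0,1] intensity vector into 256 bins.
intensity_histogram <- function(x) {
  b <- pmin(floor(x * 256), 255)
  tabulate(b + 1L, nbins = 256L)
}

# Otsu-binarize an intensity matrix, optionally restricted to a mask.
# Returns all-FALSE when the restricted histogram is degenerate (a
# constant channel carries no separable signal).
otsu_binarize <- function(mat, within = NULL) {
  vals <- if (is.null(within)) as.vector(mat) else mat[within]
  h <- intensity_histogram(vals)
  if (sum(h > 0) < 2) {
    return(matrix(FALSE, nrow(mat), ncol(mat)))
  }
  thr <- otsu_threshold(h)
  mask <- matrix(pmin(floor(mat * 256), 255) >= thr, nrow(mat), ncol(mat))
  if (!is.null(within)) mask <- mask & within
  mask
}

new_fq_mask <- function(mask, pixel_pitch_um, provenance) {
  structure(mask,
    pixel_pitch_um = pixel_pitch_um,
    provenance = provenance,
    class = c("fq_mask", "matrix", "array")
  )
}

#' @export
print.fq_mask <- function(x, ...) {
  cat(sprintf(
    "<fq_mask> %d x %d px, %d foreground px (%.1f%%)\n  steps: %s\n",
    nrow(x), ncol(x), sum(x), 100 * mean(x),
    paste(attr(x, "provenance"), collapse = " -> ")
  ))
  invisible(x)
}

#' Segment liver tissue from the TPEF channel
#'
#' Otsu-thresholds the TPEF (autofluorescence) channel and discards
#' connected components whose physical area does not exceed
#' `min_tissue_area_mm2`, removing small debris and noise. The retained
#' mask may be empty.
#'
#' @param img A [multiphoton_image()].
#' @param min_tissue_area_mm2 Components with area strictly greater than
#'   this (in mm^2) are kept; default 0.1.
#' @param connectivity Pixel connectivity for tissue components (4 or 8);
#'   default 4 (tissue is bulky, diagonal-only links are noise).
#' @return Logical tissue mask (`fq_mask`) with a `provenance` attribute.
#' @export
segment_tissue <- function(img, min_tissue_area_mm2 = 0.1, connectivity = 4) {
  stopifnot(inherits(img, "multiphoton_image"))
  raw <- otsu_binarize(img$tpef)
  lab <- cpp_label_components(raw, as.integer(connectivity))
  keep_mask <- raw
  if (any(raw)) {
    px_area <- pixel_area_um2(img)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes * px_area > min_tissue_area_mm2 * 1e6)
    keep_mask <- matrix(lab %in% keep, nrow(raw), ncol(raw))
  }
  new_fq_mask(
    keep_mask, img$pixel_pitch_um,
    c("otsu_tpef", sprintf(
      "drop_components_area_le_%.3fmm2_conn%d",
      min_tissue_area_mm2, connectivity
    ))
  )
}

#' Segment collagen from the SHG channel within tissue
#'
#' Otsu-thresholds the SHG channel restricted to the tissue mask, removes
#' noise components with physical area below `min_string_um2`, then fills
#' internal gaps of at most `fill_hole_px` pixels.
#'
#' @param img A [multiphoton_image()].
#' @param tissue Tissue mask from [segment_tissue()].
#' @param min_string_um2 Components strictly smaller than this (um^2) are
#'   removed as noise; default 15.
#' @param fill_hole_px Enclosed background holes up to this many pixels
#'   are filled; default 2.
#' @param connectivity Pixel connectivity for collagen components (4 or
#'   8); default 8 (thin fibres connect diagonally).
#' @return Logical collagen mask (`fq_mask`), a subset of `tissue`.
#' @export
segment_collagen <- function(img, tissue, min_string_um2 = 15,
                             fill_hole_px = 2, connectivity = 8) {
  stopifnot(inherits(img, "multiphoton_image"))
  if (!any(tissue)) stop("tissue mask is empty", call. = FALSE)
  raw <- otsu_binarize(img$shg, within = tissue)
  px_area <- pixel_area_um2(img)
  if (any(raw)) {
    lab <- cpp_label_components(raw, as.integer(connectivity))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes * px_area >= min_string_um2)
    raw <- matrix(lab %in% keep, nrow(raw), ncol(raw))
    if (any(raw) && fill_hole_px > 0) {
      raw <- cpp_fill_holes(raw, as.integer(fill_hole_px)) &
        unclass(tissue)
    }
  }
  new_fq_mask(
    raw, img$pixel_pitch_um,
    c("otsu_shg_within_tissue",
      sprintf("remove_components_lt_%.1fum2_conn%d", min_string_um2,
              connectivity),
      sprintf("fill_holes_le_%dpx", fill_hole_px))
  )
}

#' Detect luminal structures (vessels, ducts, fissures) inside tissue
#'
#' Enclosed background holes in the tissue mask with physical area of at
#' least `min_lumen_um2` become lumen objects; smaller holes (sinusoid
#' scale) are ignored. Per-lumen shape and context features support the
#' downstream portal-tract / central-vein classification.
#'
#' Features: physical area; centroid (0-based row/col); eccentricity of
#' the pixel scatter (0 = disc); `collar_fraction`, the proportion of a
#' morphological ring of width `collar_width_um` around the lumen that is
#' collagen (portal tracts carry a collagenous sheath, central veins far
#' less); `boundary_smoothness`, the isoperimetric circularity
#' `4 * pi * area / perimeter^2`; and `neighbor_lumen_count`, the number
#' of other lumens whose centroid lies within `neighbor_radius_um`.
#'
#' @param tissue Tissue mask from [segment_tissue()].
#' @param collagen Collagen mask (may be `NULL`: collar fractions are 0).
#' @param min_lumen_um2 Minimum hole area in um^2 (default 100).
#' @param collar_width_um Width of the collagen collar ring (default 6).
#' @param neighbor_radius_um Radius for the neighbour count (default 100).
#' @return A tibble with one row per lumen, ordered by centroid
#'   (row, then col), with the lumen label image in attribute
#'   `label_image` (labels match `lumen_id`).
#' @export
detect_lumens <- function(tissue, collagen = NULL, min_lumen_um2 = 100,
                          collar_width_um = 6, neighbor_radius_um = 100) {
  if (!any(tissue)) stop("tissue mask is empty", call. = FALSE)
  pitch <- attr(tissue, "pixel_pitch_um")
  stopifnot(!is.null(pitch))
  px_area <- pitch^2
  holes <- cpp_label_components(!unclass(tissue), 8L)
  nr <- nrow(tissue); nc <- ncol(tissue)
  ids <- sort(unique(holes[holes > 0]))
  rows <- list()
  lab_out <- matrix(0L, nr, nc)
  next_id <- 0L
  for (id in ids) {
    sel <- holes == id
    idx <- which(sel, arr.ind = TRUE)
    if (any(idx[, 1] == 1 | idx[, 1] == nr | idx[, 2] == 1 | idx[, 2] == nc)) {
      next # touches border: not an enclosed lumen
    }
    area <- nrow(idx) * px_area
    if (area < min_lumen_um2) next
    r <- idx[, 1] - 1; c <- idx[, 2] - 1 # 0-based
    cr <- mean(r); cc <- mean(c)
    # eccentricity from the 2x2 covariance of pixel coordinates
    if (nrow(idx) > 1) {
      cv <- stats::cov(cbind(r, c))
      ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
      ecc <- if (ev[1] > 0) sqrt(max(0, 1 - ev[2] / ev[1])) else 0
    } else {
      ecc <- 0
    }
    # perimeter: pixels of the hole with a 4-neighbour outside the hole
    on_edge <- sel & !(rbind(sel[-1, ], FALSE) & rbind(FALSE, sel[-nr, ]) &
                       cbind(sel[, -1], FALSE) & cbind(FALSE, sel[, -nc]))
    perim <- sum(on_edge)
    smooth <- 4 * pi * nrow(idx) / max(perim, 1)^2
    # collagen collar
    ring <- cpp_dilate_disc(sel, collar_width_um / pitch) & !sel
    collar <- if (!is.null(collagen) && any(ring)) {
      sum(unclass(collagen)[ring]) / sum(ring)
    } else 0
    next_id <- next_id + 1L
    lab_out[sel] <- next_id # provisional; relabeled below
    rows[[length(rows) + 1]] <- tibble::tibble(
      area_um2 = area, centroid_row = cr, centroid_col = cc,
      eccentricity = ecc, collar_fraction = collar,
      boundary_smoothness = smooth, .tmp = next_id
    )
  }
  if (length(rows) == 0) {
    out <- tibble::tibble(
      lumen_id = integer(), area_um2 = numeric(), centroid_row = numeric(),
      centroid_col = numeric(), eccentricity = numeric(),
      collar_fraction = numeric(), boundary_smoothness = numeric(),
      neighbor_lumen_count = integer()
    )
    attr(out, "label_image") <- lab_out
    attr(out, "pixel_pitch_um") <- pitch
    return(out)
  }
  out <- dplyr::bind_rows(rows)
  ord <- order(out$centroid_row, out$centroid_col)
  out <- out[ord, ]
  relab <- match(seq_len(next_id), out$.tmp)
  lab_final <- matrix(0L, nr, nc)
  nz <- lab_out > 0
  lab_final[nz] <- relab[lab_out[nz]]
  out$lumen_id <- seq_len(nrow(out))
  # neighbour counts on final ordering
  d <- as.matrix(stats::dist(cbind(out$centroid_row, out$centroid_col))) *
    pitch
  out$neighbor_lumen_count <- as.integer(rowSums(d <= neighbor_radius_um) - 1)
  out <- dplyr::select(
    out, "lumen_id", "area_um2", "centroid_row", "centroid_col",
    "eccentricity", "collar_fraction", "boundary_smoothness",
    "neighbor_lumen_count"
  )
  attr(out, "label_image") <- lab_final
  attr(out, "pixel_pitch_um") <- pitch
  out
}
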