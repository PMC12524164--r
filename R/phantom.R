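# Zone label codes shared by the phantom ground truth and build_zone_map().
ZONE_CODES <- c(
  background = 0L, lumen = 1L, portal = 2L, periportal = 3L,
  zone2 = 4L, pericentral = 5L, central_vein = 6L
)

zone_name <- function(code) names(ZONE_CODES)[match(code, ZONE_CODES)]

# Evaluate code with a private RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stage-conditional collagen presets: planted density per zone (fraction
# of zone tissue area) and string geometry. Periportal strings lengthen
# and thicken with stage; fine perisinusoidal (chicken-wire) collagen
# appears from F1-F2; bridging septa from F3.
stage_presets <- function(stage) {
  stopifnot(stage %in% 0:4)
  density <- rbind(
    c(periportal = 0.02, zone2 = 0.000, pericentral = 0.005),
    c(periportal = 0.07, zone2 = 0.008, pericentral = 0.015),
    c(periportal = 0.13, zone2 = 0.020, pericentral = 0.035),
    c(periportal = 0.20, zone2 = 0.030, pericentral = 0.060),
    c(periportal = 0.28, zone2 = 0.045, pericentral = 0.095)
  )[stage + 1, ]
  list(
    collagen_density_by_region = as.list(density),
    string_length_um = 18 + 8 * stage,
    string_width_um = 1.6 + 0.55 * stage,
    portal_collar_um = 2.5 + 2.0 * stage,
    bridging = stage >= 3,
    n_bridges = c(0, 0, 0, 2, 4)[stage + 1]
  )
}

#' Specification for a synthetic two-channel tissue phantom
#'
#' Describes a stage-conditional liver lobule phantom: dark luminal
#' landmarks (portal tracts with a collagen collar whose thickness grows
#' with stage, and thin-walled central veins) embedded in autofluorescent
#' parenchyma, with collagen strings planted per zone at stage-dependent
#' density and geometry, and bridging septa from F3.
#'
#' @param stage Fibrosis stage, integer 0-4. Sets defaults for densities,
#'   string geometry, collar thickness and bridging.
#' @param canvas_px Square canvas side in pixels (default 1024; at the
#'   default pitch this is a 400 x 400 um mosaic = 0.16 mm^2, so the
#'   standard tissue-area filter is exercisable).
#' @param pixel_pitch_um Micrometres per pixel (default 0.390625).
#' @param n_portal_tracts,n_central_veins Landmark counts (defaults 2, 2).
#' @param collagen_density_by_region Named list with entries `periportal`,
#'   `zone2`, `pericentral` in \[0, 1\]; `NULL` uses the stage preset.
#' @param bridging Plant portal-central septa? `NULL` = stage preset.
#' @param periportal_band_um,pericentral_band_um Zone band widths used to
#'   build the ground-truth zone map (defaults 100).
#' @param planted_strings Optional data frame (`region`, `length_um`,
#'   `width_um`) of strings to plant verbatim (axis-aligned, fully inside
#'   their region) in addition to the density-driven fill.
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   phantom.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(stage, canvas_px = 1024, pixel_pitch_um = 0.390625,
                         n_portal_tracts = 2, n_central_veins = 2,
                         collagen_density_by_region = NULL, bridging = NULL,
                         periportal_band_um = 100, pericentral_band_um = 100,
                         planted_strings = NULL, seed = 1L) {
  stopifnot(
    stage %in% 0:4, canvas_px >= 64, pixel_pitch_um > 0,
    n_portal_tracts >= 0, n_central_veins >= 0,
    n_portal_tracts + n_central_veins >= 1
  )
  preset <- stage_presets(stage)
  if (is.null(collagen_density_by_region)) {
    collagen_density_by_region <- preset$collagen_density_by_region
  }
  stopifnot(all(unlist(collagen_density_by_region) >= 0),
            all(unlist(collagen_density_by_region) <= 1))
  if (is.null(bridging)) bridging <- preset$bridging
  structure(list(
    stage = as.integer(stage), canvas_px = as.integer(canvas_px),
    pixel_pitch_um = pixel_pitch_um,
    n_portal_tracts = as.integer(n_portal_tracts),
    n_central_veins = as.integer(n_central_veins),
    collagen_density_by_region = collagen_density_by_region,
    bridging = isTRUE(bridging),
    n_bridges = if (isTRUE(bridging)) max(preset$n_bridges, 2L) else 0L,
    string_length_um = preset$string_length_um,
    string_width_um = preset$string_width_um,
    portal_collar_um = preset$portal_collar_um,
    central_collar_um = 1.2 + 0.6 * stage,
    periportal_band_um = periportal_band_um,
    pericentral_band_um = pericentral_band_um,
    planted_strings = planted_strings,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Rasterize an ellipse: logical matrix of pixels whose center lies inside.
raster_ellipse <- function(nr, nc, cr, cc, a_px, b_px, theta) {
  rr <- matrix(seq_len(nr) - 1, nr, nc) - cr
  cc_ <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc) - cc
  u <- cos(theta) * rr + sin(theta) * cc_
  v <- -sin(theta) * rr + cos(theta) * cc_
  (u / a_px)^2 + (v / b_px)^2 <= 1
}

# Rasterize a rotated rectangle (capsule-free, sharp ends) centred at
# (cr, cc) with half-length hl and half-width hw in pixels.
raster_rect <- function(nr, nc, cr, cc, hl, hw, theta) {
  ext <- ceiling(hl + hw + 2)
  r0 <- max(1, floor(cr - ext)); r1 <- min(nr, ceiling(cr + ext))
  c0 <- max(1, floor(cc - ext)); c1 <- min(nc, ceiling(cc + ext))
  if (r0 > r1 || c0 > c1) return(NULL)
  rs <- r0:r1; cs <- c0:c1
  rr <- matrix(rs - 1, length(rs), length(cs)) - cr
  cc_ <- matrix(rep(cs - 1, each = length(rs)), length(rs), length(cs)) - cc
  u <- cos(theta) * rr + sin(theta) * cc_
  v <- -sin(theta) * rr + cos(theta) * cc_
  inside <- abs(u) <= hl & abs(v) <= hw
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  cbind(idx[, 1] + r0 - 1, idx[, 2] + c0 - 1)
}

#' Generate a synthetic SHG/TPEF tissue phantom with exact ground truth
#'
#' Builds the two-channel image described by a [phantom_spec()]:
#' landmarks are laid out on a jittered checkerboard grid (portal tracts
#' and central veins interleaved), the five-region zone map is derived by
#' geodesic banding around the landmarks, and collagen strings are
#' planted zone by zone until each requested density is reached. The TPEF
#' channel shows bright parenchyma with dark lumens; the SHG channel
#' shows planted collagen over low Gaussian background noise, Otsu
#' separable by construction.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements
#'   * `image`: a [multiphoton_image()];
#'   * `truth`: list with `zone_map` (integer matrix, codes in
#'     `attr(, "legend")`), `collagen_mask`, `lumen_table` (one row per
#'     lumen with its true class), `string_inventory` (one row per
#'     planted string: region, nominal length/width, realised pixel
#'     area), and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$canvas_px
  pitch <- spec$pixel_pitch_um
  px_area <- pitch^2
  k <- spec$n_portal_tracts + spec$n_central_veins
  g <- ceiling(sqrt(k))
  cell_um <- n * pitch / g
  if (cell_um < 70) {
    stop(sprintf(
      "canvas too small: %d landmarks need grid cells >= 70 um, got %.1f um",
      k, cell_um
    ), call. = FALSE)
  }
  with_seed(spec$seed, {
    # --- landmark layout: checkerboard interleave of portals/centrals ---
    cells <- expand.grid(gr = seq_len(g), gc = seq_len(g))
    cells$parity <- (cells$gr + cells$gc) %% 2
    cells <- cells[order(cells$parity, cells$gr, cells$gc), ]
    cell_px <- n / g
    types <- c(rep("portal_tract", spec$n_portal_tracts),
               rep("central_vein", spec$n_central_veins))
    # portals on one parity, centrals on the other, spill over if needed
    ord <- c(which(cells$parity == 0), which(cells$parity == 1))
    slots <- cells[ord[seq_len(k)], ]
    lum_rows <- list()
    lumen_mask <- matrix(FALSE, n, n)
    portal_collar <- matrix(FALSE, n, n)
    central_collar <- matrix(FALSE, n, n)
    portal_seed <- matrix(FALSE, n, n)
    central_seed <- matrix(FALSE, n, n)
    for (i in seq_len(k)) {
      type <- types[i]
      cr <- (slots$gr[i] - 0.5) * cell_px + runif(1, -0.06, 0.06) * cell_px
      cc <- (slots$gc[i] - 0.5) * cell_px + runif(1, -0.06, 0.06) * cell_px
      if (type == "portal_tract") {
        a <- runif(1, 10, 16) / pitch
        b <- a * runif(1, 0.55, 0.8)
      } else {
        a <- runif(1, 14, 20) / pitch
        b <- a * runif(1, 0.85, 1.0)
      }
      th <- runif(1, 0, pi)
      lum <- raster_ellipse(n, n, cr, cc, a, b, th)
      collar_w <- if (type == "portal_tract") spec$portal_collar_um else
        spec$central_collar_um
      ring <- cpp_dilate_disc(lum, collar_w / pitch) & !lum
      lumen_mask <- lumen_mask | lum
      if (type == "portal_tract") {
        portal_collar <- portal_collar | ring
        portal_seed <- portal_seed | lum | ring
      } else {
        central_collar <- central_collar | ring
        central_seed <- central_seed | lum | ring
      }
      lum_rows[[i]] <- tibble::tibble(
        class = type, centroid_row = cr, centroid_col = cc,
        area_um2 = sum(lum) * px_area
      )
    }
    lumen_table <- dplyr::bind_rows(lum_rows)
    tissue <- !lumen_mask

    # --- ground-truth zonation by geodesic banding -----------------------
    dist_p <- cpp_geodesic_distance(tissue | portal_seed, portal_seed) * pitch
    dist_c <- cpp_geodesic_distance(tissue | central_seed, central_seed) * pitch
    zone <- matrix(ZONE_CODES[["zone2"]], n, n)
    in_pp <- dist_p <= spec$periportal_band_um
    in_pc <- dist_c <= spec$pericentral_band_um
    both <- in_pp & in_pc
    zone[in_pp] <- ZONE_CODES[["periportal"]]
    zone[in_pc & !in_pp] <- ZONE_CODES[["pericentral"]]
    # overlap: nearer landmark wins, exact tie -> periportal
    zone[both] <- ifelse(dist_p[both] <= dist_c[both],
                         ZONE_CODES[["periportal"]],
                         ZONE_CODES[["pericentral"]])
    zone[portal_collar] <- ZONE_CODES[["portal"]]
    zone[central_collar] <- ZONE_CODES[["central_vein"]]
    zone[lumen_mask] <- ZONE_CODES[["lumen"]]
    attr(zone, "legend") <- ZONE_CODES
    attr(zone, "bands_um") <- c(periportal = spec$periportal_band_um,
                                pericentral = spec$pericentral_band_um)

    # --- collagen: collars + spurs + planted strings ---------------------
    collagen <- portal_collar | central_collar
    inv <- list()
    sid <- 0L
    # parenchymal strings keep a stand-off from the vessel walls (and the
    # bridging septa, below) so free fibrosis does not chain into the
    # portal/central stroma cluster; 8 um clears the collar annulus used
    # by downstream lumen feature extraction
    keepout <- cpp_dilate_disc(portal_seed | central_seed, 8 / pitch)

    # portal spurs: short radial strings attached to the portal collar,
    # their number and calibre growing with stage (fibrous expansion of
    # the tract)
    n_spurs <- 2L * spec$stage
    if (n_spurs > 0 && spec$n_portal_tracts >= 1) {
      pl <- lumen_table[lumen_table$class == "portal_tract", ]
      for (ip in seq_len(nrow(pl))) {
        base_r <- sqrt(pl$area_um2[ip] / pi) / pitch # px
        for (js in seq_len(n_spurs)) {
          a <- runif(1, 0, 2 * pi)
          L <- (6 + 3 * spec$stage) * runif(1, 0.7, 1.3) / pitch
          W <- (1.2 + 0.5 * spec$stage) / pitch
          d0 <- base_r + spec$portal_collar_um / pitch
          ctr_r <- pl$centroid_row[ip] + (d0 + L / 2 - 2) * cos(a)
          ctr_c <- pl$centroid_col[ip] + (d0 + L / 2 - 2) * sin(a)
          px <- raster_rect(n, n, ctr_r, ctr_c, L / 2, W / 2, a)
          if (is.null(px)) next
          px <- px[!lumen_mask[px], , drop = FALSE]
          if (nrow(px) < 3) next
          sid <- sid + 1L
          maj <- zone_name(as.integer(names(which.max(table(zone[px])))))
          inv[[sid]] <- tibble::tibble(
            string_id = sid, region = maj, length_um = L * pitch,
            width_um = W * pitch, area_um2 = nrow(px) * px_area,
            n_px = nrow(px), kind = "spur"
          )
          collagen[px] <- TRUE
        }
      }
    }
    # bridging septa: thick strings linking portal and central landmarks
    bridge_mask <- matrix(FALSE, n, n)
    if (spec$bridging && spec$n_portal_tracts >= 1 &&
        spec$n_central_veins >= 1) {
      pl <- lumen_table[lumen_table$class == "portal_tract", ]
      cl <- lumen_table[lumen_table$class == "central_vein", ]
      pairs <- expand.grid(p = seq_len(nrow(pl)), c = seq_len(nrow(cl)))
      pairs$d <- sqrt((pl$centroid_row[pairs$p] - cl$centroid_row[pairs$c])^2 +
                      (pl$centroid_col[pairs$p] - cl$centroid_col[pairs$c])^2)
      pairs <- pairs[order(pairs$d), ]
      nb <- min(spec$n_bridges, nrow(pairs))
      for (j in seq_len(nb)) {
        p <- pairs$p[j]; cidx <- pairs$c[j]
        mr <- (pl$centroid_row[p] + cl$centroid_row[cidx]) / 2
        mc <- (pl$centroid_col[p] + cl$centroid_col[cidx]) / 2
        th <- atan2(cl$centroid_col[cidx] - pl$centroid_col[p],
                    cl$centroid_row[cidx] - pl$centroid_row[p])
        L <- pairs$d[j] * pitch
        W <- runif(1, 6, 8) + 2 * spec$stage
        px <- raster_rect(n, n, mr, mc, L / 2 / pitch, W / 2 / pitch, th)
        if (is.null(px)) next
        keep <- !lumen_mask[px]
        px <- px[keep, , drop = FALSE]
        sid <- sid + 1L
        maj <- zone_name(as.integer(names(which.max(table(zone[px])))))
        inv[[sid]] <- tibble::tibble(
          string_id = sid, region = maj, length_um = L, width_um = W,
          area_um2 = nrow(px) * px_area, n_px = nrow(px), kind = "bridge"
        )
        collagen[px] <- TRUE
        bridge_mask[px] <- TRUE
      }
      keepout <- keepout | cpp_dilate_disc(bridge_mask, 3)
    }

    plant_region <- function(region_name, target_frac, collagen) {
      code <- ZONE_CODES[[region_name]]
      region_px <- which(zone == code)
      if (length(region_px) == 0 || target_frac <= 0) return(collagen)
      # the target counts collagen added by the parenchymal fill itself,
      # on top of whatever stroma (collars, spurs, septa) already crosses
      # the region
      baseline <- sum(collagen[region_px])
      target <- target_frac * length(region_px)
      guard <- 0
      while (sum(collagen[region_px]) - baseline < target && guard < 4000) {
        guard <- guard + 1
        anchor <- region_px[sample.int(length(region_px), 1)]
        ar <- (anchor - 1) %% n
        ac <- (anchor - 1) %/% n
        L <- max(8, rnorm(1, spec$string_length_um, 0.25 * spec$string_length_um))
        W <- max(0.8, rnorm(1, spec$string_width_um, 0.3))
        if (region_name != "periportal") W <- min(W, 1.8) # fine chicken-wire
        th <- runif(1, 0, pi)
        px <- raster_rect(n, n, ar, ac, L / 2 / pitch, W / 2 / pitch, th)
        if (is.null(px)) next
        # clip to the declared region (and the vessel stand-off) so the
        # ground truth stays exact
        keep <- zone[px] == code & !lumen_mask[px] & !keepout[px]
        px <- px[keep, , drop = FALSE]
        if (nrow(px) < 3) next
        # strings are laid down mostly non-touching (1-px moat) so
        # regional fibrosis stays a population of distinct fibres rather
        # than one percolated cluster; occasional contact is allowed
        if (runif(1) > 0.1) {
          touches <- FALSE
          for (dr2 in -1:1) {
            for (dc2 in -1:1) {
              nb <- cbind(pmin(pmax(px[, 1] + dr2, 1), n),
                          pmin(pmax(px[, 2] + dc2, 1), n))
              if (any(collagen[nb])) { touches <- TRUE; break }
            }
            if (touches) break
          }
          if (touches) next
        }
        sid <<- sid + 1L
        inv[[sid]] <<- tibble::tibble(
          string_id = sid, region = region_name, length_um = L, width_um = W,
          area_um2 = nrow(px) * px_area, n_px = nrow(px), kind = "string"
        )
        collagen[px] <- TRUE
      }
      collagen
    }
    for (rn in c("periportal", "zone2", "pericentral")) {
      dens <- spec$collagen_density_by_region[[rn]]
      if (!is.null(dens)) collagen <- plant_region(rn, dens, collagen)
    }

    # explicit strings: axis-aligned, fully inside their region
    if (!is.null(spec$planted_strings)) {
      ps <- spec$planted_strings
      for (j in seq_len(nrow(ps))) {
        code <- ZONE_CODES[[ps$region[j]]]
        hl <- ps$length_um[j] / 2 / pitch
        hw <- ps$width_um[j] / 2 / pitch
        placed <- FALSE
        cand <- which(zone == code)
        for (try in seq_len(400)) {
          anchor <- sample(cand, 1)
          ar <- (anchor - 1) %% n + runif(1, -0.5, 0.5)
          ac <- (anchor - 1) %/% n + runif(1, -0.5, 0.5)
          # reject anchors whose full extent would leave the canvas
          if (ar - hl < 1 || ar + hl > n - 2 || ac - hw < 1 ||
              ac + hw > n - 2) next
          px <- raster_rect(n, n, ar, ac, hl, hw, 0)
          if (is.null(px)) next
          if (all(zone[px] == code)) {
            sid <- sid + 1L
            inv[[sid]] <- tibble::tibble(
              string_id = sid, region = ps$region[j],
              length_um = ps$length_um[j], width_um = ps$width_um[j],
              area_um2 = nrow(px) * px_area, n_px = nrow(px),
              kind = "planted"
            )
            collagen[px] <- TRUE
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop(sprintf("could not place requested %s string (%.0f x %.1f um)",
                       ps$region[j], ps$length_um[j], ps$width_um[j]),
               call. = FALSE)
        }
      }
    }

    collagen <- collagen & tissue

    inventory <- if (sid > 0) dplyr::bind_rows(inv) else tibble::tibble(
      string_id = integer(), region = character(), length_um = numeric(),
      width_um = numeric(), area_um2 = numeric(), n_px = integer(),
      kind = character()
    )

    # --- render channels --------------------------------------------------
    tpef <- matrix(rnorm(n * n, 0.55, 0.07), n, n)
    tpef[lumen_mask] <- rnorm(sum(lumen_mask), 0.04, 0.012)
    shg <- matrix(abs(rnorm(n * n, 0.05, 0.025)), n, n)
    shg[collagen] <- rnorm(sum(collagen), 0.68, 0.08)
    tpef <- pmin(pmax(tpef, 0), 1)
    shg <- pmin(pmax(shg, 0), 1)

    list(
      image = multiphoton_image(shg, tpef, pitch),
      truth = list(
        zone_map = zone, collagen_mask = collagen,
        lumen_table = lumen_table, string_inventory = inventory, spec = spec
      )
    )
  })
}
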