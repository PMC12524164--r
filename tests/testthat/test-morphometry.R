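# A zone map stub: all tissue is zone2 unless a region matrix is given.
stub_zone_map <- function(n, pitch = 0.390625, codes = NULL) {
  z <- if (is.null(codes)) {
    matrix(fibroquant:::ZONE_CODES[["zone2"]], n, n)
  } else codes
  structure(z, legend = fibroquant:::ZONE_CODES,
            bands_um = c(periportal = 100, pericentral = 100),
            pixel_pitch_um = pitch,
            class = c("fq_zone_map", "matrix", "array"))
}

mask_of <- function(m, pitch = 0.390625) {
  fibroquant:::new_fq_mask(m, pitch, "test")
}

test_that("string decomposition measures a planted ribbon", {
  n <- 160
  m <- matrix(FALSE, n, n)
  m[21:24, 11:138] <- TRUE # 4 x 128 px ribbon
  strings <- extract_strings(mask_of(m), stub_zone_map(n))
  expect_equal(nrow(strings), 1)
  expect_equal(strings$area_um2, 128 * 4 * 0.390625^2) # 78.125 um^2
  # frozen reference-skeleton arc length for this ribbon: 48.599 um
  # (one-px midline of 125 px with two diagonal end steps)
  expect_lt(abs(strings$length_um - 48.599) / 48.599, 0.10)
  expect_equal(strings$width_um, strings$area_um2 / strings$length_um)
  expect_false(strings$is_blob)
  # empty mask and two components
  expect_equal(nrow(extract_strings(mask_of(matrix(FALSE, n, n)),
                                    stub_zone_map(n))), 0)
  m2 <- m
  m2[100:103, 11:80] <- TRUE
  expect_equal(nrow(extract_strings(mask_of(m2), stub_zone_map(n))), 2)
})

test_that("compact blobs are re-parameterised as sqrt(area)", {
  n <- 64
  m <- matrix(FALSE, n, n)
  m[20:39, 20:39] <- TRUE # 20 x 20 square
  s <- extract_strings(mask_of(m), stub_zone_map(n))
  expect_true(s$is_blob)
  expect_equal(s$length_um, sqrt(s$area_um2))
  expect_equal(s$width_um, s$length_um)
})

test_that("scale equivariance: pitch doubles lengths, quadruples areas", {
  n <- 128
  set.seed(3)
  m <- matrix(FALSE, n, n)
  m[10:12, 20:90] <- TRUE
  m[60:100, 40:42] <- TRUE
  s1 <- extract_strings(mask_of(m, 0.390625), stub_zone_map(n, 0.390625))
  s2 <- extract_strings(mask_of(m, 0.78125), stub_zone_map(n, 0.78125))
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(s2$length_um, 2 * s1$length_um)
  expect_equal(s2$area_um2, 4 * s1$area_um2)
  expect_equal(s2$width_um, 2 * s1$width_um)
})

test_that("threshold classification is a closed lower bound and partitions", {
  strings <- tibble::tibble(
    string_id = 1:4, region = "zone2", n_px = 10,
    area_um2 = c(30, 60, 90, 120), length_um = c(10, 20, 30, 40),
    width_um = c(3.0, 3.0, 3.0, 2.99), is_blob = FALSE
  )
  out <- classify_strings(strings, thick_um = 3, long_um = 40)
  expect_equal(out$is_thick, c(TRUE, TRUE, TRUE, FALSE)) # >= is thick
  expect_equal(out$is_long, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(sum(out$is_thick) + sum(!out$is_thick), nrow(out))
})

test_that("aggregation clusters by closing and splits %Area additively", {
  n <- 200
  m <- matrix(FALSE, n, n)
  # a dense bundle: three ribbons 2 px apart (closing at 5 um fuses them)
  m[50:53, 20:120] <- TRUE
  m[56:59, 20:120] <- TRUE
  m[62:65, 20:120] <- TRUE
  # one small isolated string far away
  m[150:151, 150:169] <- TRUE
  cm <- mask_of(m)
  zm <- stub_zone_map(n)
  s <- extract_strings(cm, zm)
  s <- classify_strings(s)
  s <- classify_aggregation(s, cm, close_radius_um = 5, agg_area_um2 = 100)
  bundle <- s$area_um2 > 30
  expect_true(all(s$is_aggregated[bundle]))
  expect_false(any(s$is_aggregated[!bundle]))
  s$is_chickenwire <- FALSE
  qfp <- compute_qfp_table(s, zm)
  expect_equal(qfp[["%Zone2Agg"]] + qfp[["%Zone2Dis"]], qfp[["%Zone2"]])
})

test_that("q-FP table obeys its partition identities on random phantoms", {
  p <- small_params()
  for (seed in 1:6) {
    ph <- generate_phantom(small_phantom_spec(
      stage = sample(0:4, 1), seed = 700 + seed
    ))
    res <- analyze_with_truth(ph, p)
    qfp <- res$qfp
    for (suffix in c("", "PT", "PeriPortal", "ChickenWire", "Zone2",
                     "CV", "PeriCentral")) {
      expect_equal(qfp[[paste0("#ThinStr", suffix)]] +
                     qfp[[paste0("#ThickStr", suffix)]],
                   qfp[[paste0("#Str", suffix)]])
      expect_equal(qfp[[paste0("#ShortStr", suffix)]] +
                     qfp[[paste0("#LongStr", suffix)]],
                   qfp[[paste0("#Str", suffix)]])
      pct_area <- if (suffix == "") qfp[["%Area"]] else
        qfp[[paste0("%", suffix)]]
      expect_equal(qfp[[paste0("%", suffix, "Agg")]] +
                     qfp[[paste0("%", suffix, "Dis")]], pct_area)
    }
    expect_gte(qfp[["%SHG"]], 0)
    expect_lte(qfp[["%SHG"]], 100)
  }
})

test_that("q-FP table flags absent regions and empty masks as zeros", {
  n <- 100
  zm <- stub_zone_map(n) # no portal region present
  s <- extract_strings(mask_of(matrix(FALSE, n, n)), zm)
  s <- classify_strings(s)
  s$is_aggregated <- logical(0)
  s$is_chickenwire <- logical(0)
  qfp <- compute_qfp_table(s, zm)
  expect_equal(qfp[["#Str"]], 0)
  expect_equal(qfp[["StrLengthPT"]], 0)
  expect_equal(qfp[["%SHG"]], 0)
  present <- attr(qfp, "region_present")
  expect_false(present[["portal"]])
  expect_true(present[["zone2"]])
})

test_that("%SHG recovers a planted overall collagen fraction", {
  dens <- list(periportal = 0.12, zone2 = 0.12, pericentral = 0.12)
  ph <- generate_phantom(phantom_spec(
    stage = 2, canvas_px = 512, collagen_density_by_region = dens,
    bridging = FALSE, periportal_band_um = 50, pericentral_band_um = 50,
    seed = 77
  ))
  p <- analysis_params(min_tissue_area_mm2 = 0.01,
                       periportal_band_um = 50, pericentral_band_um = 50)
  res <- analyze_with_truth(ph, p)
  gt_frac <- 100 * sum(ph$truth$collagen_mask) /
    sum(ph$truth$zone_map != attr(ph$truth$zone_map, "legend")[["lumen"]])
  expect_lt(abs(res$qfp[["%SHG"]] - gt_frac), 0.5)
})

test_that("portal morphometrics respond monotonically to stage", {
  p <- small_params()
  out <- purrr::map_dfr(0:4, function(stage) {
    purrr::map_dfr(1:6, function(r) {
      ph <- generate_phantom(small_phantom_spec(stage = stage,
                                                seed = 900 + 10 * stage + r))
      res <- analyze_with_truth(ph, p)
      tibble::tibble(stage = stage,
                     width = res$qfp[["StrWidthPT"]],
                     len = res$qfp[["StrLengthPT"]],
                     pp = res$qfp[["%PeriPortal"]])
    })
  })
  # positive rank correlation with stage for the top-ranked parameters
  expect_gte(cor(out$stage, out$width, method = "spearman"), 0.6)
  expect_gte(cor(out$stage, out$len, method = "spearman"), 0.6)
  expect_gte(cor(out$stage, out$pp, method = "spearman"), 0.6)
  # strong overall effect: cirrhotic phantoms far above stage 0
  m <- function(v, s) mean(v[out$stage == s])
  expect_gt(m(out$width, 4), 1.5 * m(out$width, 0))
  expect_gt(m(out$len, 4), 3 * m(out$len, 0))
  expect_gt(m(out$pp, 4), 3 * m(out$pp, 0))
})
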