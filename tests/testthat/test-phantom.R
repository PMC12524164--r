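test_that("phantom generation is bit-identical under one seed", {
  spec <- small_phantom_spec(stage = 2, seed = 11)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$shg, b$image$shg)
  expect_identical(a$image$tpef, b$image$tpef)
  expect_identical(a$truth$zone_map, b$truth$zone_map)
  expect_identical(a$truth$string_inventory, b$truth$string_inventory)
  # a different seed gives a different field
  c <- generate_phantom(small_phantom_spec(stage = 2, seed = 12))
  expect_false(identical(a$image$shg, c$image$shg))
})

test_that("zero collagen density leaves only vessel-wall collars", {
  spec <- small_phantom_spec(
    stage = 0, seed = 3,
    collagen_density_by_region = list(periportal = 0, zone2 = 0,
                                      pericentral = 0)
  )
  ph <- generate_phantom(spec)
  expect_equal(nrow(ph$truth$string_inventory), 0)
  # remaining collagen is exactly the collars: all within one collar
  # width of a lumen
  legend <- attr(ph$truth$zone_map, "legend")
  collar_zones <- ph$truth$zone_map %in%
    legend[c("portal", "central_vein")]
  expect_true(all(collar_zones[ph$truth$collagen_mask]))
  expect_gt(sum(ph$truth$collagen_mask), 0)
})

test_that("an explicitly planted string is inventoried with its geometry", {
  spec <- small_phantom_spec(
    stage = 0, seed = 5,
    collagen_density_by_region = list(periportal = 0, zone2 = 0,
                                      pericentral = 0),
    planted_strings = data.frame(region = "periportal", length_um = 50,
                                 width_um = 4)
  )
  ph <- generate_phantom(spec)
  inv <- ph$truth$string_inventory
  expect_equal(nrow(inv), 1)
  expect_equal(inv$region, "periportal")
  # nominal geometry: area = length x width = 200 um^2 by construction
  expect_equal(inv$length_um * inv$width_um, 200)
  # realised pixel area within rasterization error of the nominal area
  expect_lt(abs(inv$area_um2 - 200) / 200, 0.10)
  # every planted pixel lies inside the declared region
  legend <- attr(ph$truth$zone_map, "legend")
  in_pp <- ph$truth$zone_map == legend[["periportal"]]
  planted <- ph$truth$collagen_mask &
    !(ph$truth$zone_map %in% legend[c("portal", "central_vein")])
  expect_true(all(in_pp[planted]))
})

test_that("ground-truth collagen fraction tracks the requested density", {
  dens <- list(periportal = 0.15, zone2 = 0.03, pericentral = 0.05)
  ph <- generate_phantom(phantom_spec(
    stage = 2, canvas_px = 1024, collagen_density_by_region = dens,
    bridging = FALSE, seed = 21
  ))
  legend <- attr(ph$truth$zone_map, "legend")
  for (rn in names(dens)) {
    sel <- ph$truth$zone_map == legend[[rn]]
    got <- sum(ph$truth$collagen_mask[sel]) / sum(sel)
    expect_lt(abs(got - dens[[rn]]), 0.02)
  }
})

test_that("zone map partitions the canvas and canvas sizing is checked", {
  ph <- generate_phantom(small_phantom_spec(stage = 3, seed = 9))
  expect_equal(sum(ph$truth$zone_map >= 0), length(ph$truth$zone_map))
  # stage 3 default plants bridging septa
  expect_true(any(ph$truth$string_inventory$kind == "bridge"))
  expect_error(
    generate_phantom(phantom_spec(stage = 1, canvas_px = 256,
                                  n_portal_tracts = 5,
                                  n_central_veins = 4)),
    "too small"
  )
})

test_that("segmentation recovers planted collagen almost exactly", {
  ph <- generate_phantom(small_phantom_spec(stage = 2, seed = 31))
  p <- small_params()
  tissue <- segment_tissue(ph$image, p$min_tissue_area_mm2)
  collagen <- segment_collagen(ph$image, tissue)
  gt <- ph$truth$collagen_mask
  jac <- sum(collagen & gt) / sum(collagen | gt)
  expect_gte(jac, 0.95)
  expect_gte(sum(collagen & gt) / sum(gt), 0.99)
})

test_that("multiphoton TIFF round trip preserves channels and pitch", {
  ph <- generate_phantom(phantom_spec(
    stage = 1, canvas_px = 192, n_portal_tracts = 1, n_central_veins = 0,
    periportal_band_um = 30, pericentral_band_um = 30, seed = 41
  ))
  path <- withr::local_tempfile(fileext = ".tif")
  write_multiphoton_tiff(ph$image, path)
  back <- read_multiphoton_tiff(path)
  expect_equal(back$pixel_pitch_um, ph$image$pixel_pitch_um,
               tolerance = 1e-6)
  # 16-bit quantization: 1/65535 resolution
  expect_lt(max(abs(back$shg - ph$image$shg)), 1e-4)
  expect_lt(max(abs(back$tpef - ph$image$tpef)), 1e-4)
})
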