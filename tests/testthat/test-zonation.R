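# Build a simple tissue field with one circular hole and an optional
# collagen ring around it.
ring_fixture <- function(n = 160, centre = c(80, 80), r_hole = 15,
                         ring_width_px = 16, ring = TRUE,
                         pitch = 0.390625) {
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  d2 <- (rr - centre[1])^2 + (cc - centre[2])^2
  hole <- d2 <= r_hole^2
  tpef <- matrix(0.8, n, n)
  tpef[1:2, 1:2] <- 0.03
  tpef[hole] <- 0.03
  shg <- matrix(0.05, n, n)
  if (ring) shg[d2 > r_hole^2 & d2 <= (r_hole + ring_width_px)^2] <- 0.8
  img <- multiphoton_image(shg, tpef, pitch)
  tissue <- segment_tissue(img, min_tissue_area_mm2 = 1e-4)
  collagen <- segment_collagen(img, tissue)
  lumens <- detect_lumens(tissue, collagen)
  list(img = img, tissue = tissue, collagen = collagen, lumens = lumens)
}

test_that("collar fraction separates sheathed from bare lumens", {
  with_ring <- ring_fixture(ring = TRUE)
  without <- ring_fixture(ring = FALSE)
  expect_equal(nrow(with_ring$lumens), 1)
  expect_gt(with_ring$lumens$collar_fraction, 0.95)
  expect_equal(without$lumens$collar_fraction, 0)
  expect_lt(with_ring$lumens$eccentricity, 0.1) # disc
  f <- lumen_features(with_ring$lumens)
  expect_named(f, c("lumen_id", "area_um2", "eccentricity",
                    "collar_fraction", "boundary_smoothness",
                    "neighbor_lumen_count"))
})

test_that("CART landmark classifier fits separable data and bounds depth", {
  set.seed(5)
  n <- 60
  feats <- tibble::tibble(
    area_um2 = runif(n, 200, 1200),
    eccentricity = runif(n, 0, 0.8),
    collar_fraction = c(runif(n / 2, 0.6, 1), runif(n / 2, 0, 0.2)),
    boundary_smoothness = runif(n, 0.5, 1.3),
    neighbor_lumen_count = sample(0:3, n, TRUE)
  )
  labels <- rep(c("portal_tract", "central_vein"), each = n / 2)
  model <- train_landmark_classifier(feats, labels)
  expect_equal(predict_landmarks(model, feats), labels)
  stump <- train_landmark_classifier(feats, labels, max_depth = 1)
  # a depth-1 tree has exactly one split: root plus two leaves
  expect_equal(nrow(stump$tree$frame), 3)
  expect_error(train_landmark_classifier(feats, rep("portal_tract", n)),
               "2 classes")
})

test_that("landmark classifier reaches 95% accuracy on held-out phantoms", {
  # pool lumens from many small phantoms; first third trains, rest tests
  phs <- lapply(1:80, function(i) {
    generate_phantom(small_phantom_spec(stage = (i - 1) %% 5, seed = 500 + i))
  })
  p <- small_params()
  collect <- function(ph) {
    tissue <- segment_tissue(ph$image, p$min_tissue_area_mm2)
    collagen <- segment_collagen(ph$image, tissue)
    lum <- detect_lumens(tissue, collagen)
    if (nrow(lum) == 0) return(NULL)
    cbind(lumen_features(lum), truth = match_lumens_to_truth(lum, ph$truth))
  }
  all <- dplyr::bind_rows(lapply(phs, collect))
  train <- all[seq_len(floor(nrow(all) / 3)), ]
  test <- all[-seq_len(floor(nrow(all) / 3)), ]
  expect_gte(nrow(test), 200)
  model <- train_landmark_classifier(train[names(train) != "truth"],
                                     train$truth, seed = 99)
  acc <- mean(predict_landmarks(model, test) == test$truth)
  expect_gte(acc, 0.95)
})

test_that("zone bands follow geodesic distance and partition tissue", {
  fx <- ring_fixture(n = 300, centre = c(150, 150), r_hole = 15)
  cls <- "portal_tract"
  band_um <- 40
  zm <- build_zone_map(fx$tissue, fx$lumens, cls, fx$collagen,
                       periportal_band_um = band_um,
                       pericentral_band_um = band_um)
  legend <- attr(zm, "legend")
  # partition: every tissue pixel gets exactly one in-tissue label
  tis_labels <- zm[unclass(fx$tissue)]
  expect_true(all(tis_labels %in%
                    legend[c("portal", "periportal", "zone2",
                             "pericentral", "central_vein")]))
  expect_equal(sum(fx$tissue), length(tis_labels))
  # distance oracle: pixels just inside / outside the band edge measured
  # from the portal region boundary
  dist_p <- fibroquant:::cpp_geodesic_distance(
    unclass(fx$tissue) | (zm == legend[["portal"]]),
    zm == legend[["portal"]]
  ) * fx$img$pixel_pitch_um
  inside <- dist_p > 0 & dist_p <= band_um - 1 & unclass(fx$tissue)
  outside <- dist_p > band_um + 1 & unclass(fx$tissue)
  expect_true(all(zm[inside] == legend[["periportal"]]))
  expect_true(all(zm[outside] == legend[["zone2"]]))
  # band monotonicity: growing the band never shrinks the periportal set
  zm2 <- build_zone_map(fx$tissue, fx$lumens, cls, fx$collagen,
                        periportal_band_um = band_um + 15,
                        pericentral_band_um = band_um)
  pp1 <- zm == legend[["periportal"]]
  pp2 <- zm2 == legend[["periportal"]]
  expect_true(all(pp2[pp1]))
})

test_that("zone map without landmarks falls back to zone2", {
  fx <- ring_fixture(ring = FALSE)
  expect_message(
    zm <- build_zone_map(fx$tissue, fx$lumens, rep("other", nrow(fx$lumens))),
    "zone2"
  )
  legend <- attr(zm, "legend")
  expect_true(all(zm[unclass(fx$tissue)] == legend[["zone2"]]))
})

test_that("chicken-wire flags thin detached strings in zone2", {
  fx <- ring_fixture(n = 300, centre = c(80, 80), r_hole = 15)
  # add a thin free string far from the landmark and a string touching
  # the portal collar
  shg <- fx$img$shg
  shg[250:253, 100:180] <- 0.8   # thin far string (~1.6 um wide)
  shg[80, 96:140] <- 0.8         # 1-px line touching the collar edge
  img2 <- multiphoton_image(shg, fx$img$tpef, fx$img$pixel_pitch_um)
  tissue <- segment_tissue(img2, min_tissue_area_mm2 = 1e-4)
  collagen <- segment_collagen(img2, tissue)
  lumens <- detect_lumens(tissue, collagen)
  zm <- build_zone_map(tissue, lumens, "portal_tract", collagen,
                       periportal_band_um = 20, pericentral_band_um = 20)
  strings <- extract_strings(collagen, zm)
  strings <- classify_strings(strings)
  strings <- assign_chickenwire(strings, zm, attach_dist_um = 10,
                                thick_um = 3)
  far <- strings$string_id[vapply(strings$string_id, function(id) {
    any(attr(strings, "label_image")[250:253, 100:180] == id)
  }, logical(1))]
  expect_true(all(strings$is_chickenwire[strings$string_id %in% far]))
  # the ring+attached line component sits in the portal region: not
  # chicken-wire
  ring_id <- attr(strings, "label_image")[80, 97]
  expect_false(strings$is_chickenwire[strings$string_id == ring_id])
  # no strings -> no flags
  empty <- extract_strings(
    fibroquant:::new_fq_mask(matrix(FALSE, 50, 50), 0.390625, "none"),
    zm[1:50, 1:50, drop = FALSE] |> structure(
      legend = attr(zm, "legend"), pixel_pitch_um = 0.390625,
      class = c("fq_zone_map", "matrix", "array"))
  )
  flagged <- assign_chickenwire(empty, zm, 10, 3)
  expect_equal(nrow(flagged), 0)
})
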