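# Shared fixture builders; everything is generated in code.

# A flat-field image with an optional bright blob set, as an Otsu-friendly
# two-level intensity matrix.
flat_image <- function(n = 64, bg = 0.05, pitch = 0.390625) {
  tpef <- matrix(0.8, n, n)
  tpef[1:2, 1:2] <- 0.03 # dark corner so the TPEF histogram is bimodal
  multiphoton_image(
    shg = matrix(bg, n, n),
    tpef = tpef,
    pixel_pitch_um = pitch
  )
}

# Put a rectangular bright blob into a channel matrix (1-based rows/cols).
add_blob <- function(mat, rows, cols, value = 0.8) {
  mat[rows, cols] <- value
  mat
}

# A small, fast phantom spec used across tests: 150 x 150 um canvas,
# bands shrunk to fit.
small_phantom_spec <- function(stage, seed, canvas_px = 384, ...) {
  phantom_spec(
    stage = stage, canvas_px = canvas_px,
    periportal_band_um = 35, pericentral_band_um = 35,
    seed = seed, ...
  )
}

small_params <- function(canvas_px = 384, pitch = 0.390625) {
  analysis_params(
    min_tissue_area_mm2 = (canvas_px * pitch)^2 / 1e6 / 4,
    periportal_band_um = 35, pericentral_band_um = 35
  )
}

# Analyze a phantom using its ground-truth lumen classes (bypasses the
# CART model where the test is not about classification).
analyze_with_truth <- function(ph, params) {
  tissue <- segment_tissue(ph$image, params$min_tissue_area_mm2)
  collagen <- segment_collagen(ph$image, tissue, params$min_string_um2,
                               params$fill_hole_px)
  lum <- detect_lumens(tissue, collagen, params$min_lumen_um2,
                       params$collar_width_um)
  cls <- match_lumens_to_truth(lum, ph$truth)
  analyze_specimen(ph$image, landmark_classes = cls, params = params)
}

# Brute-force Otsu oracle: direct between-class variance at every split,
# computed by plain summation, with the same mean-of-ties rule.
otsu_oracle <- function(counts) {
  total <- sum(counts)
  score <- numeric(255)
  for (t in 1:255) {
    lower <- counts[1:t]; upper <- counts[(t + 1):256]
    w0 <- sum(lower) / total; w1 <- sum(upper) / total
    if (w0 == 0 || w1 == 0) { score[t] <- 0; next }
    mu0 <- sum((0:(t - 1)) * lower) / sum(lower)
    mu1 <- sum((t:255) * upper) / sum(upper)
    score[t] <- w0 * w1 * (mu0 - mu1)^2
  }
  mean(which(score >= max(score) - 1e-12))
}

# Brute-force AUC oracle over all positive-negative pairs.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}
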