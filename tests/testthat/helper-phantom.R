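# Shared fixtures: all phantoms are generated in code at test time.

# 64 x 64 phantom geometry used for segmentation tests (level height 8 px)
tiny_spec64 <- function(noise_sd = 0.05, ...) {
  phantom_spec(image_shape = c(64L, 64L), vertebra_height_px = 6L,
               vertebra_width_px = 10L, intervertebral_gap_px = 2L,
               spine_col_center = 40L, aorta_width_px = 8L, aorta_gap_px = 2L,
               calc_thickness_px = 2L, noise_sd = noise_sd, ...)
}

# randomized phantom geometry + coverage, reproducible from a seed
random_phantom_spec <- function(seed, max_side = Inf, tilt = 0) {
  set.seed(seed)
  h <- sample(18:36, 1)
  g <- sample(5:12, 1)
  w <- sample(20:36, 1)
  aw <- sample(12:24, 1)
  ag <- sample(2:8, 1)
  th <- sample(2:3, 1)
  rows <- 6 * h + 5 * g + sample(10:30, 1)
  center <- w %/% 2 + aw + ag + th + sample(4:10, 1)
  cols <- center + w %/% 2 + sample(8:20, 1)
  if (rows > max_side || cols > max_side) {
    h <- sample(8:10, 1); g <- sample(3:5, 1)
    w <- sample(12:18, 1); aw <- sample(8:12, 1); ag <- sample(2:4, 1)
    th <- 2L
    rows <- 6 * h + 5 * g + sample(4:8, 1)
    center <- w %/% 2 + aw + ag + th + 4L
    cols <- center + w %/% 2 + 8L
    stopifnot(rows <= max_side, cols <= max_side)
  }
  if (tilt != 0) {   # headroom so rotation keeps the anatomy in frame
    rows <- rows + 80L
    center <- center + 40L
    cols <- cols + 80L
  }
  cov <- coverage_spec()
  cov[] <- ifelse(runif(8) < 0.35, 0, runif(8))
  phantom_spec(image_shape = c(rows, cols), vertebra_height_px = h,
               vertebra_width_px = w, intervertebral_gap_px = g,
               spine_col_center = center, aorta_width_px = aw,
               aorta_gap_px = ag, calc_thickness_px = th, coverage = cov,
               spine_tilt_deg = tilt, noise_sd = 0.02, seed = seed)
}

# wide truth scores of a phantom case as a named vector L1_ant..L4_post
truth_scores <- function(case) {
  setNames(case$truth$score,
           paste0(case$truth$level, "_",
                  ifelse(case$truth$wall == "anterior", "ant", "post")))
}

result_scores <- function(result) {
  setNames(result$segments$score,
           paste0(result$segments$level, "_",
                  ifelse(result$segments$wall == "anterior", "ant", "post")))
}
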