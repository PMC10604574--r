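# Synthetic lateral-radiograph phantom with ground-truth Kauppila scores
# known by construction: a vertical column of six separated vertebral bodies
# (T12-L5), an aortic band strictly anterior to (left of) the spine, and
# calcification strips on either aortic wall with controllable per-level
# longitudinal coverage.

#' Per-segment coverage specification
#'
#' Builds the named coverage vector used by [phantom_spec()]: one fraction in
#' `[0, 1]` per scored wall segment (L1-L4, anterior and posterior).
#'
#' @param ... Named fractions such as `L2_ant = 0.5`, `L3_post = 1`.
#'   Unnamed defaults are 0. `default` sets all eight at once.
#' @param default Fraction used for unspecified segments.
#' @return Named numeric vector of length 8.
#' @examples
#' coverage_spec(L2_ant = 0.5)
#' coverage_spec(default = 1)
#' @export
coverage_spec <- function(..., default = 0) {
  nm <- as.vector(t(outer(paste0("L", 1:4), c("ant", "post"), paste, sep = "_")))
  cov <- setNames(rep(as.numeric(default), 8L), nm)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), nm)
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      abort(sprintf("unknown coverage segment(s): %s",
                    paste(bad, collapse = ", ")))
    cov[names(dots)] <- as.numeric(unlist(dots))
  }
  cov
}

#' Phantom specification
#'
#' Geometry, per-segment calcification coverage, noise and seed for one
#' synthetic case. Units are pixels unless suffixed otherwise. The phantom
#' follows the package's orientation convention: rows run cranial to caudal,
#' the aorta sits at smaller column indices than the spine.
#'
#' @param image_shape `(rows, cols)` of the image.
#' @param pixel_spacing_mm Physical pixel pitch, scalar or `(row, col)`.
#' @param vertebra_height_px,vertebra_width_px,intervertebral_gap_px Vertebral
#'   body geometry; six bodies and five gaps must fit in the rows.
#' @param spine_col_center Column index (0-based) of the vertebral column
#'   center.
#' @param aorta_width_px Width of the aortic band.
#' @param aorta_gap_px Gap between the spine's anterior edge and the aortic
#'   band's posterior edge.
#' @param calc_thickness_px Thickness of calcification strips (2-3 px is
#'   typical; thickness does not affect the score, which uses longitudinal
#'   extent only).
#' @param coverage Named length-8 vector from [coverage_spec()]: requested
#'   longitudinal coverage fraction per (level, wall) segment. T12 and L5
#'   receive no calcification (the score is defined for L1-L4 only).
#' @param spine_tilt_deg Small rotation of the whole anatomy, degrees.
#' @param noise_sd Gaussian intensity noise standard deviation.
#' @param intensities Rendering intensities before noise.
#' @param seed RNG seed for noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(320L, 180L),
                         pixel_spacing_mm = 0.14,
                         vertebra_height_px = 40L,
                         vertebra_width_px = 40L,
                         intervertebral_gap_px = 10L,
                         spine_col_center = 120L,
                         aorta_width_px = 24L,
                         aorta_gap_px = 6L,
                         calc_thickness_px = 3L,
                         coverage = coverage_spec(),
                         spine_tilt_deg = 0,
                         noise_sd = 0.02,
                         intensities = c(background = 0.1, aorta = 0.35,
                                         vertebra = 0.9, calc = 1.0),
                         seed = 1L) {
  spec <- structure(
    list(image_shape = as.integer(image_shape),
         pixel_spacing_mm = rep(as.numeric(pixel_spacing_mm), length.out = 2L),
         vertebra_height_px = as.integer(vertebra_height_px),
         vertebra_width_px = as.integer(vertebra_width_px),
         intervertebral_gap_px = as.integer(intervertebral_gap_px),
         spine_col_center = as.integer(spine_col_center),
         aorta_width_px = as.integer(aorta_width_px),
         aorta_gap_px = as.integer(aorta_gap_px),
         calc_thickness_px = as.integer(calc_thickness_px),
         coverage = coverage,
         spine_tilt_deg = as.numeric(spine_tilt_deg),
         noise_sd = as.numeric(noise_sd),
         intensities = intensities,
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  fail <- function(field, msg)
    abort(sprintf("invalid phantom_spec field `%s`: %s", field, msg))
  s <- spec
  if (length(s$image_shape) != 2L || any(s$image_shape < 1L))
    fail("image_shape", "must be two positive integers")
  for (f in c("vertebra_height_px", "vertebra_width_px",
              "intervertebral_gap_px", "aorta_width_px", "calc_thickness_px"))
    if (s[[f]] < 1L) fail(f, "must be a positive integer")
  if (s$aorta_gap_px < 0L) fail("aorta_gap_px", "must be non-negative")
  if (any(s$pixel_spacing_mm <= 0)) fail("pixel_spacing_mm", "must be positive")
  spine_rows <- 6L * s$vertebra_height_px + 5L * s$intervertebral_gap_px
  if (spine_rows > s$image_shape[1L])
    fail("vertebra_height_px",
         sprintf("6 bodies + 5 gaps need %d rows but image has %d",
                 spine_rows, s$image_shape[1L]))
  nm <- names(coverage_spec())
  if (length(s$coverage) != 8L || !setequal(names(s$coverage), nm))
    fail("coverage", "must be a named length-8 vector from coverage_spec()")
  if (any(s$coverage < 0 | s$coverage > 1))
    fail("coverage", "fractions must lie in [0, 1]")
  spine_left <- s$spine_col_center - s$vertebra_width_px %/% 2L
  aorta_right <- spine_left - s$aorta_gap_px - 1L
  aorta_left <- aorta_right - s$aorta_width_px + 1L
  if (aorta_left < 0L)
    fail("aorta_width_px", "aortic band extends past the left image edge")
  if (aorta_right >= spine_left)
    fail("aorta_gap_px", "aorta must lie strictly anterior to the spine")
  if (spine_left + s$vertebra_width_px > s$image_shape[2L])
    fail("spine_col_center", "vertebral column extends past the right edge")
  if (s$calc_thickness_px * 2L > s$aorta_width_px)
    fail("calc_thickness_px", "strips on both walls must fit inside the aorta")
  if (abs(s$spine_tilt_deg) > 30)
    fail("spine_tilt_deg", "tilt must be within +/-30 degrees")
  if (s$noise_sd < 0) fail("noise_sd", "must be non-negative")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d px, vertebrae %dx%d gap %d, aorta %d px, tilt %.1f deg, seed %d\n",
              x$image_shape[1L], x$image_shape[2L], x$vertebra_height_px,
              x$vertebra_width_px, x$intervertebral_gap_px, x$aorta_width_px,
              x$spine_tilt_deg, x$seed))
  cov <- x$coverage[x$coverage > 0]
  cat("  coverage:",
      if (length(cov)) paste(sprintf("%s=%.2f", names(cov), cov),
                             collapse = " ") else "none", "\n")
  invisible(x)
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# internal geometry shared by the generator and tests:
# level height equals vertebra height + gap (boundaries at gap midpoints)
phantom_geometry <- function(spec) {
  h <- spec$vertebra_height_px
  g <- spec$intervertebral_gap_px
  spine_rows <- 6L * h + 5L * g
  top <- (spec$image_shape[1L] - spine_rows) %/% 2L
  spine_left <- spec$spine_col_center - spec$vertebra_width_px %/% 2L
  aorta_right <- spine_left - spec$aorta_gap_px - 1L
  aorta_left <- aorta_right - spec$aorta_width_px + 1L
  vert_top <- top + (0:5) * (h + g)               # 0-based top row per body
  list(top = top, level_height = h + g,
       spine_left = spine_left,
       spine_right = spine_left + spec$vertebra_width_px - 1L,
       aorta_left = aorta_left, aorta_right = aorta_right,
       vert_top = vert_top,
       vert_center = vert_top + (h - 1) / 2,
       aorta_row_range = c(top, top + spine_rows - 1L))
}

#' Generate one phantom case
#'
#' Renders the multi-class mask and intensity image described by a
#' [phantom_spec()] and derives the ground-truth Kauppila result from the
#' realized (whole-pixel-rounded) coverage via [score_from_ratio()]. The
#' calcification strip for a segment with requested coverage `c` spans
#' `round(c * level_height)` rows, centered within the level, on the outer
#' (anterior wall) or inner (posterior wall) aortic boundary.
#'
#' @param spec A `phantom_spec`.
#' @return An object of class `phantom_case`: `$image` (a [radiograph()]),
#'   `$mask` (integer matrix), `$truth` (tibble of per-segment realized
#'   coverage and scores plus attributes), `$truth_total`, `$truth_severity`,
#'   `$spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  geo <- phantom_geometry(spec)
  lb <- aac_labels()
  shp <- spec$image_shape
  mask <- matrix(lb[["background"]], shp[1L], shp[2L])

  # aortic band spans the full spine extent
  ar <- geo$aorta_row_range
  mask[(ar[1L]:ar[2L]) + 1L, (geo$aorta_left:geo$aorta_right) + 1L] <-
    lb[["aorta"]]
  # six vertebral bodies
  for (vt in geo$vert_top)
    mask[(vt:(vt + spec$vertebra_height_px - 1L)) + 1L,
         (geo$spine_left:geo$spine_right) + 1L] <- lb[["vertebra"]]

  # calcification strips on L1-L4 (vertebral bodies 2..5), truth by construction
  th <- spec$calc_thickness_px
  ant_cols <- (geo$aorta_left + 0:(th - 1L)) + 1L
  post_cols <- (geo$aorta_right - (th - 1L):0) + 1L
  truth <- kauppila_segments()
  truth$requested <- 0
  truth$realized <- 0
  truth$score <- 0L
  g <- spec$intervertebral_gap_px
  H <- geo$level_height
  for (k in 1:4) {
    # integer row range of level Lk: from the gap midpoint above (inclusive
    # under the caudal half-plane rule) spanning exactly H rows
    lev_start <- as.integer(ceiling(geo$vert_top[k + 1L] - (g + 1) / 2))
    for (wall in c("ant", "post")) {
      covr <- spec$coverage[[paste0("L", k, "_", wall)]]
      n <- round(covr * H)
      i <- which(truth$level == paste0("L", k) &
                 truth$wall == ifelse(wall == "ant", "anterior", "posterior"))
      truth$requested[i] <- covr
      truth$realized[i] <- n / H
      truth$score[i] <- score_from_ratio(n / H)
      if (n > 0L) {
        r0 <- lev_start + (H - n) %/% 2L   # centered, always inside the level
        rows <- (r0:(r0 + n - 1L)) + 1L
        cols <- if (wall == "ant") ant_cols else post_cols
        mask[rows, cols] <- if (wall == "ant") lb[["calc_anterior"]] else
          lb[["calc_posterior"]]
      }
    }
  }
  storage.mode(mask) <- "integer"

  inten <- spec$intensities
  img <- matrix(inten[["background"]], shp[1L], shp[2L])
  img[mask == lb[["aorta"]]] <- inten[["aorta"]]
  img[mask == lb[["vertebra"]]] <- inten[["vertebra"]]
  img[mask %in% c(lb[["calc_anterior"]], lb[["calc_posterior"]])] <-
    inten[["calc"]]

  if (spec$spine_tilt_deg != 0) {
    mask <- rotate_nearest(mask, spec$spine_tilt_deg,
                           fill = lb[["background"]])
    img <- rotate_nearest(img, spec$spine_tilt_deg,
                          fill = inten[["background"]])
  }
  if (spec$noise_sd > 0)
    img <- img + with_seed(spec$seed,
                           matrix(rnorm(length(img), 0, spec$noise_sd),
                                  nrow(img)))

  total <- sum(truth$score)
  structure(
    list(image = radiograph(img, spec$pixel_spacing_mm,
                            sprintf("phantom_seed%d", spec$seed)),
         mask = mask,
         truth = truth,
         truth_total = total,
         truth_severity = as.character(severity_from_total(total)),
         spec = spec),
    class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s: truth total %d (%s)\n",
              x$image$source_id, x$truth_total, x$truth_severity))
  invisible(x)
}

# rigid rotation about the image center, nearest-neighbour resampling
rotate_nearest <- function(m, deg, fill = 0) {
  affine_resample(m, angle_deg = deg, scale = 1, translate = c(0, 0),
                  method = "nearest", fill = fill)
}

severity_bands <- function() {
  list(mild = c(0L, 4L), moderate = c(5L, 15L), severe = c(16L, 24L))
}

# integer pixel extents whose ratio n/h falls strictly inside a score band
# (exact under whole-pixel rounding, so realized severity equals the target)
extent_choices <- function(score, h) {
  n <- 0:h
  r <- n / h
  keep <- switch(as.character(score),
                 "0" = r == 0,
                 "1" = r > 0 & r < 1 / 3,
                 "2" = r >= 1 / 3 & r < 2 / 3,
                 "3" = r >= 2 / 3)
  n[keep]
}

# random 8-segment score composition with a given total, each segment 0..3
random_composition <- function(total) {
  s <- integer(8L)
  while (sum(s) < total) {
    idx <- which(s < 3L)
    i <- if (length(idx) == 1L) idx else sample(idx, 1L)
    s[i] <- s[i] + 1L
  }
  s
}

#' Generate a seeded phantom cohort with a severity mix and 80/10/10 split
#'
#' Draws per-case coverage so each case's ground-truth total falls in the
#' requested severity band (mild 0-4, moderate 5-15, severe 16-24). Band
#' counts are exact up to rounding: `floor(n * fraction)` per band with
#' remainders assigned by largest fractional part. The split is a seeded
#' random partition into training/validation/test at 80/10/10 (floor for the
#' two small sets; remainders go to training).
#'
#' @param n Number of cases, at least 10.
#' @param severity_mix Length-3 fractions `(mild, moderate, severe)` summing
#'   to 1. The default matches a fairly balanced screening population.
#' @param seed RNG seed.
#' @param base_spec Template [phantom_spec()] providing the geometry; its
#'   coverage and seed fields are overridden per case.
#' @return Tibble with one row per case: `case_id`, `split`, `L1_ant` ..
#'   `L4_post` (truth scores), `total`, `severity`, and a `case` list-column
#'   of `phantom_case` objects.
#' @export
generate_cohort <- function(n, severity_mix = c(mild = 0.46, moderate = 0.31,
                                                severe = 0.23),
                            seed = 1L, base_spec = phantom_spec()) {
  if (n < 10L) abort("`n` must be at least 10")
  if (length(severity_mix) != 3L || abs(sum(severity_mix) - 1) > 1e-8)
    abort("`severity_mix` must be three fractions summing to 1")
  h <- phantom_geometry(base_spec)$level_height
  if (!all(lengths(lapply(0:3, extent_choices, h = h)) > 0))
    abort(sprintf(
      "level height %d px too coarse to realize every score band", h))

  counts <- floor(n * severity_mix)
  rem <- n - sum(counts)
  if (rem > 0L) {
    extra <- order(n * severity_mix - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  bands <- severity_bands()
  band_of_case <- rep(names(bands), counts)

  with_seed(seed, {
    cases <- lapply(seq_len(n), function(i) {
      band <- bands[[band_of_case[i]]]
      total <- sample(band[1L]:band[2L], 1L)
      scores <- random_composition(total)
      cov <- vapply(scores, function(sc) {
        sample(rep(extent_choices(sc, h), 2L), 1L) / h  # rep guards length-1
      }, numeric(1))
      sp <- base_spec
      sp$coverage <- setNames(cov, names(coverage_spec()))
      sp$seed <- sample.int(.Machine$integer.max, 1L)
      generate_phantom(sp)
    })
    n_val <- floor(n * 0.10)
    n_test <- floor(n * 0.10)
    split <- rep("training", n)
    idx <- sample.int(n)
    split[idx[seq_len(n_val)]] <- "validation"
    split[idx[n_val + seq_len(n_test)]] <- "test"
    truth <- purrr::imap_dfr(cases, function(cs, i) {
      seg <- cs$truth
      wide <- setNames(as.list(seg$score),
                       paste0(seg$level, "_",
                              ifelse(seg$wall == "anterior", "ant", "post")))
      tibble::as_tibble(c(list(case_id = sprintf("case%04d", i)), wide,
                          list(total = cs$truth_total,
                               severity = cs$truth_severity)))
    })
    truth$split <- split
    truth$case <- cases
    dplyr::relocate(truth, "split", .after = "case_id")
  })
}
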