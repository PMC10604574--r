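# Stage-one / stage-two image preprocessing: side cropping, isotropic
# resize with symmetric zero padding, intensity normalization, paired
# image/mask augmentation, and the aorta-region crop for the second
# segmentation stage.

#' Preprocessing configuration
#'
#' @param target_shape Output shape `(rows, cols)` after resize+pad.
#' @param crop_left_frac,crop_right_frac Fractions of columns removed from
#'   the left and right image sides (pixel counts are floored).
#' @param scale_range,rotation_range_deg,translation_max_frac Augmentation
#'   ranges: uniform scale, rotation in degrees, and translation as a
#'   fraction of each axis length.
#' @param crop_after_resize Apply the side crop after (rather than before)
#'   the resize+pad step. The default crops first, so the stated fractions
#'   refer to the acquired field of view.
#' @param aorta_margin_px Margin around the aortic bounding box in
#'   [crop_to_aorta()].
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_shape = c(517L, 576L),
                              crop_left_frac = 0.40,
                              crop_right_frac = 0.10,
                              scale_range = c(0.95, 1.05),
                              rotation_range_deg = c(-10, 10),
                              translation_max_frac = 0.10,
                              crop_after_resize = FALSE,
                              aorta_margin_px = 5L) {
  if (crop_left_frac < 0 || crop_right_frac < 0 ||
      crop_left_frac + crop_right_frac >= 1)
    abort("crop fractions must be non-negative and sum to less than 1")
  if (length(scale_range) != 2L || scale_range[1L] > 1 || scale_range[2L] < 1)
    abort("`scale_range` must contain 1")
  structure(
    list(target_shape = as.integer(target_shape),
         crop_left_frac = crop_left_frac,
         crop_right_frac = crop_right_frac,
         scale_range = as.numeric(scale_range),
         rotation_range_deg = as.numeric(rotation_range_deg),
         translation_max_frac = as.numeric(translation_max_frac),
         crop_after_resize = isTRUE(crop_after_resize),
         aorta_margin_px = as.integer(aorta_margin_px)),
    class = "preprocess_config")
}

#' Crop fixed fractions from the left and right image sides
#'
#' Removes `floor(crop_left_frac * cols)` columns from the left and
#' `floor(crop_right_frac * cols)` from the right; the retained region is
#' contiguous and rows are unchanged.
#'
#' @param image A [radiograph()] or matrix.
#' @param cfg A [preprocess_config()].
#' @return A cropped `radiograph`.
#' @export
crop_sides <- function(image, cfg = preprocess_config()) {
  image <- as_radiograph(image)
  nc <- ncol(image$pixels)
  left <- floor(cfg$crop_left_frac * nc)
  right <- floor(cfg$crop_right_frac * nc)
  if (left + right >= nc) abort("side crop removes the whole image")
  out <- image$pixels[, (left + 1L):(nc - right), drop = FALSE]
  radiograph(out, image$spacing_mm, image$source_id)
}

# bilinear resize of a matrix to (nr, nc), sampling at aligned pixel centers
bilinear_resize <- function(m, nr, nc) {
  if (nr == nrow(m) && nc == ncol(m)) return(m)
  # map output pixel centers into input coordinates (0-based centers)
  sr <- nrow(m) / nr
  sc <- ncol(m) / nc
  r <- (seq_len(nr) - 0.5) * sr - 0.5
  cc <- (seq_len(nc) - 0.5) * sc - 0.5
  r0 <- pmin(pmax(floor(r), 0), nrow(m) - 1L)
  r1 <- pmin(r0 + 1, nrow(m) - 1L)
  c0 <- pmin(pmax(floor(cc), 0), ncol(m) - 1L)
  c1 <- pmin(c0 + 1, ncol(m) - 1L)
  fr <- pmin(pmax(r - r0, 0), 1)
  fc <- pmin(pmax(cc - c0, 0), 1)
  m00 <- m[r0 + 1L, c0 + 1L, drop = FALSE]
  m01 <- m[r0 + 1L, c1 + 1L, drop = FALSE]
  m10 <- m[r1 + 1L, c0 + 1L, drop = FALSE]
  m11 <- m[r1 + 1L, c1 + 1L, drop = FALSE]
  wr <- matrix(fr, nr, nc)
  wc <- matrix(fc, nr, nc, byrow = TRUE)
  m00 * (1 - wr) * (1 - wc) + m01 * (1 - wr) * wc +
    m10 * wr * (1 - wc) + m11 * wr * wc
}

#' Resize isotropically to a target shape with symmetric zero padding
#'
#' The image is scaled by a single factor (preserving the aspect ratio) so it
#' fits inside `target`, bilinearly interpolated, and zero-padded
#' symmetrically on the remaining axis. Pixel spacing metadata is divided by
#' the scale factor.
#'
#' @param image A [radiograph()] or matrix.
#' @param target Output `(rows, cols)`, default 517 x 576.
#' @return A `radiograph` of exactly the target shape, with attributes
#'   `scale` and `pad` (top, left) recording the transform.
#' @export
resize_pad <- function(image, target = c(517L, 576L)) {
  image <- as_radiograph(image)
  d <- dim(image$pixels)
  s <- min(target[1L] / d[1L], target[2L] / d[2L])
  nr <- min(round(d[1L] * s), target[1L])
  nc <- min(round(d[2L] * s), target[2L])
  resized <- bilinear_resize(image$pixels, nr, nc)
  out <- matrix(0, target[1L], target[2L])
  pad_top <- (target[1L] - nr) %/% 2L
  pad_left <- (target[2L] - nc) %/% 2L
  out[pad_top + seq_len(nr), pad_left + seq_len(nc)] <- resized
  res <- radiograph(out, image$spacing_mm / s, image$source_id)
  attr(res, "scale") <- s
  attr(res, "pad") <- c(top = pad_top, left = pad_left)
  res
}

#' Normalize intensities to the unit interval
#'
#' Centers the image to zero mean, then min-max rescales to `[0, 1]` (the
#' centering does not change the min-max result but mirrors the intended
#' zero-mean step; the operative contract is output min 0 and max 1).
#' Idempotent. A constant image yields all 0.5 with a warning.
#'
#' @param image A [radiograph()] or matrix.
#' @return A normalized `radiograph`.
#' @export
normalize_intensity <- function(image) {
  image <- as_radiograph(image)
  x <- image$pixels - mean(image$pixels)
  rng <- max(x) - min(x)
  if (rng == 0) {
    warn("constant image: normalized to all 0.5")
    out <- matrix(0.5, nrow(x), ncol(x))
  } else {
    out <- (x - min(x)) / rng
  }
  radiograph(out, image$spacing_mm, image$source_id)
}

# inverse-mapping affine resampler shared by augmentation and the phantom's
# tilt. Output pixel p maps from input position
#   R(-theta)/scale * (p - center - translate) + center
# so positive `translate` shifts content toward larger (row, col).
affine_resample <- function(m, angle_deg = 0, scale = 1,
                            translate = c(0, 0),
                            method = c("bilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  d <- dim(m)
  ctr <- (d - 1) / 2
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  rows <- matrix(seq_len(d[1L]) - 1 - ctr[1L] - translate[1L], d[1L], d[2L])
  cols <- matrix(seq_len(d[2L]) - 1 - ctr[2L] - translate[2L], d[1L], d[2L],
                 byrow = TRUE)
  # inverse rotation (by -angle) and inverse scale
  src_r <- (co * rows + si * cols) / scale + ctr[1L]
  src_c <- (-si * rows + co * cols) / scale + ctr[2L]
  if (method == "nearest") {
    ri <- round(src_r); ci <- round(src_c)
    ok <- ri >= 0 & ri <= d[1L] - 1 & ci >= 0 & ci <= d[2L] - 1
    out <- matrix(fill, d[1L], d[2L])
    out[ok] <- m[cbind(ri[ok] + 1L, ci[ok] + 1L)]
    storage.mode(out) <- storage.mode(m)
    return(out)
  }
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  out <- matrix(fill, d[1L], d[2L])
  val <- function(ri, ci) {
    ok <- ri >= 0 & ri <= d[1L] - 1 & ci >= 0 & ci <= d[2L] - 1
    v <- matrix(fill, d[1L], d[2L])
    v[ok] <- m[cbind(ri[ok] + 1L, ci[ok] + 1L)]
    v
  }
  val(r0, c0) * (1 - fr) * (1 - fc) + val(r0, c0 + 1) * (1 - fr) * fc +
    val(r0 + 1, c0) * fr * (1 - fc) + val(r0 + 1, c0 + 1) * fr * fc
}

#' Random paired augmentation of an image and its mask
#'
#' Draws a uniform scale, rotation and translation from the configured
#' ranges and applies the same rigid+scale transform to both inputs: the
#' image with bilinear interpolation, the mask with nearest-neighbour (so
#' the label set is preserved).
#'
#' @param image A [radiograph()] or matrix.
#' @param mask Integer mask aligned with `image`.
#' @param cfg A [preprocess_config()].
#' @param seed RNG seed for the parameter draw.
#' @return List with `image`, `mask` and the drawn `params`.
#' @export
augment <- function(image, mask, cfg = preprocess_config(), seed = 1L) {
  image <- as_radiograph(image)
  if (!all(dim(image$pixels) == dim(mask)))
    abort("image and mask must be aligned")
  d <- dim(mask)
  params <- with_seed(seed, list(
    scale = runif(1, cfg$scale_range[1L], cfg$scale_range[2L]),
    angle = runif(1, cfg$rotation_range_deg[1L], cfg$rotation_range_deg[2L]),
    translate = c(runif(1, -1, 1) * cfg$translation_max_frac * d[1L],
                  runif(1, -1, 1) * cfg$translation_max_frac * d[2L])))
  img <- affine_resample(image$pixels, params$angle, params$scale,
                         params$translate, "bilinear", fill = 0)
  msk <- affine_resample(mask, params$angle, params$scale, params$translate,
                         "nearest", fill = 0L)
  list(image = radiograph(img, image$spacing_mm, image$source_id),
       mask = msk, params = params)
}

#' Crop an image to the aortic region
#'
#' Returns the bounding box of the aorta mask expanded by a margin (clipped
#' at the image borders), with pixels outside the mask zeroed, plus the
#' offset needed to map stage-two predictions back into full-image
#' coordinates.
#'
#' @param image A [radiograph()] or matrix.
#' @param aorta_mask Logical or 0/1 matrix marking the aortic region.
#' @param margin_px Margin around the bounding box, default 5.
#' @return List with `image` (cropped `radiograph`), `offset` (0-based
#'   `(row, col)` of the crop origin) and `bbox` (half-open row/col ranges).
#' @export
crop_to_aorta <- function(image, aorta_mask, margin_px = 5L) {
  image <- as_radiograph(image)
  if (!any(aorta_mask != 0)) abort("empty aorta mask: nothing to crop")
  if (!all(dim(image$pixels) == dim(aorta_mask)))
    abort("image and aorta mask must be aligned")
  idx <- which(aorta_mask != 0, arr.ind = TRUE)
  r0 <- max(min(idx[, 1L]) - margin_px, 1L)
  r1 <- min(max(idx[, 1L]) + margin_px, nrow(aorta_mask))
  c0 <- max(min(idx[, 2L]) - margin_px, 1L)
  c1 <- min(max(idx[, 2L]) + margin_px, ncol(aorta_mask))
  px <- image$pixels
  px[aorta_mask == 0] <- 0
  out <- px[r0:r1, c0:c1, drop = FALSE]
  list(image = radiograph(out, image$spacing_mm, image$source_id),
       offset = c(row = r0 - 1L, col = c0 - 1L),
       bbox = list(rows = c(r0 - 1L, r1), cols = c(c0 - 1L, c1)))
}

#' Stage-one preprocessing chain
#'
#' Side crop, isotropic resize with symmetric padding, and intensity
#' normalization, in the configured order.
#'
#' @param image A [radiograph()] or matrix.
#' @param cfg A [preprocess_config()].
#' @return A normalized `radiograph` of the target shape.
#' @export
preprocess_image <- function(image, cfg = preprocess_config()) {
  image <- as_radiograph(image)
  if (cfg$crop_after_resize) {
    image <- resize_pad(image, cfg$target_shape)
    image <- crop_sides(image, cfg)
  } else {
    image <- crop_sides(image, cfg)
    image <- resize_pad(image, cfg$target_shape)
  }
  normalize_intensity(image)
}
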