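test_that("side cropping removes floored pixel counts from left and right", {
  img <- radiograph(matrix(runif(200 * 100), 200, 100))
  out <- crop_sides(img, preprocess_config())
  expect_equal(dim(out$pixels), c(200L, 50L))  # 100 - 40 - 10
  # the retained region is the contiguous middle-right block
  expect_equal(out$pixels, img$pixels[, 41:90])

  odd <- radiograph(matrix(runif(20 * 10), 20, 10))
  expect_equal(ncol(crop_sides(odd)$pixels), 5L)  # 10 - floor(4) - floor(1)

  noop <- preprocess_config(crop_left_frac = 0, crop_right_frac = 0)
  expect_equal(crop_sides(img, noop)$pixels, img$pixels)
  expect_error(preprocess_config(crop_left_frac = 0.7, crop_right_frac = 0.3),
               "sum to less than 1")
})

test_that("resize_pad reaches the exact target with isotropic scale and symmetric padding", {
  tgt <- c(517L, 576L)
  # same aspect ratio: pure 2x downscale, no padding
  big <- radiograph(matrix(runif(1034 * 1152), 1034, 1152), spacing_mm = 0.1)
  out <- resize_pad(big, tgt)
  expect_equal(dim(out$pixels), tgt)
  expect_equal(attr(out, "scale"), 0.5)
  expect_equal(unname(attr(out, "pad")), c(0L, 0L))
  expect_equal(out$spacing_mm, c(0.2, 0.2))

  # already at target: content unchanged, zero padding
  at <- radiograph(matrix(runif(prod(tgt)), tgt[1], tgt[2]))
  out2 <- resize_pad(at, tgt)
  expect_equal(out2$pixels, at$pixels)

  # square input pads the wider target axis symmetrically (within 1 px)
  sq <- radiograph(matrix(runif(100 * 100), 100, 100))
  out3 <- resize_pad(sq, tgt)
  expect_equal(dim(out3$pixels), tgt)
  pad <- attr(out3, "pad")
  total_pad <- tgt[2] - round(100 * attr(out3, "scale"))
  expect_true(abs(pad[["left"]] - total_pad / 2) <= 0.5)
  expect_true(all(out3$pixels[, seq_len(pad[["left"]])] == 0))
})

test_that("intensity normalization hits [0,1] exactly and is idempotent", {
  img <- radiograph(matrix(c(0, 10, 2, 7), 2, 2))
  out <- normalize_intensity(img)
  expect_equal(range(out$pixels), c(0, 1))
  expect_equal(out$pixels[1, 1], 0)
  expect_equal(out$pixels[2, 1], 1)

  # affine invariance: a*x + b (a > 0) normalizes identically
  x <- matrix(runif(400), 20, 20)
  n1 <- normalize_intensity(radiograph(x))$pixels
  n2 <- normalize_intensity(radiograph(3.7 * x + 11))$pixels
  expect_equal(n1, n2, tolerance = 1e-12)

  # the zero-mean intermediate really has mean zero
  centered <- x - mean(x)
  expect_equal(mean(centered), 0, tolerance = 1e-12)

  # idempotent
  expect_equal(normalize_intensity(radiograph(n1))$pixels, n1,
               tolerance = 1e-12)

  expect_warning(out <- normalize_intensity(radiograph(matrix(5, 3, 3))),
                 "constant")
  expect_true(all(out$pixels == 0.5))
})

test_that("augmentation applies one transform to both image and mask", {
  pc <- generate_phantom(tiny_spec64(coverage = coverage_spec(L2_ant = 0.5)))
  cfg <- preprocess_config()
  a <- augment(pc$image, pc$mask, cfg, seed = 11L)
  b <- augment(pc$image, pc$mask, cfg, seed = 11L)
  expect_identical(a$image$pixels, b$image$pixels)   # determinism
  expect_identical(a$mask, b$mask)
  # nearest-neighbour keeps the label set
  expect_true(all(unique(as.vector(a$mask)) %in%
                  unique(as.vector(pc$mask))))
  # identity ranges reproduce the input
  idcfg <- preprocess_config(scale_range = c(1, 1),
                             rotation_range_deg = c(0, 0),
                             translation_max_frac = 0)
  id <- augment(pc$image, pc$mask, idcfg, seed = 5L)
  expect_equal(id$mask, pc$mask)
  expect_equal(id$image$pixels, pc$image$pixels, tolerance = 1e-12)
})

test_that("augmentation preserves the six vertebral components of the phantom", {
  pc <- generate_phantom(phantom_spec())
  for (s in 1:5) {
    a <- augment(pc$image, pc$mask, preprocess_config(), seed = s)
    part <- extract_vertebral_components(a$mask)
    expect_equal(part$n, 6L)
  }
})

test_that("crop_to_aorta returns the masked bounding box and a usable offset", {
  pc <- generate_phantom(phantom_spec(coverage = coverage_spec(L3_ant = 0.6)))
  lb <- aac_labels()
  aorta <- matrix(pc$mask %in% lb[c("aorta", "calc_anterior",
                                    "calc_posterior")], nrow(pc$mask))
  cr <- crop_to_aorta(pc$image, aorta, margin_px = 0L)
  idx <- which(aorta, arr.ind = TRUE)
  expect_equal(dim(cr$image$pixels),
               c(diff(range(idx[, 1])) + 1L, diff(range(idx[, 2])) + 1L))
  expect_equal(unname(cr$offset),
               c(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L))
  # pixels outside the mask are zeroed
  sub <- aorta[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2])]
  expect_true(all(cr$image$pixels[!sub] == 0))

  # margin expands but clips at borders
  cr5 <- crop_to_aorta(pc$image, aorta, margin_px = 5L)
  expect_equal(nrow(cr5$image$pixels),
               min(max(idx[, 1]) + 5, nrow(aorta)) - max(min(idx[, 1]) - 5, 1) + 1L)

  # whole-image mask with margin 0 is the identity crop
  allm <- matrix(1, 4, 4)
  img4 <- radiograph(matrix(runif(16), 4, 4))
  expect_equal(crop_to_aorta(img4, allm, 0L)$image$pixels, img4$pixels)
  # single pixel
  one <- matrix(0, 4, 4); one[2, 3] <- 1
  expect_equal(dim(crop_to_aorta(img4, one, 0L)$image$pixels), c(1L, 1L))
  expect_error(crop_to_aorta(img4, matrix(0, 4, 4)), "empty")
})

test_that("the preprocessing chain is deterministic", {
  img <- radiograph(matrix(runif(300 * 200), 300, 200))
  cfg <- preprocess_config(target_shape = c(128L, 144L))
  a <- preprocess_image(img, cfg)
  b <- preprocess_image(img, cfg)
  expect_identical(a$pixels, b$pixels)
  expect_equal(dim(a$pixels), c(128L, 144L))
  expect_equal(range(a$pixels), c(0, 1))
})
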