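# Readers and writers: radiographs (PNG/TIFF/NIfTI with a JSON sidecar for
# pixel spacing and photometric interpretation), integer masks (lossless
# PNG or NIfTI round-trip), score tables (CSV) and YAML pipeline
# configuration.

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE)
  else list()
}

file_ext <- function(path) tolower(tools::file_ext(sub("\\.gz$", "", path)))

#' Read a radiograph from PNG, TIFF or NIfTI
#'
#' Grayscale pixel data are returned in `[0, 1]`; multi-channel images are
#' averaged. Pixel spacing comes from a JSON sidecar (`<path>.json`, field
#' `spacing_mm`), from the NIfTI header, or defaults to 0.14 mm. A sidecar
#' `photometric: "MONOCHROME1"` entry (inverted display convention) flips
#' intensities at read so that higher values always mean denser tissue.
#'
#' @param path Image path (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @param spacing_mm Optional override of the pixel spacing.
#' @return A [radiograph()].
#' @export
read_radiograph <- function(path, spacing_mm = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  ext <- file_ext(path)
  meta <- read_sidecar(path)
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    nii = as.array(RNifti::readNifti(path)),
    abort(sprintf("unsupported image format: .%s", ext)))
  if (length(dim(px)) == 3L) px <- apply(px, c(1L, 2L), mean)
  if (ext == "nii" && is.null(meta$spacing_mm) && is.null(spacing_mm)) {
    pd <- RNifti::pixdim(RNifti::readNifti(path))
    if (length(pd) >= 2L && all(pd[1:2] > 0)) spacing_mm <- pd[1:2]
  }
  if (identical(meta$photometric, "MONOCHROME1")) px <- max(px) - px
  radiograph(px,
             spacing_mm = spacing_mm %||% meta$spacing_mm %||% 0.14,
             source_id = meta$source_id %||%
               tools::file_path_sans_ext(basename(path)))
}

#' Write a radiograph
#'
#' TIFF output is 16-bit, PNG 8-bit, NIfTI float; intensities are clipped
#' to `[0, 1]` for the integer formats. A JSON sidecar records the pixel
#' spacing and source id.
#'
#' @param image A [radiograph()].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(image, path) {
  ext <- file_ext(path)
  px <- image$pixels
  if (ext %in% c("png", "tif", "tiff")) px <- pmin(pmax(px, 0), 1)
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L),
    nii = RNifti::writeNifti(RNifti::asNifti(px,
            pixdim = c(image$spacing_mm, 1)), path),
    abort(sprintf("unsupported image format: .%s", ext)))
  jsonlite::write_json(
    list(spacing_mm = image$spacing_mm, source_id = image$source_id),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write an integer multi-class mask
#'
#' PNG masks store the label integer in an 8-bit channel (lossless for
#' labels 0-255); NIfTI masks store integers directly. The label map is
#' written to the JSON sidecar and checked on read.
#'
#' @param mask Integer label matrix.
#' @param path Mask path (`.png` or `.nii`/`.nii.gz`).
#' @param labels Named label map, default [aac_labels()].
#' @return `write_mask` returns `path` invisibly; `read_mask` the integer
#'   matrix.
#' @export
write_mask <- function(mask, path, labels = aac_labels()) {
  mask <- validate_mask(mask, labels)
  ext <- file_ext(path)
  switch(ext,
    png = png::writePNG(mask / 255, path),
    nii = RNifti::writeNifti(RNifti::asNifti(mask, datatype = "int16"), path),
    abort(sprintf("unsupported mask format: .%s", ext)))
  jsonlite::write_json(list(labels = as.list(labels)), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, labels = aac_labels()) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  ext <- file_ext(path)
  meta <- read_sidecar(path)
  m <- switch(ext,
    png = round(png::readPNG(path) * 255),
    nii = as.array(RNifti::readNifti(path)),
    abort(sprintf("unsupported mask format: .%s", ext)))
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  if (!is.null(meta$labels)) labels <- unlist(meta$labels)
  validate_mask(m, labels)
}

#' Write / read a score table as CSV
#'
#' Columns: `case_id`, `L1_ant` .. `L4_post`, `total`, `severity` (plus any
#' extra columns such as `split` or `rater`).
#'
#' @param scores Tibble, e.g. from [score_cases()] or [generate_cohort()]
#'   (list-columns are dropped).
#' @param path CSV path.
#' @return `write_scores_csv` returns `path` invisibly; `read_scores_csv` a
#'   tibble.
#' @export
write_scores_csv <- function(scores, path) {
  flat <- scores[, !vapply(scores, is.list, logical(1)), drop = FALSE]
  write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_csv
#' @export
read_scores_csv <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a phantom case to disk
#'
#' Writes the image (16-bit TIFF by default), the mask (PNG) and a truth
#' row appended to a CSV by the caller.
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if needed).
#' @param stem File stem, default the case's source id.
#' @return Named character vector of the files written.
#' @export
write_phantom_case <- function(case, dir, stem = case$image$source_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img <- file.path(dir, paste0(stem, ".tiff"))
  msk <- file.path(dir, paste0(stem, "_mask.png"))
  write_radiograph(case$image, img)
  write_mask(case$mask, msk)
  c(image = img, mask = msk)
}
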