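#' Integer labels used in multi-class masks
#'
#' The default label map shared by the phantom generator, the segmentation
#' models and the scoring engine: 0 background, 1 vertebra, 2 aorta,
#' 3 anterior-wall calcification, 4 posterior-wall calcification,
#' 5 generic (wall-unassigned) calcification.
#'
#' @return Named integer vector.
#' @export
aac_labels <- function() {
  c(background = 0L, vertebra = 1L, aorta = 2L,
    calc_anterior = 3L, calc_posterior = 4L, calc = 5L)
}

#' Construct a radiograph
#'
#' A radiograph is a 2D grayscale pixel grid plus its physical pixel spacing.
#' Pixels are stored as a base matrix indexed `[row, col]` with row 1 at the
#' top (cranial end).
#'
#' @param pixels Numeric matrix of intensities.
#' @param spacing_mm Pixel spacing in mm, length-2 `(row, col)` or a scalar
#'   recycled to both axes. Default 0.14 mm, a typical detector pitch for
#'   lateral lumbar radiographs.
#' @param source_id Identifier string carried through the pipeline.
#' @return An object of class `radiograph`.
#' @export
radiograph <- function(pixels, spacing_mm = 0.14, source_id = "unknown") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    abort("`pixels` must have positive dimensions")
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 2L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    abort("`spacing_mm` must be strictly positive")
  structure(
    list(pixels = pixels, spacing_mm = spacing_mm,
         source_id = as.character(source_id)[1L]),
    class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %s: %d x %d px, spacing %.4g x %.4g mm, range [%.3g, %.3g]\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels),
              x$spacing_mm[1L], x$spacing_mm[2L],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.radiograph <- function(x) dim(x$pixels)

as_radiograph <- function(x, template = NULL, source_id = NULL) {
  if (inherits(x, "radiograph")) return(x)
  radiograph(x,
             spacing_mm = if (is.null(template)) 0.14 else template$spacing_mm,
             source_id = source_id %||%
               (if (is.null(template)) "unknown" else template$source_id))
}

#' Validate a multi-class mask
#'
#' Checks that a mask is an integer-valued matrix whose labels are a subset
#' of the given label map.
#'
#' @param mask Integer matrix.
#' @param labels Named integer label map, default [aac_labels()].
#' @return The mask, invisibly, as an integer matrix.
#' @export
validate_mask <- function(mask, labels = aac_labels()) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix")
  m <- mask
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(abs(mask - m) > 0))
    abort("`mask` must be integer-valued")
  extra <- setdiff(unique(as.vector(m)), unname(labels))
  if (length(extra))
    abort(sprintf("mask contains labels outside the label map: %s",
                  paste(extra, collapse = ", ")))
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based pixel-center coordinates of mask == value, as an n x 2 (row, col)
# matrix. Used throughout the geometry code.
label_coords <- function(mask, value) {
  idx <- which(mask == value)
  if (!length(idx)) return(matrix(numeric(0), ncol = 2L,
                                  dimnames = list(NULL, c("row", "col"))))
  cbind(row = (idx - 1L) %% nrow(mask),
        col = (idx - 1L) %/% nrow(mask))
}
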