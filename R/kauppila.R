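# Kauppila scoring engine: converts a multi-class mask (vertebrae, aorta,
# calcifications) into per-segment AAC scores, a 0-24 total and a severity
# category.
#
# The Kauppila system scores the anterior and posterior aortic wall adjacent
# to each of L1-L4 by the fraction of the wall's longitudinal extent that is
# calcified: 0 (none), 1 (< 1/3), 2 (1/3 to 2/3), 3 (>= 2/3). Level
# boundaries sit at the midpoints of the intervertebral spaces.

#' Kauppila segment score from a longitudinal coverage ratio
#'
#' Maps the fraction of a wall segment's longitudinal extent that is
#' calcified to the 0-3 Kauppila score: 0 for no calcification, 1 below 1/3,
#' 2 from 1/3 up to (but excluding) 2/3, and 3 from 2/3 upward. The 1/3 and
#' 2/3 boundaries are closed from below, so a ratio of exactly 1/3 scores 2
#' and exactly 2/3 scores 3.
#'
#' @param ratio Numeric vector of coverage ratios in `[0, 1]`.
#' @return Integer vector of scores in `0:3`.
#' @examples
#' score_from_ratio(c(0, 0.2, 0.5, 0.8))
#' @export
score_from_ratio <- function(ratio) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)))
    abort("`ratio` must be finite numeric")
  if (any(ratio < 0 | ratio > 1))
    abort("`ratio` must lie in [0, 1]")
  ifelse(ratio == 0, 0L,
         ifelse(ratio < 1 / 3, 1L,
                ifelse(ratio < 2 / 3, 2L, 3L)))
}

#' Severity category from a total Kauppila score
#'
#' @param total Integer vector of total scores in `0:24`.
#' @return Factor with levels `mild` (0-4), `moderate` (5-15), `severe`
#'   (16-24).
#' @export
severity_from_total <- function(total) {
  if (any(!is.finite(total)) || any(total < 0 | total > 24))
    abort("`total` must lie in [0, 24]")
  cut(total, breaks = c(-0.5, 4.5, 15.5, 24.5),
      labels = c("mild", "moderate", "severe"))
}

kauppila_segments <- function() {
  tidyr::expand_grid(level = paste0("L", 1:4),
                     wall = c("anterior", "posterior"))
}

#' Extract and order the six vertebral connected components
#'
#' Labels the vertebra class of a mask into 8-connected components, keeps the
#' six largest, and orders them cranial to caudal along the principal axis of
#' all vertebra pixels (topmost component = T12).
#'
#' @param mask Integer multi-class mask.
#' @param labels Label map, default [aac_labels()].
#' @param lenient If `TRUE`, fewer than six components is tolerated and the
#'   components found are ordered and named from the top; otherwise it is an
#'   error.
#' @return An object of class `vertebral_partition`: component pixel
#'   coordinates, centroids, the unit spine axis (pointing caudally), and the
#'   relabelled component matrix.
#' @export
extract_vertebral_components <- function(mask, labels = aac_labels(),
                                         lenient = FALSE) {
  mask <- validate_mask(mask, labels)
  vert <- mask == labels[["vertebra"]]
  if (!any(vert)) abort("no vertebra pixels in mask")
  lab <- cc_label(vert)
  sizes <- cc_sizes(lab)
  k <- length(sizes)
  if (k > 6L) {
    keep <- order(sizes, decreasing = TRUE)[1:6]
    warn(sprintf("dropping %d small vertebral component(s)", k - 6L))
    lab[!(lab %in% keep)] <- 0L
    lab <- match(lab, c(0L, sort(keep))) - 1L
    dim(lab) <- dim(mask)
    k <- 6L
  }
  if (k < 6L && !lenient)
    abort(sprintf("insufficient vertebral components: found %d, expected 6", k))

  coords_all <- label_coords(lab > 0L, TRUE)
  # principal axis of the whole column, oriented cranial -> caudal
  pc <- eigen(stats::cov(coords_all), symmetric = TRUE)$vectors[, 1L]
  if (pc[1L] < 0) pc <- -pc
  axis <- pc / sqrt(sum(pc^2))

  comps <- lapply(seq_len(k), function(i) label_coords(lab, i))
  centroids <- t(vapply(comps, colMeans, numeric(2)))
  ord <- order(centroids %*% axis)
  comps <- comps[ord]
  centroids <- centroids[ord, , drop = FALSE]
  # relabel matrix 1..k in cranio-caudal order
  relab <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_len(k)) relab[lab == ord[i]] <- i
  nm <- c("T12", "L1", "L2", "L3", "L4", "L5")[seq_len(k)]
  rownames(centroids) <- nm
  names(comps) <- nm

  structure(
    list(components = comps, centroids = centroids, spine_axis = axis,
         label_matrix = relab, n = k, dim = dim(mask)),
    class = "vertebral_partition")
}

#' @export
print.vertebral_partition <- function(x, ...) {
  cat(sprintf("<vertebral_partition> %d components, spine axis (%.3f, %.3f)\n",
              x$n, x$spine_axis[1L], x$spine_axis[2L]))
  if (!is.null(x$level_heights_px))
    cat("  level heights (px):",
        paste(sprintf("%s=%.1f", names(x$level_heights_px),
                      x$level_heights_px), collapse = ", "), "\n")
  invisible(x)
}

#' Compute vertebral level boundaries and level heights
#'
#' For each adjacent pair of vertebral components a separating straight line
#' is placed: its direction is perpendicular to the centroid-to-centroid
#' vector of the pair, and it is anchored at the midpoint of the
#' intervertebral gap (midway between the caudal edge of the upper vertebra
#' and the cranial edge of the lower one, measured along the pair axis).
#' Level heights for L1-L4 are the axial distances between consecutive
#' boundaries along the spine axis.
#'
#' @param partition A `vertebral_partition` from
#'   [extract_vertebral_components()].
#' @return The partition, augmented with `boundaries` (normals, offsets,
#'   anchors) and `level_heights_px`.
#' @export
compute_level_boundaries <- function(partition) {
  stopifnot(inherits(partition, "vertebral_partition"))
  k <- partition$n
  if (k < 2L) abort("need at least two vertebral components for boundaries")
  nb <- k - 1L
  normals <- matrix(NA_real_, nb, 2L)
  offsets <- numeric(nb)
  anchors <- matrix(NA_real_, nb, 2L)
  for (i in seq_len(nb)) {
    u <- partition$centroids[i + 1L, ] - partition$centroids[i, ]
    u <- u / sqrt(sum(u^2))
    a <- max(partition$components[[i]] %*% u)       # caudal edge of upper
    b <- min(partition$components[[i + 1L]] %*% u)  # cranial edge of lower
    t0 <- (a + b) / 2                               # gap midpoint
    cm <- (partition$centroids[i, ] + partition$centroids[i + 1L, ]) / 2
    normals[i, ] <- u
    offsets[i] <- t0
    anchors[i, ] <- cm + (t0 - sum(cm * u)) * u
  }
  nmp <- names(partition$components)
  rownames(normals) <- rownames(anchors) <- names(offsets) <-
    paste(nmp[-k], nmp[-1L], sep = "/")
  partition$boundaries <- list(normals = normals, offsets = offsets,
                               anchors = anchors)
  if (k == 6L) {
    ax <- partition$spine_axis
    h <- as.vector(diff(anchors %*% ax))  # boundary gaps = L1..L4 heights
    names(h) <- paste0("L", 1:4)
    partition$level_heights_px <- h
  }
  partition
}

# Assign arbitrary (row, col) coordinates to vertebral levels.
# Returns 0 for above T12/L1, 1..4 for L1..L4, 5 for below L4/L5.
# A pixel's level index is the number of boundaries it lies caudal to.
level_of_coords <- function(coords, partition) {
  if (is.null(partition$boundaries)) abort("boundaries not computed")
  if (!nrow(coords)) return(integer(0))
  b <- partition$boundaries
  S <- coords %*% t(b$normals) - rep(b$offsets, each = nrow(coords))
  as.integer(rowSums(S >= 0))
}

#' Partition the aorta by vertebral level
#'
#' Assigns each aorta pixel to the vertebral level (L1-L4) whose two boundary
#' half-planes contain it. Pixels cranial to the T12/L1 boundary or caudal to
#' the L4/L5 boundary are excluded from scoring.
#'
#' @param mask Multi-class mask (the aorta class is used; calcification
#'   pixels, which sit inside the aortic band, are included).
#' @param partition A `vertebral_partition` with boundaries.
#' @param labels Label map.
#' @return Tibble with columns `level`, `row`, `col` (one row per assigned
#'   aorta pixel).
#' @export
partition_aorta <- function(mask, partition, labels = aac_labels()) {
  mask <- validate_mask(mask, labels)
  aorta_ids <- labels[c("aorta", "calc_anterior", "calc_posterior", "calc")]
  coords <- label_coords(matrix(mask %in% aorta_ids, nrow(mask)), TRUE)
  if (!nrow(coords)) {
    warn("empty aorta mask; all level regions empty")
    return(tibble::tibble(level = character(0), row = numeric(0),
                          col = numeric(0)))
  }
  lev <- level_of_coords(coords, partition)
  keep <- lev >= 1L & lev <= 4L
  tibble::tibble(level = paste0("L", lev[keep]),
                 row = coords[keep, 1L], col = coords[keep, 2L])
}

#' Aortic centerline along the spine axis
#'
#' Treats the aorta as one entity and, for each axial position (projection
#' onto the spine axis, rounded to pixel bins), returns the midpoint of the
#' aorta's extent perpendicular to the axis. Axial gaps are filled by linear
#' interpolation.
#'
#' @param mask Multi-class mask (aorta plus embedded calcification classes).
#' @param partition A `vertebral_partition` (supplies the spine axis).
#' @param labels Label map.
#' @return A list with `s` (axial bin centers) and `q` (perpendicular
#'   centerline coordinate), plus the axis vectors; query it with
#'   [centerline_at()].
#' @export
aorta_centerline <- function(mask, partition, labels = aac_labels()) {
  mask <- validate_mask(mask, labels)
  aorta_ids <- labels[c("aorta", "calc_anterior", "calc_posterior", "calc")]
  coords <- label_coords(matrix(mask %in% aorta_ids, nrow(mask)), TRUE)
  if (!nrow(coords)) abort("empty aorta mask: no centerline")
  centerline_from_coords(coords, partition$spine_axis)
}

centerline_from_coords <- function(coords, axis) {
  perp <- c(-axis[2L], axis[1L])
  s <- as.vector(coords %*% axis)
  q <- as.vector(coords %*% perp)
  bin <- round(s)
  qmin <- tapply(q, bin, min)
  qmax <- tapply(q, bin, max)
  sb <- as.numeric(names(qmin))
  ordb <- order(sb)
  sb <- sb[ordb]
  qc <- ((qmin + qmax) / 2)[ordb]
  # fill axial gaps by linear interpolation onto the full bin range
  full <- seq(min(sb), max(sb))
  qfull <- stats::approx(sb, qc, xout = full, rule = 2)$y
  list(s = full, q = qfull, axis = axis, perp = perp)
}

#' Evaluate a centerline at axial positions
#'
#' @param centerline Result of [aorta_centerline()].
#' @param s Axial positions (projections onto the spine axis).
#' @return Perpendicular centerline coordinates (constant-extrapolated
#'   beyond the aorta's axial range).
#' @export
centerline_at <- function(centerline, s) {
  stats::approx(centerline$s, centerline$q, xout = s, rule = 2)$y
}

#' Classify calcification pixels as anterior or posterior wall
#'
#' Each 8-connected calcification component is assigned to the aortic wall on
#' the side of the centerline where the majority of its pixels lie:
#' components on the side away from the vertebral column are anterior-wall,
#' components on the vertebral side are posterior-wall. An exact 50/50 split
#' is assigned posterior.
#'
#' @param mask Multi-class mask.
#' @param centerline Result of [aorta_centerline()].
#' @param partition A `vertebral_partition`.
#' @param labels Label map.
#' @param trust_labels If `TRUE` and the mask already carries separate
#'   anterior/posterior calcification labels, those pass through unchanged.
#' @param min_component_px Calcification components smaller than this many
#'   pixels are dropped before classification (default 0: keep all).
#' @return Tibble with columns `row`, `col`, `wall`, `component`.
#' @export
classify_wall <- function(mask, centerline, partition, labels = aac_labels(),
                          trust_labels = FALSE, min_component_px = 0L) {
  mask <- validate_mask(mask, labels)
  calc_ids <- labels[c("calc_anterior", "calc_posterior", "calc")]
  has_walls <- any(mask == labels[["calc_anterior"]]) ||
    any(mask == labels[["calc_posterior"]])
  no_generic <- !any(mask == labels[["calc"]])
  if (trust_labels && has_walls && no_generic) {
    ant <- label_coords(mask, labels[["calc_anterior"]])
    pos <- label_coords(mask, labels[["calc_posterior"]])
    return(tibble::tibble(
      row = c(ant[, 1L], pos[, 1L]), col = c(ant[, 2L], pos[, 2L]),
      wall = rep(c("anterior", "posterior"), c(nrow(ant), nrow(pos))),
      component = NA_integer_))
  }
  calc <- matrix(mask %in% calc_ids, nrow(mask))
  if (!any(calc))
    return(tibble::tibble(row = numeric(0), col = numeric(0),
                          wall = character(0), component = integer(0)))
  lab <- cc_label(calc)
  sizes <- cc_sizes(lab)
  if (min_component_px > 0L) {
    drop <- which(sizes < min_component_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  coords <- label_coords(lab > 0L, TRUE)
  if (!nrow(coords))
    return(tibble::tibble(row = numeric(0), col = numeric(0),
                          wall = character(0), component = integer(0)))
  comp <- lab[lab > 0L]

  axis <- centerline$axis
  perp <- centerline$perp
  s <- as.vector(coords %*% axis)
  q <- as.vector(coords %*% perp)
  qc <- centerline_at(centerline, s)
  # which perpendicular direction points toward the vertebrae?
  vert_q <- mean(do.call(rbind, partition$components) %*% perp)
  vert_sign <- sign(vert_q - mean(centerline$q))
  if (vert_sign == 0) vert_sign <- 1
  vertebra_side <- (q - qc) * vert_sign > 0
  # majority vote per component; ties (exactly 50/50) go posterior
  frac_vert <- tapply(vertebra_side, comp, mean)
  wall_of <- ifelse(frac_vert >= 0.5, "posterior", "anterior")
  tibble::tibble(row = coords[, 1L], col = coords[, 2L],
                 wall = unname(wall_of[as.character(comp)]),
                 component = comp)
}

# union length of pixel-resolution intervals [s - 0.5, s + 0.5]
interval_union_length <- function(s) {
  if (!length(s)) return(0)
  s <- sort(s)
  lo <- s - 0.5
  hi <- s + 0.5
  # merge: a new interval starts where lo exceeds the running max hi
  starts <- c(TRUE, lo[-1L] > cummax(hi[-length(hi)]))
  grp <- cumsum(starts)
  sum(tapply(hi, grp, max) - tapply(lo, grp, min))
}

#' Measure per-segment longitudinal calcification coverage
#'
#' For each of the eight (level, wall) segments, projects that wall's
#' calcification pixels within the level onto the spine axis, merges the
#' pixel-resolution projection intervals, and divides the union length by the
#' level height. Multiple plaques aggregate as the union of their axial
#' projections, never the sum, so the ratio cannot exceed 1 by double
#' counting; ratios above 1 (possible when plaques overhang the aorta) are
#' clipped with a warning.
#'
#' @param walls Tibble from [classify_wall()].
#' @param partition A `vertebral_partition` with boundaries and level
#'   heights.
#' @return Tibble with one row per segment: `level`, `wall`,
#'   `calc_extent_px`, `level_height_px`, `ratio`.
#' @export
measure_coverage <- function(walls, partition) {
  if (is.null(partition$level_heights_px))
    abort("partition lacks level heights; call compute_level_boundaries()")
  segs <- kauppila_segments()
  if (nrow(walls)) {
    coords <- cbind(walls$row, walls$col)
    lev <- level_of_coords(coords, partition)
    walls <- walls |>
      dplyr::mutate(level = paste0("L", lev),
                    s = as.vector(coords %*% partition$spine_axis)) |>
      dplyr::filter(lev >= 1L, lev <= 4L)
  } else {
    walls <- dplyr::mutate(walls, level = character(0), s = numeric(0))
  }
  ext <- walls |>
    dplyr::group_by(.data$level, .data$wall) |>
    dplyr::summarise(calc_extent_px = interval_union_length(.data$s),
                     .groups = "drop")
  out <- segs |>
    dplyr::left_join(ext, by = c("level", "wall")) |>
    dplyr::mutate(
      calc_extent_px = dplyr::coalesce(.data$calc_extent_px, 0),
      level_height_px = unname(partition$level_heights_px[.data$level]),
      ratio = .data$calc_extent_px / .data$level_height_px)
  if (any(out$ratio > 1)) {
    warn("coverage ratio above 1 clipped to 1")
    out$ratio <- pmin(out$ratio, 1)
  }
  out
}

#' Score a multi-class mask with the Kauppila system
#'
#' Runs the full geometric scoring chain: extract and order the six
#' vertebral components, place level boundaries at intervertebral gap
#' midpoints, build the aortic centerline, classify calcifications by wall,
#' measure per-segment longitudinal coverage, and convert ratios to scores.
#'
#' @param mask Integer multi-class mask (see [aac_labels()]).
#' @param labels Label map.
#' @param trust_wall_labels Use anterior/posterior labels already present in
#'   the mask instead of geometric wall classification.
#' @param min_calc_component_px Minimum plaque component size in pixels
#'   (default 0; raise for noisy predicted masks).
#' @param lenient Tolerate missing components/aorta, scoring what is
#'   resolvable and accumulating warnings instead of failing.
#' @return An object of class `kauppila_result`: `$segments` (tibble with
#'   per-segment measurements and scores), `$total` (0-24), `$severity`
#'   (mild/moderate/severe) and `$warnings`.
#' @export
score_case <- function(mask, labels = aac_labels(), trust_wall_labels = FALSE,
                       min_calc_component_px = 0L, lenient = FALSE) {
  warnings <- character(0)
  part <- extract_vertebral_components(mask, labels, lenient = lenient)
  part <- compute_level_boundaries(part)
  if (is.null(part$level_heights_px))
    abort("cannot score: fewer than six vertebral components")

  calc_ids <- labels[c("calc_anterior", "calc_posterior", "calc")]
  any_calc <- any(mask %in% calc_ids)
  aorta_ids <- labels[c("aorta", "calc_anterior", "calc_posterior", "calc")]
  any_aorta <- any(mask %in% aorta_ids)

  if (!any_calc) {
    walls <- tibble::tibble(row = numeric(0), col = numeric(0),
                            wall = character(0), component = integer(0))
  } else {
    if (any(mask == labels[["aorta"]])) {
      cl <- aorta_centerline(mask, part, labels)
    } else {
      warnings <- c(warnings,
                    "no aorta class present; centerline taken from calcification pixels")
      warn(warnings[length(warnings)])
      coords <- label_coords(matrix(mask %in% calc_ids, nrow(mask)), TRUE)
      cl <- centerline_from_coords(coords, part$spine_axis)
    }
    walls <- classify_wall(mask, cl, part, labels,
                           trust_labels = trust_wall_labels,
                           min_component_px = min_calc_component_px)
  }
  if (!any_aorta) {
    warnings <- c(warnings, "empty aorta mask; all segment scores 0")
    warn(warnings[length(warnings)])
  }

  segments <- measure_coverage(walls, part) |>
    dplyr::mutate(score = score_from_ratio(.data$ratio))
  total <- sum(segments$score)
  structure(
    list(segments = segments, total = total,
         severity = as.character(severity_from_total(total)),
         partition = part, warnings = warnings),
    class = "kauppila_result")
}

#' @export
print.kauppila_result <- function(x, ...) {
  cat(sprintf("<kauppila_result> total %d/24, severity %s\n",
              x$total, x$severity))
  wide <- x$segments |>
    dplyr::mutate(seg = paste0(.data$level, "_",
                               substr(.data$wall, 1, 3))) |>
    dplyr::select("seg", "score")
  cat("  ", paste(sprintf("%s=%d", wide$seg, wide$score), collapse = " "),
      "\n")
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @rdname score_case
#' @param x A `kauppila_result`.
#' @param ... Unused.
#' @method tidy kauppila_result
#' @export
tidy.kauppila_result <- function(x, ...) {
  x$segments |>
    dplyr::select("level", "wall", "calc_extent_px", "level_height_px",
                  "ratio", "score")
}

#' @rdname score_case
#' @method glance kauppila_result
#' @export
glance.kauppila_result <- function(x, ...) {
  tibble::tibble(total = x$total, severity = x$severity,
                 n_segments = nrow(x$segments),
                 n_warnings = length(x$warnings))
}

# one-row wide form used by score tables and CSV output
result_row <- function(result, case_id = "case") {
  seg <- result$segments |>
    dplyr::mutate(seg = paste0(.data$level, "_",
                               ifelse(.data$wall == "anterior", "ant", "post")))
  wide <- setNames(as.list(seg$score), seg$seg)
  tibble::as_tibble(c(list(case_id = case_id), wide,
                      list(total = result$total, severity = result$severity)))
}

#' Score many masks into a tidy score table
#'
#' @param masks Named list of multi-class masks.
#' @param ... Passed to [score_case()].
#' @return Tibble with one row per case: `case_id`, `L1_ant` .. `L4_post`,
#'   `total`, `severity`.
#' @export
score_cases <- function(masks, ...) {
  ids <- names(masks) %||% sprintf("case%03d", seq_along(masks))
  purrr::map2_dfr(masks, ids, function(m, id) result_row(score_case(m, ...), id))
}
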