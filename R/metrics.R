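# Segmentation-quality metrics (Dice, volume similarity, Hausdorff
# distance) and score-agreement statistics (Kendall's W with tie
# correction, Pearson r with adjusted R2, Bland-Altman limits of
# agreement, severity confusion and accuracy).

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`. When both masks are empty the
#' convention is 1 (perfect agreement on absence), with a warning.
#'
#' @param a,b Logical or 0/1 matrices of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) abort("mask shapes differ")
  a <- a != 0; b <- b != 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) {
    warn("both masks empty: Dice = 1 by convention")
    return(1)
  }
  2 * sum(a & b) / (sa + sb)
}

#' Volume similarity
#'
#' `1 - ||A| - |B|| / (|A| + |B|)`: agreement in size only, insensitive to
#' location (two equal-sized disjoint masks score 1). Both empty gives 1 by
#' convention, with a warning.
#'
#' @inheritParams dice
#' @return Scalar in `[0, 1]`.
#' @export
volume_similarity <- function(a, b) {
  if (!all(dim(a) == dim(b))) abort("mask shapes differ")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0L) {
    warn("both masks empty: VS = 1 by convention")
    return(1)
  }
  1 - abs(sa - sb) / (sa + sb)
}

# boundary pixels: foreground with at least one 4-neighbour outside the mask
# (image border counts as outside)
boundary_coords <- function(m) {
  m <- m != 0
  d <- dim(m)
  pad <- matrix(FALSE, d[1L] + 2L, d[2L] + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L)] <- m
  inner <- pad[1:d[1L] + 1L, 1:d[2L] + 1L] &
    pad[1:d[1L], 1:d[2L] + 1L] & pad[1:d[1L] + 2L, 1:d[2L] + 1L] &
    pad[1:d[1L] + 1L, 1:d[2L]] & pad[1:d[1L] + 1L, 1:d[2L] + 2L]
  which(m & !inner, arr.ind = TRUE)
}

#' Hausdorff distance between two masks, in millimetres
#'
#' The symmetric maximum of directed Hausdorff distances between the masks'
#' boundary pixel sets, with Euclidean distances scaled by the pixel
#' spacing. `percentile < 100` gives the robust percentile variant of the
#' directed distances.
#'
#' @inheritParams dice
#' @param spacing_mm Pixel spacing `(row, col)` in mm (scalar recycled).
#' @param percentile Percentile of directed boundary distances (100 = exact
#'   maximum).
#' @return Distance in mm; `Inf` with a warning if either mask is empty.
#' @export
hausdorff <- function(a, b, spacing_mm = 1, percentile = 100) {
  if (!all(dim(a) == dim(b))) abort("mask shapes differ")
  if (!any(a != 0) || !any(b != 0)) {
    warn("empty mask: Hausdorff distance undefined, returning Inf")
    return(Inf)
  }
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 2L)
  pa <- boundary_coords(a); pb <- boundary_coords(b)
  dr <- outer(pa[, 1L], pb[, 1L], `-`) * spacing_mm[1L]
  dc <- outer(pa[, 2L], pb[, 2L], `-`) * spacing_mm[2L]
  d2 <- dr^2 + dc^2
  dir_ab <- sqrt(apply(d2, 1L, min))
  dir_ba <- sqrt(apply(d2, 2L, min))
  if (percentile >= 100) max(max(dir_ab), max(dir_ba))
  else max(quantile(dir_ab, percentile / 100),
           quantile(dir_ba, percentile / 100))
}

#' Segmentation metrics for each class of two multi-class masks
#'
#' @param pred,ref Integer multi-class masks.
#' @param labels Named label map (background is skipped).
#' @param spacing_mm Pixel spacing for the Hausdorff distance.
#' @return Tibble with columns `class`, `dsc`, `vs`, `hd_mm`.
#' @export
segmentation_metrics <- function(pred, ref, labels = aac_labels(),
                                 spacing_mm = 1) {
  labels <- labels[names(labels) != "background"]
  present <- vapply(labels, function(v) any(pred == v) || any(ref == v),
                    logical(1))
  purrr::map_dfr(names(labels)[present], function(nm) {
    a <- pred == labels[[nm]]
    b <- ref == labels[[nm]]
    tibble::tibble(class = nm, dsc = dice(a, b), vs = volume_similarity(a, b),
                   hd_mm = hausdorff(a, b, spacing_mm))
  })
}

#' Kendall's coefficient of concordance with tie correction
#'
#' Agreement among `m` raters each ranking the same `n` items, using
#' mid-ranks for ties: `W = 12 S / (m^2 (n^3 - n) - m * sum(T_j))` where `S`
#' is the sum of squared deviations of the item rank sums and
#' `T_j = sum(t^3 - t)` over the tie groups of rater `j`.
#'
#' @param ratings Numeric matrix, `n` items x `m` raters (ordinal scores).
#' @return Scalar in `[0, 1]`, or `NA` with a warning if every rater ties
#'   all items (W undefined).
#' @export
kendall_w <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); m <- ncol(ratings)
  if (n < 2L || m < 2L) abort("need at least 2 items and 2 raters")
  R <- apply(ratings, 2L, rank)  # mid-ranks for ties
  Ri <- rowSums(R)
  S <- sum((Ri - mean(Ri))^2)
  Tj <- apply(ratings, 2L, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })
  denom <- m^2 * (n^3 - n) - m * sum(Tj)
  if (denom <= 0) {
    warn("all items tied for every rater: Kendall's W undefined")
    return(NA_real_)
  }
  12 * S / denom
}

#' Pearson correlation and adjusted R-squared
#'
#' Standard Pearson `r` plus `adj R2 = 1 - (1 - r^2)(n - 1)/(n - p - 1)`
#' for a simple regression of one score on the other (`p = 1` predictor by
#' default).
#'
#' @param x,y Paired numeric vectors (`n >= 3`, nonzero variance).
#' @param p Number of predictors in the underlying regression.
#' @return Tibble with `r`, `adj_r2`, `n`.
#' @export
pearson_adj_r2 <- function(x, y, p = 1L) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired")
  n <- length(x)
  if (n < 3L) abort("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance input")
  r <- cor(x, y)
  tibble::tibble(r = r, adj_r2 = 1 - (1 - r^2) * (n - 1) / (n - p - 1), n = n)
}

#' Bland-Altman agreement analysis
#'
#' Paired-difference summary of `test - ref`: bias (mean difference), 95%
#' limits of agreement `bias +/- 1.96 sd` (sample standard deviation), and
#' the 95% CI of the bias `bias +/- 1.96 sd / sqrt(n)`.
#'
#' @param test,ref Paired numeric vectors, `n >= 2`.
#' @return Object of class `bland_altman` (also a one-row tibble) with
#'   columns `bias`, `loa_low`, `loa_high`, `bias_ci_low`, `bias_ci_high`,
#'   `sd_diff`, `n`.
#' @export
bland_altman <- function(test, ref) {
  if (length(test) != length(ref)) abort("`test` and `ref` must be paired")
  n <- length(test)
  if (n < 2L) abort("need at least 2 pairs")
  d <- test - ref
  bias <- mean(d)
  s <- sd(d)
  out <- tibble::tibble(
    bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    bias_ci_low = bias - 1.96 * s / sqrt(n),
    bias_ci_high = bias + 1.96 * s / sqrt(n),
    sd_diff = s, n = n)
  attr(out, "differences") <- d
  attr(out, "means") <- (test + ref) / 2
  class(out) <- c("bland_altman", class(out))
  out
}

#' Severity confusion matrix and overall accuracy
#'
#' @param pred,ref Severity labels (`mild`/`moderate`/`severe`), same
#'   length.
#' @return List with `confusion` (3x3 table, rows = reference) and
#'   `accuracy` (trace / total).
#' @export
severity_agreement <- function(pred, ref) {
  if (length(pred) != length(ref)) abort("`pred` and `ref` must be paired")
  lv <- c("mild", "moderate", "severe")
  if (!all(pred %in% lv) || !all(ref %in% lv))
    abort("severity labels must be mild/moderate/severe")
  pred <- factor(pred, lv); ref <- factor(ref, lv)
  cm <- table(reference = ref, predicted = pred)
  list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm))
}

#' Full score-agreement report between two score tables
#'
#' Combines the agreement statistics used to compare automatic and
#' reference Kauppila scores: Kendall's W on the totals (two raters),
#' Pearson r and adjusted R2, Bland-Altman bias with 95% CI and limits of
#' agreement, and the severity confusion matrix with overall accuracy.
#'
#' @param pred,ref Score tables (tibbles with at least `total` and
#'   `severity`, e.g. from [score_cases()]), or numeric vectors of totals
#'   (severity then derived via [severity_from_total()]).
#' @return Object of class `aac_agreement`.
#' @export
agreement_report <- function(pred, ref) {
  get_tot <- function(x) if (is.numeric(x)) x else x$total
  get_sev <- function(x) {
    if (is.numeric(x)) as.character(severity_from_total(x))
    else as.character(x$severity)
  }
  tp <- get_tot(pred); tr <- get_tot(ref)
  sev <- severity_agreement(get_sev(pred), get_sev(ref))
  structure(
    list(kendall_w = kendall_w(cbind(tp, tr)),
         pearson = pearson_adj_r2(tp, tr),
         bland_altman = bland_altman(tp, tr),
         confusion = sev$confusion,
         accuracy = sev$accuracy,
         n = length(tp)),
    class = "aac_agreement")
}

#' @export
print.aac_agreement <- function(x, ...) {
  ba <- x$bland_altman
  cat(sprintf("<aac_agreement> n = %d\n", x$n))
  cat(sprintf("  Kendall W %.3f | Pearson r %.3f (adj R2 %.3f)\n",
              x$kendall_w, x$pearson$r, x$pearson$adj_r2))
  cat(sprintf("  bias %.2f (95%% CI %.2f to %.2f), LoA %.2f to %.2f\n",
              ba$bias, ba$bias_ci_low, ba$bias_ci_high,
              ba$loa_low, ba$loa_high))
  cat(sprintf("  severity accuracy %.3f\n", x$accuracy))
  invisible(x)
}

#' @rdname agreement_report
#' @param x An `aac_agreement`.
#' @param ... Unused.
#' @method tidy aac_agreement
#' @export
tidy.aac_agreement <- function(x, ...) {
  ba <- x$bland_altman
  tibble::tibble(
    statistic = c("kendall_w", "pearson_r", "adj_r2", "bias", "bias_ci_low",
                  "bias_ci_high", "loa_low", "loa_high", "severity_accuracy"),
    value = c(x$kendall_w, x$pearson$r, x$pearson$adj_r2, ba$bias,
              ba$bias_ci_low, ba$bias_ci_high, ba$loa_low, ba$loa_high,
              x$accuracy))
}

#' @rdname agreement_report
#' @method glance aac_agreement
#' @export
glance.aac_agreement <- function(x, ...) {
  ba <- x$bland_altman
  tibble::tibble(kendall_w = x$kendall_w, pearson_r = x$pearson$r,
                 adj_r2 = x$pearson$adj_r2, bias = ba$bias,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 severity_accuracy = x$accuracy, n = x$n)
}
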