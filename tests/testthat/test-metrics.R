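test_that("Dice and volume similarity match hand-counted examples", {
  a <- matrix(0, 5, 5); a[1:2, 1:2] <- 1           # 4 px
  b <- matrix(0, 5, 5); b[2:3, 1:2] <- 1           # 4 px, overlap 2
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, matrix(0, 5, 5) + (a == 0)), 0)   # disjoint
  expect_equal(dice(a, b), dice(b, a))

  expect_equal(volume_similarity(a, b), 1)          # equal sizes, any overlap
  c30 <- matrix(0, 10, 10); c30[1:3, 1:10] <- 1     # 30 px
  c10 <- matrix(0, 10, 10); c10[10, 1:10] <- 1      # 10 px
  expect_equal(volume_similarity(c30, c10), 0.5)    # 1 - 20/40
  expect_equal(volume_similarity(c30, matrix(0, 10, 10)), 0)
  expect_warning(expect_equal(dice(matrix(0, 2, 2), matrix(0, 2, 2)), 1),
                 "empty")
})

test_that("Hausdorff distance scales with pixel spacing and translation", {
  a <- matrix(0, 10, 10); a[5, 2] <- 1
  b <- matrix(0, 10, 10); b[5, 5] <- 1
  expect_equal(hausdorff(a, b, spacing_mm = 2), 6)   # 3 px * 2 mm
  expect_equal(hausdorff(a, a, 1), 0)
  expect_equal(hausdorff(a, b, 1), hausdorff(b, a, 1))

  # translation property for a compact blob
  blob <- matrix(0, 20, 20); blob[5:8, 5:8] <- 1
  shifted <- matrix(0, 20, 20); shifted[9:12, 5:8] <- 1
  expect_equal(hausdorff(blob, shifted, 1), 4)
  expect_warning(expect_equal(hausdorff(blob, matrix(0, 20, 20), 1), Inf),
                 "empty")
})

test_that("Hausdorff agrees with a brute-force all-pairs oracle on random masks", {
  brute_hd <- function(a, b) {
    pa <- which(a != 0, arr.ind = TRUE); pb <- which(b != 0, arr.ind = TRUE)
    # oracle: boundary via per-pixel neighbour scan, then direct max-min loops
    is_bnd <- function(m, p) {
      r <- p[1]; c <- p[2]
      nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
      any(apply(nb, 1, function(q)
        q[1] < 1 || q[1] > nrow(m) || q[2] < 1 || q[2] > ncol(m) ||
          m[q[1], q[2]] == 0))
    }
    pa <- pa[apply(pa, 1, function(p) is_bnd(a, p)), , drop = FALSE]
    pb <- pb[apply(pb, 1, function(p) is_bnd(b, p)), , drop = FALSE]
    dmin_a <- apply(pa, 1, function(p)
      min(sqrt((p[1] - pb[, 1])^2 + (p[2] - pb[, 2])^2)))
    dmin_b <- apply(pb, 1, function(p)
      min(sqrt((p[1] - pa[, 1])^2 + (p[2] - pa[, 2])^2)))
    max(max(dmin_a), max(dmin_b))
  }
  set.seed(31)
  for (k in 1:8) {
    a <- matrix(0, 15, 15); b <- matrix(0, 15, 15)
    a[sample(225, 30)] <- 1; b[sample(225, 30)] <- 1
    expect_equal(hausdorff(a, b, 1), brute_hd(a, b),
                 label = sprintf("random mask pair %d", k))
    # triangle inequality spot check with a third mask
    cm <- matrix(0, 15, 15); cm[sample(225, 30)] <- 1
    expect_lte(hausdorff(a, b, 1),
               hausdorff(a, cm, 1) + hausdorff(cm, b, 1) + 1e-9)
  }
})

test_that("Kendall's W handles perfect agreement, reversal and ties", {
  expect_equal(kendall_w(cbind(1:5, 1:5)), 1)
  expect_equal(kendall_w(cbind(c(10, 20, 30), c(1, 2, 3))), 1)  # same ranking
  # m = 2 exactly reversed rankings of n = 3 distinct items:
  # rank sums all equal -> S = 0 -> W = 0
  expect_equal(kendall_w(cbind(c(1, 2, 3), c(3, 2, 1))), 0)
  # permutation invariance
  r <- cbind(c(0, 3, 7, 12, 24), c(1, 2, 9, 14, 20), c(0, 4, 8, 11, 23))
  pi <- sample(5)
  expect_equal(kendall_w(r), kendall_w(r[pi, , drop = FALSE]))
  expect_true(kendall_w(r) >= 0 && kendall_w(r) <= 1)
  # all tied everywhere: undefined
  expect_warning(w <- kendall_w(matrix(2, 4, 3)), "undefined")
  expect_true(is.na(w))
})

test_that("Kendall's W with ties matches the independent vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(17)
  for (k in 1:5) {
    r <- matrix(sample(0:6, 36, replace = TRUE), 12, 3)  # heavy ties
    if (any(apply(r, 2, function(x) length(unique(x))) == 1)) next
    vg <- vegan::kendall.global(r)  # raters as columns = variables
    expect_equal(kendall_w(r), unname(vg$Concordance_analysis["W", 1]),
                 tolerance = 1e-10, label = sprintf("tied matrix %d", k))
  }
})

test_that("Pearson r and adjusted R2 follow the standard formulas", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_adj_r2(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_adj_r2(x, 2 * x + 1)$adj_r2, 1)
  expect_equal(pearson_adj_r2(x, -x)$r, -1)
  # hand-computed n = 4 example
  y <- c(2, 1, 4, 3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_adj_r2(x, y)
  expect_equal(res$r, r_hand)
  expect_equal(res$adj_r2, 1 - (1 - r_hand^2) * 3 / 2)
  # cross-check against lm()
  fit <- summary(lm(y ~ x))
  expect_equal(res$adj_r2, fit$adj.r.squared, tolerance = 1e-12)
  expect_error(pearson_adj_r2(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("Bland-Altman bias, limits and CI match closed forms", {
  expect_equal(bland_altman(1:5, 1:5)$bias, 0)
  expect_equal(bland_altman(1:5, 1:5)$loa_low, 0)
  ba2 <- bland_altman(c(3, 4, 5), c(1, 2, 3))   # constant +2 offset
  expect_equal(ba2$bias, 2)
  expect_equal(c(ba2$loa_low, ba2$loa_high), c(2, 2))
  # d = {-1, 1}: sd = sqrt(2), LoA = 0 +/- 1.96*sqrt(2)
  ba3 <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(ba3$bias, 0)
  expect_equal(ba3$loa_high, 1.96 * sqrt(2))
  expect_equal(ba3$bias_ci_high, 1.96 * sqrt(2) / sqrt(2))
  expect_true(ba3$loa_low <= ba3$bias && ba3$bias <= ba3$loa_high)
})

test_that("Bland-Altman limits cover about 95% of large normal samples", {
  set.seed(5)
  ref <- rnorm(4000, 10, 3)
  test <- ref + rnorm(4000, 0.5, 1)
  ba <- bland_altman(test, ref)
  d <- test - ref
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_gt(cover, 0.935)
  expect_lt(cover, 0.965)
})

test_that("severity agreement counts the confusion matrix and accuracy", {
  ref <- c("mild", "mild", "moderate", "severe", "severe")
  pred <- c("mild", "moderate", "moderate", "severe", "mild")
  sa <- severity_agreement(pred, ref)
  expect_equal(sa$accuracy, 3 / 5)
  expect_equal(sum(sa$confusion), 5)
  expect_equal(unname(rowSums(sa$confusion)), c(2, 1, 2))
  expect_equal(severity_agreement(ref, ref)$accuracy, 1)
  expect_equal(severity_agreement(rev(ref), ref)$accuracy, 1 / 5)
  # hand-built 10-case vector with 7 matches
  r10 <- rep(c("mild", "moderate", "severe"), c(4, 3, 3))
  p10 <- r10; p10[c(1, 5, 9)] <- c("severe", "mild", "mild")
  expect_equal(severity_agreement(p10, r10)$accuracy, 0.7)
})

test_that("agreement_report combines the statistics consistently", {
  pred <- c(0, 3, 10, 17, 24, 5, 2, 12)
  ref <- c(1, 3, 9, 20, 24, 4, 2, 13)
  rep <- agreement_report(pred, ref)
  expect_equal(rep$pearson$r, cor(pred, ref))
  expect_equal(rep$bland_altman$bias, mean(pred - ref))
  expect_equal(rep$kendall_w, kendall_w(cbind(pred, ref)))
  g <- glance(rep)
  expect_equal(g$n, 8L)
  td <- tidy(rep)
  expect_equal(td$value[td$statistic == "bias"], mean(pred - ref))
})
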