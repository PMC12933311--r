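test_that("frame differences are absolute, symmetric, and convert to mm", {
  a <- c(0, 2, 4.5, 7)
  expect_equal(frame_differences(a, a), rep(0, 4))
  expect_equal(frame_differences(a + 2, a), rep(2, 4))
  expect_equal(median(frame_differences(a + 2, a)) * 0.2, 0.4)
  expect_equal(frame_differences(a, a + 2), frame_differences(a + 2, a))
  da <- data.frame(ivus_frame = 0:3, oct_frame_continuous = a)
  db <- data.frame(ivus_frame = 0:2, oct_frame_continuous = a[1:3])
  expect_error(frame_differences(da, db), "same IVUS frames")
})

test_that("angle differences are circular and bounded by 180", {
  expect_equal(angle_differences(350, 10), 20)
  expect_equal(angle_differences(10, 350), 20)
  expect_equal(angle_differences(123, 123), 0)
  expect_equal(angle_differences(0, 180), 180)
  set.seed(31)
  x <- runif(50, 0, 360); y <- runif(50, 0, 360)
  expect_true(all(angle_differences(x, y) >= 0 & angle_differences(x, y) <= 180))
})

test_that("Lin's CCC matches its closed form under a constant offset", {
  set.seed(37)
  x <- rnorm(200, 5, 2)
  expect_equal(lin_ccc(x, x), 1)
  expect_equal(lin_ccc(x - mean(x), -(x - mean(x))), -1)
  for (cc in c(0.5, 2, 10)) {
    s2 <- mean((x - mean(x))^2)            # population variance
    expect_equal(lin_ccc(x, x + cc), 2 * s2 / (2 * s2 + cc^2),
                 tolerance = 1e-12)
  }
  expect_error(lin_ccc(rep(1, 5), rep(2, 5)), "constant")
})

test_that("CCC never exceeds the Pearson correlation in magnitude", {
  set.seed(41)
  for (i in 1:25) {
    x <- rnorm(30); y <- 2 * x + rnorm(30) + runif(1, -3, 3)
    expect_lte(abs(lin_ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
})

test_that("Spearman correlation: monotone transforms, reversal, tie mid-ranks", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_r(x, exp(x)), 1)
  expect_equal(spearman_r(x, -x), -1)
  # tie case checked against explicit mid-rank Pearson computation
  a <- c(1, 2, 2, 3, 5)
  b <- c(2, 1, 4, 4, 6)
  ra <- c(1, 2.5, 2.5, 4, 5); rb <- c(2, 1, 3.5, 3.5, 5)
  expect_equal(spearman_r(a, b),
               sum((ra - 3) * (rb - 3)) /
                 sqrt(sum((ra - 3)^2) * sum((rb - 3)^2)))
  expect_error(spearman_r(rep(1, 5), 1:5), "constant")
})

test_that("Williams Index: symmetric case, direct evaluation, invariances", {
  # all three pairwise disagreements equal -> WI = 1
  m <- rep(0, 4); e1 <- c(2, 2, -2, -2); e2 <- c(2, -2, 2, -2)
  expect_equal(williams_index(m, e1, e2)$wi, 1)
  # D(M,E1)=1, D(M,E2)=3, D(E1,E2)=2 -> WI = 2*(1/1 + 1/3)/2 = 4/3
  res <- williams_index(c(0, 0), c(1, 1), c(3, 3))
  expect_equal(res$wi, 4 / 3)
  expect_equal(res$d_experts, 2)
  # model strictly closer to both experts than they are to each other
  set.seed(43)
  e1 <- rnorm(50); e2 <- e1 + rnorm(50, 0, 2); m <- (e1 + e2) / 2
  expect_gt(williams_index(m, e1, e2)$wi, 1)
  # invariant to relabeling the experts and to frame permutations
  w12 <- williams_index(m, e1, e2, groups = rep(1:5, each = 10))
  w21 <- williams_index(m, e2, e1, groups = rep(1:5, each = 10))
  expect_equal(w12$wi, w21$wi)
  expect_equal(w12$ci, w21$ci)
  perm <- sample(50)
  expect_equal(williams_index(m[perm], e1[perm], e2[perm])$wi, w12$wi)
  expect_error(williams_index(m, m, e2), "zero")
})

test_that("Williams Index jackknife CI brackets the estimate", {
  set.seed(47)
  e1 <- rnorm(60); e2 <- e1 + rnorm(60); m <- e1 + rnorm(60)
  g <- rep(1:6, each = 10)
  res <- williams_index(m, e1, e2, groups = g)
  expect_lt(res$ci[1], res$ci[2])
  expect_true(res$ci[1] < res$wi && res$wi < res$ci[2])
  # circular kernel stays defined for angle series
  resc <- williams_index(m * 40 %% 360, e1 * 40 %% 360, e2 * 40 %% 360,
                         groups = g, circular = TRUE)
  expect_gt(resc$wi, 0)
})

test_that("Bland-Altman bias and limits behave under shifts", {
  set.seed(53)
  x <- rnorm(40)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$lower, 0)
  expect_equal(ba0$upper, 0)
  ba <- bland_altman(x, x - 1.5)
  expect_equal(ba$bias, 1.5)
  y <- x + rnorm(40)
  bay <- bland_altman(x, y)
  expect_equal(bay$upper - bay$bias, bay$bias - bay$lower)
  expect_equal(bay$upper - bay$lower, 2 * 1.96 * sd(x - y))
})

test_that("Wilcoxon signed-rank: exact p equals sign enumeration, ties handled", {
  set.seed(59)
  for (i in 1:10) {
    x <- rnorm(8); y <- x + rnorm(8, 0.5)
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$p_value, wilcoxon_enumeration(x, y), tolerance = 1e-12)
    expect_equal(res$method, "exact")
  }
  # with tied absolute differences (mid-ranks)
  x <- c(5, 3, 8, 1, 9, 2, 7, 4)
  y <- c(4, 5, 6, 2, 5, 1, 5, 2)   # |d| has ties
  expect_equal(wilcoxon_signed_rank(x, y)$p_value, wilcoxon_enumeration(x, y),
               tolerance = 1e-12)
})

test_that("Wilcoxon agrees with stats::wilcox.test where both are exact", {
  set.seed(61)
  x <- rnorm(12); y <- x + rnorm(12, 0.3)   # continuous: no ties, no zeros
  res <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # large n: normal approximation with continuity correction
  x <- rnorm(60); y <- x + rnorm(60, 0.2)
  res <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("Wilcoxon error paths and symmetry", {
  x <- rnorm(10)
  expect_error(wilcoxon_signed_rank(x, x), "zero")
  expect_error(wilcoxon_signed_rank(1:5, c(2, 3, 4, 5, 6)), "at least 6")
  y <- x + rnorm(10)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcoxon_signed_rank(y, x)$p_value)
})

test_that("agreement and observer reports assemble the expected summaries", {
  set.seed(67)
  n <- 40
  truthy <- cumsum(runif(n, 1.5, 3.5))
  mk <- function(noise, rot_noise) {
    data.frame(ivus_frame = 0:(n - 1),
               oct_frame_continuous = truthy + rnorm(n, 0, noise),
               rotation_deg = (90 + rnorm(n, 0, rot_noise)) %% 360)
  }
  e1 <- mk(2, 8); e2 <- mk(2, 8); m <- mk(1, 4)
  rep1 <- agreement_report(m, e1)
  expect_s3_class(rep1, "agreement_report")
  expect_equal(rep1$median_frame_diff_mm, rep1$median_frame_diff * 0.2)
  expect_true(rep1$ccc > 0.9 && rep1$ccc <= 1)
  expect_true(rep1$median_angle_diff_deg >= 0)
  obs <- observer_report(m, e1, e2, groups = rep(1:4, each = 10))
  expect_s3_class(obs, "observer_report")
  expect_gt(obs$wi_frames$wi, 0)
  expect_gt(obs$wi_angles$wi, 0)
  expect_output(print(obs), "Williams Index")
})
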