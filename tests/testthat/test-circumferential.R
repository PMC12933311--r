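test_that("circular profile: constant radius, branch binning, calcium passthrough", {
  f <- frame("IVUS", 0, 0, TRUE, lumen = regular_polygon(90, 2))
  p <- circular_profile(f)
  expect_true(all(abs(p$radius - 2) < 1e-2))
  expect_equal(p$branch, numeric(180))
  expect_equal(p$calc, numeric(180))
  # a 1x1 box centered at 90 degrees from the centroid lands in bin 46
  # (0-based bin 45 covers [90, 92))
  fb <- frame("IVUS", 0, 0, TRUE, lumen = regular_polygon(90, 2),
              branches = branch_box(0, 1.5, 1, 1))
  pb <- circular_profile(fb)
  expect_equal(which(pb$branch > 0), 46)
  expect_equal(pb$branch[46], 1)
})

test_that("rotating frame annotations shifts all profile channels equally", {
  calc <- integer(180); calc[20:40] <- 1L
  f <- frame("OCT", 0, 0, TRUE, lumen = ellipse_polygon(2, 1.2, n = 360),
             branches = branch_box(1.5, 0.3, 0.5, 0.5), calcium = calc)
  pb <- pullback("OCT", list(f, frame("OCT", 1, 0.2, TRUE,
                                      regular_polygon(90, 2))), 0.2)
  base <- circular_profile(pb$frames[[1]])
  for (k in c(7, 45)) {
    rot <- rotate_pullback(pb, 2 * k)
    shifted <- circular_profile(rot$frames[[1]])
    expect_equal(shifted$radius, ivoctreg:::rotate_bins(base$radius, k),
                 tolerance = 1e-6)
    expect_equal(shifted$branch, ivoctreg:::rotate_bins(base$branch, k),
                 tolerance = 1e-9)
    expect_equal(shifted$calc, ivoctreg:::rotate_bins(base$calc, k))
  }
})

test_that("ncc handles perfect, inverted and constant inputs", {
  a <- sin(1:180 / 7) + 0.2
  expect_equal(ncc(a, a), 1)
  expect_equal(ncc(a - mean(a), -(a - mean(a))), -1)
  expect_equal(ncc(rep(2, 180), a), 0)
  expect_equal(ncc(a, rep(0, 180)), 0)
  expect_error(ncc(1:5, 1:6), "equal length")
})

test_that("rotation cost row finds constructed shifts and is shift-equivariant", {
  p <- test_profile()
  self <- rotation_cost_row(p, p)
  expect_equal(which.min(self), 1)            # zero rotation
  expect_lt(min(self), 1e-9)
  expect_true(all(self >= 0 & self <= 2))
  # OCT constructed as IVUS seen under a 40-degree catheter rotation
  po <- shift_profile(p, 20)
  row <- rotation_cost_row(p, po)
  expect_equal(which.min(row), 21)            # k = 20 -> 40 degrees
  # exhaustive shift oracle: equivariance of the whole row
  for (k in c(5, 77)) {
    rk <- rotation_cost_row(p, shift_profile(p, k))
    expect_equal(rk, ivoctreg:::rotate_bins(self, k), tolerance = 1e-9)
  }
})

test_that("rotation cost is invariant to a common radius offset (mean removal)", {
  p <- test_profile()
  po <- shift_profile(p, 13)
  p2 <- p; p2$radius <- p$radius + 5
  po2 <- po; po2$radius <- po$radius + 5
  expect_equal(rotation_cost_row(p, po), rotation_cost_row(p2, po2),
               tolerance = 1e-9)
})

test_that("a near-circular radius channel is treated as uninformative", {
  p <- test_profile()
  p$radius <- 1.5 + 1e-4 * cos(2 * ((0:179) * 2 + 1) * pi / 180)
  po <- shift_profile(p, 30)
  row <- rotation_cost_row(p, po)
  # only branch + calc inform: minimum cost is 1/3 (radius contributes 0)
  expect_equal(min(row), 1 / 3, tolerance = 1e-9)
  expect_equal(which.min(row), 31)
})

test_that("landmark pairs require the feature in both modalities, with fallback", {
  mk <- function(modality, idx, branch = FALSE, calc = FALSE, ecc = 0) {
    calcium <- integer(180); if (calc) calcium[1:40] <- 1L
    frame(modality, idx, idx * 0.5, TRUE,
          lumen = ellipse_polygon(2 * (1 + ecc), 2, n = 90),
          branches = if (branch) branch_box(1.5, 0, 0.5, 0.5),
          calcium = calcium)
  }
  ivus <- pullback("IVUS", list(mk("IVUS", 0, branch = TRUE),
                                mk("IVUS", 1, calc = TRUE),
                                mk("IVUS", 2)), 0.5)
  oct <- pullback("OCT", list(mk("OCT", 0, branch = TRUE),
                              mk("OCT", 1),
                              mk("OCT", 2)), 0.5)
  fm <- data.frame(ivus_frame = 0:2, oct_frame_continuous = c(0, 1, 2))
  lm <- select_landmark_pairs(fm, ivus, oct)
  # pair 1: branch in both -> selected; pair 2: calcium only in IVUS -> not
  expect_equal(as.integer(lm), 1L)
  expect_false(attr(lm, "fallback"))
  # no qualifying pair anywhere: eccentricity fallback picks the most oval
  ivus2 <- pullback("IVUS", list(mk("IVUS", 0), mk("IVUS", 1, ecc = 0.5),
                                 mk("IVUS", 2)), 0.5)
  oct2 <- pullback("OCT", list(mk("OCT", 0), mk("OCT", 1, ecc = 0.5),
                               mk("OCT", 2)), 0.5)
  lm2 <- select_landmark_pairs(fm, ivus2, oct2)
  expect_equal(as.integer(lm2), 2L)
  expect_true(attr(lm2, "fallback"))
})

test_that("dp rotation path equals per-row argmin with the penalty off", {
  set.seed(17)
  R <- matrix(runif(5 * 180), 5, 180)
  res <- dp_rotation_path(R, lambda_shape = 0, max_step_deg = 360)
  expect_equal(res$path, apply(R, 1, which.min))
  single <- dp_rotation_path(R[1, , drop = FALSE], 150, 30)
  expect_equal(single$path, which.min(R[1, ]))
  expect_error(dp_rotation_path(R, lambda_shape = -1, 30), ">= 0")
})

test_that("dp rotation path equals exhaustive enumeration on small instances", {
  set.seed(23)
  for (i in 1:30) {
    tt <- sample(2:4, 1)
    R <- matrix(runif(tt * 8), tt, 8)
    lambda <- runif(1, 0, 20)
    ms <- sample(c(360, 135, 90), 1)
    res <- dp_rotation_path(R, lambda, ms)
    expect_equal(res$cost, brute_dp_rotation(R, lambda, ms), tolerance = 1e-12)
    # returned path reproduces the returned cost
    ang <- (0:7) * 360 / 8
    steps <- angle_differences(ang[res$path[-1]], ang[res$path[-tt]])
    expect_true(all(steps <= ms + 1e-9))
    expect_equal(sum(R[cbind(seq_len(tt), res$path)]) +
                   lambda * sum((steps / 360)^2), res$cost, tolerance = 1e-12)
  }
})

test_that("infinite shape regularization yields the best constant rotation", {
  set.seed(29)
  R <- matrix(runif(6 * 12), 6, 12)
  res <- dp_rotation_path(R, lambda_shape = 1e9, max_step_deg = 360)
  expect_equal(length(unique(res$path)), 1)
  expect_equal(unique(res$path), which.min(colSums(R)))
})

test_that("circular interpolation follows the shorter arc with constant extension", {
  expect_equal(interpolate_rotations(c(1, 3), c(10, 30), 2), 20)
  expect_equal(interpolate_rotations(c(1, 3), c(350, 10), 2), 0)
  expect_equal(interpolate_rotations(5, 77, 1:9), rep(77, 9))
  # constant extension before the first / after the last landmark
  expect_equal(interpolate_rotations(c(3, 5), c(100, 120), c(1, 7)),
               c(100, 120))
  # output stays in [0, 360)
  out <- interpolate_rotations(c(1, 2, 3), c(350, 10, 330), seq(1, 3, 0.25))
  expect_true(all(out >= 0 & out < 360))
})
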