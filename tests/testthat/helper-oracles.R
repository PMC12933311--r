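# Independent oracles and small fixture builders used across the suite.

# regular n-gon, optionally translated / phase-rotated
regular_polygon <- function(n, r = 1, cx = 0, cy = 0, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# ellipse with semi-axes a (x) and b (y), sampled as an n-gon
ellipse_polygon <- function(a, b, n = 256, cx = 0, cy = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + a * cos(th), cy + b * sin(th))
}

# a frame with a square lumen of given area centered at the origin
square_frame <- function(modality, index, position_mm, area = 4, is_ed = TRUE,
                         branches = NULL, calcium = rep(0L, 180)) {
  h <- sqrt(area) / 2
  frame(modality, index, position_mm, is_ed,
        lumen = rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h)),
        branches = branches, calcium = calcium)
}

# exhaustive enumeration of all monotone warping paths (steps right, down,
# diagonal) from (1,1) to (n,m); returns the minimal total cost and one
# minimizing path
brute_dtw <- function(D) {
  n <- nrow(D); m <- ncol(D)
  best <- Inf
  best_path <- NULL
  rec <- function(i, j, acc, path) {
    acc <- acc + D[i, j]
    path[[length(path) + 1L]] <- c(i, j)
    if (i == n && j == m) {
      if (acc < best) {
        best <<- acc
        best_path <<- do.call(rbind, path)
      }
      return(invisible(NULL))
    }
    if (i < n && j < m) rec(i + 1, j + 1, acc, path)
    if (i < n) rec(i + 1, j, acc, path)
    if (j < m) rec(i, j + 1, acc, path)
    invisible(NULL)
  }
  rec(1L, 1L, 0, list())
  list(total_cost = best, pairs = best_path)
}

# exhaustive enumeration over all K^T rotation paths for the regularized
# DP; returns the minimal total cost
brute_dp_rotation <- function(R, lambda_shape, max_step_deg) {
  tt <- nrow(R); K <- ncol(R)
  ang <- (seq_len(K) - 1) * 360 / K
  circ <- function(a, b) { d <- abs(a - b) %% 360; pmin(d, 360 - d) }
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), tt)))
  cost <- numeric(nrow(grid))
  for (t in seq_len(tt)) cost <- cost + R[t, grid[, t]]
  if (tt > 1) {
    for (t in 2:tt) {
      d <- circ(ang[grid[, t - 1]], ang[grid[, t]])
      cost <- cost + lambda_shape * (d / 360)^2
      cost[d > max_step_deg + 1e-9] <- Inf
    }
  }
  min(cost)
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign vectors
wilcoxon_enumeration <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_lo <- mean(w_all <= w_obs + 1e-9)
  p_hi <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# synthetic circular profile with asymmetric structure in all channels
test_profile <- function() {
  th <- ((0:179) * 2 + 1) * pi / 180
  radius <- 1.5 + 0.3 * cos(2 * th) + 0.12 * sin(th)
  branch <- numeric(180); branch[30] <- 1.2
  calc <- as.numeric(((0:179) * 2 + 1) >= 200 & ((0:179) * 2 + 1) < 280)
  structure(list(radius = radius, branch = branch, calc = calc),
            class = "circular_profile")
}

# shift a circular profile so it plays the OCT role at rotation 2k degrees:
# a vessel feature at angle a appears in the OCT image at a - 2k
shift_profile <- function(p, k) {
  structure(list(radius = ivoctreg:::rotate_bins(p$radius, -k),
                 branch = ivoctreg:::rotate_bins(p$branch, -k),
                 calc = ivoctreg:::rotate_bins(p$calc, -k)),
            class = "circular_profile")
}

noiseless_config <- function(seed) {
  phantom_config(contour_noise_sd_mm = 0, drift_step_sd_deg = 0,
                 ivus_cardiac_jitter_mm = 0, feature_dropout_prob = 0,
                 seed = seed)
}
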