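# Circumferential registration: circular profiles sampled in 2-degree
# increments, rotation cost rows from feature-weighted normalized
# cross-correlation, landmark selection, the shape-regularized
# dynamic-programming rotation path, and circular interpolation.

#' Circular feature profile of a frame
#'
#' Samples three channels along 180 directions in 2-degree increments around
#' the lumen centroid: the centroid-to-boundary distance (`radius`, mm), the
#' side-branch box area assigned to the bin containing each box center
#' (`branch`, mm^2), and the binary calcium flags (`calc`).
#'
#' @param frame An `"ivoct_frame"`.
#' @return An object of class `"circular_profile"`: list of three length-180
#'   numeric vectors `radius`, `branch`, `calc`.
#' @export
circular_profile <- function(frame) {
  stopifnot(inherits(frame, "ivoct_frame"))
  radius <- radial_profile(frame$lumen, 180L)
  attributes(radius) <- NULL
  branch <- numeric(180)
  b <- frame$branches
  if (nrow(b) > 0) {
    ctr <- contour_centroid(frame$lumen)
    ang <- (atan2(b$cy - ctr[2], b$cx - ctr[1]) * 180 / pi) %% 360
    bin <- pmin(floor(ang / 2) + 1, 180)
    for (r in seq_len(nrow(b))) {
      branch[bin[r]] <- branch[bin[r]] + b$width[r] * b$height[r]
    }
  }
  structure(list(radius = radius, branch = branch,
                 calc = as.numeric(frame$calcium)),
            class = "circular_profile")
}

#' Normalized cross-correlation of two circular channels
#'
#' Pearson-style: mean-removed, variance-normalized inner product, in
#' `[-1, 1]`. A constant channel carries no rotational information and
#' returns 0 by convention.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`, or 0 if either input is constant.
#' @export
ncc <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  a <- a - mean(a); b <- b - mean(b)
  sa <- sqrt(sum(a^2)); sb <- sqrt(sum(b^2))
  if (sa == 0 || sb == 0) return(0)
  sum(a * b) / (sa * sb)
}

#' Rotation cost row for one landmark pair
#'
#' For each candidate rotation `2k` degrees (k = 0..179) the OCT channels are
#' circularly rotated counter-clockwise by `k` bins and the per-channel NCC
#' with the IVUS profile is combined as a weighted mean `s_k`; the cost is
#' `1 - s_k`, in `[0, 2]`. The minimizing rotation is the CCW angle by which
#' the OCT frame must be rotated to align with its IVUS pair.
#'
#' A constant channel is uninformative and scores 0 (the NCC convention).
#' The radius channel extends this to *constant at sampling resolution*: a
#' profile whose total variation is below `radius_floor` times its mean is
#' indistinguishable from the chord-sagitta artifact of resampling a
#' polygonal contour on the 2-degree grid, and its scale-invariant NCC
#' would otherwise amplify that artifact into spurious rotation evidence;
#' such near-circular frames score 0 on the radius channel. The default
#' floor (1% relative radius modulation, i.e. eccentricity < 0.01) is far
#' below any clinically meaningful lumen eccentricity.
#'
#' @param p_ivus,p_oct `"circular_profile"` objects.
#' @param w Nonnegative channel weights `(radius, branch, calc)`, sum > 0.
#' @param radius_floor Relative variation below which the radius channel is
#'   treated as uninformative.
#' @return Numeric vector of 180 costs, one per candidate rotation.
#' @export
rotation_cost_row <- function(p_ivus, p_oct, w = c(1, 1, 1),
                              radius_floor = 0.01) {
  check_weights(w, 3)
  w <- w / sum(w)
  informative <- function(r) diff(range(r)) >= radius_floor * mean(r)
  rad_ok <- informative(p_ivus$radius) && informative(p_oct$radius)
  vapply(0:179, function(k) {
    s <- (if (rad_ok)
            w[1] * ncc(p_ivus$radius, rotate_bins(p_oct$radius, k)) else 0) +
         w[2] * ncc(p_ivus$branch, rotate_bins(p_oct$branch, k)) +
         w[3] * ncc(p_ivus$calc,   rotate_bins(p_oct$calc,   k))
    1 - s
  }, numeric(1))
}

#' Select landmark pairs for rotational registration
#'
#' Mirrors the analyst strategy of rotating at frames with distinctive
#' anatomy: a matched pair is a landmark when the IVUS frame *and* its
#' matched OCT frame each contain a side branch or calcium. When no pair
#' qualifies, the single pair with the largest summed lumen eccentricity is
#' used as a fallback (flagged in the `"fallback"` attribute).
#'
#' @param full_map Longitudinal correspondence from [expand_alignment()].
#' @param ivus,oct The two pullbacks.
#' @return Integer vector of row indices into `full_map`, with attribute
#'   `"oct_frame"` giving the matched (rounded) 0-based OCT frame index and
#'   attribute `"fallback"`.
#' @export
select_landmark_pairs <- function(full_map, ivus, oct) {
  if (nrow(full_map) == 0) stop("empty correspondence", call. = FALSE)
  ivus_by_idx <- structure(ivus$frames, names = frame_indices(ivus))
  oct_by_idx <- structure(oct$frames, names = frame_indices(oct))
  oct_idx <- pmin(pmax(round(full_map$oct_frame_continuous), 0),
                  max(frame_indices(oct)))
  has_feature <- function(f) {
    !is.null(f) && (branch_area_total(f) > 0 || calcium_fraction(f$calcium) > 0)
  }
  sel <- vapply(seq_len(nrow(full_map)), function(r) {
    fi <- ivus_by_idx[[as.character(full_map$ivus_frame[r])]]
    fo <- oct_by_idx[[as.character(oct_idx[r])]]
    has_feature(fi) && has_feature(fo)
  }, logical(1))
  fallback <- FALSE
  if (any(sel)) {
    out <- which(sel)
  } else {
    fallback <- TRUE
    ecc <- vapply(seq_len(nrow(full_map)), function(r) {
      fi <- ivus_by_idx[[as.character(full_map$ivus_frame[r])]]
      fo <- oct_by_idx[[as.character(oct_idx[r])]]
      eccentricity(radial_profile(fi$lumen)) +
        eccentricity(radial_profile(fo$lumen))
    }, numeric(1))
    out <- which.max(ecc)
  }
  attr(out, "oct_frame") <- oct_idx[out]
  attr(out, "fallback") <- fallback
  out
}

#' Shape-regularized dynamic-programming rotation path
#'
#' Finds, over the ordered landmark pairs (rows of `R`), the rotation path
#' minimizing the summed rotation cost plus a quadratic penalty on the
#' circular step between consecutive rows:
#' `A[t, k] = R[t, k] + min_j (A[t-1, j] + lambda_shape * (d(j, k)/360)^2)`
#' over predecessors `j` whose circular step `d(j, k)` does not exceed
#' `max_step_deg`. The answer is read by backtracking from the minimum of
#' the final row. Ties prefer the smaller circular step, then the smaller
#' rotation index.
#'
#' @param R T x K cost matrix; column `k` is the rotation `(k-1) * 360/K`
#'   degrees (K = 180 for 2-degree bins).
#' @param lambda_shape Regularization weight, >= 0.
#' @param max_step_deg Largest allowed circular step between consecutive
#'   rows, in degrees (>= 0; 0 forces a constant path).
#' @return List with `rotation_deg` (length T, in `[0, 360)`), `path`
#'   (1-based column indices), and `cost`.
#' @export
dp_rotation_path <- function(R, lambda_shape = 150, max_step_deg = 30) {
  if (!is.matrix(R) || any(!is.finite(R))) {
    stop("R must be a finite cost matrix", call. = FALSE)
  }
  if (!is.finite(lambda_shape) || lambda_shape < 0) {
    stop("lambda_shape must be >= 0", call. = FALSE)
  }
  if (!is.finite(max_step_deg) || max_step_deg < 0) {
    stop("max_step_deg must be >= 0", call. = FALSE)
  }
  tt <- nrow(R); K <- ncol(R)
  ang <- (seq_len(K) - 1) * 360 / K
  step <- outer(ang, ang, circular_difference)   # step[j, k]
  feas <- step <= max_step_deg + 1e-9
  pen <- lambda_shape * (step / 360)^2
  A <- matrix(Inf, tt, K)
  ptr <- matrix(NA_integer_, tt, K)
  A[1, ] <- R[1, ]
  if (tt > 1) {
    for (t in 2:tt) {
      for (k in seq_len(K)) {
        cand <- A[t - 1, ] + pen[, k]
        cand[!feas[, k]] <- Inf
        j <- order(cand, step[, k], seq_len(K))[1]
        A[t, k] <- R[t, k] + cand[j]
        ptr[t, k] <- j
      }
    }
  }
  path <- integer(tt)
  path[tt] <- which.min(A[tt, ])
  if (tt > 1) {
    for (t in tt:2) path[t - 1] <- ptr[t, path[t]]
  }
  list(rotation_deg = ang[path], path = path, cost = min(A[tt, ]))
}

#' Circular interpolation of landmark rotations
#'
#' Linearly interpolates rotations between consecutive landmarks along the
#' shorter circular arc (an exact 180-degree gap is traversed clockwise,
#' deterministically), parameterized by pair position; before the first and
#' after the last landmark the rotation is extended as a constant.
#'
#' @param positions Increasing landmark positions (e.g. row numbers of the
#'   matched-pair table).
#' @param rotations Landmark rotations in degrees, same length.
#' @param at Positions at which to evaluate.
#' @return Rotations in `[0, 360)` at `at`.
#' @export
interpolate_rotations <- function(positions, rotations, at) {
  if (length(positions) < 1 || length(positions) != length(rotations)) {
    stop("need at least one landmark rotation, with matching positions",
         call. = FALSE)
  }
  if (length(positions) == 1) {
    return(rep(rotations %% 360, length(at)))
  }
  if (any(diff(positions) <= 0)) {
    stop("landmark positions must be strictly increasing", call. = FALSE)
  }
  # unwrap onto the real line so each consecutive jump is the shorter arc
  jumps <- ((diff(rotations) + 180) %% 360) - 180
  unwrapped <- rotations[1] + cumsum(c(0, jumps))
  out <- stats::approx(positions, unwrapped, xout = at, rule = 2)$y
  out %% 360
}
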