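# Planar geometry of annotated cross-sections: polygon area/centroid,
# centroid-anchored radial profiles, eccentricity, calcium fraction.
# All coordinates are catheter-centered, in mm; angles in degrees,
# counter-clockwise from the +x axis.

#' Validate a lumen contour
#'
#' A contour is a closed polygon given as an n x 2 numeric matrix of (x, y)
#' vertices in mm; the last vertex implicitly connects back to the first.
#'
#' @param points An n x 2 numeric matrix (or coercible data frame) of vertices.
#' @param require_area If `TRUE` (default), also require nonzero signed area.
#' @return The validated vertex matrix.
#' @keywords internal
validate_contour <- function(points, require_area = TRUE) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) != 2 || !is.numeric(points)) {
    stop("invalid contour: expected an n x 2 numeric matrix of (x, y) points",
         call. = FALSE)
  }
  if (nrow(points) < 3) {
    stop(sprintf("invalid contour: need at least 3 points, got %d",
                 nrow(points)), call. = FALSE)
  }
  if (any(!is.finite(points))) {
    stop("invalid contour: non-finite coordinates", call. = FALSE)
  }
  if (require_area && signed_area(points) == 0) {
    stop("invalid contour: degenerate polygon (zero signed area)",
         call. = FALSE)
  }
  points
}

signed_area <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area of a lumen contour
#'
#' Shoelace area of the closed polygon, in mm^2.
#'
#' @param contour An n x 2 vertex matrix (n >= 3).
#' @return Positive area in mm^2.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' contour_area(sq) # 1
#' @export
contour_area <- function(contour) {
  contour <- validate_contour(contour)
  abs(signed_area(contour))
}

#' Area centroid of a lumen contour
#'
#' @param contour An n x 2 vertex matrix with nonzero area.
#' @return Numeric `c(x, y)` in mm.
#' @export
contour_centroid <- function(contour) {
  contour <- validate_contour(contour)
  x <- contour[, 1]; y <- contour[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
}

#' Radial profile of a contour about its centroid
#'
#' Samples the distance from the lumen centroid to the contour boundary along
#' `n_bins` equally spaced directions. Bin `b` (1-based) covers the half-open
#' angular interval `[(b-1)*w, b*w)` degrees with `w = 360/n_bins`, and is
#' sampled along its bin-center ray, i.e. at `(2b - 1)` degrees for the
#' default 180 bins of 2 degrees.
#'
#' The boundary distance is found by ray-polygon intersection (nearest
#' crossing along the ray). For contours that are not star-shaped about their
#' centroid a ray can miss the boundary; such bins fall back to the nearest
#' vertex distance within the bin (or overall) and are flagged in the
#' `"missed"` attribute.
#'
#' @param contour An n x 2 vertex matrix.
#' @param n_bins Number of angular bins (default 180, i.e. 2-degree bins).
#' @return Numeric vector of length `n_bins` of radii in mm, with a logical
#'   attribute `"missed"` marking fallback bins.
#' @export
radial_profile <- function(contour, n_bins = 180L) {
  contour <- validate_contour(contour)
  n_bins <- as.integer(n_bins)
  if (n_bins < 4L) stop("n_bins must be >= 4", call. = FALSE)
  ctr <- contour_centroid(contour)
  n <- nrow(contour)
  p1 <- contour
  p2 <- contour[c(2:n, 1), , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  qx <- p1[, 1] - ctr[1];  qy <- p1[, 2] - ctr[2]
  # vertex angles/distances, for the fallback path
  vang <- (atan2(qy, qx) * 180 / pi) %% 360
  vdist <- sqrt(qx^2 + qy^2)
  width <- 360 / n_bins
  centers <- (seq_len(n_bins) - 0.5) * width
  out <- numeric(n_bins)
  missed <- logical(n_bins)
  eps <- 1e-12
  for (b in seq_len(n_bins)) {
    th <- centers[b] * pi / 180
    dx <- cos(th); dy <- sin(th)
    denom <- dx * ey - dy * ex          # cross(ray dir, edge dir)
    ok <- abs(denom) > eps
    t <- (qx * ey - qy * ex) / denom    # distance along the ray
    u <- (qx * dy - qy * dx) / denom    # position along the edge
    hit <- ok & t > eps & u >= -1e-9 & u < 1 - 1e-9
    if (any(hit)) {
      out[b] <- min(t[hit])
    } else {
      missed[b] <- TRUE
      in_bin <- vang >= (b - 1) * width & vang < b * width
      out[b] <- if (any(in_bin)) min(vdist[in_bin]) else min(vdist)
    }
  }
  if (any(missed)) {
    warning(sprintf(
      "contour not star-shaped about centroid: %d/%d bins used nearest-vertex fallback",
      sum(missed), n_bins), call. = FALSE)
  }
  attr(out, "missed") <- missed
  out
}

#' Lumen eccentricity from a radial profile
#'
#' Defined as `(max - min) / max` of the centroid-anchored radial profile:
#' 0 for a circle, approaching 1 for extreme elongation. Scale invariant.
#'
#' @param profile Numeric vector of positive radii (mm).
#' @return Value in `[0, 1)`.
#' @export
eccentricity <- function(profile) {
  profile <- as.numeric(profile)
  if (length(profile) == 0 || any(!is.finite(profile)) || any(profile <= 0)) {
    stop("eccentricity requires a vector of positive finite radii",
         call. = FALSE)
  }
  (max(profile) - min(profile)) / max(profile)
}

#' Validate a calcium arc label vector
#'
#' 180 binary flags, one per 2-degree angular bin around the lumen centroid;
#' bin b (1-based) covers [2(b-1), 2b) degrees counter-clockwise from +x.
#'
#' @param flags Vector of 180 values in {0, 1}.
#' @return Integer vector of length 180.
#' @keywords internal
validate_calcium <- function(flags) {
  flags <- as.numeric(flags)
  if (length(flags) != 180) {
    stop(sprintf("calcium arc must have exactly 180 values, got %d",
                 length(flags)), call. = FALSE)
  }
  if (any(!flags %in% c(0, 1))) {
    stop("calcium arc values must be 0 or 1", call. = FALSE)
  }
  as.integer(flags)
}

#' Fraction of the lumen circumference with calcium
#'
#' @param flags 180 binary per-2-degree-bin calcium flags.
#' @return Proportion of flagged bins, in `[0, 1]`.
#' @export
calcium_fraction <- function(flags) {
  mean(validate_calcium(flags))
}
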