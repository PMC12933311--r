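# Longitudinal matching: feature-weighted distance matrix, dynamic time
# warping with full boundary constraints and symmetric unit steps, and
# expansion of the warping path into a functional frame-to-frame map.

#' Feature-weighted Euclidean distance
#'
#' `sqrt(sum(w * (u - v)^2))` over the four feature channels.
#'
#' @param u,v Feature vectors of equal length.
#' @param w Nonnegative weights, at least one positive.
#' @return Distance >= 0.
#' @export
weighted_euclidean <- function(u, v, w = c(1, 1, 1, 1)) {
  check_weights(w, length(u))
  if (length(u) != length(v)) stop("u and v must have equal length", call. = FALSE)
  sqrt(sum(w * (u - v)^2))
}

check_weights <- function(w, len) {
  if (length(w) != len || any(!is.finite(w)) || any(w < 0) || all(w == 0)) {
    stop(sprintf(
      "weights must be %d nonnegative finite values with at least one > 0",
      len), call. = FALSE)
  }
  invisible(w)
}

#' Pairwise distance matrix between two feature sequences
#'
#' @param a,b `"feature_sequence"` objects or plain M x 4 feature matrices.
#' @param w Channel weights (lumen, branch, calcium, position).
#' @return An `nrow(a) x nrow(b)` matrix of weighted Euclidean distances.
#' @export
distance_matrix <- function(a, b, w = c(1, 1, 1, 1)) {
  A <- feature_matrix(a); B <- feature_matrix(b)
  check_weights(w, ncol(A))
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in seq_len(ncol(A))) {
    d2 <- d2 + w[k] * outer(A[, k], B[, k], "-")^2
  }
  sqrt(d2)
}

#' Dynamic time warping over a distance matrix
#'
#' Accumulates `C[i, j] = D[i, j] + min(C[i-1, j-1], C[i-1, j], C[i, j-1])`
#' with `C[1, 1] = D[1, 1]` (symmetric three-direction steps, unit slope
#' weights, both endpoints matched), then backtraces from the terminal cell.
#' Ties in the backtrace prefer the diagonal predecessor, then the vertical
#' `(i-1, j)` predecessor, making the returned path deterministic.
#'
#' @param D Distance matrix with finite entries, at least 2 x 2.
#' @param band Optional Sakoe-Chiba band half-width, in columns about the
#'   rescaled diagonal; `NULL` (default) disables the constraint.
#' @return List with `total_cost` and `pairs`, a P x 2 matrix of 1-based
#'   (row, column) path positions from `(1, 1)` to `(n, m)`.
#' @export
dtw_align <- function(D, band = NULL) {
  if (!is.matrix(D) || nrow(D) < 2 || ncol(D) < 2) {
    stop("D must be a matrix with at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(!is.finite(D))) {
    stop("distance matrix contains non-finite entries", call. = FALSE)
  }
  n <- nrow(D); m <- ncol(D)
  allowed <- matrix(TRUE, n, m)
  if (!is.null(band)) {
    if (!is.finite(band) || band < 0) stop("band must be >= 0", call. = FALSE)
    for (i in seq_len(n)) {
      allowed[i, ] <- abs((i - 1) * (m - 1) / (n - 1) - (seq_len(m) - 1)) <= band
    }
    allowed[1, 1] <- TRUE
    allowed[n, m] <- TRUE
  }
  C <- matrix(Inf, n, m)
  C[1, 1] <- D[1, 1]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if ((i == 1 && j == 1) || !allowed[i, j]) next
      best <- Inf
      if (i > 1 && j > 1 && C[i - 1, j - 1] < best) best <- C[i - 1, j - 1]
      if (i > 1 && C[i - 1, j] < best) best <- C[i - 1, j]
      if (j > 1 && C[i, j - 1] < best) best <- C[i, j - 1]
      C[i, j] <- D[i, j] + best
    }
  }
  if (!is.finite(C[n, m])) {
    stop("no feasible warping path (band too narrow)", call. = FALSE)
  }
  # backtrace, tie order: diagonal, then (i-1, j), then (i, j-1)
  i <- n; j <- m
  path <- matrix(NA_integer_, n + m, 2)
  p <- 1L
  path[p, ] <- c(i, j)
  while (i > 1 || j > 1) {
    cand_v <- c(
      if (i > 1 && j > 1) C[i - 1, j - 1] else Inf,
      if (i > 1) C[i - 1, j] else Inf,
      if (j > 1) C[i, j - 1] else Inf)
    pick <- which.min(cand_v)  # which.min keeps the first of tied minima
    if (pick == 1L) { i <- i - 1L; j <- j - 1L }
    else if (pick == 2L) i <- i - 1L
    else j <- j - 1L
    p <- p + 1L
    path[p, ] <- c(i, j)
  }
  pairs <- path[p:1, , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  list(total_cost = C[n, m], pairs = pairs)
}

#' Expand a warping path into a functional frame map
#'
#' Converts the (possibly many-to-one) DTW path over retained-frame positions
#' into one continuous OCT frame index per retained IVUS frame: where an IVUS
#' frame appears in several path pairs, the mean of its matched OCT original
#' indices is taken. The result is non-decreasing by path monotonicity.
#'
#' @param pairs P x 2 matrix of 1-based path positions from [dtw_align()].
#' @param ivus_retained 0-based original IVUS frame indices of the rows.
#' @param oct_retained 0-based original OCT frame indices of the columns.
#' @return Data frame with columns `ivus_frame` (0-based original index) and
#'   `oct_frame_continuous`.
#' @export
expand_alignment <- function(pairs, ivus_retained, oct_retained) {
  if (!is.matrix(pairs) || ncol(pairs) != 2) {
    stop("pairs must be a P x 2 matrix", call. = FALSE)
  }
  n <- length(ivus_retained)
  if (max(pairs[, 1]) > n || max(pairs[, 2]) > length(oct_retained)) {
    stop("path positions exceed the retained index vectors", call. = FALSE)
  }
  oct_idx <- oct_retained[pairs[, 2]]
  mapped <- vapply(split(oct_idx, factor(pairs[, 1], levels = seq_len(n))),
                   mean, numeric(1))
  data.frame(ivus_frame = as.integer(ivus_retained),
             oct_frame_continuous = unname(mapped))
}

#' Interpolate a frame map to arbitrary IVUS frames
#'
#' Linear interpolation of the continuous OCT index in original IVUS frame
#' index, with constant extension beyond the mapped range.
#'
#' @param full_map Data frame from [expand_alignment()].
#' @param at IVUS frame indices (0-based) to interpolate at.
#' @return Numeric vector of continuous OCT frame indices.
#' @export
interpolate_alignment <- function(full_map, at) {
  stats::approx(full_map$ivus_frame, full_map$oct_frame_continuous,
                xout = at, rule = 2)$y
}
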