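# Longitudinal feature signals: the four per-frame matching features,
# Gaussian smoothing along the pullback axis, and modality-specific
# down-sampling into the sequences consumed by dynamic time warping.

FEATURE_NAMES <- c("lumen_area_norm", "branch_area_norm",
                   "calc_fraction", "position_norm")

#' Per-frame longitudinal matching features
#'
#' Extracts the four features used for longitudinal matching from every
#' frame of a pullback:
#' \itemize{
#'   \item `lumen_area_norm`: lumen area divided by the maximum lumen area
#'     observed in the vessel;
#'   \item `branch_area_norm`: total side-branch box area, normalized by the
#'     same maximum lumen area (clamped to 1);
#'   \item `calc_fraction`: proportion of the circumference with calcium;
#'   \item `position_norm`: relative frame position `i/(N-1)`.
#' }
#' All four lie in `[0, 1]`; `position_norm` is strictly increasing.
#'
#' @param pb An `"ivoct_pullback"`.
#' @return Data frame with one row per frame and the four feature columns.
#' @export
raw_features <- function(pb) {
  stopifnot(inherits(pb, "ivoct_pullback"))
  areas <- vapply(pb$frames, function(f) contour_area(f$lumen), numeric(1))
  amax <- max(areas)
  if (amax <= 0) stop("invalid pullback: maximum lumen area is 0", call. = FALSE)
  n <- length(pb$frames)
  data.frame(
    lumen_area_norm = areas / amax,
    branch_area_norm = pmin(
      vapply(pb$frames, branch_area_total, numeric(1)) / amax, 1),
    calc_fraction = vapply(pb$frames, function(f) calcium_fraction(f$calcium),
                           numeric(1)),
    position_norm = (seq_len(n) - 1) / (n - 1)
  )
}

#' Gaussian smoothing of a longitudinal signal
#'
#' Convolves the signal with a discrete Gaussian kernel truncated at
#' `+/- 4 sigma` and renormalized to sum to one, using reflect padding at
#' the sequence ends. `sigma_frames = 0` is the identity. The kernel is a
#' convex combination, so output values never leave `[min(x), max(x)]`.
#'
#' @param x Numeric signal (length >= 1).
#' @param sigma_frames Kernel standard deviation in frames, >= 0.
#' @return Smoothed signal of the same length.
#' @export
gaussian_smooth <- function(x, sigma_frames) {
  if (!is.finite(sigma_frames) || sigma_frames < 0) {
    stop("sigma_frames must be >= 0", call. = FALSE)
  }
  n <- length(x)
  if (sigma_frames == 0 || n == 1) return(x)
  r <- ceiling(4 * sigma_frames)
  w <- exp(-(seq(-r, r))^2 / (2 * sigma_frames^2))
  w <- w / sum(w)
  # reflect indices about the ends without duplicating the edge sample
  reflect <- function(i) {
    if (n == 1) return(rep(1L, length(i)))
    p <- (i - 1) %% (2 * n - 2)
    ifelse(p < n, p + 1, 2 * n - 1 - p)
  }
  vapply(seq_len(n), function(i) {
    sum(w * x[reflect(i + seq(-r, r))])
  }, numeric(1))
}

#' Down-sample a feature table to the analysed frames
#'
#' IVUS retains the end-diastolic (ED) frames, in order; OCT retains every
#' second frame starting from the first. `position_norm` is recomputed over
#' the retained frames so both modalities span `[0, 1]`.
#'
#' @param pb The source pullback.
#' @param features Per-frame feature data frame, as from [raw_features()]
#'   (usually after smoothing).
#' @param sigma_frames Smoothing width that produced `features` (recorded).
#' @return An object of class `"feature_sequence"`: list with `modality`,
#'   `vectors` (an M x 4 matrix), `retained_indices` (0-based original frame
#'   indices), and `sigma_frames`.
#' @export
downsample_features <- function(pb, features, sigma_frames = NA_real_) {
  stopifnot(inherits(pb, "ivoct_pullback"))
  if (nrow(features) != length(pb$frames)) {
    stop("features must have one row per frame", call. = FALSE)
  }
  if (pb$modality == "IVUS") {
    keep <- which(vapply(pb$frames, `[[`, logical(1), "is_ed"))
    if (length(keep) < 2) {
      stop("invalid pullback: fewer than 2 ED frames in IVUS", call. = FALSE)
    }
  } else {
    keep <- seq(1L, length(pb$frames), by = 2L)
    if (length(keep) < 2) {
      stop("invalid pullback: fewer than 2 retained OCT frames", call. = FALSE)
    }
  }
  v <- as.matrix(features[keep, FEATURE_NAMES])
  m <- nrow(v)
  v[, "position_norm"] <- (seq_len(m) - 1) / (m - 1)
  rownames(v) <- NULL
  structure(list(
    modality = pb$modality,
    vectors = v,
    retained_indices = frame_indices(pb)[keep],
    sigma_frames = sigma_frames
  ), class = "feature_sequence")
}

#' Build the smoothed, down-sampled feature sequence of a pullback
#'
#' Convenience pipeline: [raw_features()], Gaussian smoothing of the lumen,
#' branch and calcium channels (the position channel is left untouched so it
#' stays strictly monotone), then [downsample_features()].
#'
#' @param pb An `"ivoct_pullback"`.
#' @param sigma_frames Smoothing width in frames (default 2).
#' @return A `"feature_sequence"`.
#' @export
feature_sequence <- function(pb, sigma_frames = 2) {
  feats <- raw_features(pb)
  for (ch in c("lumen_area_norm", "branch_area_norm", "calc_fraction")) {
    feats[[ch]] <- gaussian_smooth(feats[[ch]], sigma_frames)
  }
  downsample_features(pb, feats, sigma_frames)
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("%s feature sequence: %d retained frames (sigma = %s frames)\n",
              x$modality, nrow(x$vectors), format(x$sigma_frames)))
  invisible(x)
}

feature_matrix <- function(x) {
  if (inherits(x, "feature_sequence")) return(x$vectors)
  m <- as.matrix(x)
  if (ncol(m) != 4) stop("expected 4 feature columns", call. = FALSE)
  m
}
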