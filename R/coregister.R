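# End-to-end co-registration pipeline: features -> DTW -> landmark
# rotations -> interpolated rotation series.

#' Registration configuration
#'
#' Hyperparameters of the two registration stages. The feature and channel
#' weights were tuned on held-out data in the original development of this
#' kind of pipeline; unit weights are the neutral defaults here and every
#' weight is exposed.
#'
#' @param sigma_frames Gaussian smoothing width of the longitudinal feature
#'   signals, in frames (default 2).
#' @param dtw_weights Feature weights (lumen, branch, calcium, position)
#'   of the DTW distance.
#' @param dtw_band Optional Sakoe-Chiba band half-width (`NULL` = off).
#' @param ncc_weights Channel weights (radius, branch, calcium) of the
#'   rotational NCC.
#' @param lambda_shape Shape-regularization weight of the rotation path.
#' @param max_step_deg Largest rotation change allowed between consecutive
#'   landmark pairs (degrees).
#' @return A validated list of class `"coreg_config"`.
#' @export
coreg_config <- function(sigma_frames = 2,
                         dtw_weights = c(1, 1, 1, 1),
                         dtw_band = NULL,
                         ncc_weights = c(1, 1, 1),
                         lambda_shape = 150,
                         max_step_deg = 30) {
  if (!is.finite(sigma_frames) || sigma_frames < 0) {
    stop("sigma_frames must be >= 0", call. = FALSE)
  }
  check_weights(dtw_weights, 4)
  check_weights(ncc_weights, 3)
  if (!is.null(dtw_band) && (!is.finite(dtw_band) || dtw_band < 0)) {
    stop("dtw_band must be NULL or >= 0", call. = FALSE)
  }
  if (!is.finite(lambda_shape) || lambda_shape < 0) {
    stop("lambda_shape must be >= 0", call. = FALSE)
  }
  if (!is.finite(max_step_deg) || max_step_deg < 0) {
    stop("max_step_deg must be >= 0", call. = FALSE)
  }
  structure(list(sigma_frames = sigma_frames,
                 dtw_weights = as.numeric(dtw_weights),
                 dtw_band = dtw_band,
                 ncc_weights = as.numeric(ncc_weights),
                 lambda_shape = lambda_shape,
                 max_step_deg = max_step_deg),
            class = "coreg_config")
}

#' Co-register an IVUS and an OCT pullback
#'
#' Runs the full registration pipeline:
#' \enumerate{
#'   \item per-frame features, Gaussian smoothing, modality-specific
#'     down-sampling ([feature_sequence()]);
#'   \item feature-weighted distance matrix and DTW with backtrace
#'     ([dtw_align()]), expanded to a continuous OCT index per IVUS ED frame
#'     ([expand_alignment()]);
#'   \item landmark-pair selection ([select_landmark_pairs()]), rotation
#'     cost rows by feature-weighted NCC ([rotation_cost_row()]), the
#'     shape-regularized DP rotation path ([dp_rotation_path()]), and
#'     circular interpolation to all matched pairs
#'     ([interpolate_rotations()]).
#' }
#'
#' @param ivus,oct The two pullbacks (`"ivoct_pullback"`).
#' @param config A [coreg_config()].
#' @return An object of class `"ivoct_coreg"`: `alignment` (data frame with
#'   `ivus_frame`, `oct_frame_continuous`, `rotation_deg`, `is_path_node`,
#'   `is_landmark`), plus `path`, `total_cost`, `landmarks`, `fallback`,
#'   and the `config` used.
#' @export
coregister <- function(ivus, oct, config = coreg_config()) {
  stopifnot(inherits(ivus, "ivoct_pullback"), inherits(oct, "ivoct_pullback"))
  if (ivus$modality != "IVUS" || oct$modality != "OCT") {
    stop("arguments must be an IVUS and an OCT pullback, in that order",
         call. = FALSE)
  }
  stopifnot(inherits(config, "coreg_config"))

  fi <- feature_sequence(ivus, config$sigma_frames)
  fo <- feature_sequence(oct, config$sigma_frames)
  D <- distance_matrix(fi, fo, config$dtw_weights)
  al <- dtw_align(D, band = config$dtw_band)
  full_map <- expand_alignment(al$pairs, fi$retained_indices,
                               fo$retained_indices)

  lm <- select_landmark_pairs(full_map, ivus, oct)
  oct_lm <- attr(lm, "oct_frame")
  oct_by_idx <- structure(oct$frames, names = frame_indices(oct))
  ivus_by_idx <- structure(ivus$frames, names = frame_indices(ivus))
  R <- t(vapply(seq_along(lm), function(t) {
    pi_ <- circular_profile(ivus_by_idx[[as.character(full_map$ivus_frame[lm[t]])]])
    po <- circular_profile(oct_by_idx[[as.character(oct_lm[t])]])
    rotation_cost_row(pi_, po, config$ncc_weights)
  }, numeric(180)))
  dp <- dp_rotation_path(R, config$lambda_shape, config$max_step_deg)
  rot <- interpolate_rotations(lm, dp$rotation_deg, seq_len(nrow(full_map)))

  alignment <- data.frame(
    ivus_frame = full_map$ivus_frame,
    oct_frame_continuous = full_map$oct_frame_continuous,
    rotation_deg = rot %% 360,
    is_path_node = TRUE,
    is_landmark = seq_len(nrow(full_map)) %in% lm
  )
  structure(list(alignment = alignment,
                 path = al$pairs,
                 total_cost = al$total_cost,
                 landmarks = lm,
                 landmark_rotation_deg = dp$rotation_deg,
                 fallback = attr(lm, "fallback"),
                 config = config),
            class = "ivoct_coreg")
}

#' @export
print.ivoct_coreg <- function(x, ...) {
  cat(sprintf(
    "IVUS-OCT co-registration: %d matched ED frames, %d landmark pairs%s, DTW cost %.3f\n",
    nrow(x$alignment), length(x$landmarks),
    if (isTRUE(x$fallback)) " (eccentricity fallback)" else "",
    x$total_cost))
  invisible(x)
}

#' Registration errors of a co-registration against phantom ground truth
#'
#' @param coreg An `"ivoct_coreg"` result on a phantom pair.
#' @param pair The `"phantom_pair"` (or its `truth` element).
#' @return List with `frame_error` (|estimated - true| continuous OCT frame
#'   index per IVUS frame, in 0.2 mm OCT frames for the default spacing)
#'   and `angle_error_deg` (circular).
#' @export
phantom_errors <- function(coreg, pair) {
  truth <- true_correspondence(pair)
  est <- coreg$alignment
  keep <- match(est$ivus_frame, truth$ivus_frame)
  if (any(is.na(keep))) stop("alignment frames not found in ground truth",
                             call. = FALSE)
  truth <- truth[keep, ]
  list(
    frame_error = abs(est$oct_frame_continuous - truth$true_oct_index),
    angle_error_deg = circular_difference(est$rotation_deg,
                                          truth$true_rotation_deg)
  )
}
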