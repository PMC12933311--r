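# Domain containers: branch boxes, frames, pullbacks; acquisition
# arithmetic; annotation rotation helper.

#' Side-branch bounding box
#'
#' Axis-aligned rectangle marking a side-branch ostium, in the
#' catheter-centered mm plane.
#'
#' @param cx,cy Box center (mm).
#' @param width,height Box side lengths (mm), both > 0.
#' @return A one-row data frame with columns `cx`, `cy`, `width`, `height`.
#' @export
branch_box <- function(cx, cy, width, height) {
  if (!all(is.finite(c(cx, cy, width, height)))) {
    stop("branch box fields must be finite numbers", call. = FALSE)
  }
  if (width <= 0 || height <= 0) {
    stop("branch box width and height must be > 0", call. = FALSE)
  }
  data.frame(cx = cx, cy = cy, width = width, height = height)
}

validate_branches <- function(branches) {
  if (is.null(branches) || (is.data.frame(branches) && nrow(branches) == 0)) {
    return(data.frame(cx = numeric(0), cy = numeric(0),
                      width = numeric(0), height = numeric(0)))
  }
  if (!is.data.frame(branches) ||
      !all(c("cx", "cy", "width", "height") %in% names(branches))) {
    stop("branches must be a data frame with columns cx, cy, width, height",
         call. = FALSE)
  }
  if (any(branches$width <= 0) || any(branches$height <= 0)) {
    stop("branch box width and height must be > 0", call. = FALSE)
  }
  branches[, c("cx", "cy", "width", "height")]
}

#' One annotated cross-sectional frame
#'
#' @param modality `"IVUS"` or `"OCT"`.
#' @param index 0-based frame index within the pullback.
#' @param position_mm Longitudinal catheter position of the frame.
#' @param is_ed End-diastolic flag (meaningful for IVUS; `TRUE` for OCT).
#' @param lumen Lumen contour, an n x 2 vertex matrix (mm).
#' @param branches Data frame of side-branch boxes (possibly empty); see
#'   [branch_box()].
#' @param calcium 180 binary calcium flags, one per 2-degree bin.
#' @return An object of class `"ivoct_frame"`.
#' @export
frame <- function(modality, index, position_mm, is_ed, lumen,
                  branches = NULL, calcium = rep(0L, 180)) {
  modality <- match.arg(modality, c("IVUS", "OCT"))
  index <- as.integer(index)
  if (is.na(index) || index < 0L) stop("frame index must be >= 0", call. = FALSE)
  if (!is.finite(position_mm)) stop("position_mm must be finite", call. = FALSE)
  structure(list(
    modality = modality,
    index = index,
    position_mm = as.numeric(position_mm),
    is_ed = isTRUE(is_ed),
    lumen = validate_contour(lumen),
    branches = validate_branches(branches),
    calcium = validate_calcium(calcium)
  ), class = "ivoct_frame")
}

#' Total side-branch box area in a frame
#'
#' Sum of width x height over all branch boxes; 0 when no branch is marked.
#' Overlapping boxes are not de-duplicated (boxes mark distinct ostia).
#'
#' @param frame An `"ivoct_frame"` object.
#' @return Area in mm^2.
#' @export
branch_area_total <- function(frame) {
  b <- frame$branches
  if (nrow(b) == 0) return(0)
  sum(b$width * b$height)
}

#' An ordered pullback of annotated frames
#'
#' @param modality `"IVUS"` or `"OCT"`; all frames must agree.
#' @param frames List of [frame()] objects with strictly increasing
#'   `position_mm` and unique indices; at least 2.
#' @param frame_spacing_mm Nominal inter-frame spacing (mm).
#' @return An object of class `"ivoct_pullback"`.
#' @export
pullback <- function(modality, frames, frame_spacing_mm) {
  modality <- match.arg(modality, c("IVUS", "OCT"))
  if (!is.list(frames) || length(frames) < 2) {
    stop("a pullback needs at least 2 frames", call. = FALSE)
  }
  if (!all(vapply(frames, inherits, logical(1), "ivoct_frame"))) {
    stop("frames must be a list of ivoct_frame objects", call. = FALSE)
  }
  mods <- vapply(frames, `[[`, character(1), "modality")
  if (any(mods != modality)) {
    stop("all frames must share the pullback modality", call. = FALSE)
  }
  pos <- vapply(frames, `[[`, numeric(1), "position_mm")
  if (any(diff(pos) <= 0)) {
    stop("frame positions must be strictly increasing", call. = FALSE)
  }
  idx <- vapply(frames, `[[`, integer(1), "index")
  if (anyDuplicated(idx)) stop("frame indices must be unique", call. = FALSE)
  if (!is.finite(frame_spacing_mm) || frame_spacing_mm <= 0) {
    stop("frame_spacing_mm must be > 0", call. = FALSE)
  }
  structure(list(
    modality = modality,
    frames = frames,
    frame_spacing_mm = as.numeric(frame_spacing_mm)
  ), class = "ivoct_pullback")
}

#' @export
print.ivoct_pullback <- function(x, ...) {
  cat(sprintf("%s pullback: %d frames, %.3g mm nominal spacing, %.1f-%.1f mm\n",
              x$modality, length(x$frames), x$frame_spacing_mm,
              x$frames[[1]]$position_mm,
              x$frames[[length(x$frames)]]$position_mm))
  invisible(x)
}

n_frames <- function(pb) length(pb$frames)

frame_positions <- function(pb) {
  vapply(pb$frames, `[[`, numeric(1), "position_mm")
}

frame_indices <- function(pb) {
  vapply(pb$frames, `[[`, integer(1), "index")
}

#' Rotate all angular annotations of a pullback
#'
#' Rotates every frame's contour vertices and branch-box centers about the
#' catheter axis by `degrees` counter-clockwise, and shifts the calcium flags
#' by the corresponding whole number of 2-degree bins. `degrees` must be a
#' multiple of 2 so that the binned calcium labels rotate exactly.
#'
#' @param pb An `"ivoct_pullback"`.
#' @param degrees Rotation angle, CCW, a multiple of 2.
#' @return The rotated pullback.
#' @export
rotate_pullback <- function(pb, degrees) {
  k <- degrees / 2
  if (abs(k - round(k)) > 1e-9) {
    stop("degrees must be a multiple of 2 (the calcium bin width)",
         call. = FALSE)
  }
  k <- as.integer(round(k)) %% 180L
  th <- degrees * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pb$frames <- lapply(pb$frames, function(f) {
    f$lumen <- f$lumen %*% t(rot)
    if (nrow(f$branches) > 0) {
      xy <- as.matrix(f$branches[, c("cx", "cy")]) %*% t(rot)
      f$branches$cx <- xy[, 1]
      f$branches$cy <- xy[, 2]
    }
    f$calcium <- rotate_bins(f$calcium, k)
    f
  })
  pb
}

# circularly rotate a binned profile CCW by k bins: out[b] = x[b - k]
rotate_bins <- function(x, k) {
  n <- length(x)
  x[((seq_len(n) - 1 - k) %% n) + 1]
}

# smallest angular separation between two angles, in [0, 180]
circular_difference <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Acquisition arithmetic
#'
#' Small helpers tying pullback speed and frame rate to longitudinal
#' geometry: `frame_spacing_mm()` is the inter-frame distance of a pullback
#' acquired at `speed_mm_s` while recording `frame_rate_hz` frames per
#' second; `analysis_interval_mm()` is the spacing after retaining every
#' `retain_every`-th frame; `segment_length_mm()` is the length covered by
#' `n_frames` frames analysed at a given interval.
#'
#' @param speed_mm_s Pullback speed (mm/s).
#' @param frame_rate_hz Acquisition frame rate (frames/s).
#' @return Spacing / interval / length in mm.
#' @examples
#' frame_spacing_mm(36, 180)              # 0.2 mm between raw OCT frames
#' analysis_interval_mm(0.2, 2)           # 0.4 mm between analysed frames
#' segment_length_mm(111, 0.4)            # 44.4 mm segment
#' @export
frame_spacing_mm <- function(speed_mm_s, frame_rate_hz) {
  if (speed_mm_s <= 0 || frame_rate_hz <= 0) {
    stop("speed and frame rate must be > 0", call. = FALSE)
  }
  speed_mm_s / frame_rate_hz
}

#' @rdname frame_spacing_mm
#' @param spacing_mm Raw inter-frame spacing (mm).
#' @param retain_every Keep every `retain_every`-th frame.
#' @export
analysis_interval_mm <- function(spacing_mm, retain_every = 2L) {
  spacing_mm * retain_every
}

#' @rdname frame_spacing_mm
#' @param n_frames Number of analysed frames.
#' @param interval_mm Interval between analysed frames (mm).
#' @export
segment_length_mm <- function(n_frames, interval_mm) {
  n_frames * interval_mm
}
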