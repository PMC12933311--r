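# File formats: JSON pullback annotation documents (nested contours do not
# fit flat CSV), CSV alignment and ground-truth tables, JSON reports.
# Reading validates strictly, naming the offending frame.

#' Write a pullback to a JSON annotation file
#'
#' The document holds the pullback metadata plus one record per frame:
#' 0-based `index`, `position_mm`, `is_ed`, the lumen contour as an array of
#' `[x, y]` points, the branch boxes, and the 180 calcium flags.
#'
#' @param pb An `"ivoct_pullback"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pullback <- function(pb, path) {
  stopifnot(inherits(pb, "ivoct_pullback"))
  doc <- list(
    modality = pb$modality,
    frame_spacing_mm = pb$frame_spacing_mm,
    frames = lapply(pb$frames, function(f) {
      list(index = f$index,
           position_mm = f$position_mm,
           is_ed = f$is_ed,
           lumen = unname(f$lumen),
           branches = if (nrow(f$branches)) f$branches else list(),
           calcium = f$calcium)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pullback from a JSON annotation file
#'
#' Validates the schema strictly: required fields, 180 calcium flags,
#' contours of at least 3 points, strictly increasing positions and unique
#' indices; errors name the offending frame.
#'
#' @param path Path to a file written by [write_pullback()] (or following
#'   the same schema).
#' @return An `"ivoct_pullback"`.
#' @export
read_pullback <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("modality", "frame_spacing_mm", "frames")) {
    if (is.null(doc[[key]])) {
      stop(sprintf("pullback schema error: missing field '%s'", key),
           call. = FALSE)
    }
  }
  if (!doc$modality %in% c("IVUS", "OCT")) {
    stop(sprintf("pullback schema error: unknown modality '%s'", doc$modality),
         call. = FALSE)
  }
  if (length(doc$frames) < 2) {
    stop("pullback schema error: need at least 2 frames", call. = FALSE)
  }
  frames <- lapply(seq_along(doc$frames), function(i) {
    fr <- doc$frames[[i]]
    where <- sprintf("frame %d", i - 1)
    for (key in c("index", "position_mm", "is_ed", "lumen", "calcium")) {
      if (is.null(fr[[key]])) {
        stop(sprintf("pullback schema error: %s: missing field '%s'",
                     where, key), call. = FALSE)
      }
    }
    if (length(fr$calcium) != 180) {
      stop(sprintf("pullback schema error: %s: calcium must have 180 values, got %d",
                   where, length(fr$calcium)), call. = FALSE)
    }
    lumen <- do.call(rbind, lapply(fr$lumen, function(p) {
      if (length(p) != 2) {
        stop(sprintf("pullback schema error: %s: lumen points must be [x, y] pairs",
                     where), call. = FALSE)
      }
      as.numeric(p)
    }))
    branches <- NULL
    if (length(fr$branches)) {
      branches <- do.call(rbind, lapply(fr$branches, function(b) {
        for (key in c("cx", "cy", "width", "height")) {
          if (is.null(b[[key]])) {
            stop(sprintf("pullback schema error: %s: branch box missing '%s'",
                         where, key), call. = FALSE)
          }
        }
        data.frame(cx = as.numeric(b$cx), cy = as.numeric(b$cy),
                   width = as.numeric(b$width), height = as.numeric(b$height))
      }))
    }
    tryCatch(
      frame(doc$modality, fr$index, fr$position_mm, fr$is_ed,
            lumen, branches, unlist(fr$calcium)),
      error = function(e) {
        stop(sprintf("pullback schema error: %s: %s", where,
                     conditionMessage(e)), call. = FALSE)
      })
  })
  pos <- vapply(frames, `[[`, numeric(1), "position_mm")
  bad <- which(diff(pos) <= 0)
  if (length(bad)) {
    stop(sprintf("pullback schema error: frame %d: positions not strictly increasing",
                 bad[1]), call. = FALSE)
  }
  pullback(doc$modality, frames, doc$frame_spacing_mm)
}

#' Write a co-registration result as CSV
#'
#' One row per matched IVUS ED frame, columns `ivus_frame`,
#' `oct_frame_continuous`, `rotation_deg` (in `[0, 360)`), `is_path_node`,
#' `is_landmark`. Deterministic: the same result always produces the same
#' bytes.
#'
#' @param x An `"ivoct_coreg"` or a compatible data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  df <- if (inherits(x, "ivoct_coreg")) x$alignment else x
  stopifnot(is.data.frame(df))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an alignment CSV
#'
#' @param path CSV written by [write_alignment()].
#' @return Data frame.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("ivus_frame", "oct_frame_continuous")
  if (!all(need %in% names(df))) {
    stop(sprintf("alignment file must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write / read phantom ground truth as CSV
#'
#' Columns `ivus_frame`, `true_oct_index`, `true_rotation_deg`.
#'
#' @param truth A `"phantom_pair"`, its `truth` element, or the table from
#'   [true_correspondence()].
#' @param path CSV path.
#' @return `path` / the ground-truth data frame.
#' @export
write_ground_truth <- function(truth, path) {
  if (!is.data.frame(truth)) truth <- true_correspondence(truth)
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("ivus_frame", "true_oct_index", "true_rotation_deg")
  if (!all(need %in% names(df))) {
    stop(sprintf("ground truth file must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write an agreement or observer report as JSON
#'
#' @param report An `"agreement_report"` or `"observer_report"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_recursive(report), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}
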