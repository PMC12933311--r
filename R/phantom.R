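# Phantom pullback simulator: a tapered, smoothly eccentric vessel with
# randomly placed side branches and calcium deposits, acquired twice —
# as an ED-gated IVUS pullback with residual cardiac jitter and as a fast
# OCT pullback with a rotational drift random walk — with the true frame
# correspondence and the true per-frame OCT rotation retained as ground
# truth for every registration stage.

#' Phantom simulator configuration
#'
#' Geometry and noise parameters of the simulated vessel and of the two
#' acquisitions. The defaults describe a realistic 40 mm coronary segment
#' imaged under moderate annotation noise: IVUS ED frames every 0.5 mm
#' (0.5 mm/s pullback gated once per cardiac cycle) with 0.05 mm residual
#' longitudinal jitter, OCT frames every 0.2 mm (36 mm/s at 180 fps), a
#' 1 degree/frame rotational drift random walk, 0.05 mm contour noise, and
#' a 10% chance that a branch or calcium annotation is missed on any frame.
#'
#' @param length_mm Vessel length (>= 10 x the largest frame spacing).
#' @param base_radius_mm Proximal lumen radius.
#' @param taper_rate Fractional radius loss from proximal to distal end.
#' @param eccentricity_amp Peak amplitude of the smooth cross-sectional
#'   eccentricity modulation (`cos 2 theta` term).
#' @param n_branches,branch_width_deg,branch_span_mm Number of side-branch
#'   events, their angular width range (degrees) and longitudinal extent.
#' @param n_calcium,calcium_arc_deg,calcium_span_mm Number of calcium
#'   deposits, their angular arc range (degrees) and longitudinal extent.
#' @param ivus_frame_spacing_mm,ivus_cardiac_jitter_mm IVUS ED frame spacing
#'   and the sd of the residual longitudinal jitter.
#' @param oct_frame_spacing_mm OCT frame spacing.
#' @param drift_step_sd_deg Sd of the per-OCT-frame rotational drift step.
#' @param contour_noise_sd_mm Additive radial noise on contour vertices.
#' @param feature_dropout_prob Probability that an active branch/calcium
#'   event is missing from a given frame's annotations.
#' @param contour_points Number of contour vertices emitted per frame.
#' @param seed Integer seed; the simulator is deterministic given the config.
#' @return A validated list of class `"phantom_config"`.
#' @export
phantom_config <- function(length_mm = 40,
                           base_radius_mm = 1.75,
                           taper_rate = 0.4,
                           eccentricity_amp = 0.25,
                           n_branches = 4L,
                           branch_width_deg = c(25, 60),
                           branch_span_mm = 1.5,
                           n_calcium = 3L,
                           calcium_arc_deg = c(30, 100),
                           calcium_span_mm = 3,
                           ivus_frame_spacing_mm = 0.5,
                           ivus_cardiac_jitter_mm = 0.05,
                           oct_frame_spacing_mm = 0.2,
                           drift_step_sd_deg = 1,
                           contour_noise_sd_mm = 0.05,
                           feature_dropout_prob = 0.1,
                           contour_points = 96L,
                           seed = 1L) {
  cfg <- list(length_mm = length_mm, base_radius_mm = base_radius_mm,
              taper_rate = taper_rate, eccentricity_amp = eccentricity_amp,
              n_branches = as.integer(n_branches),
              branch_width_deg = branch_width_deg,
              branch_span_mm = branch_span_mm,
              n_calcium = as.integer(n_calcium),
              calcium_arc_deg = calcium_arc_deg,
              calcium_span_mm = calcium_span_mm,
              ivus_frame_spacing_mm = ivus_frame_spacing_mm,
              ivus_cardiac_jitter_mm = ivus_cardiac_jitter_mm,
              oct_frame_spacing_mm = oct_frame_spacing_mm,
              drift_step_sd_deg = drift_step_sd_deg,
              contour_noise_sd_mm = contour_noise_sd_mm,
              feature_dropout_prob = feature_dropout_prob,
              contour_points = as.integer(contour_points),
              seed = as.integer(seed))
  with(cfg, {
    if (length_mm <= 0 || base_radius_mm <= 0 ||
        ivus_frame_spacing_mm <= 0 || oct_frame_spacing_mm <= 0) {
      stop("lengths and spacings must be > 0", call. = FALSE)
    }
    if (length_mm < 10 * max(ivus_frame_spacing_mm, oct_frame_spacing_mm)) {
      stop("length_mm must be at least 10 x the largest frame spacing",
           call. = FALSE)
    }
    if (taper_rate < 0 || taper_rate >= 1) {
      stop("taper_rate must be in [0, 1)", call. = FALSE)
    }
    if (eccentricity_amp < 0 || eccentricity_amp >= 1) {
      stop("eccentricity_amp must be in [0, 1)", call. = FALSE)
    }
    if (feature_dropout_prob < 0 || feature_dropout_prob > 1) {
      stop("feature_dropout_prob must be in [0, 1]", call. = FALSE)
    }
    if (ivus_cardiac_jitter_mm < 0 || drift_step_sd_deg < 0 ||
        contour_noise_sd_mm < 0) {
      stop("noise standard deviations must be >= 0", call. = FALSE)
    }
    if (n_branches < 0 || n_calcium < 0) {
      stop("event counts must be >= 0", call. = FALSE)
    }
    if (contour_points < 8) stop("contour_points must be >= 8", call. = FALSE)
  })
  structure(cfg, class = "phantom_config")
}

# smooth eccentricity modulation along the vessel, bounded by the amplitude
phantom_ecc <- function(vessel, s) {
  cfg <- vessel$cfg
  cfg$eccentricity_amp *
    (0.5 - 0.5 * cos(2 * pi * s / cfg$length_mm + vessel$ecc_phase))
}

#' Lumen radius of a phantom vessel
#'
#' `r(s, theta) = base * (1 - taper * s/L) * (1 + ecc(s) * cos(2 theta))`
#' with a smooth `ecc(s) <= eccentricity_amp`.
#'
#' @param vessel A `"phantom_vessel"` from [make_phantom()].
#' @param s Arc-length position (mm).
#' @param theta_deg Angle(s) in degrees, vessel frame.
#' @return Radius (mm), vectorized over `theta_deg`.
#' @export
phantom_radius <- function(vessel, s, theta_deg) {
  cfg <- vessel$cfg
  cfg$base_radius_mm * (1 - cfg$taper_rate * s / cfg$length_mm) *
    (1 + phantom_ecc(vessel, s) * cos(2 * theta_deg * pi / 180))
}

#' Generate a ground-truth phantom vessel
#'
#' Places `n_branches` side-branch events and `n_calcium` calcium deposits
#' uniformly at random along the vessel without longitudinal overlap
#' (rejection sampling with bounded retries), each with a random angular
#' position/extent, and draws the phase of the eccentricity modulation.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A `"phantom_config"`.
#' @return A `"phantom_vessel"`: the config plus `ecc_phase` and the
#'   `branches` / `calcium` event tables (`s_lo`, `s_hi`, angles in the
#'   vessel frame).
#' @export
make_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  ecc_phase <- stats::runif(1, 0, 2 * pi)
  spans <- c(rep(cfg$branch_span_mm, cfg$n_branches),
             rep(cfg$calcium_span_mm, cfg$n_calcium))
  n_ev <- length(spans)
  centers <- numeric(0)
  if (n_ev > 0) {
    margin <- 1
    lo <- margin + spans / 2
    hi <- cfg$length_mm - margin - spans / 2
    if (any(hi <= lo)) stop("phantom config error: events do not fit", call. = FALSE)
    ok <- FALSE
    for (try in seq_len(1000)) {
      centers <- stats::runif(n_ev, lo, hi)
      sep <- outer(centers, centers, function(a, b) abs(a - b))
      need <- outer(spans, spans, function(a, b) (a + b) / 2)
      diag(sep) <- Inf
      if (all(sep >= need)) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("phantom config error: could not place events without overlap",
           call. = FALSE)
    }
  }
  bi <- seq_len(cfg$n_branches)
  ci <- cfg$n_branches + seq_len(cfg$n_calcium)
  branches <- data.frame(
    s_lo = centers[bi] - spans[bi] / 2,
    s_hi = centers[bi] + spans[bi] / 2,
    angle_deg = stats::runif(cfg$n_branches, 0, 360),
    width_deg = stats::runif(cfg$n_branches, cfg$branch_width_deg[1],
                             cfg$branch_width_deg[2]))
  calcium <- data.frame(
    s_lo = centers[ci] - spans[ci] / 2,
    s_hi = centers[ci] + spans[ci] / 2,
    start_deg = stats::runif(cfg$n_calcium, 0, 360),
    arc_deg = stats::runif(cfg$n_calcium, cfg$calcium_arc_deg[1],
                           cfg$calcium_arc_deg[2]))
  structure(list(cfg = cfg, ecc_phase = ecc_phase,
                 branches = branches, calcium = calcium),
            class = "phantom_vessel")
}

# angle (deg) within a circular arc [start, start + width)?
in_arc <- function(angle_deg, start_deg, width_deg) {
  ((angle_deg - start_deg) %% 360) < width_deg
}

# Emit one annotated frame at arc-length s, with the image frame rotated
# so that a vessel-frame feature at angle a appears at image angle a - phi.
emit_frame <- function(vessel, s, phi_deg, modality, index, position_mm) {
  cfg <- vessel$cfg
  p <- cfg$contour_points
  th_img <- (seq_len(p) - 1) * 360 / p
  r <- phantom_radius(vessel, s, th_img + phi_deg) +
    stats::rnorm(p, 0, cfg$contour_noise_sd_mm)
  r <- pmax(r, 0.05)
  rad <- th_img * pi / 180
  lumen <- cbind(r * cos(rad), r * sin(rad))
  branches <- NULL
  for (e in seq_len(nrow(vessel$branches))) {
    ev <- vessel$branches[e, ]
    if (s < ev$s_lo || s > ev$s_hi) next
    if (stats::runif(1) < cfg$feature_dropout_prob) next
    a_img <- (ev$angle_deg - phi_deg) %% 360
    rr <- phantom_radius(vessel, s, ev$angle_deg)
    side <- max(rr * ev$width_deg * pi / 180, 0.05)
    bb <- branch_box(rr * cos(a_img * pi / 180), rr * sin(a_img * pi / 180),
                     side, side)
    branches <- if (is.null(branches)) bb else rbind(branches, bb)
  }
  calc <- integer(180)
  bin_centers_img <- (0:179) * 2 + 1
  for (e in seq_len(nrow(vessel$calcium))) {
    ev <- vessel$calcium[e, ]
    if (s < ev$s_lo || s > ev$s_hi) next
    if (stats::runif(1) < cfg$feature_dropout_prob) next
    hit <- in_arc(bin_centers_img + phi_deg, ev$start_deg, ev$arc_deg)
    calc[hit] <- 1L
  }
  frame(modality, index, position_mm, is_ed = TRUE,
        lumen = lumen, branches = branches, calcium = calc)
}

#' Acquire the IVUS pullback of a phantom vessel
#'
#' ED frame positions are `i * ivus_frame_spacing_mm` plus zero-mean
#' Gaussian cardiac jitter, sorted (ED gating leaves positions monotone but
#' jittered). Contours get additive radial noise; branch and calcium
#' annotations within an event's range are each dropped independently with
#' `feature_dropout_prob`. Deterministic given the config seed.
#'
#' @param vessel A `"phantom_vessel"`.
#' @return List with `pullback` (an `"ivoct_pullback"`) and `s`, the true
#'   arc-length of each frame.
#' @export
acquire_ivus <- function(vessel) {
  cfg <- vessel$cfg
  set.seed(cfg$seed + 1L)
  sp <- cfg$ivus_frame_spacing_mm
  n <- floor(cfg$length_mm / sp) + 1
  s <- (seq_len(n) - 1) * sp + stats::rnorm(n, 0, cfg$ivus_cardiac_jitter_mm)
  s <- sort(pmin(pmax(s, 0), cfg$length_mm))
  if (any(diff(s) <= 0)) {           # keep strictly increasing under ties
    s <- s + (seq_len(n) - 1) * 1e-9
  }
  frames <- lapply(seq_len(n), function(i) {
    emit_frame(vessel, s[i], phi_deg = 0, modality = "IVUS",
               index = i - 1L, position_mm = (i - 1) * sp)
  })
  list(pullback = pullback("IVUS", frames, sp), s = s)
}

#' Acquire the OCT pullback of a phantom vessel
#'
#' Frames at exact `j * oct_frame_spacing_mm`; the catheter rotation starts
#' uniform in `[0, 360)` and drifts as a Gaussian random walk with step sd
#' `drift_step_sd_deg`. All angular annotations are rotated by the frame's
#' drift before emission; the noise/dropout model matches the IVUS
#' acquisition. Deterministic given the config seed.
#'
#' @param vessel A `"phantom_vessel"`.
#' @return List with `pullback`, `s` (true arc-lengths) and `rotation_deg`,
#'   the true per-frame rotation in `[0, 360)` (the CCW angle aligning each
#'   OCT frame with the vessel/IVUS orientation).
#' @export
acquire_oct <- function(vessel) {
  cfg <- vessel$cfg
  set.seed(cfg$seed + 2L)
  sp <- cfg$oct_frame_spacing_mm
  n <- floor(cfg$length_mm / sp) + 1
  s <- (seq_len(n) - 1) * sp
  phi0 <- stats::runif(1, 0, 360)
  steps <- stats::rnorm(n - 1, 0, cfg$drift_step_sd_deg)
  phi <- (phi0 + cumsum(c(0, steps))) %% 360
  frames <- lapply(seq_len(n), function(j) {
    emit_frame(vessel, s[j], phi_deg = phi[j], modality = "OCT",
               index = j - 1L, position_mm = s[j])
  })
  list(pullback = pullback("OCT", frames, sp), s = s, rotation_deg = phi)
}

#' Simulate a paired phantom acquisition with ground truth
#'
#' @param cfg A `"phantom_config"`.
#' @return An object of class `"phantom_pair"`: `ivus` and `oct` pullbacks,
#'   plus `truth`, a list with the true per-frame arc-lengths of both
#'   modalities, the true per-OCT-frame rotation, the event tables, and the
#'   OCT frame spacing.
#' @export
simulate_phantom <- function(cfg = phantom_config()) {
  vessel <- make_phantom(cfg)
  iv <- acquire_ivus(vessel)
  oc <- acquire_oct(vessel)
  structure(list(
    ivus = iv$pullback,
    oct = oc$pullback,
    truth = list(ivus_s = iv$s, oct_s = oc$s,
                 oct_rotation_deg = oc$rotation_deg,
                 branches = vessel$branches, calcium = vessel$calcium,
                 oct_frame_spacing_mm = cfg$oct_frame_spacing_mm),
    config = cfg
  ), class = "phantom_pair")
}

#' True IVUS-to-OCT correspondence of a phantom
#'
#' Inverts the OCT arc-length grid: each IVUS frame's continuous OCT index
#' is `(s_IVUS - s_OCT[1]) / oct_frame_spacing_mm`, clamped to the OCT
#' range; the true rotation is looked up at the nearest OCT frame.
#'
#' @param truth The `truth` element of a `"phantom_pair"` (or the pair).
#' @return Data frame with `ivus_frame` (0-based), `true_oct_index`, and
#'   `true_rotation_deg`.
#' @export
true_correspondence <- function(truth) {
  if (inherits(truth, "phantom_pair")) truth <- truth$truth
  m <- length(truth$oct_s)
  idx <- (truth$ivus_s - truth$oct_s[1]) / truth$oct_frame_spacing_mm
  idx <- pmin(pmax(idx, 0), m - 1)
  data.frame(
    ivus_frame = seq_along(truth$ivus_s) - 1L,
    true_oct_index = idx,
    true_rotation_deg = truth$oct_rotation_deg[round(idx) + 1]
  )
}
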