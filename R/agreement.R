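# Observer-agreement evaluation suite: frame/angle difference summaries,
# Lin's concordance correlation, Spearman correlation, the Williams Index
# with a jackknife confidence interval, Bland-Altman limits of agreement,
# and the Wilcoxon signed-rank test.

#' Per-frame longitudinal differences between two frame maps
#'
#' @param map_a,map_b Continuous OCT frame indices over the same IVUS
#'   frames: numeric vectors of equal length, or data frames with columns
#'   `ivus_frame` and `oct_frame_continuous` covering identical frame sets.
#' @return Numeric vector of absolute differences, in OCT frames.
#' @export
frame_differences <- function(map_a, map_b) {
  v <- align_maps(map_a, map_b, "oct_frame_continuous")
  abs(v$a - v$b)
}

#' Per-frame circular angle differences, in degrees
#'
#' `min(|a-b| mod 360, 360 - |a-b| mod 360)`, always in `[0, 180]`.
#'
#' @param rot_a,rot_b Rotations in degrees over the same frames (vectors or
#'   data frames with `ivus_frame` and `rotation_deg`).
#' @return Numeric vector of circular absolute differences.
#' @export
angle_differences <- function(rot_a, rot_b) {
  v <- align_maps(rot_a, rot_b, "rotation_deg")
  circular_difference(v$a, v$b)
}

align_maps <- function(a, b, col) {
  if (is.data.frame(a) && is.data.frame(b)) {
    if (!identical(as.integer(a$ivus_frame), as.integer(b$ivus_frame))) {
      stop("the two maps must cover the same IVUS frames", call. = FALSE)
    }
    list(a = a[[col]], b = b[[col]])
  } else {
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) != length(b)) {
      stop("the two maps must cover the same IVUS frames", call. = FALSE)
    }
    list(a = a, b = b)
  }
}

#' Lin's concordance correlation coefficient
#'
#' `2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, with
#' population (1/n) moments as in Lin's original definition. Penalizes both
#' loss of correlation and location/scale shift, so `|CCC| <= |Pearson r|`.
#'
#' @param x,y Numeric vectors, length >= 3, not both constant.
#' @return Concordance in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  check_paired(x, y)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  if (vx == 0 && vy == 0) {
    stop("CCC undefined: both series are constant", call. = FALSE)
  }
  2 * mean((x - mx) * (y - my)) / (vx + vy + (mx - my)^2)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks under ties), via
#' [stats::cor()].
#'
#' @param x,y Numeric vectors, length >= 3, neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_r <- function(x, y) {
  check_paired(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined for a constant series", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

check_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in input", call. = FALSE)
  }
  invisible(NULL)
}

#' Williams Index of model-vs-experts agreement
#'
#' Ratio of the model's average agreement with two experts to the experts'
#' inter-agreement:
#' `WI = 0.5 * (1/D(M, E1) + 1/D(M, E2)) / (1/D(E1, E2))`,
#' with disagreement `D` the mean absolute difference (circular, in
#' degrees, when `circular = TRUE`). A WI above 1 means the model agrees
#' with the experts more than they agree with each other.
#'
#' The 95% confidence interval is a delete-one jackknife over `groups`
#' (typically the vessel each observation belongs to, matching the
#' per-vessel structure of a test set); with `groups = NULL` every
#' observation is its own group.
#'
#' @param model,expert1,expert2 Numeric series over the same frames.
#' @param groups Optional resampling-unit labels (e.g. vessel ids).
#' @param circular Use the circular absolute difference (for angles).
#' @return List with `wi`, `ci` (length-2, `NA` when fewer than 3 groups),
#'   and the three pairwise disagreements.
#' @export
williams_index <- function(model, expert1, expert2, groups = NULL,
                           circular = FALSE) {
  n <- length(model)
  if (length(expert1) != n || length(expert2) != n) {
    stop("all three series must cover the same frames", call. = FALSE)
  }
  dd <- function(a, b, idx = seq_len(n)) {
    if (circular) mean(circular_difference(a[idx], b[idx]))
    else mean(abs(a[idx] - b[idx]))
  }
  wi_of <- function(idx) {
    d12 <- dd(expert1, expert2, idx)
    dm1 <- dd(model, expert1, idx)
    dm2 <- dd(model, expert2, idx)
    if (d12 == 0 || dm1 == 0 || dm2 == 0) {
      stop("Williams Index undefined: a pairwise disagreement is zero",
           call. = FALSE)
    }
    d12 * (1 / dm1 + 1 / dm2) / 2
  }
  wi <- wi_of(seq_len(n))
  if (is.null(groups)) groups <- seq_len(n)
  g <- unique(groups)
  ci <- c(NA_real_, NA_real_)
  if (length(g) >= 3) {
    loo <- vapply(g, function(gg) wi_of(which(groups != gg)), numeric(1))
    pseudo <- length(g) * wi - (length(g) - 1) * loo
    se <- stats::sd(pseudo) / sqrt(length(g))
    ci <- mean(pseudo) + c(-1.96, 1.96) * se
  }
  list(wi = wi, ci = ci,
       d_experts = dd(expert1, expert2),
       d_model_e1 = dd(model, expert1),
       d_model_e2 = dd(model, expert2))
}

#' Bland-Altman bias and limits of agreement
#'
#' @param x,y Paired measurements, length >= 3.
#' @return List with `bias = mean(x - y)` and `lower`/`upper` limits
#'   `bias +/- 1.96 * sd(x - y)` (sample sd).
#' @export
bland_altman <- function(x, y) {
  check_paired(x, y)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s)
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Two-sided test that the paired differences `x - y` are symmetric about
#' zero. Zero differences are dropped; absolute differences are mid-ranked
#' under ties. For n <= 25 the p-value is exact, from the full distribution
#' of the positive-rank sum over all 2^n sign assignments (computed by
#' generating-function convolution, which handles tied mid-ranks); for
#' larger n a normal approximation with continuity correction and
#' tie-corrected variance `sum(r^2)/4` is used.
#'
#' @param x,y Paired samples; at least 6 nonzero differences required.
#' @return List with `statistic` (positive-rank sum V), `p_value`, `n`
#'   (nonzero pairs) and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero", call. = FALSE)
  if (n < 6) {
    stop("need at least 6 nonzero paired differences", call. = FALSE)
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    # distribution of sum(eps * r) over eps in {0,1}^n; double the ranks so
    # mid-ranks become integers
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1)
    f[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(tot + 1 - ri)])
      f <- f + shifted
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * W))
    p_lo <- sum(probs[seq_len(w2 + 1)])
    p_hi <- sum(probs[(w2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(sum(r^2) / 4)
    z <- (W - mu - 0.5 * sign(W - mu)) / sigma
    p <- if (W == mu) 1 else 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with continuity correction"
  }
  list(statistic = W, p_value = p, n = n, method = method)
}

#' Pairwise agreement report between two registrations
#'
#' Summarizes the agreement between two longitudinal (and optionally
#' rotational) correspondence estimates over the same IVUS frames: median
#' (IQR) frame and angle differences, Lin's CCC, Spearman correlation, and
#' Bland-Altman bias/limits on the frame maps.
#'
#' @param est,ref Alignment tables (data frames with `ivus_frame`,
#'   `oct_frame_continuous` and optionally `rotation_deg`).
#' @param oct_spacing_mm OCT inter-frame spacing used to convert frame
#'   differences to mm (default 0.2).
#' @return An object of class `"agreement_report"`.
#' @export
agreement_report <- function(est, ref, oct_spacing_mm = 0.2) {
  fd <- frame_differences(est, ref)
  rep <- list(
    n = length(fd),
    median_frame_diff = stats::median(fd),
    frame_diff_iqr = unname(stats::quantile(fd, c(0.25, 0.75))),
    median_frame_diff_mm = stats::median(fd) * oct_spacing_mm,
    ccc = lin_ccc(est$oct_frame_continuous, ref$oct_frame_continuous),
    spearman_r = spearman_r(est$oct_frame_continuous,
                            ref$oct_frame_continuous),
    bland_altman = bland_altman(est$oct_frame_continuous,
                                ref$oct_frame_continuous)
  )
  if (!is.null(est$rotation_deg) && !is.null(ref$rotation_deg)) {
    ad <- angle_differences(est, ref)
    rep$median_angle_diff_deg <- stats::median(ad)
    rep$angle_diff_iqr <- unname(stats::quantile(ad, c(0.25, 0.75)))
  }
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d matched frames\n", x$n))
  cat(sprintf("  frame difference: median %.2f (IQR %.2f-%.2f) frames = %.2f mm\n",
              x$median_frame_diff, x$frame_diff_iqr[1], x$frame_diff_iqr[2],
              x$median_frame_diff_mm))
  cat(sprintf("  CCC %.4f, Spearman r %.4f, Bland-Altman bias %.3f (%.3f, %.3f)\n",
              x$ccc, x$spearman_r, x$bland_altman$bias,
              x$bland_altman$lower, x$bland_altman$upper))
  if (!is.null(x$median_angle_diff_deg)) {
    cat(sprintf("  angle difference: median %.1f (IQR %.1f-%.1f) deg\n",
                x$median_angle_diff_deg, x$angle_diff_iqr[1],
                x$angle_diff_iqr[2]))
  }
  invisible(x)
}

#' Three-way observer report: a model against two reference observers
#'
#' Produces the standard evaluation table for a registration method against
#' two independent reference registrations: the pairwise agreement of the
#' references with each other and of the model with each reference, the
#' Williams Index (longitudinal, and circumferential when rotations are
#' present) with its jackknife CI, and a Wilcoxon signed-rank comparison of
#' the inter-reference differences against the model-vs-first-reference
#' differences.
#'
#' @param model,ref1,ref2 Alignment tables over the same IVUS frames.
#' @param groups Optional per-frame vessel labels for the jackknife.
#' @param oct_spacing_mm OCT inter-frame spacing (mm).
#' @return An object of class `"observer_report"`: list with the three
#'   pairwise [agreement_report()]s, `wi_frames`, optionally `wi_angles`,
#'   and `wilcoxon_frames`.
#' @export
observer_report <- function(model, ref1, ref2, groups = NULL,
                            oct_spacing_mm = 0.2) {
  out <- list(
    ref1_vs_ref2 = agreement_report(ref1, ref2, oct_spacing_mm),
    model_vs_ref1 = agreement_report(model, ref1, oct_spacing_mm),
    model_vs_ref2 = agreement_report(model, ref2, oct_spacing_mm),
    wi_frames = williams_index(model$oct_frame_continuous,
                               ref1$oct_frame_continuous,
                               ref2$oct_frame_continuous, groups = groups),
    wilcoxon_frames = tryCatch(
      wilcoxon_signed_rank(frame_differences(ref1, ref2),
                           frame_differences(model, ref1)),
      error = function(e) NULL)
  )
  if (!is.null(model$rotation_deg) && !is.null(ref1$rotation_deg) &&
      !is.null(ref2$rotation_deg)) {
    out$wi_angles <- williams_index(model$rotation_deg, ref1$rotation_deg,
                                    ref2$rotation_deg, groups = groups,
                                    circular = TRUE)
  }
  structure(out, class = "observer_report")
}

#' @export
print.observer_report <- function(x, ...) {
  row <- function(label, r) {
    cat(sprintf("  %-16s frames %.2f (%.2f-%.2f)%s\n", label,
                r$median_frame_diff, r$frame_diff_iqr[1], r$frame_diff_iqr[2],
                if (!is.null(r$median_angle_diff_deg))
                  sprintf("; angle %.1f (%.1f-%.1f) deg",
                          r$median_angle_diff_deg, r$angle_diff_iqr[1],
                          r$angle_diff_iqr[2]) else ""))
  }
  cat("Observer agreement (median difference, IQR)\n")
  row("ref1 vs ref2", x$ref1_vs_ref2)
  row("model vs ref1", x$model_vs_ref1)
  row("model vs ref2", x$model_vs_ref2)
  cat(sprintf("  Williams Index (frames): %.3f (95%% CI %.3f-%.3f)\n",
              x$wi_frames$wi, x$wi_frames$ci[1], x$wi_frames$ci[2]))
  if (!is.null(x$wi_angles)) {
    cat(sprintf("  Williams Index (angles): %.3f (95%% CI %.3f-%.3f)\n",
                x$wi_angles$wi, x$wi_angles$ci[1], x$wi_angles$ci[2]))
  }
  if (!is.null(x$wilcoxon_frames)) {
    cat(sprintf("  Wilcoxon (inter-ref vs model-ref frame diffs): p = %.4f\n",
                x$wilcoxon_frames$p_value))
  }
  invisible(x)
}
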