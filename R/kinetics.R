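#' Tumor region-of-interest mask
#'
#' @param mask logical matrix (same shape as the image frames); `TRUE`
#'   inside the tumor as annotated on the co-registered ultrasound B-scan.
#' @param label short text label.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "tumor") {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask, na.rm = TRUE))
    stop("ROI mask has no TRUE pixel", call. = FALSE)
  structure(list(mask = mask, label = label), class = "roi_mask")
}

#' PDT treatment timeline
#'
#' Milestones of a monitoring session: baseline start, light on, light off
#' and end of monitoring, all in seconds of recording time. `t_active_end`
#' (the detected end of active PDT) is filled in by
#' [detect_active_pdt_end()].
#'
#' @param t_baseline_start,t_light_on,t_light_off,t_end milestones (s),
#'   with `t_baseline_start <= t_light_on < t_light_off <= t_end`.
#' @param t_active_end optional detected end of active PDT, inside
#'   `[t_light_on, t_end]`.
#' @return An object of class `pdt_timeline`.
#' @export
pdt_timeline <- function(t_baseline_start = 0, t_light_on, t_light_off,
                         t_end, t_active_end = NA_real_) {
  if (!(t_baseline_start <= t_light_on && t_light_on < t_light_off &&
        t_light_off <= t_end))
    stop("timeline must satisfy baseline <= light_on < light_off <= end",
         call. = FALSE)
  if (!is.na(t_active_end) &&
      (t_active_end < t_light_on || t_active_end > t_end))
    stop("t_active_end must lie in [t_light_on, t_end]", call. = FALSE)
  structure(list(t_baseline_start = t_baseline_start,
                 t_light_on = t_light_on, t_light_off = t_light_off,
                 t_end = t_end, t_active_end = t_active_end),
            class = "pdt_timeline")
}

#' ROI-mean StO2/HbT trace
#'
#' Averages StO2 and HbT over the ROI for every frame, excluding masked
#' (zero) pixels, i.e. only pixels that are inside the ROI *and* above the
#' noise floor contribute. Frames with no valid ROI pixel yield `NA` and are
#' flagged; they are skipped (not imputed) by the downstream filtering and
#' normalization.
#'
#' @param maps an `oximetry_stack` from [unmix_stack()] (after
#'   [apply_threshold()]), or a list of [oximetry_maps()].
#' @param roi a [roi_mask()] of matching shape.
#' @param timeline a [pdt_timeline()].
#' @return An object of class `sto2_trace` with channels `t`, `raw`,
#'   `hbt_raw` and (initially `NULL`) `filtered`, `normalized`, plus the
#'   timeline and a `n_valid` pixel count per frame.
#' @export
roi_mean_trace <- function(maps, roi, timeline) {
  if (!inherits(roi, "roi_mask")) stop("roi must be a roi_mask", call. = FALSE)
  if (inherits(maps, "oximetry_stack")) {
    d <- dim(maps$sto2)[1:2]
    if (!identical(d, dim(roi$mask)))
      stop("ROI shape does not match the maps", call. = FALSE)
    nT <- length(maps$t)
    rvec <- as.logical(roi$mask)
    sto2 <- matrix(maps$sto2, ncol = nT)[rvec, , drop = FALSE]
    hbt <- matrix(maps$hbt, ncol = nT)[rvec, , drop = FALSE]
    ok <- matrix(maps$mask, ncol = nT)[rvec, , drop = FALSE]
    n_valid <- colSums(ok)
    raw <- ifelse(n_valid > 0, colSums(sto2 * ok) / n_valid, NA_real_)
    hbt_raw <- ifelse(n_valid > 0, colSums(hbt * ok) / n_valid, NA_real_)
    tt <- maps$t
  } else {
    maps <- if (inherits(maps, "oximetry_maps")) list(maps) else maps
    if (!identical(dim(maps[[1L]]$sto2), dim(roi$mask)))
      stop("ROI shape does not match the maps", call. = FALSE)
    per <- vapply(maps, function(m) {
      ok <- roi$mask & m$mask
      n <- sum(ok)
      c(if (n > 0) mean(m$sto2[ok]) else NA_real_,
        if (n > 0) mean(m$hbt[ok]) else NA_real_,
        n, m$t)
    }, numeric(4))
    raw <- per[1L, ]; hbt_raw <- per[2L, ]
    n_valid <- per[3L, ]; tt <- per[4L, ]
  }
  structure(list(t = tt, raw = raw, filtered = NULL, normalized = NULL,
                 hbt_raw = hbt_raw, n_valid = n_valid,
                 timeline = timeline, roi_label = roi$label),
            class = "sto2_trace")
}

#' Sliding-window median filter with truncated edges
#'
#' One-dimensional running median of window length `order`. At the series
#' edges the window is truncated to the in-bounds samples (no padding):
#' zero-padding would bias the 100% baseline downward at the recording
#' start. `NA` samples are excluded from each window's median.
#'
#' @param values numeric vector.
#' @param order odd window length, `1 <= order <= length(values)`
#'   (default 15).
#' @return Filtered vector of the same length.
#' @export
median_filter_trace <- function(values, order = 15L) {
  n <- length(values)
  if (length(order) != 1L || order %% 2L != 1L || order < 1L)
    stop("filter order must be a single odd integer >= 1", call. = FALSE)
  if (order > n)
    stop("filter order exceeds series length", call. = FALSE)
  half <- (order - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- values[max(1L, i - half):min(n, i + half)]
    w <- w[!is.na(w)]
    out[i] <- if (length(w)) stats::median(w) else NA_real_
  }
  out
}

#' Normalize a trace to a 100% pre-treatment baseline
#'
#' Multiplies the series by `100 / baseline_mean`, where the baseline mean
#' is taken over the pre-light window `[t_baseline_start, t_light_on)`.
#' The normalized series then averages exactly 100 over that window,
#' removing inter-subject variation in resting StO2.
#'
#' @param values numeric vector (typically the filtered channel).
#' @param t sample times (s), same length.
#' @param timeline a [pdt_timeline()].
#' @return Normalized vector (percent of baseline).
#' @export
normalize_trace <- function(values, t, timeline) {
  idx <- t >= timeline$t_baseline_start & t < timeline$t_light_on
  base <- values[idx]
  base <- base[!is.na(base)]
  if (!length(base))
    stop("no baseline samples in [t_baseline_start, t_light_on)",
         call. = FALSE)
  bm <- mean(base)
  if (!is.finite(bm) || bm <= 0)
    stop("baseline mean must be positive to normalize", call. = FALSE)
  values * (100 / bm)
}

#' Filter and normalize an ROI trace
#'
#' Fills the `filtered` (running median, [median_filter_trace()]) and
#' `normalized` ([normalize_trace()]) channels of a trace. The Methods
#' order is filter first, then normalize.
#'
#' @param trace an `sto2_trace` from [roi_mean_trace()].
#' @param filter_order odd median-filter window (default 15).
#' @return The trace with `filtered` and `normalized` channels set.
#' @export
build_sto2_trace <- function(trace, filter_order = 15L) {
  trace$filtered <- median_filter_trace(trace$raw, filter_order)
  trace$normalized <- normalize_trace(trace$filtered, trace$t,
                                      trace$timeline)
  trace
}

#' Moving least-squares slope of a time series
#'
#' Per-index ordinary least-squares slope of value against time over a
#' centered window of `window` samples, truncated at the series edges.
#' `NA` samples are dropped within each window; windows with fewer than two
#' usable samples yield `NA`.
#'
#' @param values numeric vector (normalized StO2, percent).
#' @param t times in seconds.
#' @param window window length in samples, >= 2 (default 15).
#' @return Slope series in percent per minute.
#' @export
moving_slope <- function(values, t, window = 15L) {
  n <- length(values)
  if (length(window) != 1L || window < 2L)
    stop("slope window must be a single integer >= 2", call. = FALSE)
  if (window > n)
    stop("slope window exceeds series length", call. = FALSE)
  lo_half <- (window - 1L) %/% 2L
  hi_half <- window %/% 2L
  tm <- t / 60                       # minutes
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - lo_half):min(n, i + hi_half)
    y <- values[j]; x <- tm[j]
    ok <- !is.na(y)
    if (sum(ok) < 2L) next
    x <- x[ok]; y <- y[ok]
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    if (sxx == 0) next
    out[i] <- sum(xc * y) / sxx
  }
  out
}

#' Mean StO2 depletion rate over the start of irradiation
#'
#' Averages the [moving_slope()] of the normalized channel over the first
#' `duration` seconds of light (`t` in `[t_light_on, t_light_on +
#' duration]`), the summary used to compare treatment groups.
#'
#' @param trace an `sto2_trace` with a `normalized` channel (see
#'   [build_sto2_trace()]).
#' @param duration averaging span in seconds after light-on (default 300,
#'   i.e. the first 5 min of irradiation).
#' @param window moving-slope window in samples (default 15).
#' @return Scalar rate in normalized percent per minute (negative =
#'   depletion).
#' @export
mean_depletion_rate <- function(trace, duration = 300, window = 15L) {
  if (is.null(trace$normalized))
    stop("trace has no normalized channel; run build_sto2_trace() first",
         call. = FALSE)
  tl <- trace$timeline
  if (tl$t_light_on + duration > max(trace$t))
    warning("averaging window extends past the recording; ",
            "using available samples")
  slopes <- moving_slope(trace$normalized, trace$t, window)
  idx <- trace$t >= tl$t_light_on & trace$t <= tl$t_light_on + duration
  if (!any(idx)) stop("no samples in the rate window", call. = FALSE)
  mean(slopes[idx], na.rm = TRUE)
}

#' Detect the end of active PDT
#'
#' Active PDT is the interval of ongoing photochemical oxygen depletion; it
#' ends when the tumor StO2 trace stops decreasing. The default `argmin`
#' rule locates the global minimum of the normalized channel over the light
#' interval `[t_light_on, t_light_off]`. Because the sliding-median filter
#' maps a V-shaped trough onto a run of exactly tied samples (several
#' consecutive windows share the same median sample), the minimum is
#' generically a tied plateau rather than a point; returning its first
#' sample would bias the estimate early by up to half a filter window. The
#' rule therefore returns the center of the tied run -- unless the run
#' reaches the last sample of the light interval, in which case the trace
#' was still declining when the light stopped and `t_light_off` is returned
#' (active PDT lasts until the end of the light dose); a strictly monotone
#' decline yields `t_light_off` as a special case. The alternative
#' `plateau` rule returns the first time after which the trace never drops
#' more than `delta` below its running minimum for `run` consecutive
#' samples, a sustained-non-decrease criterion for traces whose minimum is
#' noisy or flat.
#'
#' @param trace an `sto2_trace` with a `normalized` channel.
#' @param rule `"argmin"` (default) or `"plateau"`.
#' @param delta plateau tolerance in normalized percent (default 0.5).
#' @param run plateau run length in samples (default 15).
#' @return Time of the end of active PDT (s).
#' @export
detect_active_pdt_end <- function(trace, rule = c("argmin", "plateau"),
                                  delta = 0.5, run = 15L) {
  rule <- match.arg(rule)
  if (is.null(trace$normalized))
    stop("trace has no normalized channel; run build_sto2_trace() first",
         call. = FALSE)
  tl <- trace$timeline
  idx <- which(trace$t >= tl$t_light_on & trace$t <= tl$t_light_off &
                 !is.na(trace$normalized))
  if (!length(idx))
    stop("no usable samples in the light interval", call. = FALSE)
  v <- trace$normalized[idx]
  if (rule == "argmin") {
    tied <- which(v == min(v))
    run <- tied[1L]
    while ((run[length(run)] + 1L) %in% tied)
      run <- c(run, run[length(run)] + 1L)
    if (run[length(run)] == length(v)) return(tl$t_light_off)
    return(trace$t[idx[run[ceiling(length(run) / 2)]]])
  }
  rmin <- cummin(v)
  n <- length(v)
  for (i in seq_len(n)) {
    hi <- i + run
    if (hi > n) break
    if (all(v[(i + 1L):hi] > rmin[i] - delta)) return(trace$t[idx[i]])
  }
  tl$t_light_off
}

#' Severinghaus oxygen dissociation curve
#'
#' Empirical blood oxygen relation
#' `S = 100 / (23400 / (p^3 + 150 p) + 1)` mapping oxygen partial pressure
#' `p` (mmHg) to hemoglobin saturation (percent). Strictly increasing on
#' `p > 0`; at 10 mmHg it evaluates to ~10% saturation, the conventional
#' hypoxia landmark.
#'
#' @param po2 oxygen partial pressure(s) in mmHg, > 0.
#' @return Saturation in percent, in (0, 100).
#' @export
severinghaus_so2 <- function(po2) {
  if (any(!is.finite(po2)) || any(po2 <= 0))
    stop("pO2 must be finite and > 0", call. = FALSE)
  100 / (23400 / (po2^3 + 150 * po2) + 1)
}

#' Inverse Severinghaus relation
#'
#' Solves the Severinghaus curve for pO2 given a saturation, via the unique
#' positive root of the monotone cubic `p^3 + 150 p = 23400 S/(100 - S)`.
#'
#' @param so2 saturation(s) in percent, in (0, 100).
#' @return pO2 in mmHg.
#' @export
severinghaus_po2 <- function(so2) {
  if (any(!is.finite(so2)) || any(so2 <= 0) || any(so2 >= 100))
    stop("SO2 must lie strictly between 0 and 100 percent", call. = FALSE)
  vapply(so2, function(s) {
    k <- 23400 * s / (100 - s)
    stats::uniroot(function(p) p^3 + 150 * p - k,
                   lower = 0, upper = max(1, k^(1 / 3) + 1),
                   tol = 1e-12)$root
  }, numeric(1))
}

#' Compare depletion rates across treatment groups
#'
#' Ordinary one-way ANOVA across groups followed by Tukey's honestly
#' significant difference pairwise comparisons; pairs with adjusted
#' p < `alpha` are flagged significant.
#'
#' @param rates numeric vector of per-subject rates (normalized percent per
#'   minute), or a data.frame with columns `group` and `rate`.
#' @param group grouping factor (ignored when `rates` is a data.frame).
#' @param alpha significance level (default 0.05).
#' @return A data.frame with one row per group pair: `pair`, `diff`, `lwr`,
#'   `upr`, `p_adj`, `significant`; the ANOVA F statistic and p-value are
#'   attached as attributes `F`, `p_value`.
#' @export
compare_group_rates <- function(rates, group = NULL, alpha = 0.05) {
  if (is.data.frame(rates)) {
    group <- rates$group
    rates <- rates$rate
  }
  group <- factor(group)
  if (nlevels(group) < 2L)
    stop("need at least two groups", call. = FALSE)
  n_per <- table(group)
  if (any(n_per < 2L))
    stop("every group needs at least two subjects; offending group(s): ",
         paste(names(n_per)[n_per < 2L], collapse = ", "), call. = FALSE)
  fit <- stats::aov(rates ~ group, data = data.frame(rates = rates,
                                                     group = group))
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  out <- data.frame(pair = rownames(tk),
                    diff = tk[, "diff"], lwr = tk[, "lwr"],
                    upr = tk[, "upr"], p_adj = tk[, "p adj"],
                    significant = tk[, "p adj"] < alpha,
                    row.names = NULL)
  attr(out, "F") <- an[["F value"]][1L]
  attr(out, "p_value") <- an[["Pr(>F)"]][1L]
  out
}
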