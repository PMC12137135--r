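#' Light dose from fluence rate and duration
#'
#' `dose = fluence_rate/1000 * duration`, in J/cm^2 (conventionally printed
#' as "J"): 100 mW/cm^2 for 15 min gives 90 J, 400 mW/cm^2 gives 360 J.
#'
#' @param fluence_rate fluence rate in mW/cm^2, > 0.
#' @param duration irradiation time in seconds, > 0.
#' @return Energy dose in J (per cm^2).
#' @export
light_dose <- function(fluence_rate, duration) {
  if (any(!is.finite(fluence_rate)) || any(fluence_rate <= 0) ||
      any(!is.finite(duration)) || any(duration <= 0))
    stop("fluence rate and duration must be positive", call. = FALSE)
  fluence_rate / 1000 * duration
}

#' Default analysis parameters
#'
#' The pipeline defaults: 15th-order trace median filter, 15-sample
#' moving-slope window, 20 x 20 px corner noise patches, a 300 s (5 min)
#' rate-averaging window, the `argmin` endpoint rule and the centroid ROI
#' split.
#'
#' @return Named list of parameters.
#' @export
default_parameters <- function() {
  list(filter_order = 15L, slope_window = 15L, patch_size = 20L,
       rate_duration = 300, endpoint_rule = "argmin",
       split = "centroid", threshold_override = NA_real_)
}

#' Run the full oximetry analysis on a frame stack
#'
#' Executes the pipeline in memory: non-negative spectral unmixing of every
#' frame, corner-patch noise-floor estimation and masking, ROI-mean trace
#' extraction with median filtering and baseline normalization, depletion
#' rate and end-of-active-PDT detection, the active-PDT delta map
#' (pre-light vs end of active PDT) and the reoxygenation map (end of
#' active PDT vs end of monitoring), plus lateral-half ROI rates for
#' asymmetric-dose analysis.
#'
#' @param stack a [frame_stack()].
#' @param roi a [roi_mask()].
#' @param timeline a [pdt_timeline()].
#' @param ext an [extinction_table()] (default bundled values).
#' @param params parameter list as from [default_parameters()]; entries may
#'   be overridden individually.
#' @return List with `trace` (annotated `sto2_trace`), `threshold`,
#'   `maps` (oximetry maps at the pre-light, active-end and final
#'   milestones), `delta_active`, `reoxygenation` (both `delta_map`s),
#'   `halves` (left/right ROI masks and their depletion rates) and
#'   `summary` (named numeric vector).
#' @export
analyze_stack <- function(stack, roi, timeline, ext = hb_extinction(),
                          params = default_parameters()) {
  params <- utils::modifyList(default_parameters(), params)
  E <- extinction_matrix(ext)
  d <- dim(stack$frames[[1L]]$img_750)
  if (!identical(d, dim(roi$mask)))
    stop("ROI shape does not match the frames", call. = FALSE)
  tt <- frame_times(stack)

  # Unmix only the pixels the kinetics need (ROI + corner noise patches);
  # full frames are unmixed at the three milestones below. Numerically
  # identical to unmixing the whole stack, since the solve is per-pixel.
  ps <- params$patch_size
  if (d[1L] < ps || d[2L] < 2L * ps)
    stop(sprintf("image %d x %d too small for two %d x %d corner patches",
                 d[1L], d[2L], ps, ps), call. = FALSE)
  corner <- matrix(FALSE, d[1L], d[2L])
  corner[seq_len(ps), c(seq_len(ps), (d[2L] - ps + 1L):d[2L])] <- TRUE
  sel <- which(roi$mask | corner)
  nsel <- length(sel)
  m750 <- vapply(stack$frames, function(f) f$img_750[sel], numeric(nsel))
  m850 <- vapply(stack$frames, function(f) f$img_850[sel], numeric(nsel))
  C <- nnls2v(E, as.numeric(m750), as.numeric(m850))
  hbt_sel <- matrix(C$hbo + C$hbd, nsel)
  sto2_sel <- matrix(0, nsel, ncol(hbt_sel))
  pos <- hbt_sel > 0
  sto2_sel[pos] <- 100 * matrix(C$hbo, nsel)[pos] / hbt_sel[pos]

  threshold <- if (is.finite(params$threshold_override)) {
    params$threshold_override
  } else {
    mean(hbt_sel[corner[sel], ])
  }
  ok_sel <- hbt_sel >= threshold & hbt_sel > 0

  masked_mean <- function(member) {
    inr <- member[sel]
    ok <- ok_sel[inr, , drop = FALSE]
    n <- colSums(ok)
    ifelse(n > 0,
           colSums(sto2_sel[inr, , drop = FALSE] * ok) / n, NA_real_)
  }
  raw <- masked_mean(roi$mask)
  nok <- colSums(ok_sel[roi$mask[sel], , drop = FALSE])
  hbt_raw <- {
    inr <- roi$mask[sel]
    ok <- ok_sel[inr, , drop = FALSE]
    ifelse(nok > 0,
           colSums(hbt_sel[inr, , drop = FALSE] * ok) / nok, NA_real_)
  }
  trace <- structure(list(t = tt, raw = raw, filtered = NULL,
                          normalized = NULL, hbt_raw = hbt_raw,
                          n_valid = nok, timeline = timeline,
                          roi_label = roi$label),
                     class = "sto2_trace")
  trace <- build_sto2_trace(trace, params$filter_order)
  rate <- mean_depletion_rate(trace, params$rate_duration,
                              params$slope_window)
  t_active <- detect_active_pdt_end(trace, params$endpoint_rule)
  trace$timeline$t_active_end <- t_active

  idx_pre <- max(which(tt < timeline$t_light_on))
  idx_active <- which.min(abs(tt - t_active))
  idx_end <- length(tt)
  milestone <- function(i) {
    apply_threshold(compute_oximetry(stack$frames[[i]], ext), threshold)
  }
  maps <- list(pre_light = milestone(idx_pre),
               active_end = milestone(idx_active),
               final = milestone(idx_end))
  delta_active <- delta_sto2(maps$pre_light, maps$active_end)
  reox <- reoxygenation_map(maps$active_end, maps$final)

  halves <- split_roi_lateral(roi, params$split)
  half_rate <- function(half) {
    if (!any(half$mask)) return(NA_real_)
    tr <- structure(list(t = tt, raw = masked_mean(half$mask),
                         filtered = NULL, normalized = NULL,
                         hbt_raw = NULL, n_valid = NULL,
                         timeline = timeline, roi_label = half$label),
                    class = "sto2_trace")
    tr <- build_sto2_trace(tr, params$filter_order)
    mean_depletion_rate(tr, params$rate_duration, params$slope_window)
  }
  halves$rate_left <- half_rate(halves$left)
  halves$rate_right <- half_rate(halves$right)

  base_idx <- trace$t >= timeline$t_baseline_start &
    trace$t < timeline$t_light_on
  summary <- c(baseline_sto2 = mean(trace$raw[base_idx], na.rm = TRUE),
               noise_threshold = threshold,
               depletion_rate = rate,
               t_active_end = t_active,
               reox_positive_fraction = positive_fraction(reox, roi),
               rate_left = halves$rate_left,
               rate_right = halves$rate_right)

  list(trace = trace, threshold = threshold, maps = maps,
       delta_active = delta_active, reoxygenation = reox,
       halves = halves, summary = summary)
}

#' Export a kinetics trace as CSV with a milestone sidecar
#'
#' Writes `t_s,raw_sto2,filtered_sto2,normalized_sto2,hbt,segment`
#' (segment is `baseline`, `light` or `post`) and a JSON sidecar with the
#' timeline milestones.
#'
#' @param trace an `sto2_trace`.
#' @param basename output path without extension.
#' @return Invisibly, the two file paths.
#' @export
write_trace_csv <- function(trace, basename) {
  tl <- trace$timeline
  seg <- ifelse(trace$t < tl$t_light_on, "baseline",
                ifelse(trace$t < tl$t_light_off, "light", "post"))
  df <- data.frame(t_s = trace$t,
                   raw_sto2 = trace$raw,
                   filtered_sto2 = trace$filtered,
                   normalized_sto2 = trace$normalized,
                   hbt = trace$hbt_raw,
                   segment = seg)
  csv <- paste0(basename, ".csv")
  json <- paste0(basename, "_milestones.json")
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(unclass(tl), json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(csv = csv, json = json))
}

#' Read a kinetics trace written by [write_trace_csv()]
#' @param basename path without extension.
#' @return An `sto2_trace`.
#' @export
read_trace_csv <- function(basename) {
  df <- utils::read.csv(paste0(basename, ".csv"))
  tl <- jsonlite::read_json(paste0(basename, "_milestones.json"),
                            simplifyVector = TRUE)
  structure(list(t = df$t_s, raw = df$raw_sto2, filtered = df$filtered_sto2,
                 normalized = df$normalized_sto2, hbt_raw = df$hbt,
                 n_valid = NULL,
                 timeline = pdt_timeline(tl$t_baseline_start, tl$t_light_on,
                                         tl$t_light_off, tl$t_end,
                                         if (is.null(tl$t_active_end))
                                           NA_real_ else tl$t_active_end),
                 roi_label = "tumor"),
            class = "sto2_trace")
}

#' Write an ROI mask as a 0/255 PNG
#' @param roi a [roi_mask()].
#' @param path output PNG path.
#' @export
write_roi_png <- function(roi, path) {
  png::writePNG(roi$mask * 1, path)
  invisible(path)
}

#' Read an ROI mask from a 0/255 PNG
#' @param path PNG path.
#' @param label ROI label.
#' @return A [roi_mask()].
#' @export
read_roi_png <- function(path, label = "tumor") {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  roi_mask(img > 0.5, label)
}

#' Write a delta map as a pseudocolor PNG
#'
#' Diverging blue-white-red rendering of the (display-filtered) signed
#' change map, symmetric about zero, with invalid pixels in gray; mirrors
#' the conventional overlay styling of StO2 change maps.
#'
#' @param dmap a `delta_map`.
#' @param path output PNG path.
#' @param limit color scale limit in percent (default the 99th percentile
#'   of |delta|).
#' @param display_filter apply the 3x3 [display_median_filter()] first
#'   (default TRUE).
#' @export
write_delta_png <- function(dmap, path, limit = NULL,
                            display_filter = TRUE) {
  d <- if (display_filter) display_median_filter(dmap$delta) else dmap$delta
  if (is.null(limit))
    limit <- max(1e-6, stats::quantile(abs(d[dmap$mask]), 0.99,
                                       na.rm = TRUE))
  x <- pmin(1, pmax(-1, d / limit))
  ramp <- grDevices::colorRamp(c("blue", "white", "red"))
  rgb <- ramp((as.numeric(x) + 1) / 2) / 255
  img <- array(0.5, c(nrow(d), ncol(d), 3L))
  for (k in 1:3) {
    ch <- matrix(rgb[, k], nrow(d), ncol(d))
    ch[!dmap$mask] <- 0.5
    img[, , k] <- ch
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' Schema (version 1): `paths: {stack, roi, output}` plus optional
#' `extinction`; `timeline: {t_baseline_start, t_light_on, t_light_off,
#' t_end}`; optional `parameters` overriding [default_parameters()]; and
#' an optional `seed`.
#'
#' @param path YAML file path.
#' @return A validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$paths$stack) || is.null(cfg$paths$roi) ||
      is.null(cfg$paths$output))
    stop("config must provide paths: stack, roi, output", call. = FALSE)
  tl <- cfg$timeline
  if (is.null(tl))
    stop("config must provide the treatment timeline", call. = FALSE)
  cfg$timeline <- pdt_timeline(tl$t_baseline_start %||% 0, tl$t_light_on,
                               tl$t_light_off, tl$t_end)
  cfg$parameters <- utils::modifyList(default_parameters(),
                                      cfg$parameters %||% list())
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the pipeline from a configuration and write the report bundle
#'
#' Loads the stack (TIFF + JSON sidecar) and ROI (PNG), runs
#' [analyze_stack()], and writes the trace CSV with milestone sidecar, the
#' active-PDT and reoxygenation delta-map PNGs, and a JSON summary
#' (baseline StO2, noise threshold, depletion rate, end of active PDT,
#' reoxygenation-positive fraction, half-ROI rates). Deterministic: a rerun
#' with the same inputs produces byte-identical CSV output.
#'
#' @param config a `run_config` from [read_run_config()], or a path to the
#'   YAML file.
#' @return Invisibly, the [analyze_stack()] result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stack <- read_frame_stack(config$paths$stack)
  roi <- read_roi_png(config$paths$roi)
  ext <- if (!is.null(config$paths$extinction)) {
    read_extinction_table(config$paths$extinction)
  } else hb_extinction()
  out_dir <- config$paths$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  res <- analyze_stack(stack, roi, config$timeline, ext,
                       config$parameters)
  write_trace_csv(res$trace, file.path(out_dir, "trace"))
  write_delta_png(res$delta_active, file.path(out_dir, "delta_active.png"))
  write_delta_png(res$reoxygenation,
                  file.path(out_dir, "reoxygenation.png"))
  jsonlite::write_json(as.list(res$summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
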