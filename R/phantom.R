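#' Synthetic tumor-phantom specification
#'
#' Configuration for the digital phantom that emulates the study's tumors
#' under PDT monitoring: a 2D elliptical tumor cross-section with spatially
#' varying hemoglobin content and baseline saturation, fluence-rate-
#' dependent oxygen dynamics (sharp initial StO2 drop, transient
#' vasodilation rise, steady decline to a trough, heterogeneous post-trough
#' reoxygenation concentrated at the rim), and noisy two-wavelength frame
#' rendering.
#'
#' Kinetics are phenomenological. Per pixel with local fluence rate
#' `Phi(x)` (sum of fiber contributions; lateral fibers contribute a linear
#' lateral gradient), saturation follows the explicit-Euler update
#' `S <- S + dt * (-k_consume * Phi * P(t) * S/100 + v(t) * (S0 - S)
#'   - k_shutdown * W(x, t) * S + r(x) * rec_rate * (S0 - S) * [t > t*])`
#' clipped to \\[0, 100\\], where `P(t) = exp(-k_bleach * Phibar * t)` is the
#' photosensitizer availability (clamped to 0 once it falls below
#' `ps_floor`, i.e. photosensitizer exhaustion), `v(t)` a Gaussian-bump
#' vasodilation reflow, `W = 1 - exp(-D/shutdown_dose)` a vascular-shutdown
#' state driven by the accumulated local photodynamic dose
#' `D = integral(Phi * P dt)`, and `r(x)` the programmed recovering region
#' (rim band plus an interior patch). The programmed trough `t*` is the
#' photosensitizer-exhaustion time `t_on + log(1/ps_floor)/(k_bleach *
#' Phibar)`, capped at light-off. HbT is modulated +/-20% by vasodilation
#' and shutdown. The vascular responses are reactions to photodynamic
#' insult, so a phantom without photosensitizer (`k_consume = 0`, the
#' light-only group) is exactly static.
#'
#' @param h,w grid size in pixels.
#' @param spacing pixel spacing, mm/px (isotropic).
#' @param tumor_center (row, col) of the tumor ellipse center, px.
#' @param tumor_semi_axes (axial, lateral) semi-axes, px.
#' @param hbt_base baseline HbT level (arbitrary units).
#' @param n_blobs,blob_amp,blob_sigma_mm vessel-blob texture: count,
#'   amplitude relative to `hbt_base`, Gaussian radius (mm).
#' @param s0_mean,s0_sd baseline saturation mean and spatial SD (percent).
#' @param fibers data.frame with columns `direction`
#'   (`"in_plane"|"left"|"right"`) and `fluence` (mW/cm^2); the treatment
#'   fluence rate is the sum over fibers.
#' @param lateral_gradient relative lateral fall-off of the side fibers
#'   (0.5: a side fiber deposits 1.5x its nominal fluence at its own edge
#'   and 0.5x at the far edge).
#' @param timeline a [pdt_timeline()].
#' @param frame_period frame interval, s.
#' @param k_consume oxygen-consumption coefficient,
#'   % per (mW/cm^2 x min) at full saturation and fresh photosensitizer.
#' @param k_bleach photosensitizer photobleaching rate, per (mW/cm^2 x min).
#' @param ps_floor photosensitizer fraction below which photodynamic action
#'   stops (exhaustion).
#' @param vaso_amplitude vasodilation reflow gain, per min (fraction of the
#'   saturation deficit restored per minute at the bump peak).
#' @param vaso_peak_min,vaso_width_min bump peak time (min of recording
#'   time) and Gaussian width (min).
#' @param k_shutdown vascular-shutdown depletion coefficient, per min at
#'   full shutdown.
#' @param shutdown_dose photodynamic dose scale (mW min/cm^2) at which
#'   shutdown saturates to 1 - 1/e.
#' @param recovery_rim_mm width of the recovering rim band, mm.
#' @param recovery_rate post-trough reoxygenation rate, fraction of the
#'   deficit per minute.
#' @param recovery_interior_fraction fraction of non-rim tumor pixels that
#'   also recover (one contiguous interior patch).
#' @param noise_sd additive Gaussian channel noise, SD relative to the mean
#'   tumor signal of each wavelength.
#' @param gain per-wavelength multiplicative system gain, length 2.
#' @param seed integer seed; all stochastic draws flow from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(h = 128L, w = 128L, spacing = 0.1,
                         tumor_center = c(0.55 * h, (w + 1) / 2),
                         tumor_semi_axes = c(0.16 * h, 0.22 * w),
                         hbt_base = 1, n_blobs = 25L, blob_amp = 1.5,
                         blob_sigma_mm = 0.4,
                         s0_mean = 60, s0_sd = 8,
                         fibers = data.frame(
                           direction = rep("in_plane", 4L),
                           fluence = rep(25, 4L)),
                         lateral_gradient = 0.5,
                         timeline = pdt_timeline(0, 300, 1200, 1800),
                         frame_period = 4,
                         k_consume = 0.05,
                         k_bleach = log(4) / 2800,
                         ps_floor = 0.25,
                         vaso_amplitude = 0.35, vaso_peak_min = 7,
                         vaso_width_min = 1,
                         k_shutdown = 0.02, shutdown_dose = 500,
                         recovery_rim_mm = 0.6, recovery_rate = 0.2,
                         recovery_interior_fraction = 0.1,
                         noise_sd = 0.02, gain = c(1, 1),
                         seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  if (any(spec$fibers$fluence < 0))
    stop("fiber fluences must be >= 0", call. = FALSE)
  if (!all(spec$fibers$direction %in% c("in_plane", "left", "right")))
    stop("fiber direction must be in_plane, left or right", call. = FALSE)
  if (spec$frame_period <= 0)
    stop("frame period must be positive", call. = FALSE)
  if (spec$s0_mean <= 0 || spec$s0_mean >= 100)
    stop("baseline saturation mean must lie in (0, 100)", call. = FALSE)
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(spec$gain) != 2L || any(spec$gain <= 0))
    stop("gain must be two positive per-wavelength multipliers",
         call. = FALSE)
  spec$seed <- as.integer(seed)
  spec
}

# Lateral fluence-rate profile (mW/cm^2) as a function of column index.
fluence_profile <- function(spec) {
  u <- if (spec$w > 1L) (seq_len(spec$w) - 1) / (spec$w - 1) else 0.5
  phi <- numeric(spec$w)
  g <- spec$lateral_gradient
  for (i in seq_len(nrow(spec$fibers))) {
    f <- spec$fibers$fluence[i]
    phi <- phi + switch(spec$fibers$direction[i],
                        in_plane = rep(f, spec$w),
                        left = f * (1 + g * (1 - 2 * u)),
                        right = f * (1 + g * (2 * u - 1)))
  }
  phi
}

# Smooth Gaussian random field on an h x w grid (separable convolution).
smooth_field <- function(h, w, sigma_px) {
  z <- matrix(stats::rnorm(h * w), h, w)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(m) {           # rows, replicate-padded
    mp <- m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + nrow(m) - 1L), , drop = FALSE]
    out
  }
  z <- pad_conv(z)
  z <- t(pad_conv(t(z)))
  z / stats::sd(z)
}

#' Simulate ground-truth PDT oxygen dynamics
#'
#' Integrates the phantom kinetics of [phantom_spec()] and returns the
#' per-frame ground-truth saturation and HbT fields together with the
#' tumor ROI, the programmed recovering region and the milestone timeline
#' (including the programmed trough time, i.e. the true end of active PDT).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth`: list with `sto2`, `hbt`
#'   (H x W x T arrays, zero outside the tumor), `t` (frame times, s),
#'   `roi` ([roi_mask()]), `recovering` (logical map),
#'   `recovering_fraction` (programmed fraction of ROI pixels that
#'   recover), `s0` (baseline saturation field), `milestones`
#'   ([pdt_timeline()] with `t_active_end` set to the programmed trough)
#'   and the `spec`.
#' @export
simulate_dynamics <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("spec must be a phantom_spec", call. = FALSE)
  tl <- spec$timeline
  times <- seq(tl$t_baseline_start, tl$t_end - spec$frame_period,
               by = spec$frame_period)
  nT <- length(times)
  dt <- spec$frame_period / 60            # minutes

  set.seed(spec$seed)
  h <- spec$h; w <- spec$w
  rr <- row(matrix(0, h, w)); cc <- col(matrix(0, h, w))
  rho <- sqrt(((rr - spec$tumor_center[1]) / spec$tumor_semi_axes[1])^2 +
              ((cc - spec$tumor_center[2]) / spec$tumor_semi_axes[2])^2)
  tumor <- rho <= 1
  if (!any(tumor)) stop("tumor ellipse contains no pixel", call. = FALSE)
  np <- sum(tumor)

  # baseline saturation field: smooth heterogeneity, clipped to (0, 100)
  s0_map <- spec$s0_mean + spec$s0_sd * smooth_field(h, w, 6)
  s0 <- pmin(95, pmax(15, s0_map[tumor]))

  # baseline HbT texture: base level plus Gaussian vessel blobs
  hbt0_map <- matrix(spec$hbt_base, h, w)
  sig_px <- spec$blob_sigma_mm / spec$spacing
  centers <- which(tumor)[sample.int(np, min(spec$n_blobs, np))]
  for (ctr in centers) {
    amp <- spec$hbt_base * spec$blob_amp * stats::runif(1, 0.5, 1)
    d2 <- (rr - rr[ctr])^2 + (cc - cc[ctr])^2
    hbt0_map <- hbt0_map + amp * exp(-d2 / (2 * sig_px^2))
  }
  hbt0 <- hbt0_map[tumor]

  # local fluence rate and global photosensitizer decay
  phi <- fluence_profile(spec)[cc[tumor]]
  phibar <- mean(phi)
  has_ps <- spec$k_consume > 0
  t_trough <-
    if (has_ps && spec$k_bleach > 0 && phibar > 0) {
      min(tl$t_light_off,
          tl$t_light_on + 60 * log(1 / spec$ps_floor) /
            (spec$k_bleach * phibar))
    } else tl$t_light_off

  # programmed recovering region: rim band + interior patch. Recovery is a
  # vascular response to photodynamic insult, so without photosensitizer
  # the region is empty.
  if (has_ps) {
    rim_rel <- spec$recovery_rim_mm /
      (min(spec$tumor_semi_axes) * spec$spacing)
    rec <- rho[tumor] >= 1 - rim_rel
    interior <- which(!rec)
    if (spec$recovery_interior_fraction > 0 && length(interior)) {
      rad <- sqrt(spec$recovery_interior_fraction * length(interior) / pi)
      ctr_row <- spec$tumor_center[1]
      ctr_col <- spec$tumor_center[2] - spec$tumor_semi_axes[2] / 2
      d2 <- (rr[tumor] - ctr_row)^2 + (cc[tumor] - ctr_col)^2
      rec <- rec | (!rec & d2 <= rad^2)
    }
  } else {
    rec <- rep(FALSE, np)
  }

  # stability of the explicit update
  lip <- spec$k_consume * max(phi) / 100 + spec$vaso_amplitude +
    spec$k_shutdown + spec$recovery_rate
  if (dt * lip > 0.5)
    stop(sprintf(paste0("time step too large for stable integration; ",
                        "use frame_period <= %.2f s"), 0.5 / lip * 60),
         call. = FALSE)

  sto2 <- array(0, c(h, w, nT))
  hbt <- array(0, c(h, w, nT))
  S <- s0
  D <- numeric(np)                       # accumulated photodynamic dose
  for (i in seq_len(nT)) {
    t <- times[i]
    lit <- t >= tl$t_light_on && t < tl$t_light_off
    P <- if (has_ps && lit) {
      p <- exp(-spec$k_bleach * phibar * (t - tl$t_light_on) / 60)
      if (p < spec$ps_floor) 0 else p
    } else 0
    v <- if (has_ps && t >= tl$t_light_on) {
      spec$vaso_amplitude *
        exp(-((t / 60 - spec$vaso_peak_min)^2) / (2 * spec$vaso_width_min^2))
    } else 0
    W <- if (has_ps) 1 - exp(-D / spec$shutdown_dose) else 0
    vn <- if (spec$vaso_amplitude > 0) v / spec$vaso_amplitude else 0

    frame_s <- matrix(0, h, w); frame_s[tumor] <- S
    frame_h <- matrix(0, h, w)
    frame_h[tumor] <- pmax(0, hbt0 * (1 + 0.2 * vn - 0.2 * W))
    sto2[, , i] <- frame_s
    hbt[, , i] <- frame_h

    dS <- -spec$k_consume * phi * P * S / 100 + v * (s0 - S) -
      spec$k_shutdown * W * S +
      (if (has_ps && t > t_trough) spec$recovery_rate * rec * (s0 - S)
       else 0)
    S <- pmin(100, pmax(0, S + dt * dS))
    if (lit) D <- D + phi * P * dt
  }

  # realized true trough: frame-grid argmin of the noiseless ROI-mean
  # trace over the light interval (earliest on ties)
  true_trace <- apply(sto2, 3, function(m) mean(m[tumor]))
  lit_idx <- which(times >= tl$t_light_on & times <= tl$t_light_off)
  t_trough_true <- times[lit_idx[which.min(true_trace[lit_idx])]]

  structure(list(sto2 = sto2, hbt = hbt, t = times,
                 roi = roi_mask(tumor, "tumor"),
                 recovering = {m <- matrix(FALSE, h, w); m[tumor] <- rec; m},
                 recovering_fraction = mean(rec),
                 s0 = {m <- matrix(0, h, w); m[tumor] <- s0; m},
                 t_exhaustion = t_trough,
                 milestones = pdt_timeline(tl$t_baseline_start,
                                           tl$t_light_on, tl$t_light_off,
                                           tl$t_end, t_trough_true),
                 spec = spec),
            class = "phantom_truth")
}

#' Render noisy two-wavelength frames from a phantom truth
#'
#' Forward model of the photoacoustic measurement: per wavelength,
#' `img = gain * (eps_hbo * c_hbo + eps_hbd * c_hbd) + N(0, noise_sd *
#' mean_signal)`, with `c_hbo = hbt * sto2/100`, `c_hbd = hbt - c_hbo`, the
#' mean signal taken over tumor pixels and frames, and the background
#' outside the tumor carrying noise only. Reproducible from the spec seed.
#'
#' @param truth a `phantom_truth` from [simulate_dynamics()].
#' @param ext an [extinction_table()] (default the bundled hemoglobin
#'   compilation).
#' @param spec the phantom spec (defaults to `truth$spec`).
#' @return A [frame_stack()].
#' @export
render_frames <- function(truth, ext = hb_extinction(), spec = truth$spec) {
  E <- extinction_matrix(ext)
  nT <- length(truth$t)
  tum <- truth$roi$mask
  chbo_mean <- mean(apply(truth$hbt * truth$sto2 / 100, 3, function(m)
    mean(m[tum])))
  chbd_mean <- mean(apply(truth$hbt * (1 - truth$sto2 / 100), 3, function(m)
    mean(m[tum])))
  mean_sig <- as.numeric(E %*% c(chbo_mean, chbd_mean)) * spec$gain
  sd_noise <- spec$noise_sd * mean_sig

  set.seed(spec$seed + 1000003L)
  d <- dim(tum)
  frames <- vector("list", nT)
  for (i in seq_len(nT)) {
    chbo <- truth$hbt[, , i] * truth$sto2[, , i] / 100
    chbd <- truth$hbt[, , i] - chbo
    img750 <- spec$gain[1] * (E[1, 1] * chbo + E[1, 2] * chbd)
    img850 <- spec$gain[2] * (E[2, 1] * chbo + E[2, 2] * chbd)
    if (spec$noise_sd > 0) {
      img750 <- img750 + matrix(stats::rnorm(prod(d), 0, sd_noise[1]), d[1])
      img850 <- img850 + matrix(stats::rnorm(prod(d), 0, sd_noise[2]), d[1])
    }
    frames[[i]] <- frame_pair(img750, img850, truth$t[i])
  }
  frame_stack(frames, pixel_spacing = rep(spec$spacing, 2))
}

#' Build a named phantom fixture
#'
#' Deterministic study-condition fixtures: a 5-min baseline, 15 min of
#' light and ~10 min of follow-up at a 4 s frame period on a 128 x 128
#' grid. The treatment fluence rate is split over four fibers and totals
#' 100 mW/cm^2 for `"LFR"` (90 J light dose), 400 mW/cm^2 for `"HFR"`
#' (360 J) and for `"light_only"` (no photosensitizer, so `k_consume = 0`
#' and the vascular responses are absent); `"asymmetric"` keeps the two
#' in-plane fibers at 100 mW/cm^2 and sets the left fiber to 150 and the
#' right to 50, producing a lateral dose gradient across the tumor.
#'
#' @param case one of `"LFR"`, `"HFR"`, `"light_only"`, `"asymmetric"`.
#' @param seed integer seed.
#' @param ... further arguments forwarded to [phantom_spec()] (e.g. a
#'   smaller grid for quick experiments).
#' @return List with elements `case`, `spec`, `truth`
#'   ([simulate_dynamics()] output), `stack` ([render_frames()] output)
#'   and `roi`.
#' @export
make_fixture <- function(case = c("LFR", "HFR", "light_only", "asymmetric"),
                         seed = 1L, ...) {
  case <- match.arg(case)
  preset <- switch(case,
    LFR = list(fibers = data.frame(direction = rep("in_plane", 4L),
                                   fluence = rep(25, 4L))),
    HFR = list(fibers = data.frame(direction = rep("in_plane", 4L),
                                   fluence = rep(100, 4L))),
    light_only = list(fibers = data.frame(direction = rep("in_plane", 4L),
                                          fluence = rep(100, 4L)),
                      k_consume = 0),
    asymmetric = list(fibers = data.frame(
      direction = c("in_plane", "in_plane", "left", "right"),
      fluence = c(100, 100, 150, 50))))
  args <- utils::modifyList(c(preset, list(seed = seed)), list(...))
  spec <- do.call(phantom_spec, args)
  truth <- simulate_dynamics(spec)
  stack <- render_frames(truth, spec = spec)
  list(case = case, spec = spec, truth = truth, stack = stack,
       roi = truth$roi)
}
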