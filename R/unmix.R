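#' Per-pixel oximetry maps
#'
#' Container for the unmixed product of one frame pair: oxygen saturation
#' (`sto2`, percent), total hemoglobin (`hbt`, arbitrary units,
#' c_HbO + c_HbD) and a validity mask. Pixels that fail the mask carry 0 in
#' both channels, mirroring the zeroing convention used for display, but the
#' mask is the authoritative validity signal: downstream code must never
#' treat a masked 0 as true 0% saturation.
#'
#' @param sto2 numeric matrix, percent in \\[0, 100\\] where valid, 0 elsewhere.
#' @param hbt numeric matrix, >= 0; > 0 where valid.
#' @param mask logical matrix, `TRUE` = pixel above the noise floor.
#' @param t acquisition time (s).
#' @return An object of class `oximetry_maps`.
#' @export
oximetry_maps <- function(sto2, hbt, mask, t) {
  if (!identical(dim(sto2), dim(hbt)) || !identical(dim(sto2), dim(mask)))
    stop("sto2, hbt and mask must share dimensions", call. = FALSE)
  structure(list(sto2 = sto2, hbt = hbt, mask = mask, t = as.numeric(t)),
            class = "oximetry_maps")
}

# Non-negative least squares for the L x 2 hemoglobin system, vectorized
# over measurement vectors m1, m2 (one element per pixel, one vector per
# wavelength). With two unknowns the KKT active sets can be enumerated:
# either the unconstrained solution is feasible, or exactly one component
# is clamped to zero and the other is the non-negative 1-D projection with
# the smaller residual (the ||m||^2 term cancels from the comparison).
# Returns list(hbo, hbd).
nnls2v <- function(E, m1, m2) {
  r1 <- range(m1); r2 <- range(m2)
  if (!all(is.finite(r1)) || !all(is.finite(r2)))
    stop("measurements must be finite", call. = FALSE)
  G11 <- sum(E[, 1L]^2); G22 <- sum(E[, 2L]^2)
  G12 <- sum(E[, 1L] * E[, 2L])
  det <- G11 * G22 - G12^2
  B1 <- E[1L, 1L] * m1 + E[2L, 1L] * m2
  B2 <- E[1L, 2L] * m1 + E[2L, 2L] * m2
  c1 <- (G22 * B1 - G12 * B2) / det
  c2 <- (G11 * B2 - G12 * B1) / det
  bad <- which(c1 < 0 | c2 < 0)
  if (length(bad)) {
    a1 <- B1[bad] / G11; a1[a1 < 0] <- 0      # HbD clamped to 0
    a2 <- B2[bad] / G22; a2[a2 < 0] <- 0      # HbO clamped to 0
    pick1 <- a1^2 * G11 - 2 * a1 * B1[bad] <=
             a2^2 * G22 - 2 * a2 * B2[bad]
    z1 <- numeric(length(bad)); z2 <- z1
    z1[pick1] <- a1[pick1]
    z2[!pick1] <- a2[!pick1]
    c1[bad] <- z1
    c2[bad] <- z2
  }
  list(hbo = c1, hbd = c2)
}

# Matrix-interface wrapper used by unmix_pixel (supports L >= 2
# wavelengths; the design always has two columns, so the same active-set
# enumeration is exact).
nnls2 <- function(E, M) {
  if (!is.matrix(M)) M <- matrix(M, nrow = nrow(E))
  if (nrow(E) == 2L) {
    out <- nnls2v(E, M[1L, ], M[2L, ])
    return(rbind(out$hbo, out$hbd))
  }
  if (any(!is.finite(M)))
    stop("measurements must be finite", call. = FALSE)
  G <- crossprod(E)
  B <- crossprod(E, M)
  Cu <- solve(G, B)
  out <- Cu
  bad <- which(Cu[1L, ] < 0 | Cu[2L, ] < 0)
  if (length(bad)) {
    a1 <- pmax(0, B[1L, bad] / G[1L, 1L])
    a2 <- pmax(0, B[2L, bad] / G[2L, 2L])
    pick1 <- a1^2 * G[1L, 1L] - 2 * a1 * B[1L, bad] <=
             a2^2 * G[2L, 2L] - 2 * a2 * B[2L, bad]
    out[1L, bad] <- ifelse(pick1, a1, 0)
    out[2L, bad] <- ifelse(pick1, 0, a2)
  }
  out
}

#' Non-negative spectral unmixing of one measurement pair
#'
#' Solves `min ||E c - m||_2 subject to c >= 0` for the two hemoglobin
#' chromophores, where `E` holds the molar extinction coefficients and `m`
#' the photoacoustic amplitudes at the acquisition wavelengths. The 2-unknown
#' problem is solved in closed form: if the unconstrained solution is
#' non-negative it is returned exactly; otherwise one component is clamped
#' to zero and the other is the non-negative one-dimensional projection with
#' the smaller residual. The same enumeration is exact for any number of
#' wavelengths >= 2 (the design always has two columns).
#'
#' @param m numeric vector of measurements, one per wavelength of `ext`.
#' @param ext an [extinction_table()].
#' @return Named numeric vector `c(hbo = ..., hbd = ...)`, both >= 0.
#' @examples
#' ext <- hb_extinction()
#' unmix_pixel(c(ext$eps_hbo[1] * 2, ext$eps_hbo[2] * 2), ext)  # pure HbO
#' @export
unmix_pixel <- function(m, ext) {
  E <- extinction_matrix(ext)
  if (length(m) != nrow(E))
    stop("measurement length must match wavelength count", call. = FALSE)
  out <- nnls2(E, matrix(as.numeric(m), ncol = 1L))
  c(hbo = out[1L, 1L], hbd = out[2L, 1L])
}

#' Unmix a frame pair into oximetry maps
#'
#' Applies [unmix_pixel()] at every pixel; `hbt = c_hbo + c_hbd` and
#' `sto2 = 100 c_hbo / hbt` where `hbt > 0`. Pixels with `hbt = 0` are
#' undefined: stored as 0 with `mask = FALSE`. All other pixels carry
#' `mask = TRUE` (no noise threshold is applied here; see
#' [apply_threshold()]).
#'
#' @param pair a [frame_pair()].
#' @param ext an [extinction_table()] covering 750 and 850 nm.
#' @return An [oximetry_maps()].
#' @export
compute_oximetry <- function(pair, ext) {
  if (!inherits(pair, "frame_pair"))
    stop("pair must be a frame_pair", call. = FALSE)
  E <- extinction_matrix(ext)
  d <- dim(pair$img_750)
  C <- nnls2v(E, as.numeric(pair$img_750), as.numeric(pair$img_850))
  hbt <- C$hbo + C$hbd
  valid <- hbt > 0
  sto2 <- numeric(length(hbt))
  sto2[valid] <- 100 * C$hbo[valid] / hbt[valid]
  oximetry_maps(matrix(sto2, d[1L], d[2L]),
                matrix(hbt, d[1L], d[2L]),
                matrix(valid, d[1L], d[2L]),
                pair$t)
}

#' Unmix every frame of a stack
#'
#' Array-based equivalent of mapping [compute_oximetry()] over the stack,
#' vectorized over all pixels of all frames.
#'
#' @param stack a [frame_stack()].
#' @param ext an [extinction_table()].
#' @return An object of class `oximetry_stack`: list with `sto2` and `hbt`
#'   (H x W x T arrays), `mask` (H x W x T logical array), `t` (times, s)
#'   and `pixel_spacing`.
#' @export
unmix_stack <- function(stack, ext) {
  E <- extinction_matrix(ext)
  d <- dim(stack$frames[[1L]]$img_750)
  nT <- length(stack$frames)
  C <- nnls2v(E, as.numeric(stack_channel_matrix(stack, "img_750")),
              as.numeric(stack_channel_matrix(stack, "img_850")))
  hbt <- C$hbo + C$hbd
  valid <- hbt > 0
  sto2 <- numeric(length(hbt))
  sto2[valid] <- 100 * C$hbo[valid] / hbt[valid]
  structure(list(sto2 = array(sto2, c(d, nT)),
                 hbt = array(hbt, c(d, nT)),
                 mask = array(valid, c(d, nT)),
                 t = frame_times(stack),
                 pixel_spacing = stack$pixel_spacing),
            class = "oximetry_stack")
}

#' Extract one frame of an oximetry stack
#' @param ostack an `oximetry_stack` from [unmix_stack()].
#' @param i frame index.
#' @return An [oximetry_maps()].
#' @export
oximetry_frame <- function(ostack, i) {
  oximetry_maps(ostack$sto2[, , i], ostack$hbt[, , i], ostack$mask[, , i],
                ostack$t[i])
}

#' Estimate the recording's noise floor from corner patches
#'
#' The threshold is the mean HbT over a `patch_size` x `patch_size` area in
#' both top corners (shallowest rows, which lie above the tissue surface and
#' contain only system noise), pooled across every frame of the recording.
#' One threshold is produced per recording.
#'
#' @param x an `oximetry_stack`, a list of [oximetry_maps()], or a single
#'   [oximetry_maps()].
#' @param patch_size side of the square corner patch in pixels (default 20).
#' @return Scalar threshold in HbT units.
#' @export
estimate_noise_floor <- function(x, patch_size = 20L) {
  hbt_list <-
    if (inherits(x, "oximetry_stack")) {
      lapply(seq_along(x$t), function(i) x$hbt[, , i])
    } else if (inherits(x, "oximetry_maps")) {
      list(x$hbt)
    } else if (is.list(x)) {
      lapply(x, function(m) if (inherits(m, "oximetry_maps")) m$hbt else m)
    } else stop("unsupported input for noise-floor estimation", call. = FALSE)
  d <- dim(hbt_list[[1L]])
  if (d[1L] < patch_size || d[2L] < 2L * patch_size)
    stop(sprintf("image %d x %d too small for two %d x %d corner patches",
                 d[1L], d[2L], patch_size, patch_size), call. = FALSE)
  rows <- seq_len(patch_size)
  cl <- seq_len(patch_size)
  cr <- (d[2L] - patch_size + 1L):d[2L]
  vals <- unlist(lapply(hbt_list, function(h) c(h[rows, cl], h[rows, cr])))
  mean(vals)
}

#' Apply a noise-floor threshold to oximetry maps
#'
#' Pixels with `hbt < threshold` are set to zero in both channels and marked
#' invalid; surviving pixels keep their values with `mask = TRUE`. The
#' operation is idempotent for a fixed threshold.
#'
#' @param maps an [oximetry_maps()] or `oximetry_stack`.
#' @param threshold non-negative HbT threshold from [estimate_noise_floor()].
#' @return Object of the same class with the mask applied.
#' @export
apply_threshold <- function(maps, threshold) {
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0)
    stop("threshold must be a single finite non-negative value",
         call. = FALSE)
  keep <- maps$hbt >= threshold & maps$hbt > 0
  maps$hbt[!keep] <- 0
  maps$sto2[!keep] <- 0
  maps$mask <- keep
  maps
}
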