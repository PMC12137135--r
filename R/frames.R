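#' Two-wavelength photoacoustic frame pair
#'
#' One co-registered acquisition: a 750 nm image, an 850 nm image and the
#' acquisition time. Intensities are in arbitrary photoacoustic units and
#' may contain noise of either sign.
#'
#' @param img_750,img_850 numeric matrices of identical dimensions
#'   (rows = depth, row 1 = shallowest / transducer-proximal).
#' @param t acquisition time in seconds relative to the recording start.
#' @return An object of class `frame_pair`.
#' @export
frame_pair <- function(img_750, img_850, t) {
  img_750 <- as.matrix(img_750)
  img_850 <- as.matrix(img_850)
  if (!identical(dim(img_750), dim(img_850)))
    stop("frame pair images must share dimensions", call. = FALSE)
  if (length(t) != 1L || !is.finite(t) || t < 0)
    stop("acquisition time must be a single finite non-negative value",
         call. = FALSE)
  structure(list(img_750 = img_750, img_850 = img_850, t = as.numeric(t)),
            class = "frame_pair")
}

#' Time-ordered stack of frame pairs
#'
#' @param frames list of [frame_pair()] objects with strictly increasing
#'   acquisition times and identical image dimensions.
#' @param pixel_spacing numeric length-2 vector, (axial, lateral) mm/pixel.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_spacing = c(0.1, 0.1)) {
  if (!length(frames)) stop("frame stack is empty", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "frame_pair")))
    stop("all elements must be frame_pair objects", call. = FALSE)
  tt <- vapply(frames, `[[`, numeric(1), "t")
  if (any(diff(tt) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  d0 <- dim(frames[[1L]]$img_750)
  ok <- vapply(frames, function(f) identical(dim(f$img_750), d0), logical(1))
  if (!all(ok)) stop("all frames must share image dimensions", call. = FALSE)
  structure(list(frames = frames,
                 pixel_spacing = as.numeric(pixel_spacing)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1L]]$img_750)
  tt <- frame_times(x)
  cat(sprintf("Photoacoustic frame stack: %d frame pairs of %d x %d px, t = %.1f..%.1f s\n",
              length(x$frames), d[1], d[2], min(tt), max(tt)))
  invisible(x)
}

#' Acquisition times of a frame stack
#' @param stack a [frame_stack()].
#' @return numeric vector of times (s).
#' @export
frame_times <- function(stack) {
  vapply(stack$frames, `[[`, numeric(1), "t")
}

# Flatten one wavelength channel into a pixels x frames matrix.
stack_channel_matrix <- function(stack, channel = c("img_750", "img_850")) {
  channel <- match.arg(channel)
  vapply(stack$frames, function(f) as.numeric(f[[channel]]),
         numeric(length(stack$frames[[1L]]$img_750)))
}

#' Write a frame stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are wavelength-interleaved (750, 850, 750, 850, ...). Because the
#' TIFF writer stores samples in \\[0, 1\\], the recording is affinely mapped
#' onto that range and the mapping (`scale_offset`, `scale_range`) is stored
#' in the sidecar so that [read_frame_stack()] restores the original
#' intensities to 32-bit float precision.
#'
#' @param stack a [frame_stack()].
#' @param basename output path without extension; writes `<basename>.tif`
#'   and `<basename>.json`.
#' @return Invisibly, the two file paths.
#' @export
write_frame_stack <- function(stack, basename) {
  tt <- frame_times(stack)
  pages <- vector("list", 2L * length(stack$frames))
  for (i in seq_along(stack$frames)) {
    pages[[2L * i - 1L]] <- stack$frames[[i]]$img_750
    pages[[2L * i]] <- stack$frames[[i]]$img_850
  }
  lo <- min(vapply(pages, min, numeric(1)))
  hi <- max(vapply(pages, max, numeric(1)))
  rng <- if (hi > lo) hi - lo else 1
  pages <- lapply(pages, function(p) (p - lo) / rng)
  tif <- paste0(basename, ".tif")
  json <- paste0(basename, ".json")
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L, compression = "none")
  meta <- list(times_s = tt,
               wavelengths_nm = c(750, 850),
               pixel_spacing_mm = stack$pixel_spacing,
               scale_offset = lo,
               scale_range = rng)
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tif = tif, json = json))
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param basename path without extension, as given to [write_frame_stack()].
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(basename) {
  tif <- paste0(basename, ".tif")
  json <- paste0(basename, ".json")
  if (!file.exists(tif) || !file.exists(json))
    stop("frame stack files not found: ", basename, ".{tif,json}",
         call. = FALSE)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  nwl <- length(meta$wavelengths_nm)
  pages <- tiff::readTIFF(tif, all = TRUE)
  if (length(pages) %% nwl != 0L)
    stop("corrupt stack: page count ", length(pages),
         " not divisible by wavelength count ", nwl, call. = FALSE)
  nframes <- length(pages) %/% nwl
  if (length(meta$times_s) != nframes)
    stop("corrupt stack: sidecar lists ", length(meta$times_s),
         " times for ", nframes, " frames", call. = FALSE)
  lo <- meta$scale_offset
  rng <- meta$scale_range
  frames <- lapply(seq_len(nframes), function(i) {
    frame_pair(pages[[2L * i - 1L]] * rng + lo,
               pages[[2L * i]] * rng + lo,
               meta$times_s[i])
  })
  frame_stack(frames, pixel_spacing = meta$pixel_spacing_mm)
}
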