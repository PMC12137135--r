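#' Milestone difference map of StO2
#'
#' Element-wise `sto2(t_to) - sto2(t_from)` restricted to pixels valid at
#' both milestones; pixels valid at only one milestone are excluded
#' (`mask = FALSE`, value 0) rather than treated as a change from or to 0,
#' which would fabricate +/-100% swings at the noise floor. With the
#' default argument order (`map_from` before the light dose, `map_to` at
#' the end of active PDT) negative values mean deoxygenation over the
#' interval.
#'
#' @param map_from,map_to [oximetry_maps()] of identical shape.
#' @return An object of class `delta_map`: list with `delta` (signed
#'   percent), `mask`, `t_from`, `t_to`.
#' @export
delta_sto2 <- function(map_from, map_to) {
  if (!identical(dim(map_from$sto2), dim(map_to$sto2)))
    stop("milestone maps must share dimensions", call. = FALSE)
  ok <- map_from$mask & map_to$mask
  delta <- matrix(0, nrow(ok), ncol(ok))
  delta[ok] <- map_to$sto2[ok] - map_from$sto2[ok]
  structure(list(delta = delta, mask = ok,
                 t_from = map_from$t, t_to = map_to$t),
            class = "delta_map")
}

#' Reoxygenation map after active PDT
#'
#' [delta_sto2()] from the end of active PDT to the end of the monitoring
#' period; positive values mark reoxygenating tissue (residual functional
#' vasculature), negative values continued deoxygenation.
#'
#' @param end_active [oximetry_maps()] at the end of active PDT.
#' @param end_monitoring [oximetry_maps()] at the end of monitoring.
#' @return A `delta_map`.
#' @export
reoxygenation_map <- function(end_active, end_monitoring) {
  delta_sto2(end_active, end_monitoring)
}

#' 3x3 median filter for display
#'
#' Per-pixel median of the 3x3 neighborhood with nearest-edge replication.
#' Display-only smoothing of pseudocolor maps; it must never feed the
#' statistics.
#'
#' @param map2d numeric matrix, at least 3 x 3.
#' @return Filtered matrix of the same dimensions.
#' @export
display_median_filter <- function(map2d) {
  d <- dim(map2d)
  if (is.null(d) || d[1L] < 3L || d[2L] < 3L)
    stop("map must be at least 3 x 3", call. = FALSE)
  ri <- c(1L, seq_len(d[1L]), d[1L])      # replicated edge index
  ci <- c(1L, seq_len(d[2L]), d[2L])
  pad <- map2d[ri, ci]
  neigh <- vapply(1:3, function(dr) {
    vapply(1:3, function(dc) {
      pad[dr:(dr + d[1L] - 1L), dc:(dc + d[2L] - 1L)]
    }, numeric(d[1L] * d[2L]))
  }, matrix(0, d[1L] * d[2L], 3L))
  dim(neigh) <- c(d[1L] * d[2L], 9L)
  matrix(apply(neigh, 1L, stats::median), d[1L], d[2L])
}

#' Split an ROI into lateral halves
#'
#' Splits the ROI at its own lateral centroid column (not the image
#' midline, unless requested): left = ROI columns strictly below the
#' centroid, right = columns at or above it. The halves partition the ROI
#' exactly. Used for asymmetric-dose analyses where the two tumor
#' hemispheres receive different fluence rates.
#'
#' @param roi a [roi_mask()].
#' @param at `"centroid"` (default) or `"midline"` (image center column).
#' @return List with elements `left` and `right`, both [roi_mask()]s
#'   (an empty half is returned as a plain all-FALSE matrix with a
#'   warning).
#' @export
split_roi_lateral <- function(roi, at = c("centroid", "midline")) {
  at <- match.arg(at)
  m <- roi$mask
  cols <- col(m)[m]
  cut <- if (at == "centroid") mean(cols) else (ncol(m) + 1) / 2
  left <- m & (col(m) < cut)
  right <- m & (col(m) >= cut)
  mk <- function(half, lab) {
    if (!any(half)) {
      warning("degenerate ROI: ", lab, " half is empty")
      return(structure(list(mask = half, label = paste0(roi$label, "_", lab)),
                       class = "roi_mask"))
    }
    roi_mask(half, paste0(roi$label, "_", lab))
  }
  list(left = mk(left, "left"), right = mk(right, "right"))
}

#' Fraction of ROI pixels that reoxygenate
#'
#' @param dmap a `delta_map` (typically from [reoxygenation_map()]).
#' @param roi a [roi_mask()].
#' @return Fraction in \\[0, 1\\] of valid ROI pixels with positive change.
#' @export
positive_fraction <- function(dmap, roi) {
  ok <- dmap$mask & roi$mask
  if (!any(ok)) return(NA_real_)
  mean(dmap$delta[ok] > 0)
}
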