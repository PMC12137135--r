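#' Molar extinction table for hemoglobin unmixing
#'
#' Bundles the molar extinction coefficients of oxyhemoglobin (HbO) and
#' deoxyhemoglobin (HbD) at the photoacoustic acquisition wavelengths.
#' The two-wavelength oximetry model requires the sign structure that makes
#' the linear system well conditioned: deoxyhemoglobin dominates at 750 nm
#' and oxyhemoglobin at 850 nm, on opposite sides of the ~800 nm isosbestic
#' point.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param eps_hbo molar extinction of oxyhemoglobin at each wavelength
#'   (cm^-1 M^-1), strictly positive.
#' @param eps_hbd molar extinction of deoxyhemoglobin at each wavelength
#'   (cm^-1 M^-1), strictly positive.
#' @return An object of class `extinction_table`: a list with fields
#'   `wavelengths`, `eps_hbo`, `eps_hbd`.
#' @examples
#' ext <- hb_extinction()
#' ext$eps_hbd[1] > ext$eps_hbo[1]  # HbD dominates at 750 nm
#' @export
extinction_table <- function(wavelengths, eps_hbo, eps_hbd) {
  wavelengths <- as.numeric(wavelengths)
  eps_hbo <- as.numeric(eps_hbo)
  eps_hbd <- as.numeric(eps_hbd)
  if (length(wavelengths) < 2L)
    stop("extinction table needs at least two wavelengths", call. = FALSE)
  if (length(eps_hbo) != length(wavelengths) ||
      length(eps_hbd) != length(wavelengths))
    stop("coefficient vectors must match the wavelength vector in length",
         call. = FALSE)
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop("wavelengths must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(eps_hbo)) || any(eps_hbo <= 0) ||
      any(!is.finite(eps_hbd)) || any(eps_hbd <= 0))
    stop("extinction coefficients must be finite and strictly positive",
         call. = FALSE)
  out <- structure(list(wavelengths = wavelengths,
                        eps_hbo = eps_hbo, eps_hbd = eps_hbd),
                   class = "extinction_table")
  validate_extinction_sign_structure(out)
  out
}

# 750/850 sign structure check (only enforced when both bands are present)
validate_extinction_sign_structure <- function(ext) {
  i750 <- match(750, ext$wavelengths)
  i850 <- match(850, ext$wavelengths)
  if (!is.na(i750) && ext$eps_hbd[i750] <= ext$eps_hbo[i750])
    stop("at 750 nm deoxyhemoglobin extinction must exceed oxyhemoglobin",
         call. = FALSE)
  if (!is.na(i850) && ext$eps_hbo[i850] <= ext$eps_hbd[i850])
    stop("at 850 nm oxyhemoglobin extinction must exceed deoxyhemoglobin",
         call. = FALSE)
  invisible(ext)
}

#' Read an extinction table from CSV
#'
#' Reads a comma-separated table with header
#' `wavelength_nm,eps_hbo,eps_hbd`, subsets it to the requested acquisition
#' wavelengths and validates the result.
#'
#' @param path path to the CSV file.
#' @param wavelengths acquisition wavelengths (nm) that must be present;
#'   default `c(750, 850)`.
#' @return An [extinction_table()].
#' @export
read_extinction_table <- function(path, wavelengths = c(750, 850)) {
  if (!file.exists(path))
    stop("extinction table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path)
  need <- c("wavelength_nm", "eps_hbo", "eps_hbd")
  if (!all(need %in% names(tab)))
    stop("extinction CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  idx <- match(wavelengths, tab$wavelength_nm)
  if (anyNA(idx))
    stop("extinction table is missing required wavelength(s): ",
         paste(wavelengths[is.na(idx)], collapse = ", "), call. = FALSE)
  ord <- order(wavelengths)
  extinction_table(wavelengths[ord],
                   tab$eps_hbo[idx][ord],
                   tab$eps_hbd[idx][ord])
}

#' Bundled hemoglobin extinction coefficients at 750 and 850 nm
#'
#' Loads the package's copy of the standard tabulated hemoglobin molar
#' extinction compilation at the two acquisition wavelengths. Because
#' photoacoustic amplitudes are in arbitrary units, only the ratios of
#' these coefficients matter; HbT is consequently reported in arbitrary
#' units throughout.
#'
#' @return An [extinction_table()] with rows at 750 and 850 nm.
#' @export
hb_extinction <- function() {
  read_extinction_table(
    system.file("extdata", "hb_extinction.csv", package = "paoxim",
                mustWork = TRUE))
}

# 2 x 2 design matrix with columns (HbO, HbD)
extinction_matrix <- function(ext) {
  cbind(hbo = ext$eps_hbo, hbd = ext$eps_hbd)
}

#' @export
print.extinction_table <- function(x, ...) {
  cat("Hemoglobin extinction table (cm^-1 M^-1)\n")
  print(data.frame(wavelength_nm = x$wavelengths,
                   eps_hbo = x$eps_hbo, eps_hbd = x$eps_hbd),
        row.names = FALSE)
  invisible(x)
}
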