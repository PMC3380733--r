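#' Construct a tandem mass spectrum
#'
#' Validates and canonicalizes one MS/MS scan: peaks are sorted by ascending
#' m/z, duplicate m/z values are merged by summing their intensities (the
#' downstream pair-counting features assume distinct peaks), and zero-intensity
#' peaks are dropped.
#'
#' @param id unique spectrum identifier (character scalar).
#' @param precursor_mz precursor m/z in Thomson (positive).
#' @param precursor_charge assumed precursor charge (positive integer).
#' @param mz numeric vector of fragment m/z values (positive).
#' @param intensity numeric vector of fragment intensities (non-negative),
#'   same length as `mz`.
#'
#' @return An object of class `ms2_spectrum`: a list with elements `id`,
#'   `precursor_mz`, `precursor_charge` and `peaks` (a data.frame with columns
#'   `mz`, `intensity`, strictly increasing in `mz`).
#' @examples
#' s <- spectrum("scan1", 601.00728, 1,
#'               mz = c(400, 200, 257.02), intensity = c(60, 10, 30))
#' s$peaks
#' @export
spectrum <- function(id, precursor_mz, precursor_charge, mz, intensity) {
  if (length(id) != 1L || is.na(id) || !nzchar(as.character(id)))
    stop("'id' must be a non-empty scalar")
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L || precursor_mz <= 0)
    stop("'precursor_mz' must be a single positive number")
  precursor_charge <- as.integer(precursor_charge)
  if (length(precursor_charge) != 1L || is.na(precursor_charge) || precursor_charge < 1L)
    stop("'precursor_charge' must be a positive integer")
  if (length(mz) != length(intensity))
    stop("'mz' and 'intensity' must have the same length")
  if (any(mz <= 0)) stop("all m/z values must be positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")

  keep <- intensity > 0
  mz <- mz[keep]; intensity <- intensity[keep]
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
      mz <- unique(mz)
    }
  }
  structure(list(
    id = as.character(id),
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = precursor_charge,
    peaks = data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity))
  ), class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("MS/MS spectrum '%s': precursor %.4f m/z (charge %d), %d peaks\n",
              x$id, x$precursor_mz, x$precursor_charge, nrow(x$peaks)))
  invisible(x)
}

n_peaks <- function(s) nrow(s$peaks)
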