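#' @name quality-features
#' @title The ten spectral quality features
#'
#' @description
#' Each feature is a real-valued summary of one MS/MS spectrum designed so
#' that larger values indicate higher quality. All pair-based features treat
#' every peak as singly charged and compare masses with the tolerance carried
#' in the [mass_constants()] object (default 0.5 Da).
#'
#' \describe{
#'   \item{f1 `f1_complement_intensity`}{total normalized intensity of peaks
#'     participating in at least one complementary pair (two peaks whose m/z
#'     values sum to the precursor pair-sum target); in \[0, 1\].}
#'   \item{f2 `f2_uncharged_precursor_mass`}{mass of the uncharged precursor
#'     ion, `precursor_mz * z - z * proton`, in Da.}
#'   \item{f3 `f3_aa_difference_count`}{number of unordered peak pairs whose
#'     m/z difference matches one of the 20 amino-acid residue masses; a pair
#'     matching several residues counts once.}
#'   \item{f4 `f4_mean_delta_mass`}{mean gap between consecutive peaks, Da.}
#'   \item{f5 `f5_good_diff_fraction`}{the Good-Diff fraction: sum of
#'     `NormI(x) + NormI(y)` over unordered pairs whose m/z difference matches
#'     a residue mass (each qualifying pair contributes once).}
#'   \item{f6 `f6_complementary_pair_count`}{number of complementary pairs.}
#'   \item{f7 `f7_neutral_loss_pair_count`}{number of pairs differing by the
#'     mass of water or ammonia.}
#'   \item{f8 `f8_intense_peak_ratio`}{fraction of peaks whose intensity
#'     exceeds 1 percent of the total intensity.}
#'   \item{f9 `f9_delta_mass_std`}{sample standard deviation of consecutive
#'     peak gaps, Da.}
#'   \item{f10 `f10_support_ion_pair_count`}{number of pairs differing by the
#'     mass of a CO or an NH group (a-/z-ion support).}
#' }
#'
#' Degenerate spectra (fewer than 2 peaks, or fewer than 3 for f9) yield 0
#' for the pair-based features with a warning, so batch processing never
#' aborts.
#'
#' @param spectrum a [spectrum()] object.
#' @param constants a [mass_constants()] object.
#' @return A single numeric value (fraction, Da or count as documented).
NULL

#' Normalized peak intensities
#'
#' `NormI(x) = intensity(x) / total intensity`; values sum to 1.
#'
#' @param spectrum a [spectrum()] object with at least one peak.
#' @return A data.frame with columns `mz` and `normi`.
#' @export
normalized_intensities <- function(spectrum) {
  p <- spectrum$peaks
  if (nrow(p) == 0L) stop("degenerate spectrum: no peaks")
  tot <- sum(p$intensity)
  if (tot <= 0) stop("degenerate spectrum: zero total intensity")
  data.frame(mz = p$mz, normi = p$intensity / tot)
}

# --- windowed pair-scan machinery over the sorted peak list ------------------

# number of sorted values <= x / < x
.fi_le <- function(x, mz) findInterval(x, mz)
.fi_lt <- function(x, mz) findInterval(x, mz, left.open = TRUE)

# merge targets +/- tol into disjoint closed intervals
.merge_intervals <- function(targets, tol) {
  targets <- sort(unique(targets))
  lo <- targets - tol; hi <- targets + tol
  keep_lo <- lo[1]; out <- NULL; cur_hi <- hi[1]
  for (k in seq_along(lo)[-1]) {
    if (lo[k] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[k])
    } else {
      out <- rbind(out, c(keep_lo, cur_hi))
      keep_lo <- lo[k]; cur_hi <- hi[k]
    }
  }
  rbind(out, c(keep_lo, cur_hi))
}

# per-peak count of partners j > i with mz_j - mz_i inside the interval union
.diff_pair_counts <- function(mz, targets, tol) {
  iv <- .merge_intervals(targets, tol)
  cnt <- integer(length(mz))
  hi_idx <- lo_idx <- NULL
  res <- vector("list", nrow(iv))
  for (k in seq_len(nrow(iv))) {
    a <- max(iv[k, 1], .Machine$double.eps)  # diffs are strictly positive
    b <- iv[k, 2]
    hi <- .fi_le(mz + b, mz)
    lo <- .fi_lt(mz + a, mz)
    cnt <- cnt + pmax(0L, hi - lo)
    res[[k]] <- cbind(lo, hi)
  }
  list(count = cnt, ranges = res)
}

# count pairs and the NormI pair-sum for difference-type features
.diff_pair_stats <- function(spectrum, targets, tol, want_normi = FALSE) {
  mz <- spectrum$peaks$mz
  if (length(mz) < 2L) return(list(count = 0L, normi_sum = 0))
  d <- .diff_pair_counts(mz, targets, tol)
  out <- list(count = sum(d$count), normi_sum = 0)
  if (want_normi) {
    normi <- normalized_intensities(spectrum)$normi
    cumN <- cumsum(normi)
    s <- 0
    for (r in d$ranges) {
      lo <- r[, 1]; hi <- r[, 2]
      k <- pmax(0L, hi - lo)
      upper_sum <- ifelse(hi >= 1, cumN[pmax(hi, 1L)], 0) -
                   ifelse(lo >= 1, cumN[pmax(lo, 1L)], 0)
      upper_sum[k == 0L] <- 0
      s <- s + sum(k * normi) + sum(upper_sum)
    }
    out$normi_sum <- s
  }
  out
}

# complementary (sum-type) pairs against target S; returns the pair count and
# the per-peak participation flag
.sum_pair_stats <- function(spectrum, constants) {
  mz <- spectrum$peaks$mz
  n <- length(mz)
  if (n < 2L) return(list(count = 0L, participates = logical(n)))
  S <- pair_sum_target(spectrum, constants)
  tol <- constants$tolerance
  hi <- .fi_le(S + tol - mz, mz)
  lo <- .fi_lt(S - tol - mz, mz)
  idx <- seq_len(n)
  # partners strictly above i (each unordered pair counted at its lower member)
  cnt_above <- pmax(0L, hi - pmax(lo, idx))
  # any partner at all (exclude the peak pairing with itself)
  in_range <- pmax(0L, hi - lo)
  self <- as.integer(mz >= S - tol - mz & mz <= S + tol - mz)
  list(count = sum(cnt_above), participates = (in_range - self) > 0L)
}

.warn_degenerate <- function(spectrum, what, need) {
  warning(sprintf("spectrum '%s': fewer than %d peaks, %s set to 0",
                  spectrum$id, need, what), call. = FALSE)
  0
}

#' @rdname quality-features
#' @export
f1_complement_intensity <- function(spectrum, constants = mass_constants()) {
  if (n_peaks(spectrum) < 2L)
    return(.warn_degenerate(spectrum, "f1", 2L))
  st <- .sum_pair_stats(spectrum, constants)
  normi <- normalized_intensities(spectrum)$normi
  sum(normi[st$participates])
}

#' @rdname quality-features
#' @export
f2_uncharged_precursor_mass <- function(spectrum, constants = mass_constants()) {
  z <- spectrum$precursor_charge
  spectrum$precursor_mz * z - z * constants$proton
}

#' @rdname quality-features
#' @export
f3_aa_difference_count <- function(spectrum, constants = mass_constants()) {
  .diff_pair_stats(spectrum, constants$residue_masses, constants$tolerance)$count
}

#' @rdname quality-features
#' @export
f4_mean_delta_mass <- function(spectrum) {
  if (n_peaks(spectrum) < 2L)
    return(.warn_degenerate(spectrum, "f4", 2L))
  mean(diff(spectrum$peaks$mz))
}

#' @rdname quality-features
#' @export
f5_good_diff_fraction <- function(spectrum, constants = mass_constants()) {
  if (n_peaks(spectrum) < 2L) return(0)
  .diff_pair_stats(spectrum, constants$residue_masses, constants$tolerance,
                   want_normi = TRUE)$normi_sum
}

#' @rdname quality-features
#' @export
f6_complementary_pair_count <- function(spectrum, constants = mass_constants()) {
  .sum_pair_stats(spectrum, constants)$count
}

#' @rdname quality-features
#' @export
f7_neutral_loss_pair_count <- function(spectrum, constants = mass_constants()) {
  .diff_pair_stats(spectrum, c(constants$water, constants$ammonia),
                   constants$tolerance)$count
}

#' @rdname quality-features
#' @export
f8_intense_peak_ratio <- function(spectrum) {
  p <- spectrum$peaks
  if (nrow(p) == 0L) stop("degenerate spectrum: no peaks")
  tot <- sum(p$intensity)
  mean(p$intensity > 0.01 * tot)
}

#' @rdname quality-features
#' @export
f9_delta_mass_std <- function(spectrum) {
  if (n_peaks(spectrum) < 3L)
    return(.warn_degenerate(spectrum, "f9", 3L))
  stats::sd(diff(spectrum$peaks$mz))
}

#' @rdname quality-features
#' @export
f10_support_ion_pair_count <- function(spectrum, constants = mass_constants()) {
  .diff_pair_stats(spectrum, c(constants$co_group, constants$nh_group),
                   constants$tolerance)$count
}

feature_names <- paste0("f", 1:10)

#' Compute the quality feature matrix for a set of spectra
#'
#' Applies all ten features (see [quality-features]) to each spectrum.
#' Degenerate spectra (too few peaks) receive the documented degenerate values
#' (0 for pair-based features) rather than aborting the batch; each such
#' spectrum is reported with a warning.
#'
#' @param spectra list of [spectrum()] objects.
#' @param constants a [mass_constants()] object.
#' @return A data.frame with columns `id`, `f1` ... `f10`, one row per
#'   spectrum in input order.
#' @examples
#' s <- spectrum("S_A", 601.00728, 1,
#'               mz = c(200, 257.02, 400), intensity = c(10, 30, 60))
#' compute_feature_matrix(list(s))
#' @export
compute_feature_matrix <- function(spectra, constants = mass_constants()) {
  rows <- lapply(spectra, function(s) {
    np <- n_peaks(s)
    if (np < 2L)
      warning(sprintf("spectrum '%s': %d peak(s); pair features set to 0",
                      s$id, np), call. = FALSE)
    suppressWarnings(c(
      f1 = if (np >= 2L) f1_complement_intensity(s, constants) else 0,
      f2 = f2_uncharged_precursor_mass(s, constants),
      f3 = f3_aa_difference_count(s, constants),
      f4 = if (np >= 2L) f4_mean_delta_mass(s) else 0,
      f5 = f5_good_diff_fraction(s, constants),
      f6 = f6_complementary_pair_count(s, constants),
      f7 = f7_neutral_loss_pair_count(s, constants),
      f8 = if (np >= 1L) f8_intense_peak_ratio(s) else 0,
      f9 = if (np >= 3L) f9_delta_mass_std(s) else 0,
      f10 = f10_support_ion_pair_count(s, constants)
    ))
  })
  ids <- vapply(spectra, `[[`, "", "id")
  if (length(rows)) {
    m <- do.call(rbind, rows)
    out <- data.frame(id = ids, m, row.names = NULL)
  } else {
    out <- data.frame(id = character(),
                      matrix(numeric(), 0, 10,
                             dimnames = list(NULL, feature_names)))
  }
  out
}

#' Write / read a feature table as tab-separated text
#'
#' @param features data.frame as returned by [compute_feature_matrix()].
#' @param path file path.
#' @return `path` (write) or the feature data.frame (read).
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(id = "character"), check.names = FALSE)
}
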