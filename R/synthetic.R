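#' Configuration for the synthetic spectrum generator
#'
#' Defines the study conditions for labelled synthetic MS/MS data. High-quality
#' spectra are singly-charged b-/y-ion ladders of random peptides (consecutive
#' same-series ions differ by residue masses; b/y pairs are complementary with
#' respect to the precursor pair-sum target) decorated with water/ammonia-loss
#' satellites and noise peaks. Poor-quality spectra are uniform-random noise
#' peaks with a precursor mass biased low. Defaults emulate a low-resolution
#' ion-trap run dominated by poor spectra (about 95 percent poor at the default counts).
#'
#' @param n_high,n_poor numbers of high-/poor-quality spectra (defaults 50 and
#'   950, i.e. 5 percent high).
#' @param peptide_length_range integer range of peptide lengths (default 8-16).
#' @param noise_peaks_range integer range of noise peaks added to a
#'   high-quality spectrum (default 10-40).
#' @param poor_peaks_range integer range of peaks in a poor-quality spectrum
#'   (default 20-70, roughly matching high-quality peak counts so pair
#'   structure, not peak count, carries the signal).
#' @param fragment_intensity,noise_intensity lognormal parameters
#'   (`meanlog`, `sdlog`) for fragment and noise peak intensities.
#' @param neutral_loss_prob probability that a kept fragment ion gains a
#'   water- or ammonia-loss satellite (default 0.3).
#' @param complement_drop_prob probability that any single fragment ion is
#'   missing from the spectrum (default 0.2).
#' @param mz_jitter_sd Gaussian m/z jitter applied to fragment peaks, in Da
#'   (default 0.05).
#' @param min_peaks minimum number of peaks per generated spectrum (default 5).
#' @param seed integer seed; mandatory for reproducibility.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_high = 50L, n_poor = 950L,
                       peptide_length_range = c(8L, 16L),
                       noise_peaks_range = c(10L, 40L),
                       poor_peaks_range = c(20L, 70L),
                       fragment_intensity = list(meanlog = log(500), sdlog = 0.5),
                       noise_intensity = list(meanlog = log(5), sdlog = 1.2),
                       neutral_loss_prob = 0.3,
                       complement_drop_prob = 0.2,
                       mz_jitter_sd = 0.05,
                       min_peaks = 5L,
                       seed) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is mandatory for reproducible simulation")
  stopifnot(n_high >= 0, n_poor >= 0,
            neutral_loss_prob >= 0, neutral_loss_prob <= 1,
            complement_drop_prob >= 0, complement_drop_prob <= 1,
            mz_jitter_sd >= 0, min_peaks >= 1)
  structure(list(
    n_high = as.integer(n_high), n_poor = as.integer(n_poor),
    peptide_length_range = as.integer(peptide_length_range),
    noise_peaks_range = as.integer(noise_peaks_range),
    poor_peaks_range = as.integer(poor_peaks_range),
    fragment_intensity = fragment_intensity,
    noise_intensity = noise_intensity,
    neutral_loss_prob = neutral_loss_prob,
    complement_drop_prob = complement_drop_prob,
    mz_jitter_sd = mz_jitter_sd,
    min_peaks = as.integer(min_peaks),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Any subset of the [sim_config()] fields may be given; the rest keep their
#' defaults. `seed` is required (in the file or as the argument).
#'
#' @param path path to a YAML file.
#' @param seed fallback seed if the file does not set one.
#' @return A [sim_config()] object.
#' @export
read_sim_config <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- seed
  known <- names(formals(sim_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, cfg)
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rint <- function(range) {
  if (range[1] >= range[2]) return(range[1])
  range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
}

.sim_high <- function(config, id, constants) {
  L <- rint(config$peptide_length_range)
  res <- sample(constants$residue_masses, L, replace = TRUE)
  M <- sum(res) + constants$water                 # neutral peptide mass
  precursor_mz <- M + constants$proton            # singly charged precursor
  target <- switch(constants$pair_sum_convention,
                   uncharged = M,
                   protonated = M + constants$proton,
                   by = M + 2 * constants$proton)

  b <- constants$proton + cumsum(res)[seq_len(L - 1L)]  # b-ion ladder
  y <- target - b                                       # complementary partners
  ions <- c(b, y)
  keep <- stats::runif(length(ions)) >= config$complement_drop_prob
  ions <- ions[keep]
  fi <- config$fragment_intensity
  int <- stats::rlnorm(length(ions), fi$meanlog, fi$sdlog)

  # neutral-loss satellites of kept ions
  sat <- stats::runif(length(ions)) < config$neutral_loss_prob
  if (any(sat)) {
    loss <- sample(c(constants$water, constants$ammonia), sum(sat), replace = TRUE)
    ions <- c(ions, ions[sat] - loss)
    int <- c(int, int[sat] * stats::runif(sum(sat), 0.2, 0.5))
  }

  if (config$mz_jitter_sd > 0)
    ions <- ions + stats::rnorm(length(ions), 0, config$mz_jitter_sd)

  n_noise <- rint(config$noise_peaks_range)
  deficit <- config$min_peaks - (length(ions) + n_noise)
  if (deficit > 0) n_noise <- n_noise + deficit
  ni <- config$noise_intensity
  mz <- c(ions, stats::runif(n_noise, 100, M))
  int <- c(int, stats::rlnorm(n_noise, ni$meanlog, ni$sdlog))
  ok <- mz > 0
  spectrum(id, precursor_mz, 1L, mz[ok], int[ok])
}

.sim_poor <- function(config, id, constants) {
  n <- max(config$min_peaks, rint(config$poor_peaks_range))
  precursor_mz <- stats::runif(1, 300, 900)  # poor spectra: small precursor mass
  ni <- config$noise_intensity
  spectrum(id, precursor_mz, 1L,
           stats::runif(n, 100, 1600),
           stats::rlnorm(n, ni$meanlog, ni$sdlog))
}

#' Simulate one high-quality spectrum
#'
#' Draws a random peptide, emits singly-charged b- and y-ion ladders (b/y
#' pairs complementary with respect to the precursor pair-sum target), drops
#' ions at random, adds neutral-loss satellites and noise peaks, and jitters
#' fragment m/z. The precursor fields are consistent with the peptide mass.
#' Seeded by `config$seed`; the caller's RNG state is untouched.
#'
#' @param config a [sim_config()] object.
#' @param id spectrum identifier.
#' @param constants a [mass_constants()] object.
#' @return A [spectrum()] object.
#' @export
simulate_high <- function(config, id = "high_1", constants = mass_constants()) {
  with_seed(config$seed, .sim_high(config, id, constants))
}

#' Simulate one poor-quality spectrum
#'
#' Uniform-random m/z peaks with noise-distributed intensities and a small,
#' randomly drawn precursor mass. Seeded by `config$seed`.
#'
#' @inheritParams simulate_high
#' @return A [spectrum()] object.
#' @export
simulate_poor <- function(config, id = "poor_1", constants = mass_constants()) {
  with_seed(config$seed, .sim_poor(config, id, constants))
}

#' Simulate a labelled spectrum dataset
#'
#' Generates `n_high` high-quality and `n_poor` poor-quality spectra, shuffles
#' them, and returns the spectra together with the ground-truth label table.
#' Fully deterministic given the config (same seed, same config: identical
#' output).
#'
#' @inheritParams simulate_high
#' @return A list with elements `spectra` (list of [spectrum()] objects) and
#'   `labels` (data.frame `id`, `label` as in [read_labels()]).
#' @examples
#' d <- simulate_dataset(sim_config(n_high = 5, n_poor = 20, seed = 1))
#' table(d$labels$label)
#' @export
simulate_dataset <- function(config, constants = mass_constants()) {
  if (config$n_high + config$n_poor < 1L) stop("nothing to simulate")
  with_seed(config$seed, {
    highs <- lapply(seq_len(config$n_high), function(i)
      .sim_high(config, sprintf("high_%04d", i), constants))
    poors <- lapply(seq_len(config$n_poor), function(i)
      .sim_poor(config, sprintf("poor_%04d", i), constants))
    spectra <- c(highs, poors)
    lab <- c(rep("high", config$n_high), rep("poor", config$n_poor))
    perm <- sample.int(length(spectra))
    spectra <- spectra[perm]
    lab <- lab[perm]
    list(
      spectra = spectra,
      labels = data.frame(id = vapply(spectra, `[[`, "", "id"),
                          label = factor(lab, levels = c("high", "poor")))
    )
  })
}
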