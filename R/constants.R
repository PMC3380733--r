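#' Mass constants for spectral feature computation
#'
#' Bundles the monoisotopic residue masses of the 20 standard amino acids and
#' the small-molecule masses used by the pair-counting features, together with
#' the m/z matching tolerance and the complementary pair-sum convention.
#'
#' Residue masses are monoisotopic (the mass of an amino acid within a peptide
#' chain, i.e. minus water). Leucine/isoleucine share one mass and
#' glutamine/lysine differ by 0.036 Da; both near-duplicates are retained in
#' the table, and a peak pair whose difference matches several residues is
#' counted once.
#'
#' The pair-sum convention fixes the target \eqn{T} against which two fragment
#' m/z values \eqn{x + y \approx T} are declared complementary:
#' \describe{
#'   \item{`"uncharged"`}{\eqn{T = } uncharged precursor mass
#'     (\eqn{m/z \cdot z - z \cdot proton}); the default.}
#'   \item{`"protonated"`}{\eqn{T = M + proton}, the singly protonated
#'     precursor mass.}
#'   \item{`"by"`}{\eqn{T = M + 2 \cdot proton}, the sum of singly protonated
#'     b- and y-ion m/z values from one backbone bond.}
#' }
#'
#' @param tolerance m/z matching tolerance in Da (default 0.5, suited to
#'   low-resolution ion-trap spectra).
#' @param pair_sum_convention one of `"uncharged"`, `"protonated"`, `"by"`.
#' @param residue_masses named numeric vector of residue masses in Da;
#'   defaults to the 20 standard monoisotopic masses.
#'
#' @return An object of class `mass_constants`: a list with elements
#'   `residue_masses`, `water`, `ammonia`, `co_group`, `nh_group`, `proton`,
#'   `tolerance`, `pair_sum_convention`.
#' @examples
#' mc <- mass_constants()
#' mc$residue_masses[["G"]]  # glycine, 57.02146
#' @export
mass_constants <- function(tolerance = 0.5,
                           pair_sum_convention = c("uncharged", "protonated", "by"),
                           residue_masses = NULL) {
  pair_sum_convention <- match.arg(pair_sum_convention)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0)
    stop("'tolerance' must be a single positive number")
  if (is.null(residue_masses)) residue_masses <- .residue_masses_mono
  if (!is.numeric(residue_masses) || any(residue_masses <= 0))
    stop("residue masses must be positive numbers")
  structure(list(
    residue_masses = residue_masses,
    water    = 18.010565,
    ammonia  = 17.026549,
    co_group = 27.994915,
    nh_group = 15.010899,
    proton   = 1.00727646688,
    tolerance = tolerance,
    pair_sum_convention = pair_sum_convention
  ), class = "mass_constants")
}

# monoisotopic residue masses (Da), amino acid minus water
.residue_masses_mono <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Read mass-constant overrides from a YAML file
#'
#' The file may define any subset of `tolerance`, `pair_sum_convention` and
#' `residue_masses` (a named map); unspecified entries keep their defaults.
#'
#' @param path path to a YAML file.
#' @return A [mass_constants()] object.
#' @export
read_mass_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rm_tab <- .residue_masses_mono
  if (!is.null(cfg$residue_masses)) {
    ov <- unlist(cfg$residue_masses)
    unknown <- setdiff(names(ov), names(rm_tab))
    if (length(unknown))
      stop("unknown residue(s) in config: ", paste(unknown, collapse = ", "))
    rm_tab[names(ov)] <- ov
  }
  mass_constants(
    tolerance = if (is.null(cfg$tolerance)) 0.5 else cfg$tolerance,
    pair_sum_convention =
      if (is.null(cfg$pair_sum_convention)) "uncharged" else cfg$pair_sum_convention,
    residue_masses = rm_tab
  )
}

#' @export
print.mass_constants <- function(x, ...) {
  cat("Mass constants (monoisotopic)\n")
  cat("  tolerance:          ", x$tolerance, "Da\n")
  cat("  pair-sum convention:", x$pair_sum_convention, "\n")
  cat("  residues:           ", length(x$residue_masses), "entries,",
      format(min(x$residue_masses)), "-", format(max(x$residue_masses)), "Da\n")
  invisible(x)
}

# Target m/z sum for a complementary pair under the configured convention.
pair_sum_target <- function(spectrum, constants) {
  m_unch <- spectrum$precursor_mz * spectrum$precursor_charge -
    spectrum$precursor_charge * constants$proton
  switch(constants$pair_sum_convention,
         uncharged  = m_unch,
         protonated = m_unch + constants$proton,
         by         = m_unch + 2 * constants$proton)
}
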