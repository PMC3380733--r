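# Shared fixtures, all built in code.

# Three-peak spectrum with one complementary pair (200 + 400 = uncharged
# precursor mass 600) and one glycine gap (257.02 - 200 = 57.02).
fixture_sa <- function() {
  spectrum("S_A", precursor_mz = 601.00728, precursor_charge = 1,
           mz = c(200.0, 257.02, 400.0), intensity = c(10, 30, 60))
}

# hand-derived feature vector of fixture_sa() (f9 = sd(c(57.02, 142.98)))
fixture_sa_features <- c(
  f1 = 0.7, f2 = 600.0, f3 = 1, f4 = 100.0, f5 = 0.4,
  f6 = 1, f7 = 0, f8 = 1.0, f9 = 60.78291, f10 = 0
)

random_spectrum <- function(id = "r", max_peaks = 50) {
  n <- sample(2:max_peaks, 1)
  spectrum(id,
           precursor_mz = runif(1, 400, 1200),
           precursor_charge = sample(1:3, 1),
           mz = round(runif(n, 100, 1500), 4),
           intensity = rlnorm(n, 3, 1))
}

random_assignments <- function(n, m) {
  matrix(sample(1:2, n * m, replace = TRUE), n, m)
}

write_tmp_mgf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".mgf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
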