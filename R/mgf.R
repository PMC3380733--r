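#' Read spectra from a Mascot Generic Format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS` and `CHARGE`
#' headers. Per-block problems (missing PEPMASS, a non-numeric peak line) cause
#' that block to be rejected with a warning naming the reason; the remaining
#' blocks are still returned. Structural problems at file level (e.g. an
#' `END IONS` without a matching `BEGIN IONS`) are errors.
#'
#' Spectrum ids come from `TITLE`, or are synthesized as
#' `"<filename>#<ordinal>"` when absent. A missing `CHARGE` defaults to 1 with
#' a warning; charge strings `"2+"`, `"2"`, `"+2"` all parse to 2, and when
#' several charges are listed (`"2+ and 3+"`) the first is used with a warning.
#' Peaks are sorted ascending by m/z, exact duplicate m/z merged, and
#' zero-intensity peaks dropped (see [spectrum()]).
#'
#' @param path path to an MGF file.
#' @return A list of [spectrum()] objects.
#' @seealso [write_mgf()]
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  fname <- basename(path)

  spectra <- list()
  in_block <- FALSE
  block <- NULL
  ordinal <- 0L

  flush_block <- function(block, ordinal) {
    hdr <- block$header
    if (is.null(hdr$pepmass)) {
      warning(sprintf("MGF block %d rejected: no PEPMASS", ordinal))
      return(NULL)
    }
    id <- if (!is.null(hdr$title)) hdr$title else sprintf("%s#%d", fname, ordinal)
    charge <- hdr$charge
    if (is.null(charge)) {
      warning(sprintf("MGF block %d ('%s'): no CHARGE, defaulting to 1", ordinal, id))
      charge <- 1L
    }
    spectrum(id, hdr$pepmass, charge,
             mz = block$mz, intensity = block$intensity)
  }

  for (ln in lines) {
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (in_block) stop("malformed MGF: nested BEGIN IONS")
      in_block <- TRUE
      ordinal <- ordinal + 1L
      block <- list(header = list(), mz = numeric(), intensity = numeric(),
                    bad = FALSE, reason = NULL)
      next
    }
    if (ln == "END IONS") {
      if (!in_block) stop("malformed MGF: END IONS without BEGIN IONS")
      in_block <- FALSE
      if (block$bad) {
        warning(sprintf("MGF block %d rejected: %s", ordinal, block$reason))
      } else {
        s <- flush_block(block, ordinal)
        if (!is.null(s)) spectra[[length(spectra) + 1L]] <- s
      }
      next
    }
    if (!in_block) next  # headers outside blocks are ignored
    if (grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "TITLE") {
        block$header$title <- val
      } else if (key == "PEPMASS") {
        pm <- suppressWarnings(as.numeric(strsplit(trimws(val), "\\s+")[[1]][1]))
        if (is.na(pm)) { block$bad <- TRUE; block$reason <- "non-numeric PEPMASS" }
        else block$header$pepmass <- pm
      } else if (key == "CHARGE") {
        block$header$charge <- parse_charge(val)
      }
      next
    }
    # peak line: "mz intensity" (whitespace separated)
    tok <- strsplit(ln, "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      block$bad <- TRUE
      block$reason <- sprintf("non-numeric peak line '%s'", ln)
      next
    }
    block$mz <- c(block$mz, vals[1])
    block$intensity <- c(block$intensity, vals[2])
  }
  if (in_block) stop("malformed MGF: unterminated BEGIN IONS block")
  spectra
}

# "2+", "+2", "2" -> 2L; multiple charges take the first, with a warning
parse_charge <- function(val) {
  toks <- regmatches(val, gregexpr("[+-]?[0-9]+[+-]?", val))[[1]]
  if (!length(toks)) {
    warning(sprintf("unparseable CHARGE '%s', defaulting to 1", val))
    return(1L)
  }
  if (length(toks) > 1L)
    warning(sprintf("multiple charges in '%s'; using the first", val))
  z <- as.integer(gsub("[+-]", "", toks[1]))
  if (grepl("-", toks[1], fixed = TRUE)) z <- -z
  if (is.na(z) || z < 1L) {
    warning(sprintf("invalid CHARGE '%s', defaulting to 1", val))
    return(1L)
  }
  z
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]: `read_mgf(write_mgf(S))` reproduces ids, precursor
#' fields and peak lists up to float formatting.
#'
#' @param spectra list of [spectrum()] objects (may be empty).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s$id),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      sprintf("CHARGE=%d+", s$precursor_charge),
      sprintf("%.6f %.6f", s$peaks$mz, s$peaks$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Read a spectrum quality label table
#'
#' Reads a two-column delimited text file (comma or tab separated, no header)
#' mapping spectrum id to a quality label. Labels are normalized to
#' `"high"`/`"poor"`; `"H"`/`"P"` (any case) are accepted aliases.
#'
#' @param path path to the label file.
#' @return A data.frame with columns `id` (character) and `label`
#'   (factor with levels `high`, `poor`).
#' @export
read_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[,\t]")
  if (any(lengths(parts) < 2L)) stop("label file must have two delimited columns")
  id <- trimws(vapply(parts, `[[`, "", 1L))
  raw <- tolower(trimws(vapply(parts, `[[`, "", 2L)))
  if (anyDuplicated(id)) {
    stop("duplicate spectrum id(s) in label file: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  label <- ifelse(raw %in% c("high", "h"), "high",
                  ifelse(raw %in% c("poor", "p"), "poor", NA_character_))
  if (anyNA(label)) {
    stop("unknown label token(s): ",
         paste(unique(raw[is.na(label)]), collapse = ", "))
  }
  data.frame(id = id, label = factor(label, levels = c("high", "poor")))
}

#' Write a spectrum quality label table
#'
#' @param labels data.frame with columns `id`, `label` (as from [read_labels()]).
#' @param path output path; written as tab-separated text without header.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(labels$id, as.character(labels$label)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
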