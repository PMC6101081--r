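# Deconvoluted spectra: containers, msalign/TSV IO, ppm matching and
# intensity pooling of complementary fragment masses.

#' Construct a deconvoluted spectrum
#'
#' Holds a precursor neutral monoisotopic mass and a peak list of neutral
#' monoisotopic fragment masses with intensities, as produced by top-down
#' deconvolution tools. Peaks are stored sorted by mass.
#'
#' @param spectrum_id Identifier.
#' @param precursor_mass Precursor neutral monoisotopic mass (Da).
#' @param masses Numeric vector of neutral fragment masses (Da).
#' @param intensities Nonnegative intensities, same length as `masses`.
#' @param charges Optional integer charges (informational).
#' @param activation One of `"CID"`, `"HCD"`, `"ETD"`.
#' @return Object of class `deconv_spectrum`.
#' @export
deconv_spectrum <- function(spectrum_id, precursor_mass, masses,
                            intensities, charges = NULL,
                            activation = c("CID", "HCD", "ETD")) {
  activation <- match.arg(activation)
  stopifnot(is.numeric(precursor_mass), length(precursor_mass) == 1L,
            precursor_mass > 0, length(masses) == length(intensities))
  if (length(masses) > 0L) {
    stopifnot(all(masses > 0), all(intensities >= 0))
  }
  if (is.null(charges)) charges <- rep(NA_integer_, length(masses))
  ord <- order(masses)
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mass = precursor_mass,
                 activation = activation,
                 peaks = data.frame(mass = masses[ord],
                                    intensity = intensities[ord],
                                    charge = charges[ord])),
            class = "deconv_spectrum")
}

#' @export
print.deconv_spectrum <- function(x, ...) {
  cat("deconvoluted spectrum", x$spectrum_id, "(", x$activation, ")\n")
  cat("precursor neutral mass:", format(x$precursor_mass, nsmall = 4), "Da;",
      nrow(x$peaks), "peaks\n")
  invisible(x)
}

# ---- IO --------------------------------------------------------------------

#' Read deconvoluted spectra in the msalign dialect
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `KEY=VALUE` headers (at least
#' `PRECURSOR_MASS`; `ID` and `ACTIVATION` are used when present) and one
#' `mass intensity [charge]` line per peak. Unknown header keys are ignored.
#'
#' @param path File path.
#' @return List of `deconv_spectrum` objects (empty for an empty file).
#' @export
read_msalign <- function(path) {
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  headers <- list(); masses <- numeric(0); intens <- numeric(0); charges <- integer(0)
  block_start <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block) stop("nested BEGIN IONS at line ", ln, call. = FALSE)
      in_block <- TRUE; block_start <- ln
      headers <- list(); masses <- numeric(0); intens <- numeric(0); charges <- integer(0)
    } else if (line == "END IONS") {
      if (!in_block) stop("END IONS without BEGIN IONS at line ", ln, call. = FALSE)
      id <- if (!is.null(headers$ID)) headers$ID else paste0("spectrum_", length(spectra) + 1L)
      if (is.null(headers$PRECURSOR_MASS)) {
        stop("block '", id, "' starting at line ", block_start,
             " has no PRECURSOR_MASS", call. = FALSE)
      }
      act <- if (!is.null(headers$ACTIVATION)) toupper(headers$ACTIVATION) else "CID"
      if (!act %in% c("CID", "HCD", "ETD")) act <- "CID"
      spectra[[length(spectra) + 1L]] <- deconv_spectrum(
        id, as.numeric(headers$PRECURSOR_MASS), masses, intens, charges, act)
      in_block <- FALSE
    } else if (!in_block) {
      stop("content outside BEGIN IONS/END IONS at line ", ln, call. = FALSE)
    } else if (grepl("=", line, fixed = TRUE)) {
      eq <- regexpr("=", line, fixed = TRUE)
      headers[[substr(line, 1L, eq - 1L)]] <- substr(line, eq + 1L, nchar(line))
    } else {
      fields <- strsplit(line, "[\t ]+")[[1]]
      vals <- suppressWarnings(as.numeric(fields))
      if (length(fields) < 2L || anyNA(vals[1:2])) {
        id <- if (!is.null(headers$ID)) headers$ID else "<unnamed>"
        stop("malformed peak line ", ln, " in block '", id, "': ", line,
             call. = FALSE)
      }
      masses <- c(masses, vals[1]); intens <- c(intens, vals[2])
      charges <- c(charges, if (length(vals) >= 3L) as.integer(vals[3]) else NA_integer_)
    }
  }
  if (in_block) stop("unterminated BEGIN IONS block at line ", block_start, call. = FALSE)
  spectra
}

#' Write spectra in the msalign dialect
#'
#' @param spectra A `deconv_spectrum` or list of them.
#' @param path Output path.
#' @export
write_msalign <- function(spectra, path) {
  if (inherits(spectra, "deconv_spectrum")) spectra <- list(spectra)
  con <- file(path, "w"); on.exit(close(con))
  for (sp in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("ID=", sp$spectrum_id),
                 paste0("ACTIVATION=", sp$activation),
                 paste0("PRECURSOR_MASS=", sprintf("%.17g", sp$precursor_mass))),
               con)
    if (nrow(sp$peaks) > 0L) {
      writeLines(paste(sprintf("%.17g", sp$peaks$mass),
                       sprintf("%.17g", sp$peaks$intensity),
                       ifelse(is.na(sp$peaks$charge), 1L, sp$peaks$charge),
                       sep = "\t"), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read a single spectrum from the plain TSV dialect
#'
#' Header line `neutral_mass<TAB>intensity[<TAB>charge]`, one peak per line,
#' precursor mass in a `#PRECURSOR_MASS=` comment; one spectrum per file.
#'
#' @param path File path.
#' @param spectrum_id Identifier (defaults to the file name).
#' @export
read_spectrum_tsv <- function(path, spectrum_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  prec <- NA_real_; act <- "CID"
  for (line in lines[startsWith(lines, "#")]) {
    if (grepl("^#\\s*PRECURSOR_MASS=", line)) {
      prec <- as.numeric(sub("^#\\s*PRECURSOR_MASS=", "", line))
    }
    if (grepl("^#\\s*ACTIVATION=", line)) {
      act <- toupper(trimws(sub("^#\\s*ACTIVATION=", "", line)))
    }
  }
  if (is.na(prec)) stop("no #PRECURSOR_MASS= comment in ", path, call. = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE)
  if (!all(c("neutral_mass", "intensity") %in% names(tab))) {
    stop("TSV spectrum needs columns neutral_mass and intensity", call. = FALSE)
  }
  if (is.null(spectrum_id)) spectrum_id <- basename(path)
  deconv_spectrum(spectrum_id, prec, tab$neutral_mass, tab$intensity,
                  if ("charge" %in% names(tab)) tab$charge else NULL,
                  if (act %in% c("CID", "HCD", "ETD")) act else "CID")
}

#' Write a spectrum in the plain TSV dialect
#' @param spectrum A `deconv_spectrum`.
#' @param path Output path.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("#PRECURSOR_MASS=", sprintf("%.17g", spectrum$precursor_mass)),
               paste0("#ACTIVATION=", spectrum$activation),
               "neutral_mass\tintensity\tcharge"), con)
  if (nrow(spectrum$peaks) > 0L) {
    writeLines(paste(sprintf("%.17g", spectrum$peaks$mass),
                     sprintf("%.17g", spectrum$peaks$intensity),
                     ifelse(is.na(spectrum$peaks$charge), 1L, spectrum$peaks$charge),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read spectra from msalign or TSV by extension
#' @param path File path (`.msalign`/`.mgf`-style blocks, or `.tsv`).
#' @export
read_spectra <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    list(read_spectrum_tsv(path))
  } else {
    read_msalign(path)
  }
}

# ---- Ion schemes and matching ----------------------------------------------

#' Fragment ion-type scheme
#'
#' One N-terminal and one C-terminal ion type with their neutral-mass
#' offsets relative to prefix/suffix residue masses. `"by"` (CID/HCD):
#' b = prefix + 0, y = suffix + water. `"cz"` (ETD): c = prefix + NH3,
#' z-dot = suffix + (water - NH3 + H).
#'
#' @param name `"by"` or `"cz"`.
#' @return List with `name`, `n_term_offset`, `c_term_offset`, `labels`.
#' @export
ion_scheme <- function(name = c("by", "cz")) {
  name <- match.arg(name)
  nh3 <- .formula_mass(c(N = 1, H = 3))
  h <- .ELEMENT_MONO[["H"]]
  switch(name,
    by = list(name = "by", n_term_offset = 0, c_term_offset = WATER_MONO,
              labels = c("b", "y")),
    cz = list(name = "cz", n_term_offset = nh3,
              c_term_offset = WATER_MONO - nh3 + h,
              labels = c("c", "z")))
}

#' Default ion scheme for an activation type
#' @param activation `"CID"`, `"HCD"` or `"ETD"`.
#' @export
scheme_for_activation <- function(activation) {
  if (toupper(activation) == "ETD") ion_scheme("cz") else ion_scheme("by")
}

#' Relative (ppm) mass match
#'
#' TRUE iff `|observed - theoretical| <= tol_ppm * 1e-6 * theoretical`; the
#' window is computed against the theoretical mass and is symmetric.
#'
#' @param observed,theoretical Masses in Da (vectorized).
#' @param tol_ppm Tolerance in ppm.
#' @export
ppm_match <- function(observed, theoretical, tol_ppm) {
  stopifnot(tol_ppm >= 0)
  # tiny relative slack so the exact boundary m * (1 + tol * 1e-6) matches
  # despite floating-point rounding
  abs(observed - theoretical) <= tol_ppm * 1e-6 * theoretical * (1 + 1e-9)
}

# Sum of intensities of peaks within the ppm window of each theoretical mass.
# Peaks may contribute to every theoretical mass they match.
.window_intensity <- function(theoretical, peak_mass, peak_int, tol_ppm) {
  if (length(peak_mass) == 0L || length(theoretical) == 0L) {
    return(numeric(length(theoretical)))
  }
  half <- tol_ppm * 1e-6 * theoretical
  lo <- findInterval(theoretical - half, peak_mass, left.open = TRUE) # peaks strictly below lower edge
  hi <- findInterval(theoretical + half, peak_mass)        # peaks at or below upper edge
  csum <- c(0, cumsum(peak_int))
  csum[hi + 1L] - csum[lo + 1L]
}

#' Raw intensity of a prefix residue mass
#'
#' Sum of the intensities of peaks matching the N-terminal fragment mass
#' (`m + n_term_offset`) plus peaks matching the complementary C-terminal
#' fragment mass (`(total_residue_mass - m) + c_term_offset`), each within
#' the ppm tolerance of the theoretical mass.
#'
#' @param m Prefix residue mass(es), Da (vectorized).
#' @param spectrum A `deconv_spectrum`.
#' @param total_residue_mass Residue-mass total of the proteoform (Da).
#' @param scheme An `ion_scheme()`.
#' @param tol_ppm Fragment tolerance in ppm.
#' @return Numeric vector of pooled intensities (0 where nothing matches).
#' @export
raw_intensity <- function(m, spectrum, total_residue_mass,
                          scheme = ion_scheme("by"), tol_ppm = 15) {
  stopifnot(all(m >= -1e-9), all(m <= total_residue_mass + 1e-9))
  pm <- spectrum$peaks$mass
  pi_ <- spectrum$peaks$intensity
  .window_intensity(m + scheme$n_term_offset, pm, pi_, tol_ppm) +
    .window_intensity((total_residue_mass - m) + scheme$c_term_offset, pm, pi_, tol_ppm)
}

#' Relative intensities of a set of prefix residue masses
#'
#' Each raw intensity divided by the largest raw intensity; an all-zero
#' input maps to all zeros.
#'
#' @inheritParams raw_intensity
#' @param masses Prefix residue masses (Da), at least one.
#' @export
relative_intensities <- function(masses, spectrum, total_residue_mass,
                                 scheme = ion_scheme("by"), tol_ppm = 15) {
  stopifnot(length(masses) >= 1L)
  raw <- raw_intensity(masses, spectrum, total_residue_mass, scheme, tol_ppm)
  mx <- max(raw)
  if (mx <= 0) return(rep(0, length(raw)))
  raw / mx
}

#' Theoretical fragment neutral masses of a proteoform
#'
#' N- and C-terminal fragment masses at every internal cleavage site
#' (positions 1..n-1) under the given ion scheme.
#'
#' @param pf A `proteoform`.
#' @param scheme An `ion_scheme()`.
#' @return Data frame with columns `site`, `type` and `mass`.
#' @export
theoretical_fragments <- function(pf, scheme = ion_scheme("by")) {
  pre <- proteoform_prefix_masses(pf)
  n <- length(pre) - 1L
  if (n < 2L) {
    return(data.frame(site = integer(0), type = character(0), mass = numeric(0)))
  }
  total <- pre[n + 1L]
  sites <- seq_len(n - 1L)
  data.frame(
    site = c(sites, sites),
    type = rep(scheme$labels, each = n - 1L),
    mass = c(pre[sites + 1L] + scheme$n_term_offset,
             (total - pre[sites + 1L]) + scheme$c_term_offset))
}
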