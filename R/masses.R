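# Monoisotopic atomic masses (CODATA/IUPAC values, Da) used to derive the
# residue-mass table from elemental compositions.
.ELEMENT_MONO <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196, S = 31.97207100)

# Residue (amino acid minus water) elemental compositions, 20 standard residues.
.RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

.formula_mass <- function(fm) sum(.ELEMENT_MONO[names(fm)] * fm)

#' Monoisotopic residue masses of the 20 standard amino acids
#'
#' Named numeric vector of residue (amino acid minus water) monoisotopic
#' masses in Da, derived from elemental compositions.
#' @export
AA_MONO_MASSES <- vapply(.RESIDUE_FORMULA, .formula_mass, numeric(1))

#' Monoisotopic mass of water (Da)
#' @export
WATER_MONO <- .formula_mass(c(H = 2, O = 1))

# Isotopologue spacing (Da) used for the optional +-1 Da precursor windows,
# following the deconvolution convention.
ISOTOPE_SPACING <- 1.00235

# Cumulative PTM shifts are merged after rounding to 1e-5 Da: chains whose
# shift sums agree to 0.01 mDa are numerically the same mass (e.g. two
# methylations vs one dimethylation), while acetylation (42.01056) and
# trimethylation (42.04695) stay distinct.
.MASS_KEY_DIGITS <- 5L
.mkey <- function(x) round(x * 10^.MASS_KEY_DIGITS)

#' Monoisotopic residue mass of an amino acid
#'
#' @param aa Character vector of single amino-acid letters (the 20 standard
#'   residues).
#' @return Numeric vector of residue masses in Da.
#' @examples
#' residue_mass("G")
#' residue_mass(c("K", "R"))
#' @export
residue_mass <- function(aa) {
  aa <- as.character(aa)
  bad <- !(aa %in% names(AA_MONO_MASSES))
  if (any(bad)) {
    stop("unknown amino-acid letter(s): ",
         paste(unique(aa[bad]), collapse = ", "), call. = FALSE)
  }
  unname(AA_MONO_MASSES[aa])
}

.seq_chars <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) return(character(0))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% names(AA_MONO_MASSES))
  if (any(bad)) {
    stop("invalid residue(s) in sequence: ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  }
  chars
}

#' Prefix residue masses of an unmodified sequence
#'
#' Returns p_0, ..., p_n where p_i is the sum of the residue masses of the
#' first i amino acids (p_0 = 0). Suffix residue masses follow as
#' s_i = p_n - p_(n-i).
#'
#' @param sequence Amino-acid string.
#' @return Numeric vector of length `nchar(sequence) + 1`.
#' @export
prefix_residue_masses <- function(sequence) {
  chars <- .seq_chars(sequence)
  c(0, cumsum(residue_mass(chars)))
}

# ---- Expected-PTM table ----------------------------------------------------

.validate_ptm_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("name", "mass_shift", "residues") %in% names(tab)))
  if (any(tab$mass_shift == 0)) stop("PTM mass shifts must be nonzero", call. = FALSE)
  if (anyDuplicated(tab$name)) stop("duplicate PTM names", call. = FALSE)
  for (i in seq_len(nrow(tab))) {
    res <- .ptm_residues(tab$residues[i])
    if (length(res) == 0L) stop("PTM '", tab$name[i], "' has no residues", call. = FALSE)
    bad <- !(res %in% names(AA_MONO_MASSES))
    if (any(bad)) {
      stop("PTM '", tab$name[i], "' names invalid residue(s): ",
           paste(res[bad], collapse = ", "), call. = FALSE)
    }
  }
  class(tab) <- c("ptm_table", "data.frame")
  tab
}

.ptm_residues <- function(residues) {
  toupper(trimws(strsplit(residues, ",", fixed = TRUE)[[1]]))
}

#' Default expected-PTM table for histone work
#'
#' The five expected PTMs commonly allowed on core histones: acetylation and
#' mono/di-methylation on R and K, trimethylation on R, and phosphorylation
#' on S, T and Y, with their monoisotopic mass shifts in Da.
#'
#' @return A `ptm_table` data frame with columns `name`, `mass_shift` and
#'   `residues` (comma-separated residue letters).
#' @export
default_ptm_table <- function() {
  .validate_ptm_table(data.frame(
    name = c("Acetylation", "Methylation", "Dimethylation",
             "Trimethylation", "Phosphorylation"),
    mass_shift = c(42.01056, 14.01565, 28.03130, 42.04695, 79.96633),
    residues = c("R,K", "R,K", "R,K", "R", "S,T,Y"),
    stringsAsFactors = FALSE))
}

#' Read an expected-PTM table from TSV or YAML
#'
#' TSV files need columns `name`, `monoisotopic_mass` (or `mass_shift`) and
#' `residues`; YAML files hold a list of records with the same fields.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"yaml"`.
#' @return A `ptm_table` data frame.
#' @export
read_ptm_table <- function(path, format = c("auto", "tsv", "yaml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "tsv"
  }
  if (format == "yaml") {
    # keep bare T/Y/N residue letters as strings, not YAML booleans
    recs <- yaml::read_yaml(path, handlers = list("bool#yes" = identity,
                                                  "bool#no" = identity))
    tab <- data.frame(
      name = vapply(recs, function(r) as.character(r$name), character(1)),
      mass_shift = vapply(recs, function(r) {
        as.numeric(if (!is.null(r$monoisotopic_mass)) r$monoisotopic_mass else r$mass_shift)
      }, numeric(1)),
      residues = vapply(recs, function(r) paste(r$residues, collapse = ","), character(1)),
      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    if ("monoisotopic_mass" %in% names(tab) && !("mass_shift" %in% names(tab))) {
      tab$mass_shift <- tab$monoisotopic_mass
    }
    tab <- tab[, c("name", "mass_shift", "residues")]
  }
  .validate_ptm_table(tab)
}

# PTMs applicable to a given residue letter (the set T_i for position i).
.ptms_at <- function(ptm_table, aa) {
  keep <- vapply(ptm_table$residues, function(r) aa %in% .ptm_residues(r),
                 logical(1))
  ptm_table[keep, , drop = FALSE]
}

# ---- Proteoform ------------------------------------------------------------

#' Construct a proteoform
#'
#' A proteoform is a base sequence plus site-localized expected PTMs, at most
#' one PTM per residue position.
#'
#' @param sequence Amino-acid string.
#' @param mods Data frame with columns `position` (1-based) and `name`
#'   (PTM name found in `ptm_table`); may have zero rows.
#' @param ptm_table Expected-PTM table used to resolve names and validate
#'   residue specificity.
#' @return An object of class `proteoform` with elements `sequence` and
#'   `mods` (columns `position`, `name`, `mass_shift`, ordered by position).
#' @export
proteoform <- function(sequence, mods = NULL, ptm_table = default_ptm_table()) {
  chars <- .seq_chars(sequence)
  if (is.null(mods) || nrow(mods) == 0L) {
    mods <- data.frame(position = integer(0), name = character(0),
                       mass_shift = numeric(0), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("position", "name") %in% names(mods)))
    mods$position <- as.integer(mods$position)
    if (any(mods$position < 1L | mods$position > length(chars))) {
      stop("modification position outside 1..", length(chars), call. = FALSE)
    }
    if (anyDuplicated(mods$position)) {
      stop("at most one PTM per residue position", call. = FALSE)
    }
    idx <- match(mods$name, ptm_table$name)
    if (anyNA(idx)) {
      stop("unknown PTM name(s): ",
           paste(unique(mods$name[is.na(idx)]), collapse = ", "), call. = FALSE)
    }
    mods$mass_shift <- ptm_table$mass_shift[idx]
    for (j in seq_len(nrow(mods))) {
      res <- chars[mods$position[j]]
      allowed <- .ptm_residues(ptm_table$residues[idx[j]])
      if (!(res %in% allowed)) {
        stop("PTM '", mods$name[j], "' not allowed on residue ", res,
             " at position ", mods$position[j], call. = FALSE)
      }
    }
    mods <- mods[order(mods$position), c("position", "name", "mass_shift")]
    rownames(mods) <- NULL
  }
  structure(list(sequence = sequence, mods = mods), class = "proteoform")
}

#' Neutral molecular mass of a proteoform (Da)
#'
#' Residue-mass sum plus PTM mass shifts plus one water.
#' @param pf A `proteoform`.
#' @export
proteoform_mass <- function(pf) {
  stopifnot(inherits(pf, "proteoform"))
  sum(residue_mass(.seq_chars(pf$sequence))) + sum(pf$mods$mass_shift) + WATER_MONO
}

#' Prefix residue masses of a proteoform
#'
#' p_i plus the cumulative PTM shift over the first i positions, for
#' i = 0..n.
#' @param pf A `proteoform`.
#' @export
proteoform_prefix_masses <- function(pf) {
  p <- prefix_residue_masses(pf$sequence)
  shift <- numeric(length(p))
  if (nrow(pf$mods) > 0L) {
    per_pos <- numeric(length(p) - 1L)
    per_pos[pf$mods$position] <- pf$mods$mass_shift
    shift <- c(0, cumsum(per_pos))
  }
  p + shift
}

#' @export
format.proteoform <- function(x, ...) {
  chars <- .seq_chars(x$sequence)
  ann <- rep("", length(chars))
  if (nrow(x$mods) > 0L) {
    ann[x$mods$position] <- paste0("[", x$mods$name, "]")
  }
  paste0(paste0(chars, ann, collapse = ""))
}

#' @export
print.proteoform <- function(x, ...) {
  cat("proteoform:", format(x), "\n")
  cat("mass:", format(proteoform_mass(x), nsmall = 5), "Da,",
      nrow(x$mods), "modification(s)\n")
  invisible(x)
}

#' Parse a bracket-annotated proteoform string
#'
#' Inverse of `format.proteoform()`: e.g. `"GK[Acetylation]GKL"`.
#' @param x Character scalar.
#' @param ptm_table Expected-PTM table for name resolution.
#' @export
parse_proteoform <- function(x, ptm_table = default_ptm_table()) {
  stopifnot(is.character(x), length(x) == 1L)
  seq_chars <- character(0)
  mods <- list()
  rest <- x
  while (nchar(rest) > 0L) {
    ch <- substr(rest, 1L, 1L)
    if (ch == "[") {
      close <- regexpr("]", rest, fixed = TRUE)
      if (close < 0L) stop("unbalanced '[' in proteoform string", call. = FALSE)
      if (length(seq_chars) == 0L) stop("modification before first residue", call. = FALSE)
      mods[[length(mods) + 1L]] <- data.frame(
        position = length(seq_chars),
        name = substr(rest, 2L, close - 1L), stringsAsFactors = FALSE)
      rest <- substr(rest, close + 1L, nchar(rest))
    } else {
      seq_chars <- c(seq_chars, ch)
      rest <- substr(rest, 2L, nchar(rest))
    }
  }
  proteoform(paste(seq_chars, collapse = ""),
             if (length(mods)) do.call(rbind, mods) else NULL,
             ptm_table = ptm_table)
}

# ---- Proteoform and prefix-mass-set enumeration ----------------------------

#' Enumerate modified proteoforms of a protein
#'
#' Brute-force enumeration of all proteoforms carrying at least one expected
#' PTM (at most one PTM per position), optionally restricted to a precursor
#' mass window and a bound on the total PTM mass shift. Intended for short
#' sequences and as an oracle for the graph construction.
#'
#' @param sequence Amino-acid string.
#' @param ptm_table Expected-PTM table.
#' @param precursor_mass Optional neutral precursor mass (Da); when given,
#'   only proteoforms whose molecular mass falls within the ppm window (and
#'   optionally the +-1 Da isotopologue windows) are returned.
#' @param precursor_tol_ppm Precursor mass tolerance in ppm.
#' @param allow_pm1da Also accept +-1.00235 Da precursor offsets.
#' @param shift_bound Upper bound (Da) on the summed PTM shifts.
#' @param include_unmodified Include the zero-PTM proteoform.
#' @param max_forms Safety cap on the enumeration size.
#' @return List of `proteoform` objects.
#' @export
enumerate_proteoforms <- function(sequence, ptm_table = default_ptm_table(),
                                  precursor_mass = NULL, precursor_tol_ppm = 15,
                                  allow_pm1da = FALSE, shift_bound = Inf,
                                  include_unmodified = FALSE,
                                  max_forms = 1e6) {
  chars <- .seq_chars(sequence)
  options <- lapply(chars, function(a) .ptms_at(ptm_table, a))
  n_opt <- vapply(options, nrow, integer(1)) + 1L
  if (prod(n_opt) > max_forms) {
    stop("proteoform space too large for brute-force enumeration", call. = FALSE)
  }
  assignments <- list(data.frame(position = integer(0), name = character(0),
                                 stringsAsFactors = FALSE))
  for (i in seq_along(chars)) {
    opts <- options[[i]]
    if (nrow(opts) == 0L) next
    extended <- list()
    for (asg in assignments) {
      extended[[length(extended) + 1L]] <- asg
      if (nrow(asg) > 0L) shift <- sum(ptm_table$mass_shift[match(asg$name, ptm_table$name)])
      else shift <- 0
      for (j in seq_len(nrow(opts))) {
        if (shift + opts$mass_shift[j] <= shift_bound + 1e-9) {
          extended[[length(extended) + 1L]] <- rbind(
            asg, data.frame(position = i, name = opts$name[j],
                            stringsAsFactors = FALSE))
        }
      }
    }
    assignments <- extended
  }
  pfs <- lapply(assignments, function(asg) {
    proteoform(sequence, if (nrow(asg)) asg else NULL, ptm_table = ptm_table)
  })
  if (!include_unmodified) {
    pfs <- Filter(function(pf) nrow(pf$mods) > 0L, pfs)
  }
  if (!is.null(precursor_mass)) {
    centers <- precursor_mass
    if (allow_pm1da) centers <- c(centers, precursor_mass + c(-1, 1) * ISOTOPE_SPACING)
    keep <- vapply(pfs, function(pf) {
      m <- proteoform_mass(pf)
      any(abs(m - centers) <= precursor_tol_ppm * 1e-6 * centers)
    }, logical(1))
    pfs <- pfs[keep]
  }
  pfs
}

#' Per-position prefix-mass sets restricted by the precursor mass
#'
#' Computes the sets P_0..P_n of distinct i-th prefix residue masses over all
#' proteoforms with expected PTMs that are consistent with the precursor
#' mass: a cumulative shift is kept at position i only if it is reachable on
#' positions 1..i (forward) and completable on positions i+1..n to a total
#' shift matching the precursor window (backward). With
#' `precursor_mass = NULL` only the forward reachability under `shift_bound`
#' is applied (used for graph-size surveys).
#'
#' When several total shifts are compatible with the precursor windows, the
#' one with the smallest absolute precursor deviation is kept, so that layer
#' n carries a single mass.
#'
#' @inheritParams enumerate_proteoforms
#' @param precursor_tol_ppm Precursor tolerance (ppm) applied per window.
#' @return An object of class `prefix_mass_sets`: list with `sequence`, `p`
#'   (unmodified prefix masses), `shift_sets` and `sets` (length n+1 lists of
#'   sorted cumulative shifts / prefix masses), `target_shift` (total PTM
#'   shift implied by the precursor, or NA), `total_residue_mass`, and the
#'   parameters used. Empty `sets[[n + 1]]` means no proteoform explains the
#'   precursor.
#' @export
enumerate_prefix_mass_sets <- function(sequence, ptm_table = default_ptm_table(),
                                       precursor_mass = NULL,
                                       precursor_tol_ppm = 15,
                                       allow_pm1da = FALSE,
                                       shift_bound = Inf) {
  stopifnot(is.null(precursor_mass) || precursor_mass > 0, shift_bound >= 0)
  chars <- .seq_chars(sequence)
  n <- length(chars)
  p <- c(0, cumsum(residue_mass(chars)))
  shifts_at <- lapply(chars, function(a) .ptms_at(ptm_table, a)$mass_shift)

  # forward: cumulative shifts achievable on positions 1..i
  fwd <- vector("list", n + 1L)
  fwd[[1]] <- 0
  for (i in seq_len(n)) {
    cur <- fwd[[i]]
    nxt <- cur
    for (s in shifts_at[[i]]) {
      cand <- cur + s
      nxt <- c(nxt, cand[cand <= shift_bound + 1e-9])
    }
    nxt <- nxt[!duplicated(.mkey(nxt))]
    fwd[[i + 1L]] <- sort(nxt)
  }

  empty <- function() {
    structure(list(sequence = sequence, p = p,
                   shift_sets = rep(list(numeric(0)), n + 1L),
                   sets = rep(list(numeric(0)), n + 1L),
                   target_shift = NA_real_,
                   total_residue_mass = NA_real_,
                   precursor_mass = precursor_mass,
                   shift_bound = shift_bound),
              class = "prefix_mass_sets")
  }

  if (is.null(precursor_mass)) {
    sets <- lapply(seq_len(n + 1L), function(i) p[i] + fwd[[i]])
    return(structure(list(sequence = sequence, p = p, shift_sets = fwd,
                          sets = sets, target_shift = NA_real_,
                          total_residue_mass = NA_real_,
                          precursor_mass = NULL, shift_bound = shift_bound),
                     class = "prefix_mass_sets"))
  }

  # acceptable total shifts: achievable, bounded, and within a precursor window
  centers <- precursor_mass
  if (allow_pm1da) centers <- c(centers, precursor_mass + c(-1, 1) * ISOTOPE_SPACING)
  totals <- fwd[[n + 1L]]
  dev <- rep(Inf, length(totals))
  for (M in centers) {
    d <- abs(p[n + 1L] + totals + WATER_MONO - M)
    ok <- d <= precursor_tol_ppm * 1e-6 * M
    dev[ok] <- pmin(dev[ok], d[ok])
  }
  if (!any(is.finite(dev))) return(empty())
  target <- totals[which.min(dev)]

  # backward: shifts achievable on positions i+1..n
  bwd <- vector("list", n + 1L)
  bwd[[n + 1L]] <- 0
  for (i in rev(seq_len(n))) {
    cur <- bwd[[i + 1L]]
    nxt <- cur
    for (s in shifts_at[[i]]) {
      cand <- cur + s
      nxt <- c(nxt, cand[cand <= shift_bound + 1e-9])
    }
    nxt <- nxt[!duplicated(.mkey(nxt))]
    bwd[[i]] <- sort(nxt)
  }

  shift_sets <- vector("list", n + 1L)
  for (i in seq_len(n + 1L)) {
    d <- fwd[[i]]
    need <- .mkey(target - d)
    shift_sets[[i]] <- d[need %in% .mkey(bwd[[i]])]
  }
  sets <- lapply(seq_len(n + 1L), function(i) p[i] + shift_sets[[i]])
  structure(list(sequence = sequence, p = p, shift_sets = shift_sets,
                 sets = sets, target_shift = target,
                 total_residue_mass = p[n + 1L] + target,
                 precursor_mass = precursor_mass, shift_bound = shift_bound),
            class = "prefix_mass_sets")
}

#' @export
print.prefix_mass_sets <- function(x, ...) {
  n <- length(x$sets) - 1L
  cat("prefix-mass sets over", n, "positions;",
      sum(lengths(x$sets)), "masses total\n")
  if (!is.na(x$target_shift)) {
    cat("total PTM shift implied by precursor:",
        format(x$target_shift, nsmall = 5), "Da\n")
  }
  invisible(x)
}

#' Read a protein sequence from a FASTA file
#'
#' @param path FASTA file path.
#' @param id Optional record identifier; the first record is used otherwise.
#' @return Character scalar amino-acid sequence.
#' @export
read_protein_fasta <- function(path, id = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  if (!is.null(id)) {
    hit <- which(vapply(names(seqs), function(nm) {
      identical(nm, id) || startsWith(nm, paste0(id, " ")) ||
        strsplit(nm, "[ |]")[[1]][1] == id
    }, logical(1)))
    if (length(hit) == 0L) stop("FASTA record not found: ", id, call. = FALSE)
    seqs <- seqs[hit[1]]
  }
  as.character(seqs[[1]])
}
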