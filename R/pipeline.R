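# End-to-end identification: graph construction, ME2SF solving, path
# decoding, scoring and the single-vs-pair decision; batch driver.

#' Identification run parameters
#'
#' Bundles the tolerances and decision thresholds of the identification
#' pipeline with their standard defaults: 15 ppm fragment and precursor
#' tolerances, a 200 Da cap on the precursor-vs-unmodified mass difference,
#' a 600 Da bound on summed PTM shifts, total flow 100, a 10 matched-ion
#' reporting cutoff, and pair-acceptance gains of 10 ions or 20% intensity.
#'
#' @param frag_tol_ppm Fragment mass tolerance (ppm).
#' @param prec_tol_ppm Precursor mass tolerance (ppm).
#' @param max_prec_shift Maximum difference (Da) between the precursor mass
#'   and the unmodified protein mass.
#' @param shift_bound Bound (Da) on summed PTM shifts.
#' @param total_flow Total integer flow value (100 = percent).
#' @param min_ions Minimum matched fragment ions to report a result.
#' @param pair_ion_gain Extra matched ions required to flag a pair as better
#'   than its high-abundance single proteoform.
#' @param pair_intensity_gain Fractional extra explained intensity (0.20 =
#'   20%) required to flag a pair as better.
#' @param allow_pm1da Accept +-1.00235 Da precursor offsets.
#' @param scheme `"by"`, `"cz"`, or NULL to pick per spectrum activation.
#' @return List of class `homtm_params`.
#' @export
homtm_params <- function(frag_tol_ppm = 15, prec_tol_ppm = 15,
                         max_prec_shift = 200, shift_bound = 600,
                         total_flow = 100, min_ions = 10,
                         pair_ion_gain = 10, pair_intensity_gain = 0.20,
                         allow_pm1da = TRUE, scheme = NULL) {
  structure(list(frag_tol_ppm = frag_tol_ppm, prec_tol_ppm = prec_tol_ppm,
                 max_prec_shift = max_prec_shift, shift_bound = shift_bound,
                 total_flow = as.integer(total_flow), min_ions = min_ions,
                 pair_ion_gain = pair_ion_gain,
                 pair_intensity_gain = pair_intensity_gain,
                 allow_pm1da = allow_pm1da, scheme = scheme),
            class = "homtm_params")
}

#' Matched fragment ions and explained intensity of proteoforms
#'
#' Counts the experimental peaks that match at least one theoretical N- or
#' C-terminal fragment mass of at least one of the given proteoforms (each
#' peak counted once) and sums their intensities.
#'
#' @param proteoforms A `proteoform` or list of 1-2 proteoforms sharing the
#'   base sequence.
#' @param spectrum A `deconv_spectrum`.
#' @param scheme An `ion_scheme()`.
#' @param tol_ppm Fragment tolerance (ppm).
#' @return List with `matched_ions` (integer) and `explained_intensity`.
#' @export
score_proteoforms <- function(proteoforms, spectrum, scheme = ion_scheme("by"),
                              tol_ppm = 15) {
  if (inherits(proteoforms, "proteoform")) proteoforms <- list(proteoforms)
  stopifnot(length(proteoforms) >= 1L)
  seqs <- unique(vapply(proteoforms, function(pf) pf$sequence, character(1)))
  if (length(seqs) != 1L) stop("proteoforms must share the base sequence", call. = FALSE)
  theo <- unique(unlist(lapply(proteoforms, function(pf) {
    theoretical_fragments(pf, scheme)$mass
  })))
  pm <- spectrum$peaks$mass
  if (length(pm) == 0L || length(theo) == 0L) {
    return(list(matched_ions = 0L, explained_intensity = 0))
  }
  matched <- vapply(pm, function(x) any(ppm_match(x, theo, tol_ppm)), logical(1))
  list(matched_ions = sum(matched),
       explained_intensity = sum(spectrum$peaks$intensity[matched]))
}

.result_row <- function(spectrum, status, reason = NA_character_,
                        pf1 = NA_character_, ab1 = NA_integer_,
                        pf2 = NA_character_, ab2 = NA_integer_,
                        ions_pair = NA_integer_, ions_single = NA_integer_,
                        inten_pair = NA_real_, inten_single = NA_real_,
                        flow_error = NA_integer_, pair_better = NA) {
  data.frame(spectrum_id = spectrum$spectrum_id,
             status = status, reason = reason,
             proteoform1 = pf1, abundance1 = ab1,
             proteoform2 = pf2, abundance2 = ab2,
             matched_ions_pair = ions_pair,
             matched_ions_single = ions_single,
             explained_intensity_pair = inten_pair,
             explained_intensity_single = inten_single,
             flow_error = flow_error, pair_better = pair_better,
             stringsAsFactors = FALSE)
}

#' Identify the proteoform pair explaining one spectrum
#'
#' Builds the layered mass graph, solves the minimum-error 2-splittable
#' flow, decodes the two paths into proteoforms with their flow values as
#' relative abundances, scores them against the spectrum and decides
#' between a single-proteoform and a proteoform-pair report.
#'
#' @param sequence Protein amino-acid string.
#' @param spectrum A `deconv_spectrum`.
#' @param ptm_table Expected-PTM table.
#' @param params An `homtm_params()` bundle.
#' @return One-row data frame with the identification result. `status` is
#'   `"pair"`, `"single"`, `"below_cutoff"` (fewer matched ions than
#'   `min_ions`) or `"skipped"` (precursor out of range or unexplainable;
#'   `reason` says why). For pairs, `abundance1 + abundance2 = total_flow`
#'   and proteoform 1 is the higher-abundance one; `pair_better` records
#'   whether the pair beats its high-abundance single proteoform by the ion
#'   or intensity gain thresholds.
#' @export
identify_spectrum <- function(sequence, spectrum,
                              ptm_table = default_ptm_table(),
                              params = homtm_params()) {
  unmod_mass <- prefix_residue_masses(sequence)[nchar(sequence) + 1L] + WATER_MONO
  if (abs(spectrum$precursor_mass - unmod_mass) > params$max_prec_shift) {
    return(.result_row(spectrum, "skipped", "precursor shift beyond cap"))
  }
  scheme <- if (is.null(params$scheme)) scheme_for_activation(spectrum$activation)
            else ion_scheme(params$scheme)
  g <- tryCatch(
    build_graph(sequence, spectrum, ptm_table,
                tol_ppm = params$frag_tol_ppm,
                precursor_tol_ppm = params$prec_tol_ppm,
                allow_pm1da = params$allow_pm1da,
                shift_bound = params$shift_bound,
                total_flow = params$total_flow, scheme = scheme),
    error = function(e) e)
  if (inherits(g, "error")) {
    return(.result_row(spectrum, "skipped", conditionMessage(g)))
  }
  sol <- solve_me2sf(g)
  pf1 <- decode_path(g, sol$paths[[1]])
  pf2 <- decode_path(g, sol$paths[[2]])
  # order by abundance, higher first
  if (sol$flows[2] > sol$flows[1]) {
    tmp <- pf1; pf1 <- pf2; pf2 <- tmp
    sol$flows <- rev(sol$flows)
  }
  is_single <- sol$flows[2] == 0L || identical(format(pf1), format(pf2))
  if (is_single) sol$flows <- c(g$total_flow, 0L)

  single_score <- score_proteoforms(pf1, spectrum, scheme, params$frag_tol_ppm)
  pair_score <- if (is_single) single_score else {
    score_proteoforms(list(pf1, pf2), spectrum, scheme, params$frag_tol_ppm)
  }
  if (pair_score$matched_ions < params$min_ions) {
    return(.result_row(spectrum, "below_cutoff", "fewer matched ions than cutoff",
                       pf1 = format(pf1), ab1 = sol$flows[1],
                       pf2 = if (is_single) NA_character_ else format(pf2),
                       ab2 = if (is_single) NA_integer_ else sol$flows[2],
                       ions_pair = pair_score$matched_ions,
                       ions_single = single_score$matched_ions,
                       inten_pair = pair_score$explained_intensity,
                       inten_single = single_score$explained_intensity,
                       flow_error = sol$error, pair_better = FALSE))
  }
  pair_better <- !is_single &&
    ((pair_score$matched_ions - single_score$matched_ions >= params$pair_ion_gain) ||
     (pair_score$explained_intensity >=
        single_score$explained_intensity * (1 + params$pair_intensity_gain) &&
      pair_score$explained_intensity > single_score$explained_intensity))
  .result_row(spectrum, if (is_single) "single" else "pair",
              pf1 = format(pf1), ab1 = sol$flows[1],
              pf2 = if (is_single) NA_character_ else format(pf2),
              ab2 = if (is_single) NA_integer_ else sol$flows[2],
              ions_pair = pair_score$matched_ions,
              ions_single = single_score$matched_ions,
              inten_pair = pair_score$explained_intensity,
              inten_single = single_score$explained_intensity,
              flow_error = sol$error, pair_better = pair_better)
}

#' Batch identification over a spectrum file
#'
#' Runs `identify_spectrum()` over every spectrum in an msalign or TSV
#' file, writes a per-spectrum results TSV and a summary text file, and
#' logs progress to stderr. Spectrum-level failures are recorded as skipped
#' rows, never fatal.
#'
#' @param protein_fasta Path to the protein FASTA (first record used unless
#'   `fasta_id` is given).
#' @param spectra_file Path to an msalign or TSV spectrum file.
#' @param ptm_table Expected-PTM table (or path readable by
#'   `read_ptm_table()`).
#' @param params An `homtm_params()` bundle.
#' @param out_prefix Output path prefix; writes `<prefix>_results.tsv` and
#'   `<prefix>_summary.txt`. NULL writes nothing.
#' @param fasta_id Optional FASTA record id.
#' @return Invisibly, a list with `results` (data frame) and `summary`.
#' @export
run_batch <- function(protein_fasta, spectra_file,
                      ptm_table = default_ptm_table(),
                      params = homtm_params(), out_prefix = NULL,
                      fasta_id = NULL) {
  if (is.character(ptm_table)) ptm_table <- read_ptm_table(ptm_table)
  sequence <- read_protein_fasta(protein_fasta, fasta_id)
  spectra <- read_spectra(spectra_file)
  rows <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    t0 <- Sys.time()
    row <- tryCatch(identify_spectrum(sequence, sp, ptm_table, params),
                    error = function(e) {
                      .result_row(sp, "skipped", conditionMessage(e))
                    })
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("[homtm] %s: %s (%.2fs)", sp$spectrum_id, row$status, dt))
    rows[[i]] <- row
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    .result_row(list(spectrum_id = "none"), "skipped")[0, ]
  summary <- list(
    n_spectra = length(spectra),
    n_single = sum(results$status == "single"),
    n_pair = sum(results$status == "pair"),
    n_below_cutoff = sum(results$status == "below_cutoff"),
    n_skipped = sum(results$status == "skipped"),
    n_pair_ion_gain = sum(results$status == "pair" &
      results$matched_ions_pair - results$matched_ions_single >= params$pair_ion_gain),
    n_pair_intensity_gain = sum(results$status == "pair" &
      results$explained_intensity_pair >
        results$explained_intensity_single * (1 + params$pair_intensity_gain) -
        1e-12 & results$explained_intensity_pair > results$explained_intensity_single))
  if (!is.null(out_prefix)) {
    utils::write.table(results, paste0(out_prefix, "_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(
      "homtm batch summary",
      sprintf("spectra:              %d", summary$n_spectra),
      sprintf("single proteoforms:   %d", summary$n_single),
      sprintf("proteoform pairs:     %d", summary$n_pair),
      sprintf("below ion cutoff:     %d", summary$n_below_cutoff),
      sprintf("skipped:              %d", summary$n_skipped),
      sprintf("pairs with >=%g extra ions:        %d",
              params$pair_ion_gain, summary$n_pair_ion_gain),
      sprintf("pairs with >=%g%% extra intensity:  %d",
              100 * params$pair_intensity_gain, summary$n_pair_intensity_gain)),
      paste0(out_prefix, "_summary.txt"))
  }
  invisible(list(results = results, summary = summary))
}
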