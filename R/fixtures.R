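# Synthetic-data generators: deconvoluted HomMTM spectra with known ground
# truth, and random layered graphs for solver-vs-oracle sweeps.

#' Simulation configuration for a synthetic HomMTM spectrum
#'
#' Describes a mixture of one or two proteoforms of the same protein with
#' integer abundances summing to 100, the ion scheme, and the noise model:
#' per-fragment dropout, uniform ppm mass jitter, bounded multiplicative
#' intensity noise, and uniform decoy peaks.
#'
#' Per cleavage site one N-terminal and one C-terminal base intensity are
#' drawn log-uniformly from `intensity_range` (mimicking instrument dynamic
#' range); every proteoform's fragment at that site scales the site
#' intensity by the proteoform's abundance, so that per-layer intensity
#' shares reflect the mixture ratio. Decoy peaks draw their intensity from
#' the low quantile of the signal intensities.
#'
#' @param proteoforms List of 1 or 2 `proteoform` objects sharing the base
#'   sequence (and, for pairs, the molecular mass within tolerance).
#' @param abundances Positive integers summing to 100, one per proteoform.
#' @param scheme An `ion_scheme()`.
#' @param dropout Per-fragment dropout probability in [0, 1).
#' @param jitter_ppm Half-width of the uniform mass jitter (ppm).
#' @param intensity_noise Half-width of the uniform multiplicative
#'   intensity noise (e.g. 0.1 scales by U(0.9, 1.1)).
#' @param n_noise_peaks Number of decoy peaks.
#' @param intensity_range Range for the log-uniform site base intensities.
#' @param precursor_offset_da Constant added to the precursor mass (e.g.
#'   +-1.00235 to exercise the +-1 Da path).
#' @param seed Integer seed; the simulation is reproducible from it.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(proteoforms, abundances = c(70L, 30L),
                              scheme = ion_scheme("by"), dropout = 0,
                              jitter_ppm = 0, intensity_noise = 0,
                              n_noise_peaks = 0,
                              intensity_range = c(1e3, 1e6),
                              precursor_offset_da = 0, seed = 1L) {
  if (inherits(proteoforms, "proteoform")) proteoforms <- list(proteoforms)
  stopifnot(length(proteoforms) %in% c(1L, 2L),
            length(abundances) == length(proteoforms),
            all(abundances > 0), sum(abundances) == 100,
            dropout >= 0, dropout < 1)
  seqs <- unique(vapply(proteoforms, function(pf) pf$sequence, character(1)))
  if (length(seqs) != 1L) stop("proteoforms must share the base sequence", call. = FALSE)
  structure(list(proteoforms = proteoforms,
                 abundances = as.integer(abundances), scheme = scheme,
                 dropout = dropout, jitter_ppm = jitter_ppm,
                 intensity_noise = intensity_noise,
                 n_noise_peaks = n_noise_peaks,
                 intensity_range = intensity_range,
                 precursor_offset_da = precursor_offset_da,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a deconvoluted HomMTM spectrum with ground truth
#'
#' Emits the N- and C-terminal fragment neutral masses of each proteoform
#' under the configured ion scheme, pools intensities of coinciding
#' fragments across proteoforms in proportion to their abundances, applies
#' dropout, mass jitter, intensity noise and decoy peaks, and sets the
#' precursor to the shared molecular mass. Deterministic given the seed.
#'
#' @param config A `simulation_config()`.
#' @param spectrum_id Identifier for the emitted spectrum.
#' @param prec_tol_ppm Tolerance used to check the shared-mass (HomMTM)
#'   condition of a proteoform pair.
#' @return List with `spectrum` (a `deconv_spectrum`) and `truth`
#'   (proteoform strings, abundances, precursor mass, seed).
#' @export
simulate_spectrum <- function(config, spectrum_id = "sim", prec_tol_ppm = 15) {
  stopifnot(inherits(config, "sim_config"))
  masses <- vapply(config$proteoforms, proteoform_mass, numeric(1))
  if (length(masses) == 2L &&
      abs(masses[1] - masses[2]) > prec_tol_ppm * 1e-6 * masses[1]) {
    stop("proteoform masses differ beyond tolerance; not a HomMTM mixture",
         call. = FALSE)
  }
  set.seed(config$seed)
  n <- nchar(config$proteoforms[[1]]$sequence)
  # one base intensity per (site, terminal side)
  base <- matrix(exp(stats::runif(2L * (n - 1L),
                                  log(config$intensity_range[1]),
                                  log(config$intensity_range[2]))),
                 nrow = n - 1L, ncol = 2L)
  frag_mass <- numeric(0); frag_int <- numeric(0)
  key <- numeric(0)
  for (q in seq_along(config$proteoforms)) {
    fr <- theoretical_fragments(config$proteoforms[[q]], config$scheme)
    side <- ifelse(fr$type == config$scheme$labels[1], 1L, 2L)
    contrib <- config$abundances[q] / 100 * base[cbind(fr$site, side)]
    k <- .mkey(fr$mass)
    hit <- match(k, key)
    new <- is.na(hit)
    frag_mass <- c(frag_mass, fr$mass[new])
    frag_int <- c(frag_int, contrib[new])
    key <- c(key, k[new])
    if (any(!new)) {
      idx <- hit[!new]
      frag_int[idx] <- frag_int[idx] + contrib[!new]
    }
  }
  keep <- stats::runif(length(frag_mass)) >= config$dropout
  frag_mass <- frag_mass[keep]; frag_int <- frag_int[keep]
  if (config$intensity_noise > 0 && length(frag_int) > 0L) {
    frag_int <- frag_int * stats::runif(length(frag_int),
                                        1 - config$intensity_noise,
                                        1 + config$intensity_noise)
  }
  if (config$jitter_ppm > 0 && length(frag_mass) > 0L) {
    frag_mass <- frag_mass * (1 + stats::runif(length(frag_mass),
                                               -config$jitter_ppm,
                                               config$jitter_ppm) * 1e-6)
  }
  if (config$n_noise_peaks > 0L) {
    lo <- if (length(frag_int) > 0L) stats::quantile(frag_int, 0.1) else 1
    noise_mass <- stats::runif(config$n_noise_peaks, 50, masses[1])
    noise_int <- stats::runif(config$n_noise_peaks, 0.2 * lo, lo)
    frag_mass <- c(frag_mass, noise_mass)
    frag_int <- c(frag_int, noise_int)
  }
  spectrum <- deconv_spectrum(spectrum_id,
                              masses[1] + config$precursor_offset_da,
                              frag_mass, frag_int,
                              activation = if (config$scheme$name == "cz") "ETD" else "CID")
  truth <- list(proteoforms = vapply(config$proteoforms, format, character(1)),
                abundances = config$abundances,
                precursor_mass = masses[1] + config$precursor_offset_da,
                seed = config$seed)
  list(spectrum = spectrum, truth = truth)
}

#' Write a simulation ground-truth record as JSON
#'
#' @param truth The `truth` element returned by `simulate_spectrum()`.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Random layered graph for solver sweeps
#'
#' Connected layered directed graph with a single source and sink, random
#' interior layer widths, random edges (every vertex keeps at least one
#' incoming and one outgoing edge), and random nonnegative integer
#' capacities summing to the total flow in every layer.
#'
#' @param seed Integer seed.
#' @param h Number of layers (at least 2).
#' @param max_l Maximum interior layer width.
#' @param f Total integer flow value.
#' @param edge_prob Probability of each optional extra edge.
#' @return A pruned `layered_graph`.
#' @export
random_layered_graph <- function(seed, h = 5, max_l = 4, f = 20,
                                 edge_prob = 0.4) {
  stopifnot(h >= 2, max_l >= 1, f >= 1)
  set.seed(seed)
  widths <- c(1L, if (h > 2) sample.int(max_l, h - 2L, replace = TRUE), 1L)
  layer <- rep(0:(h - 1L), widths)
  offsets <- c(0L, cumsum(widths))
  caps <- integer(length(layer))
  for (k in seq_len(h)) {
    idx <- offsets[k] + seq_len(widths[k])
    caps[idx] <- if (widths[k] == 1L) f else {
      as.integer(stats::rmultinom(1, f, stats::runif(widths[k], 0.05, 1)))
    }
  }
  ef <- integer(0); et <- integer(0)
  for (k in seq_len(h - 1L)) {
    a <- offsets[k] + seq_len(widths[k])
    b <- offsets[k + 1L] + seq_len(widths[k + 1L])
    # guarantee coverage on both sides, then optional extras
    for (v in b) { ef <- c(ef, if (length(a) == 1L) a else sample(a, 1L)); et <- c(et, v) }
    for (u in a) {
      if (!(u %in% ef[et %in% b])) {
        ef <- c(ef, u); et <- c(et, if (length(b) == 1L) b else sample(b, 1L))
      }
    }
    extra <- expand.grid(from = a, to = b)
    pick <- stats::runif(nrow(extra)) < edge_prob
    ef <- c(ef, extra$from[pick]); et <- c(et, extra$to[pick])
  }
  edges <- unique(data.frame(from = ef, to = et))
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  g <- layered_graph(data.frame(layer = layer, capacity = caps), edges, f)
  prune_unreachable(g)
}
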