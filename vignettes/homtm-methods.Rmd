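---
title: "Identifying proteoform pairs in HomMTM spectra as a minimum-error 2-splittable flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying proteoform pairs in HomMTM spectra as a minimum-error 2-splittable flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homtm)
```

## The problem

Ultramodified proteins such as core histones carry combinations of
post-translational modifications (PTMs) whose positional isomers have
identical molecular masses. Liquid chromatography cannot separate such
proteoforms, so a top-down MS/MS scan may co-fragment two (or more)
proteoforms of the *same* protein at the same precursor mass — a
*homogeneous multiplexed tandem mass* (HomMTM) spectrum. Conventional
search tools assign one proteoform per spectrum and therefore
mis-localize or ignore the minor species. `homtm` identifies *two*
proteoforms and their relative abundances from a single deconvoluted
HomMTM spectrum, given the protein sequence and a table of expected PTMs.

## From spectrum to layered graph

The protein $P = a_1 a_2 \ldots a_n$ has prefix residue masses
$p_i = \sum_{k \le i} \mathrm{Mass}(a_k)$, $p_0 = 0$. A proteoform with
expected PTMs shifts $p_i$ by the summed mass shifts of the PTMs on its
first $i$ residues. Let $\mathcal{Q}_M$ be the proteoforms (at most one
PTM per residue, each allowed on that residue) whose molecular mass
matches the precursor $M$ within tolerance, and $\mathcal{P}_i$ the set
of distinct $i$-th prefix residue masses over $\mathcal{Q}_M$. The
package computes $\mathcal{P}_0 \ldots \mathcal{P}_n$ by a forward /
backward reachability sweep over cumulative PTM-shift values: a shift is
kept at position $i$ only if it is attainable on residues $1..i$ and
completable on residues $i{+}1..n$ to the total shift implied by the
precursor.

The layered graph is then built in five steps: one vertex per mass in
each $\mathcal{P}_i$ (layer $i$); an edge between consecutive-layer
masses whose difference is $\mathrm{Mass}(a_{i+1})$, possibly plus the
shift of a PTM allowed on $a_{i+1}$; the unique layer-0 and layer-$n$
vertices are source and sink; vertices on no source–sink path are
removed; and each vertex receives the intensity share of its mass within
its layer. The intensity of a prefix mass $m$ pools every peak matching
the N-terminal fragment mass of $m$ and every peak matching the
complementary C-terminal fragment mass of the proteoform's residue total
minus $m$ (b/y offsets $0$ and $+\mathrm{H_2O}$ for CID/HCD, c/z
offsets $+\mathrm{NH_3}$ and $+\mathrm{H_2O}-\mathrm{NH_3}+\mathrm{H}$
for ETD). Every source-to-sink path decodes to exactly one proteoform in
$\mathcal{Q}_M$, and a flow on a path is that proteoform's relative
abundance.

## The ME2SF problem and the solver

Given integer vertex capacities $c(v)$ and a total flow $f$ (100 here,
so flows read as percentages), a 2-splittable flow is a pair
$(P_1, f_1), (P_2, f_2)$ of source–sink paths with integer flows,
$f_1 + f_2 = f$. The flow on a vertex is the sum of the flows of the
paths containing it, and the objective is to minimize
$\sum_{v \in V} |f(v) - c(v)|$ — summed over *all* vertices, so a vertex
on neither path contributes its full capacity. The solver is exact and
has two stages:

* **Packing.** Only $|V| + 1$ flow splits need to be considered: one
  packing $(c(v), f - c(v))$ per vertex capacity below $f$, plus the
  special packing $(f, 0)$. An exchange argument (shift flow between the
  two paths by the smallest error among vertices private to one path)
  shows this candidate set always contains an optimal packing; the test
  suite verifies that claim exhaustively against all integer splits on
  hundreds of random graphs.
* **Routing.** For a fixed packing, a dynamic program over ordered
  same-layer vertex pairs $(v_1, v_2)$ computes the minimum partial-flow
  error $D(v_1, v_2)$, with per-layer cost
  $\varepsilon(v_1, v_2) = |c(v_1) - f_1 - f_2|$ when $v_1 = v_2$ and
  $|c(v_1) - f_1| + |c(v_2) - f_2|$ otherwise, **plus the capacities of
  the layer's remaining vertices**. The last term is required for
  $D(t,t)$ to equal the objective above: the pair cost alone ignores
  capacity stranded on off-path vertices, and the two quantities have
  different minimizers (a shared-vertex pair can look cheaper than a
  distinct pair while stranding more capacity). Because the term is
  constant per pair, the recurrence and its $O(l^4 h)$ cost are
  unchanged ($l$ = widest layer, $h$ = layers). Backtracking recovers
  the path pair; with candidate packings the full solver is
  $O(l^4 h |V|)$.

Ties are resolved deterministically: packings are tried in decreasing
order of $f_1$, and the DP takes the first minimum in column-major
order of predecessor pairs. A winning $(f, 0)$ packing is reported as a
single proteoform at 100% (a zero-flow path is arbitrary and leaves the
error unchanged, so the second path is canonicalized to the first).

## Reported result and decision rule

`identify_spectrum()` reports the decoded pair sorted by abundance. A
result is reported only when the peaks matching either proteoform's
theoretical fragments number at least `min_ions` (default 10). A pair is
flagged `pair_better` when it explains at least `pair_ion_gain` (10)
more peaks, or at least `pair_intensity_gain` (20%) more summed peak
intensity, than its higher-abundance member alone — peaks are counted at
the peak level, once each, so a pair can never score below its members.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `frag_tol_ppm` | 15 | fragment match window, ppm of the theoretical mass, symmetric |
| `prec_tol_ppm` | 15 | precursor match window per candidate precursor |
| `allow_pm1da` | TRUE | extra precursor windows at $M \pm 1.00235$ Da (deconvolution isotope error) |
| `max_prec_shift` | 200 Da | skip spectra whose precursor is further from the unmodified mass |
| `shift_bound` | 600 Da | cap on summed PTM shifts; controls graph size |
| `total_flow` | 100 | flow quantum; abundances are percentages |
| `min_ions` | 10 | matched-ion reporting cutoff |
| `pair_ion_gain`, `pair_intensity_gain` | 10, 0.20 | pair-vs-single acceptance margins |

The graph grows quickly with `shift_bound` when four or five PTM types
are expected (`graph_stats()` surveys this); 500–600 Da keeps histone-scale
graphs tractable, while 1000–1500 Da is fine for one or two PTM types.

## Numerical choices

* Residue masses are monoisotopic, derived from elemental compositions;
  the water constant is monoisotopic 18.010565 Da throughout, including
  the y-ion offset — an average-mass water would be incompatible with
  15 ppm windows.
* Cumulative PTM shifts are merged after rounding to $10^{-5}$ Da. With
  the default table this merges exactly the chains that coincide
  numerically (two methylations = one dimethylation, three = one
  trimethylation on the same prefix) while keeping acetylation
  (42.01056) and trimethylation (42.04695) apart.
* When several total PTM shifts are compatible with the precursor
  windows (typically via the $\pm 1$ Da option), the one with the
  smallest absolute precursor deviation is kept so that layer $n$ has a
  single sink mass.
* Layer intensity shares are quantized to integers by largest-remainder
  rounding (ties to the lower mass), so per-layer capacities sum to the
  total flow exactly and the solver works in integer arithmetic; a layer
  with no matched peaks gets equal shares.
* A peak may contribute intensity to every theoretical mass it matches;
  exclusive assignment would need an arbitrary tie-break and the shares
  are renormalized per layer anyway.

## The synthetic-spectrum generator

`simulate_spectrum()` emulates *deconvoluted* HomMTM spectra: all N- and
C-terminal fragment neutral masses of each proteoform, with one
log-uniform base intensity per cleavage site and terminal side (range
$10^3$–$10^6$, mimicking instrument dynamic range) scaled by each
proteoform's abundance, so that per-layer intensity shares reflect the
mixture ratio; coinciding fragment masses pool their contributions.
Configurable corruption: per-fragment dropout, uniform ppm mass jitter,
bounded multiplicative intensity noise, uniform decoy peaks, and a
constant precursor offset to exercise the $\pm 1$ Da path. It does not
simulate charge states, isotopic envelopes, deconvolution artifacts
other than the precursor offset, internal/neutral-loss ions, or
correlated noise — so passing closed-loop tests demonstrates
correctness of the graph/flow machinery on ideal-to-moderately-corrupted
inputs, not robustness to real instrument data.

`random_layered_graph()` generates connected layered graphs with random
widths, edges and per-layer capacity partitions for solver-vs-oracle
sweeps; `brute_force_me2sf()` is the independent oracle, enumerating all
path pairs and all integer flow splits.

## Problem sizes exercised by the test suite

The solver-exactness and packing-sufficiency sweeps use 500 random
graphs with up to 5 layers, 4 vertices per layer and flows up to 20 —
small enough for the brute-force oracle yet wide enough to produce
shared, crossing and disjoint optimal path pairs. The abundance-recovery
sweep uses 100 seeded acetyl-isomer mixtures of the 9-residue worked
example at 20% fragment dropout. The graph-size survey runs the 102-residue
mature human histone H4 sequence (shipped in `inst/extdata/`) at shift
bounds of 50 and 600 Da.

## Known limitations

* **Dropout biases abundances upward.** If both fragments supporting the
  minor proteoform at a layer are missing, renormalization hands that
  layer's whole share to the major mass (100:0); if only one side
  survives, the wide dynamic range of site intensities can skew the
  share arbitrarily. With few informative layers (proteoforms differing
  at one site on a short protein) a single corrupted layer can flip the
  best packing, and exact ties resolve toward the larger $f_1$. The test
  suite measures this directly: at 20% dropout on the 9-mer example,
  about two-thirds of replicates recover the major abundance within
  ±10 flow units.
* Only residue-specific PTMs from the expected table are modeled: no
  terminal modifications, sequence variants, truncations, or unexpected
  (blind) mass shifts.
* One spectrum is interpreted at a time with one ion scheme; paired
  CID/ETD evidence for the same precursor is not combined.
* The exact solver covers $k = 2$; the brute-force oracle handles small
  $k > 2$ for experimentation only, since candidate-packing enumeration
  does not generalize.
* Graph-size counts depend on the merging convention for numerically
  identical modification chains; `graph_stats()` counts merged distinct
  masses, forward-reachable under the shift bound, without a precursor
  constraint. Surveys using other conventions will differ.

## A worked example

```{r example, eval = FALSE}
pt <- default_ptm_table()
pfs <- list(parse_proteoform("GK[Acetylation]GK[Acetylation]LKAKE", pt),
            parse_proteoform("GKGK[Acetylation]LK[Acetylation]AKE", pt))
sim <- simulate_spectrum(simulation_config(pfs, c(70L, 30L), seed = 1L))
identify_spectrum("GKGKLKAKE", sim$spectrum, pt, homtm_params())
```

The two positional isomers (identical masses, acetylation on K2/K4
versus K4/K6) are recovered with abundances 70 and 30 and flow error 0;
the same run backs the package's acceptance script.
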