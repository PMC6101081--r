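# Shared fixtures: the acetylated 9-mer worked example and small builders.

EXAMPLE_SEQ <- "GKGKLKAKE"

example_pair <- function(pt = default_ptm_table()) {
  list(parse_proteoform("GK[Acetylation]GK[Acetylation]LKAKE", pt),
       parse_proteoform("GKGK[Acetylation]LK[Acetylation]AKE", pt))
}

example_sim <- function(seed = 1L, abundances = c(70L, 30L), ...) {
  cfg <- simulation_config(example_pair(), abundances, seed = seed, ...)
  simulate_spectrum(cfg)
}

# A hand-built layered graph: two vertex-disjoint interior paths with
# capacities 70/30 in every interior layer, single source/sink with
# capacity 100.
two_lane_graph <- function(n_interior = 3, caps = c(70L, 30L), flow = 100L) {
  layer <- c(0L, rep(seq_len(n_interior), each = 2L), n_interior + 1L)
  capacity <- c(flow, rep(caps, n_interior), flow)
  ids_hi <- 2L * seq_len(n_interior)       # high-capacity lane vertex ids
  ids_lo <- ids_hi + 1L
  from <- c(1L, 1L,
            if (n_interior > 1) c(ids_hi[-n_interior], ids_lo[-n_interior]),
            ids_hi[n_interior], ids_lo[n_interior])
  to <- c(ids_hi[1L], ids_lo[1L],
          if (n_interior > 1) c(ids_hi[-1L], ids_lo[-1L]),
          rep(2L * n_interior + 2L, 2L))
  g <- layered_graph(data.frame(layer = layer, capacity = capacity),
                     data.frame(from = from, to = to), flow)
  prune_unreachable(g)
}

# Random peptide with guaranteed modifiable residues, for enumeration sweeps.
random_modifiable_seq <- function(len) {
  paste(sample(c("K", "R", "S", "G", "A", "L"), len, replace = TRUE),
        collapse = "")
}
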