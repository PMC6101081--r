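test_that("the worked-example graph has n+1 layers and conserves layer capacity", {
  sim <- example_sim(seed = 2L)
  g <- build_graph(EXAMPLE_SEQ, sim$spectrum)
  expect_s3_class(g, "mass_graph")
  expect_identical(g$n_layers, 10L)
  expect_identical(sum(g$vertices$layer == 0L), 1L)
  expect_identical(sum(g$vertices$layer == 9L), 1L)
  caps_by_layer <- tapply(g$vertices$capacity, g$vertices$layer, sum)
  expect_true(all(caps_by_layer == 100L))
})

test_that("paths decode bijectively onto the precursor-consistent proteoforms", {
  sim <- example_sim(seed = 2L)
  g <- build_graph(EXAMPLE_SEQ, sim$spectrum)
  paths <- enumerate_paths(g)
  pt <- default_ptm_table()[default_ptm_table()$name == "Acetylation", ]
  qm <- enumerate_proteoforms(EXAMPLE_SEQ, pt,
                              precursor_mass = sim$spectrum$precursor_mass)
  # two acetylations on 4 lysines: choose(4, 2) proteoforms
  expect_length(qm, choose(4, 2))
  decoded <- vapply(paths, function(p) format(decode_path(g, p)), character(1))
  expect_identical(anyDuplicated(decoded), 0L)
  expect_setequal(decoded, vapply(qm, format, character(1)))
  # decoding then re-encoding reproduces the vertex masses along the path
  for (k in seq_along(paths)) {
    pf <- decode_path(g, paths[[k]])
    expect_equal(g$vertices$mass[paths[[k]]], proteoform_prefix_masses(pf),
                 tolerance = 1e-9)
    win <- 15e-6 * sim$spectrum$precursor_mass
    expect_lt(abs(proteoform_mass(pf) - sim$spectrum$precursor_mass), win)
  }
})

test_that("a zero-shift precursor yields a single forced path", {
  pf <- proteoform(EXAMPLE_SEQ)
  sim <- simulate_spectrum(simulation_config(list(pf), 100L, seed = 4L))
  g <- build_graph(EXAMPLE_SEQ, sim$spectrum)
  expect_identical(nrow(g$vertices), 10L)
  expect_length(enumerate_paths(g), 1L)
  expect_true(all(g$vertices$capacity == 100L))
})

test_that("an unexplainable precursor is rejected", {
  sp <- deconv_spectrum("odd", proteoform_mass(proteoform(EXAMPLE_SEQ)) + 5.5,
                        c(200, 300), c(1, 1))
  expect_error(build_graph(EXAMPLE_SEQ, sp), "unexplainable")
})

test_that("capacity quantization is proportional, exact and deterministic", {
  expect_identical(quantize_capacities(c(70, 30), 100), c(70L, 30L))
  expect_identical(quantize_capacities(c(1, 1, 1), 100), c(34L, 33L, 33L))
  expect_identical(quantize_capacities(5, 100), 100L)
  expect_identical(quantize_capacities(c(0, 0, 0), 10), c(4L, 3L, 3L))
  set.seed(8)
  for (i in 1:50) {
    raw <- runif(sample(1:6, 1), 0, 100) * rbinom(1, 1, 0.9)
    f <- sample(1:200, 1)
    q <- quantize_capacities(raw, f)
    expect_identical(sum(q), f)
    expect_true(all(q >= 0L))
    if (sum(raw) > 0) {
      expect_true(all(abs(q - raw / sum(raw) * f) < 1))
    }
  }
})

test_that("pruning keeps exactly the vertices on source-sink paths", {
  skip_if_not_installed("igraph")
  # dangling interior vertex (id 3) has no outgoing edge
  g <- layered_graph(
    data.frame(layer = c(0L, 1L, 1L, 2L), capacity = c(10L, 10L, 0L, 10L)),
    data.frame(from = c(1L, 1L, 2L), to = c(2L, 3L, 4L)), 10L)
  pg <- prune_unreachable(g)
  expect_identical(nrow(pg$vertices), 3L)
  expect_identical(prune_unreachable(pg)$vertices, pg$vertices)

  for (seed in 1:25) {
    g <- random_layered_graph(seed, h = sample(3:6, 1), max_l = 4, f = 10)
    # drop a random edge subset to create unreachable vertices, keep s-t link
    keep_e <- runif(nrow(g$edges)) < 0.7
    sub <- g
    sub$edges <- g$edges[keep_e, , drop = FALSE]
    ig <- igraph::graph_from_data_frame(sub$edges[, c("from", "to")],
                                        vertices = data.frame(seq_len(nrow(g$vertices))))
    s <- 1; t <- nrow(g$vertices)
    fwd <- as.integer(igraph::subcomponent(ig, s, mode = "out"))
    bwd <- as.integer(igraph::subcomponent(ig, t, mode = "in"))
    expected <- sort(intersect(fwd, bwd))
    if (!(t %in% fwd)) {
      expect_error(prune_unreachable(sub), "disconnected")
    } else {
      pg <- prune_unreachable(sub)
      expect_identical(nrow(pg$vertices), length(expected))
      expect_identical(prune_unreachable(pg)$vertices, pg$vertices)
    }
  }
})

test_that("graph size grows monotonically with the PTM-shift bound", {
  seqs <- c(EXAMPLE_SEQ, "SGRGKGGKGLGKGGAKRHRK")
  for (s in seqs) {
    sizes <- vapply(c(0, 15, 30, 45, 90, 200), function(b) {
      st <- graph_stats(s, shift_bound = b)
      c(st$n_vertices, st$n_edges)
    }, numeric(2))
    expect_true(all(diff(sizes[1, ]) >= 0))
    expect_true(all(diff(sizes[2, ]) >= 0))
  }
})

test_that("graph exports list every edge", {
  sim <- example_sim(seed = 2L)
  g <- build_graph(EXAMPLE_SEQ, sim$spectrum)
  f <- tempfile(fileext = ".tsv")
  write_graph_tsv(g, f)
  expect_identical(length(readLines(f)), nrow(g$edges) + 1L)
  dot <- graph_dot(g)
  expect_match(dot, "digraph")
  expect_identical(lengths(regmatches(dot, gregexpr("->", dot))),
                   nrow(g$edges))
})
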