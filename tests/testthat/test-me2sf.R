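test_that("candidate packings follow the two generation rules", {
  g <- two_lane_graph(n_interior = 2, caps = c(70L, 30L))
  s <- candidate_packings(g, 100)
  expect_identical(s[, "f1"], c(100L, 70L, 30L))
  expect_identical(s[, "f2"], c(0L, 30L, 70L))

  # all capacities equal to the flow: only the special packing remains
  g2 <- layered_graph(data.frame(layer = 0:2, capacity = c(10L, 10L, 10L)),
                      data.frame(from = 1:2, to = 2:3), 10L)
  expect_identical(candidate_packings(g2), cbind(f1 = 10L, f2 = 0L))

  for (seed in 1:20) {
    g3 <- random_layered_graph(seed, h = 4, max_l = 4, f = 17)
    expect_lte(nrow(candidate_packings(g3)), nrow(g3$vertices) + 1L)
  }
})

test_that("the ordered-pair error matches its closed form", {
  g <- layered_graph(
    data.frame(layer = c(0L, 1L, 1L, 1L, 2L),
               capacity = c(100L, 70L, 30L, 40L, 100L)),
    data.frame(from = c(1L, 1L, 1L, 2L, 3L, 4L), to = c(2L, 3L, 4L, 5L, 5L, 5L)),
    100L)
  expect_identical(pair_error(g, 1L, 1L, 70L, 30L), 0L)   # |100 - 100|
  expect_identical(pair_error(g, 2L, 3L, 70L, 30L), 0L)
  expect_identical(pair_error(g, 2L, 3L, 30L, 70L), 80L)  # 40 + 40
  expect_identical(pair_error(g, 4L, 4L, 70L, 30L), 60L)  # |40 - 100|
  expect_error(pair_error(g, 1L, 2L, 70L, 30L), "same layer")
})

test_that("routing a single-path graph is forced and reports the full error", {
  caps <- c(10L, 7L, 3L, 10L)
  g <- layered_graph(data.frame(layer = 0:3, capacity = caps),
                     data.frame(from = 1:3, to = 2:4), 10L)
  for (f1 in c(10L, 7L, 4L)) {
    sol <- route(g, f1, 10L - f1)
    expect_identical(sol$paths[[1]], 1:4)
    expect_identical(sol$paths[[2]], 1:4)
    expect_identical(sol$error, as.integer(sum(abs(10L - caps))))
  }
})

test_that("the two-lane fixture routes disjoint paths with zero error", {
  g <- two_lane_graph(n_interior = 3, caps = c(70L, 30L))
  sol <- route(g, 70L, 30L)
  expect_identical(sol$error, 0L)
  expect_length(intersect(setdiff(sol$paths[[1]], c(1L, nrow(g$vertices))),
                          setdiff(sol$paths[[2]], c(1L, nrow(g$vertices)))), 0L)
  full <- solve_me2sf(g)
  expect_identical(full$error, 0L)
  expect_setequal(full$flows, c(70L, 30L))
})

test_that("the special packing canonicalizes to a single path", {
  caps <- c(10L, 10L, 10L)
  g <- layered_graph(data.frame(layer = 0:2, capacity = caps),
                     data.frame(from = 1:2, to = 2:3), 10L)
  sol <- solve_me2sf(g)
  expect_identical(sol$flows, c(10L, 0L))
  expect_identical(sol$paths[[1]], sol$paths[[2]])
  expect_identical(sol$error, 0L)
})

test_that("solver equals the brute-force oracle on random layered graphs", {
  for (seed in 1:80) {
    h <- sample(3:5, 1)
    f <- sample(5:20, 1)
    g <- random_layered_graph(seed, h = h, max_l = 4, f = f)
    sol <- solve_me2sf(g)
    bf <- brute_force_me2sf(g)
    expect_identical(sol$error, bf$error)
    # stored error always equals the from-scratch recomputation
    expect_identical(flow_solution_error(g, sol), as.numeric(sol$error))
    expect_identical(flow_solution_error(g, bf), as.numeric(bf$error))
    # 2-splittable can never be worse than the best single path
    expect_lte(sol$error, brute_force_me2sf(g, k = 1)$error)
    # swapping the packing roles leaves the optimum unchanged
    swapped <- route(g, sol$flows[2], sol$flows[1])
    expect_identical(swapped$error, sol$error)
  }
})

test_that("optimal distinct-path solutions balance over/under-flow counts", {
  # at a non-perfect minimum-error vertex of the symmetric difference, the
  # over/under-flow vertex counts must balance across the two private sets
  checked <- 0L
  for (seed in 1:400) {
    g <- random_layered_graph(seed, h = sample(3:5, 1), max_l = 4,
                              f = sample(5:20, 1))
    sol <- solve_me2sf(g)
    p1 <- sol$paths[[1]]; p2 <- sol$paths[[2]]
    f1 <- sol$flows[1]; f2 <- sol$flows[2]
    if (identical(p1, p2) || f1 == 0L || f2 == 0L) next
    v1 <- setdiff(p1, p2); v2 <- setdiff(p2, p1)
    if (length(c(v1, v2)) == 0L) next
    fv <- numeric(nrow(g$vertices))
    fv[p1] <- fv[p1] + f1; fv[p2] <- fv[p2] + f2
    errs <- abs(fv - g$vertices$capacity)
    if (min(errs[c(v1, v2)]) == 0) next  # perfect-flow witness: lemma silent
    n1p <- sum(fv[v1] > g$vertices$capacity[v1])
    n1m <- sum(fv[v1] < g$vertices$capacity[v1])
    n2p <- sum(fv[v2] > g$vertices$capacity[v2])
    n2m <- sum(fv[v2] < g$vertices$capacity[v2])
    expect_identical(n1p + n2m, n1m + n2p)
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("brute force handles degenerate flows and small k", {
  g <- two_lane_graph(n_interior = 2, caps = c(6L, 4L), flow = 10L)
  # zero flow: every vertex error equals its capacity
  bf0 <- brute_force_me2sf(g, flow = 0)
  expect_identical(bf0$error, as.integer(sum(g$vertices$capacity)))
  # k = 1 on the two-lane graph: must absorb the minor lane error twice
  bf1 <- brute_force_me2sf(g, k = 1)
  expect_identical(bf1$error, 2L * 2L * 4L)
  # k = 3 can never be worse than k = 2
  bf3 <- brute_force_me2sf(g, k = 3, max_ops = 5e6)
  expect_lte(bf3$error, brute_force_me2sf(g)$error)
  expect_error(brute_force_me2sf(g, k = 2, max_ops = 10), "too large")
})
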