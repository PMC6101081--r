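# Exact minimum-error 2-splittable flow solver on layered directed graphs:
# candidate packing enumeration, dynamic-programming routing over ordered
# vertex pairs, backtracking, and brute-force oracles.
#
# The flow error follows the problem definition: the sum over ALL vertices
# of |f(v) - c(v)|, where a vertex on neither path has f(v) = 0 and so
# contributes its full capacity. The routing DP therefore charges, in each
# layer, the ordered-pair error plus the capacities of the layer's off-pair
# vertices; this keeps the recurrence intact while making D(t,t) equal the
# total error of the reported flow.

#' Candidate flow-value packings
#'
#' The candidate set S: one packing `(c(v), f - c(v))` for every vertex
#' capacity `c(v) < f`, plus the special packing `(f, 0)`; duplicates
#' removed, ordered by decreasing first component. At most `|V| + 1`
#' packings.
#'
#' @param graph A `layered_graph`.
#' @param flow Total integer flow value (defaults to the graph's).
#' @return Integer matrix with columns `f1`, `f2`.
#' @export
candidate_packings <- function(graph, flow = graph$total_flow) {
  stopifnot(flow >= 1)
  caps <- graph$vertices$capacity
  f1 <- sort(unique(c(flow, caps[caps < flow])), decreasing = TRUE)
  cbind(f1 = as.integer(f1), f2 = as.integer(flow - f1))
}

#' Error of an ordered vertex pair under a packing
#'
#' `|c(v1) - f1 - f2|` when the two vertices coincide, otherwise
#' `|c(v1) - f1| + |c(v2) - f2|`.
#'
#' @param graph A `layered_graph`.
#' @param v1,v2 Vertex ids in the same layer.
#' @param f1,f2 Nonnegative integer flow values.
#' @return Nonnegative integer.
#' @export
pair_error <- function(graph, v1, v2, f1, f2) {
  lay <- graph$vertices$layer
  if (lay[v1] != lay[v2]) stop("v1 and v2 must lie in the same layer", call. = FALSE)
  c1 <- graph$vertices$capacity[v1]
  c2 <- graph$vertices$capacity[v2]
  as.integer(if (v1 == v2) abs(c1 - f1 - f2) else abs(c1 - f1) + abs(c2 - f2))
}

# Total Definition-1 error of a path pair: sum over all vertices of
# |f(v) - c(v)| with f(v) = f1*[v in P1] + f2*[v in P2].
.flow_error <- function(graph, path1, path2, f1, f2) {
  fv <- numeric(nrow(graph$vertices))
  fv[path1] <- fv[path1] + f1
  fv[path2] <- fv[path2] + f2
  sum(abs(fv - graph$vertices$capacity))
}

#' Recompute the error of a flow solution from scratch
#'
#' @param graph A `layered_graph`.
#' @param solution A `flow_solution`.
#' @return The Definition-style error (sum over all vertices).
#' @export
flow_solution_error <- function(graph, solution) {
  .flow_error(graph, solution$paths[[1]], solution$paths[[2]],
              solution$flows[1], solution$flows[2])
}

.flow_solution <- function(paths, flows, error) {
  structure(list(paths = paths, flows = as.integer(flows),
                 error = as.integer(error)), class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("2-splittable flow: flows", paste(x$flows, collapse = "/"),
      "error", x$error, "\n")
  for (i in seq_along(x$paths)) {
    cat("  path", i, ": ", paste(x$paths[[i]], collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}

#' Minimum-error routing of one packing
#'
#' Dynamic program over ordered same-layer vertex pairs (v1, v2): D(v1, v2)
#' is the minimum error of partial 2-splittable flows whose paths end at v1
#' and v2, built up layer by layer from D(s, s) and recovered at the sink by
#' backtracking. Deterministic: ties pick the smallest predecessor pair in
#' column-major order of (v1', v2').
#'
#' @param graph A pruned `layered_graph` (every vertex on an s-t path).
#' @param f1,f2 Packing with `f1 + f2` equal to the intended total flow.
#' @return A `flow_solution` with `error = D(t, t)`.
#' @export
route <- function(graph, f1, f2) {
  v <- graph$vertices
  nv <- nrow(v)
  layer_ids <- split(seq_len(nv), v$layer)
  nlay <- length(layer_ids)
  if (nlay < 1L || length(layer_ids[[1]]) != 1L) {
    stop("graph must have a single source", call. = FALSE)
  }
  in_adj <- .in_adj(graph)
  if (nlay > 1L && any(vapply(unlist(layer_ids[-1]),
                              function(i) length(in_adj[[i]]) == 0L, logical(1)))) {
    stop("graph has a vertex with no predecessor; prune it first", call. = FALSE)
  }

  eps_mat <- function(ids) {
    caps <- v$capacity[ids]
    ctot <- sum(caps)
    l <- length(ids)
    E <- outer(abs(caps - f1), abs(caps - f2), `+`) + (ctot - outer(caps, caps, `+`))
    diag(E) <- abs(caps - f1 - f2) + (ctot - caps)
    E
  }

  D <- eps_mat(layer_ids[[1]])
  back <- vector("list", nlay)   # back[[k]][a, b, 1:2] = predecessor indices
  for (k in seq_len(nlay - 1L) + 1L) {
    ids <- layer_ids[[k]]
    prev_ids <- layer_ids[[k - 1L]]
    l <- length(ids)
    E <- eps_mat(ids)
    Dn <- matrix(Inf, l, l)
    bk <- array(NA_integer_, c(l, l, 2L))
    preds <- lapply(ids, function(i) match(in_adj[[i]], prev_ids))
    for (a in seq_len(l)) {
      pa <- preds[[a]]
      for (b in seq_len(l)) {
        pb <- preds[[b]]
        sub <- D[pa, pb, drop = FALSE]
        w <- which.min(sub)            # column-major; first minimum wins
        m <- sub[w]
        ai <- (w - 1L) %% length(pa) + 1L
        bi <- (w - 1L) %/% length(pa) + 1L
        Dn[a, b] <- m + E[a, b]
        bk[a, b, ] <- c(prev_ids[pa[ai]], prev_ids[pb[bi]])
      }
    }
    D <- Dn
    back[[k]] <- bk
  }
  # sink layer is a single vertex; D is 1x1
  err <- D[1L, 1L]
  p1 <- integer(nlay); p2 <- integer(nlay)
  a <- layer_ids[[nlay]][1L]; b <- a
  p1[nlay] <- a; p2[nlay] <- b
  for (k in rev(seq_len(nlay - 1L) + 1L)) {
    ids <- layer_ids[[k]]
    bk <- back[[k]]
    pred <- bk[match(a, ids), match(b, ids), ]
    a <- pred[1L]; b <- pred[2L]
    p1[k - 1L] <- a; p2[k - 1L] <- b
  }
  .flow_solution(list(p1, p2), c(f1, f2), err)
}

#' Solve the minimum-error 2-splittable flow problem exactly
#'
#' Routes every candidate packing and returns the best flow; by the
#' candidate-set sufficiency property this is the global optimum over all
#' integer packings. When the winning packing is `(f, 0)` the second path is
#' canonicalized to equal the first (a zero-flow path leaves the error
#' unchanged).
#'
#' @param graph A pruned `layered_graph`.
#' @param flow Total integer flow value (defaults to the graph's).
#' @return A `flow_solution` with elements `paths` (two vertex-id vectors),
#'   `flows` and `error`.
#' @export
solve_me2sf <- function(graph, flow = graph$total_flow) {
  packs <- candidate_packings(graph, flow)
  best <- NULL
  for (i in seq_len(nrow(packs))) {
    sol <- route(graph, packs[i, 1L], packs[i, 2L])
    if (is.null(best) || sol$error < best$error) best <- sol
  }
  if (best$flows[2L] == 0L) best$paths[[2L]] <- best$paths[[1L]]
  best
}

#' Brute-force minimum-error k-splittable flow oracle
#'
#' Exhaustive enumeration over path multisets and integer flow
#' compositions; exact but exponential, guarded by an operation cap.
#' Intended as the independent test oracle for the dynamic-programming
#' solver (k = 2) and for small k > 2 experiments.
#'
#' @param graph A `layered_graph`.
#' @param flow Total integer flow value.
#' @param k Number of paths (1, 2, or a small integer).
#' @param max_ops Cap on `n_paths^k * (flow + 1)^(k - 1)`.
#' @return A `flow_solution` (with `k` paths and flows for general k).
#' @export
brute_force_me2sf <- function(graph, flow = graph$total_flow, k = 2,
                              max_ops = 2e7) {
  paths <- enumerate_paths(graph)
  np <- length(paths)
  if (np == 0L) stop("no source-to-sink path", call. = FALSE)
  if (np^k * (flow + 1)^(k - 1) > max_ops) {
    stop("instance too large for brute force; use solve_me2sf", call. = FALSE)
  }
  caps <- graph$vertices$capacity
  nv <- length(caps)
  X <- matrix(0, np, nv)
  for (i in seq_len(np)) X[i, paths[[i]]] <- 1

  if (k == 1L) {
    errs <- rowSums(abs(X * flow - matrix(caps, np, nv, byrow = TRUE)))
    i <- which.min(errs)
    return(.flow_solution(list(paths[[i]]), flow, errs[i]))
  }
  if (k == 2L) {
    best_err <- Inf; best <- NULL
    capm <- matrix(caps, np, nv, byrow = TRUE)
    for (f1 in 0:flow) {
      f2 <- flow - f1
      for (a in seq_len(np)) {
        fv_base <- matrix(X[a, ] * f1, np, nv, byrow = TRUE)
        errs <- rowSums(abs(fv_base + X * f2 - capm))
        b <- which.min(errs)
        if (errs[b] < best_err) {
          best_err <- errs[b]
          best <- list(paths = list(paths[[a]], paths[[b]]), flows = c(f1, f2))
        }
      }
    }
    return(.flow_solution(best$paths, best$flows, best_err))
  }
  # general small k: path index tuples x compositions of flow into k parts
  best_err <- Inf; best <- NULL
  tuples <- as.matrix(expand.grid(rep(list(seq_len(np)), k)))
  comps <- .compositions(flow, k)
  for (ti in seq_len(nrow(tuples))) {
    incid <- X[tuples[ti, ], , drop = FALSE]
    for (ci in seq_len(nrow(comps))) {
      fv <- as.vector(comps[ci, ] %*% incid)
      err <- sum(abs(fv - caps))
      if (err < best_err) {
        best_err <- err
        best <- list(paths = lapply(tuples[ti, ], function(i) paths[[i]]),
                     flows = comps[ci, ])
      }
    }
  }
  .flow_solution(best$paths, best$flows, best_err)
}

# all nonnegative integer k-tuples summing to f
.compositions <- function(f, k) {
  if (k == 1L) return(matrix(f, 1L, 1L))
  out <- list()
  for (first in 0:f) {
    rest <- .compositions(f - first, k - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}
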