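# Layered vertex-capacitated graph built from the prefix-mass sets and a
# deconvoluted spectrum. Layers are indexed 0..n; layer i holds i-residue
# prefix masses; layer 0 is the source, layer n the sink.

#' Construct a layered graph
#'
#' Low-level constructor shared by the spectral graph builder and the random
#' graph generator. Vertices must be ordered by (layer, then position within
#' layer); edges connect consecutive layers only.
#'
#' @param vertices Data frame with columns `layer` (0-based) and `capacity`
#'   (nonnegative integer); optional `mass`, `shift`, `raw_intensity`.
#' @param edges Data frame with columns `from`, `to` (row indices into
#'   `vertices`); optional `position`, `ptm`.
#' @param total_flow Positive integer total flow value.
#' @return Object of class `layered_graph`.
#' @export
layered_graph <- function(vertices, edges, total_flow) {
  stopifnot(is.data.frame(vertices), all(c("layer", "capacity") %in% names(vertices)),
            total_flow >= 1)
  vertices$id <- seq_len(nrow(vertices))
  if (is.unsorted(vertices$layer)) stop("vertices must be ordered by layer", call. = FALSE)
  if (nrow(edges) > 0L) {
    dl <- vertices$layer[edges$to] - vertices$layer[edges$from]
    if (any(dl != 1L)) stop("edges must connect consecutive layers", call. = FALSE)
  }
  layers <- sort(unique(vertices$layer))
  if (sum(vertices$layer == layers[1]) != 1L ||
      sum(vertices$layer == layers[length(layers)]) != 1L) {
    stop("first and last layers must hold exactly one vertex", call. = FALSE)
  }
  structure(list(vertices = vertices, edges = edges,
                 n_layers = length(layers),
                 total_flow = as.integer(total_flow)),
            class = "layered_graph")
}

#' @export
print.layered_graph <- function(x, ...) {
  cat(class(x)[1], "with", x$n_layers, "layers,",
      nrow(x$vertices), "vertices,", nrow(x$edges), "edges; total flow",
      x$total_flow, "\n")
  invisible(x)
}

# adjacency: list over vertices of outgoing / incoming neighbor ids
.out_adj <- function(graph) {
  adj <- vector("list", nrow(graph$vertices))
  if (nrow(graph$edges) > 0L) {
    sp <- split(graph$edges$to, factor(graph$edges$from,
                                       levels = seq_len(nrow(graph$vertices))))
    adj <- unname(sp)
  }
  adj
}

.in_adj <- function(graph) {
  adj <- vector("list", nrow(graph$vertices))
  if (nrow(graph$edges) > 0L) {
    sp <- split(graph$edges$from, factor(graph$edges$to,
                                         levels = seq_len(nrow(graph$vertices))))
    adj <- unname(sp)
  }
  adj
}

#' Remove vertices not on any source-to-sink path
#'
#' Keeps exactly the vertices reachable from the source and co-reachable
#' from the sink; edges incident to removed vertices are dropped.
#' Idempotent.
#'
#' @param graph A `layered_graph`.
#' @return The pruned graph (same class).
#' @export
prune_unreachable <- function(graph) {
  nv <- nrow(graph$vertices)
  s <- 1L
  t <- nv
  fwd <- logical(nv); fwd[s] <- TRUE
  if (nrow(graph$edges) > 0L) {
    ord <- order(graph$vertices$layer[graph$edges$from])
    for (e in ord) {
      if (fwd[graph$edges$from[e]]) fwd[graph$edges$to[e]] <- TRUE
    }
    bwd <- logical(nv); bwd[t] <- TRUE
    for (e in rev(ord)) {
      if (bwd[graph$edges$to[e]]) bwd[graph$edges$from[e]] <- TRUE
    }
  } else {
    bwd <- logical(nv); bwd[t] <- TRUE
  }
  keep <- fwd & bwd
  if (!keep[s] || !keep[t] || !fwd[t]) {
    stop("source and sink are disconnected", call. = FALSE)
  }
  newid <- cumsum(keep)
  vertices <- graph$vertices[keep, , drop = FALSE]
  rownames(vertices) <- NULL
  vertices$id <- seq_len(nrow(vertices))
  edges <- graph$edges
  if (nrow(edges) > 0L) {
    ke <- keep[edges$from] & keep[edges$to]
    edges <- edges[ke, , drop = FALSE]
    edges$from <- newid[edges$from]
    edges$to <- newid[edges$to]
    rownames(edges) <- NULL
  }
  out <- graph
  out$vertices <- vertices
  out$edges <- edges
  out
}

#' Quantize raw intensities to integer capacities
#'
#' Largest-remainder (Hamilton) rounding of the intensity shares of one
#' layer so that the capacities are nonnegative integers summing exactly to
#' `total_flow`; ties are broken by lower index (lower mass). An all-zero
#' layer receives equal shares.
#'
#' @param raw Nonnegative raw intensities of one layer.
#' @param total_flow Positive integer.
#' @return Integer vector, same length as `raw`, summing to `total_flow`.
#' @export
quantize_capacities <- function(raw, total_flow) {
  stopifnot(total_flow >= 1, all(raw >= 0))
  n <- length(raw)
  shares <- if (sum(raw) > 0) raw / sum(raw) * total_flow else rep(total_flow / n, n)
  base <- floor(shares)
  rem <- shares - base
  left <- as.integer(round(total_flow - sum(base)))
  if (left > 0L) {
    give <- order(-rem, seq_len(n))[seq_len(left)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Build the layered mass graph for a spectrum
#'
#' The five-step construction: (1) one vertex per mass in each prefix-mass
#' set; (2) edges between preceding masses in consecutive layers, annotated
#' with the PTM applied (or unmodified); (3) the single layer-0 vertex is
#' the source and the single layer-n vertex the sink; (4) vertices not on
#' any source-sink path are removed; (5) capacities are the per-layer pooled
#' intensity shares, quantized to integers summing to the total flow value.
#'
#' @param sequence Protein amino-acid string.
#' @param spectrum A `deconv_spectrum`; its precursor mass restricts the
#'   proteoform set.
#' @param ptm_table Expected-PTM table.
#' @param tol_ppm Fragment mass tolerance (ppm).
#' @param precursor_tol_ppm Precursor mass tolerance (ppm).
#' @param allow_pm1da Accept +-1.00235 Da precursor offsets.
#' @param shift_bound Bound (Da) on summed PTM shifts.
#' @param total_flow Positive integer total flow value (100 = percent).
#' @param scheme An `ion_scheme()`, or NULL to pick by the spectrum's
#'   activation type.
#' @return Object of class `c("mass_graph", "layered_graph")`, with the
#'   sequence, PTM table, scheme and total residue mass attached.
#' @export
build_graph <- function(sequence, spectrum, ptm_table = default_ptm_table(),
                        tol_ppm = 15, precursor_tol_ppm = 15,
                        allow_pm1da = TRUE, shift_bound = 600,
                        total_flow = 100, scheme = NULL) {
  if (is.null(scheme)) scheme <- scheme_for_activation(spectrum$activation)
  pms <- enumerate_prefix_mass_sets(sequence, ptm_table,
                                    precursor_mass = spectrum$precursor_mass,
                                    precursor_tol_ppm = precursor_tol_ppm,
                                    allow_pm1da = allow_pm1da,
                                    shift_bound = shift_bound)
  n <- length(pms$sets) - 1L
  if (length(pms$sets[[n + 1L]]) == 0L) {
    stop("precursor unexplainable: no expected-PTM proteoform matches the precursor mass",
         call. = FALSE)
  }
  chars <- .seq_chars(sequence)
  vertices <- data.frame(
    layer = rep(0:n, lengths(pms$sets)),
    mass = unlist(pms$sets),
    shift = unlist(pms$shift_sets))
  vertices$raw_intensity <- raw_intensity(vertices$mass, spectrum,
                                          pms$total_residue_mass, scheme, tol_ppm)
  offsets <- c(0L, cumsum(lengths(pms$sets)))  # id offset per layer
  ef <- integer(0); et <- integer(0); epos <- integer(0); eptm <- character(0)
  for (i in seq_len(n)) {
    d1 <- pms$shift_sets[[i]]
    d2 <- pms$shift_sets[[i + 1L]]
    if (length(d1) == 0L || length(d2) == 0L) next
    k2 <- .mkey(d2)
    steps <- rbind(data.frame(shift = 0, ptm = NA_character_),
                   { tt <- .ptms_at(ptm_table, chars[i])
                     data.frame(shift = tt$mass_shift, ptm = tt$name) })
    for (jstep in seq_len(nrow(steps))) {
      hit <- match(.mkey(d1 + steps$shift[jstep]), k2)
      ok <- which(!is.na(hit))
      if (length(ok) > 0L) {
        ef <- c(ef, offsets[i] + ok)
        et <- c(et, offsets[i + 1L] + hit[ok])
        epos <- c(epos, rep(i, length(ok)))
        eptm <- c(eptm, rep(steps$ptm[jstep], length(ok)))
      }
    }
  }
  edges <- data.frame(from = ef, to = et, position = epos, ptm = eptm,
                      stringsAsFactors = FALSE)
  vertices$capacity <- 0L
  g <- layered_graph(vertices, edges, total_flow)
  g$sequence <- sequence
  g$ptm_table <- ptm_table
  g$scheme <- scheme
  g$total_residue_mass <- pms$total_residue_mass
  g$spectrum_id <- spectrum$spectrum_id
  class(g) <- c("mass_graph", "layered_graph")
  g <- prune_unreachable(g)
  # capacities after pruning, so removed vertices are excluded from the shares
  for (lay in unique(g$vertices$layer)) {
    idx <- which(g$vertices$layer == lay)
    g$vertices$capacity[idx] <- quantize_capacities(g$vertices$raw_intensity[idx],
                                                    total_flow)
  }
  g$vertices$capacity[1L] <- as.integer(total_flow)
  g$vertices$capacity[nrow(g$vertices)] <- as.integer(total_flow)
  g
}

#' Decode a source-to-sink path into a proteoform
#'
#' Follows the path's edges; every edge annotated with a PTM contributes a
#' modification at its position.
#'
#' @param graph A `mass_graph`.
#' @param path Integer vector of vertex ids from source to sink.
#' @return A `proteoform`.
#' @export
decode_path <- function(graph, path) {
  stopifnot(inherits(graph, "mass_graph"))
  mods <- list()
  for (k in seq_len(length(path) - 1L)) {
    hit <- which(graph$edges$from == path[k] & graph$edges$to == path[k + 1L])
    if (length(hit) == 0L) stop("path uses a nonexistent edge", call. = FALSE)
    hit <- hit[1L]
    if (!is.na(graph$edges$ptm[hit])) {
      mods[[length(mods) + 1L]] <- data.frame(
        position = graph$edges$position[hit],
        name = graph$edges$ptm[hit], stringsAsFactors = FALSE)
    }
  }
  proteoform(graph$sequence, if (length(mods)) do.call(rbind, mods) else NULL,
             ptm_table = graph$ptm_table)
}

#' Enumerate all source-to-sink paths
#'
#' Exhaustive depth-first enumeration; intended for small graphs and test
#' oracles.
#'
#' @param graph A `layered_graph`.
#' @param max_paths Safety cap.
#' @return List of integer vertex-id vectors.
#' @export
enumerate_paths <- function(graph, max_paths = 1e5) {
  out_adj <- .out_adj(graph)
  sink <- nrow(graph$vertices)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == sink) {
      if (length(paths) >= max_paths) stop("too many paths", call. = FALSE)
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in out_adj[[v]]) walk(c(path, w))
  }
  walk(1L)
  paths
}

#' Graph-size survey for a protein and PTM set
#'
#' Counts the vertices and edges of the layered graph generated from the
#' protein and the expected PTMs under a bound on the summed PTM shifts,
#' with forward reachability only (no precursor constraint, no pruning);
#' numerically identical cumulative-shift chains are merged.
#'
#' @param sequence Protein amino-acid string.
#' @param ptm_table Expected-PTM table.
#' @param shift_bound Bound (Da) on summed PTM shifts.
#' @return List with `n_vertices`, `n_edges`, `n_layers`, `shift_bound`.
#' @export
graph_stats <- function(sequence, ptm_table = default_ptm_table(),
                        shift_bound = 600) {
  chars <- .seq_chars(sequence)
  n <- length(chars)
  nv <- 1L
  ne <- 0L
  cur <- 0
  for (i in seq_len(n)) {
    shifts <- .ptms_at(ptm_table, chars[i])$mass_shift
    nxt <- cur
    ne <- ne + length(cur)                 # unmodified step from every state
    for (s in shifts) {
      cand <- cur + s
      cand <- cand[cand <= shift_bound + 1e-9]
      ne <- ne + length(cand)
      nxt <- c(nxt, cand)
    }
    cur <- sort(nxt[!duplicated(.mkey(nxt))])
    nv <- nv + length(cur)
  }
  list(n_vertices = nv, n_edges = ne, n_layers = n + 1L,
       shift_bound = shift_bound)
}

#' Export a graph as a plain-text edge list
#'
#' Vertices are written as `layer:mass:capacity`; one edge per line.
#'
#' @param graph A `layered_graph`.
#' @param path Output path.
#' @export
write_graph_tsv <- function(graph, path) {
  v <- graph$vertices
  lab <- function(i) {
    m <- if ("mass" %in% names(v)) sprintf("%.5f", v$mass[i]) else as.character(i)
    paste(v$layer[i], m, v$capacity[i], sep = ":")
  }
  lines <- c("from\tto\tptm")
  if (nrow(graph$edges) > 0L) {
    ann <- if ("ptm" %in% names(graph$edges)) {
      ifelse(is.na(graph$edges$ptm), "unmodified", graph$edges$ptm)
    } else rep("unmodified", nrow(graph$edges))
    lines <- c(lines, paste(vapply(graph$edges$from, lab, character(1)),
                            vapply(graph$edges$to, lab, character(1)),
                            ann, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' GraphViz DOT rendering of a layered graph
#'
#' @param graph A `layered_graph`.
#' @return Character scalar with the DOT source.
#' @export
graph_dot <- function(graph) {
  v <- graph$vertices
  node <- function(i) sprintf("v%d", i)
  lab <- vapply(seq_len(nrow(v)), function(i) {
    m <- if ("mass" %in% names(v)) sprintf("%.3f", v$mass[i]) else as.character(i)
    sprintf("%s [label=\"L%d %s c=%d\"];", node(i), v$layer[i], m, v$capacity[i])
  }, character(1))
  edg <- character(0)
  if (nrow(graph$edges) > 0L) {
    ann <- if ("ptm" %in% names(graph$edges)) {
      ifelse(is.na(graph$edges$ptm), "", graph$edges$ptm)
    } else rep("", nrow(graph$edges))
    edg <- sprintf("%s -> %s [label=\"%s\"];",
                   vapply(graph$edges$from, node, character(1)),
                   vapply(graph$edges$to, node, character(1)), ann)
  }
  paste(c("digraph mass_graph {", "  rankdir=LR;",
          paste0("  ", lab), paste0("  ", edg), "}"), collapse = "\n")
}
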