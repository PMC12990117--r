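# Molecule-level contact graphs from tail-bead proximity, and the network
# measures used to characterize aggregation: degree and closeness
# centrality (plus optional extras). Shortest paths and components are
# delegated to igraph; the closeness convention for disconnected graphs is
# applied on top.

#' All point pairs within a cutoff (periodic)
#'
#' Cell-list neighbor search with cell edge >= cutoff; a brute-force
#' all-pairs path is used for small systems or boxes with fewer than 3
#' cells per axis (where the cell list degenerates). Both paths return
#' identical pairs.
#'
#' @param pos n x 3 position matrix (nm).
#' @param box A `sim_box`.
#' @param cutoff Distance cutoff, nm.
#' @param brute_force_below Use the all-pairs path when n is below this.
#' @return 2-column integer matrix of index pairs (i < j).
#' @export
pairs_within <- function(pos, box, cutoff, brute_force_below = 400L) {
  L <- unclass(as_sim_box(box))
  n <- nrow(pos)
  if (n < 2L) return(matrix(integer(), 0L, 2L))
  nc <- pmax(1L, floor(L / cutoff))
  if (n <= brute_force_below || any(nc < 3L)) {
    d <- cross_distances(pos, pos, box)
    hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
    return(unname(hit[, 1:2, drop = FALSE]))
  }
  w <- pos
  for (k in 1:3) w[, k] <- w[, k] - L[k] * floor(w[, k] / L[k])
  ci <- sapply(1:3, function(k) pmin(nc[k] - 1L, floor(w[, k] / (L[k] / nc[k]))))
  cell <- ci[, 1] + nc[1] * (ci[, 2] + nc[2] * ci[, 3])
  ord <- order(cell)
  cell_of <- split(ord, cell[ord])
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out <- list()
  keys <- as.integer(names(cell_of))
  kz <- keys %/% (nc[1] * nc[2])
  ky <- (keys %/% nc[1]) %% nc[2]
  kx <- keys %% nc[1]
  lookup <- new.env(hash = TRUE)
  for (i in seq_along(keys)) assign(as.character(keys[i]), cell_of[[i]],
                                    envir = lookup)
  for (i in seq_along(keys)) {
    a <- cell_of[[i]]
    for (r in seq_len(nrow(offsets))) {
      ox <- (kx[i] + offsets[r, 1]) %% nc[1]
      oy <- (ky[i] + offsets[r, 2]) %% nc[2]
      oz <- (kz[i] + offsets[r, 3]) %% nc[3]
      key2 <- ox + nc[1] * (oy + nc[2] * oz)
      if (key2 < keys[i]) next          # visit each cell pair once
      b <- lookup[[as.character(key2)]]
      if (is.null(b)) next
      if (key2 == keys[i]) {
        if (length(a) < 2L) next
        d <- cross_distances(w[a, , drop = FALSE], w[a, , drop = FALSE], box)
        hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
        if (nrow(hit)) out[[length(out) + 1L]] <- cbind(a[hit[, 1]], a[hit[, 2]])
      } else {
        d <- cross_distances(w[a, , drop = FALSE], w[b, , drop = FALSE], box)
        hit <- which(d <= cutoff, arr.ind = TRUE)
        if (nrow(hit)) out[[length(out) + 1L]] <- cbind(a[hit[, 1]], b[hit[, 2]])
      }
    }
  }
  if (!length(out)) return(matrix(integer(), 0L, 2L))
  e <- do.call(rbind, out)
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Per-frame molecule contact graph from tail-bead proximity
#'
#' Two molecules of the chosen kind are in contact when any tail bead of
#' one lies within `cutoff` of any tail bead of the other (minimum-image
#' distance). The default cutoff, 0.7 nm, is the first minimum of the
#' tail-tail radial distribution function (the first coordination shell).
#' The node set covers all molecules of the kind, isolated ones included.
#'
#' @param frame A `cg_frame`.
#' @param map A `role_map`; `cation` uses `cation_tail` beads, `lipid` uses
#'   `lipid_tail` beads.
#' @param node_kind `"cation"` or `"lipid"`.
#' @param cutoff Contact cutoff, nm (> 0).
#' @return An object of class `contact_graph`: list with `nodes` (molecule
#'   ids), `edges` (2-column matrix of molecule ids), `kind`, `cutoff`,
#'   `time`.
#' @export
build_contact_graph <- function(frame, map, node_kind = c("cation", "lipid"),
                                cutoff = 0.7) {
  node_kind <- match.arg(node_kind)
  stopifnot(cutoff > 0)
  role <- if (node_kind == "cation") "cation_tail" else "lipid_tail"
  mol_role <- if (node_kind == "cation") "cation_head" else "phosphate"
  tails <- role_indices(frame, map, role)
  # node set: every molecule of the kind (identified by its head/phosphate
  # bead or by owning tail beads), even if isolated
  nodes <- sort(unique(c(frame$atoms$molecule_id[role_indices(frame, map, mol_role)],
                         frame$atoms$molecule_id[tails])))
  if (!length(nodes)) {
    warning("build_contact_graph: no molecules of kind '", node_kind, "'")
    return(structure(list(nodes = integer(), edges = matrix(integer(), 0L, 2L),
                          kind = node_kind, cutoff = cutoff, time = frame$time),
                     class = "contact_graph"))
  }
  mol <- frame$atoms$molecule_id[tails]
  pos <- frame_positions(frame)[tails, , drop = FALSE]
  bp <- pairs_within(pos, frame$box, cutoff)
  if (nrow(bp)) {
    m1 <- mol[bp[, 1]]; m2 <- mol[bp[, 2]]
    keep <- m1 != m2
    e <- cbind(pmin(m1[keep], m2[keep]), pmax(m1[keep], m2[keep]))
    e <- unique(e)
  } else {
    e <- matrix(integer(), 0L, 2L)
  }
  structure(list(nodes = nodes, edges = e, kind = node_kind, cutoff = cutoff,
                 time = frame$time),
            class = "contact_graph")
}

#' Build a contact graph directly from an edge list
#'
#' Constructs the same object as [build_contact_graph()] from explicit
#' nodes and edges (undirected; self-edges and duplicates are dropped).
#'
#' @param nodes Integer vector of node (molecule) ids.
#' @param edges 2-column matrix of node-id pairs (may be empty).
#' @param kind Node kind label.
#' @return A `contact_graph`.
#' @export
contact_graph_from_edges <- function(nodes, edges = matrix(integer(), 0L, 2L),
                                     kind = "cation") {
  nodes <- sort(unique(as.integer(nodes)))
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    if (!all(edges %in% nodes)) {
      stop("contact_graph_from_edges: edge endpoint outside node set",
           call. = FALSE)
    }
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                          pmax(edges[, 1], edges[, 2])))
  }
  structure(list(nodes = nodes, edges = edges, kind = kind, cutoff = NA_real_,
                 time = NA_real_),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %s: %d nodes, %d edges (cutoff %.2f nm)\n",
              x$kind, length(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

as_igraph <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  ids <- as.character(graph$nodes)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, rbind(match(as.character(graph$edges[, 1]), ids),
                                    match(as.character(graph$edges[, 2]), ids)))
  }
  g
}

#' Node degrees of a contact graph
#'
#' @param graph A `contact_graph`.
#' @return List with `degree` (named integer vector over all nodes,
#'   isolated ones included) and `mean`.
#' @export
degree_values <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  deg <- stats::setNames(integer(length(graph$nodes)),
                         as.character(graph$nodes))
  if (nrow(graph$edges)) {
    t1 <- table(as.character(graph$edges[, 1]))
    t2 <- table(as.character(graph$edges[, 2]))
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  list(degree = deg, mean = mean(deg))
}

#' Closeness centrality of a contact graph
#'
#' For a node v with `r` reachable nodes (v included) and `S` the sum of
#' shortest-path lengths to them, closeness is
#' `((r - 1) / (n - 1)) * ((r - 1) / S)`: the harmonic of the mean
#' reachable distance scaled by the reachable fraction. Isolated nodes get
#' 0; on a connected graph this reduces to `(n - 1) / S`. Values lie in
#' `[0, 1]`, reaching 1 only for a node adjacent to every other node of a
#' connected graph.
#'
#' @param graph A `contact_graph`.
#' @return List with `closeness` (named numeric vector) and `mean`.
#' @export
closeness_values <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  n <- length(graph$nodes)
  cl <- stats::setNames(numeric(n), as.character(graph$nodes))
  if (n > 1L && nrow(graph$edges)) {
    g <- as_igraph(graph)
    d <- igraph::distances(g)         # BFS shortest paths, Inf unreachable
    for (i in seq_len(n)) {
      di <- d[i, -i]
      reach <- di[is.finite(di)]
      r <- length(reach) + 1L
      if (r > 1L) {
        cl[i] <- ((r - 1) / (n - 1)) * ((r - 1) / sum(reach))
      }
    }
  }
  list(closeness = cl, mean = mean(cl))
}

#' Connected components of a contact graph
#'
#' @param graph A `contact_graph`.
#' @return List with `membership` (named integer vector of component
#'   labels), `sizes` (decreasing), `n_components`, and
#'   `largest_fraction` (size of the largest component / n).
#' @export
connected_components <- function(graph) {
  stopifnot(inherits(graph, "contact_graph"))
  n <- length(graph$nodes)
  if (n == 0L) {
    return(list(membership = integer(), sizes = integer(),
                n_components = 0L, largest_fraction = NA_real_))
  }
  comp <- igraph::components(as_igraph(graph))
  memb <- stats::setNames(as.integer(comp$membership),
                          as.character(graph$nodes))
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  list(membership = memb, sizes = sizes, n_components = comp$no,
       largest_fraction = sizes[1] / n)
}

#' Pooled centrality statistics over a trajectory window
#'
#' Builds a contact graph per frame of the window, pools per-node degree
#' and closeness values over frames, and reports pooled means plus
#' histograms. The default window is the final 20% of frames.
#'
#' @param trajectory A `cg_trajectory`.
#' @param map A `role_map`.
#' @param node_kind `"cation"` or `"lipid"`.
#' @param window Integer vector of frame indices; default the final 20%.
#' @param cutoff Contact cutoff, nm.
#' @param closeness_breaks,degree_breaks Histogram breaks.
#' @return List with `mean_degree`, `mean_closeness`, `degree_hist`,
#'   `closeness_hist` (`hist` objects), and the pooled `values`
#'   data.frame (frame, molecule_id, degree, closeness).
#' @export
centrality_time_average <- function(trajectory, map,
                                    node_kind = c("cation", "lipid"),
                                    window = NULL, cutoff = 0.7,
                                    closeness_breaks = seq(0, 1, 0.02),
                                    degree_breaks = NULL) {
  node_kind <- match.arg(node_kind)
  nf <- length(trajectory)
  if (is.null(window)) window <- seq.int(max(1L, nf - ceiling(0.2 * nf) + 1L), nf)
  if (!length(window) || any(window < 1L | window > nf)) {
    stop("centrality_time_average: empty or out-of-range window", call. = FALSE)
  }
  rows <- lapply(window, function(fi) {
    g <- build_contact_graph(trajectory[[fi]], map, node_kind, cutoff)
    dv <- degree_values(g); cv <- closeness_values(g)
    data.frame(frame = fi, molecule_id = g$nodes,
               degree = as.integer(dv$degree),
               closeness = as.numeric(cv$closeness))
  })
  vals <- do.call(rbind, rows)
  if (is.null(degree_breaks)) {
    degree_breaks <- seq(-0.5, max(vals$degree, 1) + 0.5, by = 1)
  }
  list(mean_degree = mean(vals$degree),
       mean_closeness = mean(vals$closeness),
       degree_hist = graphics::hist(vals$degree, breaks = degree_breaks,
                                    plot = FALSE),
       closeness_hist = graphics::hist(vals$closeness,
                                       breaks = closeness_breaks,
                                       plot = FALSE),
       values = vals)
}

#' Export a contact graph as an edge-list text file
#'
#' One edge per line (`id1 <tab> id2`); isolated nodes listed in a
#' trailing `# isolated:` comment so the node set is recoverable.
#'
#' @param graph A `contact_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "contact_graph"))
  con <- file(path, "w")
  writeLines(sprintf("# memscope contact graph: kind= %s cutoff= %g nm nodes= %d",
                     graph$kind, graph$cutoff, length(graph$nodes)), con)
  if (nrow(graph$edges)) {
    writeLines(sprintf("%d\t%d", graph$edges[, 1], graph$edges[, 2]), con)
  }
  touched <- unique(as.vector(graph$edges))
  iso <- setdiff(graph$nodes, touched)
  if (length(iso)) {
    writeLines(paste0("# isolated: ", paste(iso, collapse = " ")), con)
  }
  close(con)
  invisible(path)
}
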