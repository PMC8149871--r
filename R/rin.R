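# Residue interaction network: contact graph and node centralities.

#' Build a residue interaction network
#'
#' One node per residue; an undirected, unweighted edge joins two
#' residues when any pair of their heavy atoms is closer than
#' `contact_cutoff`. Contacts between residues closer than
#' `min_seq_sep` in sequence on the same chain are excluded
#' (`min_seq_sep = 1` excludes only self-contacts, so peptide
#' neighbours are kept). The graph is simplified: no self-loops, no
#' multi-edges. Isolated residues remain as nodes.
#'
#' @param atoms Atom tibble from [read_structure()].
#' @param contact_cutoff Heavy-atom distance cutoff in Angstrom.
#' @param min_seq_sep Minimum sequence separation (same chain) for an
#'   edge; 1 keeps all inter-residue contacts.
#' @return An object of class `severin_rin`: a list with `graph` (an
#'   igraph), `nodes` (tibble: `node`, `chain`, `resno`, `insert`, `aa`)
#'   and the construction parameters.
#' @export
build_rin <- function(atoms, contact_cutoff = 5.0, min_seq_sep = 1L) {
  stopifnot(contact_cutoff > 0)
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  nodes <- dplyr::distinct(heavy, .data$chain, .data$resno, .data$insert,
                           .data$aa)
  nodes <- dplyr::arrange(nodes, .data$chain, .data$resno, .data$insert)
  nodes$node <- residue_id(nodes$chain, nodes$resno, nodes$insert)
  if (nrow(nodes) < 2L) {
    warning("fewer than 2 residues; network has no edges", call. = FALSE)
  }

  ridx <- match(residue_id(heavy$chain, heavy$resno, heavy$insert),
                nodes$node)
  xyz <- cbind(heavy$x, heavy$y, heavy$z)

  # cell list on the cutoff so only atoms in adjacent cells are compared
  cell <- contact_cutoff
  cx <- floor(xyz[, 1] / cell)
  cy <- floor(xyz[, 2] / cell)
  cz <- floor(xyz[, 3] / cell)
  keys <- paste(cx, cy, cz)
  cell_atoms <- split(seq_len(nrow(heavy)), keys)
  cell_xyz <- do.call(rbind, strsplit(names(cell_atoms), " "))
  storage.mode(cell_xyz) <- "integer"
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  # half the neighbourhood (plus self-cell handled separately) to avoid
  # visiting each unordered cell pair twice
  offs <- offs[offs[, 1] > 0 |
                 (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]

  cut2 <- contact_cutoff^2
  pair_i <- integer(0)
  pair_j <- integer(0)
  add_pairs <- function(a, b) {
    # all cross pairs between atom index sets a and b within cutoff
    if (length(a) == 0L || length(b) == 0L) return(NULL)
    d2 <- outer(xyz[a, 1], xyz[b, 1], "-")^2 +
      outer(xyz[a, 2], xyz[b, 2], "-")^2 +
      outer(xyz[a, 3], xyz[b, 3], "-")^2
    hit <- which(d2 < cut2, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(NULL)
    cbind(a[hit[, 1]], b[hit[, 2]])
  }

  hits <- vector("list", 2L * length(cell_atoms))
  h <- 0L
  key_lookup <- stats::setNames(seq_along(cell_atoms), names(cell_atoms))
  for (ci in seq_along(cell_atoms)) {
    a <- cell_atoms[[ci]]
    # within-cell pairs
    if (length(a) > 1L) {
      d2 <- outer(xyz[a, 1], xyz[a, 1], "-")^2 +
        outer(xyz[a, 2], xyz[a, 2], "-")^2 +
        outer(xyz[a, 3], xyz[a, 3], "-")^2
      hit <- which(d2 < cut2 & upper.tri(d2), arr.ind = TRUE)
      if (nrow(hit) > 0L) {
        h <- h + 1L
        hits[[h]] <- cbind(a[hit[, 1]], a[hit[, 2]])
      }
    }
    around <- sweep(offs, 2, cell_xyz[ci, ], "+")
    for (oi in seq_len(nrow(around))) {
      cj <- key_lookup[paste(around[oi, 1], around[oi, 2], around[oi, 3])]
      if (is.na(cj)) next
      p <- add_pairs(a, cell_atoms[[cj]])
      if (!is.null(p)) {
        h <- h + 1L
        hits[[h]] <- p
      }
    }
  }
  pairs <- if (h > 0L) do.call(rbind, hits[seq_len(h)]) else
    matrix(integer(0), ncol = 2)

  ri <- ridx[pairs[, 1]]
  rj <- ridx[pairs[, 2]]
  keep <- ri != rj
  ri <- ri[keep]; rj <- rj[keep]
  same_chain <- nodes$chain[ri] == nodes$chain[rj]
  sep_ok <- !same_chain | abs(nodes$resno[ri] - nodes$resno[rj]) >= min_seq_sep
  ri <- ri[sep_ok]; rj <- rj[sep_ok]
  lo <- pmin(ri, rj)
  hi <- pmax(ri, rj)
  edges <- unique(cbind(lo, hi))

  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes$node)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, t(edges))
  }
  g <- igraph::simplify(g)

  structure(
    list(graph = g, nodes = nodes, contact_cutoff = contact_cutoff,
         min_seq_sep = as.integer(min_seq_sep)),
    class = "severin_rin"
  )
}

#' @export
print.severin_rin <- function(x, ...) {
  cat(sprintf(
    "Residue interaction network: %d nodes, %d edges (cutoff %.1f A, min separation %d)\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    x$contact_cutoff, x$min_seq_sep))
  invisible(x)
}

as_rin_graph <- function(x) {
  if (inherits(x, "severin_rin")) x$graph
  else if (inherits(x, "igraph")) x
  else stop("expected a `severin_rin` or igraph object", call. = FALSE)
}

#' Burt's constraint
#'
#' Structural-holes constraint of each node: with uniform tie weights
#' \eqn{p_{ij} = 1/\mathrm{deg}(i)}, the constraint is
#' \deqn{c(i) = \sum_{j \in N(i)} \Big(p_{ij} + \sum_{q \in N(i), q \neq j}
#'   p_{iq} p_{qj}\Big)^2.}
#' Low constraint marks nodes bridging otherwise unconnected groups
#' (central residues); high constraint marks peripheral, redundantly
#' embedded nodes. Isolated nodes get `NA`.
#'
#' @param network A `severin_rin` or an igraph graph (undirected,
#'   simple, unweighted).
#' @param nodes Node names (or indices) to evaluate; default all.
#' @return Named numeric vector of constraint values.
#' @export
burt_constraint <- function(network, nodes = NULL) {
  g <- as_rin_graph(network)
  # sparse algebra pays off only on large residue networks
  sparse <- igraph::vcount(g) > 400
  A <- igraph::as_adjacency_matrix(g, sparse = sparse)
  A <- (A > 0) * 1
  deg <- Matrix::rowSums(A)
  P <- A / pmax(deg, 1)          # row-stochastic for non-isolated nodes
  indirect <- P %*% P            # (PP)_ij = sum_q p_iq p_qj; q != i,j free
  tot <- (P + indirect) * (A > 0)  # only terms for j in N(i)
  cons <- Matrix::rowSums(tot^2)
  cons[deg == 0] <- NA_real_
  out <- stats::setNames(as.numeric(cons), igraph::V(g)$name)
  if (!is.null(nodes)) {
    if (is.character(nodes) && !all(nodes %in% names(out))) {
      stop("unknown node(s): ",
           paste(setdiff(nodes, names(out)), collapse = ", "), call. = FALSE)
    }
    out <- out[nodes]
  }
  out
}

#' Node centralities of a residue interaction network
#'
#' Computes the seven per-node measures used as network features:
#' degree, (unnormalized) betweenness, closeness, Burt's constraint,
#' HITS authority score, PageRank (damping 0.85), and k-core number.
#' Closeness on a disconnected graph follows the within-component
#' convention (unreachable vertices ignored); the convention is recorded
#' in the `closeness_mode` attribute. Isolated nodes get degree 0,
#' `NA` closeness and `NA` constraint.
#'
#' @param network A `severin_rin` or an igraph graph.
#' @param damping PageRank damping factor.
#' @return A tibble with one row per node: `node`, residue key columns
#'   when available, and `degree`, `betweenness`, `closeness`,
#'   `constraint`, `authority`, `pagerank`, `kcore`.
#' @export
rin_centralities <- function(network, damping = 0.85) {
  g <- as_rin_graph(network)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  clo <- suppressWarnings(igraph::closeness(g, mode = "all"))
  clo[deg == 0] <- NA_real_
  auth <- igraph::hits_scores(g)$authority
  pr <- igraph::page_rank(g, damping = damping)$vector
  kc <- igraph::coreness(g)
  cons <- burt_constraint(g)

  out <- tibble::tibble(
    node = igraph::V(g)$name,
    degree = as.integer(deg),
    betweenness = as.numeric(btw),
    closeness = as.numeric(clo),
    constraint = as.numeric(cons),
    authority = as.numeric(auth),
    pagerank = as.numeric(pr),
    kcore = as.integer(kc)
  )
  if (inherits(network, "severin_rin")) {
    out <- dplyr::left_join(network$nodes, out, by = "node")
    out <- dplyr::relocate(out, "node")
  }
  attr(out, "closeness_mode") <- "within-component (unreachable ignored)"
  out
}

#' Write a residue interaction network to disk
#'
#' @param rin A `severin_rin`.
#' @param edge_file Optional path for a two-column edge-list text file.
#' @param graphml_file Optional path for GraphML output.
#' @param node_file Optional path for the node centrality table (CSV).
#' @return `rin`, invisibly.
#' @export
write_rin <- function(rin, edge_file = NULL, graphml_file = NULL,
                      node_file = NULL) {
  if (!is.null(edge_file)) {
    igraph::write_graph(rin$graph, edge_file, format = "ncol")
  }
  if (!is.null(graphml_file)) {
    igraph::write_graph(rin$graph, graphml_file, format = "graphml")
  }
  if (!is.null(node_file)) {
    utils::write.csv(rin_centralities(rin), node_file, row.names = FALSE,
                     na = "")
  }
  invisible(rin)
}
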