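# Contact-correlation network and betweenness ranking.
#
# Edges connect residue pairs whose representative mDCC passes the
# correlation threshold (default >= 0.5) while the centers of the
# corresponding modes are in atomic contact (default < 5 A).  An edge is
# flagged "transient" when the conventional DCC of the pair stays below the
# threshold: the interaction exists only during part of the trajectory and
# only the mode-resolved correlation sees it.

#' Build the contact-correlation network
#'
#' @param x an `"mdcc_matrix"` from [mdcc()] / [residue_matrix()].
#' @param mdcc_threshold minimum representative mDCC for an edge (default 0.5).
#' @param distance_threshold maximum mode-center distance in Angstrom
#'   (default 5.0, strict `<`).
#' @param dcc_threshold conventional-DCC level below which a drawn edge is
#'   flagged transient (default 0.5).
#' @param any_mode_pair if `FALSE` (default) an edge requires the maximizing
#'   (provenance) mode pair itself to satisfy both thresholds; if `TRUE`, any
#'   mode pair jointly passing both thresholds qualifies (requires the matrix
#'   to have been built with `keep_candidates = TRUE`).
#' @return `"correlation_network"`: `nodes` (residue table + `betweenness`),
#'   `edges` (a, b, labels, mdcc, center_distance, transient, provenance
#'   atom/mode ids), `graph` (igraph object over all residues) and the
#'   thresholds used.
#' @export
build_network <- function(x, mdcc_threshold = 0.5, distance_threshold = 5.0,
                          dcc_threshold = 0.5, any_mode_pair = FALSE) {
  stopifnot(inherits(x, "mdcc_matrix"))
  rtab <- x$residues
  nres <- nrow(rtab)

  pool <- if (any_mode_pair) {
    if (is.null(x$candidates)) {
      mdccr_stop("any_mode_pair = TRUE needs a matrix built with keep_candidates = TRUE",
                 "mdccr_validation_error")
    }
    x$candidates
  } else {
    x$provenance
  }
  pass <- pool[!is.na(pool$mdcc) & pool$mdcc >= mdcc_threshold &
               pool$center_distance < distance_threshold, , drop = FALSE]
  edges <- if (nrow(pass) > 0) {
    # one edge per residue pair: best qualifying candidate
    key <- paste0(pass$a, "_", pass$b)
    keep <- unlist(lapply(split(seq_len(nrow(pass)), key), function(idx) {
      p <- pass[idx, ]
      idx[order(-p$mdcc, -p$mean_weight, p$center_distance)[1]]
    }), use.names = FALSE)
    e <- pass[keep, , drop = FALSE]
    e <- e[order(e$a, e$b), , drop = FALSE]
    dccv <- x$dcc[cbind(e$a, e$b)]
    data.frame(a = e$a, b = e$b,
               label_a = rtab$key[e$a], label_b = rtab$key[e$b],
               mdcc = e$mdcc, dcc = dccv,
               center_distance = e$center_distance,
               mean_weight = e$mean_weight,
               transient = !is.na(dccv) & dccv < dcc_threshold &
                           e$mdcc >= mdcc_threshold,
               atom_i = e$atom_i, atom_j = e$atom_j, k = e$k, l = e$l,
               stringsAsFactors = FALSE)
  } else {
    data.frame(a = integer(), b = integer(), label_a = character(),
               label_b = character(), mdcc = numeric(), dcc = numeric(),
               center_distance = numeric(), mean_weight = numeric(),
               transient = logical(), atom_i = integer(), atom_j = integer(),
               k = integer(), l = integer(), stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL

  g <- igraph::make_empty_graph(n = nres, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rtab$key)
  g <- igraph::set_vertex_attr(g, "molecule", value = rtab$molecule)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$a, edges$b),
                           mdcc = edges$mdcc, transient = edges$transient)
  }
  btw <- igraph::betweenness(g, directed = FALSE, weights = NULL)
  nodes <- rtab
  nodes$betweenness <- unname(btw)

  structure(list(nodes = nodes, edges = edges, graph = g,
                 mdcc_threshold = mdcc_threshold,
                 distance_threshold = distance_threshold,
                 dcc_threshold = dcc_threshold,
                 any_mode_pair = any_mode_pair),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf(paste0("Contact-correlation network: %d residues, %d edges",
                     " (%d transient)\n"),
              nrow(x$nodes), nrow(x$edges), sum(x$edges$transient)))
  cat(sprintf("  thresholds: mDCC >= %.2f, center distance < %.1f A\n",
              x$mdcc_threshold, x$distance_threshold))
  top <- x$nodes[order(-x$nodes$betweenness), , drop = FALSE]
  top <- top[top$betweenness > 0, , drop = FALSE]
  if (nrow(top) > 0) {
    k <- min(5L, nrow(top))
    cat("  highest betweenness:",
        paste(sprintf("%s (%.2f)", top$key[seq_len(k)],
                      top$betweenness[seq_len(k)]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Betweenness centrality of every residue
#'
#' `g(i) = sum over unordered node pairs {s,t} (s,t != i) of the fraction of
#' shortest paths between s and t that pass through i`; pairs in different
#' components contribute nothing.  Edges are unweighted.
#'
#' @param network a `"correlation_network"`.
#' @return Named numeric vector (residue key -> betweenness).
#' @export
residue_betweenness <- function(network) {
  setNames(network$nodes$betweenness, network$nodes$key)
}

#' Top-betweenness residues per molecule
#'
#' @param network a `"correlation_network"`.
#' @param per_molecule list length per molecule (default 15); molecules with
#'   fewer residues yield shorter lists.  Ties and the overall order fall
#'   back to node (topology) order, so the ranking is deterministic.
#' @return data.frame: `molecule`, `rank`, `residue` (key), `betweenness`.
#' @export
top_betweenness <- function(network, per_molecule = 15) {
  nd <- network$nodes
  out <- lapply(split(seq_len(nrow(nd)), nd$molecule), function(idx) {
    o <- idx[order(-nd$betweenness[idx], idx)]
    o <- head(o, per_molecule)
    data.frame(molecule = nd$molecule[o], rank = seq_along(o),
               residue = nd$key[o], betweenness = nd$betweenness[o],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[unique(nd$molecule)])
  rownames(out) <- NULL
  out
}

#' Export a network to disk
#'
#' @param network a `"correlation_network"`.
#' @param edges_tsv optional path: edge list (labels, mdcc, dcc, distance,
#'   transient flag).
#' @param graphml optional path: GraphML via igraph.
#' @param betweenness_tsv optional path: per-molecule betweenness ranking
#'   (rank, molecule, residue, value).
#' @param per_molecule ranking depth for `betweenness_tsv`.
#' @return Invisibly, `network`.
#' @export
export_network <- function(network, edges_tsv = NULL, graphml = NULL,
                           betweenness_tsv = NULL, per_molecule = 15) {
  if (!is.null(edges_tsv)) {
    cols <- c("label_a", "label_b", "mdcc", "dcc", "center_distance",
              "transient")
    write.table(network$edges[, cols], edges_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(graphml)) {
    igraph::write_graph(network$graph, graphml, format = "graphml")
  }
  if (!is.null(betweenness_tsv)) {
    write.table(top_betweenness(network, per_molecule), betweenness_tsv,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(network)
}

#' @export
plot.correlation_network <- function(x, ...) {
  g <- x$graph
  mol <- factor(x$nodes$molecule)
  cols <- hcl.colors(nlevels(mol), "Dark 3")[as.integer(mol)]
  lty <- ifelse(nrow(x$edges) > 0 & x$edges$transient, 2, 1)
  igraph::plot.igraph(g, vertex.color = cols, vertex.size = 8,
                      vertex.label.cex = 0.6, edge.lty = lty, ...)
  invisible(x)
}
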