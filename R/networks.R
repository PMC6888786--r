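#' Directed binary networks
#'
#' A `directed_network` is a square logical adjacency matrix with a zero
#' diagonal and unique node labels. The convention throughout the package is
#' `adjacency[s, t] == TRUE` means there is a directed edge from node `s`
#' (source) to node `t` (target). Converters from causal-connectivity results
#' (which store influence target-by-source) transpose explicitly.
#'
#' @param adjacency Square logical (or 0/1 numeric) matrix.
#' @param node_labels Character vector of unique node names; defaults to
#'   existing dimnames or `V1..Vq`.
#' @return An object of class `directed_network`.
#' @export
directed_network <- function(adjacency, node_labels = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stopf("adjacency must be square, got %d x %d", nrow(adjacency), ncol(adjacency))
  mode(adjacency) <- "logical"
  if (anyNA(adjacency)) stopf("adjacency contains missing values")
  q <- nrow(adjacency)
  if (any(diag(adjacency))) stopf("self-loops are not allowed")
  if (is.null(node_labels)) node_labels <- rownames(adjacency) %||% paste0("V", seq_len(q))
  if (length(node_labels) != q) stopf("need %d node labels, got %d", q, length(node_labels))
  if (anyDuplicated(node_labels)) stopf("node labels must be unique")
  dimnames(adjacency) <- list(node_labels, node_labels)
  structure(list(adjacency = adjacency, node_labels = as.character(node_labels)),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("Directed binary network: %d nodes, %d edges\n",
              length(x$node_labels), sum(x$adjacency)))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(x_adj(net) * 1, mode = "directed")
}

x_adj <- function(net) {
  if (inherits(net, "directed_network")) net$adjacency else net
}

# Transitive closure by repeated boolean squaring of (A | I); entry (i, j),
# i != j, is TRUE iff a directed path i -> j exists. Dense closure is simple
# to verify and adequate at the few-hundred-node scale used here.
reach_closure <- function(adj) {
  q <- nrow(adj)
  if (q <= 1) return(matrix(FALSE, q, q))
  M <- adj | diag(TRUE, q)
  for (k in seq_len(ceiling(log2(q)))) {
    M2 <- (M %*% M) > 0
    if (identical(M2, M)) break
    M <- M2
  }
  M & !diag(TRUE, q)
}

#' Successors of a node (directed-path reachability)
#'
#' Node `j` is a successor of node `i` when a directed path leads from `i`
#' to `j`; the node itself is excluded. Predecessors are the same operation
#' on the transposed adjacency.
#'
#' @param net A [directed_network()].
#' @param i Node index or label.
#' @return Integer vector of successor node indices.
#' @export
successors <- function(net, i) {
  adj <- x_adj(net)
  i <- resolve_node(net, i)
  unname(which(reach_closure(adj)[i, ]))
}

#' @rdname successors
#' @export
predecessors <- function(net, i) {
  adj <- x_adj(net)
  i <- resolve_node(net, i)
  unname(which(reach_closure(adj)[, i]))
}

resolve_node <- function(net, i) {
  if (is.character(i)) {
    k <- match(i, net$node_labels)
    if (is.na(k)) stopf("unknown node label '%s'", i)
    return(k)
  }
  as.integer(i)
}

#' Brokerage of a node
#'
#' The un-normalized middleman score of node `i` in digraph `D`: the total
#' successor count over all nodes of `D`, minus the successor counts of the
#' remaining nodes in the node-deleted graph `D - i`, minus `i`'s own
#' successor and predecessor counts. Equivalently (a tested identity), it is
#' the number of ordered pairs `(s, t)`, both different from `i`, with a
#' directed path from `s` to `t` in `D` but none in `D - i`.
#'
#' @param net A [directed_network()].
#' @param i Node index or label; if missing, brokerage of every node.
#' @return Non-negative integer (or named integer vector over nodes).
#' @export
brokerage <- function(net, i) {
  adj <- x_adj(net)
  R <- reach_closure(adj)
  succ_counts <- rowSums(R)
  one <- function(k) {
    Rm <- reach_closure(adj[-k, -k, drop = FALSE])
    as.integer(sum(succ_counts) - sum(Rm) - succ_counts[k] - sum(R[, k]))
  }
  if (!missing(i)) return(one(resolve_node(net, i)))
  out <- vapply(seq_len(nrow(adj)), one, integer(1))
  names(out) <- net$node_labels
  out
}

#' Maximal potential brokerage of a network
#'
#' Sum over nodes of the number of indirect successors (successors reachable
#' by a path but not by a direct edge); the normalizer of middleman power.
#'
#' @param net A [directed_network()].
#' @return Non-negative integer.
#' @export
max_potential_brokerage <- function(net) {
  adj <- x_adj(net)
  R <- reach_closure(adj)
  as.integer(sum(rowSums(R) - rowSums(adj)))
}

#' Middleman power of every node
#'
#' Brokerage normalized by the maximal potential brokerage of the network
#' (with a floor of 1 to keep the ratio defined on edgeless graphs). The
#' center of a reciprocal star attains the maximum value 1; nodes whose
#' removal disconnects no ordered pair score 0.
#'
#' @param net A [directed_network()].
#' @return Named numeric vector in `[0, 1]`.
#' @export
middleman_power <- function(net) {
  b <- brokerage(net)
  b / max(max_potential_brokerage(net), 1)
}

#' Is a node a middleman? (brute-force oracle)
#'
#' TRUE iff there exist nodes `s`, `t` (both different from `i`) such that a
#' directed path `s -> t` exists in the network but not after deleting `i`.
#' Implemented by breadth-first searches, independently of the closure-based
#' brokerage computation, so the two can cross-check each other.
#'
#' @param net A [directed_network()].
#' @param i Node index or label.
#' @return Logical scalar.
#' @export
middleman_oracle <- function(net, i) {
  adj <- x_adj(net)
  i <- resolve_node(net, i)
  q <- nrow(adj)
  others <- setdiff(seq_len(q), i)
  for (s in others) {
    full <- bfs_reachable(adj, s)
    pruned <- bfs_reachable(adj, s, drop = i)
    ts <- setdiff(others, s)
    if (any(full[ts] & !pruned[ts])) return(TRUE)
  }
  FALSE
}

# Reachable set from s by BFS, optionally with one node removed.
bfs_reachable <- function(adj, s, drop = NULL) {
  q <- nrow(adj)
  seen <- rep(FALSE, q)
  if (!is.null(drop) && s == drop) return(seen)
  frontier <- s
  blocked <- rep(FALSE, q)
  if (!is.null(drop)) blocked[drop] <- TRUE
  repeat {
    nxt <- integer(0)
    for (v in frontier) {
      out <- which(adj[v, ] & !seen & !blocked)
      seen[out] <- TRUE
      nxt <- c(nxt, out)
    }
    if (!length(nxt)) break
    frontier <- nxt
  }
  seen
}

#' Directed betweenness centrality
#'
#' For every ordered pair `(s, t)` with `s != i != t` and at least one
#' shortest directed path, accumulates the fraction of shortest paths that
#' pass through node `i`; unreachable pairs contribute zero and tied
#' shortest paths share weight equally. Un-normalized by default; the
#' normalized variant divides by `(q - 1)(q - 2)`.
#'
#' @param net A [directed_network()].
#' @param normalized Divide by the number of ordered pairs excluding the node.
#' @return Named numeric vector of length `q`.
#' @export
betweenness_directed <- function(net, normalized = FALSE) {
  g <- as_igraph(net)
  bc <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  q <- length(net$node_labels)
  if (normalized && q > 2) bc <- bc / ((q - 1) * (q - 2))
  names(bc) <- net$node_labels
  bc
}

#' Nodal graph measures for one network
#'
#' Computes betweenness centrality, brokerage and middleman power on a
#' binary directed network.
#'
#' @param net A [directed_network()].
#' @param subject_id Optional identifier carried into the result.
#' @return A data.frame with columns `node_label`, `bc`, `brokerage`, `mp`.
#' @export
nodal_measures <- function(net, subject_id = NA_character_) {
  b <- brokerage(net)
  out <- data.frame(
    node_label = net$node_labels,
    bc = as.numeric(betweenness_directed(net)),
    brokerage = as.integer(b),
    mp = as.numeric(b / max(max_potential_brokerage(net), 1)),
    stringsAsFactors = FALSE
  )
  attr(out, "subject_id") <- subject_id
  out
}

#' Illustrative feeder/middleman network
#'
#' An 8-node directed network used throughout the documentation and tests:
#' three feeder nodes F1-F3 each send their single outgoing edge to a
#' dedicated middleman N1-N3; each middleman points to two hub nodes N4, N5;
#' the hubs point back to all three middlemen and to each other. Deleting a
#' middleman blocks its feeder's information flow to the rest of the network
#' (the middlemen have un-normalized betweenness 4 and brokerage 4), whereas
#' the hubs lie on many geodesics (betweenness 6) yet block nothing
#' (brokerage 0) -- betweenness alone overstates their criticality.
#'
#' @return A [directed_network()] with nodes F1, F2, F3, N1, ..., N5.
#' @export
toy_middleman_network <- function() {
  labels <- c("F1", "F2", "F3", "N1", "N2", "N3", "N4", "N5")
  edges <- rbind(
    c("F1", "N1"), c("F2", "N2"), c("F3", "N3"),
    c("N1", "N4"), c("N1", "N5"),
    c("N2", "N4"), c("N2", "N5"),
    c("N3", "N4"), c("N3", "N5"),
    c("N4", "N1"), c("N4", "N2"), c("N4", "N3"), c("N4", "N5"),
    c("N5", "N1"), c("N5", "N2"), c("N5", "N3"), c("N5", "N4")
  )
  adj <- matrix(FALSE, 8, 8, dimnames = list(labels, labels))
  adj[edges] <- TRUE
  directed_network(adj, labels)
}

#' Reciprocal star network
#'
#' One center connected to `k` leaves by edges in both directions and no
#' other edges. Removing the center disconnects every ordered pair of
#' leaves, so its middleman power equals 1.
#'
#' @param k Number of leaves (>= 2).
#' @return A [directed_network()] with nodes `C`, `L1..Lk`.
#' @export
star_network <- function(k) {
  stopifnot(k >= 2)
  labels <- c("C", paste0("L", seq_len(k)))
  adj <- matrix(FALSE, k + 1, k + 1, dimnames = list(labels, labels))
  adj[1, -1] <- TRUE
  adj[-1, 1] <- TRUE
  directed_network(adj, labels)
}

#' Read and write adjacency matrices
#'
#' Dense CSV with node labels as header and row names; values 0/1.
#'
#' @param net A [directed_network()].
#' @param path File path.
#' @return `write_network_csv` returns `path` invisibly; `read_network_csv`
#'   returns a [directed_network()].
#' @export
write_network_csv <- function(net, path) {
  m <- x_adj(net) * 1L
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  directed_network(as.matrix(df) > 0, rownames(df))
}

#' Write a network as an edge list
#'
#' Tab-separated columns `source`, `target` and optionally a weight column.
#'
#' @param net A [directed_network()].
#' @param path File path.
#' @param weights Optional q x q numeric matrix in source-by-target
#'   orientation, sampled at the edges.
#' @return `path`, invisibly.
#' @export
write_edgelist_tsv <- function(net, path, weights = NULL) {
  adj <- x_adj(net)
  idx <- which(adj, arr.ind = TRUE)
  df <- data.frame(source = net$node_labels[idx[, 1]],
                   target = net$node_labels[idx[, 2]],
                   stringsAsFactors = FALSE)
  if (!is.null(weights)) df$weight <- weights[idx]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
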