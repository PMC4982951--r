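#' Network parameters of a directed trait network
#'
#' Computes, per node, the out-degree (number of arrows leaving the node),
#' in-degree (arrows entering), connectivity (their sum) and the maximum
#' effect blocking step: the largest number of downstream nodes influenced
#' along a single directed path before the effect is blocked at a node with
#' no outgoing edges. The blocking step is the length, in edges, of the
#' longest directed path starting at the node, so a sink scores 0 and a node
#' whose children are all sinks scores 1.
#'
#' @param graph a directed acyclic graph ([causal_graph()] or any acyclic
#'   igraph object).
#' @return a `data.frame` with columns `node`, `out_degree`, `in_degree`,
#'   `connectivity`, `max_effect_blocking_steps`, one row per node in the
#'   graph's vertex order.
#' @examples
#' g <- causal_graph(data.frame(source = c("a", "b"), target = c("b", "c")))
#' network_metrics(g)
#' @export
network_metrics <- function(graph) {
  stopifnot(igraph::is_igraph(graph), igraph::is_directed(graph))
  nodes <- igraph::V(graph)$name
  out_deg <- igraph::degree(graph, mode = "out")
  in_deg <- igraph::degree(graph, mode = "in")
  data.frame(
    node = nodes,
    out_degree = as.integer(out_deg[nodes]),
    in_degree = as.integer(in_deg[nodes]),
    connectivity = as.integer(out_deg[nodes] + in_deg[nodes]),
    max_effect_blocking_steps =
      as.integer(max_blocking_steps(graph)[nodes]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Maximum effect blocking steps (longest directed path)
#'
#' Dynamic program over a topological order: `steps(v) = 0` for sinks and
#' `1 + max(steps(children))` otherwise.
#'
#' @param graph a directed acyclic igraph.
#' @param node optional node name; when given, returns that node's value
#'   only.
#' @return named integer vector of path lengths (in edges), or a single
#'   integer when `node` is given.
#' @export
max_blocking_steps <- function(graph, node = NULL) {
  stopifnot(igraph::is_igraph(graph), igraph::is_directed(graph))
  if (!igraph::is_dag(graph))
    stop("maximum effect blocking steps require an acyclic graph")
  nodes <- igraph::V(graph)$name
  steps <- stats::setNames(integer(length(nodes)), nodes)
  adj <- igraph::adjacent_vertices(graph, nodes, mode = "out")
  # reverse topological order: children are finalized before their parents
  for (v in rev(topo_order(graph))) {
    ch <- adj[[v]]$name
    if (length(ch)) steps[v] <- 1L + max(steps[ch])
  }
  if (is.null(node)) return(steps)
  if (!node %in% nodes) stop("unknown node: ", node)
  steps[[node]]
}

#' Downstream influence set
#'
#' The set of nodes a group of query nodes influences, directly or
#' indirectly: the union of strict descendants.
#'
#' @param graph a directed acyclic igraph.
#' @param nodes character vector of query node names.
#' @return character vector of descendant node names (query nodes excluded
#'   unless reachable from another query node), in vertex order.
#' @export
influence_set <- function(graph, nodes) {
  all_nodes <- igraph::V(graph)$name
  missing <- setdiff(nodes, all_nodes)
  if (length(missing))
    stop("unknown node(s): ", paste(missing, collapse = ", "))
  desc <- unlist(lapply(nodes, function(v) {
    setdiff(names(igraph::subcomponent(graph, v, mode = "out")), v)
  }))
  all_nodes[all_nodes %in% desc]
}

#' Connectivity table from printed degree columns
#'
#' Assembles the network-parameter table directly from per-node out- and
#' in-degree counts (as published summaries are often reported), computing
#' connectivity as their sum and checking the degree-conservation identity
#' that both columns sum to the edge count.
#'
#' @param node character vector of node names.
#' @param out_degree,in_degree non-negative integer vectors.
#' @return a `data.frame` with columns `node`, `out_degree`, `in_degree`,
#'   `connectivity`, plus attribute `n_edges` (the common column sum).
#' @export
connectivity_table <- function(node, out_degree, in_degree) {
  stopifnot(length(node) == length(out_degree),
            length(node) == length(in_degree),
            all(out_degree >= 0), all(in_degree >= 0))
  if (sum(out_degree) != sum(in_degree))
    stop("degree conservation violated: out-degrees sum to ", sum(out_degree),
         " but in-degrees sum to ", sum(in_degree),
         "; every arrow must leave one node and enter another")
  out <- data.frame(node = as.character(node),
                    out_degree = as.integer(out_degree),
                    in_degree = as.integer(in_degree),
                    connectivity = as.integer(out_degree + in_degree),
                    stringsAsFactors = FALSE)
  attr(out, "n_edges") <- sum(out$out_degree)
  out
}
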