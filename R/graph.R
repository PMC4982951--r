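#' Construct a tiered causal graph
#'
#' Builds the directed graph object used throughout the package: an
#' \pkg{igraph} directed graph whose vertices carry a `tier` attribute,
#' either `"instrument"` (genome-side nodes, exogenous by construction) or
#' `"trait"` (phenotype-side nodes). The constructor enforces the structural
#' invariants the two-tier model imposes: the graph is acyclic, no edge
#' points into an instrument, and instruments are never connected to each
#' other.
#'
#' @param edges a two-column `data.frame` (or matrix) of edges with columns
#'   `source` and `target` (extra columns such as `weight` are kept as edge
#'   attributes), or `NULL` for an edgeless graph.
#' @param nodes optional character vector of node names; defaults to the
#'   names appearing in `edges`. Must be supplied for isolated nodes.
#' @param tiers named character vector mapping node name to
#'   `"instrument"`/`"trait"`; unnamed nodes default to `"trait"`.
#' @return an `igraph` object with vertex attribute `tier`.
#' @examples
#' g <- causal_graph(data.frame(source = "a", target = "b"))
#' igraph::V(g)$tier
#' @export
causal_graph <- function(edges = NULL, nodes = NULL, tiers = NULL) {
  if (!is.null(edges)) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2L)
      stop("`edges` needs at least columns source and target")
    names(edges)[1:2] <- c("source", "target")
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
  } else {
    edges <- data.frame(source = character(), target = character(),
                        stringsAsFactors = FALSE)
  }
  nodes <- unique(c(nodes, edges$source, edges$target))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  tier <- rep("trait", length(nodes))
  names(tier) <- nodes
  if (!is.null(tiers)) {
    unknown <- setdiff(names(tiers), nodes)
    if (length(unknown))
      stop("tier given for unknown node(s): ", paste(unknown, collapse = ", "))
    tier[names(tiers)] <- unname(tiers)
  }
  if (!all(tier %in% c("instrument", "trait")))
    stop("tiers must be 'instrument' or 'trait'")
  igraph::V(g)$tier <- unname(tier[igraph::V(g)$name])
  validate_causal_graph(g)
  g
}

#' @rdname causal_graph
#' @param graph an igraph object with a `tier` vertex attribute.
#' @export
validate_causal_graph <- function(graph) {
  stopifnot(igraph::is_igraph(graph), igraph::is_directed(graph))
  if (is.null(igraph::V(graph)$tier))
    stop("graph has no `tier` vertex attribute")
  if (!igraph::is_dag(graph))
    stop("causal graph must be acyclic")
  tier <- graph_tiers(graph)
  if (igraph::ecount(graph) > 0L) {
    el <- igraph::as_edgelist(graph)
    if (any(tier[el[, 2L]] == "instrument"))
      stop("no edge may point into an instrument node")
    if (any(tier[el[, 1L]] == "instrument" & tier[el[, 2L]] == "instrument"))
      stop("instrument nodes may not be connected to each other")
  }
  invisible(graph)
}

#' @rdname causal_graph
#' @export
graph_tiers <- function(graph) {
  stats::setNames(igraph::V(graph)$tier, igraph::V(graph)$name)
}

#' Delete instrument nodes, keeping the trait network
#'
#' The genome-side principal components serve only to anchor directions;
#' once the two-tier network is learned they are removed, leaving the
#' induced subgraph on the trait nodes with all trait-to-trait edges intact.
#'
#' @param graph a tiered causal graph (see [causal_graph()]).
#' @return the induced subgraph on trait nodes (tier attributes preserved).
#' @export
trait_subgraph <- function(graph) {
  tier <- graph_tiers(graph)
  igraph::induced_subgraph(graph, igraph::V(graph)[tier == "trait"])
}

#' Read and write causal graphs
#'
#' Tab-separated edge lists (columns `source`, `target`, optional
#' `provenance`/`weight`, plus a `#node<TAB>tier` header block carrying
#' isolated nodes and tier tags) are the canonical interchange format.
#' GraphML round-trips through \pkg{igraph}; DOT is export-only.
#'
#' @param path file path.
#' @param format `"tsv"`, `"graphml"` or (write only) `"dot"`; guessed from
#'   the file extension when missing.
#' @return `read_causal_graph` returns an igraph object; `write_causal_graph`
#'   returns `path` invisibly.
#' @export
read_causal_graph <- function(path, format = c("auto", "tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_graph_format(path, read = TRUE)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (is.null(igraph::V(g)$tier)) igraph::V(g)$tier <- "trait"
    validate_causal_graph(g)
    return(g)
  }
  lines <- readLines(path)
  node_lines <- grep("^#node\t", lines)
  nodes <- tiers <- NULL
  if (length(node_lines)) {
    parts <- strsplit(sub("^#node\t", "", lines[node_lines]), "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
      stop("malformed node line at line ", node_lines[bad[1L]], " of ", path)
    nodes <- vapply(parts, `[`, "", 1L)
    tiers <- stats::setNames(vapply(parts, `[`, "", 2L), nodes)
  }
  body <- lines[!seq_along(lines) %in% node_lines & !grepl("^#", lines)]
  edges <- NULL
  if (length(body) > 1L) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    hdr <- fields[[1L]]
    if (!all(c("source", "target") %in% hdr))
      stop("malformed edge header at line 1 of ", path,
           ": need source and target columns")
    bad <- which(lengths(fields[-1L]) != length(hdr))
    if (length(bad))
      stop("malformed edge line at line ", bad[1L] + 1L, " of ", path)
    edges <- as.data.frame(do.call(rbind, fields[-1L]), stringsAsFactors = FALSE)
    names(edges) <- hdr
    if ("weight" %in% hdr) edges$weight <- as.numeric(edges$weight)
    edges <- edges[c("source", "target", setdiff(hdr, c("source", "target")))]
  }
  causal_graph(edges, nodes = nodes, tiers = tiers)
}

#' @rdname read_causal_graph
#' @param graph graph to serialize.
#' @export
write_causal_graph <- function(graph, path,
                               format = c("auto", "tsv", "graphml", "dot")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_graph_format(path, read = FALSE)
  validate_causal_graph(graph)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else if (format == "dot") {
    igraph::write_graph(graph, path, format = "dot")
  } else {
    tier <- graph_tiers(graph)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#node\t%s\t%s", names(tier), unname(tier)), con)
    el <- igraph::as_data_frame(graph, what = "edges")
    names(el)[1:2] <- c("source", "target")
    utils::write.table(el, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

guess_graph_format <- function(path, read) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("graphml", "xml")) return("graphml")
  if (ext %in% c("dot", "gv")) {
    if (read) stop("DOT files are export-only and cannot be read back")
    return("dot")
  }
  "tsv"
}

#' Nodes in topological order
#'
#' @param graph an acyclic igraph.
#' @return character vector of node names, sources first.
#' @keywords internal
topo_order <- function(graph) {
  if (!igraph::is_dag(graph)) stop("graph has a directed cycle")
  names(igraph::topo_sort(graph, mode = "out"))
}
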