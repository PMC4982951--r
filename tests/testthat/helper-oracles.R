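# Independent oracles used to cross-check the package's graph algorithms.
# These deliberately use naive exhaustive algorithms on small inputs.

# Longest directed path from `node` by exhaustive depth-first enumeration
# over an edge-list data.frame (columns source, target).
dfs_longest_path <- function(edges, node) {
  children <- function(v) edges$target[edges$source == v]
  walk <- function(v) {
    ch <- children(v)
    if (!length(ch)) return(0L)
    1L + max(vapply(ch, walk, 0L))
  }
  walk(node)
}

# Random DAG over `k` nodes: edges only from lower to higher label, each
# present with probability p.
random_dag_edges <- function(k, p = 0.3) {
  nodes <- sprintf("n%02d", seq_len(k))
  pairs <- t(utils::combn(nodes, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(source = pairs[keep, 1L], target = pairs[keep, 2L],
             stringsAsFactors = FALSE)
}

# d-separation by moralization: x and y are d-separated given Z iff they are
# disconnected in the moralized ancestral undirected graph with Z removed.
dsep_oracle <- function(edges, nodes, x, y, Z = character(0)) {
  parents <- function(v) edges$source[edges$target == v]
  # ancestors of the query set
  anc <- unique(c(x, y, Z))
  repeat {
    more <- unique(unlist(lapply(anc, parents)))
    new <- setdiff(more, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  e <- edges[edges$source %in% anc & edges$target %in% anc, , drop = FALSE]
  und <- rbind(e[c("source", "target")],
               stats::setNames(e[c("target", "source")], c("source", "target")))
  # moralize: marry parents of every common child
  for (v in anc) {
    pa <- parents(v)
    pa <- pa[pa %in% anc]
    if (length(pa) >= 2L) {
      pairs <- t(utils::combn(pa, 2L))
      und <- rbind(und,
                   data.frame(source = c(pairs[, 1L], pairs[, 2L]),
                              target = c(pairs[, 2L], pairs[, 1L]),
                              stringsAsFactors = FALSE))
    }
  }
  und <- und[!und$source %in% Z & !und$target %in% Z, , drop = FALSE]
  # BFS from x
  seen <- x
  frontier <- x
  while (length(frontier)) {
    nxt <- setdiff(und$target[und$source %in% frontier], seen)
    if (y %in% nxt) return(FALSE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  TRUE
}

# sorted "source->target" keys for edge-set comparison
edge_keys <- function(graph) {
  el <- igraph::as_data_frame(graph, what = "edges")
  sort(paste(el$from, el$to, sep = "->"))
}

true_fixture_edge_keys <- function(cfg = fa_sim_config()) {
  ew <- cfg$edge_weights
  sort(paste(ew$source, ew$target, sep = "->"))
}

# joint instrument+trait system of the fixture for direct data simulation
# (bypasses the genotype layer; instruments are unit-variance exogenous
# nodes wired like the configured genetic effects)
fixture_joint_system <- function(cfg = fa_sim_config()) {
  ge <- cfg$genetic_effects
  gam <- vapply(split(ge$effect, ge$trait), function(e) sqrt(sum(e^2)), 0)
  iv <- paste0("IV_", names(gam))
  edges <- rbind(cfg$edge_weights,
                 data.frame(source = iv, target = names(gam),
                            weight = unname(gam), stringsAsFactors = FALSE))
  nodes <- c(iv, cfg$trait_names)
  noise <- c(stats::setNames(rep(1, length(iv)), iv), cfg$noise_sd)
  list(edges = edges, nodes = nodes, noise = noise, iv = iv,
       traits = cfg$trait_names)
}
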