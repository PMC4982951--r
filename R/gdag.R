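#' Fit a genome-anchored causal network over quantitative traits
#'
#' The central fitting function. Genome-wide genotype dosages are LD-pruned
#' and summarised into principal-component instruments, instruments
#' significantly associated with at least one trait are retained, the
#' two-tier skeleton over instruments and traits is estimated by
#' partial-correlation tests, edges are oriented with the genome-to-phenome
#' tier constraint (the instrumental-variable anchor), instruments are then
#' deleted, and network parameters plus back-door-adjusted effect sizes are
#' computed on the resulting trait network.
#'
#' Instead of raw genotypes, precomputed instrument scores can be supplied
#' via `instruments` (a matrix or an `instrument_set`); with neither, the
#' network is learned from the traits alone and orientation relies on
#' v-structures and the deterministic fallback only.
#'
#' @param traits samples x traits numeric matrix or data.frame.
#' @param genotypes optional samples x SNPs dosage matrix (0/1/2).
#' @param instruments optional instrument score matrix or `instrument_set`.
#' @param alpha significance level used for both instrument selection and
#'   the conditional-independence tests; default 0.001.
#' @param r2_threshold LD-pruning threshold; default 0.80.
#' @param k_pcs number of candidate principal components; default 50,
#'   capped at the matrix rank bound.
#' @param max_cond maximum CI conditioning-set size; default `Inf` (grow until adjacency sizes are exhausted).
#' @param inverse_normal apply the rank-based inverse normal transform to
#'   each trait before analysis; default `FALSE`.
#' @param effects estimate per-edge causal effects; default `TRUE`.
#' @return an object of class `gdag`; see Details.
#' @details The returned list carries `graph` (two-tier network),
#'   `trait_graph`, `metrics` (per-trait network parameters), `effects`
#'   (per-edge adjusted estimates), `instruments` (the `instrument_set`, if
#'   built), `skeleton`, `alpha`, `n`, and `call`. Methods: `print`,
#'   `summary`, `coef` (edge effects), `plot`, `simulate` (draws traits
#'   from the fitted linear system).
#' @examples
#' cfg <- fa_sim_config(n_samples = 400, seed = 7)
#' sim <- simulate_traits(simulate_genotypes(cfg), cfg)
#' fit <- gdag(sim$traits, alpha = 0.01, effects = FALSE)
#' fit
#' @export
gdag <- function(traits, genotypes = NULL, instruments = NULL,
                 alpha = 0.001, r2_threshold = 0.80, k_pcs = 50L,
                 max_cond = Inf, inverse_normal = FALSE, effects = TRUE) {
  cl <- match.call()
  traits <- as.matrix(traits)
  if (is.null(colnames(traits)))
    colnames(traits) <- sprintf("T%d", seq_len(ncol(traits)))
  if (inverse_normal) traits <- apply(traits, 2L, int_transform)

  inst_set <- NULL
  scores <- NULL
  if (!is.null(instruments)) {
    if (inherits(instruments, "instrument_set")) {
      inst_set <- instruments
      if (is.null(inst_set$selected))
        inst_set <- select_instruments(inst_set, traits, alpha = alpha)
      scores <- inst_set$scores[, inst_set$selected, drop = FALSE]
    } else {
      scores <- as.matrix(instruments)
      if (is.null(colnames(scores)))
        colnames(scores) <- sprintf("PC%d", seq_len(ncol(scores)))
    }
  } else if (!is.null(genotypes)) {
    pruned <- ld_prune(genotypes, r2_threshold = r2_threshold)
    k <- min(k_pcs, nrow(pruned), ncol(pruned))
    inst_set <- compute_pcs(pruned, k = k)
    inst_set <- select_instruments(inst_set, traits, alpha = alpha)
    scores <- inst_set$scores[, inst_set$selected, drop = FALSE]
  }

  if (!is.null(scores) && ncol(scores)) {
    if (nrow(scores) != nrow(traits))
      stop("sample mismatch between instruments and traits")
    dat <- cbind(scores, traits)
    tiers <- stats::setNames(
      c(rep("instrument", ncol(scores)), rep("trait", ncol(traits))),
      colnames(dat))
  } else {
    dat <- traits
    tiers <- stats::setNames(rep("trait", ncol(traits)), colnames(traits))
  }

  skel <- estimate_skeleton(dat, tiers = tiers, alpha = alpha,
                            max_cond = max_cond)
  graph <- orient_edges(skel)
  tg <- trait_subgraph(graph)
  eff <- if (effects) estimate_all_effects(traits, tg) else NULL
  rsd <- if (effects) node_residual_sd(traits, tg) else NULL

  structure(list(graph = graph, trait_graph = tg,
                 metrics = network_metrics(tg),
                 effects = eff, residual_sd = rsd, instruments = inst_set,
                 skeleton = skel, alpha = alpha, max_cond = max_cond,
                 n = nrow(traits), call = cl),
            class = "gdag")
}

#' Fit the causal network from an analytic covariance (oracle mode)
#'
#' Runs the same skeleton + orientation machinery against a population
#' covariance matrix instead of data, with conditional independence decided
#' by exact zero partial correlation. Used to verify structure recovery on
#' the generating model, free of sampling noise.
#'
#' @param sigma covariance matrix over instruments and traits (dimnames
#'   required), e.g. from [oracle_covariance()].
#' @param tiers named tier vector covering the columns of `sigma`.
#' @param max_cond maximum conditioning-set size; default `Inf`.
#' @return a `gdag` object (no effect estimates; `n` is `Inf`).
#' @export
gdag_from_cov <- function(sigma, tiers, max_cond = Inf) {
  cl <- match.call()
  skel <- estimate_skeleton(cov_matrix = sigma, tiers = tiers, n = Inf,
                            max_cond = max_cond)
  graph <- orient_edges(skel)
  tg <- trait_subgraph(graph)
  structure(list(graph = graph, trait_graph = tg,
                 metrics = network_metrics(tg),
                 effects = NULL, instruments = NULL,
                 skeleton = skel, alpha = NA_real_, max_cond = max_cond,
                 n = Inf, call = cl),
            class = "gdag")
}

#' @export
print.gdag <- function(x, ...) {
  tier <- graph_tiers(x$graph)
  cat("Genome-anchored causal network\n")
  cat("  ", sum(tier == "trait"), " traits, ",
      igraph::ecount(x$trait_graph), " directed trait edges; ",
      sum(tier == "instrument"), " instrument(s) used\n", sep = "")
  nf <- nrow(attr(x$graph, "fallback_edges") %||% data.frame())
  if (nf) cat("  ", nf, " edge(s) oriented by the deterministic fallback\n",
              sep = "")
  cat("  n =", x$n, if (!is.na(x$alpha)) paste(", alpha =", x$alpha), "\n")
  invisible(x)
}

#' @export
summary.gdag <- function(object, ...) {
  structure(list(metrics = object$metrics,
                 effects = object$effects,
                 n = object$n, alpha = object$alpha,
                 n_instruments = sum(graph_tiers(object$graph) == "instrument"),
                 conflicts = attr(object$graph, "conflicts"),
                 fallback = attr(object$graph, "fallback_edges")),
            class = "summary.gdag")
}

#' @export
print.summary.gdag <- function(x, ...) {
  cat("Network parameters (connectivity = out + in; blocking steps =",
      "longest directed path):\n")
  print(x$metrics, row.names = FALSE)
  cat("\nEdges:", sum(x$metrics$out_degree), " Instruments:",
      x$n_instruments, " n:", x$n, "\n")
  if (!is.null(x$effects) && nrow(x$effects)) {
    cat("\nPer-edge adjusted effects (head):\n")
    print(utils::head(x$effects, 10L), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.gdag <- function(object, ...) {
  if (is.null(object$effects)) {
    warning("model was fitted without effect estimation")
    return(numeric(0))
  }
  stats::setNames(object$effects$estimate,
                  paste(object$effects$exposure, object$effects$outcome,
                        sep = "->"))
}

#' @export
plot.gdag <- function(x, trait_only = TRUE, ...) {
  g <- if (trait_only) x$trait_graph else x$graph
  tier <- graph_tiers(g)
  igraph::plot.igraph(
    g,
    vertex.color = ifelse(tier == "instrument", "gold", "palegreen3"),
    vertex.shape = ifelse(tier == "instrument", "square", "circle"),
    vertex.label.cex = 0.8, edge.arrow.size = 0.4,
    layout = igraph::layout_with_sugiyama(g)$layout, ...)
  invisible(x)
}

#' Simulate traits from the fitted causal network
#'
#' Draws samples from the linear-Gaussian system defined by the fitted
#' trait graph, the estimated per-edge coefficients and the residual
#' standard deviations of the corresponding adjustment regressions.
#'
#' @param object a `gdag` fitted with `effects = TRUE`.
#' @param nsim number of replicate data sets.
#' @param seed optional integer seed.
#' @param n samples per replicate; defaults to the fitted `n`.
#' @param ... unused.
#' @return a list of `nsim` trait matrices.
#' @export
simulate.gdag <- function(object, nsim = 1, seed = NULL, n = object$n, ...) {
  if (is.null(object$effects))
    stop("refit with effects = TRUE to simulate from the fitted system")
  if (!is.null(seed)) set.seed(seed)
  edges <- data.frame(source = object$effects$exposure,
                      target = object$effects$outcome,
                      weight = object$effects$estimate,
                      stringsAsFactors = FALSE)
  nodes <- igraph::V(object$trait_graph)$name
  noise <- object$residual_sd %||% stats::setNames(rep(1, length(nodes)), nodes)
  lapply(seq_len(nsim), function(i)
    sem_sample(n, edges, nodes = nodes, noise_sd = noise))
}
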