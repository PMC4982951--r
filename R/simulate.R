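#' Simulation configuration for genotype + trait data
#'
#' Describes a synthetic study: LD-block genotypes and quantitative traits
#' generated from a sparse acyclic linear-Gaussian structural equation
#' model, with genetic effects entering through standardized SNP dosages.
#'
#' @param n_samples,n_snps positive integers.
#' @param block_size SNPs per LD block (the last block may be short).
#' @param maf_range length-2 numeric, minor allele frequencies sampled
#'   uniformly in this interval; both ends in (0, 0.5].
#' @param within_block_r correlation in `[0, 1]` of the latent Gaussians
#'   generating the SNPs of one block; 1 makes a block's dosage columns
#'   identical (given equal MAFs), 0 makes them independent.
#' @param trait_names distinct trait names.
#' @param edge_weights `data.frame` with columns `source`, `target`,
#'   `weight`: the trait-level causal edges. Must induce a DAG.
#' @param genetic_effects `data.frame` with columns `snp` (column index into
#'   the genotype matrix), `trait`, `effect`: per-SNP effects on traits.
#' @param noise_sd residual standard deviation per trait (scalar recycled,
#'   or named vector).
#' @param seed integer seed; all simulation randomness flows from it.
#' @return an object of class `gdag_sim_config`.
#' @seealso [fa_sim_config()] for the built-in 15-metabolite configuration.
#' @export
sim_config <- function(n_samples, n_snps, block_size = 10L,
                       maf_range = c(0.05, 0.5), within_block_r = 0.9,
                       trait_names, edge_weights,
                       genetic_effects = NULL, noise_sd = 1, seed = 1L) {
  stopifnot(n_samples >= 1, n_snps >= 1, block_size >= 1)
  if (n_samples != round(n_samples) || n_snps != round(n_snps))
    stop("n_samples and n_snps must be integers")
  stopifnot(length(maf_range) == 2L, all(maf_range > 0), all(maf_range <= 0.5),
            maf_range[1] <= maf_range[2],
            within_block_r >= 0, within_block_r <= 1)
  trait_names <- as.character(trait_names)
  if (anyDuplicated(trait_names)) stop("trait_names must be distinct")
  edge_weights <- as.data.frame(edge_weights, stringsAsFactors = FALSE)
  if (nrow(edge_weights)) {
    stopifnot(all(c("source", "target", "weight") %in% names(edge_weights)))
    bad <- setdiff(unique(c(edge_weights$source, edge_weights$target)),
                   trait_names)
    if (length(bad))
      stop("edge_weights mention unknown trait(s): ", paste(bad, collapse = ", "))
    if (any(edge_weights$weight == 0))
      stop("edge weights must be nonzero (absent edges are simply omitted)")
    # construction fails on cycles
    causal_graph(edge_weights, nodes = trait_names)
  }
  if (!is.null(genetic_effects)) {
    genetic_effects <- as.data.frame(genetic_effects, stringsAsFactors = FALSE)
    stopifnot(all(c("snp", "trait", "effect") %in% names(genetic_effects)))
    if (any(genetic_effects$snp < 1 | genetic_effects$snp > n_snps))
      stop("genetic_effects reference SNP indices outside 1..n_snps")
    bad <- setdiff(genetic_effects$trait, trait_names)
    if (length(bad))
      stop("genetic_effects mention unknown trait(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(names(noise_sd))) {
    noise_sd <- stats::setNames(rep_len(noise_sd, length(trait_names)),
                                trait_names)
  } else {
    stopifnot(setequal(names(noise_sd), trait_names))
    noise_sd <- noise_sd[trait_names]
  }
  stopifnot(all(noise_sd > 0))
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps),
                 block_size = as.integer(block_size),
                 maf_range = as.numeric(maf_range),
                 within_block_r = as.numeric(within_block_r),
                 trait_names = trait_names,
                 edge_weights = edge_weights,
                 genetic_effects = genetic_effects,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "gdag_sim_config")
}

#' @export
print.gdag_sim_config <- function(x, ...) {
  cat("Simulation configuration:", x$n_samples, "samples,", x$n_snps,
      "SNPs in blocks of", x$block_size, "\n")
  cat(" ", length(x$trait_names), "traits,", nrow(x$edge_weights),
      "causal edges,",
      if (is.null(x$genetic_effects)) 0L else nrow(x$genetic_effects),
      "genetic effects; seed", x$seed, "\n")
  invisible(x)
}

#' Built-in 15-metabolite fatty-acid network configuration
#'
#' The package's reference fixture: 15 traits named after the serum fatty
#' acid metabolites of the motivating study, connected by 29 causal edges.
#' The graph matches the published out-degree of every metabolite, gives the
#' two dietary source metabolites (palmitoleate, margarate) a maximum effect
#' blocking step of 5 terminating at laurylcarnitine, keeps margarate's
#' influence from reaching myristate, and makes every other trait a
#' descendant of the two sources jointly. One genetic instrument is placed
#' on each non-sink trait (stronger on the two sources), emulating
#' genome-wide PCs that influence several metabolites while some metabolites
#' have none.
#'
#' @param n_samples cohort size; default 2479.
#' @param seed integer seed recorded in the configuration.
#' @return a `gdag_sim_config`.
#' @export
fa_sim_config <- function(n_samples = 2479L, seed = 101L) {
  e <- fa_edges()
  traits <- fa_trait_names()
  sinks <- c("Linoleate", "Dihomo-linoleate", "Laurylcarnitine")
  instrumented <- setdiff(traits, sinks)
  block_size <- 8L
  cfg_effects <- data.frame(
    snp = (seq_along(instrumented) - 1L) * block_size + 1L,
    trait = instrumented,
    effect = ifelse(instrumented %in% c("Palmitoleate", "Margarate"), 0.5, 0.3),
    stringsAsFactors = FALSE
  )
  sim_config(n_samples = n_samples, n_snps = 320L, block_size = block_size,
             maf_range = c(0.1, 0.4), within_block_r = 0.9,
             trait_names = traits, edge_weights = e,
             genetic_effects = cfg_effects, noise_sd = 1, seed = seed)
}

fa_trait_names <- function() {
  c("Myristate", "Myristoleate", "Palmitate", "Palmitoleate", "Margarate",
    "Heptadecanoate", "Stearate", "Oleate", "Nonadecanoate", "Eicosenoate",
    "Linoleate", "Linolenate", "Dihomo-linoleate", "Decanoylcarnitine",
    "Laurylcarnitine")
}

fa_edges <- function() {
  el <- matrix(c(
    "Palmitoleate", "Oleate",
    "Palmitoleate", "Myristoleate",
    "Palmitoleate", "Heptadecanoate",
    "Palmitoleate", "Eicosenoate",
    "Palmitoleate", "Palmitate",
    "Margarate", "Nonadecanoate",
    "Margarate", "Stearate",
    "Margarate", "Eicosenoate",
    "Margarate", "Dihomo-linoleate",
    "Margarate", "Linolenate",
    "Oleate", "Myristoleate",
    "Oleate", "Eicosenoate",
    "Oleate", "Dihomo-linoleate",
    "Myristoleate", "Myristate",
    "Myristate", "Eicosenoate",
    "Myristate", "Dihomo-linoleate",
    "Myristate", "Linolenate",
    "Nonadecanoate", "Stearate",
    "Nonadecanoate", "Dihomo-linoleate",
    "Stearate", "Palmitate",
    "Stearate", "Linoleate",
    "Palmitate", "Decanoylcarnitine",
    "Palmitate", "Linolenate",
    "Palmitate", "Laurylcarnitine",
    "Heptadecanoate", "Dihomo-linoleate",
    "Eicosenoate", "Dihomo-linoleate",
    "Eicosenoate", "Laurylcarnitine",
    "Linolenate", "Linoleate",
    "Decanoylcarnitine", "Laurylcarnitine"
  ), ncol = 2L, byrow = TRUE)
  data.frame(source = el[, 1L], target = el[, 2L],
             weight = rep_len(c(0.45, 0.32, 0.38, 0.29, 0.41, 0.35, 0.27),
                              nrow(el)),
             stringsAsFactors = FALSE)
}

#' Ground truth of a simulation configuration
#'
#' @param config a `gdag_sim_config`.
#' @return a list of class `gdag_truth` with the generating trait DAG
#'   (edge attribute `weight`), the edge-weight table and the set of traits
#'   receiving direct genetic effects.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "gdag_sim_config"))
  dag <- causal_graph(config$edge_weights, nodes = config$trait_names)
  targets <- if (is.null(config$genetic_effects)) character(0) else
    unique(config$genetic_effects$trait)
  structure(list(dag = dag, weights = config$edge_weights,
                 instrument_targets = targets),
            class = "gdag_truth")
}

#' Simulate LD-block genotype dosages
#'
#' SNPs come in blocks of `block_size`. Within a block each SNP is generated
#' by thresholding a latent Gaussian — shared-factor correlated across the
#' block at `within_block_r` — at the quantiles of its Hardy-Weinberg dosage
#' distribution `Binomial(2, MAF)`, so marginals are exact and within-block
#' dosage correlation is tunable. Blocks are mutually independent.
#'
#' @param config a `gdag_sim_config`.
#' @return integer matrix (samples x SNPs, values 0/1/2) with sample IDs as
#'   rownames and SNP IDs as colnames; per-SNP MAFs in attribute `maf`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "gdag_sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_snps
  rho <- config$within_block_r
  blocks <- split(seq_len(p), ceiling(seq_len(p) / config$block_size))
  G <- matrix(0L, n, p,
              dimnames = list(sprintf("S%04d", seq_len(n)),
                              sprintf("snp%05d", seq_len(p))))
  maf <- numeric(p)
  for (idx in blocks) {
    shared <- stats::rnorm(n)
    for (j in idx) {
      maf[j] <- stats::runif(1, config$maf_range[1], config$maf_range[2])
      z <- sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n)
      # dosage thresholds reproduce Binomial(2, maf) marginals exactly
      q0 <- stats::qnorm((1 - maf[j])^2)
      q1 <- stats::qnorm(1 - maf[j]^2)
      G[, j] <- ifelse(z <= q0, 0L, ifelse(z <= q1, 1L, 2L))
    }
  }
  attr(G, "maf") <- stats::setNames(maf, colnames(G))
  G
}

#' Simulate traits from the structural equation model
#'
#' Traits are generated in topological order of the configured DAG:
#' each trait is the weighted sum of its parent traits, plus genetic effects
#' on standardized SNP dosages, plus independent Gaussian noise.
#'
#' @param genotypes matrix from [simulate_genotypes()] (may be `NULL` when
#'   the configuration has no genetic effects).
#' @param config the `gdag_sim_config` used for the genotypes.
#' @return a list with `traits` (numeric matrix, samples x traits) and
#'   `truth` (see [ground_truth()]).
#' @export
simulate_traits <- function(genotypes, config) {
  stopifnot(inherits(config, "gdag_sim_config"))
  truth <- ground_truth(config)
  n <- config$n_samples
  if (!is.null(genotypes)) stopifnot(nrow(genotypes) == n)
  set.seed(config$seed + 1L)
  gmat <- NULL
  ge <- config$genetic_effects
  if (!is.null(ge) && nrow(ge)) {
    if (is.null(genotypes)) stop("configuration has genetic effects but no genotypes given")
    gmat <- scale(genotypes[, ge$snp, drop = FALSE])
    mono <- which(apply(genotypes[, ge$snp, drop = FALSE], 2, stats::var) == 0)
    if (length(mono)) {
      warning("monomorphic causal SNP(s) contribute no genetic effect: ",
              paste(colnames(genotypes)[ge$snp[mono]], collapse = ", "))
      gmat[, mono] <- 0
    }
  }
  Y <- matrix(0, n, length(config$trait_names),
              dimnames = list(rownames(genotypes) %||% sprintf("S%04d", seq_len(n)),
                              config$trait_names))
  ew <- config$edge_weights
  for (tr in topo_order(truth$dag)) {
    y <- stats::rnorm(n, sd = config$noise_sd[[tr]])
    par_rows <- which(ew$target == tr)
    for (r in par_rows) y <- y + ew$weight[r] * Y[, ew$source[r]]
    if (!is.null(gmat)) {
      g_rows <- which(ge$trait == tr)
      # gmat has one column per genetic_effects row, in row order
      for (r in g_rows) y <- y + ge$effect[r] * gmat[, r]
    }
    Y[, tr] <- y
  }
  list(traits = Y, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic covariance of a linear-Gaussian structural equation model
#'
#' For the system `y = B'y + e` with `B[i, j]` the effect of node `i` on
#' node `j` and `e ~ N(0, diag(noise_sd^2))`, the covariance is
#' `(I - B')^{-1} D (I - B')^{-T}`.
#'
#' @param edges `data.frame` with `source`, `target`, `weight`.
#' @param nodes node names (defaults to those appearing in `edges`).
#' @param noise_sd scalar or named vector of residual standard deviations.
#' @return covariance matrix with dimnames `nodes`.
#' @export
sem_covariance <- function(edges, nodes = NULL, noise_sd = 1) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  nodes <- nodes %||% unique(c(edges$source, edges$target))
  k <- length(nodes)
  B <- matrix(0, k, k, dimnames = list(nodes, nodes))
  if (nrow(edges)) B[cbind(edges$source, edges$target)] <- edges$weight
  if (is.null(names(noise_sd)))
    noise_sd <- stats::setNames(rep_len(noise_sd, k), nodes)
  D <- diag(noise_sd[nodes]^2, k)
  Minv <- solve(diag(k) - t(B))
  S <- Minv %*% D %*% t(Minv)
  dimnames(S) <- list(nodes, nodes)
  S
}

#' Sample from a linear-Gaussian structural equation model
#'
#' Generic SEM sampler over arbitrary named nodes (instrument nodes
#' included), used by tests and benchmarks that bypass the genotype layer.
#'
#' @inheritParams sem_covariance
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return numeric matrix n x nodes.
#' @export
sem_sample <- function(n, edges, nodes = NULL, noise_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  nodes <- nodes %||% unique(c(edges$source, edges$target))
  if (is.null(names(noise_sd)))
    noise_sd <- stats::setNames(rep_len(noise_sd, length(nodes)), nodes)
  g <- causal_graph(edges, nodes = nodes)
  Y <- matrix(0, n, length(nodes), dimnames = list(NULL, nodes))
  for (v in topo_order(g)) {
    y <- stats::rnorm(n, sd = noise_sd[[v]])
    rows <- which(edges$target == v)
    for (r in rows) y <- y + edges$weight[r] * Y[, edges$source[r]]
    Y[, v] <- y
  }
  Y
}

#' Joint instrument + trait covariance implied by a configuration
#'
#' Builds the analytic covariance of the system in which each instrumented
#' trait receives a unit-variance composite instrument node (named
#' `IV_<trait>`) whose edge weight is the root-sum-square of that trait's
#' standardized genetic effects. Exact when each trait's causal SNPs are
#' mutually independent (distinct LD blocks), as in the built-in fixture.
#'
#' @param config a `gdag_sim_config` with genetic effects.
#' @return list with `sigma` (covariance matrix over instruments then
#'   traits) and `tiers` (named tier vector for [estimate_skeleton()]).
#' @export
oracle_covariance <- function(config) {
  stopifnot(inherits(config, "gdag_sim_config"))
  ge <- config$genetic_effects
  if (is.null(ge) || !nrow(ge)) stop("configuration has no genetic effects")
  gam <- vapply(split(ge$effect, ge$trait), function(e) sqrt(sum(e^2)), 0)
  iv_nodes <- paste0("IV_", names(gam))
  edges <- rbind(config$edge_weights[c("source", "target", "weight")],
                 data.frame(source = iv_nodes, target = names(gam),
                            weight = unname(gam), stringsAsFactors = FALSE))
  nodes <- c(iv_nodes, config$trait_names)
  noise <- c(stats::setNames(rep(1, length(iv_nodes)), iv_nodes),
             config$noise_sd)
  tiers <- stats::setNames(
    c(rep("instrument", length(iv_nodes)), rep("trait", length(config$trait_names))),
    nodes)
  list(sigma = sem_covariance(edges, nodes = nodes, noise_sd = noise),
       tiers = tiers)
}

#' Rank-based inverse normal transform
#'
#' Maps a numeric vector to normal scores via `qnorm((rank - 3/8)/(n + 1/4))`
#' (Blom offsets), the usual normalization for metabolite abundances whose
#' raw distributions are skewed. Ties share the average rank; `NA`s are kept.
#'
#' @param x numeric vector.
#' @return numeric vector of normal scores.
#' @export
int_transform <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  out
}

#' Write a simulated study to disk
#'
#' Emits the genotype TSV (rows = samples, header = SNP IDs), trait TSV,
#' ground-truth edge list TSV (`source`, `target`, `weight`) and the
#' configuration as JSON.
#'
#' @param dir output directory (created if needed).
#' @param genotypes,traits,truth,config pieces from [simulate_genotypes()]
#'   and [simulate_traits()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dir, genotypes, traits, truth, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_matrix(genotypes, file.path(dir, "genotypes.tsv"))
  write_tsv_matrix(traits, file.path(dir, "traits.tsv"))
  utils::write.table(truth$weights, file.path(dir, "truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(config)
  jsonlite::write_json(cfg, file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

write_tsv_matrix <- function(m, path) {
  df <- data.frame(sample = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
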