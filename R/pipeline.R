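#' Pipeline configuration
#'
#' Collects the file paths and tuning parameters of a full run. All
#' randomness in a run flows from the single `seed`. The configuration
#' serializes losslessly to JSON ([write_pipeline_config()],
#' [read_pipeline_config()]).
#'
#' @param genotype_file,trait_file input TSVs (rows = samples, first column
#'   sample ID); may be `NULL` when `sim` is given, in which case the study
#'   is simulated into `out_dir/sim/`.
#' @param out_dir output directory for run artifacts.
#' @param alpha significance level (instrument selection and CI tests).
#' @param r2_threshold LD-pruning threshold.
#' @param k_pcs candidate principal components.
#' @param max_cond maximum CI conditioning-set size.
#' @param seed integer master seed.
#' @param inverse_normal rank-based inverse normal transform of traits.
#' @param mode `"data"` (fit from data) or `"oracle"` (fit from the analytic
#'   covariance of `sim`; requires `sim`).
#' @param sim optional `gdag_sim_config`.
#' @return object of class `gdag_pipeline_config`.
#' @export
pipeline_config <- function(genotype_file = NULL, trait_file = NULL,
                            out_dir = "gdag_run", alpha = 0.001,
                            r2_threshold = 0.80, k_pcs = 50L, max_cond = Inf,
                            seed = 1L, inverse_normal = FALSE,
                            mode = c("data", "oracle"), sim = NULL) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha <= 1, r2_threshold > 0, r2_threshold <= 1,
            k_pcs >= 1, max_cond >= 0)
  if (mode == "oracle" && is.null(sim))
    stop("oracle mode requires a simulation configuration (`sim`)")
  if (!is.null(sim)) stopifnot(inherits(sim, "gdag_sim_config"))
  structure(list(genotype_file = genotype_file, trait_file = trait_file,
                 out_dir = out_dir, alpha = alpha,
                 r2_threshold = r2_threshold, k_pcs = as.integer(k_pcs),
                 max_cond = if (is.finite(max_cond)) as.integer(max_cond) else Inf,
                 seed = as.integer(seed),
                 inverse_normal = isTRUE(inverse_normal), mode = mode,
                 sim = sim),
            class = "gdag_pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `gdag_pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "gdag_pipeline_config"))
  x <- unclass(config)
  if (!is.null(x$sim)) x$sim <- unclass(x$sim)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(x$sim)) {
    s <- x$sim
    sim <- sim_config(n_samples = s$n_samples, n_snps = s$n_snps,
                      block_size = s$block_size, maf_range = s$maf_range,
                      within_block_r = s$within_block_r,
                      trait_names = s$trait_names,
                      edge_weights = as.data.frame(s$edge_weights),
                      genetic_effects =
                        if (is.null(s$genetic_effects)) NULL else
                          as.data.frame(s$genetic_effects),
                      noise_sd = unlist(s$noise_sd), seed = s$seed)
  }
  pipeline_config(genotype_file = x$genotype_file,
                  trait_file = x$trait_file, out_dir = x$out_dir,
                  alpha = x$alpha, r2_threshold = x$r2_threshold,
                  k_pcs = x$k_pcs, max_cond = as.numeric(x$max_cond),
                  seed = x$seed,
                  inverse_normal = x$inverse_normal, mode = x$mode,
                  sim = sim)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> LD prune -> PC instruments -> instrument
#' selection -> network learning -> instrument deletion -> network metrics
#' -> effect estimation, writing each artifact under `config$out_dir` and a
#' JSON run manifest recording package version, seed and a config hash. In
#' oracle mode the network is learned from the analytic covariance of the
#' simulated system instead of data (no effect table).
#'
#' @param config a `gdag_pipeline_config`.
#' @param quiet suppress progress messages.
#' @return the fitted `gdag` object, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "gdag_pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[gdagnet] ", ...)
  set.seed(config$seed)

  if (config$mode == "oracle") {
    say("oracle mode: learning from the analytic covariance")
    fit <- run_stage("learn", {
      oc <- oracle_covariance(config$sim)
      gdag_from_cov(oc$sigma, oc$tiers, max_cond = config$max_cond)
    })
    genotypes <- traits <- NULL
  } else {
    if (!is.null(config$sim) && (is.null(config$genotype_file) ||
                                 is.null(config$trait_file))) {
      say("simulating study data")
      sim_out <- run_stage("simulate", {
        g <- simulate_genotypes(config$sim)
        tt <- simulate_traits(g, config$sim)
        write_simulation(file.path(out, "sim"), g, tt$traits, tt$truth,
                         config$sim)
        list(genotypes = g, traits = tt$traits)
      })
      genotypes <- sim_out$genotypes
      traits <- sim_out$traits
    } else {
      say("reading inputs")
      genotypes <- run_stage("read", {
        if (is.null(config$genotype_file)) NULL else
          read_tsv_matrix(config$genotype_file)
      })
      traits <- run_stage("read", read_tsv_matrix(config$trait_file))
    }
    if (config$inverse_normal) traits <- apply(traits, 2L, int_transform)

    inst <- NULL
    if (!is.null(genotypes)) {
      pruned <- run_stage("prune",
                          ld_prune(genotypes, config$r2_threshold))
      say("LD pruning kept ", ncol(pruned), " of ", ncol(genotypes), " SNPs")
      writeLines(colnames(pruned), file.path(out, "pruned_snps.txt"))
      inst <- run_stage("instruments", {
        k <- min(config$k_pcs, nrow(pruned), ncol(pruned))
        select_instruments(compute_pcs(pruned, k = k), traits,
                           alpha = config$alpha)
      })
      say(length(inst$selected), " instrument PC(s) selected at alpha = ",
          config$alpha)
      write_tsv_matrix(inst$scores, file.path(out, "instrument_scores.tsv"))
      utils::write.table(inst$associations,
                         file.path(out, "instrument_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    fit <- run_stage("learn",
                     gdag(traits, instruments = inst, alpha = config$alpha,
                          max_cond = config$max_cond,
                          effects = FALSE))
    fit$effects <- run_stage("effects",
                             estimate_all_effects(traits, fit$trait_graph))
    fit$residual_sd <- node_residual_sd(traits, fit$trait_graph)
  }

  run_stage("write", {
    write_causal_graph(fit$graph, file.path(out, "two_tier_graph.tsv"))
    write_causal_graph(fit$graph, file.path(out, "two_tier_graph.graphml"))
    write_causal_graph(fit$trait_graph, file.path(out, "trait_graph.tsv"))
    write_causal_graph(fit$trait_graph, file.path(out, "trait_graph.graphml"))
    write_causal_graph(fit$trait_graph, file.path(out, "trait_graph.dot"))
    prov <- igraph::as_data_frame(fit$graph, what = "edges")
    names(prov)[1:2] <- c("source", "target")
    utils::write.table(prov, file.path(out, "orientation_provenance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    m <- fit$metrics
    names(m)[1L] <- "metabolite"
    utils::write.table(m, file.path(out, "metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(fit$effects)) {
      eff <- fit$effects
      names(eff)[names(eff) == "n_used"] <- "n"
      utils::write.table(eff, file.path(out, "effects.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  })

  cfg_path <- file.path(out, "config.json")
  write_pipeline_config(config, cfg_path)
  manifest <- list(
    package = "gdagnet",
    version = as.character(utils::packageVersion("gdagnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    mode = config$mode,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_traits = sum(graph_tiers(fit$graph) == "trait"),
    n_instruments = sum(graph_tiers(fit$graph) == "instrument"),
    n_trait_edges = igraph::ecount(fit$trait_graph))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("run complete: ", out)
  invisible(fit)
}
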