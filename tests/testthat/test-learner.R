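trait_tiers <- function(nms) stats::setNames(rep("trait", length(nms)), nms)

test_that("a causal chain yields the right skeleton and separating set", {
  edges <- data.frame(source = c("A", "B"), target = c("B", "C"),
                      weight = c(1, 1))
  Y <- sem_sample(5000, edges, seed = 41L)
  sk <- estimate_skeleton(Y, tiers = trait_tiers(colnames(Y)))
  adj <- sk$adjacency
  expect_true(adj["A", "B"] && adj["B", "C"])
  expect_false(adj["A", "C"])
  expect_identical(sk$sepsets[["A\tC"]], "B")
})

test_that("independent traits produce edges at roughly the test level", {
  set.seed(43)
  edge_counts <- replicate(30, {
    Y <- matrix(stats::rnorm(500 * 5), 500, 5,
                dimnames = list(NULL, LETTERS[1:5]))
    sum(estimate_skeleton(Y, tiers = trait_tiers(LETTERS[1:5]))$adjacency) / 2
  })
  # 10 pairs at alpha = 0.001: false edges should be rare
  expect_lt(mean(edge_counts), 0.2)
})

test_that("an instrumented exposure orients its downstream edge (MR core)", {
  edges <- data.frame(source = c("I1", "A"), target = c("A", "B"),
                      weight = c(0.6, 0.7))
  Y <- sem_sample(5000, edges, seed = 47L)
  tiers <- c(I1 = "instrument", A = "trait", B = "trait")
  sk <- estimate_skeleton(Y, tiers = tiers)
  expect_false(sk$adjacency["I1", "B"])  # I1 _||_ B given A
  g <- orient_edges(sk)
  el <- igraph::as_data_frame(g, what = "edges")
  expect_true(any(el$from == "A" & el$to == "B"))
  expect_identical(el$provenance[el$from == "A" & el$to == "B"], "meek")
  # and the same on the analytic covariance
  S <- sem_covariance(edges, nodes = c("I1", "A", "B"))
  fit <- gdag_from_cov(S, tiers)
  expect_identical(edge_keys(fit$trait_graph), "A->B")
})

test_that("an uninstrumented single edge falls back deterministically", {
  edges <- data.frame(source = "A", target = "B", weight = 1)
  S <- sem_covariance(edges, nodes = c("B", "A"))
  fit <- gdag_from_cov(S, trait_tiers(c("A", "B")))
  fb <- attr(fit$graph, "fallback_edges")
  expect_identical(nrow(fb), 1L)
  expect_identical(fb$source, "A")       # lexicographic tie-break
  el <- igraph::as_data_frame(fit$graph, what = "edges")
  expect_identical(el$provenance, "fallback")
})

test_that("oracle covariance recovers the fixture network exactly", {
  cfg <- fa_sim_config()
  oc <- oracle_covariance(cfg)
  fit <- gdag_from_cov(oc$sigma, oc$tiers)
  expect_identical(edge_keys(fit$trait_graph), true_fixture_edge_keys(cfg))
  expect_identical(nrow(attr(fit$graph, "conflicts")), 0L)
  expect_identical(nrow(attr(fit$graph, "fallback_edges")), 0L)
})

test_that("skeleton from the analytic covariance equals the true adjacency", {
  cfg <- fa_sim_config()
  oc <- oracle_covariance(cfg)
  sk <- estimate_skeleton(cov_matrix = oc$sigma, tiers = oc$tiers, n = Inf)
  tn <- cfg$trait_names
  got <- sk$adjacency[tn, tn]
  want <- matrix(FALSE, 15, 15, dimnames = list(tn, tn))
  want[cbind(cfg$edge_weights$source, cfg$edge_weights$target)] <- TRUE
  want <- want | t(want)
  expect_identical(got, want)
})

test_that("the learned graph is always acyclic and tier-consistent", {
  set.seed(53)
  for (rep in 1:8) {
    k <- sample(4:6, 1)
    edges <- random_dag_edges(k, p = 0.5)
    nodes <- sprintf("n%02d", seq_len(k))
    if (nrow(edges)) edges$weight <- stats::runif(nrow(edges), 0.4, 0.9)
    iv_on <- sample(nodes, 2L)
    all_edges <- rbind(edges,
                       data.frame(source = paste0("IV_", iv_on),
                                  target = iv_on, weight = 0.6))
    Y <- sem_sample(800, all_edges, nodes = c(paste0("IV_", iv_on), nodes))
    tiers <- stats::setNames(
      c(rep("instrument", 2L), rep("trait", k)), colnames(Y))
    g <- orient_edges(estimate_skeleton(Y, tiers = tiers, alpha = 0.01))
    expect_true(igraph::is_dag(g))
    expect_silent(validate_causal_graph(g))
  }
})

test_that("deleting instruments leaves the induced trait network intact", {
  g <- causal_graph(data.frame(source = c("PC1", "PC2", "A", "B"),
                               target = c("A", "B", "B", "C")),
                    tiers = c(PC1 = "instrument", PC2 = "instrument"))
  tg <- trait_subgraph(g)
  expect_identical(sort(igraph::V(tg)$name), c("A", "B", "C"))
  expect_identical(edge_keys(tg), c("A->B", "B->C"))

  only_inst <- causal_graph(nodes = c("PC1", "PC2"),
                            tiers = c(PC1 = "instrument", PC2 = "instrument"))
  expect_equal(igraph::vcount(trait_subgraph(only_inst)), 0)
})

test_that("without instruments fewer edges are determinately oriented", {
  cfg <- fa_sim_config()
  oc <- oracle_covariance(cfg)
  with_iv <- gdag_from_cov(oc$sigma, oc$tiers)
  n_det_iv <- sum(igraph::E(with_iv$trait_graph)$provenance != "fallback")

  S_traits <- sem_covariance(cfg$edge_weights, nodes = cfg$trait_names,
                             noise_sd = cfg$noise_sd)
  no_iv <- gdag_from_cov(S_traits, trait_tiers(cfg$trait_names))
  el <- igraph::as_data_frame(no_iv$graph, what = "edges")
  n_det_no <- sum(el$provenance != "fallback")
  expect_lt(n_det_no, n_det_iv)
})

test_that("structure recovery improves with sample size on the fixture", {
  sys <- fixture_joint_system()
  truth_keys <- true_fixture_edge_keys()
  f1_at <- function(n, reps, seed0) {
    vapply(seq_len(reps), function(r) {
      Y <- sem_sample(n, sys$edges, nodes = sys$nodes,
                      noise_sd = sys$noise, seed = seed0 + r)
      fit <- gdag(Y[, sys$traits], instruments = Y[, sys$iv],
                  effects = FALSE)
      got <- edge_keys(fit$trait_graph)
      tp <- sum(got %in% truth_keys)
      prec <- if (length(got)) tp / length(got) else 0
      rec <- tp / length(truth_keys)
      if (tp == 0) 0 else 2 * prec * rec / (prec + rec)
    }, 0)
  }
  f1 <- list(f1_at(500, 20, 100), f1_at(2000, 20, 200), f1_at(8000, 20, 300))
  mc_se <- function(a, b) sqrt(stats::var(a) / length(a) +
                                 stats::var(b) / length(b))
  # non-decreasing within 3 Monte-Carlo standard errors of the difference
  expect_gt(mean(f1[[2]]) - mean(f1[[1]]), -3 * mc_se(f1[[1]], f1[[2]]))
  expect_gt(mean(f1[[3]]) - mean(f1[[2]]), -3 * mc_se(f1[[2]], f1[[3]]))
  expect_gt(mean(f1[[3]]), 0.8)
})

test_that("tiny samples skip large conditioning sets with a warning", {
  Y <- matrix(stats::rnorm(3 * 3), 3, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_warning(estimate_skeleton(Y, tiers = trait_tiers(c("A", "B", "C"))),
                 "too small")
})
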