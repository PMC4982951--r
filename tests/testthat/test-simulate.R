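two_trait_config <- function(n, weight = 1, seed = 5L) {
  sim_config(n_samples = n, n_snps = 4L, block_size = 2L,
             trait_names = c("A", "B"),
             edge_weights = if (weight != 0)
               data.frame(source = "A", target = "B", weight = weight)
             else data.frame(source = character(), target = character(),
                             weight = numeric()),
             noise_sd = 1, seed = seed)
}

test_that("perfectly correlated latents give identical dosage columns in a block", {
  cfg <- sim_config(n_samples = 500, n_snps = 6L, block_size = 3L,
                    maf_range = c(0.3, 0.3), within_block_r = 1,
                    trait_names = "A",
                    edge_weights = data.frame(source = character(),
                                              target = character(),
                                              weight = numeric()),
                    seed = 3L)
  G <- simulate_genotypes(cfg)
  expect_identical(G[, 1L], G[, 2L])
  expect_identical(G[, 2L], G[, 3L])
  expect_identical(G[, 4L], G[, 6L])
})

test_that("independent latents give near-zero within-block dosage correlation", {
  cfg <- sim_config(n_samples = 4000, n_snps = 10L, block_size = 5L,
                    maf_range = c(0.2, 0.4), within_block_r = 0,
                    trait_names = "A",
                    edge_weights = data.frame(source = character(),
                                              target = character(),
                                              weight = numeric()),
                    seed = 4L)
  G <- simulate_genotypes(cfg)
  cc <- stats::cor(G[, 1:5])
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("dosage means match the binomial expectation 2*MAF", {
  cfg <- sim_config(n_samples = 20000, n_snps = 10L, block_size = 5L,
                    maf_range = c(0.3, 0.3), within_block_r = 0.5,
                    trait_names = "A",
                    edge_weights = data.frame(source = character(),
                                              target = character(),
                                              weight = numeric()),
                    seed = 8L)
  G <- simulate_genotypes(cfg)
  expect_true(all(abs(colMeans(G) - 0.6) < 0.02))
})

test_that("equal seeds reproduce the simulation byte-for-byte", {
  cfg <- fa_sim_config(n_samples = 200, seed = 21L)
  G1 <- simulate_genotypes(cfg); T1 <- simulate_traits(G1, cfg)
  G2 <- simulate_genotypes(cfg); T2 <- simulate_traits(G2, cfg)
  expect_identical(G1, G2)
  expect_identical(serialize(T1$traits, NULL), serialize(T2$traits, NULL))

  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_simulation(d1, G1, T1$traits, T1$truth, cfg)
  write_simulation(d2, G2, T2$traits, T2$truth, cfg)
  for (f in c("genotypes.tsv", "traits.tsv", "truth_edges.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("unlinked traits come out mutually independent", {
  cfg <- sim_config(n_samples = 6000, n_snps = 2L, block_size = 2L,
                    trait_names = c("A", "B", "C"),
                    edge_weights = data.frame(source = character(),
                                              target = character(),
                                              weight = numeric()),
                    seed = 9L)
  tt <- simulate_traits(NULL, cfg)
  cc <- stats::cor(tt$traits)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("a unit-weight edge reproduces the closed-form SEM covariance", {
  # A -> B with weight 1, unit noises: Var(B) = 2, corr(A, B) = 1/sqrt(2)
  cfg <- two_trait_config(20000)
  tt <- simulate_traits(NULL, cfg)
  A <- tt$traits[, "A"]; B <- tt$traits[, "B"]
  expect_equal(stats::var(B), 2, tolerance = 0.05)
  expect_equal(stats::cor(A, B), 1 / sqrt(2), tolerance = 0.03)

  S <- sem_covariance(cfg$edge_weights, nodes = c("A", "B"))
  expect_equal(S["B", "B"], 2)
  expect_equal(S["A", "B"] / sqrt(S["A", "A"] * S["B", "B"]), 1 / sqrt(2))
})

test_that("sample covariance converges to the analytic SEM covariance", {
  edges <- data.frame(source = c("w", "w", "x", "y"),
                      target = c("x", "y", "z", "z"),
                      weight = c(0.8, -0.5, 0.6, 0.7))
  n <- 8000
  Y <- sem_sample(n, edges, noise_sd = 1, seed = 31L)
  S_hat <- stats::cov(Y)
  S <- sem_covariance(edges, nodes = colnames(Y))
  # Monte-Carlo standard error of a covariance entry
  se <- sqrt((outer(diag(S), diag(S)) + S^2) / n)
  expect_true(all(abs(S_hat - S[colnames(Y), colnames(Y)]) < 3.5 * se))
})

test_that("the 15-metabolite fixture matches the published degree structure", {
  cfg <- fa_sim_config()
  truth <- ground_truth(cfg)
  m <- network_metrics(truth$dag)
  expect_equal(sum(m$out_degree), 29L)
  expect_equal(sum(m$in_degree), 29L)
  expect_equal(nrow(m), 15L)
  # published out-degrees, metabolite by metabolite
  pub_out <- c(Myristate = 3, Myristoleate = 1, Palmitate = 3,
               Palmitoleate = 5, Margarate = 5, Heptadecanoate = 1,
               Stearate = 2, Oleate = 3, Nonadecanoate = 2, Eicosenoate = 2,
               Linoleate = 0, Linolenate = 1, `Dihomo-linoleate` = 0,
               Decanoylcarnitine = 1, Laurylcarnitine = 0)
  expect_equal(stats::setNames(m$out_degree, m$node)[names(pub_out)],
               pub_out, ignore_attr = FALSE, tolerance = 0)
  # the two dietary sources block after 5 steps, at laurylcarnitine
  expect_equal(max_blocking_steps(truth$dag, "Palmitoleate"), 5L)
  expect_equal(max_blocking_steps(truth$dag, "Margarate"), 5L)
  expect_false("Myristate" %in% influence_set(truth$dag, "Margarate"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_samples = 0, n_snps = 10, trait_names = "A",
                          edge_weights = data.frame()), "n_samples")
  expect_error(two_trait_config(-5), "n_samples")
  cyc <- data.frame(source = c("A", "B"), target = c("B", "A"),
                    weight = c(1, 1))
  expect_error(sim_config(n_samples = 10, n_snps = 2,
                          trait_names = c("A", "B"), edge_weights = cyc),
               "acyclic")
  expect_error(sim_config(n_samples = 10, n_snps = 2, trait_names = "A",
                          edge_weights = data.frame(source = character(),
                                                    target = character(),
                                                    weight = numeric()),
                          genetic_effects = data.frame(snp = 9, trait = "A",
                                                       effect = 1)),
               "SNP indices")
})

test_that("the inverse normal transform yields normal scores and keeps order", {
  x <- c(5, 1, 3, NA, 2)
  z <- int_transform(x)
  expect_true(is.na(z[4]))
  expect_identical(order(z[-4]), order(x[-4]))
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-10)
})
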