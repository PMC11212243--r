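test_that("symmetric normalization divides weights by sqrt of the degree product", {
  # single unit edge: degrees 1 and 1
  net <- interaction_network(data.frame(a = "A", b = "B", w = 1))
  w <- normalize_network(net)
  expect_equal(w["A", "B"], 1)
  # star with 4 unit spokes: hub degree 4, spoke degree 1 -> 1/sqrt(4)
  star <- interaction_network(data.frame(a = "H", b = c("S1", "S2", "S3", "S4"),
                                         w = 1))
  ws <- normalize_network(star)
  expect_equal(unname(ws["H", "S1"]), 0.5)
  # no edges at all: zero operator with isolated nodes retained
  empty <- interaction_network(data.frame(a = character(), b = character(),
                                          w = numeric()),
                               nodes = c("A", "B"))
  expect_equal(sum(normalize_network(empty)), 0)
  expect_equal(dim(normalize_network(empty)), c(2L, 2L))
})

test_that("network constructor canonicalizes edges and rescales STRING confidences", {
  expect_message(
    net <- interaction_network(data.frame(a = c("A", "B"), b = c("B", "A"),
                                          w = c(900, 700))),
    "STRING")
  expect_equal(nrow(net$edges), 1L)   # duplicate pair collapsed
  expect_equal(net$edges$weight, 0.9) # max weight kept, rescaled
  expect_warning(interaction_network(data.frame(a = c("A", "A"),
                                                b = c("A", "B"),
                                                w = c(0.5, 0.5))),
                 "self-loop")
})

test_that("propagation matches the direct linear-solve oracle", {
  # 3-node path, single seed
  net <- path_network()
  f <- propagate(c(A = 1), net, alpha = 0.5, tol = 1e-12)
  expect_equal(f, propagate_oracle(net, c(A = 1), alpha = 0.5),
               tolerance = 1e-8)
  # random weighted networks up to 200 nodes, both normalizations
  set.seed(11)
  for (n in c(25, 200)) for (nrm in c("symmetric", "row")) {
    cfg <- sim_config(n_genes = n, n_disease_genes = 5,
                      edge_prob = 4 / n, module_factor = 8, rng_seed = n)
    truth <- list(genes = sprintf("G%05d", 1:n),
                  disease_genes = sprintf("G%05d", 1:5))
    rnet <- simulate_network(cfg, truth)
    seeds <- stats::setNames(rpois(20, 2) + 1, sample(truth$genes, 20))
    f1 <- propagate(seeds, rnet, alpha = 0.5, tol = 1e-12,
                    normalization = nrm)
    f2 <- propagate_oracle(rnet, seeds, alpha = 0.5, normalization = nrm)
    expect_equal(max(abs(f1 - f2)), 0, tolerance = 1e-8)
  }
})

test_that("propagation limits and symmetries behave as expected", {
  net <- path_network()
  # alpha near 0: scores approach the normalized seed vector
  f0 <- propagate(c(A = 2, C = 2), net, alpha = 1e-8)
  expect_equal(unname(f0[c("A", "C")]), c(0.5, 0.5), tolerance = 1e-6)
  # two symmetric nodes with equal seeds get equal scores
  two <- interaction_network(data.frame(a = "A", b = "B", w = 0.7))
  f2 <- propagate(c(A = 1, B = 1), two)
  expect_equal(unname(f2["A"]), unname(f2["B"]))
  # scores are non-negative and deterministic for fixed inputs
  expect_true(all(f2 >= 0))
  expect_identical(propagate(c(A = 1, B = 1), two),
                   propagate(c(A = 1, B = 1), two))
  # seeds off the network are dropped with a warning
  expect_warning(propagate(c(A = 1, ZZZ = 5), two), "dropped")
  expect_error(suppressWarnings(propagate(c(ZZZ = 1), two)), "seed")
  # non-convergence reports the residual
  expect_error(propagate(c(A = 1), net, alpha = 0.99, max_iter = 2),
               "converge")
})

test_that("null ensemble moments match exhaustive enumeration on a tiny network", {
  # 5 genes, 1 patient with 1 mutation: the null mean is the average of
  # the 5 single-seed propagation vectors
  edges <- data.frame(a = c("A", "B", "C", "D"), b = c("B", "C", "D", "E"),
                      w = c(0.9, 0.5, 0.7, 0.4))
  net <- interaction_network(edges)
  exact <- rowMeans(vapply(net$nodes, function(g)
    propagate(stats::setNames(1, g), net, tol = 1e-10),
    numeric(length(net$nodes))))
  profiles <- data.frame(sample_id = "s1", gene = "A")
  nul <- null_ensemble(profiles, net, n_null = 10000, rng_seed = 3)
  se <- nul$null_sd / sqrt(10000)
  expect_true(all(abs(nul$null_mean - exact[nul$gene]) <= 3 * se + 1e-12))
  expect_error(null_ensemble(profiles, net, n_null = 1), "at least 2")
})

test_that("null ensemble is reproducible for a fixed seed", {
  net <- path_network()
  profiles <- data.frame(sample_id = c("s1", "s1", "s2"),
                         gene = c("A", "B", "C"))
  n1 <- null_ensemble(profiles, net, n_null = 50, rng_seed = 9)
  n2 <- null_ensemble(profiles, net, n_null = 50, rng_seed = 9)
  expect_identical(n1, n2)
  n3 <- null_ensemble(profiles, net, n_null = 50, rng_seed = 10)
  expect_false(identical(n1$null_mean, n3$null_mean))
})

test_that("z-scores standardize against the null and sort descending", {
  obs <- c(g1 = 0.5, g2 = 0.2, g3 = 0.3)
  nul <- data.frame(gene = c("g1", "g2", "g3"),
                    null_mean = c(0.5, 0.1, 0.3),
                    null_sd = c(0.1, 0.05, 0))
  z <- zscore_genes(obs, nul)
  expect_equal(z$z[z$gene == "g1"], 0)
  expect_equal(z$z[z$gene == "g2"], 2)
  expect_true(is.na(z$z[z$gene == "g3"]))  # zero-SD gene flagged undefined
  expect_identical(z$gene[1], "g2")        # sorted by z descending
  # boundary: score = mean + 3 sd -> z = 3
  z3 <- zscore_genes(c(g1 = 0.8), data.frame(gene = "g1", null_mean = 0.5,
                                             null_sd = 0.1))
  expect_equal(z3$z, 3)
  expect_error(zscore_genes(c(gX = 1), nul), "missing")
})

test_that("scores drawn from the null mechanism are calibrated against the ensemble", {
  # observed profiles generated by the null's own law (every mutation on a
  # uniformly random gene): z should center on 0 and exceed 3 about as
  # rarely as the empirical null's own upper tail, stably across seeds
  excess <- matrix(NA_real_, 2, 25)
  means <- matrix(NA_real_, 2, 25)
  for (s in 1:2) {
    set.seed(c(21, 22)[s])
    for (r in 1:25) {
      cfg <- sim_config(n_samples = 60, n_genes = 60, n_disease_genes = 5,
                        fold = 1, module_factor = 1, edge_prob = 0.1,
                        rng_seed = sample.int(1e6, 1))
      sim <- simulate_cohort(cfg)
      net <- simulate_network(cfg, sim$truth)
      ufv <- suppressWarnings(
        ufv_filter(filter_rare_damaging(sim$variants), cfg$n_samples))
      profiles <- mutation_profiles(ufv)
      profiles$gene <- sample(net$nodes, nrow(profiles), replace = TRUE)
      obs <- suppressWarnings(propagate(seed_vector(profiles), net))
      nul <- null_ensemble(profiles, net, n_null = 300,
                           rng_seed = sample.int(1e6, 1))
      z <- zscore_genes(obs, nul)$z
      means[s, r] <- mean(z, na.rm = TRUE)
      excess[s, r] <- mean(z > 3, na.rm = TRUE)
    }
  }
  expect_lt(abs(mean(means)), 0.1)
  expect_lt(mean(excess[1, ]), 0.05)
  expect_lt(mean(excess[2, ]), 0.05)
  expect_lt(abs(mean(excess[1, ]) - mean(excess[2, ])), 0.03)
})

test_that("prioritization combines thresholds as recurrence AND/OR network", {
  rec <- data.frame(gene = c("both", "reconly", "netonly"),
                    n_ufv = c(4L, 5L, 3L), n_samples = c(4L, 5L, 3L))
  sc <- data.frame(gene = c("both", "reconly", "netonly"),
                   score = 1, null_mean = 0, null_sd = 1,
                   z = c(3.5, 2.9, 4))
  sets <- prioritize(rec, sc)
  expect_true(all(c("both") %in% sets$intersection))
  expect_setequal(sets$recurrence, c("both", "reconly"))
  expect_setequal(sets$network, c("both", "netonly"))
  expect_identical(sets$intersection, "both")
})
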