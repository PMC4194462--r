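test_that("network simulation is seeded and reproducible", {
  spec <- network_sim_spec(n_nodes = 150, target_cv = 1.5, target_cc = 0.05,
                           seed = 21)
  G1 <- suppressWarnings(simulate_network(spec, max_swaps = 500))
  G2 <- suppressWarnings(simulate_network(spec, max_swaps = 500))
  expect_identical(G1$adjacency, G2$adjacency)
})

test_that("simulated networks are simple with the requested heterogeneity", {
  spec <- network_sim_spec(n_nodes = 500, exponent = 2, target_cv = 2.86,
                           target_cc = 0.02, seed = 1)
  G <- suppressWarnings(simulate_network(spec))
  A <- G$adjacency
  expect_true(all(diag(A) == 0))
  expect_true(all(A %in% c(0, 1)))
  expect_true(isSymmetric(unname(A)))
  cv <- attr(G, "realized_cv")
  expect_gte(cv, 2.86 * 0.85)
  expect_lte(cv, 2.86 * 1.15)
})

test_that("simulated degree distributions have the requested tail slope", {
  spec <- network_sim_spec(n_nodes = 500, exponent = 2, target_cv = 2.86,
                           target_cc = 0.02, seed = 2)
  G <- suppressWarnings(simulate_network(spec))
  deg <- rowSums(G$adjacency)
  tab <- table(deg[deg > 0])
  k <- as.numeric(names(tab))
  # least-squares log-log fit over the populated head of the histogram
  # (sparse single-count tail bins would otherwise dominate the fit)
  keep <- as.numeric(tab) >= 3
  fit <- lm(log(as.numeric(tab[keep])) ~ log(k[keep]))
  expect_lt(abs(unname(coef(fit)[2]) - (-2)), 0.5)
})

test_that("embedded similarity matrices recover the planted graph exactly", {
  spec <- network_sim_spec(n_nodes = 80, target_cv = 1.5, target_cc = 0.05,
                           seed = 31)
  G <- suppressWarnings(simulate_network(spec, max_swaps = 300))
  S <- embed_similarity(G, tau_true = 0.6, delta = 0.05, seed = 32)
  expect_true(isSymmetric(unname(S)))
  expect_equal(unname(diag(S)), rep(1, 80))
  expect_identical(adjacency(S, 0.6)$adjacency, G$adjacency)

  ut <- upper.tri(S)
  edge <- G$adjacency[ut] == 1
  expect_gte(min(S[ut][edge]), 0.6)
  expect_lte(max(S[ut][!edge]), 0.6 - 0.05)
})

test_that("planted expression modules behave per relation", {
  # noiseless linear module: exact correlation
  E0 <- simulate_expression(6, 30,
                            modules = list(list(size = 4, relation = "linear")),
                            noise_sd = 0, seed = 41)
  expect_equal(apcc(E0[1, ], E0[2, ]), 1)

  # noisy linear module: high APCC
  E1 <- simulate_expression(10, 50,
                            modules = list(list(size = 6, relation = "linear")),
                            noise_sd = 0.05, seed = 42)
  S <- similarity_matrix(E1[1:6, ], "apcc")
  expect_gte(min(S[upper.tri(S)]), 0.9)

  # inverted module: sign-blind APCC still high
  E2 <- simulate_expression(6, 50,
                            modules = list(list(size = 4,
                                                relation = "inverted")),
                            noise_sd = 0.05, seed = 43)
  expect_gte(apcc(E2[1, ], E2[2, ]), 0.9)

  # quadratic module: carrier and squared gene disagree under APCC
  E3 <- simulate_expression(10, 120,
                            modules = list(list(size = 6,
                                                relation = "quadratic")),
                            noise_sd = 0.05, seed = 44)
  expect_lt(apcc(E3[1, ], E3[2, ]), 0.3)
  expect_gte(ncmi(E3[1, ], E3[2, ]), 0.5)

  # shifted module: NMRS sees through per-gene offsets and scales
  E4 <- simulate_expression(6, 50,
                            modules = list(list(size = 4,
                                                relation = "shifted")),
                            noise_sd = 0.02, seed = 45)
  expect_gte(nmrs(E4[1, ], E4[2, ]), 0.9)

  expect_identical(E1, simulate_expression(
    10, 50, modules = list(list(size = 6, relation = "linear")),
    noise_sd = 0.05, seed = 42))
  expect_equal(attr(E1, "modules"), c(rep(1L, 6), rep(0L, 4)))
})

test_that("simulated annotations drive the annotation-aware metrics", {
  # two module-cliques with fully enriched annotations: AsG = 1
  A <- rbind(cbind(graph_complete(4), matrix(0, 4, 4)),
             cbind(matrix(0, 4, 4), graph_complete(4)))
  rownames(A) <- colnames(A) <- paste0("g", 1:8)
  ann <- simulate_annotations(rownames(A), module_assignments = rep(1:2, each = 4),
                              enrichment = 1, seed = 51)
  labels <- vapply(ann$go, `[`, character(1), 1)
  expect_equal(assortativity_label(A, labels), 1)

  # single module, full enrichment: degenerate single label
  ann1 <- simulate_annotations(paste0("g", 1:4),
                               module_assignments = rep(1L, 4),
                               enrichment = 1, seed = 52)
  expect_warning(r <- assortativity_label(graph_complete(4),
                                          vapply(ann1$go, `[`, character(1), 1)),
                 "single label")
  expect_equal(r, 0)

  # no immunity genes: degenerate flag class
  ann0 <- simulate_annotations(paste0("g", 1:4), immunity_fraction = 0,
                               seed = 53)
  expect_warning(ki <- degree_domain_correlation(graph_path(4), ann0$immunity),
                 "single flag class")
  expect_equal(ki, 0)

  # degree-biased immunity flags plant a positive degree correlation
  spec <- network_sim_spec(n_nodes = 200, target_cv = 2, target_cc = 0.05,
                           seed = 54)
  G <- suppressWarnings(simulate_network(spec, max_swaps = 300))
  deg <- rowSums(G$adjacency)
  annb <- simulate_annotations(rownames(G$adjacency), immunity_fraction = 0.3,
                               degree_bias = deg, seed = 55)
  expect_gt(suppressWarnings(degree_domain_correlation(G, annb$immunity)), 0.1)
})

test_that("threshold recovery is seeded and accurate on heterogeneous graphs", {
  spec <- network_sim_spec(n_nodes = 300, target_cv = 2.86, target_cc = 0.02,
                           seed = 1)
  r1 <- recovery_experiment(spec, tau_true = 0.5, n_reps = 4, seed = 61,
                            max_swaps = 1000)
  r2 <- recovery_experiment(spec, tau_true = 0.5, n_reps = 4, seed = 61,
                            max_swaps = 1000)
  expect_identical(r1$pairs, r2$pairs)
  expect_equal(r1$eta, mean(abs(r1$pairs$tau_hat - r1$pairs$tau_true)))
  expect_lte(r1$eta, 0.02)
})

test_that("recovery error does not worsen as the similarity gap grows", {
  spec <- network_sim_spec(n_nodes = 200, target_cv = 2.5, target_cc = 0.05,
                           seed = 2)
  etas <- vapply(c(0.01, 0.05, 0.1), function(delta) {
    recovery_experiment(spec, tau_true = 0.5, n_reps = 5, seed = 71,
                        delta = delta, max_swaps = 500)$eta
  }, numeric(1))
  expect_true(all(diff(etas) <= 1e-9))
})

test_that("replicate budgets pool evenly over the true-threshold grid", {
  spec <- network_sim_spec(n_nodes = 150, target_cv = 2, target_cc = 0.05,
                           seed = 3)
  r <- recovery_validation(spec, tau_grid = c(0.4, 0.6), n_reps_total = 5,
                           seed = 81, max_swaps = 300)
  expect_equal(nrow(r$pairs), 5)
  expect_equal(sum(r$pairs$tau_true == 0.4), 3)
  expect_equal(sum(r$pairs$tau_true == 0.6), 2)
})
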