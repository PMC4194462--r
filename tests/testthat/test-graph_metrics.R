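test_that("density matches hand-worked graphs and the oracle", {
  expect_equal(network_density(graph_complete(4)), 1)
  expect_equal(network_density(graph_path(3)), 2 / 3)
  A5 <- graph_path(5) # 5 nodes, 4 edges
  expect_equal(network_density(A5), 0.4)
  expect_error(network_density(matrix(0, 1, 1)), "fewer than 2")
  for (A in atlas_adjacencies()) {
    if (nrow(A) < 2) next
    expect_equal(network_density(A), oracle_density(A))
  }
})

test_that("heterogeneity is the population CV of the degree", {
  expect_equal(degree_heterogeneity(graph_cycle(6)), 0)
  expect_equal(degree_heterogeneity(graph_star(3)),
               sqrt(mean((c(3, 1, 1, 1) - 1.5)^2)) / 1.5)
  expect_equal(degree_heterogeneity(graph_path(4)), 0.5 / 1.5)
  expect_error(degree_heterogeneity(matrix(0, 3, 3)), "mean degree")
})

test_that("betweenness centralization matches hand-worked graphs", {
  expect_equal(betweenness_centralization(graph_star(5)), 1)
  expect_equal(betweenness_centralization(graph_cycle(5)), 0)
  expect_equal(betweenness_centralization(graph_path(4)), 4 / 9)
  # disconnected input falls back to the largest component
  A <- rbind(cbind(graph_path(4), matrix(0, 4, 2)),
             matrix(0, 2, 6))
  A[5, 6] <- A[6, 5] <- 1
  rownames(A) <- colnames(A) <- paste0("g", 1:6)
  expect_warning(cen <- betweenness_centralization(A), "largest component")
  expect_equal(cen, 4 / 9)
})

test_that("centralization agrees with the brute-force oracle on small graphs", {
  for (A in atlas_adjacencies()) {
    if (nrow(A) < 3) next
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      A, mode = "undirected"))
    if (comp$no > 1) next # oracle defined on connected graphs
    expect_equal(betweenness_centralization(A), oracle_centralization(A))
  }
})

test_that("label assortativity hits the closed-form extremes", {
  # two disjoint same-label triangles: perfectly assortative
  A <- rbind(cbind(graph_triangle(), matrix(0, 3, 3)),
             cbind(matrix(0, 3, 3), graph_triangle()))
  rownames(A) <- colnames(A) <- paste0("g", 1:6)
  expect_equal(assortativity_label(A, rep(c("A", "B"), each = 3)), 1)

  # complete bipartite K2,2 labeled by side: perfectly disassortative
  K22 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  K22[1:2, 3:4] <- 1
  K22 <- K22 + t(K22)
  expect_equal(assortativity_label(K22, c("L", "L", "R", "R")), -1)

  # 4-cycle labeled A,A,B,B: e_ii equals a_i b_i, coefficient 0
  expect_equal(assortativity_label(graph_cycle(4), c("A", "A", "B", "B")), 0)

  expect_warning(r <- assortativity_label(graph_triangle(), rep("A", 3)),
                 "single label")
  expect_equal(r, 0)
})

test_that("label assortativity agrees with igraph on random labeled graphs", {
  set.seed(23)
  for (rep in 1:20) {
    A <- random_adjacency(12, 0.3, seed = 500 + rep)
    if (sum(A) == 0) next
    labels <- sample(c("x", "y", "z"), 12, replace = TRUE)
    if (length(unique(labels)) < 2) next
    ref <- igraph::assortativity_nominal(
      igraph::graph_from_adjacency_matrix(A, mode = "undirected"),
      as.integer(factor(labels)))
    if (!is.finite(ref)) next
    expect_equal(assortativity_label(A, labels), ref, tolerance = 1e-12)
  }
})

test_that("attack tolerance matches hand-worked graphs", {
  expect_equal(attack_tolerance(graph_complete(5)), 1)
  expect_equal(attack_tolerance(graph_star(5)), 0) # hub removal isolates all
  # path a-b-c-d: remove b (degree tie with c, lexicographic), L = 10/6 -> 1
  expect_equal(attack_tolerance(graph_path(4)), 5 / 3)
})

test_that("attack tolerance tie-break is lexicographic on node ids", {
  # path d-c-b-a by id: inner nodes b, c tie at degree 2; b removed first
  A <- graph_path(4)
  rownames(A) <- colnames(A) <- c("d", "c", "b", "a")
  # same topology, same result regardless of storage order of the tie
  expect_equal(attack_tolerance(A), 5 / 3)
})

test_that("degree-domain correlation is the point-biserial correlation", {
  # hubs a,b joined to each other and to both of c,d: degrees (3,3,2,2),
  # flags matching the high-degree class exactly (zero within-class variance)
  A <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  A["a", "b"] <- A["a", "c"] <- A["a", "d"] <- A["b", "c"] <- A["b", "d"] <- 1
  A <- A + t(A) # degrees a=3, b=3, c=2, d=2: zero within-class variance
  expect_equal(degree_domain_correlation(A, c(1, 1, 0, 0)), 1)

  expect_warning(r <- degree_domain_correlation(graph_cycle(4), c(1, 0, 1, 0)),
                 "zero degree variance")
  expect_equal(r, 0)
  expect_warning(r2 <- degree_domain_correlation(graph_path(4), c(1, 1, 1, 1)),
                 "single flag class")
  expect_equal(r2, 0)

  # hand point-biserial on degrees (3,2,2,1), flags (1,0,1,0)
  P <- graph_path(4)
  P["a", "c"] <- P["c", "a"] <- 1 # degrees a=2,b=2,c=3,d=1
  deg <- c(2, 2, 3, 1)
  flags <- c(0, 1, 1, 0)
  expect_equal(degree_domain_correlation(P, flags), cor(deg, flags))
})

test_that("characterize composes the eight variables with conventions", {
  ann <- annotation_table(c("a", "b", "c"),
                          go = list("GO:1", "GO:1", "GO:1"),
                          pfam = list("PF1", "PF1", "PF1"),
                          immunity = c(FALSE, FALSE, FALSE))
  row <- suppressMessages(
    characterize(gcn(graph_triangle()), ann, network_id = "tri"))
  expect_equal(row$CC, 1)
  expect_equal(row$Den, 1)
  expect_equal(row$Het, 0)
  expect_equal(row$Cen, 0)
  expect_equal(row$AsG, 0) # single label, warned convention
  expect_equal(row$AsP, 0)
  expect_equal(row$Tol, 1)
  expect_equal(row$KI, 0) # single flag class, warned convention
  expect_equal(row$n_nodes, 3)
  expect_equal(row$n_edges, 3)

  # deterministic rerun
  row2 <- suppressMessages(
    characterize(gcn(graph_triangle()), ann, network_id = "tri"))
  expect_identical(row, row2)
})

test_that("characterization rows respect the variable ranges", {
  set.seed(41)
  for (rep in 1:5) {
    A <- random_adjacency(25, 0.2, seed = 700 + rep)
    if (any(rowSums(A) == 0)) {
      keep <- rowSums(A) > 0
      A <- A[keep, keep]
    }
    ann <- simulate_annotations(rownames(A), seed = rep,
                                immunity_fraction = 0.3)
    row <- suppressMessages(suppressWarnings(
      characterize(gcn(A), ann, network_id = paste0("r", rep))))
    expect_true(row$CC >= 0 && row$CC <= 1)
    expect_true(row$Den >= 0 && row$Den <= 1)
    expect_gte(row$Het, 0)
    expect_true(row$Cen >= 0 && row$Cen <= 1)
    expect_true(row$AsG >= -1 && row$AsG <= 1)
    expect_true(row$AsP >= -1 && row$AsP <= 1)
    expect_gte(row$Tol, 0)
    expect_true(row$KI >= -1 && row$KI <= 1)
  }
})

test_that("all eight variables are invariant under node relabeling", {
  set.seed(43)
  A <- random_adjacency(15, 0.3, seed = 99)
  keep <- rowSums(A) > 0
  A <- A[keep, keep]
  ann <- simulate_annotations(rownames(A), seed = 3, immunity_fraction = 0.4)
  perm <- sample(nrow(A))
  B <- A[perm, perm]
  r1 <- suppressMessages(suppressWarnings(characterize(gcn(A), ann, "x")))
  r2 <- suppressMessages(suppressWarnings(characterize(gcn(B), ann, "x")))
  vars <- c("CC", "Cen", "Het", "Den", "AsG", "AsP", "Tol", "KI")
  expect_equal(r1[, vars], r2[, vars])
})

test_that("the size diagnostic separates size-free from size-driven variables", {
  # clustering and heterogeneity are targeted by the generator independently
  # of network size, so their size correlation is weak; density scales as
  # mean_degree / (N - 1) at fixed degree distribution, and the diagnostic
  # must flag that structural dependence
  set.seed(97)
  sizes <- rep(c(50, 100, 150, 200, 300, 400), 2)
  cvs <- sample(seq(1.2, 2.8, by = 0.2), 12, replace = TRUE)
  ccs <- sample(seq(0.03, 0.2, by = 0.01), 12, replace = TRUE)
  rows <- lapply(seq_along(sizes), function(i) {
    spec <- network_sim_spec(n_nodes = sizes[i], target_cv = cvs[i],
                             target_cc = ccs[i], seed = 60 + i)
    G <- suppressWarnings(simulate_network(spec, max_swaps = 500))
    A <- G$adjacency
    keep <- rowSums(A) > 0
    G <- gcn(A[keep, keep, drop = FALSE])
    ann <- simulate_annotations(rownames(G$adjacency), seed = i,
                                immunity_fraction = 0.3,
                                degree_bias = rowSums(G$adjacency))
    suppressMessages(suppressWarnings(
      characterize(G, ann, network_id = paste0("n", i))))
  })
  Tm <- characterization_matrix(rows)
  cors <- suppressWarnings(variable_size_correlation(Tm, Tm$meta$n_nodes))
  expect_lte(abs(cors[["CC"]]), 0.5)
  expect_lte(abs(cors[["Het"]]), 0.5)
  expect_lt(cors[["Den"]], -0.5)
})
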