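#' Network density
#'
#' Fraction of realized edges, `2 E / (N (N - 1))`, over the network's own
#' node set.
#'
#' @param G a `gcn`, adjacency matrix, or igraph graph.
#' @return density in `[0, 1]`.
#' @export
network_density <- function(G) {
  A <- as_adjacency_gcn(G)
  n <- nrow(A)
  if (n < 2L) stop("density undefined for fewer than 2 nodes")
  sum(A) / (n * (n - 1))
}

#' Degree heterogeneity
#'
#' Coefficient of variation of the node degree: population standard
#' deviation of degrees divided by the mean degree. Zero for regular graphs,
#' large for scale-free-like topologies dominated by hubs.
#'
#' @param G a `gcn`, adjacency matrix, or igraph graph.
#' @return heterogeneity `>= 0`.
#' @export
degree_heterogeneity <- function(G) {
  k <- igraph::degree(as_igraph_gcn(G))
  m <- mean(k)
  if (m == 0) stop("mean degree is zero")
  sqrt(mean((k - m)^2)) / m
}

#' Betweenness centralization
#'
#' Freeman centralization of the pair-normalized betweenness: how dominated
#' the network is by the node that participates in the most shortest paths.
#' `sum(b_max - b_i) / (N - 1)` with `b_i` the betweenness of node i
#' normalized by the number of pairs it could connect. 1 for a star, 0 for
#' vertex-transitive graphs such as cycles or cliques. Disconnected inputs
#' are reduced to their largest component with a warning.
#'
#' @param G a `gcn`, adjacency matrix, or igraph graph.
#' @return centralization in `[0, 1]`.
#' @export
betweenness_centralization <- function(G) {
  g <- .largest_component(as_igraph_gcn(G), "centralization")
  n <- igraph::vcount(g)
  if (n < 3L) stop("centralization needs at least 3 nodes")
  b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  sum(max(b) - b) / (n - 1)
}

.largest_component <- function(g, what) {
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning(what, " computed on largest component (input disconnected)")
    g <- igraph::induced_subgraph(
      g, which(comp$membership == which.max(comp$csize)))
  }
  g
}

#' Nominal label assortativity
#'
#' Newman's assortativity coefficient for categorical node labels:
#' `r = (sum_i e_ii - sum_i a_i b_i) / (1 - sum_i a_i b_i)` over the edge
#' mixing matrix e (fraction of edge ends joining each pair of label
#' classes). +1 when every edge joins same-label nodes, negative for
#' disassortative mixing (-1 for a complete bipartite label split). Used to
#' quantify whether co-expressed genes share functional annotations (GO,
#' PFAM).
#'
#' @param G a `gcn`, adjacency matrix, or igraph graph.
#' @param labels one categorical label per network node.
#' @return assortativity in `[-1, 1]`; 0 with a warning when all nodes share
#'   one label (undefined denominator) or the network has no edges.
#' @export
assortativity_label <- function(G, labels) {
  A <- as_adjacency_gcn(G)
  n <- nrow(A)
  stopifnot(length(labels) == n)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2L) {
    warning("single label on all nodes; assortativity = 0")
    return(0)
  }
  ut <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  if (nrow(ut) == 0L) {
    warning("no edges; assortativity = 0")
    return(0)
  }
  li <- factor(labels[ut[, 1L]], levels = lev)
  lj <- factor(labels[ut[, 2L]], levels = lev)
  # each undirected edge contributes both orientations
  e <- (table(li, lj) + table(lj, li)) / (2 * nrow(ut))
  a <- rowSums(e)
  s <- sum(a * a)
  if (1 - s == 0) {
    warning("degenerate mixing matrix; assortativity = 0")
    return(0)
  }
  (sum(diag(e)) - s) / (1 - s)
}

#' Tolerance to targeted hub attacks
#'
#' Simulates directed perturbations (e.g. pathogen effectors targeting hub
#' proteins) by removing, in a single batch, the `ceiling(f N)` nodes of
#' highest degree (ties broken lexicographically by node id). Tolerance is
#' the ratio `L(G) / L(G')` of the mean shortest-path length over the
#' largest component before and after the attack: values near 1 mean path
#' lengths are unaffected, below 1 mean the network disintegrates into
#' longer paths, and 0 is returned when fewer than 2 nodes remain connected.
#' Disconnected inputs are reduced to their largest component with a
#' warning.
#'
#' @param G a `gcn`, adjacency matrix, or igraph graph.
#' @param attack_fraction fraction of nodes to remove (default 0.05).
#' @return tolerance `>= 0`.
#' @export
attack_tolerance <- function(G, attack_fraction = 0.05) {
  stopifnot(attack_fraction > 0, attack_fraction < 1)
  g <- .largest_component(as_igraph_gcn(G), "attack tolerance")
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  L0 <- igraph::mean_distance(g, directed = FALSE)
  deg <- igraph::degree(g)
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))
  victims <- order(-deg, ids)[seq_len(ceiling(attack_fraction * n))]
  g2 <- igraph::delete_vertices(g, victims)
  comp <- igraph::components(g2)
  if (comp$no == 0L || max(comp$csize) < 2L) return(0)
  g2 <- igraph::induced_subgraph(
    g2, which(comp$membership == which.max(comp$csize)))
  L1 <- igraph::mean_distance(g2, directed = FALSE)
  L0 / L1
}

#' Correlation between node degree and a boolean domain flag
#'
#' Point-biserial (Pearson) correlation between node degree and a 0/1 flag,
#' e.g. the presence of immunity-associated protein domains (NBS, LRR,
#' kinase, WRKY). Positive values mean hubs are enriched for flagged genes.
#'
#' @param G a `gcn`, adjacency matrix, or igraph graph.
#' @param flags logical (or 0/1) vector, one per network node.
#' @return correlation in `[-1, 1]`; 0 with a warning when only one flag
#'   class is present or degree variance is zero.
#' @export
degree_domain_correlation <- function(G, flags) {
  k <- igraph::degree(as_igraph_gcn(G))
  stopifnot(length(flags) == length(k))
  f <- as.numeric(as.logical(flags))
  if (length(unique(f)) < 2L) {
    warning("single flag class; degree-domain correlation = 0")
    return(0)
  }
  if (var(k) == 0) {
    warning("zero degree variance; degree-domain correlation = 0")
    return(0)
  }
  cor(k, f)
}

# one categorical label per node: the node's most frequent term within the
# network (frequency counted across all nodes), ties broken lexicographically
.dominant_labels <- function(term_sets) {
  counts <- table(unlist(term_sets))
  vapply(term_sets, function(terms) {
    if (length(terms) == 0L) return("unannotated")
    terms <- sort(unique(terms))
    terms[which.max(counts[terms])]
  }, character(1))
}

#' Characterize a network with the eight graph variables
#'
#' Computes one row of the networks-by-variables characterization table:
#' clustering coefficient (CC), betweenness centralization (Cen), degree
#' heterogeneity (Het), density (Den), GO- and PFAM-label assortativity
#' (AsG, AsP), attack tolerance (Tol) and the degree-immunity correlation
#' (KI), plus metadata. For the assortativity coefficients, each node's
#' GO/PFAM term set is reduced to a single categorical label: its most
#' frequent term within the network (ties lexicographic), `"unannotated"`
#' when empty. Genes absent from the annotation table get empty term sets
#' and a false immunity flag.
#'
#' @param G a `gcn`, adjacency matrix, or igraph graph.
#' @param ann an [annotation_table()] covering (some of) the network's genes,
#'   or `NULL` for no annotations.
#' @param network_id identifier for the network.
#' @param species,stress_group metadata labels carried into the row.
#' @param attack_fraction passed to [attack_tolerance()].
#' @return one-row data frame with metadata and the eight variables.
#' @export
characterize <- function(G, ann = NULL, network_id = "net",
                         species = NA_character_,
                         stress_group = NA_character_,
                         attack_fraction = 0.05) {
  A <- as_adjacency_gcn(G)
  ids <- rownames(A)
  n <- length(ids)
  if (is.null(ann)) {
    ann <- annotation_table(ids)
  }
  idx <- match(ids, ann$gene_id)
  go <- pfam <- replicate(n, character(0), simplify = FALSE)
  imm <- rep(FALSE, n)
  found <- !is.na(idx)
  go[found] <- ann$go[idx[found]]
  pfam[found] <- ann$pfam[idx[found]]
  imm[found] <- ann$immunity[idx[found]]

  quiet <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      .log_msg("characterize(", network_id, "): ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  data.frame(
    network_id = network_id, species = species, stress_group = stress_group,
    n_nodes = n, n_edges = sum(A) / 2,
    CC = observed_clustering(G),
    Cen = quiet(betweenness_centralization(G)),
    Het = degree_heterogeneity(G),
    Den = network_density(G),
    AsG = quiet(assortativity_label(G, .dominant_labels(go))),
    AsP = quiet(assortativity_label(G, .dominant_labels(pfam))),
    Tol = quiet(attack_tolerance(G, attack_fraction)),
    KI = quiet(degree_domain_correlation(G, imm)),
    stringsAsFactors = FALSE
  )
}
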