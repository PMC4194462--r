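# Brute-force graph oracles, independent of the package implementation and
# of igraph. All operate on binary adjacency matrices.

oracle_clustering <- function(A) {
  n <- nrow(A)
  coefs <- numeric(0)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k > 1) {
      d <- 0
      for (a in seq_len(k - 1)) {
        for (b in (a + 1):k) {
          d <- d + A[nb[a], nb[b]]
        }
      }
      coefs <- c(coefs, 2 * d / (k * (k - 1)))
    }
  }
  if (length(coefs) == 0) 0 else mean(coefs)
}

oracle_density <- function(A) {
  n <- nrow(A)
  sum(A[upper.tri(A)]) / (n * (n - 1) / 2)
}

# all-pairs shortest-path distances by Floyd-Warshall
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

# geodesic counts: N[s, t] = number of shortest s-t paths
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  N <- matrix(0, n, n)
  diag(N) <- 1
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || is.infinite(D[s, t])) next
      pred <- which(A[, t] == 1 & D[s, ] == D[s, t] - 1)
      N[s, t] <- sum(N[s, pred])
    }
  }
  N
}

# betweenness of every node (undirected; each unordered pair once)
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  N <- oracle_path_counts(A, D)
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || is.infinite(D[s, t])) next
        if (D[s, v] + D[v, t] == D[s, t]) {
          b[v] <- b[v] + N[s, v] * N[v, t] / N[s, t]
        }
      }
    }
  }
  b
}

oracle_centralization <- function(A) {
  n <- nrow(A)
  b <- oracle_betweenness(A) / ((n - 1) * (n - 2) / 2)
  sum(max(b) - b) / (n - 1)
}

# simple Erdos-Renyi adjacency matrix
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  rownames(A) <- colnames(A) <- paste0("g", seq_len(n))
  A
}

# all 156 + 52 simple graphs on <= 6 nodes from the igraph atlas
atlas_adjacencies <- function() {
  lapply(0:208, function(i) {
    g <- igraph::graph_from_atlas(i)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    if (nrow(A) > 0) rownames(A) <- colnames(A) <- paste0("g", seq_len(nrow(A)))
    A
  })
}

# named small graphs used across tests
graph_triangle <- function() {
  A <- matrix(1, 3, 3) - diag(3)
  rownames(A) <- colnames(A) <- c("a", "b", "c")
  A
}

graph_path <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  rownames(A) <- colnames(A) <- letters[seq_len(n)]
  A
}

graph_star <- function(leaves) {
  A <- matrix(0, leaves + 1, leaves + 1)
  A[1, -1] <- A[-1, 1] <- 1
  rownames(A) <- colnames(A) <- c("hub", paste0("l", seq_len(leaves)))
  A
}

graph_cycle <- function(n) {
  A <- graph_path(n)
  A[1, n] <- A[n, 1] <- 1
  A
}

graph_complete <- function(n) {
  A <- matrix(1, n, n) - diag(n)
  rownames(A) <- colnames(A) <- letters[seq_len(n)]
  A
}
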