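#' Gene co-expression network objects
#'
#' A `gcn` wraps a binary, symmetric adjacency matrix with zero diagonal,
#' plus the similarity threshold (`tau_star`) that produced it, if any.
#'
#' @param A binary symmetric numeric matrix with zero diagonal; rownames are
#'   gene ids (generated if absent).
#' @param tau_star optional similarity threshold used to build the network.
#' @return object of class `gcn`.
#' @export
gcn <- function(A, tau_star = NULL) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (any(A != 0 & A != 1)) stop("adjacency must be binary")
  if (!isSymmetric(unname(A))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have zero diagonal")
  if (is.null(rownames(A))) {
    rownames(A) <- colnames(A) <- paste0("g", seq_len(nrow(A)))
  }
  colnames(A) <- rownames(A)
  structure(list(adjacency = A, tau_star = tau_star), class = "gcn")
}

#' @export
print.gcn <- function(x, ...) {
  A <- x$adjacency
  cat("Gene co-expression network:", nrow(A), "nodes,",
      sum(A[upper.tri(A)]), "edges")
  if (!is.null(x$tau_star)) cat(", tau* =", x$tau_star)
  cat("\n")
  invisible(x)
}

#' Coerce a network to its adjacency matrix / an igraph graph
#'
#' @param G a `gcn`, a binary adjacency matrix, or an igraph graph.
#' @return `as_adjacency_gcn`: binary adjacency matrix with gene dimnames;
#'   `as_igraph_gcn`: undirected igraph graph.
#' @export
as_adjacency_gcn <- function(G) {
  if (inherits(G, "gcn")) return(G$adjacency)
  if (inherits(G, "igraph")) {
    A <- as.matrix(igraph::as_adjacency_matrix(G))
    A[A > 1] <- 1
    if (is.null(rownames(A))) {
      rownames(A) <- colnames(A) <- paste0("g", seq_len(nrow(A)))
    }
    return(A)
  }
  gcn(G)$adjacency
}

#' @rdname as_adjacency_gcn
#' @export
as_igraph_gcn <- function(G) {
  if (inherits(G, "igraph")) return(G)
  A <- as_adjacency_gcn(G)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

#' Threshold a similarity matrix into a network
#'
#' The adjacency function: genes i and j are joined by an edge exactly when
#' their similarity `s_ij >= tau` (ties included). Self-loops are excluded.
#'
#' @param S symmetric similarity matrix in `[0, 1]`.
#' @param tau similarity threshold in `(0, 1]`.
#' @return a [gcn] with `tau_star = tau`.
#' @export
adjacency <- function(S, tau) {
  stopifnot(is.matrix(S), tau > 0, tau <= 1)
  A <- (S >= tau) * 1
  diag(A) <- 0
  gcn(A, tau_star = tau)
}

#' Observed (average) clustering coefficient
#'
#' The mean of the node clustering coefficients `2 D_i / (k_i (k_i - 1))`
#' over the K nodes with degree `k_i > 1`, where `D_i` counts edges among the
#' neighbors of node i. Returns 0 when no node has degree above 1.
#'
#' @param G a `gcn`, adjacency matrix, or igraph graph.
#' @return clustering coefficient C in `[0, 1]`.
#' @export
observed_clustering <- function(G) {
  g <- as_igraph_gcn(G)
  .observed_clustering_igraph(g)
}

.observed_clustering_igraph <- function(g) {
  deg <- igraph::degree(g)
  eligible <- deg > 1
  if (!any(eligible)) return(0)
  lt <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(lt[eligible])
}

#' Expected clustering coefficient of a degree-matched random graph
#'
#' For a random graph with the same degree distribution, the expected
#' clustering coefficient is `(kd_bar - k_bar)^2 / (k_bar^3 N)`, where
#' `k_bar` and `kd_bar` are the mean degree and mean squared degree and N is
#' the number of connected nodes (`k >= 1`); all three quantities are
#' computed over connected nodes only. Returns 0 when the graph has no
#' edges.
#'
#' @param G a `gcn`, adjacency matrix, or igraph graph.
#' @return expected clustering coefficient `Cr >= 0`.
#' @export
expected_random_clustering <- function(G) {
  deg <- igraph::degree(as_igraph_gcn(G))
  .expected_random_clustering_deg(deg)
}

.expected_random_clustering_deg <- function(deg) {
  k <- deg[deg >= 1]
  N <- length(k)
  if (N == 0L) return(0)
  kbar <- mean(k)
  kdbar <- mean(k^2)
  (kdbar - kbar)^2 / (kbar^3 * N)
}

#' Clustering-coefficient curve over the threshold grid
#'
#' For every candidate threshold on the fixed grid 0.01, 0.02, ..., 0.99 the
#' similarity matrix is thresholded and the observed clustering coefficient
#' C, its random-graph expectation Cr, their absolute difference |C - Cr|,
#' the number of connected nodes and the edge count are recorded. The
#' absolute difference accommodates heterogeneous networks where Cr exceeds
#' C.
#'
#' @param S symmetric similarity matrix in `[0, 1]` over at least 3 genes.
#' @param grid threshold grid (fixed by default; override only for
#'   experimentation).
#' @return data frame of class `threshold_curve` with columns `tau`, `C`,
#'   `Cr`, `abs_diff`, `n_connected`, `n_edges`.
#' @export
threshold_curve <- function(S, grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(is.matrix(S), nrow(S) >= 3L)
  n <- nrow(S)
  ut <- which(upper.tri(S))
  sims <- S[ut]
  ij <- arrayInd(ut, dim(S))
  ord <- order(sims)
  sims <- sims[ord]
  ij <- ij[ord, , drop = FALSE]

  res <- data.frame(tau = grid, C = 0, Cr = 0, abs_diff = 0,
                    n_connected = 0L, n_edges = 0L)
  for (v in seq_along(grid)) {
    first <- .lower_bound(sims, grid[v])
    if (first > length(sims)) {
      next # empty graph: C = Cr = 0
    }
    keep <- first:length(sims)
    g <- igraph::make_graph(t(ij[keep, , drop = FALSE]), n = n,
                            directed = FALSE)
    deg <- igraph::degree(g)
    C <- .observed_clustering_igraph(g)
    Cr <- .expected_random_clustering_deg(deg)
    res$C[v] <- C
    res$Cr[v] <- Cr
    res$abs_diff[v] <- abs(C - Cr)
    res$n_connected[v] <- sum(deg >= 1)
    res$n_edges[v] <- length(keep)
  }
  class(res) <- c("threshold_curve", class(res))
  res
}

# index of first element >= x in sorted vector v (length(v) + 1 if none)
.lower_bound <- function(v, x) {
  lo <- 1L; hi <- length(v) + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (v[mid] < x) lo <- mid + 1L else hi <- mid
  }
  lo
}

#' Select the similarity threshold from a clustering-coefficient curve
#'
#' The selected threshold `tau*` is the first local maximum of the
#' `|C - Cr|` curve: the smallest grid value whose absolute difference
#' strictly exceeds that of the next grid value (plateaus are skipped until
#' the strict drop), subject to two robustness conditions. Both C and Cr are
#' computed from one realized graph per grid value, so `|C - Cr|` wiggles by
#' tiny amounts in the random-edge regime and any such wiggle is formally a
#' local maximum under the literal first-descent rule. A candidate must
#' therefore (i) be a maximum of its neighborhood — at least as large as
#' every value within `window` grid steps on either side, and risen into
#' from the left — and (ii) reach `min_peak_frac` of the curve's reference
#' maximum, taken over thresholds where the network still retains at least
#' `conn_frac` of the genes as connected nodes (near-empty remnant graphs
#' produce arbitrarily large `|C - Cr|` spikes that would otherwise distort
#' the reference). On curves with no qualifying point (e.g. monotone
#' non-decreasing), the argmax over the connectivity-masked grid is
#' returned with a warning.
#'
#' @param curve a [threshold_curve()] result.
#' @param window half-width, in grid steps, of the neighborhood a candidate
#'   must dominate (default 5).
#' @param min_peak_frac minimum candidate height as a fraction of the
#'   reference maximum (default 1/3).
#' @param conn_frac minimum fraction of genes connected for a grid value to
#'   enter the reference maximum (default 0.05).
#' @return the selected threshold `tau*`.
#' @export
select_threshold <- function(curve, window = 5L, min_peak_frac = 1 / 3,
                             conn_frac = 0.05) {
  stopifnot(nrow(curve) >= 1L, window >= 0L,
            min_peak_frac >= 0, min_peak_frac <= 1)
  d <- curve$abs_diff
  if (all(d == 0)) stop("degenerate similarity matrix")
  m <- length(d)
  n_genes <- max(curve$n_connected)
  masked <- curve$n_connected >= conn_frac * n_genes
  if (!any(masked)) masked <- rep(TRUE, m)
  ref_max <- max(d[masked])
  if (m > 1L) {
    drop_next <- d[-m] > d[-1L]            # strict fall to the next grid value
    rose_into <- c(FALSE, d[-1L] >= d[-m]) # not below the previous value
    dominant <- vapply(seq_len(m - 1L), function(v) {
      lo <- max(1L, v - window)
      hi <- min(m, v + window)
      d[v] >= max(d[lo:hi])
    }, logical(1))
    cand <- which(drop_next & rose_into[seq_len(m - 1L)] & dominant &
                    masked[seq_len(m - 1L)] &
                    d[-m] >= min_peak_frac * ref_max)
    if (length(cand) > 0L) return(curve$tau[cand[1L]])
  }
  warning("no local maximum in |C - Cr|; returning grid argmax")
  curve$tau[masked][which.max(d[masked])]
}

#' Build a gene co-expression network from a similarity matrix
#'
#' Composes the full thresholding step: scan the threshold grid
#' ([threshold_curve()]), select `tau*` ([select_threshold()]), threshold the
#' matrix ([adjacency()]) and drop isolated nodes so the node count reflects
#' the connected network.
#'
#' @param S symmetric similarity matrix in `[0, 1]` over at least 3 genes.
#' @param grid threshold grid passed to [threshold_curve()].
#' @return a [gcn] restricted to connected nodes, with attributes `curve`
#'   (the threshold curve) and `n_total` (gene count before dropping
#'   isolated nodes).
#' @export
build_gcn <- function(S, grid = seq(0.01, 0.99, by = 0.01)) {
  curve <- threshold_curve(S, grid = grid)
  tau <- select_threshold(curve)
  net <- adjacency(S, tau)
  A <- net$adjacency
  keep <- rowSums(A) > 0
  out <- gcn(A[keep, keep, drop = FALSE], tau_star = tau)
  attr(out, "curve") <- curve
  attr(out, "n_total") <- nrow(A)
  out
}
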