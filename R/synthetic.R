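#' Specification for a simulated power-law network
#'
#' Describes the generative conditions for [simulate_network()]: a
#' truncated power-law degree distribution `P(k) ~ k^-exponent` with the
#' truncation point tuned to reach a target coefficient of variation of the
#' degree, and degree-preserving rewiring toward a target average clustering
#' coefficient. The default targets mirror heterogeneous co-expression
#' networks (CV(k) = 2.86, C = 0.02, exponent 2).
#'
#' @param n_nodes number of nodes (>= 10).
#' @param exponent degree-distribution exponent (> 1; default 2).
#' @param target_cv desired coefficient of variation of the degree (> 0).
#' @param target_cc desired average clustering coefficient in `[0, 1]`.
#' @param seed integer seed.
#' @return object of class `network_sim_spec`.
#' @export
network_sim_spec <- function(n_nodes = 300, exponent = 2, target_cv = 2.86,
                             target_cc = 0.02, seed = 1) {
  stopifnot(n_nodes >= 10, exponent > 1, target_cv > 0,
            target_cc >= 0, target_cc <= 1)
  structure(list(n_nodes = as.integer(n_nodes), exponent = exponent,
                 target_cv = target_cv, target_cc = target_cc,
                 seed = as.integer(seed)),
            class = "network_sim_spec")
}

# theoretical CV of p(k) ~ k^-exponent on 1..K
.powerlaw_cv <- function(K, exponent) {
  k <- seq_len(K)
  p <- k^(-exponent)
  p <- p / sum(p)
  m1 <- sum(k * p)
  m2 <- sum(k^2 * p)
  sqrt(max(m2 - m1^2, 0)) / m1
}

#' Simulate a power-law network with target heterogeneity and clustering
#'
#' Degrees are drawn by inverse-CDF sampling from a discrete truncated
#' power-law `P(k) ~ k^-exponent`, `k = 1..K`, where the truncation point K
#' is chosen so the distribution's coefficient of variation matches
#' `target_cv`; the draw with realized CV closest to the target over a few
#' attempts is kept. A simple graph is realized from the degree sequence by
#' the configuration model (multi-edges and self-loops collapsed), then
#' degree-preserving edge swaps are applied in batches and accepted when
#' they move the average clustering coefficient toward `target_cc`, up to
#' `max_swaps` swaps. If the realized CV is not within 15% of the target or
#' the realized clustering not within 0.05, the best effort is returned
#' with a warning.
#'
#' @param spec a [network_sim_spec()].
#' @param max_swaps total budget of degree-preserving edge swaps for
#'   clustering tuning (default 10000).
#' @return a [gcn] with attributes `realized_cv` and `realized_cc`.
#' @export
simulate_network <- function(spec, max_swaps = 10000L) {
  stopifnot(inherits(spec, "network_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes

  cand_K <- 2:(n - 1L)
  cvs <- vapply(cand_K, .powerlaw_cv, numeric(1), exponent = spec$exponent)
  K <- cand_K[which.min(abs(cvs - spec$target_cv))]

  # finite samples under-disperse relative to the distribution's CV (the tail
  # is rarely drawn, and collapsing multi-edges trims hubs further), so the
  # truncation point is adapted multiplicatively on the realized CV
  best_g <- NULL
  best_gap <- Inf
  for (attempt in 1:25) {
    p <- seq_len(K)^(-spec$exponent)
    p <- p / sum(p)
    deg <- sample.int(K, n, replace = TRUE, prob = p)
    deg <- pmin(deg, n - 1L)
    if (sum(deg) %% 2L == 1L) deg[which.min(deg)] <- deg[which.min(deg)] + 1L
    g_try <- igraph::simplify(
      igraph::sample_degseq(deg, method = "configuration"))
    k_real <- igraph::degree(g_try)
    cv <- sqrt(mean((k_real - mean(k_real))^2)) / mean(k_real)
    gap <- abs(cv - spec$target_cv) / spec$target_cv
    if (gap < best_gap) {
      best_g <- g_try
      best_gap <- gap
    }
    if (gap <= 0.05) break
    K <- max(2L, min(n - 1L, as.integer(round(K * (spec$target_cv / cv)^1.5))))
  }
  g <- best_g
  if (best_gap > 0.15) {
    warning("realized CV(k) deviates from target by ",
            round(100 * best_gap), "% (best effort)")
  }

  # batched hill-climb toward the target clustering coefficient
  cc <- .observed_clustering_igraph(g)
  batch <- 50L
  used <- 0L
  while (used < max_swaps && abs(cc - spec$target_cc) > 0.005) {
    g_try <- try(igraph::rewire(
      g, igraph::keeping_degseq(niter = batch)), silent = TRUE)
    used <- used + batch
    if (inherits(g_try, "try-error")) break
    cc_try <- .observed_clustering_igraph(g_try)
    if (abs(cc_try - spec$target_cc) < abs(cc - spec$target_cc)) {
      g <- g_try
      cc <- cc_try
    }
  }
  if (abs(cc - spec$target_cc) > 0.05) {
    warning("realized clustering ", signif(cc, 3),
            " not within 0.05 of target ", spec$target_cc, " (best effort)")
  }

  A <- as.matrix(igraph::as_adjacency_matrix(g))
  rownames(A) <- colnames(A) <- sprintf("g%04d", seq_len(n))
  out <- gcn(A)
  deg_real <- rowSums(A)
  attr(out, "realized_cv") <-
    sqrt(mean((deg_real - mean(deg_real))^2)) / mean(deg_real)
  attr(out, "realized_cc") <- cc
  out
}

#' Embed a known threshold into a similarity matrix
#'
#' Constructs a similarity matrix whose true threshold is known: pairs
#' joined by an edge in the planted network draw similarities uniformly from
#' `[tau_true, 1]`, non-edges from `[0, tau_true - delta]`. Thresholding at
#' `tau_true` recovers the planted graph exactly, which makes the
#' construction the ground truth for validating threshold selection.
#'
#' @param G planted network (a `gcn`, adjacency matrix, or igraph graph).
#' @param tau_true true threshold in `(0, 1)`.
#' @param delta separation gap below the threshold (default 0.02; must be
#'   `< tau_true`).
#' @param seed integer seed.
#' @return symmetric similarity matrix with unit diagonal.
#' @export
embed_similarity <- function(G, tau_true, delta = 0.02, seed = 1) {
  stopifnot(tau_true > 0, tau_true < 1, delta > 0, delta < tau_true)
  A <- as_adjacency_gcn(G)
  n <- nrow(A)
  set.seed(seed)
  S <- matrix(0, n, n, dimnames = dimnames(A))
  ut <- upper.tri(S)
  edge <- A[ut] == 1
  vals <- numeric(sum(ut))
  vals[edge] <- runif(sum(edge), min = tau_true, max = 1)
  vals[!edge] <- runif(sum(!edge), min = 0, max = tau_true - delta)
  S[ut] <- vals
  S <- S + t(S)
  diag(S) <- 1
  S
}

#' Simulate an expression matrix with planted co-expression modules
#'
#' Each module is driven by a latent profile `z ~ N(0, 1)` over samples;
#' member genes derive from it according to the module's relation, plus
#' Gaussian noise of standard deviation `noise_sd`:
#'
#' * `linear`: gene = z + noise (high APCC within the module);
#' * `inverted`: genes alternate between z and -z (APCC is sign-blind);
#' * `quadratic`: genes alternate between z and z^2, so cross pairs are
#'   non-linearly (quadratically) dependent — near-zero APCC, high NCMI;
#' * `shifted`: gene = a_g z + b_g with per-gene positive scale and offset
#'   (same shape at different absolute levels, the NMRS use case).
#'
#' Genes not assigned to any module are independent `N(0, 1)` noise.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param modules list of modules, each `list(size =, relation =)` with
#'   relation one of `"linear"`, `"inverted"`, `"quadratic"`, `"shifted"`;
#'   sizes must sum to at most `n_genes`.
#' @param noise_sd Gaussian noise standard deviation (default 0.1).
#' @param seed integer seed.
#' @return numeric matrix (genes x samples) with a `modules` attribute
#'   giving each gene's module index (0 = background).
#' @export
simulate_expression <- function(n_genes, n_samples, modules = list(),
                                noise_sd = 0.1, seed = 1) {
  stopifnot(noise_sd >= 0, n_genes >= 1, n_samples >= 1)
  sizes <- vapply(modules, function(m) as.integer(m$size), integer(1))
  stopifnot(sum(sizes) <= n_genes)
  set.seed(seed)
  E <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  assign <- integer(n_genes)
  row <- 1L
  for (m in seq_along(modules)) {
    size <- sizes[m]
    relation <- match.arg(modules[[m]]$relation,
                          c("linear", "inverted", "quadratic", "shifted"))
    z <- rnorm(n_samples)
    for (g in seq_len(size)) {
      base <- switch(relation,
        linear = z,
        inverted = if (g %% 2L == 0L) -z else z,
        quadratic = if (g %% 2L == 0L) z^2 else z,
        shifted = runif(1, 0.5, 2) * z + runif(1, -3, 3))
      E[row, ] <- base + if (noise_sd > 0) rnorm(n_samples, sd = noise_sd)
                         else 0
      assign[row] <- m
      row <- row + 1L
    }
  }
  attr(E, "modules") <- assign
  E
}

#' Simulate a gene annotation table
#'
#' Genes in the same module share that module's signature GO term and PFAM
#' domain with probability `enrichment`; otherwise (and for background
#' genes) terms are drawn uniformly from the term pools. Immunity flags are
#' drawn at the given overall fraction; when `degree_bias` is supplied
#' (node degrees), flag probability is proportional to degree, which plants
#' a positive degree-immunity correlation.
#'
#' @param gene_ids character vector of gene ids.
#' @param n_go,n_pfam sizes of the GO / PFAM term pools.
#' @param module_assignments integer module index per gene (0 or `NA` =
#'   background); defaults to all background.
#' @param enrichment probability a module gene carries its module's
#'   signature term.
#' @param immunity_fraction overall fraction of immunity-flagged genes.
#' @param seed integer seed.
#' @param degree_bias optional numeric vector of node degrees used to bias
#'   immunity flags toward hubs.
#' @return an [annotation_table()].
#' @export
simulate_annotations <- function(gene_ids, n_go = 20, n_pfam = 15,
                                 module_assignments = NULL,
                                 enrichment = 0.8, immunity_fraction = 0.1,
                                 seed = 1, degree_bias = NULL) {
  stopifnot(enrichment >= 0, enrichment <= 1,
            immunity_fraction >= 0, immunity_fraction <= 1)
  n <- length(gene_ids)
  if (is.null(module_assignments)) module_assignments <- integer(n)
  module_assignments[is.na(module_assignments)] <- 0L
  stopifnot(length(module_assignments) == n)
  set.seed(seed)

  go_pool <- sprintf("GO:%07d", seq_len(n_go))
  pfam_pool <- sprintf("PF%05d", seq_len(n_pfam))
  draw <- function(pool, sig) {
    lapply(seq_len(n), function(i) {
      m <- module_assignments[i]
      if (m > 0L && runif(1) < enrichment) {
        sig[[m]]
      } else {
        sample(pool, 1L)
      }
    })
  }
  n_mod <- max(module_assignments, 0L)
  go_sig <- as.list(go_pool[((seq_len(max(n_mod, 1L)) - 1L) %% n_go) + 1L])
  pfam_sig <- as.list(pfam_pool[((seq_len(max(n_mod, 1L)) - 1L) %% n_pfam) + 1L])

  if (is.null(degree_bias)) {
    imm <- runif(n) < immunity_fraction
  } else {
    stopifnot(length(degree_bias) == n)
    pr <- immunity_fraction * degree_bias / max(mean(degree_bias),
                                                .Machine$double.eps)
    imm <- runif(n) < pmin(pr, 1)
  }
  annotation_table(gene_ids, go = draw(go_pool, go_sig),
                   pfam = draw(pfam_pool, pfam_sig), immunity = imm)
}

#' Threshold-recovery experiment on simulated networks
#'
#' For each replicate: simulate a power-law network, embed a known true
#' threshold into a similarity matrix, run the full threshold-selection
#' procedure ([threshold_curve()] + [select_threshold()]), and record the
#' selected threshold. The summary statistic is the mean absolute error
#' `eta = mean(|tau_hat - tau_true|)`. Failed replicates are excluded with a
#' log entry.
#'
#' @param spec a [network_sim_spec()] describing the planted networks.
#' @param tau_true true threshold in `(0, 1)`.
#' @param n_reps number of replicates (>= 2).
#' @param seed integer seed; replicate r uses sub-seeds derived from
#'   `seed + r`.
#' @param delta separation gap for [embed_similarity()].
#' @param max_swaps clustering-tuning budget per simulated network.
#' @return object of class `recovery_result`: list with `pairs` (data frame
#'   tau_true, tau_hat) and `eta`.
#' @export
recovery_experiment <- function(spec, tau_true, n_reps = 50, seed = 1,
                                delta = 0.02, max_swaps = 2000L) {
  stopifnot(n_reps >= 2)
  hats <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    sub <- (seed + 7919L * r) %% .Machine$integer.max
    res <- try({
      sp <- spec
      sp$seed <- sub
      G <- suppressWarnings(simulate_network(sp, max_swaps = max_swaps))
      S <- embed_similarity(G, tau_true, delta = delta, seed = sub + 1L)
      suppressWarnings(select_threshold(threshold_curve(S)))
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      .log_msg("recovery replicate ", r, " failed and was excluded: ",
               attr(res, "condition")$message)
    } else {
      hats[r] <- res
    }
  }
  pairs <- data.frame(tau_true = tau_true, tau_hat = hats)
  pairs <- pairs[!is.na(pairs$tau_hat), , drop = FALSE]
  structure(list(pairs = pairs,
                 eta = mean(abs(pairs$tau_hat - pairs$tau_true))),
            class = "recovery_result")
}

#' Threshold recovery pooled over a grid of true thresholds
#'
#' Distributes a total replicate budget as evenly as possible over the true
#' thresholds, runs [recovery_experiment()] for each, and pools the
#' per-replicate absolute errors into a single `eta`.
#'
#' @param spec a [network_sim_spec()].
#' @param tau_grid true thresholds to plant (default 0.3, 0.5, 0.7, 0.9).
#' @param n_reps_total total replicates across the grid (default 50).
#' @param seed integer seed.
#' @param ... passed to [recovery_experiment()].
#' @return object of class `recovery_result` with pooled `pairs` and `eta`.
#' @export
recovery_validation <- function(spec, tau_grid = c(0.3, 0.5, 0.7, 0.9),
                                n_reps_total = 50, seed = 1, ...) {
  n_tau <- length(tau_grid)
  reps <- rep(n_reps_total %/% n_tau, n_tau)
  extra <- n_reps_total %% n_tau
  if (extra > 0) reps[seq_len(extra)] <- reps[seq_len(extra)] + 1L
  parts <- vector("list", n_tau)
  for (i in seq_len(n_tau)) {
    parts[[i]] <- recovery_experiment(spec, tau_grid[i], n_reps = reps[i],
                                      seed = seed + 104729L * i, ...)$pairs
  }
  pairs <- do.call(rbind, parts)
  structure(list(pairs = pairs,
                 eta = mean(abs(pairs$tau_hat - pairs$tau_true))),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("Threshold recovery:", nrow(x$pairs), "replicates, eta =",
      signif(x$eta, 4), "\n")
  invisible(x)
}
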