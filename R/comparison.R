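#' Assemble a characterization matrix from per-network rows
#'
#' Binds [characterize()] rows and splits them into the numeric
#' networks-by-variables matrix used for PCA and the metadata columns
#' carried alongside.
#'
#' @param rows list of one-row data frames from [characterize()], or a data
#'   frame of such rows.
#' @param variables which columns form the characterization matrix (default:
#'   the eight graph variables).
#' @return list with `values` (numeric matrix, networks x variables) and
#'   `meta` (data frame with network_id, species, stress_group, n_nodes,
#'   n_edges).
#' @export
characterization_matrix <- function(rows,
                                    variables = c("CC", "Cen", "Het", "Den",
                                                  "AsG", "AsP", "Tol", "KI")) {
  df <- if (is.data.frame(rows)) rows else do.call(rbind, rows)
  stopifnot(all(variables %in% colnames(df)))
  values <- as.matrix(df[, variables, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- df$network_id
  if (anyNA(values)) stop("characterization matrix has missing cells")
  meta_cols <- intersect(c("network_id", "species", "stress_group",
                           "n_nodes", "n_edges"), colnames(df))
  list(values = values, meta = df[, meta_cols, drop = FALSE])
}

#' Principal component analysis of a characterization matrix
#'
#' Columns are standardized (z-scored with the sample standard deviation) so
#' the eight variables, which live on incommensurate scales, contribute
#' equally; the PCA then diagonalizes their correlation matrix.
#' Zero-variance columns are dropped with a warning.
#'
#' @param T numeric matrix, networks in rows, variables in columns (or the
#'   list returned by [characterization_matrix()]).
#' @param standardize logical; set `FALSE` to skip z-scoring (covariance
#'   PCA).
#' @return object of class `gcn_pca`: list with `eigenvalues`,
#'   `explained_variance` (percentages summing to 100), `scores`
#'   (networks x components), `loadings`, `var_cor` (variable-component
#'   correlations, the correlation circle), `center`, `scale`.
#' @export
gcn_pca <- function(T, standardize = TRUE) {
  if (is.list(T) && !is.data.frame(T) && !is.matrix(T)) T <- T$values
  T <- as.matrix(T)
  stopifnot(nrow(T) >= 3L)
  if (anyNA(T)) stop("characterization matrix has missing cells")
  sds <- apply(T, 2L, sd)
  if (standardize && any(sds == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(T)[sds == 0], collapse = ", "))
    T <- T[, sds > 0, drop = FALSE]
  }
  p <- prcomp(T, center = TRUE, scale. = standardize)
  eig <- p$sdev^2
  ev <- 100 * eig / sum(eig)
  scores <- p$x
  Z <- scale(T, center = TRUE, scale = standardize)
  var_cor <- suppressWarnings(cor(Z, scores))
  var_cor[is.na(var_cor)] <- 0
  structure(list(eigenvalues = eig, explained_variance = ev,
                 scores = scores, loadings = p$rotation, var_cor = var_cor,
                 center = p$center,
                 scale = if (standardize) p$scale else rep(1, ncol(T))),
            class = "gcn_pca")
}

#' @export
print.gcn_pca <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "networks x", nrow(x$loadings),
      "variables\n")
  ev <- round(x$explained_variance, 1)
  cat("Explained variance (%):", paste(ev, collapse = ", "), "\n")
  invisible(x)
}

#' K-means clustering with BIC-based selection of the cluster number
#'
#' Runs K-means (squared Euclidean, best of `n_starts` random starts) on the
#' retained principal-component scores for each candidate number of clusters
#' k = 1..k_max, and scores each solution with
#' `BIC(k) = n log(W_k / n) + k log(n)` where `W_k` is the total
#' within-cluster sum of squares. The number of clusters is chosen by the
#' elbow heuristic — the k with the largest positive curvature (second
#' difference) of the BIC curve — with the BIC minimizer exposed as an
#' alternative.
#'
#' @param scores numeric matrix, networks in rows, retained PCs in columns.
#' @param k_max largest candidate number of clusters (must be < number of
#'   networks).
#' @param n_starts random restarts per k (default 100).
#' @param seed integer seed controlling all restarts.
#' @param rule `"elbow"` (default) or `"min"` for the BIC minimizer.
#' @return object of class `gcn_clustering`: list with `bic` (data frame k,
#'   BIC, W), `k` (chosen), `k_elbow`, `k_min_bic`, `assignments` (for the
#'   chosen k), `seed`, `n_starts`, `rule`.
#' @export
kmeans_bic <- function(scores, k_max, n_starts = 100, seed = 1,
                       rule = c("elbow", "min")) {
  rule <- match.arg(rule)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(k_max >= 1L, k_max < n, n_starts >= 1L)

  set.seed(seed)
  W <- numeric(k_max)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    if (k == 1L) {
      W[k] <- sum(scale(scores, scale = FALSE)^2)
      fits[[k]] <- list(cluster = rep(1L, n))
    } else {
      fit <- NULL
      for (attempt in 1:5) {
        fit <- tryCatch(
          kmeans(scores, centers = k, nstart = n_starts, iter.max = 100),
          error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(fit) && length(unique(fit$cluster)) == k) break
        .log_msg("kmeans k=", k, ": degenerate solution, restarting")
      }
      if (is.null(fit)) stop("kmeans failed for k = ", k)
      W[k] <- fit$tot.withinss
      fits[[k]] <- fit
    }
  }
  bic <- n * log(pmax(W, .Machine$double.eps) / n) +
    seq_len(k_max) * log(n)

  k_min_bic <- which.min(bic)
  k_elbow <- if (k_max >= 3L) {
    curv <- bic[1:(k_max - 2L)] - 2 * bic[2:(k_max - 1L)] + bic[3:k_max]
    which.max(curv) + 1L
  } else {
    k_min_bic
  }
  k_sel <- if (rule == "elbow") k_elbow else k_min_bic
  structure(list(bic = data.frame(k = seq_len(k_max), BIC = bic, W = W),
                 k = k_sel, k_elbow = k_elbow, k_min_bic = k_min_bic,
                 assignments = fits[[k_sel]]$cluster,
                 seed = seed, n_starts = n_starts, rule = rule),
            class = "gcn_clustering")
}

#' @export
print.gcn_clustering <- function(x, ...) {
  cat("K-means/BIC over k = 1..", nrow(x$bic), ": chosen k = ", x$k,
      " (", x$rule, " rule; min-BIC k = ", x$k_min_bic, ")\n", sep = "")
  invisible(x)
}

#' Cross-tabulate cluster assignments against group labels
#'
#' @param assignments cluster id per network.
#' @param groups label per network (stress group, species, ...).
#' @return contingency table of cluster x group counts.
#' @export
cross_tab <- function(assignments, groups) {
  if (length(assignments) != length(groups)) stop("length mismatch")
  table(cluster = assignments, group = groups)
}

#' Correlation of each characterization variable with network size
#'
#' Diagnostic for size bias: Pearson correlation of every variable column
#' with the network node counts. Small magnitudes indicate the
#' characterization (and hence the PCA) is not driven by network size.
#'
#' @param T numeric matrix, networks in rows, variables in columns (or a
#'   [characterization_matrix()] result).
#' @param sizes node count per network.
#' @return named numeric vector of correlations; 0 with a warning for
#'   zero-variance columns.
#' @export
variable_size_correlation <- function(T, sizes) {
  if (is.list(T) && !is.data.frame(T) && !is.matrix(T)) T <- T$values
  T <- as.matrix(T)
  if (nrow(T) != length(sizes)) stop("length mismatch")
  apply(T, 2L, function(v) {
    if (sd(v) == 0 || sd(sizes) == 0) {
      warning("zero variance; correlation = 0")
      return(0)
    }
    cor(v, sizes)
  })
}
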