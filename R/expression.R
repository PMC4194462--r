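#' Collapse probe-level expression to gene level
#'
#' Microarray platforms measure probes, not genes. Given a probe-level
#' expression matrix and a probe-to-gene conversion table, this collapses to a
#' gene-level matrix: ambiguous probes (matching more than one gene) are
#' removed entirely, and when several probes match a single gene the maximum
#' expression among them is assigned to the gene, sample by sample.
#'
#' @param probe_matrix numeric matrix of expression values, probes in rows
#'   (rownames are probe ids), samples in columns. `NA` marks missing values.
#' @param probe_map data frame with columns `probe_id` and `gene_id`; a probe
#'   may map to zero, one or many genes.
#' @param per_sample logical; if `TRUE` (default) the maximum is taken
#'   element-wise per sample, ignoring `NA` (a cell is `NA` only when all of a
#'   gene's probes are missing there). If `FALSE` the single probe with the
#'   highest mean expression represents the gene (max-mean probe selection).
#' @return numeric matrix with gene ids as rownames; genes with no surviving
#'   probe are absent.
#' @examples
#' pm <- rbind(p1 = c(2, 3), p2 = c(5, 1))
#' colnames(pm) <- c("s1", "s2")
#' map <- data.frame(probe_id = c("p1", "p2"), gene_id = c("gA", "gA"))
#' collapse_probes(pm, map) # gA = (5, 3)
#' @export
collapse_probes <- function(probe_matrix, probe_map, per_sample = TRUE) {
  stopifnot(is.matrix(probe_matrix), nrow(probe_matrix) > 0L)
  if (is.null(probe_map) || nrow(probe_map) == 0L) {
    stop("no mapping: probe map is empty")
  }
  map <- unique(probe_map[, c("probe_id", "gene_id")])
  map$probe_id <- as.character(map$probe_id)
  map$gene_id <- as.character(map$gene_id)

  # probes hitting more than one gene are dropped entirely
  n_genes_per_probe <- table(map$probe_id)
  ambiguous <- names(n_genes_per_probe)[n_genes_per_probe > 1L]
  map <- map[!(map$probe_id %in% ambiguous), , drop = FALSE]
  map <- map[map$probe_id %in% rownames(probe_matrix), , drop = FALSE]
  if (nrow(map) == 0L) {
    out <- probe_matrix[0L, , drop = FALSE]
    return(out)
  }

  genes <- sort(unique(map$gene_id))
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(probe_matrix),
                dimnames = list(genes, colnames(probe_matrix)))
  for (g in genes) {
    probes <- map$probe_id[map$gene_id == g]
    block <- probe_matrix[probes, , drop = FALSE]
    if (per_sample) {
      vals <- apply(block, 2L, function(v) {
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
      })
    } else {
      means <- rowMeans(block, na.rm = TRUE)
      means[is.nan(means)] <- -Inf
      vals <- block[which.max(means), ]
    }
    out[g, ] <- vals
  }
  out
}

#' Filter samples and genes by missingness
#'
#' Two-stage filter applied in a fixed order. Stage 1 removes every sample
#' with observed (non-missing) values for less than `sample_min` of the common
#' gene list. Stage 2, on the stage-1 result, removes every gene observed in
#' less than `gene_min` of the remaining samples.
#'
#' @param E numeric matrix, genes in rows, samples in columns, `NA` missing.
#' @param common_genes character vector of gene ids defining the common gene
#'   list used for the sample filter; defaults to all rows of `E`.
#' @param sample_min minimum fraction of common genes a sample must cover
#'   (default 0.5).
#' @param gene_min minimum fraction of remaining samples a gene must cover
#'   (default 0.75).
#' @return the filtered matrix.
#' @export
filter_expression <- function(E, common_genes = rownames(E),
                              sample_min = 0.5, gene_min = 0.75) {
  stopifnot(is.matrix(E), sample_min >= 0, sample_min <= 1,
            gene_min >= 0, gene_min <= 1)
  common <- intersect(common_genes, rownames(E))
  if (length(common) == 0L) stop("no common genes present in matrix")

  obs <- !is.na(E[common, , drop = FALSE])
  sample_cov <- colSums(obs) / length(common)
  keep_s <- sample_cov >= sample_min
  if (!any(keep_s)) stop("empty after sample filter")
  E1 <- E[, keep_s, drop = FALSE]

  gene_cov <- rowSums(!is.na(E1)) / ncol(E1)
  keep_g <- gene_cov >= gene_min
  E1[keep_g, , drop = FALSE]
}

#' Merge expression matrices from several experiments
#'
#' Aligns matrices on a common gene list and concatenates their samples, with
#' sample ids tagged by experiment so they remain unique. Values are taken as
#' given (no re-normalization); genes absent from a contributing experiment
#' become missing cells in `union` mode.
#'
#' @param matrices list of two or more gene-by-sample matrices.
#' @param tags character vector of experiment tags, one per matrix; defaults
#'   to the list names or `exp1`, `exp2`, ...
#' @param genes either `"intersection"` (default: genes present in every
#'   matrix) or `"union"` (genes present in at least one).
#' @return merged matrix with `source` attribute giving the experiment tag of
#'   each sample column.
#' @export
merge_experiments <- function(matrices, tags = NULL,
                              genes = c("intersection", "union")) {
  genes <- match.arg(genes)
  stopifnot(is.list(matrices), length(matrices) >= 2L)
  if (is.null(tags)) {
    tags <- names(matrices)
    if (is.null(tags) || any(!nzchar(tags))) {
      tags <- paste0("exp", seq_along(matrices))
    }
  }
  stopifnot(length(tags) == length(matrices))

  gene_sets <- lapply(matrices, rownames)
  common <- if (genes == "intersection") {
    Reduce(intersect, gene_sets)
  } else {
    Reduce(union, gene_sets)
  }
  common <- sort(unique(common))
  if (length(common) == 0L) stop("empty common gene list")

  blocks <- vector("list", length(matrices))
  for (i in seq_along(matrices)) {
    M <- matrices[[i]]
    block <- matrix(NA_real_, nrow = length(common), ncol = ncol(M),
                    dimnames = list(common,
                                    paste(tags[i], colnames(M), sep = ".")))
    present <- intersect(common, rownames(M))
    block[present, ] <- M[present, , drop = FALSE]
    blocks[[i]] <- block
  }
  merged <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(merged))) {
    stop("duplicate sample ids after tagging")
  }
  attr(merged, "source") <- rep(tags, vapply(matrices, ncol, integer(1)))
  merged
}
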