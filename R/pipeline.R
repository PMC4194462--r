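#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline. Expression inputs may
#' be given as file paths (`expression_paths`, TSV as read by
#' [read_expression_tsv()]) or as in-memory matrices (`matrices`); exactly
#' one must be supplied.
#'
#' @param expression_paths character vector of expression TSV paths, named
#'   by experiment tag.
#' @param matrices named list of gene-by-sample matrices (alternative to
#'   `expression_paths`).
#' @param probe_map_path optional probe-to-gene TSV ([read_probe_map()]).
#' @param annotation_path optional annotation TSV ([read_annotations_tsv()]).
#' @param meta optional data frame with columns `experiment`, `species`,
#'   `stress_group` (one row per experiment).
#' @param measure similarity measure (default `"ncmi"`).
#' @param bins NCMI histogram bins (default `"auto"`).
#' @param sample_min,gene_min missingness filter fractions
#'   ([filter_expression()]).
#' @param grid similarity threshold grid.
#' @param attack_fraction hub fraction removed by [attack_tolerance()].
#' @param n_pcs principal components retained for clustering (default 3).
#' @param k_max largest candidate cluster number (default: one less than
#'   the number of networks, capped at 20).
#' @param n_starts K-means restarts (default 100).
#' @param seed global seed; stage s uses sub-seed `seed + 1000 * s` (stages
#'   numbered in execution order), so any stage can be reproduced in
#'   isolation.
#' @param out_dir output directory for [run_pipeline()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression_paths = NULL, matrices = NULL,
                            probe_map_path = NULL, annotation_path = NULL,
                            meta = NULL, measure = "ncmi", bins = "auto",
                            sample_min = 0.5, gene_min = 0.75,
                            grid = seq(0.01, 0.99, by = 0.01),
                            attack_fraction = 0.05, n_pcs = 3,
                            k_max = NULL, n_starts = 100, seed = 1,
                            out_dir = tempfile("gcnforge_run_")) {
  if (is.null(expression_paths) == is.null(matrices)) {
    stop("supply exactly one of expression_paths or matrices")
  }
  measure <- match.arg(measure, c("apcc", "ncmi", "nmrs"))
  structure(list(expression_paths = expression_paths, matrices = matrices,
                 probe_map_path = probe_map_path,
                 annotation_path = annotation_path, meta = meta,
                 measure = measure, bins = bins, sample_min = sample_min,
                 gene_min = gene_min, grid = grid,
                 attack_fraction = attack_fraction, n_pcs = n_pcs,
                 k_max = k_max, n_starts = n_starts,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full network construction and comparison pipeline
#'
#' `multi` mode merges all experiments into one expression matrix and
#' builds a single network from it (the multi-experiment path); `single`
#' mode builds one network per experiment and, when at least three result,
#' compares them by PCA and K-means clustering. Every stage's artifact is
#' written under the output directory together with a `manifest.json`
#' recording parameters, input hashes and the package version; all outputs
#' are deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @param mode `"single"` or `"multi"`.
#' @return invisibly, a list with the networks, characterization table and
#'   (single mode, >= 3 networks) PCA and clustering results, plus
#'   `out_dir`.
#' @export
run_pipeline <- function(config, mode = c("single", "multi")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  mats <- .stage("read_expression", {
    if (!is.null(config$matrices)) {
      config$matrices
    } else {
      setNames(lapply(config$expression_paths, read_expression_tsv),
               names(config$expression_paths))
    }
  })
  if (is.null(names(mats)) || any(!nzchar(names(mats)))) {
    names(mats) <- paste0("exp", seq_along(mats))
  }

  if (!is.null(config$probe_map_path)) {
    pm <- read_probe_map(config$probe_map_path)
    mats <- .stage("collapse_probes",
                   lapply(mats, collapse_probes, probe_map = pm))
  }

  ann <- if (!is.null(config$annotation_path)) {
    .stage("read_annotations", read_annotations_tsv(config$annotation_path))
  } else {
    NULL
  }

  if (mode == "multi") {
    merged <- if (length(mats) >= 2L) {
      .stage("merge_experiments", merge_experiments(mats))
    } else {
      mats[[1L]]
    }
    mats <- list(merged = merged)
  }

  mats <- .stage("filter_expression", lapply(mats, function(M) {
    filter_expression(M, sample_min = config$sample_min,
                      gene_min = config$gene_min)
  }))

  networks <- list()
  rows <- list()
  for (tag in names(mats)) {
    S <- .stage(paste0("similarity[", tag, "]"),
                similarity_matrix(mats[[tag]], measure = config$measure,
                                  bins = config$bins))
    net <- .stage(paste0("threshold[", tag, "]"),
                  suppressWarnings(build_gcn(S, grid = config$grid)))
    curve <- attr(net, "curve")
    write.table(curve, file.path(config$out_dir,
                                 paste0(tag, "_threshold_curve.csv")),
                sep = ",", row.names = FALSE, quote = FALSE)
    write_network(net, file.path(config$out_dir, paste0(tag, ".sif")),
                  format = "sif")
    write_network(net, file.path(config$out_dir, paste0(tag, "_edges.tsv")),
                  format = "tsv")
    networks[[tag]] <- net

    mrow <- if (!is.null(config$meta)) {
      config$meta[match(tag, config$meta$experiment), , drop = FALSE]
    } else {
      data.frame(species = NA_character_, stress_group = NA_character_)
    }
    rows[[tag]] <- suppressMessages(characterize(
      net, ann = ann, network_id = tag,
      species = mrow$species[1L], stress_group = mrow$stress_group[1L],
      attack_fraction = config$attack_fraction))
  }

  char <- do.call(rbind, rows)
  char_path <- file.path(config$out_dir, "characterization.csv")
  .write_characterization_csv(char, char_path)

  result <- list(networks = networks, characterization = char,
                 out_dir = config$out_dir)

  if (mode == "single" && length(networks) >= 3L) {
    Tm <- characterization_matrix(char)
    pca <- .stage("pca", suppressWarnings(gcn_pca(Tm)))
    n_pcs <- min(config$n_pcs, ncol(pca$scores))
    scores <- pca$scores[, seq_len(n_pcs), drop = FALSE]
    write.table(data.frame(network_id = rownames(scores), scores),
                file.path(config$out_dir, "pca_scores.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(eigenvalues = pca$eigenvalues,
           explained_variance = pca$explained_variance,
           var_cor = as.data.frame(pca$var_cor)),
      file.path(config$out_dir, "pca.json"), digits = NA, auto_unbox = TRUE)

    k_max <- config$k_max
    if (is.null(k_max)) k_max <- min(length(networks) - 1L, 20L)
    clust <- .stage("kmeans", kmeans_bic(scores, k_max = k_max,
                                         n_starts = config$n_starts,
                                         seed = config$seed + 2000L))
    jsonlite::write_json(
      list(bic = clust$bic, k = clust$k, k_min_bic = clust$k_min_bic,
           assignments = setNames(as.list(clust$assignments),
                                  rownames(scores))),
      file.path(config$out_dir, "clusters.json"), digits = NA,
      auto_unbox = TRUE)
    result$pca <- pca
    result$clustering <- clust
    if (!is.null(config$meta)) {
      result$cross_tab <- cross_tab(
        clust$assignments,
        config$meta$stress_group[match(names(networks),
                                       config$meta$experiment)])
    }
  }

  manifest <- list(
    package = "gcnforge",
    version = as.character(utils::packageVersion("gcnforge")),
    mode = mode, seed = config$seed, measure = config$measure,
    bins = config$bins, sample_min = config$sample_min,
    gene_min = config$gene_min, attack_fraction = config$attack_fraction,
    n_pcs = config$n_pcs, n_starts = config$n_starts,
    experiments = names(networks),
    input_md5 = if (!is.null(config$expression_paths)) {
      as.list(tools::md5sum(config$expression_paths))
    } else {
      "in-memory"
    }
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(result)
}

.write_characterization_csv <- function(char, path) {
  num <- vapply(char, is.numeric, logical(1))
  out <- char
  out[num] <- lapply(out[num], function(v) format(v, digits = 15, trim = TRUE))
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
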