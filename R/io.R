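#' Read an expression matrix from TSV
#'
#' Expected layout: first column `gene_id`, remaining columns one per sample
#' with sample ids in the header, tab-separated, empty cells meaning missing.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows, `NA` for missing cells.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  if (colnames(df)[1L] != "gene_id") {
    stop("expression TSV must have 'gene_id' as first column")
  }
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in expression TSV")
  M <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- gene_ids
  M
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]: missing cells are written empty and
#' finite values with full precision, so a read/write round trip is
#' bit-stable.
#'
#' @param E numeric matrix with gene rownames and sample colnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(E, path) {
  stopifnot(is.matrix(E), !is.null(rownames(E)), !is.null(colnames(E)))
  cells <- format(E, digits = 17, trim = TRUE, scientific = FALSE)
  cells[is.na(E)] <- ""
  df <- data.frame(gene_id = rownames(E), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(E))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene conversion table
#'
#' @param path TSV file with columns `probe_id` and `gene_id`.
#' @return data frame with unique (probe_id, gene_id) pairs.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% colnames(df))) {
    stop("probe map TSV must have columns 'probe_id' and 'gene_id'")
  }
  unique(df[, c("probe_id", "gene_id")])
}

#' Read a gene annotation table
#'
#' Expected columns: `gene_id`, `go_terms` and `pfam_domains`
#' (semicolon-joined term ids, possibly empty) and `immunity_domain` (0/1).
#'
#' @param path TSV file path.
#' @return data frame of class `annotation_table` with list-columns `go` and
#'   `pfam` and a logical `immunity` column.
#' @export
read_annotations_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  needed <- c("gene_id", "go_terms", "pfam_domains", "immunity_domain")
  if (!all(needed %in% colnames(df))) {
    stop("annotation TSV must have columns: ", paste(needed, collapse = ", "))
  }
  annotation_table(
    gene_ids = df$gene_id,
    go = strsplit(ifelse(is.na(df$go_terms), "", df$go_terms), ";",
                  fixed = TRUE),
    pfam = strsplit(ifelse(is.na(df$pfam_domains), "", df$pfam_domains), ";",
                    fixed = TRUE),
    immunity = as.logical(as.integer(df$immunity_domain))
  )
}

#' Build an annotation table
#'
#' @param gene_ids character vector of unique gene ids.
#' @param go,pfam lists of character vectors (possibly empty) of GO term /
#'   PFAM domain ids, one element per gene.
#' @param immunity logical vector flagging genes carrying immunity-associated
#'   protein domains.
#' @return data frame of class `annotation_table`.
#' @export
annotation_table <- function(gene_ids, go = NULL, pfam = NULL,
                             immunity = NULL) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  n <- length(gene_ids)
  empty <- replicate(n, character(0), simplify = FALSE)
  clean <- function(l) lapply(l, function(v) v[nzchar(v)])
  ann <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  ann$go <- if (is.null(go)) empty else clean(go)
  ann$pfam <- if (is.null(pfam)) empty else clean(pfam)
  ann$immunity <- if (is.null(immunity)) rep(FALSE, n) else as.logical(immunity)
  stopifnot(length(ann$go) == n, length(ann$pfam) == n,
            length(ann$immunity) == n)
  class(ann) <- c("annotation_table", class(ann))
  ann
}

#' Write an annotation table to TSV
#'
#' @param ann an `annotation_table` (see [annotation_table()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(ann, path) {
  df <- data.frame(
    gene_id = ann$gene_id,
    go_terms = vapply(ann$go, paste, character(1), collapse = ";"),
    pfam_domains = vapply(ann$pfam, paste, character(1), collapse = ";"),
    immunity_domain = as.integer(ann$immunity),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a square similarity matrix
#'
#' Square, headered TSV with gene ids as both header and first column.
#'
#' @param path file path.
#' @return numeric symmetric matrix.
#' @export
read_similarity_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  S <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(S) <- "double"
  rownames(S) <- as.character(df[[1L]])
  if (!identical(rownames(S), colnames(S))) {
    stop("similarity TSV is not square with matching gene ids")
  }
  S
}

#' @rdname read_similarity_tsv
#' @param S numeric symmetric similarity matrix with gene dimnames.
#' @export
write_similarity_tsv <- function(S, path) {
  df <- data.frame(gene_id = rownames(S), S, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network
#'
#' Writes a `gcn` (or adjacency matrix) as a SIF file
#' (`gene_a <TAB> co <TAB> gene_b`, one line per edge, isolated nodes as
#' single-field lines), as a headered edge-list TSV, or as GraphML.
#'
#' @param G a `gcn` object or binary adjacency matrix.
#' @param path output file path.
#' @param format one of `"sif"`, `"tsv"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(G, path, format = c("sif", "tsv", "graphml")) {
  format <- match.arg(format)
  A <- as_adjacency_gcn(G)
  ids <- rownames(A)
  ut <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  if (format == "sif") {
    lines <- character(0)
    if (nrow(ut) > 0L) {
      lines <- paste(ids[ut[, 1L]], "co", ids[ut[, 2L]], sep = "\t")
    }
    isolated <- ids[rowSums(A) == 0]
    writeLines(c(lines, isolated), path)
  } else if (format == "tsv") {
    df <- data.frame(gene_a = ids[ut[, 1L]], gene_b = ids[ut[, 2L]])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph_gcn(G), path, format = "graphml")
  }
  invisible(path)
}
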