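# Readers and writers for the pipeline's plain-text formats. The canonical
# tabular dialect is TSV with a header row; missing values are written as NA
# and read back from either "NA" or an empty field.

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", na.strings = c("", "NA"),
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}

matrix_to_df <- function(m) {
  data.frame(reporter = rownames(m), m, check.names = FALSE,
             row.names = NULL)
}

df_to_matrix <- function(d) {
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write an expression dataset as a directory of TSV files
#'
#' Emits `M.tsv` (log2 ratios), `A.tsv` (mean log2 intensities),
#' `confidence.tsv` (0/1 flags) and `design.tsv` into `dir`.
#'
#' @param dataset an [expression_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset_tsv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "expression_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(matrix_to_df(dataset$M), file.path(dir, "M.tsv"))
  write_tsv(matrix_to_df(dataset$A), file.path(dir, "A.tsv"))
  conf <- dataset$confidence * 1L
  write_tsv(matrix_to_df(conf), file.path(dir, "confidence.tsv"))
  write_tsv(dataset$design, file.path(dir, "design.tsv"))
  invisible(dir)
}

#' Read an expression dataset written by [write_dataset_tsv()]
#'
#' @param dir directory holding `M.tsv`, `A.tsv`, `confidence.tsv`,
#'   `design.tsv`.
#' @return an [expression_dataset()].
#' @export
read_dataset_tsv <- function(dir) {
  for (f in c("M.tsv", "A.tsv", "confidence.tsv", "design.tsv"))
    if (!file.exists(file.path(dir, f)))
      stopf("expression data file missing: %s", file.path(dir, f))
  M <- df_to_matrix(read_tsv(file.path(dir, "M.tsv")))
  A <- df_to_matrix(read_tsv(file.path(dir, "A.tsv")))
  conf <- df_to_matrix(read_tsv(file.path(dir, "confidence.tsv"))) == 1
  design <- read_tsv(file.path(dir, "design.tsv"))
  expression_dataset(M, A, conf, design)
}

#' Write promoters as FASTA (one record per gene, 60-column lines)
#'
#' @param promoters a [promoter_set()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  stopifnot(inherits(promoters, "promoter_set"))
  x <- Biostrings::DNAStringSet(promoters$seqs)
  Biostrings::writeXStringSet(x, path, width = 60)
  invisible(path)
}

#' Read promoters from FASTA
#'
#' @param path FASTA path.
#' @param window declared window length (defaults to the longest record).
#' @return a [promoter_set()].
#' @export
read_promoters_fasta <- function(path, window = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- setNames(as.character(x), sub("\\s.*$", "", names(x)))
  promoter_set(seqs, window = window %||% max(nchar(seqs)))
}

#' Read a genome FASTA as named contig sequences
#'
#' @param path FASTA path.
#' @return named character vector of contigs.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a gene-to-term map in GMT format
#'
#' One line per term: term id, description, then tab-separated gene ids.
#'
#' @param term_map named list of character vectors (term -> genes).
#' @param path output path.
#' @param descriptions optional named descriptions (defaults to the term id).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(term_map, path, descriptions = NULL) {
  lines <- vapply(names(term_map), function(t) {
    paste(c(t, descriptions[[t]] %||% t, term_map[[t]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-to-term map
#'
#' @param path GMT file path.
#' @return named list of character vectors, class `gene_term_map`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stopf("malformed GMT line(s): %s",
                      paste(which(bad), collapse = ", "))
  tm <- lapply(parts, function(p) p[-(1:2)])
  names(tm) <- vapply(parts, `[[`, character(1), 1)
  structure(tm, class = "gene_term_map",
            descriptions = vapply(parts, `[[`, character(1), 2))
}

#' Read a motif file (name TAB IUPAC consensus per line)
#'
#' Lines starting with `#` are comments. Several lines may share a name
#' (binding-site variants of one factor); they are returned as separate
#' patterns.
#'
#' @param path motif file path.
#' @return list of [motif_pattern()] objects.
#' @export
read_motifs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lapply(parts, function(p) {
    if (length(p) < 2) stopf("malformed motif line: '%s'", paste(p, collapse = " "))
    motif_pattern(p[1], p[2])
  })
}

#' Write an interaction network as node/edge TSV files and GraphML
#'
#' @param network an [build_direct_interaction_network()] result.
#' @param prefix output path prefix; writes `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv` and `<prefix>.graphml`.
#' @return character vector of paths written, invisibly.
#' @export
write_network <- function(network, prefix) {
  stopifnot(inherits(network, "interaction_network"))
  paths <- c(paste0(prefix, "_nodes.tsv"), paste0(prefix, "_edges.tsv"),
             paste0(prefix, ".graphml"))
  write_tsv(network$nodes, paths[1])
  write_tsv(network$edges, paths[2])
  g <- igraph::graph_from_data_frame(
    network$edges[, c("source", "target", "type", "directed")],
    directed = FALSE, vertices = network$nodes)
  igraph::write_graph(g, paths[3], format = "graphml")
  invisible(paths)
}
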