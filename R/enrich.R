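#' Term enrichment of a gene list by Fisher exact or EASE score
#'
#' For every annotation term overlapping the gene list, computes the
#' one-sided upper-tail hypergeometric probability of drawing at least `k`
#' term genes in a list of size `n` from a background of `N` genes of which
#' `K` carry the term. `mode = "ease"` is the conservative "modified Fisher"
#' variant that decrements the observed overlap by one before taking the
#' tail (an overlap of 1 therefore scores p = 1). Adjusted p-values are
#' Benjamini-Hochberg across the reported terms.
#'
#' @param gene_list character vector of genes of interest (subset of
#'   `background`).
#' @param background character vector: the background population (e.g. all
#'   reporters passing the expression filter).
#' @param term_map named list of character vectors (term -> annotated
#'   genes), e.g. from [simulate_annotation_table()] or [read_gmt()].
#'   Annotated genes outside the background are dropped (a warning reports
#'   how many).
#' @param mode `"ease"` (default, DAVID-style) or `"fisher"`.
#' @return data frame of class `enrichment_result`, one row per term with
#'   overlap `k >= 1`: `term`, `n`, `N`, `K`, `k`, `p`, `p_adjust`, `mode`;
#'   sorted by adjusted then raw p.
#' @export
fisher_enrichment <- function(gene_list, background, term_map,
                              mode = c("ease", "fisher")) {
  mode <- match.arg(mode)
  gene_list <- unique(gene_list); background <- unique(background)
  if (!length(gene_list) || !length(background))
    stopf("gene list and background must be non-empty")
  if (!all(gene_list %in% background))
    stopf("gene list must be a subset of the background")
  n <- length(gene_list); N <- length(background)

  dropped <- sum(vapply(term_map, function(g) sum(!g %in% background),
                        integer(1)))
  if (dropped > 0)
    warning(sprintf("%d term annotations outside the background were dropped",
                    dropped), call. = FALSE)

  rows <- lapply(names(term_map), function(term) {
    genes <- intersect(term_map[[term]], background)
    K <- length(genes)
    k <- length(intersect(genes, gene_list))
    if (k < 1) return(NULL)
    keff <- if (mode == "ease") k - 1L else k
    # upper tail P(X >= keff); phyper(keff - 1, ...) with keff = 0 gives 1
    p <- phyper(keff - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, n = n, N = N, K = K, k = k, p = p)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(term = character(), n = integer(), N = integer(),
                       K = integer(), k = integer(), p = numeric())
  rows$p_adjust <- bh_adjust(rows$p)
  rows$mode <- rep(mode, nrow(rows))
  rows <- rows[order(rows$p_adjust, rows$p, rows$term), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("enrichment_result", "data.frame")
  rows
}
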