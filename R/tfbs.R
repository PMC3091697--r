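#' Promoter sequence set
#'
#' Upstream sequences keyed by gene id, with the declared extraction window
#' and a per-gene truncation flag (set when a promoter is shorter than the
#' window because it ran off the contig edge).
#'
#' @param seqs named character vector of uppercase DNA (may contain N).
#' @param window declared window length in bp.
#' @param truncated logical vector (recycled / defaulted from lengths).
#' @return object of class `promoter_set`.
#' @export
promoter_set <- function(seqs, window, truncated = NULL) {
  if (length(seqs) && (is.null(names(seqs)) || anyDuplicated(names(seqs))))
    stopf("promoter sequences need unique gene-id names")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (any(lens > window)) stopf("sequence longer than declared window")
  if (is.null(truncated)) truncated <- lens < window
  structure(list(seqs = seqs, window = window,
                 truncated = setNames(truncated, names(seqs))),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat("promoter_set:", length(x$seqs), "genes, window", x$window, "bp,",
      sum(x$truncated), "truncated\n")
  invisible(x)
}

#' IUPAC consensus motif
#'
#' @param name transcription-factor label.
#' @param consensus IUPAC nucleotide string (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @return object of class `motif_pattern`.
#' @export
motif_pattern <- function(name, consensus) {
  consensus <- toupper(consensus)
  if (!is_iupac(consensus))
    stopf("'%s' is not a valid non-empty IUPAC consensus", consensus)
  structure(list(name = name, consensus = consensus), class = "motif_pattern")
}

# IUPAC consensus -> regular expression with explicit base classes. An N in
# the subject never matches because classes only list A/C/G/T.
iupac_regex <- function(consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Extract upstream (promoter) windows from a genome
#'
#' For a plus-strand gene with translation start `s`, returns the genomic
#' interval `[s - window, s - 1]` (left-truncated at base 1); for a
#' minus-strand gene, `[s + 1, s + window]` (right-truncated at the contig
#' end), reverse-complemented. All sequences are reported 5'->3' relative to
#' the gene. Coordinates are 1-based inclusive.
#'
#' @param genes data frame with columns `id`, `contig`, `start` (translation
#'   start), `strand` (`+`/`-`).
#' @param genome named character vector or `Biostrings::DNAStringSet` of
#'   contig sequences.
#' @param window bp upstream of the translation start (default 2000).
#' @return a [promoter_set()]; per-gene failures (unknown contig, start
#'   outside the contig) are collected in `attr(, "errors")` rather than
#'   raised.
#' @export
extract_upstream <- function(genes, genome, window = 2000L) {
  need <- c("id", "contig", "start", "strand")
  if (!all(need %in% names(genes))) stopf("gene table lacks columns: %s",
    paste(setdiff(need, names(genes)), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  window <- check_count(window, "window", min = 1)
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  genome <- toupper(genome)

  seqs <- character(0); trunc <- logical(0)
  errors <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!g$contig %in% names(genome)) {
      errors[[length(errors) + 1L]] <- data.frame(
        id = g$id, reason = sprintf("unknown contig '%s'", g$contig))
      next
    }
    clen <- nchar(genome[[g$contig]])
    if (g$start < 1 || g$start > clen) {
      errors[[length(errors) + 1L]] <- data.frame(
        id = g$id, reason = "translation start outside contig")
      next
    }
    if (g$strand == "+") {
      from <- max(1L, g$start - window); to <- g$start - 1L
      s <- if (to >= from) substr(genome[[g$contig]], from, to) else ""
    } else {
      from <- g$start + 1L; to <- min(clen, g$start + window)
      s <- if (to >= from) revcomp(substr(genome[[g$contig]], from, to)) else ""
    }
    seqs[g$id] <- s
    trunc[g$id] <- nchar(s) < window
  }
  out <- promoter_set(seqs, window = window, truncated = trunc)
  attr(out, "errors") <- if (length(errors)) do.call(rbind, errors) else
    data.frame(id = character(), reason = character())
  out
}

#' Scan promoters for an IUPAC consensus motif
#'
#' Counts every exact IUPAC-compatible match, including overlapping ones, on
#' the requested strand(s). Minus-strand occurrences are located by scanning
#' the reverse complement of the motif on the stored sequence; all positions
#' are 1-based starts on the promoter as stored. An N in the promoter never
#' matches any pattern symbol.
#'
#' @param promoters a [promoter_set()].
#' @param motif a [motif_pattern()] (or a bare IUPAC string).
#' @param strands `"both"` (default), `"plus"` or `"minus"`.
#' @return data frame of class `scan_result`: `gene`, `plus`, `minus`
#'   (match counts) and `presence` (any match); match start positions per
#'   gene in `attr(, "positions")`, the motif name in `attr(, "motif")`.
#' @export
scan_promoters <- function(promoters, motif, strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  stopifnot(inherits(promoters, "promoter_set"))
  if (!inherits(motif, "motif_pattern")) motif <- motif_pattern(motif, motif)
  rx_plus <- sprintf("(?=%s)", iupac_regex(motif$consensus))
  rx_minus <- sprintf("(?=%s)", iupac_regex(revcomp(motif$consensus)))

  find <- function(seq, rx) {
    m <- gregexpr(rx, seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  genes <- names(promoters$seqs)
  pos <- lapply(genes, function(g) {
    s <- promoters$seqs[[g]]
    list(plus = if (strands %in% c("both", "plus")) find(s, rx_plus) else integer(0),
         minus = if (strands %in% c("both", "minus")) find(s, rx_minus) else integer(0))
  })
  names(pos) <- genes
  out <- data.frame(
    gene = genes,
    plus = vapply(pos, function(p) length(p$plus), integer(1)),
    minus = vapply(pos, function(p) length(p$minus), integer(1)),
    row.names = NULL)
  out$presence <- out$plus + out$minus > 0
  attr(out, "positions") <- pos
  attr(out, "motif") <- motif$name
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Pooled two-proportion z-test
#'
#' `z = (p1 - p2) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))` with the pooled
#' proportion `pbar = (x1 + x2)/(n1 + n2)`; two-sided normal p-value, no
#' continuity correction. A degenerate pooled proportion of 0 or 1 yields
#' `z = 0`, `p = 1`.
#'
#' @param x1,n1 foreground successes and size.
#' @param x2,n2 background successes and size.
#' @return list with `z`, `p`, `p1`, `p2`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stopf("cohort sizes must be >= 1")
  if (x1 > n1 || x2 > n2 || x1 < 0 || x2 < 0) stopf("need 0 <= x <= n")
  p1 <- x1 / n1; p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  if (pbar == 0 || pbar == 1) return(list(z = 0, p = 1, p1 = p1, p2 = p2))
  z <- (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Compare motif presence between regulated and control gene cohorts
#'
#' The tested quantity is presence/absence (>= 1 site anywhere on either
#' scanned strand) per gene: the percentage of genes carrying the motif in
#' the foreground (regulated) list is compared with that in the background
#' (non-regulated control) cohort by the pooled two-proportion z-test,
#' two-sided.
#'
#' @param foreground a [scan_promoters()] result over the regulated genes.
#' @param background a [scan_promoters()] result over the control cohort.
#' @param alpha significance level (default 0.05).
#' @return data frame (class `tfbs_comparison`) with one row: `motif`, `x1`,
#'   `n1`, `x2`, `n2`, `pct_fg`, `pct_bg`, `z`, `p`, `significant`.
#' @export
compare_tfbs_frequency <- function(foreground, background, alpha = 0.05) {
  stopifnot(inherits(foreground, "scan_result"),
            inherits(background, "scan_result"))
  x1 <- sum(foreground$presence); n1 <- nrow(foreground)
  x2 <- sum(background$presence); n2 <- nrow(background)
  zt <- two_proportion_z(x1, n1, x2, n2)
  out <- data.frame(
    motif = attr(foreground, "motif") %||% NA_character_,
    x1 = x1, n1 = n1, x2 = x2, n2 = n2,
    pct_fg = 100 * zt$p1, pct_bg = 100 * zt$p2,
    z = zt$z, p = zt$p, significant = zt$p < alpha)
  class(out) <- c("tfbs_comparison", "data.frame")
  out
}

#' Select a non-regulated control cohort
#'
#' Uniform sample, without replacement, of genes never called regulated at
#' any time point; reproducible under the seed.
#'
#' @param all_genes character vector of candidate gene ids.
#' @param regulated character vector of genes regulated at >= 1 time point.
#' @param size cohort size (default 198).
#' @param seed integer seed.
#' @return character vector of `size` gene ids.
#' @export
select_control_cohort <- function(all_genes, regulated, size = 198L, seed = 1L) {
  size <- check_count(size, "size")
  pool <- setdiff(unique(all_genes), regulated)
  if (length(pool) < size)
    stopf("only %d never-regulated genes available, need %d", length(pool), size)
  if (size == 0) return(character(0))
  if (length(pool) == size) return(sort(pool))
  withr::with_seed(sub_seed(seed, "cohort"), sort(sample(pool, size)))
}
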