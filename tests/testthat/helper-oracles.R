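# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the code paths they check.

# Step-up FDR adjustment written as the textbook definition: for each p_i,
# q_i = min over all p_j >= p_i of (p_(rank j) * m / rank j), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  sapply(seq_len(m), function(i) {
    cand <- sapply(seq_len(m), function(j) {
      r_j <- sum(p <= p[j])
      if (p[j] >= p[i]) p[j] * m / r_j else Inf
    })
    min(1, min(cand))
  })
}

# Upper-tail hypergeometric probability by direct summation of the counting
# formula, P(X >= k) = sum_i C(K,i) C(N-K, n-i) / C(N,n).
hyper_tail_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Naive IUPAC scanner: expand the motif to explicit per-position character
# sets and slide a window over the subject, comparing membership per
# position. Subject letters outside A/C/G/T (e.g. N) never match.
iupac_sets_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

naive_scan_oracle <- function(seq, motif) {
  sets <- iupac_sets_oracle[strsplit(toupper(motif), "")[[1]]]
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars); w <- length(sets)
  if (w > L) return(integer(0))
  hits <- integer(0)
  for (s in 1:(L - w + 1)) {
    ok <- TRUE
    for (j in 1:w) {
      if (!chars[s + j - 1] %in% sets[[j]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# Reverse complement via a hand-rolled IUPAC complement map (independent of
# Biostrings, which the implementation uses).
revcomp_oracle <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Small hand-built expression dataset: nr reporters, one or more time
# points, n replicates per condition, M supplied or zero.
toy_dataset <- function(M, times = 1, n_rep = 3,
                        conditions = c("depleted", "control")) {
  design <- expand.grid(replicate = seq_len(n_rep), time = times,
                        condition = conditions, stringsAsFactors = FALSE)
  design$array_id <- sprintf("%s_t%s_r%d", design$condition, design$time,
                             design$replicate)
  stopifnot(ncol(M) == nrow(design))
  colnames(M) <- design$array_id
  if (is.null(rownames(M))) rownames(M) <- sprintf("g%03d", seq_len(nrow(M)))
  A <- matrix(10, nrow(M), ncol(M), dimnames = dimnames(M))
  conf <- matrix(TRUE, nrow(M), ncol(M), dimnames = dimnames(M))
  expression_dataset(M, A, conf, design[, c("array_id", "condition",
                                            "time", "replicate")])
}

all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in all_perms(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}
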