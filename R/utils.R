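# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# IUPAC nucleotide codes mapped to the set of concrete bases each matches.
# An N in a *subject* sequence is never matched by any pattern symbol; these
# sets therefore contain only A/C/G/T.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_iupac <- function(x) {
  nchar(x) > 0 && all(strsplit(toupper(x), "")[[1]] %in% names(IUPAC_SETS))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single fraction in [0, 1]", name)
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stopf("'%s' must be a whole number >= %d", name, min)
  invisible(as.integer(x))
}

# Deterministic sub-seed for a named generator stream, all flowing from one
# master seed. Kept below 2^31 - 1 so it is a valid R integer.
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}
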