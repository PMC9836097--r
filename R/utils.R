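# Internal helpers shared across modules. All coordinates are 1-based
# inclusive and circular: position arithmetic is modulo chromosome length.

#' @importFrom stats quantile median sd cor.test kruskal.test setNames rnorm runif
#' @importFrom utils read.delim write.table
NULL

# map any integer offset onto [1, L]
circ_pos <- function(p, L) ((p - 1L) %% L) + 1L

# clockwise distance from a to b on a circle of length L (0 .. L-1)
circ_cw <- function(a, b, L) (b - a) %% L

# shortest circular distance between two positions (0 .. L/2)
circ_dist <- function(a, b, L) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

# circular midpoint of an interval; start > end means the interval wraps
circ_mid <- function(start, end, L) {
  span <- (end - start) %% L
  circ_pos(start + floor(span / 2), L)
}

# length in bp of a circular interval (start > end wraps)
circ_span <- function(start, end, L) ((end - start) %% L) + 1L

# does circular position p lie in the circular interval [start, end]?
circ_in <- function(p, start, end, L) {
  circ_cw(start, p, L) <= circ_cw(start, end, L)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# counts of A, C, G, T, N in a plain character string
base_counts <- function(s) {
  v <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                   letters = c("A", "C", "G", "T", "N"))
  stats::setNames(as.integer(v), c("A", "C", "G", "T", "N"))
}

# extract a circular subsequence [start, end] (wraps when start > end)
circ_substr <- function(seq, start, end) {
  L <- nchar(seq)
  if (start <= end) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, L), substr(seq, 1, end))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
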