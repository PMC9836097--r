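# Independent brute-force oracles used across the suite. These deliberately
# use naive character-level scans, direct formulas and hand-ranked
# statistics so they share no code path with the package implementation.

random_dna <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

oracle_base_counts <- function(s) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  c(A = sum(v == "A"), C = sum(v == "C"), G = sum(v == "G"),
    T = sum(v == "T"), N = sum(v == "N"))
}

oracle_gc_skew <- function(s) {
  n <- oracle_base_counts(s)
  gc <- n[["G"]] + n[["C"]]
  if (gc == 0) NA_real_ else (n[["G"]] - n[["C"]]) / gc
}

oracle_gc_content <- function(s) {
  n <- oracle_base_counts(s)
  tot <- n[["A"]] + n[["C"]] + n[["G"]] + n[["T"]]
  if (tot == 0) NA_real_ else (n[["G"]] + n[["C"]]) / tot
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# circular reference-strand substring, start > end wraps
oracle_region <- function(seq, start, end) {
  L <- nchar(seq)
  if (start <= end) substr(seq, start, end) else
    paste0(substr(seq, start, L), substr(seq, 1, end))
}

# naive codon tally of a coding-strand sequence (complete codons only)
oracle_codon_counts <- function(s) {
  len <- nchar(s) - nchar(s) %% 3
  counts <- integer(0)
  if (len >= 3) {
    for (i in seq(1, len, by = 3)) {
      cd <- substr(s, i, i + 2)
      counts[cd] <- (if (is.na(counts[cd])) 0L else counts[cd]) + 1L
    }
  }
  counts
}

# naive circular IUPAC scan: per-position letter-set comparison
oracle_motif_scan <- function(seq, motif) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  L <- nchar(seq)
  k <- nchar(motif)
  v <- strsplit(paste0(seq, substr(seq, 1, k - 1)), "", fixed = TRUE)[[1]]
  pat <- strsplit(motif, "", fixed = TRUE)[[1]]
  hits <- integer(0)
  for (i in seq_len(L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!v[i + j - 1] %in% sets[[pat[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# Kruskal-Wallis H from first principles (mid-ranks, tie correction)
oracle_kruskal_H <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# a small genome record built by hand for coordinate tests
toy_record <- function(seq = "ATGGCGTAAACCGGTTAACC",
                       genes = data.frame(gene_id = "g1", start = 1, end = 9,
                                          strand = "+")) {
  genome_record("toy", seq, genes)
}

# hand-built skew track (for peak-calling tests independent of sequence)
manual_track <- function(values, step = 10L, window = 10L, id = "toy") {
  n <- length(values)
  structure(list(chromosome_id = id,
                 positions = as.integer(seq(1L + window %/% 2L, by = step,
                                            length.out = n)),
                 values = as.numeric(values), window = as.integer(window),
                 step = as.integer(step), length = as.integer(n * step),
                 circular = TRUE),
            class = "skew_track")
}

# interval-set Jaccard on a circle, via base-resolution masks
circ_mask <- function(intervals, L) {
  m <- logical(L)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (s <= e) m[s:e] <- TRUE else m[c(s:L, 1:e)] <- TRUE
  }
  m
}

mask_jaccard <- function(m1, m2) sum(m1 & m2) / sum(m1 | m2)
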