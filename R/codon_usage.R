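# Codon-usage statistics: per-group codon counts, relative usage between
# peak and background gene sets, per-codon GC composition and skew,
# matched-codon groups, and rank correlations. Genetic code: bacterial
# translation table 11 (identical to the standard code for translation).

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# cached per-codon letter matrix (64 x 3), built once at install time
.CODON_LETTERS <- local({
  b <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  m <- matrix(unlist(strsplit(cods, "")), ncol = 3, byrow = TRUE)
  rownames(m) <- cods
  m
})

codon_amino_acid <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  unname(ifelse(is.na(aa), NA_character_, aa))
}

#' Count codons over a gene set
#'
#' Codons are read 5'->3' on each gene's coding strand (`-` strand genes
#' are reverse-complemented first). Genes whose length is not a multiple
#' of 3 contribute their complete codons only (with a warning); genes
#' containing `N` are excluded.
#'
#' @param record A [genome_record].
#' @param gene_ids Gene identifiers (default: all genes of the record).
#' @return Named integer vector of length 64 (codon -> count), with
#'   attributes `genome_id` and `n_genes`.
#' @export
codon_counts <- function(record, gene_ids = record$genes$gene_id) {
  if (!length(gene_ids)) stop("empty gene set")
  missing <- setdiff(gene_ids, record$genes$gene_id)
  if (length(missing)) stop("unknown gene_ids: ", paste(missing, collapse = ", "))
  counts <- stats::setNames(integer(64), all_codons())
  n_used <- 0L
  ragged <- 0L
  for (gid in gene_ids) {
    s <- gene_sequence(record, gid)
    if (grepl("N", s, fixed = TRUE)) next
    len <- nchar(s)
    if (len %% 3L != 0L) {
      ragged <- ragged + 1L
      len <- len - len %% 3L
      if (len == 0L) next
      s <- substr(s, 1L, len)
    }
    cod <- substring(s, seq(1L, len, by = 3L), seq(3L, len, by = 3L))
    tab <- table(factor(cod, levels = all_codons()))
    counts <- counts + as.integer(tab)
    n_used <- n_used + 1L
  }
  if (ragged) warning(ragged, " gene(s) not divisible by 3; trailing bases dropped")
  attr(counts, "genome_id") <- record$id
  attr(counts, "n_genes") <- n_used
  counts
}

# codon counts -> frequencies over sense codons (stops excluded)
codon_frequencies <- function(counts, drop_stops = TRUE) {
  cods <- names(counts)
  if (drop_stops) {
    keep <- codon_amino_acid(cods) != "*"
    counts <- counts[keep]
  }
  tot <- sum(counts)
  if (tot == 0) return(stats::setNames(rep(NA_real_, length(counts)), names(counts)))
  counts / tot
}

#' Relative codon usage between a peak and a background profile
#'
#' Counts are first normalized to frequencies within each group (over
#' sense codons) so that genome and group size do not dominate. In
#' `difference_ratio` mode (default) the statistic per codon is
#' `(f_peak - f_non_peak) / f_non_peak`; in `ratio` mode it is
#' `f_peak / f_non_peak`. Codons absent from the background are `NA`.
#'
#' When lists of per-genome profiles are supplied, the per-genome values
#' are computed first and summarized codon-wise by the cohort median.
#'
#' @param peak,non_peak Codon count vectors from [codon_counts], or lists
#'   of such vectors (one per genome).
#' @param mode `"difference_ratio"` or `"ratio"`.
#' @return Named numeric vector over sense codons, with attribute `mode`;
#'   for list input the cohort median per codon.
#' @export
relative_codon_usage <- function(peak, non_peak,
                                 mode = c("difference_ratio", "ratio")) {
  mode <- match.arg(mode)
  if (is.list(peak) || is.list(non_peak)) {
    stopifnot(is.list(peak), is.list(non_peak), length(peak) == length(non_peak))
    per <- mapply(function(p, np) relative_codon_usage(p, np, mode),
                  peak, non_peak)
    out <- apply(per, 1, stats::median, na.rm = TRUE)
    attr(out, "mode") <- mode
    return(out)
  }
  fp <- codon_frequencies(peak)
  fn <- codon_frequencies(non_peak)
  out <- ifelse(is.na(fn) | fn == 0, NA_real_,
                if (mode == "difference_ratio") (fp - fn) / fn else fp / fn)
  out <- stats::setNames(as.numeric(out), names(fp))
  attr(out, "mode") <- mode
  out
}

#' Per-codon GC composition and skew
#'
#' For each codon: its amino acid (one-letter code, `*` for stops), its GC
#' count (number of G or C bases, 0-3), and its GC skew
#' `(#G - #C)/(#G + #C)` (`NA` when the codon has no G or C).
#'
#' @param codons Character vector of DNA triplets (default: all 64).
#' @return `data.frame` with columns `codon`, `amino_acid`, `gc_count`,
#'   `g_count`, `c_count`, `gc_skew`.
#' @export
codon_gc_stats <- function(codons = all_codons()) {
  if (any(!codons %in% all_codons())) {
    stop("non-ACGT triplet: ",
         paste(setdiff(codons, all_codons()), collapse = ", "))
  }
  g <- rowSums(.CODON_LETTERS[codons, , drop = FALSE] == "G")
  c_ <- rowSums(.CODON_LETTERS[codons, , drop = FALSE] == "C")
  gc <- g + c_
  data.frame(codon = codons, amino_acid = codon_amino_acid(codons),
             gc_count = gc, g_count = unname(g), c_count = unname(c_),
             gc_skew = ifelse(gc == 0, NA_real_, (g - c_) / gc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Matched codon groups: same amino acid, same GC content
#'
#' Groups sense codons that encode the same amino acid with identical GC
#' count (GC count > 0), keeping only groups of two or more codons. Within
#' such a group the codons differ only in their G-versus-C balance, so
#' comparing their usage isolates GC-skew preference from GC-content
#' effects.
#'
#' @return `data.frame` of the retained codons with columns `group`
#'   (`"<aa>_gc<k>"`), `codon`, `amino_acid`, `gc_count`, `gc_skew`.
#' @export
matched_codon_table <- function() {
  st <- codon_gc_stats()
  st <- st[st$amino_acid != "*" & st$gc_count > 0, , drop = FALSE]
  st$group <- paste0(st$amino_acid, "_gc", st$gc_count)
  sizes <- table(st$group)
  st <- st[st$group %in% names(sizes)[sizes >= 2L], , drop = FALSE]
  st <- st[order(st$group, st$codon), c("group", "codon", "amino_acid",
                                        "gc_count", "gc_skew")]
  row.names(st) <- NULL
  st
}

#' Spearman correlation of codon usage with codon composition
#'
#' Rank correlation between per-codon (median) relative usage and a codon
#' covariate: GC count, GC skew, G count or C count. Codons with undefined
#' usage or covariate (e.g. GC skew of GC-free codons) are excluded.
#'
#' @param usage Named numeric vector of per-codon relative usage (names are
#'   codons).
#' @param covariate One of `"gc_count"`, `"gc_skew"`, `"g_count"`,
#'   `"c_count"`.
#' @return List with `rho`, `p.value`, `n`.
#' @export
usage_correlations <- function(usage,
                               covariate = c("gc_count", "gc_skew",
                                             "g_count", "c_count")) {
  covariate <- match.arg(covariate)
  st <- codon_gc_stats(names(usage))
  x <- st[[covariate]]
  ok <- !is.na(usage) & !is.na(x)
  if (sum(ok) < 4L) stop("need >= 4 codons with defined values")
  if (length(unique(x[ok])) == 1L) stop("constant covariate")
  ct <- suppressWarnings(
    stats::cor.test(usage[ok], x[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = sum(ok))
}
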