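# IUPAC motif scanning on circular chromosomes and positional profiles.
# The CcrM methylation motif GANTC is self-reverse-complementary as a
# pattern, so reference-strand scanning finds the same site set as
# double-strand scanning; non-palindromic motifs are scanned on both
# strands.

iupac_ok <- function(motif) {
  grepl("^[ACGTRYSWKMBDHVN]+$", motif)
}

# is the IUPAC pattern its own reverse complement (as a degenerate set)?
iupac_palindromic <- function(motif) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  identical(rc, motif)
}

#' Find IUPAC motif sites on a circular chromosome
#'
#' Reports all (possibly overlapping) match start positions on the
#' reference strand, including matches wrapping across the origin of
#' coordinates. `N` bases in the chromosome never match any pattern
#' position. Palindromic patterns (such as `GANTC`) are scanned on the
#' reference strand only; non-palindromic patterns are additionally
#' scanned on the reverse strand, positions reported as reference-strand
#' match starts with a `strand` column.
#'
#' @param record A [genome_record] or plain DNA string.
#' @param motif IUPAC motif (default `"GANTC"`).
#' @return `data.frame` with columns `start` (sorted) and `strand`.
#' @export
find_motif_sites <- function(record, motif = "GANTC") {
  if (!iupac_ok(motif)) stop("invalid IUPAC code in motif: ", motif)
  seq <- if (inherits(record, "genome_record")) record$sequence else record
  L <- nchar(seq)
  k <- nchar(motif)
  pad <- if (k > 1L) substr(seq, 1L, min(k - 1L, L)) else ""
  padded <- Biostrings::DNAString(paste0(seq, pad))
  scan_one <- function(pat) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), padded,
                                  fixed = FALSE)
    st <- Biostrings::start(m)
    if (length(st)) {
      # Biostrings lets subject N satisfy degenerate pattern codes; the
      # contract here is that N never matches
      hasN <- vapply(as.character(m), function(x)
        grepl("N", x, fixed = TRUE), logical(1))
      st <- st[!hasN]
    }
    sort(st[st <= L])
  }
  plus <- scan_one(motif)
  out <- data.frame(start = plus,
                    strand = rep("+", length(plus)),
                    stringsAsFactors = FALSE)
  if (!iupac_palindromic(motif)) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    minus <- scan_one(rc)
    out <- rbind(out, data.frame(start = minus,
                                 strand = rep("-", length(minus)),
                                 stringsAsFactors = FALSE))
    out <- out[!duplicated(out[c("start", "strand")]), , drop = FALSE]
  }
  out <- out[order(out$start), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Equal-composition control motifs for GANTC
#'
#' Returns the two permuted patterns with the same base composition as
#' GANTC (`CGANT`, `CTGAN`), used to check that a positional pattern of
#' GANTC sites is not a mere base-composition effect.
#'
#' @param motif Must be `"GANTC"`; controls for other motifs must be
#'   supplied by the user.
#' @return Character vector `c("CGANT", "CTGAN")`.
#' @export
control_motifs <- function(motif = "GANTC") {
  if (!identical(toupper(motif), "GANTC")) {
    stop("controls are defined for GANTC only; supply your own for ", motif)
  }
  c("CGANT", "CTGAN")
}

#' Binned positional profile of motif sites
#'
#' Counts sites per equal-width bin on the normalized chromosome.
#'
#' @param sites Integer vector of site start positions (or the
#'   `data.frame` from [find_motif_sites]).
#' @param chromosome_length Chromosome length in bp.
#' @param n_bins Number of bins (default 100).
#' @return Integer vector of length `n_bins`.
#' @export
binned_profile <- function(sites, chromosome_length, n_bins = 100L) {
  if (is.data.frame(sites)) sites <- sites$start
  if (length(sites) && (min(sites) < 1L || max(sites) > chromosome_length)) {
    stop("sites outside [1, chromosome_length]")
  }
  if (!length(sites)) return(integer(n_bins))
  bin <- pmin(floor((sites - 1) * n_bins / chromosome_length) + 1L, n_bins)
  tabulate(bin, nbins = n_bins)
}

#' Cumulative positional profile of motif sites
#'
#' Cumulative site count along the chromosome normalized to `n_points`
#' positions; the chromosome is assumed already reoriented to the desired
#' anchor (ori or a gene, via [reorient_to_position] / [reorient_to_gene]).
#'
#' @inheritParams binned_profile
#' @param n_points Number of normalized positions (default 1000).
#' @return Non-decreasing integer vector of length `n_points`; its last
#'   element is the total number of sites.
#' @export
cumulative_profile <- function(sites, chromosome_length, n_points = 1000L) {
  if (is.data.frame(sites)) sites <- sites$start
  if (!length(sites)) return(integer(n_points))
  pt <- pmin(pmax(ceiling(sites * n_points / chromosome_length), 1L), n_points)
  cumsum(tabulate(pt, nbins = n_points))
}
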