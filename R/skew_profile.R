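# GC content and GC skew: windowed tracks over circular chromosomes,
# cohort-averaged normalized profiles, relative skews, and peak calling by
# sliding local quantiles.

#' GC skew of a DNA segment
#'
#' GC skew is `(G - C) / (G + C)`. `N` bases are ignored; a segment with no
#' G or C has undefined skew, reported as `NA` (never 0).
#'
#' @param segment Character vector of DNA strings.
#' @return Numeric vector in `[-1, 1]`, `NA` where `G + C = 0`.
#' @export
gc_skew <- function(segment) {
  if (!length(segment) || any(!nzchar(segment))) stop("empty segment")
  vapply(segment, function(s) {
    n <- base_counts(s)
    gc <- n[["G"]] + n[["C"]]
    if (gc == 0L) NA_real_ else (n[["G"]] - n[["C"]]) / gc
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC content of a DNA segment
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from both numerator
#' and denominator.
#'
#' @param segment Character vector of DNA strings.
#' @return Numeric vector in `[0, 1]` (`NA` if the segment is all `N`).
#' @export
gc_content <- function(segment) {
  if (!length(segment) || any(!nzchar(segment))) stop("empty segment")
  vapply(segment, function(s) {
    n <- base_counts(s)
    acgt <- sum(n[c("A", "C", "G", "T")])
    if (acgt == 0L) NA_real_ else (n[["G"]] + n[["C"]]) / acgt
  }, numeric(1), USE.NAMES = FALSE)
}

# cumulative G and C indicator sums with circular padding of `pad` bases;
# returns closures counting G and C in [i, j] of the padded sequence
circ_base_cumsums <- function(seq, pad) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (pad > 0L) v <- c(v, v[seq_len(min(pad, length(v)))])
  list(G = c(0L, cumsum(v == "G")), C = c(0L, cumsum(v == "C")))
}

#' Windowed GC-skew track of a circular chromosome
#'
#' Slides a window of `window` bp (default 10 kb) around the circular
#' chromosome in steps of `step` bp and records `(G - C)/(G + C)` per
#' placement. Windows wrap across the origin of coordinates; each value is
#' anchored at its window's centre position.
#'
#' @param record A [genome_record], or a plain DNA string.
#' @param window Window size in bp (default 10000).
#' @param step Step between window starts in bp (default `window / 10`).
#'
#' @return A `skew_track`: list with `chromosome_id`, `positions` (window
#'   centres, bp), `values` (`NA` where `G + C = 0`), `window`, `step`,
#'   `circular = TRUE`.
#' @export
skew_track <- function(record, window = 10000L, step = max(1L, window %/% 10L)) {
  seq <- if (inherits(record, "genome_record")) record$sequence else record
  id <- if (inherits(record, "genome_record")) record$id else "chr"
  L <- nchar(seq)
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L) stop("window must be >= 1")
  if (window > L) stop("window exceeds chromosome length")
  cs <- circ_base_cumsums(seq, pad = window - 1L)
  starts <- seq.int(1L, L, by = step)
  gw <- cs$G[starts + window] - cs$G[starts]
  cw <- cs$C[starts + window] - cs$C[starts]
  tot <- gw + cw
  vals <- ifelse(tot == 0L, NA_real_, (gw - cw) / tot)
  structure(
    list(chromosome_id = id,
         positions = as.integer(circ_pos(starts + window %/% 2L, L)),
         values = as.numeric(vals),
         window = window, step = step, length = L, circular = TRUE),
    class = "skew_track")
}

#' @export
print.skew_track <- function(x, ...) {
  cat("<skew_track> ", x$chromosome_id, ": ", length(x$values),
      " windows of ", x$window, " bp (step ", x$step, ")\n", sep = "")
  cat("  skew range ", paste(round(range(x$values, na.rm = TRUE), 4),
                             collapse = " .. "), "\n", sep = "")
  invisible(x)
}

# skew in n_bins equal non-overlapping bins starting at coordinate 1
binned_skew <- function(record, n_bins = 1000L) {
  seq <- if (inherits(record, "genome_record")) record$sequence else record
  L <- nchar(seq)
  cs <- circ_base_cumsums(seq, pad = 0L)
  bounds <- floor(seq(0, L, length.out = n_bins + 1L))
  g <- diff(cs$G[bounds + 1L])
  c_ <- diff(cs$C[bounds + 1L])
  tot <- g + c_
  ifelse(tot == 0, NA_real_, (g - c_) / tot)
}

#' Cohort-mean normalized GC-skew profile
#'
#' For each chromosome, computes GC skew in non-overlapping bins of 0.1 % of
#' its length (1000 bins by default) clockwise from coordinate 1 (records
#' are expected to be ori-oriented), then averages bin-wise across the
#' cohort. Undefined bins are excluded from each mean.
#'
#' @param records List of ori-oriented [genome_record]s.
#' @param n_bins Number of bins (default 1000).
#' @return Numeric vector of length `n_bins`.
#' @export
mean_normalized_track <- function(records, n_bins = 1000L) {
  if (inherits(records, "genome_record")) records <- list(records)
  if (!length(records)) stop("empty genome list")
  m <- vapply(records, binned_skew, numeric(n_bins), n_bins = n_bins)
  rowMeans(m, na.rm = TRUE)
}

#' Call GC-skew peaks by sliding local quantiles
#'
#' A track position is flagged `high` (`low`) when its skew value is
#' strictly greater (smaller) than the empirical `1 - quantile`
#' (`quantile`) order-statistic of the defined track values inside the
#' `local_window` bp window centred on it (circular). Runs of adjacent
#' flagged positions are merged; each flagged position contributes its step
#' bin, so an interval spans the flagged run plus half a step on each side.
#'
#' @param track A [skew_track].
#' @param quantile Tail fraction (default 0.03, i.e. upper/lower 3 %).
#' @param local_window Width of the local pool in bp (default 150000). When
#'   it exceeds the chromosome length, global quantiles are used with a
#'   warning.
#'
#' @return A `peak_annotation`: list with `chromosome_id`, `intervals`
#'   (`data.frame` start, end, side in `{high, low}`; `start > end` wraps),
#'   `quantile`, `local_window`, and the flag vector `flagged` parallel to
#'   the track.
#' @export
detect_skew_peaks <- function(track, quantile = 0.03, local_window = 150000L) {
  stopifnot(inherits(track, "skew_track"))
  if (quantile <= 0 || quantile >= 0.5) stop("quantile must be in (0, 0.5)")
  if (local_window < track$window) stop("local_window must be >= track window")
  v <- track$values
  n <- length(v)
  L <- track$length
  global <- local_window >= L
  if (global) {
    warning("local_window exceeds chromosome length; using global quantiles")
  }
  side <- rep(NA_character_, n)
  if (global) {
    pool <- v[!is.na(v)]
    hi <- stats::quantile(pool, 1 - quantile, type = 1, names = FALSE)
    lo <- stats::quantile(pool, quantile, type = 1, names = FALSE)
    side[!is.na(v) & v > hi] <- "high"
    side[!is.na(v) & v < lo] <- "low"
  } else {
    half <- as.integer(floor((local_window / 2) / track$step))
    for (i in seq_len(n)) {
      if (is.na(v[i])) next
      idx <- ((i - half):(i + half) - 1L) %% n + 1L
      pool <- v[idx]
      pool <- pool[!is.na(pool)]
      hi <- stats::quantile(pool, 1 - quantile, type = 1, names = FALSE)
      lo <- stats::quantile(pool, quantile, type = 1, names = FALSE)
      if (v[i] > hi) side[i] <- "high" else if (v[i] < lo) side[i] <- "low"
    }
  }
  intervals <- flags_to_intervals(side, track)
  structure(
    list(chromosome_id = track$chromosome_id, intervals = intervals,
         quantile = quantile, local_window = as.integer(local_window),
         flagged = side, positions = track$positions, length = L),
    class = "peak_annotation")
}

# merge runs of adjacent same-side flags into bp intervals; each flagged
# position covers its step bin [centre - step/2, centre + step/2)
flags_to_intervals <- function(side, track) {
  n <- length(side)
  L <- track$length
  halfstep <- track$step %/% 2L
  out <- data.frame(start = integer(), end = integer(), side = character(),
                    stringsAsFactors = FALSE)
  if (!any(!is.na(side))) return(out)
  # runs over the circular index sequence: unwrap by rotating to an
  # unflagged position when one exists
  rot <- which(is.na(side))[1]
  if (is.na(rot)) rot <- 1L
  ord <- ((rot:(rot + n - 1L)) - 1L) %% n + 1L
  s <- side[ord]
  r <- rle(ifelse(is.na(s), ".", s))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "."
  res <- lapply(which(keep), function(k) {
    i1 <- ord[starts[k]]; i2 <- ord[ends[k]]
    data.frame(
      start = as.integer(circ_pos(track$positions[i1] - halfstep, L)),
      end = as.integer(circ_pos(track$positions[i2] + halfstep, L)),
      side = r$values[k], stringsAsFactors = FALSE)
  })
  if (!length(res)) return(out)
  res <- do.call(rbind, res)
  res[order(res$start), , drop = FALSE]
}

#' @export
print.peak_annotation <- function(x, ...) {
  cat("<peak_annotation> ", x$chromosome_id, ": ",
      sum(x$intervals$side == "high"), " high / ",
      sum(x$intervals$side == "low"), " low intervals (q = ", x$quantile,
      ", local window ", x$local_window, " bp)\n", sep = "")
  invisible(x)
}

#' Relative GC skew of a sample region versus a control
#'
#' `(skew_sample - skew_control) / skew_control`; undefined (`NA`) when the
#' control skew is zero.
#'
#' @param sample,control Numeric skew values (vectorized).
#' @return Numeric vector.
#' @export
relative_skew <- function(sample, control) {
  ifelse(is.na(control) | control == 0, NA_real_,
         (sample - control) / control)
}

#' Per-gene GC skew and GC content
#'
#' Skew and content of each gene's chromosomal region, computed on the
#' reference (+) strand regardless of the gene's coding strand. The
#' reference-strand convention is what makes per-replichore typicality
#' (positive skew on the right replichore, negative on the left) comparable
#' across genes of either orientation.
#'
#' @param record A [genome_record].
#' @return `data.frame` with columns `gene_id`, `skew`, `gc_content`.
#' @export
per_gene_skew <- function(record) {
  g <- record$genes
  if (!nrow(g)) {
    return(data.frame(gene_id = character(), skew = numeric(),
                      gc_content = numeric(), stringsAsFactors = FALSE))
  }
  segs <- mapply(function(s, e) region_sequence(record, s, e),
                 g$start, g$end)
  data.frame(gene_id = g$gene_id, skew = gc_skew(segs),
             gc_content = gc_content(segs), stringsAsFactors = FALSE)
}

#' Label genes as peak or non-peak by midpoint membership
#'
#' A gene is `peak` iff its circular midpoint lies inside a flagged
#' interval of the peak annotation.
#'
#' @param record A [genome_record].
#' @param peaks A `peak_annotation` for the same chromosome.
#' @param sides Which interval sides count as peak (default both).
#' @return `data.frame` with columns `gene_id`, `label` (`"peak"` /
#'   `"non_peak"`), `side` (`NA` for non-peak genes).
#' @export
assign_genes_to_peaks <- function(record, peaks, sides = c("high", "low")) {
  stopifnot(inherits(peaks, "peak_annotation"))
  if (!identical(record$id, peaks$chromosome_id)) {
    stop("chromosome id mismatch: record '", record$id, "' vs peaks '",
         peaks$chromosome_id, "'")
  }
  mids <- gene_midpoints(record)
  iv <- peaks$intervals[peaks$intervals$side %in% sides, , drop = FALSE]
  lab <- rep("non_peak", length(mids))
  hit_side <- rep(NA_character_, length(mids))
  if (nrow(iv)) {
    for (j in seq_len(nrow(iv))) {
      inside <- circ_in(mids, iv$start[j], iv$end[j], record$length)
      lab[inside] <- "peak"
      hit_side[inside] <- iv$side[j]
    }
  }
  data.frame(gene_id = record$genes$gene_id, label = lab, side = hit_side,
             stringsAsFactors = FALSE)
}
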