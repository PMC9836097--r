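# Replichore assignment, leading/lagging strand, typical-skew versus
# potential-inversion classification, repeat filtering and gene-to-repeat
# distance classes.

#' Replichore model of a circular chromosome
#'
#' The origin and terminus of replication split the circle into the right
#' replichore (the arc ori -> ter, clockwise, i.e. in increasing
#' coordinates) and the left replichore (ter -> ori).
#'
#' @param ori,ter Origin and terminus positions (1-based); must differ.
#' @param length Chromosome length in bp.
#' @return An object of class `replichore_model`.
#' @export
replichore_model <- function(ori, ter, length) {
  ori <- as.integer(ori); ter <- as.integer(ter); length <- as.integer(length)
  if (ori == ter) stop("ori and ter must differ")
  structure(list(ori = ori, ter = ter, length = length),
            class = "replichore_model")
}

#' Infer the replication terminus
#'
#' `antipodal` (default) places ter diametrically opposite ori. The
#' `skew_extremum` method takes the maximum of the cumulative binned GC
#' skew of the ori-oriented chromosome: on a chromosome with the typical
#' skew pattern the cumulative skew rises along the right replichore and
#' falls along the left, peaking at ter.
#'
#' @param record A [genome_record] with `ori` set.
#' @param method `"antipodal"` or `"skew_extremum"`.
#' @param n_bins Bins used by the skew-extremum method (default 1000).
#' @return Terminus position (1-based integer).
#' @export
infer_ter <- function(record, method = c("antipodal", "skew_extremum"),
                      n_bins = 1000L) {
  method <- match.arg(method)
  if (is.null(record$ori)) stop("ori unset")
  L <- record$length
  if (method == "antipodal") {
    return(as.integer(circ_pos(record$ori + L %/% 2L, L)))
  }
  oriented <- if (record$ori == 1L) record else
    reorient_to_position(record, record$ori)
  b <- binned_skew(oriented, n_bins = n_bins)
  b[is.na(b)] <- 0
  k <- which.max(cumsum(b))
  # centre of the k-th bin, mapped back to the original coordinates
  pos_oriented <- round((k - 0.5) * L / n_bins)
  as.integer(circ_pos(pos_oriented + record$ori - 1L, L))
}

#' Classify genes by replichore, strand class, and skew typicality
#'
#' For each gene: the replichore is decided by its circular midpoint; the
#' gene is `leading` (co-directional with the replication fork) iff it is
#' on the `+` strand of the right replichore or the `-` strand of the left
#' replichore, else `lagging`. The GC skew sign (reference strand) then
#' decides typicality: `typical` iff positive on the right replichore or
#' negative on the left; any non-zero deviation from that pattern is a
#' `potential_inversion`. Genes whose midpoint falls exactly on ori or ter
#' are assigned to the right replichore.
#'
#' @param record A [genome_record].
#' @param model A [replichore_model]; defaults to the record's `ori` with an
#'   antipodal ter.
#' @param gene_skew Optional numeric vector of per-gene reference-strand GC
#'   skews (defaults to [per_gene_skew] of the record).
#'
#' @return `data.frame` with columns `gene_id`, `replichore`
#'   (`right`/`left`), `strand_class` (`leading`/`lagging`), `orientation`
#'   (`co_directional`/`head_on`), `skew_sign`
#'   (`positive`/`negative`/`zero`), `typical`, `potential_inversion`
#'   (both `NA` when the skew sign is zero/undefined).
#' @export
classify_gene_architecture <- function(record, model = NULL, gene_skew = NULL) {
  g <- record$genes
  L <- record$length
  if (is.null(model)) {
    ter <- record$ter %||% infer_ter(record, "antipodal")
    model <- replichore_model(record$ori, ter, L)
  }
  if (is.null(gene_skew)) gene_skew <- per_gene_skew(record)$skew
  if (length(gene_skew) != nrow(g)) stop("gene_skew length mismatch")
  mids <- gene_midpoints(record)
  # right replichore: the arc [ori, ter) clockwise; midpoint on ori or ter
  # counts as right
  arc_right <- circ_cw(model$ori, model$ter, L)
  d <- circ_cw(model$ori, mids, L)
  repl <- ifelse(d <= arc_right, "right", "left")
  leading <- (repl == "right" & g$strand == "+") |
    (repl == "left" & g$strand == "-")
  sign_ <- ifelse(is.na(gene_skew) | gene_skew == 0, "zero",
                  ifelse(gene_skew > 0, "positive", "negative"))
  typical <- ifelse(sign_ == "zero", NA,
                    (repl == "right" & sign_ == "positive") |
                      (repl == "left" & sign_ == "negative"))
  data.frame(
    gene_id = g$gene_id,
    replichore = repl,
    strand_class = ifelse(leading, "leading", "lagging"),
    orientation = ifelse(leading, "co_directional", "head_on"),
    skew_sign = sign_,
    typical = typical,
    potential_inversion = ifelse(is.na(typical), NA, !typical),
    stringsAsFactors = FALSE)
}

#' Per-genome architecture proportions
#'
#' Summarizes [classify_gene_architecture] output per genome (and
#' optionally per gene subset): percentage of genes on the leading and
#' lagging strand, percentage following the typical GC skew, the four
#' strand-by-typicality categories, and cross-genome means and standard
#' deviations. Genes with zero/undefined skew are reported separately and
#' excluded from typicality percentages.
#'
#' @param records List of [genome_record]s (or a single record).
#' @param gene_sets Optional named list mapping a group label to a list
#'   (indexed like `records`) of gene-id vectors; the special group `all`
#'   is always included.
#' @return List with `per_genome` (`data.frame`, one row per genome x
#'   group) and `summary` (mean and sd of each percentage per group).
#' @export
architecture_summary <- function(records, gene_sets = NULL) {
  if (inherits(records, "genome_record")) records <- list(records)
  if (!length(records)) stop("empty input")
  groups <- c(list(all = NULL), gene_sets)
  rows <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    cls <- classify_gene_architecture(rec)
    for (grp in names(groups)) {
      sel <- cls
      if (!is.null(groups[[grp]])) {
        sel <- cls[cls$gene_id %in% groups[[grp]][[i]], , drop = FALSE]
      }
      n <- nrow(sel)
      if (!n) next
      defined <- sel[!is.na(sel$typical), , drop = FALSE]
      nd <- nrow(defined)
      pct <- function(x) if (nd) 100 * sum(x) / nd else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = rec$id, group = grp, n_genes = n, n_skew_defined = nd,
        pct_leading = 100 * mean(sel$strand_class == "leading"),
        pct_lagging = 100 * mean(sel$strand_class == "lagging"),
        pct_typical = pct(defined$typical),
        pct_leading_typical = pct(defined$strand_class == "leading" & defined$typical),
        pct_leading_inverted = pct(defined$strand_class == "leading" & !defined$typical),
        pct_lagging_typical = pct(defined$strand_class == "lagging" & defined$typical),
        pct_lagging_inverted = pct(defined$strand_class == "lagging" & !defined$typical),
        stringsAsFactors = FALSE)
    }
  }
  per_genome <- do.call(rbind, rows)
  num <- names(per_genome)[vapply(per_genome, is.numeric, logical(1))]
  num <- setdiff(num, c("n_genes", "n_skew_defined"))
  summ <- do.call(rbind, lapply(split(per_genome, per_genome$group), function(d) {
    data.frame(group = d$group[1],
               stat = c("mean", "sd"),
               rbind(colMeans(d[num], na.rm = TRUE),
                     apply(d[num], 2, stats::sd, na.rm = TRUE)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(per_genome = per_genome, summary = summ)
}

#' Kruskal-Wallis comparison of per-genome proportions across categories
#'
#' Thin wrapper over [stats::kruskal.test] for comparing per-genome
#' category proportions (e.g. the four strand-by-typicality categories)
#' across groups. When every observation is identical the statistic is
#' degenerate and `p = 1` is reported with a warning.
#'
#' @param values Numeric vector of observations, or a list of numeric
#'   vectors (one per category).
#' @param groups Category labels parallel to `values` (ignored when
#'   `values` is a list).
#' @return List with `statistic` (H), `df`, and `p.value`.
#' @export
compare_groups_kruskal <- function(values, groups = NULL) {
  if (is.list(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 categories")
  if (any(table(groups) < 2L)) stop("need >= 2 observations per category")
  if (length(unique(values)) == 1L) {
    warning("all values identical; p-value undefined, reporting 1")
    return(list(statistic = 0, df = nlevels(groups) - 1L, p.value = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Filter a repeat table to long, high-identity, non-overlapping pairs
#'
#' Keeps repeat pairs strictly longer than `min_len` bp and with identity
#' strictly above `min_identity`, and discards pairs whose two copies
#' overlap each other (tandem / self-overlapping repeats).
#'
#' @param repeats `data.frame` with columns `start1`, `end1`, `start2`,
#'   `end2`, `length`, `identity` (identity as a fraction in `[0, 1]`).
#' @param min_len Length threshold in bp (default 800, strict).
#' @param min_identity Identity threshold (default 0.90, strict).
#' @return The filtered `data.frame`. Malformed rows (NA in any used
#'   column) are dropped with a message.
#' @export
filter_repeats <- function(repeats, min_len = 800, min_identity = 0.90) {
  need <- c("start1", "end1", "start2", "end2", "length", "identity")
  if (!all(need %in% names(repeats))) {
    stop("repeat table must have columns ", paste(need, collapse = ", "))
  }
  ok <- stats::complete.cases(repeats[need])
  if (any(!ok)) message("dropping ", sum(!ok), " malformed repeat rows")
  r <- repeats[ok, , drop = FALSE]
  keep <- r$length > min_len & r$identity > min_identity
  r <- r[keep, , drop = FALSE]
  overlapping <- r$start1 <= r$end2 & r$start2 <= r$end1
  r[!overlapping, , drop = FALSE]
}

#' Classify genes as near or far from repeats
#'
#' For each gene, the distance is the minimum circular gap (bp) between the
#' gene interval and any repeat copy, 0 when they overlap. A gene is `far`
#' iff its distance exceeds `length / 1000` of the genome size, `near`
#' otherwise.
#'
#' @param record A [genome_record].
#' @param repeats Filtered repeat table (see [filter_repeats]).
#' @param threshold Distance threshold in bp (default `length / 1000`).
#' @return `data.frame` with columns `gene_id`, `distance`, `class`. With
#'   no repeats every gene is `far` at the capped distance `length / 2`
#'   (with a warning).
#' @export
repeat_distance_class <- function(record, repeats,
                                  threshold = record$length / 1000) {
  g <- record$genes
  L <- record$length
  if (!nrow(repeats)) {
    warning("no repeats on chromosome; all genes classed far at distance L/2")
    return(data.frame(gene_id = g$gene_id, distance = rep(L / 2, nrow(g)),
                      class = rep("far", nrow(g)), stringsAsFactors = FALSE))
  }
  copies <- rbind(
    data.frame(start = repeats$start1, end = repeats$end1),
    data.frame(start = repeats$start2, end = repeats$end2))
  dist <- vapply(seq_len(nrow(g)), function(i) {
    min(vapply(seq_len(nrow(copies)), function(j) {
      interval_circ_gap(g$start[i], g$end[i], copies$start[j], copies$end[j], L)
    }, numeric(1)))
  }, numeric(1))
  data.frame(gene_id = g$gene_id, distance = dist,
             class = ifelse(dist > threshold, "far", "near"),
             stringsAsFactors = FALSE)
}

# minimum circular gap between two (possibly wrapped) intervals; 0 if they
# overlap
interval_circ_gap <- function(s1, e1, s2, e2, L) {
  span1 <- circ_span(s1, e1, L); span2 <- circ_span(s2, e2, L)
  # clockwise gap from end of interval 1 to start of interval 2
  gap12 <- circ_cw(e1, s2, L) - 1
  gap21 <- circ_cw(e2, s1, L) - 1
  # overlap iff either gap is "negative" in circular terms, i.e. the start
  # of one lies within the other
  if (circ_in(s2, s1, e1, L) || circ_in(s1, s2, e2, L)) return(0)
  min(gap12, gap21)
}
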