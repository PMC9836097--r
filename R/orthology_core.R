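# Orthologue presence matrices: Proteinortho-dialect parsing, core-gene
# calling, peak enrichment of core genes, per-family peak frequency and
# the 16-bin localization heatmap.

#' Construct an orthologue matrix
#'
#' @param membership A list-matrix (families x genomes) whose cells are
#'   character vectors of gene ids (length 0 = absent; co-orthologs allowed).
#' @param families,genomes Row and column identifiers.
#' @param labels Optional named character vector family_id ->
#'   `{core, gta, other}`.
#' @return An object of class `ortho_matrix`.
#' @export
ortho_matrix <- function(membership, families, genomes, labels = NULL) {
  stopifnot(is.matrix(membership), is.list(membership))
  dimnames(membership) <- list(families, genomes)
  structure(list(membership = membership, families = families,
                 genomes = genomes, labels = labels),
            class = "ortho_matrix")
}

#' @export
print.ortho_matrix <- function(x, ...) {
  cat("<ortho_matrix> ", length(x$families), " families x ",
      length(x$genomes), " genomes\n", sep = "")
  pres <- presence_matrix(x)
  cat("  families present in all genomes: ", sum(rowSums(pres) ==
        length(x$genomes)), "\n", sep = "")
  invisible(x)
}

# logical families x genomes presence matrix
presence_matrix <- function(mat) {
  apply(mat$membership, c(1, 2), function(cell) length(cell[[1]]) > 0L)
}

#' Read a Proteinortho-style orthologue matrix
#'
#' Expects the `.proteinortho` TSV dialect: a header line starting with
#' `# Species` followed by `Genes`, `Alg.-Conn.` and one column per
#' genome; one row per gene family; `*` for absence; commas separating
#' co-orthologs.
#'
#' @param path Path to the TSV file.
#' @return An [ortho_matrix] with families named `fam_<row>`.
#' @export
read_proteinortho <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 4L) stop("not a Proteinortho matrix: too few columns")
  genomes <- header[-(1:3)]
  d <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) != length(header)) stop("ragged rows in ", path)
  cells <- as.matrix(d[, -(1:3), drop = FALSE])
  membership <- matrix(lapply(cells, function(x) {
    if (is.na(x) || x == "*" || x == "") character() else
      strsplit(x, ",", fixed = TRUE)[[1]]
  }), nrow = nrow(cells), ncol = ncol(cells))
  fams <- paste0("fam_", seq_len(nrow(cells)))
  ortho_matrix(membership, fams, genomes)
}

#' Write an orthologue matrix in the Proteinortho TSV dialect
#'
#' @param mat An [ortho_matrix].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_proteinortho <- function(mat, path) {
  pres <- presence_matrix(mat)
  n_genes <- apply(mat$membership, 1, function(row) sum(lengths(row)))
  body <- apply(mat$membership, c(1, 2), function(cell) {
    v <- cell[[1]]
    if (!length(v)) "*" else paste(v, collapse = ",")
  })
  lines <- c(
    paste(c("# Species", "Genes", "Alg.-Conn.", mat$genomes), collapse = "\t"),
    vapply(seq_len(nrow(body)), function(i) {
      paste(c(sum(pres[i, ]), n_genes[i], "1",
              body[i, ]), collapse = "\t")
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Call core gene families
#'
#' A family is core when it is present (non-empty membership) in at least
#' `ceiling(fraction * n_genomes)` genomes; the default 0.9 reproduces the
#' "present in >= 90 % of genomes within an order" rule (for small cohorts
#' the ceiling gives the nearest genome count at or above 90 %).
#'
#' @param mat An [ortho_matrix].
#' @param fraction Core-calling threshold in `(0, 1]` (default 0.9).
#' @return Character vector of core family ids.
#' @export
call_core <- function(mat, fraction = 0.9) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  ng <- length(mat$genomes)
  if (ng < 1L) stop("need >= 1 genome")
  pres <- presence_matrix(mat)
  need <- ceiling(fraction * ng)
  mat$families[rowSums(pres) >= need]
}

# flatten an ortho_matrix + per-genome peak labels into one gene-level table
gene_label_table <- function(mat, peak_labels, core = call_core(mat)) {
  rows <- list()
  for (g in mat$genomes) {
    lab <- peak_labels[[g]]
    if (is.null(lab)) next
    for (fi in seq_along(mat$families)) {
      ids <- mat$membership[[fi, match(g, mat$genomes)]]
      if (!length(ids)) next
      m <- match(ids, lab$gene_id)
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = mat$families[fi], genome_id = g, gene_id = ids,
        peak = !is.na(m) & lab$label[m] == "peak",
        core = mat$families[fi] %in% core,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no genes labelled; check peak_labels genome ids")
  do.call(rbind, rows)
}

#' Core-gene enrichment in GC-skew peaks
#'
#' The ratio of the percentage of peak-region genes that belong to core
#' families to the percentage of non-peak genes that do, pooled over all
#' genomes.
#'
#' @param mat An [ortho_matrix].
#' @param peak_labels Named list (genome id -> `data.frame` with columns
#'   `gene_id`, `label` as produced by [assign_genes_to_peaks]).
#' @param core Core family ids (default [call_core] on `mat`).
#' @return List with `ratio`, `pct_core_peak`, `pct_core_non_peak`, and the
#'   pooled gene counts.
#' @export
core_peak_enrichment <- function(mat, peak_labels, core = call_core(mat)) {
  tab <- gene_label_table(mat, peak_labels, core)
  n_peak <- sum(tab$peak)
  n_non <- sum(!tab$peak)
  if (!n_peak || !n_non) stop("need genes in both peak and non-peak classes")
  p1 <- 100 * sum(tab$peak & tab$core) / n_peak
  p0 <- 100 * sum(!tab$peak & tab$core) / n_non
  if (p0 == 0) stop("no core genes outside peaks; ratio undefined")
  list(ratio = p1 / p0, pct_core_peak = p1, pct_core_non_peak = p0,
       n_peak = n_peak, n_non_peak = n_non)
}

#' Per-family presence and peak frequency
#'
#' For each family: in how many genomes it is present, and in how many of
#' those at least one of its member genes lies in a GC-skew peak. Families
#' absent everywhere are excluded.
#'
#' @inheritParams core_peak_enrichment
#' @return `data.frame` with columns `family_id`, `n_genomes_present`,
#'   `n_in_peak`.
#' @export
family_peak_frequency <- function(mat, peak_labels) {
  tab <- gene_label_table(mat, peak_labels, core = character())
  agg_pres <- tapply(tab$genome_id, tab$family_id,
                     function(x) length(unique(x)))
  inpeak <- tab[tab$peak, , drop = FALSE]
  agg_peak <- tapply(inpeak$genome_id, inpeak$family_id,
                     function(x) length(unique(x)))
  fams <- names(agg_pres)
  data.frame(family_id = fams,
             n_genomes_present = as.integer(agg_pres),
             n_in_peak = as.integer(ifelse(is.na(agg_peak[fams]), 0L,
                                           agg_peak[fams])),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Localization heatmap of gene families over 16 chromosome bins
#'
#' Places each homologue's circular midpoint into
#' `floor(n_bins * midpoint / length)` (0-based bin index, clamped to
#' `n_bins - 1`) on its ori-oriented, length-normalized chromosome and
#' counts per family and bin.
#'
#' @param records List of ori-oriented [genome_record]s whose genes carry
#'   `family_id`.
#' @param family_ids Families to include (default: all seen).
#' @param n_bins Number of bins (default 16).
#' @return Integer matrix families x bins (columns `bin_0` ..).
#' @export
localization_heatmap <- function(records, family_ids = NULL, n_bins = 16L) {
  if (inherits(records, "genome_record")) records <- list(records)
  rows <- list()
  for (rec in records) {
    g <- rec$genes
    keep <- !is.na(g$family_id)
    if (!is.null(family_ids)) keep <- keep & g$family_id %in% family_ids
    if (!any(keep)) next
    mids <- gene_midpoints(rec)[keep]
    bin <- pmin(floor(n_bins * mids / rec$length), n_bins - 1L)
    rows[[length(rows) + 1L]] <- data.frame(family_id = g$family_id[keep],
                                            bin = bin)
  }
  if (!length(rows)) {
    fams <- family_ids %||% character()
    out <- matrix(0L, length(fams), n_bins,
                  dimnames = list(fams, paste0("bin_", seq_len(n_bins) - 1L)))
    return(out)
  }
  d <- do.call(rbind, rows)
  fams <- family_ids %||% sort(unique(d$family_id))
  out <- table(factor(d$family_id, levels = fams),
               factor(d$bin, levels = 0:(n_bins - 1L)))
  out <- matrix(as.integer(out), nrow = length(fams),
                dimnames = list(fams, paste0("bin_", 0:(n_bins - 1L))))
  out
}
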