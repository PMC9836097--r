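# Reading, modelling, rotating and writing circular chromosomes with their
# gene annotations. Coordinates follow GFF3: 1-based inclusive; a gene with
# start > end wraps across the origin of the coordinate system.

#' Construct a circular genome record
#'
#' A `genome_record` bundles one closed circular chromosome with its CDS
#' annotations. It is the central container passed between all analysis
#' stages.
#'
#' @param id Chromosome identifier (matches the FASTA header / GFF seqid).
#' @param sequence DNA sequence as a single character string over
#'   \code{A,C,G,T,N}.
#' @param genes `data.frame` with columns `gene_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), and optionally `product` and `family_id`. `start > end`
#'   denotes a gene wrapping the origin of coordinates.
#' @param ori Replication-origin position in `[1, length]`.
#' @param ter Replication-terminus position, or `NULL` if not yet inferred.
#' @param provenance Free-text note on where the record came from and which
#'   rotations were applied.
#'
#' @return An object of class `genome_record`: a list with elements `id`,
#'   `sequence`, `length`, `ori`, `ter`, `genes`, `provenance`.
#' @export
genome_record <- function(id, sequence, genes = empty_genes(), ori = 1L,
                          ter = NULL, provenance = "") {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 1L) stop("sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!nrow(genes)) genes <- empty_genes()
  required <- c("gene_id", "start", "end", "strand")
  if (!all(required %in% names(genes))) {
    stop("genes must have columns gene_id, start, end, strand")
  }
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  if (!"family_id" %in% names(genes)) genes$family_id <- NA_character_
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id)) stop("gene_ids must be unique")
  if (nrow(genes)) {
    if (any(genes$start < 1L | genes$start > L | genes$end < 1L | genes$end > L)) {
      stop("gene coordinates outside [1, length]")
    }
    if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  if (ori < 1L || ori > L) stop("ori outside [1, length]")
  if (!is.null(ter) && (ter < 1L || ter > L)) stop("ter outside [1, length]")
  structure(
    list(id = as.character(id), sequence = sequence, length = L,
         ori = as.integer(ori), ter = if (is.null(ter)) NULL else as.integer(ter),
         genes = genes[, c("gene_id", "start", "end", "strand", "product",
                           "family_id")],
         provenance = provenance),
    class = "genome_record")
}

empty_genes <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             strand = character(), product = character(),
             family_id = character(), stringsAsFactors = FALSE)
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$id, ": ", format(x$length, big.mark = ","),
      " bp circular, ", nrow(x$genes), " CDS\n", sep = "")
  cat("  ori = ", x$ori,
      if (!is.null(x$ter)) paste0(", ter = ", x$ter) else ", ter unset",
      "\n", sep = "")
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Read a circular chromosome and its CDS annotations
#'
#' Reads one chromosome from a FASTA file and its gene annotations from a
#' GFF3 file, keeping only CDS features. Wrap-around genes may be encoded in
#' the GFF3 with `end > sequence length` together with a
#' `circular_wrap=true` attribute; an out-of-range end without that
#' declaration is an error.
#'
#' @param fasta_path Path to a FASTA file holding the chromosome sequence.
#' @param gff_path Path to a GFF3 file with CDS features for that chromosome.
#' @param ori Replication-origin position. If omitted, `ori = 1` is assumed
#'   with a warning (supply the true origin whenever it is known).
#' @param id Optional sequence id to select when the FASTA holds several
#'   records; defaults to the first record.
#'
#' @return A [genome_record].
#' @export
read_genome <- function(fasta_path, gff_path, ori = NULL, id = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  if (!file.exists(gff_path)) stop("GFF not found: ", gff_path)
  dna <- Biostrings::readDNAStringSet(fasta_path)
  nm <- sub("\\s.*$", "", names(dna))
  if (is.null(id)) id <- nm[1] else {
    if (!id %in% nm) stop("sequence id '", id, "' not in FASTA")
  }
  seq <- as.character(dna[[match(id, nm)]])
  L <- nchar(seq)

  gff <- rtracklayer::import(gff_path)
  gff <- gff[gff$type == "CDS"]
  gff <- gff[as.character(GenomicRanges::seqnames(gff)) == id]
  if (!length(gff) && length(dna) == 1L) {
    # tolerate a GFF written against a differently-decorated header
    gff <- rtracklayer::import(gff_path)
    gff <- gff[gff$type == "CDS"]
    if (length(unique(as.character(GenomicRanges::seqnames(gff)))) > 1L) {
      stop("FASTA/GFF sequence-id mismatch for '", id, "'")
    }
  }
  meta <- S4Vectors::mcols(gff)
  getcol <- function(col) {
    if (col %in% names(meta)) as.character(meta[[col]]) else
      rep(NA_character_, length(gff))
  }
  gene_id <- getcol("ID")
  if (all(is.na(gene_id))) gene_id <- getcol("Name")
  if (all(is.na(gene_id)) && length(gff)) {
    gene_id <- paste0(id, "_cds", seq_along(gff))
  }
  start <- GenomicRanges::start(gff)
  end <- GenomicRanges::end(gff)
  wrap <- tolower(getcol("circular_wrap")) %in% "true"
  bad <- end > L & !wrap
  if (any(bad)) {
    stop("CDS end beyond sequence length without circular_wrap declaration: ",
         paste(gene_id[bad], collapse = ", "))
  }
  end[wrap] <- end[wrap] - L
  if (any(start < 1L | start > L)) stop("gene coordinate outside [1, length]")
  genes <- data.frame(
    gene_id = gene_id, start = start, end = as.integer(end),
    strand = as.character(GenomicRanges::strand(gff)),
    product = getcol("product"), family_id = getcol("family_id"),
    stringsAsFactors = FALSE)
  if (nrow(genes) && any(!genes$strand %in% c("+", "-"))) {
    stop("CDS strand must be '+' or '-'")
  }
  if (is.null(ori)) {
    warning("no ori supplied; assuming ori = 1")
    ori <- 1L
  }
  genome_record(id, seq, genes, ori = ori,
                provenance = paste0("read from ", basename(fasta_path), " + ",
                                    basename(gff_path)))
}

#' Rotate a circular chromosome so a given position becomes coordinate 1
#'
#' Rotation is the reorientation step applied before all positional
#' analyses: the chromosome is cut at `new_first` and relinearized so that
#' `new_first` maps to coordinate 1. Gene coordinates, strand, `ori` and
#' `ter` are remapped modulo the chromosome length; genes spanning the cut
#' become wrap-around genes (`start > end`).
#'
#' @param record A [genome_record].
#' @param new_first Position (1-based) that becomes the first base.
#'
#' @return The rotated [genome_record].
#' @export
reorient_to_position <- function(record, new_first) {
  L <- record$length
  new_first <- as.integer(new_first)
  if (length(new_first) != 1L || is.na(new_first) || new_first < 1L ||
      new_first > L) {
    stop("new_first outside [1, length]")
  }
  remap <- function(p) as.integer(circ_pos(p - new_first + 1L, L))
  seq <- circ_substr(record$sequence,
                     new_first, circ_pos(new_first - 1L, L))
  if (new_first == 1L) seq <- record$sequence
  genes <- record$genes
  if (nrow(genes)) {
    genes$start <- remap(genes$start)
    genes$end <- remap(genes$end)
  }
  genome_record(record$id, seq, genes,
                ori = remap(record$ori),
                ter = if (is.null(record$ter)) NULL else remap(record$ter),
                provenance = paste0(record$provenance,
                                    "; rotated to position ", new_first))
}

#' Rotate a chromosome so a gene's 5' end becomes coordinate 1
#'
#' Anchors the rotation at the gene's 5' end on its coding strand: the
#' `start` field for `+` genes, the `end` field for `-` genes. Used to
#' anchor chromosomes at the GTA major capsid protein (MCP) gene.
#'
#' @param record A [genome_record].
#' @param gene_id Identifier of the anchor gene.
#'
#' @return The rotated [genome_record].
#' @export
reorient_to_gene <- function(record, gene_id) {
  i <- match(gene_id, record$genes$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", gene_id)
  anchor <- if (record$genes$strand[i] == "+") record$genes$start[i] else
    record$genes$end[i]
  reorient_to_position(record, anchor)
}

#' Write a genome record to FASTA + GFF3
#'
#' The files round-trip: [read_genome] on the written pair reconstructs an
#' equal record. Wrap-around genes are written with `end + length` and a
#' `circular_wrap=true` attribute.
#'
#' @param record A [genome_record].
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, the record.
#' @export
write_genome <- function(record, fasta_path, gff_path) {
  dna <- Biostrings::DNAStringSet(record$sequence)
  names(dna) <- record$id
  Biostrings::writeXStringSet(dna, fasta_path)

  g <- record$genes
  lines <- "##gff-version 3"
  if (nrow(g)) {
    wrap <- g$start > g$end
    end_out <- ifelse(wrap, g$end + record$length, g$end)
    attrs <- paste0("ID=", g$gene_id)
    has_prod <- !is.na(g$product)
    attrs[has_prod] <- paste0(attrs[has_prod], ";product=", g$product[has_prod])
    has_fam <- !is.na(g$family_id)
    attrs[has_fam] <- paste0(attrs[has_fam], ";family_id=", g$family_id[has_fam])
    attrs[wrap] <- paste0(attrs[wrap], ";circular_wrap=true")
    lines <- c(lines, paste(record$id, "skewscape", "CDS", g$start, end_out,
                            ".", g$strand, "0", attrs, sep = "\t"))
  }
  writeLines(lines, gff_path)
  invisible(record)
}

#' Extract the coding-strand sequence of a gene
#'
#' @param record A [genome_record].
#' @param gene_id Gene identifier.
#' @return Character string: the gene's sequence 5'->3' on its coding strand.
#' @export
gene_sequence <- function(record, gene_id) {
  i <- match(gene_id, record$genes$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", gene_id)
  s <- circ_substr(record$sequence, record$genes$start[i], record$genes$end[i])
  if (record$genes$strand[i] == "-") s <- revcomp(s) else s
}

# reference-strand sequence of a (possibly wrapped) region
region_sequence <- function(record, start, end) {
  circ_substr(record$sequence, start, end)
}

# circular midpoints of all genes in a record
gene_midpoints <- function(record) {
  if (!nrow(record$genes)) return(integer())
  mapply(circ_mid, record$genes$start, record$genes$end,
         MoreArgs = list(L = record$length))
}
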