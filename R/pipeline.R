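# End-to-end orchestration: reorient -> skew -> peaks -> architecture ->
# codons -> core/enrichment -> motifs over a cohort, driven by one
# declarative configuration, with self-describing TSV outputs and a
# machine-readable summary.

default_config <- function() {
  list(
    genomes = list(),          # list of list(fasta=, gff=, ori=)
    matrix = NULL,             # Proteinortho-dialect TSV path
    repeats = list(),          # named list genome_id -> repeat TSV path
    gta_gene_ids = character(),
    window = 10000L, step = 1000L,
    quantile = 0.03, local_window = 150000L,
    core_fraction = 0.9,
    repeat_min_len = 800, repeat_min_identity = 0.9,
    heatmap_bins = 16L, motif_bins = 100L, motif_points = 1000L,
    motif = "GANTC",
    out_dir = "skewscape_out", seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Schema and range checks for [run_pipeline] configurations; unknown keys
#' are rejected. When genome FASTA files are readable, the skew window is
#' checked against the shortest chromosome.
#'
#' @param config Named list of configuration values (missing keys take the
#'   defaults, which equal the standard analysis parameterization: 10 kb
#'   window, 3 % quantile, 150 kb local window, 90 % core threshold,
#'   800 bp / 90 % identity repeat thresholds, 16/100/1000 bins).
#' @return Character vector of issues; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  issues <- character()
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    issues <- c(issues, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- def
  known <- setdiff(names(config), unknown)
  cfg[known] <- config[known]  # shallow merge: list values replace wholesale
  chk <- function(cond, msg) if (!isTRUE(cond)) issues <<- c(issues, msg)
  chk(is_scalar_number(cfg$quantile) && cfg$quantile > 0 && cfg$quantile < 0.5,
      "quantile must be in (0, 0.5)")
  chk(is_scalar_number(cfg$window) && cfg$window >= 1,
      "window must be >= 1")
  chk(is_scalar_number(cfg$step) && cfg$step >= 1, "step must be >= 1")
  chk(is_scalar_number(cfg$local_window) && cfg$local_window >= cfg$window,
      "local_window must be >= window")
  chk(is_scalar_number(cfg$core_fraction) && cfg$core_fraction > 0 &&
        cfg$core_fraction <= 1, "core_fraction must be in (0, 1]")
  chk(is_scalar_number(cfg$repeat_min_len) && cfg$repeat_min_len >= 0,
      "repeat_min_len must be >= 0")
  chk(is_scalar_number(cfg$repeat_min_identity) && cfg$repeat_min_identity >= 0 &&
        cfg$repeat_min_identity <= 1, "repeat_min_identity must be in [0, 1]")
  for (b in c("heatmap_bins", "motif_bins", "motif_points")) {
    chk(is_scalar_number(cfg[[b]]) && cfg[[b]] >= 1, paste(b, "must be >= 1"))
  }
  chk(iupac_ok(cfg$motif), "motif must be a valid IUPAC pattern")
  for (g in cfg$genomes) {
    if (!is.list(g) || is.null(g$fasta) || is.null(g$gff)) {
      issues <- c(issues, "each genome entry needs fasta and gff paths")
      next
    }
    if (file.exists(g$fasta)) {
      len <- sum(Biostrings::fasta.seqlengths(g$fasta)[1])
      if (is_scalar_number(cfg$window) && cfg$window > len) {
        issues <- c(issues,
                    paste0("window exceeds chromosome length of ", g$fasta))
      }
    } else {
      issues <- c(issues, paste0("missing FASTA: ", g$fasta))
    }
    if (!file.exists(g$gff)) {
      issues <- c(issues, paste0("missing GFF: ", g$gff))
    }
  }
  issues
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML configuration file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

write_stage_tsv <- function(d, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# skewscape output; coordinates 1-based inclusive, circular",
               vapply(names(meta), function(k)
                 paste0("# ", k, "=", meta[[k]]), character(1))), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full genome-architecture pipeline
#'
#' Executes, for a cohort of ori-supplied genomes: reorientation to ori,
#' GC-skew tracks, sliding-quantile peak calling, gene-architecture
#' classification, peak/non-peak codon usage with rank correlations,
#' core-gene calling and peak enrichment (when an orthologue matrix is
#' given), repeat-distance classes (when repeat tables are given), and
#' motif profiles. All stage outputs are written as TSV with `# key=value`
#' header metadata, plus a machine-readable `summary.json`; the run is
#' deterministic for fixed inputs and seed.
#'
#' @param config Named list (see [validate_config]) or a YAML path.
#' @param records Optional list of pre-built [genome_record]s, bypassing
#'   the FASTA/GFF manifest (used for synthetic cohorts).
#' @return Invisibly, the summary list (also written to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(config = list(), records = NULL) {
  if (is.character(config)) config <- read_config(config)
  issues <- validate_config(config)
  if (length(issues)) stop("invalid config:\n  ", paste(issues, collapse = "\n  "))
  cfg <- default_config()
  cfg[names(config)] <- config
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (is.null(records)) {
    records <- stage("genome_io", lapply(cfg$genomes, function(g) {
      rec <- read_genome(g$fasta, g$gff, ori = g$ori %||% 1L)
      if (rec$ori != 1L) rec <- reorient_to_position(rec, rec$ori) else rec
    }))
  }
  if (!length(records)) stop("stage 'genome_io' failed: no genomes")
  for (i in seq_along(records)) {
    if (is.null(records[[i]]$ter)) {
      records[[i]]$ter <- infer_ter(records[[i]], "antipodal")
    }
  }
  ids <- vapply(records, `[[`, character(1), "id")

  meta <- list(window = cfg$window, step = cfg$step, quantile = cfg$quantile,
               local_window = cfg$local_window, seed = cfg$seed)

  tracks <- stage("skew", lapply(records, skew_track,
                                 window = cfg$window, step = cfg$step))
  for (i in seq_along(tracks)) {
    t <- tracks[[i]]
    write_stage_tsv(data.frame(chromosome = t$chromosome_id,
                               position = t$positions, skew = t$values),
                    file.path(cfg$out_dir, paste0(ids[i], "_track.tsv")), meta)
  }

  peaks <- stage("peaks", lapply(tracks, detect_skew_peaks,
                                 quantile = cfg$quantile,
                                 local_window = cfg$local_window))
  for (i in seq_along(peaks)) {
    iv <- peaks[[i]]$intervals
    iv <- data.frame(chromosome = rep(ids[i], nrow(iv)), iv)
    write_stage_tsv(iv, file.path(cfg$out_dir, paste0(ids[i], "_peaks.tsv")),
                    meta)
  }

  peak_labels <- stage("peaks", {
    pl <- lapply(seq_along(records), function(i)
      assign_genes_to_peaks(records[[i]], peaks[[i]]))
    stats::setNames(pl, ids)
  })

  arch <- stage("architecture", architecture_summary(records))
  cls_all <- stage("architecture", lapply(records, classify_gene_architecture))
  for (i in seq_along(records)) {
    d <- cbind(cls_all[[i]], label = peak_labels[[i]]$label)
    write_stage_tsv(d, file.path(cfg$out_dir,
                                 paste0(ids[i], "_architecture.tsv")), meta)
  }
  write_stage_tsv(arch$per_genome,
                  file.path(cfg$out_dir, "architecture_summary.tsv"), meta)

  codon <- stage("codons", {
    has_both <- vapply(peak_labels, function(l)
      any(l$label == "peak") && any(l$label == "non_peak"), logical(1))
    if (!any(has_both)) NULL else {
      use <- which(has_both)
      pk <- lapply(use, function(i) codon_counts(
        records[[i]],
        peak_labels[[i]]$gene_id[peak_labels[[i]]$label == "peak"]))
      np <- lapply(use, function(i) codon_counts(
        records[[i]],
        peak_labels[[i]]$gene_id[peak_labels[[i]]$label == "non_peak"]))
      med <- relative_codon_usage(pk, np)
      st <- codon_gc_stats(names(med))
      d <- cbind(st, relative_usage = as.numeric(med))
      write_stage_tsv(d, file.path(cfg$out_dir, "codon_usage.tsv"),
                      c(meta, mode = attr(med, "mode")))
      corr <- usage_correlations(med, "gc_skew")
      list(median_usage = med, rho_gc_skew = corr$rho, p_gc_skew = corr$p.value,
           n_genomes = length(use))
    }
  })

  ortho <- NULL
  if (!is.null(cfg$matrix)) {
    ortho <- stage("core", {
      mat <- if (inherits(cfg$matrix, "ortho_matrix")) cfg$matrix else
        read_proteinortho(cfg$matrix)
      core <- call_core(mat, cfg$core_fraction)
      enr <- core_peak_enrichment(mat, peak_labels, core)
      fpf <- family_peak_frequency(mat, peak_labels)
      write_stage_tsv(fpf, file.path(cfg$out_dir, "family_peak_frequency.tsv"),
                      meta)
      hm <- localization_heatmap(records, n_bins = cfg$heatmap_bins)
      write_stage_tsv(data.frame(family_id = rownames(hm), hm,
                                 check.names = FALSE),
                      file.path(cfg$out_dir, "localization_heatmap.tsv"), meta)
      list(n_core = length(core), enrichment = enr$ratio,
           pct_core_peak = enr$pct_core_peak,
           pct_core_non_peak = enr$pct_core_non_peak)
    })
  }

  repeat_summary <- NULL
  if (length(cfg$repeats)) {
    repeat_summary <- stage("repeats", {
      rows <- lapply(ids, function(id) {
        path <- cfg$repeats[[id]]
        if (is.null(path)) return(NULL)
        raw <- utils::read.delim(path, comment.char = "#")
        filt <- filter_repeats(raw, cfg$repeat_min_len, cfg$repeat_min_identity)
        rec <- records[[match(id, ids)]]
        cls <- repeat_distance_class(rec, filt)
        write_stage_tsv(cls, file.path(cfg$out_dir,
                                       paste0(id, "_repeat_distance.tsv")),
                        meta)
        data.frame(genome_id = id, n_repeats = nrow(filt),
                   pct_far = 100 * mean(cls$class == "far"))
      })
      do.call(rbind, rows)
    })
  }

  motifs <- stage("motifs", {
    per <- lapply(seq_along(records), function(i) {
      sites <- find_motif_sites(records[[i]], cfg$motif)
      bp <- binned_profile(sites, records[[i]]$length, cfg$motif_bins)
      cp <- cumulative_profile(sites, records[[i]]$length, cfg$motif_points)
      write_stage_tsv(data.frame(bin = seq_along(bp), count = bp),
                      file.path(cfg$out_dir, paste0(ids[i], "_motif_bins.tsv")),
                      c(meta, motif = cfg$motif))
      write_stage_tsv(data.frame(point = seq_along(cp), cumulative = cp),
                      file.path(cfg$out_dir,
                                paste0(ids[i], "_motif_cumulative.tsv")),
                      c(meta, motif = cfg$motif))
      length(sites$start)
    })
    list(motif = cfg$motif, sites_per_genome = unlist(per))
  })

  summary <- list(
    n_genomes = length(records),
    genome_ids = ids,
    parameters = meta,
    architecture = arch$summary,
    codon = if (is.null(codon)) NULL else
      codon[c("rho_gc_skew", "p_gc_skew", "n_genomes")],
    core = ortho,
    repeats = repeat_summary,
    motifs = motifs)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(summary)
}
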