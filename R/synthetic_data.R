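# Seedable generator of circular genomes with planted architecture:
# replichore-dependent GC skew, high-skew segments, region-dependent codon
# usage, a contiguous GTA-like gene cluster, long repeats, an ori-anchored
# methylation-motif density gradient, and matched orthologue matrices with
# a known core set. Every dataset is emitted together with its ground
# truth so each pipeline stage can be tested against planted parameters.

#' Specification of a synthetic circular genome
#'
#' The defaults describe a mid-sized alphaproteobacterial chromosome:
#' 2 Mb, 60 % GC, a replichore GC-skew amplitude of 0.1 (the skew of the
#' background sequence is `+0.1` on the right replichore and `-0.1` on the
#' left), and a modest leading-strand bias of 55 % for gene placement.
#'
#' @param length Chromosome length in bp.
#' @param ori Origin position (default 1, i.e. the genome is emitted
#'   ori-oriented).
#' @param skew_amplitude Background GC skew per replichore, in `(0, 1)`:
#'   `P(G) - P(C) = gc_content * skew_amplitude` on the right replichore,
#'   mirrored on the left, so the windowed skew of the background equals
#'   `+/- skew_amplitude`.
#' @param gc_content Background GC fraction.
#' @param peak_segments `data.frame` with columns `start`, `end`,
#'   `extra_amplitude`: segments whose skew is raised by `extra_amplitude`
#'   above the local replichore background.
#' @param n_genes Number of background genes to place (excluding the
#'   cluster).
#' @param gene_length_codons `c(mean, sd)` of gene lengths in codons
#'   (including start and stop; minimum 60).
#' @param leading_fraction Probability that a placed gene is on the leading
#'   strand of its replichore.
#' @param cluster Optional planted GTA-like cluster:
#'   `list(position =, n_genes =, strand =)`; its genes are contiguous and
#'   share one strand.
#' @param peak_codon_bias Multiplier applied inside peak segments to the
#'   sampling weight of codons with positive GC skew (1 = no bias).
#' @param repeats Optional `data.frame` with columns `length`, `identity`,
#'   `start1`, `start2`: repeat pairs realized by copying the first
#'   interval onto the second with point mutations at rate `1 - identity`.
#' @param motif_gradient Ratio of planted GANTC site density at the start
#'   versus the end of the ori-oriented chromosome (linear in between);
#'   1 = no planted sites.
#' @param motif_density Mean planted GANTC sites per kb when a gradient is
#'   planted.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return An object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(length = 2e6, ori = 1L, skew_amplitude = 0.1,
                           gc_content = 0.6, peak_segments = NULL,
                           n_genes = 0L, gene_length_codons = c(300, 80),
                           leading_fraction = 0.55, cluster = NULL,
                           peak_codon_bias = 1, repeats = NULL,
                           motif_gradient = 1, motif_density = 0.5,
                           seed = 1L) {
  length <- as.integer(length)
  stopifnot(length > 0L, ori >= 1L, ori <= length,
            skew_amplitude > 0, skew_amplitude < 1,
            gc_content > 0, gc_content < 1,
            leading_fraction >= 0, leading_fraction <= 1,
            peak_codon_bias > 0, motif_gradient >= 1, motif_density >= 0)
  if (!is.null(peak_segments)) {
    peak_segments <- as.data.frame(peak_segments)
    stopifnot(all(c("start", "end", "extra_amplitude") %in%
                    names(peak_segments)))
    if (any(peak_segments$start < 1 | peak_segments$end > length |
              peak_segments$start > peak_segments$end)) {
      stop("peak segments must be linear intervals within [1, length]")
    }
  }
  if (!is.null(cluster)) {
    stopifnot(is.list(cluster),
              all(c("position", "n_genes", "strand") %in% names(cluster)),
              cluster$position >= 1, cluster$position <= length,
              cluster$strand %in% c("+", "-"))
  }
  if (!is.null(repeats)) {
    repeats <- as.data.frame(repeats)
    stopifnot(all(c("length", "identity", "start1", "start2") %in%
                    names(repeats)))
  }
  structure(list(
    length = length, ori = as.integer(ori), skew_amplitude = skew_amplitude,
    gc_content = gc_content, peak_segments = peak_segments,
    n_genes = as.integer(n_genes), gene_length_codons = gene_length_codons,
    leading_fraction = leading_fraction, cluster = cluster,
    peak_codon_bias = peak_codon_bias, repeats = repeats,
    motif_gradient = motif_gradient, motif_density = motif_density,
    seed = as.integer(seed)), class = "synthetic_spec")
}

# per-position planted skew profile (reference strand)
planted_skew_profile <- function(spec) {
  L <- spec$length
  d <- (seq_len(L) - spec$ori) %% L
  s <- ifelse(d < L / 2, spec$skew_amplitude, -spec$skew_amplitude)
  if (!is.null(spec$peak_segments)) {
    for (i in seq_len(nrow(spec$peak_segments))) {
      idx <- spec$peak_segments$start[i]:spec$peak_segments$end[i]
      s[idx] <- s[idx] + spec$peak_segments$extra_amplitude[i]
    }
  }
  pmin(pmax(s, -0.99), 0.99)
}

# sample iid bases with per-position GC skew s and GC content gc
sample_bases <- function(s, gc) {
  pG <- gc * (1 + s) / 2
  pC <- gc * (1 - s) / 2
  u <- stats::runif(length(s))
  ifelse(u < pG, "G",
         ifelse(u < pG + pC, "C",
                ifelse(u < pG + pC + (1 - gc) / 2, "A", "T")))
}

stop_codons <- c("TAA", "TAG", "TGA")

# codon sampling weights for a region with coding-strand base probs
codon_weights <- function(pA, pC, pG, pT, bias_gskew = 1) {
  p <- c(A = pA, C = pC, G = pG, T = pT)
  pm <- matrix(p[.CODON_LETTERS], ncol = 3)
  w <- pm[, 1] * pm[, 2] * pm[, 3]
  names(w) <- rownames(.CODON_LETTERS)
  w[stop_codons] <- 0
  if (bias_gskew != 1) {
    st <- codon_gc_stats()
    pos <- st$codon[!is.na(st$gc_skew) & st$gc_skew > 0]
    w[pos] <- w[pos] * bias_gskew
  }
  w / sum(w)
}

# place n non-overlapping linear intervals of the given lengths, avoiding
# occupied positions: random inter-gene gaps drawn from the free space,
# walking left to right and skipping occupied blocks. Robust up to high
# gene densities where naive rejection sampling stalls.
place_intervals <- function(lens, L, occupied) {
  n <- length(lens)
  free_total <- L - sum(occupied) - sum(lens)
  if (free_total < 0) {
    stop("infeasible packing: too many genes for genome length")
  }
  # bases immediately before an occupied block can be forfeited when a gene
  # window straddles it; reserve that worst case out of the gap budget
  n_blocks <- sum(diff(c(FALSE, occupied)) == 1L)
  margin <- n_blocks * max(lens, 0L) + 1L
  gaps <- stats::rexp(n + 1L)
  gaps <- floor(gaps / sum(gaps) * max(0, free_total - margin))
  starts <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    repeat {
      if (pos + lens[i] - 1L > L) {
        stop("infeasible packing: too many genes for genome length")
      }
      seg <- occupied[pos:(pos + lens[i] - 1L)]
      if (!any(seg)) break
      pos <- pos + max(which(seg))
    }
    starts[i] <- pos
    occupied[pos:(pos + lens[i] - 1L)] <- TRUE
    pos <- pos + lens[i]
  }
  list(starts = starts, occupied = occupied)
}

#' Generate a synthetic circular genome with planted truth
#'
#' Realizes a [synthetic_spec]: background bases are drawn per replichore
#' with the stated skew amplitude (plus segment extras); genes are placed
#' non-overlapping with ORFs sampled from region-appropriate codon
#' multinomials (G-skew-biased codons up-weighted inside peak segments by
#' `peak_codon_bias`); cluster genes are contiguous on the stated strand;
#' repeat pairs are implanted as mutated duplications; GANTC sites are
#' implanted with a linear ori-to-end density gradient after disrupting
#' background occurrences outside genes.
#'
#' @param spec A [synthetic_spec].
#' @param id Chromosome identifier.
#' @return List with `record` (a [genome_record]) and `truth` (per-gene
#'   labels, planted segments, repeats, motif parameters, and the spec).
#' @export
generate_genome <- function(spec, id = "synth_chr") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  L <- spec$length
  s <- planted_skew_profile(spec)
  v <- sample_bases(s, spec$gc_content)

  segs <- spec$peak_segments
  in_segment <- function(pos) {
    if (is.null(segs)) return(FALSE)
    any(pos >= segs$start & pos <= segs$end)
  }

  occupied <- logical(L)
  genes <- empty_genes()
  truth_genes <- NULL

  make_genes <- function(starts, lens_bp, strands, cluster_flag) {
    n <- length(starts)
    if (!n) return(NULL)
    data.frame(start = starts, end = starts + lens_bp - 1L,
               strand = strands, in_cluster = cluster_flag,
               stringsAsFactors = FALSE)
  }

  gene_tbl <- NULL
  # cluster genes: contiguous block at the stated position
  if (!is.null(spec$cluster)) {
    ncl <- spec$cluster$n_genes
    lens <- pmax(60L, round(stats::rnorm(ncl, spec$gene_length_codons[1],
                                         spec$gene_length_codons[2]))) * 3L
    starts <- spec$cluster$position + c(0L, cumsum(lens[-ncl] + 10L))
    if (max(starts + lens - 1L) > L) stop("cluster does not fit in genome")
    occupied[spec$cluster$position:max(starts + lens - 1L)] <- TRUE
    gene_tbl <- make_genes(starts, lens, rep(spec$cluster$strand, ncl), TRUE)
  }
  # background genes
  if (spec$n_genes > 0L) {
    lens <- pmax(60L, round(stats::rnorm(spec$n_genes,
                                         spec$gene_length_codons[1],
                                         spec$gene_length_codons[2]))) * 3L
    pl <- place_intervals(lens, L, occupied)
    occupied <- pl$occupied
    # leading with probability leading_fraction given the replichore
    mids <- pl$starts + lens %/% 2L
    d <- (mids - spec$ori) %% L
    right <- d < L / 2
    lead <- stats::runif(spec$n_genes) < spec$leading_fraction
    strands <- ifelse(right, ifelse(lead, "+", "-"),
                      ifelse(lead, "-", "+"))
    gene_tbl <- rbind(gene_tbl, make_genes(pl$starts, lens, strands, FALSE))
  }

  if (!is.null(gene_tbl)) {
    gene_tbl <- gene_tbl[order(gene_tbl$start), , drop = FALSE]
    gene_tbl$gene_id <- sprintf("%s_g%04d", id, seq_len(nrow(gene_tbl)))
    # write ORFs: codons drawn from the region's coding-strand multinomial
    for (i in seq_len(nrow(gene_tbl))) {
      st <- gene_tbl$start[i]; en <- gene_tbl$end[i]
      mid <- (st + en) %/% 2L
      sreg <- s[mid]
      gc <- spec$gc_content
      # coding-strand base probabilities; for "-" genes the coding strand
      # is the complement of the reference strand
      sign_ <- if (gene_tbl$strand[i] == "+") 1 else -1
      pG <- gc * (1 + sign_ * sreg) / 2
      pC <- gc * (1 - sign_ * sreg) / 2
      pA <- (1 - gc) / 2; pT <- pA
      bias <- if (in_segment(mid)) spec$peak_codon_bias else 1
      w <- codon_weights(pA, pC, pG, pT, bias)
      ncod <- (en - st + 1L) %/% 3L
      body <- sample(all_codons(), ncod - 2L, replace = TRUE, prob = w)
      orf <- paste0("ATG", paste(body, collapse = ""),
                    sample(stop_codons, 1L))
      if (gene_tbl$strand[i] == "-") orf <- revcomp(orf)
      v[st:en] <- strsplit(orf, "")[[1]]
    }
  }

  # repeats: mutated duplications of the first copy onto the second
  planted_repeats <- NULL
  if (!is.null(spec$repeats)) {
    r <- spec$repeats
    for (i in seq_len(nrow(r))) {
      len <- r$length[i]
      src <- r$start1[i]:(r$start1[i] + len - 1L)
      dst <- r$start2[i]:(r$start2[i] + len - 1L)
      if (max(src, dst) > L) stop("repeat outside genome")
      copy <- v[src]
      nmut <- round((1 - r$identity[i]) * len)
      if (nmut > 0L) {
        at <- sample.int(len, nmut)
        copy[at] <- vapply(copy[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      }
      v[dst] <- copy
    }
    planted_repeats <- data.frame(
      start1 = r$start1, end1 = r$start1 + r$length - 1L,
      start2 = r$start2, end2 = r$start2 + r$length - 1L,
      length = r$length, identity = r$identity)
  }

  # motif gradient: clear background GANTC outside genes, then implant
  # sites with density linear from d0 (position 1) to d0/gradient
  # (position L)
  n_implanted <- 0L
  if (spec$motif_gradient > 1 || spec$motif_density > 0) {
    if (spec$motif_gradient > 1) {
      for (pass in 1:5) {
        hits <- find_motif_sites(paste(v, collapse = ""), "GANTC")$start
        hits <- hits[!occupied[hits]]
        if (!length(hits)) break
        v[circ_pos(hits + 1L, L)] <- "C"  # GANTC -> GCNTC
      }
      n_target <- round(spec$motif_density * L / 1000)
      k <- 1 - 1 / spec$motif_gradient
      placed <- 0L
      guard <- 0L
      while (placed < n_target && guard < n_target * 50L) {
        guard <- guard + 1L
        x <- stats::runif(1)
        # rejection sampling against the linear density 1 - k*x
        if (stats::runif(1) > (1 - k * x)) next
        pos <- max(1L, min(L - 4L, round(x * L)))
        idx <- pos:(pos + 4L)
        if (any(occupied[idx])) next
        v[idx] <- c("G", "A", sample(c("A", "C", "G", "T"), 1L), "T", "C")
        occupied[idx] <- TRUE
        placed <- placed + 1L
      }
      n_implanted <- placed
    }
  }

  seqstr <- paste(v, collapse = "")
  genes_df <- if (is.null(gene_tbl)) empty_genes() else
    data.frame(gene_id = gene_tbl$gene_id, start = gene_tbl$start,
               end = gene_tbl$end, strand = gene_tbl$strand,
               product = ifelse(gene_tbl$in_cluster, "GTA cluster protein",
                                NA_character_),
               family_id = NA_character_, stringsAsFactors = FALSE)
  rec <- genome_record(id, seqstr, genes_df, ori = spec$ori,
                       ter = as.integer(circ_pos(spec$ori + L %/% 2L, L)),
                       provenance = sprintf("synthetic (seed %d)", spec$seed))

  truth_genes <- NULL
  if (!is.null(gene_tbl)) {
    mids <- (gene_tbl$start + gene_tbl$end) %/% 2L
    d <- (mids - spec$ori) %% L
    right <- d < L / 2
    leading <- (right & gene_tbl$strand == "+") |
      (!right & gene_tbl$strand == "-")
    truth_genes <- data.frame(
      gene_id = gene_tbl$gene_id, start = gene_tbl$start,
      end = gene_tbl$end, strand = gene_tbl$strand,
      replichore = ifelse(right, "right", "left"),
      strand_class = ifelse(leading, "leading", "lagging"),
      in_peak = vapply(mids, in_segment, logical(1)),
      in_cluster = gene_tbl$in_cluster, stringsAsFactors = FALSE)
  }
  truth <- list(genes = truth_genes, peak_segments = segs,
                repeats = planted_repeats,
                motif = list(gradient = spec$motif_gradient,
                             density = spec$motif_density,
                             n_implanted = n_implanted),
                spec = spec)
  list(record = rec, truth = truth)
}

#' Generate an orthologue matrix with a known core set
#'
#' Core families (and any GTA families) are present in every genome;
#' accessory families are present in each genome independently with
#' `presence_prob_accessory`. The planted core set is the union of core
#' and GTA families (both are universally present by construction).
#'
#' @param n_genomes,n_core,n_accessory Cohort dimensions.
#' @param presence_prob_accessory Per-genome presence probability of each
#'   accessory family (default 0.3, the sporadic occupancy typical of
#'   accessory genes).
#' @param gta_family_ids Ids of GTA families to include (present in all
#'   genomes).
#' @param seed Integer seed.
#' @return List with `matrix` (an [ortho_matrix]), `core` (the planted
#'   core family ids) and `genomes`.
#' @export
generate_ortho_matrix <- function(n_genomes = 20L, n_core = 50L,
                                  n_accessory = 200L,
                                  presence_prob_accessory = 0.3,
                                  gta_family_ids = character(),
                                  seed = 1L) {
  stopifnot(n_genomes >= 1L, n_core >= 0L, n_accessory >= 0L,
            presence_prob_accessory >= 0, presence_prob_accessory <= 1)
  set.seed(seed)
  genomes <- sprintf("genome_%02d", seq_len(n_genomes))
  core <- if (n_core) sprintf("core_%03d", seq_len(n_core)) else character()
  acc <- if (n_accessory) sprintf("acc_%03d", seq_len(n_accessory)) else
    character()
  fams <- c(gta_family_ids, core, acc)
  membership <- matrix(vector("list", length(fams) * n_genomes),
                       nrow = length(fams), ncol = n_genomes)
  universal <- fams %in% c(gta_family_ids, core)
  for (gi in seq_len(n_genomes)) {
    present <- universal | stats::runif(length(fams)) < presence_prob_accessory
    col <- rep(list(character()), length(fams))
    col[present] <- as.list(paste0(genomes[gi], ".", fams[present]))
    membership[, gi] <- col
  }
  mat <- ortho_matrix(membership, fams, genomes)
  list(matrix = mat, core = c(gta_family_ids, core), genomes = genomes)
}

#' Plant biased peak labels on the genes of an orthologue matrix
#'
#' Assigns each gene of each genome a peak/non-peak label, with genes of
#' core families `prob_core / prob_other` times as likely to be labelled
#' peak as the rest. With sporadically present accessory families and a
#' minority core (the generator defaults), the pooled core-percentage
#' ratio measured by [core_peak_enrichment] approximates the planted rate
#' bias.
#'
#' @param mat An [ortho_matrix].
#' @param core Family ids to treat as core (default: families labelled
#'   `core_*`/`gta_*` by the generator naming scheme).
#' @param prob_core,prob_other Peak-label probability for genes of core
#'   and non-core families (defaults 0.15 and 0.05: a 3:1 bias).
#' @param seed Integer seed.
#' @return Named list genome id -> `data.frame(gene_id, label)`, the
#'   format expected by [core_peak_enrichment].
#' @export
generate_peak_labels <- function(mat, core = grep("^(core|gta)_", mat$families,
                                                  value = TRUE),
                                 prob_core = 0.15, prob_other = 0.05,
                                 seed = 1L) {
  set.seed(seed)
  out <- list()
  for (gi in seq_along(mat$genomes)) {
    ids <- unlist(mat$membership[, gi])
    if (!length(ids)) next
    fam <- rep(mat$families, vapply(mat$membership[, gi], length, integer(1)))
    p <- ifelse(fam %in% core, prob_core, prob_other)
    out[[mat$genomes[gi]]] <- data.frame(
      gene_id = ids,
      label = ifelse(stats::runif(length(ids)) < p, "peak", "non_peak"),
      stringsAsFactors = FALSE)
  }
  out
}

#' Generate a cohort of genomes emulating one taxonomic order
#'
#' Produces `n_genomes` genomes from a shared [synthetic_spec] template
#' with genome-specific length jitter and seeds, a shared planted cluster
#' and core families, and the matching orthologue matrix: cluster genes
#' map to shared `gta_*` families, a fixed set of background genes to
#' shared `core_*` families, and the remainder to genome-private
#' accessory families.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param spec Template [synthetic_spec] (its `seed` seeds the cohort).
#' @param n_core Number of shared core families planted among background
#'   genes.
#' @param length_jitter Relative length jitter (default 0.05); planted
#'   segment and cluster positions scale with the length.
#' @return List with `records`, `truths`, `matrix` (an [ortho_matrix]),
#'   `core` (planted core family ids) and `gta_families`.
#' @export
generate_order <- function(n_genomes, spec = synthetic_spec(),
                           n_core = 50L, length_jitter = 0.05) {
  stopifnot(n_genomes >= 1L)
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, n_genomes)
  jit <- 1 + stats::runif(n_genomes, -length_jitter, length_jitter)
  records <- vector("list", n_genomes)
  truths <- vector("list", n_genomes)
  ids <- sprintf("genome_%02d", seq_len(n_genomes))
  for (i in seq_len(n_genomes)) {
    Li <- as.integer(round(spec$length * jit[i]))
    f <- Li / spec$length
    segs <- spec$peak_segments
    if (!is.null(segs)) {
      segs <- data.frame(start = pmax(1L, as.integer(round(segs$start * f))),
                         end = pmin(Li, as.integer(round(segs$end * f))),
                         extra_amplitude = segs$extra_amplitude)
    }
    cl <- spec$cluster
    if (!is.null(cl)) {
      cl$position <- max(1L, as.integer(round(cl$position * f)))
    }
    sp <- synthetic_spec(
      length = Li, ori = 1L, skew_amplitude = spec$skew_amplitude,
      gc_content = spec$gc_content, peak_segments = segs,
      n_genes = spec$n_genes, gene_length_codons = spec$gene_length_codons,
      leading_fraction = spec$leading_fraction, cluster = cl,
      peak_codon_bias = spec$peak_codon_bias, repeats = spec$repeats,
      motif_gradient = spec$motif_gradient,
      motif_density = spec$motif_density, seed = seeds[i])
    g <- generate_genome(sp, id = ids[i])
    records[[i]] <- g$record
    truths[[i]] <- g$truth
  }

  # family assignment: cluster genes -> shared gta families; the first
  # n_core background genes (by position) -> shared core families;
  # remaining genes -> private accessory families
  gta_fams <- character()
  for (i in seq_len(n_genomes)) {
    tg <- truths[[i]]$genes
    if (is.null(tg)) next
    fam <- rep(NA_character_, nrow(tg))
    cl_idx <- which(tg$in_cluster)
    if (length(cl_idx)) {
      gta_fams <- sprintf("gta_%02d", seq_along(cl_idx))
      fam[cl_idx] <- gta_fams
    }
    bg_idx <- which(!tg$in_cluster)
    ncore_i <- min(n_core, length(bg_idx))
    if (ncore_i > 0L) {
      fam[bg_idx[seq_len(ncore_i)]] <- sprintf("core_%03d", seq_len(ncore_i))
    }
    rest <- bg_idx[-seq_len(ncore_i)]
    if (length(rest) && ncore_i < length(bg_idx)) {
      fam[rest] <- sprintf("acc_%s_%04d", ids[i], seq_along(rest))
    }
    records[[i]]$genes$family_id <- fam
    truths[[i]]$genes$family_id <- fam
  }

  fams <- sort(unique(unlist(lapply(records, function(r)
    r$genes$family_id[!is.na(r$genes$family_id)]))))
  membership <- matrix(vector("list", length(fams) * n_genomes),
                       nrow = length(fams), ncol = n_genomes)
  for (i in seq_len(n_genomes)) {
    g <- records[[i]]$genes
    for (j in which(!is.na(g$family_id))) {
      fi <- match(g$family_id[j], fams)
      membership[[fi, i]] <- c(membership[[fi, i]], g$gene_id[j])
    }
  }
  mat <- ortho_matrix(membership, fams, ids)
  core_planted <- c(grep("^core_", fams, value = TRUE),
                    grep("^gta_", fams, value = TRUE))
  list(records = records, truths = truths, matrix = mat,
       core = core_planted, gta_families = sort(gta_fams), genome_ids = ids)
}
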