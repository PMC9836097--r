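# GC skew/content, tracks, cohort profiles and sliding-quantile peaks.

test_that("gc_skew and gc_content match the formula on fixed cases", {
  expect_equal(gc_skew("GGGGCC"), (4 - 2) / 6)
  expect_true(is.na(gc_skew("ATATAT")))
  expect_equal(gc_content("GCGC"), 1.0)
  expect_equal(gc_content("ATGC"), 0.5)
  # N is ignored by both statistics
  expect_equal(gc_skew("GGNNCC"), 0)
  expect_equal(gc_content("GCNNAT"), 0.5)
  expect_error(gc_skew(character()), "empty")
  expect_error(gc_content(""), "empty")
})

test_that("gc statistics agree with brute-force counting on random inputs", {
  set.seed(101)
  for (i in 1:50) {
    s <- random_dna(sample(10:1000, 1), prob = runif(4))
    expect_equal(gc_skew(s), oracle_gc_skew(s))
    expect_equal(gc_content(s), oracle_gc_content(s))
  }
})

test_that("skew symmetry under reverse complement", {
  set.seed(102)
  for (i in 1:20) {
    s <- random_dna(200)
    expect_equal(gc_skew(oracle_revcomp(s)), -gc_skew(s))
    expect_equal(gc_content(oracle_revcomp(s)), gc_content(s))
  }
})

test_that("skew_track handles homogeneous and two-phase chromosomes", {
  g <- paste(rep("G", 500), collapse = "")
  t <- skew_track(g, window = 100, step = 10)
  expect_true(all(t$values == 1))
  expect_equal(length(t$values), 50L)

  # G-rich half then C-rich half: positive then negative
  set.seed(103)
  half1 <- random_dna(5000, prob = c(.2, .1, .5, .2))
  half2 <- random_dna(5000, prob = c(.2, .5, .1, .2))
  t2 <- skew_track(paste0(half1, half2), window = 500, step = 100)
  interior1 <- t2$positions < 4500
  interior2 <- t2$positions > 5500 & t2$positions < 9500
  expect_true(all(t2$values[interior1] > 0))
  expect_true(all(t2$values[interior2] < 0))
  expect_error(skew_track(g, window = 0), "window")
  expect_error(skew_track(g, window = 1000), "exceeds")
})

test_that("skew_track windows wrap the circular origin", {
  # A 20-bp circle: windows starting near the end wrap onto the start
  s <- paste0(paste(rep("G", 10), collapse = ""),
              paste(rep("C", 10), collapse = ""))
  t <- skew_track(s, window = 4, step = 1)
  expect_equal(length(t$values), 20L)
  # window starting at 19 covers positions 19,20,1,2 = C,C,G,G -> skew 0
  expect_equal(t$values[19], 0)
})

test_that("track of a rotated chromosome is the rotated track", {
  set.seed(104)
  s <- random_dna(2000)
  w <- 100L; st <- 20L
  t0 <- skew_track(s, window = w, step = st)
  k <- 401L  # multiple of step plus 1 keeps window phase aligned
  rot <- paste0(substr(s, k, 2000), substr(s, 1, k - 1))
  t1 <- skew_track(rot, window = w, step = st)
  shift <- (k - 1L) %/% st
  expect_equal(t1$values, t0$values[((seq_along(t0$values) - 1 + shift) %%
                                       length(t0$values)) + 1])
})

test_that("mean_normalized_track averages bin-wise across the cohort", {
  g1 <- genome_record("a", paste(rep("G", 1000), collapse = ""))
  g2 <- genome_record("b", paste(rep("C", 1200), collapse = ""))
  expect_equal(mean_normalized_track(list(g1), n_bins = 10),
               binned <- rep(1, 10))
  expect_equal(mean_normalized_track(list(g1, g2), n_bins = 10), rep(0, 10))
  expect_error(mean_normalized_track(list()), "empty")
})

test_that("cohort mean track flips sign at the planted terminus", {
  specs <- lapply(1:10, function(i)
    synthetic_spec(length = 500000, skew_amplitude = 0.1, seed = 300 + i))
  recs <- lapply(specs, function(sp) generate_genome(sp)$record)
  prof <- mean_normalized_track(recs, n_bins = 1000)
  expect_true(all(prof[10:490] > 0))
  expect_true(all(prof[520:990] < 0))
  crossings <- which(diff(sign(prof)) != 0)
  expect_true(any(abs(crossings - 500) <= 2))
})

test_that("peak calling: ties, single spike, and negation symmetry", {
  # constant track: strict inequality yields no flags
  t <- manual_track(rep(0.2, 100))
  p <- suppressWarnings(detect_skew_peaks(t, quantile = 0.03, local_window = 1000))
  expect_equal(nrow(p$intervals), 0L)

  # single positive spike among zeros: exactly that position flagged high
  v <- rep(0, 100); v[37] <- 0.5
  t <- manual_track(v)
  p <- suppressWarnings(detect_skew_peaks(t, quantile = 0.03, local_window = 1000))
  expect_identical(which(p$flagged == "high"), 37L)
  expect_false(any(p$flagged == "low", na.rm = TRUE))

  # negating all values swaps the high and low interval sets exactly
  t2 <- manual_track(-v)
  p2 <- suppressWarnings(detect_skew_peaks(t2, quantile = 0.03, local_window = 1000))
  expect_identical(which(p2$flagged == "low"), 37L)
  expect_equal(p2$intervals[c("start", "end")], p$intervals[c("start", "end")])
  expect_identical(p2$intervals$side, "low")
})

test_that("flagged positions follow the local order-statistic rule", {
  # explicit empirical-quantile computation on a hand-made track
  set.seed(105)
  v <- round(rnorm(200), 3)
  t <- manual_track(v, step = 100, window = 100)
  q <- 0.05; lw <- 3000  # 15 positions each side
  p <- detect_skew_peaks(t, quantile = q, local_window = lw)
  half <- floor((lw / 2) / 100)
  for (i in sample(seq_along(v), 25)) {
    idx <- ((i - half):(i + half) - 1) %% 200 + 1
    pool <- sort(v[idx])
    hi <- pool[ceiling((1 - q) * length(pool))]
    lo <- pool[max(1, ceiling(q * length(pool)))]
    expected <- if (v[i] > hi) "high" else if (v[i] < lo) "low" else NA
    expect_identical(p$flagged[i], as.character(expected))
  }
})

test_that("peak calling flags about 2q of a tie-free random track", {
  set.seed(106)
  t <- manual_track(rnorm(2000), step = 1000, window = 1000)
  p <- detect_skew_peaks(t, quantile = 0.03, local_window = 150000)
  rate <- mean(!is.na(p$flagged))
  expect_lt(rate, 2 * 0.03 + 0.01)
  expect_gt(rate, 0.03)  # both tails contribute
})

test_that("peak calling commutes with chromosome rotation", {
  set.seed(107)
  sp <- synthetic_spec(length = 100000, skew_amplitude = 0.15, seed = 42)
  rec <- generate_genome(sp)$record
  t0 <- skew_track(rec, window = 2000, step = 500)
  p0 <- detect_skew_peaks(t0, 0.05, local_window = 20000)
  k <- 20001L  # multiple of step plus 1: window phase preserved
  rot <- reorient_to_position(rec, k)
  t1 <- skew_track(rot, window = 2000, step = 500)
  p1 <- detect_skew_peaks(t1, 0.05, local_window = 20000)
  shift <- (k - 1L) %/% 500L
  n <- length(t0$values)
  expect_identical(p1$flagged,
                   p0$flagged[((seq_len(n) - 1 + shift) %% n) + 1])
})

test_that("large planted segments attract high flags and are always hit", {
  # the local-quantile rule marks the extreme tail of each neighbourhood,
  # so planted segments are reliably hit and enriched in flags even though
  # their full extent is not traced
  set.seed(108)
  segs <- data.frame(start = c(150000, 500000, 800000),
                     end = c(150000, 500000, 800000) + 49999,
                     extra_amplitude = 0.3)
  sp <- synthetic_spec(length = 1e6, skew_amplitude = 0.1,
                       peak_segments = segs, seed = 77)
  rec <- generate_genome(sp)$record
  t <- skew_track(rec, window = 10000, step = 1000)
  p <- detect_skew_peaks(t, 0.03, local_window = 150000)
  hi <- p$intervals[p$intervals$side == "high", , drop = FALSE]
  planted <- circ_mask(segs, rec$length)
  for (i in seq_len(nrow(segs))) {
    seg_mask <- circ_mask(segs[i, ], rec$length)
    expect_true(any(circ_mask(hi, rec$length) & seg_mask))
  }
  in_seg <- planted[t$positions]
  rate_in <- mean(!is.na(p$flagged[in_seg]) & p$flagged[in_seg] == "high")
  rate_out <- mean(!is.na(p$flagged[!in_seg]) & p$flagged[!in_seg] == "high")
  expect_gt(rate_in, 2 * rate_out)
})

test_that("global fallback warns when the local window exceeds the genome", {
  t <- manual_track(c(rep(0, 50), 1, rep(0, 49)))
  expect_warning(p <- detect_skew_peaks(t, 0.03, local_window = 10000),
                 "global")
  expect_identical(which(p$flagged == "high"), 51L)
})

test_that("relative_skew follows its definition and marks undefined", {
  expect_equal(relative_skew(0.06, 0.03), 1.0)
  expect_equal(relative_skew(0.04, 0.04), 0.0)
  expect_true(is.na(relative_skew(0.5, 0)))
  # per-replichore comparison on a synthetic genome, by hand
  seg <- 0.22; host <- 0.1
  expect_equal(relative_skew(seg, host), (seg - host) / host)
})

test_that("per_gene_skew uses the reference strand for both orientations", {
  r <- genome_record("c", "AAGGCCAAAA",
                     data.frame(gene_id = c("p", "m"), start = c(3, 3),
                                end = c(6, 6), strand = c("+", "-")))
  d <- per_gene_skew(r)
  expect_equal(d$skew, c(0, 0))
  expect_equal(d$gc_content, c(1, 1))
  # reference-strand values identical regardless of annotated strand
  expect_equal(d$skew[1], d$skew[2])

  sp <- synthetic_spec(length = 20000, n_genes = 15, seed = 9)
  rec <- generate_genome(sp)$record
  d <- per_gene_skew(rec)
  for (i in seq_len(nrow(rec$genes))) {
    seg <- oracle_region(rec$sequence, rec$genes$start[i], rec$genes$end[i])
    expect_equal(d$skew[i], oracle_gc_skew(seg))
    expect_equal(d$gc_content[i], oracle_gc_content(seg))
  }
})

test_that("genes are assigned to peaks by circular midpoint", {
  r <- genome_record("toy", random_dna(1000),
                     data.frame(gene_id = c("in_hi", "out", "wrapmid"),
                                start = c(100, 500, 990),
                                end = c(140, 540, 30), strand = "+"))
  p <- structure(list(chromosome_id = "toy",
                      intervals = data.frame(start = c(90, 980),
                                             end = c(150, 20),
                                             side = c("high", "low")),
                      quantile = 0.03, local_window = 1000),
                 class = "peak_annotation")
  lab <- assign_genes_to_peaks(r, p)
  expect_equal(lab$label, c("peak", "non_peak", "peak"))
  expect_equal(lab$side, c("high", NA, "low"))
  lab_hi <- assign_genes_to_peaks(r, p, sides = "high")
  expect_equal(lab_hi$label, c("peak", "non_peak", "non_peak"))
  p$chromosome_id <- "other"
  expect_error(assign_genes_to_peaks(r, p), "mismatch")
})
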