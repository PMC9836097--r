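# Replichores, leading/lagging strand, typicality, repeats.

test_that("the eight-row strand/skew truth table is reproduced exactly", {
  # genome of 1000 bp, ori = 1, ter = 501: right replichore = [1, 500]
  L <- 1000
  combos <- expand.grid(repl = c("right", "left"), strand = c("+", "-"),
                        skew = c(0.1, -0.1), stringsAsFactors = FALSE)
  mid <- ifelse(combos$repl == "right", 250, 750)
  genes <- data.frame(gene_id = sprintf("g%d", seq_len(nrow(combos))),
                      start = mid - 10, end = mid + 10,
                      strand = combos$strand)
  rec <- genome_record("c", random_dna(L), genes, ori = 1, ter = 501)
  cls <- classify_gene_architecture(rec, gene_skew = combos$skew)

  expect_equal(cls$replichore, combos$repl)
  lead <- (combos$repl == "right" & combos$strand == "+") |
    (combos$repl == "left" & combos$strand == "-")
  expect_equal(cls$strand_class, ifelse(lead, "leading", "lagging"))
  expect_equal(cls$orientation, ifelse(lead, "co_directional", "head_on"))
  typical <- (combos$repl == "right" & combos$skew > 0) |
    (combos$repl == "left" & combos$skew < 0)
  expect_equal(cls$typical, typical)
  expect_equal(cls$potential_inversion, !typical)
  # spot-check three printed rows:
  # right/leading/positive -> typical, no inversion
  i <- which(combos$repl == "right" & combos$strand == "+" & combos$skew > 0)
  expect_true(cls$typical[i] && !cls$potential_inversion[i])
  # right/lagging/negative -> not typical, potential inversion
  i <- which(combos$repl == "right" & combos$strand == "-" & combos$skew < 0)
  expect_true(!cls$typical[i] && cls$potential_inversion[i])
  # left/leading/negative -> typical, no inversion
  i <- which(combos$repl == "left" & combos$strand == "-" & combos$skew < 0)
  expect_true(cls$typical[i] && !cls$potential_inversion[i])
})

test_that("zero or undefined gene skew yields a third, unclassified state", {
  rec <- genome_record("c", random_dna(1000),
                       data.frame(gene_id = c("z", "u"), start = c(100, 600),
                                  end = c(120, 620), strand = "+"),
                       ori = 1, ter = 501)
  cls <- classify_gene_architecture(rec, gene_skew = c(0, NA))
  expect_equal(cls$skew_sign, c("zero", "zero"))
  expect_true(all(is.na(cls$typical)))
  expect_true(all(is.na(cls$potential_inversion)))
})

test_that("infer_ter: antipodal default and skew-extremum on planted flip", {
  rec <- genome_record("c", random_dna(10000), ori = 1)
  expect_equal(infer_ter(rec, "antipodal"), 5001L)

  sp <- synthetic_spec(length = 400000, skew_amplitude = 0.12, seed = 13)
  rec <- generate_genome(sp)$record
  ter <- infer_ter(rec, "skew_extremum")
  expect_lt(abs(ter - rec$length / 2), 0.02 * rec$length)
  # both methods agree on a clean genome
  expect_lt(abs(ter - infer_ter(rec, "antipodal")), 0.05 * rec$length)
})

test_that("architecture labels are invariant under rotation", {
  sp <- synthetic_spec(length = 50000, n_genes = 30, skew_amplitude = 0.2,
                       seed = 31)
  rec <- generate_genome(sp)$record
  cls0 <- classify_gene_architecture(rec)
  rot <- reorient_to_position(rec, 17000)
  cls1 <- classify_gene_architecture(rot)
  ord0 <- order(cls0$gene_id); ord1 <- order(cls1$gene_id)
  expect_equal(cls1$replichore[ord1], cls0$replichore[ord0])
  expect_equal(cls1$strand_class[ord1], cls0$strand_class[ord0])
  expect_equal(cls1$typical[ord1], cls0$typical[ord0])
})

test_that("reverse complement swaps replichores but keeps strand class", {
  sp <- synthetic_spec(length = 40000, n_genes = 25, skew_amplitude = 0.2,
                       seed = 37)
  rec <- generate_genome(sp)$record
  L <- rec$length
  # reverse complement the whole chromosome: gene (s,e,+) -> (L-e+1, L-s+1, -)
  g <- rec$genes
  rcg <- data.frame(gene_id = g$gene_id, start = L - g$end + 1L,
                    end = L - g$start + 1L,
                    strand = ifelse(g$strand == "+", "-", "+"))
  rcrec <- genome_record("rc", oracle_revcomp(rec$sequence), rcg,
                         ori = L - rec$ori + 1L, ter = L - rec$ter + 1L)
  cls <- classify_gene_architecture(rec)
  clsrc <- classify_gene_architecture(rcrec)
  m <- match(cls$gene_id, clsrc$gene_id)
  swap <- c(right = "left", left = "right")
  expect_equal(clsrc$replichore[m], unname(swap[cls$replichore]))
  expect_equal(clsrc$strand_class[m], cls$strand_class)
  expect_equal(clsrc$typical[m], cls$typical)
})

test_that("architecture_summary recovers planted strand bias", {
  # all genes leading and typical -> 100 % leading
  rec <- genome_record("c", paste(c(rep("G", 500), rep("C", 500)),
                                  collapse = ""),
                       data.frame(gene_id = c("a", "b"), start = c(10, 600),
                                  end = c(90, 680), strand = c("+", "-")),
                       ori = 1, ter = 501)
  s <- architecture_summary(list(rec))
  expect_equal(s$per_genome$pct_leading, 100)
  expect_equal(s$per_genome$pct_typical, 100)

  # planted 60 % leading over a cohort, recovered within binomial error
  cohort <- lapply(1:4, function(i)
    generate_genome(synthetic_spec(length = 150000, n_genes = 120,
                                   leading_fraction = 0.6,
                                   skew_amplitude = 0.2,
                                   gene_length_codons = c(100, 20),
                                   seed = 500 + i))$record)
  s <- architecture_summary(cohort)
  m <- mean(s$per_genome$pct_leading)
  expect_lt(abs(m - 60), 3 * 100 * sqrt(0.6 * 0.4 / (120 * 4)))

  # the four strand-by-typicality categories sum to 100 % per genome
  four <- s$per_genome[, c("pct_leading_typical", "pct_leading_inverted",
                           "pct_lagging_typical", "pct_lagging_inverted")]
  expect_equal(unname(rowSums(four)), rep(100, nrow(four)))
})

test_that("kruskal wrapper matches a hand-ranked H and handles degeneracy", {
  vals <- list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22))
  res <- compare_groups_kruskal(vals)
  H <- oracle_kruskal_H(unlist(vals), rep(1:3, each = 3))
  expect_equal(res$statistic, H)
  expect_equal(res$df, 2L)
  # two identical groups -> p ~ 1 (H = 0)
  res2 <- compare_groups_kruskal(list(c(1, 2, 3), c(1, 2, 3)))
  expect_gt(res2$p.value, 0.9)
  expect_warning(res3 <- compare_groups_kruskal(list(c(5, 5), c(5, 5))),
                 "identical")
  expect_equal(res3$p.value, 1)
  expect_error(compare_groups_kruskal(list(c(1, 2))), "2 categories")
  expect_error(compare_groups_kruskal(list(1, 2)), "2 observations")
})

test_that("filter_repeats applies strict thresholds and overlap exclusion", {
  r <- data.frame(
    start1 = c(100, 100, 100, 2000),
    end1 = c(900, 1300, 1000, 3300),
    start2 = c(5000, 5000, 500, 9000),
    end2 = c(5800, 6200, 1400, 10300),
    length = c(800, 1200, 900, 1300),
    identity = c(0.95, 0.91, 0.95, 0.90))
  f <- filter_repeats(r)
  # row1: length == 800 excluded (strict); row3: copies overlap; row4:
  # identity == 0.90 excluded (strict); row2 kept
  expect_equal(nrow(f), 1L)
  expect_equal(f$length, 1200)
  # malformed rows are dropped, not fatal
  r$identity[2] <- NA
  expect_message(f2 <- filter_repeats(r), "malformed")
  expect_equal(nrow(f2), 0L)
})

test_that("repeat distance classes use minimum circular gaps", {
  L <- 10000
  rec <- genome_record("c", random_dna(L),
                       data.frame(gene_id = c("near_ori", "overlap", "far"),
                                  start = c(50, 3000, 5000),
                                  end = c(60, 3100, 5100), strand = "+"))
  reps <- data.frame(start1 = c(9900, 3050), end1 = c(10000, 3900),
                     start2 = c(4000, 7000), end2 = c(4100, 7850),
                     length = c(101, 851), identity = c(.99, .95))
  d <- repeat_distance_class(rec, reps)
  # gene 50..60 vs copy 9900..10000: circular gap 49 -> far (threshold 10)
  expect_equal(d$distance[d$gene_id == "near_ori"], 49)
  expect_equal(d$class[d$gene_id == "near_ori"], "far")
  expect_equal(d$distance[d$gene_id == "overlap"], 0)
  expect_equal(d$class[d$gene_id == "overlap"], "near")

  # random placements agree with a brute-force all-pairs circular scan
  set.seed(201)
  g <- data.frame(gene_id = sprintf("g%d", 1:12),
                  start = sample(L, 12), end = NA, strand = "+")
  g$end <- (g$start + sample(50:400, 12) - 1L - 1L) %% L + 1L
  rec2 <- genome_record("c", random_dna(L), g)
  reps2 <- data.frame(start1 = c(1200, 8000), end1 = c(2100, 8900),
                      start2 = c(6100, 9500), end2 = c(7000, 400),
                      length = 901, identity = .95)
  d2 <- repeat_distance_class(rec2, reps2)
  copies <- rbind(data.frame(s = reps2$start1, e = reps2$end1),
                  data.frame(s = reps2$start2, e = reps2$end2))
  for (i in seq_len(nrow(g))) {
    gene_pos <- if (g$start[i] <= g$end[i]) g$start[i]:g$end[i] else
      c(g$start[i]:L, 1:g$end[i])
    best <- Inf
    for (j in seq_len(nrow(copies))) {
      cp <- if (copies$s[j] <= copies$e[j]) copies$s[j]:copies$e[j] else
        c(copies$s[j]:L, 1:copies$e[j])
      dd <- outer(gene_pos, cp, function(a, b) pmin((a - b) %% L, (b - a) %% L))
      best <- min(best, min(dd))
    }
    # the reported distance is the gap (bases strictly between), i.e. the
    # minimum pairwise base distance minus one when disjoint
    expect_equal(d2$distance[i], max(best - 1, 0))
    expect_lte(d2$distance[i], L / 2)
  }

  expect_warning(d3 <- repeat_distance_class(rec, reps[0, ]), "no repeats")
  expect_true(all(d3$class == "far"))
})
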