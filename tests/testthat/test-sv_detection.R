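mk_pairs <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  read_pair_records(df$chrom1, df$pos1, df$strand1, df$chrom2, df$pos2,
                    df$strand2, df$mapq, df$mismatches)
}

test_that("discordance pre-filters apply strict boundaries", {
  base <- list(chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
               chrom2 = "chr1", pos2 = 500000L, strand2 = "-")
  at37 <- mk_pairs(c(base, mapq = 37L, mismatches = 0L))
  expect_equal(nrow(select_discordant_pairs(at37, 550)), 0L)
  at38 <- mk_pairs(c(base, mapq = 38L, mismatches = 0L))
  expect_equal(nrow(select_discordant_pairs(at38, 550)), 1L)
  mm3 <- mk_pairs(c(base, mapq = 60L, mismatches = 3L))
  expect_equal(nrow(select_discordant_pairs(mm3, 550)), 0L)
  mm2 <- mk_pairs(c(base, mapq = 60L, mismatches = 2L))
  expect_equal(nrow(select_discordant_pairs(mm2, 550)), 1L)

  # proper FR pair within the insert bound is concordant
  conc <- mk_pairs(chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
                   chrom2 = "chr1", pos2 = 1300L, strand2 = "-",
                   mapq = 60L, mismatches = 0L)
  expect_equal(nrow(select_discordant_pairs(conc, 1000)), 0L)
  # same span, wrong orientation -> discordant
  disc <- mk_pairs(chrom1 = "chr1", pos1 = 1000L, strand1 = "-",
                   chrom2 = "chr1", pos2 = 1300L, strand2 = "+",
                   mapq = 60L, mismatches = 0L)
  expect_equal(nrow(select_discordant_pairs(disc, 1000)), 1L)
  # interchromosomal is always discordant
  inter <- mk_pairs(chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
                    chrom2 = "chr2", pos2 = 1100L, strand2 = "-",
                    mapq = 60L, mismatches = 0L)
  expect_equal(nrow(select_discordant_pairs(inter, 1000)), 1L)
  expect_equal(nrow(select_discordant_pairs(inter[0, ], 1000)), 0L)
})

test_that("end clustering chains positions within the gap", {
  p <- mk_pairs(chrom1 = "chr1", pos1 = c(100L, 450L, 900L), strand1 = "+",
                chrom2 = "chr1", pos2 = c(2e6L, 2e6L + 300L, 2e6L + 600L),
                strand2 = "-", mapq = 60L, mismatches = 0L)
  cl <- cluster_ends(p, gap = 400)
  fwd <- cl$clusters[cl$clusters$side == "forward", ]
  expect_equal(nrow(fwd), 2L)           # {100,450} and {900}: 350<=400<450
  expect_equal(sort(fwd$n_members), c(1L, 2L))

  chain <- mk_pairs(chrom1 = "chr1", pos1 = c(0L, 400L, 800L), strand1 = "+",
                    chrom2 = "chr1", pos2 = c(5e6L, 5e6L, 5e6L), strand2 = "-",
                    mapq = 60L, mismatches = 0L)
  cc <- cluster_ends(chain, gap = 400)
  expect_equal(sum(cc$clusters$side == "forward"), 1L)  # single-linkage chain
  expect_equal(cc$clusters$n_members[cc$clusters$side == "forward"], 3L)

  e <- cluster_ends(p[0, ], gap = 400)
  expect_equal(nrow(e$clusters), 0L)
})

test_that("clustering matches a brute-force single-linkage oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:200, 1)
    p <- mk_pairs(
      chrom1 = sample(c("chr1", "chr2"), n, TRUE),
      pos1 = sample.int(20000L, n, TRUE),
      strand1 = sample(c("+", "-"), n, TRUE),
      chrom2 = sample(c("chr1", "chr2"), n, TRUE),
      pos2 = 1000000L + sample.int(20000L, n, TRUE),
      strand2 = sample(c("+", "-"), n, TRUE),
      mapq = 60L, mismatches = 0L)
    cl <- cluster_ends(p, gap = 400)
    ends <- cl$ends
    oracle <- brute_force_single_linkage(ends$chrom, ends$strand, ends$pos)
    # same partition: cluster labels must be a bijection
    expect_equal(length(unique(paste(oracle, ends$cluster_id))),
                 length(unique(oracle)))
    expect_equal(length(unique(ends$cluster_id)), length(unique(oracle)))
    # every end appears exactly once
    expect_equal(nrow(ends), 2L * n)
    expect_equal(sort(unique(ends$pair_id)), 1:n)
  }
})

test_that("cluster pairing groups supporting read pairs correctly", {
  # 8 pairs all linking one forward and one reverse cluster
  p8 <- mk_pairs(chrom1 = "chr1", pos1 = 1000L + (0:7) * 40L, strand1 = "+",
                 chrom2 = "chr1", pos2 = 500000L + (0:7) * 40L, strand2 = "-",
                 mapq = 60L, mismatches = 0L)
  pc <- pair_clusters(cluster_ends(p8), p8)
  expect_equal(nrow(pc), 1L)
  expect_equal(pc$n_support, 8L)

  # F1 linked to two distinct reverse clusters, 6 supports each
  p12 <- mk_pairs(chrom1 = "chr1", pos1 = rep(1000L + (0:5) * 40L, 2), strand1 = "+",
                  chrom2 = "chr1",
                  pos2 = c(500000L + (0:5) * 40L, 900000L + (0:5) * 40L),
                  strand2 = "-", mapq = 60L, mismatches = 0L)
  pc2 <- pair_clusters(cluster_ends(p12), p12)
  expect_equal(nrow(pc2), 2L)
  expect_equal(pc2$n_support, c(6L, 6L))
  expect_equal(length(unique(pc2$cluster1)), 1L)   # shared forward cluster

  expect_equal(nrow(pair_clusters(cluster_ends(p8[0, ]), p8[0, ])), 0L)

  # a pair whose ends collapse into one cluster is flagged and dropped
  tight <- mk_pairs(chrom1 = "chr1", pos1 = 1000L, strand1 = "+",
                    chrom2 = "chr1", pos2 = 1200L, strand2 = "+",
                    mapq = 60L, mismatches = 0L)
  expect_warning(out <- pair_clusters(cluster_ends(tight), tight),
                 "same cluster")
  expect_equal(nrow(out), 0L)
})

test_that("the six-pair support threshold is exact", {
  mk_n <- function(n) {
    mk_pairs(chrom1 = "chr1", pos1 = 1000L + seq_len(n) * 30L, strand1 = "+",
             chrom2 = "chr1", pos2 = 500000L + seq_len(n) * 30L, strand2 = "-",
             mapq = 60L, mismatches = 0L)
  }
  p6 <- mk_n(6); p5 <- mk_n(5)
  expect_equal(nrow(call_svs(pair_clusters(cluster_ends(p6), p6))), 1L)
  expect_equal(nrow(call_svs(pair_clusters(cluster_ends(p5), p5))), 0L)
})

test_that("SV classification is total over orientations and chromosomes", {
  strands <- expand.grid(s1 = c("+", "-"), s2 = c("+", "-"),
                         stringsAsFactors = FALSE)
  intra <- classify_sv("chr1", "chr1", strands$s1, strands$s2)
  # grid rows: (+,+) (-,+) (+,-) (-,-)
  expect_equal(intra, c("inverted_rearrangement", "tandem_duplication",
                        "deletion", "inverted_rearrangement"))
  expect_setequal(unique(intra),
                  c("deletion", "tandem_duplication", "inverted_rearrangement"))
  inter <- classify_sv("chr1", "chr2", strands$s1, strands$s2)
  expect_true(all(inter == "translocation"))
  expect_equal(classify_sv("chr1", "chr1", "+", "-"), "deletion")
  expect_equal(classify_sv("chr1", "chr1", "-", "+"), "tandem_duplication")
  expect_equal(classify_sv("chr1", "chr1", "+", "+"), "inverted_rearrangement")
})

test_that("panel subtraction requires both breakpoints to match", {
  call <- data.frame(chrom1 = "chr1", bp1 = 1e5, strand1 = "+",
                     chrom2 = "chr1", bp2 = 2e5, strand2 = "-",
                     sv_type = "deletion", n_support = 8L, somatic = NA,
                     sample_id = "S1", distance = 1e5,
                     stringsAsFactors = FALSE)
  class(call) <- c("sv_calls", "data.frame")
  panel_both <- data.frame(chrom1 = "chr1", bp1 = 100300, chrom2 = "chr1",
                           bp2 = 199800, sv_type = "tandem_duplication")
  expect_equal(nrow(subtract_panel(call, panel_both)), 0L)
  panel_one <- transform(panel_both, bp2 = 195000)
  kept <- subtract_panel(call, panel_one)
  expect_equal(nrow(kept), 1L)
  expect_true(kept$somatic)
  kept2 <- subtract_panel(call, panel_both[0, ])
  expect_true(kept2$somatic)
})

test_that("SV summary reports counts, proportions and distances", {
  calls <- data.frame(
    chrom1 = "chr1", bp1 = c(1, 1, 1, 1) * 1e6, strand1 = "+",
    chrom2 = "chr1", bp2 = 1e6 + c(1e3, 1e5, 1e7, 5e3), strand2 = "-",
    sv_type = c("tandem_duplication", "tandem_duplication", "deletion",
                "inverted_rearrangement"),
    n_support = c(8L, 9L, 10L, 11L), somatic = TRUE, sample_id = "S1",
    stringsAsFactors = FALSE)
  calls$distance <- abs(calls$bp2 - calls$bp1)
  class(calls) <- c("sv_calls", "data.frame")
  sm <- summarize_svs(calls)
  expect_equal(sm$tandem_proportion, 0.5)
  expect_equal(sum(sm$counts), sm$total)

  d3 <- transform(calls[1:3, ], distance = c(1e3, 1e5, 1e7))
  class(d3) <- c("sv_calls", "data.frame")
  sm3 <- summarize_svs(d3)
  expect_equal(sm3$median_distance, 1e5)
  expect_equal(sm3$median_log10_distance, 5)

  sm0 <- summarize_svs(empty_calls <- detect_svs(mk_pairs(
    chrom1 = character(0), pos1 = integer(0), strand1 = character(0),
    chrom2 = character(0), pos2 = integer(0), strand2 = character(0),
    mapq = integer(0), mismatches = integer(0))))
  expect_equal(sm0$total, 0L)
  expect_true(is.na(sm0$median_distance))
})

test_that("caller output obeys the support and filter invariants end to end", {
  s <- simulate_sample(sim_config(seed = 9, n_snps_per_segment = 20L,
                                  n_snvs = 20L))
  disc <- select_discordant_pairs(s$read_pairs, 550)
  expect_true(all(disc$mapq > 37 & disc$mismatches <= 2))
  calls <- detect_svs(s$read_pairs,
                      panel = clonesv:::panel_junctions_to_calls(s$panel_junctions))
  expect_true(all(calls$n_support >= 6))
  expect_true(all(is.na(calls$distance) == (calls$chrom1 != calls$chrom2)))
  pr <- sv_precision_recall(calls, s$truth$sv_truth)
  expect_gte(pr$precision, 0.95)
  expect_gte(pr$recall, 0.95)
})
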