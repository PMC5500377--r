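test_that("clone tree enforces its invariants", {
  expect_s3_class(tn19_tree(), "clone_tree")
  expect_error(clone_tree(c("a", "b"), c(0.5, 0.5), c(NA, NA)),
               "exactly one truncal")
  expect_error(clone_tree(c("a", "b", "c"), c(0.5, 0.3, 0.3),
                          c(NA, "a", "a")), "sibling")
  expect_error(clone_tree("a", 1.2, NA), "\\[0, 1\\]")
})

test_that("het-SNP depths follow the mixture minor fraction", {
  tree <- tn19_tree()
  seg <- data.frame(chrom = "chr1", start = 0L, end = 2e6, clone_id = "truncal",
                    major_cn = 1L, minor_cn = 0L)
  # pure normal: clone_id not in tree -> c = 0 -> minor fraction 1/2
  seg_n <- transform(seg, clone_id = "normal", minor_cn = 1L)
  obs <- simulate_het_snp_depths(seg_n, tree, 160, 2000, seed = 7)
  minor <- ifelse(obs$phased_minor == "alt", obs$tumor_alt, obs$tumor_ref)
  expect_equal(sum(minor) / sum(obs$tumor_ref + obs$tumor_alt), 0.5,
               tolerance = 0.02)

  # fully clonal loss: c = 1 -> minor fraction 0
  tree1 <- clone_tree("truncal", 1, NA)
  obs1 <- simulate_het_snp_depths(seg, tree1, 160, 500, seed = 8)
  minor1 <- ifelse(obs1$phased_minor == "alt", obs1$tumor_alt, obs1$tumor_ref)
  expect_identical(sum(minor1), 0L)

  # c = 0.89 -> f = (1-0.89)/(2-0.89) = 0.0991 within +-0.01 at n = 2000
  obs89 <- simulate_het_snp_depths(seg, tree, 160, 2000, seed = 1)
  minor89 <- ifelse(obs89$phased_minor == "alt", obs89$tumor_alt, obs89$tumor_ref)
  f_hat <- sum(minor89) / sum(obs89$tumor_ref + obs89$tumor_alt)
  expect_lt(abs(f_hat - (1 - 0.89) / (2 - 0.89)), 0.01)

  # depth conservation at every site
  expect_true(all(obs89$tumor_ref + obs89$tumor_alt >= 1))
  expect_true(all(obs89$normal_ref >= 0 & obs89$normal_alt >= 0))

  expect_error(simulate_het_snp_depths(seg, tree, -5, 10, 1), "coverage")
})

test_that("read-pair generation respects the orientation contract", {
  td <- data.frame(sv_type = "tandem_duplication", chrom1 = "chr1", bp1 = 1e6,
                   chrom2 = "chr1", bp2 = 1.005e6, n_support = 8L)
  pairs <- simulate_discordant_pairs(td, seed = 3, n_background = 0L,
                                     noise_per_bp = 0, junk_frac = 0)
  expect_equal(nrow(pairs), 8L)
  expect_true(all(pairs$strand1 == "-" & pairs$strand2 == "+"))
  expect_true(all(abs(pairs$pos1 - 1e6) <= 400))

  tra <- data.frame(sv_type = "translocation", chrom1 = "chr1", bp1 = 1e6,
                    chrom2 = "chr2", bp2 = 2e6, n_support = 6L)
  pt <- simulate_discordant_pairs(tra, seed = 4, n_background = 0L,
                                  noise_per_bp = 0, junk_frac = 0)
  expect_true(all(pt$chrom1 != pt$chrom2))

  expect_error(simulate_discordant_pairs(transform(td, n_support = 0L), seed = 1),
               "n_support")
})

test_that("background-only input produces no callable clusters", {
  empty <- default_sv_truth()[0, ]
  pairs <- simulate_discordant_pairs(empty, n_background = 100L, seed = 11)
  calls <- detect_svs(pairs)
  expect_equal(nrow(calls), 0L)
})

test_that("SNV catalog matches the signature mixture and clone VAF algebra", {
  profiles <- synthetic_signature_profiles()
  tree <- tn19_tree()
  segs <- default_segments()
  # pure profile-1 mixture: empirical spectrum close in total variation
  snvs <- simulate_snv_catalog(profiles, c(1, 0, 0), 10000L, tree, segs,
                               seed = 5)
  spec <- trinucleotide_spectrum(snvs)
  tv <- 0.5 * sum(abs(as.numeric(spec) / sum(spec) - profiles[, 1]))
  expect_lt(tv, 0.03)

  # truncal SNVs at CN 1 have expected VAF c/(2-c) = 0.80
  tr <- snvs[snvs$clone_id == "truncal", ]
  expect_equal(mean(tr$vaf), 0.89 / (2 - 0.89), tolerance = 0.01)

  # per-strand counts sum to alt depth
  expect_true(all(snvs$alt_fwd + snvs$alt_rev == snvs$alt_depth))

  expect_equal(nrow(simulate_snv_catalog(profiles, c(1, 0, 0), 0L, tree, segs,
                                         seed = 1)), 0L)
  expect_error(simulate_snv_catalog(profiles, c(0.7, 0.2, 0.2), 10L, tree,
                                    segs, seed = 1), "sum to 1")
})

test_that("simulate_sample is deterministic and round-trips through files", {
  cfg <- sim_config(seed = 42, n_snps_per_segment = 50L, n_snvs = 40L,
                    n_background = 50L)
  s1 <- simulate_sample(cfg)
  s2 <- simulate_sample(cfg)
  expect_identical(s1$snp_observations, s2$snp_observations)
  expect_identical(s1$read_pairs, s2$read_pairs)
  expect_identical(s1$snv_candidates, s2$snv_candidates)

  # default config always carries major=1/minor=0 evidence and a 2-clone tree
  expect_true(any(s1$segments$major_cn == 1 & s1$segments$minor_cn == 0))
  expect_equal(nrow(s1$truth$clone_tree), 2L)

  d1 <- file.path(tempdir(), "samp_a"); d2 <- file.path(tempdir(), "samp_b")
  write_sample(s1, d1); write_sample(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  rt <- read_sample(d1)
  expect_equal(rt$truth$purity, 0.89)
  expect_equal(nrow(rt$read_pairs), nrow(s1$read_pairs))
  expect_equal(rt$read_pairs$pos1, s1$read_pairs$pos1)
  expect_equal(sort(unlist(rt$truth$exposures)),
               sort(s1$truth$exposures))
  unlink(c(d1, d2), recursive = TRUE)
})
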