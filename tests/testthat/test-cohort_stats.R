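ann_row <- function(b1_mut = NA, rc_mut = NA, b1_beta = NA, rc_beta = NA) {
  data.frame(sample_id = "S", brca1_disruptive_mutation = b1_mut,
             rad51c_disruptive_mutation = rc_mut,
             brca1_promoter_beta = b1_beta, rad51c_promoter_beta = rc_beta,
             stringsAsFactors = FALSE)
}

test_that("HR status classification follows the methylation/mutation rule", {
  expect_equal(classify_hr_status(ann_row(b1_mut = FALSE, b1_beta = 0.25)),
               "defective")
  expect_equal(classify_hr_status(ann_row(b1_mut = FALSE, rc_mut = FALSE,
                                          b1_beta = 0.05, rc_beta = 0.05)),
               "intact")
  expect_equal(classify_hr_status(ann_row(rc_mut = TRUE)), "defective")
  expect_equal(classify_hr_status(ann_row()), "unknown")
  # boundary: beta exactly at the threshold is not above it
  expect_equal(classify_hr_status(ann_row(b1_beta = 0.2)), "intact")
  # monotone in beta: raising a beta never flips defective -> intact
  grid <- seq(0, 1, by = 0.05)
  st <- classify_hr_status(do.call(rbind, lapply(grid, function(b)
    ann_row(b1_beta = b))))
  first_def <- match("defective", st)
  expect_true(all(st[first_def:length(st)] == "defective"))
  expect_error(classify_hr_status(ann_row(b1_beta = 1.3)), "beta")
})

test_that("Fisher exact test reproduces the cohort enrichment p-value", {
  # SVs near the TGFA locus: 6 of the TNBC vs 11 of the non-TNBC tumors
  res <- fisher_exact_2x2(6, 104, 11, 976)
  expect_equal(signif(res$p.value, 2), 0.0044)
  expect_equal(res$odds.ratio, 6 * 976 / (104 * 11))
  expect_equal(fisher_exact_2x2(2, 2, 2, 2)$p.value, 1.0)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
  # agrees with the standard implementation on a handful of tables
  for (tb in list(c(3, 7, 9, 2), c(0, 5, 5, 0), c(10, 1, 2, 12))) {
    expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])$p.value,
                 stats::fisher.test(matrix(tb, 2, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Fisher p matches exhaustive enumeration on all tables with total <= 25", {
  for (total in c(5, 12, 25)) {
    combos <- expand.grid(a = 0:total, b = 0:total, c = 0:total)
    combos <- combos[combos$a + combos$b + combos$c <= total, ]
    combos$d <- total - combos$a - combos$b - combos$c
    combos <- combos[combos$d >= 0 & rowSums(combos) > 0, ]
    p_impl <- mapply(function(a, b, c, d) fisher_exact_2x2(a, b, c, d)$p.value,
                     combos$a, combos$b, combos$c, combos$d)
    p_orac <- mapply(fisher_enum_oracle, combos$a, combos$b, combos$c, combos$d)
    expect_equal(p_impl, p_orac, tolerance = 1e-12)
  }
})

test_that("Wilcoxon rank-sum exact and approximate paths behave as stated", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$method, "exact")
  expect_equal(r$p.value, 0.1)   # 2 / choose(6, 3)
  same <- wilcoxon_rank_sum(c(1.5, 2.5, 3.5, 4.5), c(1.5, 2.5, 3.5, 4.5))
  expect_gte(same$p.value, 0.99)
  # symmetry of the exact path
  set.seed(4)
  x <- rnorm(8); y <- rnorm(8, 1)
  expect_equal(wilcoxon_rank_sum(x, y)$p.value,
               wilcoxon_rank_sum(y, x)$p.value)
  # exact vs approximate agreement on tie-free 15 vs 15
  set.seed(5)
  x15 <- rnorm(15); y15 <- rnorm(15, 0.7)
  pe <- wilcoxon_rank_sum(x15, y15, exact_below = 20)$p.value
  pa <- wilcoxon_rank_sum(x15, y15, exact_below = 1)$p.value
  expect_equal(wilcoxon_rank_sum(x15, y15, exact_below = 1)$method, "normal")
  expect_lt(abs(pe - pa), 0.01)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")
})

test_that("the cohort report orders, flags and compares samples", {
  mk_sample <- function(n_sv, brca, hr, seed) {
    calls <- data.frame(
      chrom1 = "chr1", bp1 = seq_len(n_sv) * 1e6, strand1 = "-",
      chrom2 = "chr1", bp2 = seq_len(n_sv) * 1e6 + 5e4, strand2 = "+",
      sv_type = "tandem_duplication", n_support = 8L, somatic = TRUE,
      sample_id = "x", stringsAsFactors = FALSE)
    calls$distance <- abs(calls$bp2 - calls$bp1)
    class(calls) <- c("sv_calls", "data.frame")
    profiles <- synthetic_signature_profiles()
    mix <- c(brca, 1 - brca - 0.1, 0.1)
    snvs <- simulate_snv_catalog(profiles, mix, 400L, tn19_tree(),
                                 default_segments(), seed = seed)
    list(sv_summary = summarize_svs(calls),
         clones = clonesv:::new_clone_fit(
           cbind(compute_clonality(c(0.8, 0.3)), n_members = c(10L, 5L),
                 method = "cn_global"), "cn_global"),
         exposures = fit_signature_exposures(trinucleotide_spectrum(snvs),
                                             profiles),
         hr_status = hr)
  }
  samples <- list(low = mk_sample(4, 0.2, "intact", 1),
                  high = mk_sample(12, 0.8, "defective", 2))
  rep <- build_report(samples)
  expect_equal(rep$table$sample_id, c("high", "low"))   # BRCA-ratio ordering
  expect_false(any(rep$table$incomplete))

  # empty cohort: header-only table
  rep0 <- build_report(list())
  expect_equal(nrow(rep0$table), 0L)
  expect_true(all(c("sample_id", "n_sv", "hr_status") %in% names(rep0$table)))

  # missing component flagged, not dropped
  partial <- samples
  partial$low$exposures <- NULL
  repp <- build_report(partial)
  expect_true(repp$table$incomplete[repp$table$sample_id == "low"])
  expect_equal(nrow(repp$table), 2L)
})

test_that("a 3x SV-count difference is detectable at n = 8 vs 8", {
  set.seed(17)
  defective <- rpois(8, 90)   # HR-defective: ~3x the SV burden
  intact <- rpois(8, 30)
  p <- wilcoxon_rank_sum(defective, intact)$p.value
  expect_lt(p, 0.05)
})
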