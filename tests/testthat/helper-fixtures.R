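# Shared fixtures, all generated in code.

tn19_tree <- function() {
  clone_tree(c("truncal", "sub1"), c(0.89, 0.42), c(NA, "truncal"))
}

# a small, fast configuration for tests that only need clonal evidence
clonal_only_config <- function(seed, n_snps = 400L, n_snvs = 300L) {
  sim_config(seed = seed, n_snps_per_segment = n_snps, n_snvs = n_snvs,
             sv_truth = default_sv_truth()[0, ],
             panel_junctions = default_panel_junctions()[0, ],
             n_background = 0L, noise_per_bp = 0, junk_frac = 0)
}

# brute-force O(n^2) single-linkage clustering oracle over end positions
brute_force_single_linkage <- function(chrom, strand, pos, gap = 400) {
  n <- length(pos)
  id <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (chrom[i] == chrom[j] && strand[i] == strand[j] &&
          abs(pos[i] - pos[j]) <= gap && id[i] != id[j]) {
        id[id == max(id[i], id[j])] <- min(id[i], id[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(id, unique(id))
}

# exhaustive two-sided Fisher p by direct enumeration with explicit
# binomial-coefficient arithmetic (independent of dhyper)
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  prob_of <- function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  ps <- vapply(xs, prob_of, numeric(1))
  obs <- prob_of(a)
  sum(ps[ps <= obs * (1 + 1e-7)])
}

make_snv_df <- function(depth, alt, fwd = NULL, chrom = "chr1",
                        pos = seq_along(depth), ref = "C", alt_base = "T") {
  fwd <- fwd %||% floor(alt / 2)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt_base,
             depth = depth, alt_depth = alt, alt_fwd = fwd,
             alt_rev = alt - fwd, context = "ACG",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
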