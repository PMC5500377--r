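#' Clone tree constructor
#'
#' A clone tree holds the tumor's clonal composition: one truncal (founding)
#' clone whose alterations are shared by all tumor cells, plus nested
#' subclones. Cellularity is the fraction of *all* cells (tumor and
#' contaminating normal) belonging to a clone, so the truncal cellularity
#' equals the tumor purity.
#'
#' @param clone_id character vector of clone identifiers.
#' @param cellularity numeric vector in `[0, 1]`, one per clone.
#' @param parent_id parent clone of each clone; `NA` for the truncal clone.
#' @return A `clone_tree` object: a data frame of clones with attribute
#'   `truncal_id`.
#' @examples
#' clone_tree(c("truncal", "sub1"), c(0.89, 0.42), c(NA, "truncal"))
#' @export
clone_tree <- function(clone_id, cellularity, parent_id) {
  stopifnot(length(clone_id) == length(cellularity),
            length(clone_id) == length(parent_id))
  if (any(cellularity < 0 | cellularity > 1)) {
    stop_config("cellularities must lie in [0, 1]")
  }
  roots <- which(is.na(parent_id))
  if (length(roots) != 1L) stop_config("exactly one truncal clone (parent NA) required")
  clones <- data.frame(clone_id = as.character(clone_id),
                       cellularity = as.numeric(cellularity),
                       parent_id = as.character(parent_id),
                       stringsAsFactors = FALSE)
  # parent must contain its children: each child <= parent, siblings sum <= parent
  for (i in seq_len(nrow(clones))) {
    kids <- clones$parent_id == clones$clone_id[i] & !is.na(clones$parent_id)
    if (any(kids)) {
      if (sum(clones$cellularity[kids]) > clones$cellularity[i] + 1e-12) {
        stop_config("sibling cellularities exceed parent cellularity")
      }
    }
  }
  structure(clones, truncal_id = clones$clone_id[roots], class = c("clone_tree", "data.frame"))
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("Clone tree (truncal: ", attr(x, "truncal_id"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

clone_cellularity <- function(tree, clone_id) {
  if (is.na(clone_id) || identical(clone_id, "normal")) return(0)
  i <- match(clone_id, tree$clone_id)
  if (is.na(i)) stop_config("unknown clone_id: ", clone_id)
  tree$cellularity[i]
}

#' Default synthetic genome
#'
#' Three 50-Mbp chromosomes with a centromere at 25 Mbp each; small enough
#' that the whole pipeline runs in seconds, large enough that random
#' discordant noise essentially never forms a six-pair cluster.
#'
#' @export
default_genome <- function() {
  data.frame(chrom = c("chr1", "chr2", "chr3"),
             length = rep(5e7, 3), centromere = rep(2.5e7, 3),
             stringsAsFactors = FALSE)
}

default_sv_truth <- function() {
  data.frame(
    sv_type = c("tandem_duplication", "tandem_duplication", "tandem_duplication",
                "deletion", "deletion",
                "inverted_rearrangement", "inverted_rearrangement", "inverted_rearrangement",
                "translocation", "translocation"),
    chrom1 = c("chr1", "chr1", "chr2", "chr1", "chr2", "chr2", "chr3", "chr3", "chr1", "chr2"),
    bp1    = c(10e6, 20e6, 15e6, 30e6, 35e6, 20e6, 10e6, 30e6, 40e6, 45e6),
    chrom2 = c("chr1", "chr1", "chr2", "chr1", "chr2", "chr2", "chr3", "chr3", "chr2", "chr3"),
    bp2    = c(10.005e6, 20.3e6, 15.0055e6, 30.3e6, 35.05e6, 30e6, 20.2e6, 32e6, 5e6, 8e6),
    n_support = c(8L, 12L, 9L, 10L, 7L, 15L, 11L, 6L, 14L, 9L),
    stringsAsFactors = FALSE)
}

default_panel_junctions <- function() {
  data.frame(
    sv_type = c("deletion", "tandem_duplication"),
    chrom1 = c("chr1", "chr3"), bp1 = c(5e6, 40e6),
    chrom2 = c("chr1", "chr3"), bp2 = c(5.002e6, 40.003e6),
    n_support = c(8L, 7L), stringsAsFactors = FALSE)
}

default_segments <- function(genome = default_genome()) {
  # 24 x 1.5 Mbp segments: 12 truncal LOH (1,0), 6 subclonal LOH (1,0),
  # 6 untouched diploid (1,1); spread over the genome away from SV loci.
  seg_per_chrom <- 8L
  out <- list()
  clone_cycle <- c("truncal", "truncal", "sub1", "normal",
                   "truncal", "truncal", "sub1", "normal")
  for (ci in seq_len(nrow(genome))) {
    start <- (seq_len(seg_per_chrom) - 1) * 6e6 + 1e6
    cl <- clone_cycle
    out[[ci]] <- data.frame(
      chrom = genome$chrom[ci], start = start, end = start + 1.5e6,
      clone_id = cl,
      major_cn = ifelse(cl == "normal", 1L, 1L),
      minor_cn = ifelse(cl == "normal", 1L, 0L),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-tumor generator. The defaults describe
#' a tumor modelled on a deeply sequenced triple-negative breast cancer:
#' truncal clone at 89% cellularity with one subclone at 42%, ~160x mean
#' coverage, allele-specific copy-number segments including major=1/minor=0
#' loss-of-heterozygosity regions, ten somatic structural variants spanning
#' the four classes, a two-junction artifact panel, and SNVs drawn from a
#' three-signature mixture.
#'
#' @param seed master seed; every random stream derives from it.
#' @param purity truncal cellularity in `(0, 1]`.
#' @param subclone_cellularity cellularity of the single default subclone
#'   (set `NULL` for a monoclonal tumor).
#' @param coverage mean sequencing depth.
#' @param n_snps_per_segment heterozygous SNPs simulated per CN segment.
#' @param segments per-clone allele-specific CN segment table
#'   (chrom, start, end, clone_id, major_cn, minor_cn).
#' @param sv_truth ground-truth SV table (sv_type, chrom1, bp1, chrom2, bp2,
#'   n_support).
#' @param panel_junctions recurrent artifact junctions present in both the
#'   tumor reads and the normal panel.
#' @param signature_mix nonnegative signature weights summing to 1.
#' @param n_snvs number of somatic SNVs to simulate.
#' @param insert_mean,insert_sd paired-end insert size model (bp).
#' @param n_background number of concordant background read pairs.
#' @param noise_per_bp density of random discordant noise pairs
#'   (default 1 per 100 kbp).
#' @param junk_frac fraction of additional pairs that fail the mapping
#'   quality / mismatch filters (exercises the pre-filters).
#' @param genome chromosome table (chrom, length, centromere).
#' @param sample_id sample label carried on every record.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, purity = 0.89, subclone_cellularity = 0.42,
                       coverage = 160, n_snps_per_segment = 500L,
                       segments = default_segments(genome),
                       sv_truth = default_sv_truth(),
                       panel_junctions = default_panel_junctions(),
                       signature_mix = c(brca_like = 0.6, age_like = 0.3, apobec_like = 0.1),
                       n_snvs = 300L,
                       insert_mean = 350, insert_sd = 50,
                       n_background = 1000L, noise_per_bp = 1e-5,
                       junk_frac = 0.05,
                       genome = default_genome(),
                       sample_id = "S1") {
  if (purity <= 0 || purity > 1) stop_config("purity must lie in (0, 1]")
  if (coverage <= 0) stop_config("coverage must be positive")
  if (abs(sum(signature_mix) - 1) > 1e-9 || any(signature_mix < 0)) {
    stop_config("signature_mix must be nonnegative and sum to 1 (within 1e-9)")
  }
  if (is.null(subclone_cellularity)) {
    tree <- clone_tree("truncal", purity, NA_character_)
    segments <- segments[segments$clone_id != "sub1", , drop = FALSE]
  } else {
    tree <- clone_tree(c("truncal", "sub1"), c(purity, subclone_cellularity),
                       c(NA, "truncal"))
  }
  structure(list(seed = as.integer(seed), purity = purity,
                 clone_tree = tree, coverage = coverage,
                 n_snps_per_segment = as.integer(n_snps_per_segment),
                 segments = segments, sv_truth = sv_truth,
                 panel_junctions = panel_junctions,
                 signature_mix = signature_mix, n_snvs = as.integer(n_snvs),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 n_background = as.integer(n_background),
                 noise_per_bp = noise_per_bp, junk_frac = junk_frac,
                 genome = genome, sample_id = sample_id),
            class = "sim_config")
}

#' Simulate read depths at heterozygous SNPs over one CN segment
#'
#' Models a mixture of tumor cells carrying the segment's allele-specific
#' copy-number state (fraction `c`, the assigned clone's cellularity) and
#' remaining cells that are diploid heterozygous. Total tumor depth at a SNP
#' is Poisson around the coverage scaled by the average total copy number;
#' reads from the minor (phased, possibly lost) allele are Binomial with
#' success probability
#' `f = (c * minor + (1 - c)) / (c * (major + minor) + 2 * (1 - c))`.
#' For a major=1/minor=0 segment this is `f = (1 - c) / (2 - c)`.
#'
#' @param segment one-row data frame (or list) with `chrom`, `start`, `end`,
#'   `clone_id`, `major_cn`, `minor_cn`.
#' @param tree a [clone_tree()].
#' @param coverage mean depth.
#' @param n_snps number of SNPs to simulate.
#' @param seed RNG seed.
#' @param sample_id sample label.
#' @return data frame of heterozygous-SNP observations (1-based positions)
#'   with truth column `phased_minor` naming the minor allele.
#' @export
simulate_het_snp_depths <- function(segment, tree, coverage, n_snps, seed,
                                    sample_id = "S1") {
  if (coverage <= 0) stop_config("coverage must be positive")
  if (!inherits(tree, "clone_tree") || nrow(tree) == 0L) {
    stop_config("a non-empty clone_tree is required")
  }
  cc <- clone_cellularity(tree, segment$clone_id)
  M <- as.numeric(segment$major_cn); m <- as.numeric(segment$minor_cn)
  tot <- cc * (M + m) + 2 * (1 - cc)
  f <- (cc * m + (1 - cc)) / tot
  with_seed(seed, {
    pos <- sort(sample(seq.int(segment$start + 1L, segment$end), n_snps))
    norm_depth <- pmax(1L, stats::rpois(n_snps, coverage))
    norm_alt <- stats::rbinom(n_snps, norm_depth, 0.5)
    tum_depth <- pmax(1L, stats::rpois(n_snps, coverage * tot / 2))
    minor_reads <- stats::rbinom(n_snps, tum_depth, f)
    phased_minor <- sample(c("ref", "alt"), n_snps, replace = TRUE)
    tumor_alt <- ifelse(phased_minor == "alt", minor_reads, tum_depth - minor_reads)
    data.frame(sample = sample_id, chrom = segment$chrom, pos = pos,
               normal_ref = norm_depth - norm_alt, normal_alt = norm_alt,
               tumor_ref = tum_depth - tumor_alt, tumor_alt = tumor_alt,
               phased_minor = phased_minor, stringsAsFactors = FALSE)
  })
}

# jitter helpers: leftmost aligned positions of reads flanking a breakpoint.
# '+' ends sit upstream of the breakpoint, '-' ends at/after it.
jit_plus <- function(n, bp, insert_mean, read_len = 100) {
  if (insert_mean <= read_len) {
    stop_config("insert_mean must exceed the read length")
  }
  as.integer(round(bp - stats::runif(n, read_len, insert_mean)))
}
jit_minus <- function(n, bp, insert_mean, read_len = 100) {
  as.integer(round(bp + stats::runif(n, 0, insert_mean - read_len)))
}

# Supporting pairs for one junction under the caller's orientation convention
# (canonically ordered ends): deletion (+,-), tandem duplication (-,+),
# inverted rearrangement (+,+) or (-,-), translocation (+,-) by convention.
junction_support_pairs <- function(sv, insert_mean, inv_strand = "+") {
  n <- sv$n_support
  type <- sv$sv_type
  if (type == "deletion" || type == "translocation") {
    s1 <- "+"; s2 <- "-"
    p1 <- jit_plus(n, sv$bp1, insert_mean); p2 <- jit_minus(n, sv$bp2, insert_mean)
  } else if (type == "tandem_duplication") {
    s1 <- "-"; s2 <- "+"
    p1 <- jit_minus(n, sv$bp1, insert_mean); p2 <- jit_plus(n, sv$bp2, insert_mean)
  } else if (type == "inverted_rearrangement") {
    if (inv_strand == "+") {
      s1 <- s2 <- "+"
      p1 <- jit_plus(n, sv$bp1, insert_mean); p2 <- jit_plus(n, sv$bp2, insert_mean)
    } else {
      s1 <- s2 <- "-"
      p1 <- jit_minus(n, sv$bp1, insert_mean); p2 <- jit_minus(n, sv$bp2, insert_mean)
    }
  } else stop_config("unknown sv_type: ", type)
  data.frame(chrom1 = sv$chrom1, pos1 = p1, strand1 = s1,
             chrom2 = sv$chrom2, pos2 = p2, strand2 = s2,
             mapq = 60L, mismatches = sample(0:2, n, replace = TRUE,
                                             prob = c(0.7, 0.2, 0.1)),
             stringsAsFactors = FALSE)
}

#' Simulate discordant and background read pairs
#'
#' Every ground-truth junction contributes `n_support` pairs whose
#' orientations follow the caller's classification convention and whose
#' leftmost positions are jittered within the insert-size range of the
#' breakpoints. Background consists of concordant (FR, insert-sized) pairs,
#' uniform random discordant noise at `noise_per_bp`, and a small fraction
#' of pairs that fail the mapping-quality/mismatch pre-filters.
#'
#' @inheritParams sim_config
#' @param sv_truth ground-truth junction table; may have zero rows.
#' @param seed RNG seed.
#' @param read_len read length (bp) used for position jitter.
#' @return canonically ordered read-pair records (0-based leftmost positions).
#' @export
simulate_discordant_pairs <- function(sv_truth, insert_mean = 350, insert_sd = 50,
                                      n_background = 1000L, seed = 1L,
                                      genome = default_genome(),
                                      noise_per_bp = 1e-5, junk_frac = 0.05,
                                      read_len = 100, sample_id = "S1") {
  if (nrow(sv_truth) > 0 && any(sv_truth$n_support < 1)) {
    stop_config("each truth SV needs n_support >= 1")
  }
  with_seed(seed, {
    parts <- list()
    if (nrow(sv_truth) > 0) {
      inv_strands <- rep(c("+", "-"), length.out = nrow(sv_truth))
      parts <- lapply(seq_len(nrow(sv_truth)), function(i) {
        junction_support_pairs(sv_truth[i, ], insert_mean, inv_strands[i])
      })
    }
    # concordant FR background
    if (n_background > 0) {
      ci <- sample(nrow(genome), n_background, replace = TRUE)
      p1 <- as.integer(floor(stats::runif(n_background, 1, genome$length[ci] - 2000)))
      gap <- pmax(50, round(stats::rnorm(n_background, insert_mean - read_len, insert_sd)))
      parts$background <- data.frame(
        chrom1 = genome$chrom[ci], pos1 = p1, strand1 = "+",
        chrom2 = genome$chrom[ci], pos2 = p1 + as.integer(gap), strand2 = "-",
        mapq = 60L, mismatches = sample(0:2, n_background, replace = TRUE,
                                        prob = c(0.7, 0.2, 0.1)),
        stringsAsFactors = FALSE)
    }
    # uniform discordant noise
    n_noise <- as.integer(round(sum(genome$length) * noise_per_bp))
    if (n_noise > 0) {
      c1 <- sample(nrow(genome), n_noise, replace = TRUE)
      c2 <- sample(nrow(genome), n_noise, replace = TRUE)
      parts$noise <- data.frame(
        chrom1 = genome$chrom[c1],
        pos1 = as.integer(floor(stats::runif(n_noise, 1, genome$length[c1] - 200))),
        strand1 = sample(c("+", "-"), n_noise, replace = TRUE),
        chrom2 = genome$chrom[c2],
        pos2 = as.integer(floor(stats::runif(n_noise, 1, genome$length[c2] - 200))),
        strand2 = sample(c("+", "-"), n_noise, replace = TRUE),
        mapq = sample(38:60, n_noise, replace = TRUE),
        mismatches = sample(0:2, n_noise, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    # pairs that must be removed by the mapq/mismatch pre-filters
    n_junk <- as.integer(round(junk_frac * (n_background + n_noise)))
    if (n_junk > 0) {
      cj <- sample(nrow(genome), n_junk, replace = TRUE)
      bad_mapq <- sample(c(TRUE, FALSE), n_junk, replace = TRUE)
      parts$junk <- data.frame(
        chrom1 = genome$chrom[cj],
        pos1 = as.integer(floor(stats::runif(n_junk, 1, genome$length[cj] - 200))),
        strand1 = sample(c("+", "-"), n_junk, replace = TRUE),
        chrom2 = genome$chrom[cj],
        pos2 = as.integer(floor(stats::runif(n_junk, 1, genome$length[cj] - 200))),
        strand2 = sample(c("+", "-"), n_junk, replace = TRUE),
        mapq = ifelse(bad_mapq, sample(0:37, n_junk, replace = TRUE), 60L),
        mismatches = ifelse(bad_mapq, sample(0:2, n_junk, replace = TRUE),
                            sample(3:6, n_junk, replace = TRUE)),
        stringsAsFactors = FALSE)
    }
    all <- do.call(rbind, unname(parts))
    if (is.null(all)) {
      all <- data.frame(chrom1 = character(), pos1 = integer(), strand1 = character(),
                        chrom2 = character(), pos2 = integer(), strand2 = character(),
                        mapq = integer(), mismatches = integer(),
                        stringsAsFactors = FALSE)
    }
    read_pair_records(all$chrom1, all$pos1, all$strand1,
                      all$chrom2, all$pos2, all$strand2,
                      all$mapq, all$mismatches, sample_id)
  })
}

#' Simulate a signature-mixed somatic SNV catalog
#'
#' Trinucleotide contexts are drawn from the weighted mixture of the given
#' 96-channel signature profiles; each SNV is assigned to a clone, placed in
#' a compatible CN region, and its allele depths are drawn Binomially around
#' the VAF implied by clone cellularity, purity and local copy number
#' (`vaf = m / (purity * CN_t + 2 * (1 - purity))` for multiplicity 1).
#' Per-strand alt counts split Binomial(alt, 0.5). Half of the records are
#' emitted with a purine reference (reverse-complemented raw context) to
#' exercise the pyrimidine-centric channel folding downstream.
#'
#' @param signature_profiles 96 x k probability matrix (see
#'   [synthetic_signature_profiles()]).
#' @param signature_mix nonnegative weights over the profiles, summing to 1.
#' @param n_snvs number of SNVs.
#' @param tree a [clone_tree()].
#' @param segments CN segment table; SNVs are placed on truncal major=1/minor=0
#'   segments (constant CN 1 across tumor cells) by default, or on diploid
#'   segments via `snv_region = "cn2"`.
#' @param seed RNG seed.
#' @param coverage mean depth.
#' @param purity truncal cellularity.
#' @param clone_weights sampling weights over the clones (default equal).
#' @param snv_region `"cn1"` or `"cn2"`.
#' @return SNV table with truth columns `clone_id`, `channel`, `true_ccf`.
#' @export
simulate_snv_catalog <- function(signature_profiles, signature_mix, n_snvs,
                                 tree, segments, seed = 1L, coverage = 160,
                                 purity = max(tree$cellularity),
                                 clone_weights = NULL,
                                 snv_region = c("cn1", "cn2")) {
  snv_region <- match.arg(snv_region)
  if (abs(sum(signature_mix) - 1) > 1e-9 || any(signature_mix < 0)) {
    stop_config("signature_mix must be nonnegative and sum to 1 (within 1e-9)")
  }
  channels <- trinucleotide_channels()
  stopifnot(nrow(signature_profiles) == 96L,
            ncol(signature_profiles) == length(signature_mix))
  if (n_snvs == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), depth = integer(), alt_depth = integer(),
                      alt_fwd = integer(), alt_rev = integer(), context = character(),
                      clone_id = character(), local_total_cn = integer(),
                      vaf = numeric(), channel = character(), true_ccf = numeric(),
                      stringsAsFactors = FALSE))
  }
  host <- if (snv_region == "cn1") {
    segments[segments$clone_id == "truncal" & segments$major_cn == 1 &
               segments$minor_cn == 0, , drop = FALSE]
  } else {
    segments[segments$clone_id == "normal", , drop = FALSE]
  }
  if (nrow(host) == 0L) stop_config("no compatible host segments for SNVs")
  cn_t <- if (snv_region == "cn1") 1L else 2L
  mix_prob <- as.numeric(signature_profiles %*% signature_mix)
  with_seed(seed, {
    ch_idx <- sample.int(96L, n_snvs, replace = TRUE, prob = mix_prob)
    wt <- clone_weights %||% rep(1, nrow(tree))
    cl_idx <- sample.int(nrow(tree), n_snvs, replace = TRUE, prob = wt)
    m <- tree$cellularity[cl_idx]
    denom <- purity * cn_t + 2 * (1 - purity)
    vaf_exp <- m / denom
    seg_idx <- sample.int(nrow(host), n_snvs, replace = TRUE)
    pos <- as.integer(floor(stats::runif(n_snvs, host$start[seg_idx] + 1,
                                         host$end[seg_idx])))
    depth <- pmax(1L, stats::rpois(n_snvs, coverage * denom / 2))
    alt <- stats::rbinom(n_snvs, depth, vaf_exp)
    fwd <- stats::rbinom(n_snvs, alt, 0.5)
    ch <- channels[ch_idx]
    parsed <- parse_channel(ch)
    flip <- stats::runif(n_snvs) < 0.5
    ref <- ifelse(flip, revcomp(parsed$ref), parsed$ref)
    altb <- ifelse(flip, revcomp(parsed$alt), parsed$alt)
    ctx <- ifelse(flip, revcomp(parsed$context), parsed$context)
    data.frame(chrom = host$chrom[seg_idx], pos = pos, ref = ref, alt = altb,
               depth = depth, alt_depth = alt, alt_fwd = fwd, alt_rev = alt - fwd,
               context = ctx, clone_id = tree$clone_id[cl_idx],
               local_total_cn = cn_t, vaf = alt / depth, channel = ch,
               true_ccf = m, stringsAsFactors = FALSE)
  })
}

#' Simulate a full synthetic tumor sample
#'
#' Orchestrates the SNP-depth, read-pair and SNV generators under one
#' configuration and bundles the ground truth. Per-segment minor-allele log R
#' ratios are computed from the simulated depths (truth phasing), so the
#' segment table carries realistic sampling noise.
#'
#' @param config a [sim_config()].
#' @return A `synthetic_sample` list: `snp_observations`, `segments`
#'   (with `lrr_minor`, `n_snps`), `read_pairs`, `panel_pairs` truth panel
#'   junction table, `snv_candidates`, and `truth`.
#' @export
simulate_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- config$clone_tree
  segs <- config$segments
  snp_parts <- vector("list", nrow(segs))
  lrr <- numeric(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    obs <- simulate_het_snp_depths(segs[i, ], tree, config$coverage,
                                   config$n_snps_per_segment,
                                   seed = sub_seed(config$seed, i),
                                   sample_id = config$sample_id)
    minor_reads <- ifelse(obs$phased_minor == "alt", obs$tumor_alt, obs$tumor_ref)
    lrr[i] <- log2(pmax(mean(minor_reads), 0.25) / (config$coverage / 2))
    snp_parts[[i]] <- obs
  }
  segs$lrr_minor <- lrr
  segs$n_snps <- config$n_snps_per_segment
  snps <- do.call(rbind, snp_parts)

  # artifact junctions appear in the tumor reads too
  sv_all <- rbind(config$sv_truth, config$panel_junctions)
  pairs <- simulate_discordant_pairs(
    sv_all, config$insert_mean, config$insert_sd, config$n_background,
    seed = sub_seed(config$seed, 1000L), genome = config$genome,
    noise_per_bp = config$noise_per_bp, junk_frac = config$junk_frac,
    sample_id = config$sample_id)

  snvs <- simulate_snv_catalog(
    synthetic_signature_profiles()[, names(config$signature_mix), drop = FALSE],
    config$signature_mix, config$n_snvs, tree, segs,
    seed = sub_seed(config$seed, 2000L), coverage = config$coverage,
    purity = config$purity)

  structure(list(
    sample_id = config$sample_id,
    snp_observations = snps, segments = segs, read_pairs = pairs,
    panel_junctions = config$panel_junctions, snv_candidates = snvs,
    truth = list(clone_tree = tree, purity = config$purity,
                 sv_truth = config$sv_truth,
                 exposures = config$signature_mix),
    config = config), class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat("Synthetic tumor sample", x$sample_id, "\n")
  cat("  clones:   ", paste0(x$truth$clone_tree$clone_id, "=",
                             x$truth$clone_tree$cellularity, collapse = ", "), "\n")
  cat("  SNPs:     ", nrow(x$snp_observations), "over", nrow(x$segments), "segments\n")
  cat("  pairs:    ", nrow(x$read_pairs), "(incl. background/noise)\n")
  cat("  truth SVs:", nrow(x$truth$sv_truth), "  SNVs:", nrow(x$snv_candidates), "\n")
  invisible(x)
}

#' Write / read a synthetic sample directory
#'
#' Serializes a sample to the tabular interchange formats (SNP TSV, BEDPE,
#' SNV TSV, segment TSV, truth JSON). `read_sample()` round-trips the files
#' back into an equivalent bundle.
#'
#' @param sample a `synthetic_sample`.
#' @param dir output directory (created if needed).
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_snp_tsv(sample$snp_observations, file.path(dir, "snps.tsv"))
  write_tsv_dot(sample$snp_observations, file.path(dir, "snps_phased.tsv"))
  write_pairs_bedpe(sample$read_pairs, file.path(dir, "pairs.bedpe"))
  write_segments_tsv(sample$segments, file.path(dir, "segments.tsv"))
  write_snv_tsv(sample$snv_candidates, file.path(dir, "snvs.tsv"))
  panel <- panel_junctions_to_calls(sample$panel_junctions, sample$sample_id)
  write_sv_bedpe(panel, file.path(dir, "panel.bedpe"))
  truth <- list(sample_id = sample$sample_id,
                purity = sample$truth$purity,
                clone_tree = as.data.frame(sample$truth$clone_tree),
                truncal_id = attr(sample$truth$clone_tree, "truncal_id"),
                sv_truth = sample$truth$sv_truth,
                exposures = as.list(sample$truth$exposures))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_sample
#' @export
read_sample <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  tree <- clone_tree(truth$clone_tree$clone_id, truth$clone_tree$cellularity,
                     truth$clone_tree$parent_id)
  structure(list(
    sample_id = truth$sample_id,
    snp_observations = read_tsv_dot(file.path(dir, "snps_phased.tsv")),
    segments = read_segments_tsv(file.path(dir, "segments.tsv")),
    read_pairs = read_pairs_bedpe(file.path(dir, "pairs.bedpe")),
    panel_junctions = NULL,
    panel_calls = read_sv_bedpe(file.path(dir, "panel.bedpe")),
    snv_candidates = read_snv_tsv(file.path(dir, "snvs.tsv")),
    truth = list(clone_tree = tree, purity = truth$purity,
                 sv_truth = truth$sv_truth,
                 exposures = unlist(truth$exposures))),
    class = "synthetic_sample")
}

#' Random intrachromosomal SV truth set with trimodal breakpoint distances
#'
#' Draws junction distances from a three-component log-normal mixture (modes
#' near 5 kbp, 300 kbp and 10 Mbp, mirroring the trimodal breakpoint-distance
#' distribution of HR-deficient breast tumors); the short modes are emitted
#' mostly as tandem duplications and deletions, the long mode mostly as
#' inverted rearrangements.
#'
#' @param n_svs junctions to draw.
#' @param seed RNG seed.
#' @param genome chromosome table.
#' @param modes mixture mode distances (bp).
#' @param weights mixture weights.
#' @param sd_log10 within-mode spread (log10 units).
#' @return sv_truth data frame for [simulate_discordant_pairs()].
#' @export
simulate_trimodal_sv_truth <- function(n_svs = 30L, seed = 1L,
                                       genome = default_genome(),
                                       modes = c(5e3, 3e5, 1e7),
                                       weights = c(1, 1, 1) / 3,
                                       sd_log10 = 0.15) {
  with_seed(seed, {
    comp <- sample.int(3L, n_svs, replace = TRUE, prob = weights)
    dist <- round(10^(stats::rnorm(n_svs, log10(modes)[comp], sd_log10)))
    type <- ifelse(comp == 3L,
                   sample(c("inverted_rearrangement", "tandem_duplication"),
                          n_svs, replace = TRUE, prob = c(0.8, 0.2)),
                   sample(c("tandem_duplication", "deletion"),
                          n_svs, replace = TRUE, prob = c(0.7, 0.3)))
    ci <- sample(nrow(genome), n_svs, replace = TRUE)
    bp1 <- vapply(seq_len(n_svs), function(i) {
      floor(stats::runif(1, 1e5, genome$length[ci[i]] - dist[i] - 1e5))
    }, numeric(1))
    data.frame(sv_type = type, chrom1 = genome$chrom[ci], bp1 = bp1,
               chrom2 = genome$chrom[ci], bp2 = bp1 + dist,
               n_support = sample(6:20, n_svs, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

# Represent truth/panel junction tables in SV-call form (for panel BEDPE and
# truth matching).
panel_junctions_to_calls <- function(junctions, sample_id = NA_character_) {
  if (nrow(junctions) == 0L) {
    return(empty_sv_calls())
  }
  out <- data.frame(
    chrom1 = junctions$chrom1, bp1 = as.numeric(junctions$bp1), strand1 = "*",
    chrom2 = junctions$chrom2, bp2 = as.numeric(junctions$bp2), strand2 = "*",
    sv_type = junctions$sv_type, n_support = junctions$n_support,
    somatic = NA, sample_id = sample_id, stringsAsFactors = FALSE)
  out$distance <- ifelse(out$chrom1 == out$chrom2, abs(out$bp2 - out$bp1), NA_real_)
  class(out) <- c("sv_calls", "data.frame")
  out
}
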