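---
title: "Models and methods in clonesv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in clonesv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonesv)
```

clonesv bundles the computational core of a tumor whole-genome analysis:
a paired-cluster structural-variant (SV) caller, two complementary routes to
the tumor's clonal architecture, a copy-number model for interhomolog
inverted rearrangements, trinucleotide-spectrum/signature-exposure
summaries, and the cohort statistics used to relate these to homologous
recombination (HR) status. This vignette describes each model, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The paired-cluster SV caller

Evidence is a table of discordant read pairs (0-based leftmost positions,
strands, pair mapping quality, mismatch count). Pre-filters keep pairs with
mapping quality **strictly greater than 37** and **at most two mismatches**;
a surviving pair is discordant if it is interchromosomal, spans more than
the proper-insert bound, or has non-FR orientation. The insert bound
defaults to `insert_mean + 4 * insert_sd` (550 bp under the generator's
350 ± 50 bp insert model); the underlying study does not state its bound, so
it is exposed as a parameter.

Read ends are grouped per (chromosome, strand) by single linkage: sorted
positions are chained while successive gaps are at most **400 bp**. Ends on
the forward strand form forward clusters, reverse ends reverse clusters.
Candidate junctions are pairs of clusters linked by at least one read pair;
each read pair supports exactly one junction. Junctions with at least
**six** supporting pairs become calls.

Two conventions had to be fixed where the procedure is under-specified:

* **Orientation.** On the canonically ordered ends, `(+,-)` is a deletion,
  `(-,+)` a tandem duplication, `(+,+)` or `(-,-)` an inverted
  rearrangement, and any interchromosomal junction a translocation. This is
  the standard Illumina paired-end convention and is used symmetrically by
  the simulator. It implies that inverted rearrangements pair two clusters
  of the *same* side — forward with forward, reverse with reverse — so
  cluster pairing is implemented over all side combinations. A read pair
  whose two ends chain into one and the same cluster (a junction shorter
  than the clustering gap) is dropped with a warning.
* **Breakpoint position.** The innermost cluster edge: the maximum member
  position for a forward cluster, the minimum for a reverse cluster. With
  no split-read refinement this is accurate to roughly one insert length,
  which is why truth matching in the tests uses a ±400 bp tolerance.

Panel-of-normals subtraction removes a call when any panel junction matches
**both** breakpoints within 1 kbp on the same chromosomes; the tolerance is
a parameter, since the study states only that panel junctions were removed.
No minimum cluster width or maximum cluster size is enforced.

Summaries report per-type counts, the tandem-duplication proportion,
breakpoint distances of intrachromosomal calls (interchromosomal calls have
no distance and are excluded), and a Gaussian-kernel 2-D density over
(log10 support, log10 distance) via `MASS::kde2d`; `distance_modes()`
extracts modes of the 1-D log-distance density for multimodality checks.

## Clonal architecture

**Copy-number route.** In a genomic segment where the tumor genotype is one
major copy and zero minor copies, carried by a fraction $c$ of all cells
(tumor and normal together), the minor allele's read fraction is

$$f = \frac{1 - c}{2 - c}, \qquad c = \frac{1 - 2f}{1 - f}.$$

This inversion is the unique algebra consistent with the mixture and needs
no purity input — which is exactly why such segments anchor the analysis.
The minor-allele log R ratio of a segment is
$\mathrm{lrr} = \log_2(\text{observed minor depth} / \text{haploid depth})$,
so on clean data $c = 1 - 2^{\mathrm{lrr}}$. The calibration therefore fits
ordinary least squares of the per-segment $c$ (from pooled minor fractions)
on the transformed predictor $x = 1 - 2^{\mathrm{lrr}}$: exact on noiseless
input, with the two coefficients absorbing depth-normalization offsets. A
plain line in lrr itself was rejected because the relation is visibly curved
over the relevant range (residuals up to 0.08 across $c \in [0.3, 0.9]$,
versus machine precision for the transformed fit).

Clones are then found by k-means on the minor-allele LRR of *all*
minor-CN-zero segments, SNP-count weighted. k is chosen by the silhouette
score over $k = 2..5$ subject to every cluster holding at least 5% of the
SNP-weighted mass, with two guards: a one-cluster fallback when no k
qualifies, and a minimum silhouette of 0.75 for accepting any multi-cluster
solution — k-means will happily split a single tight cluster, but such a
split's silhouette stays moderate while genuinely separated clones (which
is what "a few subclones of detectable size" look like at 160× coverage)
score near 1. Cluster centers map to cellularities through the calibration;
**clonality** is $100 \cdot c_i / c_{\text{truncal}}$ with the truncal
(largest) clone at 100% by definition, rounded to whole percent in reports.
The worked two-clone case — cellularities 0.89 and 0.42 — gives clonalities
100 and 47.

The minor allele at each SNP is taken as the lower-depth tumor allele,
pooled per segment (per-SNP phasing is out of scope); heterozygous sites are
admitted when the normal alt fraction lies in [0.3, 0.7]. Calibration is per
sample, not pooled across a cohort.

**VAF route.** Within low-CN regions (total CN 1 or 2, where mutation
multiplicity is forced to 1), SNVs are clustered by a k-component binomial
mixture over (alt reads, depth): component $k$ has success probability
$\theta_k = m_k \cdot \mathrm{mult} / (p\,\mathrm{CN} + 2(1-p))$ with $m_k$
the cellular fraction and $p$ the purity. This is a deliberately simple
stand-in for Dirichlet-process clonal clustering: EM with 10 restarts
(quantile-of-VAFa initialization, jittered after the first), absolute
log-likelihood tolerance 1e-8, at most 1000 iterations, and BIC selection
over $k = 1..5$ ($2k - 1$ free parameters). The observed-data log-likelihood
is non-decreasing by construction and asserted in tests. Components closer
than $10^{-3}$ in cellular fraction are merged. `compute_vafa()` exposes the
same rescaling for single variants — including promoter-methylation read
counts treated as variants with multiplicity 1 (whether one or both alleles
are methylated is not identifiable here; the multiplicity is a switch).

## The interhomolog inverted rearrangement

The model event: the centromere-distal part of one arm of haplotype A,
beyond a breakpoint, is replaced by an *inverted* copy of the
centromere-distal part of the **opposite** arm of haplotype B. Replacing
distal segments on opposite arms is the only variant that leaves exactly one
centromere on every derivative — same-arm breakpoints would delete or
duplicate a centromere and are rejected as invalid. The consequences, all
asserted in tests:

* copy number 1 from the lost terminus to the breakpoint, 3 from the gained
  breakpoint to the opposite terminus, 2 elsewhere (a zero-length loss gives
  a pure gain);
* total copies obey mass balance ($2L - \text{lost} + \text{gained}$);
* the junction, expressed as read pairs, is an intrachromosomal inverted
  rearrangement whose breakpoints flank the centromere: `(-,-)` when the
  p-terminal segment is lost, `(+,+)` when the q-terminal one is (derived
  from walking the derivative sequence; the study does not print the strand
  configuration, so the simulator and caller simply share this convention).

Which haplotype receives is a parameter; coordinates are segment-resolution
with breakpoints splitting segments on the fly. Breakage-fusion-bridge,
chromothripsis and replication-based mechanisms are out of scope.

## Spectra and exposures

Somatic filters: WES mode drops candidates with depth < 20 or VAF < 0.10;
WGS mode drops VAF < 0.05; both require at least one alternate read on each
strand and absence from the population and panel sets; each failing record
carries its first failing rule (depth, vaf, strand, population, panel — in
that order). The filter is idempotent on its own pass list.

Spectra use the conventional 96-channel pyrimidine-centric layout
(substitution-major, context-lexicographic); purine-reference records are
reverse-complemented on the fly, invalid contexts are tallied and skipped,
and channel counts conserve the input count. Exposures are fitted by
nonnegative least squares (`pracma::lsqnonneg`) of the normalized spectrum
on fixed profile columns, renormalized to sum to one; de novo signature
extraction is explicitly out of scope.

The three shipped profiles (`synthetic_signature_profiles()`, also under
`inst/extdata/`) are synthetic stand-ins, not estimates of any published
signature: an age-like profile concentrated on N[C>T]G (CpG deamination), an
APOBEC-like profile on T[C>T]W / T[C>G]W, and a broad BRCA-like profile with
geometrically decaying channel weights (ratio 0.88, interleaved across
classes). The decay rate was set from a sampling-error analysis: recovery
tests compare an empirical spectrum of n = 10,000 draws to its generating
profile in total variation, and a near-uniform 96-channel profile has
expected TV ≈ 0.039 at that n, while this profile's is ≈ 0.022 — broad
enough to look signature-like, concentrated enough that the multinomial
noise bound used in validation is meaningful.

## Cohort statistics

HR status is *defective* on any disruptive BRCA1/RAD51C mutation or any
available promoter methylation β strictly above 0.2, *intact* when all
available evidence is negative, *unknown* with no evidence; low expression
is reported as corroboration but never flips the status, matching the
operational definition used with methylation arrays. Fisher's exact test
uses the probability-mass two-sided convention (the sum of same-margin
tables with probability not exceeding the observed — the same convention as
`stats::fisher.test`, against which and against exhaustive enumeration it is
verified), with the sample odds ratio $ad/bc$. The Wilcoxon rank-sum test
uses the exact permutation distribution when both samples have at most 20
observations and no ties, otherwise a tie-corrected normal approximation
without continuity correction (so the two paths agree to < 0.01 on tie-free
data); the method used is always reported. Raw p-values only — no multiplicity
correction is applied. The cohort report orders samples by descending
BRCA-like exposure and, when both HR groups have two or more complete
samples, compares SV counts, tandem-duplication counts and log10 median
distances between groups.

## The synthetic-data generator

The generator is the package's ground truth and encodes the study
conditions as defaults: a truncal clone at 89% cellularity with one nested
subclone at 42% (the worked tumor), 160× mean coverage, 24 segments of
1.5 Mbp (12 truncal and 6 subclonal major=1/minor=0, 6 diploid) with 500
heterozygous SNPs each, ten somatic junctions spanning all four SV classes
with 6–15 supporting pairs, a two-junction artifact panel also present in
the tumor reads, 300 SNVs from a 0.6/0.3/0.1 three-signature mixture placed
in truncal CN-1 regions, and a 3 × 50 Mbp genome with centromeres at 25 Mbp
— small enough that the full pipeline runs in seconds. Depths are Poisson
around the CN-scaled mean (the study reports only mean coverage; an
overdispersion knob is deliberately absent — Poisson is the default model
and segments pool hundreds of SNPs, so modest overdispersion would not move
the pooled fractions). Allele and strand splits are Binomial. Discordant
noise defaults to 1 pair per 100 kbp, uniformly placed — at that density a
spurious six-pair cluster is vanishingly rare on the 150 Mbp genome, which
the background-only test verifies. A separate generator draws junction
distances from a three-mode log-normal mixture (5 kbp, 300 kbp, 10 Mbp;
0.15 log10 within-mode SD) to emulate the trimodal breakpoint-distance
structure. All streams are seeded, with per-record sub-seeds derived from
(seed, index), so identical configurations reproduce byte-identical files.

What it does **not** emulate — and hence what green tests do not show about
real data: no read sequences or alignment (evidence enters at the record
level, so mapping artifacts beyond the simulated junk fraction are absent),
no GC or mappability bias in depth, no subclonal copy-number nesting beyond
one level, no kataegis or clustered mutational processes, and SNVs are
placed only in regions where multiplicity is unambiguous. Real-data
complications such as overlapping clones in LRR space, heavy depth
overdispersion, or signatures outside the provided dictionary will degrade
the inferences in ways these tests cannot detect.

## Problem sizes and numerical choices

Validation uses 20 replicate two-clone simulations (400 SNPs/segment, 300
SNVs) for clonal recovery, 20 catalogs of 10,000 SNVs for exposure
recovery, six 30-junction samples for distance-mode recovery, and every
2×2 table with total at most 25 for the Fisher oracle — sizes chosen so
the whole suite completes in a few minutes on one core while keeping
sampling error well inside the asserted tolerances. Degenerate inputs are
handled explicitly: empty pair tables and empty call sets flow through the
caller; a single qualifying segment makes calibration error rather than
extrapolate; a single SNV yields a one-component fit equal to its adjusted
frequency; identical cluster centers and near-identical mixture components
are merged; all-zero spectra are an error. Probabilities inside the EM are
clamped to $[10^{-9}, 1 - 10^{-9}]$; k-means uses 10 random starts under a
fixed seed.
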