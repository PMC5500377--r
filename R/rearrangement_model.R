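#' A pair of homologous chromosomes at segment resolution
#'
#' Both haplotypes (A and B) carry one copy of every segment delimited by
#' `boundaries`; the centromere sits at a single coordinate strictly inside
#' the chromosome.
#'
#' @param chrom chromosome label.
#' @param length chromosome length (bp).
#' @param centromere centromere coordinate (bp), in `(0, length)`.
#' @param boundaries optional additional segment boundaries.
#' @return object of class `homolog_pair`.
#' @export
homolog_pair <- function(chrom, length, centromere, boundaries = numeric(0)) {
  if (centromere <= 0 || centromere >= length) {
    stop_config("centromere must lie strictly inside the chromosome")
  }
  b <- sort(unique(c(0, length, centromere, boundaries)))
  if (any(b < 0 | b > length)) stop_config("boundaries outside chromosome")
  structure(list(chrom = chrom, length = length, centromere = centromere,
                 boundaries = b),
            class = "homolog_pair")
}

#' @export
print.homolog_pair <- function(x, ...) {
  cat("Homolog pair", x$chrom, "length", x$length,
      "centromere", x$centromere, "\n")
  cat(" ", length(x$boundaries) - 1, "segments\n")
  invisible(x)
}

#' Interhomolog inverted-rearrangement event
#'
#' The terminal (centromere-distal) segment of one arm of the recipient
#' haplotype, beyond `bp_lost`, is replaced by an inverted copy of the
#' terminal segment of the *opposite* arm of the donor haplotype, beyond
#' `bp_gained`. Because the exchanged segments are centromere-distal on
#' opposite arms, every derivative keeps exactly one centromere.
#'
#' @param bp_lost breakpoint on the recipient haplotype.
#' @param bp_gained breakpoint on the donor haplotype, on the opposite arm.
#' @param recipient which haplotype receives (`"A"` default).
#' @export
interhomolog_inversion <- function(bp_lost, bp_gained, recipient = "A") {
  structure(list(bp_lost = bp_lost, bp_gained = bp_gained,
                 recipient = recipient,
                 donor = setdiff(c("A", "B"), recipient)),
            class = "interhomolog_inversion")
}

arm_of <- function(pair, pos) if (pos < pair$centromere) "p" else "q"

#' Apply an interhomolog inverted rearrangement
#'
#' @param pair a [homolog_pair()].
#' @param event an [interhomolog_inversion()].
#' @return a `derivative_set`: list of derivative chromosomes, each a data
#'   frame of pieces `(hap, start, end, strand)` in derivative order, plus
#'   the junction description.
#' @export
apply_interhomolog_inversion <- function(pair, event) {
  l <- event$bp_lost; g <- event$bp_gained
  if (l < 0 || l > pair$length || g < 0 || g > pair$length) {
    stop_config("event breakpoints outside the chromosome")
  }
  arm_l <- arm_of(pair, l); arm_g <- arm_of(pair, g)
  # a breakpoint exactly at a terminus is a degenerate zero-length loss and
  # belongs to whichever arm makes the event valid
  if (l == 0) arm_l <- "p"
  if (l == pair$length) arm_l <- "q"
  if (arm_l == arm_g) {
    stop(errorCondition(
      "invalid event: breakpoints on the same arm would duplicate or delete the centromere",
      class = c("clonesv_invalid_event", "error")))
  }
  rec <- event$recipient; don <- event$donor
  piece <- function(hap, start, end, strand) {
    if (end <= start) return(NULL)
    data.frame(hap = hap, start = start, end = end, strand = strand,
               stringsAsFactors = FALSE)
  }
  if (arm_l == "p") {
    # recipient loses [0, l); gains inverted donor [g, length)
    deriv_rec <- rbind(piece(don, g, pair$length, "-"),
                       piece(rec, l, pair$length, "+"))
    junction <- list(chrom = pair$chrom, bp1 = l, bp2 = g,
                     strand1 = "-", strand2 = "-")
  } else {
    # recipient loses [l, length); gains inverted donor [0, g)
    deriv_rec <- rbind(piece(rec, 0, l, "+"),
                       piece(don, 0, g, "-"))
    junction <- list(chrom = pair$chrom, bp1 = g, bp2 = l,
                     strand1 = "+", strand2 = "+")
  }
  deriv_don <- piece(don, 0, pair$length, "+")
  # canonical order of junction breakpoints
  if (junction$bp1 > junction$bp2) {
    junction[c("bp1", "bp2")] <- junction[c("bp2", "bp1")]
    junction[c("strand1", "strand2")] <- junction[c("strand2", "strand1")]
  }
  derivs <- stats::setNames(list(deriv_rec, deriv_don), c(rec, don))
  structure(list(pair = pair, event = event, derivatives = derivs,
                 junction = junction),
            class = "derivative_set")
}

#' Count centromeres on each derivative chromosome
#'
#' @param dset a `derivative_set`.
#' @return integer vector, one count per derivative.
#' @export
count_centromeres <- function(dset) {
  cen <- dset$pair$centromere
  vapply(dset$derivatives, function(d) {
    sum(d$start < cen & cen <= d$end)
  }, integer(1))
}

#' @export
print.derivative_set <- function(x, ...) {
  cat("Derivative chromosomes after interhomolog inverted rearrangement\n")
  cat(sprintf("  lost beyond %g (recipient %s), gained beyond %g (donor %s)\n",
              x$event$bp_lost, x$event$recipient, x$event$bp_gained, x$event$donor))
  cat(sprintf("  junction: %s:%g(%s) -- %s:%g(%s), crosses centromere: %s\n",
              x$junction$chrom, x$junction$bp1, x$junction$strand1,
              x$junction$chrom, x$junction$bp2, x$junction$strand2,
              x$junction$bp1 < x$pair$centromere && x$junction$bp2 >= x$pair$centromere))
  cat("  centromeres per derivative:",
      paste(count_centromeres(x), collapse = ", "), "\n")
  invisible(x)
}

#' Copy-number profile implied by a derivative set
#'
#' Walks every derivative's piece list and counts, for each elementary
#' interval of the reference chromosome, how many copies exist across all
#' derivatives.
#'
#' @param dset a `derivative_set` (or a plain list of piece data frames).
#' @param boundaries optional extra interval boundaries to report at.
#' @return BED-like data frame `(chrom, start, end, cn)`.
#' @export
cn_profile <- function(dset, boundaries = NULL) {
  pair <- dset$pair
  derivs <- dset$derivatives
  b <- sort(unique(c(pair$boundaries, boundaries,
                     dset$event$bp_lost, dset$event$bp_gained)))
  starts <- b[-length(b)]; ends <- b[-1]
  cn <- integer(length(starts))
  for (d in derivs) {
    for (j in seq_len(nrow(d))) {
      cn <- cn + as.integer(starts >= d$start[j] & ends <= d$end[j])
    }
  }
  data.frame(chrom = pair$chrom, start = starts, end = ends, cn = cn,
             stringsAsFactors = FALSE)
}

#' Simulate read pairs supporting the derivative junction
#'
#' Emits discordant pairs with the orientation implied by the derivative
#' structure (`(-,-)` when the recipient loses its p-terminal arm segment,
#' `(+,+)` when it loses the q-terminal one), jittered within the insert
#' range, for piping into the SV caller.
#'
#' @param dset a `derivative_set`.
#' @param n_support number of supporting pairs.
#' @param insert_mean insert size (bp).
#' @param seed RNG seed.
#' @param sample_id sample label.
#' @export
junction_read_pairs <- function(dset, n_support = 10L, insert_mean = 350,
                                seed = 1L, sample_id = "S1") {
  if (min(abs(dset$junction$bp2 - dset$junction$bp1)) <= 2 * insert_mean) {
    stop_config("junction span too small relative to the insert size")
  }
  j <- dset$junction
  sv <- data.frame(sv_type = "inverted_rearrangement", chrom1 = j$chrom,
                   bp1 = j$bp1, chrom2 = j$chrom, bp2 = j$bp2,
                   n_support = n_support, stringsAsFactors = FALSE)
  with_seed(seed, {
    df <- junction_support_pairs(sv, insert_mean,
                                 inv_strand = j$strand1)
    read_pair_records(df$chrom1, df$pos1, df$strand1, df$chrom2, df$pos2,
                      df$strand2, df$mapq, df$mismatches, sample_id)
  })
}
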