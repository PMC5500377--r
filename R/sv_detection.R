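#' Construct canonically ordered read-pair records
#'
#' Discordant paired-end evidence: each record carries the two aligned ends
#' (0-based leftmost positions, strands), the pair's mapping quality and
#' mismatch count. Ends are swapped where needed so that
#' `(chrom1, pos1) <= (chrom2, pos2)` lexicographically.
#'
#' @param chrom1,pos1,strand1,chrom2,pos2,strand2 per-end coordinates.
#' @param mapq Phred-scaled mapping quality (pair minimum).
#' @param mismatches mismatch count (pair maximum).
#' @param sample_id sample label.
#' @return data frame of class `read_pairs`.
#' @export
read_pair_records <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                              mapq, mismatches, sample_id = NA_character_) {
  df <- data.frame(chrom1 = as.character(chrom1), pos1 = as.integer(pos1),
                   strand1 = as.character(strand1),
                   chrom2 = as.character(chrom2), pos2 = as.integer(pos2),
                   strand2 = as.character(strand2),
                   mapq = as.integer(mapq), mismatches = as.integer(mismatches),
                   sample_id = rep(as.character(sample_id),
                                   length.out = length(chrom1)),
                   stringsAsFactors = FALSE)
  if (any(df$mapq < 0) || any(df$mismatches < 0)) {
    stop_config("mapq and mismatches must be nonnegative")
  }
  swap <- df$chrom2 < df$chrom1 | (df$chrom1 == df$chrom2 & df$pos2 < df$pos1)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "pos1", "strand1")]
    df[swap, c("chrom1", "pos1", "strand1")] <- df[swap, c("chrom2", "pos2", "strand2")]
    df[swap, c("chrom2", "pos2", "strand2")] <- tmp
  }
  class(df) <- c("read_pairs", "data.frame")
  df
}

empty_sv_calls <- function() {
  out <- data.frame(chrom1 = character(), bp1 = numeric(), strand1 = character(),
                    chrom2 = character(), bp2 = numeric(), strand2 = character(),
                    sv_type = character(), n_support = integer(),
                    somatic = logical(), sample_id = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("sv_calls", "data.frame")
  out
}

#' Select discordant read pairs
#'
#' Pre-filters: mapping quality strictly greater than 37 and at most two
#' mismatches. A surviving pair is discordant when its orientation is not the
#' proper forward-reverse configuration, or its ends are farther apart than
#' `insert_max`, or its ends map to different chromosomes. Order-stable.
#'
#' @param pairs `read_pairs` data frame.
#' @param insert_max maximum proper-pair span (bp); the simulator default
#'   corresponds to `insert_mean + 4 * insert_sd`.
#' @param min_mapq pairs must exceed this mapping quality (strict).
#' @param max_mismatches maximum mismatch count (inclusive).
#' @return the discordant subset, same class, original order.
#' @export
select_discordant_pairs <- function(pairs, insert_max = 550,
                                    min_mapq = 37L, max_mismatches = 2L) {
  if (insert_max <= 0) stop_config("insert_max must be positive")
  if (nrow(pairs) == 0L) return(pairs)
  quality <- pairs$mapq > min_mapq & pairs$mismatches <= max_mismatches
  proper <- pairs$chrom1 == pairs$chrom2 &
    pairs$strand1 == "+" & pairs$strand2 == "-" &
    abs(pairs$pos2 - pairs$pos1) <= insert_max
  pairs[quality & !proper, , drop = FALSE]
}

#' Cluster read ends along the genome
#'
#' Single-linkage grouping per (chromosome, strand): ends are sorted and
#' chained while successive positions differ by at most `gap` bp. Forward
#' clusters collect `+` ends, reverse clusters `-` ends. Every end of every
#' input pair lands in exactly one cluster.
#'
#' @param pairs `read_pairs` data frame.
#' @param gap maximum distance between successive member positions (bp).
#' @return list with `clusters` (cluster_id, side, chrom, start, end,
#'   n_members) and `ends` (pair_id, end (1 or 2), chrom, pos, strand,
#'   cluster_id).
#' @export
cluster_ends <- function(pairs, gap = 400) {
  if (gap <= 0) stop_config("gap must be positive")
  n <- nrow(pairs)
  if (n == 0L) {
    return(list(clusters = data.frame(cluster_id = integer(), side = character(),
                                      chrom = character(), start = integer(),
                                      end = integer(), n_members = integer(),
                                      stringsAsFactors = FALSE),
                ends = data.frame(pair_id = integer(), end = integer(),
                                  chrom = character(), pos = integer(),
                                  strand = character(), cluster_id = integer(),
                                  stringsAsFactors = FALSE)))
  }
  ends <- data.frame(
    pair_id = rep(seq_len(n), 2L), end = rep(1:2, each = n),
    chrom = c(pairs$chrom1, pairs$chrom2), pos = c(pairs$pos1, pairs$pos2),
    strand = c(pairs$strand1, pairs$strand2), stringsAsFactors = FALSE)
  o <- order(ends$chrom, ends$strand, ends$pos)
  ends <- ends[o, ]
  same_group <- ends$chrom[-1] == ends$chrom[-nrow(ends)] &
    ends$strand[-1] == ends$strand[-nrow(ends)] &
    (ends$pos[-1] - ends$pos[-nrow(ends)]) <= gap
  ends$cluster_id <- cumsum(c(1L, !same_group))
  cl <- do.call(rbind, lapply(split(ends, ends$cluster_id), function(g) {
    data.frame(cluster_id = g$cluster_id[1],
               side = if (g$strand[1] == "+") "forward" else "reverse",
               chrom = g$chrom[1], start = min(g$pos), end = max(g$pos),
               n_members = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(cl) <- NULL
  list(clusters = cl, ends = ends[order(ends$pair_id, ends$end), ])
}

#' Pair breakpoint clusters through their linking read pairs
#'
#' Groups read pairs by the (cluster of end 1, cluster of end 2) combination,
#' emitting one candidate junction per linked cluster pair. Forward-reverse
#' combinations carry deletion/tandem-duplication junctions; same-side
#' (forward-forward or reverse-reverse) combinations carry inverted
#' rearrangements. A read pair supports exactly one paired-cluster. A pair
#' whose two ends collapse into one and the same cluster indicates an
#' inconsistent junction (shorter than the clustering gap) and is dropped
#' with a warning.
#'
#' @param clustering result of [cluster_ends()].
#' @param pairs the `read_pairs` the clustering was built from.
#' @return data frame, one row per paired-cluster: member cluster ids, per-end
#'   chrom/strand, innermost-edge breakpoint estimates, `n_support`, and the
#'   supporting pair ids in a list column `support_ids`.
#' @export
pair_clusters <- function(clustering, pairs) {
  ends <- clustering$ends
  cl <- clustering$clusters
  if (nrow(ends) == 0L) {
    return(data.frame(cluster1 = integer(), cluster2 = integer(),
                      chrom1 = character(), bp1 = numeric(), strand1 = character(),
                      chrom2 = character(), bp2 = numeric(), strand2 = character(),
                      n_support = integer(), stringsAsFactors = FALSE))
  }
  c1 <- ends$cluster_id[ends$end == 1L][order(ends$pair_id[ends$end == 1L])]
  c2 <- ends$cluster_id[ends$end == 2L][order(ends$pair_id[ends$end == 2L])]
  self <- c1 == c2
  if (any(self)) {
    warning(sum(self), " pair(s) with both ends in the same cluster dropped ",
            "(junction shorter than the clustering gap)")
  }
  keep <- which(!self)
  if (length(keep) == 0L) {
    return(data.frame(cluster1 = integer(), cluster2 = integer(),
                      chrom1 = character(), bp1 = numeric(), strand1 = character(),
                      chrom2 = character(), bp2 = numeric(), strand2 = character(),
                      n_support = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(c1[keep], c2[keep])
  groups <- split(keep, key)
  row_of <- function(id) which(cl$cluster_id == id)
  out <- do.call(rbind, lapply(groups, function(ids) {
    a <- row_of(c1[ids[1]]); b <- row_of(c2[ids[1]])
    # innermost edge: max position for a forward cluster, min for reverse
    bp_a <- if (cl$side[a] == "forward") cl$end[a] else cl$start[a]
    bp_b <- if (cl$side[b] == "forward") cl$end[b] else cl$start[b]
    data.frame(cluster1 = cl$cluster_id[a], cluster2 = cl$cluster_id[b],
               chrom1 = cl$chrom[a], bp1 = bp_a,
               strand1 = if (cl$side[a] == "forward") "+" else "-",
               chrom2 = cl$chrom[b], bp2 = bp_b,
               strand2 = if (cl$side[b] == "forward") "+" else "-",
               n_support = length(ids), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$support_ids <- unname(groups)
  out
}

#' Classify a junction into the four SV types
#'
#' Interchromosomal junctions are translocations. Intrachromosomal junctions
#' are classified from the strand pair of the canonically ordered ends:
#' `(+,-)` deletion, `(-,+)` tandem duplication, `(+,+)` or `(-,-)` inverted
#' rearrangement. The mapping is total: every orientation receives a type.
#'
#' @param chrom1,chrom2 chromosomes of the ordered ends.
#' @param strand1,strand2 strands of the ordered ends.
#' @return character vector of SV types.
#' @export
classify_sv <- function(chrom1, chrom2, strand1, strand2) {
  n <- max(length(chrom1), length(chrom2), length(strand1), length(strand2))
  chrom1 <- rep_len(chrom1, n); chrom2 <- rep_len(chrom2, n)
  strand1 <- rep_len(strand1, n); strand2 <- rep_len(strand2, n)
  ifelse(chrom1 != chrom2, "translocation",
         ifelse(strand1 == "+" & strand2 == "-", "deletion",
                ifelse(strand1 == "-" & strand2 == "+", "tandem_duplication",
                       "inverted_rearrangement")))
}

#' Call structural variants from paired clusters
#'
#' Emits one call per paired-cluster supported by at least `min_support` read
#' pairs. Breakpoints are the innermost cluster edges; types follow
#' [classify_sv()]; ends are canonically ordered and the breakpoint distance
#' is reported for intrachromosomal calls.
#'
#' @param paired result of [pair_clusters()].
#' @param min_support minimum supporting pairs (default 6).
#' @param sample_id sample label.
#' @return `sv_calls` data frame.
#' @export
call_svs <- function(paired, min_support = 6L, sample_id = NA_character_) {
  keep <- paired[paired$n_support >= min_support, , drop = FALSE]
  if (nrow(keep) == 0L) return(empty_sv_calls())
  swap <- keep$chrom2 < keep$chrom1 |
    (keep$chrom1 == keep$chrom2 & keep$bp2 < keep$bp1)
  if (any(swap)) {
    tmp <- keep[swap, c("chrom1", "bp1", "strand1")]
    keep[swap, c("chrom1", "bp1", "strand1")] <- keep[swap, c("chrom2", "bp2", "strand2")]
    keep[swap, c("chrom2", "bp2", "strand2")] <- tmp
  }
  out <- data.frame(
    chrom1 = keep$chrom1, bp1 = as.numeric(keep$bp1), strand1 = keep$strand1,
    chrom2 = keep$chrom2, bp2 = as.numeric(keep$bp2), strand2 = keep$strand2,
    sv_type = classify_sv(keep$chrom1, keep$chrom2, keep$strand1, keep$strand2),
    n_support = keep$n_support, somatic = NA, sample_id = sample_id,
    stringsAsFactors = FALSE)
  out$distance <- ifelse(out$chrom1 == out$chrom2, abs(out$bp2 - out$bp1), NA_real_)
  out <- out[order(out$chrom1, out$bp1, out$chrom2, out$bp2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sv_calls", "data.frame")
  out
}

#' Run the full paired-cluster SV caller
#'
#' Convenience wrapper: pre-filter discordant pairs, cluster ends, pair
#' clusters, emit calls, and (optionally) subtract a panel of normals.
#'
#' @inheritParams select_discordant_pairs
#' @inheritParams cluster_ends
#' @inheritParams call_svs
#' @param panel optional `sv_calls`-like panel of artifact junctions.
#' @param panel_tol breakpoint matching tolerance for panel subtraction (bp).
#' @export
detect_svs <- function(pairs, insert_max = 550, gap = 400, min_support = 6L,
                       panel = NULL, panel_tol = 1000,
                       sample_id = pairs$sample_id[1] %||% NA_character_) {
  disc <- select_discordant_pairs(pairs, insert_max)
  paired <- pair_clusters(cluster_ends(disc, gap), disc)
  calls <- call_svs(paired, min_support, sample_id)
  if (!is.null(panel)) calls <- subtract_panel(calls, panel, panel_tol)
  else calls$somatic <- rep(TRUE, nrow(calls))
  calls
}

#' Subtract a panel of normals from SV calls
#'
#' A call is removed when a panel junction (of any type) has both breakpoints
#' within `tol` bp of the call's breakpoints on matching chromosomes.
#' Survivors are flagged somatic.
#'
#' @param calls `sv_calls`.
#' @param panel panel junction table with `chrom1, bp1, chrom2, bp2`.
#' @param tol matching tolerance (bp).
#' @export
subtract_panel <- function(calls, panel, tol = 1000) {
  if (nrow(calls) == 0L) return(calls)
  if (is.null(panel) || nrow(panel) == 0L) {
    calls$somatic <- rep(TRUE, nrow(calls))
    return(calls)
  }
  hit <- vapply(seq_len(nrow(calls)), function(i) {
    any(panel$chrom1 == calls$chrom1[i] & panel$chrom2 == calls$chrom2[i] &
          abs(panel$bp1 - calls$bp1[i]) <= tol &
          abs(panel$bp2 - calls$bp2[i]) <= tol)
  }, logical(1))
  out <- calls[!hit, , drop = FALSE]
  out$somatic <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Summarize a set of SV calls
#'
#' Counts per type, the proportion of tandem duplications, breakpoint
#' distances of intrachromosomal calls (raw and log10, with median), and a
#' Gaussian-kernel two-dimensional density grid over
#' (log10 supporting reads, log10 distance).
#'
#' @param calls `sv_calls`.
#' @param grid_n grid resolution per axis for the 2-D density.
#' @return object of class `sv_summary`.
#' @export
summarize_svs <- function(calls, grid_n = 50L) {
  types <- c("translocation", "inverted_rearrangement", "deletion",
             "tandem_duplication")
  counts <- vapply(types, function(t) sum(calls$sv_type == t), integer(1))
  total <- sum(counts)
  dist <- calls$distance[!is.na(calls$distance) & calls$distance > 0]
  sup <- calls$n_support[!is.na(calls$distance) & calls$distance > 0]
  med <- if (length(dist)) stats::median(dist) else NA_real_
  dens <- NULL
  if (length(dist) >= 8 && length(unique(sup)) > 1 && length(unique(dist)) > 1) {
    dens <- MASS::kde2d(log10(sup), log10(dist), n = grid_n,
                        lims = c(range(log10(sup)) + c(-0.3, 0.3),
                                 range(log10(dist)) + c(-0.5, 0.5)))
  }
  structure(list(counts = counts, total = total,
                 tandem_proportion = if (total) unname(counts["tandem_duplication"]) / total else NA_real_,
                 distances = dist, log10_distances = log10(dist),
                 median_distance = med,
                 median_log10_distance = if (length(dist)) stats::median(log10(dist)) else NA_real_,
                 density = dens, n_supports = sup),
            class = "sv_summary")
}

#' @export
print.sv_summary <- function(x, ...) {
  cat("SV summary:", x$total, "calls\n")
  print(x$counts)
  cat(sprintf("  tandem-duplication proportion: %.3f\n", x$tandem_proportion))
  if (!is.na(x$median_distance)) {
    cat(sprintf("  median breakpoint distance: %.0f bp (log10 = %.2f)\n",
                x$median_distance, log10(x$median_distance)))
  }
  invisible(x)
}

#' @export
summary.sv_calls <- function(object, ...) summarize_svs(object, ...)

#' @export
print.sv_calls <- function(x, ...) {
  cat("SV calls:", nrow(x), "junctions",
      if (isTRUE(all(x$somatic))) "(somatic)" else "", "\n")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Local maxima of the log10 breakpoint-distance density
#'
#' Kernel density estimate over pooled log10 distances; returns the modes in
#' decreasing prominence, for checking multimodal (e.g. trimodal) breakpoint
#' distance distributions.
#'
#' @param log10_distances numeric vector.
#' @param bw kernel bandwidth (log10 units).
#' @export
distance_modes <- function(log10_distances, bw = 0.25) {
  d <- stats::density(log10_distances, bw = bw)
  y <- d$y
  peak <- which(diff(sign(diff(y))) == -2) + 1L
  peak <- peak[order(y[peak], decreasing = TRUE)]
  d$x[peak]
}

#' Precision and recall of SV calls against a truth table
#'
#' Greedy one-to-one matching: a call matches a truth junction when the
#' chromosomes agree and both breakpoints are within `tol` bp.
#'
#' @param calls `sv_calls`.
#' @param truth truth table with `chrom1, bp1, chrom2, bp2`.
#' @param tol matching tolerance (bp).
#' @return list with `precision`, `recall`, `n_matched`.
#' @export
sv_precision_recall <- function(calls, truth, tol = 400) {
  used <- rep(FALSE, nrow(truth))
  matched <- 0L
  for (i in seq_len(nrow(calls))) {
    j <- which(!used & truth$chrom1 == calls$chrom1[i] &
                 truth$chrom2 == calls$chrom2[i] &
                 abs(truth$bp1 - calls$bp1[i]) <= tol &
                 abs(truth$bp2 - calls$bp2[i]) <= tol)
    if (length(j)) { used[j[1]] <- TRUE; matched <- matched + 1L }
  }
  list(precision = if (nrow(calls)) matched / nrow(calls) else NA_real_,
       recall = if (nrow(truth)) matched / nrow(truth) else NA_real_,
       n_matched = matched)
}
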