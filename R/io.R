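#' File readers and writers for the tabular interchange formats
#'
#' All tables are tab-delimited UTF-8 with a header row and `.` for missing
#' values. Read-pair and junction tables use BEDPE conventions (0-based,
#' half-open intervals); SNP and SNV tables use 1-based positions.
#'
#' @param x data frame to write.
#' @param path file path.
#' @name clonesv-io
NULL

write_tsv_dot <- function(x, path) {
  y <- x
  for (j in seq_along(y)) {
    v <- y[[j]]
    if (is.logical(v)) v <- ifelse(is.na(v), NA, ifelse(v, "TRUE", "FALSE"))
    y[[j]] <- v
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_dot <- function(path, ...) {
  utils::read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE, ...)
}

#' @rdname clonesv-io
#' @export
write_snp_tsv <- function(x, path) {
  cols <- c("sample", "chrom", "pos", "normal_ref", "normal_alt",
            "tumor_ref", "tumor_alt")
  write_tsv_dot(x[, cols], path)
}

#' @rdname clonesv-io
#' @export
read_snp_tsv <- function(path) read_tsv_dot(path)

#' @rdname clonesv-io
#' @export
write_snv_tsv <- function(x, path) {
  cols <- c("chrom", "pos", "ref", "alt", "depth", "alt_depth",
            "alt_fwd", "alt_rev", "context")
  extra <- setdiff(names(x), cols)
  write_tsv_dot(x[, c(cols, extra)], path)
}

#' @rdname clonesv-io
#' @export
read_snv_tsv <- function(path) read_tsv_dot(path)

#' @rdname clonesv-io
#' @export
write_segments_tsv <- function(x, path) {
  cols <- c("chrom", "start", "end", "clone_id", "major_cn", "minor_cn")
  extra <- intersect(c("lrr_minor", "n_snps"), names(x))
  write_tsv_dot(x[, c(cols, extra)], path)
}

#' @rdname clonesv-io
#' @export
read_segments_tsv <- function(path) read_tsv_dot(path)

#' Write/read read pairs or SV calls as BEDPE
#'
#' Read pairs are written with a read length of `read_len` bp so that
#' `end = start + read_len`; the extra `mismatches` column carries the
#' per-pair mismatch count. SV calls written through [write_sv_bedpe()]
#' carry `sv_type`, `n_support` and `somatic` extra columns instead.
#'
#' @param pairs data frame of read pairs (see [simulate_discordant_pairs()]).
#' @param path file path.
#' @param read_len read length in bp used to fill the BEDPE end columns.
#' @export
write_pairs_bedpe <- function(pairs, path, read_len = 100L) {
  bed <- data.frame(
    chrom1 = pairs$chrom1, start1 = pairs$pos1, end1 = pairs$pos1 + read_len,
    chrom2 = pairs$chrom2, start2 = pairs$pos2, end2 = pairs$pos2 + read_len,
    name = if (!is.null(pairs$name)) pairs$name else sprintf("pair%06d", seq_len(nrow(pairs))),
    mapq = pairs$mapq, strand1 = pairs$strand1, strand2 = pairs$strand2,
    mismatches = pairs$mismatches,
    sample_id = if (!is.null(pairs$sample_id)) pairs$sample_id else NA,
    stringsAsFactors = FALSE)
  write_tsv_dot(bed, path)
}

#' @rdname write_pairs_bedpe
#' @export
read_pairs_bedpe <- function(path) {
  bed <- read_tsv_dot(path)
  read_pair_records(
    chrom1 = bed$chrom1, pos1 = bed$start1, strand1 = bed$strand1,
    chrom2 = bed$chrom2, pos2 = bed$start2, strand2 = bed$strand2,
    mapq = bed$mapq, mismatches = bed$mismatches,
    sample_id = bed$sample_id %||% NA_character_)
}

#' @rdname write_pairs_bedpe
#' @param calls an `sv_calls` data frame (see [call_svs()]).
#' @export
write_sv_bedpe <- function(calls, path) {
  bed <- data.frame(
    chrom1 = calls$chrom1, start1 = calls$bp1, end1 = calls$bp1 + 1L,
    chrom2 = calls$chrom2, start2 = calls$bp2, end2 = calls$bp2 + 1L,
    name = sprintf("sv%04d", seq_len(nrow(calls))),
    score = calls$n_support,
    strand1 = calls$strand1, strand2 = calls$strand2,
    sv_type = calls$sv_type, n_support = calls$n_support,
    somatic = calls$somatic,
    sample_id = calls$sample_id %||% NA,
    stringsAsFactors = FALSE)
  write_tsv_dot(bed, path)
}

#' @rdname write_pairs_bedpe
#' @export
read_sv_bedpe <- function(path) {
  bed <- read_tsv_dot(path)
  out <- data.frame(
    chrom1 = bed$chrom1, bp1 = bed$start1, strand1 = bed$strand1,
    chrom2 = bed$chrom2, bp2 = bed$start2, strand2 = bed$strand2,
    sv_type = bed$sv_type, n_support = bed$n_support,
    somatic = as.logical(bed$somatic),
    sample_id = bed$sample_id %||% NA,
    stringsAsFactors = FALSE)
  out$distance <- ifelse(out$chrom1 == out$chrom2, abs(out$bp2 - out$bp1), NA_real_)
  class(out) <- c("sv_calls", "data.frame")
  out
}

#' @rdname clonesv-io
#' @export
write_clones_tsv <- function(x, path) {
  cols <- c("clone_id", "method", "cellularity", "clonality", "n_members")
  write_tsv_dot(as.data.frame(x)[, cols], path)
}

#' @rdname clonesv-io
#' @export
write_exposures_tsv <- function(x, path) {
  df <- data.frame(signature = names(coef(x)), exposure = as.numeric(coef(x)),
                   stringsAsFactors = FALSE)
  write_tsv_dot(df, path)
}

#' Read or write a signature-profile matrix
#'
#' 96 rows (one per trinucleotide channel, see [trinucleotide_channels()]),
#' one `channel` label column plus one column per signature, each column a
#' probability vector summing to 1.
#'
#' @param profiles matrix (96 x k) with channel rownames.
#' @param path file path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  df <- data.frame(channel = rownames(profiles), as.data.frame(profiles),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_dot(df, path)
}

#' @rdname write_profiles_tsv
#' @export
read_profiles_tsv <- function(path) {
  df <- read_tsv_dot(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$channel
  m[trinucleotide_channels(), , drop = FALSE]
}
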