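#' The 96 canonical trinucleotide substitution channels
#'
#' Pyrimidine-centric layout: six substitution classes (C>A, C>G, C>T, T>A,
#' T>C, T>G) in that order, each crossed with the 16 flanking-base contexts
#' in lexicographic order, e.g. `A[C>A]A`, `A[C>A]C`, ...
#'
#' @return character vector of length 96.
#' @export
trinucleotide_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(u, d)
      paste0(u, "[", s, "]", d))))
  }))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(ch)
    paste(rev(ch), collapse = ""), character(1)))
}

# split "A[C>T]G" into context "ACG", ref "C", alt "T"
parse_channel <- function(ch) {
  up <- substr(ch, 1, 1); ref <- substr(ch, 3, 3)
  alt <- substr(ch, 5, 5); down <- substr(ch, 7, 7)
  list(context = paste0(up, ref, down), ref = ref, alt = alt)
}

#' Synthetic three-signature profile set
#'
#' Deterministic stand-ins with the qualitative shapes of the signatures seen
#' in homologous-recombination-deficient breast tumors: a broad, flat-ish
#' BRCA-like signature; an age-like signature concentrated on C>T at CpG
#' (`N[C>T]G`) channels; and an APOBEC-like signature concentrated on
#' `T[C>T]A/T` and `T[C>G]A/T`. These are test profiles, not estimates of any
#' published signature.
#'
#' @return 96 x 3 probability matrix with channel rownames.
#' @export
synthetic_signature_profiles <- function() {
  ch <- trinucleotide_channels()
  # broad profile with geometrically decaying channel weights, interleaved
  # across the substitution classes by a fixed stride
  rank <- order((seq_len(96) * 37) %% 96)
  brca <- numeric(96)
  brca[rank] <- 0.88^(0:95)
  age <- rep(0.08, 96)
  age[grepl("\\[C>T\\]G$", ch)] <- 5
  apobec <- rep(0.04, 96)
  apobec[grepl("^T\\[C>T\\][AT]$", ch)] <- 10
  apobec[grepl("^T\\[C>G\\][AT]$", ch)] <- 8
  m <- cbind(brca_like = brca / sum(brca), age_like = age / sum(age),
             apobec_like = apobec / sum(apobec))
  rownames(m) <- ch
  m
}

#' Apply the somatic-variant filter rules
#'
#' WES mode: drop candidates with read depth below 20 or VAF below 0.10.
#' WGS mode: drop candidates with non-reference allele frequency below 0.05.
#' Both modes require support on both strands (at least one forward and one
#' reverse alt read) and absence from the population database and the normal
#' panel. Each failing candidate is annotated with its *first* failing rule
#' (checked in the order depth, vaf, strand, population, panel).
#'
#' @param candidates SNV table with `depth`, `alt_depth`, `alt_fwd`,
#'   `alt_rev` (and `chrom`, `pos`, `ref`, `alt` when sets are used).
#' @param mode `"wgs"` or `"wes"`.
#' @param population_set,panel_set character vectors of `chrom:pos:ref:alt`
#'   keys to exclude.
#' @return list with `pass` (the surviving rows) and `fail` (failing rows
#'   with a `reason` column).
#' @export
apply_somatic_filters <- function(candidates, mode = c("wgs", "wes"),
                                  population_set = character(0),
                                  panel_set = character(0)) {
  mode <- match.arg(mode)
  vaf_min <- if (mode == "wes") 0.10 else 0.05
  n <- nrow(candidates)
  vaf <- candidates$alt_depth / candidates$depth
  key <- if (all(c("chrom", "pos", "ref", "alt") %in% names(candidates))) {
    paste(candidates$chrom, candidates$pos, candidates$ref, candidates$alt, sep = ":")
  } else rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  flag <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  if (mode == "wes") flag(candidates$depth < 20, "depth")
  flag(vaf < vaf_min, "vaf")
  flag(candidates$alt_fwd < 1 | candidates$alt_rev < 1, "strand")
  flag(key %in% population_set, "population")
  flag(key %in% panel_set, "panel")
  pass <- candidates[is.na(reason), , drop = FALSE]
  fail <- candidates[!is.na(reason), , drop = FALSE]
  fail$reason <- reason[!is.na(reason)]
  rownames(pass) <- rownames(fail) <- NULL
  list(pass = pass, fail = fail)
}

#' Trinucleotide mutation spectrum
#'
#' Counts SNVs into the 96 pyrimidine-centric channels. Records with a purine
#' reference base are reverse-complemented (context and alternate allele)
#' before channel lookup. Records whose context contains a non-ACGT character
#' (or that describe no substitution) are skipped with a warning and counted
#' in the `discarded` attribute.
#'
#' @param snvs SNV table with `ref`, `alt` and a 3-base `context` column
#'   (the reference base with its two flanking bases).
#' @return named numeric vector of length 96 (class `spectrum`), channel
#'   counts summing to `nrow(snvs) - discarded`.
#' @export
trinucleotide_spectrum <- function(snvs) {
  channels <- trinucleotide_channels()
  counts <- stats::setNames(numeric(96), channels)
  if (nrow(snvs) == 0L) {
    return(structure(counts, discarded = 0L, class = "spectrum"))
  }
  ref <- toupper(snvs$ref); alt <- toupper(snvs$alt)
  ctx <- toupper(snvs$context)
  ok <- grepl("^[ACGT]{3}$", ctx) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T") & ref != alt &
    substr(ctx, 2, 2) == ref
  if (any(!ok)) {
    warning(sum(!ok), " record(s) with invalid context or alleles discarded")
  }
  ref <- ref[ok]; alt <- alt[ok]; ctx <- ctx[ok]
  pur <- ref %in% c("A", "G")
  if (any(pur)) {
    ctx[pur] <- revcomp(ctx[pur])
    ref[pur] <- substr(ctx[pur], 2, 2)
    alt[pur] <- chartr("ACGT", "TGCA", alt[pur])
  }
  lab <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
  tab <- table(factor(lab, levels = channels))
  counts[] <- as.numeric(tab)
  structure(counts, discarded = sum(!ok), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("Trinucleotide spectrum:", sum(x), "mutations over 96 channels")
  d <- attr(x, "discarded")
  if (!is.null(d) && d > 0) cat(" (", d, " discarded)", sep = "")
  cat("\n")
  top <- sort(unclass(x), decreasing = TRUE)[1:5]
  cat("  top channels:", paste0(names(top), "=", round(top, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Fit signature exposures by nonnegative least squares
#'
#' Projects the normalized spectrum onto the given signature profiles under
#' nonnegativity, then renormalizes the weights to sum to 1. De novo
#' signature extraction is out of scope: the profiles are fixed inputs.
#'
#' @param spectrum a [trinucleotide_spectrum()] result (counts or
#'   probabilities, length 96).
#' @param profiles 96 x k probability matrix.
#' @return object of class `exposure_fit`; `coef()` returns the normalized
#'   exposures, `$residual` the NNLS residual norm.
#' @export
fit_signature_exposures <- function(spectrum, profiles) {
  v <- as.numeric(spectrum)
  if (length(v) != 96L || nrow(profiles) != 96L) {
    stop_config("spectrum and profiles must use the 96-channel layout")
  }
  if (sum(v) <= 0) stop("all-zero spectrum: no mutations to fit", call. = FALSE)
  p <- v / sum(v)
  fit <- pracma::lsqnonneg(as.matrix(profiles), p)
  w <- fit$x
  if (sum(w) <= 0) stop("degenerate NNLS fit", call. = FALSE)
  exposures <- stats::setNames(w / sum(w), colnames(profiles))
  structure(list(exposures = exposures, residual = sqrt(fit$resid.norm),
                 raw_weights = w),
            class = "exposure_fit")
}

#' @export
coef.exposure_fit <- function(object, ...) object$exposures

#' @export
print.exposure_fit <- function(x, ...) {
  cat("Signature exposures (NNLS):\n")
  print(round(x$exposures, 4))
  cat(sprintf("  residual norm: %.4g\n", x$residual))
  invisible(x)
}
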