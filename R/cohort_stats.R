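#' Classify homologous-recombination status
#'
#' A sample is HR-defective when it carries a disruptive mutation of BRCA1 or
#' RAD51C, or when any available promoter methylation beta value exceeds the
#' threshold (default 0.2). It is intact when all available evidence is
#' negative, and unknown when no evidence is available. Low mRNA expression
#' is corroborating only and never flips the status by itself.
#'
#' @param annotation data frame with logical columns
#'   `brca1_disruptive_mutation`, `rad51c_disruptive_mutation` and numeric
#'   columns `brca1_promoter_beta`, `rad51c_promoter_beta` (NA = missing).
#' @param beta_threshold methylation beta threshold.
#' @return character vector: `"defective"`, `"intact"` or `"unknown"`.
#' @export
classify_hr_status <- function(annotation, beta_threshold = 0.2) {
  betas <- cbind(annotation$brca1_promoter_beta, annotation$rad51c_promoter_beta)
  if (any(betas < 0 | betas > 1, na.rm = TRUE)) {
    stop_config("promoter beta values must lie in [0, 1]")
  }
  muts <- cbind(annotation$brca1_disruptive_mutation,
                annotation$rad51c_disruptive_mutation)
  mut_hit <- apply(muts, 1, function(z) isTRUE(any(z)))
  beta_hit <- apply(betas > beta_threshold, 1, function(z) isTRUE(any(z)))
  any_evidence <- apply(!is.na(muts), 1, any) | apply(!is.na(betas), 1, any)
  ifelse(mut_hit | beta_hit, "defective",
         ifelse(any_evidence, "intact", "unknown"))
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test. The two-sided p-value follows the
#' probability-mass convention: the sum, over all tables with the observed
#' margins, of probabilities no larger than that of the observed table. The
#' reported odds ratio is the sample odds ratio `ad / bc` (`Inf` when
#' `bc = 0` with `ad > 0`; `NaN` when both products are 0).
#'
#' @param a,b,c,d the four cells, row-wise (`a`, `b` top row), or a 2x2
#'   matrix passed as `a`.
#' @return list with `p.value`, `odds.ratio` and the table.
#' @examples
#' fisher_exact_2x2(6, 98, 11, 965)  # p ~ 0.0044
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) { b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1] }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("at least one positive margin required", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c > 0) (a * d) / (b * c) else if (a * d > 0) Inf else NaN
  list(p.value = min(1, p), odds.ratio = or,
       table = matrix(cells, 2, 2, byrow = TRUE))
}

#' Wilcoxon rank-sum test with explicit exact/approximate paths
#'
#' Uses the exact permutation distribution of the rank sum when both samples
#' have at most `exact_below` observations and there are no ties; otherwise a
#' normal approximation with tie correction (no continuity correction, so the
#' two paths agree closely on tie-free data). The method actually used is
#' reported.
#'
#' @param x,y numeric samples.
#' @param exact_below exact-path size limit (per sample).
#' @return list with `p.value`, `method` (`"exact"` or `"normal"`), and the
#'   rank-sum statistic `W` of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_below = 20L) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  ties <- any(duplicated(c(x, y)))
  use_exact <- length(x) <= exact_below && length(y) <= exact_below && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = FALSE))
  list(p.value = wt$p.value,
       method = if (use_exact) "exact" else "normal",
       W = unname(wt$statistic))
}

#' Assemble a cohort report
#'
#' One row per sample: SV counts by type, tandem-duplication proportion,
#' median breakpoint distance, number of clones with truncal cellularity and
#' subclone clonalities, signature exposures and HR status. Samples are
#' ordered by descending BRCA-like signature exposure. When both HR groups
#' are present, group comparisons (SV count, tandem-duplication count,
#' log10 median distance) are tested with the Wilcoxon rank-sum test.
#'
#' @param samples named list; each element a list with components
#'   `sv_summary` (an `sv_summary`), `clones` (a `clone_fit`), `exposures`
#'   (an `exposure_fit`), and `hr_status` (string). Missing components mark
#'   the sample incomplete (kept in the table, flagged).
#' @param brca_signature name of the BRCA-like profile column.
#' @return object of class `cohort_report`: `$table` plus `$comparisons`.
#' @export
build_report <- function(samples, brca_signature = "brca_like") {
  rows <- lapply(names(samples), function(id) {
    s <- samples[[id]]
    complete <- !is.null(s$sv_summary) && !is.null(s$clones) &&
      !is.null(s$exposures) && !is.null(s$hr_status)
    counts <- if (!is.null(s$sv_summary)) s$sv_summary$counts else
      stats::setNames(rep(NA_integer_, 4),
                      c("translocation", "inverted_rearrangement", "deletion",
                        "tandem_duplication"))
    exp_b <- if (!is.null(s$exposures)) unname(coef(s$exposures)[brca_signature]) else NA_real_
    truncal <- if (!is.null(s$clones)) max(s$clones$clones$cellularity) else NA_real_
    sub_clon <- if (!is.null(s$clones) && nrow(s$clones$clones) > 1) {
      paste(round(s$clones$clones$clonality[-1]), collapse = ";")
    } else ""
    data.frame(sample_id = id,
               n_sv = sum(counts), n_translocation = counts[["translocation"]],
               n_inverted = counts[["inverted_rearrangement"]],
               n_deletion = counts[["deletion"]],
               n_tandem_dup = counts[["tandem_duplication"]],
               tandem_proportion = if (!is.null(s$sv_summary)) s$sv_summary$tandem_proportion else NA_real_,
               median_distance = if (!is.null(s$sv_summary)) s$sv_summary$median_distance else NA_real_,
               truncal_cellularity = truncal,
               subclone_clonality = sub_clon,
               brca_exposure = exp_b,
               hr_status = s$hr_status %||% NA_character_,
               incomplete = !complete,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(tab) && nrow(tab)) {
    tab <- tab[order(-ifelse(is.na(tab$brca_exposure), -Inf, tab$brca_exposure)), ]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(sample_id = character(), n_sv = integer(),
                      n_translocation = integer(), n_inverted = integer(),
                      n_deletion = integer(), n_tandem_dup = integer(),
                      tandem_proportion = numeric(), median_distance = numeric(),
                      truncal_cellularity = numeric(),
                      subclone_clonality = character(),
                      brca_exposure = numeric(), hr_status = character(),
                      incomplete = logical(), stringsAsFactors = FALSE)
  }
  comparisons <- NULL
  def <- tab$hr_status == "defective" & !tab$incomplete
  int <- tab$hr_status == "intact" & !tab$incomplete
  if (sum(def, na.rm = TRUE) >= 2 && sum(int, na.rm = TRUE) >= 2) {
    cmp <- function(v) wilcoxon_rank_sum(v[which(def)], v[which(int)])
    comparisons <- list(
      n_sv = cmp(tab$n_sv),
      n_tandem_dup = cmp(tab$n_tandem_dup),
      log10_median_distance = cmp(log10(tab$median_distance)))
  }
  structure(list(table = tab, comparisons = comparisons), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report:", nrow(x$table), "sample(s)\n")
  if (nrow(x$table)) print.data.frame(x$table, row.names = FALSE, digits = 3)
  if (!is.null(x$comparisons)) {
    cat("HR-defective vs intact (Wilcoxon rank-sum):\n")
    for (nm in names(x$comparisons)) {
      cat(sprintf("  %-24s p = %.4g (%s)\n", nm,
                  x$comparisons[[nm]]$p.value, x$comparisons[[nm]]$method))
    }
  }
  invisible(x)
}
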