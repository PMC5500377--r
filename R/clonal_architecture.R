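#' Cellularity from the minor-allele read fraction
#'
#' In a region where a fraction `c` of all cells carries the tumor genotype
#' {major 1, minor 0} and the remaining cells are diploid heterozygous, the
#' minor allele contributes a read fraction `f = (1 - c) / (2 - c)`.
#' Inverting: `c = (1 - 2 f) / (1 - f)`, clipped to `[0, 1]`.
#'
#' @param f minor-allele read fraction(s), each in `[0, 0.5]`.
#' @return cellularity value(s) in `[0, 1]`.
#' @examples
#' cellularity_from_minor_fraction(c(0.5, 1/3, 0))  # 0, 0.5, 1
#' @export
cellularity_from_minor_fraction <- function(f) {
  if (any(f < 0 | f > 0.5 + 1e-12)) {
    stop("minor fraction must lie in [0, 0.5]; orient alleles before calling",
         call. = FALSE)
  }
  clip01((1 - 2 * f) / (1 - f))
}

# Pool SNPs falling in a segment; minor allele = lower-depth tumor allele.
pooled_minor_fraction <- function(segment, snps) {
  sel <- snps$chrom == segment$chrom &
    snps$pos > segment$start & snps$pos <= segment$end
  s <- snps[sel, , drop = FALSE]
  # admission rule: heterozygous in normal
  naf <- s$normal_alt / pmax(1, s$normal_alt + s$normal_ref)
  s <- s[naf >= 0.3 & naf <= 0.7, , drop = FALSE]
  if (nrow(s) == 0L) return(list(f = NA_real_, n = 0L, minor_mean = NA_real_))
  minor <- pmin(s$tumor_ref, s$tumor_alt)
  tot <- s$tumor_ref + s$tumor_alt
  list(f = sum(minor) / sum(tot), n = nrow(s), minor_mean = mean(minor))
}

#' Calibrate minor-allele log R ratio against tumor cellularity
#'
#' Uses segments with major CN 1 and minor CN 0, where cellularity is
#' unambiguous: the pooled minor-allele fraction of each segment is converted
#' to cellularity by [cellularity_from_minor_fraction()], and cellularity is
#' then regressed on the minor-allele LRR. Since the noiseless relation is
#' `c = 1 - 2^lrr`, the least-squares line is fitted on the transformed
#' predictor `x = 1 - 2^lrr` (exact on clean data, and the two free
#' coefficients absorb depth-normalization offsets).
#'
#' @param segments CN segment table with `major_cn`, `minor_cn`, `lrr_minor`.
#' @param snps heterozygous-SNP observation table.
#' @return object of class `lrr_calibration` with coefficients, `r.squared`
#'   and `n`; use [predict()] to map LRR values to cellularities.
#' @export
calibrate_lrr_to_cellularity <- function(segments, snps) {
  qual <- segments[segments$major_cn == 1 & segments$minor_cn == 0, , drop = FALSE]
  if (nrow(qual) >= 1) {
    pooled <- lapply(seq_len(nrow(qual)), function(i) pooled_minor_fraction(qual[i, ], snps))
    qual$f <- vapply(pooled, `[[`, numeric(1), "f")
    qual <- qual[!is.na(qual$f), , drop = FALSE]
  }
  if (nrow(qual) < 2 || length(unique(round(qual$lrr_minor, 10))) < 2) {
    stop(errorCondition(
      "calibration impossible: need >= 2 major=1/minor=0 segments with distinct LRR",
      class = c("clonesv_calibration_error", "error")))
  }
  cc <- cellularity_from_minor_fraction(pmin(qual$f, 0.5))
  x <- 1 - 2^qual$lrr_minor
  fit <- stats::lm(cc ~ x)
  structure(list(coefficients = stats::coef(fit),
                 r.squared = summary(fit)$r.squared,
                 n = nrow(qual),
                 segments = qual[, c("chrom", "start", "end", "lrr_minor", "f")],
                 cellularities = cc),
            class = "lrr_calibration")
}

#' @export
print.lrr_calibration <- function(x, ...) {
  cat(sprintf("LRR-cellularity calibration on %d segments: c = %.4f + %.4f * (1 - 2^lrr), R^2 = %.4f\n",
              x$n, x$coefficients[1], x$coefficients[2], x$r.squared))
  invisible(x)
}

#' @param object an `lrr_calibration`.
#' @param lrr minor-allele LRR values to map to cellularity.
#' @param ... unused.
#' @rdname calibrate_lrr_to_cellularity
#' @export
predict.lrr_calibration <- function(object, lrr, ...) {
  clip01(object$coefficients[1] + object$coefficients[2] * (1 - 2^lrr))
}

#' Annotate segments with SNP-derived minor fraction and LRR
#'
#' Computes, for each segment, the number of admissible heterozygous SNPs,
#' the pooled minor-allele fraction, and (if absent) the minor-allele LRR as
#' `log2(mean minor depth / haploid depth)`, with the haploid depth estimated
#' from the normal-sample depths.
#'
#' @param segments CN segment table.
#' @param snps SNP observation table.
#' @export
annotate_segments <- function(segments, snps) {
  haploid <- mean(snps$normal_ref + snps$normal_alt) / 2
  pooled <- lapply(seq_len(nrow(segments)), function(i)
    pooled_minor_fraction(segments[i, ], snps))
  segments$n_snps <- vapply(pooled, `[[`, integer(1), "n")
  segments$minor_fraction <- vapply(pooled, `[[`, numeric(1), "f")
  if (is.null(segments$lrr_minor)) {
    mm <- vapply(pooled, `[[`, numeric(1), "minor_mean")
    segments$lrr_minor <- log2(pmax(mm, 0.25) / haploid)
  }
  segments
}

#' Clonality from clone cellularities
#'
#' The truncal clone (largest cellularity) is set to 100% and every clone's
#' clonality is `100 * cellularity / truncal cellularity`. Reported values
#' are conventionally rounded to the nearest integer percent.
#'
#' @param cellularities numeric vector in `(0, 1]`.
#' @param clone_id optional labels.
#' @return data frame with `clone_id`, `cellularity`, `clonality`.
#' @examples
#' compute_clonality(c(0.89, 0.42))  # clonalities 100 and ~47.2
#' @export
compute_clonality <- function(cellularities, clone_id = NULL) {
  if (length(cellularities) == 0L) stop("empty cellularity vector", call. = FALSE)
  if (any(cellularities <= 0 | cellularities > 1)) {
    stop("cellularities must lie in (0, 1]", call. = FALSE)
  }
  o <- order(cellularities, decreasing = TRUE)
  cc <- cellularities[o]
  ids <- (clone_id %||% paste0("clone", seq_along(cellularities)))[o]
  data.frame(clone_id = ids, cellularity = cc,
             clonality = 100 * cc / cc[1], stringsAsFactors = FALSE)
}

# weighted silhouette score for 1-D k-means assignment
silhouette_1d <- function(x, w, assign, centers) {
  k <- length(centers)
  if (k < 2) return(NA_real_)
  s <- numeric(length(x))
  for (i in seq_along(x)) {
    same <- assign == assign[i]
    a <- if (sum(w[same]) > w[i]) {
      sum(w[same] * abs(x[same] - x[i])) / (sum(w[same]) - w[i])
    } else 0
    b <- min(vapply(setdiff(seq_len(k), assign[i]), function(kk) {
      oth <- assign == kk
      if (!any(oth)) return(Inf)
      sum(w[oth] * abs(x[oth] - x[i])) / sum(w[oth])
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  sum(w * s) / sum(w)
}

#' Infer the global clonal architecture from copy-number evidence
#'
#' k-means clustering of the minor-allele LRR values of all minor-CN-zero
#' segments (SNP-count weighted, by replicating segment values); the number
#' of clones is chosen by the silhouette score over k = 2..`k_max`, requiring
#' every cluster to carry at least 5% of the SNP-weighted mass, with a
#' one-cluster fallback. Cluster centers are mapped to cellularities through
#' the LRR calibration and converted to clonalities.
#'
#' @param segments CN segment table (only `minor_cn == 0` rows are used)
#'   with `lrr_minor` and `n_snps`.
#' @param calibration an [calibrate_lrr_to_cellularity()] fit.
#' @param k_max maximum number of clones considered.
#' @param min_mass minimum SNP-weighted cluster mass (fraction).
#' @param sil_min minimum silhouette for accepting a multi-cluster solution;
#'   guards against splitting a single tight cluster, where k-means always
#'   finds a partition but the silhouette stays moderate.
#' @param seed k-means initialization seed.
#' @return object of class `clone_fit` (method `"cn_global"`).
#' @export
infer_global_clones <- function(segments, calibration, k_max = 5L,
                                min_mass = 0.05, sil_min = 0.75, seed = 1L) {
  seg <- segments[segments$minor_cn == 0, , drop = FALSE]
  if (nrow(seg) == 0L) {
    stop(errorCondition("no minor_cn = 0 segments: no evidence for global clonal analysis",
                        class = c("clonesv_noevidence_error", "error")))
  }
  x <- seg$lrr_minor
  w <- as.numeric(seg$n_snps %||% rep(1, nrow(seg)))
  n_distinct <- length(unique(round(x, 9)))
  cands <- with_seed(seed, {
    lapply(seq_len(max(1L, min(k_max, n_distinct))), function(k) {
      km <- if (k == 1) {
        list(centers = matrix(sum(w * x) / sum(w)), cluster = rep(1L, length(x)))
      } else {
        stats::kmeans(x, centers = k, nstart = 10, iter.max = 100)
      }
      mass <- vapply(seq_len(k), function(kk) sum(w[km$cluster == kk]) / sum(w),
                     numeric(1))
      list(k = k, centers = as.numeric(km$centers), cluster = km$cluster,
           mass = mass,
           sil = silhouette_1d(x, w, km$cluster, as.numeric(km$centers)))
    })
  })
  ok <- vapply(cands, function(cd) cd$k >= 2 && all(cd$mass >= min_mass) &&
                 !is.na(cd$sil) && cd$sil >= sil_min, logical(1))
  best <- if (any(ok)) {
    sils <- vapply(cands, function(cd) ifelse(is.na(cd$sil), -Inf, cd$sil), numeric(1))
    sils[!ok] <- -Inf
    cands[[which.max(sils)]]
  } else cands[[1]]
  cells <- unname(predict(calibration, best$centers))
  cells <- pmin(pmax(cells, 1e-6), 1)
  # collapse indistinguishable centers
  o <- order(cells, decreasing = TRUE)
  cells <- cells[o]
  members <- vapply(seq_len(best$k), function(kk) sum(best$cluster == o[kk]), integer(1))
  dup <- c(FALSE, abs(diff(cells)) < 1e-6)
  if (any(dup)) {
    members <- vapply(split(members, cumsum(!dup)), sum, numeric(1))
    cells <- cells[!dup]
  }
  clones <- compute_clonality(cells)
  clones$n_members <- as.integer(members)
  clones$method <- "cn_global"
  new_clone_fit(clones, method = "cn_global",
                details = list(k = length(cells), silhouette = best$sil,
                               centers = best$centers, calibration = calibration))
}

new_clone_fit <- function(clones, method, details = list()) {
  structure(list(clones = clones, method = method, details = details),
            class = "clone_fit")
}

#' @export
print.clone_fit <- function(x, ...) {
  cat("Clonal architecture (", x$method, "): ", nrow(x$clones), " clone(s)\n", sep = "")
  df <- x$clones
  df$clonality <- round(df$clonality)
  print.data.frame(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.clone_fit <- function(object, ...) {
  cat("Method:", object$method, "\n")
  print(object)
  if (!is.null(object$details$silhouette) && !is.na(object$details$silhouette)) {
    cat(sprintf("silhouette = %.3f\n", object$details$silhouette))
  }
  if (!is.null(object$details$bic)) {
    cat("BIC by k:", paste(round(object$details$bic, 1), collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
coef.clone_fit <- function(object, ...) {
  stats::setNames(object$clones$cellularity, object$clones$clone_id)
}

#' Copy-number-adjusted allele frequency (VAFa)
#'
#' Rescales a raw VAF by local copy number and tumor purity so the result is
#' interpretable as the fraction of all cells carrying the variant:
#' `vafa = vaf * (purity * CN_t + 2 * (1 - purity)) / multiplicity`,
#' clipped to `[0, 1]`.
#'
#' @param vaf variant allele frequency (fraction of reads).
#' @param purity truncal cellularity in `(0, 1]`.
#' @param local_total_cn total tumor copy number at the locus.
#' @param multiplicity copies per tumor cell carrying the variant (>= 1).
#' @export
compute_vafa <- function(vaf, purity, local_total_cn, multiplicity = 1) {
  if (any(multiplicity < 1)) stop("multiplicity must be >= 1", call. = FALSE)
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]", call. = FALSE)
  clip01(vaf * (purity * local_total_cn + 2 * (1 - purity)) / multiplicity)
}

# EM for a k-component binomial mixture over (alt, depth) with success
# probabilities theta_ik = m_k * a_i, a_i = mult / (purity*CN_i + 2(1-purity)).
binmix_em <- function(alt, depth, a, k, m_init, tol = 1e-8, max_iter = 1000L) {
  n <- length(alt)
  m <- m_init
  pi_k <- rep(1 / k, k)
  eps <- 1e-9
  loglik <- -Inf
  trace <- numeric(0)
  m_upper <- min(1, (1 - eps) / max(a))
  lch <- lchoose(depth, alt)  # constant binomial coefficient term
  a_const <- length(unique(a)) == 1L
  nseq <- seq_len(n)
  trace <- numeric(max_iter)
  n_iter <- 0L
  for (iter in seq_len(max_iter)) {
    theta <- pmin(pmax(outer(a, m), eps), 1 - eps)  # n x k
    logp <- lch + alt * log(theta) + (depth - alt) * log1p(-theta)
    logp <- logp + matrix(log(pi_k), n, k, byrow = TRUE)
    mx <- logp[cbind(nseq, max.col(logp, ties.method = "first"))]
    lse <- mx + log(rowSums(exp(logp - mx)))
    new_ll <- sum(lse)
    r <- exp(logp - lse)                      # responsibilities
    pi_k <- colMeans(r)
    if (a_const) {
      m <- pmin(m_upper, pmax(eps, (colSums(r * alt) / pmax(colSums(r * depth), eps)) / a[1]))
    } else {
      for (kk in seq_len(k)) {
        obj <- function(mm) {
          th <- pmin(pmax(mm * a, eps), 1 - eps)
          -sum(r[, kk] * (alt * log(th) + (depth - alt) * log1p(-th)))
        }
        m[kk] <- stats::optimize(obj, c(eps, m_upper), tol = 1e-10)$minimum
      }
    }
    n_iter <- iter
    trace[iter] <- new_ll
    if (is.finite(loglik) && new_ll - loglik < tol) { loglik <- new_ll; break }
    loglik <- new_ll
  }
  trace <- trace[seq_len(n_iter)]
  list(m = m, pi = pi_k, loglik = loglik, trace = trace, r = r)
}

#' Cluster SNVs into clones by a binomial mixture over allele depths
#'
#' A declared stand-in for full Bayesian clonal clustering: a k-component
#' binomial mixture over `(alt_depth, depth)` whose component success
#' probabilities are `theta_k = m_k * multiplicity / (purity * CN_t +
#' 2 (1 - purity))`, with `m_k` the component's cellular fraction. Fitted by
#' EM (10 restarts, tolerance 1e-8, at most 1000 iterations); the number of
#' components is selected by BIC over k = 1..`k_max`. Intended for SNVs in
#' low-CN regions (`local_total_cn` 1 or 2) where the multiplicity is forced.
#'
#' @param snvs SNV table with `alt_depth`, `depth`, `local_total_cn`.
#' @param purity truncal cellularity.
#' @param k_max maximum number of components.
#' @param multiplicity variant copies per carrying cell.
#' @param restarts EM restarts per k.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations.
#' @param seed RNG seed for restarts.
#' @return object of class `clone_fit` (method `"vaf_local"`); details carry
#'   the per-iteration log-likelihood trace of the selected fit.
#' @export
cluster_vaf_clones <- function(snvs, purity, k_max = 5L, multiplicity = 1,
                               restarts = 10L, tol = 1e-8, max_iter = 1000L,
                               seed = 1L) {
  n <- nrow(snvs)
  if (n < 1L) {
    stop(errorCondition("no SNVs: cannot fit even a one-component mixture",
                        class = c("clonesv_noevidence_error", "error")))
  }
  stopifnot(all(snvs$depth > 0), all(snvs$local_total_cn %in% c(1L, 2L)))
  a <- multiplicity / (purity * snvs$local_total_cn + 2 * (1 - purity))
  alt <- snvs$alt_depth; depth <- snvs$depth
  vafa_i <- clip01((alt / depth) / a)
  fits <- list()
  with_seed(seed, {
    for (k in seq_len(min(k_max, n))) {
      best <- NULL
      for (r in seq_len(restarts)) {
        qs <- stats::quantile(vafa_i, probs = (seq_len(k) - 0.5) / k, names = FALSE)
        m0 <- clip01(qs + stats::rnorm(k, 0, 0.03 * (r > 1)))
        m0 <- pmin(pmax(m0, 0.01), 0.999)
        fit <- binmix_em(alt, depth, a, k, m0, tol, max_iter)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      n_par <- 2 * k - 1
      best$bic <- -2 * best$loglik + n_par * log(n)
      best$k <- k
      fits[[k]] <- best
    }
  })
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  sel <- fits[[which.min(bics)]]
  o <- order(sel$m, decreasing = TRUE)
  m_sorted <- sel$m[o]
  members <- as.integer(round(sel$pi[o] * n))
  # collapse components with indistinguishable cellular fractions
  dupe <- c(FALSE, abs(diff(m_sorted)) < 1e-3)
  if (any(dupe)) {
    members <- as.integer(vapply(split(members, cumsum(!dupe)), sum, numeric(1)))
    m_sorted <- m_sorted[!dupe]
  }
  clones <- compute_clonality(pmin(m_sorted, 1))
  clones$n_members <- members
  clones$method <- "vaf_local"
  new_clone_fit(clones, method = "vaf_local",
                details = list(k = length(m_sorted), bic = bics,
                               loglik_trace = sel$trace, pi = sel$pi))
}
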