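#' Replicate-based genotyping error rate
#'
#' For every declared replicate pair (original sample plus independent
#' re-extraction/re-scoring), the per-locus error rate is the fraction of
#' pairs whose band calls disagree at that locus; the overall rate is the
#' mean over loci. The alternative aggregation (mismatch fraction per
#' pair, averaged over pairs) is reported alongside.
#'
#' @param ds A `dompop_dataset` with at least one `replicate_of` link.
#' @return An object of class `error_report`: list with `per_locus_error`,
#'   `mean_error`, `per_pair_error`, `mean_error_per_pair`,
#'   `n_replicate_pairs`, and `replicate_ids` (the copies to exclude
#'   downstream).
#' @export
replicate_error_rate <- function(ds) {
  reps <- ds$samples[!is.na(ds$samples$replicate_of), , drop = FALSE]
  if (nrow(reps) == 0)
    stop("no replicate pairs declared; supply an error rate via configuration instead")
  a <- ds$bands[reps$individual_id, , drop = FALSE]
  b <- ds$bands[reps$replicate_of, , drop = FALSE]
  mism <- a != b
  per_locus <- colMeans(mism)
  per_pair <- rowMeans(mism)
  structure(list(per_locus_error = per_locus,
                 mean_error = mean(per_locus),
                 per_pair_error = stats::setNames(per_pair, reps$individual_id),
                 mean_error_per_pair = mean(per_pair),
                 n_replicate_pairs = nrow(reps),
                 replicate_ids = reps$individual_id),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("<error_report> ", x$n_replicate_pairs, " replicate pairs, ",
      length(x$per_locus_error), " loci\n", sep = "")
  cat(sprintf("  mean error per locus: %.4f (per pair: %.4f)\n",
              x$mean_error, x$mean_error_per_pair))
  invisible(x)
}

#' Clone (genet) detection by sub-error mismatch clustering
#'
#' Two samples are ramets of the same genet when their band profiles
#' differ at no more than `round(error_rate * L)` loci; genets are the
#' single-linkage connected components of that relation.
#'
#' @param ds A `dompop_dataset` (replicate copies dropped internally).
#' @param error_rate Genotyping error rate in [0, 1).
#' @return List of class `genet_assignment` with `genet` (named integer
#'   vector individual -> genet label), `threshold_mismatches`, and
#'   `multi_ramet` (data frame of genets with more than one ramet).
#' @export
detect_clones <- function(ds, error_rate) {
  stopifnot(error_rate >= 0, error_rate < 1)
  ds <- drop_replicates(ds)
  L <- ncol(ds$bands)
  thr <- round(error_rate * L)
  d <- hamming_rows(ds$bands)
  comp <- graph_components(d <= thr)
  names(comp) <- rownames(ds$bands)
  sizes <- table(comp)
  multi <- names(sizes)[sizes > 1]
  multi_df <- if (length(multi) > 0)
    data.frame(genet = as.integer(multi),
               n_ramets = as.integer(sizes[multi]),
               members = vapply(multi, function(g)
                 paste(names(comp)[comp == as.integer(g)], collapse = ";"), ""),
               stringsAsFactors = FALSE)
  else
    data.frame(genet = integer(0), n_ramets = integer(0), members = character(0))
  structure(list(genet = comp, threshold_mismatches = thr, multi_ramet = multi_df),
            class = "genet_assignment")
}

#' @export
print.genet_assignment <- function(x, ...) {
  cat("<genet_assignment> ", length(unique(x$genet)), " genets among ",
      length(x$genet), " samples (threshold ", x$threshold_mismatches,
      " mismatches)\n", sep = "")
  if (nrow(x$multi_ramet) > 0)
    cat("  multi-ramet genets:", nrow(x$multi_ramet), "\n")
  else cat("  no ramets of the same genet found\n")
  invisible(x)
}

#' Fragment size vs band frequency screen (size homoplasy)
#'
#' Tests the Pearson correlation between fragment size and band frequency
#' across the loci of one primer combination. Smaller fragments are more
#' homoplasy-prone; a significant negative correlation triggers a scan of
#' minimum-size cutoffs (50-bp steps) until the correlation among the
#' retained loci is no longer significant.
#'
#' @param ds A `dompop_dataset` with locus metadata.
#' @param primer_combo The primer combination label to screen.
#' @param alpha Significance level (default 0.05).
#' @param step Cutoff step in bp (default 50).
#' @return List of class `size_freq_screen`: `r`, `p`, `decision`
#'   (`"ok"`, `"negative_correlation"` or `"NA"`), and when a scan ran,
#'   `cutoff_bp`, `n_dropped` and the `scan` table.
#' @export
size_frequency_screen <- function(ds, primer_combo, alpha = 0.05, step = 50) {
  if (is.null(ds$locus_meta)) stop("dataset has no locus metadata (fragment sizes)")
  ds <- drop_replicates(ds)
  meta <- ds$locus_meta
  sel <- meta$primer_combo == primer_combo
  if (sum(sel) < 3) {
    warning("fewer than 3 loci for primer combination '", primer_combo, "'")
    return(structure(list(r = NA_real_, p = NA_real_, decision = "NA"),
                     class = "size_freq_screen"))
  }
  size <- meta$size_bp[sel]
  f <- colMeans(ds$bands[, meta$locus_id[sel], drop = FALSE])
  if (stats::sd(f) == 0 || stats::sd(size) == 0) {
    warning("degenerate frequencies or sizes; correlation undefined")
    return(structure(list(r = NA_real_, p = NA_real_, decision = "NA"),
                     class = "size_freq_screen"))
  }
  ct <- stats::cor.test(size, f)
  out <- list(r = unname(ct$estimate), p = ct$p.value, decision = "ok",
              n_loci = sum(sel))
  if (ct$p.value < alpha && ct$estimate < 0) {
    out$decision <- "negative_correlation"
    cuts <- seq(ceiling(min(size) / step) * step, max(size) - step, by = step)
    scan <- data.frame(cutoff_bp = cuts, r = NA_real_, p = NA_real_,
                       n_kept = NA_integer_)
    for (i in seq_along(cuts)) {
      keep <- size >= cuts[i]
      scan$n_kept[i] <- sum(keep)
      if (sum(keep) >= 3 && stats::sd(f[keep]) > 0 && stats::sd(size[keep]) > 0) {
        ct_i <- stats::cor.test(size[keep], f[keep])
        scan$r[i] <- unname(ct_i$estimate)
        scan$p[i] <- ct_i$p.value
      }
      if (is.finite(scan$p[i]) && scan$p[i] > alpha) break
    }
    scan <- scan[!is.na(scan$n_kept) & seq_len(nrow(scan)) <= i, , drop = FALSE]
    hit <- which(scan$p > alpha)[1]
    out$scan <- scan
    out$cutoff_bp <- if (is.na(hit)) NA_real_ else scan$cutoff_bp[hit]
    out$n_dropped <- if (is.na(hit)) NA_integer_ else out$n_loci - scan$n_kept[hit]
  }
  structure(out, class = "size_freq_screen")
}

# G-statistic (likelihood-ratio chi-square) for all 2x2 tables of locus
# pairs, computed in closed form. For a binary predictor/response the
# logistic regression with intercept and slope is saturated, so the LRT
# of the slope equals the G-test of independence on the 2x2 table.
ld_pair_stats <- function(x) {
  n <- nrow(x)
  n11 <- crossprod(x)                   # both present
  cs <- colSums(x)
  n10 <- outer(cs, cs, function(a, b) a) - n11  # locus i present, j absent
  n01 <- t(n10)
  n00 <- n - n11 - n10 - n01
  gterm <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  ri1 <- n11 + n10; ri0 <- n01 + n00
  cj1 <- n11 + n01; cj0 <- n10 + n00
  g2 <- 2 * (gterm(n11, ri1 * cj1 / n) + gterm(n10, ri1 * cj0 / n) +
             gterm(n01, ri0 * cj1 / n) + gterm(n00, ri0 * cj0 / n))
  list(g2 = g2, zero_cell = (n11 == 0) | (n10 == 0) | (n01 == 0) | (n00 == 0))
}

#' Pairwise linkage-disequilibrium scan over loci
#'
#' For every unordered pair of loci, a likelihood-ratio test of the slope
#' in a logistic regression of one locus' band presence on the other's
#' (equivalently, the G-test of the 2x2 contingency table, computed in
#' closed form). P-values are corrected by Benjamini-Hochberg; pairs with
#' an empty contingency cell (perfect separation of the logistic fit) are
#' flagged.
#'
#' @param ds A `dompop_dataset`.
#' @param cutoffs P-value cutoffs at which to report the fraction of
#'   significant pairs (default `c(1e-4, 0.01, 0.05)`).
#' @param fdr FDR level at which to report the q-value-significant count.
#' @return List of class `ld_scan_result` with `pairs` (data frame:
#'   `locus_a`, `locus_b`, `p`, `q`, `flagged`), `fraction_significant`
#'   and `n_fdr_significant`.
#' @export
ld_scan <- function(ds, cutoffs = c(1e-4, 0.01, 0.05), fdr = 0.05) {
  ds <- drop_replicates(ds)
  L <- ncol(ds$bands)
  if (L < 2) stop("need at least 2 loci")
  st <- ld_pair_stats(ds$bands)
  ut <- upper.tri(st$g2)
  p <- stats::pchisq(st$g2[ut], df = 1, lower.tail = FALSE)
  idx <- which(ut, arr.ind = TRUE)
  pairs <- data.frame(locus_a = colnames(ds$bands)[idx[, 1]],
                      locus_b = colnames(ds$bands)[idx[, 2]],
                      p = p, q = stats::p.adjust(p, "BH"),
                      flagged = st$zero_cell[ut],
                      stringsAsFactors = FALSE)
  cutoffs <- sort(cutoffs, decreasing = TRUE)
  frac <- vapply(cutoffs, function(a) mean(pairs$p < a), numeric(1))
  structure(list(pairs = pairs,
                 fraction_significant = stats::setNames(frac, format(cutoffs)),
                 n_fdr_significant = sum(pairs$q <= fdr)),
            class = "ld_scan_result")
}

#' @export
print.ld_scan_result <- function(x, ...) {
  cat("<ld_scan_result> ", nrow(x$pairs), " locus pairs\n", sep = "")
  for (i in seq_along(x$fraction_significant))
    cat(sprintf("  fraction p < %s: %.4f\n", names(x$fraction_significant)[i],
                x$fraction_significant[i]))
  cat("  pairs significant at FDR:", x$n_fdr_significant, "\n")
  invisible(x)
}

#' Band-frequency filter
#'
#' Removes loci whose overall band frequency lies outside the closed
#' interval [`min_f`, `max_f`]; near-fixed loci are unreliable and can
#' create spurious correlations.
#'
#' @param ds A `dompop_dataset`.
#' @param min_f,max_f Frequency bounds (defaults 0.05 and 0.95).
#' @return List with `dataset` (filtered), `kept`, `dropped`.
#' @export
frequency_filter <- function(ds, min_f = 0.05, max_f = 0.95) {
  core <- drop_replicates(ds)
  f <- colMeans(core$bands)
  keep <- f >= min_f & f <= max_f
  if (!any(keep)) stop("all loci removed by the frequency filter")
  list(dataset = ds_subset(ds, loci = colnames(ds$bands)[keep]),
       kept = colnames(ds$bands)[keep],
       dropped = colnames(ds$bands)[!keep])
}

#' Reduce clusters of redundant loci to single representatives
#'
#' Loci whose presence vectors are concordant at a rate of at least
#' `identity_threshold` (1.0 = identical columns) are clustered by single
#' linkage; the lowest-index locus of each cluster is retained. Redundant
#' loci are potentially linked and would otherwise be double-counted by
#' the likelihood assignment.
#'
#' @param ds A `dompop_dataset`.
#' @param identity_threshold Concordance needed to link two loci
#'   (default 1.0).
#' @return List with `dataset` (reduced), `keep`, `clusters` (data frame
#'   of multi-locus clusters and their representative).
#' @export
redundant_locus_clusters <- function(ds, identity_threshold = 1.0) {
  core <- drop_replicates(ds)
  x <- core$bands
  n <- nrow(x)
  d <- hamming_rows(t(x))            # mismatches between locus columns
  conc <- 1 - d / n
  comp <- graph_components(conc >= identity_threshold)
  loci <- colnames(x)
  keep <- vapply(split(seq_along(comp), comp), min, integer(1))
  clusters <- do.call(rbind, lapply(split(seq_along(comp), comp), function(ix) {
    if (length(ix) < 2) return(NULL)
    data.frame(representative = loci[min(ix)], size = length(ix),
               members = paste(loci[ix], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(clusters))
    clusters <- data.frame(representative = character(0), size = integer(0),
                           members = character(0))
  list(dataset = ds_subset(ds, loci = loci[sort(keep)]),
       keep = loci[sort(keep)], clusters = clusters)
}
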