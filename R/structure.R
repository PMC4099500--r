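# Per-locus Fst from band-absence counts (populations x loci) at
# inbreeding F: moment estimates of the null-allele frequency per deme
# (inversion of the null-phenotype fraction), among-population variance
# corrected for the delta-method sampling variance of each estimate,
# relative to q_bar(1 - q_bar). Moment estimates rather than the
# Bayesian posterior means drive the ANOVA: posterior shrinkage deflates
# the among-population variance, whereas the moment route is unbiased at
# these sample sizes (Lynch-Milligan style).
fst_per_locus <- function(kmat, nvec, F) {
  qt <- invert_null_pheno(kmat / nvec, F)
  p0 <- null_pheno_prob(qt, F)
  dg <- pmax(null_pheno_deriv(qt, F), 1e-3)
  sv <- p0 * (1 - p0) / (nvec * dg^2)
  s2 <- apply(qt, 2, stats::var)
  s2c <- pmax(s2 - colMeans(sv), 0)
  qbar <- colMeans(qt)
  denom <- qbar * (1 - qbar)
  ok <- denom > 1e-8
  fst <- rep(NA_real_, length(denom))
  fst[ok] <- s2c[ok] / denom[ok]
  fst
}

#' Global Fst from dominant-marker allele frequencies
#'
#' Per-locus Fst is the among-population variance of the estimated
#' null-allele frequency, corrected for its sampling variance, divided by
#' q(1-q) at the across-population mean; the global value is the mean
#' over polymorphic loci (SD over loci reported). Significance is
#' assessed by permuting individuals among populations (sizes kept) and
#' re-estimating frequencies each time.
#'
#' @param aft An `allele_freq_table` from [estimate_allele_freqs()].
#' @param ds The `dompop_dataset` the table was computed from (needed for
#'   the permutation test; replicate copies are dropped).
#' @param n_perm Number of permutations (default 100); 0 skips the test.
#' @param seed Integer seed.
#' @return List of class `fst_result`: `fst`, `sd_over_loci`, `p_value`,
#'   `n_permutations`, `F_is`, `per_locus`.
#' @export
fst_global <- function(aft, ds = NULL, n_perm = 100, seed = 1) {
  F <- attr(aft, "F")
  kmat <- aft_mat(aft, "k_absent")
  nvec <- aft_mat(aft, "n")[, 1]
  if (nrow(kmat) < 2) stop("need at least 2 populations")
  per_locus <- fst_per_locus(kmat, nvec, F)
  if (all(is.na(per_locus))) stop("Fst undefined: dataset is monomorphic")
  obs <- mean(per_locus, na.rm = TRUE)
  pval <- NA_real_
  if (n_perm > 0) {
    if (is.null(ds)) stop("permutation test needs the dataset")
    ds <- drop_replicates(ds)
    set.seed(seed)
    labels <- ds$samples$population_id
    perm <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      sh <- sample(labels)
      k_b <- t(vapply(rownames(kmat), function(p)
        colSums(ds$bands[sh == p, , drop = FALSE] == 0L),
        numeric(ncol(ds$bands))))
      perm[b] <- mean(fst_per_locus(k_b, nvec, F), na.rm = TRUE)
    }
    pval <- perm_pvalue(obs, perm)
  }
  structure(list(fst = obs, sd_over_loci = stats::sd(per_locus, na.rm = TRUE),
                 p_value = pval, n_permutations = n_perm, F_is = F,
                 per_locus = per_locus),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> Fst = %.4f (SD over loci %.4f), F_is = %.4f\n",
              x$fst, x$sd_over_loci, x$F_is))
  if (is.finite(x$p_value))
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$p_value, x$n_permutations))
  invisible(x)
}

# AMOVA sums of squares from squared Euclidean distances among binary
# phenotypes (d^2 between two 0/1 rows = their Hamming distance).
amova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    ix <- which(groups == g)
    if (length(ix) > 1) {
      sub <- d2[ix, ix, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(ix)
    }
  }
  c(among = ss_total - ss_within, within = ss_within, total = ss_total)
}

phipt_once <- function(d2, groups) {
  n <- length(groups)
  k <- length(unique(groups))
  ss <- amova_ss(d2, groups)
  df_a <- k - 1
  df_w <- n - k
  ms_a <- ss["among"] / df_a
  ms_w <- ss["within"] / df_w
  sizes <- table(groups)
  n0 <- (n - sum(sizes^2) / n) / df_a
  var_w <- unname(ms_w)
  var_a <- unname((ms_a - ms_w) / n0)
  phi <- var_a / (var_a + var_w)
  list(ss = ss, df = c(among = df_a, within = df_w),
       ms = c(among = unname(ms_a), within = unname(ms_w)),
       var_components = c(among = var_a, within = var_w),
       n0 = n0, phi_pt = phi)
}

#' Phi-PT by AMOVA on binary phenotypes
#'
#' Analysis of molecular variance on the pairwise squared Euclidean
#' distances between band profiles, partitioning variance among and
#' within populations (or any grouping). Phi-PT is the among-group share
#' of the total variance; its significance comes from permuting
#' individuals among groups.
#'
#' @param ds A `dompop_dataset`.
#' @param grouping Optional character vector (one label per individual,
#'   in dataset row order); defaults to population membership.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @param pairwise If `TRUE`, additionally compute the matrix of pairwise
#'   population Phi-PT values and their p-values.
#' @return List of class `amova_result` with the AMOVA table entries,
#'   `phi_pt`, `p_value`, and optionally `pairwise_phi`, `pairwise_p`.
#' @export
phipt_amova <- function(ds, grouping = NULL, n_perm = 999, seed = 1,
                        pairwise = FALSE) {
  ds <- drop_replicates(ds)
  if (is.null(grouping)) grouping <- ds$samples$population_id
  stopifnot(length(grouping) == nrow(ds$bands))
  if (length(unique(grouping)) < 2) stop("need at least 2 groups")
  d2 <- hamming_rows(ds$bands)
  res <- phipt_once(d2, grouping)
  set.seed(seed)
  pval <- NA_real_
  if (n_perm > 0) {
    perm <- vapply(seq_len(n_perm), function(b)
      phipt_once(d2, sample(grouping))$phi_pt, numeric(1))
    pval <- perm_pvalue(res$phi_pt, perm)
  }
  out <- c(res, list(p_value = pval, n_permutations = n_perm))
  if (pairwise) {
    pops <- sort(unique(grouping))
    np <- length(pops)
    phi_m <- matrix(NA_real_, np, np, dimnames = list(pops, pops))
    p_m <- phi_m
    diag(phi_m) <- 0
    for (i in seq_len(np - 1)) for (j in (i + 1):np) {
      ix <- which(grouping %in% c(pops[i], pops[j]))
      if (min(table(grouping[ix])) == 1)
        warning("pairwise Phi-PT with a group of size 1: ",
                pops[i], " vs ", pops[j])
      sub <- d2[ix, ix, drop = FALSE]
      r <- phipt_once(sub, grouping[ix])
      phi_m[i, j] <- phi_m[j, i] <- r$phi_pt
      if (n_perm > 0) {
        perm <- vapply(seq_len(n_perm), function(b)
          phipt_once(sub, sample(grouping[ix]))$phi_pt, numeric(1))
        p_m[i, j] <- p_m[j, i] <- perm_pvalue(r$phi_pt, perm)
      }
    }
    out$pairwise_phi <- phi_m
    out$pairwise_p <- p_m
  }
  structure(out, class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  tab <- data.frame(df = x$df, SS = x$ss[c("among", "within")],
                    MS = x$ms, var = x$var_components)
  print(round(tab, 4))
  cat(sprintf("  Phi-PT = %.4f", x$phi_pt))
  if (is.finite(x$p_value))
    cat(sprintf(", permutation p = %.4g (%d permutations)", x$p_value,
                x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Nei's standard genetic distance between populations
#'
#' For each population pair, D = -ln( Jxy / sqrt(Jx Jy) ) with the
#' identities J averaged over loci on the two-allele frequencies
#' (q, 1 - q) estimated for dominant data.
#'
#' @param aft An `allele_freq_table`.
#' @return A `dist_matrix`: list with `d` (symmetric matrix, zero
#'   diagonal, `NA` where the between-population identity is
#'   non-positive) and `metric_name`.
#' @export
nei_distance_matrix <- function(aft) {
  q <- aft_qmat(aft)
  p <- 1 - q
  np <- nrow(q)
  d <- matrix(0, np, np, dimnames = list(rownames(q), rownames(q)))
  jx <- rowMeans(q^2 + p^2)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (i < j) {
      jxy <- mean(q[i, ] * q[j, ] + p[i, ] * p[j, ])
      if (jxy <= 0) {
        warning("non-positive between-population identity; distance set NA")
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- -log(jxy / sqrt(jx[i] * jx[j]))
      }
    }
  }
  structure(list(d = d, metric_name = "nei_1972"), class = "dist_matrix")
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: double-centred Gower matrix and
#' eigendecomposition, axes ordered by eigenvalue, percent variance from
#' the positive eigenvalues.
#'
#' @param dm A `dist_matrix` (see [nei_distance_matrix()]) or a symmetric
#'   matrix.
#' @param k Number of axes to keep (default all with positive eigenvalue).
#' @return List of class `pcoa_result` with `coords`, `eigenvalues`,
#'   `pct_variance`.
#' @export
pcoa <- function(dm, k = NULL) {
  d <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  if (anyNA(d))
    stop("distance matrix has NA entries; impute or remove those populations")
  n <- nrow(d)
  mds <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- mds$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  coords <- mds$points
  if (is.null(k)) k <- max(1, sum(pos[seq_len(ncol(coords))]))
  k <- min(k, ncol(coords))
  structure(list(coords = coords[, seq_len(k), drop = FALSE],
                 eigenvalues = eig,
                 pct_variance = 100 * pmax(eig, 0) / sum(pmax(eig, 0))),
            class = "pcoa_result")
}

#' Bootstrap neighbour-joining consensus tree over populations
#'
#' Loci are resampled with replacement; Nei distances and a
#' neighbour-joining tree are computed per replicate. The full-data NJ
#' tree is midpoint-rooted and annotated with percent bootstrap support
#' per internal node; a majority-rule consensus topology is returned
#' alongside.
#'
#' @param ds A `dompop_dataset` (replicates dropped internally).
#' @param F Inbreeding coefficient used for frequency estimation.
#' @param prior Prior choice for [estimate_allele_freqs()].
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return List of class `nj_consensus` with `tree` (midpoint-rooted
#'   `phylo` with support in `node.label`), `consensus` (majority-rule
#'   `phylo`), `newick` (the rooted annotated tree as a Newick string),
#'   and `n_dropped` replicates.
#' @export
nj_consensus <- function(ds, F, prior = "fitted", n_boot = 100, seed = 1) {
  ds <- drop_replicates(ds)
  if (nrow(ds$populations) < 4) stop("need at least 4 populations")
  set.seed(seed)
  aft <- estimate_allele_freqs(ds, F, prior)
  d_full <- nei_distance_matrix(aft)$d
  if (anyNA(d_full)) stop("NA distances on the full data")
  full <- ape::nj(stats::as.dist(d_full))
  loci <- colnames(ds$bands)
  boots <- list()
  n_dropped <- 0
  for (b in seq_len(n_boot)) {
    take <- sample(loci, length(loci), replace = TRUE)
    sub <- ds$bands[, take, drop = FALSE]
    colnames(sub) <- sprintf("B%04d", seq_along(take))
    ds_b <- ds
    ds_b$bands <- sub
    ds_b$locus_meta <- NULL
    aft_b <- estimate_allele_freqs(ds_b, F, prior)
    d_b <- suppressWarnings(nei_distance_matrix(aft_b)$d)
    if (anyNA(d_b)) {
      n_dropped <- n_dropped + 1
      next
    }
    boots[[length(boots) + 1]] <- ape::nj(stats::as.dist(d_b))
  }
  if (n_dropped > 0)
    message(n_dropped, " bootstrap replicate(s) dropped (NA distances)")
  support <- ape::prop.clades(full, boots, rooted = FALSE)
  support[is.na(support)] <- 0
  pct <- round(100 * support / length(boots))
  rooted <- phangorn::midpoint(full)
  # map support onto the rooted tree's splits
  rooted_support <- ape::prop.clades(rooted, boots, rooted = FALSE)
  rooted_support[is.na(rooted_support)] <- 0
  rooted$node.label <- round(100 * rooted_support / length(boots))
  cons <- ape::consensus(boots, p = 0.5)
  structure(list(tree = rooted, consensus = cons,
                 newick = ape::write.tree(rooted),
                 support = pct, n_boot = length(boots),
                 n_dropped = n_dropped),
            class = "nj_consensus")
}

#' @export
print.nj_consensus <- function(x, ...) {
  cat("<nj_consensus> ", length(x$tree$tip.label), " populations, ",
      x$n_boot, " bootstrap replicates", sep = "")
  if (x$n_dropped > 0) cat(" (", x$n_dropped, " dropped)", sep = "")
  cat("\n  ", substr(x$newick, 1, 70), "...\n", sep = "")
  invisible(x)
}

#' Great-circle distance matrix between population centroids
#'
#' @param ds A `dompop_dataset`.
#' @return Symmetric matrix of distances in km.
#' @export
pop_geo_distances <- function(ds) {
  p <- ds$populations
  np <- nrow(p)
  d <- matrix(0, np, np, dimnames = list(p$population_id, p$population_id))
  for (i in seq_len(np)) {
    d[i, ] <- gc_dist_km(p$lon[i], p$lat[i], p$lon, p$lat)
  }
  d[abs(d) < 1e-12] <- 0
  (d + t(d)) / 2
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between the off-diagonal entries of a genetic and
#' a geographic distance matrix; one-sided significance by permuting the
#' rows/columns of one matrix.
#'
#' @param genetic_dm,geographic_dm Square symmetric matrices (or
#'   `dist_matrix` objects) with matching labels.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List of class `mantel_result` with `r`, `p_value`,
#'   `n_permutations`.
#' @export
mantel_ibd <- function(genetic_dm, geographic_dm, n_perm = 999, seed = 1) {
  g <- if (inherits(genetic_dm, "dist_matrix")) genetic_dm$d else as.matrix(genetic_dm)
  e <- if (inherits(geographic_dm, "dist_matrix")) geographic_dm$d else as.matrix(geographic_dm)
  if (!is.null(rownames(g)) && !is.null(rownames(e))) {
    stopifnot(setequal(rownames(g), rownames(e)))
    e <- e[rownames(g), rownames(g)]
  }
  lt <- lower.tri(g)
  if (stats::sd(g[lt]) == 0 || stats::sd(e[lt]) == 0)
    stop("constant distance matrix: Mantel r undefined")
  r_obs <- stats::cor(g[lt], e[lt])
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) {
    ix <- sample(nrow(e))
    stats::cor(g[lt], e[ix, ix][lt])
  }, numeric(1))
  structure(list(r = r_obs, p_value = perm_pvalue(r_obs, perm),
                 n_permutations = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r = %.4f, one-sided p = %.4g (%d permutations)\n",
              x$r, x$p_value, x$n_permutations))
  invisible(x)
}
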