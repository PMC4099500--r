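#' Convert a selfing rate to the equilibrium inbreeding coefficient
#'
#' Under equilibrium partial self-fertilisation at rate `s`, the
#' inbreeding coefficient is F = s / (2 - s).
#'
#' @param s Selfing rate in [0, 1].
#' @return The inbreeding coefficient F in [0, 1].
#' @export
selfing_to_inbreeding <- function(s) {
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0) || any(s > 1))
    stop("selfing rate must lie in [0, 1]")
  s / (2 - s)
}

# Probability of the null (band-absent) phenotype given null-allele
# frequency q and inbreeding F: homozygote qq plus the inbreeding excess.
null_pheno_prob <- function(q, F) {
  q^2 + F * q * (1 - q)
}

# d P0 / d q, used for delta-method sampling variances of q_hat.
null_pheno_deriv <- function(q, F) {
  2 * q + F * (1 - 2 * q)
}

# Invert P0(q) = p0 for q in [0,1] at inbreeding F.
invert_null_pheno <- function(p0, F) {
  if (F >= 1 - 1e-12) return(p0)
  (-F + sqrt(F^2 + 4 * (1 - F) * p0)) / (2 * (1 - F))
}

# Gauss-Legendre nodes/weights on [0,1], cached per session.
.gl_cache <- new.env(parent = emptyenv())
gl_nodes <- function(n_nodes = 512) {
  key <- as.character(n_nodes)
  if (is.null(.gl_cache[[key]])) {
    gl <- pracma::gaussLegendre(n_nodes, 0, 1)
    .gl_cache[[key]] <- list(x = gl$x, w = gl$w)
  }
  .gl_cache[[key]]
}

#' Posterior mean of the null-allele frequency at one population-locus cell
#'
#' Model: the band-absent count is Binomial(n, P0(q)) with
#' P0(q) = q^2 + F q (1 - q); the prior on q is Beta(a, b). The posterior
#' mean is computed by deterministic Gauss-Legendre quadrature on [0, 1]
#' (512 nodes by default), computed on the log scale for stability.
#'
#' @param k Band-absent count (0..n).
#' @param n Sample size.
#' @param F Inbreeding coefficient in [0, 1].
#' @param a,b Beta prior parameters.
#' @param n_nodes Number of quadrature nodes.
#' @details The integral is computed in the prior-CDF variable
#'   u = pbeta(q; a, b), i.e. nodes q = qbeta(u; a, b), which absorbs the
#'   prior density exactly and keeps the rule accurate even for singular
#'   priors (a or b below 1).
#' @return The posterior mean E[q | k].
#' @export
posterior_mean_q <- function(k, n, F, a = 1, b = 1, n_nodes = 512) {
  stopifnot(k >= 0, k <= n, n >= 1)
  posterior_mean_q_all_k(n, F, a, b, n_nodes)[k + 1L]
}

# Posterior means for all k = 0..n at once (vectorised over quadrature grid).
posterior_mean_q_all_k <- function(n, F, a = 1, b = 1, n_nodes = 512) {
  gl <- gl_nodes(n_nodes)
  q <- stats::qbeta(gl$x, a, b)        # prior-CDF transform
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  p0 <- pmin(pmax(null_pheno_prob(q, F), 1e-300), 1 - 1e-16)
  lp0 <- log(p0)
  l1m <- log1p(-p0)
  ks <- 0:n
  # log binomial kernels: nodes x (n+1); the prior is absorbed in the nodes
  lw <- outer(lp0, ks) + outer(l1m, n - ks)
  lw <- sweep(lw, 2, apply(lw, 2, max))
  wm <- gl$w * exp(lw)
  colSums(wm * q) / colSums(wm)
}

# Cached lookup of posterior means keyed by (n, F, a, b).
.post_cache <- new.env(parent = emptyenv())
posterior_table <- function(n, F, a, b) {
  key <- paste(n, signif(F, 10), signif(a, 10), signif(b, 10), sep = "|")
  if (is.null(.post_cache[[key]]))
    .post_cache[[key]] <- posterior_mean_q_all_k(n, F, a, b)
  .post_cache[[key]]
}

# Method-of-moments Beta fit on the allele scale from observed null
# fractions, floored to avoid degenerate priors.
fit_beta_prior <- function(null_fracs, F, floor = 0.25) {
  qs <- invert_null_pheno(pmin(pmax(null_fracs, 0), 1), F)
  m <- mean(qs)
  v <- stats::var(qs)
  if (!is.finite(v) || v <= 0 || m <= 0 || m >= 1) return(c(a = 1, b = 1))
  common <- m * (1 - m) / v - 1
  if (!is.finite(common) || common <= 0) return(c(a = 1, b = 1))
  c(a = max(m * common, floor), b = max((1 - m) * common, floor))
}

# Counts of band-absent phenotypes per population x locus.
absence_counts <- function(ds) {
  pops <- ds$populations$population_id
  k <- do.call(rbind, lapply(pops, function(p) {
    rows <- ds$samples$population_id == p
    colSums(ds$bands[rows, , drop = FALSE] == 0L)
  }))
  rownames(k) <- pops
  k
}

#' Bayesian allele-frequency estimation for dominant markers
#'
#' Estimates the per-population null-allele frequency q at every locus
#' from band-absence counts, under inbreeding F, as the posterior mean of
#' a Beta-prior model with likelihood k ~ Binomial(n, q^2 + F q (1 - q)).
#' The non-uniform ("fitted") prior is a Beta whose parameters are set by
#' method of moments from the across-cells distribution of observed null
#' fractions mapped to the allele scale.
#'
#' @param ds A `dompop_dataset` (replicate copies are dropped internally).
#' @param F Inbreeding coefficient (see [selfing_to_inbreeding()]).
#' @param prior `"fitted"` (default) or `"uniform"`.
#' @return A data frame of class `allele_freq_table` with columns
#'   `population_id`, `locus_id`, `n`, `k_absent`, `q_hat` and `f_hat`
#'   (expected band frequency, 1 - P0(q_hat)); attributes `F`, `prior`,
#'   `prior_ab`.
#' @export
estimate_allele_freqs <- function(ds, F, prior = c("fitted", "uniform")) {
  prior <- match.arg(prior)
  ds <- drop_replicates(ds)
  if (nrow(ds$bands) == 0) stop("empty dataset")
  k <- absence_counts(ds)
  ns <- ds$populations$n
  if (any(ns == 0)) stop("population with n = 0")
  ab <- c(a = 1, b = 1)
  if (prior == "fitted")
    ab <- fit_beta_prior(as.vector(k / ns), F)
  q_hat <- matrix(0, nrow(k), ncol(k), dimnames = dimnames(k))
  for (i in seq_along(ns)) {
    tab <- posterior_table(ns[i], F, ab["a"], ab["b"])
    q_hat[i, ] <- tab[k[i, ] + 1L]
  }
  out <- data.frame(
    population_id = rep(ds$populations$population_id, times = ncol(k)),
    locus_id = rep(colnames(ds$bands), each = nrow(k)),
    n = rep(ns, times = ncol(k)),
    k_absent = as.vector(k),
    q_hat = as.vector(q_hat),
    stringsAsFactors = FALSE)
  out$f_hat <- 1 - null_pheno_prob(out$q_hat, F)
  attr(out, "F") <- F
  attr(out, "prior") <- prior
  attr(out, "prior_ab") <- ab
  class(out) <- c("allele_freq_table", "data.frame")
  out
}

# population x locus matrix of one allele_freq_table column
aft_mat <- function(aft, col = "q_hat") {
  pops <- unique(aft$population_id)
  loci <- unique(aft$locus_id)
  stopifnot(nrow(aft) == length(pops) * length(loci))
  ord <- order(match(aft$locus_id, loci), match(aft$population_id, pops))
  matrix(aft[[col]][ord], nrow = length(pops), ncol = length(loci),
         dimnames = list(pops, loci))
}

aft_qmat <- function(aft) aft_mat(aft, "q_hat")

# Draw-standardised subsample IDs: populations larger than max_n are
# subsampled to max_n; smaller ones kept whole.
standardised_draw <- function(ds, max_n) {
  members <- pop_members(ds)
  unlist(lapply(members, function(ids) {
    if (length(ids) > max_n) sample(ids, max_n) else ids
  }), use.names = FALSE)
}

#' Nei's gene diversity (Hj) with standardised sample sizes
#'
#' Hj per population is the mean over loci of 2 q (1 - q) at the
#' estimated null-allele frequencies. Populations larger than `max_n`
#' individuals are repeatedly subsampled to `max_n` and the statistic is
#' averaged over `n_draws` random draws.
#'
#' @param ds A `dompop_dataset`.
#' @param F Inbreeding coefficient.
#' @param prior Prior choice, as in [estimate_allele_freqs()].
#' @param max_n Standardised maximum sample size (default 8).
#' @param n_draws Number of subsample draws (default 20).
#' @param seed Integer seed controlling the draws.
#' @return Data frame with `population_id`, `n`, `n_used`, `Hj`.
#' @export
nei_gene_diversity <- function(ds, F, prior = "fitted", max_n = 8,
                               n_draws = 20, seed = 1) {
  ds <- drop_replicates(ds)
  set.seed(seed)
  pops <- ds$populations$population_id
  acc <- matrix(0, length(pops), n_draws, dimnames = list(pops, NULL))
  for (d in seq_len(n_draws)) {
    ids <- standardised_draw(ds, max_n)
    sub <- ds_subset(ds, individuals = ids)
    aft <- estimate_allele_freqs(sub, F, prior)
    q <- aft_qmat(aft)
    acc[rownames(q), d] <- rowMeans(2 * q * (1 - q))
  }
  data.frame(population_id = pops, n = ds$populations$n,
             n_used = pmin(ds$populations$n, max_n),
             Hj = rowMeans(acc), stringsAsFactors = FALSE)
}

#' Proportion of polymorphic loci at a frequency level
#'
#' The percentage of loci whose band frequency lies strictly inside
#' (level, 1 - level) in the population, computed on standardised
#' subsamples as for [nei_gene_diversity()].
#'
#' @inheritParams nei_gene_diversity
#' @param level Polymorphism level (default 0.05, the "5% level").
#' @return Data frame with `population_id`, `n`, `n_used`, `PPL` (percent).
#' @export
ppl <- function(ds, level = 0.05, max_n = 8, n_draws = 20, seed = 1) {
  ds <- drop_replicates(ds)
  set.seed(seed)
  pops <- ds$populations$population_id
  acc <- matrix(0, length(pops), n_draws, dimnames = list(pops, NULL))
  for (d in seq_len(n_draws)) {
    ids <- standardised_draw(ds, max_n)
    sub <- ds_subset(ds, individuals = ids)
    for (p in pops) {
      rows <- sub$samples$population_id == p
      f <- colMeans(sub$bands[rows, , drop = FALSE])
      acc[p, d] <- 100 * mean(f > level & f < 1 - level)
    }
  }
  data.frame(population_id = pops, n = ds$populations$n,
             n_used = pmin(ds$populations$n, max_n),
             PPL = rowMeans(acc), stringsAsFactors = FALSE)
}

#' Frequency-down-weighted rarity index (DW)
#'
#' For each population, the sum over loci of the population's band count
#' divided by the total band count in the dataset, normalised by the
#' number of individuals in the population. Populations carrying bands
#' that are globally rare but locally common score high.
#'
#' @param ds A `dompop_dataset`.
#' @return Data frame with `population_id`, `n`, `DW`.
#' @export
dw_rarity <- function(ds) {
  ds <- drop_replicates(ds)
  total <- colSums(ds$bands)
  use <- total > 0  # bands absent from the whole dataset carry no signal
  pops <- ds$populations$population_id
  dw <- vapply(pops, function(p) {
    rows <- ds$samples$population_id == p
    cnt <- colSums(ds$bands[rows, , drop = FALSE])
    sum(cnt[use] / total[use]) / sum(rows)
  }, numeric(1))
  data.frame(population_id = pops, n = ds$populations$n, DW = unname(dw),
             stringsAsFactors = FALSE)
}
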