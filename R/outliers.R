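#' Build pooled and pairwise comparison specifications
#'
#' Pooled comparisons contrast all dune against all fen populations
#' within each named geographic scale; pairwise comparisons cover every
#' population pair at one designated scale and are tagged `control` when
#' both populations share a habitat (dune-dune or fen-fen).
#'
#' @param ds A `dompop_dataset`.
#' @param scales Named list of population-ID vectors, one per geographic
#'   scale (e.g. `continental`, `landscape`, `regional_a`, `regional_b`).
#' @param pairwise_scale Name of the scale whose populations are also
#'   compared pairwise (default the first).
#' @return List of comparison specs (class `comparison_spec` each): name,
#'   `kind` (`pooled`/`pairwise`), `scale`, `pops_a`, `pops_b`,
#'   `habitat_a`, `habitat_b`, `control`.
#' @export
build_comparisons <- function(ds, scales, pairwise_scale = names(scales)[1]) {
  stopifnot(length(scales) >= 1, !is.null(names(scales)))
  pops <- ds$populations
  specs <- list()
  for (sc in names(scales)) {
    ids <- scales[[sc]]
    stopifnot(all(ids %in% pops$population_id))
    hab <- pops$habitat[match(ids, pops$population_id)]
    dunes <- ids[hab == "dune"]
    fens <- ids[hab == "fen"]
    if (length(dunes) == 0 || length(fens) == 0) {
      warning("scale '", sc, "' has a single habitat; pooled comparison skipped")
    } else {
      specs[[length(specs) + 1]] <- structure(
        list(name = paste0("pooled_", sc), kind = "pooled", scale = sc,
             pops_a = dunes, pops_b = fens, habitat_a = "dune",
             habitat_b = "fen", control = FALSE),
        class = "comparison_spec")
    }
  }
  ids <- scales[[pairwise_scale]]
  if (length(ids) >= 2) {
    cmb <- utils::combn(sort(ids), 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      ha <- pops$habitat[pops$population_id == a]
      hb <- pops$habitat[pops$population_id == b]
      specs[[length(specs) + 1]] <- structure(
        list(name = paste0("pair_", a, "_", b), kind = "pairwise",
             scale = pairwise_scale, pops_a = a, pops_b = b,
             habitat_a = ha, habitat_b = hb, control = (ha == hb)),
        class = "comparison_spec")
    }
  }
  specs
}

# Per-locus two-group Fst and expected heterozygosity for one comparison:
# individuals of each group pooled, null-allele frequencies estimated with
# a uniform prior, sampling-variance-corrected Fst as elsewhere.
comparison_fst <- function(ds, comparison, F) {
  ds <- drop_replicates(ds)
  ga <- ds$samples$population_id %in% comparison$pops_a
  gb <- ds$samples$population_id %in% comparison$pops_b
  na <- sum(ga); nb <- sum(gb)
  stopifnot(na > 0, nb > 0)
  ka <- colSums(ds$bands[ga, , drop = FALSE] == 0L)
  kb <- colSums(ds$bands[gb, , drop = FALSE] == 0L)
  ta <- posterior_table(na, F, 1, 1)
  tb <- posterior_table(nb, F, 1, 1)
  qmat <- rbind(ta[ka + 1L], tb[kb + 1L])
  fst <- fst_per_locus(rbind(ka, kb), c(na, nb), F)
  qbar <- colMeans(qmat)
  data.frame(locus_id = colnames(ds$bands), fst = fst,
             he = 2 * qbar * (1 - qbar),
             q_a = qmat[1, ], q_b = qmat[2, ],
             stringsAsFactors = FALSE)
}

#' Conditional neutral envelope for two-sample Fst given He
#'
#' Simulates dominant loci under an island-model null: ancestral
#' band-allele frequency drawn uniformly, group allele frequencies Beta
#' around it with spread set by a target Fst, individuals sampled with
#' inbreeding `F_is`, dominant phenotypes emitted, and the same
#' estimator applied as to the data. The target is calibrated
#' iteratively so the mean simulated Fst matches `mean_fst`. The result
#' binned by He yields empirical upper-tail probabilities.
#'
#' @param mean_fst Observed neutral mean Fst to match (in (0, 1)).
#' @param sample_sizes Integer vector `c(nA, nB)` of group sizes.
#' @param F_is Inbreeding coefficient.
#' @param n_sim Number of simulated loci (default 50000).
#' @param seed Integer seed.
#' @param n_bins Number of He bins (default 20); bins with fewer than
#'   `min_per_bin` loci are merged with a warning.
#' @param min_per_bin Minimum simulated loci per bin (default 200).
#' @return List of class `fst_envelope`: simulated `fst`/`he`, bin
#'   breaks, calibrated target, and `pvalue(fst, he)`, a vectorised
#'   function returning upper-tail probabilities; `quantile(prob, he)`
#'   returns envelope quantiles per He.
#' @export
envelope_null <- function(mean_fst, sample_sizes, F_is, n_sim = 50000,
                          seed = 1, n_bins = 20, min_per_bin = 200) {
  stopifnot(mean_fst > 0, mean_fst < 1, length(sample_sizes) == 2)
  set.seed(seed)
  tables <- lapply(sample_sizes, function(n) posterior_table(n, F_is, 1, 1))
  simulate_once <- function(fst_t) {
    conc <- 1 / fst_t - 1
    pbar <- stats::runif(n_sim, 0.02, 0.98)
    qmat <- matrix(0, 2, n_sim)
    kmat <- matrix(0L, 2, n_sim)
    for (g in 1:2) {
      pg <- stats::rbeta(n_sim, pbar * conc, (1 - pbar) * conc)
      pg <- pmin(pmax(pg, 1e-9), 1 - 1e-9)
      p0 <- null_pheno_prob(1 - pg, F_is)
      kmat[g, ] <- stats::rbinom(n_sim, sample_sizes[g], p0)
      qmat[g, ] <- tables[[g]][kmat[g, ] + 1L]
    }
    fst <- fst_per_locus(kmat, sample_sizes, F_is)
    qbar <- colMeans(qmat)
    list(fst = fst, he = 2 * qbar * (1 - qbar))
  }
  fst_t <- mean_fst
  sim <- NULL
  for (it in 1:4) {
    sim <- simulate_once(fst_t)
    m <- mean(sim$fst, na.rm = TRUE)
    if (m <= 0) m <- 1e-4
    fst_t <- min(max(fst_t * mean_fst / m, 1e-4), 0.99)
  }
  ok <- is.finite(sim$fst) & is.finite(sim$he)
  fst <- sim$fst[ok]; he <- sim$he[ok]
  breaks <- unique(stats::quantile(he, probs = seq(0, 1, length.out = n_bins + 1)))
  bin_of <- function(h) {
    b <- findInterval(h, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    b
  }
  bins <- bin_of(he)
  counts <- tabulate(bins, nbins = length(breaks) - 1)
  if (any(counts > 0 & counts < min_per_bin)) {
    warning("sparse He bins; widening to ", max(3, n_bins %/% 2), " bins")
    breaks <- unique(stats::quantile(he, probs = seq(0, 1, length.out = max(3, n_bins %/% 2) + 1)))
    bins <- bin_of(he)
  }
  by_bin <- split(fst, bins)
  by_bin <- lapply(by_bin, sort)
  pvalue <- function(fst_obs, he_obs) {
    b <- bin_of(he_obs)
    vapply(seq_along(fst_obs), function(i) {
      if (!is.finite(fst_obs[i])) return(NA_real_)
      v <- by_bin[[as.character(b[i])]]
      if (is.null(v)) v <- fst
      (1 + sum(v >= fst_obs[i])) / (length(v) + 1)
    }, numeric(1))
  }
  quant <- function(prob, he_obs) {
    b <- bin_of(he_obs)
    vapply(seq_along(he_obs), function(i) {
      v <- by_bin[[as.character(b[i])]]
      if (is.null(v)) v <- fst
      stats::quantile(v, prob, names = FALSE)
    }, numeric(1))
  }
  structure(list(fst = fst, he = he, breaks = breaks,
                 target_fst = fst_t, mean_fst = mean(fst),
                 pvalue = pvalue, quantile = quant),
            class = "fst_envelope")
}

#' Envelope-based outlier detection for one comparison
#'
#' Per-locus two-sample Fst values are compared with the He-conditional
#' neutral envelope. The neutral mean is estimated with a trimming loop:
#' an envelope is built at the raw mean Fst, provisional outliers
#' (p < 0.05) are removed, the mean is re-estimated and the envelope
#' rebuilt before final upper-tail probabilities are computed.
#' Benjamini-Hochberg control at `fdr` flags directional-selection
#' candidates (upper tail only).
#'
#' @param ds A `dompop_dataset`.
#' @param comparison A `comparison_spec`.
#' @param F Inbreeding coefficient.
#' @param fdr FDR level (default 0.05).
#' @param n_sim Simulated loci for the envelope (default 50000).
#' @param seed Integer seed.
#' @return Data frame of class `outlier_calls`: one row per locus with
#'   `comparison`, `detector = "envelope"`, `statistic` (Fst), `he`,
#'   `p`, `q`, `decision`.
#' @export
envelope_detect <- function(ds, comparison, F, fdr = 0.05, n_sim = 50000,
                            seed = 1) {
  obs <- comparison_fst(ds, comparison, F)
  sizes <- c(sum(ds$samples$population_id %in% comparison$pops_a &
                   is.na(ds$samples$replicate_of)),
             sum(ds$samples$population_id %in% comparison$pops_b &
                   is.na(ds$samples$replicate_of)))
  usable <- is.finite(obs$fst)
  m0 <- mean(obs$fst[usable])
  m0 <- max(m0, 1e-3)
  env <- envelope_null(m0, sizes, F, n_sim = n_sim, seed = seed)
  p0 <- env$pvalue(obs$fst, obs$he)
  keep <- usable & (is.na(p0) | p0 >= 0.05)
  m1 <- max(mean(obs$fst[keep], na.rm = TRUE), 1e-3)
  if (abs(m1 - m0) / m0 > 0.01) {
    env <- envelope_null(m1, sizes, F, n_sim = n_sim, seed = seed + 1)
    p0 <- env$pvalue(obs$fst, obs$he)
  }
  q <- rep(NA_real_, length(p0))
  q[!is.na(p0)] <- stats::p.adjust(p0[!is.na(p0)], "BH")
  out <- data.frame(comparison = comparison$name, locus_id = obs$locus_id,
                    detector = "envelope", statistic = obs$fst, he = obs$he,
                    p = p0, q = q,
                    decision = !is.na(q) & q <= fdr,
                    stringsAsFactors = FALSE)
  attr(out, "envelope") <- env
  class(out) <- c("outlier_calls", "data.frame")
  out
}

#' Spike-and-slab Bayesian outlier detection for one comparison
#'
#' A hierarchical beta model of group allele frequencies: for locus i and
#' group j, the estimated null-allele frequency follows
#' Beta(m_i * theta_ij, (1 - m_i) * theta_ij) with
#' logit(Fst_ij) = alpha_i * gamma_i + beta_j. The locus effect alpha_i
#' carries a spike-and-slab prior (inclusion probability
#' 1/(1 + prior_odds), slab Normal(0, 2)); beta_j absorbs genome-wide
#' differentiation. Metropolis-within-Gibbs sampling returns the
#' posterior inclusion probability per locus; "strong evidence" for
#' divergent (directional) selection is declared at posterior >= 0.91
#' with a positive locus effect.
#'
#' @param ds A `dompop_dataset`.
#' @param comparison A `comparison_spec`.
#' @param F Inbreeding coefficient.
#' @param mcmc List: `n_iter` (default 3000), `burn_in` (1000),
#'   `thin` (2), `prior_odds` (10).
#' @param seed Integer seed.
#' @param threshold Posterior inclusion threshold (default 0.91).
#' @return Data frame of class `outlier_calls` with `detector = "bayes"`,
#'   `statistic` (posterior inclusion probability), `alpha` (posterior
#'   mean locus effect), `decision`, and an `unreliable` flag where the
#'   split-chain Rhat of a flagged locus effect exceeds 1.1.
#' @export
bayes_detect <- function(ds, comparison, F,
                         mcmc = list(), seed = 1, threshold = 0.91) {
  mc <- utils::modifyList(list(n_iter = 3000, burn_in = 1000, thin = 2,
                               prior_odds = 10, flat_likelihood = FALSE), mcmc)
  obs <- comparison_fst(ds, comparison, F)
  qh <- pmin(pmax(rbind(obs$q_a, obs$q_b), 1e-4), 1 - 1e-4)
  sizes <- c(sum(ds$samples$population_id %in% comparison$pops_a &
                   is.na(ds$samples$replicate_of)),
             sum(ds$samples$population_id %in% comparison$pops_b &
                   is.na(ds$samples$replicate_of)))
  # delta-method sampling variance of each frequency estimate; the
  # sampler convolves it with the deme-level Beta variance so that
  # sampling noise does not masquerade as differentiation
  p0 <- null_pheno_prob(qh, F)
  dg <- pmax(null_pheno_deriv(qh, F), 1e-3)
  sv <- p0 * (1 - p0) / (sizes * dg^2)
  fit <- spike_slab_fst_mcmc(qh, sv = sv, n_iter = mc$n_iter,
                             burn_in = mc$burn_in,
                             thin = mc$thin, prior_odds = mc$prior_odds,
                             seed = seed, flat_likelihood = mc$flat_likelihood)
  incl <- fit$inclusion
  alpha <- fit$alpha_mean
  decision <- incl >= threshold & alpha > 0
  unreliable <- decision & fit$rhat > 1.1
  out <- data.frame(comparison = comparison$name, locus_id = obs$locus_id,
                    detector = "bayes", statistic = incl, he = obs$he,
                    alpha = alpha, decision = decision,
                    unreliable = unreliable, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit[c("beta_mean", "acceptance")]
  class(out) <- c("outlier_calls", "data.frame")
  out
}

# Metropolis-within-Gibbs sampler for the spike-and-slab Fst model.
# qh: groups x loci matrix of estimated frequencies in (0,1); sv: matching
# sampling variances of those estimates (0 = treat them as exact).
spike_slab_fst_mcmc <- function(qh, sv = 0 * qh, n_iter = 3000, burn_in = 1000,
                                thin = 2, prior_odds = 10, seed = 1,
                                slab_sd = 2, beta_prior = c(-1, 1.8),
                                flat_likelihood = FALSE) {
  set.seed(seed)
  J <- nrow(qh); L <- ncol(qh)
  pi_incl <- 1 / (1 + prior_odds)
  # state; theta is L x J with theta_ij = (1 - Fst)/Fst, logit(Fst) = alpha_i + beta_j
  m <- pmin(pmax(colMeans(qh), 0.02), 0.98)
  alpha <- rep(0, L)
  gamma <- rep(FALSE, L)
  beta <- rep(beta_prior[1], J)
  theta <- exp(-outer(alpha * gamma, beta, "+"))
  # Beta likelihood with the estimate's sampling variance convolved in by
  # moment matching: total variance = deme variance m(1-m)/(theta+1) plus
  # the sampling variance, re-expressed as an effective concentration.
  beta_ll_j <- function(m, theta_j, j) {
    mm <- m * (1 - m)
    vtot <- mm / (theta_j + 1) + sv[j, ]
    theta_eff <- pmax(mm / vtot - 1, 0.1)
    stats::dbeta(qh[j, ], m * theta_eff, (1 - m) * theta_eff, log = TRUE)
  }
  comp_ll <- function(m, theta) {
    if (flat_likelihood) return(rep(0, L))
    ll <- rep(0, L)
    for (j in 1:J)
      ll <- ll + beta_ll_j(m, theta[, j], j)
    ll
  }
  cur_ll <- comp_ll(m, theta)
  n_keep <- (n_iter - burn_in) %/% thin
  incl_sum <- rep(0, L)
  alpha_draws <- matrix(0, n_keep, L)
  beta_sum <- rep(0, J)
  acc <- c(m = 0, alpha = 0, toggle = 0, beta = 0)
  kept <- 0
  for (it in seq_len(n_iter)) {
    # m update (logit random walk, uniform prior with Jacobian)
    mp <- inv_logit(logit(m) + stats::rnorm(L, 0, 0.3))
    mp <- pmin(pmax(mp, 1e-6), 1 - 1e-6)
    ll_p <- comp_ll(mp, theta)
    lr <- ll_p - cur_ll + log(mp * (1 - mp)) - log(m * (1 - m))
    take <- log(stats::runif(L)) < lr
    m[take] <- mp[take]
    cur_ll[take] <- ll_p[take]
    acc["m"] <- acc["m"] + mean(take)
    # alpha random walk for included loci
    if (any(gamma)) {
      ap <- alpha
      ap[gamma] <- alpha[gamma] + stats::rnorm(sum(gamma), 0, 0.4)
      theta_p <- exp(-outer(ap * gamma, beta, "+"))
      ll_p <- comp_ll(m, theta_p)
      lr <- ll_p - cur_ll +
        stats::dnorm(ap, 0, slab_sd, log = TRUE) -
        stats::dnorm(alpha, 0, slab_sd, log = TRUE)
      lr[!gamma] <- -Inf
      take <- log(stats::runif(L)) < lr
      alpha[take] <- ap[take]
      theta[take, ] <- theta_p[take, , drop = FALSE]
      cur_ll[take] <- ll_p[take]
      if (any(gamma)) acc["alpha"] <- acc["alpha"] + mean(take[gamma])
    }
    # toggle gamma with independence proposal from the slab prior
    ap <- ifelse(gamma, 0, stats::rnorm(L, 0, slab_sd))
    gp <- !gamma
    theta_p <- exp(-outer(ap * gp, beta, "+"))
    ll_p <- comp_ll(m, theta_p)
    lr <- ll_p - cur_ll + ifelse(gp, log(pi_incl) - log(1 - pi_incl),
                                 log(1 - pi_incl) - log(pi_incl))
    take <- log(stats::runif(L)) < lr
    alpha[take] <- ap[take]
    gamma[take] <- gp[take]
    theta[take, ] <- theta_p[take, , drop = FALSE]
    cur_ll[take] <- ll_p[take]
    acc["toggle"] <- acc["toggle"] + mean(take)
    # beta updates (one at a time; likelihood over all loci)
    for (j in 1:J) {
      bp <- beta
      bp[j] <- beta[j] + stats::rnorm(1, 0, 0.15)
      theta_p <- theta
      theta_p[, j] <- exp(-(alpha * gamma + bp[j]))
      ll_pj <- if (flat_likelihood) rep(0, L) else beta_ll_j(m, theta_p[, j], j)
      ll_cj <- if (flat_likelihood) rep(0, L) else beta_ll_j(m, theta[, j], j)
      lr <- sum(ll_pj - ll_cj) +
        stats::dnorm(bp[j], beta_prior[1], beta_prior[2], log = TRUE) -
        stats::dnorm(beta[j], beta_prior[1], beta_prior[2], log = TRUE)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        beta <- bp
        theta <- theta_p
        cur_ll <- cur_ll + ll_pj - ll_cj
        acc["beta"] <- acc["beta"] + 1 / J
      }
    }
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1
      incl_sum <- incl_sum + gamma
      alpha_draws[kept, ] <- alpha * gamma
      beta_sum <- beta_sum + beta
    }
  }
  inclusion <- incl_sum / kept
  # split-chain Rhat on the effective locus effect
  half <- kept %/% 2
  rhat <- rep(1, L)
  if (half >= 10) {
    a1 <- alpha_draws[seq_len(half), , drop = FALSE]
    a2 <- alpha_draws[half + seq_len(half), , drop = FALSE]
    w <- (apply(a1, 2, stats::var) + apply(a2, 2, stats::var)) / 2
    bvar <- half * (colMeans(a1) - colMeans(a2))^2 / 2
    v <- (half - 1) / half * w + bvar / half
    rhat <- ifelse(w > 1e-12, sqrt(v / w), 1)
  }
  am <- colSums(alpha_draws) / pmax(incl_sum, 1)
  list(inclusion = inclusion, alpha_mean = am,
       beta_mean = beta_sum / kept, rhat = rhat,
       acceptance = acc / n_iter, n_kept = kept)
}

#' Run both detectors across a set of comparisons
#'
#' Pooled between-habitat comparisons are scanned by both the envelope
#' and the Bayesian detector; pairwise comparisons (including the
#' same-habitat controls) by the Bayesian detector only, mirroring the
#' multi-scale genome-scan design.
#'
#' @param ds A `dompop_dataset`.
#' @param comparisons List of `comparison_spec` from [build_comparisons()].
#' @param F Inbreeding coefficient.
#' @param fdr FDR level for the envelope detector.
#' @param n_sim Envelope simulation size.
#' @param mcmc MCMC settings for [bayes_detect()].
#' @param seed Integer master seed (per-comparison children derived).
#' @return A single `outlier_calls` data frame stacking all calls.
#' @export
run_outlier_scan <- function(ds, comparisons, F, fdr = 0.05, n_sim = 50000,
                             mcmc = list(), seed = 1) {
  seeds <- child_seeds(seed, 2 * length(comparisons))
  calls <- list()
  for (k in seq_along(comparisons)) {
    cmp <- comparisons[[k]]
    if (cmp$kind == "pooled") {
      calls[[length(calls) + 1]] <-
        envelope_detect(ds, cmp, F, fdr = fdr, n_sim = n_sim,
                        seed = seeds[2 * k - 1])
    }
    calls[[length(calls) + 1]] <-
      bayes_detect(ds, cmp, F, mcmc = mcmc, seed = seeds[2 * k])
  }
  out <- do.call(rbind, lapply(calls, function(x) {
    x$alpha <- if ("alpha" %in% names(x)) x$alpha else NA_real_
    x$p <- if ("p" %in% names(x)) x$p else NA_real_
    x$q <- if ("q" %in% names(x)) x$q else NA_real_
    x$unreliable <- if ("unreliable" %in% names(x)) x$unreliable else FALSE
    x[, c("comparison", "locus_id", "detector", "statistic", "he",
          "alpha", "p", "q", "decision", "unreliable")]
  }))
  class(out) <- c("outlier_calls", "data.frame")
  out
}

#' Consensus outlier decision across scales and detectors
#'
#' A locus is a significant outlier when (i) both detectors flag it in at
#' least one pooled between-habitat comparison, or (ii) the Bayesian
#' detector flags it in at least one between-habitat pairwise
#' comparison. A candidate is rejected when it is also flagged in any
#' same-habitat (control) comparison.
#'
#' @param calls An `outlier_calls` data frame (see [run_outlier_scan()]).
#' @param comparisons The comparison specs the calls were computed from.
#' @return List of class `consensus_result`: `significant` (data frame
#'   locus / supporting comparisons), `rejected` (locus / disqualifying
#'   control comparison), `candidates` (pre-control candidates).
#' @export
consensus_outliers <- function(calls, comparisons) {
  info <- do.call(rbind, lapply(comparisons, function(cmp)
    data.frame(comparison = cmp$name, kind = cmp$kind,
               control = cmp$control, stringsAsFactors = FALSE)))
  x <- merge(as.data.frame(calls), info, by = "comparison")
  flagged <- x[x$decision, , drop = FALSE]
  # (i) both detectors in one pooled between-habitat comparison
  pooled <- flagged[flagged$kind == "pooled" & !flagged$control, , drop = FALSE]
  cand_pooled <- if (nrow(pooled) > 0) {
    both <- stats::aggregate(detector ~ comparison + locus_id, data = pooled,
                             FUN = function(d) length(unique(d)))
    unique(both[both$detector >= 2, c("locus_id", "comparison")])
  } else {
    data.frame(locus_id = character(0), comparison = character(0))
  }
  # (ii) bayes in one between-habitat pairwise comparison
  pw <- flagged[flagged$kind == "pairwise" & !flagged$control &
                  flagged$detector == "bayes", c("locus_id", "comparison"),
                drop = FALSE]
  cand <- unique(rbind(cand_pooled, pw))
  # control rejection: flagged by any detector in any control comparison
  ctrl <- flagged[flagged$control, c("locus_id", "comparison"), drop = FALSE]
  rejected <- unique(ctrl[ctrl$locus_id %in% cand$locus_id, , drop = FALSE])
  names(rejected)[2] <- "control_comparison"
  sig_loci <- setdiff(unique(cand$locus_id), rejected$locus_id)
  significant <- if (length(sig_loci) > 0)
    do.call(rbind, lapply(sig_loci, function(l)
      data.frame(locus_id = l,
                 support = paste(sort(cand$comparison[cand$locus_id == l]),
                                 collapse = ";"),
                 stringsAsFactors = FALSE)))
  else data.frame(locus_id = character(0), support = character(0))
  structure(list(significant = significant, rejected = rejected,
                 candidates = cand),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> ", nrow(x$significant), " significant outlier(s)",
      sep = "")
  if (nrow(x$rejected) > 0)
    cat("; ", length(unique(x$rejected$locus_id)),
        " candidate(s) rejected by control comparisons", sep = "")
  cat("\n")
  if (nrow(x$significant) > 0) print(x$significant)
  invisible(x)
}

#' Replicated outliers across statistically independent comparisons
#'
#' A significant outlier is replicated when it is supported by two
#' between-habitat pairwise comparisons that share no population —
#' evidence for parallel divergence rather than a single divergent pair.
#'
#' @param cr A `consensus_result`.
#' @param comparisons The comparison specs.
#' @return Data frame with `locus_id` and the independent comparison pair.
#' @export
replicated_outliers <- function(cr, comparisons) {
  byname <- stats::setNames(comparisons, vapply(comparisons, `[[`, "", "name"))
  out <- list()
  for (i in seq_len(nrow(cr$significant))) {
    locus <- cr$significant$locus_id[i]
    supp <- strsplit(cr$significant$support[i], ";")[[1]]
    supp <- supp[vapply(supp, function(s)
      byname[[s]]$kind == "pairwise" && !byname[[s]]$control, logical(1))]
    if (length(supp) < 2) next
    found <- NULL
    for (a in seq_along(supp)) for (b in seq_along(supp)) {
      if (a < b) {
        pa <- c(byname[[supp[a]]]$pops_a, byname[[supp[a]]]$pops_b)
        pb <- c(byname[[supp[b]]]$pops_a, byname[[supp[b]]]$pops_b)
        if (length(intersect(pa, pb)) == 0) {
          found <- c(supp[a], supp[b])
          break
        }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found))
      out[[length(out) + 1]] <- data.frame(locus_id = locus,
                                           comparison_1 = found[1],
                                           comparison_2 = found[2],
                                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(locus_id = character(0), comparison_1 = character(0),
                      comparison_2 = character(0)))
  do.call(rbind, out)
}
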