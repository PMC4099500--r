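#' Per-population band frequencies with zero correction
#'
#' Band frequencies per population and locus, with frequencies of exactly
#' 0 replaced by c/(n+1) and of exactly 1 by 1 - c/(n+1) so that every
#' genotype keeps a finite log-likelihood. The likelihood machinery is
#' driven directly by these band frequencies.
#'
#' @param ds A `dompop_dataset` (replicates dropped internally).
#' @param zero_correction The constant c (default 1).
#' @return List of class `band_freq_table`: `f` (populations x loci
#'   corrected frequency matrix), `counts` (band counts), `n` (per
#'   population), `zero_correction`.
#' @export
band_frequencies <- function(ds, zero_correction = 1) {
  ds <- drop_replicates(ds)
  pops <- ds$populations$population_id
  counts <- do.call(rbind, lapply(pops, function(p) {
    colSums(ds$bands[ds$samples$population_id == p, , drop = FALSE])
  }))
  rownames(counts) <- pops
  n <- ds$populations$n
  f <- correct_freq(counts, n, zero_correction)
  structure(list(f = f, counts = counts, n = stats::setNames(n, pops),
                 zero_correction = zero_correction),
            class = "band_freq_table")
}

# Apply the c/(n+1) boundary correction to count/n frequencies.
correct_freq <- function(counts, n, c0) {
  f <- counts / n
  lo <- c0 / (n + 1)
  f <- pmax(f, matrix(lo, nrow(f), ncol(f)))
  f <- pmin(f, matrix(1 - lo, nrow(f), ncol(f)))
  if (any(f <= 0 | f >= 1)) stop("corrected frequency outside (0, 1)")
  f
}

# Leave-one-out frequency row for individual i against its home
# population: i's bands are removed before computing (and correcting)
# the home frequencies.
loo_freq_row <- function(bft, ds, individual) {
  home <- ds$samples$population_id[ds$samples$individual_id == individual]
  n <- bft$n[home]
  if (n <= 1) return(NULL)  # a singleton home leaves no data to score against
  cnt <- bft$counts[home, ] - ds$bands[individual, ]
  out <- correct_freq(matrix(cnt, 1), n - 1, bft$zero_correction)[1, ]
  stats::setNames(out, colnames(bft$f))
}

#' Log10-likelihood of a genotype in each candidate population
#'
#' LL(pop) = sum over loci of x * log10 f + (1 - x) * log10(1 - f),
#' treating loci as independent given the population's band frequencies.
#'
#' @param genotype Binary vector (length = number of loci).
#' @param f Populations x loci matrix of corrected band frequencies.
#' @return Named vector of log10-likelihoods per population.
#' @export
allocation_loglik <- function(genotype, f) {
  if (length(genotype) != ncol(f)) stop("genotype length != locus count")
  if (any(f <= 0 | f >= 1)) stop("frequencies must lie strictly in (0, 1)")
  drop(log10(f) %*% genotype + log10(1 - f) %*% (1 - genotype))
}

# log10-likelihood matrix of many genotypes (rows) against populations.
loglik_matrix <- function(genotypes, f) {
  genotypes %*% t(log10(f)) + (1 - genotypes) %*% t(log10(1 - f))
}

#' Likelihood allocation of every individual to its most likely source
#'
#' Each individual is scored against every candidate population by band
#' frequencies; the home population uses leave-one-out frequencies so an
#' individual never informs the frequencies it is scored against. The
#' individual is allocated to the best population when the log10 margin
#' over the runner-up reaches `mld` ("ten times more likely" at mld = 1);
#' an exact tie (margin 0 between distinct populations) leaves it
#' unallocated. Exclusion p-values per population compare the observed
#' likelihood with those of `n_rand` genotypes simulated from that
#' population's frequencies; an individual below `alpha_exclude`
#' everywhere is declared of unsampled origin ("excluded").
#'
#' @param ds A `dompop_dataset`.
#' @param mld Minimum log10-likelihood difference (default 1).
#' @param zero_correction Boundary correction constant (default 1).
#' @param alpha_exclude Exclusion threshold (default 0.001).
#' @param n_rand Simulated genotypes per population for the exclusion
#'   test (default 1000); 0 disables exclusion.
#' @param seed Integer seed.
#' @return Data frame of class `allocation_table` with per-individual
#'   home, best and second-best population, `margin`, `status`
#'   (`allocated`/`unallocated`/`excluded`), `source` (when allocated)
#'   and minimum exclusion p; the full log-likelihood and exclusion-p
#'   matrices ride along as attributes.
#' @export
allocate <- function(ds, mld = 1, zero_correction = 1, alpha_exclude = 0.001,
                     n_rand = 1000, seed = 1) {
  stopifnot(mld >= 0)
  ds <- drop_replicates(ds)
  set.seed(seed)
  bft <- band_frequencies(ds, zero_correction)
  pops <- rownames(bft$f)
  ids <- ds$samples$individual_id
  ll <- loglik_matrix(ds$bands, bft$f)
  rownames(ll) <- ids
  # leave-one-out home column
  for (i in seq_along(ids)) {
    home <- ds$samples$population_id[i]
    f_loo <- loo_freq_row(bft, ds, ids[i])
    ll[i, home] <- if (is.null(f_loo)) NA_real_ else
      sum(ds$bands[i, ] * log10(f_loo) + (1 - ds$bands[i, ]) * log10(1 - f_loo))
  }
  # null likelihood distributions per population for exclusion p-values
  pmat <- matrix(NA_real_, length(ids), length(pops),
                 dimnames = list(ids, pops))
  if (n_rand > 0) {
    for (j in seq_along(pops)) {
      fj <- bft$f[j, ]
      sim <- matrix(stats::rbinom(n_rand * length(fj), 1, rep(fj, each = n_rand)),
                    n_rand, length(fj))
      ll_sim <- drop(sim %*% log10(fj) + (1 - sim) %*% log10(1 - fj))
      lsort <- sort(ll_sim)
      cnt <- findInterval(ll[, j], lsort)
      pmat[, j] <- cnt / n_rand
    }
  }
  out <- data.frame(individual_id = ids,
                    home = ds$samples$population_id,
                    best = NA_character_, second = NA_character_,
                    margin = NA_real_, status = NA_character_,
                    source = NA_character_, p_max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    lli <- ll[i, ]
    cand <- which(!is.na(lli))
    ord <- cand[order(lli[cand], decreasing = TRUE)]
    tied <- length(ord) > 1 && lli[ord[1]] == lli[ord[2]]
    out$best[i] <- pops[ord[1]]
    out$second[i] <- if (length(ord) > 1) pops[ord[2]] else NA_character_
    out$margin[i] <- if (length(ord) > 1) lli[ord[1]] - lli[ord[2]] else Inf
    out$p_max[i] <- if (n_rand > 0) max(pmat[i, cand]) else NA_real_
    excluded <- n_rand > 0 && all(pmat[i, cand] < alpha_exclude)
    if (excluded) {
      out$status[i] <- "excluded"
    } else if (out$margin[i] >= mld && !tied) {
      out$status[i] <- "allocated"
      out$source[i] <- out$best[i]
    } else {
      out$status[i] <- "unallocated"
    }
  }
  attr(out, "loglik") <- ll
  attr(out, "exclusion_p") <- pmat
  attr(out, "mld") <- mld
  attr(out, "alpha_exclude") <- alpha_exclude
  class(out) <- c("allocation_table", "data.frame")
  out
}

#' Assignment power by simulated genotypes
#'
#' For each population, `n_sim` genotypes are simulated locus-wise
#' Bernoulli from its observed (corrected) band frequencies and
#' re-assigned against all candidate populations. Rates of correct
#' allocation, wrong allocation and non-allocation are averaged over
#' populations and `n_iter` repetitions, at every requested stringency
#' level.
#'
#' @param ds A `dompop_dataset`.
#' @param mlds Stringency levels (default `0:3`).
#' @param n_sim Genotypes per population per iteration (default 1000).
#' @param n_iter Repetitions (default 10).
#' @param zero_correction Boundary correction constant.
#' @param seed Integer seed.
#' @return Data frame of class `power_report` with one row per MLD:
#'   `correct`, `wrong`, `unallocated`, `failure` (wrong + unallocated);
#'   attribute `failure_increase` holds failure(max MLD) - failure(MLD 0).
#' @export
power_simulation <- function(ds, mlds = 0:3, n_sim = 1000, n_iter = 10,
                             zero_correction = 1, seed = 1) {
  ds <- drop_replicates(ds)
  set.seed(seed)
  bft <- band_frequencies(ds, zero_correction)
  pops <- rownames(bft$f)
  L <- ncol(bft$f)
  lf <- t(log10(bft$f))
  l1f <- t(log10(1 - bft$f))
  acc <- array(0, dim = c(length(mlds), 3, length(pops), n_iter))
  for (it in seq_len(n_iter)) {
    for (j in seq_along(pops)) {
      fj <- bft$f[j, ]
      sim <- matrix(stats::rbinom(n_sim * L, 1, rep(fj, each = n_sim)), n_sim, L)
      ll <- sim %*% lf + (1 - sim) %*% l1f
      top <- max.col(ll, ties.method = "first")
      best <- ll[cbind(seq_len(n_sim), top)]
      ll[cbind(seq_len(n_sim), top)] <- -Inf
      second <- apply(ll, 1, max)
      margin <- best - second
      for (m in seq_along(mlds)) {
        assigned <- margin >= mlds[m] & margin > 0
        correct <- assigned & (top == j)
        wrong <- assigned & (top != j)
        acc[m, , j, it] <- c(mean(correct), mean(wrong), mean(!assigned))
      }
    }
  }
  rates <- apply(acc, c(1, 2), mean)
  out <- data.frame(mld = mlds, correct = rates[, 1], wrong = rates[, 2],
                    unallocated = rates[, 3])
  out$failure <- out$wrong + out$unallocated
  attr(out, "failure_increase") <- out$failure[nrow(out)] - out$failure[1]
  attr(out, "per_population") <- apply(acc, c(1, 2, 3), mean)
  class(out) <- c("power_report", "data.frame")
  out
}

#' @export
print.power_report <- function(x, ...) {
  cat("<power_report>\n")
  print(round(as.data.frame(x), 4))
  cat(sprintf("  failure-rate increase MLD %d -> %d: %+.1f%%\n",
              x$mld[1], x$mld[nrow(x)], 100 * attr(x, "failure_increase")))
  invisible(x)
}

#' Effective long-distance dispersal bounds from an allocation table
#'
#' Putative immigrants are allocated individuals whose assigned source
#' differs from the population they were sampled in. Because a single
#' founder can seed a population, the number of distinct ordered
#' source-destination combinations (plus the individuals excluded from
#' all candidates, i.e. of unsampled origin) forms the lower bound on the
#' migration rate; the proportion of immigrant individuals (plus
#' excluded) among all unambiguously assigned individuals forms the upper
#' bound. Distances are great-circle between population centroids;
#' directions are initial bearings binned into eight 45-degree sectors.
#'
#' @param at An `allocation_table` from [allocate()].
#' @param ds The matching `dompop_dataset`.
#' @return List of class `ldd_estimate`: counts, bounds (percent, one
#'   decimal by round-half-even), `events` (immigrant list with km and
#'   sector), distance summaries, modal direction sector(s).
#' @export
ldd_estimate <- function(at, ds) {
  ds <- drop_replicates(ds)
  alloc <- at$status == "allocated"
  excl <- at$status == "excluded"
  n_total <- sum(alloc) + sum(excl)
  if (n_total == 0) stop("no allocated individuals")
  imm <- alloc & at$source != at$home
  events <- at[imm, c("individual_id", "source", "home"), drop = FALSE]
  names(events)[3] <- "destination"
  p <- ds$populations
  if (nrow(events) > 0) {
    si <- match(events$source, p$population_id)
    di <- match(events$destination, p$population_id)
    events$distance_km <- gc_dist_km(p$lon[si], p$lat[si], p$lon[di], p$lat[di])
    events$bearing <- gc_bearing(p$lon[si], p$lat[si], p$lon[di], p$lat[di])
    events$sector <- compass_sector(events$bearing)
  } else {
    events$distance_km <- numeric(0)
    events$bearing <- numeric(0)
    events$sector <- factor(character(0),
                            levels = levels(compass_sector(0)))
  }
  pairs <- unique(events[, c("source", "destination")])
  lower <- 100 * (nrow(pairs) + sum(excl)) / n_total
  upper <- 100 * (nrow(events) + sum(excl)) / n_total
  pair_sectors <- if (nrow(pairs) > 0) {
    si <- match(pairs$source, p$population_id)
    di <- match(pairs$destination, p$population_id)
    compass_sector(gc_bearing(p$lon[si], p$lat[si], p$lon[di], p$lat[di]))
  } else events$sector
  sec_tab <- table(pair_sectors)
  modal <- names(sec_tab)[sec_tab == max(sec_tab) & sec_tab > 0]
  structure(list(n_allocated = n_total, n_immigrants = nrow(events),
                 n_distinct_pairs = nrow(pairs), n_excluded = sum(excl),
                 lower_bound_pct = round(lower, 1),
                 upper_bound_pct = round(upper, 1),
                 events = events,
                 median_distance_km = if (nrow(events) > 0)
                   stats::median(events$distance_km) else NA_real_,
                 range_distance_km = if (nrow(events) > 0)
                   range(events$distance_km) else c(NA_real_, NA_real_),
                 modal_sectors = modal),
            class = "ldd_estimate")
}

#' @export
print.ldd_estimate <- function(x, ...) {
  cat("<ldd_estimate>\n")
  cat(sprintf("  %d assigned (%d immigrants in %d distinct source-destination pairs, %d of unsampled origin)\n",
              x$n_allocated, x$n_immigrants, x$n_distinct_pairs, x$n_excluded))
  cat(sprintf("  migration rate between %.1f%% and %.1f%%\n",
              x$lower_bound_pct, x$upper_bound_pct))
  if (x$n_immigrants > 0)
    cat(sprintf("  distances: median %.1f km (range %.1f-%.1f); main direction(s): %s\n",
                x$median_distance_km, x$range_distance_km[1],
                x$range_distance_km[2], paste(x$modal_sectors, collapse = ", ")))
  invisible(x)
}

#' Sensitivity of assignments to candidate populations and locus subsets
#'
#' Repeats the allocation under alternative scenarios (subsets of
#' candidate source populations and/or loci) and counts how many shared
#' individuals change their assignment relative to the first (baseline)
#' scenario.
#'
#' @param ds A `dompop_dataset`.
#' @param scenarios Named list; each element is a list with optional
#'   `populations` (candidate population IDs; individuals of other
#'   populations are dropped) and `loci` (locus IDs).
#' @param ... Passed to [allocate()].
#' @return List of class `sensitivity_report`: `allocations` (one table
#'   per scenario) and `changes` (data frame of scenario, n shared,
#'   n changed, pct changed vs baseline).
#' @export
sensitivity_reallocation <- function(ds, scenarios, ...) {
  stopifnot(length(scenarios) >= 2)
  ds <- drop_replicates(ds)
  tabs <- lapply(scenarios, function(sc) {
    d <- ds
    if (!is.null(sc$populations)) {
      keep <- d$samples$individual_id[d$samples$population_id %in% sc$populations]
      d <- ds_subset(d, individuals = keep)
    }
    if (!is.null(sc$loci)) d <- ds_subset(d, loci = sc$loci)
    allocate(d, ...)
  })
  base <- tabs[[1]]
  changes <- do.call(rbind, lapply(seq_along(tabs), function(k) {
    tb <- tabs[[k]]
    shared <- intersect(base$individual_id, tb$individual_id)
    b <- base[match(shared, base$individual_id), ]
    t2 <- tb[match(shared, tb$individual_id), ]
    same <- (b$status == t2$status) &
      (is.na(b$source) == is.na(t2$source)) &
      (is.na(b$source) | is.na(t2$source) |
         b$source == t2$source)
    data.frame(scenario = names(scenarios)[k], n_shared = length(shared),
               n_changed = sum(!same),
               pct_changed = round(100 * mean(!same), 1),
               stringsAsFactors = FALSE)
  }))
  structure(list(allocations = tabs, changes = changes),
            class = "sensitivity_report")
}
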