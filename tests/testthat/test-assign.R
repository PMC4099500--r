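test_that("band frequencies apply the c/(n+1) boundary correction", {
  m <- rbind(a = c(1, 0, 1), b = c(1, 0, 0), c = c(0, 0, 1), d = c(0, 0, 0))
  colnames(m) <- c("L1", "L2", "L3")
  ds <- dataset_from_matrix(m, pops = rep("A", 4))
  bft <- band_frequencies(ds)
  expect_equal(unname(bft$f["A", "L1"]), 0.5)       # 2 of 4
  expect_equal(unname(bft$f["A", "L2"]), 1 / 5)     # 0 of 4 -> c/(n+1)
  m2 <- rbind(a = c(1), b = c(1), c = c(1), d = c(1))
  colnames(m2) <- "L1"
  bft2 <- band_frequencies(dataset_from_matrix(m2, rep("A", 4)))
  expect_equal(unname(bft2$f["A", "L1"]), 1 - 1 / 5)
})

test_that("leave-one-out removes the focal individual before correcting", {
  # pop of 3 with one band copy held by the focal individual
  m <- rbind(x = c(1, 0), y = c(0, 1), z = c(0, 1))
  colnames(m) <- c("L1", "L2")
  ds <- dataset_from_matrix(m, pops = rep("A", 3))
  bft <- band_frequencies(ds)
  f_loo <- dompop:::loo_freq_row(bft, ds, "x")
  expect_equal(unname(f_loo["L1"]), 1 / 3)   # 0 of 2 -> corrected zero c/(n'+1)
  expect_equal(unname(f_loo["L2"]), 1 - 1 / 3)  # 2 of 2 -> corrected one
  # singleton home population leaves nothing to score against
  ds1 <- dataset_from_matrix(m, pops = c("A", "B", "B"))
  bft1 <- band_frequencies(ds1)
  expect_null(dompop:::loo_freq_row(bft1, ds1, "x"))
})

test_that("allocation log-likelihood matches closed forms and a hand toy", {
  f <- matrix(0.5, 2, 6, dimnames = list(c("A", "B"), paste0("L", 1:6)))
  g <- c(1, 0, 1, 1, 0, 0)
  ll <- allocation_loglik(g, f)
  expect_equal(unname(ll), rep(6 * log10(0.5), 2))
  # hand-set frequencies, 2 pops x 3 loci
  f2 <- rbind(A = c(0.8, 0.3, 0.6), B = c(0.2, 0.5, 0.9))
  colnames(f2) <- paste0("L", 1:3)
  g2 <- c(1, 0, 1)
  expect_equal(unname(allocation_loglik(g2, f2)),
               c(log10(0.8) + log10(0.7) + log10(0.6),
                 log10(0.2) + log10(0.5) + log10(0.9)), tolerance = 1e-12)
  expect_error(allocation_loglik(c(1, 0), f2), "length")
  expect_error(allocation_loglik(g2, f2 * 2), "strictly")
})

test_that("strong differentiation allocates home with wide margins; ties unallocate", {
  sim <- simulate_metapopulation(sim_params(n_pops = 4, sizes = rep(20, 4),
                                            n_loci = 250, fst = 0.25, seed = 51))
  at <- allocate(sim$dataset, mld = 1, n_rand = 0, seed = 1)
  expect_gt(mean(at$status == "allocated" & at$source == at$home), 0.9)
  expect_gt(median(at$margin), 3)
  # two identical candidate populations tie at margin 0 for an outsider
  set.seed(9)
  prof <- rbinom(30, 1, 0.5)
  m <- rbind(t(replicate(4, prof)),
             B1 = prof, B2 = prof, B3 = prof, C1 = prof, C2 = prof, C3 = prof)
  rownames(m) <- c(paste0("A", 1:4), paste0("B", 1:3), paste0("C", 1:3))
  colnames(m) <- paste0("L", 1:30)
  m[1:3, 1:12] <- 1 - m[1:3, 1:12]  # make most of A distinct; A4 matches prof
  ds <- dataset_from_matrix(m, pops = c(rep("A", 4), rep("B", 3), rep("C", 3)))
  at2 <- allocate(ds, mld = 0, n_rand = 0, seed = 2)
  a4 <- at2[at2$individual_id == "A4", ]
  # A4's profile matches B and C exactly; the two identical candidates tie
  expect_true(all(sort(c(a4$best, a4$second)) == c("B", "C")))
  expect_equal(a4$margin, 0)
  expect_equal(a4$status, "unallocated")
})

test_that("an alien genotype is excluded everywhere", {
  set.seed(61)
  L <- 120
  m <- matrix(rbinom(40 * L, 1, 0.9), 40, L)
  m <- rbind(m, alien = rep(0L, L))
  rownames(m) <- c(sprintf("i%02d", 1:40), "alien")
  colnames(m) <- sprintf("L%03d", 1:L)
  ds <- dataset_from_matrix(m, pops = c(rep(c("A", "B"), each = 20), "A"))
  at <- allocate(ds, mld = 1, n_rand = 1000, seed = 3)
  expect_equal(at$status[at$individual_id == "alien"], "excluded")
  expect_lt(at$p_max[at$individual_id == "alien"], 0.001)
  # ordinary members are not excluded
  expect_lt(mean(at$status == "excluded"), 0.1)
})

test_that("exclusion p-values are uniform for genotypes truly from a population", {
  sim <- simulate_metapopulation(sim_params(n_pops = 3, sizes = rep(30, 3),
                                            n_loci = 120, fst = 0.15, seed = 4))
  bft <- band_frequencies(sim$dataset)
  f1 <- bft$f[1, ]
  set.seed(8)
  g <- matrix(rbinom(300 * 120, 1, rep(f1, each = 300)), 300, 120)
  ll <- drop(g %*% log10(f1) + (1 - g) %*% log10(1 - f1))
  sim2 <- matrix(rbinom(2000 * 120, 1, rep(f1, each = 2000)), 2000, 120)
  lls <- drop(sim2 %*% log10(f1) + (1 - sim2) %*% log10(1 - f1))
  pv <- vapply(ll, function(x) mean(lls <= x), numeric(1))
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("power report rates sum to one, behave monotonely, and separate indistinct pops", {
  set.seed(2)
  f <- runif(100, 0.1, 0.9)
  m <- matrix(rbinom(60 * 100, 1, rep(f, each = 60)), 60, 100,
              dimnames = list(sprintf("i%02d", 1:60), sprintf("L%03d", 1:100)))
  ds <- dataset_from_matrix(m, pops = rep(c("A", "B"), each = 30))
  pr <- power_simulation(ds, n_sim = 300, n_iter = 3, seed = 3)
  expect_equal(pr$correct + pr$wrong + pr$unallocated, rep(1, 4),
               tolerance = 1e-12)
  expect_true(all(diff(pr$unallocated) >= 0))
  expect_true(all(diff(pr$wrong) <= 1e-12))
  expect_gt(pr$unallocated[pr$mld == 3], 0.8)  # indistinguishable populations
  # well-separated populations: high correct allocation at MLD 1
  sim <- simulate_metapopulation(sim_params(n_pops = 4, sizes = rep(25, 4),
                                            n_loci = 200, fst = 0.25, seed = 6))
  pr2 <- power_simulation(sim$dataset, n_sim = 300, n_iter = 2, seed = 7)
  expect_gte(pr2$correct[pr2$mld == 1], 0.95)
})

test_that("LDD bounds reproduce the printed-count reconstruction and trivial cases", {
  # 92 assigned in total: 66 home, 24 immigrants in 12 ordered pairs, 2 excluded
  pops <- sprintf("P%02d", 1:14)
  home <- c(rep("P01", 40), rep("P02", 26), rep(sprintf("P%02d", 3:14), each = 2),
            rep("P01", 2))
  source <- c(rep("P01", 40), rep("P02", 26),
              rep(sprintf("P%02d", c(4:14, 3)), each = 2), rep(NA, 2))
  status <- c(rep("allocated", 90), rep("excluded", 2))
  at <- data.frame(individual_id = sprintf("x%03d", seq_along(home)),
                   home = home, best = ifelse(is.na(source), home, source),
                   second = NA, margin = 2, status = status, source = source,
                   p_max = 0.5, stringsAsFactors = FALSE)
  class(at) <- c("allocation_table", "data.frame")
  m <- matrix(0L, length(home), 2,
              dimnames = list(at$individual_id, c("L1", "L2")))
  m[, 1] <- rep(c(0L, 1L), length.out = nrow(m))
  ds <- dataset_from_matrix(m, pops = home,
                            habitat = rep("dune", 14),
                            lon = seq(2, 5, length.out = 14),
                            lat = seq(49, 53, length.out = 14))
  ldd <- ldd_estimate(at, ds)
  expect_equal(ldd$n_allocated, 92)
  expect_equal(ldd$n_immigrants, 24)
  expect_equal(ldd$n_distinct_pairs, 12)
  expect_equal(ldd$lower_bound_pct, 15.2)   # 100 * 14/92
  expect_equal(ldd$upper_bound_pct, 28.3)   # 100 * 26/92, round-half-even
  # no immigrants, none excluded -> (0, 0)
  at0 <- at[1:66, ]
  at0$status <- "allocated"; at0$source <- at0$home
  class(at0) <- class(at)
  ldd0 <- ldd_estimate(at0, ds)
  expect_equal(c(ldd0$lower_bound_pct, ldd0$upper_bound_pct), c(0, 0))
  # zero allocated errors
  atx <- at; atx$status <- "unallocated"
  class(atx) <- class(at)
  expect_error(ldd_estimate(atx, ds), "no allocated")
})

test_that("immigrant events carry great-circle distances and compass sectors", {
  sim <- simulate_metapopulation(sim_params(
    n_pops = 5, sizes = rep(15, 5), n_loci = 250, fst = 0.25, seed = 71,
    migrants = data.frame(source = c(1, 2), destination = c(3, 4), count = 2)))
  at <- allocate(sim$dataset, mld = 1, n_rand = 0, seed = 2)
  ldd <- ldd_estimate(at, sim$dataset)
  expect_gte(ldd$n_immigrants, 4)
  expect_true(all(ldd$events$distance_km > 0))
  expect_true(all(ldd$events$sector %in%
                    c("N", "NE", "E", "SE", "S", "SW", "W", "NW")))
  p <- sim$dataset$populations
  ev <- ldd$events[1, ]
  d_direct <- geosphere::distHaversine(
    c(p$lon[p$population_id == ev$source], p$lat[p$population_id == ev$source]),
    c(p$lon[p$population_id == ev$destination], p$lat[p$population_id == ev$destination])) / 1000
  expect_equal(ev$distance_km, d_direct, tolerance = 1e-9)
})

test_that("sensitivity reallocation counts changed assignments across scenarios", {
  sim <- simulate_metapopulation(sim_params(n_pops = 5, sizes = rep(15, 5),
                                            n_loci = 200, fst = 0.25, seed = 81))
  ds <- sim$dataset
  all_pops <- ds$populations$population_id
  sc <- list(base = list(populations = all_pops),
             same = list(populations = all_pops),
             fewer = list(populations = all_pops[1:3]))
  rep_ <- sensitivity_reallocation(ds, sc, mld = 1, n_rand = 0, seed = 3)
  expect_equal(rep_$changes$n_changed[rep_$changes$scenario == "same"], 0)
  expect_equal(rep_$changes$pct_changed[rep_$changes$scenario == "base"], 0)
  expect_true(all(rep_$changes$n_shared[1:2] == nrow(ds$samples)))
})
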