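sim_island <- function(seed = 1, fst = 0.1, n_pops = 8, n = 15, L = 120, ...) {
  simulate_metapopulation(sim_params(n_pops = n_pops, sizes = rep(n, n_pops),
                                     n_loci = L, fst = fst, seed = seed, ...))
}

test_that("Fst is near zero for identical populations and near one for fixed ones", {
  set.seed(5)
  # identical populations: one pool split in two
  m <- matrix(rbinom(60 * 80, 1, 0.4), 60, 80,
              dimnames = list(sprintf("i%02d", 1:60), sprintf("L%02d", 1:80)))
  ds <- dataset_from_matrix(m, pops = rep(c("A", "B"), each = 30))
  aft <- estimate_allele_freqs(ds, F = 0.5)
  expect_lt(fst_global(aft, n_perm = 0)$fst, 0.03)
  # populations fixed for alternative bands
  m2 <- rbind(matrix(rep(c(1L, 0L), each = 40), 20, 80, byrow = TRUE),
              matrix(rep(c(0L, 1L), each = 40), 20, 80, byrow = TRUE))
  dimnames(m2) <- dimnames(matrix(0, 40, 80,
                                  dimnames = list(sprintf("i%02d", 1:40),
                                                  sprintf("L%02d", 1:80))))
  ds2 <- dataset_from_matrix(m2, pops = rep(c("A", "B"), each = 20))
  aft2 <- estimate_allele_freqs(ds2, F = 0.5)
  expect_gt(fst_global(aft2, n_perm = 0)$fst, 0.9)
  # monomorphic dataset is an error
  mono <- matrix(1L, 10, 6, dimnames = list(sprintf("i%02d", 1:10),
                                            sprintf("L%d", 1:6)))
  aftm <- estimate_allele_freqs(dataset_from_matrix(mono, rep(c("A", "B"), 5)),
                                F = 0.5)
  expect_error(fst_global(aftm, n_perm = 0), "monomorphic")
})

test_that("island-model simulation recovers the target Fst and a calibrated p-value", {
  sim <- sim_island(seed = 31, fst = 0.10, n_pops = 10, n = 20, L = 150)
  aft <- estimate_allele_freqs(sim$dataset, sim$truth$F)
  res <- fst_global(aft, sim$dataset, n_perm = 50, seed = 2)
  expect_lt(abs(res$fst - 0.10), 0.03)
  expect_gte(res$p_value, 1 / 51)           # observed counted into the null set
  expect_lte(res$p_value, 0.05)
})

test_that("Fst and Phi-PT are stable under duplicating every individual", {
  # exact invariance holds for the variance ratio itself; the finite-sample
  # correction shrinks with n, so allow a small drift at these sizes
  sim <- sim_island(seed = 12, n_pops = 4, n = 30, L = 60)
  ds <- sim$dataset
  m2 <- rbind(ds$bands, ds$bands)
  rownames(m2) <- c(rownames(ds$bands), paste0(rownames(ds$bands), "_d"))
  ds2 <- dataset_from_matrix(m2, pops = rep(ds$samples$population_id, 2))
  a1 <- phipt_amova(ds, n_perm = 0)
  a2 <- phipt_amova(ds2, n_perm = 0)
  expect_lt(abs(a2$phi_pt - a1$phi_pt), 0.02)
  f1 <- fst_global(estimate_allele_freqs(ds, 0.8), n_perm = 0)$fst
  f2 <- fst_global(estimate_allele_freqs(ds2, 0.8), n_perm = 0)$fst
  expect_lt(abs(f2 - f1), 0.02)
})

test_that("AMOVA table matches the hand-worked 2x3x4 toy and vegan's partition", {
  m <- rbind(i1 = c(1, 1, 0, 0), i2 = c(1, 0, 0, 0), i3 = c(1, 1, 1, 0),
             j1 = c(0, 0, 1, 1), j2 = c(0, 1, 1, 1), j3 = c(0, 0, 1, 0))
  colnames(m) <- paste0("L", 1:4)
  ds <- dataset_from_matrix(m, pops = rep(c("P1", "P2"), each = 3))
  res <- phipt_amova(ds, n_perm = 99, seed = 1)
  # hand-worked: SS_among 3, SS_within 8/3, sigma2_A 7/9, sigma2_W 2/3
  expect_equal(unname(res$ss["among"]), 3)
  expect_equal(unname(res$ss["within"]), 8 / 3)
  expect_equal(unname(res$var_components["among"]), 7 / 9)
  expect_equal(unname(res$var_components["within"]), 2 / 3)
  expect_equal(res$phi_pt, 7 / 13)
  # independent SS partition: vegan adonis2 on the same squared distances
  skip_if_not_installed("vegan")
  grp <- data.frame(pop = rep(c("P1", "P2"), each = 3))
  ad <- vegan::adonis2(sqrt(dist(m)^2) ~ pop, data = grp, permutations = 2,
                       method = "euclidean")
  expect_equal(ad$SumOfSqs[1], 3, tolerance = 1e-10)
  expect_equal(ad$SumOfSqs[2], 8 / 3, tolerance = 1e-10)
})

test_that("Phi-PT permutation p is calibrated under label shuffling", {
  set.seed(8)
  m <- matrix(rbinom(40 * 50, 1, 0.5), 40, 50,
              dimnames = list(sprintf("i%02d", 1:40), sprintf("L%02d", 1:50)))
  ds <- dataset_from_matrix(m, pops = rep(c("A", "B"), each = 20))
  ps <- vapply(1:10, function(s) {
    sh <- ds
    sh$samples$population_id <- sample(sh$samples$population_id)
    phipt_amova(sh, n_perm = 99, seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.2)   # null p-values not concentrated at 0
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Nei distance is zero for identical frequencies and matches a hand toy", {
  # two populations, two loci with set frequencies via direct table
  aft <- data.frame(population_id = rep(c("A", "B"), 2),
                    locus_id = rep(c("L1", "L2"), each = 2),
                    n = 10, k_absent = 0,
                    q_hat = c(0.2, 0.6, 0.5, 0.3))
  aft$f_hat <- 1 - aft$q_hat^2
  attr(aft, "F") <- 0
  class(aft) <- c("allele_freq_table", "data.frame")
  dm <- nei_distance_matrix(aft)
  # hand: Jx = mean(.2^2+.8^2, .5^2+.5^2)=.59; Jy = mean(.6^2+.4^2,.3^2+.7^2)=.55
  # Jxy = mean(.2*.6+.8*.4, .5*.3+.5*.7) = mean(.44,.5) = .47
  expect_equal(dm$d["A", "B"], -log(0.47 / sqrt(0.59 * 0.55)), tolerance = 1e-12)
  expect_equal(diag(dm$d), c(A = 0, B = 0))
  aft_same <- aft
  aft_same$q_hat <- rep(c(0.2, 0.5), each = 2)
  dm2 <- nei_distance_matrix(aft_same)
  expect_equal(dm2$d["A", "B"], 0, tolerance = 1e-12)
})

test_that("PCoA recovers planted coordinates and satisfies the eigen identities", {
  set.seed(4)
  xy <- cbind(runif(12, 0, 10), runif(12, 0, 10))
  d <- as.matrix(dist(xy))
  rownames(d) <- colnames(d) <- sprintf("P%02d", 1:12)
  res <- pcoa(d, k = 2)
  # Procrustes-align the recovered configuration onto the truth
  a <- scale(res$coords, scale = FALSE)
  b <- scale(xy, scale = FALSE)
  sv <- svd(t(b) %*% a)
  rot <- sv$v %*% t(sv$u)
  expect_lt(max(abs(a %*% rot - b)), 1e-8)
  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  r3 <- pcoa(d3)
  pos <- r3$eigenvalues[r3$eigenvalues > 1e-10]
  expect_equal(length(pos), 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-10)
  # sum of eigenvalues equals the trace of the centred Gower matrix
  g <- -0.5 * scale(t(scale(t(d^2), scale = FALSE)), scale = FALSE)
  expect_equal(sum(res$eigenvalues), sum(diag(g)), tolerance = 1e-8)
  expect_error(pcoa(matrix(c(0, NA, NA, 0), 2)), "NA")
})

test_that("NJ consensus recovers planted clades with high support", {
  # two clearly diverged clades of populations
  set.seed(19)
  base1 <- rbinom(150, 1, 0.5)
  base2 <- 1 - base1
  mk_pop <- function(base, id, n = 10, noise = 0.05) {
    m <- t(replicate(n, ifelse(runif(150) < noise, 1 - base, base)))
    rownames(m) <- sprintf("%s_i%02d", id, 1:n)
    m
  }
  m <- rbind(mk_pop(base1, "A"), mk_pop(base1, "B"),
             mk_pop(base2, "C"), mk_pop(base2, "D"))
  colnames(m) <- sprintf("L%03d", 1:150)
  ds <- dataset_from_matrix(m, pops = rep(c("A", "B", "C", "D"), each = 10))
  res <- nj_consensus(ds, F = 0.5, n_boot = 30, seed = 3)
  expect_s3_class(res$tree, "phylo")
  expect_true(ape::is.rooted(res$tree))
  # output parses as valid Newick, support within [0, 100]
  reparsed <- ape::read.tree(text = res$newick)
  expect_setequal(reparsed$tip.label, c("A", "B", "C", "D"))
  sup <- suppressWarnings(as.numeric(res$tree$node.label))
  sup <- sup[is.finite(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # the planted split {A,B} | {C,D} is in the consensus with high support
  cons_splits <- ape::prop.part(res$consensus)
  labs <- attr(cons_splits, "labels")
  found <- any(vapply(cons_splits, function(s)
    setequal(labs[s], c("A", "B")) || setequal(labs[s], c("C", "D")),
    logical(1)))
  expect_true(found)
  expect_true(any(sup >= 95))
})

test_that("a single bootstrap replicate is its own consensus", {
  sim <- sim_island(seed = 23, n_pops = 5, n = 10, L = 80)
  res <- nj_consensus(sim$dataset, F = 0.8, n_boot = 1, seed = 2)
  expect_equal(ape::Ntip(res$consensus), 5)
})

test_that("Mantel test hits its exact and constructed anchors", {
  set.seed(6)
  n <- 10
  geo <- as.matrix(dist(cbind(runif(n), runif(n))))
  dimnames(geo) <- list(sprintf("P%02d", 1:n), sprintf("P%02d", 1:n))
  # genetic == geographic: r = 1, p = 1/(n_perm+1)
  res <- mantel_ibd(geo, geo, n_perm = 199, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 1 / 200)
  # linear + small noise
  gen <- 0.2 + 0.5 * geo + matrix(runif(n * n, 0, 0.01), n, n)
  gen <- (gen + t(gen)) / 2; diag(gen) <- 0
  dimnames(gen) <- dimnames(geo)
  res2 <- mantel_ibd(gen, geo, n_perm = 999, seed = 2)
  expect_gt(res2$r, 0.9)
  expect_lte(res2$p_value, 0.001)
  # agreement with vegan's mantel statistic
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(as.dist(gen), as.dist(geo), permutations = 99)
  expect_equal(res2$r, unname(vg$statistic), tolerance = 1e-12)
  expect_error(mantel_ibd(matrix(0, n, n, dimnames = dimnames(geo)), geo),
               "constant")
})

test_that("null Mantel p-values are roughly uniform", {
  set.seed(41)
  ps <- vapply(1:12, function(s) {
    a <- as.matrix(dist(runif(8))); b <- as.matrix(dist(runif(8)))
    mantel_ibd(a, b, n_perm = 99, seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.2)
})

test_that("population geographic distances are symmetric and match geosphere", {
  ds <- toy_dataset()
  d <- pop_geo_distances(ds)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(A = 0, B = 0))
  direct <- geosphere::distHaversine(c(3.1, 51), c(4, 52)) / 1000
  expect_equal(d["A", "B"], direct, tolerance = 1e-9)
})
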