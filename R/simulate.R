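#' Simulation parameters for the metapopulation generator
#'
#' Collects every knob of [simulate_metapopulation()]: an island-model
#' metapopulation of partially selfing diploids scored with dominant
#' markers. Deme band-allele frequencies are drawn around a locus-specific
#' ancestral frequency with a Beta distribution whose spread matches the
#' target Fst; individuals are genotyped with inbreeding F = s/(2 - s);
#' selected loci receive a habitat-specific shift on the logit of the
#' ancestral frequency; migrants carry a full genotype drawn from their
#' source deme; scoring error flips each band call independently.
#'
#' @param n_pops Number of populations.
#' @param sizes Integer vector of population sizes (length `n_pops`).
#' @param n_loci Number of dominant loci.
#' @param fst Target island-model Fst in (0, 1).
#' @param selfing Selfing rate s in [0, 1); converted internally to
#'   F = s/(2 - s).
#' @param habitat Character vector (`"dune"`/`"fen"`) per population.
#' @param ancestral_beta Two Beta parameters for the ancestral band-allele
#'   frequency distribution (U-shaped by default, as AFLP band-frequency
#'   spectra typically are).
#' @param n_selected Number of loci under habitat-associated divergent
#'   selection.
#' @param delta Logit-scale habitat effect for selected loci; dune demes
#'   get +delta/2, fen demes -delta/2 on the ancestral logit.
#' @param migrants Data frame with columns `source`, `destination`,
#'   `count` (population indices or IDs), or `NULL` for none.
#' @param error_rate Per-band flip probability (genotyping error).
#' @param n_replicate_pairs Number of individuals duplicated as replicate
#'   samples (both copies flipped independently).
#' @param bbox Bounding box `c(lon_min, lon_max, lat_min, lat_max)` for
#'   random population placement.
#' @param seed Integer master seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_pops = 10,
                       sizes = rep(15, n_pops),
                       n_loci = 200,
                       fst = 0.10,
                       selfing = 0.91,
                       habitat = rep(c("dune", "fen"), length.out = n_pops),
                       ancestral_beta = c(0.6, 0.6),
                       n_selected = 0,
                       delta = 0,
                       migrants = NULL,
                       error_rate = 0,
                       n_replicate_pairs = 0,
                       bbox = c(2.0, 5.5, 49.0, 53.5),
                       seed = 1) {
  stopifnot(length(sizes) == n_pops, all(sizes >= 1),
            length(habitat) == n_pops, all(habitat %in% c("dune", "fen")),
            fst > 0, fst < 1, selfing >= 0, selfing < 1,
            error_rate >= 0, error_rate <= 1,
            n_selected >= 0, n_selected <= n_loci)
  if (!is.null(migrants)) {
    migrants <- as.data.frame(migrants)
    stopifnot(all(c("source", "destination", "count") %in% names(migrants)))
    if (any(migrants$source == migrants$destination))
      stop("migrant source must differ from destination")
  }
  structure(list(n_pops = n_pops, sizes = as.integer(sizes), n_loci = n_loci,
                 fst = fst, selfing = selfing, habitat = habitat,
                 ancestral_beta = ancestral_beta, n_selected = n_selected,
                 delta = delta, migrants = migrants, error_rate = error_rate,
                 n_replicate_pairs = n_replicate_pairs, bbox = bbox,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Study-shaped parameter preset
#'
#' Parameters shaped like the fen-orchid study system: 38 populations
#' (23 dune slack, 16 fen) with sizes spanning 3 to 72 and summing to 422
#' individuals, 451 dominant loci, selfing rate 0.91, target Fst 0.09,
#' per-band scoring error 0.024, 40 replicate pairs, and coordinates
#' spanning roughly 600 km of the North Sea coastal plain.
#'
#' @param seed Master seed.
#' @param ... Overrides passed on to [sim_params()] (e.g. `fst = 0.2`).
#' @return A `sim_params` object.
#' @export
study_shaped_preset <- function(seed = 1, ...) {
  sizes <- c(72, 30, 22, 18, 15, 14, 12, 11, 10, 9, 8, 8, 7, 6, 6, 5, 5,
             4, 4, 3, 3, 3, 3,                                # 23 dune, 278 plants
             28, 18, 14, 12, 11, 10, 9, 8, 7, 6, 5, 5, 4, 4, 3)  # 15 fen, 144 plants
  # 38 populations, sizes in [3, 72], 422 individuals in total
  args <- list(n_pops = 38L, sizes = sizes, n_loci = 451L, fst = 0.09,
               selfing = 0.91,
               habitat = rep(c("dune", "fen"), times = c(23L, 15L)),
               error_rate = 0.024, n_replicate_pairs = 40L,
               bbox = c(1.5, 5.8, 49.2, 53.5), seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_params, args)
}

# Draw dominant phenotypes for n individuals at loci with band-allele
# frequencies p (vector over loci) under inbreeding F: with probability F
# the two allele draws are identical by descent.
draw_phenotypes <- function(n, p, F) {
  L <- length(p)
  a1 <- matrix(stats::rbinom(n * L, 1, rep(p, each = n)), n, L)
  a2 <- matrix(stats::rbinom(n * L, 1, rep(p, each = n)), n, L)
  ibd <- matrix(stats::runif(n * L) < F, n, L)
  a2[ibd] <- a1[ibd]
  (a1 | a2) * 1L
}

#' Simulate a metapopulation dataset with known truth
#'
#' @param p A [sim_params()] object.
#' @return A list with `dataset` (a `dompop_dataset`) and `truth`, the
#'   truth tables: `origin` (true source population per individual),
#'   `deme_freqs` (true band-allele frequency matrix, populations x loci),
#'   `selected_loci`, `migrants`, `replicates`, and `F` (the inbreeding
#'   coefficient implied by the selfing rate).
#' @export
simulate_metapopulation <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  set.seed(p$seed)
  Fis <- selfing_to_inbreeding(p$selfing)
  pop_ids <- sprintf("P%02d", seq_len(p$n_pops))
  locus_ids <- sprintf("L%03d", seq_len(p$n_loci))

  # ancestral band-allele frequencies, kept polymorphic
  pbar <- stats::rbeta(p$n_loci, p$ancestral_beta[1], p$ancestral_beta[2])
  pbar <- pmin(pmax(pbar, 0.03), 0.97)
  selected <- if (p$n_selected > 0) sort(sample.int(p$n_loci, p$n_selected)) else integer(0)
  # divergent selection acts on standing variation: planted selected loci
  # start from mid-range ancestral frequencies
  if (length(selected) > 0)
    pbar[selected] <- stats::runif(length(selected), 0.35, 0.65)

  # deme band-allele frequencies: Beta island model around (shifted) pbar
  conc <- 1 / p$fst - 1
  deme <- matrix(0, p$n_pops, p$n_loci, dimnames = list(pop_ids, locus_ids))
  for (j in seq_len(p$n_pops)) {
    mu <- pbar
    if (length(selected) > 0) {
      shift <- if (p$habitat[j] == "dune") p$delta / 2 else -p$delta / 2
      mu[selected] <- inv_logit(logit(pbar[selected]) + shift)
    }
    deme[j, ] <- stats::rbeta(p$n_loci, mu * conc, (1 - mu) * conc)
  }
  deme <- pmin(pmax(deme, 1e-6), 1 - 1e-6)

  # genotypes
  geno <- vector("list", p$n_pops)
  ind_ids <- vector("list", p$n_pops)
  for (j in seq_len(p$n_pops)) {
    geno[[j]] <- draw_phenotypes(p$sizes[j], deme[j, ], Fis)
    ind_ids[[j]] <- sprintf("%s_i%02d", pop_ids[j], seq_len(p$sizes[j]))
    rownames(geno[[j]]) <- ind_ids[[j]]
  }

  # planted first-generation migrants: genotype from source, label destination
  origin <- rep(pop_ids, times = p$sizes)
  names(origin) <- unlist(ind_ids)
  migrant_rows <- NULL
  if (!is.null(p$migrants)) {
    for (r in seq_len(nrow(p$migrants))) {
      src <- as.character(p$migrants$source[r])
      dst <- as.character(p$migrants$destination[r])
      if (!src %in% pop_ids) src <- pop_ids[as.integer(p$migrants$source[r])]
      if (!dst %in% pop_ids) dst <- pop_ids[as.integer(p$migrants$destination[r])]
      js <- match(src, pop_ids); jd <- match(dst, pop_ids)
      cnt <- p$migrants$count[r]
      take <- sample.int(p$sizes[jd], cnt)
      repl <- draw_phenotypes(cnt, deme[js, ], Fis)
      geno[[jd]][take, ] <- repl
      ids <- rownames(geno[[jd]])[take]
      origin[ids] <- src
      migrant_rows <- rbind(migrant_rows,
                            data.frame(individual_id = ids, source = src,
                                       destination = dst, stringsAsFactors = FALSE))
    }
  }

  bands <- do.call(rbind, geno)

  # replicate samples: duplicate the pre-error genotype, flip both copies
  rep_map <- NULL
  if (p$n_replicate_pairs > 0) {
    take <- sample.int(nrow(bands), p$n_replicate_pairs)
    rep_ids <- paste0(rownames(bands)[take], "_rep")
    rep_geno <- bands[take, , drop = FALSE]
    rownames(rep_geno) <- rep_ids
    rep_map <- data.frame(individual_id = rep_ids,
                          replicate_of = rownames(bands)[take],
                          stringsAsFactors = FALSE)
    bands <- rbind(bands, rep_geno)
  }

  # genotyping error: independent per-band flips on every emitted row
  if (p$error_rate > 0) {
    flips <- matrix(stats::runif(length(bands)) < p$error_rate,
                    nrow(bands), ncol(bands))
    bands <- 1L * xor(bands == 1L, flips)
  }
  storage.mode(bands) <- "integer"
  colnames(bands) <- locus_ids

  # coordinates: populations placed uniformly in the bounding box
  lon <- stats::runif(p$n_pops, p$bbox[1], p$bbox[2])
  lat <- stats::runif(p$n_pops, p$bbox[3], p$bbox[4])

  home <- rep(pop_ids, times = p$sizes)
  names(home) <- unlist(ind_ids)
  all_ids <- rownames(bands)
  base_of <- sub("_rep$", "", all_ids)
  samples <- data.frame(
    individual_id = all_ids,
    population_id = home[base_of],
    habitat = p$habitat[match(home[base_of], pop_ids)],
    lon = lon[match(home[base_of], pop_ids)],
    lat = lat[match(home[base_of], pop_ids)],
    replicate_of = ifelse(grepl("_rep$", all_ids), base_of, NA_character_),
    stringsAsFactors = FALSE)

  meta <- data.frame(locus_id = locus_ids,
                     primer_combo = rep(sprintf("PC%d", 1:4), length.out = p$n_loci),
                     size_bp = 60 + (seq_len(p$n_loci) * 7) %% 500,
                     stringsAsFactors = FALSE)

  ds <- assemble_dataset(band_matrix(bands, meta), samples)
  truth <- list(origin = origin, deme_freqs = deme,
                selected_loci = locus_ids[selected],
                migrants = migrant_rows, replicates = rep_map,
                F = Fis, params = p)
  list(dataset = ds, truth = truth)
}
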