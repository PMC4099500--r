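#' Construct and validate a band-presence matrix
#'
#' A `band_matrix` holds a binary individuals-by-loci matrix of dominant
#' marker phenotypes (1 = band present, 0 = absent, no missing values)
#' together with optional per-locus metadata (primer combination and
#' fragment size in base pairs).
#'
#' @param presence Numeric or integer matrix with entries in \{0, 1\};
#'   rownames are individual IDs, colnames are locus IDs.
#' @param locus_meta Optional data frame with columns `locus_id`,
#'   `primer_combo`, `size_bp` (one row per locus). `NULL` when fragment
#'   metadata is unavailable; operations that need fragment sizes
#'   (the size-homoplasy screen) then refuse to run.
#' @return An object of class `band_matrix`: a list with elements
#'   `presence` and `locus_meta`.
#' @export
band_matrix <- function(presence, locus_meta = NULL) {
  presence <- as.matrix(presence)
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop("presence matrix must carry individual IDs as rownames and locus IDs as colnames")
  if (anyDuplicated(rownames(presence)))
    stop("duplicated individual IDs: ",
         paste(unique(rownames(presence)[duplicated(rownames(presence))]), collapse = ", "))
  if (anyDuplicated(colnames(presence)))
    stop("duplicated locus IDs: ",
         paste(unique(colnames(presence)[duplicated(colnames(presence))]), collapse = ", "))
  bad <- which(!(presence %in% c(0, 1)))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(presence)) + 1
    j <- ((bad[1] - 1) %/% nrow(presence)) + 1
    stop(sprintf("non-binary value %s at individual '%s', locus '%s'",
                 format(presence[i, j]), rownames(presence)[i], colnames(presence)[j]))
  }
  storage.mode(presence) <- "integer"
  if (!is.null(locus_meta)) {
    locus_meta <- as.data.frame(locus_meta)
    need <- c("locus_id", "primer_combo", "size_bp")
    if (!all(need %in% names(locus_meta)))
      stop("locus_meta needs columns: ", paste(need, collapse = ", "))
    if (!setequal(locus_meta$locus_id, colnames(presence)))
      stop("locus_meta IDs do not match matrix loci")
    locus_meta <- locus_meta[match(colnames(presence), locus_meta$locus_id), , drop = FALSE]
    rownames(locus_meta) <- NULL
    if (any(!is.finite(locus_meta$size_bp)) || any(locus_meta$size_bp <= 0))
      stop("fragment sizes must be positive")
  }
  structure(list(presence = presence, locus_meta = locus_meta),
            class = "band_matrix")
}

#' Read a band-presence matrix from CSV/TSV
#'
#' The file holds one header row of locus IDs and one row per individual,
#' with the individual ID in the first column. Rows containing missing
#' values are dropped (dominant pipelines keep only fully genotyped
#' samples); the number dropped is reported via `message()`.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param meta_path Optional path of the locus metadata sidecar CSV with
#'   columns `locus_id`, `primer_combo`, `size_bp`.
#' @return A [band_matrix()].
#' @export
read_band_matrix <- function(path, dialect = c("csv", "tsv"), meta_path = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  incomplete <- rowSums(is.na(m)) > 0
  if (any(incomplete)) {
    message(sum(incomplete), " incomplete individual(s) dropped at read time")
    m <- m[!incomplete, , drop = FALSE]
  }
  meta <- if (!is.null(meta_path))
    utils::read.csv(meta_path, stringsAsFactors = FALSE) else NULL
  bm <- band_matrix(m, meta)
  message("band matrix: ", nrow(bm$presence), " individuals x ",
          ncol(bm$presence), " loci")
  bm
}

#' Write a band-presence matrix (and optional locus sidecar) to disk
#'
#' @param bm A [band_matrix()].
#' @param path Output file for the matrix.
#' @param dialect `"csv"` or `"tsv"`.
#' @param meta_path Optional output path for the locus metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(bm, path, dialect = c("csv", "tsv"), meta_path = NULL) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(individual_id = rownames(bm$presence), bm$presence,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path) && !is.null(bm$locus_meta))
    utils::write.csv(bm$locus_meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate the sample table
#'
#' Expects columns `individual_id`, `population_id`, `habitat`
#' (`"dune"` or `"fen"`), `lon`, `lat` (decimal degrees, WGS84) and
#' optionally `replicate_of` linking replicate samples to their original.
#'
#' @param path CSV file path.
#' @return A validated data frame (class `sample_table`).
#' @export
read_sample_table <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_table(st)
}

#' @rdname read_sample_table
#' @param st A data frame with the sample-table columns.
#' @export
validate_sample_table <- function(st) {
  need <- c("individual_id", "population_id", "habitat", "lon", "lat")
  miss <- setdiff(need, names(st))
  if (length(miss) > 0) stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(st$individual_id))
    stop("duplicated individual IDs in sample table")
  badh <- setdiff(unique(st$habitat), c("dune", "fen"))
  if (length(badh) > 0) stop("unknown habitat label(s): ", paste(badh, collapse = ", "))
  if (any(!is.finite(st$lat)) || any(st$lat < -90 | st$lat > 90))
    stop("latitude out of range [-90, 90]")
  if (any(!is.finite(st$lon)) || any(st$lon < -180 | st$lon > 180))
    stop("longitude out of range [-180, 180]")
  if (is.null(st$replicate_of)) st$replicate_of <- NA_character_
  st$replicate_of[st$replicate_of %in% c("", NA)] <- NA_character_
  known <- is.na(st$replicate_of) | st$replicate_of %in% st$individual_id
  if (!all(known))
    stop("replicate_of refers to unknown individual(s): ",
         paste(st$replicate_of[!known], collapse = ", "))
  st <- st[, c(need, "replicate_of")]
  class(st) <- c("sample_table", "data.frame")
  st
}

#' Write a sample table to CSV
#' @param st A sample table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(st, path) {
  utils::write.csv(as.data.frame(st), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble the validated dataset
#'
#' Joins a band matrix with its sample table, builds the population
#' registry (members, habitat, centroid coordinates) and enforces the
#' cross-input invariants: the two ID sets must match exactly, every
#' population has at least one member, and habitat is constant within a
#' population.
#'
#' @param bm A [band_matrix()].
#' @param st A sample table (see [read_sample_table()]).
#' @return An object of class `dompop_dataset`: list with `bands` (the
#'   binary matrix), `samples` (rows aligned with the matrix),
#'   `locus_meta`, and `populations` (registry data frame).
#' @export
assemble_dataset <- function(bm, st) {
  st <- validate_sample_table(as.data.frame(st))
  ids_m <- rownames(bm$presence)
  only_m <- setdiff(ids_m, st$individual_id)
  only_s <- setdiff(st$individual_id, ids_m)
  if (length(only_m) > 0 || length(only_s) > 0)
    stop("ID mismatch between band matrix and sample table; ",
         "only in matrix: [", paste(only_m, collapse = ", "), "]; ",
         "only in samples: [", paste(only_s, collapse = ", "), "]")
  ids <- sort(ids_m)
  bands <- bm$presence[ids, , drop = FALSE]
  samples <- st[match(ids, st$individual_id), , drop = FALSE]
  rownames(samples) <- NULL
  hab_per_pop <- tapply(samples$habitat, samples$population_id,
                        function(h) length(unique(h)))
  if (any(hab_per_pop > 1))
    stop("habitat not constant within population(s): ",
         paste(names(hab_per_pop)[hab_per_pop > 1], collapse = ", "))
  pops <- do.call(rbind, lapply(split(samples, samples$population_id), function(d) {
    data.frame(population_id = d$population_id[1], habitat = d$habitat[1],
               n = nrow(d), lon = mean(d$lon), lat = mean(d$lat),
               stringsAsFactors = FALSE)
  }))
  pops <- pops[order(pops$population_id), , drop = FALSE]
  rownames(pops) <- NULL
  structure(list(bands = bands, samples = samples,
                 locus_meta = bm$locus_meta, populations = pops),
            class = "dompop_dataset")
}

#' @export
print.dompop_dataset <- function(x, ...) {
  cat("<dompop_dataset> ", nrow(x$bands), " individuals x ", ncol(x$bands),
      " loci, ", nrow(x$populations), " populations\n", sep = "")
  cat("  habitats:", paste(sprintf("%s=%d", names(table(x$populations$habitat)),
                                   table(x$populations$habitat)), collapse = ", "), "\n")
  n_rep <- sum(!is.na(x$samples$replicate_of))
  if (n_rep > 0) cat("  replicate samples:", n_rep, "\n")
  invisible(x)
}

# --- dataset subsetting helpers (used throughout the pipeline) ---------------

#' Subset a dataset by loci or individuals
#'
#' Rebuilds the population registry after subsetting, so the invariants of
#' [assemble_dataset()] keep holding.
#'
#' @param ds A `dompop_dataset`.
#' @param loci Character vector of locus IDs to keep (default all).
#' @param individuals Character vector of individual IDs to keep (default all).
#' @return A `dompop_dataset`.
#' @export
ds_subset <- function(ds, loci = NULL, individuals = NULL) {
  bands <- ds$bands
  meta <- ds$locus_meta
  if (!is.null(loci)) {
    bands <- bands[, loci, drop = FALSE]
    if (!is.null(meta)) meta <- meta[match(loci, meta$locus_id), , drop = FALSE]
  }
  samples <- ds$samples
  if (!is.null(individuals)) {
    bands <- bands[individuals, , drop = FALSE]
    samples <- samples[samples$individual_id %in% individuals, , drop = FALSE]
    # drop dangling replicate links
    samples$replicate_of[!(samples$replicate_of %in% samples$individual_id)] <- NA
  }
  assemble_dataset(band_matrix(bands, meta), samples)
}

#' Drop replicate copies from a dataset
#'
#' Replicate samples exist only to estimate the genotyping error rate and
#' are excluded from all downstream statistics.
#'
#' @param ds A `dompop_dataset`.
#' @return A `dompop_dataset` without the rows whose `replicate_of` is set.
#' @export
drop_replicates <- function(ds) {
  keep <- ds$samples$individual_id[is.na(ds$samples$replicate_of)]
  if (length(keep) == nrow(ds$bands)) return(ds)
  ds_subset(ds, individuals = keep)
}

# Membership list: population_id -> individual ids
pop_members <- function(ds) {
  split(ds$samples$individual_id, ds$samples$population_id)
}
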