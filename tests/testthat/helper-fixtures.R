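# Small in-code fixtures shared across tests.

toy_band_matrix <- function() {
  m <- matrix(c(1, 0, 1, 0,
                1, 1, 0, 0,
                0, 1, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("a1", "a2", "b1"), paste0("L", 1:4)))
  meta <- data.frame(locus_id = paste0("L", 1:4),
                     primer_combo = c("PC1", "PC1", "PC2", "PC2"),
                     size_bp = c(100, 220, 150, 300))
  band_matrix(m, meta)
}

toy_sample_table <- function() {
  data.frame(individual_id = c("a1", "a2", "b1"),
             population_id = c("A", "A", "B"),
             habitat = c("dune", "dune", "fen"),
             lon = c(3.1, 3.1, 4.0), lat = c(51.0, 51.0, 52.0),
             stringsAsFactors = FALSE)
}

toy_dataset <- function() assemble_dataset(toy_band_matrix(), toy_sample_table())

# A dataset built directly from a genotype matrix and a population map.
dataset_from_matrix <- function(m, pops, habitat = NULL,
                                lon = NULL, lat = NULL, replicate_of = NULL) {
  upops <- unique(pops)
  if (is.null(habitat)) habitat <- rep(c("dune", "fen"), length.out = length(upops))
  if (is.null(lon)) lon <- seq(3, 5, length.out = length(upops))
  if (is.null(lat)) lat <- seq(50, 52, length.out = length(upops))
  st <- data.frame(individual_id = rownames(m),
                   population_id = pops,
                   habitat = habitat[match(pops, upops)],
                   lon = lon[match(pops, upops)],
                   lat = lat[match(pops, upops)],
                   stringsAsFactors = FALSE)
  if (!is.null(replicate_of)) st$replicate_of <- replicate_of
  assemble_dataset(band_matrix(m), st)
}
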