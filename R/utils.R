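# Internal helpers shared across the pipeline.

logit <- function(p) log(p / (1 - p))

inv_logit <- stats::plogis

#' @importFrom geosphere distHaversine bearing destPoint
NULL

# Great-circle distance in km between two sets of lon/lat points.
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

# Initial great-circle bearing (degrees in [0, 360)) from point 1 to point 2.
gc_bearing <- function(lon1, lat1, lon2, lat2) {
  (geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2)) + 360) %% 360
}

# Bin bearings into the 8 compass sectors of 45 degrees centred on N, NE, ...
compass_sector <- function(bearing) {
  sectors <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  factor(sectors[floor(((bearing + 22.5) %% 360) / 45) + 1], levels = sectors)
}

# Connected components of a logical adjacency matrix (single linkage).
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue) > 0L) {
        v <- queue[[1L]]
        queue <- queue[-1L]
        nb <- which(adj[v, ] & is.na(comp))
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

# Pairwise Hamming distances between the rows of a binary matrix.
hamming_rows <- function(x) {
  x <- as.matrix(x)
  k <- rowSums(x)
  cross <- tcrossprod(x)
  d <- outer(k, k, "+") - 2 * cross
  diag(d) <- 0
  d
}

# Derive a stream of child seeds from one master seed, staying within
# 32-bit integer range.
child_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483647L
}

# Permutation p-value with the observed statistic counted in the null set.
perm_pvalue <- function(observed, permuted) {
  (1 + sum(permuted >= observed)) / (length(permuted) + 1)
}
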