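# Shared fixtures, built lazily and cached for the whole test run.

.cache <- new.env(parent = emptyenv())

default_phantom <- function() {
  if (is.null(.cache$phantom)) .cache$phantom <- generate_phantom()
  .cache$phantom
}

# homogeneous slab volume of one tissue id filling the whole grid
slab_volume <- function(nx, ny, nz, pitch, id = 1L) {
  label_volume(array(as.integer(id), c(nx, ny, nz)), pitch)
}

# single-tissue synthetic spectra covering 400-1100 nm with flat properties
flat_spectra <- function(mu_a, mu_s, g, n, id = 1L) {
  spectra_table(data.frame(tissue_id = as.integer(id),
                           wavelength = c(400, 1100),
                           mu_a = mu_a, mu_s = mu_s, g = g, n = n))
}

# brute-force oracle: per-voxel best-priority assignment
oracle_resolve <- function(masks, table) {
  shp <- dim(masks[[1]])
  ids <- vapply(names(masks), tissue_id, integer(1), table = table)
  ranks <- table$priority_rank[match(ids, table$id)]
  out <- array(0L, shp)
  for (i in seq_len(shp[1])) for (j in seq_len(shp[2])) for (k in seq_len(shp[3])) {
    best <- 0L; bestrank <- Inf
    for (m in seq_along(masks)) {
      if (masks[[m]][i, j, k] && ranks[m] < bestrank) {
        best <- ids[m]; bestrank <- ranks[m]
      }
    }
    out[i, j, k] <- best
  }
  out
}

# brute-force oracle: one simultaneous majority-filter sweep (6-neighbourhood),
# iterated to a fixed point
oracle_cleanup <- function(lab, max_iter = 25L) {
  d <- dim(lab)
  for (it in seq_len(max_iter)) {
    out <- lab
    changed <- FALSE
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      nb <- integer(0)
      if (i > 1) nb <- c(nb, lab[i - 1, j, k])
      if (i < d[1]) nb <- c(nb, lab[i + 1, j, k])
      if (j > 1) nb <- c(nb, lab[i, j - 1, k])
      if (j < d[2]) nb <- c(nb, lab[i, j + 1, k])
      if (k > 1) nb <- c(nb, lab[i, j, k - 1])
      if (k < d[3]) nb <- c(nb, lab[i, j, k + 1])
      if (!length(nb) || any(nb == lab[i, j, k])) next
      tb <- table(nb)
      winners <- as.integer(names(tb)[tb == max(tb)])
      out[i, j, k] <- min(winners)
      changed <- TRUE
    }
    lab <- out
    if (!changed) break
  }
  lab
}
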