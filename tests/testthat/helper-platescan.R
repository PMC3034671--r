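# Shared fixture builders. Everything is generated in code; no stored data.

random_plate <- function(nr = 8, nc = 12, seed = NULL, mask = NULL) {
  if (!is.null(seed)) set.seed(seed)
  plate_grid(matrix(rnorm(nr * nc), nr, nc), mask = mask)
}

random_assay <- function(P = 4, nr = 8, nc = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hts_assay(lapply(seq_len(P), function(p) {
    plate_grid(matrix(rnorm(nr * nc), nr, nc))
  }))
}

# Replicated assay of P plates paired (1,2), (3,4), ...
random_replicated_assay <- function(P = 4, nr = 8, nc = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pairing <- as.integer(seq_len(P) + c(1L, -1L))
  hts_assay(
    lapply(seq_len(P), function(p) plate_grid(matrix(rnorm(nr * nc), nr, nc))),
    replicate_of = pairing
  )
}

# Hit surface straight from a counts matrix (NA = masked location).
surface_from_counts <- function(counts) {
  mask <- !is.na(counts)
  total <- sum(counts[mask])
  structure(
    list(
      counts = counts, mask = mask, total = total,
      expected = total / sum(mask), threshold_c = 3, scope = "plate_wise",
      n_plates = max(counts[mask], 1)
    ),
    class = "hit_surface"
  )
}
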