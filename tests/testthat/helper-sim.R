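# Shared fixtures, built in code.  The "small world" keeps unit tests
# fast; acceptance tests build the full-scale world themselves.

small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      genome <- simulate_genome(n_chrom = 2, total_len = 8e6, seed = 42)
      landscape <- plant_landscape(
        genome, background = 5.5,
        hotspots = data.frame(chrom = "chr01", start = 15e5, end = 16e5,
                              rate = 100),
        coldspots = data.frame(chrom = "chr02", start = 1e6, end = 25e5))
      scaffolds <- fragment_scaffolds(genome, mean_len = 8e5, seed = 43)
      design <- cross_design(n_progeny = 184, error = 0, missing = 0,
                             seed = 44)
      sim <- simulate_cross(genome, landscape, scaffolds,
                            markers_per_mb = 25, design = design,
                            pileup = TRUE)
      cache <<- list(genome = genome, landscape = landscape,
                     scaffolds = scaffolds, design = design, sim = sim)
    }
    cache
  }
})

# A genotype matrix with hand-set mismatch counts between consecutive
# markers: marker i+1 differs from marker i in exactly diffs[i]
# individuals (disjoint flips, so pairwise mismatches add).
gm_with_diffs <- function(n_ind, diffs) {
  k <- length(diffs) + 1
  calls <- matrix(0L, k, n_ind)
  at <- 0
  for (i in seq_along(diffs)) {
    if (diffs[i] == 0) next
    flip <- at + seq_len(diffs[i])
    stopifnot(max(flip) <= n_ind)
    calls[(i + 1):k, flip] <- 1L
    at <- at + diffs[i]
  }
  markers <- data.frame(id = sprintf("UM%06d", seq_len(k)),
                        scaffold = "S00001",
                        position = seq_len(k) * 1000,
                        stringsAsFactors = FALSE)
  genotype_matrix(markers, calls, sprintf("F%03d", seq_len(n_ind)))
}

# One pileup row per call.
pu_row <- function(scaffold, pos, sample, A = 0, C = 0, G = 0, T = 0) {
  data.frame(scaffold = scaffold, pos = pos, sample = sample,
             A = A, C = C, G = G, T = T, stringsAsFactors = FALSE)
}
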