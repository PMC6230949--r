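# The synthetic world: genome, landscape, scaffolds, cross.

test_that("simulate_genome partitions length and places genes", {
  g <- simulate_genome(n_chrom = 19, total_len = 19e6, seed = 1)
  expect_equal(nrow(g$chromosomes), 19L)
  expect_true(all(g$chromosomes$length == 1e6))
  expect_true(all(g$genes$start >= 0))
  ok <- g$genes$end <= g$chromosomes$length[match(g$genes$chrom,
                                                  g$chromosomes$name)]
  expect_true(all(ok))
  expect_false(anyDuplicated(g$genes$id) > 0)
  expect_error(simulate_genome(n_chrom = 0), class = "radmap_param_error")
  expect_error(simulate_genome(n_chrom = 2, total_len = 1e4),
               class = "radmap_param_error")
})

test_that("gene counts follow the requested density", {
  # Poisson mean = density x length; check within 4 sd over one draw
  g <- simulate_genome(n_chrom = 1, total_len = 10e6,
                       density_amplitude = 0, seed = 5)
  expect_lt(abs(nrow(g$genes) - 282), 4 * sqrt(282))
})

test_that("windowed gene density varies at least 3-fold by default", {
  g <- simulate_genome(n_chrom = 2, total_len = 20e6, seed = 9)
  for (cn in g$chromosomes$name) {
    s <- g$genes$start[g$genes$chrom == cn]
    counts <- table(cut(s, seq(0, 1e7, by = 1e6)))
    expect_gte(max(counts) / max(min(counts), 1), 3)
  }
})

test_that("plant_landscape step function and closed-form totals", {
  g <- simulate_genome(n_chrom = 2, total_len = 4e6, gene_density = 1e-5,
                       seed = 1)
  ls <- plant_landscape(g, background = 5.5,
                        hotspots = data.frame(chrom = "chr01", start = 1e5,
                                              end = 1.2e5, rate = 60))
  L <- 2  # Mb per chromosome
  expect_equal(ls$total_cm[["chr01"]], 5.5 * (L - 0.02) + 60 * 0.02)
  expect_equal(ls$total_cm[["chr02"]], 5.5 * L)
  # intervals tile each chromosome without gaps
  iv <- ls$intervals[ls$intervals$chrom == "chr01", ]
  expect_equal(iv$start[-1], iv$end[-nrow(iv)])
  expect_equal(sum(iv$end - iv$start), 2e6)

  ls0 <- plant_landscape(g, background = 0)
  expect_true(all(ls0$total_cm == 0))

  expect_error(plant_landscape(g, background = 5.5,
                               hotspots = data.frame(chrom = "chr01",
                                                     start = 0, end = 1e5,
                                                     rate = 20)),
               class = "radmap_param_error")
  expect_error(plant_landscape(
    g, background = 1,
    hotspots = data.frame(chrom = "chr01", start = c(0, 5e4),
                          end = c(1e5, 1.5e5), rate = 20)),
    class = "radmap_param_error")
})

test_that("fragment_scaffolds partitions chromosomes, >= 1 kb each", {
  g <- simulate_genome(n_chrom = 2, total_len = 10e6, seed = 3)
  sc <- fragment_scaffolds(g, mean_len = 5e5, seed = 7)
  for (cn in g$chromosomes$name) {
    s <- sc[sc$chrom == cn, ]
    s <- s[order(s$start), ]
    expect_equal(s$start[1], 0)
    expect_equal(s$end[nrow(s)],
                 g$chromosomes$length[g$chromosomes$name == cn])
    expect_equal(s$start[-1], s$end[-nrow(s)])
  }
  expect_true(all(sc$length >= 1000))
  expect_true(all(sc$orientation %in% c("+", "-")))
  # expected count ~ Poisson(length/mean): 20 breaks over 10 Mb
  expect_lt(abs(nrow(sc) - 20), 4 * sqrt(20) + 2)
  # a huge mean length yields one scaffold per chromosome
  sc1 <- fragment_scaffolds(g, mean_len = 1e9, seed = 20)
  expect_lte(nrow(sc1), 4)
  expect_error(fragment_scaffolds(g, mean_len = 500),
               class = "radmap_param_error")
})

test_that("scaffold sequences reconstruct the chromosome", {
  g <- simulate_genome(n_chrom = 1, total_len = 5e4, gene_density = 1e-5,
                       seed = 2)
  sc_multi <- fragment_scaffolds(g, mean_len = 8e3, seed = 5)
  sc_one <- data.frame(scaffold = "W1", chrom = "chr01", start = 0,
                       end = 5e4, orientation = "+", length = 5e4)
  seq_multi <- scaffold_sequences(g, sc_multi, seed = 11)
  seq_one <- scaffold_sequences(g, sc_one, seed = 11)
  # same seed -> same underlying chromosome sequence; re-orienting and
  # concatenating the fragments must rebuild it exactly
  sc_multi <- sc_multi[order(sc_multi$start), ]
  parts <- vapply(seq_len(nrow(sc_multi)), function(i) {
    s <- seq_multi[[sc_multi$scaffold[i]]]
    if (sc_multi$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, "")
  expect_identical(paste(parts, collapse = ""), as.character(seq_one[[1]]))
})

test_that("simulate_cross segregation, determinism and error model", {
  w <- small_world()
  gm <- w$sim$gm

  # identical seed, identical world
  sim2 <- simulate_cross(w$genome, w$landscape, w$scaffolds,
                         markers_per_mb = 25, design = w$design,
                         pileup = TRUE)
  expect_identical(gm$calls, sim2$gm$calls)
  expect_identical(w$sim$pileup, sim2$pileup)
  expect_identical(w$sim$truth$markers, sim2$truth$markers)

  # 1:1 segregation: ~1% of markers fail an exact test at alpha = 0.01
  pvals <- apply(gm$calls, 1, function(x)
    stats::binom.test(sum(x == 1L), length(x))$p.value)
  expect_lt(mean(pvals < 0.01), 0.04)

  # markers on different chromosomes assort independently
  pairs <- linkage_pairs(gm)
  ti <- match(paste(gm$markers$scaffold, gm$markers$position),
              paste(w$sim$truth$markers$scaffold,
                    w$sim$truth$markers$position))
  chrom <- w$sim$truth$markers$chrom[ti]
  cross <- outer(chrom, chrom, "!=") & upper.tri(pairs$rf)
  expect_gt(mean(pairs$rf_raw[cross]), 0.42)

  expect_error(simulate_cross(w$genome,
                              structure(list(intervals = data.frame()),
                                        class = "rec_landscape"),
                              w$scaffolds, 25, w$design),
               class = "radmap_param_error")
})

test_that("mismatch fraction matches the Haldane inverse at n = 10000", {
  g <- simulate_genome(n_chrom = 1, total_len = 2e6, gene_density = 1e-5,
                       seed = 6)
  ls <- plant_landscape(g, background = 10)  # 20 cM chromosome
  sc <- data.frame(scaffold = "S1", chrom = "chr01", start = 0, end = 2e6,
                   orientation = "+", length = 2e6)
  class(sc) <- c("scaffold_truth", "data.frame")
  d <- cross_design(n_progeny = 10000, error = 0, missing = 0, seed = 8)
  sim <- simulate_cross(g, ls, sc, markers_per_mb = 10, design = d,
                        pileup = FALSE)
  mk <- sim$truth$markers
  # expected mismatch fraction between ends: r = (1 - exp(-2d/100)) / 2
  i <- which.min(mk$gpos); j <- which.max(mk$gpos)
  dcm <- mk$cm_true[j] - mk$cm_true[i]
  r_true <- 0.5 * (1 - exp(-2 * dcm / 100))
  pl <- pairwise_linkage(sim$gm, mk$id[i], mk$id[j])
  se <- sqrt(r_true * (1 - r_true) / 10000)
  expect_lt(abs(pl$rf - r_true), 3 * se + 1e-6)
})

test_that("zero-rate landscape gives perfectly co-segregating markers", {
  g <- simulate_genome(n_chrom = 1, total_len = 1e6, gene_density = 1e-5,
                       seed = 4)
  ls <- plant_landscape(g, background = 0)
  sc <- data.frame(scaffold = "S1", chrom = "chr01", start = 0, end = 1e6,
                   orientation = "+", length = 1e6)
  class(sc) <- c("scaffold_truth", "data.frame")
  d <- cross_design(n_progeny = 50, error = 0, missing = 0, seed = 5)
  sim <- simulate_cross(g, ls, sc, markers_per_mb = 20, design = d,
                        pileup = FALSE)
  lp <- linkage_pairs(sim$gm)
  R <- pmin(lp$mismatch, lp$n - lp$mismatch)
  expect_true(all(R[upper.tri(R)] == 0))
})

test_that("map length converges to the planted landscape total", {
  # error-free dense markers, several seeds; each estimate within 3 SE
  for (s in 1:3) {
    g <- simulate_genome(n_chrom = 1, total_len = 4e6, gene_density = 1e-5,
                         seed = s)
    ls <- plant_landscape(g, background = 25)  # 100 cM chromosome
    sc <- data.frame(scaffold = "S1", chrom = "chr01", start = 0, end = 4e6,
                     orientation = "+", length = 4e6)
    class(sc) <- c("scaffold_truth", "data.frame")
    d <- cross_design(n_progeny = 1000, error = 0, missing = 0,
                      seed = 100 + s)
    sim <- simulate_cross(g, ls, sc, markers_per_mb = 25, design = d,
                          pileup = FALSE)
    pairs <- linkage_pairs(sim$gm)
    groups <- group_markers(pairs)
    map <- build_map(sim$gm, groups, pairs = pairs)
    ml <- evaluate_map_length(map, sim$gm, sim$truth)
    expect_true(all(ml$within_3se))
  }
})
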