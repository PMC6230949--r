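# Marey profiles, genome-average rate, hotspot/coldspot calling and
# gene-density association.

# a profile built directly from anchor points on one chromosome
profile_from_anchors <- function(bp, cm, object = "Chr1") {
  map <- data.frame(group = "LG01", marker = sprintf("UM%06d", seq_along(bp)),
                    scaffold = "S1", position = bp, cm = cm,
                    stringsAsFactors = FALSE)
  class(map) <- c("linkage_map", "data.frame")
  attr(map, "group_lengths") <- c(LG01 = max(cm))
  attr(map, "total_cm") <- max(cm)
  asm <- structure(list(
    components = data.frame(object = object, group = "LG01", scaffold = "S1",
                            rank = 1, orientation = "+", start = 0,
                            end = max(bp) + 1, stringsAsFactors = FALSE),
    chromosomes = data.frame(object = object, group = "LG01",
                             length = max(bp) + 1, stringsAsFactors = FALSE),
    unplaced = character(), gap = 100), class = "anchored_assembly")
  marey_profile(map, asm)
}

test_that("marey_profile: interval rates, outlier repair, zero rates", {
  p <- profile_from_anchors(c(1e6, 2e6), c(10, 20))
  expect_equal(nrow(p$intervals), 1L)
  expect_equal(p$intervals$rate, 10)

  # one wild cM value breaks monotonicity and is dropped by the LNDS
  p2 <- profile_from_anchors(c(1e6, 2e6, 3e6, 4e6), c(10, 50, 20, 30))
  expect_equal(p2$anchors$cm, c(10, 20, 30))
  expect_equal(p2$anchors$bp, c(1e6, 3e6, 4e6))

  # co-located markers (same cM) give a zero-rate interval
  p3 <- profile_from_anchors(c(1e6, 2e6, 3e6), c(10, 10, 20))
  expect_equal(p3$intervals$rate, c(0, 10))

  # a map running against physical coordinates is flipped, not emptied
  p4 <- profile_from_anchors(c(1e6, 2e6, 3e6), c(20, 10, 0))
  expect_equal(nrow(p4$anchors), 3L)
  expect_equal(p4$intervals$rate, c(10, 10))
})

test_that("genome_average_rate is length-weighted", {
  p <- profile_from_anchors(c(0, 2e6), c(0, 10))
  expect_equal(genome_average_rate(p), 5)
  p2 <- profile_from_anchors(c(0, 1e6, 10e6), c(0, 10, 10))
  expect_equal(genome_average_rate(p2), 1)  # not mean(c(10, 0)) = 5
  # invariant under subdivision of intervals
  p3 <- profile_from_anchors(seq(0, 10e6, by = 5e5),
                             approx(c(0, 1e6, 10e6), c(0, 10, 10),
                                    xout = seq(0, 10e6, by = 5e5))$y)
  expect_equal(genome_average_rate(p3), 1)
})

test_that("call_hotspots: strict threshold, merging, fold annotation", {
  p <- profile_from_anchors(c(0, 1e6, 1.1e6, 1.2e6, 2.2e6),
                            c(0, 5.5, 11.5, 17.5, 23))
  hs <- call_hotspots(p, avg = 5.5, fold = 10)
  # two adjacent 60 cM/Mb intervals merge into one call
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$start, 1e6); expect_equal(hs$end, 1.2e6)
  expect_equal(hs$rate, 60)
  expect_equal(round(hs$fold, 1), 10.9)
  # an interval at exactly the threshold is not a hotspot
  p2 <- profile_from_anchors(c(0, 1e6, 1.1e6), c(0, 5.5, 5.5 + 5.5))
  expect_equal(nrow(call_hotspots(p2, avg = 5.5, fold = 10)), 0L)
  expect_error(call_hotspots(p, avg = 0), class = "radmap_param_error")
})

test_that("call_coldspots: zero runs above the span threshold", {
  p <- profile_from_anchors(c(0, 5e5, 1e6, 2.5e6, 3e6),
                            c(0, 2, 2, 2, 4))
  cs <- call_coldspots(p, min_span_mb = 1)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$start, 5e5); expect_equal(cs$end, 2.5e6)
  expect_equal(cs$span_mb, 2)
  # a 0.8 Mb zero run is below the span threshold
  p2 <- profile_from_anchors(c(0, 5e5, 13e5, 2e6), c(0, 2, 2, 4))
  expect_equal(nrow(call_coldspots(p2, min_span_mb = 1)), 0L)
})

test_that("hotspot calls are invariant under map reversal", {
  w <- small_world()
  pairs <- linkage_pairs(w$sim$gm)
  groups <- group_markers(pairs)
  map <- build_map(w$sim$gm, groups, pairs = pairs)
  pl <- assign_scaffolds(map)
  slen <- setNames(w$scaffolds$length, w$scaffolds$scaffold)
  asm <- order_and_orient(pl, map, slen)
  p1 <- marey_profile(map, asm)

  map2 <- map
  for (g in unique(map2$group)) {
    i <- map2$group == g
    map2$cm[i] <- max(map2$cm[i]) - map2$cm[i]
  }
  p2 <- marey_profile(map2, asm)
  h1 <- call_hotspots(p1, genome_average_rate(p1))
  h2 <- call_hotspots(p2, genome_average_rate(p2))
  o1 <- order(h1$object, h1$start); o2 <- order(h2$object, h2$start)
  expect_equal(h1$start[o1], h2$start[o2])
  expect_equal(h1$end[o1], h2$end[o2])
  expect_equal(h1$rate[o1], h2$rate[o2], tolerance = 1e-12)
})

test_that("per-chromosome interval cM sums to the filtered map span", {
  w <- small_world()
  pairs <- linkage_pairs(w$sim$gm)
  groups <- group_markers(pairs)
  map <- build_map(w$sim$gm, groups, pairs = pairs)
  pl <- assign_scaffolds(map)
  slen <- setNames(w$scaffolds$length, w$scaffolds$scaffold)
  asm <- order_and_orient(pl, map, slen)
  p <- marey_profile(map, asm)
  for (obj in unique(p$anchors$object)) {
    a <- p$anchors[p$anchors$object == obj, ]
    iv <- p$intervals[p$intervals$object == obj, ]
    expect_equal(sum(iv$dcm), max(a$cm) - min(a$cm))
  }
})

test_that("gene_density counts starts in the region", {
  genes <- data.frame(chrom = "Chr1",
                      start = c(10, 5e4, 9e4, 2e5),
                      end = c(2e4, 6e4, 1.2e5, 3e5),
                      id = sprintf("G%02d", 1:4))
  expect_equal(gene_density(genes, "Chr1", 0, 1e5), 3)
  expect_equal(gene_density(genes, "Chr1", 5e6, 6e6), 0)
  expect_error(gene_density(genes, "Chr1", 10, 10),
               class = "radmap_param_error")
})

test_that("associate_gene_density summarises fractions and gene lists", {
  genes <- data.frame(object = "Chr1",
                      start = c(seq(1e6, 1.09e6, by = 1e4), 5e6),
                      id = sprintf("G%02d", 1:11),
                      stringsAsFactors = FALSE)
  hs <- data.frame(object = "Chr1", start = 1e6, end = 1.1e6,
                   dcm = 10, rate = 100, fold = 18)
  cs <- data.frame(object = "Chr1", start = 3e6, end = 4.5e6, span_mb = 1.5)
  out <- associate_gene_density(hs, cs, genes, density_threshold = 3,
                                genome_avg_density = 2.82)
  expect_equal(out$hotspot_genes$gene_density, 10)
  expect_setequal(out$hotspot_genes$gene_ids[[1]], sprintf("G%02d", 1:10))
  expect_equal(out$pct_hotspots_dense, 100)
  expect_equal(out$pct_coldspots_sparse, 100)
  expect_equal(out$n_hotspot_genes, 10L)

  empty <- associate_gene_density(hs[0, ], cs[0, ], genes, 3, 2.82)
  expect_true(is.na(empty$pct_hotspots_dense))
  expect_true(is.na(empty$pct_coldspots_sparse))
})

test_that("crossover-gene coupling shows up in the association report", {
  # genes enriched inside the planted hotspots and depleted in the
  # coldspot: hotspot calls should be dense, coldspot calls sparse
  peaks <- rbind(
    data.frame(chrom = "chr01", start = 15e5, end = 16e5, mult = 8),
    data.frame(chrom = "chr02", start = 1e6, end = 25e5, mult = 0.1))
  genome <- simulate_genome(n_chrom = 2, total_len = 8e6, peaks = peaks,
                            seed = 42)
  w <- small_world()
  sim <- simulate_cross(genome, w$landscape, w$scaffolds,
                        markers_per_mb = 25, design = w$design,
                        pileup = FALSE)
  pairs <- linkage_pairs(sim$gm)
  groups <- group_markers(pairs)
  map <- build_map(sim$gm, groups, pairs = pairs)
  pl <- assign_scaffolds(map)
  slen <- setNames(w$scaffolds$length, w$scaffolds$scaffold)
  asm <- order_and_orient(pl, map, slen)
  p <- marey_profile(map, asm)
  avg <- genome_average_rate(p)
  hs <- call_hotspots(p, avg)
  cs <- call_coldspots(p)
  truth <- sim$truth
  genes_ps <- radmap:::genes_on_pseudomolecules(truth, asm)
  gdens <- genes_per_100kb(nrow(genome$genes),
                           sum(genome$chromosomes$length))
  out <- associate_gene_density(hs, cs, genes_ps,
                                genome_avg_density = gdens)
  expect_gt(nrow(hs), 0)
  expect_gt(nrow(cs), 0)
  # directional: hotspots dense, the coldspot sparse
  expect_gt(max(out$hotspot_genes$gene_density), gdens)
  expect_lt(min(out$coldspots$gene_density), gdens)
})
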