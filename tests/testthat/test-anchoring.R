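# Scaffold assignment, ordering/orientation, AGP emission, N50.

# a hand-built linkage map for rule tests
toy_map <- function() {
  df <- data.frame(
    group = c("LG01", "LG01", "LG01", "LG01", "LG01",
              "LG04", "LG04", "LG01", "LG01"),
    marker = sprintf("UM%06d", 1:9),
    scaffold = c("A", "A", "A", "B", "B", "B", "B", "C", "D"),
    position = c(100, 500, 900, 100, 400, 700, 900, 300, 200),
    cm = c(0, 2, 4, 6, 8, 1, 2, 10, 12),
    stringsAsFactors = FALSE)
  gl <- vapply(split(df$cm, df$group), max, 0)
  structure(df, class = c("linkage_map", "data.frame"),
            group_lengths = gl, total_cm = sum(gl))
}

test_that("assign_scaffolds: majority vote and chimera flag", {
  pl <- assign_scaffolds(toy_map())
  a <- pl[pl$scaffold == "A", ]
  expect_equal(a$group, "LG01"); expect_false(a$chimera); expect_true(a$placed)
  # B has 2 markers on LG01 and 2 on LG04 -> chimera, unplaced
  b <- pl[pl$scaffold == "B", ]
  expect_true(b$chimera); expect_false(b$placed)
  # single-marker scaffolds are placed by default, not when disabled
  expect_true(pl[pl$scaffold == "C", "placed"])
  pl2 <- assign_scaffolds(toy_map(), place_single_marker = FALSE)
  expect_false(pl2[pl2$scaffold == "C", "placed"])
})

test_that("order_and_orient: rank by mean cM, orientation by bp-cM trend", {
  map <- toy_map()
  pl <- assign_scaffolds(map)
  lens <- c(A = 1000, B = 1000, C = 500, D = 400)
  asm <- order_and_orient(pl, map, lens, gap = 100)
  comp <- asm$components
  # A (mean 2 cM) before C (10) before D (12); B is unplaced
  expect_equal(comp$scaffold, c("A", "C", "D"))
  expect_equal(comp$rank, 1:3)
  expect_equal(asm$unplaced, "B")
  # A: cm increases with bp -> "+"; C, D single marker -> "?"
  expect_equal(comp$orientation, c("+", "?", "?"))
  # offsets include 100 bp gaps
  expect_equal(comp$start, c(0, 1100, 1700))
  expect_equal(comp$end, c(1000, 1600, 2100))

  # reversed within-scaffold trend gives "-"
  map2 <- toy_map()
  map2$cm[1:3] <- c(4, 2, 0)
  asm2 <- order_and_orient(assign_scaffolds(map2), map2, lens, gap = 100)
  expect_equal(asm2$components$orientation[asm2$components$scaffold == "A"],
               "-")
})

test_that("emit_pseudomolecules writes AGP rows and consistent FASTA", {
  map <- data.frame(group = c("LG01", "LG01", "LG01", "LG01"),
                    marker = sprintf("UM%06d", 1:4),
                    scaffold = c("X", "X", "Y", "Y"),
                    position = c(100, 800, 200, 900),
                    cm = c(0, 1, 5, 6), stringsAsFactors = FALSE)
  class(map) <- c("linkage_map", "data.frame")
  attr(map, "group_lengths") <- c(LG01 = 6); attr(map, "total_cm") <- 6
  pl <- assign_scaffolds(map)
  seqs <- Biostrings::DNAStringSet(c(
    X = paste(rep("ACGT", 250), collapse = ""),
    Y = paste(rep("GGCA", 250), collapse = "")))
  asm <- order_and_orient(pl, map, setNames(Biostrings::width(seqs),
                                            names(seqs)), gap = 100)
  out <- emit_pseudomolecules(asm, seqs)
  expect_equal(Biostrings::width(out$fasta)[[1]], 2100)
  agp <- out$agp
  expect_equal(agp$component_type, c("W", "U", "W"))
  expect_equal(agp$object_beg, c(1, 1001, 1101))
  expect_equal(agp$object_end, c(1000, 1100, 2100))
  expect_equal(agp$part_number, 1:3)
  # gap line fields: length, type, linkage, evidence
  expect_equal(as.numeric(agp$component_id[2]), 100)
  expect_equal(agp$component_beg[2], "contig")
  expect_equal(agp$component_end[2], "yes")
  expect_equal(agp$orientation[2], "map")

  # AGP -> FASTA round trip reproduces the emitted sequence exactly
  rebuilt <- lapply(split(agp, agp$object), function(rows) {
    rows <- rows[order(rows$object_beg), ]
    paste(vapply(seq_len(nrow(rows)), function(i) {
      if (rows$component_type[i] == "U")
        return(paste(rep("N", as.integer(rows$component_id[i])),
                     collapse = ""))
      s <- seqs[[rows$component_id[i]]]
      if (rows$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, ""), collapse = "")
  })
  expect_identical(rebuilt[["Chr1"]], as.character(out$fasta[["Chr1"]]))

  # a reversed scaffold is emitted reverse-complemented
  asm$components$orientation[1] <- "-"
  out2 <- emit_pseudomolecules(asm, seqs)
  first <- Biostrings::subseq(out2$fasta[[1]], 1, 1000)
  expect_identical(as.character(first),
                   as.character(Biostrings::reverseComplement(seqs[["X"]])))

  expect_error(emit_pseudomolecules(asm, seqs["Y"]),
               class = "radmap_param_error")
})

test_that("assembly_stats matches a brute-force N50/N90 oracle", {
  oracle <- function(lengths, q) {
    s <- sort(lengths, decreasing = TRUE)
    for (i in seq_along(s)) if (sum(s[1:i]) >= q * sum(s)) return(s[i])
  }
  expect_equal(assembly_stats(c(5, 4, 3, 2, 1))$n50, 4)
  expect_equal(assembly_stats(10)$n50, 10)
  expect_equal(assembly_stats(10)$n90, 10)
  expect_equal(assembly_stats(rep(7, 13))$n50, 7)
  set.seed(99)
  for (i in 1:1000) {
    lens <- sample(1e6, sample(1:50, 1), replace = TRUE)
    st <- assembly_stats(lens)
    expect_identical(st$n50, oracle(lens, 0.5))
    expect_identical(st$n90, oracle(lens, 0.9))
  }
  expect_error(assembly_stats(numeric()), class = "radmap_param_error")
  expect_error(assembly_stats(c(5, 0)), class = "radmap_param_error")
})

test_that("joining scaffolds never lowers N50", {
  set.seed(7)
  for (i in 1:50) {
    lens <- sample(1e5, 20)
    joined <- c(sum(lens[1:2]) + 100, lens[-(1:2)])
    expect_gte(assembly_stats(joined)$n50, assembly_stats(lens)$n50)
  }
})

test_that("anchoring recovers simulated scaffold placement", {
  w <- small_world()
  pairs <- linkage_pairs(w$sim$gm)
  groups <- group_markers(pairs)
  map <- build_map(w$sim$gm, groups, pairs = pairs)
  pl <- assign_scaffolds(map)
  slen <- setNames(w$scaffolds$length, w$scaffolds$scaffold)
  asm <- order_and_orient(pl, map, slen)
  ev <- evaluate_anchoring(pl, asm, w$sim$gm, groups, w$sim$truth)
  expect_equal(ev$assignment_accuracy, 1)
  expect_equal(ev$orientation_accuracy, 1)
  expect_true(all(ev$rank_concordance >= 1 - 1e-9))
  # AGP validates: parts sequential, coordinates contiguous
  agp <- assembly_agp(asm)
  for (obj in unique(agp$object)) {
    rows <- agp[agp$object == obj, ]
    expect_equal(rows$part_number, seq_len(nrow(rows)))
    expect_equal(rows$object_beg[-1], rows$object_end[-nrow(rows)] + 1)
    expect_equal(rows$object_beg[1], 1)
  }
})
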