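# End-to-end driver: simulate -> call markers -> map -> anchor ->
# landscape -> stats -> report.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "radmap_stage_error")) stop(e)
    stage_error(stage, conditionMessage(e))
  })
}

#' Run the full pipeline on a synthetic cross
#'
#' Executes every stage on a seeded synthetic world described by the
#' configuration, writes the intermediate files and a machine-readable
#' JSON report under `cfg$outdir` (when `write_outputs` is TRUE), and
#' returns all in-memory objects for programmatic use.
#'
#' @param cfg A [default_config()] configuration.
#' @return Invisibly, a list with `truth`, `gm` (post-filter genotype
#'   matrix), `map`, `placements`, `assembly`, `profile`, `hotspots`,
#'   `coldspots`, `association` and `report`.
#' @export
run_pipeline <- function(cfg = default_config()) {
  stopifnot(inherits(cfg, "run_config"))

  sim <- run_stage("simulate", {
    genome <- simulate_genome(n_chrom = cfg$n_chrom, total_len = cfg$total_len,
                              gene_density = cfg$gene_density,
                              mean_gene_len = cfg$mean_gene_len, gc = cfg$gc,
                              seed = child_seed(cfg$seed, 1))
    landscape <- default_landscape(genome, background = cfg$background_rate,
                                   hotspot_rate = cfg$hotspot_rate)
    scaffolds <- fragment_scaffolds(genome, mean_len = cfg$scaffold_mean_len,
                                    seed = child_seed(cfg$seed, 2))
    design <- cross_design(n_progeny = cfg$n_progeny, error = cfg$error,
                           missing = cfg$missing, depth = cfg$depth,
                           parent_depth = cfg$parent_depth,
                           seed = child_seed(cfg$seed, 3))
    simulate_cross(genome, landscape, scaffolds,
                   markers_per_mb = cfg$markers_per_mb, design = design,
                   pileup = cfg$use_pileup)
  })

  gm <- run_stage("callmarkers", {
    g <- if (cfg$use_pileup) {
      defs <- define_markers(sim$pileup, "P1", "P2",
                             min_parent_depth = cfg$min_parent_depth,
                             het_min_minor_frac = cfg$het_min_minor_frac)
      call_genotypes(sim$pileup, defs, min_depth = cfg$min_depth,
                     exclude = c("P1", "P2"))
    } else sim$gm
    filter_individuals(g, max_missing = cfg$max_missing,
                       dup_identity = cfg$dup_identity,
                       min_shared = cfg$min_shared)
  })

  mapres <- run_stage("map", {
    pairs <- linkage_pairs(gm)
    groups <- group_markers(pairs, max_rf = cfg$max_rf, min_lod = cfg$min_lod)
    map <- build_map(gm, groups, pairs = pairs)
    list(pairs = pairs, groups = groups, map = map)
  })

  anch <- run_stage("anchor", {
    placements <- assign_scaffolds(mapres$map)
    slen <- setNames(sim$truth$scaffolds$length, sim$truth$scaffolds$scaffold)
    assembly <- order_and_orient(placements, mapres$map, slen, gap = cfg$gap)
    seqs <- NULL; pseudo <- NULL
    if (cfg$emit_sequences) {
      seqs <- scaffold_sequences(sim$truth$genome, sim$truth$scaffolds,
                                 seed = child_seed(cfg$seed, 4))
      pseudo <- emit_pseudomolecules(assembly, seqs)
    }
    list(placements = placements, assembly = assembly, seqs = seqs,
         pseudo = pseudo, scaffold_lengths = slen)
  })

  land <- run_stage("landscape", {
    profile <- marey_profile(mapres$map, anch$assembly)
    avg <- genome_average_rate(profile)
    hotspots <- call_hotspots(profile, avg, fold = cfg$hotspot_fold)
    coldspots <- call_coldspots(profile, min_span_mb = cfg$min_coldspot_mb)
    genes_ps <- genes_on_pseudomolecules(sim$truth, anch$assembly)
    gdens <- genes_per_100kb(nrow(sim$truth$genome$genes),
                             sum(sim$truth$genome$chromosomes$length))
    assoc <- associate_gene_density(hotspots, coldspots, genes_ps,
                                    density_threshold = cfg$density_threshold,
                                    genome_avg_density = gdens)
    list(profile = profile, avg = avg, hotspots = hotspots,
         coldspots = coldspots, association = assoc, genes_ps = genes_ps,
         genome_gene_density = gdens)
  })

  report <- run_stage("report", {
    slen <- anch$scaffold_lengths
    input_stats <- assembly_stats(unname(slen))
    placed_stats <- assembly_stats(anch$assembly$chromosomes$length)
    gl <- attr(mapres$map, "group_lengths")
    list(
      seed = cfg$seed,
      n_markers = nrow(gm$calls),
      n_individuals = length(gm$individuals),
      n_groups = length(gl),
      group_lengths_cm = as.list(gl),
      total_cm = attr(mapres$map, "total_cm"),
      marker_spacing_cm = marker_spacing(attr(mapres$map, "total_cm"),
                                         nrow(mapres$map), length(gl)),
      n_scaffolds = length(slen),
      n_placed = nrow(anch$assembly$components),
      n_unplaced = length(anch$assembly$unplaced),
      n_chimera = sum(anch$placements$chimera),
      input_n50 = input_stats$n50,
      pseudomolecule_n50 = placed_stats$n50,
      genome_avg_rate = land$avg,
      genome_gene_density = land$genome_gene_density,
      n_hotspots = nrow(land$hotspots),
      n_coldspots = nrow(land$coldspots),
      pct_hotspots_dense = land$association$pct_hotspots_dense,
      pct_coldspots_sparse = land$association$pct_coldspots_sparse)
  })

  if (isTRUE(cfg$write_outputs)) {
    run_stage("write", write_run_outputs(cfg, sim, gm, mapres, anch, land,
                                         report))
  }

  invisible(list(truth = sim$truth, pileup = sim$pileup, gm = gm,
                 pairs = mapres$pairs, groups = mapres$groups,
                 map = mapres$map, placements = anch$placements,
                 assembly = anch$assembly, profile = land$profile,
                 hotspots = land$hotspots, coldspots = land$coldspots,
                 association = land$association, report = report))
}

# Project genes from genome coordinates through the scaffold truth and
# the inferred assembly onto pseudomolecule coordinates.  Membership is
# by gene start.
genes_on_pseudomolecules <- function(truth, assembly) {
  g <- genes_on_scaffolds(truth$genome, truth$scaffolds)
  lifted <- lift_to_pseudomolecule(assembly, g$chrom, g$start)
  ok <- !is.na(lifted$pos)
  data.frame(object = lifted$object[ok], start = lifted$pos[ok],
             id = g$id[ok], stringsAsFactors = FALSE)
}

#' Genes in scaffold coordinates
#'
#' Maps each gene's start from genome to scaffold-local coordinates via
#' the scaffold truth (the coordinate system real annotations would be
#' delivered in).
#'
#' @param genome A [simulate_genome()] result.
#' @param scaffolds A [fragment_scaffolds()] truth table.
#' @return data.frame `chrom` (scaffold id), `start`, `end`, `id`.
#' @export
genes_on_scaffolds <- function(genome, scaffolds) {
  g <- genome$genes
  sc <- scaffolds
  out_scaf <- rep(NA_character_, nrow(g))
  out_pos <- rep(NA_real_, nrow(g))
  for (r in seq_len(nrow(sc))) {
    i <- g$chrom == sc$chrom[r] & g$start >= sc$start[r] & g$start < sc$end[r]
    if (!any(i)) next
    local <- g$start[i] - sc$start[r]
    if (sc$orientation[r] == "-") local <- (sc$length[r] - 1) - local
    out_scaf[i] <- sc$scaffold[r]
    out_pos[i] <- local
  }
  ok <- !is.na(out_scaf)
  data.frame(chrom = out_scaf[ok], start = out_pos[ok],
             end = out_pos[ok] + (g$end[ok] - g$start[ok]),
             id = g$id[ok], stringsAsFactors = FALSE)
}

write_run_outputs <- function(cfg, sim, gm, mapres, anch, land, report) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$outdir, f)
  write_config(cfg, p("config.yaml"))
  write_genotypes(gm, p("genotypes.tsv"))
  if (!is.null(sim$pileup)) write_pileup(sim$pileup, p("pileup.tsv"))
  write_map_tsv(mapres$map, p("map.tsv"))
  write.table(as.data.frame(anch$placements), p("placements.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_agp(assembly_agp(anch$assembly), p("assembly.agp"))
  writeLines(anch$assembly$unplaced, p("unplaced.txt"))
  write_rate_bedgraph(land$profile, p("rates.bedgraph"))
  write.table(land$hotspots, p("hotspots.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(land$coldspots, p("coldspots.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gff3(genes_on_scaffolds(sim$truth$genome, sim$truth$scaffolds),
             p("genes_scaffolds.gff3"))
  write_truth_json(sim$truth, p("truth.json"))
  if (!is.null(anch$pseudo)) {
    write_fasta(anch$seqs, p("scaffolds.fasta"))
    write_fasta(anch$pseudo$fasta, p("pseudomolecules.fasta"))
  }
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(cfg$outdir)
}
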