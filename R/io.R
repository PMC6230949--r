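# Readers and writers for the pipeline's on-disk formats.
#
# Coordinates are 0-based half-open in memory; GFF3 and AGP are written
# 1-based inclusive as their specifications require.  Conversion
# happens here and nowhere else.

#' Write / read a genotype matrix TSV
#'
#' Rows are markers (`id`, `scaffold`, `position`, then one column per
#' individual with `0`, `1` or `-` for missing).
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- gm$calls
  chr <- matrix(as.character(m), nrow(m))
  chr[is.na(chr)] <- "-"
  df <- data.frame(id = gm$markers$id, scaffold = gm$markers$scaffold,
                   position = gm$markers$position, chr,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[-(1:3)] <- gm$individuals
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  markers <- data.frame(id = df$id, scaffold = df$scaffold,
                        position = as.numeric(df$position),
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  calls <- matrix(NA_integer_, nrow(m), ncol(m))
  calls[m == "0"] <- 0L
  calls[m == "1"] <- 1L
  colnames(calls) <- colnames(m)
  genotype_matrix(markers, calls, colnames(m))
}

#' Write / read a pileup TSV
#'
#' Columns `scaffold`, `pos` (0-based), `sample`, `A`, `C`, `G`, `T`.
#'
#' @param pileup Pileup data.frame.
#' @param path File path.
#' @export
write_pileup <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read the linkage-map TSV
#'
#' Columns `group`, `marker`, `scaffold`, `position`, `cm`.
#'
#' @param map A [build_map()] result.
#' @param path File path.
#' @export
write_map_tsv <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  gl <- vapply(split(df$cm, df$group), max, 0)
  structure(df, class = c("linkage_map", "data.frame"),
            group_lengths = gl, total_cm = sum(gl))
}

#' Write / read an AGP 2.1 file
#'
#' @param agp An [assembly_agp()] data.frame.
#' @param path File path.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  write.table(agp, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_agp
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  df <- read.table(text = lines, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("object", "object_beg", "object_end", "part_number",
                 "component_type", "component_id", "component_beg",
                 "component_end", "orientation")
  df
}

#' Write a FASTA file
#'
#' @param seqs A [Biostrings::DNAStringSet].
#' @param path File path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write gene annotations as GFF3
#'
#' Genes are stored 0-based half-open in memory and written 1-based
#' inclusive.  `seqid` is the `chrom` column.
#'
#' @param genes data.frame `chrom`, `start`, `end`, `id`.
#' @param path File path.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    type = "gene", ID = genes$id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Lightweight structural validation first (every non-comment line must
#' have nine tab-separated fields with numeric bounds) so malformed
#' files fail with the offending line number; then parsed with
#' rtracklayer.
#'
#' @param path File path.
#' @param stage Label used in error messages.
#' @return data.frame `chrom`, `start` (0-based), `end`, `id`.
#' @export
read_gff3 <- function(path, stage = "read_gff3") {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9 || is.na(suppressWarnings(as.numeric(f[4]))) ||
        is.na(suppressWarnings(as.numeric(f[5]))))
      stage_error(stage, "malformed GFF3 at line ", i, " of ", path)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             id = if (!is.null(gr$ID)) as.character(gr$ID)
                  else sprintf("G%06d", seq_along(gr)),
             stringsAsFactors = FALSE)
}

#' Write marker sites as BED (0-based half-open)
#'
#' @param defs A `marker_defs` data.frame.
#' @param path File path.
#' @export
write_marker_bed <- function(defs, path) {
  df <- data.frame(defs$scaffold, defs$position, defs$position + 1, defs$id)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write per-interval recombination rates as BEDGRAPH
#'
#' @param profile A [marey_profile()].
#' @param path File path.
#' @export
write_rate_bedgraph <- function(profile, path) {
  iv <- profile$intervals
  df <- data.frame(iv$object, iv$start, iv$end, signif(iv$rate, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Serialise / load the simulator truth as JSON
#'
#' @param truth A `truth_set` (see [simulate_cross()]).
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(
    chromosomes = truth$genome$chromosomes,
    genes = truth$genome$genes,
    landscape = truth$landscape$intervals,
    hotspots = truth$landscape$hotspots,
    coldspots = truth$landscape$coldspots,
    total_cm = as.list(truth$landscape$total_cm),
    scaffolds = as.data.frame(truth$scaffolds),
    markers = truth$markers,
    design = unclass(truth$design))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Every tunable of the end-to-end pipeline with its default: the
#' scaled-down synthetic world (19 x 5 Mb chromosomes, 30 markers/Mb,
#' 184 progeny) and the standard analysis thresholds (min depth 3,
#' rf < 0.4, LOD > 10, 10x hotspot fold, 1 Mb coldspot span, 3
#' genes/100 kb density threshold).
#'
#' @param ... Overrides (unknown keys are rejected).
#' @return A named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    outdir = tempfile("radmap_run_"),
    n_chrom = 19, total_len = 95e6,
    gene_density = 2.82e-5, mean_gene_len = 11538, gc = 0.344,
    background_rate = 5.5, hotspot_rate = 100,
    scaffold_mean_len = 1e6,
    markers_per_mb = 30,
    n_progeny = 184, error = 0.005, missing = 0.15,
    depth = 8, parent_depth = 30,
    min_depth = 3, min_parent_depth = 5, het_min_minor_frac = 0.25,
    max_missing = 0.5, dup_identity = 0.95, min_shared = 100,
    max_rf = 0.4, min_lod = 10,
    gap = 100,
    hotspot_fold = 10, min_coldspot_mb = 1, density_threshold = 3,
    use_pileup = TRUE, emit_sequences = FALSE, write_outputs = TRUE)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) param_error("unknown config key(s): ",
                               paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param cfg A [default_config()] list.
#' @param path File path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}
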