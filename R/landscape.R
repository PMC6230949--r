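# Marey-map recombination-rate landscape along pseudomolecules.
#
# Each anchored marker contributes a (physical bp, genetic cM) point;
# after repairing monotonicity the local slope between consecutive
# anchors is the recombination rate in cM/Mb.  Hotspots are intervals
# whose rate exceeds a fold multiple (default 10x) of the
# length-weighted genome average; coldspots are zero-recombination runs
# longer than a minimum span (default 1 Mb).

#' Marey profile of an anchored linkage map
#'
#' Marker map positions are lifted to pseudomolecule coordinates via
#' the assembly.  Per chromosome, the cM track is flipped if it runs
#' against physical coordinates (a map and its reversal are the same
#' map), then discordant anchors are removed by the longest
#' non-decreasing subsequence on cM (ties kept), and rate intervals are
#' formed between consecutive surviving anchors.
#'
#' @param map A [build_map()] linkage map.
#' @param assembly An [order_and_orient()] assembly.
#' @return Object of class `marey_profile`: `anchors` (data.frame
#'   `object`, `bp`, `cm`) and `intervals` (data.frame `object`,
#'   `start`, `end`, `dcm`, `rate`).  Chromosomes with fewer than two
#'   usable anchors are skipped with a warning.
#' @export
marey_profile <- function(map, assembly) {
  stopifnot(inherits(map, "linkage_map"), inherits(assembly, "anchored_assembly"))
  mp <- as.data.frame(map)
  lifted <- lift_to_pseudomolecule(assembly, mp$scaffold, mp$position)
  # drop unplaced scaffolds; when the assembly carries linkage-group
  # labels (not the case for one rebuilt from a bare AGP), also drop
  # markers whose group disagrees with their scaffold's chromosome
  grp_of_obj <- unname(setNames(assembly$chromosomes$group,
                                assembly$chromosomes$object)[lifted$object])
  ok <- !is.na(lifted$pos) &
    (!(grp_of_obj %in% unique(mp$group)) | grp_of_obj == mp$group)
  ok[is.na(ok)] <- FALSE
  mp <- mp[which(ok), ]; lifted <- lifted[which(ok), ]

  anchors <- list(); intervals <- list()
  for (obj in assembly$chromosomes$object) {
    i <- lifted$object == obj
    if (sum(i) < 2) {
      warning("fewer than 2 anchors on ", obj, "; skipped")
      next
    }
    a <- data.frame(bp = lifted$pos[i], cm = mp$cm[i])
    a <- a[order(a$bp, a$cm), ]
    a <- a[!duplicated(a$bp), ]
    if (nrow(a) < 2) { warning("fewer than 2 anchors on ", obj, "; skipped"); next }
    tau <- suppressWarnings(cor(a$bp, a$cm, method = "kendall"))
    if (!is.na(tau) && tau < 0) a$cm <- max(a$cm) - a$cm
    keep <- lnds(a$cm)
    a <- a[keep, ]
    if (nrow(a) < 2) { warning("fewer than 2 anchors on ", obj, "; skipped"); next }
    anchors[[obj]] <- data.frame(object = obj, bp = a$bp, cm = a$cm,
                                 stringsAsFactors = FALSE)
    dcm <- diff(a$cm); dbp <- diff(a$bp)
    intervals[[obj]] <- data.frame(object = obj,
                                   start = head(a$bp, -1), end = tail(a$bp, -1),
                                   dcm = dcm, rate = dcm / (dbp / 1e6),
                                   stringsAsFactors = FALSE)
  }
  assert_that(length(intervals) > 0, "no chromosome had >= 2 anchors")
  structure(list(anchors = do.call(rbind, c(anchors, make.row.names = FALSE)),
                 intervals = do.call(rbind, c(intervals, make.row.names = FALSE))),
            class = "marey_profile")
}

# Longest non-decreasing subsequence (indices); leftmost-tie-keeping,
# O(n^2) dynamic program (fine at per-chromosome anchor counts).
lnds <- function(x) {
  n <- length(x)
  if (n == 0) return(integer())
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (x[j] <= x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L; prev[i] <- j
      }
    }
  }
  best <- which.max(len)
  out <- integer(len[best]); k <- len[best]; i <- best
  while (i > 0) { out[k] <- i; k <- k - 1L; i <- prev[i] }
  out
}

#' @export
print.marey_profile <- function(x, ...) {
  cat(sprintf("marey profile: %d chromosomes, %d anchors, %d intervals\n",
              length(unique(x$anchors$object)), nrow(x$anchors),
              nrow(x$intervals)))
  invisible(x)
}

#' Length-weighted genome-average recombination rate
#'
#' Total genetic length over total physical length across all profile
#' intervals -- not the mean of per-interval rates.
#'
#' @param profile A [marey_profile()].
#' @return Rate in cM/Mb.
#' @export
genome_average_rate <- function(profile) {
  stopifnot(inherits(profile, "marey_profile"))
  iv <- profile$intervals
  assert_that(nrow(iv) >= 1, "profile has no intervals")
  span <- sum(iv$end - iv$start)
  assert_that(span > 0, "zero physical span")
  sum(iv$dcm) / (span / 1e6)
}

#' Call recombination hotspots
#'
#' Intervals with rate strictly greater than `fold` times the genome
#' average; adjacent qualifying intervals are merged and the merged
#' rate recomputed over the merged span.
#'
#' @param profile A [marey_profile()].
#' @param avg Genome-average rate in cM/Mb (must be > 0).
#' @param fold Fold threshold (default 10).
#' @param merge Merge adjacent qualifying intervals? (default TRUE)
#' @return data.frame `object`, `start`, `end`, `dcm`, `rate`, `fold`.
#' @export
call_hotspots <- function(profile, avg = genome_average_rate(profile),
                          fold = 10, merge = TRUE) {
  stopifnot(inherits(profile, "marey_profile"))
  assert_that(avg > 0, "average rate must be positive")
  iv <- profile$intervals
  hot <- iv[iv$rate > fold * avg, ]
  if (nrow(hot) == 0)
    return(data.frame(object = character(), start = numeric(),
                      end = numeric(), dcm = numeric(), rate = numeric(),
                      fold = numeric(), stringsAsFactors = FALSE))
  if (merge) {
    hot <- hot[order(hot$object, hot$start), ]
    grp <- cumsum(!(c(FALSE, hot$object[-1] == hot$object[-nrow(hot)] &
                        hot$start[-1] == hot$end[-nrow(hot)])))
    hot <- do.call(rbind, lapply(split(hot, grp), function(h)
      data.frame(object = h$object[1], start = min(h$start), end = max(h$end),
                 dcm = sum(h$dcm), stringsAsFactors = FALSE)))
    hot$rate <- hot$dcm / ((hot$end - hot$start) / 1e6)
  }
  hot$fold <- hot$rate / avg
  rownames(hot) <- NULL
  hot[, c("object", "start", "end", "dcm", "rate", "fold")]
}

#' Call recombination coldspots
#'
#' Maximal runs of consecutive profile intervals with zero genetic
#' length whose physical span exceeds `min_span_mb`.
#'
#' @param profile A [marey_profile()].
#' @param min_span_mb Minimum span in Mb (strict `>`, default 1).
#' @return data.frame `object`, `start`, `end`, `span_mb`.
#' @export
call_coldspots <- function(profile, min_span_mb = 1) {
  stopifnot(inherits(profile, "marey_profile"))
  iv <- profile$intervals
  out <- list()
  for (obj in unique(iv$object)) {
    d <- iv[iv$object == obj, ]
    d <- d[order(d$start), ]
    zero <- d$dcm == 0
    if (!any(zero)) next
    run <- cumsum(c(TRUE, diff(zero) != 0 | d$start[-1] != d$end[-nrow(d)]))
    for (rr in split(seq_len(nrow(d))[zero], run[zero])) {
      s <- d$start[rr[1]]; e <- d$end[rr[length(rr)]]
      if ((e - s) / 1e6 > min_span_mb)
        out[[length(out) + 1]] <- data.frame(object = obj, start = s, end = e,
                                             span_mb = (e - s) / 1e6,
                                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(object = character(), start = numeric(),
                      end = numeric(), span_mb = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Gene density of a region
#'
#' Counts genes whose start coordinate lies in `[start, end)` and
#' scales to genes per 100 kb.
#'
#' @param genes data.frame with `chrom`/`object`, `start` columns
#'   (0-based) on the same coordinate system as the region.
#' @param chrom Chromosome/object name.
#' @param start,end Region bounds (0-based half-open); `end > start`.
#' @return Genes per 100 kb.
#' @export
gene_density <- function(genes, chrom, start, end) {
  assert_that(end > start, "region length must be positive")
  cc <- if ("object" %in% names(genes)) genes$object else genes$chrom
  n <- sum(cc == chrom & genes$start >= start & genes$start < end)
  genes_per_100kb(n, end - start)
}

#' Associate hotspots and coldspots with gene density
#'
#' For each hotspot: its gene density and member gene ids; summary
#' fractions of hotspots above a density threshold and of coldspots
#' below the genome-average density.
#'
#' @param hotspots A [call_hotspots()] result.
#' @param coldspots A [call_coldspots()] result.
#' @param genes Gene table on pseudomolecule coordinates (`object`,
#'   `start`, `id`).
#' @param density_threshold Hotspot density threshold in genes/100 kb
#'   (default 3).
#' @param genome_avg_density Genome-wide density in genes/100 kb.
#' @return List with per-hotspot `hotspot_genes` (data.frame plus
#'   `gene_ids` list-column), `pct_hotspots_dense`,
#'   `pct_coldspots_sparse` (NA when there are no calls), and counts.
#' @export
associate_gene_density <- function(hotspots, coldspots, genes,
                                   density_threshold = 3,
                                   genome_avg_density) {
  dens <- function(calls) {
    vapply(seq_len(nrow(calls)), function(i)
      gene_density(genes, calls$object[i], calls$start[i], calls$end[i]), 0)
  }
  hs <- hotspots
  if (nrow(hs)) {
    hs$gene_density <- dens(hs)
    hs$gene_ids <- lapply(seq_len(nrow(hs)), function(i) {
      cc <- if ("object" %in% names(genes)) genes$object else genes$chrom
      genes$id[cc == hs$object[i] & genes$start >= hs$start[i] &
                 genes$start < hs$end[i]]
    })
  }
  cs <- coldspots
  if (nrow(cs)) cs$gene_density <- dens(cs)
  list(hotspot_genes = hs, coldspots = cs,
       n_hotspots = nrow(hs), n_coldspots = nrow(cs),
       n_hotspot_genes = if (nrow(hs)) length(unique(unlist(hs$gene_ids))) else 0L,
       pct_hotspots_dense = if (nrow(hs))
         percentage(sum(hs$gene_density > density_threshold), nrow(hs), 1)
       else NA_real_,
       pct_coldspots_sparse = if (nrow(cs))
         percentage(sum(cs$gene_density < genome_avg_density), nrow(cs), 1)
       else NA_real_)
}
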