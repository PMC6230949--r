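# Truth-recovery metrics for simulation studies: compare pipeline
# output against the simulator's ground truth.

# Match markers of a genotype matrix to truth rows by (scaffold,
# position); returns truth indices (NA if not simulated, which cannot
# happen for simulator-derived matrices).
truth_index <- function(gm, truth) {
  match(paste(gm$markers$scaffold, gm$markers$position),
        paste(truth$markers$scaffold, truth$markers$position))
}

#' Compare linkage groups to the true chromosome partition
#'
#' @param gm The genotype matrix that was grouped.
#' @param groups A [group_markers()] result.
#' @param truth The simulator `truth_set`.
#' @return List: `exact` (TRUE when the non-singleton groups are
#'   exactly the per-chromosome marker sets), `n_groups`, `purity`
#'   (fraction of markers on their group's majority chromosome) and the
#'   `group_chrom` majority mapping.
#' @export
evaluate_grouping <- function(gm, groups, truth) {
  ti <- truth_index(gm, truth)
  chrom_of <- setNames(truth$markers$chrom[ti], gm$markers$id)
  gg <- groups$groups
  maj <- character(length(gg)); pure <- 0
  for (k in seq_along(gg)) {
    tc <- table(chrom_of[gg[[k]]])
    maj[k] <- names(tc)[which.max(tc)]
    pure <- pure + max(tc)
  }
  n_mapped <- sum(lengths(gg))
  per_chrom <- table(chrom_of)
  exact <- length(gg) == length(per_chrom) &&
    !anyDuplicated(maj) &&
    pure == n_mapped &&
    n_mapped == length(chrom_of) &&
    length(groups$unplaced) == 0
  list(exact = exact, n_groups = length(gg),
       purity = pure / n_mapped, group_chrom = maj)
}

#' Kendall correlation of marker order against truth
#'
#' Co-segregating markers share one map position and are inherently
#' unorderable, so the correlation is computed between distinct map
#' positions and the mean true genome coordinate of the markers at each
#' position.
#'
#' @param map A [build_map()] linkage map.
#' @param gm The genotype matrix used.
#' @param truth The simulator `truth_set`.
#' @return data.frame `group`, `chrom`, `n_positions`, `tau`
#'   (absolute Kendall correlation).
#' @export
evaluate_ordering <- function(map, gm, truth) {
  ti <- truth_index(gm, truth)
  key <- setNames(ti, gm$markers$id)
  mp <- as.data.frame(map)
  out <- lapply(split(mp, mp$group), function(d) {
    t_rows <- key[d$marker]
    gpos <- truth$markers$gpos[t_rows]
    chrom <- names(which.max(table(truth$markers$chrom[t_rows])))
    agg <- tapply(gpos, d$cm, mean)
    cmv <- as.numeric(names(agg))
    tau <- if (length(agg) < 2) 1 else
      suppressWarnings(abs(cor(cmv, as.numeric(agg), method = "kendall")))
    data.frame(group = d$group[1], chrom = chrom,
               n_positions = length(agg), tau = tau,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Map-length recovery against the planted landscape
#'
#' A map spans its terminal markers, so the estimable quantity is the
#' planted genetic length between the group's outermost markers
#' (`true_cm`; at dense marker coverage this is within a fraction of a
#' cM of the chromosome total, also reported as `chrom_cm`).  The
#' standard error of the estimate is the delta-method sum over
#' adjacent intervals, `var(d) = (100/(1-2r))^2 r(1-r)/n` with `r`
#' recovered from the interval's Haldane distance.
#'
#' @param map A [build_map()] linkage map.
#' @param gm Genotype matrix (for chromosome attribution and family
#'   size).
#' @param truth The simulator `truth_set`.
#' @return data.frame `group`, `chrom`, `est_cm`, `true_cm`,
#'   `chrom_cm`, `se_cm`, `within_3se`.
#' @export
evaluate_map_length <- function(map, gm, truth) {
  ti <- truth_index(gm, truth)
  key <- setNames(ti, gm$markers$id)
  n_ind <- length(gm$individuals)
  mp <- as.data.frame(map)
  out <- lapply(split(mp, mp$group), function(d) {
    t_rows <- key[d$marker]
    chrom <- names(which.max(table(truth$markers$chrom[t_rows])))
    d <- d[order(d$cm), ]
    dd <- diff(d$cm)
    # clamp at 1/(2n): an interval with zero observed recombinants
    # still has estimation uncertainty
    r <- pmax(haldane_r(dd), 1 / (2 * n_ind))
    se <- sqrt(sum((100 / (1 - 2 * r))^2 * r * (1 - r) / n_ind))
    est <- max(d$cm)
    cm_t <- truth$markers$cm_true[t_rows]
    true_cm <- max(cm_t) - min(cm_t)
    data.frame(group = d$group[1], chrom = chrom, est_cm = est,
               true_cm = true_cm,
               chrom_cm = truth$landscape$total_cm[[chrom]],
               se_cm = se,
               within_3se = abs(est - true_cm) <= 3 * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Scaffold assignment and orientation accuracy
#'
#' Assignment is correct when a placed scaffold's linkage group maps
#' (by marker majority) to the scaffold's true source chromosome.
#' Orientation is scored only for scaffolds with a determined
#' orientation, allowing one global flip per chromosome (a map and its
#' mirror image are equivalent).
#'
#' @param placements An [assign_scaffolds()] result.
#' @param assembly An [order_and_orient()] result.
#' @param gm Genotype matrix used for mapping.
#' @param groups A [group_markers()] result.
#' @param truth The simulator `truth_set`.
#' @return List: `assignment_accuracy`, `orientation_accuracy`,
#'   `n_oriented`, `rank_concordant` (per-chromosome |Kendall tau| of
#'   scaffold rank vs true position).
#' @export
evaluate_anchoring <- function(placements, assembly, gm, groups, truth) {
  grouping <- evaluate_grouping(gm, groups, truth)
  group_names <- sprintf("LG%02d", seq_along(groups$groups))
  chrom_of_group <- setNames(grouping$group_chrom, group_names)

  pl <- placements[placements$placed, ]
  sc <- truth$scaffolds
  true_chrom <- sc$chrom[match(pl$scaffold, sc$scaffold)]
  assigned_chrom <- chrom_of_group[pl$group]
  assignment_accuracy <- mean(assigned_chrom == true_chrom)

  comp <- assembly$components
  ori_ok <- 0; ori_n <- 0; taus <- numeric()
  for (obj in assembly$chromosomes$object) {
    cc <- comp[comp$object == obj, ]
    tt <- sc[match(cc$scaffold, sc$scaffold), ]
    # scaffolds tied at one map position (e.g. spanning a coldspot)
    # carry no ordering information: compare one representative per
    # distinct map position
    mc <- placements$mean_cm[match(cc$scaffold, placements$scaffold)]
    rep_rank <- tapply(cc$rank, mc, mean)
    rep_start <- tapply(tt$start, mc, mean)
    tau <- if (length(rep_rank) < 2) 1 else
      suppressWarnings(cor(rep_rank, rep_start, method = "kendall"))
    flipped <- !is.na(tau) && tau < 0
    taus <- c(taus, abs(tau))
    known <- cc$orientation != "?"
    expect <- if (flipped) flip_strand(tt$orientation) else tt$orientation
    ori_ok <- ori_ok + sum(cc$orientation[known] == expect[known])
    ori_n <- ori_n + sum(known)
  }
  list(assignment_accuracy = assignment_accuracy,
       orientation_accuracy = if (ori_n) ori_ok / ori_n else NA_real_,
       n_oriented = ori_n, rank_concordance = taus)
}

flip_strand <- function(x) ifelse(x == "+", "-", ifelse(x == "-", "+", x))

# Lift a pseudomolecule position back to true genome coordinates via
# the inferred components and the scaffold truth.  Positions in gaps
# snap to the nearest component edge.
pseudo_to_genome <- function(assembly, truth, object, pos) {
  comp <- assembly$components
  sc <- truth$scaffolds
  chrom <- rep(NA_character_, length(pos))
  gpos <- rep(NA_real_, length(pos))
  for (i in seq_along(pos)) {
    cc <- comp[comp$object == object[i], ]
    k <- which(pos[i] >= cc$start & pos[i] < cc$end)
    if (!length(k)) {
      k <- which.min(pmin(abs(pos[i] - cc$start), abs(pos[i] - cc$end)))
      local <- if (pos[i] < cc$start[k]) 0 else cc$end[k] - cc$start[k] - 1
    } else {
      k <- k[1]
      local <- pos[i] - cc$start[k]
    }
    if (cc$orientation[k] == "-")
      local <- (cc$end[k] - cc$start[k] - 1) - local
    t <- sc[sc$scaffold == cc$scaffold[k], ]
    chrom[i] <- t$chrom
    gpos[i] <- if (t$orientation == "+") t$start + local else (t$end - 1) - local
  }
  data.frame(chrom = chrom, gpos = gpos, stringsAsFactors = FALSE)
}

#' Hotspot and coldspot recovery against the planted landscape
#'
#' A planted hotspot is detected when some called hotspot, lifted back
#' to genome coordinates, lies within the planted interval expanded by
#' one marker interval on each side.  The planted coldspot is recovered
#' when a called zero-recombination run of span > `min_span_mb`
#' overlaps it.
#'
#' @param hotspots,coldspots [call_hotspots()] / [call_coldspots()]
#'   results.
#' @param assembly The [order_and_orient()] assembly.
#' @param gm Genotype matrix used.
#' @param truth The simulator `truth_set`.
#' @return List: `hotspot_detected` (logical per planted hotspot),
#'   `coldspot_recovered` (logical per planted coldspot),
#'   `coldspot_span_mb`.
#' @export
evaluate_landscape <- function(hotspots, coldspots, assembly, gm, truth) {
  ti <- truth_index(gm, truth)
  mk <- truth$markers[ti, ]

  lift_calls <- function(calls) {
    if (nrow(calls) == 0)
      return(data.frame(chrom = character(), g1 = numeric(), g2 = numeric()))
    a <- pseudo_to_genome(assembly, truth, calls$object, calls$start)
    b <- pseudo_to_genome(assembly, truth, calls$object, pmax(calls$end - 1, 0))
    data.frame(chrom = a$chrom, g1 = pmin(a$gpos, b$gpos),
               g2 = pmax(a$gpos, b$gpos), stringsAsFactors = FALSE)
  }
  hs_g <- lift_calls(hotspots)
  cs_g <- lift_calls(coldspots)

  ph <- truth$landscape$hotspots
  hotspot_detected <- vapply(seq_len(nrow(ph)), function(i) {
    m <- sort(mk$gpos[mk$chrom == ph$chrom[i]])
    lo <- max(c(0, m[m <= ph$start[i]]))
    hi_cands <- m[m >= ph$end[i]]
    hi <- if (length(hi_cands)) min(hi_cands) else
      truth$genome$chromosomes$length[
        truth$genome$chromosomes$name == ph$chrom[i]]
    any(hs_g$chrom == ph$chrom[i] & hs_g$g1 >= lo & hs_g$g2 <= hi &
          hs_g$g2 >= ph$start[i] & hs_g$g1 <= ph$end[i])
  }, TRUE)

  pc <- truth$landscape$coldspots
  coldspot_recovered <- logical(nrow(pc))
  coldspot_span <- rep(NA_real_, nrow(pc))
  for (i in seq_len(nrow(pc))) {
    hit <- cs_g$chrom == pc$chrom[i] & cs_g$g2 >= pc$start[i] &
      cs_g$g1 <= pc$end[i]
    coldspot_recovered[i] <- any(hit)
    if (any(hit))
      coldspot_span[i] <- max((cs_g$g2 - cs_g$g1)[hit]) / 1e6
  }
  list(hotspot_detected = hotspot_detected,
       coldspot_recovered = coldspot_recovered,
       coldspot_span_mb = coldspot_span)
}
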