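# Anchoring scaffolds onto the linkage map and building chromosome
# pseudomolecules (AGP 2.1 + FASTA).

#' Assign scaffolds to linkage groups
#'
#' Each scaffold is placed on the linkage group holding the majority of
#' its mapped markers.  A scaffold with at least two markers on each of
#' two or more groups is flagged as a putative chimera (mis-join) and
#' left unplaced.  The mean map position of the supporting markers is
#' recorded for ordering.
#'
#' @param map A [build_map()] linkage map.
#' @param min_chimera_markers Markers per conflicting group needed to
#'   flag a chimera (default 2).
#' @param place_single_marker Place scaffolds supported by one marker?
#'   (default TRUE; their orientation stays unknown).
#' @return data.frame of class `scaffold_placements`: `scaffold`,
#'   `group`, `n_markers`, `mean_cm`, `chimera` (logical), `placed`.
#' @export
assign_scaffolds <- function(map, min_chimera_markers = 2,
                             place_single_marker = TRUE) {
  stopifnot(inherits(map, "linkage_map"))
  tab <- data.table::as.data.table(as.data.frame(map))
  cnt <- tab[, list(n = .N, mean_cm = mean(cm)), by = c("scaffold", "group")]
  out <- cnt[, {
    o <- order(-n, group)
    best <- o[1]
    chim <- sum(n >= min_chimera_markers) >= 2
    list(group = group[best], n_markers = n[best], mean_cm = mean_cm[best],
         total_markers = sum(n), chimera = chim)
  }, by = "scaffold"]
  out$placed <- !out$chimera & (place_single_marker | out$n_markers >= 2)
  data.table::setDF(out)
  out <- out[order(out$scaffold), ]
  rownames(out) <- NULL
  structure(out, class = c("scaffold_placements", "data.frame"))
}

#' Order and orient placed scaffolds into pseudomolecules
#'
#' Within each linkage group scaffolds are sorted by the mean map
#' position of their markers (ties by scaffold id).  Orientation is the
#' sign of the Kendall correlation between within-scaffold marker bp
#' and cM where at least two distinct cM values exist; otherwise it is
#' `"?"` (treated as `+` when sequence is emitted, but reported as
#' unknown in the AGP).  Pseudomolecules are named `Chr1..ChrK` in
#' decreasing length order.
#'
#' @param placements An [assign_scaffolds()] result.
#' @param map The [build_map()] linkage map.
#' @param scaffold_lengths Named vector of scaffold lengths in bp.
#' @param gap Gap length inserted between consecutive scaffolds
#'   (default 100 bp, AGP type "U").
#' @return Object of class `anchored_assembly`: `components`
#'   (data.frame `object`, `group`, `scaffold`, `rank`, `orientation`,
#'   `start`, `end` -- 0-based half-open object coordinates),
#'   `chromosomes` (data.frame `object`, `group`, `length`),
#'   `unplaced` (character), `gap`.
#' @export
order_and_orient <- function(placements, map, scaffold_lengths, gap = 100) {
  stopifnot(inherits(placements, "scaffold_placements"),
            inherits(map, "linkage_map"))
  pl <- placements[placements$placed, ]
  assert_that(all(pl$scaffold %in% names(scaffold_lengths)),
              "missing scaffold lengths")
  mp <- as.data.frame(map)

  ori <- vapply(seq_len(nrow(pl)), function(i) {
    mm <- mp[mp$scaffold == pl$scaffold[i] & mp$group == pl$group[i], ]
    if (length(unique(mm$cm)) < 2 || length(unique(mm$position)) < 2)
      return("?")
    tau <- suppressWarnings(cor(mm$position, mm$cm, method = "kendall"))
    if (is.na(tau) || tau == 0) "?" else if (tau > 0) "+" else "-"
  }, "")
  pl$orientation <- ori

  groups <- sort(unique(pl$group))
  comp <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- pl[pl$group == groups[gi], ]
    g <- g[order(g$mean_cm, g$scaffold), ]
    len <- unname(scaffold_lengths[g$scaffold])
    start <- cumsum(c(0, head(len + gap, -1)))
    comp[[gi]] <- data.frame(group = groups[gi], scaffold = g$scaffold,
                             rank = seq_len(nrow(g)),
                             orientation = g$orientation,
                             start = start, end = start + len,
                             stringsAsFactors = FALSE)
  }
  comp <- do.call(rbind, comp)
  chrom_len <- vapply(split(comp$end, comp$group), max, 0)
  ord <- order(-chrom_len, names(chrom_len))
  chroms <- data.frame(object = sprintf("Chr%d", seq_along(ord)),
                       group = names(chrom_len)[ord],
                       length = unname(chrom_len[ord]),
                       stringsAsFactors = FALSE)
  comp$object <- chroms$object[match(comp$group, chroms$group)]
  comp <- comp[order(match(comp$object, chroms$object), comp$rank), ]
  rownames(comp) <- NULL
  unplaced <- placements$scaffold[!placements$placed]
  structure(list(components = comp[, c("object", "group", "scaffold", "rank",
                                       "orientation", "start", "end")],
                 chromosomes = chroms, unplaced = unplaced, gap = gap),
            class = "anchored_assembly")
}

#' @export
print.anchored_assembly <- function(x, ...) {
  cat(sprintf("anchored assembly: %d pseudomolecules, %d scaffolds placed, %d unplaced\n",
              nrow(x$chromosomes), nrow(x$components), length(x$unplaced)))
  invisible(x)
}

#' AGP 2.1 table of an anchored assembly
#'
#' Component (`W`) rows carry 1-based inclusive object and component
#' coordinates; inter-scaffold gaps are `U` rows of known type "contig"
#' with linkage evidence "map".  Unknown orientations are written `?`.
#'
#' @param assembly An [order_and_orient()] result.
#' @return data.frame in the 9-column AGP layout.
#' @export
assembly_agp <- function(assembly) {
  stopifnot(inherits(assembly, "anchored_assembly"))
  comp <- assembly$components
  rows <- vector("list", nrow(comp) * 2)
  k <- 0
  for (obj in assembly$chromosomes$object) {
    cc <- comp[comp$object == obj, ]
    part <- 0
    for (i in seq_len(nrow(cc))) {
      if (i > 1) {
        part <- part + 1; k <- k + 1
        rows[[k]] <- data.frame(object = obj,
                                object_beg = cc$end[i - 1] + 1,
                                object_end = cc$start[i],
                                part_number = part, component_type = "U",
                                component_id = assembly$gap,
                                component_beg = "contig",
                                component_end = "yes", orientation = "map",
                                stringsAsFactors = FALSE)
      }
      part <- part + 1; k <- k + 1
      rows[[k]] <- data.frame(object = obj, object_beg = cc$start[i] + 1,
                              object_end = cc$end[i], part_number = part,
                              component_type = "W",
                              component_id = cc$scaffold[i],
                              component_beg = "1",
                              component_end = as.character(cc$end[i] - cc$start[i]),
                              orientation = cc$orientation[i],
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Emit pseudomolecule sequences and AGP
#'
#' @param assembly An [order_and_orient()] result.
#' @param scaffold_seqs A [Biostrings::DNAStringSet] containing every
#'   placed scaffold.
#' @return List with `fasta` (pseudomolecule `DNAStringSet`) and `agp`
#'   (data.frame as [assembly_agp()]).
#' @export
emit_pseudomolecules <- function(assembly, scaffold_seqs) {
  stopifnot(inherits(assembly, "anchored_assembly"))
  comp <- assembly$components
  miss <- setdiff(comp$scaffold, names(scaffold_seqs))
  if (length(miss))
    param_error("missing sequence for scaffold(s): ",
                paste(head(miss, 5), collapse = ", "))
  gapseq <- paste(rep("N", assembly$gap), collapse = "")
  seqs <- vector("list", nrow(assembly$chromosomes))
  for (i in seq_len(nrow(assembly$chromosomes))) {
    obj <- assembly$chromosomes$object[i]
    cc <- comp[comp$object == obj, ]
    pieces <- character(nrow(cc))
    for (r in seq_len(nrow(cc))) {
      s <- scaffold_seqs[[cc$scaffold[r]]]
      if (cc$orientation[r] == "-") s <- Biostrings::reverseComplement(s)
      pieces[r] <- as.character(s)
    }
    seqs[[i]] <- paste(pieces, collapse = gapseq)
  }
  fa <- Biostrings::DNAStringSet(unlist(seqs))
  names(fa) <- assembly$chromosomes$object
  list(fasta = fa, agp = assembly_agp(assembly))
}

#' Assembly contiguity statistics
#'
#' N50 is the length `L` such that scaffolds of length >= `L` (sorted
#' descending) first accumulate at least half the total assembly
#' length; N90 analogously at 90%.
#'
#' @param lengths Positive scaffold/contig lengths in bp.
#' @return List with `n50`, `n90`, `total`, `max`, `n`.
#' @export
assembly_stats <- function(lengths) {
  assert_that(length(lengths) > 0, "empty length list")
  assert_that(all(lengths > 0), "lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(s)
  list(n50 = s[which(cs >= 0.5 * sum(s))[1]],
       n90 = s[which(cs >= 0.9 * sum(s))[1]],
       total = sum(s), max = s[1], n = length(s))
}

#' Map a scaffold-local position onto pseudomolecule coordinates
#'
#' @param assembly An [order_and_orient()] result.
#' @param scaffold Scaffold ids (vector).
#' @param position 0-based positions on the scaffolds.
#' @return data.frame `object`, `pos` (0-based pseudomolecule
#'   coordinate; NA for unplaced scaffolds).  Scaffolds with unknown
#'   orientation are lifted as `+`.
#' @export
lift_to_pseudomolecule <- function(assembly, scaffold, position) {
  stopifnot(inherits(assembly, "anchored_assembly"))
  comp <- assembly$components
  i <- match(scaffold, comp$scaffold)
  len <- comp$end[i] - comp$start[i]
  fwd <- comp$orientation[i] != "-"
  pos <- ifelse(fwd, comp$start[i] + position,
                comp$start[i] + (len - 1) - position)
  data.frame(object = comp$object[i], pos = pos, stringsAsFactors = FALSE)
}
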