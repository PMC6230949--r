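# Pseudo-testcross marker definition and genotype calling from
# per-site allele-depth evidence.
#
# A site is an informative marker when the seed parent is heterozygous
# (exactly two alleles, both well covered) and the pollen parent is
# homozygous for one of those two alleles -- i.e. the site shows no
# polymorphism in the pollen parent's reads.  Progeny then segregate
# 1:1 for presence of the seed-parent-private allele.

#' Define pseudo-testcross markers from pileup evidence
#'
#' @param pileup data.frame `(scaffold, pos, sample, A, C, G, T)` of
#'   per-site allele depths (0-based positions).
#' @param parent_a Sample id of the seed (heterozygous) parent.
#' @param parent_b Sample id of the pollen (homozygous) parent.
#' @param min_parent_depth Minimum depth per parental allele
#'   (default 5).
#' @param het_min_minor_frac Minimum minor-allele fraction for the
#'   heterozygous parent (default 0.25).
#' @return data.frame of class `marker_defs`: `id` (`UM` + 6 digits,
#'   assigned in (scaffold, position) order), `scaffold`, `position`,
#'   `allele1`, `allele2` (the seed parent's alleles; `allele1` is the
#'   one shared with the pollen parent), `allele_b`.
#' @export
define_markers <- function(pileup, parent_a, parent_b,
                           min_parent_depth = 5, het_min_minor_frac = 0.25) {
  pu <- data.table::as.data.table(pileup)
  assert_that(all(c("scaffold", "pos", "sample", "A", "C", "G", "T") %in%
                    names(pu)), "pileup is missing required columns")
  for (p in c(parent_a, parent_b))
    if (!p %in% pu$sample) param_error("unknown parent sample: ", p)

  bases <- c("A", "C", "G", "T")
  pa <- pu[pu$sample == parent_a, ]
  pb <- pu[pu$sample == parent_b, ]
  key <- function(d) paste(d$scaffold, d$pos)
  pb <- pb[match(key(pa), key(pb)), ]

  da <- as.matrix(pa[, bases, with = FALSE])
  db <- as.matrix(pb[, bases, with = FALSE])
  db[is.na(db)] <- 0L

  na_alleles <- rowSums(da > 0)
  ok_a <- na_alleles == 2
  # order the two parent-A alleles by depth (major, minor)
  top <- max.col(da, ties.method = "first")
  da2 <- da; da2[cbind(seq_len(nrow(da)), top)] <- -1L
  second <- max.col(da2, ties.method = "first")
  dmaj <- da[cbind(seq_len(nrow(da)), top)]
  dmin <- da2v <- da[cbind(seq_len(nrow(da)), second)]
  ok_a <- ok_a & dmin >= min_parent_depth & dmaj >= min_parent_depth &
    dmin / (dmaj + dmin) >= het_min_minor_frac

  nb_alleles <- rowSums(db > 0)
  topb <- max.col(db, ties.method = "first")
  dbb <- db[cbind(seq_len(nrow(db)), topb)]
  ok_b <- nb_alleles == 1 & dbb >= min_parent_depth
  b_base <- bases[topb]
  ok_b <- ok_b & (b_base == bases[top] | b_base == bases[second])

  keep <- which(ok_a & ok_b)
  defs <- data.frame(scaffold = pa$scaffold[keep], position = pa$pos[keep],
                     allele_b = b_base[keep], stringsAsFactors = FALSE)
  other <- ifelse(b_base[keep] == bases[top][keep],
                  bases[second][keep], bases[top][keep])
  defs$allele1 <- defs$allele_b
  defs$allele2 <- other
  defs <- defs[order(defs$scaffold, defs$position), ]
  defs$id <- sprintf("UM%06d", seq_len(nrow(defs)))
  rownames(defs) <- NULL
  structure(defs[, c("id", "scaffold", "position",
                     "allele1", "allele2", "allele_b")],
            class = c("marker_defs", "data.frame"))
}

#' Call F1 genotypes at defined markers
#'
#' Per individual and marker: if total depth at the two marker alleles
#' is below `min_depth` the call is missing; otherwise any read of the
#' seed-parent-private allele yields a heterozygote call (1) and
#' otherwise a homozygote call (0).  `mode = "allele"` instead requires
#' the call-supporting allele itself to reach `min_depth`.
#'
#' @param pileup Pileup data.frame (see [define_markers()]).
#' @param defs A `marker_defs` data.frame.
#' @param min_depth Minimum read depth (default 3).
#' @param exclude Samples to drop (typically the two parents).
#' @param mode `"site"` (default; depth threshold on the site total) or
#'   `"allele"`.
#' @return A [genotype_matrix()].
#' @export
call_genotypes <- function(pileup, defs, min_depth = 3,
                           exclude = character(), mode = c("site", "allele")) {
  mode <- match.arg(mode)
  assert_that(nrow(defs) >= 1, "no marker definitions")
  pu <- data.table::as.data.table(pileup)
  pu <- pu[!pu$sample %in% exclude, ]
  individuals <- sort(unique(pu$sample))

  mkey <- paste(defs$scaffold, defs$position)
  pu <- pu[paste(pu$scaffold, pu$pos) %in% mkey, ]
  mi <- match(paste(pu$scaffold, pu$pos), mkey)
  ji <- match(pu$sample, individuals)

  bases <- c("A", "C", "G", "T")
  dmat <- as.matrix(pu[, bases, with = FALSE])
  db <- dmat[cbind(seq_len(nrow(pu)), match(defs$allele_b[mi], bases))]
  dy <- dmat[cbind(seq_len(nrow(pu)),
                   match(ifelse(defs$allele_b[mi] == defs$allele1[mi],
                                defs$allele2[mi], defs$allele1[mi]), bases))]

  calls <- matrix(NA_integer_, nrow(defs), length(individuals))
  if (mode == "site") {
    ok <- db + dy >= min_depth
    val <- ifelse(dy > 0, 1L, 0L)
  } else {
    ok <- (dy >= min_depth) | (dy == 0 & db >= min_depth)
    val <- ifelse(dy >= min_depth, 1L, 0L)
  }
  calls[cbind(mi[ok], ji[ok])] <- val[ok]
  genotype_matrix(as.data.frame(defs), calls, individuals)
}

#' Filter duplicated and under-called individuals
#'
#' Drops individuals whose missing-call fraction exceeds `max_missing`,
#' then collapses near-duplicate individuals: for every pair sharing at
#' least `min_shared` co-called markers with genotype identity at least
#' `dup_identity`, only the member with fewer missing calls is kept.
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing Maximum tolerated missing fraction (default 0.5).
#' @param dup_identity Identity threshold for duplicates (default 0.95).
#' @param min_shared Minimum co-called markers to judge a pair.
#' @return The filtered [genotype_matrix()]; the removal log is in
#'   `attr(, "removed")` (data.frame `individual`, `reason`).
#' @export
filter_individuals <- function(gm, max_missing = 0.5, dup_identity = 0.95,
                               min_shared = 100) {
  stopifnot(inherits(gm, "genotype_matrix"))
  assert_that(max_missing > 0 && max_missing <= 1,
              "max_missing must be in (0, 1]")
  removed <- data.frame(individual = character(), reason = character(),
                        stringsAsFactors = FALSE)

  high <- gm$missing_frac > max_missing
  if (any(high)) {
    removed <- rbind(removed, data.frame(individual = gm$individuals[high],
                                         reason = "missing", stringsAsFactors = FALSE))
  }
  keep <- !high
  if (!any(keep)) param_error("all individuals removed by missing filter")

  G <- gm$calls[, keep, drop = FALSE]
  C <- !is.na(G); storage.mode(C) <- "double"
  A1 <- matrix(0, nrow(G), ncol(G)); A1[!is.na(G) & G == 1L] <- 1
  A0 <- matrix(0, nrow(G), ncol(G)); A0[!is.na(G) & G == 0L] <- 1
  shared <- crossprod(C)
  agree <- crossprod(A1) + crossprod(A0)
  ident <- ifelse(shared > 0, agree / shared, 0)
  ids <- gm$individuals[keep]
  nmiss <- colSums(!C)

  dup <- which(shared >= min_shared & ident >= dup_identity &
                 upper.tri(shared), arr.ind = TRUE)
  drop <- logical(length(ids))
  if (nrow(dup)) {
    for (r in seq_len(nrow(dup))) {
      a <- dup[r, 1]; b <- dup[r, 2]
      if (drop[a] || drop[b]) next
      loser <- if (nmiss[a] > nmiss[b]) a
               else if (nmiss[b] > nmiss[a]) b
               else max(a, b)
      drop[loser] <- TRUE
    }
    removed <- rbind(removed, data.frame(individual = ids[drop],
                                         reason = "duplicate",
                                         stringsAsFactors = FALSE))
  }
  final <- ids[!drop]
  if (!length(final)) param_error("all individuals removed")
  out <- genotype_matrix(gm$markers,
                         gm$calls[, final, drop = FALSE], final)
  attr(out, "removed") <- removed
  out
}
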