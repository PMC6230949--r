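# Two-point linkage analysis for a pseudo-testcross F1 design.
#
# Genotypes are 0/1 (homozygote / heterozygote for the informative
# parent's markers) with NA for missing.  Linkage phase between two
# markers is unknown in an outcross, so the recombination fraction is
# estimated as r-hat = min(M, n - M) / n where M is the number of
# co-called individuals whose calls differ: coupling phase if mismatches
# are the minority, repulsion otherwise.
#
# The two-point LOD is the base-10 likelihood ratio of linkage at r-hat
# against free recombination (r = 1/2):
#   LOD = R log10(2 r) + (n - R) log10(2 (1 - r)),  R = min(M, n - M),
# with r clamped to [1/(2n), 1/2] so co-segregating pairs stay finite.

#' Two-point linkage between two markers
#'
#' @param gm A [genotype_matrix()].
#' @param i,j Marker ids or row indices.
#' @return An object of class `pairwise_linkage`: a list with `n`
#'   (informative meioses), `mismatch`, `phase` (`"coupling"` or
#'   `"repulsion"`), `rf` (clamped estimate) and `lod`.
#' @export
pairwise_linkage <- function(gm, i, j) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gi <- marker_row(gm, i)
  gj <- marker_row(gm, j)
  ok <- !is.na(gi) & !is.na(gj)
  n <- sum(ok)
  if (n == 0) {
    return(structure(list(n = 0L, mismatch = NA_integer_, phase = NA_character_,
                          rf = NA_real_, lod = NA_real_),
                     class = "pairwise_linkage"))
  }
  m <- sum(gi[ok] != gj[ok])
  R <- min(m, n - m)
  rf <- min(max(R / n, 1 / (2 * n)), 0.5)
  lod <- R * log10(2 * rf) + (n - R) * log10(2 * (1 - rf))
  structure(list(n = as.integer(n), mismatch = as.integer(m),
                 phase = if (m <= n - m) "coupling" else "repulsion",
                 rf = rf, lod = max(lod, 0)),
            class = "pairwise_linkage")
}

#' @export
print.pairwise_linkage <- function(x, ...) {
  cat(sprintf("two-point linkage: n=%d mismatch=%s phase=%s rf=%.4f LOD=%.3f\n",
              x$n, x$mismatch, x$phase, x$rf, x$lod))
  invisible(x)
}

marker_row <- function(gm, i) {
  if (is.character(i)) {
    k <- match(i, gm$markers$id)
    assert_that(!is.na(k), "unknown marker id: ", i)
    i <- k
  }
  gm$calls[i, ]
}

#' All-pairs two-point linkage matrices
#'
#' Computes, for every pair of markers, the number of co-called
#' individuals, mismatch counts, phase-folded recombination-fraction
#' estimates and LOD scores, using dense matrix products (fast for the
#' few-thousand-marker scale typical of a RAD map).
#'
#' @param gm A [genotype_matrix()].
#' @return A list of class `linkage_pairs` with marker ids and matrices
#'   `n`, `mismatch`, `rf` (clamped to `[1/(2n), 0.5]`), `rf_raw`
#'   (unclamped `min(M, n-M)/n`) and `lod`.  Pairs with `n = 0` have
#'   `NA` rf/lod and are never treated as linked.
#' @export
linkage_pairs <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  G <- gm$calls
  C <- !is.na(G)
  A1 <- matrix(0, nrow(G), ncol(G)); A1[C & G == 1L] <- 1
  A0 <- matrix(0, nrow(G), ncol(G)); A0[C & G == 0L] <- 1
  storage.mode(C) <- "double"
  n <- tcrossprod(C)
  M <- tcrossprod(A1, A0) + tcrossprod(A0, A1)
  # elementwise min/max/clamp via primitive ops (pmin/ifelse are far too
  # slow on the ~1e7-cell matrices of a few-thousand-marker map)
  R <- M
  w <- n - M
  sel <- w < R; R[sel] <- w[sel]
  rf_raw <- R / n                       # n = 0 gives NaN
  rf_raw[n == 0] <- NA_real_
  rf <- rf_raw
  lo <- 0.5 / n                         # clamp floor 1/(2n)
  sel <- !is.na(rf) & rf < lo; rf[sel] <- lo[sel]
  lod <- R * log10(2 * rf) + (n - R) * log10(2 * (1 - rf))
  lod[n == 0] <- NA_real_
  lod[!is.na(lod) & lod < 0] <- 0
  ids <- gm$markers$id
  dimnames(n) <- dimnames(M) <- dimnames(rf) <- dimnames(rf_raw) <-
    dimnames(lod) <- list(ids, ids)
  structure(list(ids = ids, n = n, mismatch = M, rf = rf,
                 rf_raw = rf_raw, lod = lod),
            class = "linkage_pairs")
}

#' Partition markers into linkage groups
#'
#' Single-linkage clustering: two markers are joined when their
#' recombination fraction is below `max_rf` and their LOD exceeds
#' `min_lod`; linkage groups are the connected components of that
#' graph.  The defaults (rf < 0.4, LOD > 10) are the standard strict
#' criteria for validating groups in an outcross RAD map.
#'
#' @param pairs A [linkage_pairs()] result.
#' @param max_rf Recombination-fraction threshold (strict `<`).
#' @param min_lod LOD threshold (strict `>`).
#' @return A list of class `marker_groups`: `groups` (list of marker-id
#'   vectors, largest first) and `unplaced` (singleton markers).
#' @export
group_markers <- function(pairs, max_rf = 0.4, min_lod = 10) {
  stopifnot(inherits(pairs, "linkage_pairs"))
  adj <- !is.na(pairs$rf) & pairs$rf < max_rf & pairs$lod > min_lod
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(pairs$ids, comp$membership)
  sizes <- lengths(groups)
  unplaced <- unlist(groups[sizes == 1], use.names = FALSE)
  groups <- groups[sizes >= 2]
  ord <- order(-lengths(groups), vapply(groups, min, ""))
  groups <- unname(groups[ord])
  structure(list(groups = groups, unplaced = sort(unplaced)),
            class = "marker_groups")
}

#' @export
print.marker_groups <- function(x, ...) {
  cat(sprintf("%d linkage groups (%s markers), %d unplaced\n",
              length(x$groups),
              paste(range(lengths(x$groups)), collapse = "-"),
              length(x$unplaced)))
  invisible(x)
}

# Bin markers that co-segregate perfectly (min(M, n-M) == 0 over at
# least min_n co-called individuals).  Such markers are unresolvable at
# the given family size; they are ordered once per bin and re-expanded
# at a single map position.  Returns a list of id vectors, each bin
# keyed by its representative (lowest id).
coseg_bins <- function(ids, pairs, min_n = 20) {
  idx <- match(ids, pairs$ids)
  n <- pairs$n[idx, idx, drop = FALSE]
  R <- pmin(pairs$mismatch[idx, idx, drop = FALSE],
            n - pairs$mismatch[idx, idx, drop = FALSE])
  same <- n >= min_n & R == 0
  diag(same) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(same, mode = "undirected")
  comp <- igraph::components(g)$membership
  bins <- split(ids, comp)
  lapply(unname(bins), sort)
}

#' Order the markers of one linkage group
#'
#' Two-point ordering: perfectly co-segregating markers are binned, an
#' end bin is identified as the bin with the largest summed Haldane
#' distance to all others (robust to the noise of individual
#' recombination-fraction estimates), bins are seriated by distance
#' from that end, and the order is refined by 2-opt moves minimising
#' the sum of adjacent Haldane distances (the SARF criterion).  The
#' result is canonicalised so the first marker id sorts before the
#' last (an order and its reversal are the same map).
#'
#' @param ids Marker ids of one group (length >= 2).
#' @param pairs A [linkage_pairs()] result covering them.
#' @param markers Optional data.frame `id`, `scaffold`, `position`.
#'   When given, adjacent bins whose order is a statistical tie (the
#'   swap changes the SARF by at most `tie_eps` cM) are resolved by
#'   within-scaffold physical order -- the standard use of assembly
#'   information when two-point data cannot distinguish (e.g.
#'   double-crossover configurations with equal obligate
#'   recombination counts).
#' @param tie_eps SARF tie tolerance in cM for the physical tie-break
#'   (default 0.15).
#' @return Character vector of marker ids in map order.
#' @export
order_markers <- function(ids, pairs, markers = NULL, tie_eps = 0.15) {
  stopifnot(inherits(pairs, "linkage_pairs"))
  assert_that(length(ids) >= 2, "a group needs at least 2 markers")
  assert_that(all(ids %in% pairs$ids), "unknown marker ids in group")

  bins <- coseg_bins(ids, pairs)
  reps <- vapply(bins, `[[`, "", 1L)
  if (length(reps) == 1) return(sort(ids))

  idx <- match(reps, pairs$ids)
  rf <- pairs$rf_raw[idx, idx, drop = FALSE]
  if (any(is.na(rf[upper.tri(rf)])))
    param_error("group contains marker pairs with no co-called individuals")
  # Haldane distance matrix; cap rf just below 1/2 to keep it finite.
  D <- -50 * log1p(-2 * pmin(rf, 0.4999))
  diag(D) <- 0

  # anchor at an end: summed distance to all other bins is maximised at
  # the chromosome ends and averages away per-pair estimation noise
  anchor <- which.max(rowSums(D))
  ord <- order(D[anchor, ], seq_len(nrow(D)))
  ord <- refine_order(ord, D)
  if (!is.null(markers))
    ord <- physical_tie_break(ord, D, bins, markers, tie_eps)

  ordered_reps <- reps[ord]
  if (ordered_reps[1] > ordered_reps[length(ordered_reps)])
    ordered_reps <- rev(ordered_reps)
  unlist(bins[match(ordered_reps, reps)], use.names = FALSE)
}

# Swap adjacent bins that the genotype data cannot order (SARF change
# <= tie_eps) when a scaffold spanning both bins says they are in the
# wrong physical order.  The scaffold's reading direction is estimated
# from its markers in the *other* bins of the current order (a scaffold
# confined to the tied pair has unknown orientation and casts no vote).
physical_tie_break <- function(ord, D, bins, markers, tie_eps) {
  k <- length(ord)
  if (k < 2) return(ord)
  scaf_of <- setNames(markers$scaffold, markers$id)
  pos_of <- setNames(markers$position, markers$id)
  for (pass in 1:2) {
    for (i in 1:(k - 1)) {
      u <- ord[i]; v <- ord[i + 1]
      dl <- if (i > 1) D[ord[i - 1], u] else 0
      dr <- if (i + 2 <= k) D[v, ord[i + 2]] else 0
      dl2 <- if (i > 1) D[ord[i - 1], v] else 0
      dr2 <- if (i + 2 <= k) D[u, ord[i + 2]] else 0
      if (abs((dl2 + dr2) - (dl + dr)) > tie_eps) next
      mu <- bins[[u]]; mv <- bins[[v]]
      shared <- intersect(unique(scaf_of[mu]), unique(scaf_of[mv]))
      vote <- 0
      for (s in shared) {
        bin_pos <- vapply(seq_len(k), function(b) {
          m <- bins[[ord[b]]]
          mean(pos_of[m[scaf_of[m] == s]])
        }, 0)
        present <- which(!is.nan(bin_pos))
        others <- setdiff(present, c(i, i + 1))
        if (!length(others)) next
        dir <- suppressWarnings(cor(present, bin_pos[present],
                                    method = "kendall"))
        if (is.na(dir) || dir == 0) next
        pu <- mean(pos_of[mu[scaf_of[mu] == s]])
        pv <- mean(pos_of[mv[scaf_of[mv] == s]])
        if (pu == pv) next
        vote <- vote + sign(dir) * sign(pv - pu)
      }
      if (vote < 0) { ord[i] <- v; ord[i + 1] <- u }
    }
  }
  ord
}

# Alternate 2-opt (segment reversal) and Or-opt (short-segment
# relocation) until neither improves the SARF criterion.  2-opt alone
# leaves characteristic local optima on paths (a displaced block it can
# only reach through worse intermediate states); Or-opt removes them.
refine_order <- function(ord, D) {
  repeat {
    o1 <- two_opt(ord, D)
    o2 <- or_opt(o1, D)
    o3 <- window_opt(o2, D)
    if (identical(o3, ord)) break
    ord <- o3
  }
  ord
}

# Exhaustive permutation of a sliding window (width 5): resolves
# clusters of interacting near-tie misplacements that single 2-opt /
# Or-opt moves cannot escape.
window_opt <- function(ord, D, w = 5L) {
  k <- length(ord)
  if (k <= w) w <- k - 1L
  if (w < 2) return(ord)
  perms <- all_perms(w)
  repeat {
    improved <- FALSE
    for (s in 1:(k - w + 1)) {
      e <- s + w - 1
      win <- ord[s:e]
      lft <- if (s > 1) ord[s - 1] else 0L
      rgt <- if (e < k) ord[e + 1] else 0L
      wcost <- function(o) {
        cc <- sum(D[cbind(o[-w], o[-1])])
        if (lft > 0) cc <- cc + D[lft, o[1]]
        if (rgt > 0) cc <- cc + D[o[w], rgt]
        cc
      }
      base <- wcost(win)
      best <- NULL; bcost <- base
      for (p in seq_len(nrow(perms))) {
        cand <- win[perms[p, ]]
        cc <- wcost(cand)
        if (cc < bcost - 1e-12) { bcost <- cc; best <- cand }
      }
      if (!is.null(best)) { ord[s:e] <- best; improved <- TRUE }
    }
    if (!improved) break
  }
  ord
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# First-improvement 2-opt on an open path (reverse any segment,
# including prefixes and suffixes), minimising total adjacent distance;
# deterministic given the input order.
two_opt <- function(ord, D) {
  k <- length(ord)
  if (k < 3) return(ord)
  repeat {
    improved <- FALSE
    for (a in 0:(k - 2)) {            # reverse ord[(a+1)..b]
      for (b in (a + 1):(if (a == 0) k - 1 else k)) {
        left <- if (a >= 1) D[ord[a], ord[a + 1]] else 0
        right <- if (b < k) D[ord[b], ord[b + 1]] else 0
        new_left <- if (a >= 1) D[ord[a], ord[b]] else 0
        new_right <- if (b < k) D[ord[a + 1], ord[b + 1]] else 0
        if (new_left + new_right < left + right - 1e-12) {
          ord[(a + 1):b] <- rev(ord[(a + 1):b])
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord
}

# Or-opt: relocate segments of length 1..3 (forward or reversed) to any
# other position when that lowers the total adjacent distance.
or_opt <- function(ord, D) {
  k <- length(ord)
  if (k < 4) return(ord)
  path_cost <- function(o)
    sum(D[cbind(o[-length(o)], o[-1])])
  repeat {
    improved <- FALSE
    for (len in 1:3) {
      if (k - len < 2) next
      s <- 1
      while (s + len - 1 <= k) {
        e <- s + len - 1
        seg <- ord[s:e]
        rest <- ord[-(s:e)]
        base <- path_cost(ord)
        best_cost <- base; best <- NULL
        for (p in 0:length(rest)) {
          for (sg in list(seg, if (len > 1) rev(seg))) {
            if (is.null(sg)) next
            cand <- append(rest, sg, after = p)
            cc <- path_cost(cand)
            if (cc < best_cost - 1e-12) { best_cost <- cc; best <- cand }
          }
        }
        if (!is.null(best)) { ord <- best; improved <- TRUE }
        s <- s + 1
      }
    }
    if (!improved) break
  }
  ord
}

#' Build a linkage map from grouped, ordered markers
#'
#' Cumulative map positions are prefix sums of adjacent-pair Haldane
#' distances computed from the unclamped recombination-fraction
#' estimates, so perfectly co-segregating neighbours sit at the same
#' position.
#'
#' @param gm A [genotype_matrix()].
#' @param groups A [group_markers()] result, or a list of id vectors.
#' @param orders Optional list of pre-computed orders (as returned by
#'   [order_markers()]); computed if omitted.
#' @param pairs Optional [linkage_pairs()] (recomputed if omitted).
#' @return A `linkage_map`: data.frame with columns `group`, `marker`,
#'   `scaffold`, `position`, `cm`, plus attributes `group_lengths` and
#'   `total_cm`.
#' @export
build_map <- function(gm, groups, orders = NULL, pairs = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  glist <- if (inherits(groups, "marker_groups")) groups$groups else groups
  assert_that(length(glist) >= 1,
              "no linkage groups (all markers unplaced)")
  if (is.null(pairs)) pairs <- linkage_pairs(gm)
  if (is.null(orders))
    orders <- lapply(glist, order_markers, pairs = pairs,
                     markers = gm$markers)
  assert_that(length(orders) == length(glist), "orders must match groups")

  rows <- vector("list", length(orders))
  for (g in seq_along(orders)) {
    ord <- orders[[g]]
    idx <- match(ord, pairs$ids)
    k <- length(ord)
    d <- numeric(k)
    if (k > 1) {
      for (p in 2:k) {
        a <- idx[p - 1]; b <- idx[p]
        r <- pairs$rf_raw[a, b]
        d[p] <- -50 * log1p(-2 * min(r, 0.4999))
      }
    }
    mk <- gm$markers[match(ord, gm$markers$id), ]
    rows[[g]] <- data.frame(group = sprintf("LG%02d", g), marker = ord,
                            scaffold = mk$scaffold, position = mk$position,
                            cm = cumsum(d), stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  gl <- vapply(split(map$cm, map$group), max, 0)
  structure(map, class = c("linkage_map", "data.frame"),
            group_lengths = gl, total_cm = sum(gl))
}

#' @export
print.linkage_map <- function(x, ...) {
  gl <- attr(x, "group_lengths")
  cat(sprintf("linkage map: %d markers in %d groups, total %.1f cM\n",
              nrow(x), length(gl), attr(x, "total_cm")))
  invisible(x)
}
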