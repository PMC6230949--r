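# F1 pseudo-testcross simulator.
#
# Markers are heterozygous in the seed parent (alleles X/Y) and
# homozygous X in the pollen parent, so progeny are XX (coded 0) or XY
# (coded 1) and segregate 1:1.  Each maternal meiosis draws a Poisson
# number of crossovers per chromosome (mean = map length in Morgans,
# i.e. no interference -- exactly the Haldane model used downstream)
# with positions sampled proportional to the planted landscape
# intensity.  The linkage phase of the Y allele is randomised per
# marker, so downstream two-point analysis must infer coupling vs
# repulsion.

#' Describe an F1 cross design
#'
#' @param n_progeny Number of F1 individuals (default 184).
#' @param error Per-call genotyping error rate `e` in `[0, 1)`: calls
#'   are flipped 0<->1 with this probability.
#' @param missing Per-call missing rate `m` in `[0, 1)`.
#' @param depth Mean sequencing depth per progeny genotype (Poisson).
#' @param parent_depth Mean depth for the two parents (parents are
#'   sequenced deeper than progeny in a typical RAD design).
#' @param seed RNG seed; fully determines the simulated cross.
#' @return A list of class `cross_design`.
#' @export
cross_design <- function(n_progeny = 184, error = 0.005, missing = 0.15,
                         depth = 8, parent_depth = 30, seed = 1) {
  assert_that(n_progeny >= 1, "need at least one progeny")
  assert_that(error >= 0 && error < 1, "error must be in [0, 1)")
  assert_that(missing >= 0 && missing < 1, "missing must be in [0, 1)")
  assert_that(depth > 0 && parent_depth > 0, "depths must be positive")
  structure(list(n_progeny = as.integer(n_progeny), error = error,
                 missing = missing, depth = depth,
                 parent_depth = parent_depth, seed = seed),
            class = "cross_design")
}

#' Construct a genotype matrix object
#'
#' The central mapping substrate: marker definitions plus a
#' markers x individuals matrix of pseudo-testcross calls (0 =
#' homozygote, 1 = heterozygote, NA = missing).
#'
#' @param markers data.frame with at least `id`, `scaffold`, `position`
#'   (0-based bp on the scaffold).
#' @param calls Integer matrix (markers x individuals) of 0/1/NA.
#' @param individuals Character vector of individual ids.
#' @return Object of class `genotype_matrix` with per-individual
#'   `missing_frac`.
#' @export
genotype_matrix <- function(markers, calls, individuals = colnames(calls)) {
  assert_that(nrow(markers) == nrow(calls),
              "markers and call rows differ")
  assert_that(length(individuals) == ncol(calls),
              "individuals and call columns differ")
  assert_that(all(calls %in% c(0L, 1L, NA_integer_)),
              "calls must be 0, 1 or NA")
  dimnames(calls) <- list(markers$id, individuals)
  structure(list(markers = markers, individuals = individuals,
                 calls = calls,
                 missing_frac = colMeans(is.na(calls))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype matrix: %d markers x %d individuals (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Simulate RAD genotyping of an F1 cross
#'
#' Places markers along the genome as a Poisson process, maps them onto
#' the scaffold truth, simulates maternal meioses under the planted
#' landscape and emits the genotype matrix, optional per-site pileup
#' evidence, and the full ground truth.
#'
#' @param genome A [simulate_genome()] result.
#' @param landscape A [plant_landscape()] result; must be non-empty.
#' @param scaffolds A [fragment_scaffolds()] truth table.
#' @param markers_per_mb Mean marker density (default 30 / Mb).
#' @param design A [cross_design()].
#' @param parents Ids for the seed and pollen parent samples.
#' @param pileup Emit the per-site allele-depth table? (Skipping it
#'   speeds up large simulation studies that only need genotypes.)
#' @return List with `gm` (the error/missingness-affected
#'   [genotype_matrix()]), `pileup` (data.frame `scaffold, pos, sample,
#'   A, C, G, T` or NULL) and `truth` (class `truth_set`: marker truth
#'   with genome coordinates, true cM and true calls, plus the genome,
#'   landscape, scaffold truth and design).
#' @export
simulate_cross <- function(genome, landscape, scaffolds,
                           markers_per_mb = 30, design = cross_design(),
                           parents = c("P1", "P2"), pileup = TRUE) {
  stopifnot(inherits(genome, "sim_genome"),
            inherits(landscape, "rec_landscape"),
            inherits(design, "cross_design"))
  assert_that(markers_per_mb > 0, "markers_per_mb must be positive")
  assert_that(nrow(landscape$intervals) > 0, "empty landscape")

  with_seed(design$seed, {
    mk <- place_markers(genome, scaffolds, markers_per_mb)
    if (nrow(mk) < 2) param_error("simulation produced < 2 markers")
    mk$cm_true <- NA_real_
    for (cn in unique(mk$chrom)) {
      i <- mk$chrom == cn
      mk$cm_true[i] <- cum_cm(landscape, cn, mk$gpos[i])
    }
    # allele content: Y = allele private to the seed parent
    base_pairs <- matrix(c("A", "C", "G", "T"), 4)
    bx <- sample(c("A", "C", "G", "T"), nrow(mk), replace = TRUE)
    by <- vapply(bx, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    mk$allele_x <- bx   # shared with the pollen parent
    mk$allele_y <- unname(by)
    mk$phase <- sample(0:1, nrow(mk), replace = TRUE)

    n <- design$n_progeny
    truth_calls <- matrix(0L, nrow(mk), n)
    chrom_names <- genome$chromosomes$name
    for (c in seq_along(chrom_names)) {
      cn <- chrom_names[c]
      rows <- which(mk$chrom == cn)
      if (!length(rows)) next
      Lcm <- landscape$total_cm[[cn]]
      cmpos <- mk$cm_true[rows]
      for (j in seq_len(n)) {
        k <- rpois(1, Lcm / 100)
        h0 <- sample(0:1, 1)
        if (k == 0) {
          h <- rep(h0, length(rows))
        } else {
          xo <- sort(runif(k, 0, Lcm))
          h <- (h0 + findInterval(cmpos, xo)) %% 2L
        }
        truth_calls[rows, j] <- as.integer(h == mk$phase[rows])
      }
    }

    calls <- truth_calls
    if (design$error > 0) {
      flip <- matrix(runif(length(calls)) < design$error, nrow(calls))
      calls[flip] <- 1L - calls[flip]
    }
    if (design$missing > 0) {
      calls[matrix(runif(length(calls)) < design$missing, nrow(calls))] <-
        NA_integer_
    }

    progeny <- sprintf("F%03d", seq_len(n))
    markers <- data.frame(id = mk$id, scaffold = mk$scaffold,
                          position = mk$position,
                          allele1 = mk$allele_x, allele2 = mk$allele_y,
                          allele_b = mk$allele_x, stringsAsFactors = FALSE)
    gm <- genotype_matrix(markers, calls, progeny)

    pu <- if (pileup) simulate_pileup(mk, calls, progeny, parents, design)
          else NULL

    truth <- structure(list(markers = mk, calls = truth_calls,
                            genome = genome, landscape = landscape,
                            scaffolds = scaffolds, design = design,
                            parents = parents),
                       class = "truth_set")
    list(gm = gm, pileup = pu, truth = truth)
  })
}

# Markers as a Poisson process along each chromosome, lifted to
# scaffold-local coordinates via the truth placements; ids are assigned
# in (scaffold, position) lexicographic order, mirroring how real
# markers are named from mapped reads.
place_markers <- function(genome, scaffolds, markers_per_mb) {
  out <- vector("list", nrow(genome$chromosomes))
  for (c in seq_len(nrow(genome$chromosomes))) {
    cn <- genome$chromosomes$name[c]
    L <- genome$chromosomes$length[c]
    nm <- rpois(1, markers_per_mb * L / 1e6)
    gpos <- sort(floor(runif(nm, 0, L)))
    gpos <- unique(gpos)
    out[[c]] <- data.frame(chrom = cn, gpos = gpos, stringsAsFactors = FALSE)
  }
  mk <- do.call(rbind, out)
  sc <- scaffolds
  mk$scaffold <- NA_character_
  mk$position <- NA_real_
  for (r in seq_len(nrow(sc))) {
    i <- mk$chrom == sc$chrom[r] & mk$gpos >= sc$start[r] & mk$gpos < sc$end[r]
    if (!any(i)) next
    mk$scaffold[i] <- sc$scaffold[r]
    local <- mk$gpos[i] - sc$start[r]
    if (sc$orientation[r] == "-") local <- (sc$length[r] - 1) - local
    mk$position[i] <- local
  }
  mk <- mk[!is.na(mk$scaffold), ]
  mk <- mk[order(mk$scaffold, mk$position), ]
  mk$id <- sprintf("UM%06d", seq_len(nrow(mk)))
  rownames(mk) <- NULL
  mk
}

# Per-site allele depths consistent with the (possibly erroneous)
# calls: heterozygote sites always show both alleles when depth >= 2,
# homozygote sites only the shared allele; calls that were dropped as
# missing get zero depth.
simulate_pileup <- function(mk, calls, progeny, parents, design) {
  nm <- nrow(mk); np <- length(progeny)
  bases <- c("A", "C", "G", "T")
  dt_list <- vector("list", np + 2)

  depth_row <- function(sample, dx, dy) {
    d <- data.table::data.table(scaffold = mk$scaffold, pos = mk$position,
                                sample = sample, A = 0L, C = 0L, G = 0L, T = 0L)
    ix <- match(mk$allele_x, bases); iy <- match(mk$allele_y, bases)
    m <- as.matrix(d[, c("A", "C", "G", "T")])
    m[cbind(seq_len(nm), ix)] <- m[cbind(seq_len(nm), ix)] + dx
    m[cbind(seq_len(nm), iy)] <- m[cbind(seq_len(nm), iy)] + dy
    d[, c("A", "C", "G", "T") := as.data.frame(m)]
    d
  }

  # parents: seed parent heterozygous X/Y, pollen parent homozygous X
  dA <- rpois(nm, design$parent_depth)
  ax <- rbinom(nm, dA, 0.5)
  dt_list[[1]] <- depth_row(parents[1], ax, dA - ax)
  dB <- rpois(nm, design$parent_depth)
  dt_list[[2]] <- depth_row(parents[2], dB, 0L)

  for (j in seq_len(np)) {
    d <- rpois(nm, design$depth)
    cj <- calls[, j]
    d[is.na(cj)] <- 0L
    dx <- integer(nm); dy <- integer(nm)
    hom <- !is.na(cj) & cj == 0L
    dx[hom] <- d[hom]
    het <- !is.na(cj) & cj == 1L
    d1 <- het & d == 1
    dy[d1] <- 1L
    d2 <- het & d >= 2
    xx <- 1L + rbinom(sum(d2), d[d2] - 2L, 0.5)
    dx[d2] <- xx
    dy[d2] <- d[d2] - xx
    dt_list[[j + 2]] <- depth_row(progeny[j], dx, dy)
  }
  pu <- data.table::rbindlist(dt_list)
  pu <- pu[pu$A + pu$C + pu$G + pu$T > 0, ]
  data.table::setDF(pu)
  pu
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth set: %d markers, %d chromosomes, %d scaffolds, %d progeny\n",
              nrow(x$markers), nrow(x$genome$chromosomes),
              nrow(x$scaffolds), x$design$n_progeny))
  invisible(x)
}
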