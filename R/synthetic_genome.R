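# Synthetic genome, crossover landscape and scaffold truth.
#
# The generator emulates the mapping substrate of a small outcrossing
# plant genome: 19 chromosomes, a scaffold-level assembly, gene
# annotations whose windowed density varies severalfold along each
# chromosome, and a planted step-function crossover landscape with
# hotspots (>10x background) and megabase-scale coldspots.

#' Simulate a genome with annotated genes
#'
#' Chromosome lengths partition `total_len` equally.  Genes are placed
#' by an inhomogeneous Poisson point process whose intensity varies
#' sinusoidally along each chromosome (4-fold peak-to-trough by
#' default, so windowed gene density varies at least 3-fold), around a
#' configurable mean density.  Optional `peaks` intervals multiply the
#' local intensity, which lets callers couple gene density to a planted
#' recombination landscape.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param total_len Total genome length in bp (>= 10 kb per chromosome).
#' @param gene_density Mean gene density in genes per bp (default
#'   2.82e-5, i.e. 2.82 genes / 100 kb).
#' @param density_amplitude Relative amplitude of the sinusoidal
#'   intensity (0 = homogeneous; default 0.6 gives a 4-fold swing).
#' @param mean_gene_len Mean gene length in bp (default 11538).
#' @param gc GC fraction used when sequence is emitted (default 0.344).
#' @param peaks Optional data.frame `(chrom, start, end, mult)` of
#'   intensity-multiplier intervals (0-based half-open).
#' @param seed RNG seed; fully determines the result.
#' @return An object of class `sim_genome`: list with `chromosomes`
#'   (data.frame `name`, `length`), `genes` (data.frame `chrom`,
#'   `start`, `end`, `id`; 0-based half-open) and `gc`.
#' @export
simulate_genome <- function(n_chrom = 19, total_len = 95e6,
                            gene_density = 2.82e-5,
                            density_amplitude = 0.6,
                            mean_gene_len = 11538,
                            gc = 0.344, peaks = NULL, seed = 1) {
  assert_that(is.numeric(n_chrom) && n_chrom >= 1, "n_chrom must be >= 1")
  assert_that(total_len >= n_chrom * 1e4,
              "total_len must allow >= 10 kb per chromosome")
  assert_that(gene_density >= 0 && density_amplitude >= 0 &&
                density_amplitude < 1, "bad density parameters")
  n_chrom <- as.integer(n_chrom)
  len <- rep(floor(total_len / n_chrom), n_chrom)
  len[n_chrom] <- len[n_chrom] + (total_len - sum(len))
  chroms <- data.frame(name = sprintf("chr%02d", seq_len(n_chrom)),
                       length = len, stringsAsFactors = FALSE)

  genes <- with_seed(seed, {
    out <- vector("list", n_chrom)
    for (c in seq_len(n_chrom)) {
      L <- len[c]
      phase <- runif(1, 0, 2 * pi)
      period <- L / runif(1, 2, 4)
      lambda_max <- gene_density * (1 + density_amplitude) *
        max_peak_mult(peaks, chroms$name[c])
      # thinning of a homogeneous process at the intensity envelope
      n_cand <- rpois(1, lambda_max * L)
      x <- sort(runif(n_cand, 0, L))
      lam <- gene_density * (1 + density_amplitude * sin(2 * pi * x / period + phase))
      lam <- lam * peak_mult(peaks, chroms$name[c], x)
      keep <- runif(n_cand) < lam / lambda_max
      s <- floor(x[keep])
      glen <- pmax(200, round(rgamma(length(s), shape = 2,
                                     scale = mean_gene_len / 2)))
      e <- pmin(s + glen, L)
      ok <- which(e > s)
      out[[c]] <- data.frame(chrom = rep(chroms$name[c], length(ok)),
                             start = s[ok], end = e[ok],
                             stringsAsFactors = FALSE)
    }
    g <- do.call(rbind, out)
    g$id <- sprintf("G%06d", seq_len(nrow(g)))
    g
  })
  structure(list(chromosomes = chroms, genes = genes,
                 gc = setNames(rep(gc, n_chrom), chroms$name)),
            class = "sim_genome")
}

max_peak_mult <- function(peaks, chrom) {
  if (is.null(peaks)) return(1)
  p <- peaks[peaks$chrom == chrom, ]
  if (nrow(p) == 0) 1 else max(1, p$mult)
}

peak_mult <- function(peaks, chrom, x) {
  m <- rep(1, length(x))
  if (is.null(peaks)) return(m)
  p <- peaks[peaks$chrom == chrom, ]
  for (k in seq_len(nrow(p))) {
    m[x >= p$start[k] & x < p$end[k]] <- p$mult[k]
  }
  m
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("synthetic genome: %d chromosomes, %.1f Mb, %d genes\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              nrow(x$genes)))
  invisible(x)
}

#' Plant a crossover-intensity landscape
#'
#' The landscape is a per-chromosome step function of recombination
#' intensity in cM/Mb: a constant background, hotspot intervals whose
#' rate must exceed 10x the background, and coldspot intervals with
#' rate exactly zero.  Planted intervals may not overlap.
#'
#' @param genome A [simulate_genome()] result.
#' @param background Background rate in cM/Mb.
#' @param hotspots data.frame `(chrom, start, end, rate)`, 0-based
#'   half-open, `rate > 10 * background`.
#' @param coldspots data.frame `(chrom, start, end)`.
#' @return Object of class `rec_landscape`: `intervals` (tiling step
#'   function `chrom, start, end, rate`), the planted `hotspots` and
#'   `coldspots`, per-chromosome `total_cm`, and the length-weighted
#'   `genome_avg` rate.
#' @export
plant_landscape <- function(genome, background = 5.5,
                            hotspots = NULL, coldspots = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  assert_that(background >= 0, "background rate must be >= 0")
  hotspots <- hotspots %||% empty_iv(rate = TRUE)
  coldspots <- coldspots %||% empty_iv()
  if (nrow(hotspots) > 0)
    assert_that(all(hotspots$rate > 10 * background),
                "hotspot rates must exceed 10x the background")
  planted <- rbind(hotspots[, c("chrom", "start", "end")],
                   coldspots[, c("chrom", "start", "end")])
  if (nrow(planted) > 1) {
    for (cn in unique(planted$chrom)) {
      p <- planted[planted$chrom == cn, ]
      p <- p[order(p$start), ]
      if (nrow(p) > 1 && any(p$start[-1] < p$end[-nrow(p)]))
        param_error("planted intervals overlap on ", cn)
    }
  }
  iv <- vector("list", nrow(genome$chromosomes))
  for (c in seq_len(nrow(genome$chromosomes))) {
    cn <- genome$chromosomes$name[c]
    L <- genome$chromosomes$length[c]
    h <- hotspots[hotspots$chrom == cn, ]
    k <- coldspots[coldspots$chrom == cn, ]
    seg <- rbind(if (nrow(h)) data.frame(start = h$start, end = h$end, rate = h$rate),
                 if (nrow(k)) data.frame(start = k$start, end = k$end, rate = 0))
    if (is.null(seg)) seg <- data.frame(start = numeric(), end = numeric(),
                                        rate = numeric())
    assert_that(nrow(seg) == 0 || (all(seg$start >= 0) && all(seg$end <= L)),
                "planted interval outside chromosome ", cn)
    seg <- seg[order(seg$start), ]
    bnd <- sort(unique(c(0, L, seg$start, seg$end)))
    step <- data.frame(chrom = cn, start = bnd[-length(bnd)], end = bnd[-1],
                       rate = background, stringsAsFactors = FALSE)
    for (s in seq_len(nrow(seg)))
      step$rate[step$start >= seg$start[s] & step$end <= seg$end[s]] <- seg$rate[s]
    iv[[c]] <- step
  }
  intervals <- do.call(rbind, iv)
  total_cm <- vapply(split(intervals, intervals$chrom), function(d)
    sum(d$rate * (d$end - d$start) / 1e6), 0)
  total_cm <- total_cm[genome$chromosomes$name]
  structure(list(intervals = intervals, hotspots = hotspots,
                 coldspots = coldspots, total_cm = total_cm,
                 genome_avg = sum(total_cm) /
                   (sum(genome$chromosomes$length) / 1e6)),
            class = "rec_landscape")
}

empty_iv <- function(rate = FALSE) {
  d <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                  stringsAsFactors = FALSE)
  if (rate) d$rate <- numeric()
  d
}

#' Default planted landscape for the scaled-down test world
#'
#' Background 5.5 cM/Mb, three 100 kb hotspots at 100 cM/Mb (mid-arm
#' on the first three chromosomes) and one 2 Mb coldspot (on the
#' fourth chromosome).  Genomes with fewer chromosomes get hotspots on
#' all but the last chromosome and the coldspot on the last one
#' (clipped to 90% of its length).
#'
#' @param genome A [simulate_genome()] result.
#' @param background Background rate, cM/Mb.
#' @param hotspot_rate Hotspot rate, cM/Mb.
#' @return A [plant_landscape()] result.
#' @export
default_landscape <- function(genome, background = 5.5, hotspot_rate = 100) {
  cn <- genome$chromosomes$name
  L <- genome$chromosomes$length
  stopifnot(length(cn) >= 2)
  nh <- min(3, length(cn) - 1)
  ic <- min(4, length(cn))
  hs <- data.frame(chrom = cn[seq_len(nh)],
                   start = floor(L[seq_len(nh)] * 0.4),
                   end = floor(L[seq_len(nh)] * 0.4) + 1e5,
                   rate = hotspot_rate, stringsAsFactors = FALSE)
  cs <- data.frame(chrom = cn[ic],
                   start = floor(L[ic] * 0.3),
                   end = min(floor(L[ic] * 0.3) + 2e6, floor(L[ic] * 0.9)),
                   stringsAsFactors = FALSE)
  plant_landscape(genome, background = background,
                  hotspots = hs, coldspots = cs)
}

# Cumulative genetic position (cM) of physical positions on one
# chromosome under a landscape step function.
cum_cm <- function(landscape, chrom, pos) {
  iv <- landscape$intervals[landscape$intervals$chrom == chrom, ]
  iv <- iv[order(iv$start), ]
  cum <- c(0, cumsum(iv$rate * (iv$end - iv$start) / 1e6))
  k <- findInterval(pos, iv$start)
  cum[k] + iv$rate[k] * (pos - iv$start[k]) / 1e6
}

#' Fragment a genome into scaffolds with known truth
#'
#' Scaffold breakpoints follow a Poisson process with mean fragment
#' length `mean_len`; breakpoints closer than 1 kb to another boundary
#' are dropped so every scaffold is at least 1 kb.  Scaffolds partition
#' each chromosome exactly; each receives a random true orientation and
#' a shuffled identifier so scaffold names carry no positional signal.
#'
#' @param genome A [simulate_genome()] result.
#' @param mean_len Mean scaffold length in bp (>= 2 kb).
#' @param seed RNG seed.
#' @return data.frame of class `scaffold_truth`: `scaffold`, `chrom`,
#'   `start`, `end` (0-based half-open on the source chromosome),
#'   `orientation` (`+`/`-`), `length`.
#' @export
fragment_scaffolds <- function(genome, mean_len = 1e6, seed = 1) {
  stopifnot(inherits(genome, "sim_genome"))
  assert_that(mean_len >= 2000, "mean_len must be >= 2 kb")
  with_seed(seed, {
    out <- vector("list", nrow(genome$chromosomes))
    for (c in seq_len(nrow(genome$chromosomes))) {
      L <- genome$chromosomes$length[c]
      nb <- rpois(1, L / mean_len)
      br <- sort(runif(nb, 0, L))
      bnd <- c(0, br, L)
      # enforce >= 1 kb fragments
      keep <- c(TRUE, diff(bnd) >= 1000)
      bnd <- bnd[keep]
      if (bnd[length(bnd)] != L) bnd[length(bnd)] <- L
      bnd <- floor(bnd)
      s <- bnd[-length(bnd)]; e <- bnd[-1]
      out[[c]] <- data.frame(chrom = genome$chromosomes$name[c],
                             start = s, end = e,
                             orientation = sample(c("+", "-"), length(s),
                                                  replace = TRUE),
                             stringsAsFactors = FALSE)
    }
    sc <- do.call(rbind, out)
    sc$scaffold <- sprintf("S%05d", sample(seq_len(nrow(sc))))
    sc$length <- sc$end - sc$start
    rownames(sc) <- NULL
    structure(sc[, c("scaffold", "chrom", "start", "end",
                     "orientation", "length")],
              class = c("scaffold_truth", "data.frame"))
  })
}

#' Emit random scaffold sequences at the genome's GC content
#'
#' Bases are i.i.d. at the per-chromosome GC fraction.  Chromosome
#' sequence is generated once per chromosome and sliced per scaffold
#' (reverse-complemented for `-` scaffolds), so re-orienting and
#' concatenating scaffold sequences reconstructs the chromosome.
#'
#' @param genome A [simulate_genome()] result.
#' @param scaffolds A [fragment_scaffolds()] truth table.
#' @param seed RNG seed.
#' @return A [Biostrings::DNAStringSet] named by scaffold id.
#' @export
scaffold_sequences <- function(genome, scaffolds, seed = 1) {
  stopifnot(inherits(genome, "sim_genome"))
  with_seed(seed, {
    seqs <- vector("list", nrow(scaffolds))
    for (c in seq_len(nrow(genome$chromosomes))) {
      cn <- genome$chromosomes$name[c]
      L <- genome$chromosomes$length[c]
      gcf <- genome$gc[[cn]]
      p <- c((1 - gcf) / 2, gcf / 2, gcf / 2, (1 - gcf) / 2)
      chrom_seq <- Biostrings::DNAString(paste(
        sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
        collapse = ""))
      rows <- which(scaffolds$chrom == cn)
      for (r in rows) {
        s <- Biostrings::subseq(chrom_seq, scaffolds$start[r] + 1,
                                scaffolds$end[r])
        if (scaffolds$orientation[r] == "-")
          s <- Biostrings::reverseComplement(s)
        seqs[[r]] <- s
      }
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- scaffolds$scaffold
    out
  })
}
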