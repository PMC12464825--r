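#' Count read positions into fixed-width genomic bins
#'
#' Assigns each read's single coordinate (for real pA-DamID data, the GATC
#' fragment end it was counted at) to the 0-based half-open bin containing
#' it, after discarding reads below the mapping-quality cutoff.
#'
#' @param reads `data.frame` with columns `chrom`, `pos` (0-based bp) and
#'   optionally `mapq`; reads without a `mapq` column are kept.
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp (default 20000).
#' @param mapq_min Minimum mapping quality (default 10).
#' @param sample,role Metadata passed to [count_track()].
#' @return A [count_track()].
#' @export
bin_reads <- function(reads, chrom_sizes, bin_size = 20000, mapq_min = 10,
                      sample = "sample", role = "antibody") {
  stopifnot(is.data.frame(reads), all(c("chrom", "pos") %in% names(reads)))
  bad_chrom <- !reads$chrom %in% names(chrom_sizes)
  if (any(bad_chrom)) {
    stop("read ", which(bad_chrom)[1], " on undeclared chromosome '",
         reads$chrom[bad_chrom][1], "'")
  }
  out_of_range <- reads$pos < 0 |
    reads$pos >= chrom_sizes[reads$chrom]
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    stop("read ", i, " at ", reads$chrom[i], ":", reads$pos[i],
         " lies outside the declared chromosome bounds")
  }
  if ("mapq" %in% names(reads)) {
    reads <- reads[reads$mapq >= mapq_min, , drop = FALSE]
  }
  nb <- n_bins(chrom_sizes, bin_size)
  counts <- lapply(names(nb), function(ch) {
    k <- nb[[ch]]
    p <- reads$pos[reads$chrom == ch]
    tabulate(floor(p / bin_size) + 1L, nbins = k)
  })
  names(counts) <- names(nb)
  count_track(counts, bin_size, chrom_sizes, sample = sample, role = role)
}

#' log2 antibody : Dam ratio per bin
#'
#' The core pA-DamID normalization: counts are scaled to reads-per-million,
#' a pseudocount is added, and the log2 ratio of antibody over the Dam-only
#' accessibility control is taken per bin:
#' `log2((ab * 1e6 / ab_total + 1) / (dam * 1e6 / dam_total + 1))`.
#'
#' @param ab,dam [count_track()]s on the same bin grid.
#' @param pseudocount Added to both normalized counts (default 1).
#' @param per_million Scale of the library-size normalization (default 1e6).
#' @return A [binned_track()] of log2 ratios.
#' @export
normalize_log_ratio <- function(ab, dam, pseudocount = 1,
                                per_million = 1e6) {
  stopifnot(inherits(ab, "count_track"), inherits(dam, "count_track"))
  stop_if_grid_mismatch(ab, dam)
  if (ab$library_total == 0 || dam$library_total == 0) {
    stop("library totals must be positive")
  }
  a <- track_values(ab) * per_million / ab$library_total
  d <- track_values(dam) * per_million / dam$library_total
  lr <- log2((a + pseudocount) / (d + pseudocount))
  set_track_values(empty_track(ab$chrom_sizes, ab$bin_size), lr)
}

#' Genome-wide z-scaling of a track
#'
#' Centers and scales all non-missing bins to mean 0, SD 1. Applied to log2
#' ratio tracks so that experiments with different dynamic ranges become
#' comparable before domain scoring.
#'
#' @param track A [binned_track()] with at least two non-missing bins.
#' @return A [binned_track()] of z-scores; missing bins stay missing.
#' @export
zscale_track <- function(track) {
  v <- track_values(track)
  ok <- !is.na(v)
  if (sum(ok) < 2) stop("need at least two non-missing bins")
  s <- stats::sd(v[ok])
  if (s == 0) stop("track has zero variance; cannot z-scale")
  set_track_values(track, (v - mean(v[ok])) / s)
}

#' Per-bin mean across replicate tracks
#'
#' Averages replicate tracks bin by bin over the non-missing values; a bin is
#' missing in the result only if it is missing in every replicate.
#'
#' @param tracks List of [binned_track()]s on the same grid.
#' @return A [binned_track()].
#' @export
average_replicates <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  for (t in tracks) stop_if_grid_mismatch(tracks[[1]], t)
  m <- vapply(tracks, track_values, numeric(length(track_values(tracks[[1]]))))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(tracks))
  avg <- rowMeans(m, na.rm = TRUE)
  avg[!rowSums(!is.na(m))] <- NA_real_
  set_track_values(tracks[[1]], avg)
}
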