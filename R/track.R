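#' Binned genomic signal track
#'
#' The universal currency of the pipeline: fixed-width genomic bins with one
#' floating-point value each (a raw count-derived score, a log2 ratio, or a
#' z-score). Bins are 0-based, half-open, tiled from position 0 on every
#' chromosome; the final bin of a chromosome may be partial. Missing values
#' are stored as `NA` and propagate through all downstream operations.
#'
#' @param values Named list, one numeric vector per chromosome. `NA` marks
#'   missing bins. Vector `i` must have `ceiling(chrom_sizes[i] / bin_size)`
#'   elements.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, bin_size, chrom_sizes) {
  stopifnot(is.list(values), length(bin_size) == 1L, bin_size >= 1)
  chrom_sizes <- chrom_sizes[order(names(chrom_sizes))]
  if (!setequal(names(values), names(chrom_sizes))) {
    stop("chromosome names of `values` and `chrom_sizes` differ")
  }
  values <- values[names(chrom_sizes)]
  nb <- n_bins(chrom_sizes, bin_size)
  got <- vapply(values, length, integer(1))
  if (!all(got == nb)) {
    bad <- names(nb)[got != nb]
    stop("wrong number of bins on ", paste(bad, collapse = ", "))
  }
  structure(
    list(values = lapply(values, as.numeric),
         bin_size = as.numeric(bin_size),
         chrom_sizes = chrom_sizes),
    class = "binned_track"
  )
}

#' Number of bins per chromosome for a bin grid
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp.
#' @return Named integer vector.
#' @export
n_bins <- function(chrom_sizes, bin_size) {
  stats::setNames(as.integer(ceiling(chrom_sizes / bin_size)),
                  names(chrom_sizes))
}

#' @export
print.binned_track <- function(x, ...) {
  v <- unlist(x$values, use.names = FALSE)
  cat(sprintf(
    "<binned_track> %d chromosome(s), bin %g bp, %d bins (%d missing)\n",
    length(x$values), x$bin_size, length(v), sum(is.na(v))))
  invisible(x)
}

#' Concatenated bin values of a track
#'
#' Bins in chromosome-name order, then position order; the genome-wide vector
#' most statistics operate on.
#'
#' @param track A `binned_track` or `count_track`.
#' @return Numeric vector with `NA` for missing bins.
#' @export
track_values <- function(track) {
  v <- if (inherits(track, "count_track")) track$counts else track$values
  unlist(v, use.names = FALSE)
}

## Replace the per-chromosome vectors of `track` with a flat vector `v`
## (same layout as track_values()); internal.
set_track_values <- function(track, v) {
  nb <- n_bins(track$chrom_sizes, track$bin_size)
  stopifnot(length(v) == sum(nb))
  end <- cumsum(nb)
  start <- end - nb + 1L
  track$values <- stats::setNames(
    lapply(seq_along(nb), function(i) as.numeric(v[start[i]:end[i]])),
    names(nb))
  track
}

same_grid <- function(a, b) {
  isTRUE(a$bin_size == b$bin_size) &&
    identical(names(a$chrom_sizes), names(b$chrom_sizes)) &&
    isTRUE(all(a$chrom_sizes == b$chrom_sizes))
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("bin grids differ between tracks")
  invisible(TRUE)
}

#' Per-bin integer counts for one sample
#'
#' Same bin grid as [binned_track()], but holding non-negative integer read
#' counts plus sample metadata. `role` distinguishes the antibody-directed
#' sample from the freely diffusing Dam-only accessibility control.
#'
#' @param counts Named list of non-negative integer vectors, one per
#'   chromosome.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param sample Sample label.
#' @param role `"antibody"` or `"dam"`.
#' @return An object of class `count_track`.
#' @export
count_track <- function(counts, bin_size, chrom_sizes, sample = "sample",
                        role = c("antibody", "dam")) {
  role <- match.arg(role)
  v <- unlist(counts, use.names = FALSE)
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers")
  }
  obj <- binned_track(counts, bin_size, chrom_sizes)
  obj$counts <- lapply(obj$values, as.integer)
  obj$values <- NULL
  obj$sample <- sample
  obj$role <- role
  obj$library_total <- sum(v)
  class(obj) <- c("count_track", "binned_track")
  obj
}

#' @export
print.count_track <- function(x, ...) {
  cat(sprintf("<count_track> sample '%s' (%s), %d chromosome(s), bin %g bp, %d reads\n",
              x$sample, x$role, length(x$counts), x$bin_size, x$library_total))
  invisible(x)
}

#' Ordered set of LAD / iLAD domains
#'
#' Non-overlapping, sorted intervals per chromosome labelled `"LAD"` or
#' `"iLAD"`, 0-based half-open, optionally carrying a per-domain score (the
#' mean z-scaled signal over the domain's bins). Within a chromosome,
#' consecutive domains that tile the chromosome alternate in state.
#'
#' @param chrom,start,end,state Vectors describing the intervals; `state` in
#'   `{"LAD","iLAD"}`; coordinates 0-based half-open.
#' @param score Optional numeric score per domain (default `NA`).
#' @param id Optional unique identifiers; autogenerated as
#'   `"<state>_<chrom>_<n>"` when missing.
#' @return A `data.frame` of class `domain_set` with columns
#'   `chrom, start, end, state, score, id`.
#' @export
domain_set <- function(chrom, start, end, state, score = NA_real_, id = NULL) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(state))
  if (!all(state %in% c("LAD", "iLAD"))) stop("state must be 'LAD' or 'iLAD'")
  if (any(end <= start)) stop("domain intervals must satisfy start < end")
  d <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start), end = as.numeric(end),
                  state = as.character(state),
                  score = rep_len(as.numeric(score), length(chrom)),
                  stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  for (ch in unique(d$chrom)) {
    i <- d$chrom == ch
    if (any(d$start[i][-1] < d$end[i][-sum(i)])) {
      stop("overlapping domains on ", ch)
    }
  }
  if (is.null(id)) {
    within_chrom <- stats::ave(seq_len(nrow(d)), d$chrom, FUN = seq_along)
    id <- sprintf("%s_%s_%03d", d$state, d$chrom, within_chrom)
  }
  if (anyDuplicated(id)) stop("domain ids must be unique")
  d$id <- as.character(id)
  rownames(d) <- NULL
  class(d) <- c("domain_set", "data.frame")
  d
}

#' @export
print.domain_set <- function(x, ...) {
  cat(sprintf("<domain_set> %d domains (%d LAD, %d iLAD) on %d chromosome(s)\n",
              nrow(x), sum(x$state == "LAD"), sum(x$state == "iLAD"),
              length(unique(x$chrom))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Subset of a domain set, preserving the class
#'
#' @param x A `domain_set`.
#' @param keep Logical or integer index over rows.
#' @return A `domain_set`.
#' @export
domain_subset <- function(x, keep) {
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("domain_set", "data.frame")
  out
}

#' Sorted nucleosome dyad (centre) positions
#'
#' @param positions Named list with one sorted numeric vector of dyad centre
#'   positions (bp) per chromosome; positions must be strictly increasing.
#' @return An object of class `dyad_set`.
#' @export
dyad_set <- function(positions) {
  stopifnot(is.list(positions))
  for (ch in names(positions)) {
    p <- positions[[ch]]
    if (length(p) > 1 && any(diff(p) <= 0)) {
      stop("dyad positions on ", ch, " must be strictly increasing")
    }
  }
  structure(list(positions = lapply(positions, as.numeric)),
            class = "dyad_set")
}

#' @export
print.dyad_set <- function(x, ...) {
  cat(sprintf("<dyad_set> %d dyads on %d chromosome(s)\n",
              sum(vapply(x$positions, length, integer(1))),
              length(x$positions)))
  invisible(x)
}

## GRanges conversion helpers (used by IO and overlap code) --------------

domains_to_granges <- function(domains) {
  GenomicRanges::GRanges(
    seqnames = domains$chrom,
    ranges = IRanges::IRanges(start = domains$start + 1, end = domains$end),
    state = domains$state, score = domains$score, id = domains$id)
}

track_to_granges <- function(track) {
  nb <- n_bins(track$chrom_sizes, track$bin_size)
  chrom <- rep(names(nb), nb)
  bin0 <- unlist(lapply(nb, function(k) seq_len(k) - 1L), use.names = FALSE)
  start <- bin0 * track$bin_size
  end <- pmin(start + track$bin_size,
              rep(unname(track$chrom_sizes), nb))
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    score = track_values(track))
}
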