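#' Extract usable LAD borders from a domain set
#'
#' The flanks of every LAD become candidate borders, then two exclusion
#' rules apply: borders within `end_exclusion` of a chromosome end are
#' dropped (those are chromosome ends, not real borders), and borders
#' adjacent to any LAD or iLAD shorter than `min_domain` are dropped (such
#' domains span only a couple of bins and would add a noisy single-sided
#' data point).
#'
#' @param domains A [domain_set()].
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param end_exclusion Distance (bp) from chromosome ends inside which
#'   borders are discarded (default 50000).
#' @param min_domain Minimum adjacent-domain length in bp (default 50000).
#' @return `data.frame` with columns `chrom`, `pos` (bp) and `lad_side`
#'   (`"right"` if the LAD begins at the border, `"left"` if it ends there).
#' @export
extract_borders <- function(domains, chrom_sizes, end_exclusion = 50000,
                            min_domain = 50000) {
  rows <- list()
  for (ch in unique(domains$chrom)) {
    d <- domains[domains$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    len <- d$end - d$start
    csize <- chrom_sizes[[ch]]
    for (i in which(d$state == "LAD")) {
      for (side in c("right", "left")) {
        pos <- if (side == "right") d$start[i] else d$end[i]
        if (pos < end_exclusion || pos > csize - end_exclusion) next
        ## the neighbouring domain across the border
        j <- if (side == "right") which(d$end == pos) else
          which(d$start == pos)
        j <- setdiff(j, i)
        if (length(j) != 1) next          # no abutting neighbour
        if (len[i] < min_domain || len[j] < min_domain) next
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, pos = pos, lad_side = side, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), pos = numeric(0),
                      lad_side = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Consensus signal profile around LAD borders
#'
#' Every genomic bin is assigned to its closest LAD border only (ties go to
#' the lower-coordinate border), so each position contributes exactly once
#' even when borders are nearby. The signed relative position of a bin
#' (positive = LAD interior, measured between bin centre and border) then
#' indexes the mean signal and a normal-theory 95% confidence interval of
#' the mean across all contributing bins.
#'
#' @param track A [binned_track()].
#' @param borders [extract_borders()] output (must be non-empty).
#' @param window Maximum distance (bp) from the border (default 500000);
#'   bins farther than `window` from every border are unassigned.
#' @return `data.frame` of class `border_profile` with columns `rel_pos`
#'   (bp; half-bin offsets because bin centres are used), `mean`, `ci_lo`,
#'   `ci_hi` (NA where `n < 2`) and `n`.
#' @export
border_profile <- function(track, borders, window = 500000) {
  if (nrow(borders) == 0) stop("empty border list")
  bs <- track$bin_size
  rel <- numeric(0)
  val <- numeric(0)
  for (ch in names(track$values)) {
    b <- borders[borders$chrom == ch, , drop = FALSE]
    if (nrow(b) == 0) next
    v <- track$values[[ch]]
    centre <- (seq_along(v) - 0.5) * bs
    idx <- findInterval(centre, b$pos)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, nrow(b))
    d_lo <- abs(centre - b$pos[lo])
    d_hi <- abs(b$pos[hi] - centre)
    pick <- ifelse(idx == 0, hi, ifelse(idx == nrow(b), lo,
                                        ifelse(d_lo <= d_hi, lo, hi)))
    pos <- b$pos[pick]
    sign <- ifelse(b$lad_side[pick] == "right", 1, -1)
    r <- (centre - pos) * sign
    keep <- abs(r) <= window & !is.na(v)
    rel <- c(rel, r[keep])
    val <- c(val, v[keep])
  }
  if (length(rel) == 0) stop("no bins fall within the window of any border")
  grp <- factor(rel, levels = sort(unique(rel)))
  n <- as.integer(table(grp))
  mu <- tapply(val, grp, mean)
  sdv <- tapply(val, grp, stats::sd)
  se <- ifelse(n >= 2, sdv / sqrt(n), NA_real_)
  out <- data.frame(rel_pos = as.numeric(levels(grp)),
                    mean = as.numeric(mu),
                    ci_lo = as.numeric(mu - 1.96 * se),
                    ci_hi = as.numeric(mu + 1.96 * se),
                    n = n, row.names = NULL)
  class(out) <- c("border_profile", "data.frame")
  out
}
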