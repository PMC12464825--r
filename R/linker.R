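#' Linker-DNA lengths per domain state
#'
#' From nucleosome dyad (centre) positions: dyads are first intersected with
#' the domains containing them; distances between consecutive dyads within
#' the same domain are computed; distances above `short_cut` have the
#' 147-bp nucleosomal footprint subtracted (two well-separated dyads span a
#' full nucleosome), shorter distances are taken as-is; finally only linkers
#' within `[keep_min, keep_max]` bp are retained, grouped by domain state.
#' Dyad pairs spanning a domain boundary are excluded.
#'
#' @param dyads A [dyad_set()].
#' @param domains A [domain_set()].
#' @param nuc_len Nucleosome footprint subtracted from long distances
#'   (default 147 bp).
#' @param short_cut Distance threshold above which `nuc_len` is subtracted
#'   (default 100 bp).
#' @param keep_min,keep_max Retained linker-length range (defaults 1 and
#'   100 bp).
#' @return Named list with one numeric vector of linker lengths per state
#'   (`LAD`, `iLAD`).
#' @export
linker_lengths <- function(dyads, domains, nuc_len = 147, short_cut = 100,
                           keep_min = 1, keep_max = 100) {
  stopifnot(inherits(dyads, "dyad_set"), inherits(domains, "domain_set"))
  out <- list(LAD = numeric(0), iLAD = numeric(0))
  for (ch in names(dyads$positions)) {
    p <- dyads$positions[[ch]]
    if (length(p) < 2) next
    d <- domains[domains$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) next
    d <- d[order(d$start), , drop = FALSE]
    idx <- findInterval(p, d$start)
    inside <- idx >= 1 & p < c(d$end, Inf)[pmax(idx, 1)]
    idx[!inside] <- NA_integer_
    same <- !is.na(idx[-length(idx)]) & !is.na(idx[-1]) &
      idx[-length(idx)] == idx[-1]
    if (!any(same)) next
    dist <- diff(p)[same]
    linker <- ifelse(dist > short_cut, dist - nuc_len, dist)
    st <- d$state[idx[-length(idx)][same]]
    keep <- linker >= keep_min & linker <= keep_max
    for (s in c("LAD", "iLAD")) {
      out[[s]] <- c(out[[s]], linker[keep & st == s])
    }
  }
  out
}

## Area-weighted mean of a track over one interval [s, e) in bp; missing
## bins and positions outside the genome contribute zero signal but full
## width (deepTools' missingDataAsZero behaviour).
interval_mean_zero <- function(values, bin_size, s, e) {
  if (e <= s) return(0)
  i0 <- max(floor(s / bin_size), 0)
  i1 <- min(ceiling(e / bin_size) - 1, length(values) - 1)
  if (i1 < i0) return(0)
  idx <- i0:i1
  ov <- pmin(e, (idx + 1) * bin_size) - pmax(s, idx * bin_size)
  v <- values[idx + 1]
  v[is.na(v)] <- 0
  sum(v * ov) / (e - s)
}

#' Scale-regions pile-up matrix over domains
#'
#' Builds a deepTools-computeMatrix-style matrix: for every domain, fixed
#' `before` and `after` flanks are averaged in native `bs`-bp columns while
#' the domain body is rescaled to `body / bs` columns by area-weighted
#' averaging, so domains of different lengths align column-wise. Missing
#' data and positions beyond chromosome ends count as zero signal.
#'
#' @param track A [binned_track()].
#' @param domains A non-empty [domain_set()].
#' @param bs Column width in bp (default 10000).
#' @param before,after Flank lengths in bp (defaults 500000).
#' @param body Rescaled body length in bp (default 1000000).
#' @param skip_zeros Drop all-zero rows (default `FALSE`).
#' @return A numeric matrix of class `pileup_matrix` (rows = domains, ids
#'   as rownames) with attributes `rel_pos` (column coordinates in bp;
#'   body columns span `[0, body]`) and `section`
#'   (`"before"/"body"/"after"` per column). Domains shorter than `bs` are
#'   listed in `attr(, "degenerate")`.
#' @export
scaled_region_pileup <- function(track, domains, bs = 10000,
                                 before = 500000, body = 1000000,
                                 after = 500000, skip_zeros = FALSE) {
  if (nrow(domains) == 0) stop("domain set is empty")
  n_before <- as.integer(round(before / bs))
  n_body <- as.integer(round(body / bs))
  n_after <- as.integer(round(after / bs))
  ncol_total <- n_before + n_body + n_after
  m <- matrix(0, nrow(domains), ncol_total)
  rownames(m) <- domains$id
  degenerate <- character(0)
  for (i in seq_len(nrow(domains))) {
    ch <- domains$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v)) next
    s <- domains$start[i]; e <- domains$end[i]
    if (e - s < bs) degenerate <- c(degenerate, domains$id[i])
    col <- 1L
    for (j in seq_len(n_before)) {
      m[i, col] <- interval_mean_zero(v, track$bin_size,
                                      s - before + (j - 1) * bs,
                                      s - before + j * bs)
      col <- col + 1L
    }
    bnd <- seq(s, e, length.out = n_body + 1)
    for (j in seq_len(n_body)) {
      m[i, col] <- interval_mean_zero(v, track$bin_size, bnd[j], bnd[j + 1])
      col <- col + 1L
    }
    for (j in seq_len(n_after)) {
      m[i, col] <- interval_mean_zero(v, track$bin_size,
                                      e + (j - 1) * bs, e + j * bs)
      col <- col + 1L
    }
  }
  if (skip_zeros) {
    keep <- rowSums(m != 0) > 0
    m <- m[keep, , drop = FALSE]
  }
  attr(m, "rel_pos") <- c(-rev(seq_len(n_before)) * bs + bs / 2,
                          seq_len(n_body) * bs - bs / 2,
                          body + seq_len(n_after) * bs - bs / 2)
  attr(m, "section") <- rep(c("before", "body", "after"),
                            c(n_before, n_body, n_after))
  attr(m, "degenerate") <- degenerate
  class(m) <- c("pileup_matrix", class(m))
  m
}
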