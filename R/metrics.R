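#' Per-bin differential signal track
#'
#' Element-wise `perturbed - control`. Callers normally supply z-scored
#' tracks so the difference is on a dynamic-range-free scale; set
#' `rescale = TRUE` to z-scale both inputs here first.
#'
#' @param perturbed,control [binned_track()]s on the same grid.
#' @param rescale Z-scale both tracks before subtracting (default `FALSE`).
#' @return A [binned_track()]; a bin is missing if missing in either input.
#' @export
differential_track <- function(perturbed, control, rescale = FALSE) {
  stop_if_grid_mismatch(perturbed, control)
  if (rescale) {
    perturbed <- zscale_track(perturbed)
    control <- zscale_track(control)
  }
  set_track_values(control, track_values(perturbed) - track_values(control))
}

#' De-partitioning slope
#'
#' Ordinary least squares of the differential signal (perturbed - control)
#' on the control signal across bins. A negative slope means bins with high
#' NL association lose signal while low bins gain it - the hallmark of
#' genome-NL de-partitioning; a slope of `-k` corresponds to shrinking the
#' contrast by factor `1 - k`.
#'
#' @param control Control [binned_track()].
#' @param differential Differential [binned_track()]
#'   (see [differential_track()]).
#' @return An object of class `slope_result`: `slope`, `intercept`,
#'   `pearson_r`, `p`, `n`. When the differential has zero variance the
#'   correlation is reported as 0 with p = 1.
#' @export
departition_slope <- function(control, differential) {
  stop_if_grid_mismatch(control, differential)
  x <- track_values(control)
  y <- track_values(differential)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 paired non-missing bins")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0) stop("control track has zero variance")
  fit <- stats::lm.fit(cbind(1, x), y)
  if (stats::sd(y) == 0) {
    r <- 0; p <- 1
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 pearson_r = r, p = p, n = length(x)),
            class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf("<slope_result> slope %.4f, r %.3f (p %.3g, n %d)\n",
              x$slope, x$pearson_r, x$p, x$n))
  invisible(x)
}

#' Bimodality of a signal distribution
#'
#' Control pA-DamID signal is typically bimodal (LAD and iLAD modes);
#' de-partitioning collapses it to one mode. This metric fits one- and
#' two-component Gaussian mixtures by EM and combines a BIC comparison with
#' Ashman's D, `sqrt(2) * |mu1 - mu2| / sqrt(s1^2 + s2^2)` - a scale-free
#' separation index. The verdict is `bimodal` iff BIC favours two
#' components and `D > 2`.
#'
#' @param track A [binned_track()] with at least 100 non-missing bins.
#' @param min_prop Smallest admissible mixing proportion before the
#'   two-component fit is declared degenerate (default 0.02).
#' @return An object of class `bimodality_result`: `ashman_D`, `delta_BIC`
#'   (two-component minus one-component; positive favours two), `verdict`
#'   (`"bimodal"` or `"unimodal"`) and `degenerate` flag.
#' @export
bimodality_assess <- function(track, min_prop = 0.02) {
  v <- track_values(track)
  v <- v[!is.na(v)]
  if (length(v) < 100) stop("need at least 100 non-missing bins")
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  fit1 <- mclust::Mclust(v, G = 1, modelNames = "V", verbose = FALSE)
  fit2 <- mclust::Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
  degenerate <- is.null(fit2) ||
    min(fit2$parameters$pro) < min_prop ||
    min(fit2$parameters$variance$sigmasq) < 1e-12
  if (degenerate) {
    out <- list(ashman_D = NA_real_, delta_BIC = NA_real_,
                verdict = "unimodal", degenerate = TRUE,
                parameters = NULL)
    class(out) <- "bimodality_result"
    return(out)
  }
  mu <- fit2$parameters$mean
  s2 <- fit2$parameters$variance$sigmasq
  if (length(s2) == 1) s2 <- rep(s2, 2)
  D <- sqrt(2) * abs(mu[1] - mu[2]) / sqrt(s2[1] + s2[2])
  dbic <- fit2$bic - fit1$bic      # mclust BIC: larger is better
  out <- list(ashman_D = unname(D), delta_BIC = unname(dbic),
              verdict = if (dbic > 0 && D > 2) "bimodal" else "unimodal",
              degenerate = FALSE,
              parameters = list(mean = unname(mu), sigmasq = unname(s2),
                                pro = unname(fit2$parameters$pro)))
  class(out) <- "bimodality_result"
  out
}

#' @export
print.bimodality_result <- function(x, ...) {
  cat(sprintf("<bimodality_result> verdict %s (Ashman's D %.2f, delta BIC %.1f)%s\n",
              x$verdict, x$ashman_D, x$delta_BIC,
              if (x$degenerate) " [degenerate fit]" else ""))
  invisible(x)
}

#' Compare per-domain scores between LADs and iLADs
#'
#' Computes the mean signal per domain and tests the LAD score set against
#' the iLAD score set with Welch's t-test or a two-sided Wilcoxon rank-sum
#' test. Percentile trimming (top and bottom `trim_pct` percentiles) is
#' applied only to the reported score lists intended for plotting, never to
#' the test itself.
#'
#' @param track A [binned_track()].
#' @param domains A [domain_set()] containing both states.
#' @param test `"welch"` or `"wilcoxon"`.
#' @param trim_pct Percentile trimmed from each tail of the plotted lists
#'   (default 0.5, i.e. 0.5%).
#' @return A list of class `score_comparison`: `scores` (data.frame id,
#'   state, score), `trimmed` (list of per-state score vectors after
#'   trimming), `statistic`, `p`, `test`.
#' @export
domain_score_compare <- function(track, domains,
                                 test = c("welch", "wilcoxon"),
                                 trim_pct = 0.5) {
  test <- match.arg(test)
  sc <- domain_means(domains, track)
  df <- data.frame(id = domains$id, state = domains$state, score = sc,
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$score), , drop = FALSE]
  lad <- df$score[df$state == "LAD"]
  ilad <- df$score[df$state == "iLAD"]
  if (length(lad) < 2 || length(ilad) < 2) {
    stop("each state needs at least two scored domains")
  }
  ht <- if (test == "welch") {
    stats::t.test(lad, ilad, var.equal = FALSE)
  } else {
    stats::wilcox.test(lad, ilad, alternative = "two.sided", exact = FALSE)
  }
  trim <- function(x) {
    q <- stats::quantile(x, c(trim_pct / 100, 1 - trim_pct / 100),
                         names = FALSE)
    x[x >= q[1] & x <= q[2]]
  }
  structure(list(scores = df,
                 trimmed = list(LAD = trim(lad), iLAD = trim(ilad)),
                 statistic = unname(ht$statistic), p = ht$p.value,
                 test = test),
            class = "score_comparison")
}

## Membership of every grid bin (by centre) in a set of intervals.
bins_in_set <- function(set, chrom_sizes, bin_size) {
  nb <- n_bins(chrom_sizes, bin_size)
  out <- logical(sum(nb))
  offset <- c(0, cumsum(nb))[seq_along(nb)]
  names(offset) <- names(nb)
  for (ch in unique(set$chrom)) {
    if (!ch %in% names(nb)) next
    d <- set[set$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    mid <- (seq_len(nb[[ch]]) - 0.5) * bin_size
    idx <- findInterval(mid, d$start)
    hit <- idx >= 1 & mid < c(d$end, Inf)[pmax(idx, 1)]
    out[offset[[ch]] + which(hit)] <- TRUE
  }
  out
}

#' Genomic overlap between two domain subsets, with Fisher's test
#'
#' Reports the base-pair overlap (in Mb) between two interval sets and
#' tests their association over a grid of fixed-width genome bins with a
#' two-sided Fisher exact test on the 2x2 membership table.
#'
#' @param set_a,set_b [domain_set()]s (or subsets via [domain_subset()]) on
#'   the same genome.
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param bin_size Width of the bins used for the contingency table
#'   (default 20000).
#' @return An object of class `overlap_result`: `overlap_mb`, `a_mb`,
#'   `b_mb`, `table` (2x2), `p`, `odds_ratio` (`Inf`-safe), `skipped`
#'   (TRUE when a set is empty and the test was skipped).
#' @export
domain_overlap <- function(set_a, set_b, chrom_sizes, bin_size = 20000) {
  mb <- function(gr) sum(as.numeric(GenomicRanges::width(gr))) / 1e6
  gr_a <- if (nrow(set_a)) GenomicRanges::reduce(domains_to_granges(set_a))
          else GenomicRanges::GRanges()
  gr_b <- if (nrow(set_b)) GenomicRanges::reduce(domains_to_granges(set_b))
          else GenomicRanges::GRanges()
  ov <- if (length(gr_a) && length(gr_b)) {
    mb(GenomicRanges::intersect(gr_a, gr_b))
  } else 0
  if (nrow(set_a) == 0 || nrow(set_b) == 0) {
    out <- list(overlap_mb = 0, a_mb = mb(gr_a), b_mb = mb(gr_b),
                table = NULL, p = NA_real_, odds_ratio = NA_real_,
                skipped = TRUE)
    class(out) <- "overlap_result"
    return(out)
  }
  in_a <- bins_in_set(set_a, chrom_sizes, bin_size)
  in_b <- bins_in_set(set_b, chrom_sizes, bin_size)
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)),
               dnn = c("in_a", "in_b"))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  structure(list(overlap_mb = ov, a_mb = mb(gr_a), b_mb = mb(gr_b),
                 table = tab, p = ft$p.value,
                 odds_ratio = unname(ft$estimate), skipped = FALSE),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> overlap %.2f Mb (A %.2f Mb, B %.2f Mb)",
              x$overlap_mb, x$a_mb, x$b_mb))
  if (!x$skipped) cat(sprintf("; Fisher p %.3g, OR %.3g", x$p, x$odds_ratio))
  cat("\n")
  invisible(x)
}

#' Pearson correlation between two tracks
#'
#' Correlation over pairwise non-missing bins, optionally restricted by a
#' logical concordance mask (e.g. to drop bins discordant between two cell
#' lines in control data).
#'
#' @param track_a,track_b [binned_track()]s on the same grid.
#' @param mask Optional logical vector over the genome-wide bins; `FALSE`
#'   bins are excluded.
#' @return List with `r`, `p` (exact t transform, n-2 df) and `n`.
#' @export
track_correlation <- function(track_a, track_b, mask = NULL) {
  stop_if_grid_mismatch(track_a, track_b)
  a <- track_values(track_a)
  b <- track_values(track_b)
  keep <- !is.na(a) & !is.na(b)
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(a))
    keep <- keep & mask
  }
  if (sum(keep) < 3) stop("need at least 3 usable bin pairs")
  ct <- stats::cor.test(a[keep], b[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}
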