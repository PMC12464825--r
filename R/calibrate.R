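#' Spike-in scaling factors for one sample
#'
#' Computes the affine factors that convert the spike-genome (second
#' species) log2-ratio track of a sample to a z-score: offset `b` = mean and
#' scale `a` = SD over non-missing spike bins. Because all spike-ins come
#' from one biological sample, applying each sample's own factors to its
#' target-genome track puts every sample on a common scale while preserving
#' genuine global dynamic-range differences. Larger bins (default 250 kb)
#' are used for the spike genome because spike reads are sparse and larger
#' bins give more stable estimates.
#'
#' @param spike_track [binned_track()] of spike-genome log2 ratios.
#' @param min_bins Minimum non-missing spike bins required (default 20).
#' @return An object of class `calibration_factors` with elements `offset`,
#'   `scale`, `bin_size`, `n_bins`.
#' @export
compute_spikein_scaling <- function(spike_track, min_bins = 20) {
  v <- track_values(spike_track)
  v <- v[!is.na(v)]
  if (length(v) < min_bins) {
    stop("only ", length(v), " non-missing spike bins; at least ", min_bins,
         " are required for stable scaling estimates")
  }
  a <- stats::sd(v)
  if (a == 0) stop("spike track has zero variance")
  structure(list(offset = mean(v), scale = a,
                 bin_size = spike_track$bin_size, n_bins = length(v)),
            class = "calibration_factors")
}

#' @export
print.calibration_factors <- function(x, ...) {
  cat(sprintf("<calibration_factors> offset %.4f, scale %.4f (%d spike bins of %g bp)\n",
              x$offset, x$scale, x$n_bins, x$bin_size))
  invisible(x)
}

#' Apply spike-in calibration factors to a target track
#'
#' Transforms every bin as `(x - offset) / scale` using the factors derived
#' from the sample's spike-in. Unlike per-sample z-scaling, the target track
#' is deliberately not re-centred on its own statistics, so a genuine global
#' gain or loss of signal survives the transformation.
#'
#' @param target_track [binned_track()] of target-genome log2 ratios.
#' @param factors A [compute_spikein_scaling()] result.
#' @return Calibrated [binned_track()]; missing bins stay missing.
#' @export
apply_scaling <- function(target_track, factors) {
  stopifnot(inherits(factors, "calibration_factors"))
  v <- track_values(target_track)
  set_track_values(target_track, (v - factors$offset) / factors$scale)
}
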