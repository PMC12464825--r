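#' Normalized (optionally z-scored) log-ratio tracks for simulated samples
#'
#' Convenience wrapper running [normalize_log_ratio()] (and optionally
#' [zscale_track()]) on every sample of a [simulate_counts()] result, for
#' the target or the spike genome.
#'
#' @param sim A `sim_counts` object.
#' @param zscore Z-scale each replicate track (default `TRUE`); the usual
#'   order is z-scaling per replicate, then averaging per condition.
#' @param genome `"target"` or `"spike"`.
#' @return Named list of [binned_track()]s (names like `control_rep1`),
#'   with the per-track condition labels in `attr(, "condition")`.
#' @export
pa_damid_tracks <- function(sim, zscore = TRUE,
                            genome = c("target", "spike")) {
  stopifnot(inherits(sim, "sim_counts"))
  genome <- match.arg(genome)
  out <- list()
  cond <- character(0)
  for (s in sim$samples) {
    tr <- if (genome == "target") {
      normalize_log_ratio(s$ab, s$dam)
    } else {
      normalize_log_ratio(s$spike_ab, s$spike_dam)
    }
    if (zscore) tr <- zscale_track(tr)
    nm <- sprintf("%s_rep%d", s$condition, s$replicate)
    out[[nm]] <- tr
    cond[nm] <- s$condition
  }
  attr(out, "condition") <- cond
  out
}

#' Call LADs on an averaged control track
#'
#' Fits the two-state HMM and decodes domains in one step - the standard
#' route from an averaged control-condition track to a LAD model whose
#' coordinates are reused for every sample.
#'
#' @param track Averaged control [binned_track()].
#' @param emission,df,min_bins Passed to [fit_two_state_hmm()] and
#'   [segment_domains()].
#' @return List with `model` (an `hmm_model`) and `domains`
#'   (a [domain_set()]).
#' @export
call_lads <- function(track, emission = "t", df = 3, min_bins = 1) {
  model <- fit_two_state_hmm(track, emission = emission, df = df)
  list(model = model, domains = segment_domains(track, model,
                                                min_bins = min_bins))
}
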