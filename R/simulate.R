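#' Perturbation applied to the latent contrast of one condition
#'
#' Describes how the perturbed condition differs from control:
#' `departition_factor` shrinks every bin's true antibody:Dam contrast toward
#' the genome mean by a factor `1 - k` (emulating a global loss of LAD/iLAD
#' partitioning), and a fraction of domains may additionally receive a
#' constant signed shift (domain-level gains/losses).
#'
#' @param departition_factor k in `[0, 1]`; 0 leaves the contrast untouched,
#'   1 collapses it entirely onto the genome mean.
#' @param affected_lad_fraction,affected_ilad_fraction Fractions of LAD /
#'   iLAD domains receiving the additive shift.
#' @param lad_shift,ilad_shift Signed log2-contrast shifts added to every bin
#'   of an affected domain.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(departition_factor = 0,
                              affected_lad_fraction = 0,
                              affected_ilad_fraction = 0,
                              lad_shift = 0, ilad_shift = 0) {
  if (departition_factor < 0 || departition_factor > 1) {
    stop("departition_factor must lie in [0, 1]")
  }
  if (affected_lad_fraction < 0 || affected_lad_fraction > 1 ||
      affected_ilad_fraction < 0 || affected_ilad_fraction > 1) {
    stop("affected fractions must lie in [0, 1]")
  }
  structure(list(departition_factor = departition_factor,
                 affected_lad_fraction = affected_lad_fraction,
                 affected_ilad_fraction = affected_ilad_fraction,
                 lad_shift = lad_shift, ilad_shift = ilad_shift),
            class = "perturbation_spec")
}

#' Full generative description of a synthetic pA-DamID experiment
#'
#' Collects every knob of the generator: the genome, the domain-length
#' process, the count model, the perturbation, the spike-in, and the seed.
#' Defaults describe a typical pA-DamID experiment: 20-kb bins, a LAD/iLAD
#' contrast gap of 2 log2 units, per-bin biological noise of 0.3, about one
#' million reads per sample, two replicates per condition, and a 20% mouse
#' spike-in.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp); each
#'   must be at least `2 * bin_size`.
#' @param bin_size Bin width in bp (default 20000).
#' @param lad_mean_len,ilad_mean_len Mean domain lengths in bp of the
#'   geometric (in bins) length distributions; `Inf` gives single-state
#'   chromosomes.
#' @param mu_lad,mu_ilad Mean log2 antibody:Dam contrast per state; requires
#'   `mu_lad > mu_ilad`.
#' @param sigma_bin Per-bin SD of the contrast around its state mean, drawn
#'   independently per replicate (biological noise).
#' @param dam_depth,ab_depth Expected reads per Dam / antibody sample.
#' @param dispersion Negative-binomial dispersion of per-bin counts
#'   (`variance = mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param n_replicates Replicates per condition.
#' @param perturbation A [perturbation_spec()].
#' @param spike_fraction Fraction of each library drawn from the spike
#'   genome, in `[0, 1)` (default 0.20).
#' @param spike_chrom_sizes Named sizes of the spike genome.
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(chrom_sizes = c(chr1 = 50e6),
                              bin_size = 20000,
                              lad_mean_len = 1e6, ilad_mean_len = 1e6,
                              mu_lad = 1, mu_ilad = -1,
                              sigma_bin = 0.3,
                              dam_depth = 1e6, ab_depth = 1e6,
                              dispersion = 0.05,
                              n_replicates = 2,
                              perturbation = perturbation_spec(),
                              spike_fraction = 0.20,
                              spike_chrom_sizes = c(spike1 = 25e6),
                              seed = 1L) {
  if (any(chrom_sizes < 2 * bin_size)) {
    stop("every chromosome must span at least two bins")
  }
  if (!(mu_lad > mu_ilad)) stop("mu_lad must exceed mu_ilad")
  if (spike_fraction < 0 || spike_fraction >= 1) {
    stop("spike_fraction must lie in [0, 1)")
  }
  if (lad_mean_len <= 0 || ilad_mean_len <= 0 || dam_depth <= 0 ||
      ab_depth <= 0 || sigma_bin < 0 || dispersion < 0 || n_replicates < 1) {
    stop("rates and depths must be positive")
  }
  stopifnot(inherits(perturbation, "perturbation_spec"))
  structure(list(chrom_sizes = chrom_sizes[order(names(chrom_sizes))],
                 bin_size = bin_size,
                 lad_mean_len = lad_mean_len, ilad_mean_len = ilad_mean_len,
                 mu_lad = mu_lad, mu_ilad = mu_ilad, sigma_bin = sigma_bin,
                 dam_depth = dam_depth, ab_depth = ab_depth,
                 dispersion = dispersion,
                 n_replicates = as.integer(n_replicates),
                 perturbation = perturbation,
                 spike_fraction = spike_fraction,
                 spike_chrom_sizes = spike_chrom_sizes,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

## Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Geometric domain lengths (in bins, support >= 1) with mean `mean_bins`.
rgeom_len <- function(n, mean_bins) {
  if (!is.finite(mean_bins)) return(rep(Inf, n))
  if (mean_bins <= 1) return(rep(1, n))
  stats::rgeom(n, prob = 1 / mean_bins) + 1
}

#' Draw a ground-truth LAD/iLAD genome
#'
#' Tiles every chromosome with alternating LAD and iLAD domains whose lengths
#' (in bins) follow geometric distributions, mirroring the sojourn-time law
#' of the two-state Markov segmentation model used downstream. Also draws the
#' latent per-bin log2 contrast for the control and perturbed conditions.
#'
#' @param config A [simulation_config()].
#' @return An object of class `ground_truth`: `domains` (a [domain_set()]
#'   tiling each chromosome), `true_contrast` (list of `binned_track`s named
#'   `control` and `perturbed` holding the noise-free latent log2 contrast),
#'   `affected_domains` (ids of domains given an additive shift), and the
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    bs <- config$bin_size
    nb <- n_bins(config$chrom_sizes, bs)
    rows <- list()
    for (ch in names(nb)) {
      total <- nb[[ch]]
      state <- if (stats::runif(1) < 0.5) "LAD" else "iLAD"
      pos <- 0
      while (pos < total) {
        mean_bins <- (if (state == "LAD") config$lad_mean_len else
                        config$ilad_mean_len) / bs
        len <- min(rgeom_len(1, mean_bins), total - pos)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = pos * bs,
          end = min((pos + len) * bs, config$chrom_sizes[[ch]]),
          state = state, stringsAsFactors = FALSE)
        pos <- pos + len
        state <- if (state == "LAD") "iLAD" else "LAD"
      }
    }
    rows <- do.call(rbind, rows)
    domains <- domain_set(rows$chrom, rows$start, rows$end, rows$state)

    ## latent contrast: state mean per bin
    bin_state <- domain_bin_states(domains, config$chrom_sizes, bs)
    mu <- ifelse(bin_state == "LAD", config$mu_lad, config$mu_ilad)
    ctrl <- set_track_values(
      empty_track(config$chrom_sizes, bs), mu)

    ## perturbed condition: shrink toward genome mean, then shift a sampled
    ## subset of domains
    p <- config$perturbation
    m <- mean(mu)
    pert_mu <- m + (1 - p$departition_factor) * (mu - m)
    affected <- character(0)
    shift <- numeric(length(mu))
    for (st in c("LAD", "iLAD")) {
      frac <- if (st == "LAD") p$affected_lad_fraction else
        p$affected_ilad_fraction
      amount <- if (st == "LAD") p$lad_shift else p$ilad_shift
      ids <- domains$id[domains$state == st]
      k <- round(frac * length(ids))
      if (k > 0) {
        hit <- sample(ids, k)
        affected <- c(affected, hit)
        hit_bins <- domain_bin_ids(domains, config$chrom_sizes, bs) %in% hit
        shift[hit_bins] <- shift[hit_bins] + amount
      }
    }
    pert <- set_track_values(empty_track(config$chrom_sizes, bs),
                             pert_mu + shift)
    structure(list(domains = domains,
                   true_contrast = list(control = ctrl, perturbed = pert),
                   affected_domains = affected,
                   config = config),
              class = "ground_truth")
  })
}

empty_track <- function(chrom_sizes, bin_size) {
  nb <- n_bins(chrom_sizes, bin_size)
  binned_track(lapply(nb, function(k) rep(NA_real_, k)), bin_size,
               chrom_sizes)
}

## State label of every bin on the grid, from a tiling domain set.
domain_bin_states <- function(domains, chrom_sizes, bin_size) {
  ids <- domain_bin_ids(domains, chrom_sizes, bin_size)
  domains$state[match(ids, domains$id)]
}

## Domain id of every bin (by bin midpoint) on the grid; NA outside domains.
domain_bin_ids <- function(domains, chrom_sizes, bin_size) {
  nb <- n_bins(chrom_sizes, bin_size)
  out <- rep(NA_character_, sum(nb))
  offset <- c(0, cumsum(nb))[seq_along(nb)]
  names(offset) <- names(nb)
  for (ch in unique(domains$chrom)) {
    d <- domains[domains$chrom == ch, , drop = FALSE]
    k <- nb[[ch]]
    mid <- (seq_len(k) - 0.5) * bin_size
    idx <- findInterval(mid, d$start)
    hit <- idx >= 1 & mid < c(d$end, Inf)[pmax(idx, 1)]
    pos <- offset[[ch]] + seq_len(k)
    out[pos[hit]] <- d$id[idx[hit]]
  }
  out
}

rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 1e-12) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

## Log-normal random-walk accessibility background, mean-stable.
accessibility_background <- function(nb, step_sd = 0.05) {
  g <- unlist(lapply(nb, function(k) exp(cumsum(stats::rnorm(k, 0, step_sd)))),
              use.names = FALSE)
  g / mean(g)
}

#' Simulate pA-DamID count tracks for every sample
#'
#' Draws negative-binomial antibody and Dam-only counts per bin for every
#' replicate of both conditions, plus matching spike-genome counts. Dam
#' counts follow a smooth log-normal random-walk accessibility background
#' shared with the paired antibody sample; antibody counts multiply that
#' background by `2^(latent contrast + per-bin replicate noise)`. The spike
#' genome has a single latent contrast shared by all samples (the spike-in
#' is one biological sample), so any per-sample differences in its profile
#' are purely technical.
#'
#' @param truth A [simulate_genome()] result.
#' @param config The same [simulation_config()].
#' @return An object of class `sim_counts`: a list with `samples`, each
#'   element holding `condition`, `replicate`, `ab`, `dam` (target-genome
#'   [count_track()]s) and `spike_ab`, `spike_dam` (spike-genome counts),
#'   plus `spike_truth` (the shared latent spike contrast as a
#'   `binned_track`).
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "simulation_config"))
  if (!identical(truth$config$chrom_sizes, config$chrom_sizes) ||
      truth$config$bin_size != config$bin_size) {
    stop("ground truth and config describe different genomes")
  }
  with_seed(config$seed + 1L, {
    nb <- n_bins(config$chrom_sizes, config$bin_size)
    nb_spike <- n_bins(config$spike_chrom_sizes, config$bin_size)
    f <- config$spike_fraction

    ## one latent spike contrast for all samples: alternating domains on the
    ## spike genome with the same state means as the target genome
    spike_cfg <- simulation_config(
      chrom_sizes = config$spike_chrom_sizes, bin_size = config$bin_size,
      lad_mean_len = config$lad_mean_len, ilad_mean_len = config$ilad_mean_len,
      mu_lad = config$mu_lad, mu_ilad = config$mu_ilad,
      seed = sample.int(.Machine$integer.max, 1))
    spike_state <- domain_bin_states(simulate_genome(spike_cfg)$domains,
                                     config$spike_chrom_sizes,
                                     config$bin_size)
    spike_mu <- ifelse(spike_state == "LAD", config$mu_lad, config$mu_ilad)
    spike_truth <- set_track_values(
      empty_track(config$spike_chrom_sizes, config$bin_size), spike_mu)

    samples <- list()
    for (cond in c("control", "perturbed")) {
      latent <- track_values(truth$true_contrast[[cond]])
      for (rep_i in seq_len(config$n_replicates)) {
        g <- accessibility_background(nb)
        gs <- accessibility_background(nb_spike)
        noise <- stats::rnorm(length(latent), 0, config$sigma_bin)
        ab_w <- g * 2^(latent + noise)
        spike_noise <- stats::rnorm(length(spike_mu), 0, config$sigma_bin)
        ab_ws <- gs * 2^(spike_mu + spike_noise)

        dam_mu <- (1 - f) * config$dam_depth * g / sum(g)
        ab_mu <- (1 - f) * config$ab_depth * ab_w / sum(ab_w)
        dam_mu_s <- f * config$dam_depth * gs / sum(gs)
        ab_mu_s <- f * config$ab_depth * ab_ws / sum(ab_ws)

        label <- sprintf("%s_rep%d", cond, rep_i)
        mk <- function(mu, sizes, nbv, role, tag) {
          cnt <- rcounts(length(mu), mu, config$dispersion)
          end <- cumsum(nbv)
          counts <- stats::setNames(lapply(seq_along(nbv), function(i) {
            cnt[(end[i] - nbv[i] + 1L):end[i]]
          }), names(nbv))
          count_track(counts, config$bin_size, sizes,
                      sample = paste0(label, tag), role = role)
        }
        samples[[length(samples) + 1L]] <- list(
          condition = cond, replicate = rep_i,
          ab = mk(ab_mu, config$chrom_sizes, nb, "antibody", ""),
          dam = mk(dam_mu, config$chrom_sizes, nb, "dam", ""),
          spike_ab = mk(ab_mu_s, config$spike_chrom_sizes, nb_spike,
                        "antibody", "_spike"),
          spike_dam = mk(dam_mu_s, config$spike_chrom_sizes, nb_spike,
                         "dam", "_spike"))
      }
    }
    structure(list(samples = samples, spike_truth = spike_truth,
                   config = config),
              class = "sim_counts")
  })
}

#' Simulate nucleosome dyad positions with state-specific spacing
#'
#' Lays dyad centres along each domain with a mean spacing equal to the
#' state's nucleosome repeat length (NRL) plus Gaussian jitter, never closer
#' than the 147-bp nucleosome footprint. Used to test linker-length recovery.
#'
#' @param truth A [simulate_genome()] result (its `domains` are used).
#' @param nrl_lad,nrl_ilad Mean dyad-to-dyad spacing (bp) in LADs / iLADs;
#'   both must exceed 147.
#' @param jitter SD (bp) of the spacing noise.
#' @param seed Integer seed.
#' @return A [dyad_set()].
#' @export
simulate_dyads <- function(truth, nrl_lad = 197, nrl_ilad = 187,
                           jitter = 10, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (nrl_lad <= 147 || nrl_ilad <= 147) {
    stop("nucleosome repeat lengths must exceed the 147-bp footprint")
  }
  domains <- truth$domains
  with_seed(seed, {
    pos <- lapply(names(truth$config$chrom_sizes), function(ch) {
      d <- domains[domains$chrom == ch, , drop = FALSE]
      if (nrow(d) == 0) return(numeric(0))
      out <- lapply(seq_len(nrow(d)), function(i) {
        nrl <- if (d$state[i] == "LAD") nrl_lad else nrl_ilad
        len <- d$end[i] - d$start[i]
        n_max <- max(0L, floor(len / 148))
        if (n_max == 0L) return(numeric(0))
        steps <- pmax(round(stats::rnorm(n_max - 1, nrl, jitter)), 148)
        p <- d$start[i] + round(nrl / 2) + cumsum(c(0, steps))
        p[p < d$end[i]]
      })
      unlist(out, use.names = FALSE)
    })
    names(pos) <- names(truth$config$chrom_sizes)
    dyad_set(pos)
  })
}
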