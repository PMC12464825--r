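# Synthetic-data generator: domain process, count model, dyads.

test_that("simulated domains tile every chromosome with alternating states", {
  for (seed in 1:5) {
    cfg <- simulation_config(chrom_sizes = c(chrA = 8e6, chrB = 5e6),
                             seed = seed)
    d <- simulate_genome(cfg)$domains
    for (ch in c("chrA", "chrB")) {
      dc <- d[d$chrom == ch, ]
      expect_equal(dc$start[1], 0)
      expect_equal(dc$end[nrow(dc)], unname(cfg$chrom_sizes[ch]))
      if (nrow(dc) > 1) {
        expect_equal(dc$start[-1], dc$end[-nrow(dc)])
        expect_true(all(dc$state[-1] != dc$state[-nrow(dc)]))
      }
    }
  }
})

test_that("domain counts follow the geometric length law", {
  ## oracle: alternate independent geometric(1/50)+1 sojourns over 500 bins
  set.seed(42)
  oracle_counts <- replicate(400, {
    used <- 0; k <- 0
    while (used < 500) {
      used <- used + rgeom(1, 1 / 50) + 1
      k <- k + 1
    }
    k
  })
  got <- vapply(1:40, function(s) {
    cfg <- simulation_config(chrom_sizes = c(chr1 = 1e7), seed = s)
    nrow(simulate_genome(cfg)$domains)
  }, numeric(1))
  se <- sd(oracle_counts) / sqrt(length(got)) +
    sd(oracle_counts) / sqrt(length(oracle_counts))
  expect_lt(abs(mean(got) - mean(oracle_counts)), 4 * se)
})

test_that("infinite mean length gives one domain per chromosome", {
  cfg <- simulation_config(chrom_sizes = c(chr1 = 6e6),
                           lad_mean_len = Inf, ilad_mean_len = Inf, seed = 3)
  d <- simulate_genome(cfg)$domains
  expect_equal(nrow(d), 1)
  expect_equal(d$end - d$start, 6e6)
})

test_that("generator is deterministic given the seed", {
  cfg <- simulation_config(chrom_sizes = c(chr1 = 6e6), seed = 11)
  t1 <- simulate_genome(cfg)
  t2 <- simulate_genome(cfg)
  expect_identical(t1, t2)
  s1 <- simulate_counts(t1, cfg)
  s2 <- simulate_counts(t2, cfg)
  expect_identical(s1, s2)
  expect_identical(simulate_dyads(t1, seed = 5), simulate_dyads(t2, seed = 5))
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(chrom_sizes = c(chr1 = 30000)),
               "two bins")
  expect_error(simulation_config(mu_lad = -1, mu_ilad = 1), "mu_lad")
  expect_error(simulation_config(spike_fraction = 1), "spike_fraction")
  expect_error(perturbation_spec(departition_factor = 1.2),
               "departition_factor")
})

test_that("no perturbation means identical latent contrast", {
  cfg <- simulation_config(chrom_sizes = c(chr1 = 6e6), seed = 2)
  truth <- simulate_genome(cfg)
  expect_equal(track_values(truth$true_contrast$control),
               track_values(truth$true_contrast$perturbed))
  expect_length(truth$affected_domains, 0)
})

test_that("empirical LAD-iLAD log-ratio gap matches the configured contrast", {
  cfg <- simulation_config(chrom_sizes = c(chr1 = 3e7), sigma_bin = 0.3,
                           mu_lad = 1, mu_ilad = -1, dispersion = 0.05,
                           dam_depth = 3e6, ab_depth = 3e6, seed = 9)
  truth <- simulate_genome(cfg)
  sim <- simulate_counts(truth, cfg)
  trks <- pa_damid_tracks(sim, zscore = FALSE)
  ctrl <- average_replicates(trks[attr(trks, "condition") == "control"])
  st <- ladkit:::domain_bin_states(truth$domains, cfg$chrom_sizes,
                                   cfg$bin_size)
  v <- track_values(ctrl)
  gap <- mean(v[st == "LAD"]) - mean(v[st == "iLAD"])
  expect_lt(abs(gap - 2), 0.15)
})

test_that("log-ratio gap converges to the configured contrast with depth", {
  errs <- vapply(c(2e5, 1e6, 5e6), function(depth) {
    cfg <- simulation_config(chrom_sizes = c(chr1 = 2e7), sigma_bin = 0.2,
                             dam_depth = depth, ab_depth = depth, seed = 21)
    truth <- simulate_genome(cfg)
    sim <- simulate_counts(truth, cfg)
    trks <- pa_damid_tracks(sim, zscore = FALSE)
    ctrl <- average_replicates(trks[attr(trks, "condition") == "control"])
    st <- ladkit:::domain_bin_states(truth$domains, cfg$chrom_sizes,
                                     cfg$bin_size)
    v <- track_values(ctrl)
    abs(mean(v[st == "LAD"]) - mean(v[st == "iLAD"]) - 2)
  }, numeric(1))
  expect_lt(errs[3], 0.1)
  expect_lt(errs[3], errs[1] + 0.05)
})

test_that("spike-in read fraction matches the configured 20%", {
  cfg <- simulation_config(chrom_sizes = c(chr1 = 2e7), seed = 13,
                           spike_fraction = 0.20)
  sim <- simulate_counts(simulate_genome(cfg), cfg)
  spike <- sum(vapply(sim$samples, function(s)
    s$spike_ab$library_total + s$spike_dam$library_total, numeric(1)))
  total <- spike + sum(vapply(sim$samples, function(s)
    s$ab$library_total + s$dam$library_total, numeric(1)))
  ## counts are negative binomial, so allow the overdispersion-inflated
  ## (roughly 3x binomial) sampling error around the nominal 20%
  expect_lt(abs(spike / total - 0.20), 0.005)
})

test_that("dyads obey spacing, ordering and degenerate-input contracts", {
  cfg <- simulation_config(chrom_sizes = c(chr1 = 4e6, chr2 = 3e6), seed = 4)
  truth <- simulate_genome(cfg)
  ## zero jitter: spacing within a LAD is exactly the LAD repeat length
  d0 <- simulate_dyads(truth, nrl_lad = 197, nrl_ilad = 187, jitter = 0,
                       seed = 1)
  lads <- truth$domains[truth$domains$state == "LAD", ]
  one <- lads[which.max(lads$end - lads$start), ]
  p <- d0$positions[[one$chrom]]
  p <- p[p >= one$start & p < one$end]
  expect_true(all(diff(p) == 197))
  ## jitter: strictly increasing everywhere
  dj <- simulate_dyads(truth, jitter = 25, seed = 2)
  for (ch in names(dj$positions)) {
    expect_true(all(diff(dj$positions[[ch]]) > 0))
  }
  ## overlap-violating repeat length is rejected
  expect_error(simulate_dyads(truth, nrl_lad = 140, jitter = 0),
               "147")
  ## chromosome without domains yields no dyads
  truth2 <- truth
  truth2$domains <- domain_subset(truth$domains,
                                  truth$domains$chrom == "chr1")
  d2 <- simulate_dyads(truth2, seed = 1)
  expect_length(d2$positions$chr2, 0)
})
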