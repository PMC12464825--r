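# Nucleosome linker lengths and scale-regions pile-ups.

test_that("the linker rule handles its threshold cases", {
  d <- domain_set("chr1", 0, 1e6, "LAD")
  run <- function(gap) {
    dy <- dyad_set(list(chr1 = c(1000, 1000 + gap)))
    linker_lengths(dy, d)
  }
  expect_equal(run(200)$LAD, 53)     # > 100: subtract 147
  expect_equal(run(90)$LAD, 90)      # <= 100: kept as-is
  expect_length(run(147)$LAD, 0)     # 147 - 147 = 0, below keep_min
  expect_length(run(300)$LAD, 0)     # 300 - 147 = 153, above keep_max
})

test_that("linker lengths equal a brute-force oracle on random dyads", {
  set.seed(31)
  sizes <- c(chr1 = 5e5, chr2 = 3e5)
  for (rep in 1:15) {
    bounds1 <- sort(c(0, sample(seq(2e4, 4.8e5, by = 2e4), 4), 5e5))
    d <- domain_set(
      c(rep("chr1", 5), "chr2"),
      c(bounds1[-6], 0), c(bounds1[-1], 3e5),
      c(rep(c("LAD", "iLAD"), length.out = 5), "LAD"))
    pos <- lapply(sizes, function(s) {
      p <- sort(sample(0:(s - 1), 300))
      p[c(TRUE, diff(p) > 0)]
    })
    dy <- dyad_set(pos)
    got <- linker_lengths(dy, d)
    oracle <- linker_oracle(dy$positions, as.data.frame(d))
    expect_equal(sort(got$LAD), sort(oracle$LAD))
    expect_equal(sort(got$iLAD), sort(oracle$iLAD))
  }
})

test_that("linker lengths are invariant to coordinate translation", {
  set.seed(32)
  d <- domain_set(rep("chr1", 2), c(0, 3e5), c(3e5, 6e5), c("LAD", "iLAD"))
  p <- sort(sample(0:599999, 2000))
  dy <- dyad_set(list(chr1 = p))
  shift <- 1e6
  d2 <- domain_set(rep("chr1", 2), c(0, 3e5) + shift, c(3e5, 6e5) + shift,
                   c("LAD", "iLAD"))
  dy2 <- dyad_set(list(chr1 = p + shift))
  expect_identical(linker_lengths(dy, d), linker_lengths(dy2, d2))
})

test_that("an injected repeat-length difference is recovered", {
  medians <- vapply(1:5, function(s) {
    cfg <- simulation_config(chrom_sizes = c(chr1 = 1e7), seed = s)
    truth <- simulate_genome(cfg)
    dy <- simulate_dyads(truth, nrl_lad = 197, nrl_ilad = 187,
                         jitter = 15, seed = s)
    ll <- linker_lengths(dy, truth$domains)
    c(median(ll$LAD), median(ll$iLAD))
  }, numeric(2))
  expect_true(all(medians[1, ] > medians[2, ]))
  expect_equal(mean(medians[1, ] - medians[2, ]), 10, tolerance = 0.3)
})

test_that("pile-up matrix obeys the column contract and constant tracks", {
  sizes <- c(chr1 = 1e7)
  d <- domain_set(rep("chr1", 2), c(2e6, 6e6), c(3.5e6, 7e6),
                  rep("LAD", 2))
  tr <- vec_track(rep(4, 500), bin_size = 20000)
  m <- scaled_region_pileup(tr, d)
  expect_equal(ncol(m), 200)
  expect_equal(dim(m)[1], 2)
  expect_true(all(m == 4))
  expect_equal(sum(attr(m, "section") == "body"), 100)
  expect_error(scaled_region_pileup(tr, domain_subset(d, FALSE)), "empty")
})

test_that("a step track fills body columns and zeroes the flanks", {
  sizes <- c(chr1 = 1e7)
  ## domain exactly 1 Mb: body maps 1:1, flanks lie outside the domain
  d <- domain_set("chr1", 4e6, 5e6, "LAD")
  v <- rep(0, 500)
  v[(4e6 / 20000 + 1):(5e6 / 20000)] <- 1
  m <- scaled_region_pileup(vec_track(v), d)
  sec <- attr(m, "section")
  expect_true(all(m[1, sec == "body"] == 1))
  expect_true(all(m[1, sec != "body"] == 0))
})

test_that("body resampling equals an area-weighted oracle", {
  set.seed(33)
  v <- rnorm(500)
  v[sample(500, 40)] <- NA
  tr <- vec_track(v, bin_size = 20000)
  d <- domain_set(rep("chr1", 2), c(130000, 4.07e6), c(1.81e6, 6.5e6),
                  rep("LAD", 2))
  m <- scaled_region_pileup(tr, d, bs = 10000, before = 100000,
                            body = 200000, after = 100000)
  expect_equal(ncol(m), 10 + 20 + 10)
  for (i in 1:2) {
    s <- d$start[i]; e <- d$end[i]
    bnd <- seq(s, e, length.out = 21)
    oracle_body <- vapply(1:20, function(j) {
      interval_mean_bp_oracle(v, 20000, bnd[j], bnd[j + 1])
    }, numeric(1))
    expect_equal(unname(m[i, 11:30]), oracle_body, tolerance = 1e-9)
    ## flank columns re-derived at 1-bp resolution
    oracle_flank <- vapply(1:10, function(j) {
      interval_mean_bp_oracle(v, 20000, s - 100000 + (j - 1) * 10000,
                              s - 100000 + j * 10000)
    }, numeric(1))
    expect_equal(unname(m[i, 1:10]), oracle_flank, tolerance = 1e-9)
  }
  ## missing data and out-of-genome flanks count as zero
  d_edge <- domain_set("chr1", 0, 40000, "LAD")
  m_edge <- scaled_region_pileup(tr, d_edge, bs = 10000, before = 50000,
                                 body = 20000, after = 10000)
  expect_true(all(m_edge[1, 1:5] == 0))
})
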