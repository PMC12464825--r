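# De-partitioning metrics: differential tracks, slope, bimodality,
# score comparisons, overlaps, correlations.

test_that("differential tracks subtract element-wise", {
  set.seed(21)
  a <- vec_track(rnorm(100))
  expect_equal(track_values(differential_track(a, a)), rep(0, 100))
  b <- vec_track(track_values(a) + 1)
  expect_equal(track_values(differential_track(b, a)), rep(1, 100))
  c_ <- vec_track(rnorm(100))
  expect_equal(track_values(differential_track(c_, a)),
               track_values(c_) - track_values(a))
  expect_error(differential_track(a, vec_track(rnorm(50))), "grid")
})

test_that("de-partitioning slope recovers closed forms", {
  set.seed(22)
  ctrl <- vec_track(rnorm(200, 0, 1))
  ## perturbed identical: slope 0, degenerate correlation reported safely
  same <- departition_slope(ctrl, differential_track(ctrl, ctrl))
  expect_equal(same$slope, 0)
  expect_equal(same$pearson_r, 0)
  expect_equal(same$p, 1)
  ## perturbed = 0.5 * control: slope exactly -0.5, r = -1
  half <- vec_track(0.5 * track_values(ctrl))
  res <- departition_slope(ctrl, differential_track(half, ctrl))
  expect_equal(res$slope, -0.5, tolerance = 1e-12)
  expect_equal(res$pearson_r, -1, tolerance = 1e-12)
  expect_error(departition_slope(vec_track(rep(1, 10)),
                                 vec_track(rnorm(10))), "variance")
})

test_that("slope and perturbed-on-control OLS differ by exactly one", {
  set.seed(23)
  x <- rnorm(500)
  y <- 0.7 * x + rnorm(500, 0, 0.4)
  ctrl <- vec_track(x)
  pert <- vec_track(y)
  s_diff <- departition_slope(ctrl, differential_track(pert, ctrl))$slope
  s_pert <- unname(coef(lm(y ~ x))[2])
  expect_equal(s_diff, s_pert - 1, tolerance = 1e-12)
})

test_that("a clean mixture is judged bimodal with the expected Ashman D", {
  set.seed(24)
  x <- c(rnorm(5000, -2, 0.5), rnorm(5000, 2, 0.5))
  res <- bimodality_assess(vec_track(x))
  expect_equal(res$verdict, "bimodal")
  ## generative D = sqrt(2) * 4 / sqrt(0.5) = 8 / sqrt(2)
  expect_equal(res$ashman_D, sqrt(2) * 4 / sqrt(0.5), tolerance = 0.10)
})

test_that("single-mode data are judged unimodal in most runs", {
  verdicts <- vapply(1:10, function(s) {
    set.seed(100 + s)
    bimodality_assess(vec_track(rnorm(3000)))$verdict
  }, character(1))
  expect_gte(mean(verdicts == "unimodal"), 0.9)
})

test_that("bimodality is scale-free and collapses when modes coincide", {
  set.seed(26)
  x <- c(rnorm(3000, -1.5, 0.4), rnorm(3000, 1.5, 0.4))
  r1 <- bimodality_assess(vec_track(x))
  r2 <- bimodality_assess(vec_track(5 * x + 10))
  expect_equal(r1$verdict, r2$verdict)
  expect_equal(r1$ashman_D, r2$ashman_D, tolerance = 0.05)

  same_mu <- bimodality_assess(vec_track(rnorm(4000, 0, 1)))
  if (!same_mu$degenerate) {
    expect_equal(same_mu$verdict, "unimodal")
  }
  expect_error(bimodality_assess(vec_track(rnorm(50))), "100")
})

test_that("domain score comparison matches the Welch formula and trims
           only the reported lists", {
  ## two hand lists via domains over a constructed track
  lad_scores <- c(1.2, 0.8, 1.5, 1.1)
  ilad_scores <- c(-0.2, 0.1, -0.5)
  v <- rep(c(lad_scores, ilad_scores), each = 2)
  states <- rep(c("LAD", "iLAD"), c(4, 3))
  bounds <- seq(0, by = 40000, length.out = 8)
  d <- domain_set(rep("chr1", 7), bounds[-8], bounds[-1], states)
  res <- domain_score_compare(vec_track(v, bin_size = 20000), d,
                              test = "welch")
  m1 <- mean(lad_scores); m2 <- mean(ilad_scores)
  v1 <- var(lad_scores) / 4; v2 <- var(ilad_scores) / 3
  expect_equal(res$statistic, (m1 - m2) / sqrt(v1 + v2), tolerance = 1e-12)
  expect_equal(res$p,
               t.test(lad_scores, ilad_scores, var.equal = FALSE)$p.value)

  ## clearly separated scores: tiny p for both tests
  set.seed(27)
  v2_ <- c(rnorm(50, 5, 1), rnorm(50, 0, 1))
  b2 <- seq(0, by = 20000, length.out = 101)
  d2 <- domain_set(rep("chr1", 100), b2[-101], b2[-1],
                   rep(c("LAD", "iLAD"), each = 50))
  w <- domain_score_compare(vec_track(v2_), d2, test = "welch")
  expect_lt(w$p, 1e-10)
  wil <- domain_score_compare(vec_track(v2_), d2, test = "wilcoxon")
  expect_lt(wil$p, 1e-10)
  ## trimming drops the extreme tails from the lists but not the test
  expect_lte(length(w$trimmed$LAD), 50)
  expect_equal(w$p, domain_score_compare(vec_track(v2_), d2, "welch",
                                         trim_pct = 5)$p)
  expect_error(domain_score_compare(vec_track(v2_),
                                    domain_subset(d2, 1:3), "welch"),
               "two scored")
})

test_that("genomic overlap and Fisher test match exhaustive oracles", {
  sizes <- c(chr1 = 2e6)   # 100 bins of 20 kb
  set.seed(28)
  for (rep in 1:10) {
    pick <- function() {
      bins <- sort(sample(0:99, sample(5:30, 1)))
      run <- split(bins, cumsum(c(1, diff(bins) != 1)))
      s <- vapply(run, min, numeric(1)) * 20000
      e <- (vapply(run, max, numeric(1)) + 1) * 20000
      domain_set(rep("chr1", length(s)), s, e, rep("LAD", length(s)))
    }
    A <- pick(); B <- pick()
    res <- domain_overlap(A, B, sizes, bin_size = 20000)
    expect_equal(res$p, fisher_oracle(res$table), tolerance = 1e-9)
    ## symmetry of the overlap
    res_ba <- domain_overlap(B, A, sizes, bin_size = 20000)
    expect_equal(res$overlap_mb, res_ba$overlap_mb)
  }
  A <- domain_set("chr1", 0, 1e6, "LAD")
  self <- domain_overlap(A, A, sizes, bin_size = 20000)
  expect_equal(self$overlap_mb, 1)
  expect_equal(self$odds_ratio, Inf)
  disjoint <- domain_overlap(A, domain_set("chr1", 1.2e6, 1.6e6, "LAD"),
                             sizes, bin_size = 20000)
  expect_equal(disjoint$overlap_mb, 0)
  empty <- domain_overlap(domain_subset(A, FALSE), A, sizes, 20000)
  expect_true(empty$skipped)
  expect_equal(empty$overlap_mb, 0)
})

test_that("track correlation honours missing values and masks", {
  set.seed(29)
  a <- rnorm(300)
  ta <- vec_track(a)
  expect_equal(track_correlation(ta, ta)$r, 1)
  expect_equal(track_correlation(ta, vec_track(-a))$r, -1)
  b <- a + rnorm(300, 0, 0.5)
  mask <- runif(300) > 0.3       # drop ~30% of bins
  got <- track_correlation(ta, vec_track(b), mask = mask)
  expect_equal(got$r, cor(a[mask], b[mask]))
  expect_equal(got$n, sum(mask))
  expect_equal(got$p, cor.test(a[mask], b[mask])$p.value)
  expect_error(track_correlation(ta, vec_track(c(b[1:2], rep(NA, 298)))),
               "3 usable")
})
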