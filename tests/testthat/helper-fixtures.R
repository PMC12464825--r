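# Shared fixtures and independent oracles.

## One-chromosome track from a plain numeric vector.
vec_track <- function(v, bin_size = 20000, chrom = "chr1") {
  binned_track(stats::setNames(list(v), chrom), bin_size,
               stats::setNames(length(v) * bin_size, chrom))
}

## One-chromosome count track from a plain integer vector.
vec_counts <- function(v, bin_size = 20000, chrom = "chr1",
                       role = "antibody", sample = "s") {
  count_track(stats::setNames(list(v), chrom), bin_size,
              stats::setNames(length(v) * bin_size, chrom),
              sample = sample, role = role)
}

## Sample a two-state Gaussian HMM: states 1/2, Gaussian emissions.
sample_gauss_hmm <- function(n, locations, sd, stay) {
  states <- integer(n)
  states[1] <- sample(1:2, 1)
  for (t in 2:n) {
    states[t] <- if (stats::runif(1) < stay) states[t - 1] else
      3L - states[t - 1]
  }
  list(states = states,
       x = stats::rnorm(n, locations[states], sd))
}

## Exhaustive maximum-probability path over all 2^n state sequences.
viterbi_enumerate <- function(logdens, trans, init) {
  n <- nrow(logdens)
  best <- -Inf
  best_path <- NULL
  for (code in 0:(2^n - 1)) {
    path <- as.integer(intToBits(code))[1:n] + 1L
    lp <- log(init[path[1]]) + logdens[1, path[1]]
    for (t in 2:n) {
      lp <- lp + log(trans[path[t - 1], path[t]]) + logdens[t, path[t]]
    }
    if (lp > best) {
      best <- lp
      best_path <- path
    }
  }
  best_path
}

## Step-up BH adjustment, written independently of stats::p.adjust.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

## Two-sided Fisher p by exhaustive hypergeometric-table summation.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Brute-force linker rule over all consecutive same-domain dyad pairs.
linker_oracle <- function(positions, domains_df, nuc_len = 147,
                          short_cut = 100, keep_min = 1, keep_max = 100) {
  out <- list(LAD = numeric(0), iLAD = numeric(0))
  find_domain <- function(ch, p) {
    hit <- which(domains_df$chrom == ch & domains_df$start <= p &
                   p < domains_df$end)
    if (length(hit) == 1) hit else NA_integer_
  }
  for (ch in names(positions)) {
    p <- positions[[ch]]
    if (length(p) < 2) next
    for (i in seq_len(length(p) - 1)) {
      d1 <- find_domain(ch, p[i])
      d2 <- find_domain(ch, p[i + 1])
      if (is.na(d1) || is.na(d2) || d1 != d2) next
      dist <- p[i + 1] - p[i]
      linker <- if (dist > short_cut) dist - nuc_len else dist
      if (linker >= keep_min && linker <= keep_max) {
        st <- domains_df$state[d1]
        out[[st]] <- c(out[[st]], linker)
      }
    }
  }
  out
}

## Area-weighted mean over [s, e) of one chromosome's bin values, NA and
## out-of-genome as zero; independent re-derivation at 1-bp resolution.
interval_mean_bp_oracle <- function(values, bin_size, s, e) {
  bp <- seq(floor(s), ceiling(e) - 1)
  v <- ifelse(bp >= 0 & bp < length(values) * bin_size,
              values[floor(bp / bin_size) + 1], 0)
  v[is.na(v)] <- 0
  ## exact only when s, e are integers (all uses here)
  mean(v)
}
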