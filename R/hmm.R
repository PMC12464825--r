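#' @useDynLib ladkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Per-bin log emission densities under both states; missing bins get 0 in
## every state (likelihood 1), which skips them in the forward recursion.
emission_logdens <- function(x, model) {
  n <- length(x)
  ld <- matrix(0, n, 2)
  ok <- !is.na(x)
  for (s in 1:2) {
    if (model$emission == "gaussian") {
      ld[ok, s] <- stats::dnorm(x[ok], model$location[s], model$scale[s],
                                log = TRUE)
    } else {
      z <- (x[ok] - model$location[s]) / model$scale[s]
      ld[ok, s] <- stats::dt(z, df = model$df, log = TRUE) -
        log(model$scale[s])
    }
  }
  ld
}

new_hmm_model <- function(emission, location, scale, df, trans, init) {
  structure(list(emission = emission, location = location, scale = scale,
                 df = df, trans = trans, init = init,
                 loglik = NA_real_, loglik_trace = numeric(0),
                 n_iter = 0L, converged = NA),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> %s emissions%s\n", x$emission,
              if (x$emission == "t") sprintf(" (df = %g)", x$df) else ""))
  cat(sprintf("  outside: location %.4f scale %.4f | inside (LAD): location %.4f scale %.4f\n",
              x$location[1], x$scale[1], x$location[2], x$scale[2]))
  cat(sprintf("  stay probabilities: %.4f / %.4f; loglik %.2f after %d iterations (%s)\n",
              x$trans[1, 1], x$trans[2, 2], x$loglik, x$n_iter,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Fit a two-state hidden Markov model to a signal track
#'
#' Baum-Welch (EM) fit of a two-state HMM with Gaussian or Student-t
#' emissions to a genome-wide binned track, the segmentation engine behind
#' LAD calling. Each chromosome is treated as an independent chain sharing
#' one parameter set; missing bins are skipped inside the forward recursion
#' without breaking the chain. The Student-t default (fixed df) is robust to
#' occasional outlier bins. State identifiability is enforced by ordering:
#' the state with the higher location is "inside" (LAD-like).
#'
#' @param track A [binned_track()] with at least 50 non-missing bins.
#' @param emission `"t"` (default) or `"gaussian"`.
#' @param df Degrees of freedom of the t emission (fixed, default 3).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-6).
#' @return An object of class `hmm_model` with elements `location`, `scale`
#'   (state 1 = outside, state 2 = inside/LAD), `trans`, `init`, `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`.
#' @export
fit_two_state_hmm <- function(track, emission = c("t", "gaussian"), df = 3,
                              max_iter = 500, tol = 1e-6) {
  emission <- match.arg(emission)
  xs <- lapply(track$values, as.numeric)
  allx <- unlist(xs, use.names = FALSE)
  obs <- allx[!is.na(allx)]
  if (length(obs) < 50) stop("need at least 50 non-missing bins")
  if (stats::sd(obs) < 1e-10) stop("track variance is (near) zero")

  q <- stats::quantile(obs, c(0.25, 0.75), names = FALSE)
  if (diff(q) < 1e-8) q <- q + c(-1, 1) * stats::sd(obs) / 2
  model <- new_hmm_model(
    emission, location = q, scale = rep(stats::sd(obs) / 2, 2), df = df,
    trans = matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2), init = c(0.5, 0.5))

  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ## E step across chromosomes
    ll <- 0
    xi <- matrix(0, 2, 2)
    gamma1 <- c(0, 0)
    gammas <- vector("list", length(xs))
    for (i in seq_along(xs)) {
      fb <- hmm_forward_backward(emission_logdens(xs[[i]], model),
                                 model$trans, model$init)
      ll <- ll + fb$loglik
      xi <- xi + fb$xi
      gamma1 <- gamma1 + fb$gamma1
      gammas[[i]] <- fb$gamma
    }
    trace <- c(trace, ll)
    g <- do.call(rbind, gammas)
    ok <- !is.na(allx)
    g_ok <- g[ok, , drop = FALSE]
    x_ok <- allx[ok]

    ## M step
    model$init <- gamma1 / sum(gamma1)
    model$trans <- xi / rowSums(xi)
    for (s in 1:2) {
      w <- g_ok[, s]
      if (emission == "gaussian") {
        mu <- sum(w * x_ok) / sum(w)
        model$location[s] <- mu
        model$scale[s] <- sqrt(sum(w * (x_ok - mu)^2) / sum(w))
      } else {
        u <- (df + 1) / (df + ((x_ok - model$location[s]) /
                                 model$scale[s])^2)
        mu <- sum(w * u * x_ok) / sum(w * u)
        model$location[s] <- mu
        model$scale[s] <- sqrt(sum(w * u * (x_ok - mu)^2) / sum(w))
      }
      model$scale[s] <- max(model$scale[s], 1e-8)
    }

    if (iter > 1 && abs(trace[iter] - trace[iter - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("Baum-Welch did not converge within ", max_iter,
            " iterations; returning the best model so far")
  }

  ## identifiability: state 2 = higher location = inside/LAD
  if (model$location[1] > model$location[2]) {
    sw <- c(2, 1)
    model$location <- model$location[sw]
    model$scale <- model$scale[sw]
    model$init <- model$init[sw]
    model$trans <- model$trans[sw, sw]
  }
  model$loglik <- trace[length(trace)]
  model$loglik_trace <- trace
  model$n_iter <- length(trace)
  model$converged <- converged
  model
}

#' Segment a track into LAD / iLAD domains
#'
#' Decodes the most probable state path (Viterbi) of a fitted two-state HMM
#' per chromosome, then merges runs of the inside state into LADs and runs
#' of the outside state into iLADs. LADs are intended to be called once on
#' the control-condition averaged track and the resulting coordinates reused
#' for every sample.
#'
#' @param track The [binned_track()] to decode (typically the one the model
#'   was fitted on).
#' @param model A fitted [fit_two_state_hmm()] model.
#' @param min_bins Minimum domain length in bins; shorter runs are absorbed
#'   by flipping their state (default 1, i.e. no filtering).
#' @return A [domain_set()] tiling every chromosome with at least one
#'   non-missing bin; fully missing chromosomes are skipped.
#' @export
segment_domains <- function(track, model, min_bins = 1) {
  stopifnot(inherits(model, "hmm_model"))
  rows <- list()
  for (ch in names(track$values)) {
    x <- track$values[[ch]]
    if (all(is.na(x))) {
      message("chromosome ", ch, " is fully missing; no domains emitted")
      next
    }
    path <- hmm_viterbi(emission_logdens(x, model), model$trans, model$init)
    ## absorb runs shorter than min_bins into their neighbours
    repeat {
      r <- rle(path)
      if (length(r$lengths) <= 1 || min(r$lengths) >= min_bins) break
      i <- which.min(r$lengths)
      r$values[i] <- 3L - r$values[i]
      path <- inverse.rle(r)
    }
    r <- rle(path)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    rows[[ch]] <- data.frame(
      chrom = ch,
      start = starts_bin * track$bin_size,
      end = pmin(ends_bin * track$bin_size, track$chrom_sizes[[ch]]),
      state = ifelse(r$values == 2L, "LAD", "iLAD"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no chromosome had usable data")
  d <- do.call(rbind, rows)
  domain_set(d$chrom, d$start, d$end, d$state)
}

#' Mean z-scaled signal per domain (LAD score)
#'
#' The LAD score of a domain is the mean of the z-scaled NL-interaction
#' signal over the bins overlapping the domain, skipping missing bins.
#'
#' @param domains A [domain_set()].
#' @param ztrack A z-scaled [binned_track()] on the same genome.
#' @return The `domain_set` with its `score` column filled; domains whose
#'   bins are all missing get `NA` with a warning.
#' @export
lad_score <- function(domains, ztrack) {
  scores <- domain_means(domains, ztrack)
  if (anyNA(scores)) {
    warning(sum(is.na(scores)), " domain(s) had only missing bins")
  }
  domains$score <- scores
  domains
}

## Mean track value over the bins overlapping each domain (any bp overlap).
domain_means <- function(domains, track) {
  bs <- track$bin_size
  vapply(seq_len(nrow(domains)), function(i) {
    ch <- domains$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v)) return(NA_real_)
    first <- floor(domains$start[i] / bs) + 1L
    last <- min(ceiling(domains$end[i] / bs), length(v))
    vals <- v[first:last]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
}
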