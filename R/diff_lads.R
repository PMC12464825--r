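#' Per-domain, per-sample score matrix
#'
#' Builds the observation matrix for differential testing: one row per
#' domain (LADs by default), one column per sample track, entries the mean
#' z-scaled signal over the domain's bins.
#'
#' @param domains A [domain_set()] (typically called on the control average
#'   track, coordinates reused for all samples).
#' @param tracks Named list of z-scaled per-replicate [binned_track()]s.
#' @param states Domain states to keep as rows (default `"LAD"`).
#' @return Numeric matrix with domain ids as rownames and track names as
#'   colnames.
#' @export
lad_score_matrix <- function(domains, tracks, states = "LAD") {
  stopifnot(is.list(tracks), length(tracks) >= 2)
  if (is.null(names(tracks))) {
    names(tracks) <- paste0("sample", seq_along(tracks))
  }
  keep <- domain_subset(domains, domains$state %in% states)
  m <- vapply(tracks, function(tr) domain_means(keep, tr),
              numeric(nrow(keep)))
  rownames(m) <- keep$id
  m
}

#' Fit the mean-variance trend of domain scores
#'
#' The precision-weighting half of the voom-style differential test: residual
#' standard deviations (after removing condition means) are square-rooted
#' and smoothed against row means with lowess (span 0.5). The fitted curve
#' is evaluated by linear interpolation with flat extrapolation beyond the
#' fitted range. With fewer than 20 usable rows the trend degenerates to the
#' constant pooled SD, with a warning.
#'
#' @param scores Matrix of per-domain, per-sample scores (rows = domains).
#' @param condition Factor/character of length `ncol(scores)` with two
#'   levels.
#' @param span lowess span (default 0.5).
#' @return An object of class `mv_trend`; calling
#'   [predict_trend_sd()] on it returns the predicted residual SD at given
#'   row means.
#' @export
fit_mean_variance_trend <- function(scores, condition, span = 0.5) {
  dc <- decompose_scores(scores, condition)
  ok <- is.finite(dc$s2) & dc$s2 > 0
  if (sum(ok) < 20) {
    warning("fewer than 20 domains with positive residual variance; ",
            "using a constant pooled SD")
    pooled <- sqrt(mean(dc$s2[is.finite(dc$s2)]))
    return(structure(list(type = "constant", sd = pooled),
                     class = "mv_trend"))
  }
  lo <- stats::lowess(dc$mean[ok], sqrt(sqrt(dc$s2[ok])), f = span)
  structure(list(type = "lowess", x = lo$x, y = pmax(lo$y, 1e-6)),
            class = "mv_trend")
}

#' Predicted residual SD at given mean scores
#'
#' @param trend A [fit_mean_variance_trend()] object.
#' @param mean_score Numeric vector of row means.
#' @return Predicted residual SDs (same length).
#' @export
predict_trend_sd <- function(trend, mean_score) {
  stopifnot(inherits(trend, "mv_trend"))
  if (trend$type == "constant") {
    return(rep(trend$sd, length(mean_score)))
  }
  f <- stats::approxfun(trend$x, trend$y, rule = 2, ties = mean)
  f(mean_score)^2
}

## Row means, group means, residual variance and df for a two-group design.
decompose_scores <- function(scores, condition) {
  scores <- as.matrix(scores)
  condition <- as.factor(condition)
  if (length(condition) != ncol(scores)) {
    stop("condition labels must match the matrix columns")
  }
  if (nlevels(condition) != 2) stop("exactly two conditions are required")
  if (any(table(condition) < 2)) {
    stop("at least two samples per condition are required")
  }
  g1 <- condition == levels(condition)[1]
  m1 <- rowMeans(scores[, g1, drop = FALSE])
  m2 <- rowMeans(scores[, !g1, drop = FALSE])
  fitted <- outer(m1, as.numeric(g1)) + outer(m2, as.numeric(!g1))
  res <- scores - fitted
  df <- ncol(scores) - 2L
  if (df < 1) stop("zero residual degrees of freedom")
  list(mean = rowMeans(scores), m1 = m1, m2 = m2, delta = m2 - m1,
       s2 = rowSums(res^2) / df, df = df,
       n1 = sum(g1), n2 = sum(!g1), levels = levels(condition))
}

## Newton inversion of the trigamma function (solve trigamma(x) = y).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

## Empirical-Bayes fit of a scaled F prior to residual variances
## (method of moments on log s2, Smyth-style). Returns prior df d0 and
## prior variance s02; d0 = Inf means complete shrinkage to the prior.
fit_f_dist <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) return(list(df_prior = Inf, s2_prior = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(df_prior = Inf, s2_prior = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(df_prior = d0, s2_prior = s02)
}

#' Moderated differential-LAD test
#'
#' The voom/limma-style test for domains whose NL-association score changes
#' between two conditions: per-domain precision weights come from the fitted
#' mean-variance trend, per-domain residual variances are shrunk toward an
#' empirical-Bayes prior estimated from the marginal distribution of log
#' residual variances (method of moments via digamma/trigamma matching), and
#' the resulting moderated t statistics are referred to a t distribution
#' with residual-plus-prior degrees of freedom. P-values are
#' Benjamini-Hochberg adjusted; a domain is called `gain` / `loss` when its
#' adjusted p falls below `alpha`, by the sign of the score change.
#'
#' @param scores Matrix of per-domain, per-sample scores
#'   (see [lad_score_matrix()]).
#' @param condition Two-level factor over the columns; the first level is
#'   the reference (control), and `delta` is second minus first level.
#' @param trend Optional [fit_mean_variance_trend()] object; fitted from
#'   `scores` when `NULL`.
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @param prior_df Override for the prior degrees of freedom; `0` disables
#'   moderation (ordinary weighted t test), `NULL` (default) estimates it.
#' @return A `data.frame` of class `diff_lad_result` with columns
#'   `id, delta, t_mod, df_total, p, p_adj, call`; rows with any missing
#'   score are excluded and listed in `attr(, "excluded")`.
#' @export
moderated_diff_test <- function(scores, condition, trend = NULL,
                                alpha = 0.05, prior_df = NULL) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores))) {
    rownames(scores) <- paste0("domain_", seq_len(nrow(scores)))
  }
  complete <- rowSums(is.na(scores)) == 0
  excluded <- rownames(scores)[!complete]
  if (length(excluded)) {
    message(length(excluded), " domain(s) excluded for missing scores")
  }
  scores <- scores[complete, , drop = FALSE]
  if (nrow(scores) == 0) stop("no domain has complete scores")

  dc <- decompose_scores(scores, condition)
  if (is.null(trend)) {
    trend <- suppressWarnings(fit_mean_variance_trend(scores, condition))
  }
  w <- 1 / predict_trend_sd(trend, dc$mean)^2
  s2w <- w * dc$s2

  if (is.null(prior_df)) {
    prior <- fit_f_dist(s2w, dc$df)
  } else if (prior_df == 0) {
    prior <- list(df_prior = 0, s2_prior = NA_real_)
  } else {
    prior <- list(df_prior = prior_df,
                  s2_prior = fit_f_dist(s2w, dc$df)$s2_prior)
  }
  d0 <- prior$df_prior
  s2_post <- if (d0 == 0) {
    s2w
  } else if (is.infinite(d0)) {
    rep(prior$s2_prior, length(s2w))
  } else {
    (d0 * prior$s2_prior + dc$df * s2w) / (d0 + dc$df)
  }
  df_total <- dc$df + d0

  se <- sqrt(s2_post / w * (1 / dc$n1 + 1 / dc$n2))
  t_mod <- ifelse(se > 0, dc$delta / se,
                  ifelse(dc$delta == 0, 0, sign(dc$delta) * Inf))
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[se == 0 & dc$delta == 0] <- 1
  p_adj <- bh_adjust(p)
  call <- ifelse(p_adj < alpha, ifelse(dc$delta > 0, "gain", "loss"), "ns")

  out <- data.frame(id = rownames(scores), delta = dc$delta, t_mod = t_mod,
                    df_total = rep(df_total, length(t_mod)), p = p,
                    p_adj = p_adj, call = call,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  attr(out, "prior") <- prior
  attr(out, "conditions") <- dc$levels
  class(out) <- c("diff_lad_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at 1),
#' applied over all tested domains.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
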