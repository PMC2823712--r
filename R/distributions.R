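#' Per-feature component distributions
#'
#' Atomic distributions used as the factors of a naive-Bayes mixture
#' component: univariate Gaussian, discrete (categorical over a finite
#' alphabet) and exponential.  All densities are evaluated in log space and
#' a missing observation (`NA`) contributes exactly 0 to any log density,
#' i.e. missing entries are marginalized out.
#'
#' @param mean,sd Gaussian location and standard deviation (`sd > 0`).
#' @param alphabet Character vector of unique symbols.
#' @param probs Probability vector aligned with `alphabet`; defaults to
#'   uniform.  Must sum to 1 (checked to 1e-8, then renormalized exactly).
#' @param rate Exponential rate (inverse feature units), `rate > 0`.
#' @return An object of class `mix_dist` (subclass `gaussian_dist`,
#'   `discrete_dist` or `exponential_dist`).
#' @examples
#' d <- dist_discrete(c("A", "C", "G", "T"))
#' log_density(d, "A")  # log(0.25)
#' @name distributions
NULL

#' @rdname distributions
#' @export
dist_gaussian <- function(mean, sd) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd))
  if (sd <= 0) stop("Gaussian sd must be > 0, got ", sd)
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd)),
            class = c("gaussian_dist", "mix_dist"))
}

#' @rdname distributions
#' @export
dist_discrete <- function(alphabet, probs = NULL) {
  alphabet <- as.character(alphabet)
  if (anyDuplicated(alphabet)) stop("alphabet symbols must be unique")
  m <- length(alphabet)
  if (m < 1L) stop("alphabet must be non-empty")
  if (is.null(probs)) probs <- rep(1 / m, m)
  if (length(probs) != m) stop("length(probs) must equal length(alphabet)")
  if (any(probs < 0)) stop("probs must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-8) stop("probs must sum to 1")
  probs <- probs / sum(probs)
  structure(list(alphabet = alphabet, probs = as.numeric(probs)),
            class = c("discrete_dist", "mix_dist"))
}

#' @rdname distributions
#' @export
dist_exponential <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate))
  if (rate <= 0) stop("exponential rate must be > 0, got ", rate)
  structure(list(rate = as.numeric(rate)),
            class = c("exponential_dist", "mix_dist"))
}

#' Log density of a per-feature distribution
#'
#' Vectorized over `x`.  `NA` entries (missing values) contribute log factor
#' 0, i.e. the returned value is 0 at those positions.  Discrete values may
#' be given as symbols or as 1-based codes into the alphabet.
#'
#' @param dist A `mix_dist` object.
#' @param x Observation vector (numeric, or character for discrete).
#' @param feature Optional feature name used in error messages.
#' @return Numeric vector of log densities, same length as `x`.
#' @export
log_density <- function(dist, x, feature = NULL) UseMethod("log_density")

#' @export
log_density.gaussian_dist <- function(dist, x, feature = NULL) {
  out <- rep(0, length(x))
  ok <- !is.na(x)
  out[ok] <- dnorm(x[ok], dist$mean, dist$sd, log = TRUE)
  out
}

#' @export
log_density.exponential_dist <- function(dist, x, feature = NULL) {
  out <- rep(0, length(x))
  ok <- !is.na(x)
  out[ok] <- dexp(x[ok], dist$rate, log = TRUE)
  out
}

#' @export
log_density.discrete_dist <- function(dist, x, feature = NULL) {
  codes <- discrete_codes(dist$alphabet, x, feature)
  out <- rep(0, length(codes))
  ok <- !is.na(codes)
  out[ok] <- log(dist$probs)[codes[ok]]
  out
}

# map symbols or codes to 1-based alphabet indices, NA preserved
discrete_codes <- function(alphabet, x, feature = NULL) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    codes <- match(x, alphabet)
    bad <- which(!is.na(x) & is.na(codes))
    if (length(bad)) {
      stop(sprintf("symbol '%s' not in alphabet {%s}%s",
                   x[bad[1L]], paste(alphabet, collapse = ","),
                   if (is.null(feature)) "" else paste0(" for feature ", feature)))
    }
    codes
  } else {
    codes <- as.integer(x)
    bad <- which(!is.na(codes) & (codes < 1L | codes > length(alphabet)))
    if (length(bad)) {
      stop(sprintf("code %d outside alphabet of size %d%s",
                   codes[bad[1L]], length(alphabet),
                   if (is.null(feature)) "" else paste0(" for feature ", feature)))
    }
    codes
  }
}

#' Weighted maximum-likelihood fit of a per-feature distribution
#'
#' The M-step primitive: refits `dist`'s parameter family to `values` under
#' nonnegative case `weights`.  Missing values (`NA`) are excluded from all
#' sums.  Gaussian: weighted mean and (MLE, 1/sum(w)) standard deviation,
#' floored at `sd_floor`; discrete: weighted relative frequencies with an
#' optional additive pseudocount per symbol; exponential:
#' `sum(w) / sum(w * x)`.
#'
#' @param dist Distribution object giving the family (and alphabet).
#' @param values Observations (numeric, or symbols/codes for discrete).
#' @param weights Nonnegative weights, same length as `values`.
#' @param pseudocount Additive smoothing count per symbol for discrete fits
#'   (default 0: pure maximum likelihood).
#' @param sd_floor Lower bound applied to fitted standard deviations.
#' @return A new distribution object of the same class.
#' @export
weighted_fit <- function(dist, values, weights,
                         pseudocount = 0, sd_floor = 1e-6) {
  UseMethod("weighted_fit")
}

check_fit_inputs <- function(values, weights) {
  if (length(values) != length(weights)) stop("values and weights lengths differ")
  if (any(weights < 0, na.rm = TRUE)) stop("weights must be nonnegative")
}

#' @export
weighted_fit.gaussian_dist <- function(dist, values, weights,
                                       pseudocount = 0, sd_floor = 1e-6) {
  check_fit_inputs(values, weights)
  ok <- !is.na(values)
  w <- weights[ok]; x <- values[ok]
  sw <- sum(w)
  if (sw <= 0) stop_degenerate("Gaussian fit: zero total weight on observed values")
  m <- sum(w * x) / sw
  s <- sqrt(sum(w * (x - m)^2) / sw)
  dist_gaussian(m, max(s, sd_floor))
}

#' @export
weighted_fit.exponential_dist <- function(dist, values, weights,
                                          pseudocount = 0, sd_floor = 1e-6) {
  check_fit_inputs(values, weights)
  ok <- !is.na(values)
  w <- weights[ok]; x <- values[ok]
  sw <- sum(w)
  swx <- sum(w * x)
  if (sw <= 0 || swx <= 0) {
    stop_degenerate("exponential fit: zero total weight or zero weighted sum")
  }
  dist_exponential(sw / swx)
}

#' @export
weighted_fit.discrete_dist <- function(dist, values, weights,
                                       pseudocount = 0, sd_floor = 1e-6) {
  check_fit_inputs(values, weights)
  codes <- discrete_codes(dist$alphabet, values)
  ok <- !is.na(codes)
  w <- weights[ok]; cd <- codes[ok]
  if (sum(w) <= 0) stop_degenerate("discrete fit: zero total weight on observed values")
  m <- length(dist$alphabet)
  counts <- vapply(seq_len(m), function(a) sum(w[cd == a]), numeric(1))
  p <- (counts + pseudocount) / (sum(counts) + m * pseudocount)
  dist_discrete(dist$alphabet, p)
}

#' Draw values from a per-feature distribution
#'
#' Uses R's global random number stream; set a seed beforehand for
#' reproducibility.  Discrete draws are returned as symbols.
#'
#' @param dist A `mix_dist` object.
#' @param n Number of draws.
#' @return Vector of length `n`.
#' @export
sample_value <- function(dist, n = 1L) UseMethod("sample_value")

#' @export
sample_value.gaussian_dist <- function(dist, n = 1L) rnorm(n, dist$mean, dist$sd)

#' @export
sample_value.exponential_dist <- function(dist, n = 1L) rexp(n, dist$rate)

#' @export
sample_value.discrete_dist <- function(dist, n = 1L) {
  dist$alphabet[sample.int(length(dist$alphabet), n, replace = TRUE, prob = dist$probs)]
}

# internal: codes instead of symbols (dataset assembly)
sample_codes <- function(dist, n) {
  sample.int(length(dist$alphabet), n, replace = TRUE, prob = dist$probs)
}

#' Number of free parameters of a distribution or model
#'
#' @param x A distribution, component or mixture model.
#' @return Integer count of free (continuous) parameters.
#' @export
n_params <- function(x) UseMethod("n_params")

#' @export
n_params.gaussian_dist <- function(x) 2L

#' @export
n_params.exponential_dist <- function(x) 1L

#' @export
n_params.discrete_dist <- function(x) length(x$alphabet) - 1L

#' Symmetrized Kullback-Leibler divergence between two distributions
#'
#' Closed forms for same-family pairs; used by [rank_features()].
#'
#' @param d1,d2 `mix_dist` objects of the same class.
#' @return Nonnegative scalar (nats); `Inf` when supports disagree.
#' @export
sym_kl <- function(d1, d2) UseMethod("sym_kl")

#' @export
sym_kl.gaussian_dist <- function(d1, d2) {
  stopifnot(inherits(d2, "gaussian_dist"))
  kl <- function(p, q) {
    log(q$sd / p$sd) + (p$sd^2 + (p$mean - q$mean)^2) / (2 * q$sd^2) - 0.5
  }
  kl(d1, d2) + kl(d2, d1)
}

#' @export
sym_kl.exponential_dist <- function(d1, d2) {
  stopifnot(inherits(d2, "exponential_dist"))
  a <- d1$rate; b <- d2$rate
  (log(a / b) + b / a - 1) + (log(b / a) + a / b - 1)
}

#' @export
sym_kl.discrete_dist <- function(d1, d2) {
  stopifnot(inherits(d2, "discrete_dist"), identical(d1$alphabet, d2$alphabet))
  p <- d1$probs; q <- d2$probs
  both0 <- p == 0 & q == 0
  p <- p[!both0]; q <- q[!both0]
  if (any(p == 0) || any(q == 0)) return(Inf)
  sum((p - q) * (log(p) - log(q)))
}

#' @export
print.mix_dist <- function(x, ...) {
  cls <- class(x)[1L]
  fmt <- function(v) if (is.numeric(v)) paste(signif(v, 4), collapse = ",") else paste(v, collapse = ",")
  pars <- vapply(x, fmt, character(1))
  cat(sprintf("<%s> %s\n", cls, paste(names(x), pars, sep = "=", collapse = " ")))
  invisible(x)
}
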