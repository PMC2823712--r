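#' Conditional distributions for dependence-tree edges
#'
#' A dependence-tree component conditions each non-root feature on its
#' parent.  Two conditional families are supported: a conditional Gaussian
#' whose mean is linear in the parent value, and a conditional discrete
#' distribution given by a row-stochastic table (one row per parent
#' symbol).  Mixed discrete/continuous edges are not supported.
#'
#' @param intercept,slope,sd Conditional Gaussian: child mean is
#'   `intercept + slope * parent`, with noise standard deviation `sd > 0`.
#' @param parent_alphabet,child_alphabet Symbol sets of the two features.
#' @param table Matrix with `length(parent_alphabet)` rows and
#'   `length(child_alphabet)` columns; every row must sum to 1.
#' @return An object of class `cond_dist`.
#' @name conditionals
NULL

#' @rdname conditionals
#' @export
cond_gaussian <- function(intercept, slope, sd) {
  stopifnot(is.finite(intercept), is.finite(slope), is.finite(sd))
  if (sd <= 0) stop("conditional Gaussian sd must be > 0")
  structure(list(intercept = as.numeric(intercept), slope = as.numeric(slope),
                 sd = as.numeric(sd)),
            class = c("cond_gaussian", "cond_dist"))
}

#' @rdname conditionals
#' @export
cond_discrete <- function(parent_alphabet, child_alphabet, table) {
  table <- as.matrix(table)
  if (nrow(table) != length(parent_alphabet) ||
      ncol(table) != length(child_alphabet)) {
    stop("conditional table must be |parent alphabet| x |child alphabet|")
  }
  if (any(table < 0)) stop("conditional probabilities must be nonnegative")
  rs <- rowSums(table)
  if (any(abs(rs - 1) > 1e-8)) stop("every conditional table row must sum to 1")
  table <- table / rs
  structure(list(parent_alphabet = as.character(parent_alphabet),
                 child_alphabet = as.character(child_alphabet),
                 table = table),
            class = c("cond_discrete", "cond_dist"))
}

# log P(child | parent), vectorized; a position contributes 0 when either
# child or parent is missing (the factor is dropped)
cond_log_density <- function(dist, child, parent) UseMethod("cond_log_density")

#' @export
cond_log_density.cond_gaussian <- function(dist, child, parent) {
  out <- rep(0, length(child))
  ok <- !is.na(child) & !is.na(parent)
  out[ok] <- dnorm(child[ok], dist$intercept + dist$slope * parent[ok],
                   dist$sd, log = TRUE)
  out
}

#' @export
cond_log_density.cond_discrete <- function(dist, child, parent) {
  cc <- discrete_codes(dist$child_alphabet, child)
  pc <- discrete_codes(dist$parent_alphabet, parent)
  out <- rep(0, length(cc))
  ok <- !is.na(cc) & !is.na(pc)
  out[ok] <- log(dist$table)[cbind(pc[ok], cc[ok])]
  out
}

# weighted ML fit of a conditional given paired (child, parent) observations
fit_conditional <- function(child_domain, parent_domain, child, parent, weights,
                            pseudocount = 0, sd_floor = 1e-6) {
  if (child_domain$type != parent_domain$type) {
    stop("mixed discrete/continuous tree edges are not supported")
  }
  ok <- !is.na(child) & !is.na(parent)
  w <- weights[ok]
  if (sum(w) <= 0) stop_degenerate("conditional fit: zero total weight")
  if (child_domain$type == "continuous") {
    x <- parent[ok]; y <- child[ok]
    sw <- sum(w)
    mx <- sum(w * x) / sw; my <- sum(w * y) / sw
    vx <- sum(w * (x - mx)^2) / sw
    cxy <- sum(w * (x - mx) * (y - my)) / sw
    slope <- if (vx > 1e-12) cxy / vx else 0
    intercept <- my - slope * mx
    resid <- y - (intercept + slope * x)
    s <- sqrt(sum(w * resid^2) / sw)
    cond_gaussian(intercept, slope, max(s, sd_floor))
  } else {
    pa <- parent_domain$alphabet
    ca <- child_domain$alphabet
    pc <- discrete_codes(pa, parent)[ok]
    cc <- discrete_codes(ca, child)[ok]
    tab <- matrix(pseudocount, nrow = length(pa), ncol = length(ca))
    idx <- (cc - 1L) * length(pa) + pc
    acc <- rowsum(w, group = idx)
    tab[as.integer(rownames(acc))] <- tab[as.integer(rownames(acc))] + acc[, 1L]
    rs <- rowSums(tab)
    zero <- rs <= 0
    if (any(zero)) {  # parent symbol never seen: uniform placeholder row
      tab[zero, ] <- 1 / length(ca)
      rs[zero] <- 1
    }
    cond_discrete(pa, ca, tab / rs)
  }
}

#' @export
n_params.cond_gaussian <- function(x) 3L

#' @export
n_params.cond_discrete <- function(x) {
  length(x$parent_alphabet) * (length(x$child_alphabet) - 1L)
}
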