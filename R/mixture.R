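#' Naive-Bayes product component
#'
#' A mixture component that models the p features as independent, i.e. its
#' density is the product of per-feature densities.
#'
#' @param dists List of p `mix_dist` objects, one per dataset feature, in
#'   feature order.
#' @return Object of class `product_component`.
#' @export
product_component <- function(dists) {
  if (!length(dists) || !all(vapply(dists, inherits, logical(1), "mix_dist"))) {
    stop("dists must be a non-empty list of mix_dist objects")
  }
  structure(list(dists = dists), class = "product_component")
}

#' Log density of a product component at one observation row
#'
#' Sum over features of the per-feature log densities; missing entries
#' (`NA`) contribute 0.
#'
#' @param component A [product_component()].
#' @param row List or vector of p raw values (symbols for discrete
#'   features, numerics otherwise; `NA` = missing).
#' @return Scalar log density.
#' @export
product_log_density <- function(component, row) {
  p <- length(component$dists)
  if (length(row) != p) {
    stop(sprintf("row has %d entries but component has %d features", length(row), p))
  }
  sum(vapply(seq_len(p), function(j) {
    log_density(component$dists[[j]], row[[j]], feature = j)
  }, numeric(1)))
}

# vectorized over a dataset's internal columns: N-vector of log densities
comp_logdens_cols <- function(component, dataset) {
  acc <- numeric(n_samples(dataset))
  for (j in seq_along(component$dists)) {
    acc <- acc + log_density(component$dists[[j]], dataset$columns[[j]],
                             feature = dataset$feature_names[j])
  }
  acc
}

#' @export
n_params.product_component <- function(x) sum(vapply(x$dists, n_params, integer(1)))

#' Finite mixture model
#'
#' Weighted sum of K component distributions; each component is identified
#' with one cluster.  Components are naive-Bayes products
#' ([product_component()]); the CSI and dependence-tree variants are built
#' with [csi_mixture()] and [dtree_mixture()].
#'
#' @param pi Mixture coefficients (nonnegative, sum to 1; renormalized).
#' @param components List of K components.
#' @return Object of class `mixture_model`.
#' @examples
#' m <- mixture_model(c(0.3, 0.7), list(
#'   product_component(list(dist_discrete("AC", c(0.9, 0.1)))),
#'   product_component(list(dist_discrete("AC", c(0.1, 0.9))))))
#' @export
mixture_model <- function(pi, components) {
  pi <- check_pi(pi, length(components))
  structure(list(K = length(components), pi = pi, components = components),
            class = "mixture_model")
}

check_pi <- function(pi, K) {
  if (length(pi) != K) stop("length(pi) must equal number of components")
  if (any(pi < 0)) stop("mixture coefficients must be nonnegative")
  if (abs(sum(pi) - 1) > 1e-8) stop("mixture coefficients must sum to 1")
  pi / sum(pi)
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<%s> K=%d, pi=(%s)\n", class(x)[1L], x$K,
              paste(signif(x$pi, 4), collapse = ", ")))
  invisible(x)
}

#' @export
n_params.mixture_model <- function(x) {
  (x$K - 1L) + sum(vapply(x$components, n_params, integer(1)))
}

# N x K matrix of per-component log densities log P(x_i | theta_k)
component_logdens <- function(model, dataset) UseMethod("component_logdens")

#' @export
component_logdens.mixture_model <- function(model, dataset) {
  vapply(model$components, comp_logdens_cols, numeric(n_samples(dataset)),
         dataset = dataset)
}

#' Mixture log density of each dataset row
#'
#' `log sum_k pi_k P(x_i | theta_k)`, computed by log-sum-exp.
#'
#' @param model A `mixture_model` (any variant).
#' @param dataset A `mix_dataset` with matching features.
#' @return Numeric vector of length N.
#' @export
mixture_log_density <- function(model, dataset) {
  check_arity(model, dataset)
  L <- component_logdens(model, dataset)
  if (is.null(dim(L))) L <- matrix(L, ncol = model$K)
  logsumexp_rows(sweep(L, 2L, log(model$pi), `+`))
}

check_arity <- function(model, dataset) {
  p_model <- model_n_features(model)
  if (p_model != n_features(dataset)) {
    stop(sprintf("model has %d features but dataset has %d",
                 p_model, n_features(dataset)))
  }
  invisible(TRUE)
}

model_n_features <- function(model) UseMethod("model_n_features")

#' @export
model_n_features.mixture_model <- function(model) length(model$components[[1L]]$dists)

#' E-step: component-membership posteriors
#'
#' Computes the responsibilities `r_ik = pi_k P(x_i|theta_k) / sum_m pi_m
#' P(x_i|theta_m)` and the total observed log likelihood.
#'
#' @param model A `mixture_model` (any variant).
#' @param dataset A `mix_dataset`.
#' @return List with `resp` (N x K row-stochastic matrix) and `loglik`.
#' @export
e_step <- function(model, dataset) {
  check_arity(model, dataset)
  L <- component_logdens(model, dataset)
  if (is.null(dim(L))) L <- matrix(L, ncol = model$K)
  lw <- sweep(L, 2L, log(model$pi), `+`)
  lse <- logsumexp_rows(lw)
  dead <- !is.finite(lse)
  if (any(dead)) {
    stop_degenerate(sprintf(
      "sample '%s' has zero likelihood under every component",
      dataset$ids[which(dead)[1L]]))
  }
  M <- do.call(pmax, as.data.frame(lw))
  E <- exp(lw - M)
  resp <- E / rowSums(E)
  list(resp = resp, loglik = sum(lse))
}

# model-implied feature metadata (for simulation), same shape as
# dataset$domains
model_domains <- function(model) UseMethod("model_domains")

#' @export
model_domains.mixture_model <- function(model) {
  lapply(model$components[[1L]]$dists, dist_domain)
}

dist_domain <- function(dist) {
  if (inherits(dist, "discrete_dist")) {
    list(type = "discrete", alphabet = dist$alphabet)
  } else {
    list(type = "continuous")
  }
}
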