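#' Sample a synthetic dataset from a mixture model
#'
#' Draws a component per sample from the mixture coefficients, then draws
#' that sample's features from the chosen component (product, CSI-resolved,
#' or ancestral sampling along the tree for dependence-tree components).
#' Used both as the package's fixture generator and to simulate study data.
#'
#' @param model A `mixture_model` (any variant).
#' @param n Number of samples (> 0).
#' @param seed Optional integer seed; given the same seed the draw is
#'   bit-reproducible.
#' @param id_prefix Prefix for generated sample ids.
#' @return List with `dataset` (a `mix_dataset`) and `labels` (the true
#'   generating component per sample, 1-based integers).
#' @examples
#' m <- mixture_model(c(0.4, 0.6), list(
#'   product_component(list(dist_gaussian(-3, 1))),
#'   product_component(list(dist_gaussian(3, 1)))))
#' sim <- sample_dataset(m, 100, seed = 1)
#' table(sim$labels)
#' @export
sample_dataset <- function(model, n, seed = NULL, id_prefix = "s") {
  if (!is_count(n)) stop("n must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  z <- sample.int(model$K, n, replace = TRUE, prob = model$pi)
  domains <- model_domains(model)
  p <- length(domains)
  columns <- lapply(domains, function(d) {
    if (d$type == "discrete") rep(NA_integer_, n) else rep(NA_real_, n)
  })
  for (k in seq_len(model$K)) {
    idx <- which(z == k)
    if (!length(idx)) next
    block <- sample_component(model, k, length(idx))
    for (j in seq_len(p)) columns[[j]][idx] <- block[[j]]
  }
  ds <- structure(list(ids = paste0(id_prefix, seq_len(n)), columns = columns,
                       domains = domains,
                       feature_names = paste0("f", seq_len(p)),
                       missing = "?"),
                  class = "mix_dataset")
  types <- vapply(domains, `[[`, character(1), "type")
  if (all(types == "discrete")) ds$feature_names <- paste0("pos", seq_len(p))
  list(dataset = ds, labels = z)
}

# draw n_k rows from component k; returns list of p internal-coded columns
sample_component <- function(model, k, n_k) UseMethod("sample_component")

#' @export
sample_component.mixture_model <- function(model, k, n_k) {
  lapply(model$components[[k]]$dists, function(d) {
    if (inherits(d, "discrete_dist")) sample_codes(d, n_k) else sample_value(d, n_k)
  })
}
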