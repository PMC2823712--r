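#' Directed tree topology over features
#'
#' @param parent Integer vector of length p: `parent[j]` is the parent
#'   feature of j, `NA` at the root.
#' @param root Root feature index.
#' @return Object of class `tree_topology`.
#' @export
tree_topology <- function(parent, root) {
  parent <- as.integer(parent)
  p <- length(parent)
  if (p < 1L) stop("empty topology")
  if (sum(is.na(parent)) != 1L || !is.na(parent[root])) {
    stop("exactly one root (parent NA) required, at index `root`")
  }
  # acyclicity + spanning: walking up from every node must reach the root
  for (j in seq_len(p)) {
    seen <- logical(p)
    v <- j
    while (!is.na(parent[v])) {
      if (seen[v]) stop("parent map contains a cycle")
      seen[v] <- TRUE
      v <- parent[v]
    }
    if (v != root) stop("parent map does not span all features from the root")
  }
  structure(list(parent = parent, root = as.integer(root)),
            class = "tree_topology")
}

# features ordered root-first so every parent precedes its children
topo_order <- function(topology) {
  p <- length(topology$parent)
  depth <- integer(p)
  for (j in seq_len(p)) {
    v <- j
    while (!is.na(topology$parent[v])) {
      depth[j] <- depth[j] + 1L
      v <- topology$parent[v]
    }
  }
  order(depth, seq_len(p))
}

#' Dependence-tree component distribution
#'
#' First-order dependency model: the joint density factorizes as the root
#' marginal times one conditional per non-root feature given its parent
#' (conditional Gaussians for continuous features, conditional tables for
#' discrete ones).
#'
#' @param topology A [tree_topology()].
#' @param root_dist Marginal `mix_dist` of the root feature.
#' @param edge_dists List of length p: `edge_dists[[j]]` is the
#'   `cond_dist` of feature j given its parent, `NULL` at the root.
#' @return Object of class `dtree_component`.
#' @export
dtree_component <- function(topology, root_dist, edge_dists) {
  stopifnot(inherits(topology, "tree_topology"))
  p <- length(topology$parent)
  if (length(edge_dists) != p) stop("edge_dists must have one slot per feature")
  for (j in seq_len(p)) {
    if (j == topology$root) {
      if (!is.null(edge_dists[[j]])) stop("root must not carry a conditional")
    } else if (!inherits(edge_dists[[j]], "cond_dist")) {
      stop("every non-root feature needs a cond_dist")
    }
  }
  structure(list(topology = topology, root_dist = root_dist,
                 edge_dists = edge_dists),
            class = "dtree_component")
}

#' @export
n_params.dtree_component <- function(x) {
  n_params(x$root_dist) +
    sum(vapply(x$edge_dists[!vapply(x$edge_dists, is.null, logical(1))],
               n_params, integer(1)))
}

#' Log density of a dependence-tree component at one row
#'
#' `log P(x_root) + sum_j log P(x_j | x_pa(j))`.  A factor is dropped
#' (contributes 0) when its child or its parent value is missing.
#'
#' @param component A [dtree_component()].
#' @param row List/vector of p raw values.
#' @return Scalar log density.
#' @export
dtree_log_density <- function(component, row) {
  p <- length(component$topology$parent)
  if (length(row) != p) stop("row arity mismatch")
  cols <- lapply(row, function(v) v)
  dtree_logdens_vec(component, cols)[1L]
}

# vectorized over dataset columns (list of p equal-length vectors)
dtree_logdens_vec <- function(component, columns) {
  topo <- component$topology
  acc <- log_density(component$root_dist, columns[[topo$root]],
                     feature = topo$root)
  for (j in seq_along(topo$parent)) {
    if (j == topo$root) next
    acc <- acc + cond_log_density(component$edge_dists[[j]], columns[[j]],
                                  columns[[topo$parent[j]]])
  }
  acc
}

#' Responsibility-weighted mutual information between all feature pairs
#'
#' Discrete pairs: plug-in mutual information from the weighted joint
#' frequencies.  Continuous pairs: the Gaussian closed form
#' `-log(1 - rho^2) / 2` from the weighted Pearson correlation, matching
#' the conditional-Gaussian model class.  Mixed pairs are not supported.
#' Only rows where both features are observed enter a pair's estimate.
#'
#' @param dataset A `mix_dataset` whose features are all discrete or all
#'   continuous.
#' @param weights Nonnegative case weights (default uniform).
#' @return Symmetric p x p matrix (nats), zero diagonal.  Constant
#'   features get zero rows with a warning.
#' @export
mutual_information_matrix <- function(dataset, weights = NULL) {
  p <- n_features(dataset)
  N <- n_samples(dataset)
  weights <- weights %||% rep(1, N)
  if (length(weights) != N || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be nonnegative with positive sum")
  }
  types <- vapply(dataset$domains, `[[`, character(1), "type")
  if (length(unique(types)) > 1L) {
    stop("mixed discrete/continuous feature sets are not supported for trees")
  }
  M <- matrix(0, p, p)
  for (a in seq_len(p - 1L)) {
    for (b in seq((a + 1L), p)) {
      xa <- dataset$columns[[a]]; xb <- dataset$columns[[b]]
      ok <- !is.na(xa) & !is.na(xb)
      w <- weights[ok]
      if (sum(w) <= 0) next
      mi <- if (types[1L] == "discrete") {
        mi_discrete(xa[ok], xb[ok], w,
                    length(dataset$domains[[a]]$alphabet),
                    length(dataset$domains[[b]]$alphabet))
      } else {
        mi_gaussian(xa[ok], xb[ok], w)
      }
      M[a, b] <- M[b, a] <- mi
    }
  }
  const <- vapply(seq_len(p), function(j) {
    v <- dataset$columns[[j]][!is.na(dataset$columns[[j]]) & weights > 0]
    length(unique(v)) <= 1L
  }, logical(1))
  if (any(const)) {
    warning("constant feature(s): ", paste(which(const), collapse = ", "),
            "; their MI rows set to 0")
    M[const, ] <- 0
    M[, const] <- 0
  }
  M
}

mi_discrete <- function(a, b, w, ma, mb) {
  joint <- matrix(0, ma, mb)
  idx <- (b - 1L) * ma + a
  acc <- rowsum(w, group = idx)
  joint[as.integer(rownames(acc))] <- acc[, 1L]
  joint <- joint / sum(joint)
  pa <- rowSums(joint); pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * (log(joint[nz]) - log(outer(pa, pb))[nz]))
}

mi_gaussian <- function(a, b, w) {
  sw <- sum(w)
  ma <- sum(w * a) / sw; mb <- sum(w * b) / sw
  va <- sum(w * (a - ma)^2) / sw; vb <- sum(w * (b - mb)^2) / sw
  if (va <= 1e-12 || vb <= 1e-12) return(0)
  rho <- sum(w * (a - ma) * (b - mb)) / sw / sqrt(va * vb)
  rho2 <- min(rho^2, 1 - 1e-12)
  -0.5 * log(1 - rho2)
}

#' Maximum-weight spanning tree
#'
#' Kruskal's algorithm on the complete graph defined by a symmetric weight
#' matrix.  Deterministic under ties: edges are processed in decreasing
#' weight with (i, j) lexicographic tie-breaking, yielding the
#' lexicographically smallest maximum-weight edge set.  The tree is
#' directed by orienting all edges away from `root`.
#'
#' @param weights Symmetric p x p numeric matrix.
#' @param root Root feature used to direct the tree (default 1).
#' @return A [tree_topology()].
#' @export
max_weight_spanning_tree <- function(weights, root = 1L) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  if (p == 0L) stop("empty weight matrix")
  if (ncol(weights) != p) stop("weight matrix must be square")
  if (p == 1L) return(tree_topology(NA_integer_, 1L))
  pairs <- which(upper.tri(weights), arr.ind = TRUE)
  ord <- order(-weights[pairs], pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  comp <- seq_len(p)  # union-find with path compression
  find <- function(v) {
    while (comp[v] != v) {
      comp[v] <<- comp[comp[v]]
      v <- comp[v]
    }
    v
  }
  edges <- matrix(0L, p - 1L, 2L)
  taken <- 0L
  for (e in seq_len(nrow(pairs))) {
    ra <- find(pairs[e, 1L]); rb <- find(pairs[e, 2L])
    if (ra != rb) {
      comp[ra] <- rb
      taken <- taken + 1L
      edges[taken, ] <- pairs[e, ]
      if (taken == p - 1L) break
    }
  }
  adj <- lapply(seq_len(p), function(j) integer(0))
  for (e in seq_len(p - 1L)) {
    adj[[edges[e, 1L]]] <- c(adj[[edges[e, 1L]]], edges[e, 2L])
    adj[[edges[e, 2L]]] <- c(adj[[edges[e, 2L]]], edges[e, 1L])
  }
  parent <- rep(NA_integer_, p)
  visited <- logical(p)
  queue <- root
  visited[root] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in adj[[v]]) {
      if (!visited[u]) {
        visited[u] <- TRUE
        parent[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  tree_topology(parent, root)
}

#' Fit a dependence-tree component by the Chow-Liu procedure
#'
#' Estimates the topology as the maximum-weight spanning tree of the
#' weighted mutual-information graph, then fits the root marginal and all
#' parent-child conditionals by weighted maximum likelihood.  Among all
#' spanning trees this maximizes the weighted log likelihood of the fitted
#' tree (Chow-Liu optimality).
#'
#' @param dataset A `mix_dataset` (all-discrete or all-continuous).
#' @param weights Nonnegative case weights with positive sum.
#' @param root Root index for directing the tree (the density is invariant
#'   to this choice).
#' @param topology Optional fixed [tree_topology()] (skips estimation).
#' @param pseudocount,sd_floor Fit options as in [weighted_fit()].
#' @return A [dtree_component()].
#' @export
fit_dtree <- function(dataset, weights = NULL, root = 1L, topology = NULL,
                      pseudocount = 0, sd_floor = 1e-6) {
  N <- n_samples(dataset)
  weights <- weights %||% rep(1, N)
  if (sum(weights) <= 0) stop_degenerate("fit_dtree: zero total weight")
  if (is.null(topology)) {
    M <- suppressWarnings(mutual_information_matrix(dataset, weights))
    topology <- max_weight_spanning_tree(M, root = root)
  }
  p <- n_features(dataset)
  root_template <- default_dist(dataset$domains[[topology$root]])
  root_dist <- weighted_fit(root_template, dataset$columns[[topology$root]],
                            weights, pseudocount = pseudocount,
                            sd_floor = sd_floor)
  edge_dists <- vector("list", p)
  for (j in seq_len(p)) {
    if (j == topology$root) next
    pa <- topology$parent[j]
    edge_dists[[j]] <- fit_conditional(dataset$domains[[j]],
                                       dataset$domains[[pa]],
                                       dataset$columns[[j]],
                                       dataset$columns[[pa]], weights,
                                       pseudocount = pseudocount,
                                       sd_floor = sd_floor)
  }
  dtree_component(topology, root_dist, edge_dists)
}

default_dist <- function(domain) {
  if (domain$type == "discrete") dist_discrete(domain$alphabet)
  else dist_gaussian(0, 1)
}

#' Mixture of dependence trees
#'
#' A mixture whose K components are [dtree_component()]s; during EM each
#' component's topology is re-estimated at every M-step from its own
#' responsibilities, so topologies may differ per component and per
#' iteration.
#'
#' @param pi Mixture coefficients.
#' @param components List of K `dtree_component`s.
#' @param domains Feature metadata as in a `mix_dataset` (`$domains`);
#'   needed for refitting and sampling.
#' @return Object of class `dtree_mixture` (subclass of `mixture_model`).
#' @export
dtree_mixture <- function(pi, components, domains) {
  if (!all(vapply(components, inherits, logical(1), "dtree_component"))) {
    stop("components must be dtree_component objects")
  }
  pi <- check_pi(pi, length(components))
  structure(list(K = length(components), pi = pi, components = components,
                 domains = domains),
            class = c("dtree_mixture", "mixture_model"))
}

#' @export
model_n_features.dtree_mixture <- function(model) {
  length(model$components[[1L]]$topology$parent)
}

#' @export
model_domains.dtree_mixture <- function(model) model$domains

#' @export
component_logdens.dtree_mixture <- function(model, dataset) {
  vapply(model$components, dtree_logdens_vec, numeric(n_samples(dataset)),
         columns = dataset$columns)
}

#' @export
m_step.dtree_mixture <- function(model, dataset, resp, settings = em_settings()) {
  resp <- check_resp(resp, n_samples(dataset), model$K)
  N <- n_samples(dataset)
  colmass <- colSums(resp)
  model$pi <- colmass / N
  freeze <- isTRUE(attr(model, "freeze_topology"))
  for (k in seq_len(model$K)) {
    if (colmass[k] < settings$collapse_floor * N) {
      warning(sprintf("component %d collapsed; parameters held", k))
      next
    }
    model$components[[k]] <- fit_dtree(
      dataset, resp[, k],
      root = model$components[[k]]$topology$root,
      topology = if (freeze) model$components[[k]]$topology else NULL,
      pseudocount = settings$pseudocount, sd_floor = settings$sd_floor)
  }
  model
}

#' @export
sample_component.dtree_mixture <- function(model, k, n_k) {
  comp <- model$components[[k]]
  topo <- comp$topology
  p <- length(topo$parent)
  cols <- vector("list", p)
  for (j in topo_order(topo)) {
    if (j == topo$root) {
      d <- comp$root_dist
      cols[[j]] <- if (inherits(d, "discrete_dist")) sample_codes(d, n_k) else sample_value(d, n_k)
    } else {
      pv <- cols[[topo$parent[j]]]
      ed <- comp$edge_dists[[j]]
      if (inherits(ed, "cond_gaussian")) {
        cols[[j]] <- rnorm(n_k, ed$intercept + ed$slope * pv, ed$sd)
      } else {
        m <- length(ed$child_alphabet)
        cols[[j]] <- vapply(pv, function(a) {
          sample.int(m, 1L, prob = ed$table[a, ])
        }, integer(1))
      }
    }
  }
  cols
}

#' EM for a mixture of dependence trees
#'
#' Standard EM where the M-step refits each component with [fit_dtree()]
#' under that component's responsibilities, re-estimating its topology at
#' every iteration (set `freeze_topology_after` to stop re-estimating
#' after that iteration).
#'
#' @inheritParams em
#' @param model A `dtree_mixture`.
#' @param freeze_topology_after Iteration after which topologies are held
#'   fixed, or `NULL` (never).
#' @return As [em()].
#' @export
em_dtree_mixture <- function(model, dataset, settings = em_settings(),
                             freeze_topology_after = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "dtree_mixture"))
  if (is.null(freeze_topology_after)) {
    return(em(model, dataset, settings, verbose = verbose))
  }
  check_arity(model, dataset)
  trace <- numeric(0)
  prev <- NA_real_
  converged <- FALSE
  for (it in seq_len(settings$max_iter)) {
    es <- e_step(model, dataset)
    trace[it] <- es$loglik
    if (it > 1L && abs(es$loglik - prev) < settings$tol) {
      converged <- TRUE
      break
    }
    prev <- es$loglik
    attr(model, "freeze_topology") <- it > freeze_topology_after
    model <- m_step(model, dataset, es$resp, settings)
  }
  attr(model, "freeze_topology") <- NULL
  list(model = model,
       trace = structure(list(loglik_per_iter = trace, converged = converged,
                              n_iter = length(trace)),
                         class = "em_trace"))
}

#' Export a tree topology as text
#'
#' @param topology A [tree_topology()].
#' @param feature_names Optional names.
#' @return `format_tree_newick`: a Newick-like parenthesized string;
#'   `tree_edge_list`: a data.frame with columns `parent`, `child`.
#' @export
format_tree_newick <- function(topology, feature_names = NULL) {
  p <- length(topology$parent)
  feature_names <- feature_names %||% paste0("f", seq_len(p))
  children <- lapply(seq_len(p), function(j) which(topology$parent == j))
  rec <- function(v) {
    ch <- children[[v]]
    if (!length(ch)) return(feature_names[v])
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")",
           feature_names[v])
  }
  paste0(rec(topology$root), ";")
}

#' @rdname format_tree_newick
#' @export
tree_edge_list <- function(topology, feature_names = NULL) {
  p <- length(topology$parent)
  feature_names <- feature_names %||% paste0("f", seq_len(p))
  ch <- which(!is.na(topology$parent))
  data.frame(parent = feature_names[topology$parent[ch]],
             child = feature_names[ch], stringsAsFactors = FALSE)
}
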