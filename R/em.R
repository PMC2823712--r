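#' EM control settings
#'
#' @param max_iter Maximum number of EM iterations (each one E-step + one
#'   M-step).
#' @param tol Convergence tolerance on the absolute improvement of the
#'   objective (log likelihood, or the penalized objective of the
#'   constrained/structural variants) between consecutive iterations.
#' @param n_restarts Number of random restarts for [rand_max_em()].
#' @param seed Integer seed controlling all randomness of an estimation
#'   run, or `NULL` to use the current RNG state.
#' @param entropy_cutoff Normalized-entropy threshold in `[0, 1]` above
#'   which [classify()] leaves a sample unassigned, or `NULL` to disable.
#' @param pseudocount Additive smoothing count per symbol for discrete
#'   M-step fits (default 0: maximum likelihood).
#' @param sd_floor Lower bound on fitted Gaussian standard deviations.
#' @param collapse_floor A component whose total responsibility falls below
#'   `collapse_floor * N` keeps its previous parameters for that iteration
#'   (with a warning) instead of dividing by ~0.
#' @return List of class `em_settings`.
#' @export
em_settings <- function(max_iter = 100L, tol = 1e-6, n_restarts = 5L,
                        seed = NULL, entropy_cutoff = NULL,
                        pseudocount = 0, sd_floor = 1e-6,
                        collapse_floor = 1e-10) {
  stopifnot(is_count(max_iter), is.numeric(tol), tol > 0, is_count(n_restarts))
  if (!is.null(entropy_cutoff)) {
    stopifnot(entropy_cutoff >= 0, entropy_cutoff <= 1)
  }
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 n_restarts = as.integer(n_restarts), seed = seed,
                 entropy_cutoff = entropy_cutoff, pseudocount = pseudocount,
                 sd_floor = sd_floor, collapse_floor = collapse_floor),
            class = "em_settings")
}

#' M-step: weighted maximum-likelihood parameter update
#'
#' Updates the mixture coefficients to the mean responsibilities and refits
#' every component parameter by responsibility-weighted maximum likelihood.
#' The model's structure (CSI parameter sharing; tree topologies, which are
#' re-estimated) is handled by the method for each model class.
#'
#' @param model A `mixture_model` (any variant).
#' @param dataset A `mix_dataset`.
#' @param resp N x K row-stochastic responsibility matrix.
#' @param settings An [em_settings()] list.
#' @return The updated model.
#' @export
m_step <- function(model, dataset, resp, settings = em_settings()) {
  UseMethod("m_step")
}

#' @export
m_step.mixture_model <- function(model, dataset, resp, settings = em_settings()) {
  resp <- check_resp(resp, n_samples(dataset), model$K)
  N <- n_samples(dataset)
  colmass <- colSums(resp)
  model$pi <- colmass / N
  for (k in seq_len(model$K)) {
    if (colmass[k] < settings$collapse_floor * N) {
      warning(sprintf("component %d collapsed (responsibility mass %.3g); parameters held",
                      k, colmass[k]))
      next
    }
    model$components[[k]]$dists <- lapply(seq_len(n_features(dataset)), function(j) {
      weighted_fit(model$components[[k]]$dists[[j]], dataset$columns[[j]],
                   resp[, k], pseudocount = settings$pseudocount,
                   sd_floor = settings$sd_floor)
    })
  }
  model
}

check_resp <- function(resp, N, K) {
  resp <- as.matrix(resp)
  if (nrow(resp) != N || ncol(resp) != K) stop("responsibility matrix has wrong shape")
  if (any(abs(rowSums(resp) - 1) > 1e-6)) stop("responsibility rows must sum to 1")
  resp
}

#' Expectation-maximization estimation of a mixture model
#'
#' Alternates [e_step()] and [m_step()] from the supplied (initialized)
#' model until the log-likelihood improvement drops below `settings$tol`
#' or `settings$max_iter` iterations are reached.  The trace records, per
#' iteration, the observed log likelihood of the parameters entering that
#' iteration, which the EM guarantee makes nondecreasing.
#'
#' @inheritParams m_step
#' @param settings An [em_settings()] list.
#' @param verbose Print per-step log-likelihood lines.
#' @return List with `model` (fitted) and `trace` (class `em_trace`:
#'   `loglik_per_iter`, `converged`, `n_iter`).
#' @export
em <- function(model, dataset, settings = em_settings(), verbose = FALSE) {
  check_arity(model, dataset)
  trace <- numeric(0)
  prev <- NA_real_
  converged <- FALSE
  for (it in seq_len(settings$max_iter)) {
    es <- e_step(model, dataset)
    trace[it] <- es$loglik
    if (verbose) {
      diff <- if (it == 1L) es$loglik - (es$loglik - 1) else es$loglik - prev
      message(sprintf("Step %d: log likelihood: %.10g (diff = %.10g)", it, es$loglik, diff))
    }
    if (it > 1L && abs(es$loglik - prev) < settings$tol) {
      converged <- TRUE
      break
    }
    prev <- es$loglik
    model <- m_step(model, dataset, es$resp, settings)
  }
  list(model = model,
       trace = structure(list(loglik_per_iter = trace, converged = converged,
                              n_iter = length(trace)),
                         class = "em_trace"))
}

#' @export
print.em_trace <- function(x, ...) {
  cat(sprintf("<em_trace> %d iterations, %sconverged, final loglik %.6g\n",
              x$n_iter, if (x$converged) "" else "not ",
              x$loglik_per_iter[x$n_iter]))
  invisible(x)
}

#' Random-posterior initialization of a mixture model
#'
#' Draws each sample's responsibility row from a symmetric Dirichlet and
#' applies one [m_step()] to the template model, yielding a randomized but
#' data-informed starting point.
#'
#' @param model Template model defining K, the component families and (for
#'   CSI/tree variants) the structure.
#' @param dataset A `mix_dataset`.
#' @param settings An [em_settings()] list.
#' @return An initialized model of the same class.
#' @export
random_init <- function(model, dataset, settings = em_settings()) {
  resp <- rdirichlet_mat(n_samples(dataset), model$K)
  m_step(model, dataset, resp, settings)
}

#' EM with random restarts
#'
#' Runs [em()] from `settings$n_restarts` seeded random initializations of
#' the template model and returns the run with the highest final log
#' likelihood, mitigating EM's local-maximum sensitivity.
#'
#' @inheritParams em
#' @param model Template model (see [random_init()]).
#' @return As [em()], plus `restart_logliks` with every run's final value.
#' @export
rand_max_em <- function(model, dataset, settings = em_settings(), verbose = FALSE) {
  stopifnot(settings$n_restarts >= 1L)
  best <- NULL
  finals <- numeric(settings$n_restarts)
  for (r in seq_len(settings$n_restarts)) {
    if (!is.null(settings$seed)) set.seed(settings$seed + r - 1L)
    fit <- tryCatch(
      em(random_init(model, dataset, settings), dataset, settings, verbose = verbose),
      heteromix_degenerate = function(e) e
    )
    if (inherits(fit, "condition")) {
      finals[r] <- -Inf
      next
    }
    finals[r] <- fit$trace$loglik_per_iter[fit$trace$n_iter]
    if (is.null(best) || finals[r] > best$final) {
      best <- list(fit = fit, final = finals[r])
    }
  }
  if (is.null(best)) {
    stop_degenerate("all EM restarts ended in numeric degeneracy")
  }
  c(best$fit, list(restart_logliks = finals))
}

#' Posterior classification with an entropy cutoff
#'
#' Assigns each sample to the component with maximal posterior probability
#' (ties broken toward the lowest index).  When `entropy_cutoff` is set, a
#' sample whose posterior entropy, normalized by `log K` to `[0, 1]`,
#' exceeds the cutoff is left unassigned (`NA` label).
#'
#' @param model A fitted `mixture_model` (any variant).
#' @param dataset A `mix_dataset`.
#' @param entropy_cutoff Value in `[0, 1]` or `NULL` (no gating).
#' @return A `cluster_assignment`: list with `ids`, `labels` (1-based
#'   integers, `NA` = unassigned) and the N x K `posterior` matrix.
#' @export
classify <- function(model, dataset, entropy_cutoff = NULL) {
  es <- e_step(model, dataset)
  assignment_from_resp(es$resp, dataset$ids, model$K, entropy_cutoff)
}

assignment_from_resp <- function(resp, ids, K, entropy_cutoff = NULL) {
  labels <- max.col(resp, ties.method = "first")
  if (!is.null(entropy_cutoff) && K > 1L) {
    norm_ent <- apply(resp, 1L, entropy_nats) / log(K)
    labels[norm_ent > entropy_cutoff] <- NA_integer_
  }
  structure(list(ids = ids, labels = labels, posterior = resp),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  K <- ncol(x$posterior)
  cat("** Clustering **\n")
  for (k in seq_len(K)) {
    members <- x$ids[!is.na(x$labels) & x$labels == k]
    cat(sprintf("Cluster %d, size %d\n", k - 1L, length(members)))
    if (length(members)) cat("  ", paste(members, collapse = ", "), "\n", sep = "")
  }
  un <- x$ids[is.na(x$labels)]
  cat(sprintf("Unassigned due to entropy cutoff: %d\n", length(un)))
  if (length(un)) cat("  ", paste(un, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Rank features by their relevance for the clustering
#'
#' Scores each feature by the mixture-weight-weighted symmetrized
#' Kullback-Leibler divergence between the component marginals that the
#' fitted model assigns it: `score_j = sum_{k<l} w_k w_l symKL(theta_kj,
#' theta_lj)` with `w` the average responsibilities on `dataset`.  Features
#' whose parameters coincide across components score 0; the ranking is
#' deterministic.  Defined for product and CSI mixtures (dependence-tree
#' mixtures do not parameterize per-feature marginals).
#'
#' @param model Fitted mixture with `K >= 2`.
#' @param dataset A `mix_dataset`.
#' @return data.frame with columns `feature`, `score`, sorted by
#'   decreasing score (ties keep feature order).
#' @export
rank_features <- function(model, dataset) {
  if (model$K < 2L) stop("feature ranking is undefined for K = 1")
  if (inherits(model, "dtree_mixture")) {
    stop("rank_features is not defined for dependence-tree mixtures")
  }
  es <- e_step(model, dataset)
  w <- colMeans(es$resp)
  p <- n_features(dataset)
  scores <- vapply(seq_len(p), function(j) {
    dists <- marginal_dists(model, j)
    s <- 0
    for (k in seq_len(model$K - 1L)) {
      for (l in seq(k + 1L, model$K)) {
        s <- s + w[k] * w[l] * sym_kl(dists[[k]], dists[[l]])
      }
    }
    s
  }, numeric(1))
  ord <- order(-scores)
  data.frame(feature = dataset$feature_names[ord], score = scores[ord],
             stringsAsFactors = FALSE)
}

# per-component marginal distribution of feature j as parameterized by the
# model (CSI resolves the shared block)
marginal_dists <- function(model, j) UseMethod("marginal_dists")

#' @export
marginal_dists.mixture_model <- function(model, j) {
  lapply(model$components, function(comp) comp$dists[[j]])
}
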