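#' Context-specific independence (CSI) structure
#'
#' For each feature, the K components are partitioned into blocks that
#' share one parameter set: a structure with all-singleton blocks is
#' exactly a conventional naive-Bayes mixture, a single block per feature
#' is a single naive-Bayes model.  Sharing reduces the free-parameter count
#' and makes explicit which features discriminate between which clusters.
#'
#' @param groups List over features; `groups[[j]]` is a list of disjoint
#'   integer vectors (1-based component indices) covering `1:K`.
#' @param params List over features; `params[[j]]` holds one `mix_dist` per
#'   block of `groups[[j]]`, in block order.
#' @return Object of class `csi_structure`.
#' @export
csi_structure <- function(groups, params) {
  if (length(groups) != length(params)) stop("groups and params lengths differ")
  K <- max(unlist(groups[[1L]]))
  for (j in seq_along(groups)) {
    blocks <- lapply(groups[[j]], function(b) sort(as.integer(b)))
    flat <- sort(unlist(blocks))
    if (!identical(flat, seq_len(K))) {
      stop(sprintf("feature %d blocks must partition components 1..%d", j, K))
    }
    if (length(params[[j]]) != length(blocks)) {
      stop(sprintf("feature %d: one parameter set per block required", j))
    }
    ord <- order(vapply(blocks, min, integer(1)))
    groups[[j]] <- blocks[ord]
    params[[j]] <- params[[j]][ord]
  }
  structure(list(groups = groups, params = params, K = K),
            class = "csi_structure")
}

# index of the block of feature j containing component k
block_index <- function(groups_j, k) {
  for (b in seq_along(groups_j)) if (k %in% groups_j[[b]]) return(b)
  stop("component ", k, " not found in any block")
}

#' CSI mixture model
#'
#' A mixture whose component densities are evaluated through a
#' [csi_structure()]: the density of component k at feature j is that of
#' the block containing k.  Densities are identical to those of the
#' equivalent expanded conventional mixture (see [expand_csi()]).
#'
#' @param pi Mixture coefficients.
#' @param structure A [csi_structure()] over the same K.
#' @return Object of class `csi_mixture` (subclass of `mixture_model`).
#' @export
csi_mixture <- function(pi, structure) {
  stopifnot(inherits(structure, "csi_structure"))
  pi <- check_pi(pi, structure$K)
  structure(list(K = structure$K, pi = pi, structure = structure),
            class = c("csi_mixture", "mixture_model"))
}

#' Convert a conventional mixture to an all-singleton CSI mixture
#' @param model A `mixture_model` with product components.
#' @return A `csi_mixture` with one block per (feature, component).
#' @export
as_csi_mixture <- function(model) {
  if (inherits(model, "csi_mixture")) return(model)
  K <- model$K
  p <- model_n_features(model)
  groups <- rep(list(lapply(seq_len(K), identity)), p)
  params <- lapply(seq_len(p), function(j) {
    lapply(model$components, function(comp) comp$dists[[j]])
  })
  csi_mixture(model$pi, csi_structure(groups, params))
}

#' Expand a CSI mixture into the equivalent conventional mixture
#'
#' Copies every shared parameter set into each member component; the
#' expanded model assigns every row the same density as the CSI model.
#'
#' @param model A `csi_mixture`.
#' @return A plain `mixture_model` with product components.
#' @export
expand_csi <- function(model) {
  stopifnot(inherits(model, "csi_mixture"))
  st <- model$structure
  comps <- lapply(seq_len(model$K), function(k) {
    product_component(lapply(seq_along(st$groups), function(j) {
      st$params[[j]][[block_index(st$groups[[j]], k)]]
    }))
  })
  mixture_model(model$pi, comps)
}

#' @export
model_n_features.csi_mixture <- function(model) length(model$structure$groups)

#' @export
model_domains.csi_mixture <- function(model) {
  lapply(model$structure$params, function(pj) dist_domain(pj[[1L]]))
}

#' @export
component_logdens.csi_mixture <- function(model, dataset) {
  st <- model$structure
  N <- n_samples(dataset)
  L <- matrix(0, N, model$K)
  for (j in seq_along(st$groups)) {
    for (b in seq_along(st$groups[[j]])) {
      v <- log_density(st$params[[j]][[b]], dataset$columns[[j]],
                       feature = dataset$feature_names[j])
      L[, st$groups[[j]][[b]]] <- L[, st$groups[[j]][[b]]] + v
    }
  }
  L
}

#' Per-component CSI log density
#'
#' Log density of one observation row under component `k`, with shared
#' parameters resolved through the structure.
#'
#' @param model A `csi_mixture`.
#' @param row List/vector of p raw values (`NA` = missing).
#' @param k Component index (1-based).
#' @return Scalar log density.
#' @export
csi_log_density <- function(model, row, k) {
  st <- model$structure
  if (k < 1L || k > model$K) stop("component index out of range")
  p <- length(st$groups)
  if (length(row) != p) stop("row arity mismatch")
  sum(vapply(seq_len(p), function(j) {
    log_density(st$params[[j]][[block_index(st$groups[[j]], k)]], row[[j]],
                feature = j)
  }, numeric(1)))
}

#' @export
m_step.csi_mixture <- function(model, dataset, resp, settings = em_settings()) {
  resp <- check_resp(resp, n_samples(dataset), model$K)
  N <- n_samples(dataset)
  model$pi <- colSums(resp) / N
  st <- model$structure
  for (j in seq_along(st$groups)) {
    for (b in seq_along(st$groups[[j]])) {
      w <- rowSums(resp[, st$groups[[j]][[b]], drop = FALSE])
      if (sum(w) < settings$collapse_floor * N) {
        warning(sprintf("feature %d block %d collapsed; parameters held", j, b))
        next
      }
      st$params[[j]][[b]] <- weighted_fit(st$params[[j]][[b]],
                                          dataset$columns[[j]], w,
                                          pseudocount = settings$pseudocount,
                                          sd_floor = settings$sd_floor)
    }
  }
  model$structure <- st
  model
}

#' @export
sample_component.csi_mixture <- function(model, k, n_k) {
  st <- model$structure
  lapply(seq_along(st$groups), function(j) {
    d <- st$params[[j]][[block_index(st$groups[[j]], k)]]
    if (inherits(d, "discrete_dist")) sample_codes(d, n_k) else sample_value(d, n_k)
  })
}

#' @export
marginal_dists.csi_mixture <- function(model, j) {
  st <- model$structure
  lapply(seq_len(model$K), function(k) {
    st$params[[j]][[block_index(st$groups[[j]], k)]]
  })
}

#' @export
n_params.csi_mixture <- function(x) {
  (x$K - 1L) +
    sum(vapply(x$structure$params, function(pj) {
      sum(vapply(pj, n_params, integer(1)))
    }, integer(1)))
}

# weighted-ML refit of one block's parameters under the block's summed
# responsibilities
block_refit <- function(col, template, w, settings) {
  weighted_fit(template, col, w, pseudocount = settings$pseudocount,
               sd_floor = settings$sd_floor)
}

# expand per-block log-density vectors into an N x K contribution matrix
block_contrib <- function(blocks, dists, col, N, K) {
  C <- matrix(0, N, K)
  for (b in seq_along(blocks)) {
    C[, blocks[[b]]] <- log_density(dists[[b]], col)
  }
  C
}

#' Score a CSI structure under current responsibilities
#'
#' BIC-style structure score: the observed log likelihood of the candidate
#' structure with block parameters refit by responsibility-weighted
#' maximum likelihood (mixture coefficients from the responsibilities),
#' minus a complexity penalty of `penalty_weight` per free parameter.
#' Higher is better; deterministic.  Scoring the observed (marginal)
#' likelihood rather than the expected complete-data likelihood keeps the
#' search honest when several components carve up a single regime: such
#' splits barely improve the marginal fit and are pruned by the penalty,
#' while responsibility-weighted complete-data scores would always favor
#' them.
#'
#' @param structure A [csi_structure()].
#' @param dataset A `mix_dataset`.
#' @param resp N x K responsibility matrix.
#' @param penalty_weight Penalty per free parameter; default `log(N)/2`.
#' @param settings An [em_settings()] list (fit options).
#' @return Scalar score.
#' @export
score_csi_structure <- function(structure, dataset, resp,
                                penalty_weight = NULL,
                                settings = em_settings()) {
  stopifnot(inherits(structure, "csi_structure"))
  resp <- check_resp(resp, n_samples(dataset), structure$K)
  penalty_weight <- penalty_weight %||% (log(n_samples(dataset)) / 2)
  st <- structure
  for (j in seq_along(st$groups)) {
    for (b in seq_along(st$groups[[j]])) {
      if (length(st$params[[j]]) < b || is.null(st$params[[j]][[b]])) {
        stop("structure is missing a parameter set (empty block?)")
      }
      w <- rowSums(resp[, st$groups[[j]][[b]], drop = FALSE])
      st$params[[j]][[b]] <- block_refit(dataset$columns[[j]],
                                         st$params[[j]][[b]], w, settings)
    }
  }
  model <- csi_mixture(colMeans(resp), st)
  sum(mixture_log_density(model, dataset)) - penalty_weight * n_params(model)
}

# greedy bottom-up block merging for one feature, starting from singletons.
# Candidate merges are scored by the penalized observed log likelihood of
# the full mixture: `base` holds every component's log density summed over
# the other features, so a candidate's loglik is
# logsumexp(base + contribution_j + log pi).  Deterministic: pairs scanned
# in block order (blocks kept sorted by their smallest component index),
# only strict improvements accepted, so ties resolve toward the merge
# involving the lowest component index.
search_feature_partition <- function(col, template, resp, base, log_pi,
                                     penalty_weight, settings) {
  N <- nrow(resp)
  K <- ncol(resp)
  obs_ll <- function(C) sum(logsumexp_rows(sweep(base + C, 2L, log_pi, `+`)))
  blocks <- lapply(seq_len(K), identity)
  dists <- lapply(blocks, function(b) {
    block_refit(col, template, rowSums(resp[, b, drop = FALSE]), settings)
  })
  cur_ll <- obs_ll(block_contrib(blocks, dists, col, N, K))
  repeat {
    nb <- length(blocks)
    if (nb == 1L) break
    best <- NULL
    for (a in seq_len(nb - 1L)) {
      for (b in seq(a + 1L, nb)) {
        merged <- sort(c(blocks[[a]], blocks[[b]]))
        cand_blocks <- c(blocks[-c(a, b)], list(merged))
        cand_dist <- block_refit(col, template,
                                 rowSums(resp[, merged, drop = FALSE]),
                                 settings)
        cand_dists <- c(dists[-c(a, b)], list(cand_dist))
        cand_ll <- obs_ll(block_contrib(cand_blocks, cand_dists, col, N, K))
        # merging frees one parameter set
        gain <- (cand_ll - cur_ll) + penalty_weight * n_params(cand_dist)
        if (gain > 1e-9 && (is.null(best) || gain > best$gain + 1e-12)) {
          best <- list(a = a, b = b, merged = merged, dist = cand_dist,
                       ll = cand_ll, gain = gain)
        }
      }
    }
    if (is.null(best)) break
    blocks[[best$a]] <- best$merged
    dists[[best$a]] <- best$dist
    blocks[[best$b]] <- NULL
    dists[[best$b]] <- NULL
    cur_ll <- best$ll
    ord <- order(vapply(blocks, min, integer(1)))
    blocks <- blocks[ord]
    dists <- dists[ord]
  }
  list(blocks = blocks, params = dists)
}

#' Structural EM for CSI mixtures
#'
#' Alternates (a) an E-step under the current structure, (b) per-feature
#' greedy bottom-up merging of parameter-sharing blocks driven by the
#' penalized expected complete-data log likelihood, and (c) an M-step on
#' the selected structure.  The first `burn_in` iterations run plain EM to
#' stabilize the responsibilities before structural moves; afterwards the
#' search runs every `structure_every`-th iteration.  The trace records the
#' BIC-penalized observed log likelihood (monotone under score-improving
#' moves); the raw log likelihood is returned alongside.
#'
#' @inheritParams em
#' @param model A `csi_mixture` (use [as_csi_mixture()] on a conventional
#'   model for an all-singleton start).
#' @param penalty_weight Penalty per free parameter; default `log(N)/2`.
#' @param burn_in Plain-EM iterations before the first structure search
#'   (default 10).  Components whose parameters have not yet separated
#'   when the search first runs can be merged irreversibly (identical
#'   components receive identical responsibilities forever after), so the
#'   burn-in must be long enough for EM to pull the components apart.
#' @param structure_every Run the structure search every s-th iteration.
#' @return List with `model`, `trace` (penalized objective per iteration)
#'   and `loglik_per_iter` (raw observed log likelihood).
#' @export
structural_em <- function(model, dataset, settings = em_settings(),
                          penalty_weight = NULL, burn_in = 10L,
                          structure_every = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "csi_mixture"))
  check_arity(model, dataset)
  penalty_weight <- penalty_weight %||% (log(n_samples(dataset)) / 2)
  trace <- numeric(0)
  raw <- numeric(0)
  prev <- NA_real_
  converged <- FALSE
  for (it in seq_len(settings$max_iter)) {
    es <- e_step(model, dataset)
    raw[it] <- es$loglik
    trace[it] <- es$loglik - penalty_weight * n_params(model)
    if (verbose) message(sprintf("Step %d: penalized loglik: %.10g", it, trace[it]))
    if (it > 1L && abs(trace[it] - prev) < settings$tol) {
      converged <- TRUE
      break
    }
    prev <- trace[it]
    if (it > burn_in && ((it - burn_in - 1L) %% structure_every == 0L)) {
      st <- model$structure
      N <- n_samples(dataset)
      ctotal <- component_logdens(model, dataset)
      for (j in seq_along(st$groups)) {
        C_j <- block_contrib(st$groups[[j]], st$params[[j]],
                             dataset$columns[[j]], N, model$K)
        base <- ctotal - C_j
        found <- search_feature_partition(dataset$columns[[j]],
                                          st$params[[j]][[1L]], es$resp,
                                          base, log(model$pi),
                                          penalty_weight, settings)
        st$groups[[j]] <- found$blocks
        st$params[[j]] <- found$params
        ctotal <- base + block_contrib(found$blocks, found$params,
                                       dataset$columns[[j]], N, model$K)
      }
      model$structure <- st
    }
    model <- m_step(model, dataset, es$resp, settings)
  }
  list(model = model,
       trace = structure(list(loglik_per_iter = trace, converged = converged,
                              n_iter = length(trace)),
                         class = "em_trace"),
       loglik_per_iter = raw)
}

#' Merge fully identified components
#'
#' Components that share the same parameter block at every feature define
#' identical densities; they are collapsed into one component with their
#' mixture coefficients summed.  Every row's mixture density is unchanged.
#'
#' @param model A `csi_mixture`.
#' @return A `csi_mixture` with `K` reduced accordingly (possibly
#'   unchanged).
#' @export
merge_redundant_components <- function(model) {
  stopifnot(inherits(model, "csi_mixture"))
  st <- model$structure
  sig <- vapply(seq_len(model$K), function(k) {
    paste(vapply(seq_along(st$groups), function(j) {
      block_index(st$groups[[j]], k)
    }, integer(1)), collapse = "|")
  }, character(1))
  keep <- !duplicated(sig)
  if (all(keep)) return(model)
  new_of_old <- match(sig, sig[keep])  # old k -> new component index
  K_new <- sum(keep)
  pi_new <- as.vector(tapply(model$pi, new_of_old, sum))
  groups_new <- lapply(st$groups, function(gj) {
    lapply(gj, function(b) sort(unique(new_of_old[b])))
  })
  # drop duplicate blocks created by the collapse (members map identically)
  for (j in seq_along(groups_new)) {
    key <- vapply(groups_new[[j]], paste, character(1), collapse = ",")
    keep_b <- !duplicated(key)
    groups_new[[j]] <- groups_new[[j]][keep_b]
    st$params[[j]] <- st$params[[j]][keep_b]
  }
  csi_mixture(pi_new, csi_structure(groups_new, st$params))
}

#' Render a CSI structure as a component-by-feature block table
#'
#' Rows are components, columns features; equal letters within a column
#' mark components sharing that feature's parameters.
#'
#' @param model A `csi_mixture`.
#' @param feature_names Optional feature names.
#' @return Character vector of lines.
#' @export
format_csi_structure <- function(model, feature_names = NULL) {
  st <- model$structure
  p <- length(st$groups)
  feature_names <- feature_names %||% paste0("f", seq_len(p))
  tab <- vapply(seq_len(p), function(j) {
    vapply(seq_len(model$K), function(k) {
      LETTERS[block_index(st$groups[[j]], k)]
    }, character(1))
  }, character(model$K))
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = model$K)
  header <- paste(c(sprintf("%-6s", ""), sprintf("%-6s", feature_names)), collapse = "")
  rows <- vapply(seq_len(model$K), function(k) {
    paste(c(sprintf("%-6s", paste0("C", k - 1L)), sprintf("%-6s", tab[k, ])),
          collapse = "")
  }, character(1))
  c(header, rows)
}
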