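#' Pairwise clustering constraints
#'
#' Soft positive (must-link) and negative (must-not-link) preferences for
#' sample pairs, as symmetric N x N weight matrices with entries in
#' `[0, 1]` and zero diagonal.  Violations are penalized in the E-step with
#' weights `lambda_pos` / `lambda_neg` (see [constrained_e_step()]).
#'
#' @param w_pos,w_neg Symmetric N x N matrices in `[0, 1]`, zero diagonal;
#'   `NULL` means no constraints of that sign.
#' @param n Number of samples (needed when both matrices are `NULL`).
#' @return Object of class `constraint_set`.
#' @export
constraint_set <- function(w_pos = NULL, w_neg = NULL, n = NULL) {
  if (is.null(w_pos) && is.null(w_neg) && is.null(n)) {
    stop("supply at least one matrix or n")
  }
  n <- n %||% nrow(w_pos %||% w_neg)
  zero <- matrix(0, n, n)
  w_pos <- w_pos %||% zero
  w_neg <- w_neg %||% zero
  for (nm in c("w_pos", "w_neg")) {
    W <- get(nm)
    if (!is.matrix(W) || nrow(W) != n || ncol(W) != n) {
      stop(nm, " must be an N x N matrix")
    }
    if (any(W < 0) || any(W > 1)) stop(nm, " entries must lie in [0, 1]")
    if (max(abs(W - t(W))) > 1e-12) stop(nm, " must be symmetric")
    if (any(diag(W) != 0)) stop(nm, " must have a zero diagonal")
  }
  structure(list(w_pos = w_pos, w_neg = w_neg, n = n),
            class = "constraint_set")
}

#' Constraint-penalized E-step
#'
#' Redefines the membership posterior under pairwise constraints: the
#' responsibility of sample i for component k is proportional to
#' `pi_k P(x_i|theta_k) * exp(-lambda_pos * sum_j w_pos_ij (1 - r_jk))
#' * exp(-lambda_neg * sum_j w_neg_ij r_jk)`,
#' where `r_jk` are the responsibilities of the previous iteration.  With
#' empty constraints (or zero penalties) this is exactly the standard
#' E-step.  Also returns the penalized objective: the observed log
#' likelihood minus `lambda_pos` times the expected positive-constraint
#' violation mass minus `lambda_neg` times the expected negative mass,
#' both computed from the new responsibilities.
#'
#' @param model A `mixture_model` (any variant).
#' @param dataset A `mix_dataset`.
#' @param constraints A [constraint_set()].
#' @param lambda_pos,lambda_neg Nonnegative penalty weights.
#' @param prev_resp Row-stochastic N x K matrix from the previous
#'   iteration (uniform before the first).
#' @return List with `resp`, `objective` and `loglik`.
#' @export
constrained_e_step <- function(model, dataset, constraints,
                               lambda_pos = 1, lambda_neg = 1,
                               prev_resp = NULL) {
  stopifnot(inherits(constraints, "constraint_set"),
            lambda_pos >= 0, lambda_neg >= 0)
  check_arity(model, dataset)
  N <- n_samples(dataset)
  K <- model$K
  if (constraints$n != N) stop("constraint matrices do not match dataset size")
  prev_resp <- prev_resp %||% matrix(1 / K, N, K)
  prev_resp <- check_resp(prev_resp, N, K)
  L <- component_logdens(model, dataset)
  if (is.null(dim(L))) L <- matrix(L, ncol = K)
  lw <- sweep(L, 2L, log(model$pi), `+`)
  pen <- -lambda_pos * (constraints$w_pos %*% (1 - prev_resp)) -
    lambda_neg * (constraints$w_neg %*% prev_resp)
  lwp <- lw + pen
  lse <- logsumexp_rows(lwp)
  dead <- !is.finite(lse)
  if (any(dead)) {
    stop_degenerate(sprintf(
      "sample '%s' has zero penalized likelihood under every component",
      dataset$ids[which(dead)[1L]]))
  }
  M <- do.call(pmax, as.data.frame(lwp))
  E <- exp(lwp - M)
  resp <- E / rowSums(E)
  loglik <- sum(logsumexp_rows(lw))
  co <- resp %*% t(resp)  # co-assignment probabilities under independence
  pos_viol <- sum(constraints$w_pos * (1 - co)) / 2
  neg_viol <- sum(constraints$w_neg * co) / 2
  list(resp = resp,
       objective = loglik - lambda_pos * pos_viol - lambda_neg * neg_viol,
       loglik = loglik)
}

# one Gauss-Seidel sweep of the constrained posterior update: each row is
# recomputed from the *current* responsibilities of all other samples (the
# simultaneous update of constrained_e_step oscillates between the two
# anti-aligned states under strong positive coupling; the sequential sweep
# is the stable coordinate-wise version of the same update rule)
constrained_e_sweep <- function(model, dataset, constraints,
                                lambda_pos, lambda_neg, resp) {
  N <- n_samples(dataset)
  K <- model$K
  L <- component_logdens(model, dataset)
  if (is.null(dim(L))) L <- matrix(L, ncol = K)
  lw <- sweep(L, 2L, log(model$pi), `+`)
  for (i in seq_len(N)) {
    pen <- -lambda_pos * (constraints$w_pos[i, ] %*% (1 - resp)) -
      lambda_neg * (constraints$w_neg[i, ] %*% resp)
    v <- lw[i, ] + pen[1L, ]
    m <- max(v)
    if (!is.finite(m)) {
      stop_degenerate(sprintf(
        "sample '%s' has zero penalized likelihood under every component",
        dataset$ids[i]))
    }
    r <- exp(v - m)
    resp[i, ] <- r / sum(r)
  }
  loglik <- sum(logsumexp_rows(lw))
  co <- resp %*% t(resp)
  list(resp = resp,
       objective = loglik -
         lambda_pos * sum(constraints$w_pos * (1 - co)) / 2 -
         lambda_neg * sum(constraints$w_neg * co) / 2,
       loglik = loglik)
}

#' Constrained EM
#'
#' EM under pairwise constraints: each iteration updates the
#' responsibilities by a sequential (sample-by-sample) sweep of the
#' penalized posterior rule of [constrained_e_step()], then applies the
#' standard weighted-ML M-step; the procedure seeks the clustering that
#' violates the least constraint mass.  Responsibilities are seeded
#' uniform.  Convergence is tested on the penalized objective, since the
#' raw log likelihood need not be monotone under constraints.  With empty
#' constraints the run is identical to [em()].
#'
#' @inheritParams constrained_e_step
#' @param settings An [em_settings()] list.
#' @return List with `model` and `trace` (penalized objective per
#'   iteration).
#' @export
constrained_em <- function(model, dataset, constraints,
                           lambda_pos = 1, lambda_neg = 1,
                           settings = em_settings()) {
  check_arity(model, dataset)
  N <- n_samples(dataset)
  prev_resp <- matrix(1 / model$K, N, model$K)
  trace <- numeric(0)
  prev_obj <- NA_real_
  converged <- FALSE
  for (it in seq_len(settings$max_iter)) {
    es <- constrained_e_sweep(model, dataset, constraints, lambda_pos,
                              lambda_neg, prev_resp)
    trace[it] <- es$objective
    if (it > 1L && abs(es$objective - prev_obj) < settings$tol) {
      converged <- TRUE
      break
    }
    prev_obj <- es$objective
    prev_resp <- es$resp
    model <- m_step(model, dataset, es$resp, settings)
  }
  list(model = model,
       trace = structure(list(loglik_per_iter = trace, converged = converged,
                              n_iter = length(trace)),
                         class = "em_trace"),
       resp = es$resp)
}

#' Semi-supervised EM with partial hard labels
#'
#' The E-step clamps every labelled sample's responsibility row to the
#' indicator of its label; unlabelled rows get the standard posterior.
#' The traced objective is the observed log likelihood of the unlabelled
#' rows plus the complete-data log likelihood of the labelled rows, which
#' the clamped EM maximizes monotonically.  With all samples labelled the
#' first M-step already yields the supervised per-class ML estimate.
#'
#' @param model A `mixture_model` (any variant).
#' @param dataset A `mix_dataset`.
#' @param labels Integer vector of length N with component indices
#'   (1-based) for labelled samples and `NA` for unlabelled ones.
#' @param settings An [em_settings()] list.
#' @return List with `model` and `trace`.
#' @export
labeled_em <- function(model, dataset, labels, settings = em_settings()) {
  check_arity(model, dataset)
  N <- n_samples(dataset)
  K <- model$K
  labels <- as.integer(labels)
  if (length(labels) != N) stop("labels must have one entry per sample")
  lab_idx <- which(!is.na(labels))
  if (any(labels[lab_idx] < 1L | labels[lab_idx] > K)) {
    stop("labels must be component indices in 1..K")
  }
  trace <- numeric(0)
  prev <- NA_real_
  converged <- FALSE
  for (it in seq_len(settings$max_iter)) {
    L <- component_logdens(model, dataset)
    if (is.null(dim(L))) L <- matrix(L, ncol = K)
    lw <- sweep(L, 2L, log(model$pi), `+`)
    lse <- logsumexp_rows(lw)
    if (any(!is.finite(lse))) {
      stop_degenerate("a sample has zero likelihood under every component")
    }
    M <- do.call(pmax, as.data.frame(lw))
    E <- exp(lw - M)
    resp <- E / rowSums(E)
    obj <- sum(lse)
    if (length(lab_idx)) {
      resp[lab_idx, ] <- 0
      resp[cbind(lab_idx, labels[lab_idx])] <- 1
      obj <- sum(lse[-lab_idx]) + sum(lw[cbind(lab_idx, labels[lab_idx])])
    }
    trace[it] <- obj
    if (it > 1L && abs(obj - prev) < settings$tol) {
      converged <- TRUE
      break
    }
    prev <- obj
    model <- m_step(model, dataset, resp, settings)
  }
  list(model = model,
       trace = structure(list(loglik_per_iter = trace, converged = converged,
                              n_iter = length(trace)),
                         class = "em_trace"),
       resp = resp)
}

#' Turn hard labels into binary pairwise constraints
#'
#' Two labelled samples get a positive constraint of 1 when their labels
#' agree and a negative constraint of 1 when they differ; pairs involving
#' an unlabelled sample are unconstrained.  With large penalties this
#' reproduces the hard-label special case.
#'
#' @param labels Integer vector (1-based component indices, `NA` =
#'   unlabelled).
#' @return A [constraint_set()].
#' @export
labels_to_constraints <- function(labels) {
  N <- length(labels)
  w_pos <- matrix(0, N, N)
  w_neg <- matrix(0, N, N)
  lab <- which(!is.na(labels))
  for (a in lab) {
    for (b in lab) {
      if (a == b) next
      if (labels[a] == labels[b]) w_pos[a, b] <- 1 else w_neg[a, b] <- 1
    }
  }
  constraint_set(w_pos, w_neg)
}

#' Read pairwise constraints from a 3-column TSV
#'
#' Columns: `id_i`, `id_j`, signed weight in `[-1, 1]`; positive weights
#' become positive constraints, negative weights contribute their absolute
#' value as negative constraints.  Symmetrized automatically.
#'
#' @param path TSV file with a header row.
#' @param ids Dataset sample ids, fixing matrix order.
#' @return A [constraint_set()].
#' @export
read_constraints <- function(path, ids) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("constraint file needs 3 columns: id_i, id_j, weight")
  N <- length(ids)
  w_pos <- matrix(0, N, N)
  w_neg <- matrix(0, N, N)
  i <- match(as.character(tab[[1L]]), ids)
  j <- match(as.character(tab[[2L]]), ids)
  if (anyNA(i) || anyNA(j)) {
    bad <- c(tab[[1L]][is.na(i)], tab[[2L]][is.na(j)])
    stop("unknown sample id(s) in constraints: ", paste(unique(bad), collapse = ", "))
  }
  w <- as.numeric(tab[[3L]])
  if (any(abs(w) > 1)) stop("constraint weights must lie in [-1, 1]")
  for (r in seq_along(w)) {
    if (w[r] >= 0) {
      w_pos[i[r], j[r]] <- w_pos[j[r], i[r]] <- w[r]
    } else {
      w_neg[i[r], j[r]] <- w_neg[j[r], i[r]] <- -w[r]
    }
  }
  diag(w_pos) <- 0
  diag(w_neg) <- 0
  constraint_set(w_pos, w_neg)
}

#' Read partial hard labels from a 2-column TSV
#'
#' Columns: sample id, 0-based component index (matching written
#' clusterings).
#'
#' @param path TSV file with a header row.
#' @param ids Dataset sample ids.
#' @return Integer label vector (1-based internally, `NA` = unlabelled).
#' @export
read_labels <- function(path, ids) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label file needs 2 columns: id, component")
  labels <- rep(NA_integer_, length(ids))
  i <- match(as.character(tab[[1L]]), ids)
  if (anyNA(i)) {
    stop("unknown sample id(s) in labels: ",
         paste(unique(tab[[1L]][is.na(i)]), collapse = ", "))
  }
  labels[i] <- as.integer(tab[[2L]]) + 1L
  labels
}
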