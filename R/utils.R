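# internal numeric helpers

# Row-wise log-sum-exp of a finite-or--Inf matrix.  Rows that are entirely
# -Inf yield -Inf (caller decides whether that is an error).
logsumexp_rows <- function(L) {
  if (is.null(dim(L))) L <- matrix(L, nrow = 1L)
  M <- do.call(pmax, as.data.frame(L))
  finite <- is.finite(M)
  out <- rep(-Inf, nrow(L))
  if (any(finite)) {
    Lf <- L[finite, , drop = FALSE]
    Mf <- M[finite]
    out[finite] <- Mf + log(rowSums(exp(Lf - Mf)))
  }
  out
}

# One Dirichlet(alpha, ..., alpha) draw of dimension k per row, n rows.
rdirichlet_mat <- function(n, k, alpha = 1) {
  g <- matrix(rgamma(n * k, shape = alpha), nrow = n)
  g / rowSums(g)
}

# Shannon entropy of a probability vector in nats; 0 log 0 := 0.
entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_degenerate <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("heteromix_degenerate", "error", "condition")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
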