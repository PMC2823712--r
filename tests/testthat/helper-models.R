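# shared fixtures and independent oracles, all built in code

dna <- c("A", "C", "G", "T")

gauss1d_mixture <- function(means = c(-3, 3), sds = c(1, 1), pi = c(0.4, 0.6)) {
  mixture_model(pi, lapply(seq_along(means), function(k) {
    product_component(list(dist_gaussian(means[k], sds[k])))
  }))
}

# the worked two-component discrete instance: pi = (0.3, 0.7),
# P1(A) = 0.9, P2(A) = 0.1  =>  P("A") = 0.34, posterior_1 = 0.27/0.34
hand_mixture <- function() {
  mixture_model(c(0.3, 0.7), list(
    product_component(list(dist_discrete(c("A", "C"), c(0.9, 0.1)))),
    product_component(list(dist_discrete(c("A", "C"), c(0.1, 0.9))))))
}

hand_dataset <- function() {
  mix_dataset(data.frame(g = "A"), schema = "discrete",
              alphabets = list(g = c("A", "C")))
}

# random mixture over a given feature recipe ("g" gaussian, "d" discrete,
# "e" exponential); parameters drawn from the current RNG state
random_product_mixture <- function(K, recipe) {
  comps <- lapply(seq_len(K), function(k) {
    product_component(lapply(recipe, function(ty) {
      switch(ty,
        g = dist_gaussian(runif(1, -4, 4), runif(1, 0.5, 2)),
        d = dist_discrete(dna, as.vector(rdirichlet_mat_test(1, 4))),
        e = dist_exponential(runif(1, 0.3, 3)))
    }))
  })
  pi <- as.vector(rdirichlet_mat_test(1, K, alpha = 3))
  mixture_model(pi, comps)
}

rdirichlet_mat_test <- function(n, k, alpha = 1) {
  g <- matrix(rgamma(n * k, shape = alpha), nrow = n)
  g / rowSums(g)
}

# ---- Prufer-sequence enumeration of all labelled spanning trees (oracle) ---

prufer_decode <- function(pr, p) {
  degree <- rep(1L, p)
  for (v in pr) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, p - 1L, 2L)
  cnt <- 0L
  for (v in pr) {
    leaf <- min(which(degree == 1L))
    cnt <- cnt + 1L
    edges[cnt, ] <- c(leaf, v)
    degree[leaf] <- 0L
    degree[v] <- degree[v] - 1L
  }
  last <- which(degree == 1L)
  edges[p - 1L, ] <- last
  edges
}

all_spanning_trees <- function(p) {
  if (p == 1L) return(list(matrix(0L, 0L, 2L)))
  if (p == 2L) return(list(matrix(c(1L, 2L), 1L)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(p)), p - 2L)))
  lapply(seq_len(nrow(seqs)), function(i) prufer_decode(as.integer(seqs[i, ]), p))
}

tree_weight <- function(edges, W) {
  if (nrow(edges) == 0L) return(0)
  sum(W[edges])
}

topology_from_edges <- function(edges, root, p) {
  adj <- lapply(seq_len(p), function(j) integer(0))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
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

weighted_tree_loglik <- function(component, dataset, weights) {
  sum(weights * heteromix:::dtree_logdens_vec(component, dataset$columns))
}

# ---- component matching (label switching) --------------------------------

# greedy matching of learned components to true labels via the
# responsibility contingency table; returns perm with perm[learned] = true
match_components <- function(resp, true_labels, K) {
  C <- matrix(0, K, K)
  for (k in seq_len(K)) {
    C[k, ] <- colSums(resp[true_labels == k, , drop = FALSE])
  }
  perm <- integer(K)
  used_t <- used_l <- logical(K)
  for (s in seq_len(K)) {
    best <- -Inf; bi <- bj <- 0L
    for (i in seq_len(K)) {
      for (j in seq_len(K)) {
        if (!used_t[i] && !used_l[j] && C[i, j] > best) {
          best <- C[i, j]; bi <- i; bj <- j
        }
      }
    }
    perm[bj] <- bi
    used_t[bi] <- TRUE
    used_l[bj] <- TRUE
  }
  perm
}

canon_partition <- function(blocks) {
  paste(sort(vapply(blocks, function(b) paste(sort(b), collapse = ","),
                    character(1))), collapse = "|")
}

# ---- planted CSI instance (five components, four features) ---------------

csi_plant <- function() {
  list(f1 = list(c(1, 2), 3, c(4, 5)),
       f2 = list(1, c(2, 3, 4), 5),
       f3 = list(1, 2, 3, 4, 5),
       f4 = list(c(1, 2, 3, 4, 5)))
}

csi_plant_mixture <- function(sep = 4) {
  plant <- csi_plant()
  block_means <- lapply(plant, function(gj) sep * (seq_along(gj) - 1))
  K <- 5L
  means <- matrix(0, K, 4L)
  for (j in seq_along(plant)) {
    for (b in seq_along(plant[[j]])) {
      means[plant[[j]][[b]], j] <- block_means[[j]][b]
    }
  }
  mixture_model(rep(0.2, K), lapply(seq_len(K), function(k) {
    product_component(lapply(1:4, function(j) dist_gaussian(means[k, j], 1)))
  }))
}

# structural EM with restarts, best penalized score kept
csi_fit_restarts <- function(dataset, template, n_restarts, seed,
                             settings = em_settings(max_iter = 40, tol = 1e-4)) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    init <- random_init(template, dataset, settings)
    run <- structural_em(init, dataset, settings)
    final <- run$trace$loglik_per_iter[run$trace$n_iter]
    if (is.null(best) || final > best$final) best <- list(run = run, final = final)
  }
  best$run
}

# fraction of features whose learned blocks match the plant up to
# component relabeling
csi_features_recovered <- function(model, dataset, true_labels) {
  plant <- csi_plant()
  es <- e_step(model, dataset)
  perm <- match_components(es$resp, true_labels, model$K)
  st <- model$structure
  sum(vapply(seq_along(plant), function(j) {
    mapped <- lapply(st$groups[[j]], function(b) sort(perm[b]))
    canon_partition(mapped) == canon_partition(plant[[j]])
  }, logical(1)))
}

# adjusted Rand index (independent implementation for tests)
adj_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- ai * bj / choose(n, 2)
  (nij - expected) / ((ai + bj) / 2 - expected)
}

seq_model <- function(L = 8) {
  mixture_model(c(0.5, 0.5), list(
    product_component(lapply(seq_len(L), function(j) {
      dist_discrete(dna, c(0.85, 0.05, 0.05, 0.05))
    })),
    product_component(lapply(seq_len(L), function(j) {
      dist_discrete(dna, c(0.05, 0.05, 0.05, 0.85))
    }))))
}

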