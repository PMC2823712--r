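test_that("tree topology validation rejects cycles and multiple roots", {
  expect_s3_class(tree_topology(c(NA, 1, 2), 1), "tree_topology")
  expect_error(tree_topology(c(NA, 3, 2), 1), "cycle")
  expect_error(tree_topology(c(NA, NA, 2), 1), "root")
  expect_error(tree_topology(c(2, 1, NA), 3), "span|cycle")
})

test_that("the tree joint factorizes as root plus parent-child conditionals", {
  # chain A -> B -> C with extra edge B -> D
  topo <- tree_topology(c(NA, 1, 2, 2), 1)
  ab <- c("A", "C")
  root_d <- dist_discrete(ab, c(0.7, 0.3))
  cond_ba <- cond_discrete(ab, ab, rbind(c(0.9, 0.1), c(0.2, 0.8)))
  cond_cb <- cond_discrete(ab, ab, rbind(c(0.6, 0.4), c(0.3, 0.7)))
  cond_db <- cond_discrete(ab, ab, rbind(c(0.5, 0.5), c(0.1, 0.9)))
  comp <- dtree_component(topo, root_d, list(NULL, cond_ba, cond_cb, cond_db))
  row <- list("A", "C", "A", "C")
  manual <- log(0.7) + log(0.1) + log(0.3) + log(0.9)
  expect_equal(dtree_log_density(comp, row), manual, tolerance = 1e-12)

  # single-feature tree is just the root marginal
  single <- dtree_component(tree_topology(NA_integer_, 1), root_d, list(NULL))
  expect_equal(dtree_log_density(single, list("C")), log(0.3))

  # conditionals that ignore the parent reduce to the naive-Bayes product
  flat <- cond_discrete(ab, ab, rbind(c(0.6, 0.4), c(0.6, 0.4)))
  comp_flat <- dtree_component(topo, root_d, list(NULL, flat, flat, flat))
  nb <- product_component(list(root_d, dist_discrete(ab, c(0.6, 0.4)),
                               dist_discrete(ab, c(0.6, 0.4)),
                               dist_discrete(ab, c(0.6, 0.4))))
  expect_equal(dtree_log_density(comp_flat, row), product_log_density(nb, row),
               tolerance = 1e-12)
})

test_that("a discrete tree density is normalized over the full outcome grid", {
  set.seed(80)
  df <- data.frame(a = sample(dna, 400, TRUE), b = sample(dna, 400, TRUE),
                   c = sample(dna, 400, TRUE), d = sample(dna, 400, TRUE))
  # induce dependence so the tree is non-trivial
  df$b[1:200] <- df$a[1:200]
  df$c[1:150] <- df$b[1:150]
  ds <- mix_dataset(df, alphabets = stats::setNames(rep(list(dna), 4), names(df)))
  comp <- fit_dtree(ds)
  grid <- expand.grid(a = dna, b = dna, c = dna, d = dna,
                      stringsAsFactors = FALSE)
  dsg <- mix_dataset(grid, alphabets = stats::setNames(rep(list(dna), 4), names(grid)))
  expect_equal(sum(exp(heteromix:::dtree_logdens_vec(comp, dsg$columns))), 1,
               tolerance = 1e-9)
})

test_that("mutual information matches entropy and Gaussian closed forms", {
  set.seed(81)
  s <- sample(dna, 2000, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  ds <- mix_dataset(data.frame(a = s, b = s),
                    alphabets = list(a = dna, b = dna))
  M <- mutual_information_matrix(ds)
  p_hat <- as.vector(table(factor(s, dna))) / 2000
  expect_equal(M[1, 2], -sum(p_hat[p_hat > 0] * log(p_hat[p_hat > 0])),
               tolerance = 1e-9)  # I(X;X) = H(X)
  expect_equal(M[1, 1], 0)
  expect_equal(M, t(M))

  x <- rnorm(50000)
  y <- 0.5 * x + sqrt(0.75) * rnorm(50000)
  Mg <- mutual_information_matrix(mix_dataset(data.frame(x, y)))
  expect_equal(Mg[1, 2], -0.5 * log(0.75), tolerance = 0.01)

  # independent features: near zero
  z <- rnorm(50000)
  Mi <- mutual_information_matrix(mix_dataset(data.frame(x, z)))
  expect_lt(Mi[1, 2], 0.005)

  cds <- mix_dataset(data.frame(x = rnorm(100), k = rep(1, 100)))
  expect_warning(Mc <- mutual_information_matrix(cds), "constant")
  expect_true(all(Mc[2, ] == 0))
})

test_that("mixed discrete/continuous trees are rejected", {
  ds <- mix_dataset(data.frame(g = c("A", "C"), x = c(1, 2)))
  expect_error(mutual_information_matrix(ds), "mixed")
  expect_error(fit_dtree(ds), "mixed")
})

test_that("maximum-weight spanning tree matches brute-force enumeration", {
  # the worked 4-feature instance: edges {AB, BC, BD}
  W <- matrix(0, 4, 4)
  W[1, 2] <- 3; W[2, 3] <- 2; W[2, 4] <- 2
  W[1, 3] <- 1; W[1, 4] <- 1; W[3, 4] <- 1
  W <- W + t(W)
  topo <- max_weight_spanning_tree(W, root = 1)
  expect_equal(topo$parent, c(NA, 1L, 2L, 2L))

  # p = 2 degenerate case
  expect_equal(max_weight_spanning_tree(matrix(c(0, 1, 1, 0), 2))$parent,
               c(NA, 1L))
  expect_error(max_weight_spanning_tree(matrix(numeric(0), 0, 0)), "empty")

  set.seed(82)
  for (i in 1:12) {
    p <- sample(3:5, 1)
    W <- matrix(0, p, p)
    W[upper.tri(W)] <- runif(p * (p - 1) / 2)
    W <- W + t(W)
    topo <- max_weight_spanning_tree(W)
    got <- sum(W[cbind(which(!is.na(topo$parent)),
                       topo$parent[!is.na(topo$parent)])])
    oracle <- max(vapply(all_spanning_trees(p), tree_weight, numeric(1), W = W))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("ties resolve to the lexicographically smallest edge set", {
  W <- matrix(1, 3, 3); diag(W) <- 0
  topo <- max_weight_spanning_tree(W, root = 1)
  expect_equal(topo$parent, c(NA, 1L, 1L))  # edges {12, 13}, not {12, 23}
})

test_that("fit_dtree recovers a planted chain and is Chow-Liu optimal", {
  set.seed(83)
  n <- 5000
  x1 <- sample(dna, n, TRUE)
  flip <- function(parent, eps = 0.1) {
    ifelse(runif(n) < eps, sample(dna, n, TRUE), parent)
  }
  x2 <- flip(x1); x3 <- flip(x2)
  ds <- mix_dataset(data.frame(a = x1, b = x2, c = x3),
                    alphabets = stats::setNames(rep(list(dna), 3), c("a", "b", "c")))
  comp <- fit_dtree(ds)
  und <- apply(cbind(which(!is.na(comp$topology$parent)),
                     comp$topology$parent[!is.na(comp$topology$parent)]),
               1, function(e) paste(sort(e), collapse = "-"))
  expect_setequal(und, c("1-2", "2-3"))

  # optimality against every alternative topology, refit the same way
  set.seed(84)
  for (rep in 1:3) {
    df <- data.frame(a = sample(dna, 400, TRUE), b = sample(dna, 400, TRUE),
                     c = sample(dna, 400, TRUE), d = sample(dna, 400, TRUE))
    df$b[1:250] <- df$a[1:250]
    df$d[1:180] <- df$c[1:180]
    dsr <- mix_dataset(df, alphabets = stats::setNames(rep(list(dna), 4), names(df)))
    w <- runif(400, 0.2, 1)
    best <- fit_dtree(dsr, w)
    best_ll <- weighted_tree_loglik(best, dsr, w)
    for (edges in all_spanning_trees(4)) {
      alt <- fit_dtree(dsr, w, topology = topology_from_edges(edges, 1L, 4L))
      expect_lte(weighted_tree_loglik(alt, dsr, w), best_ll + 1e-9)
    }
  }
})

test_that("the joint density is invariant to the root choice after refit", {
  set.seed(85)
  df <- data.frame(a = sample(dna, 600, TRUE), b = sample(dna, 600, TRUE),
                   c = sample(dna, 600, TRUE))
  df$b[1:400] <- df$a[1:400]
  ds <- mix_dataset(df, alphabets = stats::setNames(rep(list(dna), 3), names(df)))
  f1 <- fit_dtree(ds, root = 1)
  lls <- heteromix:::dtree_logdens_vec(f1, ds$columns)
  for (r in 2:3) {
    fr <- fit_dtree(ds, root = r)
    expect_equal(heteromix:::dtree_logdens_vec(fr, ds$columns), lls,
                 tolerance = 1e-9)
  }
})

test_that("a conditional-Gaussian tree has 3p - 1 parameters and p - 1 edges", {
  topo <- tree_topology(c(NA, 1, 2, 3), 1)
  comp <- dtree_component(topo, dist_gaussian(0, 1),
                          list(NULL, cond_gaussian(0, 1, 1),
                               cond_gaussian(0, 1, 1), cond_gaussian(0, 1, 1)))
  p <- 4
  expect_equal(n_params(comp), 3 * p - 1)
  expect_equal(nrow(tree_edge_list(comp$topology)), p - 1)
})

test_that("tree mixtures recover planted per-component topologies", {
  mk <- function(mu, parent, slopes) {
    p <- length(parent)
    topo <- tree_topology(parent, which(is.na(parent)))
    eds <- vector("list", p)
    for (j in seq_len(p)) {
      if (!is.na(parent[j])) eds[[j]] <- cond_gaussian(0, slopes[j], 0.5)
    }
    dtree_component(topo, dist_gaussian(mu, 1), eds)
  }
  truth <- dtree_mixture(c(0.5, 0.5), list(
    mk(-4, c(NA, 1, 2, 3), c(NA, 0.9, 0.9, 0.9)),   # chain
    mk(4, c(NA, 1, 1, 1), c(NA, 0.9, -0.9, 0.9))),  # star
    rep(list(list(type = "continuous")), 4))
  sim <- sample_dataset(truth, 2000, seed = 86)
  fit <- rand_max_em(truth, sim$dataset,
                     em_settings(seed = 87, n_restarts = 3, max_iter = 30, tol = 1e-6))
  expect_true(all(diff(fit$trace$loglik_per_iter) >= -1e-8))
  perm <- match_components(e_step(fit$model, sim$dataset)$resp, sim$labels, 2)
  und <- function(topo) {
    ch <- which(!is.na(topo$parent))
    sort(apply(cbind(ch, topo$parent[ch]), 1,
               function(e) paste(sort(e), collapse = "-")))
  }
  learned <- lapply(fit$model$components, function(c) und(c$topology))
  expect_equal(learned[[which(perm == 1)]], und(truth$components[[1]]$topology))
  expect_equal(learned[[which(perm == 2)]], und(truth$components[[2]]$topology))
})

test_that("K = 1 tree mixture EM equals a single weighted Chow-Liu fit", {
  set.seed(88)
  df <- data.frame(a = rnorm(300), b = rnorm(300))
  df$b <- 0.8 * df$a + 0.6 * rnorm(300)
  ds <- mix_dataset(df)
  m <- dtree_mixture(1, list(fit_dtree(ds)), ds$domains)
  fit <- em(m, ds, em_settings(max_iter = 2, tol = 1e-9))
  direct <- fit_dtree(ds, rep(1, 300))
  expect_equal(fit$model$components[[1]]$root_dist$mean, direct$root_dist$mean,
               tolerance = 1e-12)
  expect_equal(fit$model$components[[1]]$edge_dists[[2]]$slope,
               direct$edge_dists[[2]]$slope, tolerance = 1e-12)
})

test_that("topology export produces newick strings and edge lists", {
  topo <- tree_topology(c(NA, 1, 2, 2), 1)
  nwk <- format_tree_newick(topo, c("A", "B", "C", "D"))
  expect_equal(nwk, "((C,D)B)A;")
  el <- tree_edge_list(topo, c("A", "B", "C", "D"))
  expect_equal(el$parent, c("A", "B", "B"))
  expect_equal(el$child, c("B", "C", "D"))
})
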