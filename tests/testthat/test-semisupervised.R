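two_cluster_model <- function(sep = 1) gauss1d_mixture(means = c(-sep, sep),
                                                       sds = c(1, 1),
                                                       pi = c(0.5, 0.5))

test_that("constraint sets are validated", {
  expect_error(constraint_set(matrix(c(0, 2, 2, 0), 2)), "\\[0, 1\\]")
  expect_error(constraint_set(matrix(c(0, 0.5, 0.2, 0), 2)), "symmetric")
  expect_error(constraint_set(matrix(c(0.3, 0, 0, 0), 2)), "diagonal")
  cs <- constraint_set(n = 3)
  expect_equal(cs$w_pos, matrix(0, 3, 3))
})

test_that("empty constraints or zero penalties reduce exactly to the standard E-step", {
  m <- two_cluster_model()
  sim <- sample_dataset(m, 60, seed = 90)
  es <- e_step(m, sim$dataset)
  empty <- constrained_e_step(m, sim$dataset, constraint_set(n = 60),
                              lambda_pos = 5, lambda_neg = 5)
  expect_equal(empty$resp, es$resp, tolerance = 1e-12)
  expect_equal(empty$objective, es$loglik, tolerance = 1e-12)

  W <- matrix(0, 60, 60); W[1, 2] <- W[2, 1] <- 1
  zero_pen <- constrained_e_step(m, sim$dataset, constraint_set(w_pos = W),
                                 lambda_pos = 0, lambda_neg = 0)
  expect_equal(zero_pen$resp, es$resp, tolerance = 1e-12)
})

test_that("constrained responsibilities always sum to one", {
  set.seed(91)
  m <- two_cluster_model()
  sim <- sample_dataset(m, 40, seed = 91)
  W <- matrix(runif(1600), 40, 40); W <- (W + t(W)) / 2; diag(W) <- 0
  V <- matrix(runif(1600), 40, 40); V <- (V + t(V)) / 2; diag(V) <- 0
  for (lp in c(0.5, 5, 50)) {
    es <- constrained_e_step(m, sim$dataset, constraint_set(W, V),
                             lambda_pos = lp, lambda_neg = 2)
    expect_true(all(abs(rowSums(es$resp) - 1) < 1e-9))
  }
})

test_that("increasing the positive penalty never decreases co-assignment mass", {
  set.seed(92)
  m <- two_cluster_model()
  sim <- sample_dataset(m, 30, seed = 92)
  W <- matrix(0, 30, 30)
  pairs <- cbind(sample(30, 8), sample(30, 8))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  W[pairs] <- 1; W <- pmax(W, t(W))
  cs <- constraint_set(w_pos = W)
  prev <- matrix(runif(60), 30, 2)
  prev <- prev / rowSums(prev)
  # alignment of the updated responsibilities with their constrained
  # partners' (previous) responsibilities: the quantity the exponential
  # tilt provably increases in lambda_pos
  co_mass <- vapply(c(0, 0.5, 1, 2, 5, 10), function(lp) {
    r <- constrained_e_step(m, sim$dataset, cs, lambda_pos = lp,
                            lambda_neg = 0, prev_resp = prev)$resp
    sum(W * (r %*% t(prev)))
  }, numeric(1))
  expect_true(all(diff(co_mass) >= -1e-9))
})

test_that("two overlapping points with a strong positive constraint co-assign", {
  m <- two_cluster_model()
  ds <- mix_dataset(data.frame(x = c(-0.1, 0.1)))
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 1
  cs <- constraint_set(w_pos = W)
  # iterate the sequential penalized update to its fixed point
  r <- matrix(0.5, 2, 2)
  for (i in 1:60) {
    r <- heteromix:::constrained_e_sweep(m, ds, cs, 10, 0, r)$resp
  }
  labels <- max.col(r)
  expect_equal(labels[1], labels[2])  # zero positive violations

  # exhaustive oracle over the 4 hard assignments of the penalized objective
  mus <- c(-1, 1)
  best <- NULL
  for (y1 in 1:2) {
    for (y2 in 1:2) {
      obj <- dnorm(-0.1, mus[y1], 1, log = TRUE) + log(0.5) +
        dnorm(0.1, mus[y2], 1, log = TRUE) + log(0.5) - 10 * (y1 != y2)
      if (is.null(best) || obj > best$obj) best <- list(y = c(y1, y2), obj = obj)
    }
  }
  ours <- dnorm(-0.1, mus[labels[1]], 1, log = TRUE) + log(0.5) +
    dnorm(0.1, mus[labels[2]], 1, log = TRUE) + log(0.5)
  expect_equal(ours, best$obj, tolerance = 1e-9)  # ties allowed
})

test_that("constrained EM with empty constraints equals standard EM exactly", {
  m <- two_cluster_model()
  sim <- sample_dataset(m, 100, seed = 93)
  set.seed(94)
  init <- random_init(m, sim$dataset)
  s <- em_settings(max_iter = 25, tol = 1e-8)
  a <- em(init, sim$dataset, s)
  b <- constrained_em(init, sim$dataset, constraint_set(n = 100), 5, 5, s)
  expect_equal(b$trace$loglik_per_iter, a$trace$loglik_per_iter,
               tolerance = 1e-12)
  expect_equal(b$model$components[[1]]$dists[[1]]$mean,
               a$model$components[[1]]$dists[[1]]$mean, tolerance = 1e-12)
})

test_that("contradictory constraints run without error", {
  m <- two_cluster_model()
  sim <- sample_dataset(m, 20, seed = 95)
  W <- matrix(0, 20, 20); W[1, 2] <- W[2, 1] <- 1
  cs <- constraint_set(w_pos = W, w_neg = W)
  fit <- constrained_em(m, sim$dataset, cs, 3, 3,
                        em_settings(max_iter = 15, tol = 1e-6))
  expect_s3_class(fit$trace, "em_trace")
})

test_that("good positive constraints improve recovery of overlapping clusters", {
  m <- two_cluster_model(sep = 1)  # heavily overlapping
  gains <- vapply(1:12, function(s) {
    sim <- sample_dataset(m, 80, seed = 900 + s)
    set.seed(9000 + s)
    init <- random_init(m, sim$dataset)
    base <- em(init, sim$dataset, em_settings(max_iter = 40, tol = 1e-6))
    base_lab <- classify(base$model, sim$dataset)$labels

    W <- matrix(0, 80, 80)
    same <- which(outer(sim$labels, sim$labels, `==`), arr.ind = TRUE)
    same <- same[same[, 1] < same[, 2], , drop = FALSE]
    set.seed(90000 + s)
    pick <- same[sample(nrow(same), 25), , drop = FALSE]
    W[pick] <- 1; W <- pmax(W, t(W))
    diff_lab <- which(outer(sim$labels, sim$labels, `!=`), arr.ind = TRUE)
    diff_lab <- diff_lab[diff_lab[, 1] < diff_lab[, 2], , drop = FALSE]
    pick2 <- diff_lab[sample(nrow(diff_lab), 25), , drop = FALSE]
    V <- matrix(0, 80, 80); V[pick2] <- 1; V <- pmax(V, t(V))

    fit <- constrained_em(init, sim$dataset, constraint_set(W, V), 4, 4,
                          em_settings(max_iter = 40, tol = 1e-6))
    con_lab <- max.col(fit$resp)
    adj_rand(con_lab, sim$labels) - adj_rand(base_lab, sim$labels)
  }, numeric(1))
  expect_gt(mean(gains), 0)
  expect_gte(mean(gains > -1e-9), 0.75)
})

test_that("labeled EM clamps labelled rows exactly and handles the limits", {
  m <- two_cluster_model(sep = 2)
  sim <- sample_dataset(m, 120, seed = 96)

  # fully labelled: supervised per-class MLE after one M-step
  fit <- labeled_em(m, sim$dataset, sim$labels,
                    em_settings(max_iter = 5, tol = 1e-9))
  x <- sim$dataset$columns[[1]]
  for (k in 1:2) {
    xx <- x[sim$labels == k]
    expect_equal(fit$model$components[[k]]$dists[[1]]$mean, mean(xx),
                 tolerance = 1e-12)
  }
  expect_equal(fit$model$pi, tabulate(sim$labels, 2) / 120, tolerance = 1e-12)
  expect_true(all(fit$resp[cbind(1:120, sim$labels)] == 1))

  # no labels: identical to standard EM
  set.seed(97)
  init <- random_init(m, sim$dataset)
  s <- em_settings(max_iter = 20, tol = 1e-8)
  a <- em(init, sim$dataset, s)
  b <- labeled_em(init, sim$dataset, rep(NA_integer_, 120), s)
  expect_equal(b$trace$loglik_per_iter, a$trace$loglik_per_iter,
               tolerance = 1e-12)

  # partial labels stay clamped through every iteration
  part <- rep(NA_integer_, 120)
  part[1:12] <- sim$labels[1:12]
  fitp <- labeled_em(init, sim$dataset, part, em_settings(max_iter = 30, tol = 1e-8))
  expect_true(all(fitp$resp[cbind(1:12, sim$labels[1:12])] == 1))
  expect_error(labeled_em(m, sim$dataset, c(3L, rep(NA_integer_, 119)),
                          em_settings()), "1..K")
})

test_that("partial labels do not hurt mean recovery on an ambiguous mixture", {
  m <- two_cluster_model(sep = 1)
  err <- function(model) {
    means <- sort(vapply(model$components, function(c) c$dists[[1]]$mean,
                         numeric(1)))
    mean(abs(means - c(-1, 1)))
  }
  res <- vapply(1:10, function(s) {
    sim <- sample_dataset(m, 150, seed = 960 + s)
    set.seed(9600 + s)
    init <- random_init(m, sim$dataset)
    settings <- em_settings(max_iter = 50, tol = 1e-7)
    base <- em(init, sim$dataset, settings)
    lab <- rep(NA_integer_, 150)
    lab[1:15] <- sim$labels[1:15]  # 10% labelled
    semi <- labeled_em(init, sim$dataset, lab, settings)
    err(semi$model) - err(base$model)
  }, numeric(1))
  expect_lte(mean(res), 0.02)
})

test_that("labels convert to binary constraints by agreement", {
  cs <- labels_to_constraints(c(1L, 1L, 2L))
  expect_equal(cs$w_pos[1, 2], 1)
  expect_equal(sum(cs$w_pos), 2)  # symmetric single pair
  expect_equal(cs$w_neg[1, 3], 1)
  expect_equal(cs$w_neg[2, 3], 1)
  expect_equal(sum(cs$w_neg), 4)
  cs2 <- labels_to_constraints(c(1L, NA, 2L))
  expect_equal(sum(cs2$w_pos), 0)
  expect_equal(cs2$w_neg[1, 3], 1)
})

test_that("hard labels and high-penalty constraints agree on separable data", {
  m <- two_cluster_model(sep = 4)
  sim <- sample_dataset(m, 60, seed = 98)
  labels <- rep(NA_integer_, 60)
  labels[1:20] <- sim$labels[1:20]
  set.seed(99)
  init <- random_init(m, sim$dataset)
  s <- em_settings(max_iter = 40, tol = 1e-7)
  hard <- labeled_em(init, sim$dataset, labels, s)
  soft <- constrained_em(init, sim$dataset, labels_to_constraints(labels),
                         1e6, 1e6, s)
  hl <- max.col(hard$resp)
  sl <- max.col(soft$resp)
  perm <- match_components(soft$resp, hl, 2)
  expect_equal(perm[sl], hl)
})

test_that("constraint and label files round-trip through the TSV readers", {
  ids <- c("s1", "s2", "s3")
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id_i\tid_j\tweight", "s1\ts2\t0.8", "s1\ts3\t-0.5"), f)
  cs <- read_constraints(f, ids)
  expect_equal(cs$w_pos[1, 2], 0.8)
  expect_equal(cs$w_pos[2, 1], 0.8)
  expect_equal(cs$w_neg[1, 3], 0.5)
  writeLines(c("id_i\tid_j\tweight", "s1\tsX\t1"), f)
  expect_error(read_constraints(f, ids), "sX")

  g <- tempfile(fileext = ".tsv")
  writeLines(c("id\tcomponent", "s2\t0", "s3\t1"), g)
  lab <- read_labels(g, ids)
  expect_equal(lab, c(NA, 1L, 2L))
})
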