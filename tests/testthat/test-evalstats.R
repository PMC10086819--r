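test_that("k-means separates well-separated 1-D clusters", {
  x <- c(0.10, 0.12, 0.90, 0.88)
  cl <- kmeans_lloyd(x, k = 2, seed = 1)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_equal(cl$cluster[3], cl$cluster[4])
  expect_false(cl$cluster[1] == cl$cluster[3])
  expect_equal(sort(cl$sizes), c(2L, 2L))
})

test_that("identical points give a degenerate partition with a warning", {
  expect_warning(cl <- kmeans_lloyd(rep(0.5, 6), k = 2, seed = 1),
                 "degenerate")
  expect_equal(cl$cluster, rep(1L, 6))
})

test_that("restarted Lloyd matches the exhaustive two-cluster optimum", {
  for (s in 1:5) {
    set.seed(s)
    x <- runif(10)
    cl <- kmeans_lloyd(x, k = 2, seed = s, n_init = 50)
    expect_equal(cl$cost, best_partition_cost(x), tolerance = 1e-9)
  }
})

test_that("PAM recovers block structure and the exhaustive medoid optimum", {
  # two tight blocks
  x <- c(0, 0.01, 0.02, 5, 5.01)
  d <- as.matrix(dist(x))
  cl <- kmedoids(d, k = 2)
  expect_equal(length(unique(cl$cluster[1:3])), 1L)
  expect_equal(length(unique(cl$cluster[4:5])), 1L)
  expect_false(cl$cluster[1] == cl$cluster[4])

  # n = 2, k = 2: singletons
  d2 <- as.matrix(dist(c(0, 1)))
  expect_equal(sort(kmedoids(d2, k = 2)$cluster), c(1L, 2L))

  # exhaustive optimum over all medoid pairs, n <= 10
  for (s in 1:5) {
    set.seed(s)
    y <- runif(9)
    dy <- as.matrix(dist(y))
    cl <- kmedoids(dy, k = 2)
    costs <- combn(9, 2, function(md)
      sum(pmin(dy[, md[1]], dy[, md[2]])))
    expect_equal(cl$cost, min(costs), tolerance = 1e-12)
  }

  expect_error(kmedoids(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("1-D W2 distance matches closed forms and the LP transport oracle", {
  expect_equal(wasserstein2_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein2_1d(2, 7), 5)
  # equal sizes: RMS of sorted differences
  set.seed(4)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(wasserstein2_1d(a, b),
               sqrt(mean((sort(a) - sort(b))^2)), tolerance = 1e-12)

  # unequal sizes vs a linear-program optimal-transport oracle
  set.seed(5)
  for (rep in 1:3) {
    a <- rnorm(7); b <- rnorm(11)
    expect_equal(wasserstein2_1d(a, b), lp_transport_w2(a, b),
                 tolerance = 1e-9)
  }
})

test_that("W2 behaves like a metric on discrete distributions", {
  set.seed(6)
  for (rep in 1:10) {
    a <- rnorm(6); b <- rnorm(9); c1 <- rnorm(7)
    dab <- wasserstein2_1d(a, b)
    expect_equal(dab, wasserstein2_1d(b, a), tolerance = 1e-12)
    expect_gte(dab, 0)
    expect_lte(dab, wasserstein2_1d(a, c1) + wasserstein2_1d(c1, b) + 1e-12)
  }
  expect_error(wasserstein2_1d(numeric(0), 1), "empty")
})

test_that("Spearman correlation handles monotone data, ties and constants", {
  x <- 1:10
  expect_equal(spearman_rho(x, x^3)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)

  # ties: equals Pearson correlation of hand-computed mid-ranks
  a <- c(1, 2, 2, 3, 5, 5, 5, 9)
  b <- c(2, 1, 4, 4, 6, 7, 7, 8)
  expect_equal(spearman_rho(a, b)$rho,
               cor(rank(a), rank(b)), tolerance = 1e-12)

  # invariance under strictly monotone transforms
  set.seed(7)
  u <- runif(15); v <- runif(15)
  expect_equal(spearman_rho(u, v)$rho, spearman_rho(exp(u), v)$rho)
  expect_equal(spearman_rho(u, v)$rho, spearman_rho(u, qlogis(v))$rho)

  expect_false(spearman_rho(rep(1, 5), 1:5)$defined)
  expect_error(spearman_rho(1:3, 1:4), "mismatch")
})

test_that("the nonparametric battery matches exact references", {
  # identical groups: H ~ 0, p ~ 1
  g <- list(a = c(1, 2, 3, 4, 5, 6), b = c(1, 2, 3, 4, 5, 6),
            c = c(1, 2, 3, 4, 5, 6))
  out <- nonparam_battery(g)
  kw <- out[out$test == "kruskal-wallis", ]
  expect_equal(kw$statistic, 0, tolerance = 1e-9)
  expect_gt(kw$p, 0.99)

  # Bonferroni over the 6 pairwise tests of 4 groups
  set.seed(8)
  g4 <- lapply(1:4, function(i) rnorm(12, mean = i / 10))
  names(g4) <- paste0("l", 1:4)
  out4 <- nonparam_battery(g4)
  pw <- out4[out4$test == "wilcoxon-signed-rank", ]
  expect_equal(nrow(pw), 6L)
  expect_equal(pw$p_adjusted, pmin(1, pw$p * 6), tolerance = 1e-12)

  # exact signed-rank null at n = 6 vs enumeration over sign patterns
  x <- c(1.1, 2.3, 0.4, 3.2, 1.9, 2.8)
  y <- c(0.8, 1.9, 0.9, 2.1, 1.2, 2.0)
  out6 <- nonparam_battery(list(x = x, y = y))
  w <- out6[out6$test == "wilcoxon-signed-rank", ]
  d <- x - y
  r <- rank(abs(d))
  Wobs <- sum(r[d > 0])
  Wall <- sapply(0:(2^6 - 1), function(mask) {
    s <- as.logical(bitwAnd(mask, 2^(0:5)))
    sum(r[s])
  })
  p_exact <- mean(abs(Wall - sum(r) / 2) >= abs(Wobs - sum(r) / 2))
  expect_equal(w$p, p_exact, tolerance = 1e-12)

  # all-zero paired differences are flagged, not crashed
  outz <- nonparam_battery(list(a = 1:5, b = 1:5))
  wz <- outz[outz$test == "wilcoxon-signed-rank", ]
  expect_true(is.na(wz$p))
  expect_match(wz$note, "zero")
})

test_that("HPD width comparison books the right rows and direction", {
  set.seed(9)
  genes <- paste0("g", 1:15)
  w12 <- setNames(runif(15, 0.05, 0.10), genes)
  w3 <- setNames(w12 + runif(15, 0.05, 0.15), genes)  # wider by construction
  res <- compare_hpd_widths(list(out3 = w3, out12 = w12))
  expect_equal(nrow(res$long), 30L)
  expect_lt(res$summary$median_width[res$summary$level == "out12"],
            res$summary$median_width[res$summary$level == "out3"])
  pw <- res$tests[res$tests$test == "wilcoxon-signed-rank", ]
  expect_lt(pw$p_adjusted, 0.01)

  # identical levels: nothing significant
  res0 <- compare_hpd_widths(list(a = w12, b = w12))
  expect_true(is.na(res0$tests$p[res0$tests$test == "wilcoxon-signed-rank"]))
  expect_error(compare_hpd_widths(list(a = w12, b = w12[1:10])), "differ")
})

test_that("cluster_estimates dispatches on the representation", {
  # scalars -> k-means
  sc <- cluster_estimates(c(0.1, 0.11, 0.9, 0.92), seed = 2)
  expect_equal(sort(sc$sizes), c(2L, 2L))
  # posterior samples -> Wasserstein + PAM
  post <- list(g1 = rnorm(50, 0), g2 = rnorm(50, 0.1),
               g3 = rnorm(50, 5), g4 = rnorm(50, 5.1))
  pc <- cluster_estimates(post, seed = 3)
  expect_equal(pc$cluster[1], pc$cluster[2])
  expect_equal(pc$cluster[3], pc$cluster[4])
  expect_false(pc$cluster[1] == pc$cluster[3])
})

test_that("adjusted Rand index agrees with an independent implementation", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(10)
  skip_if_not_installed("mclust")
  for (rep in 1:5) {
    a <- sample(1:3, 20, replace = TRUE)
    b <- sample(1:2, 20, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})
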