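test_that("single-node BIC equals the closed-form Gaussian MLE score", {
  y <- c(-1, 0, 1)
  g <- dag("y")
  # oracle: sigma2_ML = 2/3, loglik = -(3/2)(log(2*pi*2/3)+1), penalty log(3)
  closed <- -(3 / 2) * (log(2 * pi * 2 / 3) + 1) - (2 / 2) * log(3)
  expect_equal(bic_score(g, cbind(y = y)), closed, tolerance = 1e-12)
  expect_equal(closed, -4.74723, tolerance = 1e-5)
  expect_equal(bic_score(g, cbind(y = y)), oracle_family_score(y, cbind(y)[, 0]),
               tolerance = 1e-9)
})

test_that("the score decomposes over families and matches the lm oracle", {
  x <- rand_mat(50, 4, seed = 31)
  g <- dag(colnames(x), data.frame(from = c("v01", "v01", "v02"),
                                   to = c("v02", "v03", "v04")))
  total <- bic_score(g, x)
  by_node <- sum(vapply(g$nodes, function(nd) {
    methanet:::family_score(x[, nd], x[, dag_parents(g, nd), drop = FALSE])
  }, numeric(1)))
  expect_equal(total, by_node, tolerance = 1e-12)
  expect_equal(total, oracle_bic(g, x), tolerance = 1e-8)
})

test_that("an irrelevant parent lowers BIC at large n", {
  set.seed(33)
  n <- 2000
  x <- cbind(a = rnorm(n), b = rnorm(n))
  x <- cbind(x, y = 0.9 * x[, "a"] + rnorm(n, 0, 0.3))
  g_true <- dag(colnames(x), data.frame(from = "a", to = "y"))
  g_extra <- dag(colnames(x), data.frame(from = c("a", "b"), to = c("y", "y")))
  expect_gt(bic_score(g_true, x), bic_score(g_extra, x))
})

test_that("collinear parents score -Inf rather than inflating the fit", {
  set.seed(34)
  a <- rnorm(30)
  x <- cbind(a = a, b = 2 * a, y = a + rnorm(30, 0.1))
  g <- dag(colnames(x), data.frame(from = c("a", "b"), to = c("y", "y")))
  expect_identical(bic_score(g, x), -Inf)
})

test_that("exhaustive enumeration counts labeled DAGs correctly", {
  x1 <- rand_mat(20, 1, seed = 41)
  res1 <- exhaustive_search(x1)
  expect_identical(nrow(res1$dag$edges), 0L)
  expect_identical(res1$n_dags, 1L)

  x3 <- rand_mat(20, 3, seed = 42)
  expect_identical(exhaustive_search(x3)$n_dags, 25L)

  expect_error(exhaustive_search(rand_mat(10, 6, seed = 43)), "at most 5")
})

test_that("independent variables yield the empty graph", {
  x <- rand_mat(500, 2, seed = 44)
  expect_identical(nrow(hill_climb(x)$dag$edges), 0L)
  expect_identical(nrow(exhaustive_search(x)$dag$edges), 0L)
})

test_that("a strong X->Y signal is recovered exactly under a blacklist", {
  set.seed(45)
  x <- rnorm(500)
  d <- cbind(X = x, Y = x + rnorm(500, 0, 0.1))
  cons <- edge_constraints(blacklist = data.frame(from = "Y", to = "X"))
  g <- hill_climb(d, cons)$dag
  expect_identical(g$edges, data.frame(from = "X", to = "Y"))
  expect_identical(exhaustive_search(d, cons)$dag$edges,
                   data.frame(from = "X", to = "Y"))
})

test_that("whitelisted edges appear in every result", {
  for (seed in 1:5) {
    x <- rand_mat(80, 4, seed = 100 + seed)
    cons <- edge_constraints(whitelist = data.frame(from = "v01", to = "v02"))
    g <- hill_climb(x, cons)$dag
    expect_true(any(g$edges$from == "v01" & g$edges$to == "v02"))
  }
})

test_that("search respects constraints over many random tiered scenarios", {
  n_violations <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    p <- sample(3:6, 1)
    x <- rand_mat(50, p, seed = 1000 + seed)
    tiers <- sample(c("fermenter", "geobacter", "methanogen", "environment",
                      "output"), p, replace = TRUE)
    cons <- build_blacklist(data.frame(variable = colnames(x), tier = tiers))
    # add a whitelist edge on an allowed pair when one exists
    blkey <- paste(cons$blacklist$from, cons$blacklist$to)
    pairs <- expand.grid(from = colnames(x), to = colnames(x),
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to &
                     !(paste(pairs$from, pairs$to) %in% blkey), ]
    if (nrow(pairs)) {
      pick <- pairs[sample(nrow(pairs), 1), ]
      cons <- edge_constraints(cons$blacklist, pick)
    }
    g <- hill_climb(x, cons)$dag
    key <- paste(g$edges$from, g$edges$to)
    if (!dag_is_acyclic(g) || any(key %in% blkey) ||
        (nrow(cons$whitelist) &&
         !all(paste(cons$whitelist$from, cons$whitelist$to) %in% key))) {
      n_violations <- n_violations + 1L
    }
  }
  expect_identical(n_violations, 0L)
})

test_that("hill climbing never scores below its start graph", {
  for (seed in 1:10) {
    x <- rand_mat(60, 5, seed = 200 + seed)
    cons <- edge_constraints(whitelist = data.frame(from = "v01", to = "v03"))
    start <- dag(colnames(x), cons$whitelist)
    res <- hill_climb(x, cons)
    expect_gte(res$score, bic_score(start, x) - 1e-9)
    expect_equal(res$score, bic_score(res$dag, x), tolerance = 1e-6)
  }
})

test_that("search is deterministic and independent of column order", {
  x <- rand_mat(80, 5, seed = 300)
  r1 <- hill_climb(x)
  r2 <- hill_climb(x)
  expect_identical(r1$dag$edges, r2$dag$edges)
  perm <- x[, c(3, 1, 5, 2, 4)]
  r3 <- hill_climb(perm)
  expect_setequal(paste(r1$dag$edges$from, r1$dag$edges$to),
                  paste(r3$dag$edges$from, r3$dag$edges$to))
})

test_that("zero-variance columns are rejected before search", {
  x <- rand_mat(30, 3, seed = 301)
  x[, 2] <- 1
  expect_error(hill_climb(x), "zero-variance")
})

test_that("restarts escape v-structure local optima at least as often as plain greedy", {
  n <- 150
  plain <- 0L
  restarted <- 0L
  for (k in 1:15) {
    set.seed(k + 7000)
    labs <- sample(c("A", "B", "C"))  # collider child in a random label slot
    p1 <- rnorm(n)
    p2 <- rnorm(n)
    ch <- runif(1, 0.8, 1.2) * p1 + runif(1, 0.8, 1.2) * p2 +
      rnorm(n, 0, 0.2)
    x <- cbind(p1, p2, ch)
    colnames(x) <- labs
    x <- x[, order(colnames(x))]
    ex <- exhaustive_search(x)$score
    if (ex - bic_score(hill_climb(x)$dag, x) < 1e-6) plain <- plain + 1L
    hr <- hill_climb(x, restarts = 4, seed = 11)
    if (ex - bic_score(hr$dag, x) < 1e-6) restarted <- restarted + 1L
  }
  expect_gte(restarted, plain)
})
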