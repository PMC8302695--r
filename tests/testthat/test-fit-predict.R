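test_that("parentless nodes get the sample mean and ML variance", {
  set.seed(51)
  y <- rnorm(40, 5, 2)
  bn <- fit_mle(dag("y"), cbind(y = y))
  expect_equal(bn$params$y$intercept, mean(y), tolerance = 1e-12)
  expect_equal(bn$params$y$sigma2, mean((y - mean(y))^2), tolerance = 1e-12)
})

test_that("a noiseless linear relation is fit exactly with floored variance", {
  x <- seq(-2, 2, length.out = 25)
  d <- cbind(X = x, Y = 2 * x + 1)
  bn <- fit_mle(dag(colnames(d), data.frame(from = "X", to = "Y")), d)
  expect_equal(bn$params$Y$coef[["X"]], 2, tolerance = 1e-9)
  expect_equal(bn$params$Y$intercept, 1, tolerance = 1e-9)
  expect_lte(bn$params$Y$sigma2, 1e-10)
  expect_gte(bn$params$Y$sigma2, 1e-12)
})

test_that("collinear parents raise an error naming the family", {
  set.seed(52)
  a <- rnorm(20)
  d <- cbind(a = a, b = 3 * a, y = rnorm(20))
  g <- dag(colnames(d), data.frame(from = c("a", "b"), to = c("y", "y")))
  expect_error(fit_mle(g, d), "'y'")
})

test_that("SEM coefficients are recovered from simulated data", {
  sem <- build_template_sem(scenario_config())
  errs <- vapply(1:10, function(seed) {
    x <- simulate_expression(sem, 1000, seed = seed)$values
    bn <- fit_mle(sem$dag, x)
    est <- vapply(seq_len(nrow(sem$edges)), function(k) {
      bn$params[[sem$edges$to[k]]]$coef[[sem$edges$from[k]]]
    }, numeric(1))
    abs(est - sem$edges$coef)
  }, numeric(nrow(sem$edges)))
  # per-coefficient median error across seeds stays within OLS sampling error
  per_coef <- apply(errs, 1L, median)
  expect_true(all(per_coef < 0.05))
})

test_that("parents-mode prediction is the local linear evaluation", {
  d <- cbind(X = c(0, 1, 2, 3), Y = c(1, 3, 5, 7))
  bn <- fit_mle(dag(colnames(d), data.frame(from = "X", to = "Y")), d)
  expect_equal(predict_nodes(bn, c(X = 3), "Y")[["Y"]], 7, tolerance = 1e-9)
  # parentless target: its intercept, whatever the evidence says
  bn2 <- fit_mle(dag(colnames(d)), d)
  expect_equal(predict_nodes(bn2, c(X = 100), "Y")[["Y"]], mean(d[, "Y"]),
               tolerance = 1e-12)
  expect_error(predict_nodes(bn, c(Z = 1), "Y"), "parent")
})

test_that("joint prediction equals brute-force Gaussian conditioning on a chain", {
  # X -> Y -> Z with known parameters; condition Z on X only
  g <- dag(c("X", "Y", "Z"), data.frame(from = c("X", "Y"), to = c("Y", "Z")))
  bn <- structure(list(dag = g, params = list(
    X = list(intercept = 1, coef = setNames(numeric(0), character(0)),
             sigma2 = 2),
    Y = list(intercept = 0.5, coef = c(X = 0.8), sigma2 = 0.5),
    Z = list(intercept = -1, coef = c(Y = 1.5), sigma2 = 0.25)
  ), n = NA_integer_), class = "lgbn")
  # oracle: assemble the joint covariance by explicit path tracing
  var_x <- 2
  var_y <- 0.8^2 * var_x + 0.5
  var_z <- 1.5^2 * var_y + 0.25
  cov_xz <- 0.8 * 1.5 * var_x
  mu_x <- 1
  mu_y <- 0.5 + 0.8 * mu_x
  mu_z <- -1 + 1.5 * mu_y
  ev <- c(X = 2.4)
  oracle <- mu_z + cov_xz / var_x * (ev[["X"]] - mu_x)
  got <- predict_nodes(bn, ev, "Z", method = "joint")
  expect_equal(got[["Z"]], oracle, tolerance = 1e-10)
  mom <- implied_moments(bn)
  expect_equal(mom$cov["Z", "Z"], var_z, tolerance = 1e-10)
  expect_equal(mom$cov["X", "Z"], cov_xz, tolerance = 1e-10)
  # no evidence: the marginal mean
  expect_equal(predict_nodes(bn, numeric(0), "Z", method = "joint")[["Z"]],
               mu_z, tolerance = 1e-10)
})

test_that("implied covariance of fitted networks is symmetric PSD", {
  for (seed in 1:20) {
    x <- rand_mat(40, 4, seed = 400 + seed)
    g <- hill_climb(x)$dag
    mom <- implied_moments(fit_mle(g, x))
    expect_equal(mom$cov, t(mom$cov), tolerance = 1e-10)
    expect_gte(min(eigen(mom$cov, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("network TSV export reconstructs the fit bit-exactly", {
  fx <- template_fixture(n = 50, seed = 6)
  g <- hill_climb(fx$norm, fx$constraints)$dag
  bn <- fit_mle(g, fx$norm)
  ep <- file.path(tempdir(), "bn_e.tsv")
  np <- file.path(tempdir(), "bn_n.tsv")
  write_bn(bn, ep, np, metadata = fx$norm)
  back <- read_bn(ep, np)
  expect_identical(back$dag$edges, bn$dag$edges)
  for (v in bn$dag$nodes) {
    expect_identical(back$params[[v]]$intercept, bn$params[[v]]$intercept)
    expect_identical(back$params[[v]]$coef, bn$params[[v]]$coef)
    expect_identical(back$params[[v]]$sigma2, bn$params[[v]]$sigma2)
  }
  # writing the re-read network reproduces the files byte for byte
  ep2 <- file.path(tempdir(), "bn_e2.tsv")
  np2 <- file.path(tempdir(), "bn_n2.tsv")
  write_bn(back, ep2, np2, metadata = fx$norm)
  expect_identical(readLines(ep), readLines(ep2))
  expect_identical(readLines(np), readLines(np2))
})

test_that("graph exports for visualization are well-formed", {
  fx <- template_fixture(n = 40, seed = 7)
  bn <- fit_mle(hill_climb(fx$norm, fx$constraints)$dag, fx$norm)
  gp <- file.path(tempdir(), "net.graphml")
  dp <- file.path(tempdir(), "net.dot")
  export_network(bn, gp, "graphml", metadata = fx$norm)
  export_network(bn, dp, "dot", metadata = fx$norm)
  expect_true(file.exists(gp) && file.size(gp) > 0)
  expect_true(any(grepl("graphml", readLines(gp, n = 5))))
  expect_true(any(grepl("digraph", readLines(dp, n = 5))))
  ig <- igraph::read_graph(gp, format = "graphml")
  expect_identical(sort(igraph::V(ig)$name), sort(bn$dag$nodes))
  expect_identical(igraph::ecount(ig), as.numeric(nrow(bn$dag$edges)))
})
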