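test_that("Bray-Curtis similarity matches its formula and edge conventions", {
  expect_equal(bray_curtis_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(bray_curtis_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(bray_curtis_similarity(c(1, 1), c(1, 3)), 1 - 2 / 6,
               tolerance = 1e-12)
  expect_warning(out <- bray_curtis_similarity(c(0, 0), c(0, 0)), "all-zero")
  expect_identical(out, 1)
  expect_warning(clip <- bray_curtis_similarity(c(-1, 1), c(0, 1)), "clipped")
  expect_equal(clip, bray_curtis_similarity(c(0, 1), c(0, 1)))
})

test_that("Bray-Curtis is symmetric, scale-invariant and agrees with vegan", {
  skip_if_not_installed("vegan")
  set.seed(61)
  for (i in 1:20) {
    u <- runif(8)
    v <- runif(8)
    expect_equal(bray_curtis_similarity(u, v), bray_curtis_similarity(v, u))
    expect_equal(bray_curtis_similarity(3.7 * u, 3.7 * v),
                 bray_curtis_similarity(u, v), tolerance = 1e-12)
    expect_equal(bray_curtis_similarity(u, v),
                 1 - as.numeric(vegan::vegdist(rbind(u, v), "bray")),
                 tolerance = 1e-12)
  }
})

test_that("relative RMSE matches its definition and homogeneity", {
  expect_equal(relative_rmse(c(1, 2, 3, 4), c(1, 2, 3, 0)), 0.5,
               tolerance = 1e-12)
  expect_identical(relative_rmse(c(1, 2), c(1, 2)), 0)
  set.seed(62)
  y <- runif(10, 1, 5)
  t <- y + rnorm(10)
  expect_gt(relative_rmse(y, t), 0)
  expect_equal(relative_rmse(2.5 * y, 2.5 * t), relative_rmse(y, t),
               tolerance = 1e-12)
  expect_error(relative_rmse(c(0, 0), c(1, 1)), "undefined")
})

test_that("squared correlation behaves as specified", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), 3 * c(1, 2, 3) + 2), 1)
  expect_equal(r_squared(c(1, 2, 3), c(1, 3, 2)), 0.25, tolerance = 1e-12)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(r_squared(c(1, 2, 3), c(2, 2, 2)), "constant")
  # regression-based variant can be negative and is reported separately
  expect_lt(r_squared(c(1, 2, 3), c(9, 9, 8.5), method = "cod"), 0)
})

test_that("the null model predicts training-fold means", {
  v <- cbind(a = c(1, 2, 3), b = c(4, 4, 4))
  rownames(v) <- paste0("s", 1:3)
  ft <- make_ft(v)
  res <- null_model_predict(ft, c("a", "b"))
  expect_equal(res$predicted[1, "a"], 2.5)
  expect_equal(res$predicted[2, "a"], 2)
  expect_equal(res$predicted[3, "a"], 1.5)
  expect_equal(unname(res$predicted[, "b"]), c(4, 4, 4))
  # invariant to the other columns
  v2 <- v
  v2[, "b"] <- c(100, -5, 7)
  expect_identical(null_model_predict(make_ft(v2), "a")$predicted[, "a"],
                   res$predicted[, "a"])
})

test_that("LOO-CV runs one fold per sample and is deterministic", {
  fx <- template_fixture(n = 12, seed = 9)
  cv <- loo_cv(fx$norm, fx$constraints, targets = "ch4_production")
  expect_identical(nrow(cv$predicted), 12L)
  expect_identical(colnames(cv$predicted), "ch4_production")
  cv2 <- loo_cv(fx$norm, fx$constraints, targets = "ch4_production")
  expect_identical(cv$predicted, cv2$predicted)
  expect_error(loo_cv(ft_subset(fx$norm, samples = 1:2), fx$constraints,
                      targets = "ch4_production"), "n >= 3")
})

test_that("each fold equals manual retraining on the explicit subset", {
  fx <- template_fixture(n = 10, seed = 10)
  for (method in c("parents", "joint")) {
    cv <- loo_cv(fx$norm, fx$constraints, targets = "ch4_production",
                 method = method)
    for (i in c(1L, 6L)) {
      train <- ft_subset(fx$norm, samples = setdiff(1:10, i))
      hc <- hill_climb(train, fx$constraints)
      bn <- fit_mle(hc$dag, train)
      ev <- fx$norm$values[i, setdiff(ft_variables(fx$norm), "ch4_production")]
      manual <- predict_nodes(bn, ev, "ch4_production", method = method)
      expect_equal(cv$predicted[i, "ch4_production"],
                   manual[["ch4_production"]], tolerance = 1e-8)
    }
  }
})

test_that("the reconstruction report aggregates both models consistently", {
  fx <- template_fixture(n = 12, seed = 11)
  targets <- grep("^gene_", ft_variables(fx$norm), value = TRUE)[1:5]
  null <- null_model_predict(fx$norm, targets)
  rep_null <- community_reconstruction_report(null, null)
  expect_equal(rep_null$bray_curtis_mean, rep_null$null_bray_curtis_mean)

  perfect <- null
  perfect$predicted <- perfect$observed
  rep_perf <- community_reconstruction_report(perfect, null)
  expect_equal(rep_perf$bray_curtis_mean, 1)
  pv <- rep_perf$per_variable
  expect_true(all(pv$relative_rmse[pv$model == "bn"] == 0))
  expect_true(all(c("bn", "null") %in% pv$model))

  tsv <- file.path(tempdir(), "metrics.tsv")
  js <- file.path(tempdir(), "metrics.json")
  write_validation_report(rep_perf, tsv, js)
  expect_true(file.exists(tsv) && file.exists(js))
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$bray_curtis_mean, 1)
})

test_that("metrics are pure functions of their arguments", {
  set.seed(63)
  u <- runif(6)
  v <- runif(6)
  first <- bray_curtis_similarity(u, v)
  for (k in 1:3) expect_identical(bray_curtis_similarity(u, v), first)
  y <- runif(6)
  t <- runif(6)
  expect_identical(relative_rmse(y, t), relative_rmse(y, t))
  expect_identical(r_squared(y, t), r_squared(y, t))
})
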