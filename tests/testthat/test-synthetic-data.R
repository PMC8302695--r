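test_that("template SEM respects the tier ordering by construction", {
  sem <- build_template_sem(scenario_config())
  tiers <- setNames(sem$nodes$tier, sem$nodes$node)
  rank <- c(fermenter = 1, geobacter = 1, methanogen = 2, output = 3)
  for (k in seq_len(nrow(sem$edges))) {
    rf <- rank[[tiers[[sem$edges$from[k]]]]]
    rt <- rank[[tiers[[sem$edges$to[k]]]]]
    expect_lte(rf, rt)
  }
  # layout promised by the generator
  expect_gte(sum(tiers == "fermenter" & !grepl("distractor", names(tiers))), 4)
  expect_gte(sum(tiers == "geobacter"), 3)
  expect_gte(sum(tiers == "methanogen"), 3)
  expect_identical(sum(tiers == "output"), 1L)
  # distractors are disconnected
  dis <- names(tiers)[grepl("distractor", names(tiers))]
  expect_length(dis, 3)
  expect_false(any(sem$edges$from %in% dis | sem$edges$to %in% dis))
})

test_that("tier-violating SEM wiring is rejected", {
  nodes <- data.frame(node = c("m", "f"), tier = c("methanogen", "fermenter"),
                      mechanism = "other", intercept = 0, noise_sd = 1)
  expect_error(ground_truth_sem(nodes, data.frame(from = "m", to = "f",
                                                  coef = 1)),
               "tier constraint")
  nodes2 <- data.frame(node = c("o", "f"), tier = c("output", "fermenter"),
                       mechanism = "other", intercept = 0, noise_sd = 1)
  expect_error(ground_truth_sem(nodes2, data.frame(from = "o", to = "f",
                                                   coef = 1)),
               "output")
  nodes3 <- data.frame(node = "x", tier = "fermenter", mechanism = "other",
                       intercept = 0, noise_sd = 0)
  expect_error(ground_truth_sem(nodes3, empty_edges_df()), "noise_sd")
})

test_that("path weights match brute-force path enumeration", {
  h2_genes <- c("gene_hyaB", "gene_hox", "gene_hnd", "gene_ech")
  eet_genes <- c("gene_omcF", "gene_pilA")

  sem0 <- build_template_sem(scenario_config(iht_effect = 0))
  for (g in h2_genes) {
    expect_identical(sem_path_weight(sem0, g, "ch4_production"), 0)
  }

  sem <- build_template_sem(scenario_config(iht_effect = 0.8,
                                            diet_effect = 0.2))
  iht_set <- c(h2_genes, "gene_mvhADG")
  diet_set <- c(eet_genes, "gene_mvhB")
  w_iht <- sem_path_weight(sem, iht_set, "ch4_production")
  w_diet <- sem_path_weight(sem, diet_set, "ch4_production")
  expect_gt(w_iht, w_diet)
  expect_equal(w_iht, oracle_path_weight(sem, iht_set, "ch4_production"),
               tolerance = 1e-12)
  expect_equal(w_diet, oracle_path_weight(sem, diet_set, "ch4_production"),
               tolerance = 1e-12)
})

test_that("expression simulation is seeded, non-negative and metadata-complete", {
  sem <- build_template_sem(scenario_config())
  a <- simulate_expression(sem, 20, seed = 3)
  b <- simulate_expression(sem, 20, seed = 3)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values,
                         simulate_expression(sem, 20, seed = 4)$values))
  expect_true(all(a$values >= 0))
  expect_identical(a$metadata$tier, sem$nodes$tier)
  expect_identical(a$metadata$mechanism, sem$nodes$mechanism)
})

test_that("near-zero noise makes the output an exact function of its parents", {
  cfg <- scenario_config(noise_sd = 1e-9)
  sem <- build_template_sem(cfg)
  x <- simulate_expression(sem, 30, seed = 8)$values
  ed <- sem$edges[sem$edges$to == "ch4_production", ]
  pred <- as.vector(x[, ed$from] %*% ed$coef)
  # column shifts add constants, so compare after centering
  expect_equal(x[, "ch4_production"] - mean(x[, "ch4_production"]),
               pred - mean(pred), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("sample covariance matches the closed-form SEM covariance", {
  sem <- build_template_sem(scenario_config())
  mom <- implied_moments(sem)
  n <- 10000
  x <- simulate_expression(sem, n, seed = 17)$values
  S <- cov(x) * (n - 1) / n
  nodes <- sem$nodes$node
  for (i in seq_along(nodes)) {
    for (j in seq(i, length(nodes))) {
      se <- sqrt((mom$cov[i, i] * mom$cov[j, j] + mom$cov[i, j]^2) / n)
      expect_lt(abs(S[nodes[i], nodes[j]] - mom$cov[i, j]),
                3 * se + 1e-12)
    }
  }
})

test_that("disconnected distractors decorrelate from methane as n grows", {
  sem <- build_template_sem(scenario_config())
  x <- simulate_expression(sem, 4000, seed = 21)$values
  for (d in grep("distractor", colnames(x), value = TRUE)) {
    expect_lt(abs(cor(x[, d], x[, "ch4_production"])), 0.06)
  }
})

test_that("community tables satisfy compositional closure and the core rule", {
  cfg <- scenario_config(seed = 11)
  comm <- simulate_community(cfg)
  for (tab in list(comm$dna, comm$rna)) {
    expect_true(all(tab$values >= 0))
    expect_true(all(rowSums(tab$values) <= 1))
  }
  expect_setequal(select_core_taxa(comm$dna, comm$rna), comm$core)
  expect_length(comm$core, 22)
  # determinism
  comm2 <- simulate_community(cfg)
  expect_identical(comm$rna$values, comm2$rna$values)
  expect_identical(comm$environment$values, comm2$environment$values)
})

test_that("the taxon driving methane is the one most correlated with it", {
  cfg <- scenario_config(n_samples = 1000, seed = 13)
  target <- "taxon_15"
  comm <- simulate_community(cfg, ch4_weights = setNames(1, target))
  cors <- abs(cor(comm$rna$values, comm$environment$values[, "ch4_production"]))
  expect_identical(rownames(cors)[which.max(cors)], target)
})

test_that("count simulation yields consistent integer fixtures", {
  cfg <- scenario_config(seed = 19)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_true(all(rowSums(sim$counts) <= sim$library_sizes))
  sim2 <- simulate_counts(cfg)
  expect_identical(sim$counts, sim2$counts)
  # RPKM on the fixture is finite and zero exactly where counts are zero
  rpkm <- compute_rpkm(sim$counts, sim$gene_lengths, sim$library_sizes)
  expect_true(all(is.finite(rpkm$values)))
  expect_identical(rpkm$values == 0, sim$counts == 0)
})

test_that("SEM serialization round-trips exactly", {
  sem <- build_template_sem(scenario_config(iht_effect = 1 / 3))
  ep <- file.path(tempdir(), "sem_e.tsv")
  np <- file.path(tempdir(), "sem_n.tsv")
  write_sem(sem, ep, np)
  back <- read_sem(ep, np)
  expect_identical(back$edges$coef, sem$edges$coef)
  expect_identical(back$nodes$noise_sd, sem$nodes$noise_sd)
  expect_identical(back$nodes$tier, sem$nodes$tier)
})
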