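#' Simulate compositional community tables and environmental parameters
#'
#' Emulates the statistical structure the community network analysis
#' assumes: latent per-taxon activities follow a linear-Gaussian cascade
#' (fermenter taxa exogenous; Geobacter taxa driven by fermenters;
#' methanogen taxa driven by Geobacter and fermenters, all with strength
#' `community_effect`), DNA latents track RNA latents with extra noise, and
#' relative abundances arise by softmax-style closure of the exponentiated
#' latents with a remainder bucket absorbing the non-core community, so each
#' sample's abundances are non-negative and sum to < 1. The designated core
#' taxa are parameterized to pass the > 0.5\% mean abundance / > 50\%
#' occurrence rule, while distractor taxa are orders of magnitude rarer and
#' fail it. Environmental parameters (CH4 production first, then effluent
#' and operational variables) are linear functions of designated taxa's
#' latent activities plus Gaussian noise; with `env_effect = 0` they are
#' pure noise, giving an independence fixture.
#'
#' @param config a `scenario_config`.
#' @param ch4_weights optional named vector overriding the per-taxon
#'   generating weights of the CH4 column (names = taxon names); taxa not
#'   named get weight 0.
#' @return list with `dna`, `rna`, `environment` (three `feature_table`s),
#'   `core` (the designated core taxon names) and `taxon_tiers`.
#' @export
simulate_community <- function(config = scenario_config(), ch4_weights = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_samples
  k <- config$n_core_taxa
  nd <- config$n_distractor_taxa
  if (k < 3L) stop("need at least 3 core taxa (one per tier)")

  # tier layout of the core population: roughly half fermenters, a small
  # Geobacter guild, the rest methanogens
  n_geo <- max(1L, round(k * 0.18))
  n_meth <- max(1L, round(k * 0.27))
  n_ferm <- k - n_geo - n_meth
  if (n_ferm < 1L) stop("core size too small for the tier layout")
  tiers <- c(rep("fermenter", n_ferm), rep("geobacter", n_geo),
             rep("methanogen", n_meth))
  core <- sprintf("taxon_%02d", seq_len(k))
  distr <- if (nd > 0L) sprintf("rare_taxon_%02d", seq_len(nd)) else character(0)
  distr_tiers <- rep(c("fermenter", "geobacter", "methanogen"), length.out = nd)
  taxa <- c(core, distr)
  taxon_tiers <- stats::setNames(c(tiers, distr_tiers), taxa)

  ferm <- core[tiers == "fermenter"]
  geo <- core[tiers == "geobacter"]
  meth <- core[tiers == "methanogen"]
  ce <- config$community_effect

  z_rna <- with_seed(derive_seed(config$seed, "rna_latent"), {
    z <- matrix(stats::rnorm(n * length(taxa)), n, length(taxa),
                dimnames = list(sprintf("s%02d", seq_len(n)), taxa))
    # cascade: each Geobacter taxon follows one fermenter, each methanogen
    # one Geobacter and one fermenter
    for (i in seq_along(geo)) {
      drv <- ferm[(i - 1L) %% length(ferm) + 1L]
      z[, geo[i]] <- ce * z[, drv] + sqrt(max(1 - ce^2, 0.05)) * z[, geo[i]]
    }
    for (i in seq_along(meth)) {
      d1 <- geo[(i - 1L) %% length(geo) + 1L]
      d2 <- ferm[i %% length(ferm) + 1L]
      z[, meth[i]] <- ce * 0.7 * z[, d1] + ce * 0.3 * z[, d2] +
        sqrt(max(1 - ce^2, 0.05)) * z[, meth[i]]
    }
    z
  })
  z_dna <- with_seed(derive_seed(config$seed, "dna_latent"), {
    0.8 * z_rna + 0.6 * matrix(stats::rnorm(n * length(taxa)), n,
                               length(taxa), dimnames = dimnames(z_rna))
  })

  close_table <- function(z, role, seed_tag) {
    mu <- stats::setNames(c(rep(log(0.04), k), rep(log(2e-5), nd)), taxa)
    e <- exp(sweep(0.4 * z, 2L, mu, "+"))
    drop_mask <- with_seed(derive_seed(config$seed, seed_tag), {
      matrix(stats::runif(n * length(taxa)) < 0.65, n, length(taxa)) &
        matrix(rep(taxa %in% distr, each = n), n, length(taxa))
    })
    e[drop_mask] <- 0
    remainder <- 0.35  # latent mass of the non-modeled community
    rel <- e / (rowSums(e) + remainder)
    ft <- feature_table(rel, data.frame(
      variable = taxa, role = role, tier = unname(taxon_tiers),
      mechanism = "other", stringsAsFactors = FALSE))
    ft
  }
  dna <- close_table(z_dna, "taxon_dna", "dna_dropout")
  rna <- close_table(z_rna, "taxon_rna", "rna_dropout")

  env_names <- c("ch4_production", "acetate", "propionate", "ethanol",
                 "cod_removal", "coulombic_efficiency", "ph", "biogas_rate",
                 "toc")[seq_len(config$n_env)]
  w_ch4 <- stats::setNames(numeric(length(taxa)), taxa)
  if (is.null(ch4_weights)) {
    w_ch4[meth] <- config$env_effect
    w_ch4[geo] <- config$env_effect / 2
  } else {
    unknown <- setdiff(names(ch4_weights), taxa)
    if (length(unknown)) stop("ch4_weights name unknown taxa")
    w_ch4[names(ch4_weights)] <- ch4_weights
  }
  env <- with_seed(derive_seed(config$seed, "environment"), {
    m <- matrix(stats::rnorm(n * length(env_names), 0, config$noise_sd), n,
                length(env_names),
                dimnames = list(rownames(z_rna), env_names))
    m[, 1L] <- m[, 1L] + as.vector(z_rna %*% w_ch4)
    if (length(env_names) > 1L) {
      # each further variable tracks a rotating subset of fermenter taxa
      for (j in seq(2L, length(env_names))) {
        drv <- core[(j - 2L) %% k + 1L]
        m[, j] <- m[, j] + config$env_effect * z_rna[, drv]
      }
    }
    m
  })
  env_ft <- feature_table(env, data.frame(
    variable = env_names,
    role = c("output", rep("environment", length(env_names) - 1L)),
    tier = c("output", rep("environment", length(env_names) - 1L)),
    mechanism = "other", stringsAsFactors = FALSE))

  list(dna = dna, rna = rna, environment = env_ft, core = core,
       taxon_tiers = taxon_tiers)
}

#' Simulate a read-count fixture for RPKM computation
#'
#' Integer read counts per gene and sample with recorded gene lengths (bp)
#' and per-sample mapped-read totals (the library size is the mapped count
#' plus an unassigned remainder, so the per-sample sum of gene counts never
#' exceeds it).
#'
#' @param config a `scenario_config` (`n_genes`, `mean_gene_length`,
#'   `mean_depth` and `seed` are used).
#' @return list with `counts` (samples x genes integer matrix),
#'   `gene_lengths` (named, bp) and `library_sizes` (named, reads).
#' @export
simulate_counts <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_samples
  g <- config$n_genes
  genes <- sprintf("gene_%02d", seq_len(g))
  samples <- sprintf("s%02d", seq_len(n))
  with_seed(derive_seed(config$seed, "counts"), {
    lengths <- stats::setNames(
      round(stats::runif(g, 0.25, 2.5) * config$mean_gene_length), genes)
    abundance <- stats::rlnorm(g, meanlog = 0, sdlog = 1)
    depth <- stats::rpois(n, config$mean_depth)
    lam <- outer(depth / config$mean_depth,
                 abundance * lengths / sum(abundance * lengths)) *
      0.5 * config$mean_depth
    counts <- matrix(stats::rpois(n * g, lam), n, g,
                     dimnames = list(samples, genes))
    libs <- stats::setNames(rowSums(counts) +
                              stats::rpois(n, 0.5 * config$mean_depth),
                            samples)
    list(counts = counts, gene_lengths = lengths, library_sizes = libs)
  })
}
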