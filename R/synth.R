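#' @title Synthetic extreme-phenotype study generator
#'
#' @description
#' Generates a full synthetic study with the statistical structure the
#' analysis assumes: a population with rare regulatory variants that
#' multiply promoter activity (some down, some up, some not at all),
#' lognormal plasma enzyme (EL) concentrations driven by summed
#' log-activity of carried variants, a continuous trait (HDL-C) negatively
#' coupled to EL, and cohorts ascertained from the trait's upper and lower
#' percentile tails. Reporter plates, a two-locus genotype pair at a target
#' r-squared, and per-individual phenotype tables are generated alongside,
#' so every pipeline stage can run without external data. The generator is
#' also the engine for power and type-I-error studies.
#'
#' @name synth
NULL

#' Build a simulation configuration
#'
#' Defaults mirror the dimensions of the motivating study: a population of
#' 10,000, tail cohorts of 195 (trait >= 95th percentile) and 193
#' (<= 25th percentile, above a floor of 20 trait units), 17 rare variants
#' in a 4:8:5 decrease/null/increase mix, 6 assay replicates per construct,
#' and a two-locus pair at MAFs 0.278/0.279 with target r2 = 0.8.
#'
#' @param seed Integer RNG seed (required for reproducibility).
#' @param population_n Simulated population size.
#' @param n_rare_variants Number of rare variants.
#' @param carrier_freq_range Per-variant carrier (heterozygote) frequency
#'   range; frequencies are drawn uniformly within it.
#' @param direction_mix Named proportions of `decrease`, `null`,
#'   `increase` variants (must sum to 1; converted to exact counts).
#' @param effect_decrease,effect_increase Multiplicative relative promoter
#'   activity of functional variants (wild type = 1).
#' @param el_coupling Slope of log-EL on summed carried log-activity
#'   (1 = expression changes carry through to enzyme proportionally;
#'   0 gives the no-association null while keeping assay directions).
#' @param el_base Median plasma EL in ng/mL.
#' @param el_sdlog Lognormal SD of EL on the log scale.
#' @param hdl_mean Population trait mean (mg/dL).
#' @param hdl_coupling Trait decrease per population SD of EL (mg/dL).
#' @param noise_sd Residual trait SD (mg/dL).
#' @param hi_percentile,lo_percentile Ascertainment bounds (fractions).
#' @param trait_floor Individuals below this trait value are excluded from
#'   the low cohort (screens out likely monogenic outliers).
#' @param cohort_n Named sizes of the `high` and `low` cohorts.
#' @param assay_replicates Wells per construct per plate.
#' @param assay_cv Coefficient of variation of well readings.
#' @param assay_experiments Number of replicate plates.
#' @param ld_pair Named vector `maf1`, `maf2`, `target_r2` for the
#'   two-locus pair.
#' @param ld_n Individuals genotyped for the pair.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       population_n = 10000L,
                       n_rare_variants = 17L,
                       carrier_freq_range = c(0.001, 0.004),
                       direction_mix = c(decrease = 4, null = 8, increase = 5) / 17,
                       effect_decrease = 0.5,
                       effect_increase = 1.5,
                       el_coupling = 1,
                       el_base = 500,
                       el_sdlog = 0.65,
                       hdl_mean = 55,
                       hdl_coupling = 15,
                       noise_sd = 8,
                       hi_percentile = 0.95,
                       lo_percentile = 0.25,
                       trait_floor = 20,
                       cohort_n = c(high = 195L, low = 193L),
                       assay_replicates = 6L,
                       assay_cv = 0.1,
                       assay_experiments = 3L,
                       ld_pair = c(maf1 = 0.278, maf2 = 0.279, target_r2 = 0.8),
                       ld_n = 761L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$direction_mix) - 1) > 1e-8)
    stop("direction_mix must sum to 1")
  if (!all(c("decrease", "null", "increase") %in% names(cfg$direction_mix)))
    stop("direction_mix must name decrease, null and increase")
  if (cfg$hi_percentile <= 0.5 || cfg$lo_percentile >= 0.5)
    stop("percentile bounds inconsistent with extreme directions")
  if (any(cfg$carrier_freq_range <= 0) || any(cfg$carrier_freq_range >= 1))
    stop("carrier frequencies must lie in (0, 1)")
  if (diff(cfg$carrier_freq_range) < 0) stop("invalid carrier_freq_range")
  if (!all(c("high", "low") %in% names(cfg$cohort_n)))
    stop("cohort_n must name high and low")
  class(cfg) <- "sim_config"
  cfg
}

# exact direction counts from proportions (largest-remainder rounding)
direction_counts <- function(mix, v) {
  raw <- mix * v
  counts <- floor(raw)
  rem <- v - sum(counts)
  if (rem > 0) {
    order_idx <- order(raw - counts, decreasing = TRUE)
    counts[order_idx[seq_len(rem)]] <- counts[order_idx[seq_len(rem)]] + 1
  }
  counts
}

# core generative model: population genotypes -> expression -> EL -> trait
# -> tail ascertainment. Consumes the current RNG stream.
sim_core <- function(cfg) {
  v <- cfg$n_rare_variants
  n <- cfg$population_n
  freqs <- stats::runif(v, cfg$carrier_freq_range[1], cfg$carrier_freq_range[2])
  counts <- direction_counts(cfg$direction_mix[c("decrease", "null", "increase")], v)
  directions <- rep(c("decrease", "null", "increase"), counts)
  activity <- ifelse(directions == "decrease", cfg$effect_decrease,
                     ifelse(directions == "increase", cfg$effect_increase, 1))
  G <- matrix(stats::rbinom(n * v, 1L, rep(freqs, each = n)), nrow = n)
  log_el <- log(cfg$el_base) +
    cfg$el_coupling * as.numeric(G %*% log(activity)) +
    stats::rnorm(n, 0, cfg$el_sdlog)
  el <- exp(log_el)
  z_el <- (el - mean(el)) / stats::sd(el)
  hdl <- cfg$hdl_mean - cfg$hdl_coupling * z_el + stats::rnorm(n, 0, cfg$noise_sd)
  hi_thr <- stats::quantile(hdl, cfg$hi_percentile, names = FALSE)
  lo_thr <- stats::quantile(hdl, cfg$lo_percentile, names = FALSE)
  hi_pool <- which(hdl >= hi_thr)
  lo_pool <- which(hdl <= lo_thr & hdl >= cfg$trait_floor)
  if (length(hi_pool) < cfg$cohort_n["high"] ||
      length(lo_pool) < cfg$cohort_n["low"])
    stop("requested cohort size exceeds the available trait tail")
  hi_idx <- sort(sample(hi_pool, cfg$cohort_n["high"]))
  lo_idx <- sort(sample(lo_pool, cfg$cohort_n["low"]))
  list(G = G, freqs = freqs, directions = directions, activity = activity,
       el = el, hdl = hdl, hi_idx = hi_idx, lo_idx = lo_idx)
}

sim_variant_ids <- function(v) sprintf("sv%02d", seq_len(v))

#' Simulate a complete synthetic study
#'
#' Runs the generative model, ascertains the two cohorts, and assembles
#' every input the pipeline consumes: a variant catalog with per-cohort
#' carrier counts, a per-individual carrier table, reporter-assay wells
#' (one plate per experiment, with wild-type, empty-vector and variant
#' constructs), a two-locus genotype pair, and per-individual phenotypes.
#' Fully deterministic given the config (including its seed).
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_study` with elements `config`,
#'   `truth` (per-variant frequency, direction, activity), `catalog`,
#'   `cohorts`, `carriers`, `assay`, `genotype_pair` (long genotypes),
#'   `pair_table` (3x3 counts), `phenotypes`, and `population`
#'   (genotype matrix plus EL/HDL vectors).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  core <- sim_core(config)
  v <- config$n_rare_variants
  ids <- sim_variant_ids(v)
  cohorts <- data.frame(
    name = c("HIGH", "LOW"),
    n_individuals = as.integer(config$cohort_n[c("high", "low")]),
    extreme = c("high", "low"),
    percentile_bound = c(config$hi_percentile, config$lo_percentile) * 100,
    trait_floor = c(NA_real_, config$trait_floor),
    stringsAsFactors = FALSE)
  cohorts <- validate_cohorts(cohorts)

  member <- data.frame(
    individual_id = sprintf("S%05d", c(core$hi_idx, core$lo_idx)),
    cohort = rep(c("HIGH", "LOW"), times = c(length(core$hi_idx),
                                             length(core$lo_idx))),
    idx = c(core$hi_idx, core$lo_idx),
    stringsAsFactors = FALSE)

  # catalog: per-cohort heterozygote counts among sampled individuals;
  # synthetic positions spread over the sequenced region
  positions <- as.integer(round(seq(-1700, 240, length.out = v)))
  positions[positions == 0L] <- 1L
  Gh <- core$G[core$hi_idx, , drop = FALSE]
  Gl <- core$G[core$lo_idx, , drop = FALSE]
  catalog <- data.frame(
    variant_id = rep(ids, 2),
    position = rep(positions, 2),
    ref = "A", alt = "G",
    cohort = rep(c("HIGH", "LOW"), each = v),
    n_het = c(colSums(Gh), colSums(Gl)),
    n_hom_minor = 0L,
    stringsAsFactors = FALSE)
  catalog <- validate_catalog(catalog, cohorts)

  inc <- which(rbind(Gh, Gl) == 1L, arr.ind = TRUE)
  carriers <- data.frame(
    individual_id = member$individual_id[inc[, 1]],
    cohort = member$cohort[inc[, 1]],
    variant_id = ids[inc[, 2]],
    stringsAsFactors = FALSE)
  carriers <- carriers[order(carriers$individual_id, carriers$variant_id), ]
  rownames(carriers) <- NULL
  class(carriers) <- c("carrier_table", "data.frame")

  truth <- data.frame(variant_id = ids, carrier_freq = core$freqs,
                      direction = core$directions, activity = core$activity,
                      stringsAsFactors = FALSE)

  assay <- simulate_assay(truth, config)

  pair <- simulate_two_locus(config$ld_pair["maf1"], config$ld_pair["maf2"],
                             config$ld_pair["target_r2"], config$ld_n)

  phenotypes <- data.frame(
    individual_id = member$individual_id,
    cohort = member$cohort,
    trait = core$hdl[member$idx],
    el = core$el[member$idx],
    stringsAsFactors = FALSE)

  structure(list(config = config, truth = truth, catalog = catalog,
                 cohorts = cohorts, carriers = carriers, assay = assay,
                 genotype_pair = pair$genotypes, pair_table = pair$table,
                 phenotypes = phenotypes,
                 population = list(G = core$G, el = core$el,
                                   hdl = core$hdl, hi_idx = core$hi_idx,
                                   lo_idx = core$lo_idx)),
            class = "synthetic_study")
}

# reporter plates: one plate per experiment holding WT, empty-vector and
# all variant constructs; well noise is lognormal with the configured CV
simulate_assay <- function(truth, cfg) {
  sdlog <- sqrt(log(1 + cfg$assay_cv^2))
  constructs <- c("WT", "empty_vector", truth$variant_id)
  activity <- c(1, 1 / 31.9, truth$activity)   # empty vector ~32-fold below WT
  reps <- cfg$assay_replicates
  do.call(rbind, lapply(seq_len(cfg$assay_experiments), function(e) {
    k <- length(constructs) * reps
    renilla <- stats::rlnorm(k, log(2e5), 0.2)
    true_ratio <- rep(activity, each = reps)
    firefly <- renilla * 0.5 * true_ratio * stats::rlnorm(k, 0, sdlog)
    data.frame(plate_id = sprintf("E%d", e),
               construct = rep(constructs, each = reps),
               firefly = firefly, renilla = renilla,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate two-locus genotypes at a target r-squared
#'
#' Draws `2n` haplotypes from the four-haplotype distribution whose allele
#' frequencies are the given MAFs and whose D is implied by `target_r2`
#' (positive D: minor alleles co-occur), then pairs them at random into
#' diploid genotypes.
#'
#' @param maf1,maf2 Minor allele frequencies at the two loci.
#' @param target_r2 Desired squared correlation of the haplotype alleles.
#' @param n Number of diploid individuals.
#' @param seed Optional seed; when NULL the current RNG stream is used
#'   (so the call composes deterministically inside [simulate_study()]).
#' @return List: `table` (3x3 genotype counts, rows = minor-allele copies
#'   at locus 1), `genotypes` (long data.frame `individual_id`,
#'   `variant_id`, `genotype`), `haplotype_probs`.
#' @export
simulate_two_locus <- function(maf1, maf2, target_r2, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  maf1 <- unname(maf1); maf2 <- unname(maf2); target_r2 <- unname(target_r2)
  if (maf1 <= 0 || maf1 >= 1 || maf2 <= 0 || maf2 >= 1)
    stop("MAFs must lie strictly in (0, 1)")
  if (target_r2 < 0 || target_r2 > 1) stop("target_r2 must lie in [0, 1]")
  denom <- maf1 * (1 - maf1) * maf2 * (1 - maf2)
  d_max <- min(maf1 * (1 - maf2), (1 - maf1) * maf2)
  r2_max <- d_max^2 / denom
  if (target_r2 > r2_max + 1e-12)
    stop(sprintf(
      "target r2 %.3f not attainable for MAFs %.3f/%.3f (maximum %.4f)",
      target_r2, maf1, maf2, r2_max))
  D <- sqrt(target_r2 * denom)
  probs <- c(AB = maf1 * maf2 + D, Ab = maf1 * (1 - maf2) - D,
             aB = (1 - maf1) * maf2 - D, ab = (1 - maf1) * (1 - maf2) + D)
  probs <- pmax(probs, 0); probs <- probs / sum(probs)
  hap <- sample.int(4, 2 * n, replace = TRUE, prob = probs)
  h1 <- hap[seq_len(n)]; h2 <- hap[n + seq_len(n)]
  # haplotypes 1..4 = AB, Ab, aB, ab; minor-allele copies per locus
  a_copies <- (h1 <= 2) + (h2 <= 2)
  b_copies <- (h1 %in% c(1, 3)) + (h2 %in% c(1, 3))
  tab <- table(factor(a_copies, levels = 0:2), factor(b_copies, levels = 0:2))
  genotypes <- data.frame(
    individual_id = rep(sprintf("G%05d", seq_len(n)), 2),
    variant_id = rep(c("snpA", "snpB"), each = n),
    genotype = c(a_copies, b_copies),
    stringsAsFactors = FALSE)
  list(table = unclass(tab), genotypes = genotypes, haplotype_probs = probs)
}

#' Simulate a genotype with an additive lognormal trait effect
#'
#' Emulates a plasma-protein association cohort: Hardy-Weinberg genotypes
#' at the given MAF and a lognormal trait whose log-mean shifts by
#' `beta_log` per minor-allele copy.
#'
#' @param n Individuals.
#' @param maf Minor allele frequency.
#' @param beta_log Additive effect on the log-trait per allele copy.
#' @param base Median trait at genotype 0.
#' @param sdlog Residual SD on the log scale.
#' @param seed Optional seed (NULL = current stream).
#' @return data.frame with `genotype` (0/1/2) and `trait`.
#' @export
simulate_genotype_trait <- function(n, maf, beta_log, base = 500,
                                    sdlog = 0.65, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rbinom(n, 2L, maf)
  trait <- exp(log(base) + beta_log * g + stats::rnorm(n, 0, sdlog))
  data.frame(genotype = g, trait = trait)
}

#' Write a synthetic study to a directory of pipeline-ready TSV files
#'
#' Emits `cohorts.tsv`, `variants.tsv`, `carriers.tsv`, `assay.tsv`,
#' `genotypes.tsv`, `phenotypes.tsv` and `calls_truth.tsv` (the generating
#' directions, usable as functional calls when the assay stage is
#' skipped). Byte-identical across runs for the same config.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    w(as.data.frame(study$cohorts), "cohorts.tsv"),
    w(as.data.frame(study$catalog)[, c("variant_id", "position", "ref", "alt",
                                       "cohort", "n_het", "n_hom_minor")],
      "variants.tsv"),
    w(as.data.frame(study$carriers), "carriers.tsv"),
    w(study$assay, "assay.tsv"),
    w(study$genotype_pair, "genotypes.tsv"),
    w(study$phenotypes, "phenotypes.tsv"),
    w(data.frame(variant_id = study$truth$variant_id,
                 direction = study$truth$direction,
                 relative_activity = study$truth$activity,
                 p_value = ifelse(study$truth$direction == "null", 1, 0)),
      "calls_truth.tsv"))
  invisible(paths)
}

#' Power and type-I-error study for the burden tests
#'
#' Repeatedly simulates the generative model and records, for each
#' requested test, the fraction of replicates with p below `alpha`.
#' Directional tests use the true simulated directions (the question being
#' the value of direction information, not assay noise). Under a config
#' with `el_coupling = 0` the rejection rates estimate type-I error; under
#' an effect config they estimate power.
#'
#' @param config A [sim_config()]; its `seed` is ignored in favour of
#'   `seed` below.
#' @param tests Subset of `"cast"`, `"cast_decrease"`, `"cast_increase"`,
#'   `"cast_decrease_exclusive"`, `"cast_increase_exclusive"`,
#'   `"weighted_sum"`, `"c_alpha"`.
#' @param n_sims Number of replicates.
#' @param alpha Rejection threshold.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param n_permutations Permutations for the permutation-based
#'   comparators (default 500: ample resolution around alpha = 0.05 while
#'   keeping replicate studies fast).
#' @return data.frame with one row per test: rejection count, rate, and
#'   exact binomial 95% CI.
#' @export
power_study <- function(config, tests = c("cast", "cast_decrease",
                                          "cast_increase", "weighted_sum",
                                          "c_alpha"),
                        n_sims = 500L, alpha = 0.05, seed = 1L,
                        n_permutations = 500L) {
  stopifnot(inherits(config, "sim_config"))
  known <- c("cast", "cast_decrease", "cast_increase",
             "cast_decrease_exclusive", "cast_increase_exclusive",
             "weighted_sum", "c_alpha")
  bad <- setdiff(tests, known)
  if (length(bad) > 0) stop("unknown test(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  sim_seeds <- sample.int(2^31 - 2, 2 * n_sims)
  rej <- stats::setNames(integer(length(tests)), tests)
  for (i in seq_len(n_sims)) {
    set.seed(sim_seeds[i])
    core <- sim_core(config)
    Gh <- core$G[core$hi_idx, , drop = FALSE]
    Gl <- core$G[core$lo_idx, , drop = FALSE]
    n_hi <- nrow(Gh); n_lo <- nrow(Gl)
    cast_p <- function(cols) {
      if (length(cols) == 0) return(1)
      a <- sum(rowSums(Gh[, cols, drop = FALSE]) > 0)
      c_ <- sum(rowSums(Gl[, cols, drop = FALSE]) > 0)
      if (a + c_ == 0) return(1)
      fisher_exact(c(a, n_hi - a, c_, n_lo - c_))
    }
    for (tn in tests) {
      p <- switch(tn,
        cast = cast_p(seq_along(core$directions)),
        cast_decrease = cast_p(which(core$directions == "decrease")),
        cast_increase = cast_p(which(core$directions == "increase")),
        cast_decrease_exclusive = {
          cols <- which(core$directions == "decrease")
          both <- colSums(Gh[, cols, drop = FALSE]) > 0 &
                  colSums(Gl[, cols, drop = FALSE]) > 0
          cast_p(cols[!both])
        },
        cast_increase_exclusive = {
          cols <- which(core$directions == "increase")
          both <- colSums(Gh[, cols, drop = FALSE]) > 0 &
                  colSums(Gl[, cols, drop = FALSE]) > 0
          cast_p(cols[!both])
        },
        weighted_sum = weighted_sum_test(
          rbind(Gh, Gl), rep(c(TRUE, FALSE), c(n_hi, n_lo)),
          n_permutations = n_permutations,
          seed = sim_seeds[n_sims + i])$p_value,
        c_alpha = c_alpha_test(
          rbind(Gh, Gl), rep(c(TRUE, FALSE), c(n_hi, n_lo)),
          n_permutations = n_permutations,
          seed = sim_seeds[n_sims + i])$p_value)
      if (p < alpha) rej[tn] <- rej[tn] + 1L
    }
  }
  out <- data.frame(test = tests, n_sims = n_sims, rejections = unname(rej),
                    rate = unname(rej) / n_sims, stringsAsFactors = FALSE)
  ci <- t(vapply(out$rejections,
                 function(x) stats::binom.test(x, n_sims)$conf.int,
                 numeric(2)))
  out$ci_lower <- ci[, 1]
  out$ci_upper <- ci[, 2]
  out
}
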