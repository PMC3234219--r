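#' @title Pipeline orchestration and the bundled-study reproduction
#' @name pipeline
NULL

#' Path to a bundled fixture file
#'
#' The package ships the published study's variant catalog, cohort
#' definitions, per-individual carrier assignments (synthetic individual
#' ids, counts faithful to the published totals including the three
#' dual-carriers) and per-variant functional direction calls (directions
#' transcribed from the publication; activity/p numerics are synthetic
#' placeholders).
#'
#' @param file File name under `extdata/`; with no argument, lists the
#'   available fixtures.
#' @return Absolute path (or vector of file names).
#' @export
lipg_fixture <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "regulaburden")))
  path <- system.file("extdata", file, package = "regulaburden")
  if (!nzchar(path)) stop("no bundled fixture named '", file, "'")
  path
}

#' One-command reproduction of the bundled burden analysis
#'
#' Loads the bundled fixtures and runs the full collapsing analysis:
#' undirected CAST, both direction-stratified tests, and both exclusive
#' direction-stratified tests. The result is invariant to the row order of
#' the fixture files and byte-identical across runs.
#'
#' @param out_dir Optional directory; when given, the report is written as
#'   `burden_report.tsv` plus a JSON summary `burden_report.json`.
#' @return data.frame of class `burden_report` with one row per test
#'   (`test`, `direction`, `exclusive`, `carriers_high`, `carriers_low`,
#'   `n_variants_used`, `p_value`), with a `counts` attribute holding the
#'   catalog accounting (total variants, rare variants, rare private to
#'   each cohort, distinct carriers per cohort and overall).
#' @export
reproduce_lipg <- function(out_dir = NULL) {
  cohorts <- load_cohorts(lipg_fixture("lipg_cohorts.tsv"))
  catalog <- load_catalog(lipg_fixture("lipg_variants.tsv"), cohorts)
  carriers <- load_carriers(lipg_fixture("lipg_carriers.tsv"),
                            catalog = catalog, cohorts = cohorts)
  calls <- load_functional_calls(lipg_fixture("lipg_functional_calls.tsv"))
  results <- list(
    cast(catalog, carriers, cohorts),
    directional_cast(catalog, carriers, calls, "decrease", FALSE, cohorts),
    directional_cast(catalog, carriers, calls, "increase", FALSE, cohorts),
    directional_cast(catalog, carriers, calls, "decrease", TRUE, cohorts),
    directional_cast(catalog, carriers, calls, "increase", TRUE, cohorts))
  report <- do.call(rbind, lapply(results, function(r) {
    data.frame(test = r$test_name, direction = r$direction,
               exclusive = r$exclusive,
               carriers_high = r$table[1, 1], carriers_low = r$table[2, 1],
               n_variants_used = length(r$variants_used),
               p_value = r$p_value, stringsAsFactors = FALSE)
  }))
  attr(report, "counts") <- catalog_accounting(catalog, carriers, cohorts)
  class(report) <- c("burden_report", "data.frame")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(report, file.path(out_dir, "burden_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(report = report, counts = attr(report, "counts")),
      file.path(out_dir, "burden_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# catalog/carrier bookkeeping used in the reproduction report
catalog_accounting <- function(catalog, carriers, cohorts) {
  rare <- unique(catalog$variant_id[catalog$freq_class == "rare"])
  high_name <- cohorts$name[cohorts$extreme == "high"]
  low_name <- cohorts$name[cohorts$extreme == "low"]
  per_variant_cohorts <- vapply(rare, function(v) {
    rows <- catalog$variant_id == v & (catalog$n_het + catalog$n_hom_minor) > 0
    paste(sort(unique(catalog$cohort[rows])), collapse = "+")
  }, character(1))
  kh <- count_distinct_carriers(carriers, rare, high_name)
  kl <- count_distinct_carriers(carriers, rare, low_name)
  list(n_variants_total = length(unique(catalog$variant_id)),
       n_rare_variants = length(rare),
       n_rare_high_only = sum(per_variant_cohorts == high_name),
       n_rare_low_only = sum(per_variant_cohorts == low_name),
       n_rare_both = sum(grepl("\\+", per_variant_cohorts)),
       carriers_high = kh,
       carriers_low = kl,
       carriers_total = kh + kl)
}

#' Run the staged analysis pipeline on a directory of inputs
#'
#' Stages run in order: catalog (always), assay (when `assay.tsv` is
#' present, producing functional calls; otherwise `calls_truth.tsv` or
#' `functional_calls.tsv` is used), burden (undirected plus both
#' directional tests when calls are available), ld (when `genotypes.tsv`
#' is present), assoc (when `phenotypes.tsv` and `genotypes.tsv` are
#' present). A manifest with input digests, package version and per-stage
#' status is written alongside the outputs; any stage error aborts the run
#' with the stage named.
#'
#' @param input_dir Directory with `cohorts.tsv` + `variants.tsv` +
#'   `carriers.tsv`, and optional stage inputs as above.
#' @param out_dir Output directory.
#' @param alpha Significance level for assay direction calls.
#' @return The manifest, invisibly; outputs are written to `out_dir`.
#' @export
run_pipeline <- function(input_dir, out_dir, alpha = 0.05) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  in_file <- function(f) file.path(input_dir, f)
  have <- function(f) file.exists(in_file(f))
  manifest <- list(package_version = as.character(utils::packageVersion("regulaburden")),
                   input_dir = normalizePath(input_dir),
                   inputs = list(), stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- "ok"
    res
  }
  for (f in dir(input_dir, pattern = "\\.tsv$"))
    manifest$inputs[[f]] <- unname(tools::md5sum(in_file(f)))

  cohorts <- stage("catalog", {
    ch <- load_cohorts(in_file("cohorts.tsv")); ch
  })
  catalog <- stage("catalog", load_catalog(in_file("variants.tsv"), cohorts))
  carriers <- stage("catalog",
                    load_carriers(in_file("carriers.tsv"), catalog, cohorts))

  calls <- NULL
  if (have("assay.tsv")) {
    calls <- stage("assay", {
      cl <- call_variants(load_assay(in_file("assay.tsv")), alpha = alpha)
      save_functional_calls(cl, file.path(out_dir, "functional_calls.tsv"))
      cl
    })
  } else if (have("functional_calls.tsv")) {
    calls <- stage("assay", load_functional_calls(in_file("functional_calls.tsv")))
  } else if (have("calls_truth.tsv")) {
    calls <- stage("assay", load_functional_calls(in_file("calls_truth.tsv")))
  }

  burden <- stage("burden", {
    res <- list(cast(catalog, carriers, cohorts))
    if (!is.null(calls)) {
      res <- c(res, list(
        directional_cast(catalog, carriers, calls, "decrease", FALSE, cohorts),
        directional_cast(catalog, carriers, calls, "increase", FALSE, cohorts),
        directional_cast(catalog, carriers, calls, "decrease", TRUE, cohorts),
        directional_cast(catalog, carriers, calls, "increase", TRUE, cohorts)))
    }
    df <- do.call(rbind, lapply(res, function(r)
      data.frame(test = r$test_name, direction = r$direction,
                 exclusive = r$exclusive, carriers_high = r$table[1, 1],
                 carriers_low = r$table[2, 1],
                 n_variants_used = length(r$variants_used),
                 p_value = r$p_value, stringsAsFactors = FALSE)))
    utils::write.table(df, file.path(out_dir, "burden_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    df
  })

  if (have("genotypes.tsv")) {
    stage("ld", {
      gt <- utils::read.delim(in_file("genotypes.tsv"),
                              stringsAsFactors = FALSE)
      wide <- split(gt, gt$variant_id)
      snps <- names(wide)
      if (length(snps) >= 2) {
        pairs <- utils::combn(snps, 2)
        ld <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
          a <- wide[[pairs[1, j]]]; b <- wide[[pairs[2, j]]]
          b <- b[match(a$individual_id, b$individual_id), ]
          s <- ld_from_genotypes(a$genotype, b$genotype)
          data.frame(snp1 = pairs[1, j], snp2 = pairs[2, j], D = s$D,
                     D_prime = s$D_prime, r2 = s$r2, n_used = s$n_used)
        }))
        utils::write.table(ld, file.path(out_dir, "ld_report.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }

  if (have("phenotypes.tsv")) {
    stage("assoc", {
      ph <- utils::read.delim(in_file("phenotypes.tsv"),
                              stringsAsFactors = FALSE)
      if ("el" %in% names(ph)) {
        # carrier burden (any rare variant) vs log plasma enzyme
        is_carrier <- ph$individual_id %in% carriers$individual_id
        if (stats::var(is_carrier * 1) > 0) {
          fit <- additive_regression(is_carrier * 1, ph$el, transform = "log")
          utils::write.table(
            data.frame(predictor = "rare_carrier", beta = fit$beta,
                       se = fit$se, p_value = fit$p_value, n = fit$n,
                       transform = fit$transform),
            file.path(out_dir, "assoc_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
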