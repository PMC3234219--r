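#' @title Variant catalog: data model and I/O
#'
#' @description
#' The catalog holds one row per variant x cohort with genotype counts for a
#' resequenced regulatory region. Positions are signed offsets from the
#' transcription start site (TSS): negative values lie in the upstream
#' promoter, positive values in the transcribed 5' UTR; position 0 is
#' disallowed by convention. Frequency classes follow the study design:
#' rare (MAF < 1%), common (MAF >= 5%), intermediate in between.
#'
#' @name catalog
NULL

#' Read a cohort definition table
#'
#' Cohorts are the two phenotypic-extreme sequencing arms of an
#' extreme-phenotype design (e.g. trait >= 95th percentile vs <= 25th
#' percentile).
#'
#' @param path TSV with columns `name`, `n_individuals`, `extreme`
#'   (`"high"`/`"low"`), `percentile_bound` (0-100), and optionally
#'   `trait_floor` (exclusion threshold in trait units; NA if none).
#' @return A data.frame of class `cohort_spec`.
#' @export
load_cohorts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("name", "n_individuals", "extreme", "percentile_bound")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("cohort table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!"trait_floor" %in% names(df)) df$trait_floor <- NA_real_
  validate_cohorts(df)
}

validate_cohorts <- function(df) {
  if (any(df$n_individuals <= 0))
    stop("cohort sizes must be positive")
  if (!all(df$extreme %in% c("high", "low")))
    stop("cohort 'extreme' must be \"high\" or \"low\"")
  bad <- (df$extreme == "high" & df$percentile_bound < 50) |
         (df$extreme == "low"  & df$percentile_bound > 50)
  if (any(bad))
    stop("percentile bound inconsistent with extreme direction for cohort(s): ",
         paste(df$name[bad], collapse = ", "))
  if (anyDuplicated(df$name))
    stop("duplicated cohort names")
  class(df) <- c("cohort_spec", "data.frame")
  df
}

#' Load a variant catalog from TSV
#'
#' One row per variant x cohort. Counts refer to the minor allele
#' (`n_het` heterozygous carriers, `n_hom_minor` minor-allele homozygotes).
#'
#' @param path TSV with columns `variant_id`, `position`, `ref`, `alt`,
#'   `cohort`, `n_het`, `n_hom_minor`.
#' @param cohorts A `cohort_spec` (see [load_cohorts()]); used to validate
#'   cohort labels and count bounds.
#' @param region Length-2 integer vector giving the sequenced region in
#'   TSS-relative coordinates; rows outside it are rejected. Override when
#'   the sequenced region differs from the default promoter + 5' UTR span.
#' @return data.frame of class `variant_catalog` with an added `freq_class`
#'   column computed over the combined sample (see [classify_frequency()]).
#' @export
load_catalog <- function(path, cohorts, region = c(-1755L, 252L)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(variant_id = "character",
                                         ref = "character",
                                         alt = "character"))
  req <- c("variant_id", "position", "ref", "alt", "cohort",
           "n_het", "n_hom_minor")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("variant table is missing required column(s): ",
         paste(miss, collapse = ", "))
  validate_catalog(df, cohorts, region = region)
}

validate_catalog <- function(df, cohorts, region = c(-1755L, 252L)) {
  bad_row <- function(i, why)
    stop(sprintf("variant table row %d (%s): %s", i, df$variant_id[i], why))
  for (i in seq_len(nrow(df))) {
    if (df$position[i] == 0L)
      bad_row(i, "position 0 is disallowed (TSS-relative convention)")
    if (df$position[i] < region[1] || df$position[i] > region[2])
      bad_row(i, sprintf("position outside sequenced region [%d, %d]",
                         region[1], region[2]))
    if (!nzchar(df$ref[i]) || !nzchar(df$alt[i]))
      bad_row(i, "empty allele")
    if (df$ref[i] == df$alt[i])
      bad_row(i, "ref and alt alleles identical")
    if (df$n_het[i] < 0 || df$n_hom_minor[i] < 0)
      bad_row(i, "negative genotype count")
    if (!df$cohort[i] %in% cohorts$name)
      bad_row(i, paste0("unknown cohort '", df$cohort[i], "'"))
    n_coh <- cohorts$n_individuals[match(df$cohort[i], cohorts$name)]
    if (df$n_het[i] + df$n_hom_minor[i] > n_coh)
      bad_row(i, "genotype counts exceed cohort size")
  }
  df$freq_class <- catalog_freq_class(df, cohorts)
  attr(df, "cohorts") <- cohorts
  class(df) <- c("variant_catalog", "data.frame")
  df
}

# combined-sample MAF per variant -> frequency class (default policy;
# per-cohort classification is available by subsetting first)
catalog_freq_class <- function(df, cohorts) {
  n_total <- sum(cohorts$n_individuals)
  cls <- character(nrow(df))
  for (v in unique(df$variant_id)) {
    rows <- df$variant_id == v
    maf <- compute_maf(sum(df$n_hom_minor[rows]), sum(df$n_het[rows]), n_total)
    cls[rows] <- classify_frequency(maf)
  }
  cls
}

#' Write a variant catalog back to TSV
#'
#' Round-trips with [load_catalog()] field-for-field (the derived
#' `freq_class` column is dropped on write).
#'
#' @param catalog A `variant_catalog`.
#' @param path Output TSV path.
#' @export
save_catalog <- function(catalog, path) {
  cols <- c("variant_id", "position", "ref", "alt", "cohort",
            "n_het", "n_hom_minor")
  utils::write.table(as.data.frame(catalog)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minor allele frequency from genotype counts
#'
#' Allele-based MAF: (2 x homozygote count + heterozygote count) over
#' 2 x cohort size. Vectorized.
#'
#' @param n_hom_minor Minor-allele homozygote count.
#' @param n_het Heterozygote count.
#' @param n_individuals Genotyped individuals.
#' @return Allele frequency in \[0, 1\]. Warns (does not error) if > 0.5,
#'   i.e. the labelled minor allele is actually major in this sample.
#' @examples
#' compute_maf(25, 96, 195)  # 0.3744
#' @export
compute_maf <- function(n_hom_minor, n_het, n_individuals) {
  if (any(n_hom_minor < 0) || any(n_het < 0) || any(n_individuals <= 0))
    stop("counts must be non-negative and cohort size positive")
  if (any(n_hom_minor + n_het > n_individuals))
    stop("genotype counts exceed number of individuals")
  maf <- (2 * n_hom_minor + n_het) / (2 * n_individuals)
  if (any(maf > 0.5))
    warning("computed frequency > 0.5: labelled minor allele is major here")
  maf
}

#' Classify a minor allele frequency
#'
#' @param maf Frequency in \[0, 1\] (vectorized).
#' @return `"rare"` (< 1%), `"common"` (>= 5%) or `"intermediate"`.
#' @export
classify_frequency <- function(maf) {
  if (any(maf < 0 | maf > 1)) stop("frequency outside [0, 1]")
  ifelse(maf < 0.01, "rare", ifelse(maf >= 0.05, "common", "intermediate"))
}

#' Load a per-individual carrier table
#'
#' Long format: one row per (individual, variant) incidence. Validates that
#' each individual belongs to exactly one cohort and, when a catalog is
#' given, that per-cohort carrier column sums match the catalog counts
#' (carriers = `n_het + n_hom_minor`).
#'
#' @param path TSV with columns `individual_id`, `cohort`, `variant_id`.
#' @param catalog Optional `variant_catalog` for cross-validation.
#' @param cohorts Optional `cohort_spec` for label validation.
#' @return data.frame of class `carrier_table`.
#' @export
load_carriers <- function(path, catalog = NULL, cohorts = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("individual_id", "cohort", "variant_id")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("carrier table is missing required column(s): ",
         paste(miss, collapse = ", "))
  validate_carriers(df, catalog = catalog, cohorts = cohorts)
}

validate_carriers <- function(df, catalog = NULL, cohorts = NULL) {
  per_ind <- unique(df[, c("individual_id", "cohort")])
  if (anyDuplicated(per_ind$individual_id))
    stop("individual(s) assigned to more than one cohort: ",
         paste(unique(per_ind$individual_id[duplicated(per_ind$individual_id)]),
               collapse = ", "))
  if (!is.null(cohorts) && !all(df$cohort %in% cohorts$name))
    stop("carrier table references unknown cohort(s)")
  if (!is.null(catalog)) {
    unknown <- setdiff(df$variant_id, catalog$variant_id)
    if (length(unknown) > 0)
      stop("carrier table references variant(s) absent from catalog: ",
           paste(unknown, collapse = ", "))
    obs <- stats::aggregate(list(n = df$individual_id),
                            by = list(variant_id = df$variant_id,
                                      cohort = df$cohort), FUN = length)
    for (i in seq_len(nrow(obs))) {
      j <- catalog$variant_id == obs$variant_id[i] &
           catalog$cohort == obs$cohort[i]
      expected <- if (any(j)) sum(catalog$n_het[j] + catalog$n_hom_minor[j]) else 0
      if (obs$n[i] != expected)
        stop(sprintf(
          "carrier count mismatch for %s in cohort %s: table has %d, catalog says %d",
          obs$variant_id[i], obs$cohort[i], obs$n[i], expected))
    }
  }
  class(df) <- c("carrier_table", "data.frame")
  df
}

#' Count distinct carriers of a variant subset within a cohort
#'
#' The de-duplication rule of collapsing tests: an individual carrying
#' several variants of the subset is counted once.
#'
#' @param carriers A `carrier_table`.
#' @param variant_subset Character vector of variant ids (may be empty).
#' @param cohort Cohort name.
#' @return Integer count of distinct carrier individuals.
#' @export
count_distinct_carriers <- function(carriers, variant_subset, cohort) {
  if (length(variant_subset) == 0) return(0L)
  unknown <- setdiff(variant_subset, unique(carriers$variant_id))
  # unknown ids are only an error if they are not merely absent from this
  # cohort; the caller validates subset membership against the catalog
  keep <- carriers$variant_id %in% variant_subset & carriers$cohort == cohort
  length(unique(carriers$individual_id[keep]))
}

#' Carrier counts per cohort for a variant subset
#'
#' @inheritParams count_distinct_carriers
#' @param cohorts A `cohort_spec`.
#' @return Named integer vector, one distinct-carrier count per cohort.
#' @export
carriers_by_cohort <- function(carriers, variant_subset, cohorts) {
  stats::setNames(
    vapply(cohorts$name,
           function(ch) count_distinct_carriers(carriers, variant_subset, ch),
           integer(1)),
    cohorts$name)
}
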