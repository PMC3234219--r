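#' @title Rare-variant collapsing (burden) tests
#'
#' @description
#' The cohort allelic sums test (CAST) collapses all rare variants in a
#' region: individuals carrying at least one qualifying variant are
#' "carriers", and carrier counts are compared between two phenotypic
#' cohorts with Fisher's exact test. The function-informed refinements
#' implemented here stratify the collapsed set by the experimentally
#' determined direction of effect on promoter activity
#' ([directional_cast()]) and optionally restrict to variants whose
#' carriers appear in only one cohort (the exclusivity filter).
#' Frequency-weighted sum and C-alpha comparator tests are included for
#' method comparison on individual-level genotypes.
#'
#' @name burden
NULL

#' Construct a 2x2 carrier contingency table
#'
#' Layout: row 1 = cohort 1 (carriers `a`, non-carriers `b`),
#' row 2 = cohort 2 (carriers `c`, non-carriers `d`).
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return 2x2 integer matrix of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("contingency table counts must be non-negative")
  if (any(counts != round(counts))) stop("contingency table counts must be integers")
  m <- matrix(as.integer(counts), nrow = 2, byrow = TRUE,
              dimnames = list(cohort = c("cohort1", "cohort2"),
                              status = c("carrier", "non_carrier")))
  class(m) <- c("contingency_table", class(m))
  m
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional test given both margins. Writing `N` for the total,
#' `n1` for the size of cohort 1 and `K` for the total carrier count, the
#' point probability of `k` carriers in cohort 1 is hypergeometric:
#' `P(k) = choose(n1, k) choose(N - n1, K - k) / choose(N, K)`.
#' One-sided p-values sum the requested tail; the two-sided p-value uses
#' the minimum-likelihood definition, summing `P(k)` over every `k` whose
#' point probability does not exceed `P(a)` up to a relative tie tolerance.
#'
#' @param x A `contingency_table`, a 2x2 matrix, or a length-4 vector
#'   `c(a, b, c, d)` read row-wise.
#' @param alternative `"two.sided"` (default), `"greater"` (cohort 1
#'   enriched for carriers) or `"less"`.
#' @param tie_tol Relative tolerance for counting equal point
#'   probabilities into the two-sided sum (guards against floating-point
#'   asymmetry in exactly symmetric tables).
#' @return The p-value. Degenerate margins (no carriers or no
#'   non-carriers anywhere, or an empty cohort) give p = 1 with a warning.
#' @examples
#' fisher_exact(c(16, 179, 9, 184))           # 0.2142
#' fisher_exact(c(6, 189, 0, 193))            # 0.0301
#' @export
fisher_exact <- function(x, alternative = c("two.sided", "greater", "less"),
                         tie_tol = 1e-7) {
  alternative <- match.arg(alternative)
  if (is.matrix(x)) x <- c(t(x))
  if (length(x) != 4) stop("expected a 2x2 table or 4 counts")
  if (any(x < 0)) stop("counts must be non-negative")
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  N <- a + b + c_ + d
  K <- a + c_          # total carriers
  n1 <- a + b          # cohort 1 size
  if (K == 0 || K == N || n1 == 0 || n1 == N) {
    warning("degenerate margins: p = 1")
    return(1)
  }
  support <- max(0, K - (N - n1)):min(K, n1)
  pk <- stats::dhyper(support, n1, N - n1, K)
  p_obs <- pk[match(a, support)]
  p <- switch(alternative,
    greater   = sum(pk[support >= a]),
    less      = sum(pk[support <= a]),
    two.sided = sum(pk[pk <= p_obs * (1 + tie_tol)])
  )
  min(p, 1)
}

new_burden_result <- function(test_name, direction, exclusive, table,
                              p_value, sidedness, variants_used,
                              degenerate = FALSE) {
  structure(list(test_name = test_name, direction = direction,
                 exclusive = exclusive, table = table, p_value = p_value,
                 sidedness = sidedness, variants_used = variants_used,
                 degenerate = degenerate),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("%s (direction = %s%s): carriers %d/%d vs %d/%d, p = %.4g%s\n",
              x$test_name, x$direction,
              if (isTRUE(x$exclusive)) ", exclusive" else "",
              x$table[1, 1], sum(x$table[1, ]),
              x$table[2, 1], sum(x$table[2, ]),
              x$p_value,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

# shared plumbing: carrier table -> 2x2 -> Fisher
collapse_and_test <- function(variants, carriers, cohorts, test_name,
                              direction, exclusive, alternative) {
  stopifnot(nrow(cohorts) == 2)
  # order cohorts high extreme first so "cohort 1" is reproducible
  cohorts <- cohorts[order(cohorts$extreme == "high", decreasing = TRUE), ]
  k <- carriers_by_cohort(carriers, variants, cohorts)
  tab <- contingency_table(k[1], cohorts$n_individuals[1] - k[1],
                           k[2], cohorts$n_individuals[2] - k[2])
  degenerate <- sum(k) == 0 || length(variants) == 0
  p <- if (degenerate) 1 else
    suppressWarnings(fisher_exact(tab, alternative = alternative))
  new_burden_result(test_name, direction, exclusive, tab, p,
                    if (alternative == "two.sided") "two" else "one",
                    variants, degenerate)
}

#' Cohort allelic sums test (CAST)
#'
#' Collapses all rare variants regardless of functional impact and compares
#' de-duplicated carrier counts between the two cohorts.
#'
#' @param catalog A `variant_catalog`.
#' @param carriers A `carrier_table` with individual-level incidence.
#' @param cohorts A `cohort_spec` with exactly two cohorts; the
#'   high-extreme cohort is row 1 of the resulting table.
#' @param alternative Passed to [fisher_exact()]; two-sided by default.
#' @return A `burden_result`.
#' @export
cast <- function(catalog, carriers, cohorts = attr(catalog, "cohorts"),
                 alternative = "two.sided") {
  rare <- unique(catalog$variant_id[catalog$freq_class == "rare"])
  collapse_and_test(rare, carriers, cohorts, "CAST", "any", FALSE,
                    alternative)
}

#' Direction-stratified (and optionally exclusive) CAST
#'
#' The function-informed modification of CAST: only rare variants whose
#' reporter-assay call matches `direction` are collapsed; variants called
#' `"null"` are discounted entirely (their carriers count as non-carriers).
#' With `exclusive = TRUE`, variants carried in both cohorts are dropped as
#' well, enriching for variants private to one phenotypic extreme. An
#' individual carrying variants of both directions legitimately contributes
#' to both directional tests.
#'
#' @inheritParams cast
#' @param calls A `functional_call` table covering every rare variant of
#'   the catalog (a missing call is a configuration error).
#' @param direction `"decrease"` or `"increase"`.
#' @param exclusive Apply the exclusivity filter?
#' @return A `burden_result`.
#' @export
directional_cast <- function(catalog, carriers, calls,
                             direction = c("decrease", "increase"),
                             exclusive = FALSE,
                             cohorts = attr(catalog, "cohorts"),
                             alternative = "two.sided") {
  direction <- match.arg(direction)
  rare <- unique(catalog$variant_id[catalog$freq_class == "rare"])
  missing_calls <- setdiff(rare, calls$variant_id)
  if (length(missing_calls) > 0)
    stop("no functional call for rare variant(s): ",
         paste(missing_calls, collapse = ", "))
  keep <- intersect(rare, calls$variant_id[calls$direction == direction])
  if (exclusive) {
    n_cohorts_with_carrier <- vapply(keep, function(v) {
      rows <- catalog$variant_id == v &
        (catalog$n_het + catalog$n_hom_minor) > 0
      length(unique(catalog$cohort[rows]))
    }, integer(1))
    keep <- keep[n_cohorts_with_carrier <= 1]
  }
  collapse_and_test(keep, carriers, cohorts,
                    if (exclusive) "directional CAST (exclusive)"
                    else "directional CAST",
                    direction, exclusive, alternative)
}

#' Frequency-weighted sum test
#'
#' Each variant is weighted by the inverse of its estimated standard
#' deviation in the control cohort, `w_v = sqrt(n_ctrl q_v (1 - q_v))` with
#' `q_v = (m_v + 1) / (2 n_ctrl + 2)` (minor-allele count `m_v` among
#' controls, with the usual pseudo-count). Each individual's score is the
#' weighted sum `sum_v g_iv / w_v`; the statistic is the rank sum of case
#' scores, with significance from label permutation.
#'
#' @param geno Integer matrix, individuals x variants, minor-allele counts
#'   0/1/2.
#' @param is_case Logical vector: TRUE for the "case" cohort (rank-sum
#'   group), FALSE for controls (weight-estimation group).
#' @param n_permutations Number of label permutations.
#' @param seed Required RNG seed for the permutation null.
#' @return List with `statistic` (observed rank sum), `p_value` computed as
#'   `(b + 1) / (n + 1)`, and `n_permutations`.
#' @export
weighted_sum_test <- function(geno, is_case, n_permutations = 10000L, seed) {
  if (missing(seed)) stop("seed is required for the permutation null")
  geno <- as.matrix(geno)
  if (ncol(geno) == 0 || sum(geno) == 0)
    return(list(statistic = NA_real_, p_value = 1,
                n_permutations = n_permutations))
  set.seed(seed)
  n <- nrow(geno)
  n_case <- sum(is_case)
  # weights depend on who the controls are, so they must be re-estimated
  # inside every permutation; freezing them breaks exchangeability and
  # inflates the type-I error
  rank_sum <- function(case_mask) {
    n_ctrl <- n - sum(case_mask)
    m_v <- colSums(geno) - colSums(geno[case_mask, , drop = FALSE])
    q_v <- (m_v + 1) / (2 * n_ctrl + 2)
    w_v <- sqrt(n_ctrl * q_v * (1 - q_v))
    score <- as.numeric(geno %*% (1 / w_v))
    sum(rank(score)[case_mask])
  }
  x_obs <- rank_sum(is_case)
  mask <- logical(n)
  perm <- vapply(seq_len(n_permutations), function(i) {
    mask[] <- FALSE
    mask[sample.int(n, n_case)] <- TRUE
    rank_sum(mask)
  }, numeric(1))
  p <- (sum(perm >= x_obs) + 1) / (n_permutations + 1)
  list(statistic = x_obs, p_value = p, n_permutations = n_permutations)
}

#' C-alpha test of carrier-count overdispersion
#'
#' For variant `v` with `n_v` carriers in total, of which `y_v` fall in
#' cohort 1 (sampling fraction `p0`), the statistic sums
#' `(y_v - n_v p0)^2 - n_v p0 (1 - p0)` over variants: it is large when
#' carriers of individual variants segregate to one cohort or the other
#' more than binomial sampling allows, regardless of which cohort. This
#' detects bidirectional effects that cancel in an undirected CAST.
#' Significance is by label permutation (the asymptotic null is unreliable
#' for variants observed only once).
#'
#' @param incidence Logical/0-1 matrix, individuals x variants (carrier
#'   incidence).
#' @param is_case Logical vector: TRUE for cohort 1.
#' @inheritParams weighted_sum_test
#' @return List with `statistic` (observed T), `p_value` = (b+1)/(n+1)
#'   one-sided for large T, and `n_permutations`.
#' @export
c_alpha_test <- function(incidence, is_case, n_permutations = 10000L, seed) {
  if (missing(seed)) stop("seed is required for the permutation null")
  incidence <- as.matrix(incidence) * 1
  carried <- colSums(incidence) > 0
  incidence <- incidence[, carried, drop = FALSE]
  if (ncol(incidence) == 0)
    return(list(statistic = NA_real_, p_value = 1,
                n_permutations = n_permutations))
  set.seed(seed)
  n <- nrow(incidence)
  n_case <- sum(is_case)
  p0 <- n_case / n
  n_v <- colSums(incidence)
  t_stat <- function(case_idx) {
    y_v <- colSums(incidence[case_idx, , drop = FALSE])
    sum((y_v - n_v * p0)^2 - n_v * p0 * (1 - p0))
  }
  t_obs <- t_stat(which(is_case))
  perm <- vapply(seq_len(n_permutations),
                 function(i) t_stat(sample.int(n, n_case)), numeric(1))
  p <- (sum(perm >= t_obs) + 1) / (n_permutations + 1)
  list(statistic = t_obs, p_value = p, n_permutations = n_permutations)
}
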