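#' @title Two-locus linkage disequilibrium from unphased genotypes
#'
#' @description
#' Haplotype frequencies for a pair of biallelic loci are estimated from
#' unphased diploid genotypes by expectation-maximization: only the double
#' heterozygote is phase-ambiguous, and its two phase configurations are
#' fractionally assigned at each E-step in proportion to their current
#' likelihood. From the converged frequencies the usual summaries D,
#' D' and r-squared are computed.
#'
#' @name ld
NULL

# genotype-class probabilities under random union of gametes.
# p = c(AB, Ab, aB, ab); returns 3x3 matrix indexed by copies of the
# minor allele at locus A (rows 0..2) and locus B (cols 0..2).
genotype_probs <- function(p) {
  pAB <- p[1]; pAb <- p[2]; paB <- p[3]; pab <- p[4]
  matrix(c(pab^2,           2 * paB * pab,               paB^2,
           2 * pAb * pab,   2 * (pAB * pab + pAb * paB), 2 * pAB * paB,
           pAb^2,           2 * pAB * pAb,               pAB^2),
         nrow = 3, byrow = TRUE)
}

ld_loglik <- function(p, g) {
  pr <- genotype_probs(p)
  sum(g[g > 0] * log(pr[g > 0]))
}

#' EM estimation of two-locus haplotype frequencies
#'
#' @param g 3x3 matrix of genotype counts: rows index copies of the minor
#'   allele at locus A (0, 1, 2), columns at locus B.
#' @param tol Convergence threshold on the maximum absolute frequency
#'   change between iterations.
#' @param max_iter Iteration cap; exceeding it is an error (with the
#'   final frequencies in the error message).
#' @param trace Record the log-likelihood after every M-step? (It is
#'   non-decreasing; useful for diagnostics.)
#' @return List of class `haplotype_freqs`: `p` (named frequencies
#'   `AB`, `Ab`, `aB`, `ab`, where upper case marks the minor allele),
#'   `log_likelihood`, `n_iterations`, `monomorphic` flag, and (when
#'   `trace`) `loglik_trace`.
#' @export
em_haplotype_freq <- function(g, tol = 1e-10, max_iter = 1000L,
                              trace = FALSE) {
  g <- as.matrix(g)
  if (!all(dim(g) == c(3, 3))) stop("expected a 3x3 genotype count table")
  if (any(g < 0)) stop("negative genotype counts")
  n <- sum(g)
  if (n == 0) stop("empty genotype table")
  # allele counts at each locus (minor-allele copies)
  nA <- sum(g * matrix(0:2, 3, 3))          # rows = copies at A
  nB <- sum(g * matrix(0:2, 3, 3, byrow = TRUE))
  pA <- nA / (2 * n); pB <- nB / (2 * n)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    out <- list(p = c(AB = pA * pB, Ab = pA * (1 - pB),
                      aB = (1 - pA) * pB, ab = (1 - pA) * (1 - pB)),
                log_likelihood = NA_real_, n_iterations = 0L,
                monomorphic = TRUE)
    class(out) <- "haplotype_freqs"
    return(out)
  }
  # unambiguous gamete contributions (everything but the double het)
  base_AB <- 2 * g[3, 3] + g[3, 2] + g[2, 3]
  base_Ab <- 2 * g[3, 1] + g[3, 2] + g[2, 1]
  base_aB <- 2 * g[1, 3] + g[1, 2] + g[2, 3]
  base_ab <- 2 * g[1, 1] + g[1, 2] + g[2, 1]
  n11 <- g[2, 2]
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  iter <- 0L
  ll_trace <- if (trace) numeric(0) else NULL
  repeat {
    iter <- iter + 1L
    cis <- p[1] * p[4]            # AB/ab phase
    trans <- p[2] * p[3]          # Ab/aB phase
    frac <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    counts <- c(base_AB + n11 * frac, base_Ab + n11 * (1 - frac),
                base_aB + n11 * (1 - frac), base_ab + n11 * frac)
    p_new <- counts / (2 * n)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (trace) ll_trace <- c(ll_trace, ld_loglik(p, g))
    if (delta < tol) break
    if (iter >= max_iter)
      stop(sprintf(
        "EM did not converge in %d iterations (last delta %.3g, freqs %s)",
        max_iter, delta, paste(signif(p, 6), collapse = "/")))
    if (n11 == 0) break           # no ambiguity: one M-step is exact
  }
  out <- list(p = stats::setNames(p, c("AB", "Ab", "aB", "ab")),
              log_likelihood = ld_loglik(p, g),
              n_iterations = iter, monomorphic = FALSE)
  if (trace) out$loglik_trace <- ll_trace
  class(out) <- "haplotype_freqs"
  out
}

#' LD summary statistics from haplotype frequencies
#'
#' `D = pAB - pA pB`; `r2 = D^2 / (pA (1-pA) pB (1-pB))`;
#' `D' = |D| / Dmax` with the standard direction-dependent `Dmax`.
#'
#' @param h A `haplotype_freqs` object, or a length-4 numeric vector of
#'   frequencies `(AB, Ab, aB, ab)`.
#' @return List of class `ld_stats`: `D`, `D_prime`, `r2`.
#' @export
ld_stats <- function(h) {
  p <- if (inherits(h, "haplotype_freqs")) h$p else h
  if (length(p) != 4 || any(p < -1e-12) || abs(sum(p) - 1) > 1e-8)
    stop("expected 4 non-negative haplotype frequencies summing to 1")
  pA <- p[1] + p[2]; pB <- p[1] + p[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("allele frequency 0 or 1: LD statistics undefined")
  D <- unname(p[1] - pA * pB)
  d_max <- if (D < 0) min(pA * pB, (1 - pA) * (1 - pB))
           else min(pA * (1 - pB), (1 - pA) * pB)
  out <- list(D = D,
              D_prime = if (d_max > 0) abs(D) / d_max else 0,
              r2 = unname(D^2 / (pA * (1 - pA) * pB * (1 - pB))))
  class(out) <- "ld_stats"
  out
}

#' Pairwise LD directly from genotype vectors
#'
#' Convenience wrapper: cross-tabulates two 0/1/2 genotype vectors
#' (dropping pairs with a missing value), runs the EM, and returns the LD
#' statistics. Returns `D = 0` with `r2 = NA` if either locus is
#' monomorphic.
#'
#' @param gA,gB Integer vectors of minor-allele counts (0/1/2, NA allowed).
#' @param ... Passed to [em_haplotype_freq()].
#' @return An `ld_stats` list with extra fields `n_used` (complete pairs)
#'   and `haplotypes` (the fitted `haplotype_freqs`).
#' @export
ld_from_genotypes <- function(gA, gB, ...) {
  keep <- !(is.na(gA) | is.na(gB))
  g <- table(factor(gA[keep], levels = 0:2), factor(gB[keep], levels = 0:2))
  h <- em_haplotype_freq(unclass(g), ...)
  if (h$monomorphic) {
    out <- list(D = 0, D_prime = NA_real_, r2 = NA_real_)
    class(out) <- "ld_stats"
  } else {
    out <- ld_stats(h)
  }
  out$n_used <- sum(keep)
  out$haplotypes <- h
  out
}
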