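# Independent oracles, deliberately implemented apart from the package code
# paths they validate.

# Fisher's exact test by direct enumeration of all tables with the observed
# margins, point probabilities from log-binomial coefficients.
fisher_enum_oracle <- function(a, b, c, d,
                               alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  N <- a + b + c + d
  K <- a + c
  n1 <- a + b
  ks <- max(0, K - (N - n1)):min(K, n1)
  logp <- lchoose(n1, ks) + lchoose(N - n1, K - ks) - lchoose(N, K)
  pk <- exp(logp)
  p_obs <- pk[ks == a]
  switch(alternative,
         greater = sum(pk[ks >= a]),
         less = sum(pk[ks <= a]),
         two.sided = sum(pk[pk <= p_obs * (1 + 1e-7)]))
}

# pooled-variance two-sample t-test, from first principles
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tstat, p = 2 * pt(abs(tstat), df = nx + ny - 2, lower.tail = FALSE))
}

# multinomial log-likelihood of a 3x3 genotype table given haplotype
# frequencies (AB, Ab, aB, ab); own formulas, not the package's
oracle_geno_loglik <- function(p, g) {
  pAB <- p[1]; pAb <- p[2]; paB <- p[3]; pab <- p[4]
  pr <- rbind(c(pab^2, 2 * paB * pab, paB^2),
              c(2 * pAb * pab, 2 * (pAB * pab + pAb * paB), 2 * pAB * paB),
              c(pAb^2, 2 * pAB * pAb, pAB^2))
  if (any(pr[g > 0] <= 0)) return(-Inf)
  sum(g[g > 0] * log(pr[g > 0]))
}

# vectorized multinomial log-likelihood over a matrix of candidate
# frequency triples (p4 = 1 - p1 - p2 - p3)
oracle_geno_loglik_vec <- function(p1, p2, p3, g) {
  p4 <- 1 - p1 - p2 - p3
  pr <- list(`11` = p4^2, `12` = 2 * p3 * p4, `13` = p3^2,
             `21` = 2 * p2 * p4, `22` = 2 * (p1 * p4 + p2 * p3),
             `23` = 2 * p1 * p3,
             `31` = p2^2, `32` = 2 * p1 * p2, `33` = p1^2)
  ll <- 0
  for (i in 1:3) for (j in 1:3) {
    if (g[i, j] > 0)
      ll <- ll + g[i, j] * log(pmax(pr[[paste0(i, j)]], 0))
  }
  ll
}

# refining grid search over the haplotype-frequency simplex: a dense global
# first level (step 0.05), then refinements spanning +/- 2 previous steps;
# final resolution ~1.6e-5, well inside the 1e-4 comparison tolerance
grid_em_oracle <- function(g, levels = 5) {
  s0 <- seq(0, 1, by = 0.05)
  cand <- expand.grid(p1 = s0, p2 = s0, p3 = s0)
  cand <- cand[cand$p1 + cand$p2 + cand$p3 <= 1 + 1e-12, ]
  ll <- oracle_geno_loglik_vec(cand$p1, cand$p2, cand$p3, g)
  i <- which.max(ll)
  best <- as.numeric(cand[i, ]); best_ll <- ll[i]
  step <- 0.05
  for (lev in seq_len(levels)) {
    step <- step / 5
    s <- seq(-10, 10) * step
    cand <- expand.grid(p1 = best[1] + s, p2 = best[2] + s, p3 = best[3] + s)
    cand <- cand[cand$p1 >= 0 & cand$p2 >= 0 & cand$p3 >= 0 &
                 cand$p1 + cand$p2 + cand$p3 <= 1 + 1e-12, ]
    ll <- oracle_geno_loglik_vec(cand$p1, cand$p2, cand$p3, g)
    i <- which.max(ll)
    if (ll[i] > best_ll) {
      best <- as.numeric(cand[i, ])
      best_ll <- ll[i]
    }
  }
  list(p = c(AB = best[1], Ab = best[2], aB = best[3], ab = 1 - sum(best)),
       log_likelihood = best_ll)
}

# random 3x3 genotype table drawn from random haplotype frequencies under
# random gamete union; avoids the all-double-heterozygote degeneracy (a
# likelihood ridge where the maximizer is not unique)
random_genotype_table <- function(n) {
  repeat {
    p <- as.numeric(rexp(4) + 0.05)
    p <- p / sum(p)
    h1 <- sample.int(4, n, replace = TRUE, prob = p)
    h2 <- sample.int(4, n, replace = TRUE, prob = p)
    a <- (h1 <= 2) + (h2 <= 2)
    b <- (h1 %in% c(1, 3)) + (h2 %in% c(1, 3))
    g <- unclass(table(factor(a, levels = 0:2), factor(b, levels = 0:2)))
    polymorphic <- sum(g * matrix(0:2, 3, 3)) %in% seq_len(2 * n - 1) &&
      sum(g * matrix(0:2, 3, 3, byrow = TRUE)) %in% seq_len(2 * n - 1)
    if (polymorphic && g[2, 2] < n) return(g)
  }
}

# independent re-implementation of the frequency-weighted rank-sum test
# (weights re-estimated from the permuted controls each time)
weighted_sum_oracle <- function(geno, is_case, n_perm, seed) {
  set.seed(seed)
  stat <- function(lab) {
    ctrl <- geno[!lab, , drop = FALSE]
    q <- (colSums(ctrl) + 1) / (2 * nrow(ctrl) + 2)
    w <- sqrt(nrow(ctrl) * q * (1 - q))
    score <- rowSums(sweep(geno, 2, w, "/"))
    sum(rank(score)[lab])
  }
  x_obs <- stat(is_case)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (stat(sample(is_case)) >= x_obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# shared fixture loader
load_lipg_fixtures <- function() {
  cohorts <- load_cohorts(lipg_fixture("lipg_cohorts.tsv"))
  catalog <- load_catalog(lipg_fixture("lipg_variants.tsv"), cohorts)
  carriers <- load_carriers(lipg_fixture("lipg_carriers.tsv"), catalog, cohorts)
  calls <- load_functional_calls(lipg_fixture("lipg_functional_calls.tsv"))
  list(cohorts = cohorts, catalog = catalog, carriers = carriers,
       calls = calls)
}
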