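#' @title Quantitative-trait association
#'
#' @description
#' Two standard stages of cohort association analysis: (1) trait
#' residualization -- within each stratum (typically gender), the trait is
#' regressed on covariates and the residuals rescaled to mean 0, SD 1, so
#' downstream effect sizes are in trait-SD units; (2) additive genotype
#' regression -- the (optionally log-transformed) trait is regressed on
#' minor-allele count, giving a per-copy effect estimate.
#'
#' @name assoc
NULL

#' Residualize and standardize a trait within strata
#'
#' @param data data.frame with the trait and covariate columns.
#' @param trait Name of the trait column.
#' @param covariates Character vector of covariate column names (may be
#'   empty: plain z-scores are returned).
#' @param stratify_by Optional name of a stratum column (e.g. gender);
#'   residualization then runs separately per stratum.
#' @return Numeric vector aligned with `data` rows: standardized residuals
#'   (mean 0, SD 1 within each stratum). Strata smaller than the parameter
#'   count are skipped with a warning and return NA.
#' @export
residualize_standardize <- function(data, trait, covariates = character(),
                                    stratify_by = NULL) {
  if (!trait %in% names(data)) stop("trait column '", trait, "' not found")
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0)
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))
  strata <- if (is.null(stratify_by)) rep("all", nrow(data))
            else as.character(data[[stratify_by]])
  if (any(!nzchar(strata) | is.na(strata))) stop("empty stratum label")
  out <- rep(NA_real_, nrow(data))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_par <- length(covariates) + 1L
    if (length(idx) <= n_par) {
      warning("stratum '", s, "' smaller than parameter count: skipped")
      next
    }
    y <- data[[trait]][idx]
    if (any(!is.finite(y))) stop("non-finite trait value in stratum '", s, "'")
    res <- if (length(covariates) == 0) {
      y - mean(y)
    } else {
      X <- cbind(1, as.matrix(data[idx, covariates, drop = FALSE]))
      stats::lm.fit(X, y)$residuals
    }
    out[idx] <- res / stats::sd(res)
  }
  out
}

#' Additive-genotype linear regression
#'
#' Regresses the trait (identity or log scale) on minor-allele count.
#' If the coded allele is major in the analyzed sample (mean dosage > 1),
#' the coding is flipped with a warning so the reported effect is always
#' per copy of the sample minor allele.
#'
#' @param genotype Integer vector of allele counts (0/1/2).
#' @param trait Numeric trait vector, same length.
#' @param transform `"identity"` or `"log"` (natural log; trait must be
#'   positive).
#' @return List of class `assoc_result`: `beta` (per minor-allele copy, on
#'   the analysis scale), `se`, `p_value` (two-sided t), `n`, `transform`,
#'   `flipped` (allele recoding indicator).
#' @export
additive_regression <- function(genotype, trait,
                                transform = c("identity", "log")) {
  transform <- match.arg(transform)
  keep <- !(is.na(genotype) | is.na(trait))
  g <- as.numeric(genotype[keep]); y <- trait[keep]
  n <- length(g)
  if (stats::var(g) == 0)
    stop("monomorphic genotype: additive effect is not estimable")
  flipped <- FALSE
  if (mean(g) / 2 > 0.5) {
    warning("coded allele is major in this sample: flipping to minor-allele dosage")
    g <- 2 - g
    flipped <- TRUE
  }
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform requires strictly positive trait values")
    y <- log(y)
  }
  fit <- stats::lm.fit(cbind(1, g), y)
  beta <- fit$coefficients[2]
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sum((g - mean(g))^2))
  p <- 2 * stats::pt(abs(beta / se), df = n - 2, lower.tail = FALSE)
  out <- list(beta = unname(beta), se = unname(se), p_value = unname(p),
              n = n, transform = transform, flipped = flipped)
  class(out) <- "assoc_result"
  out
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("additive regression (%s scale): beta = %.4g (se %.3g), p = %.3g, n = %d\n",
              x$transform, x$beta, x$se, x$p_value, x$n))
  invisible(x)
}
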