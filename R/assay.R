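#' @title Dual-luciferase reporter normalization and direction calling
#'
#' @description
#' Each well of a reporter plate carries a firefly luciferase construct
#' (promoter under test) co-transfected with a Renilla luciferase control.
#' The firefly/Renilla ratio removes transfection-efficiency variation; the
#' ratio is then expressed relative to the mean wild-type (WT) ratio of the
#' same plate, so the WT construct has relative activity 1 by construction.
#' A variant is called functional when an unpaired Student's t-test of its
#' relative activities against the WT wells is significant at `alpha`.
#'
#' @name assay
NULL

#' Read reporter-assay well measurements
#'
#' @param path TSV with columns `plate_id`, `construct`, `firefly`,
#'   `renilla`.
#' @return data.frame of well readings.
#' @export
load_assay <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(plate_id = "character",
                                         construct = "character"))
  req <- c("plate_id", "construct", "firefly", "renilla")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("assay table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (any(df$firefly < 0)) stop("negative firefly reading")
  df
}

#' Normalize one reporter plate to its wild-type wells
#'
#' Each well's firefly/Renilla ratio is divided by the mean WT ratio of the
#' same plate. Wells with a non-positive Renilla reading are rejected with a
#' warning (the control failed, so the ratio is meaningless).
#'
#' @param wells data.frame of wells sharing one `plate_id`.
#' @param wt_label Construct label of the wild-type reference (default
#'   `"WT"`).
#' @return Input rows (minus rejected wells) with a `rel_activity` column.
#' @export
normalize_plate <- function(wells, wt_label = "WT") {
  if (length(unique(wells$plate_id)) > 1)
    stop("normalize_plate() expects wells from a single plate")
  bad <- wells$renilla <= 0
  if (any(bad)) {
    warning(sum(bad), " well(s) rejected: non-positive Renilla reading")
    wells <- wells[!bad, , drop = FALSE]
  }
  wt <- wells$construct == wt_label
  if (!any(wt))
    stop("no wild-type ('", wt_label, "') well on plate ",
         wells$plate_id[1], ": cannot normalize")
  ratio <- wells$firefly / wells$renilla
  wells$rel_activity <- ratio / mean(ratio[wt])
  wells
}

#' Call the direction of effect of a variant construct
#'
#' Two-sided unpaired t-test (pooled variance by default, per the classical
#' reporter-assay analysis; Welch via `var_equal = FALSE`) of variant vs WT
#' relative activities. Direction is `"increase"`/`"decrease"` only when
#' p < `alpha`, otherwise `"null"`.
#'
#' @param variant_acts Numeric vector of variant-well relative activities.
#' @param wt_acts Numeric vector of WT-well relative activities.
#' @param alpha Per-variant significance level (default 0.05, no
#'   multiple-testing correction: each variant is an independent hypothesis
#'   in this design).
#' @param variant_id Optional label carried into the result.
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return A one-row data.frame of class `functional_call`: `variant_id`,
#'   `relative_activity` (variant mean), `p_value`, `direction`,
#'   `n_replicates`.
#' @export
classify_direction <- function(variant_acts, wt_acts, alpha = 0.05,
                               variant_id = NA_character_, var_equal = TRUE) {
  if (length(variant_acts) < 2 || length(wt_acts) < 2)
    stop("insufficient data: need >= 2 replicates per group")
  if (stats::sd(variant_acts) == 0 && stats::sd(wt_acts) == 0 &&
      mean(variant_acts) == mean(wt_acts)) {
    p <- 1
  } else {
    p <- stats::t.test(variant_acts, wt_acts, var.equal = var_equal)$p.value
  }
  direction <- if (p < alpha) {
    if (mean(variant_acts) > mean(wt_acts)) "increase" else "decrease"
  } else "null"
  out <- data.frame(variant_id = variant_id,
                    relative_activity = mean(variant_acts),
                    p_value = p,
                    direction = direction,
                    n_replicates = length(variant_acts),
                    stringsAsFactors = FALSE)
  class(out) <- c("functional_call", "data.frame")
  out
}

#' Call all variant constructs from a multi-plate assay table
#'
#' Plates are normalized independently; a construct assayed on several
#' plates (replicate experiments) gets one call per plate and the calls must
#' agree -- disagreement yields `"null"` with a warning, since the assay
#' gives no aggregation rule across experiments. The reported
#' `relative_activity` and `p_value` are from the per-plate calls
#' (mean activity across plates; max p among agreeing significant plates,
#' so the reported p is conservative).
#'
#' @param wells Assay table as from [load_assay()].
#' @inheritParams classify_direction
#' @return data.frame of class `functional_call`, one row per non-WT
#'   construct.
#' @export
call_variants <- function(wells, alpha = 0.05, wt_label = "WT",
                          var_equal = TRUE) {
  plates <- split(wells, wells$plate_id)
  per_plate <- lapply(plates, function(pl) {
    pl <- normalize_plate(pl, wt_label = wt_label)
    wt_acts <- pl$rel_activity[pl$construct == wt_label]
    constructs <- setdiff(unique(pl$construct), wt_label)
    do.call(rbind, lapply(constructs, function(cs) {
      classify_direction(pl$rel_activity[pl$construct == cs], wt_acts,
                         alpha = alpha, variant_id = cs,
                         var_equal = var_equal)
    }))
  })
  calls <- do.call(rbind, per_plate)
  out <- do.call(rbind, lapply(split(calls, calls$variant_id), function(d) {
    dirs <- unique(d$direction)
    if (length(dirs) == 1) {
      dir <- dirs
      p <- max(d$p_value)
    } else {
      warning("plates disagree on direction for ", d$variant_id[1],
              ": calling null")
      dir <- "null"
      p <- max(d$p_value)
    }
    data.frame(variant_id = d$variant_id[1],
               relative_activity = mean(d$relative_activity),
               p_value = p, direction = dir,
               n_replicates = sum(d$n_replicates),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("functional_call", "data.frame")
  out
}

#' Read / write per-variant functional calls
#'
#' @param path TSV with columns `variant_id`, `direction`,
#'   `relative_activity`, `p_value`.
#' @return data.frame of class `functional_call`.
#' @export
load_functional_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(variant_id = "character"))
  req <- c("variant_id", "direction", "relative_activity", "p_value")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("functional-call table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!all(df$direction %in% c("decrease", "null", "increase")))
    stop("direction must be one of decrease/null/increase")
  class(df) <- c("functional_call", "data.frame")
  df
}

#' @rdname load_functional_calls
#' @param calls A `functional_call` data.frame.
#' @export
save_functional_calls <- function(calls, path) {
  cols <- c("variant_id", "direction", "relative_activity", "p_value")
  utils::write.table(as.data.frame(calls)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
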