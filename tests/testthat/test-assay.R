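make_plate <- function(ratios_by_construct, plate_id = "P1") {
  do.call(rbind, lapply(names(ratios_by_construct), function(cs) {
    r <- ratios_by_construct[[cs]]
    data.frame(plate_id = plate_id, construct = cs,
               firefly = r, renilla = 1, stringsAsFactors = FALSE)
  }))
}

test_that("plate normalization anchors the WT mean at exactly 1", {
  set.seed(7)
  pl <- make_plate(list(WT = rlnorm(6), v1 = rlnorm(6), v2 = rlnorm(6)))
  norm <- normalize_plate(pl)
  expect_equal(mean(norm$rel_activity[norm$construct == "WT"]), 1)
  # wells at exactly twice the WT mean ratio come out as 2.0
  wt_mean <- mean(pl$firefly[pl$construct == "WT"])
  pl2 <- rbind(pl, data.frame(plate_id = "P1", construct = "v3",
                              firefly = rep(2 * wt_mean, 6), renilla = 1))
  norm2 <- normalize_plate(pl2)
  expect_equal(norm2$rel_activity[norm2$construct == "v3"], rep(2, 6))
})

test_that("normalization matches the hand-computed oracle", {
  wt <- c(1.0, 1.1, 0.9, 1.05, 0.95, 1.0)
  vr <- c(0.5, 0.55, 0.45, 0.52, 0.48, 0.50)
  pl <- make_plate(list(WT = wt, v1 = vr))
  norm <- normalize_plate(pl)
  # spreadsheet-style: each ratio over mean(wt) = 1.0
  expect_equal(norm$rel_activity, c(wt, vr) / mean(wt), tolerance = 1e-12)
})

test_that("normalization is invariant to rescaling all firefly readings", {
  set.seed(8)
  for (i in 1:20) {
    pl <- make_plate(list(WT = rlnorm(6), v1 = rlnorm(6)))
    pl$renilla <- rlnorm(nrow(pl), log(2e5), 0.2)
    norm1 <- normalize_plate(pl)
    pl2 <- pl
    cc <- rexp(1) + 0.1
    pl2$firefly <- pl2$firefly * cc
    norm2 <- normalize_plate(pl2)
    expect_equal(norm2$rel_activity, norm1$rel_activity, tolerance = 1e-12)
  }
})

test_that("plates without WT error; dead-Renilla wells are rejected", {
  pl <- make_plate(list(v1 = rlnorm(6)))
  expect_error(normalize_plate(pl), "no wild-type")
  pl <- make_plate(list(WT = c(1, 1.1, 0.9), v1 = c(0.5, 0.6, 0.4)))
  pl$renilla[4] <- 0
  expect_warning(norm <- normalize_plate(pl), "rejected")
  expect_equal(nrow(norm), 5)
  expect_error(normalize_plate(make_plate(list(WT = 1), "P1")[c(1, 1), ] |>
                                 transform(plate_id = c("P1", "P2"))),
               "single plate")
})

test_that("direction calls match the pooled-t oracle and alpha rule", {
  wt <- c(1.00, 1.02, 0.98, 1.01, 0.99, 1.00)
  vr <- c(0.50, 0.52, 0.48, 0.51, 0.49, 0.50)
  call <- classify_direction(vr, wt, variant_id = "v")
  expect_equal(call$direction, "decrease")
  oracle <- pooled_t_oracle(vr, wt)
  expect_equal(call$p_value, oracle$p, tolerance = 1e-12)
  # identical groups: null at p = 1
  same <- classify_direction(wt, wt)
  expect_equal(same$direction, "null")
  expect_equal(same$p_value, 1)
  expect_error(classify_direction(1, wt), "insufficient")
  # Welch variant stays available
  expect_lt(classify_direction(vr, wt, var_equal = FALSE)$p_value, 0.05)
})

test_that("direction calling is antisymmetric under group swap", {
  set.seed(9)
  for (i in 1:25) {
    a <- rlnorm(6, 0, 0.2)
    b <- rlnorm(6, 0.3, 0.2)
    c1 <- classify_direction(a, b)
    c2 <- classify_direction(b, a)
    expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
    if (c1$direction != "null") {
      expect_equal(c2$direction,
                   if (c1$direction == "decrease") "increase" else "decrease")
    } else {
      expect_equal(c2$direction, "null")
    }
  }
})

test_that("false-call rate on true-null plates is near alpha", {
  set.seed(101)
  n_plates <- 2000
  sdlog <- sqrt(log(1 + 0.1^2))
  false_calls <- 0L
  for (i in seq_len(n_plates)) {
    wt <- rlnorm(6, 0, sdlog)
    vr <- rlnorm(6, 0, sdlog)   # true relative activity 1
    if (classify_direction(vr, wt)$direction != "null")
      false_calls <- false_calls + 1L
  }
  ci <- qbinom(c(0.025, 0.975), n_plates, 0.05)
  expect_gte(false_calls, ci[1])
  expect_lte(false_calls, ci[2])
})

test_that("multi-plate calls require agreement across experiments", {
  set.seed(10)
  mk <- function(plate, v1_mu) {
    pl <- make_plate(list(WT = rlnorm(6, 0, 0.05),
                          v1 = rlnorm(6, v1_mu, 0.05)), plate)
    pl
  }
  agree <- rbind(mk("P1", log(0.5)), mk("P2", log(0.5)))
  calls <- call_variants(agree)
  expect_equal(calls$direction, "decrease")
  disagree <- rbind(mk("P3", log(0.5)), mk("P4", log(1.8)))
  expect_warning(calls2 <- call_variants(disagree), "disagree")
  expect_equal(calls2$direction, "null")
})

test_that("functional-call tables round-trip and validate directions", {
  calls <- load_functional_calls(lipg_fixture("lipg_functional_calls.tsv"))
  expect_equal(nrow(calls), 19)
  expect_equal(sum(calls$direction == "decrease"), 5)  # 4 rare + 1 common
  path <- tempfile(fileext = ".tsv")
  save_functional_calls(calls, path)
  expect_equal(as.data.frame(load_functional_calls(path)),
               as.data.frame(calls))
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tdirection\trelative_activity\tp_value",
               "v1\tup\t1.5\t0.01"), bad)
  expect_error(load_functional_calls(bad), "direction")
})
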