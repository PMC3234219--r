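test_that("bundled catalog loads with full accounting", {
  fx <- load_lipg_fixtures()
  expect_s3_class(fx$catalog, "variant_catalog")
  expect_equal(length(unique(fx$catalog$variant_id)), 22)
  rare <- unique(fx$catalog$variant_id[fx$catalog$freq_class == "rare"])
  expect_equal(length(rare), 17)
  common <- unique(fx$catalog$variant_id[fx$catalog$freq_class == "common"])
  expect_setequal(common, c("rs9958947", "rs4245232", "rs3829632",
                            "-1358insT", "rs34474737"))
})

test_that("empty catalog (header only) loads as zero records", {
  fx <- load_lipg_fixtures()
  path <- tempfile(fileext = ".tsv")
  writeLines("variant_id\tposition\tref\talt\tcohort\tn_het\tn_hom_minor",
             path)
  cat0 <- load_catalog(path, fx$cohorts)
  expect_equal(nrow(cat0), 0)
})

test_that("catalog validation rejects malformed rows, naming them", {
  fx <- load_lipg_fixtures()
  write_rows <- function(rows) {
    path <- tempfile(fileext = ".tsv")
    writeLines(c("variant_id\tposition\tref\talt\tcohort\tn_het\tn_hom_minor",
                 rows), path)
    path
  }
  expect_error(load_catalog(write_rows("v1\t0\tA\tG\tHHDL\t1\t0"), fx$cohorts),
               "row 1.*position 0")
  expect_error(load_catalog(write_rows("v1\t-2000\tA\tG\tHHDL\t1\t0"),
                            fx$cohorts),
               "outside sequenced region")
  # region override admits the same row
  expect_silent(load_catalog(write_rows("v1\t-2000\tA\tG\tHHDL\t1\t0"),
                             fx$cohorts, region = c(-2500L, 252L)))
  expect_error(load_catalog(write_rows("v1\t-10\tA\tA\tHHDL\t1\t0"), fx$cohorts),
               "identical")
  expect_error(load_catalog(write_rows("v1\t-10\tA\tG\tHHDL\t190\t10"),
                            fx$cohorts),
               "exceed cohort size")
  expect_error(load_catalog(write_rows("v1\t-10\tA\tG\tNOPE\t1\t0"), fx$cohorts),
               "unknown cohort")
  # missing column is a schema error
  path <- tempfile(fileext = ".tsv")
  writeLines(c("variant_id\tposition\tref\talt\tcohort\tn_het", "v1\t-10\tA\tG\tHHDL\t1"),
             path)
  expect_error(load_catalog(path, fx$cohorts), "missing required column")
})

test_that("compute_maf reproduces published frequencies", {
  expect_equal(round(compute_maf(25, 96, 195), 4), 0.3744)
  expect_equal(round(compute_maf(25, 96, 195), 2), 0.37)
  expect_equal(round(compute_maf(5, 44, 195), 4), 0.1385)
  expect_equal(round(compute_maf(5, 44, 195), 2), 0.14)
  expect_equal(compute_maf(0, 0, 195), 0)
  expect_error(compute_maf(-1, 0, 195), "non-negative")
  expect_error(compute_maf(100, 100, 195), "exceed")
  expect_warning(compute_maf(150, 40, 195), "> 0.5")
})

test_that("compute_maf is monotone non-decreasing in each count", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(50:500, 1)
    hom <- sample(0:10, 1); het <- sample(0:20, 1)
    base <- compute_maf(hom, het, n)
    expect_gte(compute_maf(hom + 1, het, n), base)
    expect_gte(compute_maf(hom, het + 1, n), base)
  }
})

test_that("classify_frequency applies the <1% / >=5% thresholds", {
  expect_equal(classify_frequency(c(0.005, 0.14, 0.03)),
               c("rare", "common", "intermediate"))
  expect_equal(classify_frequency(0.01), "intermediate")  # boundary: not rare
  expect_equal(classify_frequency(0.05), "common")        # boundary: common
  expect_error(classify_frequency(1.2), "outside")
})

test_that("distinct-carrier counting de-duplicates multi-variant individuals", {
  fx <- load_lipg_fixtures()
  rare <- unique(fx$catalog$variant_id[fx$catalog$freq_class == "rare"])
  expect_equal(count_distinct_carriers(fx$carriers, rare, "HHDL"), 16)
  expect_equal(count_distinct_carriers(fx$carriers, rare, "LHDL"), 9)
  expect_equal(count_distinct_carriers(fx$carriers, character(0), "HHDL"), 0L)
  # raw incidence is larger than the de-duplicated count
  expect_equal(sum(fx$carriers$cohort == "HHDL"), 19)
  k <- carriers_by_cohort(fx$carriers, rare, fx$cohorts)
  expect_equal(unname(k), c(16L, 9L))
})

test_that("carrier table column sums are validated against the catalog", {
  fx <- load_lipg_fixtures()
  bad <- as.data.frame(fx$carriers)
  bad <- bad[-1, ]  # drop one incidence row -> count mismatch
  expect_error(validate_carriers <- regulaburden:::validate_carriers(
    bad, catalog = fx$catalog, cohorts = fx$cohorts), "mismatch")
  dup <- as.data.frame(fx$carriers)
  dup$cohort[dup$individual_id == "H01"][1] <- "LHDL"
  expect_error(regulaburden:::validate_carriers(dup), "more than one cohort")
})

test_that("catalog round-trips through save_catalog field-for-field", {
  fx <- load_lipg_fixtures()
  path <- tempfile(fileext = ".tsv")
  save_catalog(fx$catalog, path)
  back <- load_catalog(path, fx$cohorts)
  cols <- c("variant_id", "position", "ref", "alt", "cohort", "n_het",
            "n_hom_minor")
  expect_equal(as.data.frame(back)[, cols], as.data.frame(fx$catalog)[, cols])
  expect_equal(back$freq_class, fx$catalog$freq_class)
})

test_that("cohort specs validate extreme/percentile consistency", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("name\tn_individuals\textreme\tpercentile_bound",
               "X\t100\thigh\t25"), path)
  expect_error(load_cohorts(path), "inconsistent")
})
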