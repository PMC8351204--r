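test_that("fixture generation is deterministic under a fixed seed", {
  a <- generate_fixture_library("random_homologues", seed = 42, n = 15)
  b <- generate_fixture_library("random_homologues", seed = 42, n = 15)
  expect_identical(as.data.frame(a$library), as.data.frame(b$library))
  expect_identical(a$noael, b$noael)
  c2 <- generate_fixture_library("random_homologues", seed = 43, n = 15)
  expect_false(identical(a$noael, c2$noael))
  expect_error(generate_fixture_library("nonsense"), "arg")
})

test_that("the paraben bundle carries the target and published tables", {
  p <- generate_fixture_library("parabens")
  expect_equal(nrow(p$library), 4)
  expect_equal(p$library$role[p$library$compound_id == "CMS-2411"], "target")
  expect_equal(dim(p$tanimoto), c(4, 4))
  expect_equal(dim(p$zscores), c(4, 5))
})

test_that("the hair-dye bundle carries analogue study records", {
  h <- generate_fixture_library("hair_dyes")
  expect_equal(h$studies$noael, c(17, 50, 80))
  expect_equal(h$studies$loael, c(50, NA, NA))
  expect_equal(h$studies$source, c("SCCS", "SCC", "SCCP"))
  recs <- read_study_records(h$studies)
  expect_equal(unique(recs$minis_grade), 4L)
  expect_equal(unique(recs$study_reliability), 0.9)
})

test_that("the hair-dye workflow reproduces the weight-of-evidence table", {
  r <- read_across(generate_fixture_library("hair_dyes"))
  ev <- r$steps$evidence
  expect_equal(ev$role[ev$compound_id == "CMS-23938"], "target")
  expect_equal(ev$role[ev$compound_id == "CMS-60520"], "analogue")
  expect_equal(ev$role[ev$compound_id == "CMS-43204"], "similar")
  expect_equal(ev$role[ev$compound_id == "CMS-72054"], "similar")
  rr <- function(id) round_half_up(ev$read_across_reliability[ev$compound_id == id])
  expect_equal(rr("CMS-60520"), 0.75)
  expect_equal(rr("CMS-43204"), 0.55)
  expect_equal(rr("CMS-72054"), 0.56)
  # DST interval present and coherent for every candidate
  cand <- ev$compound_id != "CMS-23938"
  expect_true(all(ev$dst_belief[cand] <= ev$dst_plausibility[cand]))
  # single qualified analogue: partial report, no interval
  expect_equal(r$status, "partial")
  expect_true(any(grepl("one qualified analogue", r$messages)))
})

test_that("a library containing only the target yields a partial no-candidate report", {
  lib <- compound_library("T1", "target", smiles = "CCO", role = "target")
  r <- read_across(lib, target_id = "T1")
  expect_equal(r$status, "partial")
  expect_true(any(grepl("no candidates", r$messages)))
  expect_equal(nrow(r$steps$hits), 0)
  expect_null(r$steps$evidence)
})

test_that("the paraben fixture reproduces the published table through step 3", {
  p <- generate_fixture_library("parabens")
  r <- read_across(p, tanimoto_values = p$tanimoto[, c("toxprint", "rdkit")])
  prof <- r$steps$profiles
  exp <- paraben_expected()
  for (col in names(exp)) {
    got <- prof[[col]][match(names(exp[[col]]), prof$candidate_id)]
    expect_true(all(abs(got - exp[[col]]) <= 0.005), info = col)
  }
  expect_equal(r$status, "partial")  # no study records in the paraben bundle
})

test_that("a full report exports one csv per step and round-trips through json", {
  r <- read_across(generate_fixture_library("hair_dyes"))
  dir <- withr::local_tempdir()
  files <- export_report(r, dir, "csv_bundle")
  expect_length(files, 7)
  expect_true(all(file.exists(files)))

  jf <- export_report(r, dir, "json")
  back <- import_report(jf)
  expect_equal(back$target_id, r$target_id)
  expect_equal(back$status, r$status)
  expect_equal(back$steps$evidence$read_across_reliability,
               r$steps$evidence$read_across_reliability, tolerance = 1e-12)
  expect_equal(back$steps$evidence$role, r$steps$evidence$role)

  mf <- export_report(r, dir, "markdown")
  md <- readLines(mf)
  expect_true(any(grepl("\\| CMS-60520 \\| analogue \\| 0.83 \\| 0.90 \\| 0.75 \\|", md)))
  expect_true(any(grepl("0.56", md)))
})

test_that("identical runs export byte-identical reports", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- export_report(read_across(generate_fixture_library("hair_dyes")), d1)
  f2 <- export_report(read_across(generate_fixture_library("hair_dyes")), d2)
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
})

test_that("the command-line interface evaluates TTC queries to JSON", {
  out <- capture.output(status <- toxra_cli(c(
    "ttc", "--smiles", "[Na+].[O-]S(=O)(=O)c1cccc2ccccc12",
    "--cramer-class", "III", "--exposure", "0.35",
    "--exposure-unit", "ug_per_kg_bw_day", "--body-weight", "60")))
  expect_equal(status, 0L)
  v <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(v$outcome, "pass")
  expect_equal(v$exposure_per_person, 21)
  expect_equal(v$threshold_applied, 90)
})

test_that("the command-line interface scores study reliability", {
  out <- capture.output(toxra_cli(c(
    "reliability", "--rules", "PPPPPPPPPPPPPPFF", "--opinion", "4")))
  v <- jsonlite::fromJSON(paste(out, collapse = "\n"))
  expect_equal(v$grade, 4)
  expect_equal(v$study_reliability, 0.9)
})
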