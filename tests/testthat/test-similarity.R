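test_that("tanimoto handles identity, disjointness and the empty convention", {
  expect_equal(tanimoto(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(tanimoto(c(1, 2), c(3, 4)), 0)
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(integer(), integer()), 1)  # empty-vs-empty convention
})

test_that("fingerprint method mismatch is rejected", {
  lib <- make_small_lib()
  fa <- fingerprints(lib, "path", ids = c("A1", "A2"))
  fb <- fingerprints(lib, "maccs", ids = c("A1", "A2"))
  expect_error(tanimoto(fa, fb, "A1", "A2"), "mismatch")
})

test_that("package tanimoto agrees with the reference fingerprint-similarity routine", {
  lib <- compound_library(c("C1", "C2", "C3"),
                          smiles = c("CCCOC(=O)c1ccc(O)cc1",
                                     "COC(=O)c1ccc(O)cc1", "CCCCc1ccccc1"))
  fp <- fingerprints(lib, "path")
  # reference route: same molecules, independent bit handling via fpSim
  sdf <- ChemmineR::smiles2sdf(stats::setNames(lib$canonical_smiles,
                                               lib$compound_id))
  ref <- ChemmineR::fingerprintOB(sdf, "FP2")
  for (pair in list(c("C1", "C2"), c("C1", "C3"), c("C2", "C3"))) {
    expect_equal(tanimoto(fp, fp, pair[1], pair[2]),
                 unname(ChemmineR::fpSim(ref[pair[1]], ref[pair[2]],
                                         method = "Tanimoto", addone = 0)),
                 tolerance = 1e-12)
  }
})

test_that("pearson similarity maps correlation to [0,1] and rejects degenerate input", {
  x <- c(a = 1, b = 2, c = 4, d = 8)
  expect_equal(pearson_similarity(x, x), 1)
  expect_equal(pearson_similarity(x, -x), 0)
  expect_error(pearson_similarity(c(a = 1, b = 2), c(a = 1, b = 2)),
               "at least 3")
  expect_error(pearson_similarity(x, c(a = 1, b = 1, c = 1, d = 1)),
               "zero-variance")
})

test_that("euclidean similarity is 1/(1+distance) and property sets must match", {
  x <- c(a = 0.5, b = -1, c = 2)
  e <- euclidean_similarity(x, x)
  expect_equal(e$distance, 0)
  expect_equal(e$similarity, 1)
  y <- c(a = 1.5, b = -1, c = 2)
  expect_equal(euclidean_similarity(x, y)$similarity, 0.5)
  expect_error(euclidean_similarity(x, c(a = 1, b = 2, d = 3)), "mismatch")
})

test_that("analogue quality is a bounded, monotone geometric mean", {
  expect_equal(analogue_quality(c(1, 1, 1)), 1)
  expect_equal(analogue_quality(c(0.91, 0.94, 0.82)), 0.89, tolerance = 0.005 / 0.89)
  expect_equal(analogue_quality(c(0.85, 0.77, 0.88)), 0.83, tolerance = 0.005 / 0.83)
  expect_equal(analogue_quality(c(0.4, 0, 0.9)), 0)
  expect_error(analogue_quality(numeric()), "at least one")
  expect_error(analogue_quality(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(42)
  for (i in 1:200) {
    m <- stats::runif(sample(1:5, 1))
    aq <- analogue_quality(m)
    expect_gte(aq, min(m) - 1e-12)
    expect_lte(aq, max(m) + 1e-12)
    expect_equal(analogue_quality(rep(m[1], 4)), m[1], tolerance = 1e-12)
    # raising one measure never lowers AQ
    j <- sample(seq_along(m), 1)
    m2 <- m
    m2[j] <- min(1, m2[j] + stats::runif(1, 0, 1 - m2[j]))
    expect_gte(analogue_quality(m2), aq - 1e-12)
  }
})

test_that("similarity search enforces the threshold floor and ranks deterministically", {
  b <- generate_fixture_library("random_homologues", seed = 11, n = 12)
  expect_error(similarity_search(b$target, b$library, threshold = 0.5),
               "0.65")
  hits <- similarity_search(b$target, b$library, threshold = 0.7)
  expect_equal(hits$compound_id[1], b$target)  # self-hit ranked first
  expect_equal(hits$tanimoto[1], 1)
  expect_true(all(diff(hits$tanimoto) <= 0))

  # brute-force oracle: full pairwise matrix, filter and sort by hand
  ids <- b$library$compound_id
  fp <- fingerprints(b$library, "path")
  sims <- vapply(ids, function(id) tanimoto(fp, fp, b$target, id), numeric(1))
  keep <- names(sims)[sims >= 0.7]
  oracle <- data.frame(compound_id = keep, tanimoto = unname(sims[keep]))
  oracle <- oracle[order(-oracle$tanimoto, oracle$compound_id), ]
  expect_equal(hits$compound_id, oracle$compound_id)
  expect_equal(hits$tanimoto, oracle$tanimoto)
})

test_that("search against its own exact structure is the only hit at threshold 1", {
  lib <- compound_library(c("Q", "R"), smiles = c("CCO", "CCCCCCO"))
  hits <- similarity_search("Q", lib, threshold = 1)
  expect_equal(hits$compound_id, "Q")
  hits2 <- similarity_search("OCC", # same molecule, different SMILES
                             compound_library("R", smiles = "CCCCCCO"),
                             threshold = 1)
  expect_equal(nrow(hits2), 0)
})

test_that("a profile of the target against itself is all ones", {
  p <- generate_fixture_library("parabens")
  prof <- pairwise_profile(p$library, p$target, candidate_ids = p$target,
                           tanimoto_values = p$tanimoto[, c("toxprint", "rdkit")],
                           zscores = p$zscores)
  expect_equal(prof$tanimoto_toxprint, 1)
  expect_equal(prof$euclidean_distance, 0)
  expect_equal(prof$euclidean_similarity, 1)
  expect_equal(prof$pearson_similarity, 1)
  expect_equal(prof$aq_euclidean, 1)
  expect_equal(prof$aq_pearson, 1)
})

test_that("pairwise profiles reproduce the printed paraben similarity table", {
  prof <- paraben_profile()
  exp <- paraben_expected()
  for (col in names(exp)) {
    got <- prof[[col]][match(names(exp[[col]]), prof$candidate_id)]
    expect_true(all(abs(got - exp[[col]]) <= 0.005),
                info = paste(col, paste(round(got, 4), collapse = ", ")))
    expect_equal(round_half_up(got, 2), unname(exp[[col]]), info = col)
  }
})

test_that("similarity measures are symmetric in their arguments", {
  set.seed(7)
  for (i in 1:50) {
    x <- stats::setNames(stats::rnorm(5), letters[1:5])
    y <- stats::setNames(stats::rnorm(5), letters[1:5])
    expect_equal(pearson_similarity(x, y), pearson_similarity(y, x))
    expect_equal(euclidean_similarity(x, y)$distance,
                 euclidean_similarity(y, x)$distance)
    a <- sample(0:63, 10); b <- sample(0:63, 12)
    expect_equal(tanimoto(a, b), tanimoto(b, a))
  }
})

test_that("a candidate with missing inputs yields an error entry, not an omission", {
  p <- generate_fixture_library("parabens")
  z <- p$zscores[-2, , drop = FALSE]  # drop the butyl row
  prof <- pairwise_profile(p$library, p$target,
                           tanimoto_values = p$tanimoto[, c("toxprint", "rdkit")],
                           zscores = z)
  expect_equal(nrow(prof), 3)
  bad <- prof[prof$candidate_id == "CMS-216", ]
  expect_false(bad$status == "ok")
  expect_true(is.na(bad$aq_euclidean))
  expect_true(all(prof$status[prof$candidate_id != "CMS-216"] == "ok"))
})

test_that("profile CSV export writes two-decimal values", {
  prof <- paraben_profile()
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  back <- utils::read.csv(path)
  expect_equal(back$aq_euclidean[back$candidate_id == "CMS-216"], 0.89)
})

test_that("half-up rounding differs from banker's rounding where it should", {
  expect_equal(round_half_up(0.745), 0.75)
  expect_equal(round_half_up(0.565), 0.57)
  expect_equal(round_half_up(-0.745), -0.75)
  expect_equal(round_half_up(2.5, 0), 3)
})
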