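test_that("joint reliability is the bounded product of its inputs", {
  expect_equal(joint_reliability(1, 1), 1)
  expect_equal(joint_reliability(0.83, 0.9), 0.747)
  expect_error(joint_reliability(1.2, 0.5), "\\[0, 1\\]")
  set.seed(3)
  a <- stats::runif(100); s <- stats::runif(100)
  expect_true(all(joint_reliability(a, s) <= pmin(a, s) + 1e-12))
})

test_that("analogue qualification applies the floors with the hard floor first", {
  q <- qualify_analogue(c(0.83, 0.61, 0.9), c(0.9, 0.9, 0.4))
  expect_equal(as.character(q$status),
               c("qualified", "not_feasible", "data_unusable"))
  expect_match(q$rationale[2], "AQ 0.61 < 0.70")
  # hard floor takes precedence even when AQ is also low
  q2 <- qualify_analogue(0.2, 0.3)
  expect_equal(as.character(q2$status), "data_unusable")
})

test_that("mass construction enforces normalisation and the discount model", {
  expect_error(mass_function(0.5, 0.4, 0.2), "sum to 1")
  expect_error(mass_function(-0.1, 0.6, 0.5), "non-negative")
  m <- build_mass(1, 1)
  expect_equal(c(m$reliable, m$not_reliable, m$either), c(1, 0, 0))
  m2 <- build_mass(0.83, 0.9)
  expect_equal(c(m2$reliable, m2$not_reliable, m2$either), c(0.747, 0.153, 0.1))
  vac <- build_mass(0.5, 0)
  expect_equal(vac$either, 1)
})

test_that("Dempster combination matches the hand-computed example", {
  m1 <- mass_function(0.747, 0.153, 0.1)
  m2 <- mass_function(0.81, 0.09, 0.1)
  # conflict K = .747*.09 + .153*.81 = 0.19116; normaliser 0.80884
  comb <- dst_combine(m1, m2)
  expect_equal(comb$reliable, 0.940, tolerance = 0.001 / 0.94)
  expect_equal(comb$not_reliable, 0.047, tolerance = 0.001 / 0.047)
  expect_equal(comb$either, 0.012, tolerance = 0.001 / 0.012)
  bp <- belief_plausibility(comb)
  expect_equal(unname(bp["belief"]), 0.940, tolerance = 0.001)
  expect_equal(unname(bp["plausibility"]), 0.952, tolerance = 0.001)
})

test_that("combination is commutative with the vacuous mass as identity", {
  vac <- mass_function(0, 0, 1)
  set.seed(17)
  for (i in 1:100) {
    m1 <- random_mass(); m2 <- random_mass()
    ab <- dst_combine(m1, m2); ba <- dst_combine(m2, m1)
    expect_equal(unlist(ab), unlist(ba), tolerance = 1e-12)
    idm <- dst_combine(m1, vac)
    expect_equal(unlist(idm), unlist(m1), tolerance = 1e-12)
    expect_equal(sum(unlist(ab)), 1, tolerance = 1e-9)
    bp <- belief_plausibility(ab)
    expect_lte(bp["belief"], bp["plausibility"])
  }
  expect_error(dst_combine(mass_function(1, 0, 0), mass_function(0, 1, 0)),
               "total conflict")
})

test_that("belief/plausibility spans total certainty to total ignorance", {
  expect_equal(unname(belief_plausibility(mass_function(1, 0, 0))), c(1, 1))
  expect_equal(unname(belief_plausibility(mass_function(0, 0, 1))), c(0, 1))
})

test_that("the evidence interval narrows as the source discounts approach 1", {
  width <- function(d) {
    bp <- belief_plausibility(dst_combine(build_mass(0.83, d), build_mass(0.9, d)))
    unname(bp["plausibility"] - bp["belief"])
  }
  w <- vapply(c(0.5, 0.7, 0.9, 0.99, 1), width, numeric(1))
  expect_true(all(diff(w) < 0))
  expect_equal(w[5], 0)
})

test_that("NOAEL bounds equal the closed form in every mode", {
  # all equal values give a zero-width interval in every mode
  for (mode in c("normal_sd", "normal_mean_ci", "lognormal_sd")) {
    b <- noael_bounds(c(20, 20, 20), mode = mode)
    expect_equal(as.numeric(b), c(20, 20), info = mode)
  }

  v <- c(10, 20, 30)
  z <- 1.959964  # independently tabulated two-sided 95% normal quantile
  b <- noael_bounds(v, 0.95, "normal_sd")
  expect_equal(as.numeric(b), c(mean(v) - z * sd(v), mean(v) + z * sd(v)),
               tolerance = 1e-6)
  b2 <- noael_bounds(v, 0.95, "normal_mean_ci")
  expect_equal(as.numeric(b2),
               c(mean(v) - z * sd(v) / sqrt(3), mean(v) + z * sd(v) / sqrt(3)),
               tolerance = 1e-6)
  b3 <- noael_bounds(v, 0.95, "lognormal_sd")
  expect_equal(as.numeric(b3),
               exp(c(mean(log(v)) - z * sd(log(v)), mean(log(v)) + z * sd(log(v)))),
               tolerance = 1e-6)

  set.seed(23)
  for (i in 1:50) {
    vals <- stats::rlnorm(sample(2:12, 1), log(40), 0.8)
    got <- noael_bounds(vals, 0.95, "normal_sd")
    want <- c(max(0, mean(vals) - z * sd(vals)), mean(vals) + z * sd(vals))
    expect_equal(as.numeric(got), want, tolerance = 1e-6)
  }

  expect_error(noael_bounds(17), "no confidence interval")
  expect_error(noael_bounds(c(-1, 5)), "positive")
})

test_that("nearest-neighbour NOAELs match a brute-force oracle with exclusions", {
  b <- generate_fixture_library("random_homologues", seed = 5, n = 20)
  nitro_alert <- alert_library(data.frame(
    alert_id = "excl_nitro", category = "dart",
    label = "aromatic nitro", smarts = "c[N+](=O)[O-]"))

  got <- nearest_neighbor_noaels(b$target, b$library, threshold = 0.7,
                                 exclusion_alerts = nitro_alert)

  # oracle: pairwise Tanimoto over all compounds, then drop alert matches
  fp <- fingerprints(b$library, "path")
  ids <- b$library$compound_id
  sims <- vapply(ids, function(id) tanimoto(fp, fp, b$target, id), numeric(1))
  neighbours <- names(sims)[sims >= 0.7]
  has_alert <- vapply(neighbours, function(id) {
    nrow(match_alerts(b$library, nitro_alert, id = id)) > 0
  }, logical(1))
  keep <- neighbours[!has_alert]
  expect_setequal(names(got), keep)
  expect_equal(unname(got[keep]), unname(b$noael[keep]))

  # without exclusions the target itself is in its own neighbour set
  all_nn <- nearest_neighbor_noaels(b$target, b$library, threshold = 0.7)
  expect_true(b$target %in% names(all_nn))

  # an impossible threshold gives an explicit empty status
  none <- nearest_neighbor_noaels("CCBr", b$library, threshold = 1)
  expect_length(none, 0)
  expect_equal(attr(none, "status"), "empty")
})
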