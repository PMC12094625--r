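test_that("prevalence-to-threshold follows the upper-tail normal quantile", {
  expect_equal(threshold_from_prevalence(0.5), 0)
  expect_equal(threshold_from_prevalence(0.02275), 2, tolerance = 1e-3)
  expect_equal(threshold_from_prevalence(0.20), 0.8416, tolerance = 1e-4)
  expect_error(threshold_from_prevalence(0), "inside")
  expect_error(threshold_from_prevalence(1.2), "inside")
})

test_that("relative classes carry the design's sharing coefficients", {
  rc <- relative_classes()
  expect_equal(rc$label, c("MZ", "DZ", "FS", "HST", "HSA"))
  expect_equal(rc$alpha, c(1, 0.5, 0.5, 0.25, 0.25))
  expect_equal(rc$gamma, c(1, 1, 1, 1, 0))
  expect_equal(rc$is_twin, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(relative_class("cousin"), "unknown")
})

test_that("parameter constructor enforces the variance constraints", {
  p <- toy_params()
  expect_equal(p$Ac + p$Cc + p$Ec, 1, tolerance = 1e-10)
  expect_equal(unname(p$loadings^2 + p$As + p$Cs + p$Es), rep(1, 4),
               tolerance = 1e-10)
  expect_error(model_params(0.5, 0.1, loadings = c(-0.2, 0.5, 0.5, 0.5),
                            As = rep(0.1, 4), Cs = rep(0, 4),
                            thresholds = rep(0, 4)),
               "non-negative")
  expect_error(disorder_set(prevalence = c(0.2, 0.2, 0.06, 1.5)), "inside")
  expect_error(disorder_set(labels = c("MD", "MD", "A", "B")), "unique")
})

test_that("pure unique-environment model implies the identity covariance", {
  p <- independence_params()
  for (cl in relative_classes()$label) {
    S <- pair_liability_covariance(p, cl)
    expect_equal(unclass(S), diag(8), ignore_attr = TRUE, tolerance = 1e-14)
  }
})

test_that("half-siblings reared apart receive no shared-environment terms", {
  p1 <- toy_params()
  # same A structure, very different C structure
  p2 <- model_params(Ac = p1$Ac, Cc = 0.3, loadings = p1$loadings,
                     As = p1$As, Cs = p1$Cs + 0.1,
                     thresholds = p1$thresholds)
  S1 <- pair_liability_covariance(p1, "HSA")
  S2 <- pair_liability_covariance(p2, "HSA")
  expect_equal(S1[1:4, 5:8], S2[1:4, 5:8], tolerance = 1e-14)
})

test_that("pair covariance is symmetric with unit diagonal, and assembles the factor structure", {
  set.seed(42)
  for (rep in 1:15) {
    lam <- runif(4, 0, 0.9)
    As <- runif(4, 0, 0.3); Cs <- runif(4, 0, 0.2)
    keep <- lam^2 + As + Cs < 0.95
    As[!keep] <- 0.01; Cs[!keep] <- 0.01
    Ac <- runif(1, 0, 0.7); Cc <- runif(1, 0, 0.25)
    p <- model_params(Ac, Cc, lam, As, Cs, thresholds = rnorm(4))
    for (cl in c("MZ", "FS", "HSA")) {
      S <- suppressWarnings(pair_liability_covariance(p, cl))
      expect_equal(max(abs(S - t(S))), 0, tolerance = 1e-12)
      expect_equal(unname(diag(S)), rep(1, 8), tolerance = 1e-12)
    }
  }
})

test_that("cross-pair covariance decreases from MZ to half-siblings reared apart", {
  p <- toy_params()
  covs <- sapply(c("MZ", "DZ", "FS", "HST", "HSA"), function(cl) {
    diag(pair_liability_covariance(p, cl)[1:4, 5:8])
  })
  for (i in 1:4) expect_true(all(diff(covs[i, ]) <= 1e-12))
})

test_that("simulated liabilities reproduce the model-implied covariance", {
  # reconstructed-reference-style values; Monte Carlo covariance oracle
  p <- model_params(Ac = 0.49, Cc = 0.04,
                    loadings = c(0.83, 0.83, 0.40, 0.40),
                    As = c(0.05, 0.05, 0.15, 0.15),
                    Cs = c(0.02, 0.02, 0.03, 0.03),
                    thresholds = rep(0, 4))
  S <- pair_liability_covariance(p, "MZ")
  L <- simulate_liability_pairs(p, "MZ", 1e6, seed = 2024)
  expect_lt(max(abs(cov(L) - S)), 0.01)
  expect_equal(S["p1_MD", "p2_MD"], 0.83^2 * (0.49 + 0.04) + 0.05 + 0.02,
               tolerance = 1e-12)
})

test_that("implied components decompose totals and flag undefined shares", {
  p <- independence_params()
  ic <- implied_components(p)
  expect_equal(ic$a2, unname(p$As))
  expect_equal(ic$e2, unname(p$Es))
  p2 <- model_params(0.49, 0.04, c(0.83, 0.5, 0.5, 0.5),
                     As = c(0.05, 0.1, 0.1, 0.1), Cs = rep(0.02, 4),
                     thresholds = rep(1, 4))
  ic2 <- implied_components(p2)
  expect_equal(ic2$a2[1], 0.387561, tolerance = 1e-10)
  expect_equal(ic2$a2_share_common[1], 0.871, tolerance = 1e-3)
  expect_equal(ic2$a2 + ic2$c2 + ic2$e2, rep(1, 4), tolerance = 1e-12)
  # negative specific estimate making the total negative -> undefined share
  p3 <- model_params(0.1, 0.04, c(0.3, 0.5, 0.5, 0.5),
                     As = c(-0.02, 0.1, 0.1, 0.1), Cs = rep(0.02, 4),
                     thresholds = rep(1, 4))
  expect_true(is.na(implied_components(p3)$a2_share_common[1]))
})

test_that("implied genetic correlation: identity, symmetry, degeneracy", {
  p <- model_params(0.49, 0.04, c(0.83, 0.83, 0.5, 0),
                    As = c(0.01, 0.05, 0.1, 0.3), Cs = rep(0.01, 4),
                    thresholds = rep(1, 4))
  expect_equal(implied_genetic_correlation(p, "MD", "MD"), 1)
  expect_equal(implied_genetic_correlation(p, 1, 2), 0.9198, tolerance = 1e-4)
  expect_equal(implied_genetic_correlation(p, 1, 2),
               implied_genetic_correlation(p, 2, 1))
  expect_equal(implied_genetic_correlation(p, 1, 4), 0)  # zero loading
  p_bad <- model_params(0.2, 0, c(0, 0.5, 0.5, 0.5),
                        As = c(-0.01, 0.1, 0.1, 0.1), Cs = rep(0, 4),
                        thresholds = rep(1, 4))
  expect_error(implied_genetic_correlation(p_bad, 1, 2), "undefined")
})

test_that("bivariate pair covariance follows the correlated-factors algebra", {
  bp0 <- bivariate_params(c("MD", "AD"), a2 = c(0.5, 0.5), c2 = c(0.1, 0.1),
                          rA = 0, rC = 0, rE = 0, thresholds = c(0.8, 0.8))
  S0 <- bivariate_pair_covariance(bp0, "MZ")
  expect_equal(S0["p1_MD", "p1_AD"], 0)
  expect_equal(S0["p1_MD", "p2_AD"], 0)
  bp1 <- bivariate_params(c("MD", "AD"), a2 = c(0.5, 0.5), c2 = c(0, 0),
                          rA = 1, rC = 0, rE = 0, thresholds = c(0.8, 0.8))
  S1 <- bivariate_pair_covariance(bp1, "MZ")
  expect_equal(S1["p1_MD", "p1_AD"], 0.5)
  expect_equal(S1["p1_MD", "p2_AD"], 0.5)
  # no C contribution anywhere cross-person for HSA
  bp2 <- bivariate_params(c("MD", "AD"), a2 = c(0.3, 0.3), c2 = c(0.2, 0.2),
                          rA = 0.5, rC = 0.9, rE = 0.1, thresholds = c(0.8, 0.8))
  S2 <- bivariate_pair_covariance(bp2, "HSA")
  expect_equal(S2["p1_MD", "p2_MD"], 0.25 * 0.3)
  expect_equal(S2["p1_MD", "p2_AD"], 0.25 * bp2$covA)
  # rC must be 0 when a c2 is negative
  expect_error(bivariate_params(c("A", "B"), c(0.3, 0.3), c(-0.05, 0.1),
                                rA = 0.5, rC = 0.5, rE = 0.2,
                                thresholds = c(1, 1)), "undefined")
})

test_that("reconstructed generating sets are valid and PSD in every class", {
  p <- reference_params()
  expect_equal(p$Ac + p$Cc + p$Ec, 1, tolerance = 1e-12)
  ic <- implied_components(p)
  expect_equal(ic$a2, c(0.339476, 0.395744, 0.21, 0.43), tolerance = 1e-6)
  for (cl in relative_classes()$label) {
    expect_gte(attr(pair_liability_covariance(p, cl), "min_eigenvalue"), -1e-10)
  }
  prs <- combn(p$disorders, 2)
  for (k in seq_len(ncol(prs))) {
    bp <- default_bivariate_params(prs[1, k], prs[2, k])
    expect_equal(unname(bp$a2 + bp$c2 + bp$e2), c(1, 1), tolerance = 1e-12)
    for (cl in relative_classes()$label) {
      expect_gte(attr(bivariate_pair_covariance(bp, cl), "min_eigenvalue"),
                 -1e-10)
    }
  }
})

test_that("parameters survive a JSON round trip", {
  p <- reference_params()
  q <- params_from_json(params_to_json(p))
  expect_equal(q$loadings, p$loadings, tolerance = 1e-12)
  expect_equal(q$Cs, p$Cs, tolerance = 1e-12)
  expect_equal(q$thresholds, p$thresholds, tolerance = 1e-12)
  bp <- default_bivariate_params("IBS", "FM")
  bq <- params_from_json(params_to_json(bp))
  expect_equal(bq$covC, bp$covC)
  expect_true(is.na(bq$rC))  # negative IBS c2: C correlation undefined
  expect_equal(bq$rA, bp$rA)
  f <- tempfile(fileext = ".json")
  params_to_json(p, f)
  expect_equal(params_from_json(f)$As, p$As, tolerance = 1e-12)
  expect_error(params_from_json('{"schema_version":"other"}'), "schema")
})
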