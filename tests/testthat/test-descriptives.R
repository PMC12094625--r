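test_that("crosstabs are built per member and symmetrized across members", {
  p <- toy_params()
  d <- simulate_pairs(simulation_scenario(p, c(MZ = 2000), seed = 6))
  # within-individual table ignores member 2
  t1 <- build_crosstab(d, "MZ", "MD", "AD", type = "within_individual",
                       member = 1)
  d_mut <- d
  d_mut$p2_MD <- 1L - d_mut$p2_MD
  t1b <- build_crosstab(d_mut, "MZ", "MD", "AD", type = "within_individual",
                        member = 1)
  expect_identical(t1, t1b)
  # symmetrized cross-relative table: swapping the disorder roles transposes
  tx <- build_crosstab(d, "MZ", "MD", "AD")
  ty <- build_crosstab(d, "MZ", "AD", "MD")
  expect_identical(tx, t(ty))
  expect_equal(sum(tx), 2 * nrow(d))
  expect_error(build_crosstab(d, "FS", "MD", "AD"), "not present")
  expect_error(build_crosstab(d, "MZ", "XX", "AD"), "unknown disorder")
})

test_that("cross-relative tetrachorics agree with the model-implied covariance", {
  p <- reference_params()
  d <- simulate_pairs(simulation_scenario(p, c(MZ = 3e4), seed = 14))
  tc <- tetrachoric(build_crosstab(d, "MZ", "MD", "MD"))
  implied <- pair_liability_covariance(p, "MZ")["p1_MD", "p2_MD"]
  expect_lt(abs(tc$r - implied), 3 * tc$se)
})

test_that("correlation summary covers the three families with fixed ordering", {
  p <- toy_params()
  d <- simulate_pairs(simulation_scenario(
    p, c(HSA = 4000, MZ = 3000, FS = 5000), seed = 19))
  cs <- correlation_summary(d)
  # classes in design order, absent classes omitted
  expect_equal(unique(cs$class), c("MZ", "FS", "HSA"))
  for (cl in unique(cs$class)) {
    sub <- cs[cs$class == cl, ]
    expect_equal(sum(sub$family == "cross_relative_within_disorder"), 4L)
    expect_equal(sum(sub$family == "within_individual"), 6L)
    expect_equal(sum(sub$family == "cross_relative_cross_disorder"), 12L)
  }
  # symmetrized tables: r(a,b) equals r(b,a) in the cross-relative family
  ccd <- cs[cs$family == "cross_relative_cross_disorder" & cs$class == "MZ", ]
  for (i in seq_len(nrow(ccd))) {
    j <- which(ccd$disorder_a == ccd$disorder_b[i] &
                 ccd$disorder_b == ccd$disorder_a[i])
    expect_equal(ccd$r[i], ccd$r[j], tolerance = 1e-12)
  }
})

test_that("summary is invariant to within-pair member order", {
  p <- toy_params()
  d <- simulate_pairs(simulation_scenario(p, c(MZ = 2000, FS = 3000), seed = 25))
  d_sw <- d
  for (dd in p$disorders) {
    d_sw[[paste0("p1_", dd)]] <- d[[paste0("p2_", dd)]]
    d_sw[[paste0("p2_", dd)]] <- d[[paste0("p1_", dd)]]
  }
  attr(d_sw, "disorders") <- attr(d, "disorders")
  cs1 <- correlation_summary(d)
  cs2 <- correlation_summary(d_sw)
  expect_equal(cs1$r, cs2$r, tolerance = 1e-12)
})

test_that("independence data yield near-zero correlations throughout", {
  p <- independence_params(prev = rep(0.25, 4))
  d <- simulate_pairs(simulation_scenario(p, c(MZ = 2e4, FS = 2e4), seed = 33))
  cs <- correlation_summary(d)
  ok <- cs$status == "ok"
  expect_gt(mean(ok), 0.95)
  z <- abs(cs$r[ok]) / cs$se[ok]
  expect_lt(mean(z > 3), 0.05)  # 52 comparisons: allow the odd excursion
  expect_lt(max(z), 5)
})

test_that("reference simulation reproduces the expected comorbidity correlation", {
  p <- reference_params()
  d <- simulate_pairs(simulation_scenario(p, c(FS = 5e4), seed = 41))
  t_md_ad <- build_crosstab(d, "FS", "MD", "AD", type = "within_individual") +
    build_crosstab(d, "FS", "MD", "AD", type = "within_individual", member = 2)
  tc <- tetrachoric(t_md_ad)
  expect_lt(abs(tc$r - unname(p$loadings["MD"] * p$loadings["AD"])), 3 * tc$se)
  expect_equal(unname(p$loadings["MD"] * p$loadings["AD"]), 0.6888,
               tolerance = 1e-4)
})

test_that("the wide TSV renders undefined cells as dashes", {
  p <- toy_params()
  d <- simulate_pairs(simulation_scenario(p, c(MZ = 400, HST = 300), seed = 7))
  # force an empty FM margin in HST by zeroing the rare disorder
  d$p1_FM[d$relative_class == "HST"] <- 0L
  d$p2_FM[d$relative_class == "HST"] <- 0L
  cs <- correlation_summary(d)
  f <- tempfile(fileext = ".tsv")
  write_correlation_summary(cs, f)
  wide <- read.delim(f, check.names = FALSE)
  expect_true(all(c("MZ", "HST") %in% names(wide)))
  fm_row <- wide[wide$family == "cross_relative_within_disorder" &
                   wide$disorder_a == "FM", ]
  expect_equal(fm_row$HST, "-")
})
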