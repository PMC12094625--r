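test_that("simulation is bit-exact reproducible and round-trips through TSV", {
  sc <- default_scenario(scale = 0.005, seed = 77)
  d1 <- simulate_pairs(sc)
  d2 <- simulate_pairs(sc)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_identical(attr(d1, "scenario_hash"), attr(d2, "scenario_hash"))
  f <- tempfile(fileext = ".tsv")
  write_pair_dataset(d1, f, scenario = sc)
  d3 <- read_pair_dataset(f)
  expect_equal(as.data.frame(d3)$p1_MD, d1$p1_MD)
  expect_true(file.exists(paste0(f, ".scenario.json")))
  side <- jsonlite::fromJSON(paste0(f, ".scenario.json"))
  expect_equal(side$seed, 77)
})

test_that("default scenario reproduces the registry design counts", {
  sc <- default_scenario(scale = 1)
  expect_equal(unname(sc$counts),
               c(8052, 7216, 712762, 23623, 53873))
  sc2 <- default_scenario(scale = 0.01)
  expect_true(all(sc2$counts >= 0))
  expect_equal(unname(sc2$counts), round(c(8052, 7216, 712762, 23623, 53873) * 0.01))
})

test_that("observed prevalences match the thresholds in every class", {
  sc <- default_scenario(scale = 0.1, seed = 5)
  d <- simulate_pairs(sc)
  p <- sc$params
  for (cl in unique(d$relative_class)) {
    dc <- d[d$relative_class == cl, ]
    n2 <- 2 * nrow(dc)
    for (i in seq_along(p$disorders)) {
      K <- pnorm(famliab:::thresholds_for_class(p, cl)[i], lower.tail = FALSE)
      obs <- mean(c(dc[[paste0("p1_", p$disorders[i])]],
                    dc[[paste0("p2_", p$disorders[i])]]))
      expect_lt(abs(obs - K), 3 * sqrt(K * (1 - K) / n2) + 1e-9)
    }
  }
})

test_that("unique-environment-only model yields uncorrelated pair members", {
  p <- independence_params(prev = rep(0.3, 4))
  sc <- simulation_scenario(p, c(MZ = 1e5), seed = 9)
  d <- simulate_pairs(sc)
  for (i in 1:4) {
    r <- cor(d[[paste0("p1_", p$disorders[i])]],
             d[[paste0("p2_", p$disorders[i])]])
    expect_lt(abs(r), 3 / sqrt(nrow(d)))
  }
})

test_that("empirical pattern frequencies match the model probabilities", {
  p <- toy_params()
  n <- 1e6
  d <- simulate_pairs(simulation_scenario(p, c(MZ = n), seed = 13))
  counts <- pattern_counts(d)$classes$MZ
  probs <- pattern_probabilities(p, "MZ")
  se <- sqrt(probs * (1 - probs) / n)
  z <- abs(counts / n - probs) / pmax(se, 1e-12)
  # 256 simultaneous comparisons: allow the expected handful past 3 MC SEs
  expect_lt(sum(z > 3), 4)
  expect_lt(max(z), 5)
})

test_that("concordance is ordered MZ >= HSA for non-negative components", {
  p <- toy_params()
  d <- simulate_pairs(simulation_scenario(p, c(MZ = 1e5, HSA = 1e5), seed = 21))
  conc <- function(cl) {
    dc <- d[d$relative_class == cl, ]
    mean(dc$p1_MD & dc$p2_MD)
  }
  expect_gte(conc("MZ"), conc("HSA"))
})

test_that("non-PSD specific structure is rejected with the class named", {
  p <- model_params(Ac = 0.1, Cc = 0, loadings = c(0.9, 0.5, 0.5, 0.5),
                    As = c(0.3, 0.1, 0.1, 0.1), Cs = rep(0, 4),
                    thresholds = rep(1, 4))
  # MZ: specific covariance 0.3 > specific variance 1 - 0.81 = 0.19
  expect_error(simulate_pairs(simulation_scenario(p, c(MZ = 10), seed = 1)),
               "MZ")
})

test_that("bivariate simulation is reproducible and respects independence", {
  bp0 <- bivariate_params(c("MD", "AD"), a2 = c(0.4, 0.4), c2 = c(0.05, 0.05),
                          rA = 0, rC = 0, rE = 0,
                          thresholds = threshold_from_prevalence(c(0.2, 0.2)))
  d1 <- simulate_bivariate(bp0, c(FS = 1e5), seed = 3)
  d2 <- simulate_bivariate(bp0, c(FS = 1e5), seed = 3)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  # disorders independent: within-person and cross-person cross-disorder
  expect_lt(abs(cor(d1$p1_MD, d1$p1_AD)), 3 / sqrt(nrow(d1)))
  expect_lt(abs(cor(d1$p1_MD, d1$p2_AD)), 3 / sqrt(nrow(d1)))
  # with rA = 1 and identical components, cross-disorder cross-person
  # concordance matches same-disorder concordance within sampling error
  bp1 <- bivariate_params(c("MD", "AD"), a2 = c(0.4, 0.4), c2 = c(0, 0),
                          rA = 1, rC = 0, rE = 0,
                          thresholds = threshold_from_prevalence(c(0.2, 0.2)))
  d3 <- simulate_bivariate(bp1, c(FS = 2e5), seed = 4)
  c_same <- mean(d3$p1_MD & d3$p2_MD)
  c_cross <- mean(d3$p1_MD & d3$p2_AD)
  se <- sqrt(c_same * (1 - c_same) / nrow(d3))
  expect_lt(abs(c_same - c_cross), 4 * se)
})
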