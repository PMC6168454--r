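test_that("identity covariance structures decompose to identity correlations", {
  S_i <- diag(2); S_r <- diag(2)
  d <- make_bivariate_panel(250, 2, S_i, S_r, seed = 61)
  d$population <- "A"
  dec <- suppressMessages(pols_decompose(d, c("y1", "y2"), fixed = ~1,
                                         nboot = 100, control = fast_ctrl))
  expect_equal(diag(dec$corr_ind), c(y1 = 1, y2 = 1))
  expect_lt(abs(dec$corr_ind[1, 2]), 0.2)
  expect_lt(abs(dec$corr_res[1, 2]), 0.2)
  expect_gt(dec$per_element_lrt[["y1~y2"]]$p_value, 0.05)
})

test_that("a strong among-individual correlation is detected and recovered", {
  S_i <- matrix(c(1, 0.7, 0.7, 1), 2); S_r <- diag(2)
  hits <- 0; est <- numeric(0)
  for (s in 1:10) {
    d <- make_bivariate_panel(150, 2, S_i, S_r, seed = 600 + s)
    d$population <- "A"
    dec <- suppressMessages(pols_decompose(d, c("y1", "y2"), fixed = ~1,
                                           nboot = 50, control = fast_ctrl))
    est <- c(est, dec$corr_ind[1, 2])
    hits <- hits + (dec$per_element_lrt[["y1~y2"]]$p_value < 0.05)
  }
  expect_gte(hits, 8)   # >= 80% power at this n
  expect_lt(abs(mean(est) - 0.7), 3 * sd(est) / sqrt(length(est)))
  # correlation definition holds: corr = cov / sqrt(var_i var_j)
  expect_equal(dec$corr_ind[1, 2],
               dec$sigma_ind[1, 2] / sqrt(dec$sigma_ind[1, 1] * dec$sigma_ind[2, 2]),
               tolerance = 1e-10)
})

test_that("trait-level variance+covariance test uses the df k / k+1 mixture", {
  expect_equal(lrt_mixture("variance_covariance", df = 1),
               data.frame(weight = c(0.5, 0.5), df = c(1, 2)))
  S_i <- matrix(c(0.6, 0.3, 0.3, 0.6), 2); S_r <- diag(2)
  d <- make_bivariate_panel(120, 3, S_i, S_r, seed = 71)
  d$population <- "A"
  lr <- suppressMessages(test_variance_and_covariance(d, c("y1", "y2"), "y2",
                                                      fixed = ~1,
                                                      control = fast_ctrl))
  expect_equal(lr$mixture$df, c(1, 2))
  expect_lt(lr$p_value, 0.05)
  # null target trait: no among variance, no covariance
  S_i0 <- diag(c(0.6, 0));
  d0 <- make_bivariate_panel(60, 3, S_i0, S_r, seed = 72)
  d0$population <- "A"
  lr0 <- suppressMessages(test_variance_and_covariance(d0, c("y1", "y2"), "y2",
                                                       fixed = ~1,
                                                       control = fast_ctrl))
  expect_gt(lr0$p_value, 0.05)
})

test_that("overall structure test df equals the number of trait pairs", {
  panel <- simulate_trait_panel(sim_config(n_individuals = 16, seed = 73))
  tr <- c("hiding_time", "distance_moved", "smr", "standard_size")
  lr <- suppressMessages(test_overall_structure(panel, tr, population = "SG",
                                                control = fast_ctrl))
  expect_equal(lr$mixture$df, 6)
  expect_equal(lr$mixture$weight, 1)
})

test_that("overall statistic dominates any single-element statistic", {
  panel <- simulate_trait_panel(sim_config(n_individuals = 25, seed = 74))
  tr <- c("hiding_time", "distance_moved", "smr")
  dec <- suppressMessages(pols_decompose(panel, tr, population = "SG",
                                         nboot = 50, control = fast_ctrl))
  overall <- suppressMessages(test_overall_structure(panel, tr, population = "SG",
                                                     control = fast_ctrl))
  worst <- max(vapply(dec$per_element_lrt, function(l) l$statistic, numeric(1)))
  expect_gte(overall$statistic + 1e-4, worst)
})

test_that("cross-population equality test: df, power, and detection", {
  # opposite-sign among covariances (+/- 0.6 correlation) must be detected
  S_p <- matrix(c(1, 0.6, 0.6, 1), 2)
  S_m <- matrix(c(1, -0.6, -0.6, 1), 2)
  S_r <- diag(2)
  detected <- vapply(1:5, function(s) {
    dA <- make_bivariate_panel(40, 4, S_p, S_r, seed = 800 + s)
    dA$population <- "A"
    dB <- make_bivariate_panel(40, 4, S_m, S_r, seed = 900 + s)
    dB$population <- "B"
    dB$individual_id <- dB$individual_id + 1000
    lr <- suppressMessages(test_population_equality(rbind(dA, dB), c("y1", "y2"),
                                                    fixed = ~1,
                                                    control = fast_ctrl))
    expect_equal(lr$mixture$df, 1)   # one pair, two populations
    lr$p_value
  }, numeric(1))
  expect_gte(mean(detected < 0.05), 0.8)
  # identical structures: statistic should be modest
  dA <- make_bivariate_panel(40, 4, S_p, S_r, seed = 1100)
  dA$population <- "A"
  dB <- make_bivariate_panel(40, 4, S_p, S_r, seed = 1200)
  dB$population <- "B"; dB$individual_id <- dB$individual_id + 1000
  lr0 <- suppressMessages(test_population_equality(rbind(dA, dB), c("y1", "y2"),
                                                   fixed = ~1, control = fast_ctrl))
  expect_gt(lr0$p_value, 0.01)
  # a population missing a trait errors clearly
  dB2 <- dB[dB$trait == "y1", ]
  expect_error(test_population_equality(rbind(dA, dB2), c("y1", "y2"),
                                        fixed = ~1), "missing trait")
})

test_that("four traits give six pairwise covariance constraints", {
  expect_equal(choose(4, 2), 6)
  panel <- simulate_trait_panel(sim_config(n_individuals = 14, seed = 75))
  tr <- c("hiding_time", "distance_moved", "smr", "standard_size")
  lr <- suppressMessages(test_population_equality(panel, tr, control = fast_ctrl))
  expect_equal(lr$mixture$df, 6)
  expect_true(lr$statistic >= 0)
})

test_that("reported p-values are reproducible from serialized statistics", {
  panel <- simulate_trait_panel(sim_config(n_individuals = 18, seed = 76))
  tr <- c("hiding_time", "standard_size")
  dec <- suppressMessages(pols_decompose(panel, tr, population = "SG",
                                         nboot = 50, control = fast_ctrl))
  for (l in dec$per_element_lrt)
    expect_equal(l$p_value, mixture_lrt_p(l$statistic, l$mixture),
                 tolerance = 1e-12)
})
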