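test_that("noiseless single-state trace yields exact slopes with r2 = 1", {
  tr <- simulate_respirometry_trace(smr_slope = -0.01, active_slope = -0.05,
                                    p_active = 0, noise_sd = 0, seed = 1)
  ph <- extract_closed_phase_slopes(tr)
  closed_after <- ph[ph$start_time >= 3600, ]
  expect_true(all(abs(closed_after$slope - (-0.01)) < 1e-10))
  expect_true(all(closed_after$r_squared > 1 - 1e-12))
  expect_true(all(closed_after$retained))
})

test_that("first-hour phases are excluded regardless of fit quality", {
  tr <- simulate_respirometry_trace(-0.01, -0.05, 0, noise_sd = 0, seed = 1)
  ph <- extract_closed_phase_slopes(tr)
  early <- ph[ph$start_time < 3600, ]
  expect_gt(nrow(early), 0)
  expect_false(any(early$retained))
  expect_true(all(grepl("acclimation", early$reason)))
  # a phase starting at 30 min is acclimation even with a perfect line
  expect_false(any(ph$retained[ph$start_time < 1800 + 1]))
})

test_that("curvature that drops r2 below 0.95 causes rejection", {
  tr <- simulate_respirometry_trace(-0.02, -0.08, 0, noise_sd = 0, seed = 2)
  # inject quadratic curvature into one late closed phase; choose the bend so
  # an independently computed OLS r2 falls below the threshold
  target <- with(as.data.frame(tr), unique(phase_id[phase_type == "closed" &
                                                      time_s > 7200]))[1]
  idx <- which(tr$phase_id == target)
  tt <- tr$time_s[idx] - min(tr$time_s[idx])
  bend <- 0.5 * (tt - mean(tt))^2 / max(tt)^2
  tr$o2_mg_per_l[idx] <- tr$o2_mg_per_l[idx] + bend
  # independent r2: squared correlation of o2 with time over the trimmed window
  keep <- tt >= 120 & tt <= max(tt) - 120
  r2_oracle <- cor(tr$o2_mg_per_l[idx][keep], tt[keep])^2
  expect_lt(r2_oracle, 0.95)
  ph <- extract_closed_phase_slopes(tr)
  row <- ph[ph$phase_id == target, ]
  expect_equal(row$r_squared, r2_oracle, tolerance = 1e-8)
  expect_false(row$retained)
  expect_match(row$reason, "r2")
  # all other late phases survive: the filter is surgical
  others <- ph[ph$phase_id != target & ph$start_time >= 3600, ]
  expect_true(all(others$retained))
})

test_that("mass-specific conversion arithmetic is exact", {
  ph <- data.frame(phase_id = 1:4, slope = rep(-0.01, 4), r_squared = 1,
                   start_time = 4000 + 1:4, duration = 420, n_samples = 30,
                   retained = TRUE, reason = "")
  est <- estimate_smr(ph, fish_mass = 5e-4, chamber_volume = 1)
  # 0.01 * 60 * 1 / 0.0005 = 1200; identical rates collapse the mixture
  expect_equal(est$smr_mass_specific, 1200)
  expect_equal(est$mixture_means, c(1200, 1200))
})

test_that("EM separates two components and the lower mean is the SMR", {
  set.seed(10)
  x <- c(rnorm(60, 100, 5), rnorm(60, 200, 5))
  fit <- fit_normal_mixture2(x)
  expect_lt(abs(fit$means[1] - 100), 2)
  expect_lt(abs(fit$means[2] - 200), 2)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$weights > 0 & fit$weights < 1))
  # independent cross-check against a reference EM implementation
  if (requireNamespace("mclust", quietly = TRUE)) {
    suppressMessages(library(mclust))   # Mclust needs its namespace attached
    ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    expect_equal(sort(fit$means), sort(unname(ref$parameters$mean)),
                 tolerance = 0.02)
  }
})

test_that("EM recovery holds across seeds and multiple restarts break ties", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    x <- c(rnorm(60, 100, 5), rnorm(60, 200, 5))
    fit_normal_mixture2(x)$means[1] - 100
  }, numeric(1))
  expect_lt(max(abs(errs)) / 100, 0.02)
})

test_that("estimate_smr enforces the minimum-phase rule", {
  ph <- data.frame(phase_id = 1:3, slope = rep(-0.01, 3), r_squared = 1,
                   start_time = 4000 + 1:3, duration = 420, n_samples = 30,
                   retained = TRUE, reason = "")
  expect_error(estimate_smr(ph, fish_mass = 5e-4, chamber_volume = 1),
               "retained phases")
})

test_that("end-to-end SMR extraction tracks the resting state, not the mean", {
  # mixture lower mean must stay near the resting rate as activity increases
  rate_true <- 0.125 * 60 * 0.02 / 5e-4   # 300 mg O2 / kg / h
  est_at <- function(p_active, seed) {
    tr <- simulate_respirometry_trace(-0.125, -0.375, p_active, seed = seed)
    ph <- extract_closed_phase_slopes(tr)
    estimate_smr(ph)$smr_mass_specific
  }
  smr_low <- vapply(1:5, function(s) est_at(0.15, s), numeric(1))
  smr_high <- vapply(1:5, function(s) est_at(0.45, 50 + s), numeric(1))
  expect_lt(mean(abs(smr_low - rate_true)) / rate_true, 0.05)
  expect_lt(mean(abs(smr_high - rate_true)) / rate_true, 0.05)
  # the naive overall mean, by contrast, is pulled far above the resting rate
  tr <- simulate_respirometry_trace(-0.125, -0.375, 0.45, seed = 51)
  ph <- extract_closed_phase_slopes(tr)
  rates <- abs(ph$slope[ph$retained]) * 60 * 0.02 / 5e-4
  expect_gt(mean(rates), rate_true * 1.15)
})

test_that("mixture lower mean brackets the sample mean from below", {
  set.seed(77)
  x <- c(rnorm(50, 300, 20), rnorm(30, 600, 30))
  fit <- fit_normal_mixture2(x)
  expect_lte(fit$means[1], mean(x))
  expect_gte(fit$means[2], mean(x))
})

test_that("traces round-trip through CSV with metadata sidecar", {
  tr <- simulate_respirometry_trace(-0.02, -0.06, 0.3, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_respirometry_trace(tr, f)
  back <- read_respirometry_trace(f)
  expect_equal(back$o2_mg_per_l, tr$o2_mg_per_l, tolerance = 1e-10)
  expect_equal(attr(back, "fish_mass"), attr(tr, "fish_mass"))
  ph1 <- extract_closed_phase_slopes(tr)
  ph2 <- extract_closed_phase_slopes(back)
  expect_equal(ph1$slope, ph2$slope, tolerance = 1e-10)
})
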