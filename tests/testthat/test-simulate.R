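test_that("panel generation is deterministic and leaves global RNG untouched", {
  cfg <- sim_config(n_individuals = 10, seed = 42)
  set.seed(999); before <- .Random.seed
  p1 <- simulate_trait_panel(cfg)
  expect_identical(.Random.seed, before)
  p2 <- simulate_trait_panel(cfg)
  expect_identical(p1, p2)
  p3 <- simulate_trait_panel(sim_config(n_individuals = 10, seed = 43))
  expect_false(identical(p1$value, p3$value))
})

test_that("panel follows the design: schedule, coding, attrition, uniqueness", {
  cfg <- sim_config(seed = 5)
  panel <- simulate_trait_panel(cfg)
  expect_setequal(unique(panel$sex), c(-0.5, 0.5))
  expect_setequal(unique(panel$age_stage), c(-0.5, 0.5))
  # behavioural traits twice per stage, smr/size once per stage
  cnt <- with(panel[panel$individual_id == "SG_001", ],
              table(trait, age_stage))
  expect_equal(unname(cnt["hiding_time", ]), c(2, 2))
  expect_equal(unname(cnt["smr", ]), c(1, 1))
  expect_equal(unname(cnt["standard_size", ]), c(1, 1))
  # records are unique on (individual, stage, trial, trait)
  key <- with(panel, paste(individual_id, age_stage, trial, trait))
  expect_equal(anyDuplicated(key), 0L)
  # attrition: dropped individuals have no stage-2 records; counts match rates
  truth <- attr(panel, "truth")
  stage2 <- unique(panel$individual_id[panel$age_stage == 0.5])
  expect_length(intersect(truth$dropped, stage2), 0)
  expect_equal(sum(grepl("^SG", truth$dropped)), round(0.2 * 40))
  expect_equal(sum(grepl("^FG", truth$dropped)), round(0.025 * 40))
})

test_that("latent among-individual covariance matches the generating matrix", {
  # law-of-large-numbers check on the retained ground truth
  cfg <- sim_config(n_individuals = c(SG = 2000, FG = 2),
                    missing_rate = c(SG = 0, FG = 0), seed = 11)
  panel <- simulate_trait_panel(cfg)
  u <- attr(panel, "truth")$u$SG
  S_hat <- cov(u)
  S_true <- cfg$sigma_ind$SG
  # elementwise MC standard error of a covariance estimate
  for (i in seq_len(ncol(u))) for (j in seq_len(ncol(u))) {
    se <- sqrt((S_true[i, i] * S_true[j, j] + S_true[i, j]^2) / nrow(u))
    expect_lt(abs(S_hat[i, j] - S_true[i, j]), 3.5 * se)
  }
})

test_that("zero among-individual variance yields no excess variance of means", {
  tr <- "y"
  S0 <- matrix(0, 1, 1, dimnames = list(tr, tr))
  S1 <- matrix(1, 1, 1, dimnames = list(tr, tr))
  beta <- matrix(0, 1, 4, dimnames = list(tr, c("intercept", "age_stage", "sex", "trial")))
  cfg <- sim_config(n_individuals = c(A = 500), trait_names = tr,
                    sigma_ind = list(A = S0), sigma_res = list(A = S1),
                    beta = list(A = beta),
                    measured_per_stage = c(y = 1L),
                    missing_rate = c(A = 0), seed = 2)
  panel <- simulate_trait_panel(cfg)
  m <- tapply(panel$value, panel$individual_id, mean)  # 2 obs per individual
  excess <- var(m) - 1 / 2
  expect_lt(abs(excess), 3 * sqrt(2 / 500))
})

test_that("invalid configurations are rejected", {
  S_bad <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  S_ok <- diag(2); dimnames(S_ok) <- list(c("a", "b"), c("a", "b"))
  beta <- matrix(0, 2, 4, dimnames = list(c("a", "b"),
                                          c("intercept", "age_stage", "sex", "trial")))
  expect_error(sim_config(n_individuals = c(A = 10), trait_names = c("a", "b"),
                          sigma_ind = list(A = S_bad), sigma_res = list(A = S_ok),
                          beta = list(A = beta)),
               "positive semi-definite")
  expect_error(sim_config(n_individuals = c(A = 1), trait_names = c("a", "b"),
                          sigma_ind = list(A = S_ok), sigma_res = list(A = S_ok),
                          beta = list(A = beta)),
               ">= 2")
})

test_that("panel round-trips through CSV with ground-truth sidecar", {
  cfg <- sim_config(n_individuals = 5, seed = 3)
  panel <- simulate_trait_panel(cfg)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_trait_panel(panel, csv, truth_path = js)
  back <- read_trait_panel(csv)
  expect_equal(nrow(back), nrow(panel))
  expect_equal(back$value, panel$value, tolerance = 1e-12)
  truth <- jsonlite::fromJSON(js)
  expect_equal(truth$seed, 3)
  expect_equal(unlist(truth$n_individuals), c(SG = 5, FG = 5))
})

test_that("respirometry traces honour phase plans, mixture states and noise", {
  # noiseless, fully resting: every closed phase declines at exactly smr_slope
  tr <- simulate_respirometry_trace(smr_slope = -0.01, active_slope = -0.05,
                                    p_active = 0, noise_sd = 0, seed = 1)
  truth <- attr(tr, "truth")
  closed <- truth[truth$phase_type == "closed", ]
  expect_true(all(closed$true_slope == -0.01))
  expect_false(any(closed$active))
  # deterministic under seed
  tr2 <- simulate_respirometry_trace(-0.01, -0.05, 0.3, noise_sd = 0.02, seed = 9)
  tr3 <- simulate_respirometry_trace(-0.01, -0.05, 0.3, noise_sd = 0.02, seed = 9)
  expect_identical(tr2$o2_mg_per_l, tr3$o2_mg_per_l)
  # active states appear at roughly p_active
  st <- attr(tr2, "truth"); st <- st[st$phase_type == "closed", ]
  expect_gt(mean(st$active), 0.1); expect_lt(mean(st$active), 0.55)
  # plan with closed phases shorter than twice the trim margin is rejected
  bad_plan <- data.frame(phase_type = c("open", "closed"), duration_s = c(180, 200))
  expect_error(simulate_respirometry_trace(-0.01, -0.05, 0.3, phase_plan = bad_plan),
               "trim margin")
})

test_that("variance components are recovered across replicate small panels", {
  # univariate generating values: sigma_ind 0.382, sigma_res 0.106, 2 stages x 1
  tr <- "size"
  S_i <- matrix(0.382, 1, 1, dimnames = list(tr, tr))
  S_r <- matrix(0.106, 1, 1, dimnames = list(tr, tr))
  beta <- matrix(0, 1, 4, dimnames = list(tr, c("intercept", "age_stage", "sex", "trial")))
  ests <- t(vapply(1:30, function(s) {
    cfg <- sim_config(n_individuals = c(A = 60), trait_names = tr,
                      sigma_ind = list(A = S_i), sigma_res = list(A = S_r),
                      beta = list(A = beta), measured_per_stage = c(size = 1L),
                      missing_rate = c(A = 0), seed = 100 + s)
    p <- simulate_trait_panel(cfg)
    f <- mm_reml(p, tr, fixed = ~1, se = FALSE, control = fast_ctrl)
    c(f$sigma_ind[[1]][1, 1], f$sigma_res[[1]][1, 1])
  }, numeric(2)))
  mc_se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_lt(abs(mean(ests[, 1]) - 0.382), 3 * mc_se[1])
  expect_lt(abs(mean(ests[, 2]) - 0.106), 3 * mc_se[2])
})
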