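test_that("OLS layer: noiseless regression, group means, normal equations", {
  # noiseless line
  d <- data.frame(individual_id = 1:10, trait = "y", x = 1:10, value = 2 * (1:10))
  f <- suppressWarnings(fit_lm(d, "y", ~x))
  expect_equal(unname(coef(f)["x"]), 2, tolerance = 1e-12)
  # two-group coefficient equals the difference of group means
  set.seed(1)
  d2 <- data.frame(individual_id = 1:40, trait = "y",
                   population = rep(c("A", "B"), each = 20), value = rnorm(40))
  f2 <- fit_lm(d2, "y", ~population)
  expect_equal(unname(coef(f2)["populationB"]),
               mean(d2$value[d2$population == "B"]) -
                 mean(d2$value[d2$population == "A"]), tolerance = 1e-12)
  # random 20x3 design vs an independent direct normal-equation solve
  set.seed(2)
  X <- cbind(1, matrix(rnorm(40), 20, 2)); y <- rnorm(20)
  d3 <- data.frame(individual_id = 1:20, trait = "y",
                   x1 = X[, 2], x2 = X[, 3], value = y)
  f3 <- fit_lm(d3, "y", ~x1 + x2)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(coef(f3)), drop(beta_oracle), tolerance = 1e-10)
  # aliased columns are named
  d3$x3 <- d3$x1 + d3$x2
  expect_error(fit_lm(d3, "y", ~x1 + x2 + x3), "x3")
})

test_that("univariate REML equals the balanced one-way ANOVA closed form", {
  for (seed in c(1, 2, 3)) {
    d <- make_univariate_panel(10, 2, 1, 1, seed = seed)
    oracle <- anova_oneway_reml(d$value, d$individual_id, 2)
    f <- mm_reml(d, "y", fixed = ~1, se = FALSE, control = tight_ctrl)
    expect_lt(abs(f$sigma_ind[[1]][1, 1] - oracle["sigma_ind"]), 1e-6)
    expect_lt(abs(f$sigma_res[[1]][1, 1] - oracle["sigma_res"]), 1e-6)
  }
})

test_that("univariate REML with covariates matches lme4", {
  skip_if_not_installed("lme4")
  panel <- simulate_trait_panel(sim_config(n_individuals = 25, seed = 8))
  sub <- panel[panel$population == "SG", ]
  f <- mm_reml(sub, "hiding_time", control = tight_ctrl)
  d <- sub[sub$trait == "hiding_time", ]
  m <- lme4::lmer(value ~ age_stage + sex + trial + (1 | individual_id), d,
                  REML = TRUE)
  expect_equal(f$sigma_ind[[1]][1, 1],
               unname(lme4::VarCorr(m)$individual_id[1, 1]), tolerance = 1e-4)
  expect_equal(f$sigma_res[[1]][1, 1], unname(stats::sigma(m))^2, tolerance = 1e-4)
  expect_equal(f$reml_loglik, as.numeric(stats::logLik(m)), tolerance = 1e-5)
  expect_equal(unname(coef(f)), unname(lme4::fixef(m)), tolerance = 1e-5)
})

test_that("multivariate restricted likelihood matches dense brute force", {
  # <= 12 observations: 3 individuals x 2 occasions x 2 traits
  set.seed(3)
  toy <- expand.grid(individual_id = paste0("i", 1:3), occ = 1:2,
                     trait = c("a", "b"), stringsAsFactors = FALSE)
  toy$occasion <- paste0("o", toy$occ)
  toy$value <- rnorm(nrow(toy))
  f <- suppressMessages(mm_reml(toy, c("a", "b"), fixed = ~1, se = FALSE,
                                control = fast_ctrl))
  expect_lt(abs(brute_force_reml_ll(f) - f$reml_loglik), 1e-6)
  # and for a grouped fit with population-specific structure (4 individuals
  # per group so each group's covariance matrices are identified)
  toy2 <- expand.grid(individual_id = paste0("i", 1:8), occ = 1:2,
                      trait = c("a", "b"), stringsAsFactors = FALSE)
  toy2$occasion <- paste0("o", toy2$occ)
  toy2$value <- rnorm(nrow(toy2))
  toy2$population <- ifelse(toy2$individual_id %in% paste0("i", 1:4), "P", "Q")
  f2 <- suppressMessages(mm_reml(toy2, c("a", "b"), fixed = ~1,
                                 group = "population", se = FALSE,
                                 control = fast_ctrl))
  expect_lt(abs(brute_force_reml_ll(f2) - f2$reml_loglik), 1e-6)
})

test_that("boundary behaviour under a true zero variance", {
  at_zero <- vapply(1:40, function(s) {
    d <- make_univariate_panel(25, 2, 0, 1, seed = 200 + s)
    f <- mm_reml(d, "y", fixed = ~1, se = FALSE, control = fast_ctrl)
    f$sigma_ind[[1]][1, 1] < 1e-6
  }, logical(1))
  # about half of null replicates should pin the variance to the boundary
  expect_gt(mean(at_zero), 0.25)
  expect_lt(mean(at_zero), 0.8)
})

test_that("bivariate among-individual correlation is recovered", {
  S_i <- matrix(c(1, 0.8, 0.8, 1), 2)
  S_r <- diag(2)
  r_hat <- vapply(1:25, function(s) {
    d <- make_bivariate_panel(200, 2, S_i, S_r, seed = 300 + s)
    f <- mm_reml(d, c("y1", "y2"), fixed = ~1, se = FALSE, control = fast_ctrl)
    polsmm:::safe_cov2cor(f$sigma_ind[[1]])[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(r_hat) - 0.8), 3 * sd(r_hat) / sqrt(length(r_hat)))
})

test_that("permuting trait order permutes estimates and keeps the likelihood", {
  panel <- simulate_trait_panel(sim_config(n_individuals = 20, seed = 12))
  sub <- panel[panel$population == "SG", ]
  tr <- c("hiding_time", "distance_moved", "smr")
  f1 <- suppressMessages(mm_reml(sub, tr, se = FALSE, control = fast_ctrl))
  f2 <- suppressMessages(mm_reml(sub, rev(tr), se = FALSE, control = fast_ctrl))
  expect_equal(f1$reml_loglik, f2$reml_loglik, tolerance = 1e-4)
  expect_equal(f1$sigma_ind[[1]][tr, tr], f2$sigma_ind[[1]][tr, tr],
               tolerance = 5e-3)
})

test_that("panels are exchangeable over individual relabelling", {
  d <- make_univariate_panel(30, 3, 0.5, 1, seed = 17)
  f1 <- mm_reml(d, "y", fixed = ~1, se = FALSE, control = fast_ctrl)
  d2 <- d
  perm <- sample(unique(d$individual_id))
  d2$individual_id <- perm[match(d$individual_id, unique(d$individual_id))]
  f2 <- mm_reml(d2, "y", fixed = ~1, se = FALSE, control = fast_ctrl)
  expect_equal(f1$sigma_ind[[1]][1, 1], f2$sigma_ind[[1]][1, 1], tolerance = 1e-8)
  expect_equal(f1$reml_loglik, f2$reml_loglik, tolerance = 1e-8)
})

test_that("equality constraints never increase the restricted likelihood", {
  panel <- simulate_trait_panel(sim_config(n_individuals = 20, seed = 13))
  tr <- c("hiding_time", "standard_size")
  full <- suppressMessages(mm_reml(panel, tr, group = "population", se = FALSE,
                                   control = fast_ctrl))
  eq <- suppressMessages(mm_update(full, panel,
                                   constraints = list(among_equal_groups = "all"),
                                   se = FALSE, control = fast_ctrl))
  z <- suppressMessages(mm_update(full, panel,
                                  constraints = list(among_zero = "all"),
                                  se = FALSE, control = fast_ctrl))
  expect_lte(eq$reml_loglik, full$reml_loglik + 1e-6)
  expect_lte(z$reml_loglik, full$reml_loglik + 1e-6)
  expect_equal(full$n_parameters - 1L, eq$n_parameters)
  expect_equal(full$n_parameters - 2L, z$n_parameters)
})

test_that("Wald F reduces to the squared t ratio for single coefficients", {
  panel <- simulate_trait_panel(sim_config(n_individuals = 30, seed = 14))
  sub <- panel[panel$population == "SG", ]
  f <- mm_reml(sub, "standard_size", control = fast_ctrl)
  w <- wald_f_test(f, "age_stage")
  i <- which(f$beta_info$term == "age_stage")
  expect_equal(w$F, unname((f$beta[i] / f$se_beta[i])^2), tolerance = 1e-10)
  expect_equal(w$df1, 1)
  # huge effects give vanishing p
  sub2 <- sub
  idx <- sub2$trait == "standard_size"
  sub2$value[idx] <- sub2$value[idx] + 10 * sub2$age_stage[idx]
  f2 <- mm_reml(sub2, "standard_size", control = fast_ctrl)
  expect_lt(wald_f_test(f2, "age_stage")$p_value, 1e-6)
  expect_error(wald_f_test(f, "no_such_term"), "not found")
})

test_that("Wald F test is calibrated under the null", {
  # between-individual term (sex) with no true effect
  rej <- vapply(1:200, function(s) {
    d <- make_univariate_panel(30, 2, 0.4, 1, seed = 700 + s)
    d$sex <- rep(rep(c(-0.5, 0.5), 15), each = 2)
    f <- mm_reml(d, "y", fixed = ~sex, se = FALSE, control = fast_ctrl)
    wald_f_test(f, "sex")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.05 - 2.58 * sqrt(0.05 * 0.95 / 200))
  expect_lt(mean(rej), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200))
})

test_that("fits serialize to JSON and report convergence diagnostics", {
  d <- make_univariate_panel(15, 2, 0.5, 1, seed = 21)
  f <- mm_reml(d, "y", fixed = ~1, control = fast_ctrl)
  js <- jsonlite::fromJSON(mm_to_json(f))
  expect_equal(js$reml_loglik, f$reml_loglik, tolerance = 1e-10)
  expect_equal(js$sigma_ind[[1]][1, 1], f$sigma_ind[[1]][1, 1], tolerance = 1e-10)
  expect_true(js$converged)
  expect_type(js$grad_norm, "double")
})
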