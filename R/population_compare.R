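#' Between-population comparison of a life-history trait
#'
#' Linear model (one record per individual at the chosen stage) with
#' population as a fixed factor, optionally adjusted for a covariate measured
#' on the same records (standard size or body weight). Estimated marginal
#' means per population are evaluated at the pooled covariate mean.
#'
#' @param panel long-format panel.
#' @param trait life-history trait label.
#' @param adjust_for optional covariate column name (e.g. `"standard_size"`).
#' @param stage optional `age_stage` value to subset to (e.g. `0.5` for
#'   adults) when the trait is measured at both stages.
#' @param sex_subset optional: `"male"`/`"female"` (+0.5 / −0.5) for
#'   sex-limited traits; reported in the output.
#' @return object of class `mean_comparison`.
#' @export
compare_lht_means <- function(panel, trait, adjust_for = NULL, stage = NULL,
                              sex_subset = NULL) {
  dat <- panel[panel$trait == trait & !is.na(panel$value), , drop = FALSE]
  if (!is.null(stage)) dat <- dat[dat$age_stage == stage, , drop = FALSE]
  if (!is.null(sex_subset)) {
    sx <- if (sex_subset %in% c("male", "m", "0.5")) 0.5 else -0.5
    dat <- dat[dat$sex == sx, , drop = FALSE]
  }
  if (!nrow(dat)) stop("no observations for trait '", trait, "'")
  if (!is.null(adjust_for)) {
    # covariate values live on their own trait rows of the full panel
    cov_src <- panel[panel$trait == adjust_for & !is.na(panel$value),
                     c("individual_id", "age_stage", "value")]
    if (!nrow(cov_src))
      stop("no observations of adjustment covariate '", adjust_for, "'")
    cov_src <- aggregate(value ~ individual_id + age_stage, cov_src, mean)
    names(cov_src)[3] <- adjust_for
    dat <- merge(dat, cov_src, by = c("individual_id", "age_stage"),
                 all.x = TRUE, sort = FALSE)
    dat <- dat[complete.cases(dat[, adjust_for, drop = FALSE]), , drop = FALSE]
    # collinearity screen: a covariate explained almost entirely by population
    # cannot separate direct from mediated differences
    r2 <- summary(lm(dat[[adjust_for]] ~ factor(dat$population)))$r.squared
    if (is.finite(r2) && r2 > 0.95)
      warning("covariate '", adjust_for, "' is nearly collinear with population (R2 = ",
              round(r2, 3), "); adjusted comparison is ill-conditioned")
  }
  f <- if (is.null(adjust_for)) ~ population
       else as.formula(paste("~ population +", adjust_for))
  dat$population <- factor(dat$population)
  m <- fit_lm(dat, trait, f)

  pops <- levels(dat$population)
  grid <- data.frame(population = factor(pops, levels = pops))
  if (!is.null(adjust_for)) grid[[adjust_for]] <- mean(dat[[adjust_for]])
  X <- model.matrix(delete.response(terms(m$lm)), grid)
  emm <- drop(X %*% coef(m$lm))
  se_emm <- sqrt(diag(X %*% vcov(m$lm) %*% t(X)))
  pop_coef <- grep("^population", names(m$beta))
  out <- list(trait = trait, kind = "lm",
              means = setNames(emm, pops), se = setNames(se_emm, pops),
              difference = unname(m$beta[pop_coef]),
              se_difference = unname(m$se_beta[pop_coef]),
              p_value = unname(m$p[pop_coef]),
              covariate_adjustment = adjust_for %||% "none",
              n = nrow(dat), sex_subset = sex_subset %||% "all", model = m)
  class(out) <- "mean_comparison"
  out
}

#' Between-population comparison of behaviour or SMR via a mixed model
#'
#' Univariate individual-random-intercept LMM with population, age, sex,
#' standard size, Fulton's K and (for repeated traits) trial as fixed effects.
#' Estimated marginal means per population are evaluated at the reference
#' grid: centred continuous covariates at their pooled mean, the ±0.5-coded
#' factors at 0 (the design midpoint). The population effect is tested with a
#' Wald F test using containment degrees of freedom.
#'
#' @param panel long-format panel, standardized pooled across populations so
#'   population mean differences survive centring.
#' @param trait behavioural trait or `"smr"`.
#' @param covariates stage-level covariate traits to adjust for.
#' @param control optimizer control.
#' @return object of class `mean_comparison`.
#' @export
compare_behaviour_smr <- function(panel, trait,
                                  covariates = c("standard_size", "fulton_k"),
                                  control = mm_control()) {
  covariates <- intersect(covariates, setdiff(unique(panel$trait), trait))
  dat <- attach_stage_covariates(panel, covariates)
  dat <- dat[dat$trait == trait | dat$trait %in% covariates, , drop = FALSE]
  dat$population <- factor(dat$population)
  pops <- levels(dat$population)

  sub0 <- dat[dat$trait == trait, ]
  has_trial <- {
    key <- paste(sub0$individual_id, sub0$age_stage)
    any(tapply(sub0$trial, key, function(x) length(unique(x))) > 1, na.rm = TRUE)
  }
  varies <- function(v) v %in% names(sub0) && length(unique(sub0[[v]][!is.na(sub0[[v]])])) > 1
  terms <- c("population",
             if (varies("age_stage")) "age_stage",
             if (varies("sex")) "sex",
             Filter(varies, covariates),
             if (has_trial) "trial")
  covariates <- intersect(covariates, terms)
  f <- as.formula(paste("~", paste(terms, collapse = "+")))
  fit <- mm_reml(dat, trait, fixed = f, se = FALSE, control = control)

  info <- fit$beta_info
  sub <- dat[dat$trait == trait, ]
  ref <- list("(Intercept)" = 1, age_stage = 0, sex = 0)
  for (cv in covariates) ref[[cv]] <- mean(sub[[cv]], na.rm = TRUE)
  if (has_trial) ref$trial <- mean(sub$trial, na.rm = TRUE)

  xrow <- function(pop) {
    v <- numeric(nrow(info))
    for (k in seq_len(nrow(info))) {
      nm <- sub("^[^:]+:", "", info$name[k])
      v[k] <- if (nm %in% names(ref)) ref[[nm]]
        else if (grepl("^population", nm)) as.numeric(nm == paste0("population", pop))
        else 0
    }
    v
  }
  X <- do.call(rbind, lapply(pops, xrow))
  emm <- drop(X %*% fit$beta)
  se_emm <- sqrt(diag(X %*% fit$vcov_beta %*% t(X)))
  wt <- wald_f_test(fit, "population", response = trait)

  pop_idx <- which(info$term == "population")
  out <- list(trait = trait, kind = "lmm",
              means = setNames(emm, pops), se = setNames(se_emm, pops),
              difference = unname(fit$beta[pop_idx]),
              se_difference = unname(fit$se_beta[pop_idx]),
              p_value = wt$p_value, wald = wt,
              covariate_adjustment = if (length(covariates))
                paste(covariates, collapse = "+") else "none",
              n = fit$n_obs, sex_subset = "all", model = fit)
  class(out) <- "mean_comparison"
  out
}

#' @export
print.mean_comparison <- function(x, ...) {
  cat(sprintf("Population comparison for '%s' (%s, adjustment: %s, n = %d)\n",
              x$trait, x$kind, x$covariate_adjustment, x$n))
  for (p in names(x$means))
    cat(sprintf("  %-4s mean %8.3f (SE %.3f)\n", p, x$means[p], x$se[p]))
  cat(sprintf("  difference %.3f (SE %.3f), p = %.4g\n",
              x$difference[1], x$se_difference[1], x$p_value))
  invisible(x)
}

#' Population comparison table over several traits
#'
#' @param panel long-format panel.
#' @param lht_traits traits compared with linear models (once per individual
#'   at the adult stage unless they vary over stages).
#' @param repeated_traits traits compared with the mixed model.
#' @param ... passed to the underlying comparison functions.
#' @return data frame, one row per trait.
#' @export
population_comparison_table <- function(panel, lht_traits = character(0),
                                        repeated_traits = character(0), ...) {
  rows <- list()
  add <- function(cmp) {
    pops <- names(cmp$means)
    rows[[length(rows) + 1L]] <<- data.frame(
      trait = cmp$trait, kind = cmp$kind,
      mean_1 = cmp$means[1], se_1 = cmp$se[1],
      mean_2 = cmp$means[2], se_2 = cmp$se[2],
      p_value = cmp$p_value, adjustment = cmp$covariate_adjustment,
      n = cmp$n, stringsAsFactors = FALSE, row.names = NULL)
  }
  for (tr in lht_traits) add(compare_lht_means(panel, tr, ...))
  for (tr in repeated_traits) add(compare_behaviour_smr(panel, tr))
  do.call(rbind, rows)
}
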