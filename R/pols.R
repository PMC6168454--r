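#' Among- vs within-individual covariance decomposition for a trait set
#'
#' Fits the multivariate individual-random-intercept model by REML for one
#' population with unstructured among-individual and residual covariance
#' blocks, derives the among-individual (syndrome) and residual correlation
#' matrices, and — optionally — tests every among-individual covariance
#' element with a likelihood-ratio test against the fit with that single
#' element constrained to zero. Covariances are unbounded, so the element
#' tests use a pure chi-square with 1 df. Trait pairs never measured on a
#' shared occasion have their residual covariance fixed to zero and are
#' excluded from residual-correlation interpretation.
#'
#' @param panel long-format panel (values standardized within population
#'   recommended).
#' @param traits traits that passed the repeatability gate.
#' @param population population label to subset to; `NULL` uses the panel
#'   as-is.
#' @param fixed fixed-effect formulas, default as in [mm_reml()].
#' @param element_tests run the per-element LRTs (one refit per trait pair).
#' @param se_method,nboot,seed correlation standard errors by parametric
#'   bootstrap from the asymptotic distribution of the variance parameters.
#' @param control optimizer control.
#' @return object of class `pols_decomposition` with `sigma_ind`, `sigma_res`
#'   (plus SE matrices), `corr_ind`, `corr_res`, `corr_ind_se`,
#'   `per_element_lrt`, and the underlying `fit`.
#' @export
pols_decompose <- function(panel, traits, population = NULL, fixed = NULL,
                           element_tests = TRUE, se_method = "boot",
                           nboot = 400L, seed = 1L, control = mm_control()) {
  if (!is.null(population)) {
    panel <- panel[panel$population == population, , drop = FALSE]
    if (!nrow(panel)) stop("no rows for population '", population, "'")
  }
  fit <- mm_reml(panel, traits, fixed = fixed, among = "us", residual = "us",
                 se = TRUE, control = control)
  Sind <- fit$sigma_ind[[1]]; Sres <- fit$sigma_res[[1]]
  corr_ind <- safe_cov2cor(Sind)
  corr_res <- safe_cov2cor(Sres)

  corr_ind_se <- corr_boot_se(fit, nboot, seed)

  per_element <- list()
  if (element_tests) {
    pairs <- utils::combn(traits, 2, simplify = FALSE)
    for (pr in pairs) {
      key <- paste(pr, collapse = "~")
      red <- mm_update(fit, panel,
                       constraints = modifyList(fit$constraints,
                                                list(among_zero = list(pr))),
                       se = FALSE, control = control)
      per_element[[key]] <- lrt_mm(fit, red, lrt_mixture("chisq", df = 1),
                                   label = "chi2_1 (unbounded covariance)")
    }
  }

  out <- list(population = population %||% "(all)", traits = traits,
              sigma_ind = Sind, sigma_res = Sres,
              sigma_ind_se = fit$sigma_ind_se[[1]],
              sigma_res_se = fit$sigma_res_se[[1]],
              corr_ind = corr_ind, corr_res = corr_res,
              corr_ind_se = corr_ind_se,
              per_element_lrt = per_element, fit = fit)
  class(out) <- "pols_decomposition"
  out
}

safe_cov2cor <- function(S) {
  d <- sqrt(pmax(diag(S), 0))
  C <- S / outer(d, d)
  diag(C) <- 1
  C[!is.finite(C)] <- NA_real_
  C
}

# Parametric-bootstrap SEs of the among-individual correlations.
corr_boot_se <- function(fit, nboot, seed) {
  if (is.null(fit$theta_vcov)) return(NULL)
  pm <- fit$parmap
  Tn <- length(fit$responses)
  th <- with_seed(seed, rmvn(nboot, fit$theta, fit$theta_vcov))
  acc <- array(NA_real_, c(Tn, Tn, nboot))
  sub <- pm[pm$mat == "ind" & pm$g == 1L, ]
  for (b in seq_len(nboot)) {
    S <- matrix(0, Tn, Tn)
    for (r in seq_len(nrow(sub))) {
      v <- if (is.na(sub$par[r])) sub$fixed[r] else {
        x <- th[b, sub$par[r]]
        if (sub$kind[r] == "var") pmin(exp(2 * pmin(x, 12)), 1e10) else x
      }
      S[sub$i[r], sub$j[r]] <- v; S[sub$j[r], sub$i[r]] <- v
    }
    acc[, , b] <- safe_cov2cor(S)
  }
  se <- apply(acc, c(1, 2), sd, na.rm = TRUE)
  dimnames(se) <- dimnames(fit$sigma_ind[[1]])
  diag(se) <- 0
  se
}

#' @export
print.pols_decomposition <- function(x, ...) {
  cat("POLS covariance decomposition [", x$population, "], traits: ",
      paste(x$traits, collapse = ", "), "\n", sep = "")
  cat("\nAmong-individual correlations (SE) [p from chi2_1 LRT]:\n")
  Tn <- length(x$traits)
  for (i in seq_len(Tn - 1)) for (j in (i + 1):Tn) {
    key1 <- paste(x$traits[c(i, j)], collapse = "~")
    key2 <- paste(x$traits[c(j, i)], collapse = "~")
    lr <- x$per_element_lrt[[key1]] %||% x$per_element_lrt[[key2]]
    cat(sprintf("  %-18s ~ %-18s %6.3f (%5.3f)%s\n", x$traits[i], x$traits[j],
                x$corr_ind[i, j],
                if (!is.null(x$corr_ind_se)) x$corr_ind_se[i, j] else NA,
                if (!is.null(lr)) sprintf("  p = %.4g%s", lr$p_value,
                                          if (lr$p_value < 0.05) " *" else "")
                else ""))
  }
  cat("\nResidual (within-individual) correlations:\n")
  print(round(x$corr_res, 3))
  invisible(x)
}

#' Test one trait's among-individual variance and covariances jointly
#'
#' Compares the full multivariate fit to the fit with the target trait's
#' among-individual variance and all its covariances removed. Under the null
#' the variance sits on the boundary while the k covariances are unbounded,
#' so the reference distribution is the equal mixture of chi-square with k and
#' k + 1 df (k = number of covariances removed; with two traits this is the
#' classic one-variance-one-covariance mixture of df 1 and 2).
#'
#' @inheritParams pols_decompose
#' @param target_trait the trait whose among-individual terms are dropped.
#' @return an `mm_lrt`.
#' @export
test_variance_and_covariance <- function(panel, traits, target_trait,
                                         population = NULL, fixed = NULL,
                                         control = mm_control()) {
  stopifnot(target_trait %in% traits)
  if (!is.null(population)) panel <- panel[panel$population == population, , drop = FALSE]
  full <- mm_reml(panel, traits, fixed = fixed, among = "us", residual = "us",
                  se = FALSE, control = control)
  red <- mm_update(full, panel,
                   constraints = modifyList(full$constraints,
                                            list(drop_trait = target_trait)),
                   se = FALSE, control = control)
  k <- length(traits) - 1L
  lrt_mm(full, red, lrt_mixture("variance_covariance", df = k),
         label = sprintf("equal mixture chi2_%d + chi2_%d (boundary variance + %d covariances)",
                         k, k + 1L, k))
}

#' Cross-population equality test of the among-individual covariance structure
#'
#' Fits both populations jointly with population-specific fixed effects and
#' covariance matrices, then refits with every among-individual pairwise
#' covariance constrained equal across populations. Variances and all residual
#' structure stay population-specific, so the two fits differ by exactly
#' `choose(T, 2)` unbounded covariance parameters and the statistic is
#' referred to a pure chi-square on that many df.
#'
#' @inheritParams pols_decompose
#' @param group name of the population column.
#' @return an `mm_lrt` with the number of constrained pairs as df.
#' @export
test_population_equality <- function(panel, traits, group = "population",
                                     fixed = NULL, control = mm_control()) {
  pops <- unique(panel[[group]])
  if (length(pops) < 2L) stop("need at least two populations")
  for (p in pops) {
    miss <- setdiff(traits, unique(panel$trait[panel[[group]] == p]))
    if (length(miss))
      stop("population '", p, "' is missing trait(s): ", paste(miss, collapse = ", "))
  }
  full <- mm_reml(panel, traits, fixed = fixed, group = group, among = "us",
                  residual = "us", se = FALSE, control = control)
  red <- mm_update(full, panel,
                   constraints = modifyList(full$constraints,
                                            list(among_equal_groups = "all")),
                   se = FALSE, control = control)
  df <- choose(length(traits), 2) * (length(pops) - 1L)
  lrt_mm(full, red, lrt_mixture("chisq", df = df),
         label = sprintf("chi2_%d (pairwise among-individual covariances equal across populations)", df))
}

#' Overall test of among-individual trait covariance (POLS structure)
#'
#' Compares the full within-population multivariate fit to one with all
#' among-individual covariances constrained to zero (variances free): a
#' global test of whether any syndrome structure is present. The statistic is
#' referred to a pure chi-square on `choose(T, 2)` df.
#'
#' @inheritParams pols_decompose
#' @return an `mm_lrt`.
#' @export
test_overall_structure <- function(panel, traits, population = NULL,
                                   fixed = NULL, control = mm_control()) {
  if (!is.null(population)) panel <- panel[panel$population == population, , drop = FALSE]
  full <- mm_reml(panel, traits, fixed = fixed, among = "us", residual = "us",
                  se = FALSE, control = control)
  red <- mm_update(full, panel,
                   constraints = modifyList(full$constraints,
                                            list(among_zero = "all")),
                   se = FALSE, control = control)
  df <- choose(length(traits), 2)
  lrt_mm(full, red, lrt_mixture("chisq", df = df),
         label = sprintf("chi2_%d (all among-individual covariances zero)", df))
}
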