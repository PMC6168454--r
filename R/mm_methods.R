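#' @export
print.mm_fit <- function(x, ...) {
  cat("Multi-trait REML mixed model (individual random intercepts)\n")
  cat("  responses:", paste(x$responses, collapse = ", "), "\n")
  if (!identical(x$groups, "all")) cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  cat(sprintf("  n obs = %d, n individuals = %d, variance parameters = %d\n",
              x$n_obs, x$n_individuals, x$n_parameters))
  cat(sprintf("  REML log-likelihood = %.4f%s\n", x$reml_loglik,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  if (x$at_boundary) cat("  note: at least one variance sits at its boundary\n")
  invisible(x)
}

#' Summarize a REML mixed-model fit
#'
#' @param object an [mm_reml()] fit.
#' @param ... unused.
#' @return the object, invisibly, after printing fixed-effect and
#'   variance-component tables.
#' @export
summary.mm_fit <- function(object, ...) {
  print(object)
  tt <- data.frame(estimate = object$beta, se = object$se_beta)
  tt$t <- tt$estimate / tt$se
  dd <- object$n_obs - object$p_fixed
  tt$p <- 2 * pt(-abs(tt$t), dd)
  cat("\nFixed effects (t tests, df =", dd, "):\n")
  print(round(tt, 4))
  for (g in seq_along(object$groups)) {
    lab <- if (identical(object$groups, "all")) "" else paste0(" [", object$groups[g], "]")
    cat("\nAmong-individual covariance", lab, ":\n", sep = "")
    print(round(object$sigma_ind[[g]], 4))
    cat("Residual covariance", lab, ":\n", sep = "")
    print(round(object$sigma_res[[g]], 4))
  }
  invisible(object)
}

#' @export
coef.mm_fit <- function(object, ...) object$beta

#' @export
vcov.mm_fit <- function(object, ...) object$vcov_beta

#' @export
logLik.mm_fit <- function(object, ...) {
  structure(object$reml_loglik,
            df = object$n_parameters + object$p_fixed,
            nobs = object$n_obs, class = "logLik")
}

#' @export
fitted.mm_fit <- function(object, ...) {
  drop(object$prep$X %*% object$beta)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  object$prep$dat$value - fitted(object)
}

#' Simulate new panels from a fitted model
#'
#' Draws new trait values from the fitted model at the estimated parameters,
#' keeping the observed design (individuals, occasions, covariates).
#'
#' @param object an [mm_reml()] fit.
#' @param nsim number of simulated panels.
#' @param seed integer seed (required; no global RNG state is used).
#' @param ... unused.
#' @return a list of `nsim` data frames shaped like the fitting panel.
#' @export
simulate.mm_fit <- function(object, nsim = 1, seed = 1, ...) {
  prep <- object$prep
  mu <- fitted(object)
  Tn <- length(object$responses)
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      dat <- prep$dat
      val <- numeric(nrow(dat))
      for (i in seq_len(prep$n_ind)) {
        rows <- prep$ind_start[i] + seq_len(prep$ind_len[i])
        g <- prep$grp_of_ind[i] + 1L
        u <- drop(rmvn(1, rep(0, Tn), object$sigma_ind[[g]]))
        e <- numeric(length(rows))
        for (o in unique(prep$occ0[rows])) {
          sel <- which(prep$occ0[rows] == o)
          tr <- prep$trait0[rows][sel] + 1L
          e[sel] <- drop(rmvn(1, rep(0, length(sel)),
                              object$sigma_res[[g]][tr, tr, drop = FALSE]))
        }
        val[rows] <- u[prep$trait0[rows] + 1L] + e
      }
      dat$value <- mu + val
      dat[, setdiff(names(dat), c("..occ", "..grp"))]
    })
  })
}

#' Wald F test for a fixed-effect term
#'
#' Tests all coefficients belonging to `term` (optionally restricted to one
#' response) with a Wald F statistic. The denominator degrees of freedom use a
#' containment-style approximation: terms constant within individuals
#' (between-individual terms such as sex or population) get
#' `n_obs - p - n_individuals + 1`; within-individual terms get `n_obs - p`.
#'
#' @param fit an [mm_reml()] fit.
#' @param term a covariate name appearing in the fixed-effect formulas.
#' @param response optional response label to restrict the test to.
#' @return a list with `F`, `df1`, `df2`, `p_value`, `df_method`.
#' @export
wald_f_test <- function(fit, term, response = NULL) {
  stopifnot(inherits(fit, "mm_fit"))
  info <- fit$beta_info
  sel <- info$term == term
  if (!is.null(response)) sel <- sel & info$trait == response
  if (!any(sel)) stop("term '", term, "' not found in the fitted fixed effects")
  idx <- which(sel)
  b <- fit$beta[idx]
  Vb <- fit$vcov_beta[idx, idx, drop = FALSE]
  q <- length(idx)
  Fstat <- drop(crossprod(b, solve(Vb, b))) / q

  dat <- fit$prep$dat
  vars <- all.vars(as.formula(paste("~", term)))
  between <- all(vapply(vars, function(v) {
    if (!v %in% names(dat)) return(FALSE)
    all(tapply(dat[[v]], dat$individual_id,
               function(x) length(unique(x)) == 1L))
  }, logical(1)))
  df2 <- if (between) fit$n_obs - fit$p_fixed - fit$n_individuals + 1L
         else fit$n_obs - fit$p_fixed
  list(F = Fstat, df1 = q, df2 = df2,
       p_value = pf(Fstat, q, df2, lower.tail = FALSE),
       df_method = if (between) "containment (between-individual)"
                   else "containment (within-individual)")
}

#' Serialize a fit to JSON
#'
#' Writes estimates, standard errors, the REML log-likelihood and convergence
#' diagnostics; the result can be read back with [jsonlite::fromJSON()].
#'
#' @param fit an [mm_reml()] fit.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
mm_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "mm_fit"))
  obj <- list(
    responses = fit$responses, groups = fit$groups,
    beta = as.list(fit$beta), se_beta = as.list(fit$se_beta),
    sigma_ind = lapply(fit$sigma_ind, unclass),
    sigma_res = lapply(fit$sigma_res, unclass),
    sigma_ind_se = fit$sigma_ind_se, sigma_res_se = fit$sigma_res_se,
    reml_loglik = fit$reml_loglik, n_parameters = fit$n_parameters,
    converged = fit$converged, grad_norm = fit$grad_norm,
    at_boundary = fit$at_boundary,
    n_obs = fit$n_obs, n_individuals = fit$n_individuals)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
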