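#' Adjusted repeatability from fitted variance components
#'
#' The adjusted repeatability is the share of phenotypic variance left after
#' conditioning on the fixed effects that is attributable to consistent
#' among-individual differences: `R = sigma2_ind / (sigma2_ind + sigma2_res)`.
#'
#' @param sigma_ind among-individual variance.
#' @param sigma_res residual (within-individual) variance.
#' @return R in `[0, 1]`.
#' @examples
#' adjusted_repeatability(0.382, 0.106)  # 0.783
#' @export
adjusted_repeatability <- function(sigma_ind, sigma_res) {
  if (any(sigma_ind < 0) || any(sigma_res < 0))
    stop("variance components must be non-negative")
  tot <- sigma_ind + sigma_res
  ifelse(tot == 0, 0, sigma_ind / tot)
}

# Draw variance parameters from the asymptotic distribution of theta-hat and
# return per-draw (sigma_ind, sigma_res) for one trait of a univariate fit.
draw_components <- function(fit, nboot, seed) {
  stopifnot(inherits(fit, "mm_fit"))
  if (is.null(fit$theta_vcov))
    stop("fit was run with se = FALSE; refit with se = TRUE for bootstrap SEs")
  pm <- fit$parmap
  pi_ind <- pm$par[pm$mat == "ind" & pm$kind == "var"]
  pi_res <- pm$par[pm$mat == "res" & pm$kind == "var"]
  th <- with_seed(seed, rmvn(nboot, fit$theta, fit$theta_vcov))
  # clamp draws: near a boundary the asymptotic spread of log-SD parameters
  # can be enormous and exp() would overflow
  v <- function(x) pmin(exp(2 * pmin(x, 12)), 1e10)
  list(ind = if (length(pi_ind) && !is.na(pi_ind[1])) v(th[, pi_ind[1]])
             else rep(0, nboot),
       res = v(th[, pi_res[1]]))
}

#' Repeatability of one trait with a boundary-corrected LRT
#'
#' Fits a univariate individual-random-intercept model by REML, computes the
#' adjusted repeatability, its standard error (parametric bootstrap from the
#' asymptotic distribution of the variance parameters, or the delta method),
#' and tests the among-individual variance with a likelihood-ratio test
#' against the model without the random intercept. Because the null pins a
#' variance to the boundary of its space, the reference distribution is the
#' equal mixture of a point mass at zero and chi-square with 1 df.
#'
#' @param panel long-format panel (standardized values recommended).
#' @param trait trait label.
#' @param population optional population label to subset to.
#' @param fixed fixed-effect formula; default as in [mm_reml()].
#' @param se_method `"boot"` (parametric bootstrap) or `"delta"`.
#' @param nboot bootstrap draws.
#' @param seed seed for the bootstrap draws.
#' @param control optimizer control.
#' @return object of class `repeatability`: `trait`, `population`, `R`,
#'   `se_R`, `sigma_ind`, `sigma_res`, `lrt` (an `mm_lrt`), `fit`.
#' @export
repeatability <- function(panel, trait, population = NULL, fixed = NULL,
                          se_method = c("boot", "delta"), nboot = 1000L,
                          seed = 1L, control = mm_control()) {
  se_method <- match.arg(se_method)
  if (!is.null(population)) {
    if (!"population" %in% names(panel)) stop("panel has no 'population' column")
    panel <- panel[panel$population == population, , drop = FALSE]
    if (!nrow(panel)) stop("no rows for population '", population, "'")
  }
  full <- mm_reml(panel, trait, fixed = fixed, se = TRUE, control = control)
  if (!full$converged)
    stop("REML fit for trait '", trait, "' did not converge (gradient norm ",
         signif(full$grad_norm, 3), ")")
  reduced <- mm_update(full, panel, among = "zero", se = FALSE,
                       control = control)
  lrt <- lrt_mm(full, reduced, lrt_mixture("variance"),
                label = "equal mixture chi2_0 + chi2_1 (variance on boundary)")

  s_ind <- full$sigma_ind[[1]][trait, trait]
  s_res <- full$sigma_res[[1]][trait, trait]
  R <- adjusted_repeatability(s_ind, s_res)

  at_bound <- full$at_boundary || s_ind < 1e-6
  se_R <- if (se_method == "boot") {
    dr <- draw_components(full, nboot, seed)
    Rb <- adjusted_repeatability(pmax(dr$ind, 0), dr$res)
    if (at_bound) sd(pmax(Rb, 0)) else sd(Rb)
  } else {
    pm <- full$parmap
    pi_ind <- pm$par[pm$mat == "ind" & pm$kind == "var"][1]
    pi_res <- pm$par[pm$mat == "res" & pm$kind == "var"][1]
    # R = v1/(v1+v2), v = exp(2 theta): dR/dtheta1 = 2 v1 v2 / (v1+v2)^2, and
    # the symmetric negative for theta2
    g <- 2 * s_ind * s_res / (s_ind + s_res)^2 * c(1, -1)
    V <- full$theta_vcov[c(pi_ind, pi_res), c(pi_ind, pi_res)]
    sqrt(drop(t(g) %*% V %*% g))
  }

  out <- list(trait = trait, population = population %||% "(all)", R = R,
              se_R = se_R, sigma_ind = s_ind, sigma_res = s_res, lrt = lrt,
              se_method = se_method, fit = full)
  class(out) <- "repeatability"
  out
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Adjusted repeatability of '%s' [%s]: R = %.3f (SE %.3f)\n",
              x$trait, x$population, x$R, x$se_R))
  cat(sprintf("  sigma2_ind = %.4f, sigma2_res = %.4f\n", x$sigma_ind, x$sigma_res))
  print(x$lrt)
  invisible(x)
}

#' Repeatability table over traits and populations
#'
#' Mirrors the layout of a per-population variance-components table: one row
#' per trait and population with the variance components, adjusted
#' repeatability (SE) and the boundary-mixture LRT p-value.
#'
#' @param panel long-format panel.
#' @param traits traits to include.
#' @param populations populations; default all in the panel.
#' @param ... passed to [repeatability()].
#' @return data frame with one row per trait x population.
#' @export
repeatability_table <- function(panel, traits,
                                populations = unique(panel$population), ...) {
  rows <- list()
  for (p in populations) for (tr in traits) {
    r <- repeatability(panel, tr, population = p, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      population = p, trait = tr, sigma_ind = r$sigma_ind,
      sigma_res = r$sigma_res, R = r$R, se_R = r$se_R,
      lrt_statistic = r$lrt$statistic, lrt_p = r$lrt$p_value,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
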