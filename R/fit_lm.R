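#' Ordinary least-squares fit on one trait of a long panel
#'
#' Thin wrapper around [stats::lm()] for models without a random term (one
#' record per individual), e.g. between-population comparisons of life-history
#' traits. Errors on rank-deficient designs, naming the aliased columns.
#'
#' @param panel long-format panel (columns `trait`, `value`, covariates).
#' @param response trait label to model.
#' @param fixed one-sided formula of covariates, e.g. `~ population +
#'   standard_size`.
#' @return an object of class `mm_lm`: the underlying `lm` plus coefficient
#'   table and residual variance.
#' @export
fit_lm <- function(panel, response, fixed = ~population) {
  dat <- panel[panel$trait == response & !is.na(panel$value), , drop = FALSE]
  if (!nrow(dat)) stop("no observations of response '", response, "'")
  f <- as.formula(paste("value ~", paste(deparse(fixed[[2]]), collapse = "")))
  m <- lm(f, data = dat)
  if (anyNA(coef(m))) {
    stop("fixed-effect design is rank deficient; aliased columns: ",
         paste(names(coef(m))[is.na(coef(m))], collapse = ", "))
  }
  sm <- summary(m)
  out <- list(lm = m, response = response,
              beta = coef(m), se_beta = sm$coefficients[, "Std. Error"],
              t = sm$coefficients[, "t value"], p = sm$coefficients[, "Pr(>|t|)"],
              sigma2_res = sm$sigma^2, n_obs = nrow(dat),
              df_residual = m$df.residual)
  class(out) <- "mm_lm"
  out
}

#' @export
print.mm_lm <- function(x, ...) {
  cat("Linear model for trait '", x$response, "' (n = ", x$n_obs, ")\n", sep = "")
  print(round(data.frame(estimate = x$beta, se = x$se_beta, t = x$t, p = x$p), 4))
  cat(sprintf("Residual variance: %.4f on %d df\n", x$sigma2_res, x$df_residual))
  invisible(x)
}

#' @export
coef.mm_lm <- function(object, ...) object$beta

#' @export
vcov.mm_lm <- function(object, ...) vcov(object$lm)
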