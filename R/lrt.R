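#' Tail probability of a chi-square mixture
#'
#' Computes \eqn{p = \sum_i w_i \Pr(\chi^2_{df_i} > t)}. Likelihood-ratio
#' statistics for variance components tested against a null on the boundary of
#' the parameter space follow such mixtures: a single variance constrained
#' positive gives the equal mixture of a point mass at zero (`df = 0`) and
#' \eqn{\chi^2_1}; one variance plus k covariances gives the equal mixture of
#' \eqn{\chi^2_k} and \eqn{\chi^2_{k+1}}; unbounded covariances alone follow a
#' pure \eqn{\chi^2}.
#'
#' The `df = 0` component contributes nothing for `statistic > 0`; a zero
#' statistic yields `p = 1`.
#'
#' @param statistic likelihood-ratio statistic, `2 * (logLik_full -
#'   logLik_reduced)`, floored at zero.
#' @param mixture a data frame or matrix with columns `weight` and `df`, or a
#'   list of `c(weight, df)` pairs. Weights must sum to one.
#' @return the p-value.
#' @examples
#' mixture_lrt_p(2.706, lrt_mixture("variance"))   # ~0.05
#' mixture_lrt_p(40.25, lrt_mixture("chisq", df = 6))
#' @export
mixture_lrt_p <- function(statistic, mixture) {
  if (!is.finite(statistic)) stop("statistic must be finite")
  if (statistic < -1e-8) stop("negative likelihood-ratio statistic: ", statistic)
  statistic <- max(statistic, 0)
  if (is.list(mixture) && !is.data.frame(mixture))
    mixture <- do.call(rbind, lapply(mixture, function(x)
      data.frame(weight = x[1], df = x[2])))
  mixture <- as.data.frame(mixture)
  stopifnot(all(c("weight", "df") %in% names(mixture)))
  if (abs(sum(mixture$weight) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (statistic == 0) return(1)
  tails <- ifelse(mixture$df == 0, 0,
                  pchisq(statistic, mixture$df, lower.tail = FALSE))
  min(max(sum(mixture$weight * tails), 0), 1)
}

#' Standard mixture specifications for variance-component LRTs
#'
#' @param type `"variance"` for one variance tested on the boundary
#'   (equal mixture of df 0 and 1), `"variance_covariance"` for one boundary
#'   variance plus `k` unbounded covariances (equal mixture of df `k` and
#'   `k + 1`), `"chisq"` for a pure chi-square on `df`.
#' @param df degrees of freedom (`k` for `"variance_covariance"`).
#' @return a data frame with columns `weight` and `df`.
#' @export
lrt_mixture <- function(type = c("variance", "variance_covariance", "chisq"),
                        df = 1) {
  type <- match.arg(type)
  switch(type,
    variance = data.frame(weight = c(0.5, 0.5), df = c(0, 1)),
    variance_covariance = data.frame(weight = c(0.5, 0.5), df = c(df, df + 1)),
    chisq = data.frame(weight = 1, df = df))
}

#' Likelihood-ratio test between two nested REML fits
#'
#' The statistic is twice the difference in restricted log-likelihoods,
#' floored at zero. Both fits must share the same fixed-effect design
#' (restricted likelihoods are only comparable then); the reduced model must
#' constrain the covariance structure of the full one.
#'
#' @param full,reduced [mm_reml()] fits.
#' @param mixture reference distribution, from [lrt_mixture()].
#' @param label optional description of the tested component.
#' @return an object of class `mm_lrt` with `statistic`, `mixture`,
#'   `p_value`, `df_label`.
#' @export
lrt_mm <- function(full, reduced, mixture = lrt_mixture("chisq", df = 1),
                   label = NULL) {
  stopifnot(inherits(full, "mm_fit"), inherits(reduced, "mm_fit"))
  if (full$p_fixed != reduced$p_fixed)
    warning("fixed-effect designs differ; restricted likelihoods are not comparable")
  stat <- max(0, 2 * (full$reml_loglik - reduced$reml_loglik))
  res <- list(statistic = stat, mixture = mixture,
              p_value = mixture_lrt_p(stat, mixture),
              df_label = label %||% paste0(
                "mixture ", paste(sprintf("%g*chi2_%g", mixture$weight, mixture$df),
                                  collapse = " + ")),
              loglik_full = full$reml_loglik, loglik_reduced = reduced$reml_loglik,
              n_par_full = full$n_parameters, n_par_reduced = reduced$n_parameters)
  class(res) <- "mm_lrt"
  res
}

#' @export
print.mm_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: chi2 = %.3f, %s, p = %.4g\n",
              x$statistic, x$df_label, x$p_value))
  invisible(x)
}
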