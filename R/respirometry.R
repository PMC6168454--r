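#' Fit per-phase oxygen-depletion slopes and apply quality filters
#'
#' For every closed (sealed-chamber) phase of an intermittent-flow
#' respirometry trace, trims `trim_margin` seconds from each end, fits an
#' ordinary least-squares line to oxygen concentration against time, and
#' reports the slope per minute with its coefficient of determination. A phase
#' is retained when the fit is adequately linear (`r2 >= min_r2`) and the
#' phase starts after the acclimation cutoff; earlier phases reflect handling
#' stress rather than resting metabolism.
#'
#' @param trace a `respirometry_trace` (see [simulate_respirometry_trace()] or
#'   [read_respirometry_trace()]).
#' @param trim_margin seconds removed from each end of every closed phase.
#' @param min_r2 minimum R-squared of the linear fit for retention.
#' @param acclimation_cutoff seconds from session start before which phases
#'   are discarded.
#' @return data frame of class `closed_phases`: `phase_id`, `slope`
#'   (mg L^-1 min^-1), `r_squared`, `start_time`, `duration`, `n_samples`,
#'   `retained`, `reason`.
#' @export
extract_closed_phase_slopes <- function(trace, trim_margin = 120,
                                        min_r2 = 0.95,
                                        acclimation_cutoff = 3600) {
  stopifnot(all(c("time_s", "o2_mg_per_l", "phase_id", "phase_type") %in%
                  names(trace)))
  closed_ids <- unique(trace$phase_id[trace$phase_type == "closed"])
  if (!length(closed_ids)) {
    warning("trace contains no closed phases")
    return(structure(data.frame(phase_id = integer(0), slope = numeric(0),
                                r_squared = numeric(0), start_time = numeric(0),
                                duration = numeric(0), n_samples = integer(0),
                                retained = logical(0), reason = character(0)),
                     class = c("closed_phases", "data.frame")))
  }
  rows <- lapply(closed_ids, function(ph) {
    sub <- trace[trace$phase_id == ph, ]
    t0 <- min(sub$time_s); t1 <- max(sub$time_s)
    keep <- sub$time_s >= t0 + trim_margin & sub$time_s <= t1 - trim_margin
    sub2 <- sub[keep, ]
    if (nrow(sub2) < 3L) {
      return(data.frame(phase_id = ph, slope = NA_real_, r_squared = NA_real_,
                        start_time = t0, duration = t1 - t0,
                        n_samples = nrow(sub2), retained = FALSE,
                        reason = "too short after trimming",
                        stringsAsFactors = FALSE))
    }
    # direct OLS of o2 on time; correlation form avoids degenerate summaries
    tt <- sub2$time_s; oo <- sub2$o2_mg_per_l
    slope <- cov(tt, oo) / var(tt) * 60            # per-second -> per-minute
    r2 <- if (sd(oo) < 1e-14) NA_real_ else cor(tt, oo)^2
    ok_r2 <- is.finite(r2) && r2 >= min_r2
    ok_time <- t0 >= acclimation_cutoff
    reason <- if (ok_r2 && ok_time) "" else paste(
      c(if (!ok_r2) sprintf("r2 %.3f < %.2f", r2, min_r2),
        if (!ok_time) "within acclimation period"), collapse = "; ")
    data.frame(phase_id = ph, slope = slope, r_squared = r2, start_time = t0,
               duration = t1 - t0, n_samples = nrow(sub2),
               retained = ok_r2 && ok_time, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fish_mass") <- attr(trace, "fish_mass")
  attr(out, "chamber_volume") <- attr(trace, "chamber_volume")
  class(out) <- c("closed_phases", "data.frame")
  out
}

#' Two-component normal mixture by expectation-maximization
#'
#' EM with multiple restarts from quantile-based initializations (component
#' means started at spread quantile pairs, e.g. the 25th/75th percentiles).
#' The log-likelihood is checked to be non-decreasing across iterations.
#' Collapsing components (SD under the floor) trigger the next restart; if
#' every restart degenerates and the data are essentially constant the mixture
#' collapses to a point (both means equal).
#'
#' @param x numeric data vector (length >= 2).
#' @param restarts number of quantile-based restarts.
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   log-likelihood.
#' @param sd_floor lower bound on component SDs, as a fraction of `sd(x)`.
#' @return list with `means` (sorted ascending), `sds`, `weights`, `loglik`,
#'   `n_iter`, `converged`, `responsibilities` (posterior membership of the
#'   lower component).
#' @export
fit_normal_mixture2 <- function(x, restarts = 10L, max_iter = 500L,
                                tol = 1e-8, sd_floor = 1e-3) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop("need at least two observations for a two-component mixture")
  s_all <- sd(x)
  if (!is.finite(s_all) || s_all < 1e-12 * max(1, abs(mean(x)))) {
    # degenerate data: the mixture collapses to a point
    return(list(means = rep(mean(x), 2), sds = rep(0, 2),
                weights = c(0.5, 0.5), loglik = NA_real_, n_iter = 0L,
                converged = TRUE, responsibilities = rep(1, n)))
  }
  floor_sd <- sd_floor * s_all

  q_pairs <- cbind(seq(0.05, 0.45, length.out = restarts),
                   seq(0.95, 0.55, length.out = restarts))
  best <- NULL
  for (r in seq_len(restarts)) {
    mu <- as.numeric(quantile(x, q_pairs[r, ]))
    if (diff(mu) < 1e-12) mu <- mu + c(-1, 1) * 0.1 * s_all
    sg <- rep(max(s_all / 2, floor_sd), 2)
    w <- c(0.5, 0.5)
    ll_old <- -Inf; ok <- TRUE; it <- 0L; conv <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      d1 <- w[1] * dnorm(x, mu[1], sg[1])
      d2 <- w[2] * dnorm(x, mu[2], sg[2])
      tot <- d1 + d2
      if (any(tot <= 0) || any(!is.finite(tot))) { ok <- FALSE; break }
      ll <- sum(log(tot))
      if (ll < ll_old - 1e-6)
        stop("internal error: EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
      g <- d1 / tot
      n1 <- sum(g); n2 <- n - n1
      if (n1 < 1e-8 || n2 < 1e-8) { ok <- FALSE; break }
      mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
      sg <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                   sum((1 - g) * (x - mu[2])^2) / n2))
      if (any(sg < floor_sd)) {
        # regularized floor; if a component still pins to a single point on
        # the next pass this restart is abandoned
        if (any(sg < 0.1 * floor_sd)) { ok <- FALSE; break }
        sg <- pmax(sg, floor_sd)
      }
      w <- c(n1, n2) / n
      if (abs(ll - ll_old) < tol * (1 + abs(ll))) { ll_old <- ll; conv <- TRUE; break }
      ll_old <- ll
    }
    if (!ok) next
    cand <- list(means = mu, sds = sg, weights = w, loglik = ll_old,
                 n_iter = it, converged = conv, g = g)
    better <- is.null(best) || cand$loglik > best$loglik + 1e-9 ||
      (abs(cand$loglik - best$loglik) <= 1e-9 && min(mu) < min(best$means))
    if (better) best <- cand
  }
  if (is.null(best))
    stop("EM failed to fit a two-component mixture: all restarts degenerated")
  ord <- order(best$means)
  list(means = best$means[ord], sds = best$sds[ord],
       weights = best$weights[ord], loglik = best$loglik,
       n_iter = best$n_iter, converged = best$converged,
       responsibilities = if (ord[1] == 1L) best$g else 1 - best$g)
}

#' Estimate standard metabolic rate from retained closed phases
#'
#' Converts retained slopes to mass-specific respiration rates,
#' `rate = |slope| * 60 * chamber_volume / fish_mass` (mg O2 kg^-1 h^-1),
#' fits a two-component normal mixture by EM, and takes the lower component
#' mean as the standard metabolic rate — the resting state — with the upper
#' component absorbing phases inflated by spontaneous activity. Background
#' (microbial) respiration is not corrected for.
#'
#' @param phases a `closed_phases` table from [extract_closed_phase_slopes()].
#' @param fish_mass fish wet mass (kg); defaults to the trace metadata.
#' @param chamber_volume respirometry chamber volume (L); same default.
#' @param min_phases minimum number of retained phases (a two-component
#'   mixture needs at least 4).
#' @param restarts EM restarts, see [fit_normal_mixture2()].
#' @return object of class `smr_estimate`: `smr_mass_specific`,
#'   `mixture_means`, `mixture_sds`, `mixture_weights`, `n_phases_used`,
#'   `rates`.
#' @export
estimate_smr <- function(phases, fish_mass = attr(phases, "fish_mass"),
                         chamber_volume = attr(phases, "chamber_volume"),
                         min_phases = 4L, restarts = 10L) {
  stopifnot(is.data.frame(phases))
  if (is.null(fish_mass) || is.null(chamber_volume))
    stop("fish_mass and chamber_volume must be supplied (or carried on the trace)")
  if (fish_mass <= 0 || chamber_volume <= 0)
    stop("fish_mass and chamber_volume must be positive")
  kept <- phases[phases$retained & is.finite(phases$slope), , drop = FALSE]
  if (nrow(kept) < min_phases)
    stop("only ", nrow(kept), " retained phases; at least ", min_phases,
         " are required — relax the filters or measure longer")
  rates <- abs(kept$slope) * 60 * chamber_volume / fish_mass
  mix <- fit_normal_mixture2(rates, restarts = restarts)
  out <- list(smr_mass_specific = mix$means[1],
              mixture_means = mix$means, mixture_sds = mix$sds,
              mixture_weights = mix$weights, n_phases_used = nrow(kept),
              rates = rates, loglik = mix$loglik)
  class(out) <- "smr_estimate"
  out
}

#' @export
print.smr_estimate <- function(x, ...) {
  cat(sprintf("SMR = %.2f mg O2 kg^-1 h^-1 (lower mixture mean; %d phases)\n",
              x$smr_mass_specific, x$n_phases_used))
  cat(sprintf("  components: %.2f (sd %.2f, w %.2f) | %.2f (sd %.2f, w %.2f)\n",
              x$mixture_means[1], x$mixture_sds[1], x$mixture_weights[1],
              x$mixture_means[2], x$mixture_sds[2], x$mixture_weights[2]))
  invisible(x)
}

#' Run SMR extraction over a set of trace files
#'
#' @param files named character vector of trace CSV paths (names =
#'   `individual_id:age_stage` keys) or a data frame with columns
#'   `individual_id`, `age_stage`, `path`, and optionally `fish_mass`,
#'   `chamber_volume`.
#' @param ... passed to [extract_closed_phase_slopes()].
#' @param diagnostics_path optional JSON path for the per-phase report.
#' @return data frame `individual_id, age_stage, smr, n_phases_used`.
#' @export
smr_table <- function(files, ..., diagnostics_path = NULL) {
  if (is.character(files)) {
    keys <- strsplit(names(files), ":", fixed = TRUE)
    files <- data.frame(individual_id = vapply(keys, `[`, "", 1),
                        age_stage = vapply(keys, `[`, "", 2),
                        path = unname(files), stringsAsFactors = FALSE)
  }
  diag <- list(); rows <- list()
  for (i in seq_len(nrow(files))) {
    tr <- read_respirometry_trace(files$path[i],
                                  fish_mass = files$fish_mass[i] %||% NULL,
                                  chamber_volume = files$chamber_volume[i] %||% NULL)
    ph <- extract_closed_phase_slopes(tr, ...)
    est <- estimate_smr(ph)
    rows[[i]] <- data.frame(individual_id = files$individual_id[i],
                            age_stage = files$age_stage[i],
                            smr = est$smr_mass_specific,
                            n_phases_used = est$n_phases_used,
                            stringsAsFactors = FALSE)
    diag[[i]] <- list(individual_id = files$individual_id[i],
                      age_stage = files$age_stage[i],
                      phases = as.data.frame(ph),
                      mixture = est[c("mixture_means", "mixture_sds",
                                      "mixture_weights")])
  }
  out <- do.call(rbind, rows)
  if (!is.null(diagnostics_path))
    jsonlite::write_json(diag, diagnostics_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  out
}
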