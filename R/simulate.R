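## Default ground-truth parameters for the two-population study design:
## variance components and fixed effects follow the univariate estimates
## reported for the slow-growing (SG) and fast-growing (FG) populations on the
## standardized trait scale; the SG among-individual correlation structure is a
## single-factor pace-of-life axis with pairwise correlations of +/-0.6 over
## the four syndrome traits, the FG structure is diagonal.
default_sim_traits <- function() {
  c("emergence_latency", "hiding_time", "distance_moved", "freezing_time",
    "smr", "standard_size", "fulton_k")
}

default_sigma_ind <- function() {
  tr <- default_sim_traits()
  pols <- c("hiding_time", "distance_moved", "standard_size", "smr")
  v_sg <- c(emergence_latency = 0.02, hiding_time = 0.196, distance_moved = 0.361,
            freezing_time = 0.02, smr = 0.222, standard_size = 0.382,
            fulton_k = 0.15)
  v_fg <- c(emergence_latency = 0.02, hiding_time = 0.226, distance_moved = 0.240,
            freezing_time = 0.02, smr = 0.114, standard_size = 0.013,
            fulton_k = 0.10)
  # single-factor syndrome: loadings +/- sqrt(0.6) give pairwise corr +/- 0.6;
  # mass-specific SMR loads opposite to size and activity (larger, more active
  # fish have lower mass-specific SMR)
  lam <- setNames(rep(0, length(tr)), tr)
  lam[pols] <- sqrt(0.6) * c(1, 1, 1, -1)
  C_sg <- diag(1 - lam^2) + outer(lam, lam)
  dimnames(C_sg) <- list(tr, tr)
  S_sg <- diag(sqrt(v_sg[tr])) %*% C_sg %*% diag(sqrt(v_sg[tr]))
  dimnames(S_sg) <- list(tr, tr)
  S_fg <- diag(v_fg[tr]); dimnames(S_fg) <- list(tr, tr)
  list(SG = S_sg, FG = S_fg)
}

default_sigma_res <- function() {
  tr <- default_sim_traits()
  v_sg <- c(emergence_latency = 0.95, hiding_time = 0.775, distance_moved = 0.575,
            freezing_time = 0.95, smr = 0.185, standard_size = 0.106,
            fulton_k = 0.25)
  v_fg <- c(emergence_latency = 0.95, hiding_time = 0.721, distance_moved = 0.691,
            freezing_time = 0.95, smr = 0.300, standard_size = 0.085,
            fulton_k = 0.25)
  mk <- function(v) {
    S <- diag(v[tr]); dimnames(S) <- list(tr, tr)
    # the one robust residual correlation: mass-specific SMR falls with size
    r <- -0.4
    S["smr", "standard_size"] <- S["standard_size", "smr"] <-
      r * sqrt(S["smr", "smr"] * S["standard_size", "standard_size"])
    S
  }
  list(SG = mk(v_sg), FG = mk(v_fg))
}

default_beta <- function() {
  tr <- default_sim_traits()
  mk <- function(int, age, sex, trial) c(intercept = int, age_stage = age,
                                         sex = sex, trial = trial)
  sg <- rbind(emergence_latency = mk(-0.20, 0, 0, 0),
              hiding_time = mk(0.314, 0.168, -0.235, -0.077),
              distance_moved = mk(0.903, 0.093, -0.081, -0.613),
              freezing_time = mk(-0.30, 0, 0, 0),
              smr = mk(-0.049, -1.536, 0.237, 0),
              standard_size = mk(0.186, 1.389, -0.263, 0),
              fulton_k = mk(0, 0.3, 0, 0))
  fg <- rbind(emergence_latency = mk(0.15, 0, 0, 0),
              hiding_time = mk(-0.825, 0.113, 0.139, 0.452),
              distance_moved = mk(0.181, -0.481, 0.351, -0.138),
              freezing_time = mk(0.25, 0, 0, 0),
              smr = mk(-0.018, -1.475, 0.438, 0),
              standard_size = mk(-0.108, 1.820, -0.440, 0),
              fulton_k = mk(0, 0.3, 0, 0))
  list(SG = sg[tr, , drop = FALSE], FG = fg[tr, , drop = FALSE])
}

#' Configuration for the synthetic two-population trait panel
#'
#' Defaults emulate the study design the package is built around: two
#' populations (slow-growing SG, fast-growing FG) of 40 individuals each,
#' four behavioural traits measured twice per ontogenetic stage (two stages),
#' SMR, standard size and Fulton's K once per stage, sex and stage coded
#' ±0.5, population-specific among-individual and residual covariance
#' matrices, and individual-level attrition after stage 1 (0.2 in SG, 0.025
#' in FG, mirroring overnight-mortality rates of 8/40 and 1/40).
#'
#' @param n_individuals per-population count (scalar or named vector).
#' @param trait_names traits to simulate (must index the covariance matrices).
#' @param sigma_ind,sigma_res named lists (one matrix per population) of
#'   among-individual and residual trait covariance matrices; must be
#'   symmetric positive semi-definite.
#' @param beta named list (per population) of fixed-effect matrices, one row
#'   per trait, columns `intercept`, `age_stage`, `sex`, `trial`.
#' @param measured_per_stage named integer vector of measures per stage and
#'   trait (2 = two trials per stage, 1 = once per stage at the assay
#'   occasion).
#' @param missing_rate fraction of individuals dropped after stage 1
#'   (individual-level attrition), scalar or named per population.
#' @param seed integer seed; generation is deterministic given the config.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = c(SG = 40, FG = 40),
                       trait_names = default_sim_traits(),
                       sigma_ind = default_sigma_ind(),
                       sigma_res = default_sigma_res(),
                       beta = default_beta(),
                       measured_per_stage = NULL,
                       missing_rate = c(SG = 0.2, FG = 0.025),
                       seed = 1L) {
  pops <- names(sigma_ind)
  if (is.null(pops)) stop("sigma_ind must be a named list (one matrix per population)")
  if (length(n_individuals) == 1L && is.null(names(n_individuals)))
    n_individuals <- setNames(rep(n_individuals, length(pops)), pops)
  if (length(missing_rate) == 1L && is.null(names(missing_rate)))
    missing_rate <- setNames(rep(missing_rate, length(pops)), pops)
  if (is.null(measured_per_stage)) {
    sp <- default_trait_specs()
    measured_per_stage <- setNames(sp$measured_per_stage, sp$trait)[trait_names]
    measured_per_stage[is.na(measured_per_stage)] <- 2L
    names(measured_per_stage) <- trait_names
  }
  cfg <- list(populations = pops, n_individuals = n_individuals,
              trait_names = trait_names, sigma_ind = sigma_ind,
              sigma_res = sigma_res, beta = beta,
              measured_per_stage = measured_per_stage,
              missing_rate = missing_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (p in cfg$populations) {
    if (cfg$n_individuals[[p]] < 2) stop("n_individuals must be >= 2 per population")
    for (what in c("sigma_ind", "sigma_res")) {
      S <- cfg[[what]][[p]]
      if (is.null(S)) stop(what, " missing for population ", p)
      if (!all(cfg$trait_names %in% rownames(S)))
        stop(what, "[", p, "] must have rows/cols named by trait_names")
      S <- S[cfg$trait_names, cfg$trait_names, drop = FALSE]
      if (!is_psd(S))
        stop(what, "[", p, "] is not symmetric positive semi-definite")
    }
    if (!all(cfg$trait_names %in% rownames(cfg$beta[[p]])))
      stop("beta[", p, "] must have one row per trait")
  }
  if (any(cfg$measured_per_stage < 1)) stop("measurement counts must be >= 1")
  if (any(cfg$missing_rate < 0 | cfg$missing_rate >= 1))
    stop("missing_rate must be in [0, 1)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic POLS panel configuration\n")
  cat("  populations:", paste(sprintf("%s (n=%d)", x$populations,
                                      x$n_individuals[x$populations]),
                              collapse = ", "), "\n")
  cat("  traits:", paste(x$trait_names, collapse = ", "), "\n")
  cat("  measures per stage:", paste(sprintf("%s=%d", names(x$measured_per_stage),
                                             x$measured_per_stage), collapse = ", "), "\n")
  cat("  attrition after stage 1:", paste(sprintf("%s=%.3f", names(x$missing_rate),
                                                  x$missing_rate), collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate a long-format trait panel with known ground truth
#'
#' For each individual a latent trait vector `u ~ MVN(0, sigma_ind)` is drawn
#' once; every observation is `beta . x + u[trait] + e`, with residuals drawn
#' jointly over the traits measured on the same occasion from
#' `MVN(0, sigma_res)` and independently across occasions. Within each stage,
#' traits measured repeatedly form one occasion per trial (all behavioural
#' traits of a trial share it) and once-per-stage traits share a single assay
#' occasion. A `missing_rate` fraction of individuals per population is
#' dropped after stage 1 (attrition). The trial covariate enters the mean
#' centred (trial − mean trial), so intercepts refer to the schedule midpoint.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `individual_id`, `population`, `sex`,
#'   `age_stage`, `trial`, `trait`, `value`, `occasion`, plus attribute
#'   `"truth"` (config, latent `u` per individual, dropped individuals).
#' @export
simulate_trait_panel <- function(config) {
  validate_sim_config(config)
  tr <- config$trait_names
  Tn <- length(tr)
  multi <- names(config$measured_per_stage)[config$measured_per_stage > 1]
  once <- setdiff(tr, multi)
  stages <- c(-0.5, 0.5)

  with_seed(config$seed, {
    rows <- list(); u_all <- list(); dropped <- character(0)
    for (p in config$populations) {
      n <- config$n_individuals[[p]]
      ids <- sprintf("%s_%03d", p, seq_len(n))
      sex <- rep(c(-0.5, 0.5), length.out = n)
      Sind <- config$sigma_ind[[p]][tr, tr, drop = FALSE]
      Sres <- config$sigma_res[[p]][tr, tr, drop = FALSE]
      B <- config$beta[[p]][tr, , drop = FALSE]
      u <- rmvn(n, rep(0, Tn), Sind)
      dimnames(u) <- list(ids, tr)
      u_all[[p]] <- u
      n_drop <- round(config$missing_rate[[p]] * n)
      drop_ids <- if (n_drop > 0) sample(ids, n_drop) else character(0)
      dropped <- c(dropped, drop_ids)

      for (i in seq_len(n)) {
        for (si in seq_along(stages)) {
          if (si == 2L && ids[i] %in% drop_ids) next
          stage <- stages[si]
          # occasions: one per trial for the repeated traits, one assay
          # occasion for the once-per-stage traits
          occs <- list()
          if (length(multi)) {
            kmax <- max(config$measured_per_stage[multi])
            for (k in seq_len(kmax)) {
              tk <- multi[config$measured_per_stage[multi] >= k]
              occs[[paste0("s", si, "_t", k)]] <- list(traits = tk, trial = k)
            }
          }
          if (length(once))
            occs[[paste0("s", si, "_assay")]] <- list(traits = once, trial = 1L)

          for (oc in names(occs)) {
            tk <- occs[[oc]]$traits
            trl <- occs[[oc]]$trial
            e <- drop(rmvn(1, rep(0, length(tk)), Sres[tk, tk, drop = FALSE]))
            trl_c <- if (length(multi) && tk[1] %in% multi)
              trl - (max(config$measured_per_stage[multi]) + 1) / 2 else 0
            mu <- B[tk, "intercept"] + B[tk, "age_stage"] * stage +
              B[tk, "sex"] * sex[i] + B[tk, "trial"] * trl_c
            rows[[length(rows) + 1L]] <- data.frame(
              individual_id = ids[i], population = p, sex = sex[i],
              age_stage = stage, trial = trl, trait = tk,
              value = mu + u[i, tk] + e, occasion = oc,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    panel <- do.call(rbind, rows)
    rownames(panel) <- NULL
    attr(panel, "truth") <- list(config = config, u = u_all, dropped = dropped)
    panel
  })
}

#' Write / read the long-format trait panel CSV
#'
#' Schema: `individual_id,population,sex,age_stage,trial,trait,value`.
#' A ground-truth sidecar (covariance matrices, fixed effects, seed, dropped
#' individuals) can be written alongside as JSON.
#'
#' @param panel a panel from [simulate_trait_panel()] (or same shape).
#' @param path CSV path.
#' @param truth_path optional path for the ground-truth JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_trait_panel <- function(panel, path, truth_path = NULL) {
  cols <- c("individual_id", "population", "sex", "age_stage", "trial",
            "trait", "value")
  write.csv(panel[, cols], path, row.names = FALSE, quote = FALSE)
  truth <- attr(panel, "truth")
  if (!is.null(truth_path) && !is.null(truth)) {
    cfg <- truth$config
    jsonlite::write_json(
      list(seed = cfg$seed, populations = cfg$populations,
           n_individuals = as.list(cfg$n_individuals),
           trait_names = cfg$trait_names,
           sigma_ind = lapply(cfg$sigma_ind, function(m) unclass(m)),
           sigma_res = lapply(cfg$sigma_res, function(m) unclass(m)),
           beta = lapply(cfg$beta, function(m) unclass(m)),
           missing_rate = as.list(cfg$missing_rate),
           dropped = truth$dropped),
      truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trait_panel
#' @export
read_trait_panel <- function(path) {
  panel <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "trait", "value")
  if (!all(need %in% names(panel)))
    stop("panel CSV must contain at least: ", paste(need, collapse = ", "))
  panel
}

#' Simulate an overnight intermittent-flow respirometry trace
#'
#' Oxygen concentration in a sealed chamber falls linearly during closed
#' phases with a slope drawn per phase from a two-state mixture (resting with
#' probability `1 - p_active`, active with `p_active`); open (flush) phases
#' relax the concentration back toward air saturation. Gaussian measurement
#' noise is added per sample. Ground-truth phase states and slopes are kept in
#' the `"truth"` attribute, so slope-filtering and mixture-extraction code can
#' be scored against them.
#'
#' @param smr_slope resting (standard metabolic) O2 slope, mg L^-1 min^-1,
#'   `<= 0`.
#' @param active_slope active-state slope, same units, steeper than
#'   `smr_slope`.
#' @param p_active probability a closed phase is in the active state
#'   (`0 <= p_active < 1`).
#' @param phase_plan data frame with columns `phase_type` (`"open"`/`"closed"`)
#'   and `duration_s`; the default alternates 180 s open / 420 s closed for
#'   12 h. Closed phases must exceed twice the 120 s trim margin.
#' @param noise_sd SD of i.i.d. Gaussian sample noise (mg L^-1).
#' @param seed integer seed.
#' @param sample_dt sampling interval (s).
#' @param o2_saturation air-saturation concentration (mg L^-1).
#' @param fish_mass,chamber_volume,temperature metadata carried on the trace
#'   (kg, L, degrees C).
#' @return data frame `time_s, o2_mg_per_l, phase_id, phase_type` of class
#'   `respirometry_trace`, with attributes `truth` (per-phase state and
#'   slope), `fish_mass`, `chamber_volume`, `temperature`.
#' @export
simulate_respirometry_trace <- function(smr_slope, active_slope, p_active,
                                        phase_plan = default_phase_plan(),
                                        noise_sd = 0.01, seed = 1L,
                                        sample_dt = 5, o2_saturation = 8.6,
                                        fish_mass = 5e-4, chamber_volume = 0.02,
                                        temperature = 23) {
  if (!(abs(active_slope) > abs(smr_slope))) stop("|active_slope| must exceed |smr_slope|")
  if (smr_slope > 0) stop("smr_slope must be <= 0 (O2 declines)")
  if (p_active < 0 || p_active >= 1) stop("p_active must be in [0, 1)")
  stopifnot(all(c("phase_type", "duration_s") %in% names(phase_plan)))
  trim <- 120
  closed_dur <- phase_plan$duration_s[phase_plan$phase_type == "closed"]
  if (!length(closed_dur)) stop("phase_plan contains no closed phases")
  if (any(closed_dur <= 2 * trim))
    stop("phase_plan closed phases must be longer than twice the 120 s trim margin")

  with_seed(seed, {
    t0 <- 0; o2 <- o2_saturation
    out <- list(); truth <- list()
    for (ph in seq_len(nrow(phase_plan))) {
      dur <- phase_plan$duration_s[ph]
      type <- phase_plan$phase_type[ph]
      tt <- seq(0, dur, by = sample_dt)
      if (type == "closed") {
        active <- runif(1) < p_active
        slope <- if (active) active_slope else smr_slope   # mg/L/min
        o2_t <- o2 + slope / 60 * tt
        truth[[ph]] <- data.frame(phase_id = ph, phase_type = type,
                                  active = active, true_slope = slope,
                                  start_time_s = t0)
      } else {
        tau <- 40
        o2_t <- o2_saturation - (o2_saturation - o2) * exp(-tt / tau)
        truth[[ph]] <- data.frame(phase_id = ph, phase_type = type,
                                  active = NA, true_slope = NA_real_,
                                  start_time_s = t0)
      }
      obs <- o2_t + rnorm(length(tt), 0, noise_sd)
      out[[ph]] <- data.frame(time_s = t0 + tt, o2_mg_per_l = obs,
                              phase_id = ph, phase_type = type,
                              stringsAsFactors = FALSE)
      o2 <- o2_t[length(o2_t)]
      t0 <- t0 + dur + sample_dt
    }
    trace <- do.call(rbind, out)
    rownames(trace) <- NULL
    structure(trace, truth = do.call(rbind, truth), fish_mass = fish_mass,
              chamber_volume = chamber_volume, temperature = temperature,
              class = c("respirometry_trace", "data.frame"))
  })
}

#' @rdname simulate_respirometry_trace
#' @param hours total session length for the default plan.
#' @export
default_phase_plan <- function(hours = 12) {
  n_cycles <- floor(hours * 3600 / 600)
  data.frame(phase_type = rep(c("open", "closed"), n_cycles),
             duration_s = rep(c(180, 420), n_cycles))
}

#' Write / read a respirometry trace CSV
#'
#' Schema: `time_s,o2_mg_per_l,phase_id,phase_type`. Mass, volume and
#' temperature metadata travel in a JSON sidecar (same path with extension
#' `.meta.json`) or can be supplied to the reader.
#'
#' @param trace a `respirometry_trace`.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `respirometry_trace` (reader).
#' @export
write_respirometry_trace <- function(trace, path) {
  write.csv(as.data.frame(trace)[, c("time_s", "o2_mg_per_l", "phase_id",
                                     "phase_type")],
            path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fish_mass = attr(trace, "fish_mass"),
                            chamber_volume = attr(trace, "chamber_volume"),
                            temperature = attr(trace, "temperature")),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_respirometry_trace
#' @param fish_mass,chamber_volume,temperature metadata overriding the sidecar.
#' @export
read_respirometry_trace <- function(path, fish_mass = NULL,
                                    chamber_volume = NULL, temperature = NULL) {
  trace <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "o2_mg_per_l", "phase_id", "phase_type")
  if (!all(need %in% names(trace)))
    stop("trace CSV must contain: ", paste(need, collapse = ", "))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path) else list()
  structure(trace,
            fish_mass = fish_mass %||% meta$fish_mass,
            chamber_volume = chamber_volume %||% meta$chamber_volume,
            temperature = temperature %||% meta$temperature,
            class = c("respirometry_trace", "data.frame"))
}
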