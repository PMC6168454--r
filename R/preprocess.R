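#' Default trait specifications for the mosquitofish-style POLS panel
#'
#' Seven modelled traits with their variance-stabilizing transforms and roles:
#' emergence latency is log-transformed; hiding time, freezing time and
#' mass-specific SMR are square-root transformed; distance moved, standard
#' size and Fulton's K are untransformed. Behavioural traits are measured
#' twice per ontogenetic stage, the others once.
#'
#' @return data frame with columns `trait`, `transform`, `role`,
#'   `measured_per_stage`.
#' @export
default_trait_specs <- function() {
  data.frame(
    trait = c("emergence_latency", "hiding_time", "distance_moved",
              "freezing_time", "smr", "standard_size", "fulton_k"),
    transform = c("log", "sqrt", "none", "sqrt", "sqrt", "none", "none"),
    role = c("behaviour", "behaviour", "behaviour", "behaviour",
             "physiology", "life_history", "life_history"),
    measured_per_stage = c(2L, 2L, 2L, 2L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
}

#' Read / write trait specification tables
#'
#' @param path CSV file with header `trait,transform,role,measured_per_stage`.
#' @return data frame of trait specs.
#' @export
read_trait_specs <- function(path) {
  sp <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trait", "transform", "role", "measured_per_stage")
  if (!all(need %in% names(sp)))
    stop("trait spec file must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(sp$transform, c("none", "log", "sqrt"))
  if (length(bad)) stop("unknown transform(s): ", paste(bad, collapse = ", "))
  sp
}

#' Transform and standardize trait values
#'
#' Applies each trait's variance-stabilizing transform (`log`, `sqrt` or
#' none), then mean-centres and scales to unit variance, either pooled across
#' the whole panel or within population. The applied means and SDs are
#' attached as attribute `"scaling"` for back-transformation.
#'
#' Pooled scope preserves between-population mean differences (use it for
#' population-comparison models); per-population scope gives each population
#' zero mean and unit variance per trait (use it for within-population
#' covariance models).
#'
#' @param panel long-format panel.
#' @param specs trait spec table, default [default_trait_specs()]. Traits in
#'   the panel must all be listed.
#' @param scope `"pooled"` or `"per_population"`.
#' @return the panel with transformed, standardized `value`, and a `"scaling"`
#'   attribute (data frame trait, population, transform, mean, sd).
#' @export
transform_and_standardize <- function(panel, specs = default_trait_specs(),
                                      scope = c("pooled", "per_population")) {
  scope <- match.arg(scope)
  traits <- unique(panel$trait)
  missing_spec <- setdiff(traits, specs$trait)
  if (length(missing_spec))
    stop("no trait spec for: ", paste(missing_spec, collapse = ", "))
  if (scope == "per_population" && !"population" %in% names(panel))
    stop("per_population scope requires a 'population' column")

  out <- panel
  scaling <- list()
  pops <- if (scope == "pooled") "(pooled)" else unique(as.character(panel$population))
  for (tr in traits) {
    tf <- specs$transform[specs$trait == tr][1]
    idx_tr <- which(out$trait == tr & !is.na(out$value))
    v <- out$value[idx_tr]
    if (tf == "log") {
      bad <- which(v <= 0)
      if (length(bad))
        stop("log transform of non-positive value for trait '", tr,
             "' (first offending record: row ", idx_tr[bad[1]], ", value ",
             v[bad[1]], ")")
      v <- log(v)
    } else if (tf == "sqrt") {
      bad <- which(v < 0)
      if (length(bad))
        stop("sqrt transform of negative value for trait '", tr,
             "' (first offending record: row ", idx_tr[bad[1]], ", value ",
             v[bad[1]], ")")
      v <- sqrt(v)
    }
    out$value[idx_tr] <- v
    for (pp in pops) {
      idx <- if (scope == "pooled") idx_tr
             else idx_tr[as.character(out$population[idx_tr]) == pp]
      if (!length(idx)) next
      mu <- mean(out$value[idx]); s <- sd(out$value[idx])
      if (!is.finite(s) || s == 0) s <- 1
      out$value[idx] <- (out$value[idx] - mu) / s
      scaling[[length(scaling) + 1L]] <- data.frame(
        trait = tr, population = pp, transform = tf, mean = mu, sd = s,
        stringsAsFactors = FALSE)
    }
  }
  attr(out, "scaling") <- do.call(rbind, scaling)
  out
}

#' Numeric coding of sex and ontogenetic stage
#'
#' Maps immature/female to −0.5 and adult/male to +0.5, centring both binary
#' covariates so intercepts refer to the design midpoint. Already-coded
#' numeric columns pass through unchanged, so the mapping is idempotent.
#'
#' @param panel panel with `sex` and/or `age_stage` columns, either character
#'   labels or already-coded ±0.5 numerics.
#' @return panel with numeric `sex` and `age_stage` in {−0.5, +0.5}.
#' @export
code_covariates <- function(panel) {
  code1 <- function(x, map, what) {
    if (is.numeric(x)) {
      bad <- setdiff(unique(x[!is.na(x)]), c(-0.5, 0.5))
      if (length(bad))
        stop(what, " already numeric but takes values outside {-0.5, 0.5}: ",
             paste(bad, collapse = ", "))
      return(x)
    }
    x <- tolower(as.character(x))
    bad <- setdiff(unique(x[!is.na(x)]), names(map))
    if (length(bad))
      stop("unknown ", what, " label(s): ", paste(bad, collapse = ", "),
           "; accepted: ", paste(names(map), collapse = ", "))
    unname(map[x])
  }
  if ("sex" %in% names(panel))
    panel$sex <- code1(panel$sex, c(female = -0.5, f = -0.5, male = 0.5, m = 0.5), "sex")
  if ("age_stage" %in% names(panel))
    panel$age_stage <- code1(panel$age_stage, c(immature = -0.5, adult = 0.5),
                             "age_stage")
  panel
}

#' Fulton's condition factor
#'
#' Nutritional-state index \eqn{K = 10^4 \times W / L^3} with weight in grams
#' and length in millimetres.
#'
#' @param weight body weight (g), positive.
#' @param length standard length (mm), positive.
#' @return K (g mm^-3 x 10^4); vectorized.
#' @examples
#' fulton_k(0.2, 25)   # 0.128
#' @export
fulton_k <- function(weight, length) {
  if (any(!is.finite(weight)) || any(!is.finite(length)) ||
      any(weight <= 0) || any(length <= 0))
    stop("weight and length must be positive and finite")
  1e4 * weight / length^3
}

#' Attach stage-level traits as covariate columns
#'
#' For models of repeatedly measured traits that adjust for once-per-stage
#' covariates (standard size, Fulton's K), merges each covariate trait's value
#' per (individual, stage) onto every row of the panel.
#'
#' @param panel long-format panel.
#' @param covariate_traits trait labels to spread into columns.
#' @return the panel with one extra numeric column per covariate trait.
#' @export
attach_stage_covariates <- function(panel,
                                    covariate_traits = c("standard_size", "fulton_k")) {
  for (tr in intersect(covariate_traits, unique(panel$trait))) {
    sub <- panel[panel$trait == tr, c("individual_id", "age_stage", "value")]
    sub <- aggregate(value ~ individual_id + age_stage, sub, mean)
    names(sub)[3] <- tr
    panel <- merge(panel, sub, by = c("individual_id", "age_stage"),
                   all.x = TRUE, sort = FALSE)
  }
  panel
}
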