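#' Control parameters for the REML optimizer
#'
#' @param restarts number of dispersed starting points for the variance
#'   parameters (the first is a moment-based start).
#' @param iter_max maximum optimizer iterations per start.
#' @param rel_tol relative convergence tolerance passed to [stats::nlminb()].
#' @param grad_tol tolerance on the finite-difference gradient infinity-norm
#'   used in the post-fit convergence check (applied to free, non-boundary
#'   parameters only).
#' @param var_floor lower bound on variance components; a fitted variance
#'   within ten times this floor is flagged as sitting at the boundary.
#' @return a list of class `mm_control`.
#' @export
mm_control <- function(restarts = 3L, iter_max = 500L, rel_tol = 1e-10,
                       grad_tol = 1e-3, var_floor = 1e-10) {
  structure(list(restarts = as.integer(restarts), iter_max = as.integer(iter_max),
                 rel_tol = rel_tol, grad_tol = grad_tol, var_floor = var_floor),
            class = "mm_control")
}

# Default per-trait fixed-effect formula: age, sex and trial when the trait is
# measured repeatedly within a stage, age and sex otherwise; intercept-only
# when the panel carries none of these covariates.
default_fixed <- function(panel, responses) {
  out <- list()
  has <- function(v) v %in% names(panel)
  for (tr in responses) {
    sub <- panel[panel$trait == tr, , drop = FALSE]
    terms <- character(0)
    if (has("age_stage") && length(unique(sub$age_stage)) > 1L) terms <- c(terms, "age_stage")
    if (has("sex") && length(unique(sub$sex)) > 1L) terms <- c(terms, "sex")
    if (has("trial") && has("age_stage")) {
      key <- paste(sub$individual_id, sub$age_stage)
      reps <- tapply(sub$trial, key, function(x) length(unique(x)))
      if (any(reps > 1L, na.rm = TRUE)) terms <- c(terms, "trial")
    }
    out[[tr]] <- if (length(terms)) as.formula(paste("~", paste(terms, collapse = "+")))
                 else ~1
  }
  out
}

# Construct the measurement-occasion key. Residuals are correlated across
# traits observed on the same occasion and independent across occasions.
# Traits measured repeatedly within a stage (behavioural trials) and traits
# measured once per stage (e.g. SMR, size, taken at the same assay) form
# distinct occasion families, so their residual covariances are not estimable
# from data and are fixed to zero downstream.
make_occasion <- function(panel) {
  if ("occasion" %in% names(panel)) return(as.character(panel$occasion))
  if (all(c("age_stage", "trial") %in% names(panel))) {
    key <- paste(panel$individual_id, panel$age_stage, panel$trait)
    nrep <- tapply(panel$trial, paste(panel$individual_id, panel$age_stage, panel$trait),
                   function(x) length(unique(x)))
    per_trait <- tapply(nrep[key], panel$trait, max, na.rm = TRUE)
    multi <- names(per_trait)[per_trait > 1]
    fam <- ifelse(panel$trait %in% multi, "rep", "once")
    return(paste(panel$age_stage, panel$trial, fam, sep = "|"))
  }
  # no occasion information: every record is its own occasion
  as.character(seq_len(nrow(panel)))
}

# Assemble the per-individual data structures consumed by the C++ kernel.
mm_prepare <- function(panel, responses, fixed, individual, group, occasion) {
  stopifnot(is.data.frame(panel), all(c("trait", "value") %in% names(panel)))
  if (!individual %in% names(panel))
    stop("individual column '", individual, "' not found in panel")
  missing_tr <- setdiff(responses, unique(panel$trait))
  if (length(missing_tr))
    stop("responses not present in panel: ", paste(missing_tr, collapse = ", "))

  panel$individual_id <- panel[[individual]]
  dat <- panel[panel$trait %in% responses & !is.na(panel$value), , drop = FALSE]
  dat$..occ <- if (is.null(occasion)) make_occasion(dat) else as.character(dat[[occasion]])

  if (is.null(group)) {
    dat$..grp <- "all"
  } else {
    if (!group %in% names(dat)) stop("group column '", group, "' not found")
    dat$..grp <- as.character(dat[[group]])
  }
  groups <- sort(unique(dat$..grp))

  if (is.null(fixed)) fixed <- default_fixed(dat, responses)
  if (inherits(fixed, "formula")) fixed <- setNames(rep(list(fixed), length(responses)), responses)
  if (is.null(names(fixed)) && length(fixed) == length(responses)) names(fixed) <- responses
  if (!all(responses %in% names(fixed)))
    stop("fixed must be a formula or a named list covering every response")

  # drop rows with missing covariates used by their trait's formula
  keep <- rep(TRUE, nrow(dat))
  for (tr in responses) {
    vars <- all.vars(fixed[[tr]])
    if (length(vars)) {
      idx <- dat$trait == tr
      keep[idx] <- keep[idx] & complete.cases(dat[idx, vars, drop = FALSE])
    }
  }
  dat <- dat[keep, , drop = FALSE]

  by_group <- length(groups) > 1L

  # design blocks: one set of columns per (group x) response
  blocks <- list(); col_info <- list()
  for (g in groups) {
    for (tr in responses) {
      idx <- which(dat$trait == tr & dat$..grp == g)
      if (!length(idx)) {
        if (by_group) stop("group '", g, "' has no observations of response '", tr, "'")
        next
      }
      rhs <- fixed[[tr]]
      mm <- model.matrix(rhs, dat[idx, , drop = FALSE])
      lab <- if (by_group) paste0(g, "|", tr) else tr
      colnames(mm) <- paste0(lab, ":", colnames(mm))
      blocks[[lab]] <- list(idx = idx, mm = mm)
      col_info[[lab]] <- data.frame(name = colnames(mm), group = g, trait = tr,
                                    term = c("(Intercept)", attr(rhs, "term.labels") %||%
                                               attr(terms(rhs), "term.labels"))[
                                      attr(mm, "assign") + 1L],
                                    stringsAsFactors = FALSE)
    }
    if (!by_group) break
  }
  beta_info <- do.call(rbind, col_info)
  p <- nrow(beta_info)
  X <- matrix(0, nrow(dat), p, dimnames = list(NULL, beta_info$name))
  for (b in blocks) X[b$idx, colnames(b$mm)] <- b$mm

  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("fixed-effect design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }

  # flat, row-sorted layout for the C++ kernel: one block of rows per
  # individual, with 0-based trait/occasion/group codes
  ord <- order(match(dat$individual_id, unique(dat$individual_id)))
  dat <- dat[ord, , drop = FALSE]
  X <- X[ord, , drop = FALSE]
  trait_idx <- match(dat$trait, responses) - 1L
  grp_idx <- match(dat$..grp, groups) - 1L
  occ_idx <- as.integer(factor(paste(dat$individual_id, dat$..occ))) - 1L
  ids <- unique(dat$individual_id)
  ind_len <- as.integer(table(factor(dat$individual_id, levels = ids)))
  ind_start <- c(0L, cumsum(ind_len)[-length(ind_len)])
  grp_of_ind <- grp_idx[ind_start + 1L]

  # co-observation: is a trait pair ever measured on the same occasion?
  Tn <- length(responses)
  coobs <- diag(TRUE, Tn)
  occ_key <- paste(dat$individual_id, dat$..occ)
  tab <- table(occ_key, factor(dat$trait, levels = responses)) > 0
  cross <- crossprod(tab)
  coobs <- coobs | (cross > 0)

  list(dat = dat, X = X, y = dat$value, trait0 = trait_idx, occ0 = occ_idx,
       ind_start = ind_start, ind_len = ind_len, grp_of_ind = grp_of_ind,
       ids = ids, p = p, n = nrow(dat), n_ind = length(ids),
       responses = responses, groups = groups,
       beta_info = beta_info, coobs = coobs, fixed = fixed, by_group = by_group)
}

# Parameter map: one row per element of every covariance matrix, saying
# whether it is a free parameter (and which), or fixed (usually at zero).
# Variances are parameterized as log standard deviations, covariances on the
# natural scale (they are unbounded, matching the likelihood-ratio reference
# distributions used downstream).
build_parmap <- function(prep, among, residual, constraints) {
  responses <- prep$responses; groups <- prep$groups
  Tn <- length(responses); G <- length(groups)
  rows <- list(); counter <- 0L
  new_par <- function() { counter <<- counter + 1L; counter }

  norm_pairs <- function(x) {
    if (is.null(x)) return(character(0))
    if (identical(x, "all"))
      x <- utils::combn(responses, 2, simplify = FALSE)
    vapply(x, function(pr) paste(sort(match(pr, responses)), collapse = "-"), "")
  }
  among_zero <- norm_pairs(constraints$among_zero)
  among_equal <- norm_pairs(constraints$among_equal_groups)
  res_zero <- norm_pairs(constraints$res_zero)
  drop_trait <- constraints$drop_trait
  if (!is.null(drop_trait) && !all(drop_trait %in% responses))
    stop("drop_trait names traits absent from the responses")
  dropped <- match(drop_trait, responses)

  shared <- list()  # key -> par index for among_equal_groups elements
  for (mat in c("ind", "res")) {
    structure <- if (mat == "ind") among else residual
    for (gi in seq_len(G)) {
      for (i in seq_len(Tn)) for (j in seq_len(i)) {
        kind <- if (i == j) "var" else "cov"
        key <- paste(sort(c(i, j)), collapse = "-")
        par <- NA_integer_; fixed <- 0
        free <- structure != "zero" && (kind == "var" || structure == "us")
        if (mat == "ind" && length(dropped) && (i %in% dropped || j %in% dropped)) free <- FALSE
        if (mat == "ind" && kind == "cov" && key %in% among_zero) free <- FALSE
        if (mat == "res" && kind == "cov" &&
            (!prep$coobs[i, j] || key %in% res_zero)) free <- FALSE
        if (free) {
          if (mat == "ind" && kind == "cov" && key %in% among_equal) {
            if (is.null(shared[[key]])) shared[[key]] <- new_par()
            par <- shared[[key]]
          } else par <- new_par()
        }
        rows[[length(rows) + 1L]] <- data.frame(
          mat = mat, g = gi, i = i, j = j, kind = kind, par = par,
          fixed = fixed, stringsAsFactors = FALSE)
      }
    }
  }
  pm <- do.call(rbind, rows)
  attr(pm, "n_par") <- counter
  if (any(pm$mat == "res" & pm$kind == "cov" & is.na(pm$par) & pm$i != pm$j)) {
    nz <- pm[pm$mat == "res" & pm$kind == "cov" & is.na(pm$par), , drop = FALSE]
    never <- unique(nz[!prep$coobs[cbind(nz$i, nz$j)], c("i", "j")])
    if (nrow(never))
      message("residual covariance fixed to 0 for trait pairs never co-observed: ",
              paste(apply(never, 1, function(r)
                paste(responses[as.integer(r)], collapse = "~")), collapse = ", "))
  }
  pm
}

theta_to_sigmas <- function(theta, parmap, Tn, G) {
  val <- ifelse(is.na(parmap$par), parmap$fixed, theta[parmap$par])
  val[parmap$kind == "var" & !is.na(parmap$par)] <-
    exp(2 * val[parmap$kind == "var" & !is.na(parmap$par)])
  Sind <- Sres <- vector("list", G)
  for (g in seq_len(G)) {
    for (mat in c("ind", "res")) {
      S <- matrix(0, Tn, Tn)
      sub <- parmap$mat == mat & parmap$g == g
      S[cbind(parmap$i[sub], parmap$j[sub])] <- val[sub]
      S[cbind(parmap$j[sub], parmap$i[sub])] <- val[sub]
      if (mat == "ind") Sind[[g]] <- S else Sres[[g]] <- S
    }
  }
  list(ind = Sind, res = Sres)
}

# Moment-based starting values: split each trait's total variance into
# between- and within-individual parts from individual means.
moment_starts <- function(prep, parmap) {
  n_par <- attr(parmap, "n_par")
  theta0 <- numeric(n_par)
  dat <- prep$dat
  for (g in seq_along(prep$groups)) {
    for (t in seq_along(prep$responses)) {
      sub <- dat[dat$trait == prep$responses[t] & dat$..grp == prep$groups[g], ]
      v_tot <- max(var(sub$value), 1e-4)
      m <- tapply(sub$value, sub$individual_id, mean)
      k <- mean(table(sub$individual_id))
      w <- mean(tapply(sub$value, sub$individual_id, var), na.rm = TRUE)
      if (!is.finite(w)) w <- v_tot / 2
      b <- max(var(m) - w / max(k, 1), 0.1 * v_tot)
      w <- max(w, 0.1 * v_tot)
      pi_ind <- parmap$par[parmap$mat == "ind" & parmap$g == g &
                             parmap$i == t & parmap$j == t]
      pi_res <- parmap$par[parmap$mat == "res" & parmap$g == g &
                             parmap$i == t & parmap$j == t]
      if (length(pi_ind) && !is.na(pi_ind)) theta0[pi_ind] <- 0.5 * log(b)
      if (length(pi_res) && !is.na(pi_res)) theta0[pi_res] <- 0.5 * log(w)
    }
  }
  theta0
}

#' Fit a multi-trait REML mixed model with individual random intercepts
#'
#' Fits, by restricted maximum likelihood, the model
#' \deqn{y_{ito} = x_{ito}'\beta_t + u_{it} + e_{ito}}
#' where \eqn{u_i \sim N(0, \Sigma_{ind})} is an individual-level random
#' intercept vector over traits and residuals \eqn{e} are correlated across
#' traits measured on the same occasion (\eqn{\Sigma_{res}}) and independent
#' across occasions. Both covariance matrices may be unstructured, diagonal,
#' absent, or constrained element-wise; with a grouping factor (population)
#' each group gets its own covariance matrices (optionally with among-individual
#' covariances constrained equal across groups) and its own fixed effects.
#'
#' Variances are kept positive through a log-standard-deviation
#' parameterization; covariances are unbounded. The restricted likelihood is
#' maximized with [stats::nlminb()] from several dispersed starting points.
#'
#' @param panel long-format data frame with columns `trait`, `value`, an
#'   individual identifier, and any covariates referenced by `fixed`.
#' @param responses character vector of trait labels to model jointly.
#' @param fixed a one-sided formula applied to every response, or a named list
#'   of formulas (one per response). Default: `~ age_stage + sex (+ trial)`,
#'   trial included for traits measured repeatedly within a stage.
#' @param individual name of the individual-identifier column.
#' @param group optional name of a grouping column (e.g. `"population"`);
#'   covariance matrices and fixed effects are then group-specific.
#' @param occasion optional name of a column identifying measurement occasions;
#'   by default occasions are derived from `age_stage` and `trial`.
#' @param among,residual structure of the among-individual and residual
#'   covariance matrices: `"us"` (unstructured), `"diag"`, or (among only)
#'   `"zero"` to drop the random intercept.
#' @param constraints list with optional elements `among_zero` (list of trait
#'   pairs, or `"all"`, whose among-individual covariance is fixed to zero),
#'   `among_equal_groups` (pairs, or `"all"`, whose among-individual covariance
#'   is constrained equal across groups), `drop_trait` (trait whose
#'   among-individual variance and covariances are all removed), and
#'   `res_zero` (residual covariances fixed to zero).
#' @param se compute asymptotic standard errors of the (co)variance components
#'   from the finite-difference Hessian of the restricted likelihood.
#' @param control an [mm_control()] list.
#' @return an object of class `mm_fit`; see [summary.mm_fit()].
#' @seealso [repeatability()], [pols_decompose()], [lrt_mm()]
#' @examples
#' cfg <- sim_config(n_individuals = 15, seed = 1)
#' panel <- simulate_trait_panel(cfg)
#' fit <- mm_reml(panel, "standard_size", group = NULL,
#'                control = mm_control(restarts = 1))
#' summary(fit)
#' @export
mm_reml <- function(panel, responses, fixed = NULL,
                    individual = "individual_id", group = NULL, occasion = NULL,
                    among = c("us", "diag", "zero"),
                    residual = c("us", "diag"),
                    constraints = list(), se = TRUE, control = mm_control()) {
  among <- match.arg(among); residual <- match.arg(residual)
  prep <- mm_prepare(panel, responses, fixed, individual, group, occasion)
  parmap <- build_parmap(prep, among, residual, constraints)
  n_par <- attr(parmap, "n_par")
  Tn <- length(prep$responses); G <- length(prep$groups)
  n <- prep$n; p <- prep$p
  if (n <= p) stop("not enough observations to estimate the fixed effects")

  BIG <- 1e10
  nll <- function(theta) {
    S <- theta_to_sigmas(theta, parmap, Tn, G)
    k <- reml_kernel(prep$X, prep$y, prep$trait0, prep$occ0, prep$ind_start,
                     prep$ind_len, prep$grp_of_ind, S$ind, S$res)
    if (!isTRUE(k$ok)) return(BIG)
    ch <- tryCatch(chol(k$XtVX), error = function(e) NULL)
    if (is.null(ch)) return(BIG)
    beta <- backsolve(ch, forwardsolve(t(ch), k$XtVy))
    rss <- drop(k$ytVy - crossprod(beta, k$XtVy))
    if (!is.finite(rss) || rss < 0) rss <- max(rss, 1e-12)
    0.5 * (k$logdetV + 2 * sum(log(diag(ch))) + rss + (n - p) * log(2 * pi))
  }

  lo <- rep(-Inf, n_par); hi <- rep(Inf, n_par)
  var_pars <- unique(parmap$par[parmap$kind == "var" & !is.na(parmap$par)])
  lo[var_pars] <- 0.5 * log(control$var_floor)
  hi[var_pars] <- 15

  theta0 <- moment_starts(prep, parmap)
  starts <- list(theta0)
  if (control$restarts >= 2L) {  # pooled, among-shrunk variant
    s2 <- theta0; s2[var_pars] <- mean(theta0[var_pars]); starts <- c(starts, list(s2))
  }
  if (control$restarts >= 3L) {
    s3 <- theta0
    ind_vars <- intersect(var_pars, parmap$par[parmap$mat == "ind"])
    res_vars <- setdiff(var_pars, ind_vars)
    s3[ind_vars] <- theta0[ind_vars] - 1; s3[res_vars] <- theta0[res_vars] + 0.3
    starts <- c(starts, list(s3))
  }
  if (control$restarts > 3L) for (r in 4:control$restarts)
    starts <- c(starts, list(theta0 + 0.4 * sin(seq_len(n_par) * r)))

  best <- NULL
  for (st in starts) {
    opt <- if (n_par)
      nlminb(st, nll, lower = lo, upper = hi,
             control = list(iter.max = control$iter_max,
                            eval.max = 4L * control$iter_max,
                            rel.tol = control$rel_tol))
    else list(par = numeric(0), objective = nll(numeric(0)), convergence = 0L)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  theta_hat <- best$par

  # gradient check on free parameters not pinned at the variance floor
  grad_norm <- NA_real_
  if (n_par) {
    h <- 1e-5; g <- numeric(n_par)
    f0 <- best$objective
    for (k in seq_len(n_par)) {
      tp <- theta_hat; tm <- theta_hat
      tp[k] <- min(tp[k] + h, hi[k]); tm[k] <- max(tm[k] - h, lo[k])
      g[k] <- (nll(tp) - nll(tm)) / (tp[k] - tm[k])
    }
    at_lo <- theta_hat <= lo + 1e-8
    free_g <- g[!at_lo | g < 0]   # at a lower bound a positive gradient is optimal
    grad_norm <- if (length(free_g)) max(abs(free_g)) / max(1, abs(f0)) else 0
  }
  converged <- best$convergence == 0L ||
    (is.finite(grad_norm) && grad_norm < control$grad_tol)

  S <- theta_to_sigmas(theta_hat, parmap, Tn, G)
  k <- reml_kernel(prep$X, prep$y, prep$trait0, prep$occ0, prep$ind_start,
                   prep$ind_len, prep$grp_of_ind, S$ind, S$res)
  ch <- chol(k$XtVX)
  beta <- drop(backsolve(ch, forwardsolve(t(ch), k$XtVy)))
  names(beta) <- prep$beta_info$name
  vcov_beta <- chol2inv(ch)
  dimnames(vcov_beta) <- list(names(beta), names(beta))

  theta_vcov <- NULL
  if (se && n_par) {
    H <- tryCatch(optimHess(theta_hat, nll), error = function(e) NULL)
    if (!is.null(H)) {
      ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
      evv <- pmax(ev$values, 1e-10)
      theta_vcov <- ev$vectors %*% (t(ev$vectors) / evv)
    }
  }

  sig_se <- function(mat_name, g) {
    if (is.null(theta_vcov)) return(NULL)
    Sse <- matrix(NA_real_, Tn, Tn)
    sub <- parmap[parmap$mat == mat_name & parmap$g == g, ]
    for (r in seq_len(nrow(sub))) {
      pr <- sub$par[r]
      if (is.na(pr)) { v <- 0 } else {
        sd_th <- sqrt(max(theta_vcov[pr, pr], 0))
        v <- if (sub$kind[r] == "var") 2 * exp(2 * theta_hat[pr]) * sd_th else sd_th
      }
      Sse[sub$i[r], sub$j[r]] <- v; Sse[sub$j[r], sub$i[r]] <- v
    }
    Sse
  }
  dimn <- list(prep$responses, prep$responses)
  for (g in seq_len(G)) { dimnames(S$ind[[g]]) <- dimn; dimnames(S$res[[g]]) <- dimn }
  names(S$ind) <- names(S$res) <- prep$groups

  boundary <- rep(FALSE, nrow(parmap))
  bsel <- parmap$kind == "var" & !is.na(parmap$par)
  boundary[bsel] <- exp(2 * theta_hat[parmap$par[bsel]]) < 10 * control$var_floor

  fit <- list(
    call = match.call(), responses = prep$responses, groups = prep$groups,
    group_col = group, occasion_col = occasion,
    fixed = prep$fixed, among = among, residual = residual,
    constraints = constraints,
    beta = beta, se_beta = sqrt(diag(vcov_beta)), vcov_beta = vcov_beta,
    beta_info = prep$beta_info,
    sigma_ind = S$ind, sigma_res = S$res,
    sigma_ind_se = if (se) lapply(seq_len(G), function(g) {
      x <- sig_se("ind", g); if (!is.null(x)) dimnames(x) <- dimn; x }),
    sigma_res_se = if (se) lapply(seq_len(G), function(g) {
      x <- sig_se("res", g); if (!is.null(x)) dimnames(x) <- dimn; x }),
    reml_loglik = -best$objective, n_parameters = n_par, theta = theta_hat,
    theta_vcov = theta_vcov, parmap = parmap,
    converged = converged, grad_norm = grad_norm,
    at_boundary = any(boundary),
    n_obs = n, n_individuals = prep$n_ind, p_fixed = p,
    df_method = "containment",
    prep = prep)
  if (se) { names(fit$sigma_ind_se) <- prep$groups; names(fit$sigma_res_se) <- prep$groups }
  class(fit) <- "mm_fit"
  fit
}

#' Refit an `mm_fit` with modified constraints or structure
#'
#' Convenience used by the likelihood-ratio machinery: refits the same panel,
#' responses and fixed effects, overriding only what is supplied.
#'
#' @param fit an [mm_reml()] fit.
#' @param panel the panel the fit was estimated from.
#' @param ... arguments overriding those of the original call
#'   (`among`, `residual`, `constraints`, `control`, `se`).
#' @return an `mm_fit`.
#' @export
mm_update <- function(fit, panel, ...) {
  stopifnot(inherits(fit, "mm_fit"))
  dots <- list(...)
  args <- list(panel = panel, responses = fit$responses, fixed = fit$fixed,
               group = fit$group_col, occasion = fit$occasion_col,
               among = fit$among, residual = fit$residual,
               constraints = fit$constraints, se = !is.null(fit$theta_vcov),
               control = mm_control())
  args[names(dots)] <- dots
  do.call(mm_reml, args)
}
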