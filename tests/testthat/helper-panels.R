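# Small panel builders and independent oracles shared across the suite.

fast_ctrl <- mm_control(restarts = 1, rel_tol = 1e-8)
tight_ctrl <- mm_control(restarts = 2, rel_tol = 1e-12)

# univariate balanced panel: n_ind individuals x k occasions, intercept-only
make_univariate_panel <- function(n_ind, k, s_ind, s_res, seed, mu = 0) {
  set.seed(seed)
  u <- rnorm(n_ind, 0, sqrt(s_ind))
  data.frame(individual_id = rep(seq_len(n_ind), each = k),
             trait = "y", occasion = rep(seq_len(k), n_ind),
             value = mu + rep(u, each = k) + rnorm(n_ind * k, 0, sqrt(s_res)))
}

# bivariate panel, both traits co-observed on every occasion
make_bivariate_panel <- function(n_ind, k, sigma_ind, sigma_res, seed) {
  set.seed(seed)
  u <- polsmm:::rmvn(n_ind, c(0, 0), sigma_ind)
  rows <- expand.grid(occ = seq_len(k), individual_id = seq_len(n_ind))
  e <- polsmm:::rmvn(nrow(rows), c(0, 0), sigma_res)
  data.frame(individual_id = rep(rows$individual_id, 2),
             occasion = rep(rows$occ, 2),
             trait = rep(c("y1", "y2"), each = nrow(rows)),
             value = c(u[rows$individual_id, 1] + e[, 1],
                       u[rows$individual_id, 2] + e[, 2]))
}

# closed-form REML for the balanced one-way random-effects layout
# (interior solutions): sigma2_res = MSW, sigma2_ind = (MSB - MSW) / k
anova_oneway_reml <- function(value, individual, k) {
  m_i <- tapply(value, individual, mean)
  n_ind <- length(m_i)
  msb <- k * var(m_i)
  msw <- sum((value - m_i[as.character(individual)])^2) / (n_ind * (k - 1))
  c(sigma_ind = max(0, (msb - msw) / k), sigma_res = msw)
}

# dense brute-force restricted log-likelihood at given covariance matrices,
# built from the fit's own prepared design (independent of the C++ kernel)
brute_force_reml_ll <- function(fit) {
  prep <- fit$prep
  d <- prep$dat
  n <- prep$n
  V <- matrix(0, n, n)
  g_of_row <- prep$grp_of_ind[rep(seq_len(prep$n_ind), prep$ind_len)] + 1L
  for (r in seq_len(n)) for (s in seq_len(n)) {
    if (d$individual_id[r] != d$individual_id[s]) next
    g <- g_of_row[r]
    tr_r <- d$trait[r]; tr_s <- d$trait[s]
    v <- fit$sigma_ind[[g]][tr_r, tr_s]
    if (prep$occ0[r] == prep$occ0[s]) v <- v + fit$sigma_res[[g]][tr_r, tr_s]
    V[r, s] <- v
  }
  X <- prep$X; y <- prep$y; p <- ncol(X)
  Vi <- solve(V)
  B <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  res <- y - X %*% B
  -0.5 * drop(determinant(V)$modulus + determinant(t(X) %*% Vi %*% X)$modulus +
                t(res) %*% Vi %*% res + (n - p) * log(2 * pi))
}

# chi-square df=1 upper tail via the normal distribution (independent of pchisq)
chi1_tail <- function(t) 2 * (1 - pnorm(sqrt(t)))
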