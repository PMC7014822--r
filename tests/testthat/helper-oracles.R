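# Independent oracles used across the suite.  Each is a brute-force or
# closed-form computation kept deliberately separate from the package's own
# code paths.

# Exhaustive hypergeometric upper-tail sum: P(overlap >= k).
hyper_tail_oracle <- function(k, K, N, n) {
  j <- seq(max(k, 0), min(K, n))
  if (!length(j)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Dense 2-D grid BMDL oracle for a single-series increasing E4 fit.
# Background a and the residual variance are profiled analytically, so the
# grid enumerates the (gamma, b) box; the BMDL is the smallest closed-form
# BMD among grid points whose deviance stays within `crit`.
grid_bmdl_oracle <- function(grp, fit, bmr = 0.10,
                             crit = qchisq(0.90, 1),
                             half_width = 1.5, n_grid = 500) {
  stopifnot(length(unique(grp$series)) == 1)
  lg_hat <- log(fit$coefficients$gamma)
  lb_hat <- log(fit$coefficients$b)
  g <- expand.grid(lg = seq(lg_hat - half_width, lg_hat + half_width,
                            length.out = n_grid),
                   lb = seq(lb_hat - half_width, lb_hat + half_width,
                            length.out = n_grid))
  gam <- exp(g$lg); b <- exp(g$lb)
  N <- sum(grp$n)
  logf <- matrix(0, nrow(g), nrow(grp))
  for (j in seq_len(nrow(grp)))
    logf[, j] <- log(1 + gam * (1 - exp(-b * grp$dose[j])))
  la <- as.vector(sum(grp$n * grp$lmu) - logf %*% grp$n) / N
  S <- rep(sum(grp$ss), nrow(g))
  for (j in seq_len(nrow(grp)))
    S <- S + grp$n[j] * (grp$lmu[j] - la - logf[, j])^2
  nll <- N / 2 * (log(2 * pi * S / N) + 1)
  dev <- 2 * (nll - (-fit$logLik))
  bmd <- ifelse(gam > bmr, -log(1 - bmr / gam) / b, NA_real_)
  min(bmd[dev <= crit], na.rm = TRUE)
}

# Dense 2-D grid minimiser of the fixed-weight Hill-count objective
# sum w_i (y_i - C/(1+(d50/d)^n))^2.
grid_hill_count_oracle <- function(counts, doses, w, plateau, d50_hat, n_hat,
                                   half_width = 0.4, n_grid = 400) {
  lg <- seq(log(d50_hat) - half_width, log(d50_hat) + half_width,
            length.out = n_grid)
  ln <- seq(log(n_hat) - half_width, log(n_hat) + half_width,
            length.out = n_grid)
  best <- c(NA, NA, Inf)
  for (b in ln) {
    nn <- exp(b)
    fmat <- plateau / (1 + exp(nn * outer(lg, log(doses), `-`)) )
    # note (d50/d)^n = exp(n (log d50 - log d))
    obj <- as.vector((fmat - matrix(counts, n_grid, length(doses),
                                    byrow = TRUE))^2 %*% w)
    i <- which.min(obj)
    if (obj[i] < best[3]) best <- c(exp(lg[i]), nn, obj[i])
  }
  list(d50 = best[1], n = best[2], obj = best[3])
}

# Grubbs critical value straight from the t-quantile formula.
grubbs_crit_oracle <- function(n, alpha = 0.05) {
  t2 <- qt(1 - alpha / (2 * n), n - 2)^2
  ((n - 1) / sqrt(n)) * sqrt(t2 / (n - 2 + t2))
}

# Textbook Bartlett statistic, written independently of the package.
bartlett_stat_oracle <- function(groups) {
  n <- vapply(groups, length, integer(1))
  v <- vapply(groups, var, numeric(1))
  k <- length(groups); N <- sum(n)
  sp2 <- sum((n - 1) * v) / (N - k)
  num <- (N - k) * log(sp2) - sum((n - 1) * log(v))
  den <- 1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1))
  num / den
}

# Individual-animal records from a lognormal mean curve on the study design.
sim_apical_records <- function(mean_fun, doses = c(0, 300, 500, 750, 1000, 1500),
                               n = 6, cv = 0.25, seed = 1) {
  set.seed(seed)
  sdl <- sqrt(log(1 + cv^2))
  d <- rep(doses, each = n)
  data.frame(dose = d,
             value = mean_fun(d) * exp(rnorm(length(d), -sdl^2 / 2, sdl)))
}
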