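#' Count DEGs per dose at K-fold thresholds
#'
#' For each fold-change threshold K, counts at every dose the genes with
#' |FC| >= K and FDR <= `fdr_thresh`.  Counts are non-increasing in K at
#' each dose by construction.
#'
#' @param deg_table DE table with `gene`, `dose`, `fdr` and `fc` (signed
#'   linear) or `log2fc`.
#' @param k_values numeric vector of fold-change thresholds (each >= 1),
#'   e.g. `c(2, 3, 5, 10)`.
#' @param fdr_thresh FDR cut (default 0.05).
#' @return named list (one element per K) of data.frames `dose`, `count`.
#' @export
count_degs_by_threshold <- function(deg_table, k_values = c(2, 3, 5, 10),
                                    fdr_thresh = 0.05) {
  if (any(k_values < 1)) stop("K thresholds must be >= 1")
  tab <- as.data.frame(deg_table)
  if (!"fc" %in% names(tab)) tab$fc <- log2fc_to_fc(tab$log2fc)
  doses <- sort(unique(tab$dose))
  doses <- doses[doses > 0]
  out <- lapply(k_values, function(K) {
    cnt <- vapply(doses, function(d)
      sum(abs(tab$fc) >= K & tab$fdr <= fdr_thresh & tab$dose == d,
          na.rm = TRUE), numeric(1))
    data.frame(K = K, dose = doses, count = as.integer(cnt))
  })
  names(out) <- as.character(k_values)
  out
}

# Hill count curve: f(d) = C / (1 + (d50/d)^n), logistic in log dose.
hill_count_mean <- function(dose, d50, n, plateau) {
  plateau / (1 + (d50 / dose)^n)
}

# Vectorised damped Gauss-Newton for R replicates of the weighted
# least-squares Hill-count fit with FIXED weights.  Y: R x m count matrix,
# w: length-m weights, t1/t2: length-R starting values of (log d50, log n).
gn_hill_batch <- function(Y, doses, w, plateau, t1, t2,
                          tol = 1e-8, max_iter = 60) {
  R <- nrow(Y); m <- length(doses)
  u <- log(doses)
  W <- matrix(w, R, m, byrow = TRUE)
  obj <- function(a1, a2) {
    S <- 1 / (1 + exp(-exp(a2) * outer(-a1, u, `+`)))   # s_ri = logistic
    Fv <- plateau * S
    rowSums(W * (Y - Fv)^2)
  }
  f_cur <- obj(t1, t2)
  conv <- rep(FALSE, R)
  lam <- rep(1e-6, R)
  for (it in seq_len(max_iter)) {
    nh <- exp(t2)
    X <- outer(-t1, u, `+`)                  # log d - log d50
    S <- 1 / (1 + exp(-nh * X))
    Fv <- plateau * S
    G <- plateau * S * (1 - S)
    J1 <- -G * nh                            # d f / d t1
    J2 <- G * nh * X                         # d f / d t2
    Rres <- Y - Fv
    A <- rowSums(W * J1 * J1) + lam
    B <- rowSums(W * J1 * J2)
    Cc <- rowSums(W * J2 * J2) + lam
    g1 <- rowSums(W * J1 * Rres)
    g2 <- rowSums(W * J2 * Rres)
    det <- A * Cc - B * B
    det[abs(det) < 1e-300] <- 1e-300
    d1s <- (Cc * g1 - B * g2) / det
    d2s <- (A * g2 - B * g1) / det
    step <- rep(1, R)
    improved <- rep(FALSE, R)
    t1n <- t1; t2n <- t2; f_new <- f_cur
    for (h in 1:12) {                        # backtracking halving
      idx <- !improved & !conv
      if (!any(idx)) break
      c1 <- t1 + step * d1s; c2 <- t2 + step * d2s
      fc <- obj(c1, c2)
      good <- idx & is.finite(fc) & (fc <= f_cur + 1e-12)
      t1n[good] <- c1[good]; t2n[good] <- c2[good]; f_new[good] <- fc[good]
      improved <- improved | good
      step <- ifelse(improved, step, step / 2)
    }
    lam <- ifelse(improved, pmax(lam / 3, 1e-10), lam * 10)
    rel <- pmax(abs(t1n - t1), abs(t2n - t2)) / pmax(1, abs(t1), abs(t2))
    # converged: a successful tiny step, or a damped stall at the optimum
    conv <- conv | (improved & rel < tol) | (!improved & lam > 1e8)
    t1 <- t1n; t2 <- t2n; f_cur <- f_new
    if (all(conv)) break
  }
  list(t1 = t1, t2 = t2, obj = f_cur, converged = conv | f_cur < 1e-20)
}

#' Fit the fixed-plateau Hill curve to DEG counts by Poisson-weighted IRLS
#'
#' Fits Count = plateau / (1 + (d50/dose)^n) to per-dose DEG counts by
#' iteratively reweighted least squares: weighted least squares with
#' inverse-variance weights under a Poisson variance assumption
#' (w = 1/max(fitted, eps)), alternating weight updates and refits until
#' the relative parameter change falls below `tol`.  The control dose is
#' excluded (the model is undefined at dose 0, where the DEG count is 0 by
#' construction).
#'
#' @param counts non-negative integer DEG counts, one per positive dose
#'   (or a data.frame with `dose` and `count` columns).
#' @param doses positive doses (omit when `counts` is a data.frame).
#' @param plateau fixed plateau C (default 1000).
#' @param eps variance floor for the weights (default 1e-6).
#' @param tol relative parameter-change convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return object of class `"hill_count_fit"`: `d50`, `n`, `plateau`,
#'   `fitted`, `weights` (final inverse-variance weights), `doses`,
#'   `counts`, `converged`, `iterations`.
#' @export
fit_hill_count <- function(counts, doses = NULL, plateau = 1000, eps = 1e-6,
                           tol = 1e-8, max_iter = 100) {
  if (is.data.frame(counts)) { doses <- counts$dose; counts <- counts$count }
  if (any(doses <= 0)) stop("doses must be strictly positive (control excluded)")
  if (any(diff(order(doses)) < 0)) { o <- order(doses); doses <- doses[o]; counts <- counts[o] }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts > 0) < 2) stop("need at least 2 doses with positive counts")
  if (all(counts >= plateau))
    stop("all counts at the plateau: d50 not identifiable")
  # logit-linearisation start
  sel <- counts > 0 & counts < plateau
  z <- log(counts[sel] / (plateau - counts[sel]))
  if (sum(sel) >= 2) {
    cf <- unname(stats::lsfit(log(doses[sel]), z)$coefficients)
    n0 <- max(cf[2], 0.1)
    t1 <- -cf[1] / n0
  } else { n0 <- 1; t1 <- log(stats::median(doses)) }
  t2 <- log(n0)
  Y <- matrix(as.numeric(counts), 1)
  mu <- hill_count_mean(doses, exp(t1), n0, plateau)
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    w <- 1 / pmax(mu, eps)
    gn <- gn_hill_batch(Y, doses, w, plateau, t1, t2, tol = tol / 10)
    # relax later weight updates: the plain fixed-point iteration can fall
    # into a 2-cycle when residuals are large; damping keeps the same
    # fixed point and restores convergence
    lam <- if (iter <= 10) 1 else 0.5
    t1n <- lam * gn$t1 + (1 - lam) * t1
    t2n <- lam * gn$t2 + (1 - lam) * t2
    rel <- max(abs(t1n - t1), abs(t2n - t2)) / max(1, abs(t1), abs(t2))
    t1 <- t1n; t2 <- t2n
    mu <- hill_count_mean(doses, exp(t1), exp(t2), plateau)
    if (rel < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!is.finite(exp(t1)) || exp(t1) <= 0 || !is.finite(exp(t2)))
    converged <- FALSE                       # degenerate (counts at plateau)
  structure(list(d50 = exp(t1), n = exp(t2), plateau = plateau,
                 fitted = mu, weights = 1 / pmax(mu, eps),
                 doses = doses, counts = counts, eps = eps,
                 converged = converged, iterations = iter),
            class = "hill_count_fit")
}

#' @export
print.hill_count_fit <- function(x, ...) {
  cat(sprintf("Hill count fit: plateau %g, d50 %.4g, n %.4g (%s, %d IRLS iterations)\n",
              x$plateau, x$d50, x$n,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Dose at which a single DEG is predicted (D1)
#'
#' Closed-form inversion of the fitted count curve at a predicted count of
#' one: D1 = d50 * (C - 1)^(-1/n).
#'
#' @param fit a `"hill_count_fit"` (or list with `d50`, `n`, `plateau`).
#' @return the dose D1.
#' @export
compute_d1 <- function(fit) {
  if (fit$plateau <= 1) stop("plateau must exceed 1 for D1 to exist")
  fit$d50 * (fit$plateau - 1)^(-1 / fit$n)
}

#' Parametric-bootstrap lower bound on D1 (D1*)
#'
#' Simulates Poisson counts about the fitted curve at each dose, refits the
#' weighted Hill count model to every replicate with the weights frozen at
#' the inverse of the original fitted responses, inverts each refit to its
#' D1, and returns the 5th percentile of the sorted D1 sample — the
#' one-tailed 95% lower confidence bound.
#'
#' @param fit a converged [fit_hill_count()] result.
#' @param n_sim number of bootstrap replicates (default 10000).
#' @param seed integer seed (results are deterministic given it).
#' @param refit one of `"frozen"` (weights fixed at 1/fitted of the
#'   original fit, the default and the documented estimator) or `"irls"`
#'   (full IRLS per replicate, for sensitivity analysis).
#' @param min_count optional mask: doses whose original fitted response is
#'   below this value carry zero weight in the refits.
#' @param keep_samples keep the vector of replicate D1 values.
#' @return list of class `"d1_boot"`: `d1_star`, `n_sim`, `n_failed`
#'   (non-convergent replicates, which are resampled up to a 2x cap),
#'   `seed`, and optionally `samples`.
#' @export
bootstrap_d1star <- function(fit, n_sim = 10000, seed = 1L,
                             refit = c("frozen", "irls"), min_count = 0,
                             keep_samples = FALSE) {
  refit <- match.arg(refit)
  stopifnot(inherits(fit, "hill_count_fit"))
  if (!fit$converged) stop("bootstrap requires a converged fit")
  set.seed(as.integer(seed))
  mu <- fit$fitted
  w <- 1 / pmax(mu, fit$eps)
  if (min_count > 0) w[mu < min_count] <- 0
  m <- length(fit$doses)
  t1_hat <- log(fit$d50); t2_hat <- log(fit$n)
  draw_fit <- function(R) {
    Y <- matrix(stats::rpois(R * m, rep(mu, each = R)), R, m)
    if (refit == "frozen") {
      gn <- gn_hill_batch(Y, fit$doses, w, fit$plateau,
                          rep(t1_hat, R), rep(t2_hat, R))
      list(d50 = exp(gn$t1), n = exp(gn$t2), ok = gn$converged)
    } else {
      res <- apply(Y, 1, function(y) {
        f <- try(fit_hill_count(y, fit$doses, fit$plateau, fit$eps),
                 silent = TRUE)
        if (inherits(f, "try-error") || !f$converged) c(NA, NA)
        else c(f$d50, f$n)
      })
      list(d50 = res[1, ], n = res[2, ], ok = is.finite(res[1, ]))
    }
  }
  g <- draw_fit(n_sim)
  d1s <- g$d50 * (fit$plateau - 1)^(-1 / g$n)
  ok <- g$ok & is.finite(d1s) & d1s > 0
  n_failed <- sum(!ok)
  budget <- n_sim                    # resample cap: 2x n_sim total draws
  while (sum(ok) < n_sim && budget > 0) {
    need <- min(n_sim - sum(ok), budget)
    g2 <- draw_fit(need)
    d1_new <- g2$d50 * (fit$plateau - 1)^(-1 / g2$n)
    ok2 <- g2$ok & is.finite(d1_new) & d1_new > 0
    d1s <- c(d1s[ok], d1_new[ok2])
    ok <- rep(TRUE, length(d1s))
    n_failed <- n_failed + sum(!ok2)
    budget <- budget - need
  }
  d1s <- d1s[seq_len(min(length(d1s), n_sim))]
  if (n_failed > 0.05 * n_sim)
    stop(sprintf("bootstrap unstable: %d of %d replicates failed to converge",
                 n_failed, n_sim))
  sorted <- sort(d1s)
  d1_star <- sorted[max(1L, ceiling(0.05 * length(sorted)))]
  out <- list(d1_star = d1_star, n_sim = length(sorted),
              n_failed = n_failed, seed = seed, refit = refit)
  if (keep_samples) out$samples <- sorted
  class(out) <- "d1_boot"
  out
}

#' DEG-count point of departure (D1/D1*) across K thresholds
#'
#' End-to-end convenience wrapper: thresholds the DE table at each K,
#' fits the Poisson-weighted Hill count curve, inverts it to D1, and
#' bootstraps the one-tailed 95% lower bound D1*.
#'
#' @param deg_table DE table (see [count_degs_by_threshold()]), or a named
#'   list of count data.frames as that function returns.
#' @param k_values fold-change thresholds.
#' @param plateau fixed plateau (default 1000).
#' @param n_sim bootstrap replicates per K.
#' @param seed integer seed.
#' @param ... further arguments for [bootstrap_d1star()].
#' @return data.frame of class `"d1_result"` with one row per K: `K`,
#'   `d50`, `n`, `d1`, `d1_star`, `n_sim`, `converged`.
#' @export
d1_estimate <- function(deg_table, k_values = c(2, 3, 5, 10), plateau = 1000,
                        n_sim = 10000, seed = 1L, ...) {
  curves <- if (is.list(deg_table) && !is.data.frame(deg_table)) deg_table
            else count_degs_by_threshold(deg_table, k_values)
  rows <- lapply(names(curves), function(k) {
    cc <- curves[[k]]
    fit <- fit_hill_count(cc$count, cc$dose, plateau = plateau)
    bt <- bootstrap_d1star(fit, n_sim = n_sim, seed = seed, ...)
    data.frame(K = as.numeric(k), d50 = fit$d50, n = fit$n,
               d1 = compute_d1(fit), d1_star = bt$d1_star,
               n_sim = bt$n_sim, converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("d1_result", "data.frame")
  out
}
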