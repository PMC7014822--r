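#' Benchmark-dose modeling of continuous apical endpoints
#'
#' `fit_bmd()` fits a PROAST/EFSA-style dose-response model family to a
#' continuous endpoint under a lognormal error model, optionally with a
#' covariate (e.g. the combined sex-by-time "study" label) on the background
#' level, the potency parameter and/or the residual variance.  Input may be
#' individual-animal records or per-group summaries (n, mean, dispersion);
#' both are reduced to the same log-scale sufficient statistics, so a fit
#' from summaries reproduces the fit from the individuals that generated
#' them.
#'
#' Model families (relative response \eqn{f(x)}, response \eqn{y = a_s f(x)}):
#' \describe{
#'   \item{exponential}{nested sub-models E2 \eqn{e^{\pm bx}}, E3
#'     \eqn{e^{\pm bx^d}}, E4 \eqn{(1\pm\gamma) \mp \gamma e^{-bx}}, E5 with
#'     free shape \eqn{d}; \eqn{\gamma = |c-1|} is the fold-range.}
#'   \item{hill}{H4 \eqn{1 \pm \gamma x/(b+x)} and H5
#'     \eqn{1 \pm \gamma x^d/(b^d+x^d)}.}
#' }
#' The sub-model with lowest AIC within the requested family is retained
#' (ties broken toward fewer parameters).  The likelihood is normal on log
#' responses with the variance profiled analytically; summary input is
#' converted to log-scale sufficient statistics via the exact lognormal
#' moment relations.
#'
#' @param data data.frame. Individual layout: columns `series`, `dose`,
#'   `value`. Summary layout: `series`, `dose`, `n`, `mean`, `sd` (or `se`
#'   plus `dispersion_kind`). A single-series endpoint may omit `series`.
#' @param family `"exponential"` or `"hill"`.
#' @param bmr benchmark response as a relative change from background
#'   (default 0.10).
#' @param covariate_on character subset of `c("a", "b", "var")`: which
#'   parameters vary with the `series` covariate. Default background and
#'   residual variance.
#' @param direction `"auto"` (sign of the dose trend), `"increasing"` or
#'   `"decreasing"`.
#' @param d_max upper bound for the shape parameter d (default 4; the lower
#'   bound is 1, the EFSA shape constraint).
#' @param submodels optional character vector restricting the candidate
#'   sub-model set (e.g. `c("E4","E5")`).
#' @return An object of class `"bmdfit"` with components `coefficients`
#'   (natural-scale parameter list), `logLik`, `AIC`, `bmd` (maximum
#'   likelihood BMD, per covariate level if `"b"` is covariate-dependent),
#'   `submodel`, `family`, `direction`, and the reduced data.
#' @seealso [bmd()] for profile-likelihood BMDL/BMDU, [select_pod()] for the
#'   lowest-of-families POD rule.
#' @examples
#' d <- data.frame(dose = c(0, 300, 500, 750, 1000, 1500),
#'                 n = 6,
#'                 mean = 3 * exp(log(1.1) * c(0, 300, 500, 750, 1000, 1500) / 500),
#'                 sd = 0.5)
#' f <- fit_bmd(d, family = "exponential")
#' f$bmd  # close to 500 (10% change attained at dose 500 by construction)
#' @export
fit_bmd <- function(data, family = c("exponential", "hill"), bmr = 0.10,
                    covariate_on = c("a", "var"),
                    direction = c("auto", "increasing", "decreasing"),
                    d_max = 4, submodels = NULL) {
  family <- match.arg(family)
  direction <- match.arg(direction)
  stopifnot(bmr > 0, bmr < 1)
  if (length(covariate_on) && !all(covariate_on %in% c("a", "b", "var")))
    stop("covariate_on must be a subset of c('a','b','var')")
  grp <- reduce_dose_response(data)
  if (length(unique(grp$dose)) < 3L)
    stop("need at least 3 distinct dose levels")
  if (!any(grp$dose == 0))
    stop("a dose-0 (control) group is required in every series")

  if (direction == "auto") {
    ctr <- stats::ave(grp$lmu, grp$series)
    direction <- if (sum((grp$lmu - ctr) * grp$dose) >= 0) "increasing" else "decreasing"
  }
  sgn <- if (direction == "increasing") 1 else -1

  cands <- bmd_submodels(family)
  if (!is.null(submodels)) {
    bad <- setdiff(submodels, cands)
    if (length(bad)) stop("unknown submodel(s): ", paste(bad, collapse = ", "))
    cands <- intersect(cands, submodels)
  }

  fits <- lapply(cands, function(sm)
    fit_bmd_submodel(grp, sm, sgn, bmr, covariate_on, d_max))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no sub-model converged for family ", family)
  fits <- fits[ok]
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ks <- vapply(fits, `[[`, numeric(1), "k")
  best <- order(round(aics, 8), ks)[1L]
  fit <- fits[[best]]
  fit$family <- family
  fit$submodel_aic <- stats::setNames(aics, vapply(fits, `[[`, character(1), "submodel"))
  fit$call <- match.call()
  class(fit) <- "bmdfit"
  fit
}

bmd_submodels <- function(family) {
  switch(family,
    exponential = c("E2", "E3", "E4", "E5"),
    hill = c("H4", "H5"))
}

# Reduce either layout to log-scale sufficient statistics per (series, dose):
# n, lmu (mean of log values), ss (within-group sum of squares of logs).
reduce_dose_response <- function(data) {
  data <- as.data.frame(data)
  if (!"series" %in% names(data)) data$series <- "all"
  if (all(c("dose", "value") %in% names(data)) && !"mean" %in% names(data)) {
    if (any(!is.finite(data$value) | data$value <= 0))
      stop("individual responses must be positive (lognormal support)")
    key <- interaction(data$series, data$dose, drop = TRUE)
    lv <- log(data$value)
    n <- as.vector(tapply(lv, key, length))
    lmu <- as.vector(tapply(lv, key, mean))
    ss <- as.vector(tapply(lv, key, function(z) sum((z - mean(z))^2)))
    first <- !duplicated(key)
    grp <- data.frame(series = as.character(data$series[first]),
                      dose = data$dose[first], n = n[match(key[first], levels(key))],
                      lmu = lmu[match(key[first], levels(key))],
                      ss = ss[match(key[first], levels(key))],
                      stringsAsFactors = FALSE)
  } else if (all(c("dose", "n", "mean") %in% names(data))) {
    disp_col <- intersect(c("sd", "se", "dispersion"), names(data))[1]
    if (is.na(disp_col)) stop("summary data need an 'sd', 'se' or 'dispersion' column")
    kind <- if ("dispersion_kind" %in% names(data)) as.character(data$dispersion_kind)
            else rep(if (disp_col == "se") "se" else "sd", nrow(data))
    if (any(!is.finite(data$mean) | data$mean <= 0))
      stop("group means must be positive (lognormal support)")
    if (any(data$n < 2)) stop("each group needs n >= 2")
    sdv <- data[[disp_col]]
    sdv <- ifelse(kind == "se", sdv * sqrt(data$n), sdv)
    if (any(!is.finite(sdv) | sdv < 0)) stop("invalid dispersion values")
    lsd2 <- log(1 + (sdv / data$mean)^2)
    grp <- data.frame(series = as.character(data$series), dose = data$dose,
                      n = data$n, lmu = log(data$mean) - lsd2 / 2,
                      ss = (data$n - 1) * lsd2, stringsAsFactors = FALSE)
  } else {
    stop("data must have columns (series, dose, value) or (series, dose, n, mean, sd/se)")
  }
  if (any(grp$dose < 0)) stop("doses must be non-negative")
  for (s in unique(grp$series))
    if (!any(grp$dose[grp$series == s] == 0))
      stop("series '", s, "' lacks a dose-0 control group")
  grp[order(grp$series, grp$dose), , drop = FALSE]
}

# --- relative mean curves -------------------------------------------------
# f(x) with f(0) = 1; sgn = +1 increasing, -1 decreasing; gamma = |c - 1|.
rel_curve <- function(submodel, x, b, gamma, d, sgn) {
  switch(submodel,
    E2 = exp(sgn * b * x),
    E3 = exp(sgn * b * x^d),
    E4 = 1 + sgn * gamma * (1 - exp(-b * x)),
    E5 = 1 + sgn * gamma * (1 - exp(-b * x^d)),
    H4 = 1 + sgn * gamma * x / (b + x),
    H5 = 1 + sgn * gamma * x^d / (b^d + x^d),
    stop("unknown submodel ", submodel))
}

submodel_pars <- function(submodel) {
  switch(submodel,
    E2 = c("b"), E3 = c("b", "d"),
    E4 = c("b", "gamma"), E5 = c("b", "gamma", "d"),
    H4 = c("b", "gamma"), H5 = c("b", "gamma", "d"))
}

# Closed-form BMD from natural parameters; NA if the curve cannot reach bmr.
bmd_from_pars <- function(submodel, b, gamma, d, sgn, bmr) {
  q <- if (sgn > 0) log(1 + bmr) else -log(1 - bmr)
  switch(submodel,
    E2 = q / b,
    E3 = (q / b)^(1 / d),
    E4 = if (gamma > bmr) -log(1 - bmr / gamma) / b else NA_real_,
    E5 = if (gamma > bmr) (-log(1 - bmr / gamma) / b)^(1 / d) else NA_real_,
    H4 = if (gamma > bmr) b * bmr / (gamma - bmr) else NA_real_,
    H5 = if (gamma > bmr) b * (bmr / (gamma - bmr))^(1 / d) else NA_real_)
}

# b implied by a fixed BMD (the profile-likelihood reparameterisation).
b_from_bmd <- function(submodel, bmd, gamma, d, sgn, bmr) {
  q <- if (sgn > 0) log(1 + bmr) else -log(1 - bmr)
  switch(submodel,
    E2 = q / bmd,
    E3 = q / bmd^d,
    E4 = -log(1 - bmr / gamma) / bmd,
    E5 = -log(1 - bmr / gamma) / bmd^d,
    H4 = bmd * (gamma - bmr) / bmr,
    H5 = bmd * ((gamma - bmr) / bmr)^(1 / d))
}

# Profiled (over sigma) negative log-likelihood given log-scale means.
# Returns -logLik with sigma^2 at its conditional MLE within each variance
# stratum.  grp carries n, lmu, ss; vstrat indexes variance strata.
nll_profiled <- function(lpred, grp, vstrat) {
  if (any(!is.finite(lpred))) return(1e10)
  dev <- grp$ss + grp$n * (grp$lmu - lpred)^2
  Sv <- as.vector(rowsum(dev, vstrat))
  Nv <- as.vector(rowsum(grp$n, vstrat))
  if (any(Sv <= 0)) Sv <- pmax(Sv, 1e-12)
  sum(Nv / 2 * (log(2 * pi * Sv / Nv) + 1))
}

# Build the transformed-parameter objective for one sub-model.
# theta layout: la[1..Sa] | lb[1..Sb] | lgam | ld   (pieces present as needed)
make_bmd_objective <- function(grp, submodel, sgn, covariate_on, d_max,
                               profile_bmd = NULL, bmr = NULL) {
  pars <- submodel_pars(submodel)
  series <- factor(grp$series)
  S <- nlevels(series)
  a_idx <- if ("a" %in% covariate_on) as.integer(series) else rep(1L, nrow(grp))
  Sa <- max(a_idx)
  b_by_series <- "b" %in% covariate_on
  Sb <- if (b_by_series) S else 1L
  b_idx <- if (b_by_series) as.integer(series) else rep(1L, nrow(grp))
  vstrat <- if ("var" %in% covariate_on) as.integer(series) else rep(1L, nrow(grp))
  has_g <- "gamma" %in% pars
  has_d <- "d" %in% pars
  profiling <- !is.null(profile_bmd)
  # when profiling, the b block is replaced by the fixed BMD (per stratum the
  # profiled one); other series keep free b parameters
  nb <- if (profiling) (if (b_by_series) Sb - 1L else 0L) else Sb

  unpack <- function(theta) {
    i <- 0L
    la <- theta[seq_len(Sa)]; i <- Sa
    lb <- if (nb > 0) theta[i + seq_len(nb)] else numeric(0); i <- i + nb
    gamma <- if (has_g) {
      g <- exp(theta[i + 1L]); i <- i + 1L
      if (profiling) g + bmr else g
    } else NA_real_
    d <- if (has_d) { dd <- exp(theta[i + 1L]); i <- i + 1L; dd } else 1
    list(la = la, lb = lb, gamma = gamma, d = d)
  }
  fn <- function(theta) {
    p <- unpack(theta)
    if (profiling) {
      b_prof <- b_from_bmd(submodel, profile_bmd$bmd, p$gamma, p$d, sgn, bmr)
      if (!is.finite(b_prof) || b_prof <= 0) return(1e10)
      bvec <- if (b_by_series) {
        bv <- numeric(Sb)
        bv[profile_bmd$stratum] <- b_prof
        bv[-profile_bmd$stratum] <- exp(p$lb)
        bv
      } else b_prof
    } else bvec <- exp(p$lb)
    f <- rel_curve(submodel, grp$dose, bvec[b_idx], p$gamma, p$d, sgn)
    if (any(!is.finite(f) | f <= 0)) return(1e10)
    nll_profiled(p$la[a_idx] + log(f), grp, vstrat)
  }
  list(fn = fn, unpack = unpack, Sa = Sa, Sb = Sb, nb = nb, has_g = has_g,
       has_d = has_d, series_levels = levels(series), a_idx = a_idx,
       b_by_series = b_by_series,
       n_var = length(unique(vstrat)), vstrat = vstrat)
}

theta_bounds <- function(ob, d_max, grp, profiling = FALSE) {
  lo <- c(rep(-Inf, ob$Sa), rep(log(1e-3 / max(grp$dose)), ob$nb))
  hi <- c(rep(Inf, ob$Sa), rep(log(1e4 / max(grp$dose) * max(grp$dose)^0), ob$nb))
  # b bound scales differ between exponential (rate) and hill (dose); keep wide
  lo[seq_len(ob$nb) + ob$Sa] <- -40
  hi[seq_len(ob$nb) + ob$Sa] <- 40
  if (ob$has_g) { lo <- c(lo, log(1e-4)); hi <- c(hi, log(1e3)) }
  if (ob$has_d) { lo <- c(lo, 0); hi <- c(hi, log(d_max)) }
  list(lower = lo, upper = hi)
}

fit_bmd_submodel <- function(grp, submodel, sgn, bmr, covariate_on, d_max) {
  ob <- make_bmd_objective(grp, submodel, sgn, covariate_on, d_max)
  xmax <- max(grp$dose)
  ctl <- grp$dose == 0
  la0 <- vapply(seq_len(ob$Sa), function(i) {
    sel <- ctl & ob$a_idx == i
    if (!any(sel)) sel <- ob$a_idx == i
    mean(grp$lmu[sel])
  }, numeric(1))
  top <- tapply(grp$lmu, ob$a_idx, function(z) z[length(z)])
  g0 <- max(abs(exp(mean(top) - mean(la0)) - 1), 1.5 * bmr, 0.05)
  b_grid <- if (substr(submodel, 1, 1) == "E") {
    c(0.1, 0.3, 1, 3, 10) / xmax
  } else {
    c(0.05, 0.2, 0.5, 1, 3) * xmax
  }
  bnds <- theta_bounds(ob, d_max, grp)
  best <- NULL
  for (b0 in b_grid) {
    th0 <- c(la0, rep(log(b0), ob$Sb))
    if (ob$has_g) th0 <- c(th0, log(g0))
    if (ob$has_d) th0 <- c(th0, log(1.0001))
    opt <- try(stats::nlminb(th0, ob$fn, lower = bnds$lower, upper = bnds$upper,
                             control = list(eval.max = 2000, iter.max = 1000,
                                            rel.tol = 1e-12)), silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) return(list(converged = FALSE, submodel = submodel))
  p <- ob$unpack(best$par)
  bvec <- exp(p$lb)
  k <- length(best$par) + ob$n_var            # + variance parameters
  ll <- -best$objective
  bmds <- vapply(bvec, function(bb)
    bmd_from_pars(submodel, bb, p$gamma, p$d, sgn, bmr), numeric(1))
  names(bmds) <- if (ob$b_by_series) ob$series_levels else NULL
  sigma <- {
    lpred <- {
      f <- rel_curve(submodel, grp$dose, bvec[if (ob$b_by_series)
        as.integer(factor(grp$series)) else rep(1L, nrow(grp))], p$gamma, p$d, sgn)
      p$la[ob$a_idx] + log(f)
    }
    dev <- grp$ss + grp$n * (grp$lmu - lpred)^2
    Sv <- as.vector(rowsum(dev, ob$vstrat)); Nv <- as.vector(rowsum(grp$n, ob$vstrat))
    sqrt(Sv / Nv)
  }
  list(converged = TRUE, submodel = submodel,
       coefficients = list(
         a = stats::setNames(exp(p$la),
               if (ob$Sa > 1) ob$series_levels else NULL),
         b = bvec, gamma = p$gamma,
         c = if (is.na(p$gamma)) NA_real_ else 1 + sgn * p$gamma,
         d = p$d, sigma = sigma),
       logLik = ll, aic = 2 * k - 2 * ll, k = k,
       bmd = if (length(bmds) == 1) unname(bmds) else bmds,
       bmr = bmr, direction = if (sgn > 0) "increasing" else "decreasing",
       sgn = sgn, covariate_on = covariate_on, d_max = d_max,
       grp = grp, objective = best$objective)
}

#' Profile-likelihood benchmark-dose confidence bounds
#'
#' Computes the BMD with its lower and upper confidence bounds (BMDL, BMDU)
#' for a fitted [fit_bmd()] model by profile likelihood: the model is
#' reparameterised so the BMD is an explicit parameter, and the bounds are
#' the extreme BMD values whose profiled deviance stays within
#' \eqn{\chi^2_1(level)}.  With the default `level = 0.90` each bound is a
#' one-sided 95% limit, the convention used for BMDL/BMDU reporting.
#'
#' @param fit a `"bmdfit"` object.
#' @param level two-sided confidence level (default 0.90).
#' @return data.frame with columns `series` (only when potency is
#'   covariate-dependent), `family`, `submodel`, `bmr`, `bmd`, `bmdl`,
#'   `bmdu`, and logical flags `bmd_above_range` (BMD beyond the highest
#'   tested dose) and `bmdu_unbounded`.
#' @export
bmd <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "bmdfit"))
  crit <- stats::qchisq(level, 1)
  strata <- if ("b" %in% fit$covariate_on) seq_along(fit$coefficients$b) else 1L
  rows <- lapply(strata, function(st) {
    prof <- profile_bmd_bounds(fit, crit, stratum = st)
    data.frame(series = if (length(strata) > 1)
                 names(fit$bmd)[st] else NA_character_,
               family = fit$family, submodel = fit$submodel, bmr = fit$bmr,
               bmd = if (length(strata) > 1) fit$bmd[st] else fit$bmd,
               bmdl = prof$bmdl, bmdu = prof$bmdu,
               bmd_above_range = (if (length(strata) > 1) fit$bmd[st]
                                  else fit$bmd) > max(fit$grp$dose),
               bmdu_unbounded = prof$unbounded_up,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(strata) == 1) out$series <- NULL
  out
}

# Deviance of the profiled likelihood at a fixed BMD value.
profile_dev <- function(fit, bmd_value, stratum = 1L, start = NULL) {
  grp <- fit$grp
  ob <- make_bmd_objective(grp, fit$submodel, fit$sgn, fit$covariate_on,
                           fit$d_max, profile_bmd = list(bmd = bmd_value,
                                                         stratum = stratum),
                           bmr = fit$bmr)
  bnds <- theta_bounds(ob, fit$d_max, grp, profiling = TRUE)
  co <- fit$coefficients
  th0 <- if (!is.null(start)) start else {
    th <- log(co$a)
    if (ob$nb > 0) th <- c(th, log(co$b[-stratum]))
    if (ob$has_g) th <- c(th, log(max(co$gamma - fit$bmr, 1e-6)))
    if (ob$has_d) th <- c(th, log(max(co$d, 1.0001)))
    th
  }
  opt <- try(stats::nlminb(th0, ob$fn, lower = bnds$lower, upper = bnds$upper,
                           control = list(eval.max = 2000, iter.max = 1000,
                                          rel.tol = 1e-10)), silent = TRUE)
  if (inherits(opt, "try-error")) return(list(dev = Inf, par = NULL))
  list(dev = 2 * (opt$objective - (-fit$logLik)), par = opt$par)
}

profile_bmd_bounds <- function(fit, crit, stratum = 1L) {
  bmd_hat <- if (length(fit$bmd) > 1) fit$bmd[stratum] else fit$bmd
  if (!is.finite(bmd_hat) || bmd_hat <= 0)
    return(list(bmdl = NA_real_, bmdu = NA_real_, unbounded_up = TRUE))
  search_bound <- function(dir) {
    fac <- if (dir < 0) 0.75 else 1 / 0.75
    lim <- if (dir < 0) bmd_hat * 1e-5 else 50 * max(fit$grp$dose)
    b_prev <- bmd_hat; d_prev <- 0; st <- NULL
    b_cur <- bmd_hat * fac
    repeat {
      pr <- profile_dev(fit, b_cur, stratum, start = st)
      if (!is.finite(pr$dev)) pr$dev <- crit * 4
      if (pr$dev >= crit) break
      st <- pr$par; b_prev <- b_cur; d_prev <- pr$dev
      b_cur <- b_cur * fac
      if ((dir < 0 && b_cur < lim) || (dir > 0 && b_cur > lim))
        return(list(value = if (dir > 0) Inf else 0, unbounded = TRUE))
    }
    root <- stats::uniroot(function(b) {
      pd <- profile_dev(fit, b, stratum, start = st)$dev
      if (!is.finite(pd)) pd <- crit * 4
      pd - crit
    }, lower = min(b_prev, b_cur), upper = max(b_prev, b_cur),
       tol = bmd_hat * 2e-4)
    list(value = root$root, unbounded = FALSE)
  }
  lo <- search_bound(-1)
  hi <- search_bound(+1)
  list(bmdl = lo$value, bmdu = hi$value, unbounded_up = hi$unbounded)
}

#' Combine family-level BMD results into a point of departure
#'
#' Applies the lowest-of-families reporting rule: the POD interval is the
#' minimum BMDL and maximum BMDU across the supplied per-family results,
#' and the interval width is their ratio.
#'
#' @param results a list of data.frames as returned by [bmd()] (one per
#'   model family), or a single such data.frame.
#' @return list of class `"pod_summary"` with `bmdl`, `bmdu`, `ratio` and
#'   the per-family table.
#' @export
select_pod <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  if (!length(results)) stop("no BMD results supplied")
  tab <- do.call(rbind, results)
  if (!nrow(tab)) stop("no converged BMD results supplied")
  out <- list(bmdl = min(tab$bmdl, na.rm = TRUE),
              bmdu = max(tab$bmdu, na.rm = TRUE),
              families = tab)
  out$ratio <- out$bmdu / out$bmdl
  class(out) <- "pod_summary"
  out
}

#' @export
print.pod_summary <- function(x, ...) {
  cat("Point of departure (lowest-of-families rule)\n")
  cat(sprintf("  BMDL %.4g   BMDU %.4g   BMDU/BMDL %.3g\n",
              x$bmdl, x$bmdu, x$ratio))
  invisible(x)
}

#' @export
print.bmdfit <- function(x, ...) {
  cat(sprintf("Benchmark-dose fit: %s family, sub-model %s (%s)\n",
              x$family, x$submodel, x$direction))
  cat(sprintf("  log-likelihood %.4f   AIC %.4f   BMR %.3g\n",
              x$logLik, x$aic, x$bmr))
  cat("  BMD:", format(x$bmd, digits = 5), "\n")
  invisible(x)
}

#' @export
summary.bmdfit <- function(object, level = 0.90, ...) {
  res <- bmd(object, level = level)
  out <- list(fit = object, bmd_table = res, level = level)
  class(out) <- "summary.bmdfit"
  out
}

#' @export
print.summary.bmdfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  Profile %g%% interval:\n", 100 * x$level))
  print(x$bmd_table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.bmdfit <- function(object, ...) {
  co <- object$coefficients
  unlist(co[!vapply(co, function(z) all(is.na(z)), logical(1))])
}

#' @export
logLik.bmdfit <- function(object, ...) {
  structure(object$logLik, df = object$k, class = "logLik")
}

#' @export
predict.bmdfit <- function(object, newdata = NULL, series = NULL, ...) {
  co <- object$coefficients
  if (is.null(newdata)) newdata <- object$grp$dose
  dose <- if (is.data.frame(newdata)) newdata$dose else newdata
  a <- if (length(co$a) > 1) {
    if (is.data.frame(newdata) && "series" %in% names(newdata))
      co$a[as.character(newdata$series)]
    else if (!is.null(series)) co$a[series] else co$a[1]
  } else co$a
  b <- if (length(co$b) > 1) {
    if (!is.null(series)) co$b[series] else co$b[1]
  } else co$b
  unname(a * rel_curve(object$submodel, dose, b, co$gamma, co$d, object$sgn))
}

#' @export
plot.bmdfit <- function(x, ...) {
  grp <- x$grp
  xs <- seq(0, max(grp$dose), length.out = 200)
  series <- unique(grp$series)
  cols <- seq_along(series)
  graphics::plot(grp$dose, exp(grp$lmu), pch = 19, col = cols[match(grp$series, series)],
                 xlab = "dose (mg/kg/day)", ylab = "geometric mean response", ...)
  for (i in seq_along(series)) {
    ys <- predict(x, xs, series = if (length(x$coefficients$a) > 1) series[i] else NULL)
    graphics::lines(xs, ys, col = cols[i])
  }
  graphics::abline(v = x$bmd, lty = 2)
  graphics::legend("topleft", legend = series, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Remove one known value from a group summary
#'
#' Adjusts an (n, mean, sd) summary to the summary of the same group with a
#' single identified observation removed, using the exact algebra of sample
#' moments. Used to apply an outlier exclusion (e.g. a Grubbs-flagged
#' animal) when only group summaries and the outlying value are available.
#'
#' @param n,mean,sd group size, sample mean and sample SD.
#' @param value the observation to remove.
#' @return list with the adjusted `n`, `mean`, `sd`.
#' @examples
#' outlier_adjust_summary(6, 10.31, 13.35, 37.5)  # n=5, mean 4.872, sd ~0.995
#' @export
outlier_adjust_summary <- function(n, mean, sd, value) {
  stopifnot(n >= 3, sd >= 0)
  sumsq <- (n - 1) * sd^2 + n * mean^2
  n2 <- n - 1
  m2 <- (n * mean - value) / n2
  ss2 <- sumsq - value^2 - n2 * m2^2
  if (ss2 < 0) {
    if (ss2 < -1e-8 * sumsq) stop("removed value inconsistent with summary")
    ss2 <- 0
  }
  list(n = n2, mean = m2, sd = sqrt(ss2 / (n2 - 1)))
}
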