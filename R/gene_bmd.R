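#' Prefilter genes on raw counts
#'
#' Returns exactly the genes whose raw sequence count is strictly positive
#' in every replicate at every dose.  Requires the raw count layer; there
#' is deliberately no fallback to log-scale values.
#'
#' @param study an `"expression_study"` or a list with a `counts` matrix
#'   (genes x samples).
#' @return character vector of gene ids passing the filter.
#' @export
prefilter_genes <- function(study) {
  counts <- if (is.matrix(study)) study else study$counts
  if (is.null(counts))
    stop("raw counts are required for the prefilter (no log-value fallback)")
  rownames(counts)[apply(counts > 0, 1, all)]
}

gene_model_order <- c("linear", "poly2", "poly3", "power", "hill", "exp2")

gene_model_k <- c(linear = 2, poly2 = 3, poly3 = 4, power = 3, hill = 4,
                  exp2 = 2)

# RSS -> normal-likelihood bookkeeping (sigma counted as a free parameter)
rss_to_fit <- function(model, rss, N, pars, extra = list()) {
  rss <- max(rss, 1e-300)
  ll <- -N / 2 * (log(2 * pi * rss / N) + 1)
  c(list(model = model, rss = rss, N = N, k = unname(gene_model_k[model]),
         logLik = ll, aic = 2 * (gene_model_k[model] + 1) - 2 * ll,
         pars = pars, converged = TRUE), extra)
}

#' Fit the candidate dose-response models to one gene
#'
#' Least-squares fits (normal errors, constant variance) of the candidate
#' set: linear, quadratic and cubic polynomials, power
#' (\eqn{\beta_0+\beta_1 x^\delta}, \eqn{\delta \ge 1}), Hill
#' (\eqn{\beta_0 + v x^h/(k^h+x^h)}) and exponential
#' (\eqn{\alpha e^{\beta x}}), each with log-likelihood, AIC, and a
#' lack-of-fit goodness-of-fit p-value against the saturated group-means
#' model.  The cubic is dropped when fewer than 5 distinct doses are
#' available.
#'
#' @param y numeric response (log2 expression), one value per sample.
#' @param doses dose per sample (>= 4 distinct values including control).
#' @return named list of candidate fits.
#' @export
fit_gene_models <- function(y, doses) {
  if (any(!is.finite(y))) stop("non-finite response values")
  ud <- sort(unique(doses))
  if (length(ud) < 4) stop("need at least 4 distinct doses")
  N <- length(y)
  fg <- factor(doses)
  gm <- tapply(y, fg, mean)
  rss_sat <- sum((y - gm[fg])^2)
  g <- length(ud)
  if (stats::var(y) == 0) {
    out <- list(rss_to_fit("linear", 0, N, c(b0 = y[1], b1 = 0),
                           list(flat = TRUE, gof_p = 1)))
    names(out) <- "linear"
    return(out)
  }
  gof <- function(rss, k) {
    if (g <= k || rss_sat <= 0) return(NA_real_)
    Fstat <- ((rss - rss_sat) / (g - k)) / (rss_sat / (N - g))
    stats::pf(max(Fstat, 0), g - k, N - g, lower.tail = FALSE)
  }
  fits <- list()
  # polynomial chain
  for (deg in 1:3) {
    if (deg == 3 && g < 5) next
    X <- stats::poly(doses, degree = deg, raw = TRUE)
    fit <- stats::lsfit(X, y)
    rss <- sum(fit$residuals^2)
    model <- c("linear", "poly2", "poly3")[deg]
    pars <- stats::setNames(fit$coefficients, c("b0", paste0("b", 1:deg)))
    fits[[model]] <- rss_to_fit(model, rss, N, pars,
                                list(gof_p = gof(rss, deg + 1)))
  }
  # power: concentrate the linear part, optimise delta in [1, 8]
  rss_pow <- function(delta) sum(stats::lsfit(doses^delta, y)$residuals^2)
  op <- stats::optimize(rss_pow, c(1, 8), tol = 1e-6)
  grid_d <- c(1, 1.5, 2, 3, 5, 8)
  gv <- vapply(grid_d, rss_pow, numeric(1))
  if (min(gv) < op$objective) op <- list(minimum = grid_d[which.min(gv)],
                                         objective = min(gv))
  cf <- stats::lsfit(doses^op$minimum, y)$coefficients
  fits$power <- rss_to_fit("power", op$objective, N,
                           c(b0 = unname(cf[1]), b1 = unname(cf[2]),
                             delta = op$minimum),
                           list(gof_p = gof(op$objective, 3)))
  # hill: concentrate (b0, v); coarse grid over (k, h) then polish
  pos <- ud[ud > 0]
  rss_hill <- function(th) {
    k <- exp(th[1]); h <- exp(th[2])
    z <- doses^h / (k^h + doses^h)
    if (any(!is.finite(z))) return(1e10)
    sum(stats::lsfit(z, y)$residuals^2)
  }
  kg <- log(exp(seq(log(min(pos) / 5), log(max(pos) * 2), length.out = 7)))
  hg <- log(c(1, 2, 4, 8))
  grid <- as.matrix(expand.grid(kg, hg))
  gv <- apply(grid, 1, rss_hill)
  st <- grid[which.min(gv), ]
  oh <- stats::nlminb(st, rss_hill,
                      lower = c(log(min(pos) / 50), 0),
                      upper = c(log(max(pos) * 20), log(15)))
  kh <- exp(oh$par[1]); hh <- exp(oh$par[2])
  zz <- doses^hh / (kh^hh + doses^hh)
  cf <- stats::lsfit(zz, y)$coefficients
  fits$hill <- rss_to_fit("hill", oh$objective, N,
                          c(b0 = unname(cf[1]), v = unname(cf[2]),
                            k = unname(kh), h = unname(hh)),
                          list(gof_p = gof(oh$objective, 4)))
  # exp2: alpha * exp(beta x); concentrate alpha
  rss_exp2 <- function(beta) {
    e <- exp(beta * doses)
    a <- sum(y * e) / sum(e * e)
    sum((y - a * e)^2)
  }
  bmaxx <- 8 / max(ud)
  oe <- stats::optimize(rss_exp2, c(-bmaxx, bmaxx), tol = bmaxx * 1e-7)
  for (b0g in c(-bmaxx / 4, 0, bmaxx / 4)) {
    # optimize() can miss a narrow basin; cheap restarts guard against it
    o2 <- stats::optimize(rss_exp2, c(b0g - bmaxx / 4, b0g + bmaxx / 4),
                          tol = bmaxx * 1e-7)
    if (o2$objective < oe$objective) oe <- o2
  }
  e <- exp(oe$minimum * doses)
  a <- sum(y * e) / sum(e * e)
  fits$exp2 <- rss_to_fit("exp2", oe$objective, N,
                          c(alpha = a, beta = oe$minimum),
                          list(gof_p = gof(oe$objective, 2)))
  fits
}

#' Hierarchical best-model selection
#'
#' Within the nested linear/quadratic/cubic chain, retains the simplest
#' model that a nested F-test (alpha = 0.05) cannot reject in favour of the
#' richer one; the chain winner then competes with the power, Hill and
#' exponential candidates on lowest AIC.  A Hill fit may win only if its
#' half-maximal dose k is at least one third of the lowest positive dose;
#' otherwise it is flagged (`hill_k_demoted`) and removed from the
#' competition.  Exact AIC ties go to the model with fewer parameters,
#' then to the canonical model-name order.
#'
#' @param candidates list from [fit_gene_models()].
#' @param lowest_pos_dose lowest non-control dose (for the Hill k rule).
#' @param alpha nested-test level (default 0.05).
#' @return the winning fit, with `hill_k_demoted` attached.
#' @export
select_best_model <- function(candidates, lowest_pos_dose, alpha = 0.05) {
  ok <- vapply(candidates, function(f) isTRUE(f$converged), logical(1))
  candidates <- candidates[ok]
  if (!length(candidates)) stop("no converged candidate model")
  chain <- intersect(c("linear", "poly2", "poly3"), names(candidates))
  pick <- chain[1]
  for (nxt in chain[-1]) {
    f0 <- candidates[[pick]]; f1 <- candidates[[nxt]]
    df1 <- f1$k - f0$k
    df2 <- f0$N - f1$k
    Fstat <- ((f0$rss - f1$rss) / df1) / (f1$rss / df2)
    p <- stats::pf(max(Fstat, 0), df1, df2, lower.tail = FALSE)
    if (is.finite(p) && p <= alpha) pick <- nxt else break
  }
  pool <- c(pick, intersect(c("power", "hill", "exp2"), names(candidates)))
  demoted <- FALSE
  if ("hill" %in% pool) {
    kh <- candidates$hill$pars["k"]
    if (is.finite(kh) && kh < lowest_pos_dose / 3) {
      pool <- setdiff(pool, "hill")
      demoted <- TRUE
    }
  }
  cand <- candidates[pool]
  aics <- vapply(cand, `[[`, numeric(1), "aic")
  ks <- vapply(cand, `[[`, numeric(1), "k")
  ord <- match(names(cand), gene_model_order)
  best <- cand[[order(round(aics, 10), ks, ord)[1]]]
  best$hill_k_demoted <- demoted
  best
}

gene_curve_change <- function(fit, x) {
  p <- fit$pars
  switch(fit$model,
    linear = p["b1"] * x,
    poly2 = p["b1"] * x + p["b2"] * x^2,
    poly3 = p["b1"] * x + p["b2"] * x^2 + p["b3"] * x^3,
    power = p["b1"] * x^p["delta"],
    hill = p["v"] * x^p["h"] / (p["k"]^p["h"] + x^p["h"]),
    exp2 = p["alpha"] * (exp(p["beta"] * x) - 1))
}

#' Benchmark dose of a fitted gene model
#'
#' Solves |y(x) - y(0)| = `bmr_sd` x sigma for the smallest positive dose,
#' where sigma is the model residual SD.  Closed forms are used where the
#' model admits them (linear, power, Hill, exponential); polynomial BMDs
#' take the smallest positive real root.
#'
#' @param fit a selected model fit (see [select_best_model()]).
#' @param sigma residual SD; defaults to the fit's own
#'   \eqn{\sqrt{RSS/(N-k)}}.
#' @param bmr_sd benchmark response in residual SDs (default 1.349,
#'   equivalent to a 10% change relative to control under the study's
#'   convention).
#' @return list with `bmd` (NA with `attained = FALSE` when the curve never
#'   reaches the benchmark), `delta` (the absolute change at the BMD), and
#'   `direction` (+1/-1).
#' @export
compute_gene_bmd <- function(fit, sigma = NULL, bmr_sd = 1.349) {
  if (is.null(sigma)) sigma <- sqrt(fit$rss / (fit$N - fit$k))
  delta <- bmr_sd * sigma
  p <- fit$pars
  bmd <- switch(fit$model,
    linear = if (p["b1"] == 0) NA_real_ else delta / abs(p["b1"]),
    power = if (p["b1"] == 0) NA_real_ else (delta / abs(p["b1"]))^(1 / p["delta"]),
    hill = if (abs(p["v"]) <= delta) NA_real_
           else p["k"] * (delta / (abs(p["v"]) - delta))^(1 / p["h"]),
    exp2 = {
      a <- abs(p["alpha"]); b <- p["beta"]
      if (b == 0 || a == 0) NA_real_
      else {
        up <- sign(p["alpha"]) * sign(b)      # sign of change as dose grows
        r <- if (up > 0) 1 + delta / a else 1 - delta / a
        if (r <= 0) NA_real_ else log(r) / b  # b sign matches log(r) sign
      }
    },
    poly2 = , poly3 = {
      cf <- if (fit$model == "poly2") c(p["b1"], p["b2"])
            else c(p["b1"], p["b2"], p["b3"])
      roots <- c(polyroot(c(-delta, cf)), polyroot(c(delta, cf)))
      re <- Re(roots)[abs(Im(roots)) < 1e-8 & Re(roots) > 1e-12]
      if (length(re)) min(re) else NA_real_
    })
  bmd <- unname(bmd)
  if (is.na(bmd) || bmd < 0)
    return(list(bmd = NA_real_, attained = FALSE, delta = delta,
                direction = NA_real_))
  dirn <- sign(gene_curve_change(fit, bmd))
  list(bmd = bmd, attained = TRUE, delta = delta, direction = unname(dirn))
}

# Profiled RSS with the BMD pinned at value b (change at b equals t*delta).
# Returns the minimised RSS over the remaining mean parameters.
gene_rss_at_bmd <- function(model, y, doses, b, delta, t, pars) {
  off_fit <- function(Xfree, offset) {
    z <- y - offset
    if (is.null(Xfree)) sum((z - mean(z))^2)
    else sum(stats::lsfit(Xfree, z)$residuals^2)
  }
  switch(model,
    linear = off_fit(NULL, (t * delta / b) * doses),
    poly2 = off_fit(cbind(doses^2 - b * doses), (t * delta / b) * doses),
    poly3 = off_fit(cbind(doses^2 - b * doses, doses^3 - b^2 * doses),
                    (t * delta / b) * doses),
    power = {
      f <- function(ldel) {
        dl <- exp(ldel)
        off_fit(NULL, (t * delta / b^dl) * doses^dl)
      }
      stats::optimize(f, c(0, log(8)), tol = 1e-7)$objective
    },
    hill = {
      f <- function(th) {
        k <- exp(th[1]); h <- exp(th[2])
        zb <- b^h / (k^h + b^h)
        if (!is.finite(zb) || zb <= 0) return(1e10)
        v <- t * delta / zb
        off_fit(NULL, v * doses^h / (k^h + doses^h))
      }
      st <- c(log(max(pars["k"], 1e-3)), log(max(pars["h"], 1)))
      o <- stats::nlminb(st, f, lower = c(log(b) - 12, 0),
                         upper = c(log(b) + 12, log(15)))
      o$objective
    },
    exp2 = {
      f <- function(beta) {
        r <- exp(beta * b)
        if (abs(r - 1) < 1e-12) return(1e10)
        a <- t * delta / (r - 1)
        sum((y - a * exp(beta * doses))^2)
      }
      # the constrained RSS has a narrow basin near the fitted beta; anchor
      # a geometric grid there, then polish the best bracket
      b_hat <- unname(pars["beta"])
      grid <- unique(c(b_hat * 2^seq(-6, 6, by = 0.5),
                       -b_hat * 2^seq(-6, 6, by = 0.5)))
      grid <- grid[is.finite(grid) & grid != 0]
      if (!length(grid)) grid <- c(-4, -1, 1, 4) / max(doses)
      fv <- vapply(grid, f, numeric(1))
      i <- which.min(fv)
      lo2 <- grid[i] / 2; hi2 <- grid[i] * 2
      o <- stats::optimize(f, sort(c(lo2, hi2)), tol = abs(grid[i]) * 1e-7)
      min(o$objective, fv[i])
    })
}

#' Profile-likelihood bounds for a gene-level BMD
#'
#' BMDL/BMDU at one-sided 95% each (two-sided 90% profile deviance
#' threshold).  The benchmark offset delta = `bmr_sd` x sigma-hat is held
#' at the best fit's value while the mean-function parameters are
#' re-profiled, with the residual variance concentrated analytically.
#'
#' @param fit selected model fit; `bmd_info` the result of
#'   [compute_gene_bmd()] for it.
#' @param y,doses the gene's data.
#' @param level two-sided profile level (default 0.90).
#' @return list with `bmdl`, `bmdu` (possibly `Inf`) and `unbounded_up`.
#' @export
gene_bmd_bounds <- function(fit, bmd_info, y, doses, level = 0.90) {
  if (!bmd_info$attained)
    return(list(bmdl = NA_real_, bmdu = NA_real_, unbounded_up = TRUE))
  crit <- stats::qchisq(level, 1)
  N <- fit$N
  rss_hat <- fit$rss
  b_hat <- bmd_info$bmd
  t <- bmd_info$direction
  dev <- function(b) {
    r <- gene_rss_at_bmd(fit$model, y, doses, b, bmd_info$delta, t, fit$pars)
    N * log(max(r, 1e-300) / rss_hat)
  }
  if (dev(b_hat) > crit / 2)      # profile irregular at the MLE itself
    return(list(bmdl = NA_real_, bmdu = NA_real_, unbounded_up = TRUE))
  search <- function(dir) {
    fac <- if (dir < 0) 0.7 else 1 / 0.7
    lim <- if (dir < 0) b_hat * 1e-6 else 100 * max(doses)
    b_prev <- b_hat; b_cur <- b_hat * fac
    repeat {
      d <- dev(b_cur)
      if (!is.finite(d)) d <- 4 * crit
      if (d >= crit) break
      b_prev <- b_cur; b_cur <- b_cur * fac
      if ((dir < 0 && b_cur < lim) || (dir > 0 && b_cur > lim))
        return(list(value = if (dir > 0) Inf else 0, unbounded = TRUE))
    }
    r <- stats::uniroot(function(b) {
      d <- dev(b); if (!is.finite(d)) d <- 4 * crit; d - crit
    }, lower = min(b_prev, b_cur), upper = max(b_prev, b_cur),
       tol = b_hat * 5e-4)
    list(value = r$root, unbounded = FALSE)
  }
  lo <- search(-1); hi <- search(+1)
  list(bmdl = lo$value, bmdu = hi$value, unbounded_up = hi$unbounded)
}

#' Per-gene transcriptomic benchmark-dose analysis
#'
#' Runs the full gene-level pipeline on an expression study: raw-count
#' prefilter, candidate model fits, hierarchical selection, BMD at
#' `bmr_sd` residual SDs with profile bounds, fold-change linkage from the
#' companion DE table, and the four-rule filter cascade.  Profile bounds
#' are computed for genes that pass the goodness-of-fit, dose-range and
#' fold-change rules (a gene already excluded by those rules fails
#' regardless of its interval width).
#'
#' @param study an `"expression_study"` (or list with `log2`, `counts`,
#'   `meta`).
#' @param deg_table companion DE table; computed by [make_deg_table()] when
#'   omitted. Supplies the observed max |fold change| per gene.
#' @param bmr_sd benchmark response in residual SDs (default 1.349).
#' @param fit_p_min,ratio_max,fc_min filter thresholds (defaults 0.1, 40,
#'   1.5; see [apply_bmd_filters()]).
#' @param genes optional subset of gene ids to model.
#' @return data.frame of class `"gene_bmd_records"`: one row per modeled
#'   gene with the best model, parameters of record (`fit_p`, `bmd`,
#'   `bmdl`, `bmdu`, `max_fc`), per-rule pass flags and overall `survives`.
#' @export
gene_bmd <- function(study, deg_table = NULL, bmr_sd = 1.349,
                     fit_p_min = 0.1, ratio_max = 40, fc_min = 1.5,
                     genes = NULL) {
  keep <- prefilter_genes(study)
  if (is.null(deg_table)) deg_table <- make_deg_table(study)
  if (!is.null(genes)) keep <- intersect(keep, genes)
  doses <- study$meta$dose
  highest <- max(doses)
  lowest_pos <- min(doses[doses > 0])
  maxfc <- tapply(abs(deg_table$fc), deg_table$gene, max)
  rows <- lapply(keep, function(g) {
    y <- study$log2[g, ]
    cand <- fit_gene_models(y, doses)
    best <- select_best_model(cand, lowest_pos)
    sig <- sqrt(best$rss / (best$N - best$k))
    bi <- compute_gene_bmd(best, sigma = sig, bmr_sd = bmr_sd)
    mf <- unname(maxfc[g])
    need_ci <- !is.na(best$gof_p) && best$gof_p > fit_p_min &&
      bi$attained && bi$bmd <= highest && isTRUE(mf >= fc_min)
    ci <- if (need_ci) gene_bmd_bounds(best, bi, y, doses)
          else list(bmdl = NA_real_, bmdu = NA_real_)
    data.frame(gene = g, model = best$model, fit_p = best$gof_p,
               sigma = sig, bmd = bi$bmd, bmdl = ci$bmdl, bmdu = ci$bmdu,
               direction = if (bi$attained) bi$direction else NA_real_,
               max_fc = if (is.null(mf) || is.na(mf)) NA_real_ else mf,
               hill_k_demoted = isTRUE(best$hill_k_demoted),
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rec <- apply_bmd_filters(rec, highest_dose = highest,
                           fit_p_min = fit_p_min, ratio_max = ratio_max,
                           fc_min = fc_min)
  class(rec) <- c("gene_bmd_records", "data.frame")
  rec
}

#' The four-rule benchmark-dose filter cascade
#'
#' A record survives iff its goodness-of-fit p-value exceeds `fit_p_min`,
#' its BMDU/BMDL ratio is strictly below `ratio_max`, its BMD does not
#' exceed the highest tested dose, and its observed max |fold change| is at
#' least `fc_min`.  The four rules are a pure conjunction, so the cascade
#' is order-independent; each rule's pass/fail flag is recorded per gene.
#' Missing quantities fail their rule (a gene without a defined interval
#' cannot demonstrate a ratio below the cut).
#'
#' @param records data.frame with columns `fit_p`, `bmd`, `bmdl`, `bmdu`,
#'   `max_fc`.
#' @param highest_dose the top tested dose.
#' @param fit_p_min exclude fits with goodness-of-fit p <= this (default 0.1).
#' @param ratio_max exclude intervals with BMDU/BMDL >= this (default 40).
#' @param fc_min exclude genes with max |FC| < this (default 1.5).
#' @return the records with logical columns `pass_fit_p`, `pass_ratio`,
#'   `pass_range`, `pass_fc` and `survives`.
#' @export
apply_bmd_filters <- function(records, highest_dose, fit_p_min = 0.1,
                              ratio_max = 40, fc_min = 1.5) {
  need <- c("fit_p", "bmd", "bmdl", "bmdu", "max_fc")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (any(is.na(records$max_fc)))
    stop("missing fold-change linkage for gene(s): ",
         paste(utils::head(records$gene[is.na(records$max_fc)], 5),
               collapse = ", "))
  ratio <- records$bmdu / records$bmdl
  records$pass_fit_p <- !is.na(records$fit_p) & records$fit_p > fit_p_min
  records$pass_ratio <- !is.na(ratio) & ratio < ratio_max
  records$pass_range <- !is.na(records$bmd) & records$bmd <= highest_dose
  records$pass_fc <- records$max_fc >= fc_min
  records$survives <- records$pass_fit_p & records$pass_ratio &
    records$pass_range & records$pass_fc
  records
}

#' @export
print.gene_bmd_records <- function(x, ...) {
  cat(sprintf("Gene BMD records: %d genes modeled, %d surviving filters\n",
              nrow(x), sum(x$survives)))
  if (nrow(x)) {
    cat("  rule failures: fit_p", sum(!x$pass_fit_p),
        "| ratio", sum(!x$pass_ratio),
        "| range", sum(!x$pass_range),
        "| fc", sum(!x$pass_fc), "\n")
  }
  invisible(x)
}
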