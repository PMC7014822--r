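#' Study design for a simulated dose-response experiment
#'
#' Captures the design of the emulated in-life study: the dose levels of
#' the 28-day gavage design (0, 300, 500, 750, 1000, 1500 mg/kg/day), six
#' animals or replicates per group, and one or more series labels (sex by
#' treatment-duration covariate levels).
#'
#' @param doses strictly increasing dose vector starting at 0.
#' @param n_per_group replicates per dose (>= 2).
#' @param series character vector of covariate labels.
#' @param seed integer random seed carried with the design.
#' @return list of class `"study_design"`.
#' @export
study_design <- function(doses = c(0, 300, 500, 750, 1000, 1500),
                         n_per_group = 6, series = "males_d29", seed = 1L) {
  if (doses[1] != 0) stop("doses[1] must be 0 (control)")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (!length(series)) stop("series must be non-empty")
  structure(list(doses = doses, n_per_group = n_per_group,
                 series = as.character(series), seed = as.integer(seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", length(x$doses), "doses (",
      paste(x$doses, collapse = ", "), ") x n =", x$n_per_group,
      "per group;", length(x$series), "series\n")
  invisible(x)
}

#' True generating curve for an apical endpoint
#'
#' Defines the noiseless mean curve an endpoint follows and the
#' multiplicative lognormal noise around it.  Families mirror the fitted
#' model forms: `"exponential"` uses \eqn{a[c-(c-1)e^{-bx^d}]}
#' (unbounded \eqn{a e^{bx^d}} when `c` is omitted), `"hill"` uses
#' \eqn{a[1+(c-1)x^d/(b^d+x^d)]}, and `"flat"` is the no-effect control
#' case.  The analytic benchmark dose at relative benchmark response `bmr`
#' is attached as `true_bmd` (absent for flat curves).
#'
#' @param family `"exponential"`, `"hill"` or `"flat"`.
#' @param a background (> 0).
#' @param b potency (exponential rate, or Hill half-maximal dose).
#' @param c fold-range parameter (omit for the unbounded exponential).
#' @param d shape exponent (default 1).
#' @param noise_cv multiplicative lognormal coefficient of variation
#'   (default 0.25, a typical within-group CV for these endpoints).
#' @param bmr benchmark response defining `true_bmd` (default 0.10).
#' @return list of class `"true_curve"` with the parameters and `true_bmd`
#'   (`NA` for flat).
#' @export
true_curve <- function(family = c("exponential", "hill", "flat"), a = 1,
                       b = NULL, c = NULL, d = 1, noise_cv = 0.25,
                       bmr = 0.10) {
  family <- match.arg(family)
  if (a <= 0) stop("background a must be positive")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (family != "flat" && (is.null(b) || b <= 0))
    stop("potency b must be positive")
  sgn <- if (!is.null(c) && c < 1) -1 else 1
  gamma <- if (is.null(c)) NA_real_ else abs(c - 1)
  tb <- if (family == "flat") NA_real_ else {
    sm <- if (family == "hill") "H5" else if (is.null(c)) "E3" else "E5"
    bmd_from_pars(sm, b, gamma, d, sgn, bmr)
  }
  structure(list(family = family, a = a, b = b, c = c, d = d, sgn = sgn,
                 gamma = gamma, noise_cv = noise_cv, bmr = bmr,
                 true_bmd = tb),
            class = "true_curve")
}

curve_mean <- function(curve, x) {
  switch(curve$family,
    flat = rep(curve$a, length(x)),
    exponential = if (is.null(curve$c))
      curve$a * rel_curve("E3", x, curve$b, NA, curve$d, curve$sgn)
    else curve$a * rel_curve("E5", x, curve$b, curve$gamma, curve$d, curve$sgn),
    hill = curve$a * rel_curve("H5", x, curve$b, curve$gamma, curve$d, curve$sgn))
}

#' Simulate individual-animal apical endpoint records
#'
#' Draws one response per animal as curve mean times multiplicative
#' lognormal noise with unit mean and the curve's coefficient of
#' variation.  Deterministic under the design seed.
#'
#' @param design a [study_design()].
#' @param curve a [true_curve()]; recycled across series.
#' @return list with `data` (data.frame `series, dose, subject, value`) and
#'   `true_bmd`.
#' @export
simulate_apical_series <- function(design, curve) {
  stopifnot(inherits(design, "study_design"), inherits(curve, "true_curve"))
  set.seed(design$seed)
  sdl <- sqrt(log(1 + curve$noise_cv^2))
  rows <- expand.grid(subject = seq_len(design$n_per_group),
                      dose = design$doses, series = design$series,
                      stringsAsFactors = FALSE)
  rows <- rows[order(rows$series, rows$dose, rows$subject), c("series", "dose", "subject")]
  mu <- curve_mean(curve, rows$dose)
  noise <- exp(stats::rnorm(nrow(rows), -sdl^2 / 2, sdl))
  rows$value <- mu * noise
  rownames(rows) <- NULL
  list(data = rows, true_bmd = curve$true_bmd)
}

#' Simulate a dose-response expression study with known truth
#'
#' Generates a genes-by-samples expression matrix under the study design.
#' A configurable fraction of genes responds to dose along monotone
#' Hill-shaped curves on the log2 scale; the rest are dose-flat.  For each
#' responsive gene the generator draws a true benchmark dose and a top-dose
#' log2 fold change, then calibrates the curve so that the change reaches
#' exactly that fold change at the top dose and exactly the transcriptomic
#' benchmark response (1.349 x the generating noise SD) at the drawn true
#' BMD — making both recorded truths exactly the quantities the per-gene
#' pipeline estimates.  Gaussian noise is added on the log2 scale; raw
#' counts are obtained by exponentiation (optionally with Poisson
#' resampling).
#'
#' @param design a [study_design()] (the first series is used).
#' @param n_genes number of genes (>= 1).
#' @param responsive_fraction proportion of genes with a dose effect.
#' @param effect_law list with `bmd_range` (loguniform sampling range of
#'   true BMDs), `l2fc_range` (uniform range of top-dose |log2FC|),
#'   `p_up` (probability of up-regulation), `hill_n` (minimum generating
#'   Hill exponent; raised per gene when the drawn BMD/amplitude pair needs
#'   a steeper curve). Defaults: bmd_range c(100, 1200), l2fc_range
#'   c(0.8, 3), p_up 0.5, hill_n 2.
#' @param gene_sd per-gene log2 noise SD (default 0.25); a vector is
#'   recycled over genes.
#' @param base_range uniform range of baseline log2 expression.
#' @param poisson_counts if `TRUE`, raw counts are Poisson draws around
#'   2^log2-expression (zeros then possible); otherwise deterministic
#'   rounding with a floor of 1.
#' @return list of class `"expression_study"`: `log2` matrix, `counts`
#'   matrix, `meta` (sample data.frame: sample, dose, replicate, series)
#'   and `truth` (per-gene data.frame: gene, responsive, direction,
#'   true_bmd, true_l2fc).
#' @export
simulate_expression_study <- function(design, n_genes = 2000,
                                      responsive_fraction = 0.10,
                                      effect_law = list(),
                                      gene_sd = 0.25,
                                      base_range = c(4, 10),
                                      poisson_counts = FALSE) {
  stopifnot(inherits(design, "study_design"), n_genes >= 1,
            responsive_fraction >= 0, responsive_fraction <= 1)
  law <- utils::modifyList(list(bmd_range = c(100, 1200),
                                l2fc_range = c(0.8, 3),
                                p_up = 0.5, hill_n = 2), effect_law)
  if (any(law$bmd_range <= 0)) stop("effect_law bmd_range must be positive")
  set.seed(design$seed)
  doses <- design$doses
  nrep <- design$n_per_group
  meta <- data.frame(sample = paste0("s", seq_len(length(doses) * nrep)),
                     dose = rep(doses, each = nrep),
                     replicate = rep(seq_len(nrep), length(doses)),
                     series = design$series[1], stringsAsFactors = FALSE)
  genes <- sprintf("g%04d", seq_len(n_genes))
  n_resp <- round(n_genes * responsive_fraction)
  responsive <- c(rep(TRUE, n_resp), rep(FALSE, n_genes - n_resp))
  sdv <- rep_len(gene_sd, n_genes)
  base <- stats::runif(n_genes, base_range[1], base_range[2])
  dirn <- ifelse(stats::runif(n_genes) < law$p_up, 1, -1)
  l2fc <- stats::runif(n_genes, law$l2fc_range[1], law$l2fc_range[2])
  tbmd <- exp(stats::runif(n_genes, log(law$bmd_range[1]),
                           log(law$bmd_range[2])))
  # Each responsive gene follows a scaled Hill on log2 dose-response whose
  # change reaches exactly `l2fc` at the top dose and exactly the
  # transcriptomic benchmark response (1.349 x the gene's noise SD) at its
  # drawn true BMD.  The Hill exponent is raised per gene where the drawn
  # (BMD, amplitude) pair needs a steeper curve to satisfy both.
  delta_star <- 1.349 * sdv
  l2fc <- pmax(l2fc, delta_star * 1.5)     # amplitude must exceed the BMR
  X <- max(doses)
  h_req <- log(delta_star / l2fc) / log(pmin(tbmd / X, 0.999))
  h <- pmax(law$hill_n, 1.25 * h_req)
  Kh <- tbmd^h * X^h * (delta_star - l2fc) / (tbmd^h * l2fc - delta_star * X^h)
  amp <- l2fc * (Kh + X^h) / X^h
  mu <- matrix(base, n_genes, nrow(meta))
  resp_idx <- which(responsive)
  if (length(resp_idx)) {
    dmat <- outer(rep(1, length(resp_idx)), meta$dose)
    hm <- h[resp_idx]
    eff <- (dirn[resp_idx] * amp[resp_idx]) * dmat^hm /
      (Kh[resp_idx] + dmat^hm)
    mu[resp_idx, ] <- mu[resp_idx, ] + eff
  }
  log2m <- mu + matrix(stats::rnorm(n_genes * nrow(meta), 0, sdv),
                       n_genes, nrow(meta))
  counts <- if (poisson_counts) {
    matrix(stats::rpois(length(log2m), 2^log2m), n_genes, nrow(meta))
  } else pmax(round(2^log2m), 1)
  dimnames(log2m) <- dimnames(counts) <- list(genes, meta$sample)
  truth <- data.frame(gene = genes, responsive = responsive,
                      direction = ifelse(responsive, dirn, 0L),
                      true_bmd = ifelse(responsive, tbmd, NA_real_),
                      true_l2fc = ifelse(responsive, dirn * l2fc, 0),
                      stringsAsFactors = FALSE)
  structure(list(log2 = log2m, counts = counts, meta = meta, truth = truth),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("Expression study: %d genes x %d samples (%d responsive)\n",
              nrow(x$log2), ncol(x$log2), sum(x$truth$responsive)))
  invisible(x)
}

#' Per-dose differential-expression table (closed-loop stand-in)
#'
#' Produces a DE table from a simulated expression study by a Welch t-test
#' of each non-control dose group against control on log2 values, with
#' Benjamini-Hochberg FDR within each dose.  This is a deliberately simple
#' stand-in used to close the simulation loop; it is NOT a reimplementation
#' of, or substitute for, count-based DE testing such as DESeq2.
#'
#' @param study an `"expression_study"` (or list with `log2` and `meta`).
#' @return data.frame with `gene`, `dose`, `log2fc`, `fc` (signed linear),
#'   `pvalue`, `fdr`.
#' @export
make_deg_table <- function(study) {
  log2m <- study$log2; meta <- study$meta
  doses <- sort(unique(meta$dose))
  if (length(doses) < 2) stop("need at least one non-control dose")
  if (any(table(meta$dose) < 2)) stop("need >= 2 replicates per dose")
  ctrl <- log2m[, meta$dose == 0, drop = FALSE]
  n0 <- ncol(ctrl)
  m0 <- rowMeans(ctrl)
  v0 <- rowSums((ctrl - m0)^2) / (n0 - 1)
  out <- lapply(doses[doses > 0], function(d) {
    trt <- log2m[, meta$dose == d, drop = FALSE]
    n1 <- ncol(trt)
    m1 <- rowMeans(trt)
    v1 <- rowSums((trt - m1)^2) / (n1 - 1)
    se2 <- v0 / n0 + v1 / n1
    zero <- se2 <= 0
    se2s <- ifelse(zero, 1, se2)
    tt <- (m1 - m0) / sqrt(se2s)
    df <- se2s^2 / pmax(v0^2 / (n0^2 * (n0 - 1)) + v1^2 / (n1^2 * (n1 - 1)),
                        1e-300)
    df[zero] <- 1
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    p[zero] <- ifelse(m1[zero] == m0[zero], 1, 0)
    lfc <- m1 - m0
    data.frame(gene = rownames(log2m), dose = d, log2fc = lfc,
               fc = log2fc_to_fc(lfc), pvalue = p,
               fdr = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
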