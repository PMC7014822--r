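#' Bundled acetamide study summary tables
#'
#' Machine-readable copies of the printed group-summary tables from the
#' 28-day acetamide gavage study in Wistar rats: hepatic Ki67 labeling
#' index summaries, plasma clinical chemistry (AST, ALT, total bilirubin)
#' summaries, and per-dose differentially-expressed-gene counts at the
#' |fold change| >= 1.5 & FDR <= 0.05 threshold.  Each row carries its
#' series label (sex by treatment duration; `expA_` marks the dose-range
#' finding experiment).  Printed dispersions are stored verbatim; whether
#' they are SDs or SEs is not stated in the source tables, so the loader
#' tags them with a configurable `dispersion_kind` (default `"sd"`; see the
#' methods vignette for why SD is the defensible default).
#'
#' @param which one of `"ki67"`, `"clinchem"`, `"deg_counts"`.
#' @param dispersion_kind `"sd"` or `"se"`; how the printed `sd` column is
#'   to be interpreted downstream (ignored for `"deg_counts"`).
#' @return data.frame. Ki67: `series, dose, n, mean, sd, dispersion_kind`.
#'   Clinical chemistry adds an `endpoint` column. DEG counts:
#'   `series, direction, dose, count`.
#' @examples
#' k <- acetamide_tables("ki67")
#' subset(k, series == "females_d29" & dose == 1500)  # mean 5.69, sd 0.95
#' @export
acetamide_tables <- function(which = c("ki67", "clinchem", "deg_counts"),
                             dispersion_kind = c("sd", "se")) {
  which <- match.arg(which)
  dispersion_kind <- match.arg(dispersion_kind)
  path <- system.file("extdata", paste0("acetamide_", which, ".tsv"),
                      package = "tgxpod", mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (which != "deg_counts") tab$dispersion_kind <- dispersion_kind
  tab
}

#' The Grubbs-flagged Ki67 outlier animal
#'
#' The male day-29 1500 mg/kg/day group contains one animal whose Ki67
#' labeling index (37.5%) was roughly 5-fold above all others and was
#' flagged by Grubbs' test; the study excluded it before dose-response
#' modeling. This constant records that value so summary-level analyses can
#' reproduce the exclusion with [outlier_adjust_summary()].
#'
#' @format A list with `series`, `dose` and `value`.
#' @export
ki67_outlier <- list(series = "males_d29", dose = 1500, value = 37.5)

#' Apical benchmark-dose analysis of the bundled study tables
#'
#' Convenience wrapper reproducing the study's apical BMD workflow on the
#' bundled summaries: the female day-8 Ki67 series is excluded (variance
#' heterogeneity, Bartlett gate), the dose-range-finding series are left
#' out, the flagged male day-29 outlier is removed from its group summary,
#' and exponential + Hill families are fit with the series ("study")
#' covariate on background and variance at BMR = 10%.  The POD is the
#' lowest BMDL / highest BMDU over the two families.
#'
#' @param endpoint `"ki67"` or `"alt"`.
#' @param dispersion_kind interpretation of printed dispersions.
#' @param bmr benchmark response (default 0.10).
#' @param level two-sided confidence level for the BMD interval.
#' @return a `"pod_summary"` (see [select_pod()]).
#' @export
apical_pod <- function(endpoint = c("ki67", "alt"),
                       dispersion_kind = c("sd", "se"),
                       bmr = 0.10, level = 0.90) {
  endpoint <- match.arg(endpoint)
  dispersion_kind <- match.arg(dispersion_kind)
  if (endpoint == "ki67") {
    tab <- acetamide_tables("ki67", dispersion_kind)
    tab <- tab[tab$series %in% c("males_d8", "males_d29", "females_d29"), ]
    i <- tab$series == ki67_outlier$series & tab$dose == ki67_outlier$dose
    adj <- outlier_adjust_summary(tab$n[i], tab$mean[i],
                                  if (dispersion_kind == "se")
                                    tab$sd[i] * sqrt(tab$n[i]) else tab$sd[i],
                                  ki67_outlier$value)
    tab$n[i] <- adj$n; tab$mean[i] <- adj$mean; tab$sd[i] <- adj$sd
    tab$dispersion_kind[i] <- "sd"
  } else {
    cc <- acetamide_tables("clinchem", dispersion_kind)
    tab <- cc[cc$endpoint == "alt" & cc$series != "expA_males_d8", ]
  }
  fits <- lapply(c("exponential", "hill"), function(fam) {
    f1 <- fit_bmd(tab, family = fam, bmr = bmr, covariate_on = c("a", "var"))
    f2 <- fit_bmd(tab, family = fam, bmr = bmr,
                  covariate_on = c("a", "b", "var"))
    # series-dependent potency is accepted only on a clear AIC improvement;
    # it then yields one BMD interval per covariate level and the POD takes
    # the extremes across levels and families
    bmd(if (f2$aic < f1$aic - 2) f2 else f1, level = level)
  })
  select_pod(fits)
}
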