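#' Differential-expression thresholding
#'
#' Classifies genes as differentially expressed at each dose by the joint
#' fold-change / FDR rule: a gene is a DEG at a dose iff |FC| >= `fc_thresh`
#' and FDR <= `fdr_thresh`.  Fold changes are linear-scale; a `log2fc`
#' column is accepted and converted.  Direction follows the sign of the
#' change.
#'
#' @param table data.frame with columns `gene`, `dose`, `fdr` and either
#'   `fc` (signed linear fold change: 2 means doubled, -2 means halved) or
#'   `log2fc`.
#' @param fc_thresh linear fold-change threshold (>= 1), default 1.5. The
#'   relaxed screen uses 1.4.
#' @param fdr_thresh FDR threshold in (0, 1], default 0.05 (relaxed: 0.1).
#' @return list of class `"deg_sets"`: `by_dose` (named list per dose with
#'   `up`, `down` gene-id vectors), `union` (all DEG ids across doses, and
#'   `union_up`/`union_down`), and the thresholds used.
#' @export
deg_filter <- function(table, fc_thresh = 1.5, fdr_thresh = 0.05) {
  stopifnot(fc_thresh >= 1, fdr_thresh > 0, fdr_thresh <= 1)
  table <- as.data.frame(table)
  if (!"fc" %in% names(table)) {
    if (!"log2fc" %in% names(table)) stop("need an 'fc' or 'log2fc' column")
    table$fc <- log2fc_to_fc(table$log2fc)
  }
  if (any(table$fc == 0 | is.na(table$fc)))
    stop("malformed fold changes: zero or missing linear FC")
  if (any(abs(table$fc) < 1))
    stop("malformed fold changes: signed linear |FC| must be >= 1")
  afc <- abs(table$fc)
  is_deg <- afc >= fc_thresh & table$fdr <= fdr_thresh
  doses <- sort(unique(table$dose))
  by_dose <- lapply(doses, function(d) {
    sel <- table$dose == d & is_deg
    list(up = sort(unique(table$gene[sel & table$fc > 0])),
         down = sort(unique(table$gene[sel & table$fc < 0])))
  })
  names(by_dose) <- as.character(doses)
  out <- list(by_dose = by_dose,
              union = sort(unique(table$gene[is_deg])),
              union_up = sort(unique(table$gene[is_deg & table$fc > 0])),
              union_down = sort(unique(table$gene[is_deg & table$fc < 0])),
              fc_thresh = fc_thresh, fdr_thresh = fdr_thresh)
  class(out) <- "deg_sets"
  out
}

#' @export
print.deg_sets <- function(x, ...) {
  cat(sprintf("DEG sets at |FC| >= %.3g & FDR <= %.3g\n", x$fc_thresh, x$fdr_thresh))
  for (d in names(x$by_dose))
    cat(sprintf("  dose %s: %d up, %d down\n", d,
                length(x$by_dose[[d]]$up), length(x$by_dose[[d]]$down)))
  cat(sprintf("  union: %d genes\n", length(x$union)))
  invisible(x)
}

# signed linear FC <-> log2 FC (signed convention: -2 means halved)
log2fc_to_fc <- function(lfc) ifelse(lfc >= 0, 2^lfc, -(2^(-lfc)))

fc_to_log2fc <- function(fc) ifelse(fc >= 0, log2(fc), -log2(-fc))

#' Cross-dataset DEG overlap
#'
#' Exact intersection and union of DEG identifier sets across datasets
#' (e.g. sexes and treatment durations), with membership lists.
#'
#' @param sets a named list of character vectors of gene ids.
#' @return list with `intersection`, `union` (character vectors),
#'   `n_intersection`, `n_union`, `per_set` sizes, and the pairwise
#'   intersection count matrix.
#' @export
overlap_analysis <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  inter <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  k <- length(sets)
  pw <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  list(intersection = inter, union = sort(uni),
       n_intersection = length(inter), n_union = length(uni),
       per_set = vapply(sets, length, integer(1)), pairwise = pw)
}

#' Grubbs' test for a single outlier
#'
#' Two-sided single-outlier Grubbs test: G = max |x - mean| / sd compared
#' against the t-distribution-based critical value at level `alpha`.  At
#' most one observation is flagged; iterative removal is deliberately not
#' performed.
#'
#' @param values numeric vector, n >= 3, non-constant.
#' @param alpha significance level (default 0.05).
#' @return list with `G`, `critical`, `outlier` (the flagged value, or `NA`
#'   if none), `index`, and `p_exceeds` (logical: G > critical).
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) stop("Grubbs test needs n >= 3")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance: Grubbs statistic undefined")
  dev <- abs(values - mean(values))
  i <- which.max(dev)
  G <- dev[i] / s
  tcrit <- stats::qt(1 - alpha / (2 * n), n - 2)
  critical <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  flag <- G > critical
  list(G = G, critical = critical,
       outlier = if (flag) values[i] else NA_real_,
       index = if (flag) i else NA_integer_, p_exceeds = flag,
       alpha = alpha, n = n)
}

#' Bartlett's test of variance homogeneity
#'
#' Classic Bartlett chi-square statistic for equality of group variances,
#' used as the exclusion gate for apical dose-response series (a series
#' with p <= 0.05 is flagged for removal before BMD modeling).
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `statistic`, `df`, `p_value`, and `flagged`
#'   (p <= 0.05).
#' @export
bartlett_gate <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) stop("each group needs n >= 2")
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v == 0)) stop("a group has zero variance")
  N <- sum(n)
  sp2 <- sum((n - 1) * v) / (N - k)
  stat <- ((N - k) * log(sp2) - sum((n - 1) * log(v))) /
    (1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  p <- stats::pchisq(stat, k - 1, lower.tail = FALSE)
  list(statistic = stat, df = k - 1, p_value = p, flagged = p <= 0.05)
}

#' Fold-change magnitude distribution of DEGs
#'
#' Bins the absolute linear fold changes of the DEGs at one dose and
#' reports the percentage of DEGs per bin (summing to 100).
#'
#' @param table DE table as in [deg_filter()].
#' @param dose the dose to summarise.
#' @param breaks left edges of the |FC| bins; the last bin is open-ended.
#'   Default `c(1.5, 2, 3)` giving bins 1.5-2, 2-3, >= 3.
#' @param fc_thresh,fdr_thresh DEG definition passed to [deg_filter()].
#' @return data.frame with `bin`, `count`, `percent`; zero rows if no DEGs.
#' @export
fc_distribution <- function(table, dose, breaks = c(1.5, 2, 3),
                            fc_thresh = 1.5, fdr_thresh = 0.05) {
  table <- as.data.frame(table)
  if (!"fc" %in% names(table)) table$fc <- log2fc_to_fc(table$log2fc)
  sel <- table$dose == dose & abs(table$fc) >= fc_thresh &
    table$fdr <= fdr_thresh
  afc <- abs(table$fc[sel])
  labs <- c(paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")"),
            paste0(">=", breaks[length(breaks)]))
  if (!length(afc))
    return(data.frame(bin = character(0), count = integer(0),
                      percent = numeric(0)))
  idx <- findInterval(afc, breaks)
  counts <- tabulate(idx, nbins = length(breaks))
  data.frame(bin = labs, count = counts, percent = 100 * counts / sum(counts))
}
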