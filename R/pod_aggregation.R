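#' Read a GMT gene-set collection
#'
#' Standard tab-delimited GMT: one set per line — name, description, then
#' member gene ids.
#'
#' @param path GMT file.
#' @return list of class `"gene_set_collection"`: named list `sets` of
#'   character vectors, plus `descriptions` and `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad))
    stop("GMT line ", bad[1], " has fewer than one member gene")
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) stop("duplicate set names in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  structure(list(sets = sets,
                 descriptions = stats::setNames(vapply(parts, `[[`,
                                                       character(1), 2), nm),
                 source = path),
            class = "gene_set_collection")
}

#' Write a GMT gene-set collection
#' @param collection a `"gene_set_collection"` or named list of id vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  desc <- if (inherits(collection, "gene_set_collection"))
    collection$descriptions else stats::setNames(rep("na", length(sets)),
                                                 names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Fisher-exact over-representation of a gene selection in gene sets
#'
#' One-tailed hypergeometric (over-representation) p-value per set for the
#' selected genes against the universe.  Sets are intersected with the
#' universe first.  No multiple-testing correction is applied by default —
#' enrichment calls use the raw p-value; an optional Benjamini-Hochberg
#' column is available.
#'
#' @param selected character vector of selected gene ids (subset of
#'   `universe`).
#' @param collection a `"gene_set_collection"` or named list of id vectors.
#' @param universe character vector of background gene ids.
#' @param adjust add a BH-adjusted column (default FALSE).
#' @return data.frame: `set`, `set_size` (within universe), `overlap`,
#'   `p` (and `p_adj` when requested).
#' @export
fisher_enrichment <- function(selected, collection, universe,
                              adjust = FALSE) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  selected <- unique(as.character(selected))
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  N <- length(universe); n <- length(selected)
  out <- data.frame(set = names(sets), set_size = NA_integer_,
                    overlap = NA_integer_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sets)) {
    s <- intersect(sets[[i]], universe)
    K <- length(s)
    k <- length(intersect(s, selected))
    out$set_size[i] <- K
    out$overlap[i] <- k
    out$p[i] <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  if (adjust) out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}

#' Per-pathway BMD summaries for enriched sets
#'
#' Applies the enrichment reporting gate (Fisher p <= `p_max` and overlap
#' with the surviving genes >= `min_overlap`) and summarises each
#' reported set by the median BMDL/BMD/BMDU over its surviving member
#' genes.
#'
#' @param records surviving gene BMD records (rows with `survives` TRUE are
#'   used; a plain data.frame with `gene`, `bmd`, `bmdl`, `bmdu` works
#'   too).
#' @param collection gene sets.
#' @param universe background gene ids (convention: all genes passing the
#'   raw-count prefilter).
#' @param p_max,min_overlap reporting gate (defaults 0.1 and 10).
#' @return data.frame: `set`, `overlap`, `p`, `bmdl`, `bmd`, `bmdu`.
#' @export
pathway_pods <- function(records, collection, universe, p_max = 0.1,
                         min_overlap = 10) {
  rec <- if ("survives" %in% names(records)) records[records$survives, ]
         else records
  enr <- fisher_enrichment(rec$gene, collection, universe)
  enr <- enr[enr$p <= p_max & enr$overlap >= min_overlap, , drop = FALSE]
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  if (!nrow(enr))
    return(data.frame(set = character(0), overlap = integer(0),
                      p = numeric(0), bmdl = numeric(0), bmd = numeric(0),
                      bmdu = numeric(0)))
  su <- lapply(enr$set, function(nm) rec[rec$gene %in% sets[[nm]], ])
  data.frame(set = enr$set, overlap = enr$overlap, p = enr$p,
             bmdl = vapply(su, function(d) stats::median(d$bmdl), numeric(1)),
             bmd = vapply(su, function(d) stats::median(d$bmd), numeric(1)),
             bmdu = vapply(su, function(d) stats::median(d$bmdu), numeric(1)),
             stringsAsFactors = FALSE)
}

pod_strategies <- c("all_genes", "lowest20_genes", "top20_up", "top20_down",
                    "top20_absfc", "pathway_medians", "lowest20_pathways",
                    "most_sensitive_pathway", "common_pathways")

#' Aggregate per-gene BMDs into a transcriptional point of departure
#'
#' Implements the battery of pathway-agnostic and pathway-based POD
#' aggregation strategies: `"all_genes"` (median over all surviving
#' genes), `"lowest20_genes"` (20 genes with lowest BMD),
#' `"top20_up"`/`"top20_down"`/`"top20_absfc"` (20 most induced, most
#' repressed, or largest-|FC| genes, ranked on the DE table, ties broken
#' by FDR then gene id), `"pathway_medians"` (median of the per-enriched-
#' pathway medians), `"lowest20_pathways"` (median over the 20 enriched
#' pathways with lowest median BMD), `"most_sensitive_pathway"` (the
#' enriched pathway with the lowest median BMD), and `"common_pathways"`
#' (arithmetic mean of the per-dataset medians of pathways enriched in
#' every supplied dataset; `pods` must then be a list of pathway tables).
#' Every strategy returns the median (or designated) BMDL/BMD/BMDU triple.
#'
#' @param records surviving gene BMD records.
#' @param deg_table companion DE table (for the fold-change rankings).
#' @param pods pathway POD table from [pathway_pods()] (or a list of such
#'   tables for `"common_pathways"`).
#' @param strategy one of the strategy names above.
#' @param n_top size of the "top" selections (default 20).
#' @return one-row data.frame: `strategy`, `n` (items aggregated), `bmdl`,
#'   `bmd`, `bmdu`.
#' @export
aggregate_pod <- function(records, deg_table = NULL, pods = NULL,
                          strategy = "all_genes", n_top = 20) {
  strategy <- match.arg(strategy, pod_strategies)
  rec <- if ("survives" %in% names(records)) records[records$survives, ]
         else records
  gene_based <- strategy %in% c("all_genes", "lowest20_genes", "top20_up",
                                "top20_down", "top20_absfc")
  if (gene_based && !nrow(rec)) stop("no surviving gene records")
  med3 <- function(d) data.frame(strategy = strategy, n = nrow(d),
                                 bmdl = stats::median(d$bmdl),
                                 bmd = stats::median(d$bmd),
                                 bmdu = stats::median(d$bmdu))
  rank_by_fc <- function(decreasing_on) {
    if (is.null(deg_table)) stop("strategy needs the DE table")
    tab <- as.data.frame(deg_table)
    if (!"fc" %in% names(tab)) tab$fc <- log2fc_to_fc(tab$log2fc)
    tab <- tab[tab$gene %in% rec$gene, ]
    val <- switch(decreasing_on, up = tab$fc, down = -tab$fc,
                  absfc = abs(tab$fc))
    sc <- tapply(val, tab$gene, max)
    fd <- tapply(tab$fdr, tab$gene, min)
    ord <- order(-sc, fd, names(sc))
    utils::head(names(sc)[ord], n_top)
  }
  if (gene_based) {
    sel <- switch(strategy,
      all_genes = rec$gene,
      lowest20_genes = utils::head(rec$gene[order(rec$bmd, rec$gene)], n_top),
      top20_up = rank_by_fc("up"),
      top20_down = rank_by_fc("down"),
      top20_absfc = rank_by_fc("absfc"))
    return(med3(rec[rec$gene %in% sel, ]))
  }
  if (strategy == "common_pathways") {
    if (!is.list(pods) || is.data.frame(pods))
      stop("common_pathways needs a list of per-dataset pathway tables")
    common <- Reduce(intersect, lapply(pods, `[[`, "set"))
    if (!length(common)) stop("no pathway enriched in every dataset")
    per <- lapply(pods, function(p) p[p$set %in% common, ])
    return(data.frame(strategy = strategy, n = length(common),
                      bmdl = mean(vapply(per, function(p) stats::median(p$bmdl), numeric(1))),
                      bmd = mean(vapply(per, function(p) stats::median(p$bmd), numeric(1))),
                      bmdu = mean(vapply(per, function(p) stats::median(p$bmdu), numeric(1)))))
  }
  if (is.null(pods) || !nrow(pods))
    stop("strategy '", strategy, "' needs pathways passing the enrichment gate")
  switch(strategy,
    pathway_medians = med3(pods),
    lowest20_pathways = med3(pods[order(pods$bmd, pods$set), ][
      seq_len(min(n_top, nrow(pods))), ]),
    most_sensitive_pathway = {
      p <- pods[order(pods$bmd, pods$set), ][1, ]
      data.frame(strategy = strategy, n = 1L, bmdl = p$bmdl, bmd = p$bmd,
                 bmdu = p$bmdu)
    })
}

#' Classify transcriptional PODs against an apical BMD interval
#'
#' Classifies each POD estimate's (bmdl, bmdu) interval against the apical
#' interval with a closed-interval convention: `"below"` when the estimate
#' lies entirely below the apical BMDL, `"above"` when entirely above the
#' apical BMDU, `"spans"` otherwise (any overlap, endpoints included).
#'
#' @param pod_estimates data.frame with `strategy`, `bmdl`, `bmdu` rows
#'   (e.g. rbind of [aggregate_pod()] results).
#' @param apical list or one-row data.frame with `bmdl`, `bmdu` (e.g. a
#'   `"pod_summary"`).
#' @return the estimates with a `concordance` factor column.
#' @export
concordance_report <- function(pod_estimates, apical) {
  al <- apical$bmdl; au <- apical$bmdu
  if (!is.finite(al) || !is.finite(au) || al > au || al == au && al == 0)
    stop("degenerate apical interval")
  cls <- ifelse(pod_estimates$bmdu < al, "below",
                ifelse(pod_estimates$bmdl > au, "above", "spans"))
  pod_estimates$concordance <- factor(cls, levels = c("below", "spans",
                                                      "above"))
  pod_estimates
}
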