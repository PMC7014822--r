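#' Read and write the pipeline's tabular formats
#'
#' Thin, schema-checked readers and writers for the standard inputs: apical
#' endpoint series (individual or summary layout, auto-detected from the
#' columns), DE tables, expression matrices (TSV genes-by-samples or
#' MatrixMarket with row/column annotation files), sample metadata and
#' truth tables.  All TSVs are UTF-8, tab-separated, header row required,
#' '.' decimal.
#'
#' @param path input file.
#' @return typed object: data.frame for tables; for expression,
#'   a base or sparse matrix with dimnames.
#' @name tgx_io
NULL

read_tsv_checked <- function(path, required, what) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop(what, " file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' @rdname tgx_io
#' @export
read_apical_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (all(c("dose", "value") %in% names(tab))) return(tab)
  if (all(c("dose", "n", "mean") %in% names(tab))) return(tab)
  stop("apical file ", path,
       " matches neither the individual (dose, value) nor the summary ",
       "(dose, n, mean, sd) layout")
}

#' @rdname tgx_io
#' @export
read_deg_tsv <- function(path) {
  tab <- read_tsv_checked(path, c("gene", "dose", "fdr"), "DE table")
  if (!any(c("fc", "log2fc") %in% names(tab)))
    stop("DE table ", path, " needs an 'fc' or 'log2fc' column")
  if (!"fc" %in% names(tab)) tab$fc <- log2fc_to_fc(tab$log2fc)
  if (!"log2fc" %in% names(tab)) tab$log2fc <- fc_to_log2fc(tab$fc)
  tab
}

#' @rdname tgx_io
#' @param x object to write.
#' @export
write_deg_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tgx_io
#' @export
read_expression_matrix <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    # general storage: symmetric MM variants tie row/col dimnames together
    m <- methods::as(Matrix::readMM(path), "generalMatrix")
    rn_path <- sub("\\.mtx$", ".rows.tsv", path, ignore.case = TRUE)
    cn_path <- sub("\\.mtx$", ".cols.tsv", path, ignore.case = TRUE)
    if (file.exists(rn_path)) rownames(m) <- readLines(rn_path)
    if (file.exists(cn_path)) colnames(m) <- readLines(cn_path)
    return(m)
  }
  tab <- utils::read.delim(path, sep = "\t", row.names = 1, check.names = FALSE)
  as.matrix(tab)
}

#' @rdname tgx_io
#' @export
write_expression_matrix <- function(x, path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    sp <- if (methods::is(x, "sparseMatrix")) x
          else Matrix::Matrix(x, sparse = TRUE)   # keeps stored zeros as-is
    Matrix::writeMM(methods::as(methods::as(sp, "generalMatrix"),
                                "TsparseMatrix"), path)
    writeLines(rownames(x), sub("\\.mtx$", ".rows.tsv", path))
    writeLines(colnames(x), sub("\\.mtx$", ".cols.tsv", path))
    return(invisible(path))
  }
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Builds (or loads from YAML) the typed configuration driving
#' [run_pipeline()], validating every threshold against its domain.
#'
#' @param ... named settings overriding the defaults (see Details), or a
#'   single `file` argument naming a YAML file of them.
#' @details Recognised keys: input paths (`apical`, `expression`, `meta`,
#'   `deg`, `gmt`), `bmr` (0-1), `bmr_sd` (> 0), `fit_p_min`, `ratio_max`,
#'   `fc_min`, `enrich_p`, `min_overlap`, `k_values`, `n_sim`, `seed`,
#'   `strategies`, `simulate` (list passed to the generator when no
#'   expression input is given), `outdir`.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  if (!is.null(args$file)) {
    cfg <- yaml::read_yaml(args$file)
    args$file <- NULL
    args <- utils::modifyList(cfg, args)
  }
  cfg <- utils::modifyList(list(
    apical = NULL, expression = NULL, meta = NULL, deg = NULL, gmt = NULL,
    bmr = 0.10, bmr_sd = 1.349, fit_p_min = 0.1, ratio_max = 40,
    fc_min = 1.5, enrich_p = 0.1, min_overlap = 10,
    k_values = c(2, 3, 5, 10), n_sim = 10000, seed = 1L,
    strategies = c("all_genes", "lowest20_genes", "top20_absfc"),
    simulate = NULL, outdir = NULL), args)
  stopifnot(cfg$bmr > 0, cfg$bmr < 1, cfg$bmr_sd > 0,
            cfg$fit_p_min >= 0, cfg$fit_p_min < 1, cfg$ratio_max > 1,
            cfg$fc_min >= 1, cfg$enrich_p > 0, cfg$enrich_p <= 1,
            cfg$min_overlap >= 1, all(cfg$k_values >= 1), cfg$n_sim >= 1)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration (seed", x$seed, ")\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Run the dose-response POD pipeline end to end
#'
#' Orchestrates the stages the configuration enables: apical BMD modeling,
#' simulation (when no expression input is supplied but a `simulate` block
#' is), per-gene BMD with the filter cascade, gene-set enrichment, POD
#' aggregation strategies, the D1/D1* DEG-count estimator, and the
#' concordance classification against the apical interval.  Stages whose
#' inputs are absent are skipped; the run is deterministic given the seed.
#'
#' @param config a [pipeline_config()] (or arguments for one).
#' @return list of class `"run_report"`: `config`, and the per-stage
#'   results among `apical_pod`, `gene_records`, `pathway_pods`,
#'   `pod_estimates`, `d1`, `concordance`, `truth`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, as.list(config))
  report <- list(config = config)
  set.seed(config$seed)

  if (!is.null(config$apical)) {
    tab <- if (is.character(config$apical)) read_apical_tsv(config$apical)
           else config$apical
    fits <- lapply(c("exponential", "hill"), function(fam)
      bmd(fit_bmd(tab, family = fam, bmr = config$bmr)))
    report$apical_pod <- select_pod(fits)
  }

  study <- NULL
  if (!is.null(config$expression)) {
    mat <- if (is.character(config$expression))
      read_expression_matrix(config$expression) else config$expression
    meta <- if (is.character(config$meta))
      read_tsv_checked(config$meta, c("sample", "dose"), "metadata")
      else config$meta
    if (is.null(meta)) stop("expression input requires sample metadata ('meta')")
    study <- list(log2 = log2(as.matrix(mat)), counts = round(as.matrix(mat)),
                  meta = meta)
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    des <- study_design(doses = sim$doses %||% c(0, 300, 500, 750, 1000, 1500),
                        n_per_group = sim$n_per_group %||% 6,
                        series = sim$series %||% "sim",
                        seed = config$seed)
    study <- simulate_expression_study(des,
      n_genes = sim$n_genes %||% 2000,
      responsive_fraction = sim$responsive_fraction %||% 0.10)
    report$truth <- study$truth
  }

  deg <- NULL
  if (!is.null(config$deg)) {
    deg <- if (is.character(config$deg)) read_deg_tsv(config$deg) else config$deg
  } else if (!is.null(study)) deg <- make_deg_table(study)

  if (!is.null(study)) {
    rec <- gene_bmd(study, deg_table = deg, bmr_sd = config$bmr_sd,
                    fit_p_min = config$fit_p_min, ratio_max = config$ratio_max,
                    fc_min = config$fc_min)
    report$gene_records <- rec
    if (!is.null(config$gmt)) {
      coll <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
      universe <- prefilter_genes(study)
      report$pathway_pods <- pathway_pods(rec, coll, universe,
                                          p_max = config$enrich_p,
                                          min_overlap = config$min_overlap)
    }
    ests <- lapply(config$strategies, function(s)
      try(aggregate_pod(rec, deg, report$pathway_pods, strategy = s),
          silent = TRUE))
    ests <- ests[!vapply(ests, inherits, logical(1), "try-error")]
    if (length(ests)) report$pod_estimates <- do.call(rbind, ests)
  }

  if (!is.null(deg)) {
    report$d1 <- try(d1_estimate(deg, k_values = config$k_values,
                                 n_sim = config$n_sim, seed = config$seed),
                     silent = TRUE)
    if (inherits(report$d1, "try-error")) report$d1 <- NULL
  }

  if (!is.null(report$pod_estimates) && !is.null(report$apical_pod))
    report$concordance <- concordance_report(report$pod_estimates,
                                             report$apical_pod)
  if (!is.null(config$outdir)) write_run_report(report, config$outdir)
  class(report) <- "run_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_run_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$apical_pod))
    jsonlite::write_json(report$apical_pod[c("bmdl", "bmdu", "ratio")],
                         file.path(outdir, "apical_pod.json"),
                         auto_unbox = TRUE, digits = NA)
  for (nm in c("gene_records", "pathway_pods", "pod_estimates",
               "concordance"))
    if (!is.null(report[[nm]]))
      utils::write.table(report[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$d1))
    utils::write.table(as.data.frame(report$d1),
                       file.path(outdir, "d1_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (seed", x$config$seed, ")\n")
  if (!is.null(x$apical_pod)) {
    cat("apical: "); print(x$apical_pod)
  }
  if (!is.null(x$gene_records))
    cat("gene BMD:", nrow(x$gene_records), "modeled,",
        sum(x$gene_records$survives), "surviving\n")
  if (!is.null(x$pod_estimates)) {
    cat("POD estimates:\n"); print(x$pod_estimates, row.names = FALSE)
  }
  if (!is.null(x$d1)) { cat("D1/D1*:\n"); print(as.data.frame(x$d1), row.names = FALSE) }
  invisible(x)
}
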