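mk_records <- function(bmd, bmdl = bmd * 0.6, bmdu = bmd * 1.6,
                       genes = sprintf("g%03d", seq_along(bmd))) {
  data.frame(gene = genes, bmd = bmd, bmdl = bmdl, bmdu = bmdu,
             survives = TRUE, stringsAsFactors = FALSE)
}

test_that("Fisher enrichment p-values match closed forms and the exhaustive oracle", {
  uni <- paste0("u", 1:10)
  sel <- uni[1:5]
  # full overlap of a 5-gene set with a 5-gene selection: p = 1/C(10,5)
  p <- fisher_enrichment(sel, list(s = uni[1:5]), uni)$p
  expect_equal(p, 1 / choose(10, 5), tolerance = 1e-12)
  # zero overlap: the upper tail includes >= 0, so p = 1
  p0 <- fisher_enrichment(sel, list(s = uni[6:10]), uni)$p
  expect_equal(p0, 1)

  set.seed(4)
  for (i in 1:25) {
    N <- sample(10:50, 1)
    uni <- paste0("g", seq_len(N))
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    set_i <- sample(uni, K); sel_i <- sample(uni, n)
    k <- length(intersect(set_i, sel_i))
    p <- fisher_enrichment(sel_i, list(s = set_i), uni)$p
    expect_equal(p, hyper_tail_oracle(k, K, N, n), tolerance = 1e-12)
  }

  expect_error(fisher_enrichment("x", list(s = "x"), character(0)), "universe")
  expect_error(fisher_enrichment("zz", list(s = "a"), c("a", "b")), "subset")
})

test_that("pathway reporting gate needs p <= 0.1 and overlap >= 10", {
  rec <- mk_records(seq(100, 1000, length.out = 30))
  uni <- c(rec$gene, sprintf("x%03d", 1:170))
  sets <- list(big = rec$gene[1:12],          # overlap 12, enriched
               nine = rec$gene[1:9],          # overlap 9: never reported
               offtarget = sprintf("x%03d", 1:40))
  pp <- pathway_pods(rec, sets, uni)
  expect_identical(pp$set, "big")
  expect_false("nine" %in% pp$set)
  enr <- fisher_enrichment(rec$gene, sets, uni)
  expect_lt(enr$p[enr$set == "nine"], 0.1)   # it fails only the size gate
})

test_that("aggregation strategies honour their selection contracts", {
  rec <- mk_records(c(100, 200, 300), bmdl = c(100, 200, 300))
  out <- aggregate_pod(rec, strategy = "all_genes")
  expect_equal(out$bmdl, 200)

  single <- mk_records(150)
  out1 <- aggregate_pod(single, strategy = "all_genes")
  expect_equal(unlist(out1[c("bmdl", "bmd", "bmdu")]),
               c(bmdl = 90, bmd = 150, bmdu = 240))

  # lowest-20 median can never exceed the all-gene median
  set.seed(6)
  for (i in 1:10) {
    rec <- mk_records(exp(runif(35, log(50), log(1500))))
    a <- aggregate_pod(rec, strategy = "all_genes")
    l <- aggregate_pod(rec, strategy = "lowest20_genes")
    expect_lte(l$bmd, a$bmd)
    expect_lte(l$bmdl, a$bmdl)
  }

  # median aggregation is permutation-invariant
  rec <- mk_records(exp(runif(25, log(50), log(1500))))
  prm <- sample(nrow(rec))
  expect_equal(aggregate_pod(rec, strategy = "all_genes")[-1],
               aggregate_pod(rec[prm, ], strategy = "all_genes")[-1])

  # fold-change rankings pick the programmed extremes
  rec <- mk_records(rep(300, 25))
  deg <- data.frame(gene = rec$gene, dose = 1500,
                    fc = c(rep(1.6, 20), 8, 9, -7, -8, 2),
                    fdr = 0.01)
  top_up <- aggregate_pod(rec, deg, strategy = "top20_up", n_top = 2)
  expect_equal(top_up$n, 2)
  top_dn <- aggregate_pod(rec, deg, strategy = "top20_down", n_top = 2)
  expect_equal(top_dn$n, 2)
  expect_error(aggregate_pod(rec, deg, pods = NULL,
                             strategy = "pathway_medians"), "enrichment gate")
})

test_that("pathway-based strategies aggregate the reported sets", {
  pods <- data.frame(set = c("p1", "p2", "p3"), overlap = c(12, 15, 11),
                     p = c(0.01, 0.02, 0.05),
                     bmdl = c(100, 300, 500), bmd = c(150, 350, 550),
                     bmdu = c(200, 400, 600))
  rec <- mk_records(rep(300, 12))
  med <- aggregate_pod(rec, pods = pods, strategy = "pathway_medians")
  expect_equal(med$bmd, 350)
  low <- aggregate_pod(rec, pods = pods, strategy = "lowest20_pathways",
                       n_top = 2)
  expect_equal(low$bmd, 250)
  ms <- aggregate_pod(rec, pods = pods, strategy = "most_sensitive_pathway")
  expect_equal(ms$bmd, 150)
  cp <- aggregate_pod(rec, pods = list(a = pods, b = pods[1:2, ]),
                      strategy = "common_pathways")
  expect_equal(cp$n, 2)
  expect_equal(cp$bmd, mean(c(250, 250)))
})

test_that("concordance classification follows closed-interval logic", {
  apical <- list(bmdl = 190, bmdu = 497)
  est <- data.frame(strategy = c("a", "b", "c", "d"),
                    bmdl = c(150, 520, 20, 190),
                    bmdu = c(600, 900, 80, 497))
  out <- concordance_report(est, apical)
  expect_equal(as.character(out$concordance),
               c("spans", "above", "below", "spans"))
  expect_error(concordance_report(est, list(bmdl = 500, bmdu = 100)),
               "degenerate")
})

test_that("GMT files round-trip and malformed lines are named", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g9"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back$sets, sets)

  bad <- tempfile(fileext = ".gmt")
  writeLines(c("ok\tdesc\tg1\tg2", "broken\tdesc"), bad)
  expect_error(read_gmt(bad), "line 2")
})

test_that("genes outside every set change only the universe", {
  rec <- mk_records(seq(100, 600, length.out = 15))
  uni <- c(rec$gene, "lonely1", "lonely2")
  sets <- list(s = rec$gene[1:12])
  e1 <- fisher_enrichment(rec$gene, sets, uni)
  e2 <- fisher_enrichment(rec$gene, sets, c(uni, "lonely3"))
  expect_equal(e1$overlap, e2$overlap)
  expect_false(isTRUE(all.equal(e1$p, e2$p)))  # only the background moved
})
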