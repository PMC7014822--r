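study_doses <- rep(c(0, 300, 500, 750, 1000, 1500), each = 6)

test_that("raw-count prefilter keeps exactly the all-positive genes", {
  m <- matrix(5L, 10, 6, dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  m[2, 3] <- 0L; m[5, 1] <- 0L; m[9, 6] <- 0L
  expect_setequal(prefilter_genes(list(counts = m)),
                  paste0("g", c(1, 3, 4, 6, 7, 8, 10)))
  expect_length(prefilter_genes(list(counts = m)), 7)
  m2 <- m; m2[] <- 1L
  expect_identical(prefilter_genes(list(counts = m2)), rownames(m))
  expect_error(prefilter_genes(list(log2 = m)), "raw counts")
})

test_that("model selection keeps the simplest adequate model and honours tie-breaks", {
  set.seed(1)
  y <- 4 + 0.001 * study_doses + rnorm(length(study_doses), 0, 0.05)
  cand <- fit_gene_models(y, study_doses)
  best <- select_best_model(cand, 300)
  expect_equal(best$model, "linear")
  # exact ties go to the fewer-parameter model
  fake <- list(linear = cand$linear, poly2 = cand$poly2)
  fake$poly2$aic <- fake$linear$aic
  expect_equal(select_best_model(fake, 300)$model, "linear")
})

test_that("noise-free Hill data are recovered and low-k Hill fits are demoted", {
  mu <- 5 + 2 * study_doses / (750 + study_doses)
  cand <- fit_gene_models(mu + rnorm(length(mu), 0, 1e-6), study_doses)
  expect_equal(unname(cand$hill$pars["v"]), 2, tolerance = 1e-2)
  expect_equal(unname(cand$hill$pars["k"]), 750, tolerance = 2e-2)

  # k = 50 with lowest positive dose 300 trips the k < lowest/3 rule
  set.seed(2)
  mu2 <- 5 + 1.5 * study_doses^2 / (50^2 + study_doses^2)
  y2 <- mu2 + rnorm(length(mu2), 0, 0.05)
  cand2 <- fit_gene_models(y2, study_doses)
  expect_lt(unname(cand2$hill$pars["k"]), 100)
  best2 <- select_best_model(cand2, 300)
  expect_true(best2$hill_k_demoted)
  expect_false(best2$model == "hill")
})

test_that("gene BMD closed forms hold and vanish with the noise", {
  set.seed(3)
  sl <- 0.004
  y <- 6 + sl * study_doses + rnorm(length(study_doses), 0, 0.3)
  cand <- fit_gene_models(y, study_doses)
  lin <- cand$linear
  sig <- sqrt(lin$rss / (lin$N - lin$k))
  bi <- compute_gene_bmd(lin, sigma = sig)
  expect_equal(bi$bmd, 1.349 * sig / abs(unname(lin$pars["b1"])),
               tolerance = 1e-12)

  # Hill inversion oracle: v = 2, k = 750, h = 1, sigma = 0.2
  hill <- list(model = "hill", pars = c(b0 = 0, v = 2, k = 750, h = 1),
               rss = 1, N = 36, k = 4)
  bi_h <- compute_gene_bmd(hill, sigma = 0.2)
  delta <- 1.349 * 0.2
  expect_equal(bi_h$bmd, 750 * delta / (2 - delta), tolerance = 1e-12)
  expect_equal(bi_h$bmd, 116.9535, tolerance = 1e-4)

  # sigma -> 0 drives the BMD of any strictly monotone fit to 0
  bmds <- vapply(c(0.2, 0.02, 0.002),
                 function(s) compute_gene_bmd(lin, sigma = s)$bmd, numeric(1))
  expect_true(all(diff(bmds) < 0))
  expect_lt(bmds[3] / bmds[1], 0.02)
})

test_that("filter cascade admits exactly the constructed survivors", {
  rec <- data.frame(
    gene = paste0("g", 1:6),
    fit_p = c(0.05, 0.5, 0.5, 0.5, 0.5, 0.11),   # g1 fails fit p (<= 0.1)
    bmd = c(500, 500, 500, 2000, 500, 600),      # g4 beyond highest dose
    bmdl = c(100, 100, 100, 100, 100, 300),
    bmdu = c(300, 4000, 400, 300, 300, 600),     # g2 ratio 40 (rule is >= 40)
    max_fc = c(2, 2, 2, 2, 1.4, 2))              # g5 fails |FC| >= 1.5
  out <- apply_bmd_filters(rec, highest_dose = 1500)
  expect_identical(out$gene[out$survives], c("g3", "g6"))
  expect_false(out$pass_fit_p[1])
  expect_false(out$pass_ratio[2])   # ratio exactly 40 is excluded
  expect_false(out$pass_range[4])
  expect_false(out$pass_fc[5])
  expect_true(out$survives[6])      # fit p = 0.11 > 0.1 passes

  # pure conjunction: permuting rows permutes flags identically
  prm <- c(4, 2, 6, 1, 3, 5)
  out2 <- apply_bmd_filters(rec[prm, ], highest_dose = 1500)
  expect_identical(out2$survives, out$survives[prm])

  rec_na <- rec; rec_na$max_fc[3] <- NA
  expect_error(apply_bmd_filters(rec_na, 1500), "fold-change linkage")
})

test_that("goodness-of-fit p-values are uniform under the true model", {
  ps <- vapply(seq_len(200), function(s) {
    set.seed(s)
    y <- 5 + 0.0008 * study_doses + rnorm(length(study_doses), 0, 0.25)
    f <- fit_gene_models(y, study_doses)$linear
    f$gof_p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the generating family wins model selection at low noise", {
  hits <- vapply(seq_len(20), function(s) {
    set.seed(400 + s)
    mu <- 5 + 2 * study_doses^2 / (700^2 + study_doses^2)
    y <- mu + rnorm(length(mu), 0, 0.03)
    select_best_model(fit_gene_models(y, study_doses), 300)$model
  }, character(1))
  expect_gte(mean(hits == "hill"), 0.8)

  # the exponential needs curvature a quadratic cannot shadow before its
  # parsimony can tell; near-noise-free with a 4.5-fold top-dose rise
  hits_e <- vapply(seq_len(20), function(s) {
    set.seed(700 + s)
    y <- 5 * exp(0.001 * study_doses) + rnorm(length(study_doses), 0, 0.01)
    select_best_model(fit_gene_models(y, study_doses), 300)$model
  }, character(1))
  expect_gte(mean(hits_e == "exp2"), 0.8)
})

test_that("recovered gene BMDs track the generating BMDs across seeds", {
  rho <- vapply(seq_len(20), function(s) {
    des <- study_design(seed = 9000 + s)
    st <- simulate_expression_study(des, n_genes = 120,
                                    responsive_fraction = 0.5)
    doses <- st$meta$dose
    tr <- st$truth
    est <- vapply(tr$gene[tr$responsive], function(g) {
      best <- select_best_model(fit_gene_models(st$log2[g, ], doses), 300)
      compute_gene_bmd(best)$bmd
    }, numeric(1))
    keep <- is.finite(est)
    cor(est[keep], tr$true_bmd[tr$responsive][keep], method = "spearman")
  }, numeric(1))
  expect_gte(mean(rho >= 0.8), 0.9)
  expect_gte(min(rho), 0.7)
})

test_that("degenerate genes are flagged, not fatal", {
  flat <- fit_gene_models(rep(3, length(study_doses)), study_doses)
  expect_true(flat$linear$flat)
  expect_error(fit_gene_models(c(NA, rnorm(35)), study_doses), "non-finite")
  expect_error(fit_gene_models(rnorm(9), rep(c(0, 300, 500), each = 3)),
               "4 distinct")
})
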