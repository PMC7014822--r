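test_that("apical simulation honours flat, analytic-BMD and determinism contracts", {
  des <- study_design(seed = 4)

  flat <- true_curve("flat", a = 3, noise_cv = 0.2)
  expect_true(is.na(flat$true_bmd))
  s <- simulate_apical_series(des, flat)
  gm <- tapply(s$data$value, s$data$dose, mean)
  expect_true(all(abs(gm / 3 - 1) < 0.35))   # group means scatter around a

  # y = a exp(bx), b = log(1.1)/100: the +10% benchmark sits exactly at 100
  crv <- true_curve("exponential", a = 2, b = log(1.1) / 100, noise_cv = 0.1)
  expect_equal(crv$true_bmd, 100, tolerance = 1e-12)

  s1 <- simulate_apical_series(des, crv)
  s2 <- simulate_apical_series(des, crv)
  expect_identical(s1, s2)
  s3 <- simulate_apical_series(study_design(seed = 5), crv)
  expect_false(identical(s1$data$value, s3$data$value))
})

test_that("generator truth is consistent with the fitted BMD on noise-free data", {
  des <- study_design(seed = 1)
  crv <- true_curve("exponential", a = 3, b = 0.0015, c = 3, noise_cv = 0)
  s <- simulate_apical_series(des, crv)
  f <- fit_bmd(s$data, family = "exponential", submodels = "E4")
  expect_equal(f$bmd / s$true_bmd, 1, tolerance = 1e-3)

  crvh <- true_curve("hill", a = 2, b = 700, c = 2.5, d = 2, noise_cv = 0)
  sh <- simulate_apical_series(des, crvh)
  fh <- fit_bmd(sh$data, family = "hill", submodels = "H5")
  expect_equal(fh$bmd / sh$true_bmd, 1, tolerance = 1e-3)
})

test_that("expression generator respects fraction, noise-free limit and truth rows", {
  des <- study_design(seed = 8)
  st0 <- simulate_expression_study(des, n_genes = 120, responsive_fraction = 0)
  expect_equal(sum(st0$truth$responsive), 0)
  deg0 <- make_deg_table(st0)
  expect_lt(abs(mean(deg0$log2fc)), 0.05)     # per-dose log-ratios centre on 0

  # single responsive gene, effectively noise-free: observed top-dose log2FC
  # equals the programmed one
  st1 <- simulate_expression_study(des, n_genes = 1, responsive_fraction = 1,
                                   effect_law = list(l2fc_range = c(1, 1),
                                                     bmd_range = c(200, 200)),
                                   gene_sd = 1e-6)
  deg1 <- make_deg_table(st1)
  top <- deg1[deg1$dose == 1500, ]
  expect_equal(abs(top$log2fc), 1, tolerance = 1e-2)

  st <- simulate_expression_study(des, n_genes = 50, responsive_fraction = 0.5)
  expect_identical(st$truth$gene, rownames(st$log2))
  expect_true(all(st$truth$true_l2fc[!st$truth$responsive] == 0))
  expect_identical(st$log2,
                   simulate_expression_study(des, n_genes = 50,
                                             responsive_fraction = 0.5)$log2)
})

test_that("stand-in DE test gets the trivial cases right", {
  des <- study_design(seed = 3)
  st <- simulate_expression_study(des, n_genes = 5, responsive_fraction = 0)
  # a gene identical across all samples has log2FC 0 at every dose
  st$log2[1, ] <- 7
  deg <- make_deg_table(st)
  expect_true(all(deg$log2fc[deg$gene == "g0001"] == 0))
  # a noise-free 4-fold increase at the top dose reports log2FC = 2
  st$log2[2, ] <- 5
  st$log2[2, st$meta$dose == 1500] <- 7
  deg <- make_deg_table(st)
  expect_equal(deg$log2fc[deg$gene == "g0002" & deg$dose == 1500], 2)
  expect_equal(deg$fc[deg$gene == "g0002" & deg$dose == 1500], 4)
  # single dose level is rejected
  st2 <- list(log2 = st$log2[, st$meta$dose == 0],
              meta = st$meta[st$meta$dose == 0, ])
  expect_error(make_deg_table(st2), "non-control")
})

test_that("false-discovery proportion is controlled under the null simulation", {
  # FDR is controlled within each dose (BH is applied per dose); with no
  # responsive gene every discovery is false, so per-dose FDP is the
  # indicator of any rejection, and its average estimates the realised FDR
  fdp <- vapply(seq_len(100), function(s) {
    st <- simulate_expression_study(study_design(seed = 5000 + s),
                                    n_genes = 60, responsive_fraction = 0)
    deg <- make_deg_table(st)
    mean(vapply(split(deg$fdr, deg$dose),
                function(q) as.numeric(any(q <= 0.05)), numeric(1)))
  }, numeric(1))
  # 500 dose-by-seed draws: bound 0.05 by three binomial standard errors
  expect_lte(mean(fdp), 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("bundled study tables match their printed values", {
  k <- acetamide_tables("ki67")
  row <- k[k$series == "females_d29" & k$dose == 1500, ]
  expect_equal(row$mean, 5.69)
  expect_equal(row$sd, 0.95)
  expect_equal(row$n, 6)

  cc <- acetamide_tables("clinchem")
  alt0 <- cc[cc$endpoint == "alt" & cc$series == "males_d29" & cc$dose == 0, ]
  expect_equal(alt0$mean, 44.00)
  expect_equal(alt0$sd, 2.41)

  dg <- acetamide_tables("deg_counts")
  up <- dg[dg$series == "females_d29" & dg$direction == "up", ]
  expect_equal(up$count[order(up$dose)], c(0, 52, 109, 352, 1202))

  # the SE reading scales the stored dispersion downstream, not the file
  kse <- acetamide_tables("ki67", dispersion_kind = "se")
  expect_identical(kse$sd, k$sd)
  expect_true(all(kse$dispersion_kind == "se"))
})

test_that("design and curve validation reject impossible inputs", {
  expect_error(study_design(doses = c(100, 300)), "control|0")
  expect_error(study_design(doses = c(0, 300, 300)), "increasing")
  expect_error(study_design(n_per_group = 1), "n_per_group")
  expect_error(true_curve("exponential", a = -1, b = 0.001), "background")
  expect_error(true_curve("exponential", a = 1, b = 0.001, noise_cv = -0.1),
               "noise_cv")
  expect_error(simulate_expression_study(study_design(),
                                         effect_law = list(bmd_range = c(-5, 10))),
               "positive")
})
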