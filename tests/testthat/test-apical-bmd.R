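test_that("closed-form BMD inversions hold for exponential and Hill curves", {
  # y = a exp(bx) with b = log(1.1)/100 attains +10% exactly at dose 100
  d <- sim_apical_records(function(x) 2 * exp(log(1.1) / 100 * x),
                          cv = 1e-7, seed = 1)
  f <- fit_bmd(d, family = "exponential", submodels = "E2")
  expect_equal(f$bmd, 100, tolerance = 1e-4)
  expect_equal(unname(f$coefficients$b), log(1.1) / 100, tolerance = 1e-4)
  expect_lt(f$coefficients$sigma, 1e-5)

  # Hill: a(1 + x/(900+x)) passes +10% where x/(900+x) = 0.1, i.e. x = 100
  d2 <- sim_apical_records(function(x) 1 + x / (900 + x), cv = 1e-7, seed = 2)
  f2 <- fit_bmd(d2, family = "hill", submodels = "H4")
  expect_equal(f2$bmd, 100, tolerance = 1e-4)
})

test_that("summary-statistic fits reproduce individual-data fits", {
  d <- sim_apical_records(function(x) 3 * (1 + 2 * (1 - exp(-0.002 * x))),
                          cv = 0.2, seed = 42)
  f_ind <- fit_bmd(d, family = "exponential", submodels = "E4")
  agg <- aggregate(value ~ dose, d, function(v) c(n = length(v),
                                                  mean = mean(v),
                                                  sd = sd(v)))
  summ <- data.frame(dose = agg$dose, n = agg$value[, "n"],
                     mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  f_sum <- fit_bmd(summ, family = "exponential", submodels = "E4")
  # the lognormal moment conversion is exact only to second order, so the
  # two routes agree closely but not to machine precision
  expect_equal(f_sum$bmd, f_ind$bmd, tolerance = 5e-3)
  expect_equal(unname(f_sum$coefficients$a), unname(f_ind$coefficients$a),
               tolerance = 5e-3)
  expect_equal(f_sum$coefficients$gamma, f_ind$coefficients$gamma,
               tolerance = 5e-3)
})

test_that("background covariate is recovered and rewarded by AIC", {
  mk <- function(a, seed) {
    d <- sim_apical_records(function(x) a * (1 + 1.5 * (1 - exp(-0.0015 * x))),
                            cv = 0.15, seed = seed)
    d$series <- paste0("s", a)
    d
  }
  dat <- rbind(mk(2, 7), mk(5, 8))
  f_cov <- fit_bmd(dat, family = "exponential", submodels = "E4",
                   covariate_on = c("a", "var"))
  a_hat <- f_cov$coefficients$a
  expect_length(a_hat, 2)
  expect_equal(unname(a_hat), c(2, 5), tolerance = 0.1)
  # collapsing the covariate must cost likelihood
  dat0 <- dat; dat0$series <- "pooled"
  f_nocov <- fit_bmd(dat0, family = "exponential", submodels = "E4")
  expect_lt(f_cov$aic, f_nocov$aic)
})

test_that("BMD interval ordering, BMR monotonicity and dose-scale equivariance hold", {
  d <- sim_apical_records(function(x) 2 * (1 + 2 * (1 - exp(-0.0015 * x))),
                          cv = 0.25, seed = 11)
  f <- fit_bmd(d, family = "exponential", submodels = "E4")
  ci <- bmd(f)
  expect_true(ci$bmdl <= ci$bmd && ci$bmd <= ci$bmdu)

  # BMD strictly increasing in the benchmark response for a monotone fit
  bmds <- vapply(c(0.05, 0.10, 0.20),
                 function(b) fit_bmd(d, family = "exponential",
                                     submodels = "E4", bmr = b)$bmd,
                 numeric(1))
  expect_true(all(diff(bmds) > 0))

  # multiplying doses by s multiplies the whole interval by s
  s <- 3.7
  d2 <- d; d2$dose <- d2$dose * s
  f2 <- fit_bmd(d2, family = "exponential", submodels = "E4")
  ci2 <- bmd(f2)
  expect_equal(ci2$bmd / ci$bmd, s, tolerance = 1e-3)
  expect_equal(ci2$bmdl / ci$bmdl, s, tolerance = 5e-3)
  expect_equal(ci2$bmdu / ci$bmdu, s, tolerance = 5e-3)
})

test_that("profile-likelihood BMDL matches the dense grid-search oracle", {
  d <- sim_apical_records(function(x) 2 * (1 + 2 * (1 - exp(-0.0015 * x))),
                          cv = 0.25, seed = 23)
  f <- fit_bmd(d, family = "exponential", submodels = "E4")
  ci <- bmd(f)
  grp <- f$grp
  oracle <- grid_bmdl_oracle(grp, f)
  expect_equal(ci$bmdl, oracle, tolerance = 0.01)
})

test_that("outlier removal from a group summary reproduces exact moments", {
  set.seed(99)
  x <- c(rnorm(5, 10, 1), 40)
  adj <- outlier_adjust_summary(length(x), mean(x), sd(x), 40)
  expect_equal(adj$n, 5)
  expect_equal(adj$mean, mean(x[1:5]), tolerance = 1e-12)
  expect_equal(adj$sd, sd(x[1:5]), tolerance = 1e-10)
  expect_error(outlier_adjust_summary(6, 10, 0.1, 40), "inconsistent")
})

test_that("BMD recovery and BMDL coverage behave over repeated simulated studies", {
  true_bmd <- 400
  gamma <- 2
  b <- -log(1 - 0.10 / gamma) / true_bmd
  n_sim <- 50
  rec <- matrix(NA_real_, n_sim, 2)
  for (i in seq_len(n_sim)) {
    d <- sim_apical_records(function(x) 3 * (1 + gamma * (1 - exp(-b * x))),
                            cv = 0.25, seed = 1000 + i)
    # the reported estimator: lowest BMDL over the two model families
    fe <- fit_bmd(d, family = "exponential", submodels = c("E2", "E4"))
    fh <- fit_bmd(d, family = "hill", submodels = "H4")
    pod <- select_pod(list(bmd(fe), bmd(fh)))
    rec[i, ] <- c(if (fe$aic <= fh$aic) fe$bmd else fh$bmd, pod$bmdl)
  }
  expect_lt(abs(median(rec[, 1], na.rm = TRUE) / true_bmd - 1), 0.20)
  # nominal one-sided 95% coverage; 0.86 is the lower binomial 99% band at n=50
  expect_gte(mean(rec[, 2] <= true_bmd), 0.86)
})

test_that("degenerate inputs are rejected with informative errors", {
  d <- data.frame(dose = rep(c(0, 100, 200), each = 3), value = 5)
  expect_error(fit_bmd(data.frame(dose = rep(c(0, 100), 3),
                                  value = runif(6, 1, 2))),
               "3 distinct dose")
  expect_error(fit_bmd(data.frame(dose = rep(c(100, 200, 300), each = 3),
                                  value = runif(9, 1, 2))),
               "control")
  expect_error(fit_bmd(data.frame(dose = c(0, 100, 200), n = 6,
                                  mean = c(1, 2, 3))),
               "dispersion")
})
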