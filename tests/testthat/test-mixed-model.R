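test_that("noiseless data are recovered exactly", {
  gen <- incidence_generator(n_patients = 10, intercept = 33.5,
                             intercept_sd = 0, residual_sd = 0,
                             effects = c(tilt = -0.8, aiis_I = 0, aiis_III = 0,
                                         femoral_version = 0,
                                         acetabular_version = 0, lcea = 0),
                             seed = 7)
  tab <- simulate_incidence(gen)
  expect_equal(unique(tab$incidence_pct[tab$tilt_deg == 10]), 25.5)
  expect_equal(unique(tab$incidence_pct[tab$tilt_deg == -10]), 41.5)
  f <- fit_mixed(tab, fixed = "tilt_deg")
  expect_equal(f$coefficients$beta[2], -0.8, tolerance = 1e-8)
  expect_true(f$boundary)

  # constant response: zero slopes, intercept at the constant
  tab2 <- tab; tab2$incidence_pct <- 42
  f2 <- fit_mixed(tab2, fixed = "tilt_deg")
  expect_equal(f2$coefficients$beta[1], 42, tolerance = 1e-8)
  expect_lt(abs(f2$coefficients$beta[2]), 1e-8)
})

test_that("estimates agree with an independent REML implementation on the frozen benchmarks", {
  library(lmerTest)
  for (i in 1:5) {
    path <- system.file("extdata", sprintf("benchmark_sim_%d.csv", i),
                        package = "hipimpinge")
    tab <- read_incidence_csv(path)
    f <- fit_mixed(tab)
    d <- tab
    d$aiis_type <- relevel(factor(d$aiis_type), "II")
    lf <- lmerTest::lmer(incidence_pct ~ tilt_deg + aiis_type +
                           femoral_version + acetabular_version + lcea +
                           (1 | patient_id), data = d, REML = TRUE)
    s <- summary(lf)$coefficients
    expect_lt(max(abs(f$coefficients$beta - s[, "Estimate"]) /
                    pmax(abs(s[, "Estimate"]), 1e-8)), 1e-4)
    expect_lt(max(abs(f$coefficients$se - s[, "Std. Error"]) /
                    s[, "Std. Error"]), 1e-4)
    expect_lt(max(abs(f$coefficients$df - s[, "df"]) / s[, "df"]), 1e-4)
    expect_equal(f$reml_loglik, as.numeric(logLik(lf)), tolerance = 1e-8)
  }
})

test_that("REML is invariant to response shifts except in the intercept", {
  tab <- simulate_incidence(incidence_generator(n_patients = 30, seed = 15))
  f1 <- fit_mixed(tab)
  tab2 <- tab; tab2$incidence_pct <- tab2$incidence_pct + 7
  f2 <- fit_mixed(tab2)
  expect_equal(f2$coefficients$beta[1], f1$coefficients$beta[1] + 7,
               tolerance = 1e-6)
  expect_equal(f2$coefficients$beta[-1], f1$coefficients$beta[-1],
               tolerance = 1e-6)
  expect_equal(f2$sigma_b2, f1$sigma_b2, tolerance = 1e-6)
  expect_equal(f2$sigma_e2, f1$sigma_e2, tolerance = 1e-6)
})

test_that("error modes: singular designs and insufficient grouping", {
  tab <- simulate_incidence(incidence_generator(n_patients = 10, seed = 2))
  tab$lcea <- 30
  expect_error(fit_mixed(tab), "lcea")
  tab2 <- simulate_incidence(incidence_generator(n_patients = 10, seed = 2))
  expect_error(fit_mixed(tab2[tab2$patient_id == 1, ], fixed = "tilt_deg"),
               "2 patients")
  tab3 <- tab2[tab2$tilt_deg == 0, ]
  expect_error(fit_mixed(tab3, fixed = "tilt_deg"), "at least 2 rows")
})

test_that("the conditional AIC collapses to the marginal AIC at zero variance", {
  tab <- simulate_incidence(incidence_generator(n_patients = 25,
                                                intercept_sd = 0,
                                                residual_sd = 10, seed = 31))
  f <- fit_mixed(tab)
  fo <- hipimpinge:::.fit_fixed_only(tab, c("tilt_deg", "aiis_type",
                                            "femoral_version",
                                            "acetabular_version", "lcea"))
  # intercept variance estimated at (or next to) the boundary
  expect_lt(f$sigma_b2_ml / f$sigma_e2_ml, 1e-6)
  expect_lt(abs(f$caic - fo$aic), 0.01)
})

test_that("the conditional dof approaches one parameter per patient", {
  # strong intercept variance, tiny residual: the hat-matrix trace tends to
  # the number of patients (plus nothing for the absorbed grand mean)
  gen <- incidence_generator(n_patients = 25, intercept_sd = 40,
                             residual_sd = 0.5,
                             effects = c(tilt = 0, aiis_I = 0, aiis_III = 0,
                                         femoral_version = 0,
                                         acetabular_version = 0, lcea = 0),
                             seed = 9)
  tab <- simulate_incidence(gen)
  f <- fit_mixed(tab, fixed = NULL)          # pure intercept model
  lambda <- f$sigma_e2_ml / f$sigma_b2_ml
  Z <- stats::model.matrix(~ 0 + f$group)
  C <- cbind(f$X, Z)
  M <- crossprod(C)
  rho <- sum(diag(solve(M + diag(c(rep(0, f$p), rep(lambda, f$k)))) %*% M))
  expect_gt(rho, 24.5)
  expect_lt(rho, 25.5)
})

test_that("an irrelevant covariate does not lower the median cAIC", {
  diffs <- sapply(1:30, function(s) {
    gen <- incidence_generator(n_patients = 30,
                               effects = c(tilt = -0.8, aiis_I = 0,
                                           aiis_III = 0, femoral_version = 0,
                                           acetabular_version = 0, lcea = 0),
                               seed = 600 + s)
    tab <- simulate_incidence(gen)
    f1 <- fit_mixed(tab, fixed = "tilt_deg")
    f2 <- fit_mixed(tab, fixed = c("tilt_deg", "lcea"))
    f2$caic - f1$caic
  })
  expect_gte(median(diffs), 0)
})

test_that("model comparison reports six candidates and prefers the true structure", {
  tab <- simulate_incidence(incidence_generator(n_patients = 78, seed = 77))
  cmp <- compare_models(tab)
  expect_equal(nrow(cmp), 6)
  expect_identical(cmp$model[5], "multivariable regression")
  expect_identical(attr(cmp, "winner"), "multivariable mixed")

  # under a sparse truth (only tilt, no intercept variance) the univariate
  # tilt model is competitive
  wins <- sapply(1:20, function(s) {
    gen <- incidence_generator(n_patients = 40, intercept_sd = 0,
                               effects = c(tilt = -0.8, aiis_I = 0,
                                           aiis_III = 0, femoral_version = 0,
                                           acetabular_version = 0, lcea = 0),
                               seed = 900 + s)
    cmpi <- compare_models(simulate_incidence(gen))
    cmpi$caic[3] < cmpi$caic[6]
  })
  expect_gt(mean(wins), 0.5)

  # failed candidates are reported, comparison continues
  tabc <- tab; tabc$aiis_type <- "II"
  cmp2 <- compare_models(tabc)
  expect_false(cmp2$converged[1])
  expect_true(cmp2$converged[3])
})

test_that("the incidence generator is deterministic and well calibrated", {
  g <- incidence_generator(n_patients = 40, seed = 5)
  t1 <- simulate_incidence(g)
  t2 <- simulate_incidence(g)
  expect_identical(t1, t2)
  # expected truncation under the defaults stays below 2% (estimated at
  # large n; single small cohorts fluctuate around it)
  huge <- simulate_incidence(incidence_generator(n_patients = 60000, seed = 6))
  expect_lt(attr(huge, "truncation_fraction"), 0.02)

  # law of large numbers at the generative means
  big <- simulate_incidence(incidence_generator(n_patients = 10000, seed = 8))
  for (tau in c(-10, 0, 10)) {
    v <- big$incidence_pct[big$tilt_deg == tau]
    mu <- 48 - 0.8 * tau + 6.7 * 28 / 78
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - mu), 3 * se + 0.35)  # slight truncation shift
  }

  # lattice rounding option
  lat <- simulate_incidence(incidence_generator(n_patients = 20,
                                                lattice = TRUE, seed = 2))
  expect_true(all(abs(lat$incidence_pct * 12 / 100 -
                        round(lat$incidence_pct * 12 / 100)) < 1e-9))
})
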