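test_that("BMI range filter keeps 10 <= BMI <= 50 and logs removals", {
  tab <- data.frame(subject_id = paste0("s", 1:5),
                    bmi = c(18, 25, 9, 51, 30))
  attr(tab, "bmi_units") <- "kgm2"
  expect_message(out <- apply_inclusion_filters(tab), "removed 2 of 5")
  expect_equal(nrow(out), 3L)
  expect_equal(out$bmi, c(18, 25, 30))

  tab2 <- data.frame(subject_id = "s1", bmi = c(20, 30, 40))
  attr(tab2, "bmi_units") <- "kgm2"
  expect_message(out2 <- apply_inclusion_filters(tab2), "removed 0")
  expect_equal(out2$bmi, tab2$bmi)

  attr(tab, "bmi_units") <- "sds"
  expect_message(out3 <- apply_inclusion_filters(tab), "standardized")
  expect_equal(nrow(out3), 5L)

  tab4 <- data.frame(subject_id = "s1", bmi = 60)
  attr(tab4, "bmi_units") <- "kgm2"
  expect_error(apply_inclusion_filters(tab4), "empty cohort")
})

test_that("single-parcel regression matches hand-derived toy cases", {
  tab <- data.frame(subject_id = 1:3, bmi = c(-1, 0, 1), thk = c(1, 0, 1))
  fit <- fit_parcel_regression(tab, "thk")
  expect_equal(fit$beta, 0, tolerance = 1e-12)
  expect_equal(fit$t, 0, tolerance = 1e-12)

  # x = -2..2, y = (0,0,0,0,1): beta = 0.2, SSR = 0.4, df = 3,
  # SE = sqrt(0.4/3/10), t = sqrt(3)
  tab <- data.frame(subject_id = 1:5, bmi = -2:2, thk = c(0, 0, 0, 0, 1))
  fit <- fit_parcel_regression(tab, "thk")
  expect_equal(fit$beta, 0.2, tolerance = 1e-12)
  expect_equal(fit$t, sqrt(3), tolerance = 1e-12)
  expect_equal(fit$p, 2 * pt(sqrt(3), 3, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("beta/t/p agree with the normal-equations oracle on random designs", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(20:40, 1)
    tab <- data.frame(subject_id = seq_len(n), bmi = rnorm(n, 22, 3),
                      age = rnorm(n, 10, 1),
                      sex = sample(c("F", "M"), n, replace = TRUE),
                      thk = rnorm(n, 2.5, 0.1))
    fit <- fit_parcel_regression(tab, "thk", c("age", "sex"))
    X <- cbind(1, tab$bmi, tab$age, as.numeric(tab$sex == "M"))
    orc <- ols_oracle(X, tab$thk)
    expect_equal(fit$beta, orc$beta[2], tolerance = 1e-8)
    expect_equal(fit$t, orc$t[2], tolerance = 1e-8)
    expect_equal(fit$p, orc$p[2], tolerance = 1e-8)
  }
})

test_that("degenerate designs fail loudly", {
  set.seed(1)
  tab <- data.frame(subject_id = 1:20, bmi = rnorm(20, 22),
                    thk = rnorm(20))
  tab$bmi2 <- tab$bmi * 2
  expect_error(fit_parcel_regression(tab, "thk", "bmi2"), "collinear")
  tab$flat <- tab$bmi   # thickness an exact function of bmi
  expect_error(fit_parcel_regression(tab, "flat"), "zero residual variance")
  expect_error(fit_parcel_regression(tab[1:3, ], "thk", "bmi2"), "too few")
})

test_that("planted cohort effects are recovered within sampling error", {
  parc <- dkt_parc()
  set.seed(3)
  beta_true <- rnorm(62, 0, 0.004)
  sc <- synth_config(seed = 31, n_subjects = 500, beta_map = beta_true)
  coh <- make_cohort(parc, sc)
  omap <- build_obesity_map(coh, parc, c("age", "sex", "site"))
  within3 <- abs(omap$beta - beta_true) <= 3 * omap$se
  expect_gte(mean(within3), 0.95)
})

test_that("null cohorts give uniform p-values and no discoveries", {
  parc <- dkt_parc()
  sc <- synth_config(seed = 77, n_subjects = 200)
  coh <- make_cohort(parc, sc)
  omap <- build_obesity_map(coh, parc, c("age", "sex", "site"))
  expect_equal(sum(omap$q < 0.05, na.rm = TRUE), 0L)
  ks <- suppressWarnings(ks.test(omap$p, "punif"))
  expect_lt(unname(ks$statistic), 0.15)
  # structural invariants
  expect_true(all(sign(omap$tmap$value) == sign(omap$beta)))
  expect_true(all(omap$q >= omap$p))
})

test_that("a single strongly planted parcel dominates the t-map", {
  parc <- dkt_parc()
  beta <- setNames(rep(0, 62), parc$parcel_id)
  beta[10] <- -0.02
  sc <- synth_config(seed = 5, n_subjects = 400, beta_map = beta)
  coh <- make_cohort(parc, sc)
  omap <- build_obesity_map(coh, parc, c("age", "sex"))
  expect_equal(which.max(abs(omap$tmap$value)), 10L, ignore_attr = TRUE)
  expect_gt(abs(omap$tmap$value[10]), 6)
})

test_that("the t-map is invariant to affine covariate rescaling", {
  parc <- dkt_parc()
  sc <- synth_config(seed = 13, n_subjects = 150)
  coh <- make_cohort(parc, sc)
  m1 <- build_obesity_map(coh, parc, c("age", "ses"))
  coh2 <- coh
  coh2$age <- coh2$age * 12 + 7   # years -> months with an offset
  coh2$ses <- coh2$ses / 100
  attr(coh2, "bmi_units") <- "kgm2"
  m2 <- build_obesity_map(coh2, parc, c("age", "ses"))
  expect_equal(m1$tmap$value, m2$tmap$value, tolerance = 1e-8)
})

test_that("single-level site is dropped with a notice, map unchanged", {
  parc <- dkt_parc()
  sc <- synth_config(seed = 21, n_subjects = 120, n_sites = 1L)
  coh <- make_cohort(parc, sc)
  expect_message(m1 <- build_obesity_map(coh, parc, c("age", "site")),
                 "single level")
  m0 <- build_obesity_map(coh, parc, "age")
  expect_equal(m1$tmap$value, m0$tmap$value, tolerance = 1e-12)
  expect_false("site" %in% m1$covariates)
})

test_that("maps with and without an independent SES covariate agree", {
  parc <- dkt_parc()
  # SES has no effect on thickness here, mirroring the robustness check
  sc <- synth_config(seed = 55, n_subjects = 300,
                     covariate_effects = list(age = -0.01, sex = 0.02,
                                              site_sd = 0.02,
                                              education = 0.002, ses = 0))
  coh <- make_cohort(parc, sc)
  with_ses <- build_obesity_map(coh, parc, c("age", "sex", "ses"))
  without <- build_obesity_map(coh, parc, c("age", "sex"))
  expect_gt(cor(with_ses$tmap$value, without$tmap$value), 0.99)
})
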