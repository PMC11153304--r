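# Noiseless data from a known linear model in ilr space.
noiseless_data <- function(n = 300, seed = 21) {
  comps <- random_compositions(n, seed = seed)
  cov <- fake_covariates(n, seed = seed + 1)
  z <- ilr_transform(comps)
  beta <- c(0.4, -0.2, 0.1, -0.05)
  y <- drop(z %*% beta) + 0.02 * cov$age - 0.003 * cov$diet_score +
    0.1 * (cov$sex == "M") - 0.05 * (cov$education == "medium") +
    0.2 * (cov$smoking == "current") + 0.3 * (cov$diabetes_status == "T2D")
  list(data = cbind(as.data.frame(comps), cov, y = y), beta = beta)
}

test_that("noiseless generating coefficients are recovered exactly", {
  nd <- noiseless_data()
  fit <- fit_compositional_model(nd$data, "y")
  expect_equal(unname(fit$coefficients[paste0("ilr", 1:4)]), nd$beta,
               tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$df_residual, fit$n - length(fit$coefficients))
  # covariance symmetric PSD
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-12)
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
})

test_that("the fit is invariant to the pivot lead part", {
  ch <- small_cohort()
  d <- ch$participants
  ref <- fit_compositional_model(d, "z_cmr")
  for (lead in BEHAVIOUR_PARTS[-1]) {
    alt <- fit_compositional_model(d, "z_cmr", basis = ilr_basis(lead))
    expect_equal(fitted(alt$lm), fitted(ref$lm), tolerance = 1e-10)
    expect_equal(alt$r_squared, ref$r_squared, tolerance = 1e-10)
  }
})

test_that("predictions depend on compositions only through their ilr image", {
  nd <- noiseless_data(150)
  fit <- fit_compositional_model(nd$data, "y")
  cov1 <- list(age = 55, diet_score = 80, sex = "F", education = "low",
               smoking = "never", diabetes_status = "NGM")
  c1 <- close_composition(c(500, 300, 80, 60, 500))
  # a scaled copy has identical ilr coordinates after closure
  expect_equal(predict(fit, close_composition(c1 * 2), cov1),
               predict(fit, c1, cov1))
  # prediction differences between compositions are covariate-free
  c2 <- close_composition(c(420, 330, 100, 80, 510))
  cov2 <- list(age = 70, diet_score = 120, sex = "M", education = "high",
               smoking = "current", diabetes_status = "T2D")
  expect_equal(predict(fit, c2, cov1) - predict(fit, c1, cov1),
               predict(fit, c2, cov2) - predict(fit, c1, cov2),
               tolerance = 1e-10)
  expect_error(predict(fit, c1, modifyList(cov1, list(sex = "X"))),
               "unseen level")
})

test_that("prediction at the sample means matches the outcome mean", {
  nd <- noiseless_data(200)
  d <- nd$data
  fit <- fit_compositional_model(d, "y")
  # OLS passes through the mean of the regressors: evaluate at the ilr
  # mean (the compositional geometric mean) with per-level weights folded
  # in via averaging predictions over the observed covariate rows
  base <- geometric_mean_composition(as.matrix(d[, BEHAVIOUR_PARTS]))
  preds <- predict(fit, base,
                   d[, c("age", "diet_score", "sex", "education", "smoking",
                         "diabetes_status")])
  expect_equal(mean(preds), mean(d$y), tolerance = 1e-8)
})

test_that("waist adjustment is suppressed for waist and CMR outcomes", {
  ch <- small_cohort()
  d <- ch$participants
  d$y_waist <- d$z_waist
  plain <- fit_compositional_model(d, "y_waist",
                                   covariate_spec(adjust_waist = FALSE))
  adj <- fit_compositional_model(d, "y_waist",
                                 covariate_spec(adjust_waist = TRUE))
  expect_equal(adj$coefficients, plain$coefficients)
  # but a glycaemic outcome does gain the waist term
  with_waist <- fit_compositional_model(d, "z_fpg",
                                        covariate_spec(adjust_waist = TRUE))
  expect_true("waist" %in% names(with_waist$coefficients))
})

test_that("coefficient variance shrinks like 1/n", {
  cfg_small <- synthetic_config(n_stratum = c(NGM = 280, IGM = 80, T2D = 140),
                                seed = 31)
  cfg_big <- synthetic_config(n_stratum = c(NGM = 2240, IGM = 640, T2D = 1120),
                              seed = 32)
  v1 <- fit_compositional_model(generate_cohort(cfg_small)$participants,
                                "z_cmr")$vcov["ilr1", "ilr1"]
  v2 <- fit_compositional_model(generate_cohort(cfg_big)$participants,
                                "z_cmr")$vcov["ilr1", "ilr1"]
  slope <- log(v1 / v2) / log(4000 / 500)
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("interaction test has 4 numerator df per extra stratum level", {
  ch <- small_cohort()
  d <- ch$participants
  res_sex <- test_interaction(d, "z_cmr", stratum = "sex")
  expect_equal(res_sex$df1, 4)
  res_dm <- test_interaction(d, "z_cmr", stratum = "diabetes_status")
  expect_equal(res_dm$df1, 8)
  expect_named(res_dm$beta1_by_stratum, c("NGM", "IGM", "T2D"))
})

test_that("interaction test recovers stratum-specific slopes", {
  set.seed(77)
  n <- 800
  comps <- random_compositions(n, seed = 78)
  cov <- fake_covariates(n, seed = 79)
  z <- ilr_transform(comps)
  b1 <- ifelse(cov$sex == "M", 0.2, 0.9)
  y <- b1 * z[, "ilr1"] - 0.1 * z[, "ilr2"] + rnorm(n, 0, 0.3)
  d <- cbind(as.data.frame(comps), cov, y = y)
  res <- test_interaction(d, "y", stratum = "sex")
  expect_lt(res$p, 0.001)
  expect_true(res$significant)
  expect_lt(abs(res$beta1_by_stratum[["M"]] - 0.2), 0.15)
  expect_lt(abs(res$beta1_by_stratum[["F"]] - 0.9), 0.15)
})

test_that("stratified fits reduce to the plain fit on one stratum", {
  ch <- small_cohort()
  d <- ch$participants[ch$participants$stratum == "NGM", ]
  spec <- covariate_spec(categorical = c("sex", "education", "smoking"))
  whole <- fit_compositional_model(d, "z_cmr", spec)
  strat <- fit_stratified(d, "z_cmr",
                          covariate_spec(), stratum = "diabetes_status")
  expect_equal(names(strat), "NGM")
  expect_equal(strat$NGM$coefficients, whole$coefficients)
})

test_that("rank-deficient designs are reported, not silently dropped", {
  nd <- noiseless_data(100)
  d <- nd$data
  d$dup <- d$age  # perfectly collinear continuous covariate
  spec <- covariate_spec(continuous = c("age", "diet_score", "dup"))
  expect_error(fit_compositional_model(d, "y", spec), "collinear")
})
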