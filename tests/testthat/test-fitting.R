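# Estimation machinery: least squares, jackknife, global linkage fits.

test_that("least squares recovers exact data with zero standard error", {
  x <- 1:10
  y <- 3.5 * x
  fit <- least_squares(function(p) p[["a"]] * x - y, c(a = 1))
  expect_equal(fit$estimate[["a"]], 3.5, tolerance = 1e-9)
  expect_equal(fit$se[["a"]], 0, tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("standard errors match the closed-form linear covariance", {
  # linear model y = a + b x with known noise: cov = sigma^2 (X'X)^-1
  set.seed(71)
  x <- seq(0, 10, length.out = 40)
  y <- 2 + 0.5 * x + rnorm(40, sd = 0.3)
  fit <- least_squares(function(p) p[["a"]] + p[["b"]] * x - y, c(a = 0, b = 0))
  X <- cbind(1, x)
  sigma2 <- sum(fit$residuals^2) / (40 - 2)
  se_exact <- sqrt(diag(sigma2 * solve(crossprod(X))))
  expect_equal(unname(fit$se), unname(se_exact), tolerance = 1e-6)
  # 68.3% CI is estimate +/- one SE
  expect_equal(unname(fit$ci68[, "upper"] - fit$estimate), unname(fit$se),
               tolerance = 1e-12)
})

test_that("bounded starts converge into the interior", {
  fit <- least_squares(function(p) c(p[["a"]] - 2, 0.5 * (p[["a"]] - 2)),
                       c(a = 10), lower = 0, upper = 10)
  expect_equal(fit$estimate[["a"]], 2, tolerance = 1e-8)
})

test_that("jackknife matches the closed form for the mean", {
  expect_equal(jackknife(mean, c(1, 2, 3))$se, 0.5773503, tolerance = 1e-6)
  # jackknife SE of the mean equals s/sqrt(n) exactly
  set.seed(81)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1))
    jk <- jackknife(mean, x)
    expect_lt(abs(jk$se - stats::sd(x) / sqrt(length(x))), 1e-12)
  }
  expect_equal(jackknife(mean, rep(4, 10))$se, 0)
  expect_error(jackknife(mean, c(1, 2)), class = "ddk_domain_error")
  # data.frame datasets resample rows
  df <- data.frame(x = 1:6, y = 2 * (1:6))
  jk2 <- jackknife(function(d) coef(lm(y ~ x - 1, d))[[1]], df)
  expect_equal(jk2$se, 0, tolerance = 1e-12)
})

test_that("global linkage fit recovers ensemble and affinity from an apo/saturated pair", {
  truth <- ddk_model(k_eq = 0.67, kd_o_inactive = 10, kd_a_inactive = 100)
  obs <- data.frame(
    site = "allosteric", partner_free = c(0, Inf),
    kd_app = c(apparent_kd(truth, "allosteric", 0),
               apparent_kd(truth, "allosteric", Inf)))
  fit <- global_linkage_fit(obs, ddk_model(1, kd_o_inactive = 10,
                                           kd_a_inactive = 30),
                            free = c("k_eq", "kd_a_inactive"))
  expect_equal(fit$estimate[["k_eq"]], 0.67, tolerance = 0.01)
  expect_equal(fit$estimate[["kd_a_inactive"]], 100, tolerance = 0.01)
  expect_equal(cooperativity_factor(attr(fit, "model"))$alpha, 1.67,
               tolerance = 0.01)
})

test_that("global linkage fit recovers an intrastate coupling from noisy pairs", {
  truth <- ddk_model(k_eq = 0.67, kd_o_inactive = 10, kd_a_inactive = 100,
                     coupling_inactive = 1.8)
  kd0 <- apparent_kd(truth, "allosteric", 0)
  kdi <- apparent_kd(truth, "allosteric", Inf)
  tmpl <- ddk_model(k_eq = 0.67, kd_o_inactive = 10, kd_a_inactive = 50)
  cpl <- vapply(1:20, function(i) {
    obs <- withr::with_seed(i, data.frame(
      site = "allosteric", partner_free = c(0, Inf),
      kd_app = c(kd0, kdi) * (1 + rnorm(2, sd = 0.02))))
    g <- global_linkage_fit(obs, tmpl,
                            free = c("kd_a_inactive", "coupling_inactive"))
    g$estimate[["coupling_inactive"]]
  }, numeric(1))
  expect_lt(abs(stats::median(cpl) / 1.8 - 1), 0.10)
})

test_that("zero-noise global fits recover generating parameters across random models", {
  set.seed(91)
  for (i in 1:50) {
    truth <- ddk_model(k_eq = 10^runif(1, -1, 1),
                       kd_o_inactive = 10^runif(1, 0, 3),
                       kd_a_inactive = 10^runif(1, 0, 3))
    obs <- data.frame(
      site = "allosteric", partner_free = c(0, Inf),
      kd_app = c(apparent_kd(truth, "allosteric", 0),
                 apparent_kd(truth, "allosteric", Inf)))
    tmpl <- ddk_model(1, kd_o_inactive = truth$kd_o_inactive,
                      kd_a_inactive = 50)
    fit <- global_linkage_fit(obs, tmpl, free = c("k_eq", "kd_a_inactive"))
    expect_equal(fit$estimate[["k_eq"]], truth$k_eq, tolerance = 1e-3)
    expect_equal(fit$estimate[["kd_a_inactive"]], truth$kd_a_inactive,
                 tolerance = 1e-3)
  }
})

test_that("structurally unidentifiable requests are refused", {
  obs1 <- data.frame(site = "allosteric", partner_free = 0, kd_app = 167)
  tmpl <- ddk_model(0.67, kd_o_inactive = 10, kd_a_inactive = 100)
  expect_error(global_linkage_fit(obs1, tmpl, free = "kd_a_inactive"),
               class = "ddk_identifiability_error")
  obs2 <- data.frame(site = "allosteric", partner_free = c(0, Inf),
                     kd_app = c(167, 100))
  expect_error(
    global_linkage_fit(obs2, tmpl,
                       free = c("k_eq", "kd_a_inactive", "kd_a_active")),
    class = "ddk_identifiability_error")
})

test_that("fits are reproducible for identical inputs", {
  x <- log_grid(1, 1e4, 10)
  y <- withr::with_seed(3, dose_response_4pl(x, 1, 0, 50, 1) *
                          (1 + rnorm(10, 0.02)))
  f1 <- fit_4pl(x, y)
  f2 <- fit_4pl(x, y)
  expect_identical(f1$fit$estimate, f2$fit$estimate)
})
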