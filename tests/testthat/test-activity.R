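# Activity model, inhibition curves and synergy grids.

test_that("observed rate reflects the catalytically competent population", {
  # fully active ensemble, no inhibitors: k_obs = k_max
  m_act <- ddk_model(k_eq = 1e6, kd_o_inactive = 10, kd_a_inactive = 100)
  am <- activity_model(m_act, k_max = 2)
  expect_equal(k_obs(am, 0, 0), 2, tolerance = 1e-4)

  # saturating allosteric modulator leaving 30% inactive: k_obs = 0.70 k_max
  m30 <- allosteric_plateau_model(0.30, k_eq = 999, kd_a_inactive = 100)
  expect_equal(k_obs(activity_model(m30), 0, Inf), 0.70, tolerance = 1e-9)
  # and the 93% counterpart
  m93 <- allosteric_plateau_model(0.93, k_eq = 999, kd_a_inactive = 100)
  expect_equal(k_obs(activity_model(m93), 0, Inf), 0.07, tolerance = 1e-9)

  # k_obs stays in [0, k_max] and ligand depletion is conserved
  set.seed(51)
  for (i in 1:50) {
    m <- random_model(couplings = TRUE)
    am_i <- activity_model(m, k_max = 1)
    r <- k_obs(am_i, 10^runif(1, -1, 4), 10^runif(1, -1, 4), e_total = 20)
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("inhibition curves shift with a cooperative partner", {
  pr <- preset("aura_mb3") # threefold positive with danusertib
  grid <- log_grid(1e-3, 1e3, 15)
  alone <- inhibition_curve(pr$activity, "orthosteric", grid, partner_conc = 0)
  with_mb <- inhibition_curve(pr$activity, "orthosteric", grid,
                              partner_conc = Inf)
  mid <- function(cv) {
    ref <- cv$signal[1]
    stats::approx(cv$signal / ref, cv$ligand_total, xout = 0.5)$y
  }
  expect_lt(mid(with_mb), mid(alone)) # left-shifted at saturating partner

  # non-binding orthosteric ligand: flat curve at the uninhibited rate
  m_free <- ddk_model(k_eq = 0.67, kd_a_active = 100, kd_a_inactive = 100)
  flat <- inhibition_curve(activity_model(m_free), "orthosteric", grid)
  expect_lt(diff(range(flat$signal)), 1e-12)
  expect_equal(flat$signal[1], 0.67 / 1.67, tolerance = 1e-9)

  expect_error(inhibition_curve(pr$activity, "orthosteric", numeric(0)),
               class = "ddk_domain_error")
})

test_that("dose-for-residual from the 4PL matches the direct numeric root", {
  # dilute-enzyme regime (no ligand depletion): the mechanistic inhibition
  # curve is exactly hyperbolic in dose and the two routes must agree
  pr <- preset("aura_mb2")
  et <- 0.02
  grid <- c(0, log_grid(1e-3, 1e3, 14))
  cv <- inhibition_curve(pr$activity, "orthosteric", grid, e_total = et)
  p <- fit_4pl(grid, cv$signal)
  d_fit <- conc_at_residual(p, 0.10, reference = cv$signal[1])
  d_direct <- stats::uniroot(function(x) {
    k_obs(pr$activity, x, 0, e_total = et) - 0.10 * cv$signal[1]
  }, c(1e-4, 1e4), tol = 1e-10)$root
  expect_equal(d_fit, d_direct, tolerance = 0.02)
})

test_that("synergy grids report dose reductions matching the cooperativity", {
  # degenerate 1x1 grid at zero doses: single k_max entry, no metrics
  m_act <- ddk_model(k_eq = 1e6, kd_o_inactive = 10, kd_a_inactive = 100)
  g0 <- synergy_grid(activity_model(m_act, k_max = 3), 0, 0)
  expect_equal(dim(g0$k_obs), c(1L, 1L))
  expect_equal(g0$k_obs[1, 1], 3, tolerance = 1e-4)
  expect_true(is.na(g0$dose_for_residual[1]))

  # positively cooperative preset: fold-reduction > 1 and increasing
  pr <- preset("aura_mb3")
  kd_a <- apparent_kd(pr$model, "allosteric", 0)
  o_grid <- c(0, log_grid(1e-3, 1e3, 13))
  a_grid <- c(0, 10 * kd_a, 1000 * kd_a)
  sg <- synergy_grid(pr$activity, o_grid, a_grid)
  expect_true(all(diff(sg$fold_reduction) > 0))
  expect_gt(sg$fold_reduction[2], 1)

  # negatively cooperative preset: required orthosteric dose does not drop
  prn <- preset("abl64_510_imatinib_asciminib")
  kd_an <- apparent_kd(prn$model, "allosteric", 0)
  o_gridn <- c(0, log_grid(1, 1e6, 13))
  sgn <- synergy_grid(prn$activity, o_gridn, c(0, 1000 * kd_an))
  expect_gte(sgn$dose_for_residual[2], sgn$dose_for_residual[1] * 0.99)
})

test_that("synergy direction matches the linkage cooperativity direction", {
  set.seed(61)
  n_checked <- 0
  while (n_checked < 100) {
    m <- random_model(couplings = TRUE)
    cf <- cooperativity_factor(m)
    if (abs(log(cf$alpha)) < 0.2) next # skip near-neutral models
    am <- activity_model(m, k_max = 1)
    # residual-activity dose of the orthosteric ligand alone vs at
    # saturating allosteric partner, via direct numeric roots
    dose_at <- function(partner) {
      ref <- k_obs(am, 0, partner)
      if (ref < 1e-6) return(NA_real_)
      tryCatch(stats::uniroot(function(x) k_obs(am, x, partner) - 0.5 * ref,
                              c(1e-8, 1e12), tol = 1e-9)$root,
               error = function(e) NA_real_)
    }
    d0 <- dose_at(0); d1 <- dose_at(Inf)
    if (is.na(d0) || is.na(d1)) next
    n_checked <- n_checked + 1
    if (cf$direction == "positive") expect_lt(d1, d0) else expect_gt(d1, d0)
  }
})
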