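# Two-state linkage partition function: populations, apparent Kds,
# cooperativity and the thermodynamic-cycle symmetry.

test_that("apo ensemble and single-ligand populations match direct enumeration", {
  m <- ddk_model(k_eq = 0.67, kd_o_inactive = 10, kd_a_inactive = 100)
  expect_equal(fraction_active(m, 0, 0), 0.67 / 1.67, tolerance = 1e-12)

  # inactive-exclusive orthosteric ligand at free = kd: weights
  # {active: 0.67, inactive: 1, inactive.O: 1}
  w <- statistical_weights(m, 10, 0)
  expect_equal(unname(w[["inactive.orth"]]), 1 / 2.67, tolerance = 1e-12)
  expect_equal(fraction_active(m, 10, 0), 0.67 / 2.67, tolerance = 1e-12)

  # zero ligand: doubly bound species exactly zero
  w0 <- statistical_weights(m, 0, 0)
  expect_identical(unname(w0[["inactive.both"]]), 0)
  expect_identical(unname(w0[["active.both"]]), 0)

  # ligand that binds neither state simply never binds
  m_non <- ddk_model(k_eq = 0.67, kd_o_inactive = 10)
  w_non <- statistical_weights(m_non, 10, 1e6)
  expect_equal(sum(w_non[c("inactive.allo", "inactive.both",
                           "active.allo", "active.both")]), 0)

  expect_error(statistical_weights(m, -1, 0), class = "ddk_domain_error")
})

test_that("populations sum to one across random models and concentrations", {
  set.seed(11)
  for (i in 1:1000) {
    m <- random_model(couplings = TRUE)
    s <- sum(statistical_weights(m, 10^runif(1, -2, 5), 10^runif(1, -2, 5)))
    expect_lt(abs(s - 1), 1e-12)
  }
})

test_that("apparent Kd closed form agrees with the numeric half-occupancy root", {
  m <- ddk_model(k_eq = 0.67, kd_a_inactive = 100, kd_o_inactive = 10)
  expect_equal(apparent_kd(m, "allosteric", 0), 167, tolerance = 1e-9)
  expect_equal(apparent_kd(m, "allosteric", Inf), 100, tolerance = 1e-9)

  # state-independent ligand: partition function factorizes
  m_ind <- ddk_model(k_eq = 0.67, kd_o_inactive = 10,
                     kd_a_active = 50, kd_a_inactive = 50)
  expect_equal(apparent_kd(m_ind, "allosteric", 0), 50, tolerance = 1e-12)
  expect_equal(apparent_kd(m_ind, "allosteric", 1234), 50, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:200) {
    m <- random_model(couplings = TRUE)
    partner <- sample(c(0, 10^runif(1, 0, 4)), 1)
    for (site in c("orthosteric", "allosteric")) {
      closed <- apparent_kd(m, site, partner)
      numeric <- apparent_kd_numeric(m, site, partner)
      expect_lt(abs(closed / numeric - 1), 1e-9)
    }
  }

  m_non <- ddk_model(k_eq = 0.67, kd_o_inactive = 10)
  expect_error(apparent_kd(m_non, "allosteric", 0), class = "ddk_nonbinder_error")
})

test_that("cooperativity factor: pure selection, state independence, coupling", {
  # inactive-exclusive pair: alpha = 1 + k_eq exactly (limit law)
  m <- ddk_model(k_eq = 0.67, kd_o_inactive = 10, kd_a_inactive = 100)
  cf <- cooperativity_factor(m, "allosteric")
  expect_equal(cf$alpha, 1.67, tolerance = 1e-12)
  expect_identical(cf$direction, "positive")
  for (keq in c(0.1, 0.67, 3, 42)) {
    mi <- ddk_model(k_eq = keq, kd_o_inactive = 3, kd_a_inactive = 200)
    expect_equal(cooperativity_factor(mi)$alpha, 1 + keq, tolerance = 1e-12)
  }

  # state-independent allosteric ligand is unaffected by any partner
  m_ind <- ddk_model(k_eq = 0.67, kd_o_inactive = 10,
                     kd_a_active = 50, kd_a_inactive = 50)
  cf_ind <- cooperativity_factor(m_ind)
  expect_equal(cf_ind$alpha, 1, tolerance = 1e-12)
  expect_identical(cf_ind$direction, "none")

  # intrastate coupling multiplies the pure-selection alpha
  m3 <- ddk_model(k_eq = 0.67, kd_o_inactive = 10, kd_a_inactive = 100,
                  coupling_inactive = 3)
  expect_equal(cooperativity_factor(m3)$alpha, 1.67 * 3, tolerance = 1e-12)

  expect_error(
    cooperativity_factor(ddk_model(0.67, kd_o_inactive = 10)),
    class = "ddk_nonbinder_error")
})

test_that("thermodynamic cycle closes: alpha is site-symmetric", {
  set.seed(31)
  for (i in 1:1000) {
    m <- random_model(couplings = TRUE)
    a_o <- cooperativity_factor(m, "orthosteric")$alpha
    a_a <- cooperativity_factor(m, "allosteric")$alpha
    if (a_a == 0) {
      # mutually exclusive pair: alpha = 0 at both sites
      expect_identical(a_o, 0)
    } else {
      expect_lt(abs(a_o / a_a - 1), 1e-9)
    }
  }
})

test_that("finite near-saturating partner approximates the analytic limit", {
  # the site's apparent Kd measured at 100x and 1000x the partner's
  # (ensemble) apparent Kd agrees within 1% -- the "identical affinity at a
  # higher preincubation concentration" control for simultaneous binding
  set.seed(41)
  n_checked <- 0
  while (n_checked < 100) {
    m <- random_model(couplings = TRUE)
    y0 <- max(apparent_kd(m, "orthosteric", 0),
              apparent_kd(m, "orthosteric", Inf))
    if (!is.finite(y0)) next # mutually exclusive pair: no saturation plateau
    n_checked <- n_checked + 1
    k100 <- apparent_kd(m, "allosteric", 100 * y0)
    k1000 <- apparent_kd(m, "allosteric", 1000 * y0)
    expect_lt(abs(k100 / k1000 - 1), 0.01)
  }
})

test_that("inactive-preferring pairs tighten monotonically with partner dose", {
  m <- ddk_model(k_eq = 0.67, kd_o_active = 500, kd_o_inactive = 5,
                 kd_a_active = 2000, kd_a_inactive = 50)
  partner <- c(0, 1, 5, 20, 100, 1000, 1e5)
  kds <- vapply(partner, function(y) apparent_kd(m, "allosteric", y), numeric(1))
  expect_true(all(diff(kds) <= 1e-12))
})
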