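# Shared fixtures: random model generation and independent numeric oracles.

# Random linkage model; both ligands bind at least one state so apparent Kds
# and cooperativity are defined.
random_model <- function(couplings = FALSE) {
  rkd <- function() 10^stats::runif(1, -1, 4)
  maybe_inf <- function(kd) if (stats::runif(1) < 0.25) Inf else kd
  repeat {
    m <- try(ddk_model(
      k_eq = 10^stats::runif(1, -2, 2),
      kd_o_active = maybe_inf(rkd()), kd_o_inactive = maybe_inf(rkd()),
      kd_a_active = maybe_inf(rkd()), kd_a_inactive = maybe_inf(rkd()),
      coupling_active = if (couplings) 10^stats::runif(1, -1, 1) else 1,
      coupling_inactive = if (couplings) 10^stats::runif(1, -1, 1) else 1
    ), silent = TRUE)
    ok <- !inherits(m, "try-error") &&
      (is.finite(m$kd_o_active) || is.finite(m$kd_o_inactive)) &&
      (is.finite(m$kd_a_active) || is.finite(m$kd_a_inactive))
    if (ok) return(m)
  }
}

# Fractional occupancy of one site from the species populations (the
# independent route used to cross-check the closed-form apparent Kd).
occupancy_numeric <- function(model, site, free_site, partner_free) {
  if (site == "orthosteric") {
    w <- statistical_weights(model, free_site, partner_free)
    sum(w[c("inactive.orth", "inactive.both", "active.orth", "active.both")])
  } else {
    w <- statistical_weights(model, partner_free, free_site)
    sum(w[c("inactive.allo", "inactive.both", "active.allo", "active.both")])
  }
}

# Numeric half-occupancy root of the population-based occupancy, bracketed
# on [kd_min*1e-6, kd_max*1e6].
apparent_kd_numeric <- function(model, site, partner_free) {
  kds <- if (site == "orthosteric") {
    c(model$kd_o_active, model$kd_o_inactive)
  } else {
    c(model$kd_a_active, model$kd_a_inactive)
  }
  kds <- kds[is.finite(kds)]
  lo <- min(kds) * 1e-6
  hi <- max(kds) * 1e6
  stats::uniroot(function(x) occupancy_numeric(model, site, x, partner_free) - 0.5,
                 c(lo, hi), tol = lo * 1e-12)$root
}

# Independent mass-balance oracle for the 1:1 complex: root in free ligand.
bound_complex_numeric <- function(p_total, l_total, kd) {
  if (l_total == 0 || p_total == 0) return(0)
  f <- function(fl) fl + p_total * fl / (kd + fl) - l_total
  fl <- stats::uniroot(f, c(0, l_total), tol = 1e-13 * max(1, l_total))$root
  l_total - fl
}

log_grid <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))
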