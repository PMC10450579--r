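## Two-state conformational-selection linkage model.
##
## The protein exchanges between an active (open) and an inactive (closed)
## conformation with unliganded equilibrium constant k_eq = [active]/[inactive].
## An orthosteric and an allosteric ligand each bind with state-specific
## dissociation constants; doubly bound species may carry an additional
## intrastate coupling factor.  With both couplings equal to 1 every
## cooperativity between the two ligands arises purely from the shift of the
## conformational ensemble.

#' Names of the eight linkage species
#'
#' Two conformational states times orthosteric bound/free times allosteric
#' bound/free, in the fixed order used throughout the package.
#' @keywords internal
.ddk_species <- c(
  "inactive.apo", "inactive.orth", "inactive.allo", "inactive.both",
  "active.apo", "active.orth", "active.allo", "active.both"
)

#' Two-state double-drugging linkage model
#'
#' Constructs the central model object: a two-state conformational ensemble
#' with state-specific dissociation constants for one orthosteric and one
#' allosteric ligand, plus optional intrastate coupling factors for the
#' doubly bound species.
#'
#' @param k_eq Unliganded active/inactive equilibrium constant
#'   (dimensionless, finite and > 0).  `k_eq = 0.67` means 40% active.
#' @param kd_o_active,kd_o_inactive Dissociation constants (nM) of the
#'   orthosteric ligand for the active and inactive state.  `Inf` encodes
#'   "does not bind that state".
#' @param kd_a_active,kd_a_inactive As above for the allosteric ligand.
#' @param coupling_active,coupling_inactive Dimensionless factors (>= 0)
#'   multiplying the statistical weight of the doubly bound species within
#'   each state.  Defaults of 1 give pure conformational-selection coupling.
#' @return An object of class `ddk_model`.
#' @examples
#' m <- ddk_model(k_eq = 0.67, kd_o_inactive = 10, kd_a_inactive = 100)
#' fraction_active(m, 0, 0)  # 0.67/1.67
#' @export
ddk_model <- function(k_eq,
                      kd_o_active = Inf, kd_o_inactive = Inf,
                      kd_a_active = Inf, kd_a_inactive = Inf,
                      coupling_active = 1, coupling_inactive = 1) {
  stopifnot(is.numeric(k_eq), length(k_eq) == 1L, is.finite(k_eq), k_eq > 0)
  for (kd in list(kd_o_active, kd_o_inactive, kd_a_active, kd_a_inactive)) {
    stopifnot(is.numeric(kd), length(kd) == 1L, !is.na(kd), kd > 0)
  }
  for (cpl in list(coupling_active, coupling_inactive)) {
    stopifnot(is.numeric(cpl), length(cpl) == 1L, is.finite(cpl), cpl >= 0)
  }
  structure(
    list(
      k_eq = k_eq,
      kd_o_active = kd_o_active, kd_o_inactive = kd_o_inactive,
      kd_a_active = kd_a_active, kd_a_inactive = kd_a_inactive,
      coupling_active = coupling_active, coupling_inactive = coupling_inactive
    ),
    class = "ddk_model"
  )
}

#' @export
print.ddk_model <- function(x, ...) {
  cat("Two-state double-drugging linkage model\n")
  cat(sprintf("  k_eq (active/inactive): %g  (%.1f%% active apo)\n",
              x$k_eq, 100 * x$k_eq / (1 + x$k_eq)))
  cat(sprintf("  orthosteric Kd (nM): active %g, inactive %g\n",
              x$kd_o_active, x$kd_o_inactive))
  cat(sprintf("  allosteric  Kd (nM): active %g, inactive %g\n",
              x$kd_a_active, x$kd_a_inactive))
  cat(sprintf("  coupling: active %g, inactive %g\n",
              x$coupling_active, x$coupling_inactive))
  invisible(x)
}

.ddk_check_conc <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(errorCondition(sprintf("%s must be a single non-negative number", what),
                        class = c("ddk_domain_error", "error", "condition")))
  }
}

#' Raw statistical weights of the eight species (unnormalized)
#' @keywords internal
.ddk_raw_weights <- function(model, free_o, free_a) {
  xo_i <- free_o / model$kd_o_inactive # 0 when kd = Inf
  xa_i <- free_a / model$kd_a_inactive
  xo_a <- free_o / model$kd_o_active
  xa_a <- free_a / model$kd_a_active
  k <- model$k_eq
  w <- c(
    1, xo_i, xa_i, xo_i * xa_i * model$coupling_inactive,
    k, k * xo_a, k * xa_a, k * xo_a * xa_a * model$coupling_active
  )
  names(w) <- .ddk_species
  w
}

#' Equilibrium species populations
#'
#' Populations of the eight species (2 states x orthosteric bound/free x
#' allosteric bound/free) at given free ligand concentrations.  Weights are
#' proportional to: inactive apo = 1, active apo = `k_eq`, each bound ligand
#' multiplies its state's weight by `free/kd_state`, and doubly bound species
#' additionally carry the state's coupling factor.
#'
#' @param model A [ddk_model()].
#' @param free_o,free_a Free (not total) ligand concentrations, nM.
#' @return Named numeric vector of 8 fractions summing to 1, class
#'   `ddk_species_distribution`.
#' @export
statistical_weights <- function(model, free_o, free_a) {
  stopifnot(inherits(model, "ddk_model"))
  .ddk_check_conc(free_o, "free_o")
  .ddk_check_conc(free_a, "free_a")
  if (!is.finite(free_o) || !is.finite(free_a)) {
    stop(errorCondition(
      "free concentrations must be finite; saturation is an analytic limit handled by apparent_kd()/k_obs()",
      class = c("ddk_domain_error", "error", "condition")
    ))
  }
  w <- .ddk_raw_weights(model, free_o, free_a)
  structure(w / sum(w), class = "ddk_species_distribution")
}

#' @export
print.ddk_species_distribution <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' Fraction of the ensemble in the active state
#'
#' @inheritParams statistical_weights
#' @return Fraction in \[0, 1\].
#' @export
fraction_active <- function(model, free_o = 0, free_a = 0) {
  p <- statistical_weights(model, free_o, free_a)
  sum(p[grepl("^active", names(p))])
}

## Closed-form apparent Kd.
##
## For a given site at fixed free partner concentration y, occupancy of the
## site is theta = x*D(y) / (N(y) + x*D(y)) with
##   N(y) = sum_s b_s (1 + y/kd_partner,s)
##   D(y) = sum_s b_s (1/kd_site,s) (1 + c_s * y/kd_partner,s)
## (b_s = k_eq for active, 1 for inactive), so the half-occupancy free
## concentration is N(y)/D(y).  The saturating-partner limit is
## N_inf = sum_s b_s/kd_partner,s, D_inf = sum_s b_s c_s/(kd_site,s kd_partner,s).
.ddk_kd_app <- function(model, site, partner_free) {
  b <- c(inactive = 1, active = model$k_eq)
  cc <- c(inactive = model$coupling_inactive, active = model$coupling_active)
  if (site == "orthosteric") {
    kd_site <- c(inactive = model$kd_o_inactive, active = model$kd_o_active)
    kd_part <- c(inactive = model$kd_a_inactive, active = model$kd_a_active)
  } else {
    kd_site <- c(inactive = model$kd_a_inactive, active = model$kd_a_active)
    kd_part <- c(inactive = model$kd_o_inactive, active = model$kd_o_active)
  }
  if (all(!is.finite(kd_site))) {
    stop(errorCondition(
      sprintf("the %s ligand binds neither state: no finite half-saturation", site),
      class = c("ddk_nonbinder_error", "error", "condition")
    ))
  }
  partner_binds <- any(is.finite(kd_part))
  if (is.infinite(partner_free) && partner_binds) {
    num <- sum(b / kd_part)
    den <- sum(b * cc / (kd_site * kd_part))
    if (den == 0) return(Inf) # site cannot bind with partner saturating
    return(num / den)
  }
  y <- if (is.infinite(partner_free)) 0 else partner_free
  num <- sum(b * (1 + y / kd_part))
  den <- sum(b / kd_site * (1 + cc * y / kd_part))
  num / den
}

#' Apparent dissociation constant of one site
#'
#' Free concentration of the site's ligand at which its fractional occupancy
#' is one half, for a fixed free concentration of the partner ligand at the
#' other site.  `partner_free = Inf` evaluates the saturating-partner limit
#' analytically.
#'
#' @param model A [ddk_model()].
#' @param site `"orthosteric"` or `"allosteric"`.
#' @param partner_free Free partner concentration (nM), or `Inf` for
#'   saturation.
#' @return Apparent Kd in nM (free-ligand scale).
#' @export
apparent_kd <- function(model, site = c("orthosteric", "allosteric"),
                        partner_free = 0) {
  stopifnot(inherits(model, "ddk_model"))
  site <- match.arg(site)
  if (!is.numeric(partner_free) || length(partner_free) != 1L ||
      is.na(partner_free) || partner_free < 0) {
    stop(errorCondition("partner_free must be >= 0 (Inf = saturating)",
                        class = c("ddk_domain_error", "error", "condition")))
  }
  .ddk_kd_app(model, site, partner_free)
}

#' Cooperativity factor between the two sites
#'
#' `alpha` is the fold-change of a site's apparent Kd caused by saturating
#' the partner site: `apparent_kd(partner absent) / apparent_kd(partner
#' saturating)`.  `alpha > 1` means positive cooperativity (the partner
#' tightens binding), `alpha < 1` negative.  By thermodynamic-cycle closure
#' alpha is identical for the two sites.
#'
#' @param model A [ddk_model()].
#' @param site Site whose apparent Kd is followed (the result is
#'   site-symmetric up to rounding).
#' @param tol Relative tolerance inside which `alpha` counts as 1 ("none").
#' @return List of class `ddk_cooperativity` with elements `alpha`,
#'   `direction` (`"positive"`, `"negative"`, `"none"`), `kd_apo`,
#'   `kd_saturated`, `site`.
#' @export
cooperativity_factor <- function(model, site = c("orthosteric", "allosteric"),
                                 tol = 1e-8) {
  stopifnot(inherits(model, "ddk_model"))
  site <- match.arg(site)
  o_binds <- is.finite(model$kd_o_active) || is.finite(model$kd_o_inactive)
  a_binds <- is.finite(model$kd_a_active) || is.finite(model$kd_a_inactive)
  if (!o_binds || !a_binds) {
    stop(errorCondition(
      "cooperativity is undefined when a ligand binds neither state",
      class = c("ddk_nonbinder_error", "error", "condition")
    ))
  }
  kd0 <- .ddk_kd_app(model, site, 0)
  kdinf <- .ddk_kd_app(model, site, Inf)
  alpha <- kd0 / kdinf
  direction <- if (abs(alpha - 1) <= tol) "none"
    else if (alpha > 1) "positive" else "negative"
  structure(
    list(alpha = alpha, direction = direction,
         kd_apo = kd0, kd_saturated = kdinf, site = site),
    class = "ddk_cooperativity"
  )
}

#' @export
print.ddk_cooperativity <- function(x, ...) {
  fold <- if (x$alpha >= 1) x$alpha else 1 / x$alpha
  cat(sprintf(
    "Cooperativity at the %s site: alpha = %.4g (%s, %.3g-fold)\n",
    x$site, x$alpha, x$direction, fold))
  cat(sprintf("  apparent Kd: %.4g nM (partner absent) -> %.4g nM (partner saturating)\n",
              x$kd_apo, x$kd_saturated))
  invisible(x)
}
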