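## Mapping ensemble populations to catalytic activity under kcat/Km
## conditions, inhibition curves, and orthosteric x allosteric synergy
## grids.

#' Catalytic activity model on top of a linkage model
#'
#' Observed rate is `k_max` times the population-weighted catalytic
#' competence of the eight linkage species.  The default weights encode an
#' active-site inhibitor and an inactive (closing-competent) state that is
#' catalytically silent: active-state species without the orthosteric
#' ligand have weight 1, every inactive-state species and every
#' orthosteric-bound species weight 0.  Allosteric-bound active-state
#' species keep weight 1 (a purely conformational allosteric modulator
#' does not block catalysis).
#'
#' @param linkage A [ddk_model()].
#' @param k_max Maximal rate (min^-1) of a fully active, uninhibited
#'   ensemble.
#' @param species_weights Optional named vector over the 8 species
#'   (`inactive.apo`, `inactive.orth`, `inactive.allo`, `inactive.both`,
#'   `active.apo`, `active.orth`, `active.allo`, `active.both`), each in
#'   \[0, 1\].
#' @return Object of class `ddk_activity_model`.
#' @export
activity_model <- function(linkage, k_max = 1, species_weights = NULL) {
  stopifnot(inherits(linkage, "ddk_model"), k_max > 0)
  if (is.null(species_weights)) {
    species_weights <- stats::setNames(numeric(8), .ddk_species)
    species_weights[c("active.apo", "active.allo")] <- 1
  }
  stopifnot(setequal(names(species_weights), .ddk_species),
            all(species_weights >= 0), all(species_weights <= 1))
  structure(list(linkage = linkage, k_max = k_max,
                 species_weights = species_weights[.ddk_species]),
            class = "ddk_activity_model")
}

## Species populations at allosteric (or orthosteric) saturation: only the
## species carrying the saturating ligand retain nonzero weight.
.ddk_weights_saturated <- function(model, sat_site, free_other) {
  k <- model$k_eq
  if (sat_site == "allosteric") {
    if (!is.finite(model$kd_a_active) && !is.finite(model$kd_a_inactive)) {
      stop(errorCondition("allosteric ligand binds neither state: saturation undefined",
                          class = c("ddk_nonbinder_error", "error", "condition")))
    }
    xo_i <- free_other / model$kd_o_inactive
    xo_a <- free_other / model$kd_o_active
    w <- c(
      inactive.apo = 0, inactive.orth = 0,
      inactive.allo = 1 / model$kd_a_inactive,
      inactive.both = xo_i * model$coupling_inactive / model$kd_a_inactive,
      active.apo = 0, active.orth = 0,
      active.allo = k / model$kd_a_active,
      active.both = k * xo_a * model$coupling_active / model$kd_a_active
    )
  } else {
    if (!is.finite(model$kd_o_active) && !is.finite(model$kd_o_inactive)) {
      stop(errorCondition("orthosteric ligand binds neither state: saturation undefined",
                          class = c("ddk_nonbinder_error", "error", "condition")))
    }
    xa_i <- free_other / model$kd_a_inactive
    xa_a <- free_other / model$kd_a_active
    w <- c(
      inactive.apo = 0,
      inactive.orth = 1 / model$kd_o_inactive,
      inactive.allo = 0,
      inactive.both = xa_i * model$coupling_inactive / model$kd_o_inactive,
      active.apo = 0,
      active.orth = k / model$kd_o_active,
      active.allo = 0,
      active.both = k * xa_a * model$coupling_active / model$kd_o_active
    )
  }
  w[.ddk_species] / sum(w)
}

.ddk_occ <- function(pops) {
  c(o = sum(pops[c("inactive.orth", "inactive.both",
                   "active.orth", "active.both")]),
    a = sum(pops[c("inactive.allo", "inactive.both",
                   "active.allo", "active.both")]))
}

## Populations at total (not free) ligand concentrations: exact ligand
## depletion at enzyme concentration e_total via nested monotone root finds.
## Either total may be Inf (analytic saturation).
.ddk_populations_total <- function(model, o_total, a_total, e_total) {
  pops_at <- function(fo, fa) {
    if (is.infinite(fo) && is.infinite(fa)) {
      # both sites saturating: only doubly bound species survive
      w <- stats::setNames(numeric(8), .ddk_species)
      w["inactive.both"] <- model$coupling_inactive /
        (model$kd_o_inactive * model$kd_a_inactive)
      w["active.both"] <- model$k_eq * model$coupling_active /
        (model$kd_o_active * model$kd_a_active)
      if (sum(w) == 0) {
        stop(errorCondition("no species can carry both saturating ligands",
                            class = c("ddk_nonbinder_error", "error", "condition")))
      }
      return(w / sum(w))
    }
    if (is.infinite(fa)) .ddk_weights_saturated(model, "allosteric", fo)
    else if (is.infinite(fo)) .ddk_weights_saturated(model, "orthosteric", fa)
    else unclass(statistical_weights(model, fo, fa))
  }
  solve_o <- function(fa) {
    if (o_total == 0) return(0)
    if (is.infinite(o_total)) return(Inf)
    g <- function(fo) fo + e_total * .ddk_occ(pops_at(fo, fa))[["o"]] - o_total
    lo <- max(0, o_total - e_total)
    if (g(lo) >= 0) return(lo)
    stats::uniroot(g, c(lo, o_total),
                   tol = max(1e-14, 1e-13 * o_total))$root
  }
  if (a_total == 0 || is.infinite(a_total)) {
    fa <- if (a_total == 0) 0 else Inf
    fo <- solve_o(fa)
    return(list(populations = pops_at(fo, fa), free_o = fo, free_a = fa))
  }
  h <- function(fa) {
    fo <- solve_o(fa)
    fa + e_total * .ddk_occ(pops_at(fo, fa))[["a"]] - a_total
  }
  lo <- max(0, a_total - e_total)
  fa <- if (h(lo) >= 0) lo else {
    stats::uniroot(h, c(lo, a_total), tol = max(1e-14, 1e-13 * a_total))$root
  }
  fo <- solve_o(fa)
  list(populations = pops_at(fo, fa), free_o = fo, free_a = fa)
}

#' Observed rate under kcat/Km conditions
#'
#' `k_obs = k_max * sum(species_weight * population)` with free ligand
#' concentrations obtained from exact mass balance at the stated enzyme
#' concentration (ligand depletion handled exactly).  Either total may be
#' `Inf` to evaluate the saturating limit analytically.
#'
#' @param model A [activity_model()].
#' @param o_total,a_total Total orthosteric / allosteric ligand (nM).
#' @param e_total Total enzyme (nM, > 0); the assays behind this model use
#'   20 nM.
#' @return Rate (same units as `k_max`).
#' @export
k_obs <- function(model, o_total, a_total, e_total = 20) {
  stopifnot(inherits(model, "ddk_activity_model"), e_total > 0,
            o_total >= 0, a_total >= 0)
  sol <- .ddk_populations_total(model$linkage, o_total, a_total, e_total)
  unname(model$k_max * sum(model$species_weights * sol$populations))
}

#' Inhibition (or activation) curve over a concentration grid
#'
#' Evaluates [k_obs()] pointwise over a grid of one ligand's total
#' concentration at a fixed partner concentration (possibly `Inf`,
#' mirroring assays run at saturating modulator).
#'
#' @param model A [activity_model()].
#' @param site Which ligand is varied: `"orthosteric"` or `"allosteric"`.
#' @param conc_grid Strictly increasing total concentrations (nM).
#' @param partner_conc Fixed total partner concentration (nM or `Inf`).
#' @param e_total Total enzyme (nM).
#' @return A [titration_curve()] whose `signal` column holds `k_obs`.
#' @export
inhibition_curve <- function(model, site = c("orthosteric", "allosteric"),
                             conc_grid, partner_conc = 0, e_total = 20) {
  site <- match.arg(site)
  if (length(conc_grid) == 0) {
    stop(errorCondition("concentration grid is empty",
                        class = c("ddk_domain_error", "error", "condition")))
  }
  rates <- vapply(conc_grid, function(x) {
    if (site == "orthosteric") k_obs(model, x, partner_conc, e_total)
    else k_obs(model, partner_conc, x, e_total)
  }, numeric(1))
  titration_curve(conc_grid, rates)
}

#' Orthosteric x allosteric synergy grid
#'
#' Full `k_obs` matrix over the two dose grids, plus per-allosteric-level
#' dose-reduction metrics: for each allosteric level the orthosteric dose
#' needed for `residual` (default 10%) activity is obtained from a 4PL fit
#' of that row, referenced to the row's own zero-orthosteric rate, and the
#' fold-reduction is taken relative to the zero-allosteric row.  Rows whose
#' plateau never reaches the target are reported as `NA` ("unreachable"),
#' not as errors.  Dose metrics require at least 5 orthosteric doses.
#'
#' @param model A [activity_model()].
#' @param o_grid,a_grid Total dose grids (nM); `a_grid` entries may include
#'   `Inf` (saturating modulator).
#' @param e_total Total enzyme (nM).
#' @param residual Residual-activity fraction for the dose metric.
#' @return Object of class `ddk_synergy_grid`: `o_grid`, `a_grid`, `k_obs`
#'   (matrix, rows = allosteric levels), `dose_for_residual`,
#'   `fold_reduction`, `residual`.
#' @export
synergy_grid <- function(model, o_grid, a_grid, e_total = 20,
                         residual = 0.10) {
  stopifnot(length(o_grid) >= 1, length(a_grid) >= 1)
  mat <- matrix(NA_real_, nrow = length(a_grid), ncol = length(o_grid),
                dimnames = list(a_nM = signif(a_grid, 6),
                                o_nM = signif(o_grid, 6)))
  for (i in seq_along(a_grid)) {
    for (j in seq_along(o_grid)) {
      mat[i, j] <- k_obs(model, o_grid[j], a_grid[i], e_total)
    }
  }
  res <- .ddk_synergy_metrics(o_grid, a_grid, mat, model, e_total, residual)
  structure(
    list(o_grid = o_grid, a_grid = a_grid, k_obs = mat,
         dose_for_residual = res$dose, fold_reduction = res$fold,
         residual = residual),
    class = "ddk_synergy_grid"
  )
}

## Per-row 4PL dose metrics of a k_obs matrix.
.ddk_synergy_metrics <- function(o_grid, a_grid, mat, model = NULL,
                                 e_total = 20, residual = 0.10) {
  n_a <- length(a_grid)
  dose <- rep(NA_real_, n_a)
  if (length(o_grid) >= 5) {
    for (i in seq_len(n_a)) {
      ref <- if (!is.null(model) && o_grid[1] != 0) {
        k_obs(model, 0, a_grid[i], e_total)
      } else mat[i, 1]
      d <- tryCatch({
        p <- fit_4pl(o_grid, mat[i, ])
        conc_at_residual(p, residual, reference = ref)
      }, error = function(e) NA_real_)
      dose[i] <- d
    }
  }
  fold <- dose[1] / dose
  list(dose = dose, fold = fold)
}

#' @export
print.ddk_synergy_grid <- function(x, ...) {
  cat("Synergy grid:", length(x$a_grid), "allosteric x",
      length(x$o_grid), "orthosteric levels\n")
  print(signif(x$k_obs, 4))
  if (!all(is.na(x$dose_for_residual))) {
    cat(sprintf("Orthosteric dose for %.0f%% residual activity (nM):\n",
                100 * x$residual))
    print(signif(stats::setNames(x$dose_for_residual, signif(x$a_grid, 6)), 4))
    cat("Fold dose-reduction vs zero allosteric:\n")
    print(signif(stats::setNames(x$fold_reduction, signif(x$a_grid, 6)), 4))
  }
  invisible(x)
}
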