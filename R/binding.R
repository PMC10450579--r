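## Mass-balance solvers shared by the binding experiments.

#' Tight-binding (quadratic) complex concentration
#'
#' Exact concentration of a 1:1 complex from total protein, total ligand and
#' the dissociation constant, i.e. the physical root of the mass-balance
#' quadratic.  Computed in the numerically stable form
#' `2*P*L / (b + sqrt(b^2 - 4*P*L))` with `b = P + L + K`, which remains
#' accurate in the stoichiometric (`K -> 0`) limit.
#'
#' @param p_total,l_total Total protein and ligand concentrations (same
#'   units; the result is in those units).
#' @param kd Dissociation constant (same units).
#' @return Complex concentration; never exceeds `min(p_total, l_total)`.
#' @export
bound_complex <- function(p_total, l_total, kd) {
  if (any(p_total < 0) || any(l_total < 0) || any(kd < 0)) {
    stop(errorCondition("concentrations and kd must be non-negative",
                        class = c("ddk_domain_error", "error", "condition")))
  }
  b <- p_total + l_total + kd
  disc <- b * b - 4 * p_total * l_total
  disc[disc < 0] <- 0
  out <- 2 * p_total * l_total / (b + sqrt(disc))
  pmin(out, pmin(p_total, l_total))
}

#' Free concentrations for two ligands competing for one site
#'
#' Solves the coupled mass balance for protein P and two mutually exclusive
#' ligands L (ligand of interest) and C (competitor) binding one site:
#' the unique physical root in free protein of
#' `P_free * (1 + L_t/(kd_l + P_free) + C_t/(kd_c + P_free)) = P_t`
#' (a cubic in `P_free`), bracketed on `[0, P_t]` and polished by Newton
#' steps to machine precision.  With `c_total = 0` the result coincides with
#' [bound_complex()] to rounding.
#'
#' @param p_total,l_total,c_total Totals (same concentration units).
#' @param kd_l,kd_c Dissociation constants of L and C (same units; `Inf`
#'   encodes a non-binder).
#' @return List with `free_p`, `free_l`, `free_c`, `complex_l`, `complex_c`.
#' @export
free_concentrations_competitive <- function(p_total, l_total, c_total,
                                            kd_l, kd_c) {
  for (v in list(p_total, l_total, c_total)) .ddk_check_conc(v, "concentration")
  stopifnot(kd_l > 0, kd_c > 0)
  if (p_total == 0) {
    return(list(free_p = 0, free_l = l_total, free_c = c_total,
                complex_l = 0, complex_c = 0))
  }
  f <- function(p) {
    p * (1 + l_total / (kd_l + p) + c_total / (kd_c + p)) - p_total
  }
  root <- stats::uniroot(f, c(0, p_total),
                         tol = .Machine$double.eps * max(1, p_total))$root
  # Newton polish (f is smooth and increasing on [0, p_total])
  fprime <- function(p) {
    1 + l_total * kd_l / (kd_l + p)^2 + c_total * kd_c / (kd_c + p)^2
  }
  for (i in 1:3) {
    step <- f(root) / fprime(root)
    cand <- root - step
    if (is.finite(cand) && cand >= 0 && cand <= p_total) root <- cand
  }
  if (!is.finite(root)) {
    stop(errorCondition("competitive mass balance has no physical root",
                        class = c("ddk_solver_error", "error", "condition")))
  }
  # complexes from the cancellation-free forms L_t*P/(kd+P), C_t*P/(kd+P)
  list(
    free_p = root,
    free_l = l_total * kd_l / (kd_l + root),
    free_c = c_total * kd_c / (kd_c + root),
    complex_l = l_total * root / (kd_l + root),
    complex_c = c_total * root / (kd_c + root)
  )
}

#' Apparent Kd under competitive replacement
#'
#' Analytic competitive-shift formula for measuring a tight binder against a
#' prebound weak competitor at the same site:
#' `kd_apparent = kd_strong * (1 + competitor_free / kd_weak)`.
#'
#' @param kd_strong Intrinsic Kd of the tight ligand.
#' @param kd_weak Kd of the weak competitor (same units as
#'   `competitor_free`).
#' @param competitor_free Free competitor concentration.
#' @return Apparent Kd in the units of `kd_strong`.
#' @export
apparent_kd_competitive <- function(kd_strong, kd_weak, competitor_free) {
  stopifnot(kd_strong >= 0, kd_weak > 0, competitor_free >= 0)
  kd_strong * (1 + competitor_free / kd_weak)
}

#' Tight-binding fluorescence titration parameters
#'
#' @param f0 Baseline fluorescence (a.u.).
#' @param amp Fluorescence amplitude at full saturation (a.u., sign free).
#' @param e_total Total enzyme concentration (nM, > 0).
#' @param kd Dissociation constant (nM).
#' @return Object of class `ddk_fret_params`.
#' @export
fret_params <- function(f0, amp, e_total, kd) {
  stopifnot(is.numeric(f0), is.numeric(amp), e_total > 0, kd > 0)
  structure(list(f0 = f0, amp = amp, e_total = e_total, kd = kd),
            class = "ddk_fret_params")
}

#' Predicted fluorescence of a tight-binding titration
#'
#' Quadratic (tight-binding) binding equation for a fluorescence titration
#' at fixed enzyme concentration:
#' `F = F0 + A * ((I + Et + Kd) - sqrt((I + Et + Kd)^2 - 4*Et*I)) / (2*Et)`,
#' i.e. baseline plus amplitude times the bound fraction of the enzyme.
#'
#' @param i_conc Total ligand (titrant) concentrations, nM; vectorized.
#' @param params A [fret_params()].
#' @return Fluorescence values (a.u.).
#' @export
fret_signal <- function(i_conc, params) {
  stopifnot(inherits(params, "ddk_fret_params"))
  if (any(i_conc < 0)) {
    stop(errorCondition("ligand concentrations must be non-negative",
                        class = c("ddk_domain_error", "error", "condition")))
  }
  bound <- bound_complex(params$e_total, i_conc, params$kd)
  params$f0 + params$amp * bound / params$e_total
}

#' Titration curve container
#'
#' Pairs a strictly increasing, non-negative concentration axis with a
#' measured signal (fluorescence, or observed rate for inhibition curves).
#'
#' @param ligand_total Total ligand concentrations (nM), strictly increasing.
#' @param signal Signal values, same length.
#' @return Object of class `ddk_titration_curve` (a data.frame).
#' @export
titration_curve <- function(ligand_total, signal) {
  stopifnot(length(ligand_total) == length(signal))
  if (any(ligand_total < 0) || any(diff(ligand_total) <= 0)) {
    stop(errorCondition(
      "ligand_total must be non-negative and strictly increasing",
      class = c("ddk_domain_error", "error", "condition")))
  }
  structure(data.frame(ligand_total = ligand_total, signal = signal),
            class = c("ddk_titration_curve", "data.frame"))
}
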