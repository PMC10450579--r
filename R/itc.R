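## Isothermal titration calorimetry: injection protocol, forward heat model
## (direct and competitive-replacement) and the one-site fitter.
##
## Unit conventions: volumes in uL, cell/syringe concentrations in uM, the
## ligand-of-interest Kd in nM, competitor Kd in uM, enthalpies in kJ/mol,
## heats in uJ.  With those units q[uJ] = 1e-3 * dh * V0 * conc.

#' ITC injection protocol
#'
#' @param cell_volume Active cell volume V0 (uL).
#' @param cell_conc Titrand (protein) concentration in the cell (uM).
#' @param syringe_conc Titrant (ligand) concentration in the syringe (uM).
#' @param injection_volumes Vector of injection volumes (uL), length >= 5.
#' @param temperature Temperature (K).
#' @return Object of class `ddk_itc_protocol`.
#' @export
itc_protocol <- function(cell_volume, cell_conc, syringe_conc,
                         injection_volumes, temperature = 298.15) {
  stopifnot(cell_volume > 0, cell_conc > 0, syringe_conc > 0,
            temperature > 0, all(injection_volumes > 0))
  if (length(injection_volumes) < 5) {
    stop(errorCondition("at least 5 injections are required",
                        class = c("ddk_domain_error", "error", "condition")))
  }
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes = injection_volumes,
                 temperature = temperature),
            class = "ddk_itc_protocol")
}

#' One-site ITC model parameters
#'
#' @param kd Dissociation constant (nM, > 0).
#' @param dh Molar binding enthalpy (kJ/mol).
#' @param n Binding stoichiometry (sites per protein, > 0).
#' @param q_offset Constant per-injection background heat (uJ).
#' @return Object of class `ddk_itc_params`.
#' @export
itc_onesite_params <- function(kd, dh, n = 1, q_offset = 0) {
  stopifnot(kd > 0, n > 0, is.finite(dh), is.finite(q_offset))
  structure(list(kd = kd, dh = dh, n = n, q_offset = q_offset),
            class = "ddk_itc_params")
}

#' Competitive-replacement scheme
#'
#' Describes a weak competitor prebound in the cell, used to measure a
#' too-tight titrant by displacement.
#'
#' @param kd_weak Competitor Kd (uM).
#' @param dh_weak Competitor binding enthalpy (kJ/mol).
#' @param competitor_total Total competitor concentration in the cell (uM).
#' @return Object of class `ddk_competition_scheme`.
#' @export
competition_scheme <- function(kd_weak, dh_weak, competitor_total) {
  stopifnot(kd_weak > 0, is.finite(dh_weak), competitor_total >= 0)
  structure(list(kd_weak = kd_weak, dh_weak = dh_weak,
                 competitor_total = competitor_total),
            class = "ddk_competition_scheme")
}

#' Per-injection heats container
#'
#' @param heats Per-injection heats (uJ).
#' @param discard_first Should downstream fits drop the first injection (the
#'   usual instrument practice)?
#' @return Object of class `ddk_itc_thermogram`.
#' @export
itc_thermogram <- function(heats, discard_first = TRUE) {
  stopifnot(is.numeric(heats), length(heats) >= 1)
  structure(list(heats = as.numeric(heats),
                 discard_first = isTRUE(discard_first)),
            class = "ddk_itc_thermogram")
}

#' Simulate an ITC thermogram
#'
#' Forward model for a one-site titration, optionally against a prebound
#' weak competitor (competitive replacement).  Each injection of volume v
#' dilutes the existing cell contents by `(1 - v/V0)` and adds titrant
#' `syringe_conc * v/V0` (perfusion displacement).  The heat of injection i
#' is referenced to the bound fraction of the initial cell protein:
#' `q_i = 1e-3 * V0 * n * cell_conc * (dh * d(fb_L) + dh_weak * d(fb_C)) +
#' q_offset`, so the cumulative heat at titrant excess approaches
#' `n * dh * V0 * cell_conc` (see the methods vignette for the convention).
#'
#' @param protocol An [itc_protocol()].
#' @param params An [itc_onesite_params()].
#' @param scheme Optional [competition_scheme()].
#' @return A [itc_thermogram()] with `discard_first = FALSE` (simulated
#'   injections have no prefilling artifact).
#' @export
simulate_itc <- function(protocol, params, scheme = NULL) {
  stopifnot(inherits(protocol, "ddk_itc_protocol"),
            inherits(params, "ddk_itc_params"))
  v0 <- protocol$cell_volume
  kd_l <- params$kd / 1000 # nM -> uM
  has_comp <- !is.null(scheme) && scheme$competitor_total > 0
  if (!is.null(scheme)) stopifnot(inherits(scheme, "ddk_competition_scheme"))
  p_t <- protocol$cell_conc
  l_t <- 0
  c_t <- if (has_comp) scheme$competitor_total else 0
  kd_c <- if (has_comp) scheme$kd_weak else Inf
  sites0 <- params$n * protocol$cell_conc
  eq <- function(p, l, c) {
    sites <- params$n * p
    if (sites <= 0) return(c(fb_l = 0, fb_c = 0))
    if (!has_comp) {
      return(c(fb_l = bound_complex(sites, l, kd_l) / sites, fb_c = 0))
    }
    sol <- free_concentrations_competitive(sites, l, c, kd_l, kd_c)
    c(fb_l = sol$complex_l / sites, fb_c = sol$complex_c / sites)
  }
  fb <- eq(p_t, l_t, c_t)
  heats <- numeric(length(protocol$injection_volumes))
  for (i in seq_along(heats)) {
    d <- 1 - protocol$injection_volumes[i] / v0
    p_t <- p_t * d
    c_t <- c_t * d
    l_t <- l_t * d + protocol$syringe_conc * protocol$injection_volumes[i] / v0
    fb_new <- eq(p_t, l_t, c_t)
    q <- 1e-3 * v0 * sites0 *
      (params$dh * (fb_new["fb_l"] - fb["fb_l"]))
    if (has_comp) {
      q <- q + 1e-3 * v0 * sites0 *
        scheme$dh_weak * (fb_new["fb_c"] - fb["fb_c"])
    }
    heats[i] <- q + params$q_offset
    fb <- fb_new
  }
  itc_thermogram(heats, discard_first = FALSE)
}

#' Fit the one-site model to an ITC thermogram
#'
#' Least-squares fit of `kd`, `dh`, `n` and `q_offset` against the
#' [simulate_itc()] forward model (the same protocol and, if supplied, the
#' same known competition scheme).  The first injection is dropped when the
#' thermogram's `discard_first` flag is set.  `kd` is fitted on the log
#' scale; starting values are taken from a heat-based heuristic and refined
#' by deterministic multistart on failure.  A Wiseman c-value
#' (`cell_conc/kd`) outside `[1, 1e4]` is flagged `"c_value"` as poorly
#' identified.
#'
#' @param thermogram An [itc_thermogram()].
#' @param protocol The [itc_protocol()] used to record it.
#' @param init Optional [itc_onesite_params()] start values.
#' @param scheme Optional known [competition_scheme()] (competitive
#'   replacement with fixed competitor parameters).
#' @return A `ddk_fit` with natural-scale estimates `kd` (nM), `dh`, `n`,
#'   `q_offset`.
#' @export
fit_itc_onesite <- function(thermogram, protocol, init = NULL, scheme = NULL) {
  stopifnot(inherits(thermogram, "ddk_itc_thermogram"),
            inherits(protocol, "ddk_itc_protocol"))
  q <- thermogram$heats
  if (length(q) != length(protocol$injection_volumes)) {
    stop(errorCondition("thermogram length does not match the protocol",
                        class = c("ddk_domain_error", "error", "condition")))
  }
  keep <- if (thermogram$discard_first) -1L else seq_along(q)
  q_used <- q[keep]
  if (length(q_used) < 5) {
    stop(errorCondition("fewer than 5 usable injections",
                        class = c("ddk_domain_error", "error", "condition")))
  }
  if (stats::sd(q_used) < 1e-12 * (1 + max(abs(q_used)))) {
    stop(errorCondition(
      "degenerate thermogram: injection heats carry no binding signal",
      class = c("ddk_degenerate_data_error", "ddk_fit_error",
                "error", "condition")
    ))
  }
  if (is.null(init)) {
    dh0 <- sum(q_used - stats::median(utils::tail(q_used, 3))) /
      (1e-3 * protocol$cell_volume * protocol$cell_conc)
    if (!is.finite(dh0) || abs(dh0) < 1e-6) dh0 <- -10
    init <- itc_onesite_params(kd = protocol$cell_conc * 100, # c = 10
                               dh = dh0, n = 1,
                               q_offset = stats::median(utils::tail(q_used, 2)))
  }
  theta0 <- c(log_kd = log(init$kd), dh = init$dh, n = init$n,
              q_offset = init$q_offset)
  resid_fn <- function(theta) {
    p <- itc_onesite_params(kd = exp(theta[["log_kd"]]), dh = theta[["dh"]],
                            n = theta[["n"]], q_offset = theta[["q_offset"]])
    sim <- simulate_itc(protocol, p, scheme = scheme)
    sim$heats[keep] - q_used
  }
  fit <- least_squares(resid_fn, theta0,
                       lower = c(log(1e-4), -1e4, 0.05, -1e6),
                       upper = c(log(1e9), 1e4, 20, 1e6))
  fit <- .ddk_backtransform(fit, "log_kd")
  cval <- fit$estimate[["n"]] * protocol$cell_conc * 1000 / fit$estimate[["kd"]]
  if (cval < 1 || cval > 1e4) {
    fit$flags <- c(fit$flags, "c_value")
    warning(sprintf(
      "c-value %.3g outside [1, 1e4]: Kd poorly identified by this protocol",
      cval))
  }
  fit
}
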