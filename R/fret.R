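## Fitting tight-binding fluorescence titrations.

#' Fit the tight-binding quadratic to a fluorescence titration
#'
#' Least-squares estimation of the baseline `f0`, amplitude `amp` and
#' dissociation constant `kd` of [fret_signal()] with the enzyme
#' concentration fixed (the experimental design: enzyme is known, typically
#' 10 nM).  `kd` is fitted on the log scale.  A fitted `kd` below half the
#' enzyme concentration is flagged `"near_stoichiometric"`: in that regime
#' the curve approaches a step function and `kd` is poorly identified.
#'
#' @param curve A [titration_curve()] (at least 6 points spanning the
#'   half-saturation region).
#' @param e_total Fixed total enzyme concentration (nM).
#' @param init Optional [fret_params()] start values.
#' @return A `ddk_fit` with natural-scale estimates `f0`, `amp`, `kd` (nM).
#' @export
fit_fret <- function(curve, e_total, init = NULL) {
  stopifnot(inherits(curve, "ddk_titration_curve"), e_total > 0)
  x <- curve$ligand_total
  y <- curve$signal
  if (length(x) < 6) {
    stop(errorCondition("at least 6 titration points are required",
                        class = c("ddk_domain_error", "error", "condition")))
  }
  if (is.null(init)) {
    f0_0 <- y[1]
    amp_0 <- y[length(y)] - y[1]
    if (abs(amp_0) < 1e-12) amp_0 <- 1
    half <- f0_0 + amp_0 / 2
    kd_0 <- x[which.min(abs(y - half))]
    if (kd_0 <= 0) kd_0 <- max(e_total, stats::median(x[x > 0]))
    init <- fret_params(f0 = f0_0, amp = amp_0, e_total = e_total, kd = kd_0)
  }
  theta0 <- c(f0 = init$f0, amp = init$amp, log_kd = log(init$kd))
  resid_fn <- function(theta) {
    p <- fret_params(f0 = theta[["f0"]], amp = theta[["amp"]],
                     e_total = e_total, kd = exp(theta[["log_kd"]]))
    fret_signal(x, p) - y
  }
  fit <- least_squares(resid_fn, theta0,
                       lower = c(-Inf, -Inf, log(1e-6)),
                       upper = c(Inf, Inf, log(1e9)))
  fit <- .ddk_backtransform(fit, "log_kd")
  if (fit$estimate[["kd"]] < e_total / 2) {
    fit$flags <- c(fit$flags, "near_stoichiometric")
    warning(sprintf(
      "fitted Kd (%.3g nM) is below half the enzyme concentration (%g nM): titration is near-stoichiometric and Kd is poorly identified",
      fit$estimate[["kd"]], e_total))
  }
  fit
}
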