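## Four-parameter logistic dose-response fitting and its closed-form
## inversion to dose-for-residual-activity metrics.

#' Evaluate the four-parameter logistic
#'
#' `y = bottom + (top - bottom) / (1 + (x/ic50)^hill)`, with the `x = 0`
#' limit resolved by the sign of `hill` (`top` for `hill > 0`).
#'
#' @param x Doses (nM), non-negative; vectorized.
#' @param top,bottom Plateaus (response units).
#' @param ic50 Midpoint dose (nM, > 0).
#' @param hill Hill slope (nonzero).
#' @return Response values.
#' @export
dose_response_4pl <- function(x, top, bottom, ic50, hill) {
  stopifnot(ic50 > 0, hill != 0)
  out <- numeric(length(x))
  z <- x > 0
  out[z] <- bottom + (top - bottom) / (1 + (x[z] / ic50)^hill)
  out[!z] <- if (hill > 0) top else bottom
  out
}

#' Fit a four-parameter dose-response model
#'
#' Least-squares 4PL fit with `ic50` on the log scale, followed by
#' canonicalization to `hill > 0` (swapping `top`/`bottom` and negating
#' `hill` describes the same curve).  If the observed responses do not come
#' within 20% of both fitted plateaus the result is flagged
#' `"plateaus_unresolved"`.
#'
#' @param doses Dose vector (nM, >= 5 points).
#' @param responses Observed responses, same length.
#' @param init Optional named list/vector with `top`, `bottom`, `ic50`,
#'   `hill`.
#' @return Object of class `ddk_4pl`: elements `top`, `bottom`, `ic50`,
#'   `hill` plus the underlying `fit` (`ddk_fit`, natural scale).
#' @export
fit_4pl <- function(doses, responses, init = NULL) {
  stopifnot(length(doses) == length(responses), all(doses >= 0))
  if (length(doses) < 5) {
    stop(errorCondition("at least 5 dose-response points are required",
                        class = c("ddk_domain_error", "error", "condition")))
  }
  if (is.null(init)) {
    top0 <- max(responses)
    bot0 <- min(responses)
    mid <- (top0 + bot0) / 2
    pos <- doses[doses > 0]
    ic0 <- pos[which.min(abs(responses[doses > 0] - mid))]
    if (length(ic0) == 0 || ic0 <= 0) ic0 <- stats::median(pos)
    init <- list(top = top0, bottom = bot0, ic50 = ic0, hill = 1)
  }
  theta0 <- c(top = init$top, bottom = init$bottom,
              log_ic50 = log(init$ic50), hill = init$hill)
  resid_fn <- function(theta) {
    dose_response_4pl(doses, top = theta[["top"]], bottom = theta[["bottom"]],
                      ic50 = exp(theta[["log_ic50"]]),
                      hill = theta[["hill"]]) - responses
  }
  fit <- least_squares(resid_fn, theta0,
                       lower = c(-Inf, -Inf, log(1e-8), -20),
                       upper = c(Inf, Inf, log(1e12), 20))
  fit <- .ddk_backtransform(fit, "log_ic50")
  est <- fit$estimate
  if (est[["hill"]] < 0) { # canonicalize: same curve with hill > 0
    perm <- c("bottom", "top", "ic50", "hill")
    fit$estimate <- stats::setNames(est[perm], c("top", "bottom", "ic50", "hill"))
    fit$estimate[["hill"]] <- -fit$estimate[["hill"]]
    fit$se <- stats::setNames(fit$se[perm], c("top", "bottom", "ic50", "hill"))
    fit$ci68 <- fit$ci68[perm, , drop = FALSE]
    rownames(fit$ci68) <- c("top", "bottom", "ic50", "hill")
    est <- fit$estimate
  }
  rng <- est[["top"]] - est[["bottom"]]
  if (is.finite(rng) && rng > 0) {
    if ((min(responses) - est[["bottom"]]) > 0.2 * rng ||
        (est[["top"]] - max(responses)) > 0.2 * rng) {
      fit$flags <- c(fit$flags, "plateaus_unresolved")
    }
  }
  structure(
    list(top = unname(est[["top"]]), bottom = unname(est[["bottom"]]),
         ic50 = unname(est[["ic50"]]), hill = unname(est[["hill"]]),
         fit = fit),
    class = "ddk_4pl"
  )
}

#' @export
print.ddk_4pl <- function(x, ...) {
  cat(sprintf(
    "4PL fit: top %.4g, bottom %.4g, IC50 %.4g nM, hill %.3g\n",
    x$top, x$bottom, x$ic50, x$hill))
  if (length(x$fit$flags)) cat("  flags:", paste(x$fit$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Dose required for a residual-activity level
#'
#' Closed-form inversion of a fitted 4PL at the response `r * reference`
#' (e.g. `r = 0.10` for the dose giving 10% residual activity relative to
#' the uninhibited rate of the same curve).
#'
#' @param params A `ddk_4pl` (or any list with `top`, `bottom`, `ic50`,
#'   `hill`, with `hill > 0` for a descending curve on dose).
#' @param r Residual fraction in (0, 1).
#' @param reference Reference (uninhibited) response; defaults to the fitted
#'   `top`.
#' @return Dose (nM).  If the target response lies outside the open interval
#'   `(bottom, top)` the plateau cannot reach it and an error of class
#'   `ddk_unreachable_residual_error` is signalled.
#' @export
conc_at_residual <- function(params, r, reference = params$top) {
  stopifnot(r > 0, r < 1)
  y <- r * reference
  if (!(y > params$bottom && y < params$top)) {
    stop(errorCondition(
      sprintf("residual target %.4g lies outside the fitted plateaus (%.4g, %.4g): unreachable residual",
              y, params$bottom, params$top),
      class = c("ddk_unreachable_residual_error", "error", "condition")
    ))
  }
  params$ic50 * ((params$top - y) / (y - params$bottom))^(1 / params$hill)
}
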