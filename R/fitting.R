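## Shared estimation machinery: Levenberg-Marquardt least squares with
## linearized covariance, deterministic multistart, jackknife errors and
## global multi-condition linkage fits.

#' Nonlinear least squares with multistart and linearized errors
#'
#' Minimizes `sum(fn(par)^2)` with `minpack.lm::nls.lm` inside box bounds.
#' If the supplied start fails to converge, up to `multistart - 1`
#' additional starts are drawn deterministically (log-uniform over positive
#' finite bounds, uniform otherwise) under a fixed seed, and the best
#' converged solution is returned.  Standard errors come from the linearized
#' covariance at the optimum; the 68.3% confidence interval is estimate
#' plus/minus one standard error.
#'
#' @param fn Function of the parameter vector returning residuals.
#' @param init Named numeric start values (finite, inside bounds).
#' @param lower,upper Box bounds (recycled to `length(init)`).
#' @param multistart Total number of starts to attempt (>= 1).
#' @param ms_seed Seed for the deterministic multistart draws.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return Object of class `ddk_fit`: `estimate`, `se`, `ci68` (matrix with
#'   columns `lower`, `upper`), `residuals`, `objective` (residual sum of
#'   squares), `converged`, `nobs`, `npar`, `flags` (character vector of
#'   diagnostic flags), `info`, `message`.
#' @export
least_squares <- function(fn, init, lower = -Inf, upper = Inf,
                          multistart = 5, ms_seed = 1234L, maxiter = 300) {
  npar <- length(init)
  lower <- rep_len(lower, npar)
  upper <- rep_len(upper, npar)
  stopifnot(all(is.finite(init)), all(init >= lower), all(init <= upper))
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter,
                                     ftol = 1e-12, ptol = 1e-12, gtol = 1e-8)
  run1 <- function(start) {
    # a start exactly on a bound can stall the Marquardt step: nudge inside
    eps <- 1e-8 * pmax(1, abs(start))
    start <- pmin(pmax(start, lower + pmin(eps, (upper - lower) / 4)),
                  upper - pmin(eps, (upper - lower) / 4))
    tryCatch(minpack.lm::nls.lm(par = start, fn = fn,
                                lower = lower, upper = upper, control = ctrl),
             error = function(e) NULL)
  }
  # info 1-3: xtol/ftol convergence; 4: gradient orthogonal to the
  # residuals (an exact-fit minimum, or a stall worth a restart)
  ok <- function(f) !is.null(f) && f$info %in% 1:4 && all(is.finite(f$par))
  strict <- function(f) !is.null(f) && f$info %in% 1:3 && all(is.finite(f$par))
  best <- run1(init)
  if (!strict(best) && multistart > 1) {
    starts <- withr::with_seed(ms_seed, lapply(seq_len(multistart - 1), function(i) {
      vapply(seq_len(npar), function(j) {
        lo <- lower[j]; up <- upper[j]
        if (is.finite(lo) && is.finite(up)) {
          if (lo > 0) exp(stats::runif(1, log(lo), log(up)))
          else stats::runif(1, lo, up)
        } else {
          sc <- max(1, abs(init[j]))
          x <- init[j] + stats::rnorm(1, sd = sc)
          min(max(x, lo), up)
        }
      }, numeric(1))
    }))
    for (s in starts) {
      names(s) <- names(init)
      cand <- run1(s)
      if (ok(cand) && (!ok(best) || cand$deviance < best$deviance)) best <- cand
    }
  }
  if (!ok(best)) {
    stop(errorCondition(
      paste0("least_squares failed to converge after ", multistart, " starts",
             if (!is.null(best)) paste0(" (last message: ", best$message, ")")),
      class = c("ddk_fit_error", "error", "condition")
    ))
  }
  est <- best$par
  names(est) <- names(init)
  flags <- character(0)
  se <- tryCatch({
    cf <- suppressWarnings(summary(best)$coefficients)
    as.numeric(cf[, "Std. Error"])
  }, error = function(e) rep(NA_real_, npar))
  if (anyNA(se)) flags <- c(flags, "se_unavailable")
  names(se) <- names(init)
  ci <- cbind(lower = est - se, upper = est + se)
  structure(
    list(estimate = est, se = se, ci68 = ci,
         residuals = as.numeric(best$fvec), objective = best$deviance,
         converged = TRUE, nobs = length(best$fvec), npar = npar,
         flags = flags, info = best$info, message = best$message),
    class = "ddk_fit"
  )
}

#' @export
print.ddk_fit <- function(x, ...) {
  cat("Least-squares fit (", x$nobs, " obs, ", x$npar, " parameters)\n", sep = "")
  tab <- cbind(estimate = x$estimate, se = x$se,
               ci68_lower = x$ci68[, 1], ci68_upper = x$ci68[, 2])
  print(signif(tab, 6))
  cat(sprintf("  RSS = %.6g, converged = %s\n", x$objective, x$converged))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

## Back-transform log-scale parameters of a ddk_fit to the natural scale
## (delta method for the SE).
.ddk_backtransform <- function(fit, log_names) {
  for (nm in log_names) {
    raw <- sub("^log_", "", nm)
    i <- match(nm, names(fit$estimate))
    est <- exp(fit$estimate[i])
    fit$se[i] <- est * fit$se[i]
    fit$estimate[i] <- est
    fit$ci68[i, ] <- c(est - fit$se[i], est + fit$se[i])
    names(fit$estimate)[i] <- raw
    names(fit$se)[i] <- raw
  }
  rownames(fit$ci68) <- names(fit$estimate)
  fit
}

#' Jackknife (leave-one-out) standard errors of a fitted quantity
#'
#' Refits after deleting each observation in turn and reports the jackknife
#' standard error `sqrt((n-1)/n * sum((theta_i - theta_bar)^2))` together
#' with the jackknife bias estimate `(n-1) * (theta_bar - theta_full)`.
#'
#' @param fit_fn Function taking the dataset and returning a (possibly
#'   named) numeric vector of estimates.
#' @param dataset A data.frame (rows are observations) or a vector/list.
#' @return Object of class `ddk_jackknife`: `estimates` (matrix, one row per
#'   leave-one-out refit), `se`, `bias`, `full`, `n`, `failed` (indices of
#'   failed refits).  A single failed refit is tolerated and dropped; more
#'   than one is an error.
#' @export
jackknife <- function(fit_fn, dataset) {
  n <- NROW(dataset)
  if (n < 3) {
    stop(errorCondition("jackknife needs at least 3 observations",
                        class = c("ddk_domain_error", "error", "condition")))
  }
  drop1 <- if (is.data.frame(dataset)) {
    function(i) dataset[-i, , drop = FALSE]
  } else {
    function(i) dataset[-i]
  }
  full <- fit_fn(dataset)
  loo <- vector("list", n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    est <- tryCatch(fit_fn(drop1(i)), error = function(e) NULL)
    if (is.null(est) || anyNA(est)) failed <- c(failed, i) else loo[[i]] <- est
  }
  if (length(failed) > 1) {
    stop(errorCondition(
      sprintf("jackknife: %d leave-one-out refits failed (indices %s)",
              length(failed), paste(failed, collapse = ", ")),
      class = c("ddk_fit_error", "error", "condition")
    ))
  }
  est_mat <- do.call(rbind, loo[lengths(loo) > 0])
  colnames(est_mat) <- names(full) %||% colnames(est_mat)
  m <- nrow(est_mat)
  bar <- colMeans(est_mat)
  se <- sqrt((m - 1) / m * colSums(sweep(est_mat, 2, bar)^2))
  bias <- (m - 1) * (bar - full)
  structure(
    list(estimates = est_mat, se = se, bias = bias, full = full,
         n = n, failed = failed),
    class = "ddk_jackknife"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ddk_jackknife <- function(x, ...) {
  cat("Jackknife over", x$n, "observations\n")
  print(signif(cbind(estimate = x$full, jackknife_se = x$se, bias = x$bias), 6))
  if (length(x$failed)) cat("  failed refits:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' Global fit of linkage parameters to multi-condition apparent Kds
#'
#' Jointly fits selected parameters of a two-state linkage model to apparent
#' dissociation constants observed under several conditions (e.g. partner
#' absent and partner saturating), reproducing the analysis pattern of
#' fitting apo and orthosteric-saturated affinities to one reversible
#' two-state model with shared state affinities.  Residuals are on the log
#' scale (`log(predicted/observed)`), and all free parameters are fitted on
#' the log scale since each is positive.
#'
#' @param observations data.frame with columns `site` ("orthosteric" or
#'   "allosteric"), `partner_free` (free partner concentration in nM, `Inf`
#'   for saturation) and `kd_app` (observed apparent Kd, nM).
#' @param template A [ddk_model()] supplying every parameter not being
#'   fitted.
#' @param free Character vector of parameter names to fit, among `k_eq`,
#'   `kd_o_active`, `kd_o_inactive`, `kd_a_active`, `kd_a_inactive`,
#'   `coupling_active`, `coupling_inactive`.
#' @param init Optional named start values for the free parameters (defaults
#'   to the template's values, or 1 where the template holds `Inf`).
#' @return A `ddk_fit` (natural scale) with the fitted model attached as
#'   attribute `"model"`.
#' @export
global_linkage_fit <- function(observations, template, free, init = NULL) {
  stopifnot(inherits(template, "ddk_model"),
            is.data.frame(observations),
            all(c("site", "partner_free", "kd_app") %in% names(observations)))
  par_names <- c("k_eq", "kd_o_active", "kd_o_inactive",
                 "kd_a_active", "kd_a_inactive",
                 "coupling_active", "coupling_inactive")
  if (!all(free %in% par_names)) {
    stop("unknown parameter name in `free`")
  }
  conds <- unique(observations[c("site", "partner_free")])
  if (nrow(conds) < 2) {
    stop(errorCondition(
      "structurally unidentifiable: at least two distinct conditions (site, partner_free) are required to separate state affinities from the ensemble constant",
      class = c("ddk_identifiability_error", "error", "condition")
    ))
  }
  if (nrow(observations) < length(free)) {
    stop(errorCondition(
      sprintf("structurally unidentifiable: %d free parameters but only %d observations",
              length(free), nrow(observations)),
      class = c("ddk_identifiability_error", "error", "condition")
    ))
  }
  start <- vapply(free, function(nm) {
    v <- if (!is.null(init) && nm %in% names(init)) init[[nm]] else template[[nm]]
    if (!is.finite(v) || v <= 0) v <- if (grepl("^kd", nm)) 100 else 1
    v
  }, numeric(1))
  build <- function(theta) {
    args <- unclass(template)
    args[free] <- as.list(exp(theta))
    do.call(ddk_model, args)
  }
  resid_fn <- function(theta) {
    m <- build(theta)
    pred <- vapply(seq_len(nrow(observations)), function(i) {
      .ddk_kd_app(m, observations$site[i], observations$partner_free[i])
    }, numeric(1))
    log(pred / observations$kd_app)
  }
  th0 <- log(start)
  names(th0) <- paste0("log_", free)
  fit <- least_squares(resid_fn, th0,
                       lower = rep(log(1e-10), length(free)),
                       upper = rep(log(1e10), length(free)))
  fit <- .ddk_backtransform(fit, names(th0))
  attr(fit, "model") <- build(log(fit$estimate))
  fit
}
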