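#' von Bertalanffy growth-curve parameters
#'
#' Bundles the three parameters of the standardized growth curve
#' `H(A) = h_inf * (1 - exp(-k * (A - t0)))` relating hinge size to age:
#' the asymptotic hinge size `h_inf` (mm), the growth-rate coefficient `k`
#' (per year) and the hypothetical age at zero hinge size `t0` (years).
#' With `h_inf > 0` and `k > 0` the predicted hinge is strictly increasing
#' in age beyond `t0`.
#'
#' @param h_inf Asymptotic hinge size, mm; must be > 0.
#' @param k Growth-rate coefficient, per year; must be > 0.
#' @param t0 Hypothetical age at zero hinge size, years.
#' @return An object of class `growth_params`.
#' @export
#' @examples
#' growth_params(20, 0.3, 0)
growth_params <- function(h_inf, k, t0 = 0) {
  stopifnot(is.numeric(h_inf), is.numeric(k), is.numeric(t0))
  if (h_inf <= 0) stop("h_inf must be > 0", call. = FALSE)
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  structure(list(h_inf = h_inf, k = k, t0 = t0), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "<growth_params> h_inf = %.4f mm, k = %.5f /y, t0 = %.4f y\n",
    x$h_inf, x$k, x$t0
  ))
  invisible(x)
}

#' Predicted hinge size at age under the standardized growth curve
#'
#' Evaluates `h_inf * (1 - exp(-k * (age - t0)))`. The function is defined
#' for all real ages; predictions are positive only for `age > t0`.
#'
#' @param params A [growth_params()] object (or a `growth_fit`).
#' @param age Age(s) in years.
#' @return Predicted hinge size(s) in mm.
#' @export
#' @examples
#' predict_hinge(growth_params(20, 0.3, 0), 1) # 20 * (1 - exp(-0.3))
predict_hinge <- function(params, age) {
  params <- as_growth_params(params)
  params$h_inf * (1 - exp(-params$k * (age - params$t0)))
}

as_growth_params <- function(x) {
  if (inherits(x, "growth_fit")) return(x$params)
  if (inherits(x, "growth_params")) return(x)
  if (is.list(x) && all(c("h_inf", "k", "t0") %in% names(x))) {
    return(growth_params(x$h_inf, x$k, x$t0))
  }
  stop("expected a growth_params or growth_fit object", call. = FALSE)
}

#' Fit the standardized von Bertalanffy growth curve
#'
#' Estimates `(h_inf, k, t0)` by nonlinear least squares on every record
#' with both a hinge measurement and an age, minimizing the sum of squared
#' differences between observed and predicted hinge sizes. One global curve
#' is fitted on all complete records pooled across sites and periods — the
#' standard against which individual growth residuals are measured; a
#' per-site curve is available by restricting with `site`.
#'
#' The fit is deterministic: starting values follow a fixed rule
#' (`h_inf` start = 1.05 x maximum observed hinge; `k` start from the slope
#' of a log-linear regression of `log(1 - hinge/h_inf_start)` on age;
#' `t0` start = 0) and the bounded Levenberg-Marquardt optimizer
#' ([minpack.lm::nlsLM()]) is run with parameter tolerance 1e-8 and at most
#' `max_iter` iterations. Bounds `h_inf` in (0, 10 x max hinge],
#' `k` in (0, 10], `t0` in [-10, min age) prevent degenerate sign flips
#' without binding for realistic data.
#'
#' @param x An [assemblage()] (or record data frame).
#' @param site Optional site label; restricts the fit to that site's
#'   records.
#' @param max_iter Maximum optimizer iterations (default 500).
#' @param tol Convergence tolerance on parameters (default 1e-8).
#' @return An object of class `growth_fit` with elements `params`
#'   ([growth_params()]), `ssr` (mm^2), `n_used`, `converged`, `iterations`,
#'   and `data` (the complete records used, with fitted values and
#'   residuals).
#' @export
fit_growth_curve <- function(x, site = NULL, max_iter = 500, tol = 1e-8) {
  rec <- as_assemblage(x)$records
  if (!is.null(site)) rec <- rec[rec$site %in% site, , drop = FALSE]
  cc <- rec[!is.na(rec$hinge_mm) & !is.na(rec$age_years), , drop = FALSE]
  if (nrow(cc) < 4) {
    stop("need at least 4 records with both hinge and age (have ", nrow(cc), ")", call. = FALSE)
  }
  if (length(unique(cc$age_years)) < 3) {
    stop("need at least 3 distinct ages to identify the growth curve", call. = FALSE)
  }
  h <- cc$hinge_mm
  a <- as.numeric(cc$age_years)
  if (sd(h) == 0) {
    stop("degenerate fit: all hinge sizes equal, k is not identifiable", call. = FALSE)
  }

  h0 <- 1.05 * max(h)
  # k start from the log-linear form log(1 - H/h0) = -k (A - t0), using only
  # observations well below the provisional asymptote (near-asymptotic sizes
  # make the slope, and the Jacobian, degenerate).
  mask <- h / h0 < 0.95
  k0 <- NA_real_
  if (sum(mask) >= 3 && length(unique(a[mask])) >= 2) {
    slope <- coef(lm(log(1 - h[mask] / h0) ~ a[mask]))[[2]]
    if (is.finite(slope) && slope < 0) k0 <- -slope
  }
  if (!is.finite(k0)) k0 <- 0.2
  k0 <- min(max(k0, 0.01), 3)
  lower <- c(h_inf = 1e-8, k = 1e-8, t0 = -10)
  upper <- c(h_inf = 10 * max(h), k = 10, t0 = min(a) - 1e-9)

  ctrl <- minpack.lm::nls.lm.control(
    maxiter = max_iter, maxfev = 20L * max_iter,
    ptol = tol^1.25, ftol = tol^1.25
  )
  try_fit <- function(k_start) {
    tryCatch(
      minpack.lm::nlsLM(
        h ~ h_inf * (1 - exp(-k * (a - t0))),
        start = list(h_inf = h0, k = k_start, t0 = 0),
        lower = lower, upper = upper, control = ctrl
      ),
      error = function(e) e
    )
  }
  fit <- try_fit(k0)
  if (inherits(fit, "error")) {
    # deterministic fallback ladder of k starts
    for (k_alt in c(0.05, 0.2, 0.5, 1)) {
      fit <- try_fit(k_alt)
      if (!inherits(fit, "error")) break
    }
  }
  if (inherits(fit, "error")) {
    stop("growth-curve fit failed: ", conditionMessage(fit), call. = FALSE)
  }
  est <- coef(fit)
  if (est[["h_inf"]] <= lower[["h_inf"]] * 2 || est[["k"]] <= lower[["k"]] * 2) {
    stop("degenerate fit: h_inf or k collapsed to zero", call. = FALSE)
  }
  params <- growth_params(est[["h_inf"]], est[["k"]], est[["t0"]])
  pred <- predict_hinge(params, a)
  resid <- h - pred
  conv <- fit$convInfo
  out <- structure(
    list(
      params = params,
      ssr = sum(resid^2),
      n_used = nrow(cc),
      converged = isTRUE(conv$isConv),
      iterations = conv$finIter,
      data = tibble::tibble(
        shell_id = cc$shell_id, age_years = cc$age_years,
        hinge_mm = cc$hinge_mm, predicted_mm = pred, residual_mm = resid
      )
    ),
    class = "growth_fit"
  )
  if (!out$converged) {
    warning("growth-curve fit did not converge after ", out$iterations,
      " iterations (stop code ", conv$stopCode, ")",
      call. = FALSE
    )
  }
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Standardized von Bertalanffy growth curve\n")
  cat(sprintf(
    "  h_inf = %.4f mm   k = %.5f /y   t0 = %.4f y\n",
    x$params$h_inf, x$params$k, x$params$t0
  ))
  cat(sprintf(
    "  n = %d complete records   SSR = %.4f mm^2   converged: %s (%d iterations)\n",
    x$n_used, x$ssr, x$converged, x$iterations
  ))
  invisible(x)
}

#' Per-shell growth residuals from the standardized curve
#'
#' For every record with both hinge and age, computes the deviation of the
#' observed hinge from the size the standardized growth curve predicts at
#' that age: `residual = observed - predicted`. Negative values indicate
#' shells that grew more slowly than typical for their age (poor growing
#' conditions), positive values faster growth. Residuals remove the effect
#' of age-at-harvest on size, isolating the environmental signal.
#'
#' @param params A [growth_params()] or `growth_fit` object.
#' @param x An [assemblage()].
#' @return A tibble with columns `shell_id`, `age_years`, `hinge_mm`,
#'   `predicted_mm`, `residual_mm` — one row per complete record.
#' @export
compute_residuals <- function(params, x) {
  params <- as_growth_params(params)
  rec <- as_assemblage(x)$records
  cc <- rec[!is.na(rec$hinge_mm) & !is.na(rec$age_years), , drop = FALSE]
  pred <- predict_hinge(params, as.numeric(cc$age_years))
  tibble::tibble(
    shell_id = cc$shell_id,
    age_years = cc$age_years,
    hinge_mm = cc$hinge_mm,
    predicted_mm = pred,
    residual_mm = cc$hinge_mm - pred
  )
}
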