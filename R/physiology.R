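#' Log-phase growth rate with window and linearity gates
#'
#' Fits the least-squares slope of log2(cell density) against time (days)
#' over the in-window points, giving the relative division rate in
#' divisions per day. The window is the run of consecutive measurements
#' whose densities lie within `[lower, upper]`; when several disjoint runs
#' qualify, the longest (then earliest) is used. The Pearson correlation of
#' log2(density) with time over the same points is the linearity gate. A
#' literal reading of the rate as the slope against log2(time) is available
#' behind `log2_time = TRUE` for comparison; it is not the default because
#' rates are reported in divisions per day.
#'
#' @param curve Tibble with `time_days` (strictly increasing) and
#'   `cells_per_ml` (> 0).
#' @param lower,upper Density window in cells/mL (defaults 5e4 and 4e6,
#'   inclusive).
#' @param r_gate Linearity threshold on `r` (strict `>`, default 0.95).
#' @param log2_time Regress against log2(time) instead of linear time.
#' @return One-row tibble: `rate`, `r`, `window_start`, `window_end`,
#'   `n_points`, `passes_linearity`, `note`. When fewer than 3 in-window
#'   points exist, `rate` is `NA` and `note` explains why.
#' @export
log_phase_rate <- function(curve, lower = 5e4, upper = 4e6, r_gate = 0.95,
                           log2_time = FALSE) {
  stopifnot(all(c("time_days", "cells_per_ml") %in% names(curve)))
  if (is.unsorted(curve$time_days, strictly = TRUE)) {
    stop("time_days must be strictly increasing", call. = FALSE)
  }
  if (any(curve$cells_per_ml <= 0)) {
    stop("cell densities must be positive", call. = FALSE)
  }
  no_rate <- function(note) tibble::tibble(
    rate = NA_real_, r = NA_real_, window_start = NA_integer_,
    window_end = NA_integer_, n_points = 0L, passes_linearity = NA,
    note = note
  )
  in_win <- curve$cells_per_ml >= lower & curve$cells_per_ml <= upper
  if (!any(in_win)) return(no_rate("no measurements inside density window"))
  runs <- rle(in_win)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values)
  pick <- ok[order(-runs$lengths[ok], starts[ok])][1L]
  idx <- seq.int(starts[pick], ends[pick])
  if (length(idx) < 3L) {
    return(no_rate("fewer than 3 consecutive in-window measurements"))
  }
  x <- if (log2_time) log2(curve$time_days[idx]) else curve$time_days[idx]
  y <- log2(curve$cells_per_ml[idx])
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  tibble::tibble(
    rate = unname(stats::coef(fit)[2L]), r = r,
    window_start = idx[1L], window_end = idx[length(idx)],
    n_points = length(idx), passes_linearity = r > r_gate,
    note = ""
  )
}

#' Derive PSII fluorescence parameters from a light-curve trace
#'
#' Computes the dark-adapted maximum quantum yield Fv/Fm = (FM - F0)/FM and,
#' per actinic light step, the PSII operating yield
#' phiPSII = (FM' - Fs)/FM', non-photochemical quenching NPQ = FM/FM' - 1,
#' and the relative electron transport rate rETR = phiPSII * E.
#'
#' @param trace Tibble with per-step `E`, `Fs`, `FM_prime` and the
#'   dark-step `F0`, `FM` (repeated per row, as in the fluorometry TSV).
#' @return The trace with added `fv_fm`, `phi_psii`, `npq`, `retr`.
#' @export
fluorescence_params <- function(trace) {
  stopifnot(all(c("E", "F0", "FM", "Fs", "FM_prime") %in% names(trace)))
  if (any(trace$FM_prime <= 0)) stop("FM_prime must be positive", call. = FALSE)
  if (any(trace$F0 <= 0) || any(trace$FM < trace$F0)) {
    stop("require FM >= F0 > 0", call. = FALSE)
  }
  if (any(trace$Fs > trace$FM_prime)) {
    stop("require FM_prime >= Fs at every step", call. = FALSE)
  }
  dplyr::mutate(
    trace,
    fv_fm = (.data$FM - .data$F0) / .data$FM,
    phi_psii = (.data$FM_prime - .data$Fs) / .data$FM_prime,
    npq = .data$FM / .data$FM_prime - 1,
    retr = .data$phi_psii * .data$E
  )
}

retr_model <- function(E, rETR_M, alpha) {
  rETR_M * (1 - exp(-alpha * E / rETR_M))
}

npq_model <- function(E, NPQ_M, E50, n) {
  NPQ_M * E^n / (E50^n + E^n)
}

#' Fit the rETR light-saturation model
#'
#' Nonlinear least squares of rETR = rETR_M (1 - exp(-alpha E / rETR_M)) on
#' the steps with E <= `e_max` (default 450 umol photons m-2 s-1; higher
#' irradiances are too noisy to constrain the fit). Initialisation is
#' data-derived and deterministic: alpha from the lowest-irradiance point,
#' rETR_M from the series maximum. Derived quantities follow the fitted
#' parameters: the light-saturation parameter E_K = rETR_M / alpha and the
#' operating yield at 50 umol photons m-2 s-1,
#' phiPSII_50 = rETR_M (1 - exp(-alpha 50 / rETR_M)) / 50.
#'
#' @param E Irradiance steps (umol photons m-2 s-1).
#' @param retr Relative electron transport rates at those steps.
#' @param e_max Truncation irradiance for the fit (default 450).
#' @return An object of class `retr_fit`; see [tidy.retr_fit()] and
#'   [glance.retr_fit()]. Non-convergence is flagged (`converged = FALSE`),
#'   never thrown.
#' @export
fit_retr <- function(E, retr, e_max = 450) {
  keep <- E <= e_max
  E <- E[keep]; retr <- retr[keep]
  if (length(E) < 3L) {
    stop("need at least 3 steps with E <= ", e_max, call. = FALSE)
  }
  ord <- order(E)
  E <- E[ord]; retr <- retr[ord]
  i0 <- which(E > 0)[1L]
  alpha0 <- if (!is.na(i0) && retr[i0] > 0) retr[i0] / E[i0] else 0.1
  rm0 <- max(retr, alpha0 * max(E) / 4, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      retr ~ rETR_M * (1 - exp(-alpha * E / rETR_M)),
      start = list(rETR_M = rm0, alpha = alpha0),
      lower = c(1e-9, 1e-9),
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, ftol = 1e-15, ptol = 1e-15
      )
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out <- list(rETR_M = NA_real_, alpha = NA_real_, E_K = NA_real_,
                phi_psii_50 = NA_real_, rss = NA_real_, converged = FALSE,
                diagnostic = conditionMessage(fit),
                data = tibble::tibble(E = E, retr = retr))
  } else {
    cf <- stats::coef(fit)
    out <- list(
      rETR_M = unname(cf["rETR_M"]), alpha = unname(cf["alpha"]),
      E_K = unname(cf["rETR_M"] / cf["alpha"]),
      phi_psii_50 = unname(retr_model(50, cf["rETR_M"], cf["alpha"]) / 50),
      rss = sum(stats::resid(fit)^2), converged = TRUE, diagnostic = "",
      data = tibble::tibble(E = E, retr = retr,
                            fitted = stats::fitted(fit))
    )
  }
  structure(out, class = "retr_fit")
}

#' Fit the sigmoid NPQ light-response model
#'
#' Nonlinear least squares of NPQ = NPQ_M E^n / (E50^n + E^n), where NPQ_M
#' is the maximal NPQ, E50 the half-saturation irradiance and n the
#' sigmoidicity coefficient. Initialisation is deterministic: NPQ_M from the
#' series maximum, E50 from the step nearest half-maximal NPQ, n = 1.
#'
#' @param E Irradiance steps (umol photons m-2 s-1).
#' @param npq NPQ values at those steps.
#' @return An object of class `npq_fit`; non-convergence is flagged, never
#'   thrown.
#' @export
fit_npq <- function(E, npq) {
  if (length(E) < 4L) stop("need at least 4 steps", call. = FALSE)
  ord <- order(E)
  E <- E[ord]; npq <- npq[ord]
  m0 <- max(npq, 1e-6)
  e50_0 <- E[which.min(abs(npq - m0 / 2))]
  if (e50_0 <= 0) e50_0 <- stats::median(E[E > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      npq ~ NPQ_M * E^n / (E50^n + E^n),
      start = list(NPQ_M = m0, E50 = e50_0, n = 1),
      lower = c(1e-9, 1e-9, 1e-3), upper = c(Inf, Inf, 25),
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, ftol = 1e-15, ptol = 1e-15
      )
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out <- list(NPQ_M = NA_real_, E50_NPQ = NA_real_, n_sig = NA_real_,
                rss = NA_real_, converged = FALSE,
                diagnostic = conditionMessage(fit),
                data = tibble::tibble(E = E, npq = npq))
  } else {
    cf <- stats::coef(fit)
    out <- list(
      NPQ_M = unname(cf["NPQ_M"]), E50_NPQ = unname(cf["E50"]),
      n_sig = unname(cf["n"]), rss = sum(stats::resid(fit)^2),
      converged = TRUE, diagnostic = "",
      data = tibble::tibble(E = E, npq = npq, fitted = stats::fitted(fit))
    )
  }
  structure(out, class = "npq_fit")
}

#' Fit both light-response models from a raw fluorometry trace
#'
#' Convenience wrapper: derives per-step parameters with
#' [fluorescence_params()], then fits the rETR saturation model (truncated
#' at `e_max`) and the NPQ sigmoid (all steps).
#'
#' @param trace Fluorometry tibble as for [fluorescence_params()].
#' @param e_max rETR fit truncation (default 450).
#' @return List with elements `params` (augmented trace), `retr`
#'   (`retr_fit`) and `npq` (`npq_fit`).
#' @export
fit_light_curve <- function(trace, e_max = 450) {
  p <- fluorescence_params(trace)
  list(
    params = p,
    retr = fit_retr(p$E, p$retr, e_max = e_max),
    npq = fit_npq(p$E, p$npq)
  )
}

#' @export
print.retr_fit <- function(x, ...) {
  cat("rETR saturation fit\n")
  cat(sprintf("  rETR_M = %.4g, alpha = %.4g, E_K = %.4g, phiPSII_50 = %.4g\n",
              x$rETR_M, x$alpha, x$E_K, x$phi_psii_50))
  cat(sprintf("  rss = %.4g, converged = %s\n", x$rss, x$converged))
  invisible(x)
}

#' @export
print.npq_fit <- function(x, ...) {
  cat("NPQ sigmoid fit\n")
  cat(sprintf("  NPQ_M = %.4g, E50_NPQ = %.4g, n = %.4g\n",
              x$NPQ_M, x$E50_NPQ, x$n_sig))
  cat(sprintf("  rss = %.4g, converged = %s\n", x$rss, x$converged))
  invisible(x)
}
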