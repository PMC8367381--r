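#' Baseline-subtracted peak response of a luminescence trace
#'
#' The response amplitude of one stimulus presentation: the maximum
#' luminescence after stimulus onset minus the mean of the baseline
#' (pre-stimulus dark-incubation) window. Not clamped at zero, so a
#' below-baseline trace yields a negative response.
#'
#' @param times Numeric vector of sample times (s), strictly increasing.
#' @param values Raw luminescence values (arbitrary units).
#' @param stimulus_onset Stimulus time (s).
#' @param baseline_window Length-2 numeric, `[lo, hi]` window entirely
#'   before `stimulus_onset`; samples with `lo <= t <= hi` form the
#'   baseline.
#' @return Scalar response (arbitrary units).
#' @export
peak_response <- function(times, values, stimulus_onset,
                          baseline_window = c(-Inf, stimulus_onset)) {
  stopifnot(length(times) == length(values),
            !is.unsorted(times, strictly = TRUE),
            baseline_window[2] <= stimulus_onset)
  base <- values[times >= baseline_window[1] & times <= baseline_window[2]]
  post <- values[times > stimulus_onset]
  if (!length(base)) stop("no samples in baseline window")
  if (!length(post)) stop("no samples after stimulus onset")
  max(post) - mean(base)
}

#' Fit a sigmoidal (4PL) dose-response curve with fixed bottom
#'
#' Least-squares fit of the variable-slope logistic
#' `R(x) = B + (T - B) / (1 + 10^(h * (logEC50 - x)))` on log10
#' irradiance `x`, with the minimal asymptote `B` constrained to the
#' average raw luminescence baseline. Start values are deterministic
#' (`T` = max response, `h` = 1, `logEC50` = median dose).
#'
#' @param log_irradiance Numeric vector of log10 photon irradiances
#'   (photons cm-2 s-1).
#' @param response Responses (arbitrary units), same length.
#' @param baseline Fixed bottom asymptote `B`.
#' @return Object of class `dose_response_fit`: list with `bottom`,
#'   `top`, `hill`, `log_ec50`, `ec50`, `sse`, `ok` and, when `ok` is
#'   `FALSE`, a `flag` string explaining why (non-convergence, or a
#'   non-positive/ill-defined slope for what should be an activating
#'   response).
#' @export
fit_dose_response <- function(log_irradiance, response, baseline) {
  stopifnot(length(log_irradiance) == length(response))
  if (length(unique(log_irradiance)) < 4)
    stop("dose-response fit requires >= 4 distinct dose levels")
  df <- data.frame(x = log_irradiance, y = response)
  start <- list(top = max(response), hill = 1,
                log_ec50 = stats::median(log_irradiance))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ baseline + (top - baseline) / (1 + 10^(hill * (log_ec50 - x))),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(bottom = baseline, top = NA_real_,
                          hill = NA_real_, log_ec50 = NA_real_,
                          ec50 = NA_real_, sse = NA_real_, ok = FALSE,
                          flag = conditionMessage(fit)),
                     class = "dose_response_fit"))
  }
  p <- stats::coef(fit)
  sse <- sum(stats::resid(fit)^2)
  ok <- is.finite(p[["hill"]]) && p[["hill"]] > 0 &&
    p[["top"]] > baseline
  structure(list(bottom = baseline, top = p[["top"]], hill = p[["hill"]],
                 log_ec50 = p[["log_ec50"]], ec50 = 10^p[["log_ec50"]],
                 sse = sse, ok = ok,
                 flag = if (ok) NULL else
                   "non-activating fit (hill <= 0 or top <= bottom)"),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("4PL fit: top %.3g, hill %.3g, logEC50 %.4g (sse %.3g)\n",
                x$top, x$hill, x$log_ec50, x$sse))
  else cat("4PL fit FLAGGED:", x$flag, "\n")
  invisible(x)
}

#' Read a per-wavelength dose-response table
#'
#' CSV with columns `wavelength_nm`, `log_irradiance`, `response`
#' (optionally `replicate`).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_dose_response <- function(path) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "log_irradiance", "response")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dose-response table lacks column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Fit dose-response curves for every wavelength of an assay
#'
#' @param doses data.frame as from [read_dose_response()]; replicate
#'   points are pooled into one fit per wavelength.
#' @param baseline Fixed bottom asymptote (average raw luminescence
#'   baseline), recycled across wavelengths or a named vector by
#'   wavelength.
#' @return Named list of [fit_dose_response()] results, names the
#'   wavelengths in nm.
#' @export
fit_wavelengths <- function(doses, baseline) {
  wl <- sort(unique(doses$wavelength_nm))
  bl <- if (length(baseline) == 1) stats::setNames(rep(baseline, length(wl)),
                                                   wl)
        else baseline[as.character(wl)]
  fits <- lapply(seq_along(wl), function(i) {
    d <- doses[doses$wavelength_nm == wl[i], ]
    fit_dose_response(d$log_irradiance, d$response, bl[[i]])
  })
  stats::setNames(fits, wl)
}

#' Relative spectral sensitivity from per-wavelength EC50s
#'
#' Converts half-maximal irradiances to a relative action spectrum:
#' `s(lambda) = EC50_min / EC50(lambda)`, so the most sensitive
#' wavelength (lowest EC50) gets exactly 1 and less sensitive
#' wavelengths values in (0, 1).
#'
#' @param fits Named list of `dose_response_fit` objects keyed by
#'   wavelength (nm), as from [fit_wavelengths()]. Flagged fits are
#'   dropped with a warning; if none are usable, an error is raised.
#' @return Object of class `action_spectrum`: data.frame with columns
#'   `wavelength`, `ec50`, `sensitivity`.
#' @export
relative_sensitivity <- function(fits) {
  ok <- vapply(fits, function(f) isTRUE(f$ok), logical(1))
  if (any(!ok)) {
    warning("excluding flagged fit(s) at wavelength(s): ",
            paste(names(fits)[!ok], collapse = ", "))
    fits <- fits[ok]
  }
  if (length(fits) < 2)
    stop("action spectrum requires >= 2 usable wavelengths")
  wl <- as.numeric(names(fits))
  ec50 <- vapply(fits, `[[`, numeric(1), "ec50")
  s <- min(ec50) / ec50
  structure(data.frame(wavelength = wl, ec50 = unname(ec50),
                       sensitivity = unname(s)),
            class = c("action_spectrum", "data.frame"))
}

#' Visual pigment absorbance template (A1 retinaldehyde)
#'
#' Standard parametric absorbance nomogram for opsin:retinal pigments,
#' fully determined by the peak wavelength. The alpha band is
#' `1 / (exp(A*(a - x)) + exp(B*(b - x)) + exp(C*(c - x)) + D)` with
#' `x = lambda_max / lambda`, `A = 69.7`, `B = 28`, `C = -14.9`,
#' `D = 0.674`, `b = 0.922`, `c = 1.104` and
#' `a = 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)`.
#' The beta band is a Gaussian of amplitude 0.26 centred at
#' `189 + 0.315 * lambda_max` with width `-40.5 + 0.195 * lambda_max`.
#'
#' The summed bands are renormalized to the curve's own peak so the
#' returned absorbance lies in (0, 1] with the maximum exactly 1.
#'
#' @param wavelength Wavelength(s) in nm, within \[300, 700\].
#' @param lambda_max Peak absorbance wavelength in nm, within
#'   \[300, 700\].
#' @param beta_band Include the beta (cis) band (default `TRUE`).
#' @return Normalized absorbance value(s) in (0, 1].
#' @export
govardovskii_template <- function(wavelength, lambda_max,
                                  beta_band = TRUE) {
  if (any(wavelength < 300 | wavelength > 700))
    stop("wavelength outside [300, 700] nm")
  if (lambda_max < 300 || lambda_max > 700)
    stop("lambda_max outside [300, 700] nm")
  raw <- .govardovskii_raw(wavelength, lambda_max, beta_band)
  peak <- max(.govardovskii_raw(seq(300, 700, by = 0.25), lambda_max,
                                beta_band))
  raw / peak
}

.govardovskii_raw <- function(wavelength, lambda_max, beta_band) {
  A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
  b <- 0.922; cc <- 1.104
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  x <- lambda_max / wavelength
  alpha <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) +
                  exp(C * (cc - x)) + D)
  if (!beta_band) return(alpha)
  A_beta <- 0.26
  lm_beta <- 189 + 0.315 * lambda_max
  b_beta <- -40.5 + 0.195 * lambda_max
  beta <- A_beta * exp(-((wavelength - lm_beta) / b_beta)^2)
  alpha + beta
}

#' Estimate lambda_max by template scan
#'
#' Scans candidate peak wavelengths on a regular grid and, for each,
#' computes the sum of squared differences between the measured action
#' spectrum and the pigment template; returns the minimizer and the
#' full sum-of-squares profile.
#'
#' @param spectrum An `action_spectrum` (or data.frame with
#'   `wavelength` and `sensitivity` columns) of >= 3 wavelengths.
#' @param scan_lo,scan_hi,step Scan grid in nm (default 400-550 by 1).
#' @param beta_band Passed to [govardovskii_template()].
#' @return Object of class `template_fit`: list with `lambda_max`,
#'   `min_ss`, `ss_profile` (data.frame `lambda_max`, `ss`),
#'   `grid_step`, `ok` (`FALSE`, flagged, for a degenerate all-equal
#'   spectrum).
#' @export
fit_lambda_max <- function(spectrum, scan_lo = 400, scan_hi = 550,
                           step = 1, beta_band = TRUE) {
  stopifnot(nrow(spectrum) >= 3, scan_hi > scan_lo, step > 0)
  grid <- seq(scan_lo, scan_hi, by = step)
  ss <- vapply(grid, function(lm) {
    sum((spectrum$sensitivity -
           govardovskii_template(spectrum$wavelength, lm, beta_band))^2)
  }, numeric(1))
  i <- which.min(ss)
  degenerate <- length(unique(spectrum$sensitivity)) == 1
  structure(list(lambda_max = grid[i], min_ss = ss[i],
                 ss_profile = data.frame(lambda_max = grid, ss = ss),
                 grid_step = step, ok = !degenerate,
                 flag = if (degenerate) "degenerate flat spectrum" else NULL),
            class = "template_fit")
}

#' @export
print.template_fit <- function(x, ...) {
  cat(sprintf("Template fit: lambda_max = %g nm (ss = %.4g, grid %g nm)\n",
              x$lambda_max, x$min_ss, x$grid_step))
  if (!x$ok) cat("  FLAGGED:", x$flag, "\n")
  invisible(x)
}

#' Full action-spectrum pipeline
#'
#' Dose-response table to lambda_max in one call: per-wavelength 4PL
#' fits, EC50-based relative sensitivities, and the template scan.
#'
#' @inheritParams fit_wavelengths
#' @inheritParams fit_lambda_max
#' @return List with `fits`, `spectrum`, `template_fit`.
#' @export
action_spectrum_pipeline <- function(doses, baseline, scan_lo = 400,
                                     scan_hi = 550, step = 1,
                                     beta_band = TRUE) {
  fits <- fit_wavelengths(doses, baseline)
  spectrum <- relative_sensitivity(fits)
  list(fits = fits, spectrum = spectrum,
       template_fit = fit_lambda_max(spectrum, scan_lo, scan_hi, step,
                                     beta_band))
}
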