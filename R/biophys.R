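# Computational reductions of spectroscopy data: melt-curve Tm by the
# derivative method, ThT fluorescence enhancement, Beer-Lambert
# concentration, and CD-band G-quadruplex topology classification.

#' Construct a melt curve
#'
#' @param temperature numeric vector, degrees C; sorted on construction and
#'   required strictly increasing afterwards.
#' @param signal numeric vector (ellipticity mdeg or absorbance AU).
#' @param wavelength_nm monitoring wavelength.
#' @return Object of class `MeltCurve`.
#' @export
melt_curve <- function(temperature, signal, wavelength_nm = NA_real_) {
  stopifnot(length(temperature) == length(signal), length(signal) >= 5L)
  o <- order(temperature)
  temperature <- as.numeric(temperature[o]); signal <- as.numeric(signal[o])
  if (any(diff(temperature) <= 0)) {
    stop("temperatures must be strictly increasing after sorting")
  }
  structure(list(temperature = temperature, signal = signal,
                 wavelength_nm = wavelength_nm),
            class = "MeltCurve")
}

#' @export
print.MeltCurve <- function(x, ...) {
  cat(sprintf("MeltCurve: %d points, %.1f-%.1f degC%s\n",
              length(x$temperature), min(x$temperature), max(x$temperature),
              if (is.na(x$wavelength_nm)) "" else
                sprintf(" at %g nm", x$wavelength_nm)))
  invisible(x)
}

#' Construct a wavelength spectrum
#'
#' @param wavelength_nm numeric vector, increasing.
#' @param value numeric vector (CD mdeg or fluorescence intensity).
#' @return Object of class `Spectrum`.
#' @export
spectrum <- function(wavelength_nm, value) {
  stopifnot(length(wavelength_nm) == length(value))
  o <- order(wavelength_nm)
  structure(list(wavelength_nm = as.numeric(wavelength_nm[o]),
                 value = as.numeric(value[o])),
            class = "Spectrum")
}

#' Min-max normalize a melt curve
#'
#' @param curve a `MeltCurve`.
#' @return A `MeltCurve` with signal scaled to [0, 1].
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "MeltCurve"))
  rng <- range(curve$signal)
  if (diff(rng) == 0) stop("constant signal: no transition to normalize")
  curve$signal <- (curve$signal - rng[1]) / diff(rng)
  curve
}

moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  ifelse(is.na(sm), x, sm)  # keep raw values at the ends
}

#' Estimate melting temperature by the derivative method
#'
#' The curve is min-max normalized, resampled to a uniform temperature grid
#' by linear interpolation, smoothed by a moving average, and
#' differentiated by central differences; Tm is the temperature of the
#' extremal |dS/dT|, refined by quadratic interpolation of the derivative
#' peak. The transition is considered real when the derivative peak exceeds
#' 3x the baseline derivative noise (the median |dS/dT|); a featureless
#' linear ramp therefore reports no transition. The estimate is invariant
#' to positive affine transforms of the signal.
#'
#' @param curve a `MeltCurve` with at least 9 points.
#' @param smooth_window moving-average window (points).
#' @return Object of class `TmEstimate`: `tm_c` (`NA` when no transition),
#'   `method = "derivative"`, `transition_detected`, `peak_ratio`.
#' @export
estimate_tm <- function(curve, smooth_window = 5L) {
  stopifnot(inherits(curve, "MeltCurve"))
  if (length(curve$temperature) < 9L) stop("need at least 9 points")
  rng <- range(curve$signal)
  if (diff(rng) == 0) {
    return(structure(list(tm_c = NA_real_, method = "derivative",
                          transition_detected = FALSE, peak_ratio = 0),
                     class = "TmEstimate"))
  }
  cv <- normalize_curve(curve)
  h <- stats::median(diff(cv$temperature))
  grid <- seq(min(cv$temperature), max(cv$temperature), by = h)
  s <- stats::approx(cv$temperature, cv$signal, xout = grid)$y
  s <- moving_average(s, smooth_window)
  n <- length(grid)
  d <- (s[3:n] - s[1:(n - 2)]) / (grid[3:n] - grid[1:(n - 2)])
  td <- grid[2:(n - 1)]
  ad <- abs(d)
  i <- which.max(ad)
  baseline <- stats::median(ad)
  ratio <- if (baseline > 0) ad[i] / baseline else Inf
  detected <- ratio >= 3
  tm <- td[i]
  # refine by the vertex of a least-squares parabola over the derivative
  # peak neighborhood (up to 2 grid points each side)
  lo <- max(1L, i - 2L); hi <- min(length(d), i + 2L)
  if (hi - lo >= 2L) {
    x <- td[lo:hi] - td[i]
    y <- ad[lo:hi]
    fit <- stats::lm.fit(cbind(1, x, x^2), y)
    cf <- fit$coefficients
    if (is.finite(cf[3]) && cf[3] < 0) {
      vtx <- -cf[2] / (2 * cf[3])
      if (abs(vtx) <= h) tm <- td[i] + vtx
    }
  }
  structure(list(tm_c = if (detected) tm else NA_real_,
                 method = "derivative",
                 transition_detected = detected, peak_ratio = ratio),
            class = "TmEstimate")
}

#' @export
print.TmEstimate <- function(x, ...) {
  if (x$transition_detected) {
    cat(sprintf("Tm = %.2f degC (%s method, peak ratio %.1f)\n",
                x$tm_c, x$method, x$peak_ratio))
  } else {
    cat("no transition detected\n")
  }
  invisible(x)
}

#' Thioflavin T fluorescence enhancement
#'
#' F - F0, where F0 is the fluorescence of the dye alone and F after
#' addition of the oligonucleotide, both read at the emission maximum
#' (488 nm). Negative values are permitted and flagged with a warning.
#'
#' @param f_with_dna,f_tht_alone fluorescence readings.
#' @return Numeric enhancement.
#' @export
tht_enhancement <- function(f_with_dna, f_tht_alone) {
  d <- f_with_dna - f_tht_alone
  if (any(d < 0)) warning("negative enhancement (quenching)")
  d
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' c = A / (epsilon x l). The default extinction coefficient is the
#' Thioflavin T value of 36,000 per M per cm at 412 nm.
#'
#' @param absorbance absorbance (AU), >= 0.
#' @param epsilon molar extinction coefficient, per M per cm.
#' @param path_cm optical path length, cm.
#' @return Molar concentration.
#' @export
#' @examples
#' concentration_from_absorbance(0.36) # 1e-5 M
concentration_from_absorbance <- function(absorbance, epsilon = 36000,
                                          path_cm = 1) {
  stopifnot(all(absorbance >= 0))
  if (path_cm <= 0) stop("path length must be positive")
  absorbance / (epsilon * path_cm)
}

# local extrema of a numeric series (interior sign changes of the slope)
local_extrema <- function(x) {
  d <- diff(x)
  idx_max <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  idx_min <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  list(maxima = idx_max, minima = idx_min)
}

#' Classify G-quadruplex topology from a CD spectrum
#'
#' Applies the characteristic CD band rules for G-quadruplex folds:
#' \itemize{
#'   \item antiparallel: positive bands near 295 and 240 nm, negative band
#'     near 260 nm;
#'   \item hybrid: positive band near 290 nm with a shoulder near 260 nm
#'     and a negative band near 240 nm;
#'   \item parallel: positive band near 260 nm, negative band near 240 nm.
#' }
#' Band extrema are accepted within +/- `tol_nm` of the nominal wavelength;
#' the rules are applied in the order antiparallel, hybrid, parallel, and
#' `"indeterminate"` is returned when none fires. A shoulder is detected as
#' a stretch in 255-268 nm where |dS/dlambda| falls below 20% of the main
#' peak's flank slope while the signal stays positive. The classification
#' is invariant to uniform scaling of the spectrum.
#'
#' @param cd a `Spectrum` covering at least 230-310 nm.
#' @param tol_nm band-position tolerance.
#' @return Character scalar: `"parallel"`, `"antiparallel"`, `"hybrid"`, or
#'   `"indeterminate"`.
#' @export
classify_g4_topology <- function(cd, tol_nm = 6) {
  stopifnot(inherits(cd, "Spectrum"))
  wl <- cd$wavelength_nm; v <- cd$value
  if (min(wl) > 230 || max(wl) < 310) {
    stop("spectrum must cover 230-310 nm")
  }
  ex <- local_extrema(v)
  pos_band <- function(nm) {
    any(abs(wl[ex$maxima] - nm) <= tol_nm & v[ex$maxima] > 0)
  }
  neg_band <- function(nm) {
    any(abs(wl[ex$minima] - nm) <= tol_nm & v[ex$minima] < 0)
  }
  if (pos_band(295) && pos_band(240) && neg_band(260)) return("antiparallel")

  # hybrid: global positive maximum at 285-295 nm, negative band near 240,
  # derivative plateau (shoulder) in 255-268 nm
  imax <- which.max(v)
  if (v[imax] > 0 && wl[imax] >= 284 && wl[imax] <= 296 && neg_band(240)) {
    d <- diff(v) / diff(wl)
    wmid <- (wl[-1] + wl[-length(wl)]) / 2
    flank <- abs(d[wmid >= 268 & wmid <= wl[imax]])
    shoulder_zone <- wmid >= 255 & wmid <= 268
    vmid <- (v[-1] + v[-length(v)]) / 2
    if (length(flank) && any(shoulder_zone)) {
      sh <- abs(d[shoulder_zone]) <= 0.2 * max(flank) & vmid[shoulder_zone] > 0
      if (any(sh)) return("hybrid")
    }
  }
  if (pos_band(260) && neg_band(240)) return("parallel")
  "indeterminate"
}
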