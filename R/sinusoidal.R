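#' Fiber geometry
#'
#' @param length fiber length (m).
#' @param cross_sectional_area cross-sectional area (m^2).
#' @return A \code{"fiber_geometry"} list; \code{volume} (m^3) is derived.
#' @export
fiber_geometry <- function(length, cross_sectional_area) {
  if (length <= 0 || cross_sectional_area <= 0)
    stop("fiber length and cross-sectional area must be strictly positive")
  structure(list(length = length,
                 cross_sectional_area = cross_sectional_area,
                 volume = length * cross_sectional_area),
            class = "fiber_geometry")
}

#' Length-force trace container
#'
#' A uniformly sampled record of muscle strain (dimensionless fraction of
#' muscle length) and stress (kN/m^2) under a sinusoidal or work-loop
#' protocol.
#'
#' @param time sample times (s), uniform grid.
#' @param strain strain samples (fraction of muscle length).
#' @param stress stress samples (kN/m^2).
#' @param drive_frequency imposed oscillation frequency (Hz).
#' @param amplitude nominal strain amplitude (fraction of muscle length,
#'   i.e. 0.00125 for a 0.125\% ML oscillation).
#' @param condition named list of solution conditions, e.g.
#'   \code{list(pCa = 5, atp_mM = 12, pi_mM = 0)}.
#' @param meta free-form metadata list (generators store ground truth here).
#' @return Object of class \code{"length_force_trace"}.
#' @export
length_force_trace <- function(time, strain, stress, drive_frequency,
                               amplitude, condition = list(), meta = list()) {
  n <- length(time)
  stopifnot(length(strain) == n, length(stress) == n, n >= 4L)
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("trace must be uniformly sampled")
  if (drive_frequency <= 0) stop("drive_frequency must be positive")
  structure(list(time = time, strain = strain, stress = stress,
                 drive_frequency = drive_frequency, amplitude = amplitude,
                 condition = condition, meta = meta,
                 sample_rate = 1 / stats::median(dt)),
            class = "length_force_trace")
}

#' @export
print.length_force_trace <- function(x, ...) {
  cat(sprintf(
    "length_force_trace: %d samples at %.4g Hz, drive %.4g Hz, amplitude %.4g ML\n",
    length(x$time), x$sample_rate, x$drive_frequency, x$amplitude))
  invisible(x)
}

#' Complex modulus spectrum container
#'
#' @param frequency oscillation frequencies (Hz).
#' @param elastic elastic (in-phase) moduli E' (kN/m^2).
#' @param viscous viscous (quadrature) moduli E'' (kN/m^2).
#' @param amplitude strain amplitude shared by all points (fraction ML).
#' @return A data frame of class \code{"modulus_spectrum"} sorted by
#'   frequency, with the amplitude stored as an attribute.
#' @export
modulus_spectrum <- function(frequency, elastic, viscous, amplitude) {
  stopifnot(length(frequency) == length(elastic),
            length(frequency) == length(viscous))
  if (anyDuplicated(frequency)) stop("duplicate frequencies in spectrum")
  o <- order(frequency)
  out <- data.frame(frequency = frequency[o], elastic = elastic[o],
                    viscous = viscous[o])
  attr(out, "amplitude") <- amplitude
  class(out) <- c("modulus_spectrum", "data.frame")
  out
}

# integer-cycle analysis window: drop leading transient cycles, keep the rest
analysis_window <- function(trace, drop_cycles = 2) {
  f <- trace$drive_frequency
  t0 <- trace$time[1]
  n_cyc <- floor((trace$time[length(trace$time)] - t0) * f + 1e-9)
  if (n_cyc < 2) stop("trace holds fewer than 2 complete cycles")
  drop <- min(drop_cycles, n_cyc - 2L)
  lo <- t0 + drop / f
  hi <- t0 + n_cyc / f
  which(trace$time >= lo - 1e-12 & trace$time < hi - 1e-12)
}

#' Extract the complex modulus at the drive frequency
#'
#' Least-squares projection of stress onto \{1, sin(2 pi f t),
#' cos(2 pi f t)\} over an integer-cycle analysis window (by default the
#' first two cycles are dropped as transient settling).  The strain is
#' projected the same way and the stress phasor is referred to the strain
#' phasor, so the result is exact for \eqn{\epsilon_0 \sin} strain and
#' remains correct for an arbitrary strain phase.  With strain
#' \eqn{\epsilon_0\sin(2\pi f t)}, E' is the sine coefficient of stress
#' divided by \eqn{\epsilon_0} and E'' the cosine coefficient divided by
#' \eqn{\epsilon_0}.
#'
#' @param trace a \code{"length_force_trace"}.
#' @param drop_cycles transient cycles discarded at the start (default 2;
#'   reduced automatically so that at least 2 cycles remain).
#' @return List with \code{elastic} (E', kN/m^2), \code{viscous} (E'',
#'   kN/m^2), \code{amplitude} (measured strain amplitude),
#'   \code{offset} (mean stress over the window, kN/m^2) and
#'   \code{distorted} (TRUE when the strain harmonic distortion exceeds
#'   10\%, reported with a warning).
#' @export
extract_complex_modulus <- function(trace, drop_cycles = 2) {
  stopifnot(inherits(trace, "length_force_trace"))
  idx <- analysis_window(trace, drop_cycles)
  t <- trace$time[idx]
  f <- trace$drive_frequency
  s <- sin(2 * pi * f * t)
  co <- cos(2 * pi * f * t)
  X <- cbind(1, s, co)
  coef_strain <- stats::lm.fit(X, trace$strain[idx])$coefficients
  coef_stress <- stats::lm.fit(X, trace$stress[idx])$coefficients
  eps <- complex(real = coef_strain[2], imaginary = coef_strain[3])
  if (Mod(eps) <= 0) stop("strain carries no power at the drive frequency")
  # harmonic distortion: rms strain residual relative to fundamental amplitude
  strain_fit <- X %*% coef_strain
  distortion <- sqrt(mean((trace$strain[idx] - strain_fit)^2)) * sqrt(2) / Mod(eps)
  distorted <- distortion > 0.10
  if (distorted)
    warning(sprintf("strain harmonic distortion %.1f%% exceeds 10%%",
                    100 * distortion))
  sig <- complex(real = coef_stress[2], imaginary = coef_stress[3])
  y <- sig / eps
  list(elastic = Re(y), viscous = Im(y), amplitude = Mod(eps),
       offset = unname(coef_stress[1]), distorted = distorted)
}

#' Build a modulus spectrum from a frequency sweep of traces
#'
#' @param traces list of \code{"length_force_trace"} objects sharing
#'   amplitude and condition, with distinct drive frequencies.
#' @param drop_cycles passed to [extract_complex_modulus()].
#' @param amplitude_tol relative tolerance for the shared-amplitude check.
#' @return A \code{"modulus_spectrum"} sorted by frequency.
#' @export
sweep_spectrum <- function(traces, drop_cycles = 2, amplitude_tol = 0.05) {
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "length_force_trace")))
  freqs <- vapply(traces, `[[`, numeric(1), "drive_frequency")
  if (anyDuplicated(freqs)) stop("duplicate drive frequencies in sweep")
  amps <- vapply(traces, `[[`, numeric(1), "amplitude")
  if ((max(amps) - min(amps)) > amplitude_tol * stats::median(amps))
    stop("traces in a sweep must share the oscillation amplitude")
  ext <- lapply(traces, extract_complex_modulus, drop_cycles = drop_cycles)
  modulus_spectrum(frequency = freqs,
                   elastic = vapply(ext, `[[`, numeric(1), "elastic"),
                   viscous = vapply(ext, `[[`, numeric(1), "viscous"),
                   amplitude = stats::median(amps))
}

#' Per-frequency work and power from a modulus spectrum
#'
#' For sinusoidal strain of amplitude \eqn{\epsilon_0}, the net work per
#' cycle per unit volume is \eqn{W(f) = -\pi \epsilon_0^2 E''(f)} and the
#' power \eqn{P(f) = W(f) f}.  W is positive when the viscous modulus is
#' negative, i.e. when the fiber performs net work on the apparatus.
#' Moduli in kN/m^2 are converted to N/m^2, so W is in J/m^3 and P in W/m^3.
#'
#' @param spectrum a \code{"modulus_spectrum"}.
#' @param amplitude strain amplitude; defaults to the spectrum's.
#' @return Data frame with columns \code{frequency}, \code{work} (J/m^3)
#'   and \code{power} (W/m^3).
#' @export
work_and_power <- function(spectrum, amplitude = attr(spectrum, "amplitude")) {
  spec <- as.data.frame(spectrum)
  if (nrow(spec) == 0L) stop("empty spectrum")
  if (is.null(amplitude)) stop("strain amplitude is required")
  w <- -pi * amplitude^2 * spec$viscous * 1000
  data.frame(frequency = spec$frequency, work = w, power = w * spec$frequency)
}

#' Summary quantities of a modulus spectrum
#'
#' Reports the frequency of maximum power (f_max), maximum power, the
#' frequency of maximum work (f_Wmax), maximum work, and the elastic
#' modulus at the measured frequency nearest 500 Hz (the in-phase
#' high-frequency stiffness).  Maxima are taken over the measured grid, with
#' no interpolation, matching the discrete oscillation protocol; a maximum
#' on the boundary of the frequency range is flagged but still returned.
#'
#' @param spectrum a \code{"modulus_spectrum"} with at least 3 frequencies.
#' @param amplitude strain amplitude; defaults to the spectrum's.
#' @param stiffness_at target frequency (Hz) for the stiffness readout.
#' @param stiffness_tol maximum relative distance of the nearest measured
#'   frequency from \code{stiffness_at}; beyond it the stiffness is NA.
#' @return Object of class \code{"spectrum_summary"}: list with
#'   \code{f_max}, \code{power_max}, \code{f_wmax}, \code{work_max},
#'   \code{stiffness_500hz} and \code{boundary_flag}.
#' @export
summarize_spectrum <- function(spectrum, amplitude = attr(spectrum, "amplitude"),
                               stiffness_at = 500, stiffness_tol = 0.10) {
  spec <- as.data.frame(spectrum)
  if (nrow(spec) < 3L) stop("need at least 3 frequencies to summarize")
  wp <- work_and_power(spectrum, amplitude)
  i_p <- which.max(wp$power)
  i_w <- which.max(wp$work)
  boundary <- i_p %in% c(1L, nrow(spec)) || i_w %in% c(1L, nrow(spec))
  if (boundary)
    warning("work/power maximum lies on the boundary of the measured range")
  i_s <- which.min(abs(spec$frequency - stiffness_at))
  stiff <- if (abs(spec$frequency[i_s] - stiffness_at) <=
               stiffness_tol * stiffness_at) spec$elastic[i_s] else NA_real_
  structure(list(f_max = spec$frequency[i_p], power_max = wp$power[i_p],
                 f_wmax = spec$frequency[i_w], work_max = wp$work[i_w],
                 stiffness_500hz = stiff, boundary_flag = boundary),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("f_max  %8.4g Hz   max power %8.4g W/m^3\n", x$f_max, x$power_max))
  cat(sprintf("f_Wmax %8.4g Hz   max work  %8.4g J/m^3\n", x$f_wmax, x$work_max))
  cat(sprintf("elastic modulus near 500 Hz: %.4g kN/m^2\n", x$stiffness_500hz))
  if (x$boundary_flag) cat("note: maximum on the boundary of the measured range\n")
  invisible(x)
}

#' Passive, active and net isometric tension
#'
#' Passive tension P0 is the plateau stress of a relaxed (pCa 8.0) isometric
#' record, active tension A0 the plateau stress of the calcium-activated
#' (pCa 5.0) record, and net tension F0 = A0 - P0.  A plateau is the longest
#' run of samples whose local stress slope is below 1\%/s of the record's
#' mean stress.
#'
#' @param trace_passive,trace_active isometric \code{"length_force_trace"}
#'   objects (stress already normalized to cross-sectional area, kN/m^2).
#' @param slope_tol plateau slope tolerance, as a fraction of mean stress
#'   per second.
#' @param min_samples minimum plateau length in samples.
#' @return List of class \code{"tension_measurement"} with \code{passive_p0},
#'   \code{active_a0}, \code{net_f0} (all kN/m^2).
#' @export
measure_tension <- function(trace_passive, trace_active,
                            slope_tol = 0.01, min_samples = 5L) {
  p0 <- plateau_mean(trace_passive, slope_tol, min_samples)
  a0 <- plateau_mean(trace_active, slope_tol, min_samples)
  structure(list(passive_p0 = p0, active_a0 = a0, net_f0 = a0 - p0),
            class = "tension_measurement")
}

#' @export
print.tension_measurement <- function(x, ...) {
  cat(sprintf("passive P0 = %.4g, active A0 = %.4g, net F0 = %.4g (kN/m^2)\n",
              x$passive_p0, x$active_a0, x$net_f0))
  invisible(x)
}

plateau_mean <- function(trace, slope_tol, min_samples) {
  stopifnot(inherits(trace, "length_force_trace"))
  s <- trace$stress
  dt <- 1 / trace$sample_rate
  ref <- abs(mean(s))
  if (ref == 0) ref <- stats::sd(s) + .Machine$double.eps
  # centered local slope over a 5-sample stencil
  n <- length(s)
  win <- min(5L, n - 1L)
  slope <- abs(stats::filter(s, c(1, rep(0, win - 1), -1) / (win * dt),
                             sides = 2))
  ok <- !is.na(slope) & slope <= slope_tol * ref
  runs <- rle(as.vector(ok))
  if (!any(runs$values & runs$lengths >= min_samples))
    stop("no stress plateau found (slope criterion unmet)")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values & runs$lengths >= min_samples)
  best <- cand[which.max(runs$lengths[cand])]
  mean(s[starts[best]:ends[best]])
}
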