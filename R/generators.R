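#' Synthetic mechanical protocol
#'
#' Describes an imposed length protocol for the trace generators and the
#' cross-bridge ensemble simulator.
#'
#' @param kind one of \code{"sinusoid"}, \code{"workloop"},
#'   \code{"isometric"}.  Sinusoid and workloop share the waveform (a
#'   sinusoidal strain of the given amplitude); the distinction records
#'   intent (small-amplitude analysis vs large-amplitude loops).
#' @param frequency oscillation frequency (Hz).  For an isometric protocol
#'   the total duration is still \code{n_cycles / frequency}.
#' @param amplitude strain amplitude (fraction of muscle length).
#' @param n_cycles number of oscillation cycles (>= 1).
#' @param sample_rate sampling rate (Hz); must be at least 20x the drive
#'   frequency so that phase extraction is well conditioned.
#' @param noise_sd additive Gaussian noise, as a fraction of the stress
#'   signal amplitude (>= 0).
#' @param seed integer seed for reproducibility of the generated noise.
#' @return A \code{"synthetic_protocol"} list.
#' @export
synthetic_protocol <- function(kind = c("sinusoid", "workloop", "isometric"),
                               frequency, amplitude = 0.00125, n_cycles = 10,
                               sample_rate = 20 * frequency, noise_sd = 0,
                               seed = NULL) {
  kind <- match.arg(kind)
  if (frequency <= 0) stop("frequency must be positive")
  if (n_cycles < 1) stop("n_cycles must be at least 1")
  if (sample_rate < 20 * frequency)
    stop("sample_rate must be at least 20 times the drive frequency")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(kind = kind, frequency = frequency, amplitude = amplitude,
                 n_cycles = n_cycles, sample_rate = sample_rate,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_protocol")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a linear viscoelastic fiber trace
#'
#' Synthesizes the stress response of a linear fiber obeying the
#' three-process complex-modulus model at the drive frequency: strain is
#' \eqn{\epsilon_0 \sin(2\pi f t)} and stress is
#' \eqn{\epsilon_0 (E'(f)\sin(2\pi f t) + E''(f)\cos(2\pi f t))} plus a
#' constant offset and additive Gaussian noise.  The ground-truth moduli
#' are recorded in the trace metadata.
#'
#' @param model a \code{"nyquist_params"} object.
#' @param protocol a \code{"synthetic_protocol"} of kind \code{"sinusoid"}.
#' @param geometry optional \code{"fiber_geometry"} recorded in metadata.
#' @param offset constant stress offset (kN/m^2), e.g. the mean tension.
#' @param condition condition list stored on the trace.
#' @return A \code{"length_force_trace"} with \code{meta$e_elastic} and
#'   \code{meta$e_viscous} holding the ground truth.
#' @export
gen_linear_trace <- function(model, protocol, geometry = NULL, offset = 0,
                             condition = list()) {
  stopifnot(inherits(model, "nyquist_params"),
            inherits(protocol, "synthetic_protocol"))
  if (protocol$kind != "sinusoid")
    stop("gen_linear_trace requires a sinusoid protocol")
  f <- protocol$frequency
  if (protocol$sample_rate <= 2 * f)
    stop("sample rate below the Nyquist bound for the drive frequency")
  y <- eval_nyquist(model, f)
  eps0 <- protocol$amplitude
  n <- ceiling(protocol$n_cycles / f * protocol$sample_rate)
  t <- seq(0, by = 1 / protocol$sample_rate, length.out = n)
  strain <- eps0 * sin(2 * pi * f * t)
  stress <- eps0 * (Re(y) * sin(2 * pi * f * t) + Im(y) * cos(2 * pi * f * t)) +
    offset
  if (protocol$noise_sd > 0) {
    sd <- protocol$noise_sd * eps0 * Mod(y)
    stress <- stress + with_seed(protocol$seed, stats::rnorm(n, 0, sd))
  }
  length_force_trace(t, strain, stress, drive_frequency = f,
                     amplitude = eps0, condition = condition,
                     meta = list(e_elastic = Re(y), e_viscous = Im(y),
                                 offset = offset, model = model,
                                 geometry = geometry))
}

#' Generate a saturating (Michaelis-Menten) dose-response table
#'
#' \eqn{rate(x) = basal + v_{max} x/(K_m + x)} plus additive Gaussian noise;
#' the noiseless generation is exact.
#'
#' @param vmax saturating rate (response units).
#' @param km half-saturation concentration.
#' @param basal basal rate added to every point (default 0).
#' @param x_values concentrations (non-negative, non-empty).
#' @param noise_sd additive Gaussian noise standard deviation (response
#'   units).
#' @param seed integer seed.
#' @return Data frame with columns \code{x} and \code{rate}; the generating
#'   parameters are stored in attribute \code{"truth"}.
#' @export
gen_dose_response <- function(vmax, km, basal = 0, x_values, noise_sd = 0,
                              seed = NULL) {
  if (vmax <= 0 || km <= 0) stop("vmax and km must be strictly positive")
  if (length(x_values) == 0L) stop("x_values must be non-empty")
  if (any(x_values < 0)) stop("x_values must be non-negative")
  rate <- basal + vmax * x_values / (km + x_values)
  if (noise_sd > 0)
    rate <- rate + with_seed(seed, stats::rnorm(length(x_values), 0, noise_sd))
  out <- data.frame(x = x_values, rate = rate)
  attr(out, "truth") <- list(vmax = vmax, km = km, basal = basal)
  out
}

#' Generate a synthetic M-mode heart-wall diameter trace
#'
#' Produces a periodic diameter trace resting at the diastolic diameter
#' \code{dd} with smoothed rectangular systolic excursions down to \code{sd}
#' of duration \code{si}, one per heart period \code{hp}.  Edges are raised
#' cosines of width 10\% of \code{si}, positioned so that the time spent
#' below the 15\%-of-excursion systolic threshold equals \code{si} exactly
#' in the noiseless continuous trace.  Ground truth is stored in attribute
#' \code{"truth"}.
#'
#' @param dd diastolic diameter (um).
#' @param sd systolic diameter (um), strictly less than \code{dd}.
#' @param hp heart period (s).
#' @param si systolic interval (s), strictly less than \code{hp}.
#' @param n_beats number of beats.
#' @param sample_rate sampling rate (Hz); \code{sample_rate * si} must be at
#'   least 5 so the trough is resolved.
#' @param noise_sd additive Gaussian noise (um).
#' @param seed integer seed.
#' @param edge_frac raised-cosine edge width as a fraction of \code{si}.
#' @return Data frame with columns \code{time} (s) and \code{diameter} (um).
#' @export
gen_cardiac_trace <- function(dd, sd, hp, si, n_beats = 10,
                              sample_rate = 120, noise_sd = 0, seed = NULL,
                              edge_frac = 0.10) {
  if (sd >= dd) stop("systolic diameter must be smaller than diastolic")
  if (si >= hp) stop("systolic interval must be shorter than the heart period")
  if (sample_rate * si < 5) stop("sample_rate * si must be at least 5")
  if (n_beats < 1) stop("n_beats must be at least 1")
  w <- edge_frac * si
  # raised-cosine edges cross the 15%-of-excursion threshold a fixed
  # fraction into the edge; offset the edges so the sub-threshold time is si
  th_frac <- 0.15
  fall_in <- acos(2 * th_frac - 1) / pi * w        # from edge start to crossing
  rise_in <- w - fall_in
  pad <- 0.5 * hp
  total <- 2 * pad + (n_beats - 1) * hp + si + 2 * w
  t <- seq(0, total, by = 1 / sample_rate)
  diam <- rep(dd, length(t))
  depth <- dd - sd
  pulse_level <- function(tau) {
    # tau = time since the sub-threshold window opened; pulse spans
    # [-fall_in, si + rise_in] around it
    lev <- rep(dd, length(tau))
    fall <- tau >= -fall_in & tau < w - fall_in
    lev[fall] <- sd + depth * (1 + cos(pi * (tau[fall] + fall_in) / w)) / 2
    bottom <- tau >= w - fall_in & tau < si - rise_in
    lev[bottom] <- sd
    rise <- tau >= si - rise_in & tau < si - rise_in + w
    lev[rise] <- sd + depth * (1 - cos(pi * (tau[rise] - si + rise_in) / w)) / 2
    lev
  }
  for (k in seq_len(n_beats)) {
    onset <- pad + (k - 1) * hp
    tau <- t - onset
    in_pulse <- tau >= -fall_in & tau < si - rise_in + w
    diam[in_pulse] <- pulse_level(tau[in_pulse])
  }
  if (noise_sd > 0)
    diam <- diam + with_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  out <- data.frame(time = t, diameter = diam)
  attr(out, "truth") <- list(dd = dd, sd = sd, hp = hp, si = si,
                             n_beats = n_beats)
  out
}

#' Generate multinomial flight-outcome counts
#'
#' @param p_up,p_horizontal,p_down,p_none outcome probabilities; must each
#'   lie in [0, 1] and sum to 1.
#' @param total number of flies tested (>= 1).
#' @param seed integer seed.
#' @return A \code{"flight_counts"} object (see [flight_counts()]).
#' @export
gen_flight_counts <- function(p_up, p_horizontal, p_down, p_none, total,
                              seed = NULL) {
  p <- c(p_up, p_horizontal, p_down, p_none)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  if (total < 1) stop("total must be at least 1")
  draw <- with_seed(seed, stats::rmultinom(1, size = total, prob = p))[, 1]
  flight_counts(up = draw[1], horizontal = draw[2], down = draw[3],
                none = draw[4])
}
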