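#' Cross-bridge ensemble parameters
#'
#' Parameters of the stochastic two-state (detached/attached) cross-bridge
#' ensemble.  Bridges attach at a constant rate \code{f_att}; an attached
#' bridge with strain \eqn{x} (nm) detaches at rate
#' \eqn{g_{det0}\,e^{|x|/\delta}} where \eqn{\delta} is
#' \code{g_strain_scale} (\code{Inf} gives strain-independent detachment),
#' optionally scaled by an ATP factor \eqn{1/(1 + K_m^{ATP}/[ATP])} when
#' \code{atp_km} is supplied.  An attached bridge exerts force
#' \eqn{\kappa (x + d)} where \eqn{d} is the power-stroke displacement; the
#' ensemble stress is the summed force divided by the cross-sectional area
#' per half-sarcomere.
#'
#' @param n_bridges number of independent bridges (>= 1).
#' @param f_att attachment rate (s^-1), > 0.
#' @param g_det0 baseline detachment rate (s^-1), > 0.
#' @param g_strain_scale e-fold strain distance for detachment (nm);
#'   \code{Inf} for strain-independent detachment.
#' @param kappa cross-bridge stiffness (pN/nm), > 0.
#' @param d_stroke power-stroke displacement (nm), > 0.
#' @param atp_km optional [ATP] at half-maximal detachment (mM).
#' @param sarcomere_area cross-section per half-sarcomere (nm^2), > 0.
#' @param hs_length half-sarcomere length (nm) used to convert imposed
#'   muscle strain into bridge displacement (strain is assumed uniform down
#'   to the half-sarcomere).
#' @param strain_sign \code{"absolute"} (default) makes detachment depend
#'   on \eqn{|x|}, so stretch and release accelerate detachment equally and
#'   the ensemble is purely work-absorbing; \code{"signed"} uses
#'   \eqn{e^{x/\delta}} (detachment accelerated by positive strain only),
#'   the classic oscillatory-work kinetics of insect flight muscle, which
#'   lets the ensemble generate net work under cyclic length changes.
#' @return A \code{"crossbridge_params"} list; \code{duty_ratio}
#'   (= f_att/(f_att + g_det0)) is derived.
#' @export
crossbridge_params <- function(n_bridges, f_att, g_det0,
                               g_strain_scale = Inf, kappa, d_stroke,
                               atp_km = NULL, sarcomere_area,
                               hs_length = 1700,
                               strain_sign = c("absolute", "signed")) {
  strain_sign <- match.arg(strain_sign)
  if (n_bridges < 1) stop("n_bridges must be at least 1")
  if (f_att <= 0 || g_det0 <= 0) stop("rates must be strictly positive")
  if (g_strain_scale <= 0) stop("g_strain_scale must be positive (may be Inf)")
  if (kappa <= 0 || d_stroke <= 0 || sarcomere_area <= 0 || hs_length <= 0)
    stop("kappa, d_stroke, sarcomere_area and hs_length must be positive")
  if (!is.null(atp_km) && atp_km <= 0) stop("atp_km must be positive")
  structure(list(n_bridges = as.integer(n_bridges), f_att = f_att,
                 g_det0 = g_det0, g_strain_scale = g_strain_scale,
                 kappa = kappa, d_stroke = d_stroke, atp_km = atp_km,
                 sarcomere_area = sarcomere_area, hs_length = hs_length,
                 strain_sign = strain_sign,
                 duty_ratio = f_att / (f_att + g_det0)),
            class = "crossbridge_params")
}

#' Simulate a two-state cross-bridge ensemble under an imposed protocol
#'
#' Monte-Carlo simulation of \code{n_bridges} independent two-state bridges
#' using fixed-step tau-leap Bernoulli updates with step
#' \eqn{\Delta t = 0.02/r_{max}}, where \eqn{r_{max}} bounds the largest
#' attachment or (strain-dependent) detachment rate reachable under the
#' protocol.  Attachment strain is drawn uniformly on
#' \eqn{[-d/2, d/2]}; attached strains are advected by the imposed length
#' change.  Stress (kN/m^2) is the summed bridge force per half-sarcomere
#' cross-section, recorded on the protocol's sample grid.  Bit-reproducible
#' under a fixed protocol seed.
#'
#' @param params a \code{"crossbridge_params"} object.
#' @param protocol a \code{"synthetic_protocol"}; \code{isometric} holds the
#'   length constant for \code{n_cycles/frequency} seconds.
#' @param atp_mM ATP concentration (mM); only used when \code{params$atp_km}
#'   is set.
#' @param dt optional override of the fine integration step (s); rejected
#'   if larger than \code{0.1 / max rate} (rate overflow).
#' @return A \code{"length_force_trace"}; \code{meta$attached_frac} holds
#'   the attached fraction at each sample and \code{meta$params} the
#'   generating parameters.
#' @export
simulate_crossbridge_ensemble <- function(params, protocol, atp_mM = NULL,
                                          dt = NULL) {
  stopifnot(inherits(params, "crossbridge_params"),
            inherits(protocol, "synthetic_protocol"))
  p <- params
  atp_factor <- 1
  if (!is.null(p$atp_km) && !is.null(atp_mM)) {
    if (atp_mM <= 0) stop("atp_mM must be positive")
    atp_factor <- 1 / (1 + p$atp_km / atp_mM)
  }
  eps0 <- if (protocol$kind == "isometric") 0 else protocol$amplitude
  # largest reachable |strain|: initial spread plus full advection range
  x_max <- p$d_stroke / 2 + 2 * eps0 * p$hs_length
  g_max <- p$g_det0 * atp_factor *
    (if (is.finite(p$g_strain_scale)) exp(x_max / p$g_strain_scale) else 1)
  r_max <- max(p$f_att, g_max)
  if (!is.null(dt) && dt > 0.1 / r_max)
    stop("rate overflow: dt exceeds 0.1 / max(rates)")
  dt_target <- if (is.null(dt)) 0.02 / r_max else dt

  sample_dt <- 1 / protocol$sample_rate
  substeps <- max(1L, ceiling(sample_dt / dt_target))
  dt_fine <- sample_dt / substeps
  duration <- protocol$n_cycles / protocol$frequency
  n_samp <- floor(duration / sample_dt) + 1L
  t_samp <- (seq_len(n_samp) - 1L) * sample_dt

  strain_at <- function(tt) {
    if (protocol$kind == "isometric") rep(0, length(tt))
    else eps0 * sin(2 * pi * protocol$frequency * tt)
  }

  t_fine <- (seq_len((n_samp - 1L) * substeps + 1L) - 1L) * dt_fine
  res <- with_seed(protocol$seed,
    cb_simulate(p$n_bridges, p$f_att, p$g_det0 * atp_factor,
                if (is.finite(p$g_strain_scale)) p$g_strain_scale else -1,
                as.integer(identical(p$strain_sign, "signed")),
                p$kappa, p$d_stroke, p$sarcomere_area, p$hs_length,
                strain_at(t_fine), substeps, dt_fine, p$duty_ratio))

  length_force_trace(t_samp, strain_at(t_samp), res$stress,
                     drive_frequency = protocol$frequency,
                     amplitude = if (eps0 > 0) eps0 else protocol$amplitude,
                     condition = list(atp_mM = atp_mM),
                     meta = list(params = p, attached_frac = res$frac,
                                 protocol = protocol, dt_fine = dt_fine))
}

#' Small-amplitude modulus spectrum of a cross-bridge ensemble
#'
#' Convenience sweep: simulates the ensemble under a small-amplitude
#' sinusoid at each frequency and extracts the complex modulus, averaging
#' over \code{n_seeds} independent runs per frequency to beat down
#' Monte-Carlo noise.
#'
#' @param params a \code{"crossbridge_params"}.
#' @param frequencies drive frequencies (Hz).
#' @param amplitude strain amplitude (fraction ML).
#' @param n_cycles cycles per run.
#' @param n_seeds independent runs averaged per frequency.
#' @param seed base seed; run r at frequency i uses
#'   \code{seed + 1000 * i + r}.
#' @param sample_rate_factor samples per cycle (sample rate =
#'   factor x frequency).
#' @param atp_mM passed to the simulator.
#' @return A \code{"modulus_spectrum"}.
#' @export
crossbridge_spectrum <- function(params, frequencies, amplitude = 0.00125,
                                 n_cycles = 10, n_seeds = 3, seed = 1,
                                 sample_rate_factor = 40, atp_mM = NULL) {
  el <- vi <- numeric(length(frequencies))
  for (i in seq_along(frequencies)) {
    f <- frequencies[i]
    acc_e <- acc_v <- 0
    for (r in seq_len(n_seeds)) {
      pr <- synthetic_protocol("sinusoid", frequency = f,
                               amplitude = amplitude, n_cycles = n_cycles,
                               sample_rate = sample_rate_factor * f,
                               seed = seed + 1000L * i + r)
      tr <- simulate_crossbridge_ensemble(params, pr, atp_mM = atp_mM)
      m <- extract_complex_modulus(tr)
      acc_e <- acc_e + m$elastic
      acc_v <- acc_v + m$viscous
    }
    el[i] <- acc_e / n_seeds
    vi[i] <- acc_v / n_seeds
  }
  modulus_spectrum(frequencies, el, vi, amplitude = amplitude)
}
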