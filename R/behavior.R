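#' Flight outcome counts
#'
#' @param up,horizontal,down,none numbers of flies flying up, horizontally,
#'   down, or not at all; all non-negative, total >= 1.
#' @return A \code{"flight_counts"} list with a derived \code{total}.
#' @export
flight_counts <- function(up, horizontal, down, none) {
  v <- c(up = up, horizontal = horizontal, down = down, none = none)
  if (any(v < 0)) stop("counts must be non-negative")
  total <- sum(v)
  if (total < 1) stop("total count must be at least 1")
  structure(c(as.list(v), list(total = total)), class = "flight_counts")
}

#' Flight index
#'
#' Weighted mean of flight outcomes,
#' \eqn{(6U + 4H + 2D + 0N)/T}, ranging from 0 (no fly flies) to 6 (all fly
#' up); invariant to scaling all counts by a common factor.
#'
#' @param counts a \code{"flight_counts"} object.
#' @return Numeric index in [0, 6].
#' @export
#' @examples
#' flight_index(flight_counts(50, 30, 20, 11))
flight_index <- function(counts) {
  stopifnot(inherits(counts, "flight_counts"))
  (6 * counts$up + 4 * counts$horizontal + 2 * counts$down) / counts$total
}

#' Wingbeat frequency from a tachometer trace
#'
#' Dominant frequency of the mean-removed periodogram within a
#' physiological band, with parabolic interpolation of the peak for
#' sub-bin resolution.  A wingbeat is only reported when the peak power
#' exceeds \code{min_snr} times the median spectral power inside the band;
#' otherwise the estimator signals that no wingbeat was detected.  The
#' estimate is invariant to amplitude scaling and DC offset.
#'
#' @param signal tachometer samples; at least 0.5 s long.
#' @param sample_rate sampling rate (Hz); at least 4x the band's upper edge.
#' @param band physiological search band (Hz), default 80-300 Hz.
#' @param min_snr required ratio of peak power to median in-band power.
#' @return Estimated wingbeat frequency (Hz).
#' @export
wingbeat_frequency <- function(signal, sample_rate, band = c(80, 300),
                               min_snr = 5) {
  n <- length(signal)
  if (n / sample_rate < 0.5) stop("signal must be at least 0.5 s long")
  if (sample_rate < 4 * band[2])
    stop("sample_rate must be at least 4x the upper band edge")
  x <- signal - mean(signal)
  spec <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * sample_rate / n
  half <- freqs <= sample_rate / 2
  spec <- spec[half]; freqs <- freqs[half]
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band)) stop("no spectral bins inside the search band")
  # detection on a Bartlett-averaged spectrum: averaging 8 segment
  # periodograms tames the heavy tail of single-periodogram bins, so white
  # noise no longer produces spurious peaks above the SNR criterion
  n_seg <- 8L
  seg_len <- floor(n / n_seg)
  pavg <- 0
  for (s in seq_len(n_seg)) {
    xs <- x[((s - 1L) * seg_len + 1L):(s * seg_len)]
    pavg <- pavg + Mod(stats::fft(xs))^2 / seg_len
  }
  favg <- (seq_len(seg_len) - 1) * sample_rate / seg_len
  band_avg <- favg >= band[1] & favg <= band[2]
  if (max(pavg[band_avg]) < min_snr * stats::median(pavg[band_avg]))
    stop("no wingbeat detected: no peak above ", min_snr,
         "x the median in-band power")
  pb <- spec[in_band]; fb <- freqs[in_band]
  i <- which.max(pb)
  # parabolic interpolation on log power around the peak bin
  gi <- which(in_band)[i]
  if (gi > 1L && gi < length(spec)) {
    lp <- log(pmax(spec[(gi - 1L):(gi + 1L)], .Machine$double.xmin))
    denom <- lp[1] - 2 * lp[2] + lp[3]
    delta <- if (denom != 0) 0.5 * (lp[1] - lp[3]) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    return(freqs[gi] + delta * sample_rate / n)
  }
  fb[i]
}
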