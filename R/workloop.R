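#' Decompose the work of a closed force-length path
#'
#' Trapezoidal integration of a closed loop in absolute coordinates:
#' \code{work_generated} is \eqn{\int F\,(-dL)} over the shortening samples
#' (\eqn{dL < 0}), \code{work_absorbed} is \eqn{\int F\,dL} over the
#' lengthening samples (\eqn{dL > 0}); samples with \eqn{dL = 0} contribute
#' to neither.  Net work = generated - absorbed = \eqn{-\oint F\,dL}, the
#' (signed) area of the loop; a counter-clockwise loop in the (L, F) plane
#' gives positive net work.
#'
#' @param length absolute length samples (m), first and last describing a
#'   closed path.
#' @param force force samples (N), same length.
#' @return List with \code{generated}, \code{absorbed}, \code{net} (J).
#' @export
loop_work_path <- function(length, force) {
  stopifnot(length(length) == length(force), length(length) >= 3L)
  dL <- diff(length)
  f_mid <- (force[-1] + force[-length(force)]) / 2
  seg <- f_mid * dL
  list(generated = -sum(seg[dL < 0]),
       absorbed = sum(seg[dL > 0]),
       net = -sum(seg))
}

# start indices of cycles: strain zero-crossings with positive slope
cycle_starts <- function(strain) {
  idx <- which(strain[-length(strain)] <= 0 & strain[-1] > 0)
  idx + 1L
}

#' Integrate one work-loop cycle of a trace
#'
#' Cycles are delimited by strain zero-crossings with positive slope; the
#' requested cycle is integrated in absolute coordinates (length in m,
#' force in N) and normalized by fiber volume, giving work densities in
#' J/m^3.  The loop must close: the strain at the cycle's endpoints may
#' differ by at most 1\% of the cycle's strain excursion.
#'
#' @param trace a \code{"length_force_trace"}.
#' @param cycle_index which cycle to integrate (1-based).
#' @param geometry a \code{"fiber_geometry"}.
#' @param closure_tol relative endpoint-mismatch tolerance.
#' @return Object of class \code{"workloop_result"}: list with
#'   \code{net_work}, \code{work_generated}, \code{work_absorbed} (J/m^3),
#'   \code{power} (W/m^3), \code{frequency} (Hz), \code{amplitude_pct_ml},
#'   \code{cycle_index} and \code{direction} (\code{"counter_clockwise"}
#'   when net work is positive, else \code{"clockwise"}).
#' @export
integrate_loop <- function(trace, cycle_index, geometry,
                           closure_tol = 0.01) {
  stopifnot(inherits(trace, "length_force_trace"),
            inherits(geometry, "fiber_geometry"))
  starts <- cycle_starts(trace$strain)
  if (length(starts) < cycle_index + 1L)
    stop(sprintf("cycle %d is not fully contained in the trace", cycle_index))
  i1 <- starts[cycle_index]
  i2 <- starts[cycle_index + 1L]
  idx <- i1:i2
  strain <- trace$strain[idx]
  exc <- max(strain) - min(strain)
  if (exc <= 0) stop("degenerate (constant-strain) cycle")
  # closure: endpoints of the loop must match in both strain and stress to
  # within the stated fraction of each channel's excursion, plus one
  # sample's worth of local slope (crossings are only located to sample
  # resolution)
  closed <- function(v) {
    rng <- max(v) - min(v)
    rng == 0 ||
      abs(v[length(v)] - v[1]) <= closure_tol * rng + max(abs(diff(v)))
  }
  if (!closed(strain) || !closed(trace$stress[idx]))
    stop("open (non-periodic) cycle: endpoints differ by more than 1% of excursion")
  L <- geometry$length * (1 + strain)
  Fn <- trace$stress[idx] * 1000 * geometry$cross_sectional_area  # kN/m^2 -> N
  w <- loop_work_path(L, Fn)
  v <- geometry$volume
  net <- w$net / v
  structure(list(net_work = net,
                 work_generated = w$generated / v,
                 work_absorbed = w$absorbed / v,
                 power = net * trace$drive_frequency,
                 frequency = trace$drive_frequency,
                 amplitude_pct_ml = 100 * exc / 2,
                 cycle_index = cycle_index,
                 direction = if (net > 0) "counter_clockwise" else "clockwise"),
            class = "workloop_result")
}

#' @export
print.workloop_result <- function(x, ...) {
  cat(sprintf(
    "work loop (cycle %d, %.4g Hz, %.3g%% ML, %s):\n", x$cycle_index,
    x$frequency, x$amplitude_pct_ml, x$direction))
  cat(sprintf("  net %.4g = generated %.4g - absorbed %.4g (J/m^3); power %.4g W/m^3\n",
              x$net_work, x$work_generated, x$work_absorbed, x$power))
  invisible(x)
}

#' Power of a work-loop result
#'
#' Net work per cycle multiplied by the oscillation frequency.
#'
#' @param result a \code{"workloop_result"}.
#' @return Power (W/m^3).
#' @export
loop_power <- function(result) {
  stopifnot(inherits(result, "workloop_result"))
  result$net_work * result$frequency
}

#' Grid search for the maximum-power work-loop condition
#'
#' Runs the supplied fiber at every combination of length-change amplitude
#' and oscillation frequency, integrates the configured measurement cycle
#' (cycle 8 by default, where successive loops have become consistent), and
#' returns the condition of maximal power together with the full grid.
#'
#' @param fiber function of \code{(amplitude_pct_ml, frequency)} returning a
#'   \code{"length_force_trace"} spanning at least \code{cycle + 1} cycles.
#' @param amplitudes length-change amplitudes (\% muscle length).
#' @param frequencies oscillation frequencies (Hz).
#' @param geometry a \code{"fiber_geometry"}.
#' @param cycle measurement cycle (default 8).
#' @return List with \code{best} (the winning \code{"workloop_result"}),
#'   \code{amplitude_pct_ml}, \code{frequency}, \code{grid} (data frame of
#'   every condition) and \code{all_negative} (flag: no condition produced
#'   positive power; the least-negative one is returned).
#' @export
optimize_workloop <- function(fiber, amplitudes, frequencies, geometry,
                              cycle = 8) {
  stopifnot(is.function(fiber), length(amplitudes) >= 1L,
            length(frequencies) >= 1L)
  grid <- expand.grid(amplitude_pct_ml = sort(amplitudes),
                      frequency = sort(frequencies))
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tr <- fiber(grid$amplitude_pct_ml[i], grid$frequency[i])
    results[[i]] <- integrate_loop(tr, cycle, geometry)
  }
  grid$net_work <- vapply(results, `[[`, numeric(1), "net_work")
  grid$power <- vapply(results, `[[`, numeric(1), "power")
  best_i <- which.max(grid$power)
  all_neg <- all(grid$power <= 0)
  list(best = results[[best_i]],
       amplitude_pct_ml = grid$amplitude_pct_ml[best_i],
       frequency = grid$frequency[best_i],
       grid = grid, all_negative = all_neg)
}

#' Iterative muscle-length optimization
#'
#' Mirrors the bench protocol: stretch the muscle by \code{step_pct}\% of
#' muscle length and re-measure power, stopping when the relative power
#' gain is no more than \code{stop_gain_pct}\% (boundary inclusive).
#'
#' @param fiber function of the accumulated stretch (\% ML) returning the
#'   measured power at that length.
#' @param step_pct stretch increment (\% ML).
#' @param stop_gain_pct stopping threshold on the relative power gain (\%).
#' @param max_steps safety bound on the number of stretches.
#' @return List with \code{offset_pct} (final accumulated stretch),
#'   \code{power} (power at the final length) and \code{history} (data
#'   frame of offset and power, starting at offset 0).
#' @export
optimize_muscle_length <- function(fiber, step_pct = 2, stop_gain_pct = 3,
                                   max_steps = 25) {
  stopifnot(is.function(fiber))
  offset <- 0
  p_prev <- fiber(0)
  hist_off <- offset; hist_pow <- p_prev
  for (s in seq_len(max_steps)) {
    offset <- offset + step_pct
    p_new <- fiber(offset)
    hist_off <- c(hist_off, offset); hist_pow <- c(hist_pow, p_new)
    gain <- 100 * (p_new - p_prev) / abs(p_prev)
    if (gain <= stop_gain_pct) {
      return(list(offset_pct = offset, power = p_new,
                  history = data.frame(offset_pct = hist_off,
                                       power = hist_pow)))
    }
    p_prev <- p_new
  }
  stop("max_steps exceeded without meeting the stopping rule")
}
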