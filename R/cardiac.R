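#' Detect beats in a heart-wall diameter trace
#'
#' Systolic excursions are located as contiguous runs of samples below a
#' prominence threshold: the trace's 5th-to-95th percentile range defines
#' the excursion scale, and a run must descend at least 25\% of that range
#' below the 95th-percentile (diastolic) level to count as a beat.  One
#' beat is recorded per run, anchored at its minimum (the systolic trough);
#' runs touching the ends of the trace are discarded as partial beats.
#'
#' @param trace data frame with columns \code{time} (s) and \code{diameter}
#'   (um), sampled at >= 50 Hz for >= 2 s.
#' @param prominence_frac required trough depth as a fraction of the
#'   5th-to-95th percentile range.
#' @return Data frame with one row per beat: \code{trough_index},
#'   \code{trough_time}, \code{run_start}, \code{run_end} (sample indices
#'   of the systolic excursion).
#' @export
detect_beats <- function(trace, prominence_frac = 0.25) {
  stopifnot(is.data.frame(trace), all(c("time", "diameter") %in% names(trace)))
  t <- trace$time; d <- trace$diameter
  if (length(t) < 2L) stop("trace too short")
  sr <- 1 / stats::median(diff(t))
  if (t[length(t)] - t[1] < 2) stop("need at least 2 s of signal")
  if (sr < 50) stop("sampling rate must be at least 50 Hz")
  q <- stats::quantile(d, c(0.05, 0.95), names = FALSE)
  rng <- q[2] - q[1]
  if (rng <= 0 || rng < 1e-6 * abs(q[2]))
    stop("no beats: trace is flat")
  thresh <- q[2] - prominence_frac * rng
  below <- d < thresh
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & starts > 1L & ends < length(d)
  if (!any(keep)) stop("no beats: no trough exceeds the prominence threshold")
  starts <- starts[keep]; ends <- ends[keep]
  trough <- mapply(function(a, b) a - 1L + which.min(d[a:b]), starts, ends)
  data.frame(trough_index = trough, trough_time = t[trough],
             run_start = starts, run_end = ends)
}

#' Beat-level cardiac metrics
#'
#' For each detected beat: systolic diameter \code{sd_diam} is the trough
#' minimum; diastolic diameter \code{dd} is the median of the pre-trough
#' diastolic plateau (samples above 85\% of the excursion between the
#' previous beat and this trough); heart period \code{hp} is the interval
#' from this trough to the next (NA for the last beat); systolic interval
#' \code{si} is the contiguous time the diameter stays below
#' \code{sd_diam + si_threshold * (dd - sd_diam)} around the trough.
#'
#' @param trace data frame with \code{time} and \code{diameter}.
#' @param beats output of [detect_beats()]; detected automatically when
#'   omitted.
#' @param si_threshold systolic threshold as a fraction of excursion above
#'   the systolic minimum (default 0.15).
#' @param plateau_frac diastolic plateau threshold as a fraction of
#'   excursion (default 0.85).
#' @return Data frame with one row per beat: \code{dd}, \code{sd_diam},
#'   \code{hp}, \code{si}.
#' @export
beat_metrics <- function(trace, beats = detect_beats(trace),
                         si_threshold = 0.15, plateau_frac = 0.85) {
  t <- trace$time; d <- trace$diameter
  n_b <- nrow(beats)
  out <- data.frame(dd = numeric(n_b), sd_diam = numeric(n_b),
                    hp = numeric(n_b), si = numeric(n_b))
  dt <- stats::median(diff(t))
  for (i in seq_len(n_b)) {
    tr <- beats$trough_index[i]
    sd_diam <- d[tr]
    # pre-trough segment: from the previous beat's excursion end (or trace
    # start) to the start of this beat's excursion
    seg_lo <- if (i == 1L) 1L else beats$run_end[i - 1L] + 1L
    seg_hi <- max(beats$run_start[i] - 1L, seg_lo)
    seg <- d[seg_lo:seg_hi]
    exc0 <- max(seg) - sd_diam
    if (exc0 <= 0) stop("degenerate beat: no diastolic excursion")
    plateau <- seg[seg >= sd_diam + plateau_frac * exc0]
    if (length(plateau) < 3L) stop("diastolic plateau shorter than 3 samples")
    dd <- stats::median(plateau)
    if (dd <= sd_diam) stop("degenerate beat: dd <= sd")
    thr <- sd_diam + si_threshold * (dd - sd_diam)
    lo <- tr; while (lo > 1L && d[lo - 1L] < thr) lo <- lo - 1L
    hi <- tr; while (hi < length(d) && d[hi + 1L] < thr) hi <- hi + 1L
    # sub-threshold duration, counting half a sample beyond each end
    si <- (hi - lo) * dt + dt
    hp <- if (i < n_b) beats$trough_time[i + 1L] - beats$trough_time[i]
          else NA_real_
    out$dd[i] <- dd; out$sd_diam[i] <- sd_diam
    out$hp[i] <- hp; out$si[i] <- si
  }
  out
}

#' Summarize a heart-wall diameter trace
#'
#' Averages per-beat metrics and derives fractional shortening
#' \eqn{FS = 100 (DD - SD)/DD}, diastolic interval \eqn{DI = HP - SI} and
#' the systolic fraction \eqn{SI/HP} from the mean diameters and intervals
#' (per-beat derivation is available via \code{fs_mode = "per_beat"}).
#'
#' @param trace data frame with \code{time} and \code{diameter}.
#' @param fs_mode \code{"from_means"} (default) computes FS and SI/HP from
#'   mean diameters/intervals; \code{"per_beat"} averages per-beat ratios.
#' @param ... passed to [beat_metrics()].
#' @return Object of class \code{"cardiac_summary"}: list with \code{dd},
#'   \code{sd_diam} (um), \code{fs_pct}, \code{hp}, \code{si}, \code{di}
#'   (s), \code{si_over_hp}, \code{n_beats}, and \code{per_beat} (the beat
#'   table).
#' @export
summarize_heart <- function(trace, fs_mode = c("from_means", "per_beat"), ...) {
  fs_mode <- match.arg(fs_mode)
  beats <- detect_beats(trace)
  if (nrow(beats) < 3L) stop("need at least 3 beats to summarize a heart")
  bm <- beat_metrics(trace, beats, ...)
  dd <- mean(bm$dd); sd_diam <- mean(bm$sd_diam)
  hp <- mean(bm$hp, na.rm = TRUE); si <- mean(bm$si)
  if (fs_mode == "from_means") {
    fs <- 100 * (dd - sd_diam) / dd
    si_over_hp <- si / hp
  } else {
    fs <- mean(100 * (bm$dd - bm$sd_diam) / bm$dd)
    si_over_hp <- mean(bm$si / bm$hp, na.rm = TRUE)
  }
  structure(list(dd = dd, sd_diam = sd_diam, fs_pct = fs, hp = hp, si = si,
                 di = hp - si, si_over_hp = si_over_hp,
                 n_beats = nrow(bm), per_beat = bm),
            class = "cardiac_summary")
}

#' @export
print.cardiac_summary <- function(x, ...) {
  cat(sprintf("cardiac summary over %d beats:\n", x$n_beats))
  cat(sprintf("  DD %.4g um, SD %.4g um, FS %.3g%%\n", x$dd, x$sd_diam, x$fs_pct))
  cat(sprintf("  HP %.4g s, SI %.4g s, DI %.4g s, SI/HP %.3g\n",
              x$hp, x$si, x$di, x$si_over_hp))
  invisible(x)
}

#' Analyze the chelation/blebbistatin relaxation assay
#'
#' Each heart is measured at diastole (baseline), after extra- and
#' intracellular calcium chelation, and after subsequent blebbistatin
#' incubation.  Per heart, \eqn{\Delta_1} = post-chelation - baseline (the
#' calcium-dependent component of resting tone) and \eqn{\Delta_2} =
#' post-blebbistatin - post-chelation (the calcium-independent,
#' cross-bridge-dependent component).  Within each genotype both steps are
#' tested with paired t-tests; between two genotypes the deltas are
#' compared with unpaired two-tailed Student t-tests.
#'
#' @param records data frame with columns \code{heart_id}, \code{genotype},
#'   \code{baseline}, \code{post_chelation}, \code{post_blebbistatin}
#'   (diameters, um).
#' @return List with \code{per_genotype} (data frame of mean +/- SEM of
#'   each delta and paired-test p-values per genotype, with a
#'   \code{zero_variance} flag when a paired test is undefined) and
#'   \code{between} (data frame of unpaired comparisons of each delta
#'   between the first two genotypes, NULL when only one genotype is
#'   present).
#' @export
relaxation_assay <- function(records) {
  need <- c("heart_id", "genotype", "baseline", "post_chelation",
            "post_blebbistatin")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  records$d1 <- records$post_chelation - records$baseline
  records$d2 <- records$post_blebbistatin - records$post_chelation
  gs <- unique(records$genotype)
  per <- do.call(rbind, lapply(gs, function(g) {
    r <- records[records$genotype == g, ]
    if (nrow(r) < 2L) stop("need at least 2 hearts per genotype")
    paired_p <- function(post, pre) {
      if (stats::sd(post - pre) == 0) NA_real_
      else stats::t.test(post, pre, paired = TRUE)$p.value
    }
    data.frame(genotype = g, n = nrow(r),
               mean_d1 = mean(r$d1), sem_d1 = stats::sd(r$d1) / sqrt(nrow(r)),
               mean_d2 = mean(r$d2), sem_d2 = stats::sd(r$d2) / sqrt(nrow(r)),
               p_paired_d1 = paired_p(r$post_chelation, r$baseline),
               p_paired_d2 = paired_p(r$post_blebbistatin, r$post_chelation),
               zero_variance = stats::sd(r$d1) == 0 || stats::sd(r$d2) == 0)
  }))
  between <- NULL
  if (length(gs) >= 2L) {
    a <- records[records$genotype == gs[1], ]
    b <- records[records$genotype == gs[2], ]
    tt <- function(x, y) stats::t.test(x, y, var.equal = TRUE)$p.value
    between <- data.frame(
      delta = c("d1", "d2"),
      reference = gs[1], test = gs[2],
      p_unpaired = c(tt(a$d1, b$d1), tt(a$d2, b$d2)))
  }
  list(per_genotype = per, between = between)
}
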