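#' Three-process complex-modulus model parameters
#'
#' Container for the parameters of the three-term complex modulus model used
#' to describe oscillatory muscle fiber mechanics,
#' \deqn{Y(f) = A (2\pi i f/\alpha)^k - B\,\frac{if}{b+if} + C\,\frac{if}{c+if},}
#' where the A-process is a weak power law capturing passive viscoelasticity,
#' the B-process is the work-producing exponential process (negative viscous
#' modulus at intermediate frequencies) and the C-process the work-absorbing
#' one.  The characteristic frequencies \code{b} and \code{c} (Hz) multiplied
#' by \eqn{2\pi} give the apparent rate constants (s^-1) conventionally
#' interpreted as proxies for cross-bridge attachment/power-stroke and
#' detachment steps, respectively.
#'
#' @param A,B,C process amplitudes (modulus units, typically kN/m^2); all
#'   must be non-negative.
#' @param k dimensionless power-law exponent of the A-process, in [0, 1).
#' @param alpha reference frequency (Hz) of the power law; conventionally
#'   fixed, not fitted.
#' @param b,c characteristic frequencies (Hz) of the B- and C-processes;
#'   strictly positive.
#' @return An object of class \code{"nyquist_params"}: a named list with the
#'   seven parameters plus the derived rate constants \code{two_pi_b} and
#'   \code{two_pi_c}.
#' @seealso [eval_nyquist()], [fit_nyquist()]
#' @export
#' @examples
#' p <- nyquist_params(A = 339, k = 0.12, B = 741, b = 1036 / (2 * pi),
#'                     C = 923, c = 5376 / (2 * pi))
#' eval_nyquist(p, c(10, 100, 500))
nyquist_params <- function(A, k = 0.12, alpha = 1, B, b, C, c) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C),
            length(A) == 1L, length(B) == 1L, length(C) == 1L)
  if (A < 0 || B < 0 || C < 0)
    stop("process amplitudes A, B, C must be non-negative")
  if (k < 0 || k >= 1) stop("exponent k must lie in [0, 1)")
  if (alpha <= 0) stop("reference frequency alpha must be positive")
  if (b <= 0 || c <= 0) stop("characteristic frequencies b, c must be positive")
  structure(list(A = A, k = k, alpha = alpha, B = B, b = b, C = C, c = c,
                 two_pi_b = 2 * pi * b, two_pi_c = 2 * pi * c),
            class = "nyquist_params")
}

#' Evaluate the three-process complex modulus model
#'
#' @param params a \code{"nyquist_params"} object (or a fitted
#'   \code{"nyquist_fit"}, whose parameters are used).
#' @param f frequencies (Hz), strictly positive.
#' @return Complex vector \eqn{Y(f)}; \code{Re} is the elastic (in-phase)
#'   modulus E', \code{Im} the viscous (quadrature) modulus E''.
#' @export
eval_nyquist <- function(params, f) {
  if (inherits(params, "nyquist_fit")) params <- params$params
  if (!inherits(params, "nyquist_params"))
    stop("'params' must be a nyquist_params or nyquist_fit object")
  if (any(f <= 0)) stop("frequencies must be strictly positive")
  p <- params
  # principal branch of (i w)^k: modulus^k * exp(i k pi/2)
  w <- 2 * pi * f / p$alpha
  a_term <- p$A * w^p$k * complex(modulus = 1, argument = p$k * pi / 2)
  b_term <- -p$B * (1i * f) / (p$b + 1i * f)
  c_term <- p$C * (1i * f) / (p$c + 1i * f)
  a_term + b_term + c_term
}

# residual vector (Re, Im stacked) for least-squares fitting
nyquist_residuals <- function(par, f, y_obs, alpha) {
  p <- list(A = par[["A"]], k = par[["k"]], alpha = alpha,
            B = par[["B"]], b = par[["b"]], C = par[["C"]], c = par[["c"]])
  w <- 2 * pi * f / alpha
  y <- p$A * w^p$k * complex(modulus = 1, argument = p$k * pi / 2) -
    p$B * (1i * f) / (p$b + 1i * f) +
    p$C * (1i * f) / (p$c + 1i * f)
  d <- y - y_obs
  c(Re(d), Im(d))
}

#' Fit the three-process complex-modulus model to a measured spectrum
#'
#' Minimizes the squared complex residual
#' \eqn{\sum_f |Y_{obs}(f) - Y_{model}(f)|^2} over the six free parameters
#' \code{A, k, B, b, C, c} (the reference frequency \code{alpha} is held
#' fixed) by bounded Levenberg-Marquardt least squares
#' (\code{minpack.lm::nls.lm}) from multiple starting points: one heuristic
#' start derived from the spectrum plus \code{n_starts} random log-uniform
#' initializations.  Among converged solutions the lowest sum of squared
#' errors wins, preferring solutions with \code{b <= c} (the conventional
#' labelling: the work-producing process is the slower one); near-ties
#' (relative SSE difference below 1e-9) are broken toward the smallest
#' \code{c} for determinism.
#'
#' @param spectrum a \code{"modulus_spectrum"} (see [sweep_spectrum()]) or a
#'   data frame with columns \code{frequency}, \code{elastic}, \code{viscous}.
#' @param alpha fixed reference frequency (Hz) of the A-process power law.
#' @param f_range numeric length-2; only frequencies within this interval are
#'   fit.  The default drops the lowest frequencies, where the power-law
#'   process dominates and slow drift corrupts phase in real recordings.
#' @param n_starts number of random multi-start initializations.
#' @param seed integer seed for the random starts (reproducibility).
#' @param enforce_order prefer solutions with \code{b <= c} (the fiber
#'   convention: the work-producing process is the slower one).  Set FALSE
#'   when fitting systems whose work-producing process may be the faster
#'   one; the processes are then identified purely by their sign in the
#'   model.
#' @return Object of class \code{"nyquist_fit"}: a list with elements
#'   \code{params} (a \code{"nyquist_params"}), \code{sse},
#'   \code{n_freq_used}, \code{converged}, \code{unidentifiable} (flag set
#'   when an exponential-process amplitude collapses to the lower bound),
#'   \code{residuals} (complex, per used frequency), \code{frequency} (the
#'   frequencies used) and \code{n_starts_converged}.
#' @export
#' @examples
#' p <- nyquist_params(A = 339, k = 0.12, B = 741, b = 1036 / (2 * pi),
#'                     C = 923, c = 5376 / (2 * pi))
#' f <- exp(seq(log(0.5), log(650), length.out = 50))
#' y <- eval_nyquist(p, f)
#' spec <- modulus_spectrum(f, Re(y), Im(y), amplitude = 0.00125)
#' fit <- fit_nyquist(spec, f_range = c(0.5, 650), seed = 1)
#' coef(fit)[["two_pi_c"]]
fit_nyquist <- function(spectrum, alpha = 1, f_range = c(5, 650),
                        n_starts = 20, seed = NULL, enforce_order = TRUE) {
  spec <- as.data.frame(spectrum)
  stopifnot(all(c("frequency", "elastic", "viscous") %in% names(spec)))
  keep <- spec$frequency >= f_range[1] & spec$frequency <= f_range[2]
  spec <- spec[keep, , drop = FALSE]
  if (nrow(spec) < 6L)
    stop("need at least 6 frequencies within f_range to fit 6 parameters")
  f <- spec$frequency
  y_obs <- complex(real = spec$elastic, imaginary = spec$viscous)

  lower <- c(A = 0, k = 0, B = 0, b = 0.1, C = 0, c = 0.1)
  upper <- c(A = 1e6, k = 0.5, B = 1e6, b = 5000, C = 5000, c = 5000)
  upper[["C"]] <- 1e6

  starts <- list(heuristic_start(f, y_obs))
  if (n_starts > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    mag <- stats::median(Mod(y_obs))
    for (i in seq_len(n_starts)) {
      rates <- sort(exp(stats::runif(2, log(1), log(3000))))
      starts[[i + 1L]] <- c(
        A = exp(stats::runif(1, log(mag / 100), log(mag * 2))),
        k = stats::runif(1, 0.01, 0.4),
        B = exp(stats::runif(1, log(mag / 100), log(mag * 5))),
        b = rates[1],
        C = exp(stats::runif(1, log(mag / 100), log(mag * 5))),
        c = rates[2])
    }
  }

  fits <- lapply(starts, function(st) {
    st <- pmin(pmax(st, lower + 1e-8), upper - 1e-8)
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = nyquist_residuals, f = f, y_obs = y_obs,
                         alpha = alpha,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    list(par = res$par, sse = sum(res$fvec^2),
         converged = res$info %in% 1:4)
  })
  fits <- Filter(function(x) !is.null(x) && x$converged, fits)

  if (length(fits) == 0L) {
    # best effort from the heuristic start without convergence guarantee
    st <- pmin(pmax(starts[[1]], lower + 1e-8), upper - 1e-8)
    res <- minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                              fn = nyquist_residuals, f = f, y_obs = y_obs,
                              alpha = alpha)
    fits <- list(list(par = res$par, sse = sum(res$fvec^2), converged = FALSE))
  }

  sses <- vapply(fits, `[[`, numeric(1), "sse")
  cs <- vapply(fits, function(x) x$par[["c"]], numeric(1))
  bs <- vapply(fits, function(x) x$par[["b"]], numeric(1))
  ordered <- bs <= cs
  pool <- if (enforce_order && any(ordered)) which(ordered) else seq_along(fits)
  best_sse <- min(sses[pool])
  # near-ties resolved toward smallest c for determinism
  tied <- pool[sses[pool] <= best_sse + 1e-9 * max(best_sse, 1e-300)]
  best <- tied[which.min(cs[tied])]
  pb <- fits[[best]]$par

  params <- nyquist_params(A = pb[["A"]], k = pb[["k"]], alpha = alpha,
                           B = pb[["B"]], b = max(pb[["b"]], 1e-12),
                           C = pb[["C"]], c = max(pb[["c"]], 1e-12))
  resid <- eval_nyquist(params, f) - y_obs
  mag <- stats::median(Mod(y_obs))
  unident <- pb[["B"]] < 1e-6 * mag || pb[["C"]] < 1e-6 * mag
  structure(list(params = params, sse = fits[[best]]$sse,
                 n_freq_used = length(f),
                 converged = fits[[best]]$converged,
                 unidentifiable = unident,
                 residuals = resid, frequency = f,
                 n_starts_converged = length(fits),
                 start_sse = sses),
            class = "nyquist_fit")
}

# heuristic initialization: b from the frequency of minimum viscous modulus
# (the work-producing dip), c = 5 b, A from the mean |Y| at the high end
heuristic_start <- function(f, y_obs) {
  b0 <- f[which.min(Im(y_obs))]
  hi <- f >= stats::quantile(f, 0.8)
  A0 <- mean(Mod(y_obs)[hi])
  span <- max(Mod(y_obs)) - min(Re(y_obs))
  c(A = max(A0, 1e-3), k = 0.12,
    B = max(-2 * min(Im(y_obs)), span / 2, 1e-3), b = max(b0, 1),
    C = max(2 * max(Im(y_obs)), span / 2, 1e-3), c = min(5 * max(b0, 1), 4000))
}

#' @export
coef.nyquist_fit <- function(object, ...) {
  p <- object$params
  c(A = p$A, k = p$k, alpha = p$alpha, B = p$B, b = p$b, C = p$C, c = p$c,
    two_pi_b = p$two_pi_b, two_pi_c = p$two_pi_c)
}

#' @export
predict.nyquist_fit <- function(object, f = object$frequency, ...) {
  eval_nyquist(object$params, f)
}

#' @export
print.nyquist_fit <- function(x, digits = 4, ...) {
  p <- x$params
  cat("Three-process complex modulus fit\n")
  cat(sprintf("  A = %.*g (k = %.*g, alpha = %g Hz fixed)\n",
              digits, p$A, digits, p$k, p$alpha))
  cat(sprintf("  B = %.*g, b = %.*g Hz  (2 pi b = %.*g 1/s)\n",
              digits, p$B, digits, p$b, digits, p$two_pi_b))
  cat(sprintf("  C = %.*g, c = %.*g Hz  (2 pi c = %.*g 1/s)\n",
              digits, p$C, digits, p$c, digits, p$two_pi_c))
  cat(sprintf("  SSE %.4g over %d frequencies; converged: %s\n",
              x$sse, x$n_freq_used, x$converged))
  if (isTRUE(x$unidentifiable))
    cat("  note: an exponential-process amplitude collapsed toward zero;\n",
        "  the corresponding rate constant is not identifiable\n")
  invisible(x)
}

#' @export
summary.nyquist_fit <- function(object, ...) {
  out <- list(coefficients = coef(object), sse = object$sse,
              rmse = sqrt(object$sse / (2 * object$n_freq_used)),
              n_freq_used = object$n_freq_used,
              converged = object$converged,
              unidentifiable = object$unidentifiable,
              n_starts_converged = object$n_starts_converged)
  class(out) <- "summary.nyquist_fit"
  out
}

#' @export
print.summary.nyquist_fit <- function(x, ...) {
  cat("Three-process complex modulus fit\n\nCoefficients:\n")
  print(x$coefficients)
  cat(sprintf("\nSSE: %.6g  RMSE: %.6g  (%d frequencies, %d converged starts)\n",
              x$sse, x$rmse, x$n_freq_used, x$n_starts_converged))
  invisible(x)
}

#' @export
plot.nyquist_fit <- function(x, n_dense = 300, ...) {
  f_dense <- exp(seq(log(min(x$frequency)), log(max(x$frequency)),
                     length.out = n_dense))
  y_dense <- predict(x, f_dense)
  y_obs <- predict(x, x$frequency) - x$residuals
  graphics::plot(Re(y_obs), Im(y_obs), xlab = "elastic modulus E'",
                 ylab = "viscous modulus E''",
                 main = "Nyquist plot: data and three-process fit", ...)
  graphics::lines(Re(y_dense), Im(y_dense), col = "red3")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Percent contrast of apparent rate constants between two fits
#'
#' Reports the relative change of the apparent rate constants
#' \eqn{2\pi b} and \eqn{2\pi c} of a test fit with respect to a reference
#' fit, as \eqn{100 (x_{test} - x_{ref})/x_{ref}}, the convention used when
#' comparing mutant to control fibers.
#'
#' @param fit_ref,fit_test converged \code{"nyquist_fit"} objects (or
#'   \code{"nyquist_params"}), reference first.
#' @param round_pct round to the nearest percent for reporting (default TRUE).
#' @return Named numeric vector with elements \code{two_pi_b} and
#'   \code{two_pi_c} (percent).
#' @export
rate_constant_contrast <- function(fit_ref, fit_test, round_pct = TRUE) {
  get_p <- function(x) {
    if (inherits(x, "nyquist_fit")) {
      if (!isTRUE(x$converged)) stop("rate-constant contrast needs converged fits")
      x$params
    } else if (inherits(x, "nyquist_params")) x
    else stop("inputs must be nyquist_fit or nyquist_params objects")
  }
  a <- get_p(fit_ref); b <- get_p(fit_test)
  out <- c(two_pi_b = 100 * (b$two_pi_b - a$two_pi_b) / a$two_pi_b,
           two_pi_c = 100 * (b$two_pi_c - a$two_pi_c) / a$two_pi_c)
  if (round_pct) round(out) else out
}
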