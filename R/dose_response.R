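#' Fit the Michaelis-Menten saturation model
#'
#' Nonlinear least squares of \eqn{y = v_{max} x / (K_m + x)}.  When a basal
#' rate is supplied it is subtracted from every response first (the
#' convention for actin-activated ATPase, where basal Mg-ATPase is measured
#' without actin).  Initialization: \eqn{v_{max,0} = \max y},
#' \eqn{K_{m,0}} = the smallest concentration whose response reaches half of
#' \eqn{\max y}; both parameters are bounded below by a small positive
#' value.  The fit is flagged unidentifiable when \eqn{K_m} runs into its
#' bounds (data not saturating).
#'
#' @param x concentrations; at least 3 distinct positive values.
#' @param y responses (same length, finite).
#' @param basal optional basal rate subtracted from \code{y} before fitting.
#' @return Object of class \code{"mm_fit"}: list with \code{vmax},
#'   \code{km}, \code{efficiency} (= vmax/km), \code{se_vmax}, \code{se_km},
#'   \code{n_points}, \code{basal}, \code{unidentifiable}, \code{fit} (the
#'   underlying \code{nls} object).
#' @export
#' @examples
#' d <- gen_dose_response(vmax = 1.57, km = 0.42, basal = 0.62,
#'                        x_values = seq(0.1, 2, by = 0.1))
#' fit_mm(d$x, d$rate, basal = 0.62)
fit_mm <- function(x, y, basal = NULL) {
  stopifnot(length(x) == length(y))
  if (!all(is.finite(y))) stop("responses must be finite")
  if (length(unique(x[x > 0])) < 3L)
    stop("need at least 3 distinct positive concentrations")
  if (!is.null(basal)) y <- y - basal
  dat <- data.frame(x = x, y = y)
  vmax0 <- max(y)
  if (vmax0 <= 0) stop("responses do not rise above zero after basal subtraction")
  ord <- order(x)
  half <- x[ord][which(y[ord] >= vmax0 / 2)[1]]
  km0 <- if (is.na(half) || half <= 0) stats::median(x[x > 0]) else half
  lower <- c(vmax = 1e-12, km = 1e-12)
  upper <- c(vmax = Inf, km = 1e6 * max(x))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ vmax * x / (km + x), data = dat,
                      start = list(vmax = vmax0, km = km0),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit did not converge: ",
                             conditionMessage(e)))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  unident <- est[["km"]] <= 2 * lower[["km"]] ||
    est[["km"]] >= 0.99 * upper[["km"]]
  structure(list(vmax = est[["vmax"]], km = est[["km"]],
                 efficiency = est[["vmax"]] / est[["km"]],
                 se_vmax = unname(se["vmax"]), se_km = unname(se["km"]),
                 n_points = length(x), basal = basal,
                 unidentifiable = unident, fit = fit),
            class = "mm_fit")
}

#' @export
coef.mm_fit <- function(object, ...) c(vmax = object$vmax, km = object$km)

#' @export
predict.mm_fit <- function(object, x, ...) {
  object$vmax * x / (object$km + x)
}

#' @export
print.mm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Michaelis-Menten fit (n = %d):\n", x$n_points))
  cat(sprintf("  Vmax = %.*g +/- %.2g\n", digits, x$vmax, x$se_vmax))
  cat(sprintf("  Km   = %.*g +/- %.2g\n", digits, x$km, x$se_km))
  cat(sprintf("  catalytic efficiency Vmax/Km = %.*g\n", digits, x$efficiency))
  if (!is.null(x$basal)) cat(sprintf("  basal %.4g subtracted before fitting\n", x$basal))
  if (x$unidentifiable)
    cat("  warning: Km at its bound - data do not constrain saturation\n")
  invisible(x)
}

#' @export
summary.mm_fit <- function(object, ...) summary(object$fit, ...)

#' Catalytic efficiency of a Michaelis-Menten fit
#'
#' The ratio \eqn{v_{max}/K_m}.  Note that when replicate preparations are
#' each fit separately, the mean of per-replicate ratios is generally not
#' the ratio computed from pooled parameter estimates; report which
#' estimator is used.
#'
#' @param fit an \code{"mm_fit"}.
#' @return \code{vmax / km}.
#' @export
catalytic_efficiency <- function(fit) {
  stopifnot(inherits(fit, "mm_fit"))
  fit$vmax / fit$km
}

#' Fit f_max versus ATP concentration
#'
#' Michaelis-Menten fit of the optimal oscillation frequency f_max against
#' [ATP] (no basal subtraction); the fitted \eqn{K_m} measures the apparent
#' ATP affinity of the fiber's cross-bridge cycling rate.
#'
#' @param atp ATP concentrations (mM).
#' @param fmax f_max values (Hz).
#' @return An \code{"mm_fit"}.
#' @export
fit_fmax_vs_atp <- function(atp, fmax) fit_mm(atp, fmax, basal = NULL)

#' Linear fit of f_max versus phosphate concentration
#'
#' Ordinary least squares of f_max on [Pi]; the slope's two-sided t-test
#' p-value distinguishes fibers whose optimal frequency declines with
#' phosphate from those (control-like) with no trend.
#'
#' @param pi_mM phosphate concentrations (mM); at least 3 distinct values.
#' @param fmax f_max values (Hz).
#' @return Object of class \code{"linear_fit"}: list with \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{p_slope}, \code{fit} (the
#'   \code{lm} object).
#' @export
fit_fmax_vs_pi <- function(pi_mM, fmax) {
  stopifnot(length(pi_mM) == length(fmax))
  if (length(unique(pi_mM)) < 2L) stop("degenerate x: need at least 2 distinct [Pi]")
  if (length(pi_mM) < 3L) stop("need at least 3 points")
  fit <- stats::lm(fmax ~ pi_mM)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_slope = sm$coefficients[2, 4],
                 fit = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, digits = 4, ...) {
  cat(sprintf("linear fit: slope %.*g (p = %.3g), intercept %.*g, R^2 = %.3f\n",
              digits, x$slope, x$p_slope, digits, x$intercept, x$r_squared))
  invisible(x)
}
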