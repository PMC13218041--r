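# FRAP trace processing: double normalization, 0-100 rescaling,
# exponential-asymptote recovery fit, half-recovery time.

#' Construct a FRAP trace
#'
#' Holds the three raw channels of a photobleaching experiment: the
#' bleached region of interest (R1), an unbleached reference region (R2)
#' tracking acquisition photobleaching, and a cell-free background (R3),
#' together with their prebleach values.
#'
#' @param t seconds from bleach, non-negative increasing.
#' @param I_R1,I_R2,I_R3 intensity series, equal length.
#' @param I_R1_pre,I_R2_pre,I_R3_pre prebleach intensities.
#' @return object of class `frap_trace`.
#' @export
frap_trace <- function(t, I_R1, I_R2, I_R3,
                       I_R1_pre, I_R2_pre, I_R3_pre) {
  n <- length(t)
  if (length(I_R1) != n || length(I_R2) != n || length(I_R3) != n)
    stopf("all channels must have the same length as `t`")
  if (any(t < 0) || any(diff(t) <= 0))
    stopf("`t` must be non-negative and strictly increasing")
  pre <- c(I_R1_pre, I_R2_pre, I_R3_pre)
  if (length(pre) != 3L || any(!is.finite(pre)))
    stopf("prebleach values must be three finite numbers")
  structure(list(t = as.numeric(t), I_R1 = as.numeric(I_R1),
                 I_R2 = as.numeric(I_R2), I_R3 = as.numeric(I_R3),
                 I_R1_pre = I_R1_pre, I_R2_pre = I_R2_pre,
                 I_R3_pre = I_R3_pre),
            class = "frap_trace")
}

#' Double normalization of a FRAP trace
#'
#' Corrects the bleached-ROI signal for background and for acquisition
#' photobleaching using the reference ROI:
#' I(t) = (I_R1(t) - I_R3(t)) * (I_R2_pre - I_R3_pre) / (I_R2(t) - I_R3(t)).
#' A constant background added to all channels cancels exactly, and a
#' drifting reference is divided out.
#'
#' @param trace `frap_trace`.
#' @return numeric corrected intensity series.
#' @export
frap_double_normalize <- function(trace) {
  gap <- trace$I_R2 - trace$I_R3
  bad <- which(abs(gap) < .Machine$double.eps * 100)
  if (length(bad))
    stopf("reference - background gap is zero at t = %g s; cannot normalize",
          trace$t[bad[1L]])
  (trace$I_R1 - trace$I_R3) * (trace$I_R2_pre - trace$I_R3_pre) / gap
}

#' Min-max normalization of a corrected FRAP series to 0-100
#'
#' 100 * (I - I_min) / (I_pre - I_min): the post-bleach minimum maps to 0
#' and the prebleach intensity to 100, so the series reads directly as
#' percent recovery of the prebleach signal.
#'
#' @param series corrected intensity series.
#' @param prebleach corrected prebleach intensity.
#' @return numeric 0-100 series.
#' @export
frap_minmax_normalize <- function(series, prebleach) {
  I_min <- min(series)
  if (!(prebleach > I_min))
    stopf("degenerate trace: prebleach intensity does not exceed the minimum")
  100 * (series - I_min) / (prebleach - I_min)
}

#' Fit an exponential asymptotic recovery curve
#'
#' Least-squares fit of y(t) = a - b * c^t with a > 0, b > 0 and
#' 0 < c < 1: `a` is the asymptotic recovery limit (the mobile fraction,
#' in percent of prebleach when `y` is 0-100 normalized), `b` the bleach
#' amplitude, and `c` the per-second exponential base.
#'
#' @param t seconds (>= 8 points).
#' @param y normalized recovery series.
#' @return object of class `frap_fit`: list with `a`, `b`, `c`,
#'   `mobile_fraction` (= a), `t_half` (numeric half-recovery, see
#'   [half_time()]), `residuals`.
#' @export
fit_recovery <- function(t, y) {
  if (length(t) != length(y)) stopf("t and y must have equal length")
  if (length(t) < 8L) stopf("need at least 8 points to fit recovery")
  a0 <- max(y)
  b0 <- max(a0 - y[1L], 1e-6)
  if (diff(range(y)) < 1e-6 * max(1, abs(a0))) {
    warnf("trace is flat; degenerate fit with b ~ 0")
    fit_par <- c(a = mean(y), b = 1e-9, c = 0.5)
    res <- y - mean(y)
  } else {
    df <- data.frame(t = t, y = y)
    fit <- tryCatch(
      nls(y ~ a - b * c^t, data = df,
          start = list(a = a0, b = b0, c = 0.9),
          algorithm = "port",
          lower = c(a = 1e-9, b = 1e-9, c = 1e-9),
          upper = c(a = Inf, b = Inf, c = 1 - 1e-9),
          control = nls.control(maxiter = 500, warnOnly = FALSE)),
      error = function(e) stopf("recovery fit failed to converge: %s",
                                conditionMessage(e)))
    fit_par <- coef(fit)
    res <- as.numeric(stats::residuals(fit))
  }
  out <- structure(list(a = unname(fit_par["a"]), b = unname(fit_par["b"]),
                        c = unname(fit_par["c"]),
                        mobile_fraction = unname(fit_par["a"]),
                        residuals = res, t = t, y = y),
                   class = "frap_fit")
  # a degenerate flat trace never crosses a/2; report 0 without re-warning
  out$t_half <- if (out$b <= 1e-8) 0 else half_time(out, method = "numeric")
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("FRAP fit: y(t) = %.2f - %.2f * %.4f^t ; t1/2 = %.3f s, mobile fraction %.1f%%\n",
              x$a, x$b, x$c, x$t_half, x$mobile_fraction))
  invisible(x)
}

#' Half-recovery time of a fitted FRAP curve
#'
#' The canonical `numeric` method solves y(t) = a/2 on the fitted curve
#' a - b*c^t, giving t1/2 = log(a / (2 b)) / log(c); when the curve starts
#' at or above a/2 (b <= a/2) the crossing is at or before t = 0 and 0 is
#' returned with a warning. The `closed_form` method evaluates the
#' conventional printed expression t1/2 = log_c(1 / (2 a b)) verbatim; it
#' agrees with the numeric solve only when a = 1 (unit-normalized curves)
#' and is provided for comparison with legacy spreadsheets.
#'
#' @param fit `frap_fit` (or any list with a, b, c).
#' @param method "numeric" (default) or "closed_form".
#' @return seconds.
#' @export
half_time <- function(fit, method = c("numeric", "closed_form")) {
  method <- match.arg(method)
  a <- fit$a; b <- fit$b; c <- fit$c
  if (!(c > 0 && c < 1)) stopf("exponential base c must lie in (0, 1)")
  if (a <= 0 || b <= 0) stopf("a and b must be positive")
  if (method == "closed_form")
    return(log(1 / (2 * a * b)) / log(c))
  ratio <- a / (2 * b)          # c^t = a/(2b) at the half crossing
  if (ratio >= 1) {
    warnf("recovery already above a/2 at t = 0; returning t_half = 0")
    return(0)
  }
  log(ratio) / log(c)
}
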