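# Droplet fusion relaxation: aspect ratio series, single-exponential decay
# fit, characteristic fusion time tau and cross-event summaries.

#' Aspect ratio series from ellipse axes
#'
#' AR = l_long / l_short per frame. Frames where the nominal long axis is
#' shorter than the nominal short axis are swapped with a warning, so the
#' series is always >= 1 regardless of how the ellipse fitter ordered its
#' axes.
#'
#' @param l_long,l_short positive axis series in micrometres.
#' @return numeric AR series (>= 1).
#' @export
aspect_ratio_series <- function(l_long, l_short) {
  if (length(l_long) != length(l_short))
    stopf("axis series must have equal length")
  if (any(l_long <= 0) || any(l_short <= 0))
    stopf("ellipse axes must be strictly positive")
  swapped <- l_long < l_short
  if (any(swapped)) {
    warnf("%d frame(s) had l_long < l_short; axes swapped", sum(swapped))
    tmp <- l_long[swapped]
    l_long[swapped] <- l_short[swapped]
    l_short[swapped] <- tmp
  }
  l_long / l_short
}

#' Fit a single-exponential fusion relaxation
#'
#' Least-squares fit of AR(t) = 1 + (AR0 - 1) * exp(-t / tau), the
#' liquid-droplet coalescence model: two touching droplets relax to a
#' single sphere (AR -> 1) with characteristic fusion time tau, a proxy
#' for the inverse capillary velocity. Bounded optimisation (tau > 0,
#' AR0 >= 1) initialised from AR at t = 0 and the 1/e crossing time.
#'
#' @param t seconds (>= 6 frames, increasing).
#' @param AR aspect ratio series.
#' @return object of class `fusion_fit`: list with `AR0`, `tau`, `rss`,
#'   `fitted`.
#' @export
fit_fusion_decay <- function(t, AR) {
  if (length(t) != length(AR)) stopf("t and AR must have equal length")
  if (length(t) < 6L) stopf("need at least 6 frames to fit fusion decay")
  if (any(AR < 1 - 1e-9)) stopf("aspect ratios must be >= 1")
  amp0 <- AR[1L] - 1
  if (max(AR) - 1 < 1e-6)
    stopf("degenerate fit: AR is 1 throughout (no fusion deformation)")
  # 1/e crossing of the excess aspect ratio for the tau initial value
  below <- which(AR - 1 <= amp0 / exp(1))
  tau0 <- if (length(below)) max(t[below[1L]], diff(range(t)) / 50) else
    diff(range(t)) / 2
  df <- data.frame(t = t, AR = AR)
  fit <- tryCatch(
    nls(AR ~ 1 + (AR0 - 1) * exp(-t / tau), data = df,
        start = list(AR0 = max(AR[1L], 1 + 1e-3), tau = tau0),
        algorithm = "port",
        lower = c(AR0 = 1, tau = 1e-9),
        control = nls.control(maxiter = 500, warnOnly = FALSE)),
    error = function(e) stopf("fusion fit failed to converge: %s",
                              conditionMessage(e)))
  co <- coef(fit)
  structure(list(AR0 = unname(co["AR0"]), tau = unname(co["tau"]),
                 rss = sum(stats::residuals(fit)^2),
                 fitted = as.numeric(predict(fit)), t = t, AR = AR),
            class = "fusion_fit")
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat(sprintf("Fusion fit: AR0 = %.3f, tau = %.3f s (rss %.3g)\n",
              x$AR0, x$tau, x$rss))
  invisible(x)
}

#' Summarise fusion times across events and conditions
#'
#' Per-condition mean and SD of tau over individual fusion events, plus
#' the ratio of mean tau between two named conditions (how many times
#' slower the first relaxes than the second).
#'
#' @param fits list of `fusion_fit` objects (or numeric tau values).
#' @param conditions character vector assigning each fit to a condition;
#'   defaults to a single condition "all".
#' @param ratio optional length-2 character vector `c(numerator,
#'   denominator)` of condition names for the tau ratio.
#' @return list with `summary` (data.frame: condition, n, mean_tau,
#'   sd_tau) and optionally `tau_ratio`.
#' @export
summarize_tau <- function(fits, conditions = NULL, ratio = NULL) {
  taus <- vapply(fits, function(f)
    if (is.numeric(f)) as.numeric(f) else f$tau, numeric(1L))
  if (!length(taus)) stopf("need at least one fit")
  if (is.null(conditions)) conditions <- rep("all", length(taus))
  if (length(conditions) != length(taus))
    stopf("`conditions` must label every fit")
  split_taus <- split(taus, factor(conditions, levels = unique(conditions)))
  if (any(!lengths(split_taus)))
    stopf("empty condition: %s", names(split_taus)[!lengths(split_taus)][1L])
  summ <- data.frame(
    condition = names(split_taus),
    n = lengths(split_taus),
    mean_tau = vapply(split_taus, mean, numeric(1L)),
    sd_tau = vapply(split_taus, function(x)
      if (length(x) > 1L) sd(x) else 0, numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(summary = summ)
  if (!is.null(ratio)) {
    if (length(ratio) != 2L || !all(ratio %in% summ$condition))
      stopf("`ratio` must name two conditions present in the data")
    out$tau_ratio <- summ$mean_tau[summ$condition == ratio[1L]] /
      summ$mean_tau[summ$condition == ratio[2L]]
  }
  out
}
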