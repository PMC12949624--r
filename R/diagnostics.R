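# single-exponential decay fit A exp(-k t) over t >= 0
.fit_exp_decay <- function(time, resp) {
  A0 <- max(resp[1], 1e-9)
  k0 <- 0.1
  dr <- resp[1] - resp[length(resp)]
  if (dr > 0 && resp[1] > 0) {
    frac <- max(resp[length(resp)], 1e-6 * resp[1]) / resp[1]
    k0 <- max(-log(frac) / max(time[length(time)], 1e-9), 1e-4)
  }
  fit <- minpack.lm::nlsLM(resp ~ A * exp(-k * time),
                           start = list(A = A0, k = k0),
                           lower = c(A = 0, k = 1e-6), upper = c(A = Inf, k = 100),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(A = NA, k = NA))
  list(A = est[["A"]], k = est[["k"]], se_k = se[["k"]],
       rss = sum(stats::residuals(fit)^2), n = length(resp))
}

#' Contact-time invariance of dissociation kinetics
#'
#' The mechanism-discrimination experiment: sensorgrams recorded with
#' increasing injection (contact) times are aligned at the end of injection
#' and a single-exponential decay is fitted to each dissociation trace over
#' a common window. For a memoryless 1:1 interaction all apparent rates
#' equal `kd` regardless of contact time; slow induced-fit isomerisation
#' makes the apparent off-rate fall with contact time. The log apparent rate
#' is regressed on contact time and the slope is tested against an
#' equivalence band: slopes too small to change the rate by more than
#' `span_tol` (relative) across the whole tested contact-time range count
#' as zero. The verdict is `invariant` when the slope's 95% confidence
#' interval intersects the band AND the rate span is below `span_tol` of
#' the mean, `contact-time-dependent` when the interval lies wholly outside
#' the band, and `inconclusive` otherwise.
#'
#' @param aligned List of [sensorgram()]s from [align_dissociation()] (time
#'   zero at injection end), at least 3 contact times.
#' @param common_window Dissociation window analysed, s from alignment zero.
#' @param span_tol Relative rate-span tolerance for the invariant verdict.
#' @return Object of class `"invariance_report"`: per-trace rates with
#'   standard errors, the trend slope with confidence interval, and the
#'   verdict.
#' @export
contact_time_invariance <- function(aligned, common_window = 10,
                                    span_tol = 0.1) {
  stopifnot(is.list(aligned), length(aligned) >= 3)
  rows <- lapply(aligned, function(tr) {
    ct <- attr(tr, "contact_time")
    if (is.null(ct)) {
      sch <- attr(tr, "schedule")
      ct <- sch$assoc_end - sch$assoc_start
    }
    sel <- tr$phase == "dissociation" & !tr$masked & tr$time >= 0 &
      tr$time <= common_window
    if (sum(sel) < 5) stop("fewer than 5 unmasked samples in common window")
    f <- .fit_exp_decay(tr$time[sel], tr$response[sel])
    data.frame(contact_time = ct, rate = f$k, se = f$se_k)
  })
  tab <- do.call(rbind, rows)
  trend <- stats::lm(log(rate) ~ contact_time, data = tab)
  ci <- suppressWarnings(stats::confint(trend, "contact_time", level = 0.95))
  slope <- stats::coef(trend)[["contact_time"]]
  span <- diff(range(tab$rate)) / mean(tab$rate)
  # equivalence band: slopes that change the rate by < span_tol over the
  # tested contact-time range are indistinguishable from zero
  band <- log1p(span_tol) / diff(range(tab$contact_time))
  zero_equiv <- ci[1] <= band && ci[2] >= -band
  verdict <- if (zero_equiv && span < span_tol) "invariant"
  else if (!zero_equiv) "contact-time-dependent"
  else "inconclusive"
  structure(list(rates = tab, trend_slope = slope, trend_ci = as.numeric(ci),
                 rate_span = span, span_tol = span_tol,
                 equivalence_band = band, verdict = verdict),
            class = "invariance_report")
}

#' @export
print.invariance_report <- function(x, ...) {
  cat("Contact-time invariance of dissociation\n")
  print(transform(x$rates, rate = signif(rate, 4), se = signif(se, 3)),
        row.names = FALSE)
  cat(sprintf("trend slope %.3g /s per s of contact (95%% CI %.3g..%.3g), rate span %.1f%%\n",
              x$trend_slope, x$trend_ci[1], x$trend_ci[2], 100 * x$rate_span))
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}

#' Mono- vs bi-exponential dissociation
#'
#' Fits mono- and bi-exponential decays to a dissociation trace and prefers
#' the bi-exponential only when the corrected Akaike criterion improves by
#' more than 2 AND both amplitudes exceed a noise floor (3x the residual sd
#' of the bi-exponential fit) -- the operational definition of a "biphasic"
#' sensorgram.
#'
#' @param trace A [sensorgram()] with at least 20 unmasked dissociation
#'   samples.
#' @return List with `type` (`"mono"`/`"biphasic"`), `rates`, `amplitudes`,
#'   and `delta_aicc` (mono minus bi; positive favours bi).
#' @export
detect_biphasic <- function(trace) {
  stopifnot(inherits(trace, "sensorgram"))
  sel <- trace$phase == "dissociation" & !trace$masked
  if (sum(sel) < 20) stop("need at least 20 unmasked dissociation samples")
  t <- trace$time[sel]; t <- t - t[1]
  y <- trace$response[sel]
  mono <- .fit_exp_decay(t, y)
  k0 <- mono$k
  bi <- tryCatch(minpack.lm::nlsLM(
    y ~ A1 * exp(-k1 * t) + A2 * exp(-k2 * t),
    start = list(A1 = mono$A * 0.6, k1 = k0 * 3, A2 = mono$A * 0.4,
                 k2 = k0 / 3),
    lower = c(A1 = 0, k1 = 1e-6, A2 = 0, k2 = 1e-6),
    upper = c(A1 = Inf, k1 = 100, A2 = Inf, k2 = 100),
    control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  n <- length(y)
  aicc_mono <- .aicc(mono$rss, n, 2)
  if (is.null(bi))
    return(list(type = "mono", rates = mono$k, amplitudes = mono$A,
                delta_aicc = NA_real_))
  rss_bi <- sum(stats::residuals(bi)^2)
  aicc_bi <- .aicc(rss_bi, n, 4)
  eb <- stats::coef(bi)
  noise_floor <- 3 * sqrt(rss_bi / max(n - 4, 1))
  delta <- aicc_mono - aicc_bi
  biphasic <- delta > 2 && eb[["A1"]] > noise_floor && eb[["A2"]] > noise_floor &&
    max(eb[["k1"]], eb[["k2"]]) / max(min(eb[["k1"]], eb[["k2"]]), 1e-12) > 1.5
  if (biphasic)
    list(type = "biphasic", rates = sort(c(eb[["k1"]], eb[["k2"]])),
         amplitudes = c(eb[["A1"]], eb[["A2"]])[order(c(eb[["k1"]], eb[["k2"]]))],
         delta_aicc = delta)
  else
    list(type = "mono", rates = mono$k, amplitudes = mono$A,
         delta_aicc = delta)
}

#' Saturation assessment of a steady-state curve
#'
#' Reports how far up its fitted isotherm the measured curve reaches:
#' `fraction_of_plateau = Req(C_top) / Rmax`, with `saturated` when the
#' fraction is at least 0.95, and a linearity flag set when a straight line
#' through the origin describes the points within a corrected-AIC difference
#' of 2 of the isotherm. For the comparison both residual sums of squares
#' are floored at a 2% relative resolution per point, so that deviations
#' smaller than "minimal curvature" (and exact noiseless data) do not count
#' as evidence against the line; this is the "no sign of saturation" regime
#' where only binding efficiency is meaningful.
#'
#' @param curve A [steady_state_curve()].
#' @param fit The matching [fit_steady_state()] result.
#' @param resolution Relative per-point resolution used as the RSS floor.
#' @return List with `fraction_of_plateau`, `saturated`, `linearity_flag`.
#' @export
saturation_check <- function(curve, fit, resolution = 0.02) {
  stopifnot(inherits(curve, "steady_state_curve"), inherits(fit, "ss_fit"))
  kd <- fit$coefficients[["KD_app_uM"]]
  c_top <- max(curve$conc_uM)
  fraction <- c_top / (c_top + kd)
  lin <- stats::lm(response ~ 0 + conc_uM, data = curve)
  floor_rss <- sum((resolution * fit$fitted)^2)
  rss_lin <- max(sum(stats::residuals(lin)^2), floor_rss)
  rss_iso <- max(fit$rss, floor_rss)
  n <- nrow(curve)
  delta <- .aicc(rss_lin, n, 1) - .aicc(rss_iso, n, 2)
  list(fraction_of_plateau = fraction,
       saturated = fraction >= 0.95,
       linearity_flag = delta < 2)
}

#' Melting temperature from a thermal-shift curve
#'
#' Initialises Tm at the extremum of the smoothed first derivative of the
#' melt signal (5-point centred moving average before differencing), then
#' refines all parameters by least-squares fit of the two-state van't Hoff
#' model with linear folded/unfolded baselines. Errors if no transition is
#' detectable (flat derivative).
#'
#' @param curve A [generate_melt_curve()]-style data.frame with columns
#'   `temperature` (degrees C) and `signal`, at least 20 points.
#' @return Object of class `"melt_fit"`: `Tm` (degrees C), `dHvH` (kJ/mol),
#'   baseline parameters, and residual noise estimate.
#' @export
estimate_tm <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("temperature", "signal") %in% names(curve)))
  if (nrow(curve) < 20) stop("need at least 20 points spanning a transition")
  temp <- curve$temperature; y <- curve$signal
  sm <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  d <- diff(as.numeric(sm)) / diff(temp)
  ok <- !is.na(d)
  d_ok <- d[ok]
  tmid <- ((temp[-1] + temp[-length(temp)]) / 2)[ok]
  # transition detectability: the derivative must deviate from its typical
  # (baseline) level by clearly more than the derivative noise
  dev <- abs(d_ok - stats::median(d_ok))
  noise_d <- stats::mad(diff(d_ok)) / sqrt(2)
  if (max(dev) < 6 * max(noise_d, 1e-12))
    stop("no detectable unfolding transition (flat derivative)")
  tm0 <- tmid[which.max(dev)]
  t0 <- temp[1]
  n_edge <- max(5, round(length(y) * 0.1))
  bf <- stats::lm(y ~ I(temp - t0), data = data.frame(y = utils::head(y, n_edge),
                                                      temp = utils::head(temp, n_edge)))
  bu <- stats::lm(y ~ I(temp - t0), data = data.frame(y = utils::tail(y, n_edge),
                                                      temp = utils::tail(temp, n_edge)))
  start <- list(af = stats::coef(bf)[[1]], bfs = stats::coef(bf)[[2]],
                au = stats::coef(bu)[[1]], bus = stats::coef(bu)[[2]],
                Tm = tm0, dH = 400)
  melt_model <- function(temp, af, bfs, au, bus, Tm, dH) {
    f <- melt_fraction(temp, Tm, dH)
    (af + bfs * (temp - t0)) * (1 - f) + (au + bus * (temp - t0)) * f
  }
  fit <- minpack.lm::nlsLM(
    y ~ melt_model(temp, af, bfs, au, bus, Tm, dH),
    start = start,
    lower = c(af = -Inf, bfs = -Inf, au = -Inf, bus = -Inf,
              Tm = min(temp), dH = 10),
    upper = c(af = Inf, bfs = Inf, au = Inf, bus = Inf,
              Tm = max(temp), dH = 5000),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  est <- stats::coef(fit)
  res <- stats::residuals(fit)
  structure(list(Tm = est[["Tm"]], dHvH = est[["dH"]],
                 baselines = list(folded = c(est[["af"]], est[["bfs"]]),
                                  unfolded = c(est[["au"]], est[["bus"]])),
                 noise_sd = stats::sd(res), n = length(y),
                 Tm_init = tm0),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Thermal-shift fit: Tm = %.2f C, dHvH = %.0f kJ/mol (noise sd %.3g, n = %d)\n",
              x$Tm, x$dHvH, x$noise_sd, x$n))
  invisible(x)
}
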