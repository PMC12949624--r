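# corrected Akaike criterion for least squares: k counts the variance too
.aicc <- function(rss, n, p) {
  k <- p + 1
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

# Wald-Wolfowitz runs test on residual signs; negative z = fewer runs than
# random = systematic (autocorrelated) residuals
.runs_z <- function(res) {
  s <- sign(res)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(-Inf)
  runs <- 1 + sum(diff(s) != 0)
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  (runs - mu) / sqrt(v)
}

#' Steady-state (isotherm) curve
#'
#' Ordered (concentration, report-point response) pairs for one analyte.
#' Replicate cycles at the same concentration are retained as separate
#' points, never averaged.
#'
#' @param conc_uM Positive concentrations, micromolar.
#' @param response Responses, RU.
#' @param analyte Label.
#' @return Object of class `"steady_state_curve"` (a data.frame).
#' @export
steady_state_curve <- function(conc_uM, response, analyte = "") {
  stopifnot(length(conc_uM) == length(response), all(conc_uM > 0))
  o <- order(conc_uM)
  out <- data.frame(conc_uM = conc_uM[o], response = response[o])
  attr(out, "analyte") <- analyte
  class(out) <- c("steady_state_curve", "data.frame")
  out
}

#' Pseudo-steady-state affinity fit
#'
#' Fits the 1:1 binding isotherm `Req(C) = Rmax C / (KD + C)` to report-point
#' data by Levenberg-Marquardt least squares, yielding the apparent
#' dissociation constant `KD^app` (micromolar) and capacity `Rmax` with
#' standard errors. When report points are not taken at true equilibrium the
#' estimate is an *apparent* KD. The fit is flagged unreliable when the top
#' concentration is below the KD estimate (no approach to saturation: the
#' near-linear regime) or when KD runs into its bound.
#'
#' @param curve A [steady_state_curve()] with at least 3 distinct
#'   concentrations.
#' @param kd_bounds KD search bounds, micromolar.
#' @return Object of class `"ss_fit"` with coefficients, standard errors,
#'   fit statistics and flags.
#' @export
fit_steady_state <- function(curve, kd_bounds = c(1e-3, 1e5)) {
  stopifnot(inherits(curve, "steady_state_curve"))
  if (length(unique(curve$conc_uM)) < 3)
    stop("need at least 3 distinct concentrations")
  C <- curve$conc_uM; y <- curve$response
  start <- list(Rmax = max(y) * 2, KD = stats::median(C))
  fit <- minpack.lm::nlsLM(
    y ~ Rmax * C / (KD + C), start = start,
    lower = c(Rmax = 1e-12, KD = kd_bounds[1]),
    upper = c(Rmax = max(y) * 1e4, KD = kd_bounds[2]),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Rmax = NA_real_, KD = NA_real_))
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  kd_at_bound <- est[["KD"]] >= kd_bounds[2] * 0.999 ||
    est[["KD"]] <= kd_bounds[1] * 1.001
  unreliable <- max(C) < est[["KD"]] || kd_at_bound
  structure(list(
    mechanism = "steady-state 1:1 isotherm",
    coefficients = c(KD_app_uM = unname(est[["KD"]]),
                     Rmax = unname(est[["Rmax"]])),
    se = c(KD_app_uM = unname(se[["KD"]]), Rmax = unname(se[["Rmax"]])),
    rss = rss, n = length(y), p = 2,
    reduced_chisq = rss / max(length(y) - 2, 1),
    aicc = .aicc(rss, length(y), 2),
    residuals = res, fitted = stats::fitted(fit), curve = curve,
    runs_z = .runs_z(res),
    flags = list(unreliable = unreliable, kd_at_bound = kd_at_bound)),
    class = c("ss_fit", "spr_fit"))
}

#' @export
print.ss_fit <- function(x, digits = 4, ...) {
  cat("Pseudo-steady-state 1:1 isotherm fit (", nrow(x$curve), " points)\n",
      sep = "")
  cat("  KD^app = ", signif(x$coefficients[["KD_app_uM"]], digits), " uM (se ",
      signif(x$se[["KD_app_uM"]], 3), ")\n", sep = "")
  cat("  Rmax   = ", signif(x$coefficients[["Rmax"]], digits), " RU (se ",
      signif(x$se[["Rmax"]], 3), ")\n", sep = "")
  if (x$flags$unreliable)
    cat("  [flag] unreliable: no saturation approached",
        if (x$flags$kd_at_bound) "(KD at bound)", "\n")
  invisible(x)
}

#' @export
coef.spr_fit <- function(object, ...) object$coefficients

#' @export
residuals.spr_fit <- function(object, ...) object$residuals

#' @export
summary.spr_fit <- function(object, ...) {
  out <- list(mechanism = object$mechanism,
              coefficients = cbind(Estimate = object$coefficients,
                                   `Std. Error` = object$se),
              rss = object$rss, n = object$n,
              reduced_chisq = object$reduced_chisq, aicc = object$aicc,
              runs_z = object$runs_z, flags = object$flags)
  class(out) <- "summary.spr_fit"
  out
}

#' @export
print.summary.spr_fit <- function(x, ...) {
  cat("Model:", x$mechanism, "\n")
  print(x$coefficients)
  cat(sprintf("n = %d, RSS = %.4g, reduced chi-sq = %.4g, AICc = %.4g, runs z = %.2f\n",
              x$n, x$rss, x$reduced_chisq, x$aicc, x$runs_z))
  flg <- names(Filter(isTRUE, x$flags))
  if (length(flg)) cat("flags:", paste(flg, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.ss_fit <- function(object, newdata = NULL, ...) {
  C <- if (is.null(newdata)) object$curve$conc_uM else newdata$conc_uM
  est <- object$coefficients
  est[["Rmax"]] * C / (est[["KD_app_uM"]] + C)
}

#' @export
plot.ss_fit <- function(x, ...) {
  graphics::plot(x$curve$conc_uM, x$curve$response, xlab = "C (uM)",
                 ylab = "Req (RU)", ...)
  Cg <- seq(0, max(x$curve$conc_uM), length.out = 200)
  graphics::lines(Cg, predict(x, data.frame(conc_uM = Cg)))
  invisible(x)
}

#' Binding efficiency from the initial isotherm slope
#'
#' Zero-intercept least-squares slope of response against concentration over
#' the lowest `n_low` concentrations of a steady-state curve, in RU/uM. In
#' the low-concentration limit of a 1:1 interaction this converges to
#' `Rmax / KD`, making it a robust ranking statistic when saturation is out
#' of reach.
#'
#' @param curve A [steady_state_curve()].
#' @param n_low Number of lowest concentrations to use (>= 2).
#' @return List with `be` (RU/uM), `se`, `n_used` and the points used.
#' @export
binding_efficiency <- function(curve, n_low = 3) {
  stopifnot(inherits(curve, "steady_state_curve"), n_low >= 2)
  if (nrow(curve) < 2) stop("need at least 2 points")
  d <- utils::head(curve[order(curve$conc_uM), ], n_low)
  if (nrow(d) < 2) stop("insufficient low-concentration points")
  fit <- stats::lm(response ~ 0 + conc_uM, data = d)
  list(be = unname(stats::coef(fit)[[1]]),
       se = unname(sqrt(diag(stats::vcov(fit)))[[1]]),
       n_used = nrow(d), points = d)
}
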