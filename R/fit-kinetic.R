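# ---- model response evaluators on a cycle's stored grid ---------------------

# closed-form 1:1 response on a cycle grid
.resp_one_to_one <- function(ka, kd, Rmax, time, phase, sch) {
  C <- sch$conc_uM * 1e-6
  r <- numeric(length(time))
  if (C > 0) {
    assoc <- phase == "association"
    diss <- phase == "dissociation"
    kobs <- ka * C + kd
    Req <- Rmax * C / (C + kd / ka)
    r[assoc] <- Req * (1 - exp(-kobs * (time[assoc] - sch$assoc_start)))
    r_end <- Req * (1 - exp(-kobs * (sch$assoc_end - sch$assoc_start)))
    r[diss] <- r_end * exp(-kd * (time[diss] - sch$assoc_end))
  }
  r
}

.resp_mechanism <- function(m, time, phase, sch) {
  if (inherits(m, "mech_one_to_one"))
    return(.resp_one_to_one(m$ka, m$kd, m$Rmax, time, phase, sch))
  if (inherits(m, "mech_heterogeneous"))
    return(.resp_one_to_one(m$ka1, m$kd1, m$Rmax1, time, phase, sch) +
             .resp_one_to_one(m$ka2, m$kd2, m$Rmax2, time, phase, sch))
  rowSums(.propagate_linear(m, sch, time, phase))
}

# ---- mechanism parameterisations (log10 scale) ------------------------------

.kin_models <- function(rmax_cap) {
  lr <- log10(rmax_cap)
  list(
    one_to_one = list(
      par_names = c("ka", "kd", "Rmax"),
      lower = c(2, -5, lr - 4), upper = c(9, 1, lr + 1),
      build = function(th) mech_one_to_one(10^th[1], 10^th[2], 10^th[3]),
      extras = function(rmax0) log10(rmax0),
      p = 3),
    two_state = list(
      par_names = c("ka1", "kd1", "ka2", "kd2", "Rmax"),
      lower = c(2, -5, -5, -5, lr - 4), upper = c(9, 1, 1, 1, lr + 1),
      build = function(th) mech_two_state(10^th[1], 10^th[2], 10^th[3],
                                          10^th[4], 10^th[5]),
      extras = function(rmax0) c(-2, -2.5, log10(rmax0)),
      p = 5),
    heterogeneous = list(
      par_names = c("ka1", "kd1", "Rmax1", "ka2", "kd2", "Rmax2"),
      lower = c(2, -5, lr - 4, 2, -5, lr - 4),
      upper = c(9, 1, lr + 1, 9, 1, lr + 1),
      build = function(th) mech_heterogeneous(10^th[1], 10^th[2], 10^th[3],
                                              10^th[4], 10^th[5], 10^th[6]),
      extras = NULL,  # handled specially: second site offset from the first
      p = 6),
    ensemble2 = list(
      par_names = c("ka1", "kd1", "ka2", "kd2", "Rmax"),
      lower = c(2, -5, 2, -5, lr - 4), upper = c(9, 1, 9, 1, lr + 1),
      build = function(th) mech_ensemble(c(10^th[1], 10^th[3]),
                                         c(10^th[2], 10^th[4]), 10^th[5]),
      extras = NULL,
      p = 5))
}

# deterministic 3x3 log grid over (ka, kd) starting points
.start_grid <- function(model_name, rmax0) {
  ka0 <- c(3, 4.5, 6)
  kd0 <- c(-2.5, -1.5, -0.5)
  g <- expand.grid(ka = ka0, kd = kd0, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) {
    ka <- g$ka[i]; kd <- g$kd[i]
    switch(model_name,
           one_to_one = c(ka, kd, log10(rmax0)),
           two_state = c(ka, kd, -2, -2.5, log10(rmax0)),
           heterogeneous = c(ka, kd, log10(rmax0 * 0.6),
                             ka + 1, kd + 1, log10(rmax0 * 0.6)),
           ensemble2 = c(ka, kd, ka + 1, kd + 1, log10(rmax0)))
  })
}

#' Global kinetic regression of a sensorgram series
#'
#' Fits one binding mechanism to all cycles of a (preprocessed) sensorgram
#' series simultaneously, sharing the kinetic parameters and surface
#' capacity across cycles, by bounded Levenberg-Marquardt least squares on
#' log-scaled parameters. Optimisation is multi-started from a deterministic
#' 3x3 logarithmic grid over the primary rate constants; ties between starts
#' are broken by lower residual sum of squares, then lower `ka`.
#'
#' @param cycles An `experiment_set` (preprocessed with [preprocess_set()]
#'   defaults) or a list of preprocessed [sensorgram()]s with concentration
#'   metadata; at least two distinct concentrations.
#' @param mechanism `"one_to_one"`, `"two_state"`, `"heterogeneous"` (two
#'   independent site classes), or `"ensemble2"` (two competing binding
#'   modes sharing one capacity).
#' @param init Optional named start values on the natural scale (replaces
#'   the multi-start grid).
#' @param rmax_cap Optional stoichiometric capacity, RU, bounding `Rmax` at
#'   ten times its value; default derives a cap from the data.
#' @return Object of class `c("kinetic_fit", "spr_fit")`.
#' @export
fit_kinetic <- function(cycles, mechanism = c("one_to_one", "two_state",
                                              "heterogeneous", "ensemble2"),
                        init = NULL, rmax_cap = NULL) {
  mechanism <- match.arg(mechanism)
  if (inherits(cycles, "experiment_set")) cycles <- preprocess_set(cycles)
  stopifnot(is.list(cycles), length(cycles) >= 1,
            all(vapply(cycles, inherits, logical(1), "sensorgram")))
  concs <- vapply(cycles, function(x) attr(x, "conc_uM"), numeric(1))
  if (length(unique(concs[concs > 0])) < 2)
    stop("global fit requires at least two distinct analyte concentrations")
  dat <- lapply(cycles, function(tr) {
    ok <- !tr$masked
    if (!any(ok)) stop("cycle is fully masked")
    list(time = tr$time, phase = tr$phase, ok = ok,
         y = tr$response[ok], sch = attr(tr, "schedule"))
  })
  y_all <- unlist(lapply(dat, `[[`, "y"))
  n <- length(y_all)
  rmax0 <- max(1e-6, max(y_all)) * 1.2
  if (is.null(rmax_cap)) rmax_cap <- rmax0 * 10
  spec <- .kin_models(rmax_cap)[[mechanism]]

  resid_fun <- function(th) {
    m <- tryCatch(spec$build(th), error = function(e) NULL)
    if (is.null(m)) return(rep(1e6, n))
    r <- tryCatch(
      unlist(lapply(dat, function(d)
        d$y - .resp_mechanism(m, d$time, d$phase, d$sch)[d$ok])),
      error = function(e) NULL)
    if (is.null(r) || anyNA(r) || any(!is.finite(r))) rep(1e6, n) else r
  }

  starts <- if (!is.null(init)) {
    if (!all(spec$par_names %in% names(init)))
      stop("init must name: ", paste(spec$par_names, collapse = ", "))
    list(log10(unname(init[spec$par_names])))
  } else .start_grid(mechanism, rmax0)

  # two-stage multi-start: short exploratory runs from every grid point,
  # then a fully converged refinement from the best; ties broken by lower
  # RSS then lower ka (deterministic)
  lm_run <- function(th0, maxiter, tol) {
    th0 <- pmin(pmax(th0, spec$lower), spec$upper)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = th0, fn = resid_fun, lower = spec$lower,
                           upper = spec$upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, ptol = tol, ftol = tol))),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(fit = fit, rss = sum(fit$fvec^2), par = fit$par)
  }
  explore_iter <- if (length(starts) > 1) 25L else 200L
  runs <- Filter(Negate(is.null),
                 lapply(starts, lm_run, maxiter = explore_iter, tol = 1e-8))
  if (!length(runs)) stop("global kinetic fit failed to converge from any start")
  rsss <- vapply(runs, `[[`, numeric(1), "rss")
  kas <- vapply(runs, function(r) r$par[1], numeric(1))
  best <- runs[[order(rsss, kas)[1]]]
  refined <- lm_run(best$par, maxiter = 200L, tol = 1e-10)
  if (!is.null(refined) && refined$rss <= best$rss) best <- refined

  fit <- best$fit
  th <- fit$par
  names(th) <- spec$par_names
  est <- 10^th
  rss <- best$rss
  p <- spec$p
  sigma2 <- rss / max(n - p, 1)
  covl <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(covl)) rep(NA_real_, p) else {
    sl <- suppressWarnings(sqrt(pmax(diag(covl), 0)))
    log(10) * est * sl                     # delta method, log10 -> natural
  }
  names(se) <- spec$par_names
  bound_hit <- (th <= spec$lower + 1e-6) | (th >= spec$upper - 1e-6)
  names(bound_hit) <- spec$par_names

  mech_est <- spec$build(unname(th))
  kd_app <- switch(mechanism,
    one_to_one = est[["kd"]] / est[["ka"]] * 1e6,
    two_state = (est[["kd1"]] / est[["ka1"]]) /
      (1 + est[["ka2"]] / max(est[["kd2"]], 1e-300)) * 1e6,
    heterogeneous = NA_real_,
    ensemble2 = 1 / (est[["ka1"]] / est[["kd1"]] +
                       est[["ka2"]] / est[["kd2"]]) * 1e6)

  resid_traces <- list()
  fitted_all <- numeric(0)
  res_all <- numeric(0)
  for (i in seq_along(dat)) {
    d <- dat[[i]]
    mu <- .resp_mechanism(mech_est, d$time, d$phase, d$sch)
    resid_traces[[i]] <- data.frame(time = d$time[d$ok],
                                    residual = d$y - mu[d$ok])
    fitted_all <- c(fitted_all, mu[d$ok])
    res_all <- c(res_all, d$y - mu[d$ok])
  }
  runs_z <- .runs_z(res_all)

  structure(list(
    mechanism = mechanism,
    coefficients = est, se = se,
    KD_app_uM = unname(kd_app),
    mech = mech_est,
    rss = rss, n = n, p = p,
    reduced_chisq = sigma2,
    aicc = .aicc(rss, n, p),
    residuals = res_all, fitted = fitted_all,
    resid_traces = resid_traces,
    conc_uM = concs,
    y_scale = sqrt(mean(y_all^2)),
    data_checksum = signif(sum(abs(y_all)) + n, 12),
    starts = data.frame(rss = rsss, ka = 10^kas),
    convergence = list(info = fit$info, message = fit$message,
                       niter = fit$niter,
                       start_spread = diff(range(rsss))),
    bound_hit = bound_hit,
    runs_z = runs_z,
    # a fit at numerical precision cannot carry residual structure
    flags = list(systematic_residuals = runs_z < -4 &&
                   rss > n * (1e-8 * sqrt(mean(y_all^2)))^2,
                 any_bound_hit = any(bound_hit))),
    class = c("kinetic_fit", "spr_fit"))
}

#' @export
print.kinetic_fit <- function(x, digits = 4, ...) {
  cat("Global kinetic fit, mechanism: ", x$mechanism, " (", x$n,
      " points, ", length(x$resid_traces), " cycles)\n", sep = "")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(signif(tab, digits))
  if (!is.na(x$KD_app_uM))
    cat("  KD^app = ", signif(x$KD_app_uM, digits), " uM\n", sep = "")
  cat(sprintf("  RSS = %.4g, AICc = %.4g, runs z = %.2f\n",
              x$rss, x$aicc, x$runs_z))
  if (x$flags$systematic_residuals) cat("  [flag] systematic residuals\n")
  if (x$flags$any_bound_hit)
    cat("  [flag] bound hit:",
        paste(names(which(x$bound_hit)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.kinetic_fit <- function(object, schedule = NULL, ...) {
  if (is.null(schedule))
    return(object$fitted)
  simulate_mechanism(object$mech, schedule)
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  graphics::plot(NA, xlim = range(unlist(lapply(x$resid_traces, `[[`, "time"))),
                 ylim = range(unlist(lapply(x$resid_traces, `[[`, "residual"))),
                 xlab = "time (s)", ylab = "residual (RU)", ...)
  for (tr in x$resid_traces) graphics::lines(tr$time, tr$residual)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Rank competing mechanism fits
#'
#' Orders fits of the same data by the corrected Akaike criterion, reports
#' pairwise differences to the best model, flags systematic residuals (runs
#' test), and declares the top two indistinguishable when their criterion
#' difference is below 2. Residual sums of squares are floored at numerical
#' precision (relative 1e-8 of the data scale) before ranking, so that fits
#' which both reproduce noiseless data to machine accuracy compare as equal
#' and the criterion's parsimony penalty decides.
#'
#' The *preferred* model applies the conventional parsimony rule for nested
#' kinetic schemes: a mechanism with more parameters is preferred over a
#' simpler one only when its criterion is decisively better -- more than
#' `prefer_margin` (default 10) units below every simpler competitor.
#' Chance improvements from absorbing noise rarely exceed a few units,
#' whereas a genuinely wrong mechanism typically loses by hundreds, so the
#' rule discriminates sharply.
#'
#' @param fits List of [fit_kinetic()] results on identical data.
#' @param prefer_margin Criterion improvement required to prefer a more
#'   complex mechanism.
#' @return Object of class `"model_comparison"`.
#' @export
compare_models <- function(fits, prefer_margin = 10) {
  stopifnot(is.list(fits), length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "spr_fit")))
  if (length(unique(vapply(fits, function(f) f$data_checksum, numeric(1)))) > 1)
    stop("fits were made on different data sets")
  aicc_eff <- vapply(fits, function(f) {
    floor_rss <- f$n * (1e-8 * (f$y_scale %||% 0))^2
    .aicc(max(f$rss, floor_rss), f$n, f$p)
  }, numeric(1))
  tab <- data.frame(
    mechanism = vapply(fits, `[[`, character(1), "mechanism"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    aicc = aicc_eff,
    runs_z = vapply(fits, `[[`, numeric(1), "runs_z"),
    systematic = vapply(fits, function(f)
      isTRUE(f$flags$systematic_residuals), logical(1)),
    stringsAsFactors = FALSE)
  o <- order(tab$aicc)
  tab <- tab[o, ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  indist <- nrow(tab) >= 2 && tab$delta_aicc[2] < 2
  # parsimony: simplest mechanism within prefer_margin of the criterion optimum
  in_margin <- tab$delta_aicc <= prefer_margin
  cand <- which(in_margin)
  preferred <- tab$mechanism[cand[order(tab$p[cand], tab$aicc[cand])][1]]
  structure(list(table = tab, fits = fits[o],
                 preferred = preferred,
                 prefer_margin = prefer_margin,
                 indistinguishable = indist),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Mechanism comparison (corrected AIC):\n")
  print(transform(x$table, rss = signif(rss, 5), aicc = signif(aicc, 6),
                  delta_aicc = signif(delta_aicc, 4),
                  runs_z = signif(runs_z, 3)), row.names = FALSE)
  cat("preferred:", x$preferred,
      if (x$indistinguishable) "(top two indistinguishable, delta < 2)", "\n")
  invisible(x)
}
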