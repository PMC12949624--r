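#' Injection schedule for one sensorgram cycle
#'
#' Times are in seconds on a common clock starting at the beginning of the
#' baseline. Phases are half-open intervals: baseline `[0, assoc_start)`,
#' association `[assoc_start, assoc_end)`, dissociation
#' `[assoc_end, diss_end]`. Analyte concentration is `conc_uM` (micromolar)
#' during association and zero elsewhere.
#'
#' @param contact_time Association (injection) duration, s.
#' @param dissociation_time Dissociation duration, s (default 15 s).
#' @param baseline Baseline duration before injection, s.
#' @param sample_rate Sampling rate, Hz.
#' @param conc_uM Analyte concentration during association, micromolar.
#' @return An object of class `"injection_schedule"`.
#' @export
injection_schedule <- function(contact_time, dissociation_time = 15,
                               baseline = 10, sample_rate = 10, conc_uM = 0) {
  stopifnot(contact_time > 0, dissociation_time > 0, baseline >= 0,
            sample_rate > 0, conc_uM >= 0)
  structure(list(
    assoc_start = baseline,
    assoc_end = baseline + contact_time,
    diss_end = baseline + contact_time + dissociation_time,
    sample_rate = sample_rate,
    conc_uM = conc_uM
  ), class = "injection_schedule")
}

#' @export
print.injection_schedule <- function(x, ...) {
  cat("Injection schedule: baseline ", x$assoc_start, " s, contact ",
      x$assoc_end - x$assoc_start, " s, dissociation ",
      x$diss_end - x$assoc_end, " s, ", x$sample_rate, " Hz, C = ",
      x$conc_uM, " uM\n", sep = "")
  invisible(x)
}

# time grid and phase labels for a schedule
schedule_grid <- function(s) {
  stopifnot(inherits(s, "injection_schedule"))
  t <- seq(0, s$diss_end, by = 1 / s$sample_rate)
  eps <- 1e-9  # half-open phases [start, end), robust to grid rounding
  phase <- ifelse(t < s$assoc_start - eps, "baseline",
                  ifelse(t < s$assoc_end - eps, "association", "dissociation"))
  list(time = t, phase = phase)
}

#' Construct a sensorgram
#'
#' A sensorgram is a data.frame with columns `time` (s), `response` (RU),
#' `phase` (`baseline`/`association`/`dissociation`) and `masked` (logical),
#' carrying cycle metadata as attributes: the [injection_schedule()], an
#' analyte label, a concentration in micromolar, a channel role
#' (`"active"`/`"reference"`) and a cycle id.
#'
#' @param time Strictly increasing numeric vector, s.
#' @param response Numeric vector, RU.
#' @param phase Character vector of phase labels.
#' @param masked Logical vector of excluded points.
#' @param schedule An [injection_schedule()] or `NULL`.
#' @param analyte,channel,cycle_id Metadata strings.
#' @param conc_uM Analyte concentration, micromolar.
#' @return Object of classes `c("sensorgram", "data.frame")`.
#' @export
sensorgram <- function(time, response, phase, masked = logical(length(time)),
                       schedule = NULL, analyte = "", conc_uM = NA_real_,
                       channel = "active", cycle_id = "") {
  stopifnot(length(time) == length(response), length(time) == length(phase),
            length(time) == length(masked))
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  out <- data.frame(time = time, response = response, phase = phase,
                    masked = as.logical(masked), stringsAsFactors = FALSE)
  attr(out, "schedule") <- schedule
  attr(out, "analyte") <- analyte
  attr(out, "conc_uM") <- conc_uM
  attr(out, "channel") <- channel
  attr(out, "cycle_id") <- cycle_id
  class(out) <- c("sensorgram", "data.frame")
  out
}

#' @export
print.sensorgram <- function(x, ...) {
  cat("Sensorgram", if (nzchar(attr(x, "cycle_id"))) paste0(" [", attr(x, "cycle_id"), "]"),
      ": ", nrow(x), " points, ", sum(x$masked), " masked\n", sep = "")
  cat("  analyte: ", attr(x, "analyte"), "  C = ", attr(x, "conc_uM"),
      " uM  channel: ", attr(x, "channel"), "\n", sep = "")
  rng <- range(x$response[!x$masked])
  cat(sprintf("  time %.1f..%.1f s, response %.2f..%.2f RU\n",
              min(x$time), max(x$time), rng[1], rng[2]))
  invisible(x)
}

#' @export
plot.sensorgram <- function(x, ...) {
  ok <- !x$masked
  graphics::plot(x$time[ok], x$response[ok], type = "l",
                 xlab = "time (s)", ylab = "response (RU)", ...)
  invisible(x)
}

# copy metadata attributes from template onto a rebuilt sensorgram
.sg_like <- function(template, time = template$time,
                     response = template$response,
                     phase = template$phase, masked = template$masked) {
  sensorgram(time, response, phase, masked,
             schedule = attr(template, "schedule"),
             analyte = attr(template, "analyte"),
             conc_uM = attr(template, "conc_uM"),
             channel = attr(template, "channel"),
             cycle_id = attr(template, "cycle_id"))
}

.same_grid <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) && all(abs(a$time - b$time) <= tol)
}
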