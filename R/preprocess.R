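#' Reference-channel subtraction
#'
#' Pointwise difference active minus reference on a shared time grid; masks
#' propagate by union. Removes bulk refractive-index offsets and other
#' common-mode artifacts.
#'
#' @param active,reference [sensorgram()]s on identical time grids.
#' @return A referenced [sensorgram()] (metadata from the active channel).
#' @export
reference_subtract <- function(active, reference) {
  stopifnot(inherits(active, "sensorgram"), inherits(reference, "sensorgram"))
  if (!.same_grid(active, reference)) stop("time grids differ")
  .sg_like(active, response = active$response - reference$response,
           masked = active$masked | reference$masked)
}

#' Blank (double-referencing) subtraction
#'
#' Subtracts the pointwise mean of zero-concentration blank cycles from a
#' trace on the same grid, removing systematic trends (drift) shared with
#' the blanks.
#'
#' @param trace A [sensorgram()].
#' @param blanks Non-empty list of blank [sensorgram()]s on the same grid.
#' @return A double-referenced [sensorgram()]; masks are the union.
#' @export
blank_subtract <- function(trace, blanks) {
  stopifnot(inherits(trace, "sensorgram"))
  if (inherits(blanks, "sensorgram")) blanks <- list(blanks)
  if (length(blanks) == 0L) stop("at least one blank cycle required")
  for (b in blanks) {
    if (!inherits(b, "sensorgram")) stop("blanks must be sensorgrams")
    if (!.same_grid(trace, b)) stop("time grids differ")
  }
  bmean <- Reduce(`+`, lapply(blanks, `[[`, "response")) / length(blanks)
  bmask <- Reduce(`|`, lapply(blanks, `[[`, "masked"))
  .sg_like(trace, response = trace$response - bmean,
           masked = trace$masked | bmask)
}

#' Solvent (DMSO mismatch) correction
#'
#' Applies the instrument-style solvent correction: the residual bulk error
#' left in a referenced trace is predicted from the *reference-channel* bulk
#' signal via a piecewise-linear calibration of (reference bulk RU,
#' correction RU) pairs, and subtracted pointwise. Bulk signals outside the
#' calibrated range are clamped to its ends with a warning.
#'
#' @param trace A referenced [sensorgram()].
#' @param reference The paired reference-channel [sensorgram()] (carrier of
#'   the bulk signal).
#' @param calibration data.frame with columns `ref_bulk` and `correction`,
#'   at least two rows.
#' @return A corrected [sensorgram()].
#' @export
solvent_correct <- function(trace, reference, calibration) {
  stopifnot(inherits(trace, "sensorgram"), inherits(reference, "sensorgram"),
            is.data.frame(calibration),
            all(c("ref_bulk", "correction") %in% names(calibration)))
  if (nrow(calibration) < 2L)
    stop("solvent calibration needs at least two points")
  if (!.same_grid(trace, reference)) stop("time grids differ")
  x <- reference$response
  rng <- range(calibration$ref_bulk)
  live <- !(trace$masked | reference$masked)   # masked points are left as-is
  out_of_range <- live & (x < rng[1] | x > rng[2])
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " point(s) outside solvent calibration range; clamped")
    x <- pmin(pmax(x, rng[1]), rng[2])
  }
  corr <- stats::approx(calibration$ref_bulk, calibration$correction,
                        xout = x, rule = 2)$y
  corr[!live] <- 0
  .sg_like(trace, response = trace$response - corr)
}

#' Mask injection-boundary spikes
#'
#' Masks points within `guard` seconds of the association start or end
#' (pressure-spike windows), producing the familiar gaps around injections.
#' Response values are never altered; masking is additive.
#'
#' @param trace A [sensorgram()] carrying an [injection_schedule()].
#' @param guard Half-width of the masked window, s; `0` masks nothing.
#' @return The trace with updated masks.
#' @export
mask_spikes <- function(trace, guard = 0.5) {
  stopifnot(inherits(trace, "sensorgram"), guard >= 0)
  if (guard == 0) return(trace)
  sch <- attr(trace, "schedule")
  if (is.null(sch)) stop("trace carries no injection schedule")
  m <- trace$masked
  for (b in c(sch$assoc_start, sch$assoc_end))
    m <- m | (abs(trace$time - b) <= guard + 1e-12)
  .sg_like(trace, masked = m)
}

#' Double-reference an entire synthetic experiment
#'
#' The conventional correction chain applied to every non-blank cycle:
#' reference-channel subtraction, then solvent correction (using the set's
#' calibration), then subtraction of the mean of the identically processed
#' blank cycles, then spike masking. Applied to a noiseless set this chain
#' returns the pure mechanism signal.
#'
#' @param set An [generate_experiment()] result.
#' @param spike_guard Guard half-width for [mask_spikes()], s.
#' @param solvent,blank Logical switches for the respective steps.
#' @return List of corrected [sensorgram()]s (non-blank cycles only), each
#'   retaining analyte/concentration metadata.
#' @export
preprocess_set <- function(set, spike_guard = 0.5, solvent = TRUE,
                           blank = TRUE) {
  stopifnot(inherits(set, "experiment_set"))
  correct_one <- function(cy) {
    tr <- reference_subtract(cy$active, cy$reference)
    tr <- mask_spikes(tr, spike_guard)   # before solvent: spikes are not bulk
    if (solvent) {
      ref <- mask_spikes(cy$reference, spike_guard)
      tr <- solvent_correct(tr, ref, set$solvent_calibration)
    }
    tr
  }
  is_blank <- vapply(set$cycles, `[[`, logical(1), "blank")
  processed_blanks <- lapply(set$cycles[is_blank], correct_one)
  out <- lapply(set$cycles[!is_blank], function(cy) {
    tr <- correct_one(cy)
    if (blank && length(processed_blanks)) {
      # blanks share the analyte's grid only when contact times match
      usable <- Filter(function(b) .same_grid(tr, b), processed_blanks)
      if (length(usable)) tr <- blank_subtract(tr, usable)
    }
    tr
  })
  out
}

#' Report points at the end of injection
#'
#' For each cycle, the mean unmasked response over a window placed just
#' before the association end (default: 1 s window ending 0.5 s before the
#' end, robust to boundary spikes), assembled per analyte into
#' concentration-response curves for pseudo-steady-state analysis. Blank
#' (zero-concentration) cycles are excluded; repeated concentrations are
#' retained as separate points.
#'
#' @param cycles List of preprocessed [sensorgram()]s (e.g. from
#'   [preprocess_set()]).
#' @param window Averaging window length, s.
#' @param guard Gap between window end and association end, s.
#' @return Named list of [steady_state_curve()]s, one per analyte.
#' @export
extract_report_points <- function(cycles, window = 1, guard = 0.5) {
  stopifnot(window > 0, guard >= 0)
  if (inherits(cycles, "sensorgram")) cycles <- list(cycles)
  pts <- lapply(cycles, function(tr) {
    conc <- attr(tr, "conc_uM")
    if (is.na(conc) || conc == 0) return(NULL)
    sch <- attr(tr, "schedule")
    if (is.null(sch)) stop("cycle carries no injection schedule")
    lo <- sch$assoc_end - guard - window
    hi <- sch$assoc_end - guard
    if (lo < sch$assoc_start)
      stop("report-point window extends before the association phase")
    sel <- tr$time >= lo - 1e-9 & tr$time < hi + 1e-9 &
      tr$phase == "association" & !tr$masked
    if (!any(sel)) stop("report-point window is empty after masking")
    data.frame(analyte = attr(tr, "analyte"), conc_uM = conc,
               response = mean(tr$response[sel]), stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts)) stop("no non-blank cycles with concentrations")
  split_pts <- split(pts, pts$analyte)
  lapply(split_pts, function(d)
    steady_state_curve(d$conc_uM, d$response, analyte = d$analyte[1]))
}

#' Align cycles at the end of injection
#'
#' Shifts each cycle's clock so that the association end is time zero (the
#' standard representation for comparing dissociation kinetics across
#' contact times), optionally normalising the response to the end-of-
#' injection value so that traces from a memoryless 1:1 interaction
#' coincide.
#'
#' @param cycles List of [sensorgram()]s with dissociation phases.
#' @param normalise Divide responses by the end-of-injection response?
#' @return List of shifted (and optionally normalised) [sensorgram()]s.
#' @export
align_dissociation <- function(cycles, normalise = FALSE) {
  if (inherits(cycles, "sensorgram")) cycles <- list(cycles)
  lapply(cycles, function(tr) {
    sch <- attr(tr, "schedule")
    if (is.null(sch) || !any(tr$phase == "dissociation"))
      stop("cycle has no dissociation phase")
    resp <- tr$response
    if (normalise) {
      at_end <- which(tr$phase == "dissociation" & !tr$masked)
      if (!length(at_end)) stop("no unmasked dissociation points")
      r0 <- resp[at_end[1]]
      if (r0 == 0) stop("zero end-of-injection response; cannot normalise")
      resp <- resp / r0
    }
    out <- sensorgram(tr$time - sch$assoc_end, resp, tr$phase, tr$masked,
                      schedule = sch, analyte = attr(tr, "analyte"),
                      conc_uM = attr(tr, "conc_uM"),
                      channel = attr(tr, "channel"),
                      cycle_id = attr(tr, "cycle_id"))
    attr(out, "contact_time") <- sch$assoc_end - sch$assoc_start
    out
  })
}
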