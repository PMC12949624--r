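#' Descending twofold-style dilution series
#'
#' Geometric dilution series from a top concentration down to a floor:
#' `top, top/factor, top/factor^2, ...`, keeping every value at or above
#' `floor` (within a 1e-9 relative tolerance, so a floor exactly on the
#' series is included).
#'
#' @param top_uM Top concentration, micromolar.
#' @param floor_uM Lowest concentration to include, micromolar.
#' @param factor Dilution factor (> 1).
#' @return Numeric vector of concentrations in micromolar, descending.
#' @examples
#' length(dilution_series(200, 0.78, 2))  # 9
#' length(dilution_series(50, 0.78, 2))   # 7
#' @export
dilution_series <- function(top_uM, floor_uM, factor = 2) {
  stopifnot(factor > 1, floor_uM > 0, floor_uM <= top_uM)
  n <- floor(log(top_uM / (floor_uM * (1 - 1e-9))) / log(factor)) + 1
  top_uM / factor^(seq_len(n) - 1)
}

#' Experiment design for a synthetic SPR run
#'
#' Captures the assay design: which analytes are injected, the dilution
#' series, injection timing, immobilisation level, and the surface model
#' used to derive binding capacity. Defaults mirror a peptide-vs-Kelch-domain
#' assay: twofold dilutions from 200 uM down to 0.78 uM, 60 s injections,
#' 15 s dissociation, ~9 kRU immobilised ligand, and two zero-concentration
#' blank cycles placed first and last.
#'
#' @param analytes data.frame with columns `label` and `mass_da`.
#' @param top_uM,floor_uM,dilution_factor Dilution series (micromolar).
#' @param contact_time Injection duration(s), s; a vector defines a
#'   contact-time series.
#' @param dissociation_time,baseline Phase durations, s.
#' @param sample_rate Sampling rate, Hz.
#' @param n_blanks Number of zero-concentration blank cycles (split between
#'   the beginning and end of each series).
#' @param immobilisation_RU Immobilised ligand level, RU.
#' @param ligand_mass_da Ligand (immobilised protein) mass, Da.
#' @param active_fraction Fraction of immobilised ligand competent to bind.
#' @return Object of class `"experiment_design"`.
#' @export
experiment_design <- function(analytes = data.frame(label = "pep1",
                                                    mass_da = 1779),
                              top_uM = 200, floor_uM = 0.78,
                              dilution_factor = 2, contact_time = 60,
                              dissociation_time = 15, baseline = 10,
                              sample_rate = 10, n_blanks = 2,
                              immobilisation_RU = 9000,
                              ligand_mass_da = 36000,
                              active_fraction = 0.25) {
  stopifnot(is.data.frame(analytes), all(c("label", "mass_da") %in% names(analytes)),
            dilution_factor > 1, all(contact_time > 0), dissociation_time > 0,
            immobilisation_RU > 0, ligand_mass_da > 0, active_fraction >= 0,
            n_blanks >= 0)
  structure(list(analytes = analytes, top_uM = top_uM, floor_uM = floor_uM,
                 dilution_factor = dilution_factor, contact_time = contact_time,
                 dissociation_time = dissociation_time, baseline = baseline,
                 sample_rate = sample_rate, n_blanks = n_blanks,
                 immobilisation_RU = immobilisation_RU,
                 ligand_mass_da = ligand_mass_da,
                 active_fraction = active_fraction),
            class = "experiment_design")
}

#' Stoichiometric binding capacity from the design
#'
#' `Rmax = immobilisation level x (analyte mass / ligand mass) x active
#' fraction` -- the standard capacity rule for a surface binding analytes of
#' known mass.
#'
#' @param design An [experiment_design()].
#' @param analyte_mass_da Analyte mass, Da.
#' @return Capacity in RU.
#' @export
rmax_from_design <- function(design, analyte_mass_da) {
  stopifnot(inherits(design, "experiment_design"), analyte_mass_da > 0)
  design$immobilisation_RU * (analyte_mass_da / design$ligand_mass_da) *
    design$active_fraction
}

#' Instrument noise and artifact model
#'
#' Parameters of the additive artifact structure applied by
#' [generate_experiment()]: white measurement noise, baseline drift, bulk
#' solvent (DMSO-mismatch) offsets during injections, and pressure spikes at
#' injection boundaries. With all magnitudes zero the generator emits the
#' pure mechanism signal.
#'
#' @param sd Additive Gaussian noise sd, RU.
#' @param drift_range Baseline drift rate drawn uniform in `+/- drift_range`,
#'   RU/s, applied to the active channel.
#' @param drift_shared If `TRUE` (default) one drift rate is drawn per
#'   experiment (a systematic surface trend, removable by blank referencing);
#'   if `FALSE` an independent rate is drawn per cycle.
#' @param spike_amp Maximum boundary-spike amplitude, RU.
#' @param spike_window Half-width of the spike window at each phase
#'   boundary, s.
#' @param bulk_per_pct Bulk refractive-index offset per % DMSO mismatch,
#'   RU/%.
#' @param bulk_imbalance Ratio of active-channel to reference-channel bulk
#'   response (< 1 models excluded volume over the protein surface; the
#'   residual after reference subtraction is what solvent correction
#'   removes).
#' @param dmso_mismatch_range DMSO mismatch drawn uniform in `+/- range`, %.
#' @param seed Integer seed; identical seeds give identical experiments.
#' @return Object of class `"noise_model"`.
#' @export
noise_model <- function(sd = 0.15, drift_range = 0.02, drift_shared = TRUE,
                        spike_amp = 20, spike_window = 0.5, bulk_per_pct = 8,
                        bulk_imbalance = 0.95, dmso_mismatch_range = 0.1,
                        seed = 1L) {
  stopifnot(sd >= 0, drift_range >= 0, spike_amp >= 0, spike_window >= 0,
            bulk_per_pct >= 0, dmso_mismatch_range >= 0)
  structure(list(sd = sd, drift_range = drift_range, drift_shared = drift_shared,
                 spike_amp = spike_amp, spike_window = spike_window,
                 bulk_per_pct = bulk_per_pct, bulk_imbalance = bulk_imbalance,
                 dmso_mismatch_range = dmso_mismatch_range,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' A noise model with every artifact switched off
#' @return A [noise_model()] emitting pure mechanism signal.
#' @export
noise_off <- function() {
  noise_model(sd = 0, drift_range = 0, spike_amp = 0, bulk_per_pct = 0,
              dmso_mismatch_range = 0)
}

# evaluate with a local RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# one synthetic cycle: active + reference traces with artifacts
.make_cycle <- function(mech, schedule, noise, drift_rate, analyte, cycle_id) {
  g <- schedule_grid(schedule)
  npt <- length(g$time)
  signal <- if (schedule$conc_uM > 0)
    .simulate_exact(mech, schedule)$response else numeric(npt)
  mismatch <- if (noise$dmso_mismatch_range > 0)
    stats::runif(1, -noise$dmso_mismatch_range, noise$dmso_mismatch_range) else 0
  assoc <- g$phase == "association"
  bulk_ref <- noise$bulk_per_pct * mismatch * assoc
  spikes <- function() {
    s <- numeric(npt)
    for (b in c(schedule$assoc_start, schedule$assoc_end)) {
      amp <- if (noise$spike_amp > 0)
        noise$spike_amp * stats::runif(1, 0.5, 1) * sample(c(-1, 1), 1) else 0
      if (amp != 0) {
        w <- abs(g$time - b) <= noise$spike_window
        s[w] <- s[w] + amp
      }
    }
    s
  }
  wn <- function() if (noise$sd > 0) stats::rnorm(npt, 0, noise$sd) else numeric(npt)
  active_resp <- signal + noise$bulk_imbalance * bulk_ref +
    drift_rate * g$time + spikes() + wn()
  ref_resp <- bulk_ref + spikes() + wn()
  mk <- function(resp, channel)
    sensorgram(g$time, resp, g$phase, schedule = schedule, analyte = analyte,
               conc_uM = schedule$conc_uM, channel = channel,
               cycle_id = cycle_id)
  list(active = mk(active_resp, "active"), reference = mk(ref_resp, "reference"),
       analyte = analyte, conc_uM = schedule$conc_uM,
       blank = schedule$conc_uM == 0,
       contact_time = schedule$assoc_end - schedule$assoc_start,
       cycle_id = cycle_id)
}

.solvent_calibration <- function(noise) {
  span <- max(noise$bulk_per_pct * noise$dmso_mismatch_range * 2, 1)
  ref_bulk <- seq(-span, span, length.out = 5)
  data.frame(ref_bulk = ref_bulk,
             correction = (noise$bulk_imbalance - 1) * ref_bulk)
}

#' Generate a complete synthetic SPR experiment
#'
#' For every analyte, a dilution series of injection cycles (plus blank
#' zero-concentration cycles placed first and last) is simulated on active
#' and reference channels with the artifact structure of [noise_model()]:
#' the active channel carries mechanism signal, bulk offset, drift, white
#' noise and boundary spikes; the reference channel carries everything but
#' the binding signal and drift. Ground truth is stored in the provenance
#' slot, never in the traces.
#'
#' @param design An [experiment_design()].
#' @param mech A mechanism object (see [mechanisms]), or a named list of
#'   mechanisms keyed by analyte label.
#' @param noise A [noise_model()].
#' @return Object of class `"experiment_set"`: list with `cycles` (each a
#'   list of `active`/`reference` [sensorgram()]s plus metadata), `design`,
#'   `noise`, `solvent_calibration`, and `provenance`.
#' @export
generate_experiment <- function(design, mech, noise = noise_model()) {
  stopifnot(inherits(design, "experiment_design"), inherits(noise, "noise_model"))
  .with_seed(noise$seed, {
    drift_exp <- if (noise$drift_range > 0 && noise$drift_shared)
      stats::runif(1, -noise$drift_range, noise$drift_range) else 0
    concs <- dilution_series(design$top_uM, design$floor_uM,
                             design$dilution_factor)
    n_pre <- ceiling(design$n_blanks / 2)
    n_post <- design$n_blanks - n_pre
    series <- c(rep(0, n_pre), concs, rep(0, n_post))
    cycles <- list()
    for (a in seq_len(nrow(design$analytes))) {
      lab <- design$analytes$label[a]
      mech_a <- if (inherits(mech, "mechanism")) mech else mech[[lab]]
      stopifnot(inherits(mech_a, "mechanism"))
      for (k in seq_along(series)) {
        drift <- if (noise$drift_range > 0 && !noise$drift_shared)
          stats::runif(1, -noise$drift_range, noise$drift_range) else drift_exp
        sch <- injection_schedule(design$contact_time[1],
                                  design$dissociation_time, design$baseline,
                                  design$sample_rate, conc_uM = series[k])
        cycles[[length(cycles) + 1L]] <-
          .make_cycle(mech_a, sch, noise, drift, lab,
                      sprintf("%s_c%02d", lab, k))
      }
    }
    structure(list(cycles = cycles, design = design, noise = noise,
                   solvent_calibration = .solvent_calibration(noise),
                   provenance = list(mechanism = mech, seed = noise$seed)),
              class = "experiment_set")
  })
}

#' @export
print.experiment_set <- function(x, ...) {
  cat("Synthetic SPR experiment: ", length(x$cycles), " cycles (",
      sum(vapply(x$cycles, `[[`, logical(1), "blank")), " blanks), ",
      nrow(x$design$analytes), " analyte(s), seed ", x$noise$seed, "\n",
      sep = "")
  invisible(x)
}

#' Generate a contact-time series experiment
#'
#' One cycle per injection (contact) time at a single analyte concentration,
#' with a common dissociation window -- the design used to test whether
#' dissociation kinetics depend on how long the analyte was in contact with
#' the surface (the signature of slow induced conformational change).
#'
#' @param design An [experiment_design()]; its first analyte is used.
#' @param mech A mechanism object.
#' @param noise A [noise_model()].
#' @param contact_times Injection durations, s.
#' @param conc_uM Single analyte concentration (default the design's top).
#' @param blanks If `TRUE` (default) a zero-concentration blank cycle is
#'   generated for every contact time so the series can be double-referenced
#'   (each contact time has its own grid, so it needs its own blank).
#' @return An `"experiment_set"` with one cycle (plus blank) per contact
#'   time.
#' @export
generate_contact_time_series <- function(design, mech, noise = noise_model(),
                                         contact_times = c(15, 30, 45, 60, 75,
                                                           90, 120, 140),
                                         conc_uM = design$top_uM,
                                         blanks = TRUE) {
  stopifnot(inherits(design, "experiment_design"), inherits(mech, "mechanism"),
            length(contact_times) >= 1, conc_uM > 0)
  .with_seed(noise$seed, {
    drift_exp <- if (noise$drift_range > 0 && noise$drift_shared)
      stats::runif(1, -noise$drift_range, noise$drift_range) else 0
    lab <- design$analytes$label[1]
    cycles <- list()
    for (k in seq_along(contact_times)) {
      drift <- if (noise$drift_range > 0 && !noise$drift_shared)
        stats::runif(1, -noise$drift_range, noise$drift_range) else drift_exp
      concs_k <- if (blanks) c(0, conc_uM) else conc_uM
      for (cu in concs_k) {
        sch <- injection_schedule(contact_times[k], design$dissociation_time,
                                  design$baseline, design$sample_rate,
                                  conc_uM = cu)
        cycles[[length(cycles) + 1L]] <-
          .make_cycle(mech, sch, noise, drift, lab,
                      sprintf("%s_ct%03d%s", lab, contact_times[k],
                              if (cu == 0) "_blank" else ""))
      }
    }
    structure(list(cycles = cycles, design = design, noise = noise,
                   solvent_calibration = .solvent_calibration(noise),
                   provenance = list(mechanism = mech, seed = noise$seed,
                                     contact_times = contact_times)),
              class = "experiment_set")
  })
}

#' Generate a synthetic thermal-shift melt curve
#'
#' Two-state van't Hoff unfolding monitored by an intrinsic-fluorescence
#' ratio: the unfolded fraction is
#' `f(T) = 1 / (1 + exp((dHvH / R) (1/T - 1/Tm)))` with temperatures in
#' kelvin, and the signal interpolates between linear folded and unfolded
#' baselines, plus Gaussian noise.
#'
#' @param Tm Melting temperature, degrees C; must lie inside the scan range.
#' @param dHvH Van't Hoff enthalpy, kJ/mol.
#' @param t_range Scan range, degrees C.
#' @param step Temperature step, degrees C.
#' @param folded,unfolded Baselines as `c(intercept, slope_per_degC)`,
#'   anchored at the scan start.
#' @param noise_sd Gaussian noise sd (signal units).
#' @param seed Integer seed.
#' @return Object of class `"melt_curve"`: data.frame with `temperature`
#'   (degrees C) and `signal`, provenance in attributes.
#' @export
generate_melt_curve <- function(Tm = 69, dHvH = 400, t_range = c(35, 95),
                                step = 0.25, folded = c(0.86, -4e-4),
                                unfolded = c(1.00, 2e-4), noise_sd = 0.002,
                                seed = 1L) {
  if (Tm <= t_range[1] || Tm >= t_range[2])
    stop("Tm must lie inside the scan range ", t_range[1], "..", t_range[2])
  temp <- seq(t_range[1], t_range[2], by = step)
  f <- melt_fraction(temp, Tm, dHvH)
  base_f <- folded[1] + folded[2] * (temp - t_range[1])
  base_u <- unfolded[1] + unfolded[2] * (temp - t_range[1])
  signal <- base_f * (1 - f) + base_u * f
  if (noise_sd > 0)
    signal <- signal + .with_seed(seed, stats::rnorm(length(temp), 0, noise_sd))
  out <- data.frame(temperature = temp, signal = signal)
  attr(out, "provenance") <- list(Tm = Tm, dHvH = dHvH, folded = folded,
                                  unfolded = unfolded, noise_sd = noise_sd,
                                  seed = seed)
  class(out) <- c("melt_curve", "data.frame")
  out
}

#' Two-state van't Hoff unfolded fraction
#' @param temp_C Temperature(s), degrees C.
#' @param Tm Midpoint, degrees C.
#' @param dHvH Van't Hoff enthalpy, kJ/mol.
#' @return Unfolded fraction in `[0, 1]`.
#' @export
melt_fraction <- function(temp_C, Tm, dHvH) {
  R <- 8.31446e-3  # kJ/(mol K)
  TK <- temp_C + 273.15
  TmK <- Tm + 273.15
  1 / (1 + exp((dHvH / R) * (1 / TK - 1 / TmK)))
}
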