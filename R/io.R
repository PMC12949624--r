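#' Write a sensorgram to a plain-text table
#'
#' Dialect: `#`-prefixed `key: value` metadata header lines (cycle id,
#' channel, analyte, concentration in micromolar, phase boundaries, sample
#' rate), then a tab-separated data block with columns `time_s`,
#' `response_RU`, `masked` (0/1). Values round-trip via [read_sensorgram()].
#'
#' @param s A [sensorgram()] carrying an [injection_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensorgram <- function(s, path) {
  stopifnot(inherits(s, "sensorgram"))
  sch <- attr(s, "schedule")
  if (is.null(sch)) stop("sensorgram carries no injection schedule")
  hdr <- c(
    paste0("# cycle_id: ", attr(s, "cycle_id")),
    paste0("# channel: ", attr(s, "channel")),
    paste0("# analyte: ", attr(s, "analyte")),
    paste0("# conc_uM: ", format(attr(s, "conc_uM"), digits = 12)),
    paste0("# assoc_start: ", format(sch$assoc_start, digits = 12)),
    paste0("# assoc_end: ", format(sch$assoc_end, digits = 12)),
    paste0("# diss_end: ", format(sch$diss_end, digits = 12)),
    paste0("# sample_rate: ", format(sch$sample_rate, digits = 12)),
    "time_s\tresponse_RU\tmasked")
  lines <- sprintf("%.9g\t%.9g\t%d", s$time, s$response, as.integer(s$masked))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a sensorgram written by [write_sensorgram()]
#'
#' @param path File path.
#' @return A [sensorgram()]. Errors on a malformed header, a missing phase
#'   boundary, or non-monotone time; a missing `masked` column defaults to
#'   all-unmasked with a warning.
#' @export
read_sensorgram <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (!length(hdr_idx) || any(diff(hdr_idx) != 1) || hdr_idx[1] != 1)
    stop("malformed header: expected leading '#' metadata block")
  meta <- list()
  for (h in lines[hdr_idx]) {
    kv <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(kv) != 3) stop("malformed header line: ", h)
    meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  for (field in c("assoc_start", "assoc_end", "diss_end", "sample_rate"))
    if (is.null(meta[[field]]))
      stop("missing required header field: ", field)
  body <- lines[-hdr_idx]
  header_row <- strsplit(body[1], "\t")[[1]]
  if (!all(c("time_s", "response_RU") %in% header_row))
    stop("malformed data header: need time_s and response_RU columns")
  dat <- utils::read.table(text = body[-1], sep = "\t",
                           col.names = header_row,
                           colClasses = "numeric")
  if (!"masked" %in% names(dat)) {
    warning("masked column absent; defaulting to unmasked")
    dat$masked <- 0
  }
  if (any(diff(dat$time_s) <= 0)) stop("non-monotone time column")
  conc <- as.numeric(meta$conc_uM %||% NA_real_)
  sch <- injection_schedule(
    contact_time = as.numeric(meta$assoc_end) - as.numeric(meta$assoc_start),
    dissociation_time = as.numeric(meta$diss_end) - as.numeric(meta$assoc_end),
    baseline = as.numeric(meta$assoc_start),
    sample_rate = as.numeric(meta$sample_rate),
    conc_uM = if (is.na(conc)) 0 else conc)
  phase <- ifelse(dat$time_s < sch$assoc_start - 1e-9, "baseline",
                  ifelse(dat$time_s < sch$assoc_end - 1e-9, "association",
                         "dissociation"))
  sensorgram(dat$time_s, dat$response_RU, phase, dat$masked != 0,
             schedule = sch, analyte = meta$analyte %||% "",
             conc_uM = conc, channel = meta$channel %||% "active",
             cycle_id = meta$cycle_id %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an experiment manifest
#'
#' Serialises the experiment definition (design, mechanism by name plus
#' parameter block, noise block, analyte table, seed) as YAML.
#'
#' @param design An [experiment_design()].
#' @param mech A mechanism object.
#' @param noise A [noise_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(design, mech, noise, path) {
  man <- list(
    design = unclass(design)[setdiff(names(unclass(design)), "analytes")],
    analytes = lapply(seq_len(nrow(design$analytes)), function(i)
      as.list(design$analytes[i, , drop = FALSE])),
    mechanism = c(list(name = class(mech)[1]),
                  lapply(unclass(mech), function(v)
                    if (is.matrix(v)) as.list(as.data.frame(v)) else v)),
    noise = unclass(noise))
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Read an experiment manifest
#'
#' @param path YAML path from [write_manifest()].
#' @return List with `design` ([experiment_design()]), `mech` (mechanism)
#'   and `noise` ([noise_model()]).
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  analytes <- do.call(rbind, lapply(man$analytes, as.data.frame))
  d <- man$design
  design <- experiment_design(
    analytes = analytes, top_uM = d$top_uM, floor_uM = d$floor_uM,
    dilution_factor = d$dilution_factor,
    contact_time = unlist(d$contact_time),
    dissociation_time = d$dissociation_time, baseline = d$baseline,
    sample_rate = d$sample_rate, n_blanks = d$n_blanks,
    immobilisation_RU = d$immobilisation_RU,
    ligand_mass_da = d$ligand_mass_da, active_fraction = d$active_fraction)
  mp <- man$mechanism
  mech <- switch(mp$name,
    mech_one_to_one = mech_one_to_one(mp$ka, mp$kd, mp$Rmax),
    mech_two_state = mech_two_state(mp$ka1, mp$kd1, mp$ka2, mp$kd2, mp$Rmax),
    mech_heterogeneous = mech_heterogeneous(mp$ka1, mp$kd1, mp$Rmax1,
                                            mp$ka2, mp$kd2, mp$Rmax2),
    mech_ensemble = mech_ensemble(unlist(mp$ka), unlist(mp$kd), mp$Rmax,
                                  if (!is.null(mp$k_int))
                                    as.matrix(as.data.frame(mp$k_int))),
    stop("unknown mechanism name in manifest: ", mp$name))
  np <- man$noise
  noise <- noise_model(sd = np$sd, drift_range = np$drift_range,
                       drift_shared = np$drift_shared,
                       spike_amp = np$spike_amp,
                       spike_window = np$spike_window,
                       bulk_per_pct = np$bulk_per_pct,
                       bulk_imbalance = np$bulk_imbalance,
                       dmso_mismatch_range = np$dmso_mismatch_range,
                       seed = np$seed)
  list(design = design, mech = mech, noise = noise)
}

#' Run the full synthetic-experiment analysis pipeline
#'
#' Chains generation, preprocessing, fitting and diagnostics on a manifest:
#' generate the experiment, double-reference it, extract report points, fit
#' the steady-state isotherm and binding efficiency per analyte, globally
#' fit the requested kinetic mechanisms and rank them, and (when the design
#' declares several contact times) run the contact-time invariance
#' diagnostic. Results are returned as a bundle and optionally written to
#' `outdir` (sensorgram tables, TSV reports, key-value summaries).
#'
#' @param manifest Path to a YAML manifest or a list as returned by
#'   [read_manifest()].
#' @param steps Subset of `c("generate", "preprocess", "fit", "diagnose")`;
#'   later steps require earlier ones.
#' @param outdir Optional output directory (created if needed).
#' @param mechanisms Mechanism names passed to [fit_kinetic()].
#' @return A list bundle with elements among `set`, `processed`, `curves`,
#'   `ss_fits`, `be`, `kinetic_fits`, `comparison`, `invariance`.
#' @export
run_pipeline <- function(manifest,
                         steps = c("generate", "preprocess", "fit", "diagnose"),
                         outdir = NULL,
                         mechanisms = c("one_to_one", "two_state",
                                        "heterogeneous")) {
  steps <- match.arg(steps, several.ok = TRUE)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }
  bundle <- list()
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  contact_series <- length(manifest$design$contact_time) > 1
  bundle$set <- stage("generate", {
    if (contact_series)
      generate_contact_time_series(manifest$design, manifest$mech,
                                   manifest$noise,
                                   contact_times = manifest$design$contact_time)
    else generate_experiment(manifest$design, manifest$mech, manifest$noise)
  })
  if (!is.null(outdir)) {
    write_manifest(manifest$design, manifest$mech, manifest$noise,
                   file.path(outdir, "manifest.yaml"))
    for (cy in bundle$set$cycles) {
      write_sensorgram(cy$active,
                       file.path(outdir, paste0(cy$cycle_id, "_active.tsv")))
      write_sensorgram(cy$reference,
                       file.path(outdir, paste0(cy$cycle_id, "_reference.tsv")))
    }
  }
  if (!"preprocess" %in% steps) return(bundle)

  bundle$processed <- stage("preprocess", preprocess_set(bundle$set))

  if ("fit" %in% steps && !contact_series) {
    bundle$curves <- stage("fit", extract_report_points(bundle$processed))
    bundle$ss_fits <- stage("fit", lapply(bundle$curves, fit_steady_state))
    bundle$be <- stage("fit", lapply(bundle$curves, binding_efficiency))
    bundle$kinetic_fits <- stage("fit", {
      fits <- lapply(mechanisms, function(mn)
        fit_kinetic(bundle$processed, mechanism = mn))
      names(fits) <- mechanisms
      fits
    })
    bundle$comparison <- stage("fit", compare_models(bundle$kinetic_fits))
    if (!is.null(outdir)) {
      ss_tab <- data.frame(
        analyte = names(bundle$ss_fits),
        KD_app_uM = vapply(bundle$ss_fits, function(f)
          f$coefficients[["KD_app_uM"]], numeric(1)),
        Rmax_RU = vapply(bundle$ss_fits, function(f)
          f$coefficients[["Rmax"]], numeric(1)),
        BE_RU_per_uM = vapply(bundle$be, `[[`, numeric(1), "be"),
        unreliable = vapply(bundle$ss_fits, function(f)
          f$flags$unreliable, logical(1)))
      utils::write.table(ss_tab, file.path(outdir, "steady_state.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(bundle$comparison$table,
                         file.path(outdir, "model_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if ("diagnose" %in% steps && contact_series) {
    bundle$invariance <- stage("diagnose", {
      aligned <- align_dissociation(bundle$processed)
      contact_time_invariance(aligned)
    })
    if (!is.null(outdir))
      writeLines(c(paste0("verdict: ", bundle$invariance$verdict),
                   paste0("trend_slope: ", bundle$invariance$trend_slope),
                   paste0("rate_span: ", bundle$invariance$rate_span)),
                 file.path(outdir, "invariance.txt"))
  }
  bundle
}
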