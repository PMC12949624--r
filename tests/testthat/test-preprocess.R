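make_flat <- function(resp, sch = injection_schedule(10, 10, 5, 10, conc_uM = 5),
                      channel = "active") {
  g <- sprkin:::schedule_grid(sch)
  sensorgram(g$time, rep(resp, length.out = length(g$time)), g$phase,
             schedule = sch, conc_uM = 5, channel = channel)
}

test_that("reference subtraction is a pointwise difference with mask union", {
  a <- make_flat(3)
  expect_true(all(reference_subtract(a, a)$response == 0))
  b <- make_flat(1)
  b$masked[5] <- TRUE
  out <- reference_subtract(a, b)
  expect_equal(out$response, rep(2, nrow(a)))
  expect_true(out$masked[5])
  short <- make_flat(1, injection_schedule(10, 5, 5, 10, conc_uM = 5))
  expect_error(reference_subtract(a, short), "grids")
})

test_that("reference subtraction doubles single-channel noise variance", {
  set.seed(31)
  sch <- injection_schedule(30, 10, 5, 10, conc_uM = 5)
  g <- sprkin:::schedule_grid(sch)
  mk <- function() sensorgram(g$time, rnorm(length(g$time), 0, 0.5), g$phase,
                              schedule = sch, conc_uM = 5)
  ratios <- replicate(20, var(reference_subtract(mk(), mk())$response) / 0.25)
  expect_gt(mean(ratios), 1.7)
  expect_lt(mean(ratios), 2.3)
})

test_that("blank subtraction removes shared drift and validates input", {
  sch <- injection_schedule(10, 10, 5, 10, conc_uM = 5)
  g <- sprkin:::schedule_grid(sch)
  drift <- 0.05 * g$time
  tr <- sensorgram(g$time, 7 + drift, g$phase, schedule = sch, conc_uM = 5)
  bl <- sensorgram(g$time, drift, g$phase, schedule = sch, conc_uM = 0)
  out <- blank_subtract(tr, list(bl))
  expect_equal(out$response, rep(7, nrow(tr)), tolerance = 1e-12)
  expect_error(blank_subtract(tr, list()), "blank")
})

test_that("double referencing flattens the generated drift", {
  des <- std_design()
  m <- truth_11()
  nm <- noise_model(sd = 0.05, drift_range = 0.02, spike_amp = 0,
                    bulk_per_pct = 0, seed = 3)
  proc <- preprocess_set(generate_experiment(des, m, nm), spike_guard = 0)
  tr <- proc[[1]]
  base <- tr$phase == "baseline"
  slope <- coef(lm(tr$response[base] ~ tr$time[base]))[[2]]
  # residual baseline slope is noise-limited, far below the drawn drift rate
  expect_lt(abs(slope), 0.01)
})

test_that("solvent correction fixes the residual bulk step", {
  cal <- data.frame(ref_bulk = c(-2, 0, 2), correction = c(0.1, 0, -0.1))
  id_cal <- data.frame(ref_bulk = c(-2, 2), correction = c(0, 0))
  tr <- make_flat(1)
  ref <- make_flat(0.5, channel = "reference")
  expect_equal(solvent_correct(tr, ref, id_cal)$response, tr$response)
  expect_error(solvent_correct(tr, ref, cal[1, ]), "at least two")
  expect_warning(solvent_correct(tr, make_flat(5), cal), "clamped")
  # synthetic mismatch: residual bulk after the full chain is < 0.5 RU
  des <- std_design()
  nm <- noise_model(sd = 0, drift_range = 0, spike_amp = 0,
                    bulk_per_pct = 8, bulk_imbalance = 0.95,
                    dmso_mismatch_range = 0.1, seed = 8)
  set <- generate_experiment(des, truth_11(), nm)
  proc <- preprocess_set(set, spike_guard = 0)
  tr <- proc[[1]]
  pure <- simulate_one_to_one(truth_11(), attr(tr, "schedule"))
  expect_lt(max(abs(tr$response - pure$response)), 0.5)
})

test_that("spike masking follows the guard and never alters values", {
  sch <- injection_schedule(10, 10, 5, 10, conc_uM = 5)
  tr <- make_flat(2, sch)
  expect_identical(mask_spikes(tr, 0), tr)
  m1 <- mask_spikes(tr, 0.5)
  per_boundary <- sapply(c(sch$assoc_start, sch$assoc_end), function(b)
    sum(m1$masked & abs(tr$time - b) <= 0.5 + 1e-9))
  expect_true(all(per_boundary %in% 10:11))
  expect_identical(m1$response, tr$response)
  all_masked <- mask_spikes(tr, 1e3)
  expect_error(extract_report_points(list(all_masked)), "empty|masked")
})

test_that("the full correction chain returns the pure signal", {
  des <- std_design()
  m <- truth_11()
  proc <- preprocess_set(generate_experiment(des, m, noise_off()))
  for (i in c(1, 5, 9)) {
    pure <- simulate_one_to_one(m, attr(proc[[i]], "schedule"))
    ok <- !proc[[i]]$masked
    expect_lt(max(abs(proc[[i]]$response[ok] - pure$response[ok])), 1e-9)
  }
})

test_that("report points approach Req only when equilibrated", {
  m <- mech_one_to_one(1e2, 5e-3, 100)  # slow: KD = 50 uM
  # long injection: report point equals Req to 0.1%
  long_sch <- injection_schedule(3000, 15, 5, 2, conc_uM = 50)
  sg <- simulate_one_to_one(m, long_sch)
  rp_long <- extract_report_points(list(sg))[[1]]
  expect_equal(rp_long$response, steady_state_response(m, 50),
               tolerance = 1e-3)
  # 15 s injection: report point below Req
  short_sch <- injection_schedule(15, 15, 5, 10, conc_uM = 50)
  rp_short <- extract_report_points(list(simulate_one_to_one(m, short_sch)))[[1]]
  expect_lt(rp_short$response, steady_state_response(m, 50) * 0.5)
})

test_that("report points ignore spike masking outside the window and keep replicates", {
  m <- truth_11()
  sch <- injection_schedule(60, 15, 5, 10, conc_uM = 100)
  sg <- simulate_one_to_one(m, sch)
  rp_plain <- extract_report_points(list(sg))[[1]]$response
  rp_masked <- extract_report_points(list(mask_spikes(sg, 0.4)))[[1]]$response
  expect_identical(rp_plain, rp_masked)
  # replicate cycles at one concentration are retained, not averaged
  two <- extract_report_points(list(sg, sg))[[1]]
  expect_equal(nrow(two), 2)
  expect_equal(two$conc_uM, c(100, 100))
})

test_that("alignment zeroes the clock at injection end", {
  m <- truth_11()
  sg <- simulate_one_to_one(m, injection_schedule(60, 15, 5, 10, conc_uM = 50))
  al <- align_dissociation(list(sg))[[1]]
  expect_equal(min(al$time[al$phase == "dissociation"]), 0)
  expect_equal(al$response, sg$response)
  base_only <- sg[sg$phase != "dissociation", ]
  class(base_only) <- class(sg)
  attr(base_only, "schedule") <- attr(sg, "schedule")
  expect_error(align_dissociation(list(structure(
    sensorgram(1:10, rep(1, 10), rep("baseline", 10))))), "dissociation")
})

test_that("two-state slow isomerisation fans out aligned dissociations", {
  des <- std_design(top_uM = 50)
  s <- generate_contact_time_series(des, truth_2s_slow(100), noise_off(),
                                    contact_times = c(15, 140))
  al <- align_dissociation(preprocess_set(s), normalise = TRUE)
  take <- function(x) x$response[x$phase == "dissociation" & !x$masked &
                                   x$time <= 10][1:80]
  # long-contact trace dissociates more slowly
  expect_gt(mean(take(al[[2]]) - take(al[[1]])), 0.01)
})
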