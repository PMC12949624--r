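iso_curve <- function(kd_uM = 35, rmax = 100,
                      conc = dilution_series(200, 0.78, 2)) {
  steady_state_curve(conc, rmax * conc / (kd_uM + conc))
}

test_that("steady-state fit recovers an exact isotherm", {
  f <- fit_steady_state(iso_curve(35, 100))
  expect_equal(f$coefficients[["KD_app_uM"]], 35, tolerance = 1e-6)
  expect_equal(f$coefficients[["Rmax"]], 100, tolerance = 1e-6)
  expect_false(f$flags$unreliable)
  expect_error(fit_steady_state(steady_state_curve(c(1, 2), c(1, 2))),
               "3 distinct")
})

test_that("a strictly linear curve drives KD to its bound and is flagged", {
  lin <- steady_state_curve(c(1, 2, 4, 8, 16), 0.3 * c(1, 2, 4, 8, 16))
  f <- fit_steady_state(lin)
  expect_true(f$flags$unreliable)
  expect_true(f$flags$kd_at_bound)
})

test_that("apparent KD from short injections exceeds the true KD", {
  m <- mech_one_to_one(1e2, 5e-3, 100)  # slow 1:1, KD = 50 uM
  kd_app <- sapply(c(15, 60), function(ct) {
    des <- std_design(contact_time = ct)
    proc <- preprocess_set(generate_experiment(des, m, noise_off()))
    fit_steady_state(extract_report_points(proc)[[1]])$coefficients[["KD_app_uM"]]
  })
  expect_gt(kd_app[1], kd_app[2])  # 15 s more biased than 60 s
  expect_gt(kd_app[2], 50)         # both above truth
})

test_that("binding efficiency approximates Rmax/KD at low concentration", {
  conc <- c(0.78, 1.56, 3.13)
  cv <- iso_curve(50, 100, conc = conc)
  be <- binding_efficiency(cv, n_low = 3)
  # oracle: closed-form zero-intercept least-squares slope on exact isotherm
  resp <- 100 * conc / (50 + conc)
  slope_exact <- sum(conc * resp) / sum(conc^2)
  expect_equal(be$be, slope_exact, tolerance = 1e-9)
  # close to the low-concentration limit Rmax/KD = 2 (exact deviation 5.1%)
  expect_lt(abs(be$be - 2) / 2, 0.06)
  # doubling responses doubles BE
  cv2 <- steady_state_curve(cv$conc_uM, 2 * cv$response)
  expect_equal(binding_efficiency(cv2, 3)$be, 2 * be$be, tolerance = 1e-9)
  expect_error(binding_efficiency(steady_state_curve(1, 1)), "at least 2")
})

test_that("BE converges to Rmax/KD as the window shrinks", {
  # window Cmax far below KD: relative error under 2%
  cv <- iso_curve(300, 100)  # window 0.78..3.125 uM ~ KD/100
  be <- binding_efficiency(cv, n_low = 3)
  expect_lt(abs(be$be - 100 / 300) / (100 / 300), 0.02)
})

test_that("BE ranking matches KD ranking at shared Rmax", {
  kds <- c(30, 60, 120, 500)
  bes <- sapply(kds, function(k) {
    mm <- mech_one_to_one(1e4, 1e4 * k * 1e-6, 100)
    proc <- preprocess_set(generate_experiment(std_design(), mm,
                                               noise_model(seed = 5)))
    binding_efficiency(extract_report_points(proc)[[1]])$be
  })
  expect_true(all(diff(bes) < 0))  # higher KD -> lower BE
})

test_that("global 1:1 fit is self-consistent on noiseless data", {
  des <- std_design()
  m <- truth_11()
  proc <- preprocess_set(generate_experiment(des, m, noise_off()))
  f <- fit_kinetic(proc, "one_to_one")
  expect_lt(abs(coef(f)[["ka"]] - m$ka) / m$ka, 1e-4)
  expect_lt(abs(coef(f)[["kd"]] - m$kd) / m$kd, 1e-4)
  expect_lt(abs(coef(f)[["Rmax"]] - m$Rmax) / m$Rmax, 1e-4)
  expect_equal(f$KD_app_uM, m$KD * 1e6, tolerance = 1e-3)
})

test_that("seeded noisy series recovers KD within 10%", {
  des <- std_design()
  m <- truth_11()
  proc <- preprocess_set(generate_experiment(des, m, noise_model(seed = 1)))
  f <- fit_kinetic(proc, "one_to_one")
  expect_lt(abs(f$KD_app_uM - m$KD * 1e6) / (m$KD * 1e6), 0.10)
})

test_that("a 1:1 fit to ensemble data shows systematic residuals and loses", {
  des <- std_design()
  truth <- mech_ensemble(c(3e3, 2e2), c(0.05, 0.005), 100)
  proc <- preprocess_set(generate_experiment(des, truth, noise_model(seed = 2)))
  f11 <- fit_kinetic(proc, "one_to_one")
  fe <- fit_kinetic(proc, "ensemble2")
  expect_true(f11$flags$systematic_residuals)
  expect_gt(f11$aicc, fe$aicc)
})

test_that("model comparison enforces identical data and handles one fit", {
  des <- std_design()
  m <- truth_11()
  proc <- preprocess_set(generate_experiment(des, m, noise_model(seed = 4)))
  proc2 <- preprocess_set(generate_experiment(des, m, noise_model(seed = 5)))
  fa <- fit_kinetic(proc, "one_to_one")
  fb <- fit_kinetic(proc2, "two_state")
  expect_error(compare_models(list(fa, fb)), "different data")
  single <- compare_models(list(fa))
  expect_equal(single$preferred, "one_to_one")
  expect_equal(single$table$delta_aicc, 0)
  expect_false(single$indistinguishable)
})

test_that("parsimony prefers 1:1 over two-state on nested noiseless truth", {
  des <- std_design()
  m <- truth_11()
  proc <- preprocess_set(generate_experiment(des, m, noise_off()))
  f1 <- fit_kinetic(proc, "one_to_one")
  f2 <- fit_kinetic(proc, "two_state")
  cmp <- compare_models(list(f1, f2))
  expect_true(cmp$preferred == "one_to_one" || cmp$indistinguishable)
  expect_equal(cmp$preferred, "one_to_one")
})

test_that("fit object methods behave like a classed model fit", {
  des <- std_design()
  m <- truth_11()
  proc <- preprocess_set(generate_experiment(des, m, noise_model(seed = 6)))
  f <- fit_kinetic(proc, "one_to_one")
  expect_named(coef(f), c("ka", "kd", "Rmax"))
  expect_length(residuals(f), f$n)
  expect_output(print(f), "KD\\^app")
  expect_output(print(summary(f)), "RSS")
  pred <- predict(f, injection_schedule(30, 15, 5, 10, conc_uM = 25))
  expect_s3_class(pred, "sensorgram")
  cv <- extract_report_points(proc)[[1]]
  fs <- fit_steady_state(cv)
  expect_equal(predict(fs, data.frame(conc_uM = 0)), 0)
  expect_output(print(fs), "KD")
})
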