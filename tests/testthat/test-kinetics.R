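test_that("closed-form 1:1 has the expected limits", {
  m <- mech_one_to_one(1e4, 0.02, 100)  # KD = 2 uM
  # C = KD, long association -> plateau Rmax/2
  sch <- injection_schedule(3000, 15, 5, 1, conc_uM = 2)
  sg <- simulate_one_to_one(m, sch)
  plateau <- max(sg$response[sg$phase == "association"])
  expect_equal(plateau, 50, tolerance = 1e-6)
  # C = 0 -> identically zero
  sg0 <- simulate_one_to_one(m, injection_schedule(15, 15, 5, 10, conc_uM = 0))
  expect_true(all(sg0$response == 0))
})

test_that("closed form agrees with the stiff integrator", {
  m <- mech_one_to_one(1e4, 0.02, 100)
  sch <- injection_schedule(15, 15, 10, 10, conc_uM = 2)
  a <- simulate_one_to_one(m, sch)
  b <- simulate_mechanism(m, sch)
  expect_lt(max(abs(a$response - b$response)), 1e-8 * m$Rmax)
})

test_that("reduction lattice: degenerate mechanisms equal 1:1", {
  sch <- injection_schedule(30, 15, 5, 10, conc_uM = 10)
  ref <- simulate_one_to_one(mech_one_to_one(5e3, 0.05, 80), sch)
  variants <- list(
    mech_ensemble(5e3, 0.05, 80),
    mech_two_state(5e3, 0.05, 0, 0, 80),
    mech_heterogeneous(5e3, 0.05, 80, 1e3, 0.1, 0))
  for (m in variants) {
    sim <- simulate_mechanism(m, sch)
    expect_lt(max(abs(sim$response - ref$response)), 1e-6 * 80)
  }
})

test_that("responses conserve capacity for random mechanisms", {
  set.seed(11)
  sch <- injection_schedule(60, 15, 5, 5, conc_uM = 500)  # strong push
  for (i in 1:10) {
    m <- if (i %% 2) random_one_to_one() else random_ensemble(interconvert = TRUE)
    sim <- simulate_mechanism(m, sch)
    expect_gte(min(sim$response), -1e-7 * total_capacity(m))
    expect_lte(max(sim$response), total_capacity(m) * (1 + 1e-7))
  }
})

test_that("exact linear propagator matches the stiff integrator", {
  set.seed(23)
  sch <- injection_schedule(45, 15, 5, 10, conc_uM = 25)
  for (i in 1:8) {
    m <- switch(i %% 4 + 1,
                random_one_to_one(),
                random_ensemble(2, interconvert = TRUE),
                random_ensemble(3, interconvert = FALSE),
                mech_two_state(10^runif(1, 3, 5), 10^runif(1, -2, -1),
                               10^runif(1, -3, -1), 10^runif(1, -3, -1),
                               runif(1, 20, 150)))
    a <- sprkin:::.simulate_exact(m, sch)
    b <- simulate_mechanism(m, sch)
    expect_lt(max(abs(a$response - b$response)), 1e-6 * total_capacity(m))
  }
})

test_that("two-state dissociation slows with contact time (slow isomerisation)", {
  m <- truth_2s_slow(100)
  rate_after <- function(ct) {
    sch <- injection_schedule(ct, 15, 5, 10, conc_uM = 200)
    sim <- simulate_mechanism(m, sch)
    d <- sim[sim$phase == "dissociation", ]
    # mean log-slope over the window
    (log(d$response[1]) - log(d$response[nrow(d)])) / (d$time[nrow(d)] - d$time[1])
  }
  expect_gt(rate_after(15), rate_after(140))
})

test_that("ensemble with separated off-rates dissociates bi-exponentially", {
  m <- mech_ensemble(c(1e4, 1e3), c(0.5, 0.01), 100)
  sch <- injection_schedule(120, 30, 5, 10, conc_uM = 50)
  sim <- simulate_mechanism(m, sch)
  d <- sim[sim$phase == "dissociation" & sim$response > 0, ]
  lr <- log(d$response)
  # convex log-trace: early slope much steeper than late slope
  k_early <- -(lr[11] - lr[1]) / (d$time[11] - d$time[1])
  nn <- nrow(d)
  k_late <- -(lr[nn] - lr[nn - 100]) / (d$time[nn] - d$time[nn - 100])
  expect_gt(k_early / k_late, 3)
})

test_that("steady-state response obeys the equilibrium laws", {
  m <- mech_one_to_one(1e4, 0.02, 100)
  expect_equal(steady_state_response(m, 2), 50)  # C = KD
  expect_equal(steady_state_response(m, 0), 0)
  mh <- mech_heterogeneous(1e4, 0.02, 60, 1e3, 0.1, 40)
  expect_equal(steady_state_response(mh, 1e9), 100, tolerance = 1e-3)
  # nondecreasing in C
  grid <- steady_state_response(mh, c(0.1, 1, 10, 100, 1000))
  expect_true(all(diff(grid) > 0))
})

test_that("ensemble steady state matches long-horizon integration", {
  m <- mech_ensemble(c(1e4, 1e3), c(0.02, 0.005), 100,
                     k_int = matrix(c(0, 0.01, 0.02, 0), 2, 2))
  sch <- injection_schedule(5000, 10, 1, 1, conc_uM = 5)
  sim <- simulate_mechanism(m, sch)
  long_t <- max(sim$response[sim$phase == "association"])
  expect_equal(steady_state_response(m, 5), long_t, tolerance = 1e-6 * 100)
})

test_that("zero-interconversion ensemble steady state equals competitive binding", {
  set.seed(5)
  for (i in 1:5) {
    m <- random_ensemble(3, interconvert = FALSE)
    C <- runif(1, 1, 100)
    kd_uM <- m$kd / m$ka * 1e6
    x <- C / kd_uM
    closed <- m$Rmax * sum(x) / (1 + sum(x))
    expect_equal(steady_state_response(m, C), closed, tolerance = 1e-9 * m$Rmax)
  }
})

test_that("matrix-exponential reference is a valid low-occupancy oracle", {
  # low-occupancy 1:1 matches the closed form
  m <- mech_one_to_one(1e4, 0.5, 100)  # KD = 50 uM
  schl <- injection_schedule(15, 15, 10, 10, conc_uM = 0.02)
  mx <- matexp_reference(m, schl)
  cf <- simulate_one_to_one(m, schl)
  expect_lt(max(abs(mx$response - cf$response)), 1e-4 * m$Rmax)
  # low-occupancy ensemble n = 3 matches the integrator
  me <- mech_ensemble(c(1e4, 5e3, 2e3), c(0.5, 0.3, 0.8), 100)
  mx3 <- matexp_reference(me, schl)
  od3 <- simulate_mechanism(me, schl)
  expect_lt(max(abs(mx3$response - od3$response)), 1e-6 * 100)
  # refusal above the occupancy bound
  expect_error(matexp_reference(m, injection_schedule(15, 15, 10, 10,
                                                      conc_uM = 50)),
               "occupancy")
})

test_that("mechanism constructors validate their parameters", {
  expect_error(mech_one_to_one(-1, 0.1, 10))
  expect_error(mech_ensemble(c(1e3, 1e3), c(0.1), 10))
  expect_error(mech_ensemble(1e3, 0.1, 10, k_int = matrix(-1, 1, 1)))
  m <- mech_ensemble(c(1e3, 1e3), c(0.1, 0.2), 10,
                     k_int = matrix(5, 2, 2))  # diagonal forced to zero
  expect_equal(diag(m$k_int), c(0, 0))
  expect_equal(total_capacity(truth_2site(100)), 100)
})
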