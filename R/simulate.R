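#' Closed-form 1:1 Langmuir sensorgram
#'
#' Analytic solution of the 1:1 binding scheme for a single injection cycle:
#' during association at constant concentration `C`,
#' `R(t) = Req (1 - exp(-(ka C + kd)(t - t0)))` with
#' `Req = Rmax C / (C + KD)`; during dissociation
#' `R(t) = R_end exp(-kd (t - t_end))`; the baseline is zero.
#'
#' @param m A [mech_one_to_one()].
#' @param schedule An [injection_schedule()]; its `conc_uM` sets the analyte
#'   concentration.
#' @param analyte,cycle_id Metadata carried onto the output.
#' @return A noiseless [sensorgram()].
#' @export
simulate_one_to_one <- function(m, schedule, analyte = "", cycle_id = "") {
  stopifnot(inherits(m, "mech_one_to_one"), inherits(schedule, "injection_schedule"))
  g <- schedule_grid(schedule)
  C <- schedule$conc_uM * 1e-6
  r <- numeric(length(g$time))
  assoc <- g$phase == "association"
  diss <- g$phase == "dissociation"
  if (C > 0) {
    kobs <- m$ka * C + m$kd
    Req <- m$Rmax * C / (C + m$KD)
    r[assoc] <- Req * (1 - exp(-kobs * (g$time[assoc] - schedule$assoc_start)))
    r_end <- Req * (1 - exp(-kobs * (schedule$assoc_end - schedule$assoc_start)))
    r[diss] <- r_end * exp(-m$kd * (g$time[diss] - schedule$assoc_end))
  }
  sensorgram(g$time, r, g$phase, schedule = schedule, analyte = analyte,
             conc_uM = schedule$conc_uM, cycle_id = cycle_id)
}

# ---- exact linear propagation ------------------------------------------------
#
# At piecewise-constant analyte concentration every supported scheme's
# mass-action equations are linear in the bound-species vector:
# dr/dt = A r + b. Propagate exactly per phase via the eigendecomposition of
# A; fall back to the stiff integrator if A is defective.

.propagate_phase <- function(A, b, r0, dt) {
  # returns states (length(dt) x n); dt are offsets >= 0 from phase start
  n <- length(r0)
  if (all(r0 == 0) && all(b == 0))
    return(matrix(0, nrow = length(dt), ncol = n))
  if (n == 1L) {
    a <- A[1, 1]
    if (a == 0) return(matrix(r0 + b * dt, ncol = 1))
    rss <- -b / a
    return(matrix(rss + (r0 - rss) * exp(a * dt), ncol = 1))
  }
  eg <- eigen(A)
  V <- eg$vectors
  if (rcond(Mod(V)) < 1e-12) stop("defective-system")
  rss <- if (all(b == 0)) numeric(n) else
    tryCatch(solve(A, -b), error = function(e) stop("defective-system"))
  cc <- solve(V, r0 - rss)
  E <- exp(outer(dt, eg$values))        # possibly complex
  states <- E %*% (t(V) * cc)           # states[t, i] = sum_k E[t,k] V[i,k] c[k]
  Re(states) + matrix(Re(rss), nrow = length(dt), ncol = n, byrow = TRUE)
}

.propagate_linear <- function(m, schedule, time, phase, system_fun = .linear_system) {
  n <- .n_states(m)
  r0 <- numeric(n)
  states <- matrix(0, nrow = length(time), ncol = n)
  bounds <- list(
    baseline = c(0, schedule$assoc_start, 0),
    association = c(schedule$assoc_start, schedule$assoc_end,
                    schedule$conc_uM * 1e-6),
    dissociation = c(schedule$assoc_end, schedule$diss_end, 0))
  for (ph in c("baseline", "association", "dissociation")) {
    idx <- which(phase == ph)
    t0 <- bounds[[ph]][1]; t1 <- bounds[[ph]][2]; C <- bounds[[ph]][3]
    sys <- system_fun(m, C)
    # one propagation serves both the grid points and the phase-end state
    st <- .propagate_phase(sys$A, sys$b, r0, c(time[idx] - t0, t1 - t0))
    if (length(idx)) states[idx, ] <- st[seq_along(idx), , drop = FALSE]
    r0 <- st[nrow(st), ]
  }
  states
}

#' Simulate a sensorgram under any binding mechanism
#'
#' Integrates the mechanism's mass-action rate equations phase by phase at
#' piecewise-constant analyte concentration using a stiff-safe implicit
#' integrator (`deSolve::lsoda`) with the analytic Jacobian. The response is
#' the total bound signal (sum over bound species / modes), continuous across
#' phase boundaries.
#'
#' @param m A mechanism object (see [mechanisms]).
#' @param schedule An [injection_schedule()].
#' @param tol Relative integration tolerance, in `(0, 1e-3]`.
#' @param analyte,cycle_id Metadata carried onto the output.
#' @return A noiseless [sensorgram()].
#' @export
simulate_mechanism <- function(m, schedule, tol = 1e-8, analyte = "",
                               cycle_id = "") {
  stopifnot(inherits(m, "mechanism"), inherits(schedule, "injection_schedule"),
            tol > 0, tol <= 1e-3)
  g <- schedule_grid(schedule)
  n <- .n_states(m)
  r0 <- numeric(n)
  resp <- numeric(length(g$time))
  bounds <- list(
    baseline = c(0, schedule$assoc_start, 0),
    association = c(schedule$assoc_start, schedule$assoc_end,
                    schedule$conc_uM * 1e-6),
    dissociation = c(schedule$assoc_end, schedule$diss_end, 0))
  atol <- tol * total_capacity(m) * 1e-2
  for (ph in c("baseline", "association", "dissociation")) {
    t0 <- bounds[[ph]][1]; t1 <- bounds[[ph]][2]; C <- bounds[[ph]][3]
    if (t1 <= t0) next
    idx <- which(g$phase == ph)
    sys <- .linear_system(m, C)
    if (all(r0 == 0) && C == 0) { r0 <- numeric(n); next }  # trivially zero
    times <- sort(unique(round(c(t0, g$time[idx], t1), 9)))
    out <- deSolve::lsoda(
      y = r0, times = times,
      func = function(t, y, parms) list(parms$A %*% y + parms$b),
      parms = sys,
      jacfunc = function(t, y, parms) parms$A,
      jactype = "fullusr", rtol = tol, atol = atol)
    diag_state <- attr(out, "istate")[1]
    if (!is.null(diag_state) && diag_state < 0)
      stop("stiff integrator failed in phase '", ph, "' (istate = ",
           diag_state, ")")
    ymat <- out[, -1, drop = FALSE]
    if (length(idx))
      resp[idx] <- rowSums(ymat[match(round(g$time[idx], 9), times), ,
                                drop = FALSE])
    r0 <- as.numeric(ymat[nrow(ymat), ])
  }
  sensorgram(g$time, resp, g$phase, schedule = schedule, analyte = analyte,
             conc_uM = schedule$conc_uM, cycle_id = cycle_id)
}

# fast exact simulation of total response on a schedule grid (used by the
# global fitter; cross-checked against simulate_mechanism in the tests)
.simulate_exact <- function(m, schedule) {
  g <- schedule_grid(schedule)
  states <- tryCatch(.propagate_linear(m, schedule, g$time, g$phase),
                     error = function(e) NULL)
  if (is.null(states))  # defective rate matrix: fall back on the integrator
    return(simulate_mechanism(m, schedule))
  sensorgram(g$time, rowSums(states), g$phase, schedule = schedule,
             conc_uM = schedule$conc_uM)
}

#' Matrix-exponential reference trace at low occupancy
#'
#' Independent oracle for the numerical integrator: the rate equations are
#' linearised by substituting free sites ~ total capacity (dropping the
#' competition for capacity), which is accurate only far from saturation.
#' The linearised system is then propagated exactly per phase. The function
#' refuses inputs whose predicted association-phase occupancy exceeds
#' `occupancy_max` of capacity, where the linearisation no longer holds.
#'
#' @param m A mechanism object.
#' @param schedule An [injection_schedule()].
#' @param occupancy_max Maximum allowed predicted fractional occupancy
#'   (default 0.01).
#' @return A noiseless [sensorgram()].
#' @export
matexp_reference <- function(m, schedule, occupancy_max = 0.01) {
  stopifnot(inherits(m, "mechanism"), inherits(schedule, "injection_schedule"))
  lin <- function(mech, C) {
    sys <- .linear_system(mech, C)
    # remove the capacity-competition coupling: keep only the decay/exchange
    # part of A plus the constant ka*C*capacity inflow
    sys0 <- .linear_system(mech, 0)
    list(A = sys0$A, b = sys$b)
  }
  C <- schedule$conc_uM * 1e-6
  if (C > 0) {
    sysA <- lin(m, C)
    rss <- tryCatch(solve(sysA$A, -sysA$b), error = function(e) NULL)
    occ <- if (is.null(rss)) Inf else sum(rss) / total_capacity(m)
    if (occ > occupancy_max)
      stop("predicted occupancy ", signif(occ, 3),
           " exceeds low-occupancy bound ", occupancy_max,
           "; matrix-exponential reference refused")
  }
  g <- schedule_grid(schedule)
  states <- .propagate_linear(m, schedule, g$time, g$phase, system_fun = lin)
  sensorgram(g$time, rowSums(states), g$phase, schedule = schedule,
             conc_uM = schedule$conc_uM)
}

#' Equilibrium (steady-state) response of a mechanism
#'
#' Response after infinitely long exposure to constant analyte concentration:
#' closed form `Rmax C / (C + KD)` for 1:1 binding, otherwise the solution of
#' the stationary linear system. `Req(0) = 0`; `Req` is nondecreasing in `C`
#' and approaches the total capacity as `C` grows.
#'
#' @param m A mechanism object.
#' @param conc_uM Analyte concentration(s), micromolar (vectorised).
#' @return Numeric vector of equilibrium responses, RU.
#' @export
steady_state_response <- function(m, conc_uM) {
  stopifnot(inherits(m, "mechanism"), all(conc_uM >= 0))
  vapply(conc_uM, function(cu) {
    C <- cu * 1e-6
    if (C == 0) return(0)
    if (inherits(m, "mech_one_to_one"))
      return(m$Rmax * C / (C + m$KD))
    sys <- .linear_system(m, C)
    sum(solve(sys$A, -sys$b))
  }, numeric(1))
}
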