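#' Binding mechanism specifications
#'
#' Constructors for the competing interaction schemes considered when SPR
#' sensorgrams are "complex", i.e. not described by simple 1:1 binding:
#'
#' * `mech_one_to_one()`: 1:1 Langmuir binding, `A + B <-> AB`.
#' * `mech_two_state()`: induced fit, `A + B <-> AB <-> AB*`; a bound complex
#'   isomerises to a second bound state. Slow isomerisation predicts
#'   contact-time-dependent dissociation.
#' * `mech_heterogeneous()`: two independent ligand site classes, each with
#'   its own rates and capacity (a model of surface heterogeneity).
#' * `mech_ensemble()`: fuzzy binding — `n` interchangeable binding modes
#'   (registers/orientations of a disordered peptide on one site) competing
#'   for a single shared capacity, with optional direct interconversion
#'   between bound modes (rearrangement without dissociating first).
#'
#' Units: association rates `ka` in 1/(M s), first-order rates (`kd`, `ka2`,
#' `kd2`, interconversion) in 1/s, capacities `Rmax` in RU.
#'
#' @param ka,kd Association / dissociation rate constants.
#' @param Rmax Surface binding capacity, RU.
#' @param ka1,kd1 Binding step rates (two-state; site 1 of heterogeneous).
#' @param ka2,kd2 Isomerisation forward/back rates (two-state, 1/s), or site-2
#'   binding rates (heterogeneous).
#' @param Rmax1,Rmax2 Per-site capacities (heterogeneous), RU.
#' @param k_int `n x n` matrix of mode interconversion rates `k[i, j]` =
#'   rate i -> j (1/s), zero diagonal; defaults to no interconversion.
#' @return An object of class `c("<scheme>", "mechanism")`.
#' @name mechanisms
NULL

#' @rdname mechanisms
#' @export
mech_one_to_one <- function(ka, kd, Rmax) {
  stopifnot(ka > 0, kd > 0, Rmax > 0)
  structure(list(ka = ka, kd = kd, Rmax = Rmax, KD = kd / ka),
            class = c("mech_one_to_one", "mechanism"))
}

#' @rdname mechanisms
#' @export
mech_two_state <- function(ka1, kd1, ka2, kd2, Rmax) {
  stopifnot(ka1 > 0, kd1 >= 0, ka2 >= 0, kd2 >= 0, Rmax > 0)
  structure(list(ka1 = ka1, kd1 = kd1, ka2 = ka2, kd2 = kd2, Rmax = Rmax),
            class = c("mech_two_state", "mechanism"))
}

#' @rdname mechanisms
#' @export
mech_heterogeneous <- function(ka1, kd1, Rmax1, ka2, kd2, Rmax2) {
  stopifnot(ka1 > 0, kd1 > 0, Rmax1 >= 0, ka2 > 0, kd2 > 0, Rmax2 >= 0)
  structure(list(ka1 = ka1, kd1 = kd1, Rmax1 = Rmax1,
                 ka2 = ka2, kd2 = kd2, Rmax2 = Rmax2),
            class = c("mech_heterogeneous", "mechanism"))
}

#' @rdname mechanisms
#' @export
mech_ensemble <- function(ka, kd, Rmax, k_int = NULL) {
  n <- length(ka)
  stopifnot(n >= 1L, length(kd) == n, all(ka > 0), all(kd >= 0), Rmax > 0)
  if (is.null(k_int)) k_int <- matrix(0, n, n)
  k_int <- as.matrix(k_int)
  stopifnot(nrow(k_int) == n, ncol(k_int) == n, all(k_int >= 0))
  diag(k_int) <- 0
  structure(list(ka = ka, kd = kd, Rmax = Rmax, k_int = k_int, n = n),
            class = c("mech_ensemble", "mechanism"))
}

#' @export
print.mechanism <- function(x, ...) {
  cat("Mechanism:", mechanism_name(x), "\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Human-readable mechanism name
#' @param m A mechanism object.
#' @return Character scalar.
#' @export
mechanism_name <- function(m) {
  switch(class(m)[1],
         mech_one_to_one = "1:1",
         mech_two_state = "two-state",
         mech_heterogeneous = "heterogeneous-ligand",
         mech_ensemble = paste0("ensemble(n=", m$n, ")"),
         stop("unknown mechanism"))
}

#' Total surface capacity of a mechanism
#' @param m A mechanism object.
#' @return Capacity in RU (upper bound on any noiseless response).
#' @export
total_capacity <- function(m) {
  switch(class(m)[1],
         mech_one_to_one = m$Rmax,
         mech_two_state = m$Rmax,
         mech_heterogeneous = m$Rmax1 + m$Rmax2,
         mech_ensemble = m$Rmax,
         stop("unknown mechanism"))
}

# Linear system dr/dt = A r + b for the bound-species vector at constant
# analyte concentration C (molar). Exact for all four schemes: with C held
# constant the mass-action equations are linear in the bound species.
.linear_system <- function(m, C) {
  UseMethod(".linear_system")
}

#' @export
.linear_system.mech_one_to_one <- function(m, C) {
  list(A = matrix(-(m$ka * C + m$kd), 1, 1), b = m$ka * C * m$Rmax)
}

#' @export
.linear_system.mech_two_state <- function(m, C) {
  # r1 = AB, r2 = AB*; binding consumes capacity Rmax - r1 - r2
  A <- matrix(c(-(m$ka1 * C + m$kd1 + m$ka2), -m$ka1 * C + m$kd2,
                m$ka2, -m$kd2),
              nrow = 2, byrow = TRUE)
  list(A = A, b = c(m$ka1 * C * m$Rmax, 0))
}

#' @export
.linear_system.mech_heterogeneous <- function(m, C) {
  A <- diag(c(-(m$ka1 * C + m$kd1), -(m$ka2 * C + m$kd2)), 2)
  list(A = A, b = c(m$ka1 * C * m$Rmax1, m$ka2 * C * m$Rmax2))
}

#' @export
.linear_system.mech_ensemble <- function(m, C) {
  n <- m$n
  # dr_i/dt = ka_i C (Rmax - sum r) - kd_i r_i + sum_j (k[j,i] r_j - k[i,j] r_i)
  A <- matrix(rep(-m$ka * C, n), nrow = n)      # -ka_i C in every column
  A <- A + t(m$k_int)                           # inflow j -> i
  diag(A) <- -m$ka * C - m$kd - rowSums(m$k_int)
  list(A = A, b = m$ka * C * m$Rmax)
}

# initial (zero) state length
.n_states <- function(m) {
  switch(class(m)[1],
         mech_one_to_one = 1L,
         mech_two_state = 2L,
         mech_heterogeneous = 2L,
         mech_ensemble = m$n)
}
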