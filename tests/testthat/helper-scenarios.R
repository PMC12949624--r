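# Shared synthetic-study scenarios. Kinetic ground truths are scenario
# parameters chosen on the affinity scale of weak peptide binders
# (KD in the tens-of-micromolar range); they are not measurements.

std_design <- function(...) experiment_design(...)

truth_11 <- function(Rmax = rmax_from_design(std_design(), 1779)) {
  mech_one_to_one(ka = 1.5e3, kd = 0.05, Rmax = Rmax)  # KD = 33.3 uM
}

truth_2s_slow <- function(Rmax = rmax_from_design(std_design(), 1493)) {
  # slow isomerisation: kd2 << kd1, so dissociation slows with contact time
  mech_two_state(ka1 = 1.5e3, kd1 = 0.08, ka2 = 0.02, kd2 = 0.002, Rmax = Rmax)
}

truth_2site <- function(Rmax = rmax_from_design(std_design(), 1493)) {
  mech_heterogeneous(ka1 = 3e3, kd1 = 0.05, Rmax1 = Rmax * 0.6,
                     ka2 = 2e2, kd2 = 0.005, Rmax2 = Rmax * 0.4)
}

# deterministic random mechanism generators for property-style tests
random_one_to_one <- function() {
  mech_one_to_one(ka = 10^runif(1, 3, 5), kd = 10^runif(1, -3, -0.5),
                  Rmax = runif(1, 20, 200))
}

random_ensemble <- function(n = sample(2:3, 1), interconvert = FALSE) {
  k_int <- if (interconvert) {
    m <- matrix(10^runif(n * n, -3, -1), n, n); diag(m) <- 0; m
  } else NULL
  mech_ensemble(ka = 10^runif(n, 3, 5), kd = 10^runif(n, -3, -0.5),
                Rmax = runif(1, 20, 200), k_int = k_int)
}

# the nine designed-peptide specification strings (acetyl/amide throughout)
table2_specs <- c(
  pep1 = "Ac-YLMELDGGRRGLVCGV-NH2",
  pep2 = "Ac-RLEYLMELDGGR-NH2",
  pep3 = "Ac-RLEYLMELD-NH2",
  pep4 = "Ac-RLEALMELDGGR-NH2",
  pep5 = "Ac-RLEYLMALDGGR-NH2",
  pep6 = "Ac-RLEYLMEADGGR-NH2",
  pep7 = "Ac-RLEYLMELAGGR-NH2",
  pep8 = "Ac-RKEYLEELDGGR-NH2 staple=2,6",
  pep9 = "Ac-GGRRGLVCGV-NH2")
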