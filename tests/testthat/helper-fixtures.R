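# Shared fixtures, built in code.

ha5 <- function() gag_topology("HA", 5)

# tiny trajectory: n frames sampled from the one-state wobble around the
# reference torsions
tiny_traj <- function(topology = gag_topology("HA", 2), n = 5, seed = 1,
                      concentration = 50, ion_model = NULL) {
  ref <- reference_torsions(topology)
  st <- conformational_state(
    mean = list(Linkage1 = c(ref$phi_ref[1], ref$psi_ref[1]),
                Linkage2 = c(ref$phi_ref[2], ref$psi_ref[2])),
    concentration = concentration)
  sample_ensemble(ensemble_spec(topology, st, n_frames = n, seed = seed,
                                ion_model = ion_model))
}

# trajectory wrapping explicit coordinate frames (list of n_atoms x 3)
traj_from_frames <- function(frames, topology, box = NA_real_, ions = NULL) {
  arr <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
  gag_trajectory(arr, topology, box = box, ions = ions)
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}
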