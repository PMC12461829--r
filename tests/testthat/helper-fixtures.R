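# Shared fixtures. Heavy artifacts (trained models) are built once per test
# run and cached in this environment so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

# small, fast synthetic config for unit tests (not the study conditions)
tiny_synth_config <- function(...) {
  defaults <- list(n_complexes = 6, n_frames = 128, n_replicas = 2,
                   fp_length = 256, fp_informative_bits = 32, seed = 11)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

tiny_model_config <- function(...) {
  defaults <- list(n_frames = 128L, fp_length = 256L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

tiny_dataset <- function() {
  if (is.null(.fixtures$tiny_ds)) {
    .fixtures$tiny_ds <- simulate_dataset(tiny_synth_config())
  }
  .fixtures$tiny_ds
}

# a deliberately simple toy trajectory: n_res residues of 3 backbone atoms
# placed on a grid, with optional per-frame displacement function
toy_trajectory <- function(n_frames = 3L, n_res = 6L, spread = 10,
                           jitter = NULL, masses = NULL) {
  atoms_per_res <- 3L
  n_atoms <- n_res * atoms_per_res
  base <- matrix(0, n_atoms, 3)
  for (r in seq_len(n_res)) {
    centre <- c(spread * r, spread * (r %% 2), 0)
    for (a in seq_len(atoms_per_res)) {
      base[(r - 1L) * atoms_per_res + a, ] <- centre + c(0.5 * a, 0, 0)
    }
  }
  coords <- array(0, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) {
    fr <- base
    if (!is.null(jitter)) fr <- jitter(fr, f)
    coords[f, , ] <- fr
  }
  trajectory_frames(
    coords,
    atom_names = rep(c("N", "CA", "C"), n_res),
    residue_ids = rep(seq_len(n_res), each = atoms_per_res),
    masses = masses)
}

# apply a rigid rotation + translation to every frame of a trajectory
rigid_transform <- function(traj, angle = 0.7, shift = c(5, -3, 2)) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  coords <- traj$coords
  for (f in seq_len(dim(coords)[1])) {
    coords[f, , ] <- sweep(coords[f, , , drop = TRUE] %*% R, 2, shift, `+`)
  }
  trajectory_frames(coords, traj$atom_names, traj$residue_ids, traj$masses)
}
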