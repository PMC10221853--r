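# Session-level fixture cache: miniature systems are deterministic for a
# given seed, so they are built once and reused across tests.
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, seed = 1L, ...) {
  key <- paste(name, seed, ..., sep = "|")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_fixture(name, seed = seed, ...)
  .fixture_cache[[key]]
}

# A hand-made trajectory object (the analysis functions only touch these
# fields), for counting/normalization tests that need exact control.
synthetic_trajectory <- function(frames, role, mol, box = box_geometry(10, 10, 10),
                                 times = NULL) {
  if (is.null(times)) times <- seq_len(dim(frames)[3]) - 1
  structure(list(frames = frames, times = times, role = role, mol = mol,
                 box = box,
                 type = rep(5L, dim(frames)[1]),
                 config = integrator_config(steps = 1L)),
            class = "md_trajectory")
}

# Tiny walled test system: a short coating chain plus one HP protein above
# it, light water. Used for umbrella / adsorption plumbing tests.
mini_single_protein_system <- function(seed = 1L, wall = "3W2.5", n = 0.25) {
  it <- interaction_table(wall = wall)
  box <- box_geometry(10, 10, 12)
  sys <- build_coating(box, G = 4, N = 8, itable = it)
  lib <- sample_protein_library(Np = 10, hp = 0.3, Gp = 1, n = 0.65,
                                t_run = 20, seed = seed)
  sys <- place_proteins(sys, lib, hmax = 6, seed = seed + 1L)
  sys <- fill_water(sys, n = n, seed = seed + 2L)
  init_velocities(sys, T = 1, seed = seed + 3L)
}
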