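# Miniature deterministic presets for tests and examples.

FIXTURE_NAMES <- c("dimer", "mini-mushroom", "mini-adsorption",
                   "single-protein", "water-slab")

#' Miniature fixture systems
#'
#' Deterministic small systems for tests and examples; identical for a fixed
#' seed. Available presets:
#'
#' * `"dimer"` — two FENE+WCA bonded beads at separation 1 in a 10^3 box.
#' * `"mini-mushroom"` — 3 x 3 coating chains of N = 10 (briefly relaxed so
#'   the coating height is meaningful), 2 proteins of Np = 12 (hp = 25%)
#'   placed on top, water at n = 0.65, in a 12^3 box.
#' * `"mini-adsorption"` — same layout at reduced water density (n = 0.3),
#'   the light variant used for qualitative adsorption-ordering runs.
#' * `"single-protein"` — one Np = 12 HP chain in a small water box at
#'   n = 0.65 (rodlike start).
#' * `"water-slab"` — dilute WCA water (n = 0.3) in an 8 x 8 x 10 box; flat
#'   density away from the walls.
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @param wall wall interaction toward proteins (name or [wall_spec()]).
#' @param ap A-P attraction (name or [pair_spec()]).
#' @return A `particle_system` ready for [run_md()].
#' @examples
#' \donttest{
#' sys <- make_fixture("dimer")
#' n_beads(sys)
#' }
#' @export
make_fixture <- function(name, seed = 1L, wall = "1W1", ap = "1LJ1.5") {
  if (!name %in% FIXTURE_NAMES)
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(FIXTURE_NAMES, collapse = ", ")))
  itable <- interaction_table(wall = wall, ap = ap)
  switch(
    name,
    "dimer" = {
      box <- box_geometry(10, 10, 10)
      sys <- empty_system(box, itable)
      sys <- sys_add(sys, rbind(c(4.5, 5, 5), c(5.5, 5, 5)), type = "R",
                     mol = 1L, mobile = TRUE, role = "coating",
                     local_bonds = cbind(1L, 2L))
      init_velocities(sys, T = 1, seed = seed)
    },
    "mini-mushroom" = mini_brush_fixture(n_water = 0.65, seed = seed,
                                         itable = itable),
    "mini-adsorption" = mini_brush_fixture(n_water = 0.3, seed = seed,
                                           itable = itable),
    "single-protein" = build_single_protein(Np = 12, hp = 0.25, n = 0.65,
                                            seed = seed, itable = itable),
    "water-slab" = {
      box <- box_geometry(8, 8, 10)
      sys <- empty_system(box, itable)
      sys <- fill_water(sys, n = 0.3, seed = seed)
      init_velocities(sys, T = 1, seed = seed + 1L)
    })
}

# Coating + 2 proteins + water in a 12^3 box. The bare coating is relaxed
# with a short Langevin run so proteins can be placed at a meaningful hmax.
mini_brush_fixture <- function(n_water, seed, itable) {
  box <- box_geometry(12, 12, 12)
  sys <- build_coating(box, G = 9, N = 10, itable = itable)
  sys <- init_velocities(sys, T = 1, seed = seed)
  tr <- run_md(sys, integrator_config(dt = 0.005, steps = 10000L,
                                      thermostat = "langevin", T = 1,
                                      seed = seed, sample_every = 10000L))
  sys <- tr$final
  lib <- sample_protein_library(Np = 12, hp = 0.25, Gp = 2, n = 0.65,
                                t_run = 30, seed = seed + 1L)
  sys <- place_proteins(sys, lib, seed = seed + 2L)
  sys <- fill_water(sys, n = n_water, seed = seed + 3L)
  init_velocities(sys, T = 1, seed = seed + 4L)
}
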