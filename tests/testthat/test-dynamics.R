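# Force assembly and MD integration.

make_pair_system <- function(pos, types, wall = "1W1", periodic_z = FALSE,
                             box = box_geometry(10, 10, 10, periodic_z = periodic_z),
                             bonds = matrix(integer(0), 0, 2)) {
  sys <- hpbrush:::empty_system(box, interaction_table(wall = wall))
  sys <- hpbrush:::sys_add(sys, pos, type = types,
                           mol = seq_len(nrow(pos)), mobile = TRUE,
                           role = "protein", local_bonds = bonds)
  sys
}

test_that("pair forces vanish beyond the WCA cutoff and obey Newton's third law", {
  sys <- make_pair_system(rbind(c(4, 5, 5), c(4 + 2^(1/6) + 0.01, 5, 5)),
                          c("R", "R"))
  f <- compute_forces(sys)
  expect_equal(f$forces, matrix(0, 2, 3))  # mid-box: wall range not reached
  expect_equal(f$epair, 0)
  sys$pos[2, 1] <- 4 + 1.05
  f <- compute_forces(sys)
  expect_gt(f$epair, 0)
  expect_equal(f$forces[1, ], -f$forces[2, ])
})

test_that("an isolated protein bead at the 9-3 minimum feels the Table value", {
  sys <- make_pair_system(rbind(c(5, 5, (2/5)^(1/6))), "P", wall = "1W1")
  f <- compute_forces(sys)
  expect_equal(f$ewall, -0.1874, tolerance = 1e-3)
  expect_equal(f$forces[1, 3], 0, tolerance = 1e-6)
  expect_equal(f$forces[1, 1:2], c(0, 0))   # wall force acts along z only
})

test_that("lateral force components sum to zero over a periodic slab", {
  sys <- cached_fixture("mini-mushroom", seed = 1)
  f <- compute_forces(sys)
  expect_equal(sum(f$forces[, 1]), 0, tolerance = 1e-9)
  expect_equal(sum(f$forces[, 2]), 0, tolerance = 1e-9)
})

test_that("compiled forces equal the numerical gradient of the total energy", {
  sys <- mini_single_protein_system(seed = 8)
  f0 <- compute_forces(sys)
  h <- 1e-6
  for (i in c(1, 40, n_beads(sys))) {  # a tether, a mid bead, a water bead
    for (d in 1:3) {
      sp <- sys; sp$pos[i, d] <- sp$pos[i, d] + h
      sm <- sys; sm$pos[i, d] <- sm$pos[i, d] - h
      grad <- (compute_forces(sp)$energy - compute_forces(sm)$energy) / (2 * h)
      expect_equal(f0$forces[i, d], -grad, tolerance = 1e-4)
    }
  }
})

test_that("bias spring energy and forces act on the group COM along z", {
  sys <- make_pair_system(rbind(c(3, 3, 4), c(3, 3, 5)), c("P", "P"))
  f <- compute_forces(sys, bias = list(k = 0.3, l = 1, group = 1:2))
  expect_equal(f$bias_z, 4.5)
  expect_equal(f$ebias, bias_energy(4.5, 0.3, 1))
  # dU/dz_i = k (zcom - l) / n on each member
  expect_equal(f$forces[1, 3] - compute_forces(sys)$forces[1, 3],
               -0.3 * (4.5 - 1) / 2, tolerance = 1e-12)
})

test_that("immobile beads never move and trajectories are well-formed", {
  sys <- cached_fixture("mini-adsorption", seed = 1)
  tr <- run_md(sys, integrator_config(steps = 500, thermostat = "langevin",
                                      seed = 2, sample_every = 100))
  expect_equal(length(tr$times), 6)
  expect_true(all(diff(tr$times) > 0))
  frozen <- which(!sys$mobile)
  expect_identical(tr$frames[frozen, , 1], tr$frames[frozen, , 6])
  expect_identical(tr$final$pos[frozen, ], sys$pos[frozen, ])
  # mobile beads did move
  expect_false(identical(tr$final$pos[sys$mobile, ], sys$pos[sys$mobile, ]))
})

test_that("Langevin runs are bit-reproducible for a fixed seed", {
  sys <- cached_fixture("water-slab", seed = 5)
  cfg <- integrator_config(steps = 300, thermostat = "langevin", seed = 17,
                           sample_every = 100)
  t1 <- run_md(sys, cfg)
  t2 <- run_md(sys, cfg)
  expect_identical(t1$final$pos, t2$final$pos)
  expect_identical(t1$thermo, t2$thermo)
  cfg$seed <- 18L
  expect_false(identical(run_md(sys, cfg)$final$pos, t1$final$pos))
})

test_that("Nose-Hoover is deterministic given initial velocities", {
  sys <- cached_fixture("water-slab", seed = 5)
  cfg <- integrator_config(steps = 300, thermostat = "nose-hoover",
                           sample_every = 300)
  expect_identical(run_md(sys, cfg)$final$pos, run_md(sys, cfg)$final$pos)
})

test_that("NVE conserves energy on a dilute slab", {
  sys <- cached_fixture("water-slab", seed = 5)
  eq <- run_md(sys, integrator_config(steps = 2000, thermostat = "langevin",
                                      seed = 6, sample_every = 2000))
  nve <- run_md(eq$final, integrator_config(steps = 5000, thermostat = "none",
                                            sample_every = 250))
  e <- nve$thermo$etot
  expect_lt(abs(e[length(e)] - e[1]) / abs(e[1]), 1e-3)
  expect_lt(max(e) - min(e), 0.5)
})

test_that("equipartition holds per velocity component under NVT", {
  sys <- cached_fixture("water-slab", seed = 5)
  tr <- run_md(sys, integrator_config(steps = 20000, thermostat = "langevin",
                                      T = 1, seed = 9, sample_every = 20000))
  v <- tr$final$vel[tr$final$mobile, ]
  comp <- colMeans(v^2)          # should each be kBT/m = 1
  expect_equal(comp, c(1, 1, 1), tolerance = 0.15)
})

test_that("overstretched bonds abort with a bead diagnostic", {
  sys <- make_pair_system(rbind(c(5, 5, 5), c(5 + 1.49, 5, 5)), c("R", "R"),
                          bonds = cbind(1L, 2L))
  sys$vel <- rbind(c(-30, 0, 0), c(30, 0, 0))
  expect_error(
    run_md(sys, integrator_config(steps = 50, thermostat = "none",
                                  sample_every = 50)),
    "overstretched")
})

test_that("a single protein collapses from its rodlike start", {
  sys <- build_single_protein(Np = 12, hp = 0.25, n = 0.65, seed = 21)
  pid <- which(sys$role == "protein")
  rod_rg <- chain_metrics(sys$pos[pid, ])$Rg
  tr <- run_md(sys, integrator_config(steps = 8000, thermostat = "nose-hoover",
                                      sample_every = 400), record = pid)
  rg <- vapply(seq_along(tr$times),
               function(f) chain_metrics(tr$frames[, , f])$Rg, numeric(1))
  expect_lt(stationary_average(rg, 0.3)$mean, 0.6 * rod_rg)
})
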