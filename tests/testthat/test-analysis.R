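# Conformational metrics, shape, adsorption, density profiles.

test_that("chain metrics reproduce the closed-form cases", {
  expect_error(chain_metrics(matrix(numeric(0), 0, 3)), "empty")
  one <- chain_metrics(cbind(1, 2, 3.5))
  expect_equal(one$Rg, 0)
  expect_equal(one$R, 0)
  expect_equal(one$h, 3.5)
  rod <- chain_metrics(cbind(0, 0, 0:9))
  expect_equal(rod$R, 9)
  expect_equal(rod$h, 9)
  # two beads at distance d: Rg^2 = d^2 / 4
  d <- 1.7
  expect_equal(chain_metrics(rbind(c(0, 0, 0), c(d, 0, 0)))$Rg2, d^2 / 4)
})

test_that("dry coating height is exact sigma N / n bookkeeping", {
  A <- 54.29 * 64.44
  expect_equal(dry_height(81 / A, 50, 0.65), 1.78, tolerance = 5e-3)
  expect_equal(dry_height(306 / A, 50, 0.65), 6.73, tolerance = 5e-3)
  expect_equal(dry_height(0.05, 0, 0.65), 0)
  expect_error(dry_height(0.05, 50, 0))
})

test_that("asphericity hits its exact limits", {
  # collinear chain: alpha = 1
  expect_equal(asphericity(cbind(0, 0, seq(0, 5, by = 0.5)))$alpha, 1)
  # three orthogonal coordinate pairs: R1 = R2 = R3, alpha = 0
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  expect_equal(asphericity(octa)$alpha, 0)
  # planar square: R1 = R2, R3 = 0 -> alpha = 1/4
  square <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  expect_equal(asphericity(square)$alpha, 0.25)
  expect_error(asphericity(rbind(c(1, 1, 1), c(1, 1, 1))), "coincident")
})

test_that("asphericity is rotation/translation invariant; eigenvalues sum to Rg^2", {
  set.seed(31)
  for (rep in 1:20) {
    coords <- matrix(rnorm(3 * 15), ncol = 3)
    s <- asphericity(coords)
    expect_equal(sum(s$eigenvalues), chain_metrics(coords)$Rg2,
                 tolerance = 1e-10)
    expect_gte(s$alpha, 0)
    expect_lte(s$alpha, 1)
    # random rigid motion
    qr_r <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    moved <- coords %*% qr_r + matrix(rnorm(3), nrow(coords), 3, byrow = TRUE)
    expect_equal(asphericity(moved)$alpha, s$alpha, tolerance = 1e-10)
  }
  # the raw-diagonal reading is NOT rotation invariant: diagnostic differs
  rod_tilted <- cbind(seq(0, 5, 0.5), seq(0, 5, 0.5), 0) %*%
    qr.Q(qr(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10), 3, 3)))
  s <- asphericity(rod_tilted)
  expect_equal(s$alpha, 1, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(s$alpha_diagonal, s$alpha, tolerance = 1e-6)))
})

test_that("adsorbed fraction counts proteins below hmax - Rg_p", {
  # 4 proteins of 2 beads each; coating hmax supplied explicitly
  nb <- 8
  frames <- array(0, dim = c(nb, 3, 3))
  com_z <- rbind(c(2, 2, 2, 9), c(2, 9, 9, 9), c(2, 2, 9, 9))  # frame x protein
  for (f in 1:3) {
    for (p in 1:4) frames[(2 * p - 1):(2 * p), 3, f] <- com_z[f, p]
  }
  traj <- synthetic_trajectory(frames, role = rep("protein", nb),
                               mol = rep(1:4, each = 2))
  ads <- adsorbed_fraction(traj, Rg_p = 1.5, hmax = 8)  # threshold 6.5
  expect_equal(ads$fads, c(3, 1, 2) / 4)
  expect_true(all(ads$fads * 4 == round(ads$fads * 4)))
  expect_true(all(ads$fads >= 0 & ads$fads <= 1))
  # all above / all below
  expect_equal(adsorbed_fraction(traj, Rg_p = 1.5, hmax = 2)$fads, c(0, 0, 0))
  expect_equal(adsorbed_fraction(traj, Rg_p = 1.5, hmax = 12)$fads, c(1, 1, 1))
  expect_error(adsorbed_fraction(traj, Rg_p = 0), "positive")
})

test_that("density profiles integrate back to the mean selected count", {
  set.seed(7)
  nb <- 50
  nf <- 4
  frames <- array(runif(nb * 3 * nf, 0, 10), dim = c(nb, 3, nf))
  traj <- synthetic_trajectory(frames, role = rep("protein", nb),
                               mol = rep(1:5, each = 10))
  prof <- density_profile(traj, dz = 0.5)
  A <- traj$box$Lx * traj$box$Ly
  expect_equal(sum(prof$rho * A * 0.5), nb, tolerance = 1e-10)
  # all beads at a single altitude occupy exactly one bin
  frames[, 3, ] <- 4.321
  traj1 <- synthetic_trajectory(frames, role = rep("protein", nb),
                                mol = rep(1:5, each = 10))
  prof1 <- density_profile(traj1, dz = 0.2)
  expect_equal(sum(prof1$rho > 0), 1)
  expect_equal(prof1$z[prof1$rho > 0], 4.3, tolerance = 0.11)
  expect_error(density_profile(traj1, dz = 0), "positive")
})

test_that("a dilute slab shows a flat bulk density profile", {
  sys <- cached_fixture("water-slab", seed = 5)
  tr <- run_md(sys, integrator_config(steps = 4000, thermostat = "langevin",
                                      seed = 3, sample_every = 200))
  prof <- density_profile(tr, selection = which(tr$role == "water"), dz = 1)
  bulk <- prof$rho[prof$z > 2 & prof$z < 8]   # away from both walls
  expect_equal(mean(bulk), 0.3, tolerance = 0.15)
  expect_lt(sd(bulk) / mean(bulk), 0.3)
})

test_that("stationary averages use the trailing fraction", {
  expect_equal(stationary_average(rep(4.2, 50))$mean, 4.2)
  expect_equal(stationary_average(rep(4.2, 50))$se, 0)
  x <- seq(0, 1, length.out = 2000)
  expect_equal(stationary_average(x, 1)$mean, 0.5)
  expect_equal(stationary_average(x, 0.3)$mean, 0.85, tolerance = 1e-3)
  expect_error(stationary_average(numeric(0)), "empty")
})

test_that("per-protein shape table aggregates over the trailing window", {
  nb <- 6
  nf <- 10
  frames <- array(rnorm(nb * 3 * nf), dim = c(nb, 3, nf))
  traj <- synthetic_trajectory(frames, role = rep("protein", nb),
                               mol = rep(1:2, each = 3))
  tab <- protein_shape_table(traj, fraction = 0.5)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$alpha >= 0 & tab$alpha <= 1))
})
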