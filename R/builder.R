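# System construction: tethered coatings, HP proteins, water, doping.

# Near-square anchor lattice: the first G sites of an nx x ny grid with
# spacing close to sqrt(A/G) in both directions.
anchor_lattice <- function(box, G) {
  nx <- max(1L, round(sqrt(G * box$Lx / box$Ly)))
  ny <- ceiling(G / nx)
  while (nx * ny < G) nx <- nx + 1L
  dx <- box$Lx / nx
  dy <- box$Ly / ny
  g <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  g <- g[seq_len(G), , drop = FALSE]
  cbind(x = (g$ix + 0.5) * dx, y = (g$iy + 0.5) * dy)
}

#' Build a tethered polymer coating
#'
#' Constructs `G` linear chains of `N` beads each, tethered by their first
#' bead to the lower wall plane (z = 0) on a uniform near-square lattice.
#' Chains start in a rodlike conformation with bond length `bond0` (the
#' FENE+WCA equilibrium, ~0.96). When a vertical rod would not fit under the
#' box height the rods are tilted in the xz-plane so their vertical extent
#' stays below `0.9 H`; a rod whose lateral run would exceed the box length
#' (so the chain would wrap onto itself) is a construction error.
#'
#' @param box a [box_geometry()].
#' @param G number of chains; the grafting density is `sigma = G / A`.
#' @param N beads per chain.
#' @param bond0 initial bond length.
#' @param itable an [interaction_table()].
#' @return A `particle_system` holding the coating; its attribute
#'   `"coating"` records `G`, `N` and `sigma`.
#' @examples
#' sys <- build_coating(box_geometry(), G = 81)   # mushroom, sigma = 0.023
#' attr(sys, "coating")$sigma
#' @export
build_coating <- function(box, G, N = 50, bond0 = 0.96,
                          itable = interaction_table()) {
  stopifnot(G >= 1, N >= 2)
  rod <- (N - 1) * bond0
  if (rod <= 0.9 * box$H) {
    dz <- bond0
    dxt <- 0
  } else {
    dz <- 0.9 * box$H / (N - 1)
    dxt <- sqrt(bond0^2 - dz^2)
    if ((N - 1) * dxt > box$Lx)
      stop(sprintf(
        "coating construction error: rod of height %.1f does not fit in box (H = %g) even when tilted",
        rod, box$H))
  }
  anchors <- anchor_lattice(box, G)
  sys <- empty_system(box, itable)
  k <- seq_len(N) - 1
  local_bonds <- cbind(seq_len(N - 1L), seq_len(N - 1L) + 1L)
  for (g in seq_len(G)) {
    pos <- cbind(anchors[g, 1] + k * dxt, anchors[g, 2], k * dz)
    sys <- sys_add(sys, pos,
                   type = c("R_tethered", rep("R", N - 1L)),
                   mol = g, mobile = c(FALSE, rep(TRUE, N - 1L)),
                   role = "coating", local_bonds = local_bonds)
  }
  attr(sys, "coating") <- list(G = G, N = N, sigma = G / box$A, bond0 = bond0)
  sys
}

#' Random hydrophobic-polar sequence
#'
#' A length-`Np` sequence with exactly `round(hp * Np)` hydrophobic (H) beads
#' at uniformly random positions, the rest polar (P). Deterministic for a
#' fixed seed.
#'
#' @param Np protein length (beads).
#' @param hp hydrophobicity ratio in (0, 1).
#' @param seed RNG seed.
#' @return character vector of `"H"`/`"P"` labels.
#' @examples
#' table(generate_hp_sequence(40, 0.25, seed = 1))   # 10 H, 30 P
#' @export
generate_hp_sequence <- function(Np, hp, seed = NULL) {
  stopifnot(Np >= 1, hp > 0, hp < 1)
  nh <- round(hp * Np)
  if (nh == 0L || nh == Np)
    warning(sprintf("degenerate composition: %d of %d beads hydrophobic", nh, Np))
  with_seed(seed, {
    s <- rep("P", Np)
    s[sample.int(Np, nh)] <- "H"
    s
  })
}

# Elongated box that fits an Np-bead rod along the periodic x direction with
# water at number density n. Used for single-protein (library) runs.
single_protein_box <- function(Np, bond0 = 0.96, Ly = 7, H = 7) {
  box_geometry(Lx = ceiling((Np - 1) * bond0 + 3), Ly = Ly, H = H,
               periodic_z = TRUE)
}

#' Build a single HP protein in a water box
#'
#' One `Np`-bead HP chain laid out rodlike along the periodic x direction at
#' mid-height, surrounded by WCA water at number density `n`. Both walls are
#' purely repulsive here (the box only serves to equilibrate the protein).
#'
#' @param Np protein length.
#' @param hp hydrophobicity ratio.
#' @param n water bead number density (total beads = `round(n * V)`).
#' @param box a [box_geometry()]; default is an elongated box fitting the rod.
#' @param seed RNG seed (sequence, water positions, velocities).
#' @param itable interaction table; the default uses a repulsive wall toward
#'   all types (protein wall attraction is irrelevant for this box).
#' @param bond0 initial bond length.
#' @return A `particle_system`; protein beads have role `"protein"`.
#' @export
build_single_protein <- function(Np = 40, hp = 0.25, n = 0.65, box = NULL,
                                 seed = 1, itable = NULL, bond0 = 0.96) {
  if (is.null(box)) box <- single_protein_box(Np, bond0)
  if (is.null(itable))
    itable <- interaction_table(wall = wall_spec(1, (2/5)^(1/6)))
  seq_hp <- generate_hp_sequence(Np, hp, seed = seed)
  rod <- (Np - 1) * bond0
  if (rod + 1 > box$Lx)
    stop("protein rod does not fit along the periodic x direction")
  x0 <- (box$Lx - rod) / 2
  pos <- cbind(x0 + (seq_len(Np) - 1) * bond0, box$Ly / 2, box$H / 2)
  sys <- empty_system(box, itable)
  sys <- sys_add(sys, pos, type = seq_hp, mol = 1L, mobile = TRUE,
                 role = "protein",
                 local_bonds = cbind(seq_len(Np - 1L), seq_len(Np - 1L) + 1L))
  sys <- fill_water(sys, n = n, seed = seed + 1L)
  sys <- init_velocities(sys, T = 1, seed = seed + 2L)
  attr(sys, "protein") <- list(Np = Np, hp = hp, sequence = seq_hp)
  sys
}

#' Sample a library of equilibrated protein conformations
#'
#' Runs NVT molecular dynamics for a single HP protein in water from a
#' rodlike start and harvests `Gp` snapshots at evenly spaced intervals from
#' the trailing part of the run (after hydrophobic collapse). Each snapshot
#' is returned centered at its center of mass, together with its sequence.
#' A snapshot whose gyration radius is still above half the rod length
#' triggers a non-collapsed warning but is returned anyway.
#'
#' @param Np,hp protein size and hydrophobicity ratio.
#' @param Gp number of conformations to harvest.
#' @param n water bead density.
#' @param t_run run duration (LJ time; full-scale protocol uses 5000).
#' @param dt integration time step.
#' @param discard leading fraction of the run excluded from harvesting.
#' @param seed RNG seed.
#' @param box optional [box_geometry()] override.
#' @return list of `Gp` conformations, each `list(coords, sequence, Rg)`;
#'   attribute `"Rg_series"` carries the full gyration-radius time series.
#' @export
sample_protein_library <- function(Np = 40, hp = 0.25, Gp = 24, n = 0.65,
                                   t_run = 5000, dt = 0.005, discard = 0.5,
                                   seed = 1, box = NULL) {
  sys <- build_single_protein(Np = Np, hp = hp, n = n, box = box, seed = seed)
  pid <- which(sys$role == "protein")
  stride <- max(1L, round(t_run / dt / 400))
  traj <- run_md(sys, integrator_config(dt = dt, steps = round(t_run / dt),
                                        thermostat = "nose-hoover",
                                        seed = seed + 3L,
                                        sample_every = stride),
                 record = pid)
  nf <- length(traj$times)
  first <- max(2L, ceiling(discard * nf))
  pick <- unique(round(seq(first, nf, length.out = Gp)))
  while (length(pick) < Gp) pick <- c(pick, nf)  # tiny runs: reuse last frame
  rg_series <- vapply(seq_len(nf), function(f) {
    chain_metrics(traj$frames[, , f])$Rg
  }, numeric(1))
  seq_hp <- attr(sys, "protein")$sequence
  lib <- lapply(pick[seq_len(Gp)], function(f) {
    xyz <- traj$frames[, , f]
    xyz <- sweep(xyz, 2, colMeans(xyz))
    rg <- chain_metrics(xyz)$Rg
    if (rg > 0.5 * (Np - 1) * 0.96)
      warning(sprintf("snapshot at t = %.1f not collapsed (Rg = %.2f)",
                      traj$times[f], rg))
    list(coords = xyz, sequence = seq_hp, Rg = rg)
  })
  attr(lib, "Rg_series") <- data.frame(time = traj$times, Rg = rg_series)
  lib
}

#' Fill a system with coarse-grained water
#'
#' Inserts monomeric water beads by rejection sampling until the total bead
#' count reaches `round(n * V)`, keeping every pairwise distance at or above
#' `mindist` (xy periodic). Insertion is restricted to `z` in
#' `[zmargin, H - zmargin]` so that no bead starts deep inside a wall.
#'
#' @param sys a `particle_system`.
#' @param n target total bead number density.
#' @param mindist minimum allowed pair distance at startup.
#' @param zmargin distance kept from either wall at insertion.
#' @param seed RNG seed.
#' @param max_tries attempt budget per bead before a density-too-high error.
#' @return The system with water added (role `"water"`, molecule id 0).
#' @export
fill_water <- function(sys, n = 0.65, mindist = 1, zmargin = 0.8, seed = NULL,
                       max_tries = 2000) {
  box <- sys$box
  target <- round(n * box$Lx * box$Ly * box$H)
  n_add <- target - nrow(sys$pos)
  if (n_add < 0)
    stop(sprintf("system already holds %d beads, above the target %d",
                 nrow(sys$pos), target))
  if (n_add == 0L) return(sys)
  seed_int <- if (is.null(seed)) sample.int(.Machine$integer.max, 1L) else as.integer(seed)
  if (box$periodic_z) zmargin <- 0
  w <- fill_water_cpp(sys$pos, box_vec(box), n_add,
                      zmargin, box$H - zmargin, mindist, seed_int, max_tries)
  sys_add(sys, w, type = "w", mol = 0L, mobile = TRUE, role = "water")
}

#' Dope a coating with attractive A-beads
#'
#' Retypes one bead per coating chain (modes `"middle"`, `"random"`,
#' `"terminal"`) or inserts immobile ligand A-beads at altitude `z_lig`
#' (mode `"ligand"`), each ligand replacing the nearest water bead so the
#' total bead count is conserved. `"none"` is the identity. The middle bead
#' is 1-based index `ceiling(N/2)` along the chain; random doping excludes
#' the tethered bead but may pick the free end.
#'
#' @param sys a `particle_system` containing a coating.
#' @param mode one of `"none"`, `"middle"`, `"random"`, `"terminal"`,
#'   `"ligand"`.
#' @param sigma_lig ligand surface density (ligand count = `round(sigma_lig * A)`).
#' @param z_lig ligand altitude.
#' @param seed RNG seed (random mode and ligand jitter).
#' @return The doped system.
#' @examples
#' sys <- build_coating(box_geometry(12, 12, 12), G = 9, N = 10)
#' doped <- apply_doping(sys, "middle")
#' sum(bead_types(doped) == "A")   # one per chain
#' @export
apply_doping <- function(sys, mode = c("none", "middle", "random", "terminal",
                                       "ligand"),
                         sigma_lig = 0.023, z_lig = 3, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(sys)
  chains <- molecule_indices(sys, "coating")
  if (!length(chains)) stop("system contains no coating to dope")
  A_code <- match("A", BEAD_TYPES)

  if (mode %in% c("middle", "random", "terminal")) {
    pick <- with_seed(seed, vapply(chains, function(ix) {
      N <- length(ix)
      switch(mode,
             middle = ix[ceiling(N / 2)],
             random = ix[sample(2:N, 1L)],
             terminal = ix[N])
    }, numeric(1)))
    sys$type[pick] <- A_code
    return(sys)
  }

  # ligand mode
  nlig <- round(sigma_lig * sys$box$A)
  if (nlig < 1L) stop("sigma_lig too small: no ligand sites on this box")
  sites <- anchor_lattice(sys$box, nlig)
  water <- which(sys$role == "water")
  if (length(water) < nlig)
    stop("not enough water beads to convert into ligands")
  Alig_code <- match("A_ligand", BEAD_TYPES)
  other <- which(sys$role != "water")
  with_seed(seed, {
    for (k in seq_len(nlig)) {
      site <- c(sites[k, 1], sites[k, 2], z_lig)
      # jitter the site away from coating/protein beads if necessary
      tries <- 0L
      repeat {
        if (!length(other)) break
        d <- pdist_xy(sys$pos[other, , drop = FALSE], site, sys$box)
        if (min(d) >= 1 || tries >= 25L) {
          if (min(d) < 1)
            message(sprintf("ligand site %d kept with clearance %.2f after jitter",
                            k, min(d)))
          break
        }
        site[1:2] <- c(sites[k, 1], sites[k, 2]) + runif(2, -0.5, 0.5)
        tries <- tries + 1L
      }
      if (tries > 0L)
        message(sprintf("ligand site %d jittered %d time(s)", k, tries))
      d <- pdist_xy(sys$pos[water, , drop = FALSE], site, sys$box)
      j <- water[which.min(d)]
      water <- setdiff(water, j)
      sys$pos[j, ] <- site
      sys$vel[j, ] <- 0
      sys$type[j] <- Alig_code
      sys$mobile[j] <- FALSE
      sys$role[j] <- "ligand"
    }
  })
  sys
}

# distances from each row of `pos` to point `p` under xy periodicity
pdist_xy <- function(pos, p, box) {
  dx <- pos[, 1] - p[1]
  dy <- pos[, 2] - p[2]
  dx <- dx - box$Lx * round(dx / box$Lx)
  dy <- dy - box$Ly * round(dy / box$Ly)
  sqrt(dx^2 + dy^2 + (pos[, 3] - p[3])^2)
}

#' Place proteins above an equilibrated coating
#'
#' Distributes `length(library)` pre-equilibrated protein conformations on a
#' uniform xy grid, each randomly rotated about z, with its lowest bead at
#' `hmax + clearance`. Placement retries with jitter until no bead comes
#' closer than `mindist` to any existing bead; exhausting the retry budget is
#' a construction error.
#'
#' @param sys a `particle_system` with a coating.
#' @param library list of conformations from [sample_protein_library()].
#' @param clearance altitude gap between the coating top and the lowest
#'   protein bead.
#' @param mindist minimum distance to existing beads.
#' @param hmax coating height reference; default: measured mean per-chain
#'   maximum altitude.
#' @param seed RNG seed.
#' @param max_tries retry budget per protein.
#' @return The system with proteins added (roles `"protein"`, fresh molecule
#'   ids).
#' @export
place_proteins <- function(sys, library, clearance = 1, mindist = 1,
                           hmax = NULL, seed = NULL, max_tries = 60) {
  Gp <- length(library)
  stopifnot(Gp >= 1)
  if (is.null(hmax)) {
    chains <- molecule_indices(sys, "coating")
    if (!length(chains)) stop("system contains no coating")
    hmax <- mean(vapply(chains, function(ix) max(sys$pos[ix, 3]), numeric(1)))
  }
  ng <- ceiling(sqrt(Gp))
  gx <- (seq_len(ng) - 0.5) * sys$box$Lx / ng
  gy <- (seq_len(ng) - 0.5) * sys$box$Ly / ng
  grid <- expand.grid(x = gx, y = gy)[seq_len(Gp), , drop = FALSE]
  mol0 <- max(sys$mol, 0L)
  with_seed(seed, {
    for (p in seq_len(Gp)) {
      conf <- library[[p]]
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        th <- runif(1, 0, 2 * pi)
        Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
        xyz <- conf$coords %*% Rz
        jit <- if (try == 1L) c(0, 0) else runif(2, -1.5, 1.5)
        xyz[, 1] <- xyz[, 1] + grid$x[p] + jit[1]
        xyz[, 2] <- xyz[, 2] + grid$y[p] + jit[2]
        xyz[, 3] <- xyz[, 3] - min(xyz[, 3]) + hmax + clearance
        if (max(xyz[, 3]) > sys$box$H - 0.8) next
        ok <- !nrow(sys$pos) ||
          min(vapply(seq_len(nrow(xyz)), function(i) {
            min(pdist_xy(sys$pos, xyz[i, ], sys$box))
          }, numeric(1))) >= mindist
        if (ok) {
          Np <- nrow(xyz)
          sys <- sys_add(sys, xyz, type = conf$sequence, mol = mol0 + p,
                         mobile = TRUE, role = "protein",
                         local_bonds = cbind(seq_len(Np - 1L), seq_len(Np - 1L) + 1L))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("could not place protein %d without overlap after %d tries",
                     p, max_tries))
    }
    sys
  })
}

#' Grafting-regime classification
#'
#' A coating is in the brush regime when the measured squared gyration radius
#' exceeds the mean surface area per chain `Sigma = 1/sigma`; well below that
#' it is a mushroom, in between intermediate.
#'
#' @param Rg2 measured mean squared gyration radius of the coating chains.
#' @param sigma grafting density.
#' @return `"brush"`, `"intermediate"` or `"mushroom"`.
#' @export
classify_regime <- function(Rg2, sigma) {
  Sigma <- 1 / sigma
  if (Rg2 > Sigma) "brush"
  else if (Rg2 >= 0.5 * Sigma) "intermediate"
  else "mushroom"
}
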