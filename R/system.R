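# Bead taxonomy. Integer codes are the storage representation; the labels are
# the type legend carried by every snapshot/trajectory file.
BEAD_TYPES <- c("R_tethered", "R", "w", "H", "P", "A", "A_ligand")

#' Simulation box geometry
#'
#' Rectangular box, periodic in x and y, bounded by implicit walls at z = 0
#' (the tethering surface) and z = H. The default is the full-scale geometry
#' with tethering area A = 3498.4.
#'
#' @param Lx,Ly lateral box lengths (periodic directions).
#' @param H box height; walls at z = 0 and z = H, unless `periodic_z`.
#' @param periodic_z if `TRUE` the box is periodic in all three directions
#'   (bulk box: no walls; used for single-protein equilibration).
#' @return A `box_geometry` object with fields `Lx`, `Ly`, `H`, area `A` and
#'   `periodic_z`.
#' @examples
#' box_geometry()$A   # 3498.4 (printed rounding)
#' @export
box_geometry <- function(Lx = 54.29, Ly = 64.44, H = 20, periodic_z = FALSE) {
  stopifnot(Lx > 0, Ly > 0, H > 0)
  structure(list(Lx = Lx, Ly = Ly, H = H, A = Lx * Ly,
                 periodic_z = isTRUE(periodic_z)),
            class = "box_geometry")
}

#' @export
print.box_geometry <- function(x, ...) {
  cat(sprintf("box %g x %g x %g (area A = %.1f, periodic in %s)\n",
              x$Lx, x$Ly, x$H, x$A, if (x$periodic_z) "x,y,z" else "x,y"))
  invisible(x)
}

#' Parse "eWzc" / "eLJrc" interaction names
#'
#' The naming scheme for interactions: `"3W2.5"` is a 9-3 wall with depth 3
#' and cutoff 2.5; `"1LJ1.5"` a truncated-shifted LJ pair interaction with
#' depth 1 and cutoff 1.5.
#'
#' @param name character scalar such as `"1W1"` or `"3LJ1.5"`.
#' @return A [wall_spec()] or [pair_spec()].
#' @export
parse_interaction_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regmatches(name, regexec("^([0-9.]+)(W|LJ)([0-9.]+)$", name))[[1]]
  if (length(m) != 4L)
    stop(sprintf("invalid interaction name '%s' (expected e.g. '3W2.5' or '1LJ1.5')",
                 name))
  eps <- as.numeric(m[2])
  cut <- as.numeric(m[4])
  if (!is.finite(eps) || !is.finite(cut) || cut <= 0)
    stop(sprintf("invalid interaction name '%s': bad numeric fields", name))
  if (m[3] == "W") wall_spec(eps, cut) else pair_spec(eps, cut)
}

#' Interaction matrix for all bead types
#'
#' Assembles the symmetric pair-potential table and the per-type wall
#' interactions. Defaults: every bead pair is WCA except the hydrophobic
#' H-H attraction (`hh`, printed value 120LJ1.19) and the polar-attractive
#' P-A / P-A_ligand interaction (`ap`). The lower wall repels coating R, water
#' and A beads (9-3 cut at its minimum), attracts protein H and P beads with
#' strength `wall`, and is not felt by tethered or ligand beads (both
#' immobile); the upper wall repels every mobile bead.
#'
#' @param wall wall interaction toward protein beads, a name like `"1W1"` or a
#'   [wall_spec()].
#' @param ap attractive A-P interaction, a name like `"1LJ1.5"` or a
#'   [pair_spec()].
#' @param hh hydrophobic attraction, name or [pair_spec()].
#' @param protein_wall_style `"93"` (default; both H and P beads feel the 9-3
#'   wall) or `"lj"` (P beads feel a 12-6 LJ wall in z instead, the literal
#'   reading of the interaction matrix).
#' @return An `interaction_table` with `eps`/`rc` 7x7 matrices and
#'   `wall_lower`/`wall_upper` per-type (epsilon, zc, style) matrices.
#' @examples
#' it <- interaction_table(wall = "3W2.5", ap = "3LJ1.5")
#' it$eps["H", "H"]   # 120
#' @export
interaction_table <- function(wall = "1W1", ap = "1LJ1.5", hh = "120LJ1.19",
                              protein_wall_style = c("93", "lj")) {
  protein_wall_style <- match.arg(protein_wall_style)
  if (is.character(wall)) wall <- parse_interaction_name(wall)
  if (is.character(ap)) ap <- parse_interaction_name(ap)
  if (is.character(hh)) hh <- parse_interaction_name(hh)
  stopifnot(inherits(wall, "wall_spec"), inherits(ap, "pair_spec"),
            inherits(hh, "pair_spec"))

  nt <- length(BEAD_TYPES)
  wca <- wca_spec()
  eps <- matrix(wca$epsilon, nt, nt, dimnames = list(BEAD_TYPES, BEAD_TYPES))
  rc <- matrix(wca$rc, nt, nt, dimnames = list(BEAD_TYPES, BEAD_TYPES))
  eps["H", "H"] <- hh$epsilon
  rc["H", "H"] <- hh$rc
  for (a in c("A", "A_ligand")) {
    eps["P", a] <- eps[a, "P"] <- ap$epsilon
    rc["P", a] <- rc[a, "P"] <- ap$rc
  }

  zrep <- (2/5)^(1/6)
  lower <- matrix(0, nt, 3, dimnames = list(BEAD_TYPES, c("epsilon", "zc", "style")))
  upper <- lower
  lower[c("R", "w", "A"), "epsilon"] <- 1
  lower[c("R", "w", "A"), "zc"] <- zrep
  lower[c("H", "P"), "epsilon"] <- wall$epsilon
  lower[c("H", "P"), "zc"] <- wall$zc
  if (protein_wall_style == "lj") lower["P", "style"] <- 1
  upper[c("R", "w", "H", "P", "A"), "epsilon"] <- 1
  upper[c("R", "w", "H", "P", "A"), "zc"] <- zrep

  structure(list(eps = eps, rc = rc, wall_lower = lower, wall_upper = upper,
                 bond = bond_spec(), wall = wall, ap = ap, hh = hh,
                 protein_wall_style = protein_wall_style),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("interaction table: wall %gW%g toward proteins, A-P %gLJ%g, H-H %gLJ%g\n",
              x$wall$epsilon, x$wall$zc, x$ap$epsilon, x$ap$rc,
              x$hh$epsilon, x$hh$rc))
  invisible(x)
}

#' Particle system container
#'
#' The complete simulation state: positions, velocities, bead types, molecule
#' ids, mobility flags, FENE bond list, box geometry and interaction table.
#' Normally constructed by the builder functions ([build_coating()],
#' [fill_water()], ...) or [make_fixture()] rather than directly.
#'
#' @param pos,vel n x 3 numeric matrices.
#' @param type integer codes into the bead taxonomy, or character labels.
#' @param mol integer molecule id (0 for monomeric water).
#' @param mobile logical; immobile beads (tethers, ligands) never move.
#' @param bonds m x 2 integer matrix of bonded bead indices (1-based).
#' @param box a [box_geometry()].
#' @param itable an [interaction_table()].
#' @param role per-bead character role: `"coating"`, `"protein"`, `"water"`
#'   or `"ligand"`.
#' @return A `particle_system` object.
#' @export
particle_system <- function(pos, vel, type, mol, mobile, bonds, box, itable,
                            role) {
  if (is.character(type)) type <- match(type, BEAD_TYPES)
  pos <- as.matrix(pos)
  vel <- as.matrix(vel)
  n <- nrow(pos)
  stopifnot(ncol(pos) == 3L, all(dim(vel) == dim(pos)),
            length(type) == n, length(mol) == n, length(mobile) == n,
            length(role) == n,
            inherits(box, "box_geometry"), inherits(itable, "interaction_table"))
  type <- as.integer(type)
  if (any(is.na(type)) || any(type < 1L) || any(type > length(BEAD_TYPES)))
    stop("invalid bead type codes")
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) && (any(bonds < 1L) || any(bonds > n)))
    stop("bond indices out of range")
  structure(list(pos = pos, vel = vel, type = type, mol = as.integer(mol),
                 mobile = as.logical(mobile), bonds = bonds, box = box,
                 itable = itable, role = role),
            class = "particle_system")
}

empty_system <- function(box, itable) {
  particle_system(pos = matrix(numeric(0), 0, 3), vel = matrix(numeric(0), 0, 3),
                  type = integer(0), mol = integer(0), mobile = logical(0),
                  bonds = matrix(integer(0), 0, 2), box = box, itable = itable,
                  role = character(0))
}

# Append beads (and bonds given in local indices of the new block).
sys_add <- function(sys, pos, type, mol, mobile, role, local_bonds = NULL,
                    vel = NULL) {
  n0 <- nrow(sys$pos)
  if (is.character(type)) type <- match(type, BEAD_TYPES)
  nn <- nrow(pos)
  if (length(type) == 1L) type <- rep(type, nn)
  if (length(mol) == 1L) mol <- rep(mol, nn)
  if (length(mobile) == 1L) mobile <- rep(mobile, nn)
  if (length(role) == 1L) role <- rep(role, nn)
  if (is.null(vel)) vel <- matrix(0, nn, 3)
  sys$pos <- rbind(sys$pos, pos)
  sys$vel <- rbind(sys$vel, vel)
  sys$type <- c(sys$type, as.integer(type))
  sys$mol <- c(sys$mol, as.integer(mol))
  sys$mobile <- c(sys$mobile, mobile)
  sys$role <- c(sys$role, role)
  if (!is.null(local_bonds) && nrow(local_bonds))
    sys$bonds <- rbind(sys$bonds, local_bonds + n0)
  sys
}

#' @export
print.particle_system <- function(x, ...) {
  tab <- table(factor(BEAD_TYPES[x$type], levels = BEAD_TYPES))
  cat(sprintf("particle system: %d beads, %d bonds, box %g x %g x %g\n",
              nrow(x$pos), nrow(x$bonds), x$box$Lx, x$box$Ly, x$box$H))
  cat("  types:", paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]),
                        collapse = ", "), "\n")
  cat(sprintf("  mobile: %d, immobile: %d\n", sum(x$mobile), sum(!x$mobile)))
  invisible(x)
}

#' Number of beads in a particle system
#' @param sys a `particle_system`.
#' @return integer bead count.
#' @export
n_beads <- function(sys) nrow(sys$pos)

#' Bead type labels of a particle system
#' @param sys a `particle_system`.
#' @return character vector of type labels.
#' @export
bead_types <- function(sys) BEAD_TYPES[sys$type]

#' Minimum pairwise bead distance (xy periodic)
#'
#' Construction-time invariant: freshly built systems keep every pair at
#' distance >= 1.
#'
#' @param sys a `particle_system`.
#' @return the smallest pairwise distance.
#' @export
min_pair_distance <- function(sys) {
  if (nrow(sys$pos) < 2L) return(Inf)
  min_pair_dist_cpp(sys$pos, box_vec(sys$box))
}

# (Lx, Ly, H, periodic_z flag) vector handed to the compiled kernels
box_vec <- function(box) c(box$Lx, box$Ly, box$H, as.numeric(box$periodic_z))

#' Maxwell-Boltzmann velocity initialization
#'
#' Draws velocities for all mobile beads at temperature `T` and removes the
#' net momentum of the mobile set; immobile beads keep zero velocity.
#'
#' @param sys a `particle_system`.
#' @param T target temperature (kBT units).
#' @param seed RNG seed.
#' @return The system with initialized velocities.
#' @export
init_velocities <- function(sys, T = 1, seed = NULL) {
  with_seed(seed, {
    n <- nrow(sys$pos)
    v <- matrix(0, n, 3)
    m <- sys$mobile
    if (any(m)) {
      v[m, ] <- matrix(rnorm(3 * sum(m), sd = sqrt(T)), ncol = 3)
      v[m, ] <- sweep(v[m, , drop = FALSE], 2, colMeans(v[m, , drop = FALSE]))
    }
    sys$vel <- v
    sys
  })
}

# Indices of beads belonging to each chain-like molecule of a given role,
# in backbone order (construction order is backbone order).
molecule_indices <- function(sys, role) {
  idx <- which(sys$role == role)
  split(idx, sys$mol[idx])
}
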