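#' Pair, bond and wall interaction specifications
#'
#' Constructors for the closed-form interactions of the model. `pair_spec()`
#' describes a truncated-and-shifted Lennard-Jones interaction ("eLJrc" in the
#' wall/pair naming scheme, e.g. `"1LJ1.5"`); the special case
#' `rc = 2^(1/6), epsilon = 1` is the purely repulsive WCA potential.
#' `wall_spec()` describes the integrated 9-3 interaction between a bead and a
#' structureless half-space ("eWzc", e.g. `"3W2.5"`); a repulsive wall is the
#' 9-3 potential cut at its minimum `zc = (2/5)^(1/6)`. `bond_spec()` is the
#' finitely extensible (FENE) backbone spring.
#'
#' @param epsilon energy depth (kBT units), >= 0.
#' @param rc,zc cutoff distance (bead diameters), > 0.
#' @param side which wall plane: `"lower"` (z = 0) or `"upper"` (z = H).
#' @param kfene FENE spring coefficient (energy / length^2).
#' @param rfene maximum bond extension (length).
#' @return A spec object (`pair_spec`, `wall_spec` or `bond_spec`).
#' @examples
#' wca_spec()                   # 1LJ2^(1/6)
#' pair_spec(3, 1.5)            # 3LJ1.5 protein-ligand attraction
#' wall_spec(1, 1)              # 1W1, the weakest attractive wall
#' repulsive_wall_spec()        # 9-3 wall cut at its minimum
#' @export
pair_spec <- function(epsilon, rc) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0,
            is.numeric(rc), length(rc) == 1L, rc > 0)
  structure(list(epsilon = epsilon, rc = rc, style = "lj/cut-shift"),
            class = "pair_spec")
}

#' @rdname pair_spec
#' @export
wca_spec <- function() pair_spec(1, 2^(1/6))

#' @rdname pair_spec
#' @param mode `"attractive"` or `"repulsive"` (cutoff forced to the minimum).
#' @export
wall_spec <- function(epsilon, zc, side = c("lower", "upper"),
                      mode = c("attractive", "repulsive")) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0,
            is.numeric(zc), length(zc) == 1L, zc > 0)
  if (mode == "repulsive") zc <- (2/5)^(1/6)
  structure(list(epsilon = epsilon, zc = zc, side = side, mode = mode),
            class = "wall_spec")
}

#' @rdname pair_spec
#' @export
repulsive_wall_spec <- function(side = c("lower", "upper")) {
  wall_spec(1, (2/5)^(1/6), side = side, mode = "repulsive")
}

#' @rdname pair_spec
#' @export
bond_spec <- function(kfene = 30, rfene = 1.5) {
  stopifnot(kfene > 0, rfene > 0)
  structure(list(kfene = kfene, rfene = rfene), class = "bond_spec")
}

#' Truncated-shifted Lennard-Jones energy and force
#'
#' Evaluates `V(r) = 4 epsilon [(r^-12 - r^-6) - (rc^-12 - rc^-6)]` for
#' `r <= rc` and 0 beyond, together with the scalar central force `-dV/dr`
#' (positive = repulsive). The energy is continuous at the cutoff by
#' construction; the force is discontinuous there unless the cutoff sits at
#' the potential minimum (the WCA case).
#'
#' @param r separation(s), must be > 0.
#' @param spec a [pair_spec()].
#' @return list with numeric vectors `energy` and `force`.
#' @examples
#' pair_energy_force(1, wca_spec())$energy   # exactly 1 kBT
#' pair_energy_force(2^(1/6), wca_spec())    # zero energy and force at cutoff
#' @export
pair_energy_force <- function(r, spec) {
  stopifnot(inherits(spec, "pair_spec"))
  if (any(!is.finite(r)) || any(r <= 0))
    stop("invalid geometry: pair separation must be > 0")
  if (any(r < 1e-6))
    stop("invalid geometry: pair separation below 1e-6 (overflow guard)")
  inside <- r <= spec$rc
  inv6 <- r^-6
  inv12 <- inv6^2
  shift <- spec$rc^-12 - spec$rc^-6
  e <- ifelse(inside, 4 * spec$epsilon * (inv12 - inv6 - shift), 0)
  f <- ifelse(inside, 24 * spec$epsilon * (2 * inv12 - inv6) / r, 0)
  list(energy = e, force = f)
}

#' FENE bond energy and force
#'
#' `V(r) = -(kfene rfene^2 / 2) ln[1 - (r/rfene)^2]`, diverging as the bond
#' approaches its maximum extension. The force `-dV/dr` is always restoring
#' (negative for r > 0).
#'
#' @param r bond length(s), `0 <= r < rfene`.
#' @param spec a [bond_spec()].
#' @return list with numeric vectors `energy` and `force`.
#' @export
fene_energy_force <- function(r, spec = bond_spec()) {
  stopifnot(inherits(spec, "bond_spec"))
  if (any(!is.finite(r)) || any(r < 0))
    stop("invalid geometry: bond length must be >= 0")
  if (any(r >= spec$rfene))
    stop(sprintf("FENE bond overstretched: length %g >= RFENE = %g",
                 max(r), spec$rfene))
  om <- 1 - (r / spec$rfene)^2
  list(energy = -0.5 * spec$kfene * spec$rfene^2 * log(om),
       force = -spec$kfene * r / om)
}

#' 9-3 wall energy and force
#'
#' Integrated Lennard-Jones interaction between a bead and a structureless
#' half-space: `W(z) = epsilon [(2/15) z^-9 - z^-3 - (2/15) zc^-9 + zc^-3]`
#' for `z <= zc`, 0 beyond. `z` is the distance from the wall plane (for the
#' upper wall, callers pass `H - z`). The minimum sits at `z = (2/5)^(1/6)`;
#' cutting there yields the purely repulsive wall. The returned force is
#' `-dW/dz` along +z (away from the wall).
#'
#' @param z distance(s) from the wall plane, must be > 0.
#' @param spec a [wall_spec()].
#' @return list with numeric vectors `energy` and `force`.
#' @examples
#' zmin <- (2/5)^(1/6)
#' wall_energy_force(zmin, wall_spec(1, 1))$energy   # about -0.187
#' @export
wall_energy_force <- function(z, spec) {
  stopifnot(inherits(spec, "wall_spec"))
  if (any(!is.finite(z)) || any(z <= 0))
    stop("invalid geometry: wall distance must be > 0")
  if (any(z < 1e-6))
    stop("invalid geometry: wall distance below 1e-6 (overflow guard)")
  inside <- z <= spec$zc
  shift <- -(2/15) * spec$zc^-9 + spec$zc^-3
  e <- ifelse(inside, spec$epsilon * ((2/15) * z^-9 - z^-3 + shift), 0)
  f <- ifelse(inside, spec$epsilon * ((6/5) * z^-10 - 3 * z^-4), 0)
  list(energy = e, force = f)
}

#' Effective wall interaction strength
#'
#' A single scalar ranking the attractiveness of a 9-3 wall:
#' `I = integral over (0, zc] of exp(-W(z)) dz` with the integrand taken as 0
#' at the wall plane (where W diverges). For a vanishing well depth the
#' integral reduces to `zc`. Strictly increasing in `epsilon` whenever the
#' cutoff extends beyond the potential minimum, so it reproduces the ordering
#' of wall types from weakly to strongly adsorbing.
#'
#' @param epsilon wall energy depth, >= 0.
#' @param zc wall cutoff distance, > 0.
#' @param rel.tol relative quadrature accuracy.
#' @return The interaction strength I (a length).
#' @examples
#' effective_wall_strength(1, 1)     # 0.307
#' effective_wall_strength(3, 2.5)   # 7.422
#' @export
effective_wall_strength <- function(epsilon, zc, rel.tol = 1e-10) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0,
            is.numeric(zc), length(zc) == 1L, zc > 0)
  if (epsilon == 0) return(zc)
  shift <- -(2/15) * zc^-9 + zc^-3
  integrand <- function(z) {
    w <- epsilon * ((2/15) * z^-9 - z^-3 + shift)
    # exp(-w) underflows to exactly 0 in double precision once w > ~745;
    # capping avoids 0 * Inf NaNs at the z -> 0 endpoint
    out <- exp(-pmin(w, 750))
    out[z <= 0] <- 0
    out
  }
  stats::integrate(integrand, 0, zc, rel.tol = rel.tol,
                   subdivisions = 500L)$value
}
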