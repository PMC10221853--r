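# Configuration parsing and file formats (XYZ, LAMMPS-dump dialect,
# LAMMPS-data-compatible snapshots, TSV tables).
#
# Conventions: 1-based bead ids in files (LAMMPS style), coordinates written
# with 9 significant digits so round-trips sit below integration noise.

CONFIG_KEYS <- list(
  system = c("box", "G", "N", "wall", "ap", "hh", "doping", "sigma_lig",
             "z_lig", "Np", "hp", "Gp", "n", "protein_wall_style", "bond0"),
  integrator = c("dt", "steps", "thermostat", "T", "damping", "sample_every",
                 "skin"),
  analysis = c("dz", "fraction"),
  umbrella = c("dk", "k_max", "t_window", "stride", "lspring", "burn_in"),
  seeds = c("build", "run")
)

#' Default run configuration (full-scale preset)
#'
#' The all-defaults configuration: 54.29 x 64.44 x 20 box, mushroom coating
#' (G = 81 chains of N = 50), S25 proteins (Np = 40, hp = 25%, Gp = 24),
#' bead density n = 0.65, weakest attractive wall 1W1, Nose-Hoover NVT at
#' T = 1 with dt = 0.005.
#'
#' @return A `run_config` list with `system`, `integrator`, `analysis`,
#'   `umbrella` and `seeds` sections.
#' @export
default_config <- function() {
  structure(list(
    system = list(box = c(54.29, 64.44, 20), G = 81, N = 50,
                  wall = "1W1", ap = "1LJ1.5", hh = "120LJ1.19",
                  doping = "none", sigma_lig = 0.023, z_lig = 3,
                  Np = 40, hp = 0.25, Gp = 24, n = 0.65,
                  protein_wall_style = "93", bond0 = 0.96),
    integrator = list(dt = 0.005, steps = 100000L, thermostat = "nose-hoover",
                      T = 1, damping = 1, sample_every = 1000L, skin = 0.3),
    analysis = list(dz = 0.2, fraction = 0.3),
    umbrella = list(dk = 0.005, k_max = 0.3, t_window = 500, stride = 10L,
                    lspring = 1, burn_in = 0.1),
    seeds = list(build = 1L, run = 1L)
  ), class = "run_config")
}

#' Parse a structured text configuration
#'
#' INI-style sections (`[system]`, `[integrator]`, `[analysis]`,
#' `[umbrella]`, `[seeds]`) of `key = value` lines; `#` starts a comment.
#' Unknown sections or keys are rejected; wall/pair interaction names must
#' parse as `eWzc` / `eLJrc`; `hp` must lie in (0, 1); lengths must be
#' positive. Missing keys take the full-scale defaults of
#' [default_config()]; empty text yields exactly those defaults.
#'
#' @param text configuration text (single string or vector of lines).
#' @return A validated `run_config`.
#' @examples
#' cfg <- parse_config("[system]\nwall = 3W2.5\nG = 306")
#' cfg$system$wall
#' @export
parse_config <- function(text = "") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% names(CONFIG_KEYS))
        stop(sprintf("unknown config section '[%s]'", section))
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop(sprintf("malformed config line '%s' (expected key = value)", ln))
    if (is.null(section))
      stop(sprintf("config line '%s' appears before any [section]", ln))
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% CONFIG_KEYS[[section]])
      stop(sprintf("unknown key '%s' in section [%s]", key, section))
    old <- cfg[[section]][[key]]
    cfg[[section]][[key]] <- if (is.character(old)) {
      val
    } else if (is.integer(old)) {
      as.integer(val)
    } else {
      as.numeric(strsplit(val, "[ ,]+")[[1]])
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  s <- cfg$system
  if (length(s$box) != 3L || any(!is.finite(s$box)) || any(s$box <= 0))
    stop("config error at [system] box: three positive lengths required")
  named_spec <- function(nm) {
    tryCatch(parse_interaction_name(s[[nm]]), error = function(e) {
      stop(sprintf("config error at [system] %s: %s", nm, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (!inherits(named_spec("wall"), "wall_spec"))
    stop(sprintf("config error at [system] wall: '%s' is not a wall name",
                 s$wall))
  for (nm in c("ap", "hh")) {
    if (!inherits(named_spec(nm), "pair_spec"))
      stop(sprintf("config error at [system] %s: '%s' is not a pair name",
                   nm, s[[nm]]))
  }
  if (!is.finite(s$hp) || s$hp <= 0 || s$hp >= 1)
    stop("config error at [system] hp: must lie in (0, 1)")
  if (!s$doping %in% c("none", "middle", "random", "terminal", "ligand"))
    stop(sprintf("config error at [system] doping: unknown mode '%s'", s$doping))
  if (!s$protein_wall_style %in% c("93", "lj"))
    stop("config error at [system] protein_wall_style: use '93' or 'lj'")
  if (any(c(s$G, s$N, s$Np, s$Gp) < 1))
    stop("config error at [system]: counts must be >= 1")
  if (s$n < 0 || s$sigma_lig < 0 || s$z_lig <= 0 || s$bond0 <= 0)
    stop("config error at [system]: negative length or density")
  i <- cfg$integrator
  if (i$dt <= 0 || i$steps < 1 || i$damping <= 0)
    stop("config error at [integrator]: dt, steps and damping must be positive")
  if (!i$thermostat %in% c("nose-hoover", "langevin", "none"))
    stop(sprintf("config error at [integrator] thermostat: '%s'", i$thermostat))
  if (cfg$analysis$dz <= 0 || cfg$analysis$fraction <= 0 || cfg$analysis$fraction > 1)
    stop("config error at [analysis]: dz > 0 and fraction in (0, 1] required")
  u <- cfg$umbrella
  if (u$dk <= 0 || u$k_max < 0 || u$t_window <= 0 || u$stride < 1)
    stop("config error at [umbrella]: invalid schedule")
  cfg
}

#' Build the complete system described by a configuration
#'
#' The full construction pipeline: tethered coating, short coating
#' equilibration (so the coating height is known), backbone doping, protein
#' library sampling and placement, water fill to the target density, ligand
#' doping, and Maxwell-Boltzmann velocities.
#'
#' @param cfg a `run_config` from [parse_config()] / [default_config()].
#' @param equilibrate_steps NVT steps used to relax the coating before
#'   proteins are placed.
#' @param library optional pre-sampled protein library (skips the
#'   single-protein runs).
#' @param t_library run duration for [sample_protein_library()].
#' @return A ready-to-run `particle_system`.
#' @export
build_system <- function(cfg = default_config(), equilibrate_steps = 20000L,
                         library = NULL, t_library = 50) {
  s <- cfg$system
  box <- box_geometry(s$box[1], s$box[2], s$box[3])
  itable <- interaction_table(wall = s$wall, ap = s$ap, hh = s$hh,
                              protein_wall_style = s$protein_wall_style)
  seed <- cfg$seeds$build
  sys <- build_coating(box, G = s$G, N = s$N, bond0 = s$bond0, itable = itable)
  if (equilibrate_steps > 0L) {
    sys <- init_velocities(sys, T = cfg$integrator$T, seed = seed)
    tr <- run_md(sys, integrator_config(dt = cfg$integrator$dt,
                                        steps = equilibrate_steps,
                                        thermostat = "langevin",
                                        T = cfg$integrator$T,
                                        damping = cfg$integrator$damping,
                                        seed = seed,
                                        sample_every = equilibrate_steps))
    sys <- tr$final
  }
  if (s$doping %in% c("middle", "random", "terminal"))
    sys <- apply_doping(sys, s$doping, seed = seed + 1L)
  if (is.null(library))
    library <- sample_protein_library(Np = s$Np, hp = s$hp, Gp = s$Gp,
                                      n = s$n, t_run = t_library,
                                      dt = cfg$integrator$dt, seed = seed + 2L)
  sys <- place_proteins(sys, library, seed = seed + 3L)
  sys <- fill_water(sys, n = s$n, seed = seed + 4L)
  if (s$doping == "ligand")
    sys <- apply_doping(sys, "ligand", sigma_lig = s$sigma_lig,
                        z_lig = s$z_lig, seed = seed + 5L)
  init_velocities(sys, T = cfg$integrator$T, seed = seed + 6L)
}

fmt9 <- function(x) formatC(x, digits = 9, format = "g")

#' Write a trajectory to XYZ or LAMMPS-dump format
#'
#' XYZ frames carry the bead type label as the element column; the dump
#' dialect carries `ITEM: ATOMS id type x y z` records with box bounds
#' (periodic x/y, fixed z).
#'
#' @param traj an `md_trajectory`.
#' @param path output file.
#' @param dialect `"xyz"` or `"lammps-dump"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, dialect = c("xyz", "lammps-dump")) {
  dialect <- match.arg(dialect)
  n <- dim(traj$frames)[1]
  nf <- length(traj$times)
  labels <- BEAD_TYPES[traj$type]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    xyz <- traj$frames[, , f, drop = FALSE]
    if (dialect == "xyz") {
      writeLines(c(as.character(n), sprintf("t = %s", fmt9(traj$times[f]))), con)
      writeLines(paste(labels, fmt9(xyz[, 1, 1]), fmt9(xyz[, 2, 1]),
                       fmt9(xyz[, 3, 1])), con)
    } else {
      writeLines(c("ITEM: TIMESTEP",
                   as.character(round(traj$times[f] / traj$config$dt)),
                   "ITEM: NUMBER OF ATOMS", as.character(n),
                   "ITEM: BOX BOUNDS pp pp ff",
                   paste(fmt9(0), fmt9(traj$box$Lx)),
                   paste(fmt9(0), fmt9(traj$box$Ly)),
                   paste(fmt9(0), fmt9(traj$box$H)),
                   "ITEM: ATOMS id type x y z"), con)
      writeLines(paste(seq_len(n), traj$type, fmt9(xyz[, 1, 1]),
                       fmt9(xyz[, 2, 1]), fmt9(xyz[, 3, 1])), con)
    }
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path input file.
#' @param dialect `"xyz"` or `"lammps-dump"`.
#' @return list with `frames` (n x 3 x n_frames), `type` (codes for dump,
#'   labels for xyz), `times` (xyz) or `steps` (dump), and `box` (dump).
#' @export
read_trajectory <- function(path, dialect = c("xyz", "lammps-dump")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "xyz") {
    frames <- list(); times <- numeric(0); type <- NULL
    i <- 1L
    while (i <= length(lines)) {
      n <- as.integer(lines[i])
      times <- c(times, as.numeric(sub("^t = ", "", lines[i + 1L])))
      rec <- do.call(rbind, strsplit(lines[i + 1L + seq_len(n)], "[ ]+"))
      type <- rec[, 1]
      frames[[length(frames) + 1L]] <-
        matrix(as.numeric(rec[, 2:4]), ncol = 3)
      i <- i + 2L + n
    }
    list(frames = array(unlist(frames), dim = c(nrow(frames[[1]]), 3,
                                                length(frames))),
         type = type, times = times)
  } else {
    frames <- list(); steps <- integer(0); type <- NULL; box <- NULL
    i <- 1L
    while (i <= length(lines)) {
      stopifnot(lines[i] == "ITEM: TIMESTEP")
      steps <- c(steps, as.integer(lines[i + 1L]))
      n <- as.integer(lines[i + 3L])
      box <- apply(do.call(rbind, strsplit(lines[i + 5L:7L], " +")), 1:2,
                   as.numeric)
      rec <- do.call(rbind, strsplit(lines[i + 8L + seq_len(n)], "[ ]+"))
      ord <- order(as.integer(rec[, 1]))
      rec <- rec[ord, , drop = FALSE]
      type <- as.integer(rec[, 2])
      frames[[length(frames) + 1L]] <- matrix(as.numeric(rec[, 3:5]), ncol = 3)
      i <- i + 9L + n
    }
    list(frames = array(unlist(frames), dim = c(nrow(frames[[1]]), 3,
                                                length(frames))),
         type = type, steps = steps, box = box)
  }
}

#' Write a particle system as a LAMMPS-data-compatible snapshot
#'
#' Atom style `molecular` (id mol type x y z) with Velocities and Bonds
#' sections and the bead-type legend as comments. [read_lammps_data()]
#' round-trips it.
#'
#' @param sys a `particle_system`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(sys, path) {
  n <- nrow(sys$pos)
  nb <- nrow(sys$bonds)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# coarse-grained brush+protein snapshot; types: %s; immobile beads: %s",
            paste(sprintf("%d=%s", seq_along(BEAD_TYPES), BEAD_TYPES),
                  collapse = " "),
            paste(which(!sys$mobile), collapse = " ")),
    "",
    sprintf("%d atoms", n),
    sprintf("%d bonds", nb),
    sprintf("%d atom types", length(BEAD_TYPES)),
    "1 bond types",
    "",
    sprintf("0 %s xlo xhi", fmt9(sys$box$Lx)),
    sprintf("0 %s ylo yhi", fmt9(sys$box$Ly)),
    sprintf("0 %s zlo zhi", fmt9(sys$box$H)),
    "",
    "Masses",
    "",
    sprintf("%d 1", seq_along(BEAD_TYPES)),
    "",
    "Atoms # molecular",
    ""), con)
  writeLines(paste(seq_len(n), sys$mol, sys$type, fmt9(sys$pos[, 1]),
                   fmt9(sys$pos[, 2]), fmt9(sys$pos[, 3])), con)
  writeLines(c("", "Velocities", ""), con)
  writeLines(paste(seq_len(n), fmt9(sys$vel[, 1]), fmt9(sys$vel[, 2]),
                   fmt9(sys$vel[, 3])), con)
  if (nb) {
    writeLines(c("", "Bonds", ""), con)
    writeLines(paste(seq_len(nb), 1L, sys$bonds[, 1], sys$bonds[, 2]), con)
  }
  invisible(path)
}

#' Read a snapshot written by [write_lammps_data()]
#'
#' @param path input file.
#' @param itable interaction table to attach (the file stores geometry and
#'   types, not potentials).
#' @return A `particle_system`. Roles are reconstructed from types
#'   (tethered/ligand from immobility, proteins from H/P, water from w).
#' @export
read_lammps_data <- function(path, itable = interaction_table()) {
  lines <- readLines(path)
  immobile <- as.integer(strsplit(sub(".*immobile beads: ?", "", lines[1]),
                                  " +")[[1]])
  immobile <- immobile[!is.na(immobile)]
  grab <- function(pat) as.numeric(sub(paste0(" ?", pat, ".*"), "",
                                       grep(pat, lines, value = TRUE)[1]))
  n <- as.integer(grab("atoms"))
  nb <- as.integer(grab("bonds$"))
  bx <- strsplit(trimws(grep("xlo xhi", lines, value = TRUE)), " +")[[1]]
  by <- strsplit(trimws(grep("ylo yhi", lines, value = TRUE)), " +")[[1]]
  bz <- strsplit(trimws(grep("zlo zhi", lines, value = TRUE)), " +")[[1]]
  box <- box_geometry(as.numeric(bx[2]) - as.numeric(bx[1]),
                      as.numeric(by[2]) - as.numeric(by[1]),
                      as.numeric(bz[2]) - as.numeric(bz[1]))
  sect <- function(name, count, ncol_) {
    i0 <- which(grepl(paste0("^", name), lines))[1] + 2L
    rec <- do.call(rbind, strsplit(trimws(lines[i0:(i0 + count - 1L)]), " +"))
    matrix(as.numeric(rec[, seq_len(ncol_)]), ncol = ncol_)
  }
  at <- sect("Atoms", n, 6L)
  at <- at[order(at[, 1]), , drop = FALSE]
  ve <- sect("Velocities", n, 4L)
  ve <- ve[order(ve[, 1]), , drop = FALSE]
  bonds <- if (nb) {
    b <- sect("Bonds", nb, 4L)
    matrix(as.integer(b[, 3:4]), ncol = 2)
  } else matrix(integer(0), 0, 2)
  type <- as.integer(at[, 3])
  mobile <- !(seq_len(n) %in% immobile)
  lab <- BEAD_TYPES[type]
  role <- ifelse(lab %in% c("H", "P"), "protein",
                 ifelse(lab == "w", "water",
                        ifelse(lab == "A_ligand", "ligand", "coating")))
  particle_system(pos = at[, 4:6], vel = ve[, 2:4], type = type,
                  mol = as.integer(at[, 2]), mobile = mobile, bonds = bonds,
                  box = box, itable = itable, role = role)
}

#' Write a run manifest
#'
#' Key-value provenance record (config hash, seeds, package version)
#' accompanying generated outputs.
#'
#' @param path output file.
#' @param cfg the `run_config` used.
#' @param extra named character vector of additional entries.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, cfg, extra = character(0)) {
  hash <- sum(utf8ToInt(paste(deparse(cfg), collapse = "")) *
                seq_along(utf8ToInt(paste(deparse(cfg), collapse = "")))) %%
    .Machine$integer.max
  lines <- c(sprintf("config_hash = %d", hash),
             sprintf("seed_build = %s", cfg$seeds$build),
             sprintf("seed_run = %s", cfg$seeds$run),
             sprintf("package_version = %s",
                     as.character(utils::packageVersion("hpbrush"))),
             sprintf("%s = %s", names(extra), extra))
  writeLines(lines, path)
  invisible(path)
}
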