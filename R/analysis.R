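# Observables: chain metrics, shape, adsorption, density profiles.

#' Chain conformational metrics
#'
#' For one chain (ordered bead coordinates, unwrapped in xy):
#' squared gyration radius `Rg^2 = N^-1 sum (r_i - r_cm)^2`, end-to-end
#' distance `R = |r_N - r_1|`, and chain height `h = max z_i`.
#'
#' @param coords N x 3 matrix of bead positions along the backbone.
#' @return list with `Rg`, `Rg2`, `R`, `R2`, `h` and `N`.
#' @examples
#' rod <- cbind(0, 0, 0:9)
#' chain_metrics(rod)$R   # 9
#' @export
chain_metrics <- function(coords) {
  coords <- rbind(coords)
  if (!nrow(coords)) stop("empty chain")
  cm <- colMeans(coords)
  dd <- sweep(coords, 2, cm)
  rg2 <- sum(dd^2) / nrow(coords)
  r2 <- sum((coords[nrow(coords), ] - coords[1, ])^2)
  list(Rg = sqrt(rg2), Rg2 = rg2, R = sqrt(r2), R2 = r2,
       h = max(coords[, 3]), N = nrow(coords))
}

#' Dry coating height
#'
#' The height a coating would have with all its monomers packed at the bulk
#' bead density: `hdry = sigma * N / n`.
#'
#' @param sigma grafting density (chains per area).
#' @param N beads per chain.
#' @param n bead number density.
#' @return `hdry` (a length).
#' @examples
#' dry_height(81 / (54.29 * 64.44), 50, 0.65)   # 1.78
#' @export
dry_height <- function(sigma, N, n) {
  stopifnot(n > 0, sigma >= 0, N >= 0)
  sigma * N / n
}

#' Gyration-tensor shape analysis
#'
#' Eigenvalues `R1 >= R2 >= R3` of the gyration tensor (so that
#' `R1 + R2 + R3 = Rg^2`) and the asphericity
#' `alpha = [(R1-R2)^2 + (R2-R3)^2 + (R3-R1)^2] / (2 (R1+R2+R3)^2)`:
#' 0 for spherically symmetric beads, 1 for a perfect rod. The eigenvalue
#' formulation makes alpha invariant under rigid rotations; the raw diagonal
#' elements of the tensor are not, and the divergence between the two
#' readings is reported as a diagnostic (`alpha_diagonal`).
#'
#' @param coords N x 3 matrix (N >= 2, not all coincident).
#' @return A `shape_record`: `eigenvalues`, `alpha`, `alpha_diagonal`,
#'   `Rg2`, `com`.
#' @examples
#' asphericity(cbind(0, 0, 1:10))$alpha   # 1 (rod)
#' @export
asphericity <- function(coords) {
  coords <- rbind(coords)
  if (nrow(coords) < 2L) stop("shape analysis needs at least 2 beads")
  cm <- colMeans(coords)
  dd <- sweep(coords, 2, cm)
  S <- crossprod(dd) / nrow(coords)
  if (sum(diag(S)) < 1e-14) stop("all beads coincident: asphericity undefined")
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0)
  asph <- function(l) {
    ((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[3] - l[1])^2) / (2 * sum(l)^2)
  }
  structure(list(eigenvalues = ev, alpha = asph(ev),
                 alpha_diagonal = asph(sort(diag(S), decreasing = TRUE)),
                 Rg2 = sum(ev), com = cm),
            class = "shape_record")
}

#' @export
print.shape_record <- function(x, ...) {
  cat(sprintf("shape: alpha = %.3f, Rg = %.3f (eigenvalues %.3g %.3g %.3g)\n",
              x$alpha, sqrt(x$Rg2), x$eigenvalues[1], x$eigenvalues[2],
              x$eigenvalues[3]))
  invisible(x)
}

# Per-frame mean coating height <h> (mean over chains of max bead z).
coating_hmax <- function(traj) {
  chains <- split(seq_len(dim(traj$frames)[1])[traj$role == "coating"],
                  traj$mol[traj$role == "coating"])
  if (!length(chains)) stop("trajectory does not record a coating")
  vapply(seq_along(traj$times), function(f) {
    mean(vapply(chains, function(ix) max(traj$frames[ix, 3, f]), numeric(1)))
  }, numeric(1))
}

#' Adsorbed protein fraction over time
#'
#' A protein counts as adsorbed at a frame when its center of mass lies
#' below the mean coating height minus the protein gyration radius:
#' `COM_z < hmax - Rg_p`. By default `hmax` is recomputed per frame from the
#' recorded coating chains (a running reference), because adsorption itself
#' shifts the coating height; pass a scalar `hmax` for a fixed reference.
#'
#' @param traj an `md_trajectory` recording protein (and, for the running
#'   reference, coating) beads.
#' @param Rg_p protein gyration radius used in the criterion, > 0.
#' @param hmax optional fixed coating-height reference (scalar) or per-frame
#'   vector; default: per-frame mean of per-chain maxima.
#' @return An `adsorption_series` data.frame: `time`, `fads`, `n_adsorbed`,
#'   `hmax`.
#' @export
adsorbed_fraction <- function(traj, Rg_p, hmax = NULL) {
  if (!is.numeric(Rg_p) || Rg_p <= 0) stop("Rg_p must be positive")
  prot <- split(seq_len(dim(traj$frames)[1])[traj$role == "protein"],
                traj$mol[traj$role == "protein"])
  if (!length(prot)) stop("trajectory records no proteins")
  if (is.null(hmax)) hmax <- coating_hmax(traj)
  if (length(hmax) == 1L) hmax <- rep(hmax, length(traj$times))
  stopifnot(length(hmax) == length(traj$times))
  nads <- vapply(seq_along(traj$times), function(f) {
    sum(vapply(prot, function(ix) {
      mean(traj$frames[ix, 3, f]) < hmax[f] - Rg_p
    }, logical(1)))
  }, numeric(1))
  structure(data.frame(time = traj$times, fads = nads / length(prot),
                       n_adsorbed = nads, hmax = hmax),
            class = c("adsorption_series", "data.frame"),
            Gp = length(prot), Rg_p = Rg_p)
}

#' Bead number density profile along z
#'
#' Histogram of selected bead altitudes over frames, normalized to a number
#' density: `rho(z) = count / (A * dz * n_frames)`, so that
#' `sum(rho * A * dz)` recovers the mean selected-bead count per frame.
#'
#' @param traj an `md_trajectory`.
#' @param selection indices into the recorded beads (default: beads with
#'   role `"protein"`).
#' @param dz bin width.
#' @param frames frame indices to include (default: all; adsorption-style
#'   analyses typically pass the trailing 30%).
#' @return A `density_profile` data.frame: `z` (bin centers), `rho`.
#' @export
density_profile <- function(traj, selection = NULL, dz = 0.2, frames = NULL) {
  if (dz <= 0) stop("bin width must be positive")
  if (is.null(selection)) selection <- which(traj$role == "protein")
  if (!length(selection)) stop("empty selection")
  if (is.null(frames)) frames <- seq_along(traj$times)
  edges <- seq(0, traj$box$H + dz, by = dz)
  zs <- as.vector(traj$frames[selection, 3, frames])
  counts <- tabulate(findInterval(zs, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  A <- traj$box$Lx * traj$box$Ly
  structure(data.frame(z = head(edges, -1L) + dz / 2,
                       rho = counts / (A * dz * length(frames))),
            class = c("density_profile", "data.frame"),
            A = A, dz = dz, n_frames = length(frames),
            n_selected = length(selection))
}

#' Stationary (trailing-window) average
#'
#' Mean and standard error over the trailing `fraction` of a series — the
#' convention used for all stationary observables (the last 30% of the data).
#' The standard error assumes uncorrelated points and is therefore a lower
#' bound for correlated MD series.
#'
#' @param x numeric series (time-ordered).
#' @param fraction trailing fraction retained, in (0, 1].
#' @return list with `mean`, `se`, `n`.
#' @examples
#' stationary_average(seq(0, 1, length.out = 1000))$mean   # about 0.85
#' @export
stationary_average <- function(x, fraction = 0.3) {
  stopifnot(fraction > 0, fraction <= 1)
  x <- x[!is.na(x)]
  if (!length(x)) stop("empty series")
  keep <- x[max(1L, length(x) - ceiling(fraction * length(x)) + 1L):length(x)]
  list(mean = mean(keep),
       se = if (length(keep) > 1L) sd(keep) / sqrt(length(keep)) else NA_real_,
       n = length(keep))
}

#' Per-protein shape table from a trajectory
#'
#' Time-averaged asphericity and mean center-of-mass altitude for each
#' protein over a trailing window.
#'
#' @param traj an `md_trajectory` recording protein beads.
#' @param fraction trailing fraction of frames used.
#' @return data.frame: `mol`, `alpha`, `com_z`.
#' @export
protein_shape_table <- function(traj, fraction = 0.3) {
  prot <- split(seq_len(dim(traj$frames)[1])[traj$role == "protein"],
                traj$mol[traj$role == "protein"])
  if (!length(prot)) stop("trajectory records no proteins")
  nf <- length(traj$times)
  use <- max(1L, nf - ceiling(fraction * nf) + 1L):nf
  rows <- lapply(names(prot), function(m) {
    ix <- prot[[m]]
    a <- vapply(use, function(f) asphericity(traj$frames[ix, , f])$alpha,
                numeric(1))
    z <- vapply(use, function(f) mean(traj$frames[ix, 3, f]), numeric(1))
    data.frame(mol = as.integer(m), alpha = mean(a), com_z = mean(z))
  })
  do.call(rbind, rows)
}
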