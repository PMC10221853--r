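# Steered-MD umbrella sampling along z and the WHAM estimator.

#' Harmonic bias energy
#'
#' The umbrella spring `w(z) = (k/2) (z - l)^2`, applied to the protein
#' center of mass along z only (no lateral constraints).
#'
#' @param z reaction coordinate value(s).
#' @param k spring stiffness.
#' @param l spring rest length.
#' @return bias energy (kBT units).
#' @examples
#' bias_energy(3, k = 0.3, l = 1)   # 0.6
#' @export
bias_energy <- function(z, k, l = 1) {
  0.5 * k * (z - l)^2
}

#' Umbrella window schedule
#'
#' The stiffness ladder `k_j = j * dk` for `j = 0 .. k_max/dk` and the
#' per-window sample count implied by the window duration, time step and
#' recording stride. With the full-scale protocol (dk = 0.005, k_max = 0.3,
#' t_window = 500, dt = 0.005, stride 10) this gives 61 windows of 10^4
#' samples each.
#'
#' @param dk stiffness increment.
#' @param k_max largest stiffness.
#' @param t_window production duration per window (LJ time).
#' @param stride recording stride (steps).
#' @param dt integration time step.
#' @return data.frame: `j`, `k`, `n_samples`.
#' @export
umbrella_schedule <- function(dk = 0.005, k_max = 0.3, t_window = 500,
                              stride = 10L, dt = 0.005) {
  stopifnot(dk > 0, k_max >= 0, t_window > 0, stride >= 1, dt > 0)
  j <- 0:round(k_max / dk)
  steps <- round(t_window / dt)
  if (steps %% stride != 0L)
    warning("t_window/dt not divisible by stride; sample count rounded down")
  data.frame(j = j, k = j * dk, n_samples = steps %/% stride)
}

new_umbrella_window <- function(k, l, samples, g = 1) {
  stopifnot(k >= 0, g > 0, g <= 1)
  structure(list(k = k, l = l, samples = as.numeric(samples),
                 N = length(samples), g = g),
            class = "umbrella_window")
}

#' Run the umbrella-sampling protocol
#'
#' Steered MD for a single protein: its center of mass is tethered toward
#' the wall by a harmonic spring of rest length `l` whose stiffness ascends
#' the schedule `k_j = j dk`. Each window starts from the previous window's
#' final state, runs an un-recorded equilibration segment of
#' `burn_in * t_window`, then a production segment of `t_window` during
#' which the COM altitude is recorded every `stride` steps.
#'
#' @param sys a `particle_system` containing exactly one protein (role
#'   `"protein"`), initially outside the coating.
#' @param dk,k_max,t_window,stride as in [umbrella_schedule()].
#' @param l spring rest length.
#' @param burn_in equilibration fraction prepended to each window.
#' @param config base [integrator_config()] (its `steps`/`sample_every` are
#'   overridden per window).
#' @param seed RNG seed (per-window seeds derive from it).
#' @return list of `umbrella_window` objects (one per stiffness), with the
#'   final system state as attribute `"final"`.
#' @export
run_umbrella_protocol <- function(sys, dk = 0.005, k_max = 0.3, t_window = 500,
                                  stride = 10L, l = 1, burn_in = 0.1,
                                  config = integrator_config(), seed = 1L) {
  prot <- which(sys$role == "protein")
  if (!length(prot)) stop("system contains no protein")
  if (length(unique(sys$mol[prot])) != 1L)
    stop("umbrella protocol expects exactly one protein")
  sched <- umbrella_schedule(dk, k_max, t_window, stride, config$dt)
  steps <- round(t_window / config$dt)
  steps <- (steps %/% stride) * stride
  burn_steps <- round(burn_in * steps)
  state <- sys
  xi <- 0
  windows <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    k <- sched$k[i]
    bias <- list(k = k, l = l, group = prot)
    if (burn_steps > 0L) {
      cfg_b <- config
      cfg_b$steps <- burn_steps
      cfg_b$sample_every <- burn_steps
      cfg_b$seed <- config$seed + 1000L * i
      tb <- run_md(state, cfg_b, record = prot[1], bias = bias, xi0 = xi)
      state <- tb$final
      xi <- tb$xi
    }
    cfg <- config
    cfg$steps <- steps
    cfg$sample_every <- as.integer(stride)
    cfg$seed <- config$seed + 1000L * i + 1L
    tr <- run_md(state, cfg, record = prot[1], bias = bias, xi0 = xi)
    state <- tr$final
    xi <- tr$xi
    windows[[i]] <- new_umbrella_window(k, l, tr$thermo$bias_z[-1])
  }
  attr(windows, "final") <- state
  attr(windows, "schedule") <- sched
  windows
}

#' WHAM configuration
#'
#' @param beta inverse temperature.
#' @param Lz upper bound of the reaction coordinate domain (the box height).
#' @param dz histogram bin width.
#' @param tol convergence tolerance on the window free energies.
#' @param max_iter iteration cap.
#' @param z0 reference altitude where the PMF is pinned to zero; default:
#'   the sampled bin farthest from the wall (bulk reference).
#' @return A `wham_config` object.
#' @export
wham_config <- function(beta = 1, Lz = 20, dz = 0.1, tol = 1e-6,
                        max_iter = 10000L, z0 = NULL) {
  stopifnot(beta > 0, Lz > 0, dz > 0, tol > 0, max_iter >= 1)
  structure(list(beta = beta, Lz = Lz, dz = dz, tol = tol,
                 max_iter = as.integer(max_iter), z0 = z0),
            class = "wham_config")
}

#' Solve the WHAM equations
#'
#' Self-consistent estimation of the unbiased probability `P(z)` from biased
#' window histograms: iterate
#' `P(z) = sum_j g_j^-1 h_j(z) / sum_j N_j g_j^-1 exp[-beta (w_j(z) - f_j)]`
#' with `exp(-beta f_j) = sum_z exp(-beta w_j(z)) P(z) dz`, until the window
#' free energies `f_j` are stationary (gauge fixed at `f_1 = 0`). The PMF is
#' `-(1/beta) ln[P(z)/P(z0)]` with `PMF(z0) = 0`.
#'
#' A single unbiased window (k = 0) reduces exactly to the log-histogram
#' estimate. Windows whose histograms do not overlap any other window
#' trigger a warning naming the gap.
#'
#' @param windows list of umbrella windows (`k`, `l`, `samples`, optional
#'   `g`); any list with those fields is accepted.
#' @param config a [wham_config()].
#' @return A `pmf_profile`: data.frame columns `z`, `pmf`, `P` plus
#'   attributes `iterations`, `converged`, `f` (window free energies).
#' @export
wham_solve <- function(windows, config = wham_config()) {
  stopifnot(length(windows) >= 1L)
  edges <- seq(0, config$Lz, by = config$dz)
  if (max(edges) < config$Lz) edges <- c(edges, max(edges) + config$dz)
  centers <- head(edges, -1L) + config$dz / 2
  B <- length(centers)
  nw <- length(windows)
  beta <- config$beta
  dzb <- config$dz

  H <- matrix(0, nw, B)
  N <- numeric(nw)
  ginv <- numeric(nw)
  W <- matrix(0, nw, B)
  for (j in seq_len(nw)) {
    win <- windows[[j]]
    if (!length(win$samples)) stop("window with no samples")
    if (any(win$samples < 0 | win$samples > config$Lz))
      stop("samples outside (0, Lz): enlarge the WHAM domain")
    H[j, ] <- tabulate(findInterval(win$samples, edges, rightmost.closed = TRUE),
                       nbins = B)
    N[j] <- length(win$samples)
    ginv[j] <- 1 / (if (is.null(win$g)) 1 else win$g)
    l <- if (is.null(win$l)) 1 else win$l
    W[j, ] <- bias_energy(centers, win$k, l)
  }

  if (nw > 1L) {
    occ <- H > 0
    for (j in seq_len(nw)) {
      others <- which(colSums(occ[-j, , drop = FALSE]) > 0)
      if (!any(occ[j, ] & seq_len(B) %in% others))
        warning(sprintf("window %d (k = %g) shares no occupied bin with any other window",
                        j, windows[[j]]$k))
    }
  }

  num <- colSums(H * ginv)
  f <- numeric(nw)
  converged <- FALSE
  it <- 0L
  expW <- exp(-beta * W)
  for (it in seq_len(config$max_iter)) {
    denom <- colSums((N * ginv * exp(beta * f)) * expW)
    P <- ifelse(denom > 0, num / denom, 0)
    s <- sum(P) * dzb
    if (s <= 0) stop("WHAM produced an empty distribution")
    P <- P / s
    fnew <- -log(pmax(expW %*% P * dzb, .Machine$double.xmin)) / beta
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- as.numeric(fnew)
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("WHAM not converged after %d iterations (max |df| = %.2g)",
                    it, delta))

  z0 <- config$z0
  if (is.null(z0)) {
    occ <- which(P > 0)
    z0 <- centers[occ[length(occ)]]  # sampled bin farthest from the wall
  }
  b0 <- which.min(abs(centers - z0))
  if (P[b0] <= 0) stop("reference altitude z0 has zero sampled probability")
  pmf <- ifelse(P > 0, -log(P / P[b0]) / beta, NA_real_)
  structure(data.frame(z = centers, pmf = pmf, P = P),
            class = c("pmf_profile", "data.frame"),
            iterations = it, converged = converged, f = f, z0 = centers[b0],
            beta = beta, dz = dzb)
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("PMF profile: %d bins, z0 = %g, %s after %d iterations\n",
              nrow(x), attr(x, "z0"),
              if (attr(x, "converged")) "converged" else "NOT converged",
              attr(x, "iterations")))
  invisible(x)
}
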