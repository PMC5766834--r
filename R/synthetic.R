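#' Synthetic 3D potential over a periodic box
#'
#' A sum of attractive Gaussian wells inside a periodic box, optionally
#' with an absorbing sphere (a perfectly adsorbing "protein" surface used
#' for association-rate runs).  Stands in for a ligand-binding free-energy
#' landscape with known ground truth.
#'
#' @param box length-3 box edge lengths (Angstrom); periodic boundaries.
#' @param wells list of wells, each \code{list(center, depth, width)}:
#'   center (Angstrom, inside the box), depth (kcal/mol, >= 0, attractive)
#'   and Gaussian width (Angstrom, > 0).
#' @param absorbing optional \code{list(center, radius)} absorbing sphere.
#' @return A \code{potential_spec}.
#' @export
potential_spec <- function(box, wells = list(), absorbing = NULL) {
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0))
    stop("box must be three positive lengths", call. = FALSE)
  for (w in wells) {
    if (w$depth < 0) stop("well depths must be >= 0 (attractive)",
                          call. = FALSE)
    if (w$width <= 0) stop("well widths must be > 0", call. = FALSE)
    if (any(w$center < 0 | w$center > box))
      stop("well centers must lie inside the box", call. = FALSE)
  }
  if (!is.null(absorbing)) {
    if (absorbing$radius <= 0) stop("absorbing radius must be > 0",
                                    call. = FALSE)
    if (any(absorbing$center - absorbing$radius < 0 |
            absorbing$center + absorbing$radius > box))
      stop("absorbing sphere overlaps the box boundary", call. = FALSE)
  }
  structure(list(box = box, wells = wells, absorbing = absorbing),
            class = "potential_spec")
}

# minimum-image displacement r - c in a periodic box
min_image <- function(d, box) d - sweep(round(sweep(d, 2, box, "/")), 2,
                                        box, "*")

#' Evaluate a synthetic potential
#' @param potential a \code{potential_spec}.
#' @param xyz matrix (n x 3) of positions (Angstrom).
#' @return Energies (kcal/mol), length n.
#' @export
potential_energy <- function(potential, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  U <- numeric(nrow(xyz))
  for (w in potential$wells) {
    d <- min_image(sweep(xyz, 2, w$center), potential$box)
    U <- U - w$depth * exp(-rowSums(d^2) / (2 * w$width^2))
  }
  U
}

potential_gradient <- function(potential, xyz) {
  g <- matrix(0, nrow(xyz), 3)
  for (w in potential$wells) {
    d <- min_image(sweep(xyz, 2, w$center), potential$box)
    e <- (w$depth / w$width^2) * exp(-rowSums(d^2) / (2 * w$width^2))
    g <- g + d * e
  }
  g
}

#' Brownian-dynamics parameters
#'
#' @param D isotropic diffusion coefficient (Angstrom^2/ns); the default
#'   76 is of the order of a small-molecule aqueous diffusion coefficient.
#' @param dt timestep (ns); default 1e-3.
#' @param temperature K.
#' @param n_steps number of integration steps per walker.
#' @param save_interval save a frame every this many steps.
#' @param seed RNG seed; every generated trajectory is reproducible from
#'   (seed, parameters).
#' @param n_ligands number of independent walkers.
#' @return A \code{bd_params} object.
#' @export
bd_params <- function(D = 76, dt = 1e-3, temperature = 300,
                      n_steps = 1e5, save_interval = 120, seed = 1,
                      n_ligands = 1) {
  if (D <= 0 || dt <= 0 || n_steps < 1 || save_interval < 1)
    stop("invalid Brownian-dynamics parameters", call. = FALSE)
  structure(list(D = D, dt = dt, temperature = temperature,
                 n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 seed = as.integer(seed),
                 n_ligands = as.integer(n_ligands)),
            class = "bd_params")
}

#' Overdamped Langevin (Brownian-dynamics) simulation
#'
#' Euler-Maruyama integration of
#' \eqn{\Delta r = -(D/k_B T)\nabla U\,dt + \sqrt{2 D\,dt}\,\eta}
#' for independent point ligands over a \code{\link{potential_spec}},
#' with periodic wrapping.  Frames are saved every
#' \code{save_interval} steps for all walkers; each walker appears as a
#' single pseudo-atom of radius 1.7 Angstrom (the synthetic world's
#' stand-in for a heavy atom).
#'
#' @param potential a \code{potential_spec} (absorbing sphere ignored
#'   here; see \code{\link{bd_association}}).
#' @param params a \code{\link{bd_params}}.
#' @param start optional matrix (n_ligands x 3) of initial positions;
#'   default uniform random in the box.
#' @return A \code{ligand_trajectory} with
#'   \code{frame_interval = dt * save_interval}.
#' @export
bd_simulate <- function(potential, params, start = NULL) {
  stopifnot(inherits(potential, "potential_spec"),
            inherits(params, "bd_params"))
  if (length(potential$wells)) {
    wmin2 <- min(vapply(potential$wells, function(w) w$width^2, numeric(1)))
    if (params$D * params$dt > 0.1 * wmin2)
      stop("timestep too large: D*dt must be well below the smallest ",
           "well width^2", call. = FALSE)
  }
  set.seed(params$seed)
  box <- potential$box
  n <- params$n_ligands
  pos <- if (is.null(start))
    cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
          stats::runif(n, 0, box[3]))
  else matrix(start, ncol = 3)
  kBT <- KB_KCAL * params$temperature
  mob <- params$D / kBT * params$dt
  sig <- sqrt(2 * params$D * params$dt)
  nfr <- params$n_steps %/% params$save_interval
  out <- vector("list", nfr)
  fi <- 0L
  for (s in seq_len(params$n_steps)) {
    drift <- -mob * potential_gradient(potential, pos)
    step <- drift + sig * matrix(stats::rnorm(3 * n), n, 3)
    if (any(abs(step) > box / 2))
      stop("unstable step larger than half the box; reduce dt",
           call. = FALSE)
    pos <- pos + step
    pos <- pos - sweep(floor(sweep(pos, 2, box, "/")), 2, box, "*")
    if (s %% params$save_interval == 0L) {
      fi <- fi + 1L
      out[[fi]] <- data.frame(frame = fi, atom = 1L,
                              ligand = seq_len(n),
                              x = pos[, 1], y = pos[, 2], z = pos[, 3],
                              radius = 1.7)
    }
  }
  ligand_trajectory(do.call(rbind, out),
                    frame_interval = params$dt * params$save_interval)
}

#' Analytic reference PMF of a synthetic potential
#'
#' Evaluates the potential at the voxel centers of a grid and references
#' it to its minimum: exactly the free-energy map a point-particle
#' equilibrium density over this potential would Boltzmann-invert to.
#'
#' @param potential a \code{potential_spec}.
#' @param grid a \code{grid_spec} inside the box.
#' @param temperature K, recorded in the result.
#' @return A \code{pmf_grid}.
#' @export
truth_pmf <- function(potential, grid, temperature = 300) {
  ctr <- expand.grid(x = axis_centers(grid, 1), y = axis_centers(grid, 2),
                     z = axis_centers(grid, 3))
  U <- potential_energy(potential, as.matrix(ctr))
  # expand.grid varies x fastest, matching R array layout
  W <- array(U, dim = grid$shape)
  W <- W - min(W)
  structure(list(grid = grid, W = W, temperature = temperature),
            class = "pmf_grid")
}

# avogadro-derived conversion: molecules per Angstrom^3 of a 1 M solution
M_PER_A3 <- 6.02214076e-4

#' Smoluchowski diffusion-limited rate 4 pi D R
#' @param D diffusion coefficient (Angstrom^2/ns).
#' @param R absorbing radius (Angstrom).
#' @return Rate constant in M^-1 s^-1.
#' @export
smoluchowski_kon <- function(D, R) 4 * pi * D * R * 1e9 * M_PER_A3

#' Absorbing-sphere association run
#'
#' Runs independent diffusing ligands over the potential; whenever a
#' ligand enters the absorbing sphere a binding event is recorded and the
#' ligand is re-injected at a uniform random position at least
#' \code{bulk_cutoff} outside the sphere surface.  With no wells the run
#' is a direct sampling of the diffusion-limited association process and
#' the Smoluchowski closed form \code{4 pi D R} is the reference (note
#' the periodic images raise the measured rate above the infinite-dilution
#' value by roughly 2.84 R/L for box edge L, and the finite timestep
#' lowers it slightly).
#'
#' @param potential a \code{potential_spec} with an absorbing sphere.
#' @param params a \code{\link{bd_params}} (\code{n_steps} is the number
#'   of steps per ligand).
#' @param bulk_cutoff re-injection clearance from the sphere surface
#'   (Angstrom); default 8.
#' @return List with \code{events} (data.frame ligand, time_ns),
#'   \code{input} (a \code{\link{kon_input}}: one row per ligand, with
#'   total unabsorbed time as bulk time), \code{conc_M} (single-molecule
#'   concentration of the box), and \code{reference} (Smoluchowski
#'   4 pi D R in M^-1 s^-1, NA when wells are present).
#' @export
bd_association <- function(potential, params, bulk_cutoff = 8) {
  stopifnot(inherits(potential, "potential_spec"),
            inherits(params, "bd_params"))
  if (is.null(potential$absorbing))
    stop("potential has no absorbing sphere", call. = FALSE)
  set.seed(params$seed)
  box <- potential$box
  ctr <- potential$absorbing$center
  R <- potential$absorbing$radius
  if (R + bulk_cutoff > min(box) / 2)
    stop("box too small for the re-injection clearance", call. = FALSE)
  sig <- sqrt(2 * params$D * params$dt)
  kBT <- KB_KCAL * params$temperature
  mob <- params$D / kBT * params$dt
  free <- length(potential$wells) == 0
  inject <- function() {
    repeat {
      p <- stats::runif(3) * box
      d <- p - ctr
      d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) > R + bulk_cutoff) return(p)
    }
  }
  events <- list()
  chunk <- 1000L
  for (lig in seq_len(params$n_ligands)) {
    pos <- inject()
    left <- params$n_steps
    t0 <- 0
    while (left > 0L) {
      m <- min(chunk, left)
      if (free) {
        steps <- matrix(stats::rnorm(3 * m, sd = sig), m, 3)
        path <- sweep(apply(steps, 2, cumsum), 2, pos, "+")
        if (m == 1L) path <- matrix(path, 1, 3)
        d <- sweep(path, 2, ctr)
        d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
        hit <- which(rowSums(d^2) < R^2)
        if (length(hit)) {
          k <- hit[1]
          events[[length(events) + 1L]] <-
            data.frame(ligand = lig, time_ns = (t0 + k) * params$dt)
          t0 <- t0 + k
          left <- left - k
          pos <- inject()
        } else {
          pos <- path[m, ] %% box
          t0 <- t0 + m
          left <- left - m
        }
      } else {
        for (s in seq_len(m)) {
          g <- potential_gradient(potential, matrix(pos, 1, 3))
          pos <- pos + as.vector(-mob * g) + stats::rnorm(3, sd = sig)
          pos <- pos %% box
          t0 <- t0 + 1
          d <- pos - ctr
          d <- d - box * round(d / box)
          if (sum(d^2) < R^2) {
            events[[length(events) + 1L]] <-
              data.frame(ligand = lig, time_ns = t0 * params$dt)
            pos <- inject()
          }
        }
        left <- left - m
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events)
  else data.frame(ligand = integer(0), time_ns = numeric(0))
  V <- prod(box)
  conc <- 1 / (V * M_PER_A3)
  cnt <- tabulate(events$ligand, nbins = params$n_ligands)
  input <- kon_input(data.frame(
    system = sprintf("lig%03d", seq_len(params$n_ligands)),
    Nb = cnt,
    t_s = rep(params$n_steps * params$dt * 1e-9, params$n_ligands),
    conc_M = conc, subunits = 1L))
  list(events = events, input = input, conc_M = conc,
       reference = if (free) smoluchowski_kon(params$D, R) else NA_real_)
}

#' Noisy synthetic current trace with known kinetics
#'
#' Simulates a stimulation protocol with \code{\link{run_protocol}},
#' records the noiseless kinetic ground truths, then adds seeded Gaussian
#' noise of standard deviation \code{noise_sd} (as a fraction of the
#' trace peak).
#'
#' @param kind protocol, "long_pulse" or "brief_pulse".
#' @param rates a \code{rate_constants}.
#' @param f binding-rate factor.
#' @param exchange 10-90 exchange time (s).
#' @param noise_sd noise standard deviation as a fraction of peak.
#' @param seed RNG seed for the noise.
#' @param dt sampling interval (s).
#' @return List with \code{trace} (noisy \code{current_trace}) and
#'   \code{truth}: for long_pulse \code{t_rise} and \code{tau_desen}, for
#'   brief_pulse \code{tau_deact}, all measured on the noiseless trace.
#' @export
synth_current <- function(kind = c("long_pulse", "brief_pulse"),
                          rates = rate_constants(), f = 1,
                          exchange = 300e-6, noise_sd = 0.02, seed = 1,
                          dt = 1e-5) {
  kind <- match.arg(kind)
  clean <- run_protocol(kind, rates = rates, f = f, exchange = exchange,
                        dt = dt)
  md <- attr(clean, "metadata")
  truth <- if (kind == "long_pulse") {
    ipk <- which.max(clean$response)
    pulse_end <- md$onset + md$pulse_duration
    list(t_rise = rise_time_10_90(clean)$t_rise,
         tau_desen = fit_monoexp(clean, window = c(clean$time_s[ipk],
                                                   pulse_end))$tau)
  } else {
    list(tau_deact = deactivation_tau(clean))
  }
  set.seed(seed)
  noisy <- clean
  noisy$response <- clean$response +
    stats::rnorm(nrow(clean), sd = noise_sd * max(clean$response))
  list(trace = noisy, truth = truth)
}
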