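#' Integrate the master equation under a concentration profile
#'
#' Solves \code{dP/dt = Q([A](t)) P} for the per-state occupancy
#' probabilities of a gating scheme driven by a time-varying agonist
#' concentration.  Two integration paths are provided: a stiff ODE solver
#' (\code{deSolve::lsoda}; the generator's affine decomposition
#' \code{Q = Q0 + [A] Q1} keeps the right-hand side cheap) and a piecewise
#' matrix-exponential propagator that holds the concentration at its
#' interval midpoint between profile samples.  The exponential path is
#' exact for piecewise-constant concentration and serves as an
#' independent cross-check of the ODE path.
#'
#' @param scheme a \code{gating_scheme}.
#' @param profile a \code{concentration_profile} covering the requested
#'   time span.
#' @param initial initial state distribution (sums to 1); default is the
#'   equilibrium at the profile's starting concentration.
#' @param times output time grid (s); default the profile's own grid.
#' @param tol relative integration tolerance (ODE path).
#' @param method \code{"ode"} or \code{"expm"}.
#' @param expm_substeps number of matrix-exponential substeps per grid
#'   interval (expm path); raise to tighten the midpoint (2nd-order
#'   Magnus) error on smooth concentration edges.
#' @return An \code{occupancy_trajectory}: list with \code{times},
#'   \code{probabilities} (time x state matrix) and the scheme.
#' @export
integrate_master <- function(scheme, profile, initial = NULL, times = NULL,
                             tol = 1e-8, method = c("ode", "expm"),
                             expm_substeps = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(scheme, "gating_scheme"))
  pt <- profile[[1]]
  pc <- profile[[2]]
  if (is.null(times)) times <- pt
  if (min(times) < pt[1] - 1e-12 || max(times) > pt[length(pt)] + 1e-12)
    stop("profile does not cover the requested time span", call. = FALSE)
  if (is.null(initial))
    initial <- equilibrium_distribution(scheme, pc[1])
  labs <- state_labels(scheme)
  if (!is.null(names(initial))) initial <- initial[labs]
  if (length(initial) != length(labs) || abs(sum(initial) - 1) > 1e-6)
    stop("initial distribution must cover all states and sum to 1",
         call. = FALSE)
  qp <- generator_matrix(scheme, 0, parts = TRUE)

  if (method == "ode") {
    cfun <- stats::approxfun(pt, pc, rule = 2)
    deriv <- function(t, y, parms) {
      Q <- qp$Q0 + cfun(t) * qp$Q1
      list(as.vector(Q %*% y))
    }
    sol <- deSolve::lsoda(y = as.numeric(initial), times = times,
                          func = deriv, rtol = tol, atol = tol * 1e-4)
    if (attr(sol, "istate")[1] < 0)
      stop("master-equation integration failed to meet tolerance",
           call. = FALSE)
    P <- unname(sol[, -1, drop = FALSE])
  } else {
    # piecewise matrix exponential on the union of the profile and output
    # grids, with the interval-midpoint concentration (2nd-order Magnus)
    grid <- sort(unique(c(pt[pt >= min(times) & pt <= max(times)], times)))
    cfun <- stats::approxfun(pt, pc, rule = 2)
    P <- matrix(0, length(times), length(labs))
    p <- as.numeric(initial)
    iout <- 1L
    if (abs(grid[1] - times[1]) < 1e-15) { P[1, ] <- p; iout <- 2L }
    cache <- new.env(parent = emptyenv())
    m <- max(1L, as.integer(expm_substeps))
    for (k in seq_along(grid)[-1]) {
      dt <- (grid[k] - grid[k - 1]) / m
      for (sub in seq_len(m)) {
        cm <- cfun(grid[k - 1] + (sub - 0.5) * dt)
        key <- sprintf("%.12e_%.12e", dt, cm)
        Pm <- cache[[key]]
        if (is.null(Pm)) {
          Pm <- as.matrix(Matrix::expm((qp$Q0 + cm * qp$Q1) * dt))
          cache[[key]] <- Pm
        }
        p <- as.vector(Pm %*% p)
      }
      while (iout <= length(times) && grid[k] >= times[iout] - 1e-15) {
        P[iout, ] <- p
        iout <- iout + 1L
      }
    }
  }
  err <- max(abs(rowSums(P) - 1))
  if (err > 1e-6)
    stop(sprintf("probability conservation violated (max |sum-1| = %.2e)",
                 err), call. = FALSE)
  colnames(P) <- labs
  structure(list(times = times, probabilities = P, scheme = scheme),
            class = "occupancy_trajectory")
}

#' Normalized current from a state-occupancy trajectory
#'
#' The response is the conductance-weighted open probability divided by
#' the largest single-state conductance, so that a population entirely in
#' the high-conductance open state gives 1 ("normalized to the maximum
#' possible response").
#'
#' @param occ an \code{occupancy_trajectory}.
#' @return A \code{current_trace}: data.frame with \code{time_s},
#'   \code{response}.
#' @export
current_from_occupancy <- function(occ) {
  stopifnot(inherits(occ, "occupancy_trajectory"))
  g <- occ$scheme$states$conductance
  resp <- as.vector(occ$probabilities %*% g) / max(g)
  new_current_trace(occ$times, resp)
}

#' Construct a current trace from time and response vectors
#' @param times times (s).
#' @param response normalized current.
#' @param metadata optional metadata list.
#' @return A \code{current_trace} data.frame.
#' @export
current_trace <- function(times, response, metadata = list()) {
  new_current_trace(times, response, metadata)
}

new_current_trace <- function(times, response, metadata = list()) {
  structure(data.frame(time_s = times, response = response),
            metadata = metadata,
            class = c("current_trace", "data.frame"))
}

#' Read a current trace from a two-column TSV file
#' @param path file path (columns: time_s, response).
#' @return A \code{current_trace}.
#' @export
read_trace_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  new_current_trace(d[[1]], d[[2]])
}

#' Simulate a stimulation protocol
#'
#' Runs the master equation for one of the standard patch-clamp
#' protocols, starting from equilibrium at zero agonist (which includes
#' the small resting desensitized fraction set by the d0 rates):
#' \describe{
#'   \item{long_pulse}{a 200 ms pulse (default 10 mM) for activation rise
#'     time and desensitization;}
#'   \item{brief_pulse}{a 1 ms pulse for deactivation after washout;}
#'   \item{two_pulse}{a conditioning pulse followed by a test pulse at
#'     each requested interpulse interval; returns the test/conditioning
#'     peak-response fractions.}
#' }
#'
#' @param kind protocol name.
#' @param rates a \code{rate_constants} object.
#' @param f binding-rate factor applied via \code{\link{scale_binding}}.
#' @param peak pulse concentration (molar).
#' @param exchange 10--90\% solution-exchange time (s).
#' @param pulse_duration pulse FWHM (s); defaults depend on \code{kind}.
#' @param intervals two_pulse only: interpulse intervals (s), measured
#'   from the end of the conditioning pulse to the start of the test pulse.
#' @param dt output sampling interval (s); default 1e-4 (10 kHz) matches
#'   typical acquisition, but rise-time work needs finer sampling.
#' @param t_tail recording time after washout (s).
#' @return For \code{long_pulse}/\code{brief_pulse} a
#'   \code{current_trace}; for \code{two_pulse} a data.frame with
#'   \code{interval_s} and \code{fraction}.
#' @examples
#' tr <- run_protocol("brief_pulse", dt = 2e-5)
#' max(tr$response)
#' @export
run_protocol <- function(kind = c("long_pulse", "brief_pulse", "two_pulse"),
                         rates = rate_constants(), f = 1,
                         peak = 0.01, exchange = 300e-6,
                         pulse_duration = NULL,
                         intervals = NULL,
                         dt = 1e-4, t_tail = NULL) {
  kind <- match.arg(kind)
  r <- if (f != 1) scale_binding(rates, f) else rates
  scheme <- build_default_scheme(r)

  if (kind == "two_pulse") {
    if (is.null(intervals) || !length(intervals))
      stop("two_pulse needs interpulse intervals", call. = FALSE)
    if (any(intervals <= 2 * exchange))
      stop("interpulse interval too short: pulses overlap", call. = FALSE)
    cond_dur <- if (is.null(pulse_duration)) 0.2 else pulse_duration
    test_dur <- 0.01
    frac <- vapply(intervals, function(gap) {
      onset1 <- 1e-3
      onset2 <- onset1 + cond_dur + gap
      t_end <- onset2 + test_dur + 5e-3
      times <- seq(0, t_end, by = dt)
      s1 <- jump_spec(peak = peak, onset_time = onset1,
                      pulse_duration = cond_dur, exchange_10_90 = exchange,
                      sample_interval = min(dt, exchange / 8, 2.5e-5))
      s2 <- jump_spec(peak = peak, onset_time = onset2,
                      pulse_duration = test_dur, exchange_10_90 = exchange,
                      sample_interval = s1$sample_interval)
      grid <- seq(0, t_end, by = s1$sample_interval)
      conc <- make_jump(s1, times = grid)$conc_M +
        make_jump(s2, times = grid)$conc_M
      prof <- structure(data.frame(time_s = grid, conc_M = conc),
                        class = c("concentration_profile", "data.frame"))
      occ <- integrate_master(scheme, prof, times = times)
      tr <- current_from_occupancy(occ)
      pk1 <- max(tr$response[tr$time_s < onset2 - exchange])
      pk2 <- max(tr$response[tr$time_s >= onset2 - exchange])
      pk2 / pk1
    }, numeric(1))
    return(data.frame(interval_s = intervals, fraction = frac))
  }

  dur <- if (!is.null(pulse_duration)) pulse_duration
         else if (kind == "long_pulse") 0.2 else 1e-3
  if (is.null(t_tail)) t_tail <- if (kind == "long_pulse") 0.02 else 0.05
  onset <- 1e-3
  t_end <- onset + dur + t_tail
  spec <- jump_spec(peak = peak, onset_time = onset, pulse_duration = dur,
                    exchange_10_90 = exchange,
                    sample_interval = min(dt, exchange / 8, 2.5e-5))
  prof <- make_jump(spec, t_end = t_end)
  times <- seq(0, t_end, by = dt)
  occ <- integrate_master(scheme, prof, times = times)
  tr <- current_from_occupancy(occ)
  attr(tr, "metadata") <- list(protocol = kind, f = f, peak = peak,
                               exchange = exchange, pulse_duration = dur,
                               onset = onset)
  tr
}

#' Sweep the binding-rate factor and tabulate kinetics
#'
#' For each combination of binding-rate factor f and solution-exchange
#' time, simulates a long pulse to measure the 10--90\% activation rise
#' time and a brief (1 ms) pulse to measure the deactivation time
#' constant (monoexponential fit after washout).
#'
#' @param f_values binding-rate factors (default the standard sweep
#'   2, 1, 0.5, 0.2, 0.1, 0.05).
#' @param exchange_values 10--90\% exchange times (s).
#' @param rates base \code{rate_constants}.
#' @param peak pulse concentration (molar).
#' @param dt output sampling interval (s).
#' @return data.frame with columns f, exchange_s, t_rise_s, tau_deact_s
#'   and fit_ok, rows sorted by f descending within each exchange.
#' @export
f_sweep <- function(f_values = c(2, 1, 0.5, 0.2, 0.1, 0.05),
                    exchange_values = 300e-6,
                    rates = rate_constants(), peak = 0.01, dt = 5e-6) {
  if (!length(f_values) || !length(exchange_values))
    stop("need non-empty f and exchange grids", call. = FALSE)
  f_values <- sort(f_values, decreasing = TRUE)
  grid <- expand.grid(f = f_values, exchange_s = exchange_values,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    f <- grid$f[i]; ex <- grid$exchange_s[i]
    t_rise <- NA_real_; tau <- NA_real_; ok <- TRUE; msg <- ""
    tryCatch({
      long <- run_protocol("long_pulse", rates = rates, f = f, peak = peak,
                           exchange = ex, dt = dt, t_tail = 2e-3,
                           pulse_duration = 0.02)
      t_rise <- rise_time_10_90(long)$t_rise
      brief <- run_protocol("brief_pulse", rates = rates, f = f, peak = peak,
                            exchange = ex, dt = dt)
      tau <- deactivation_tau(brief)
    }, error = function(e) {
      ok <<- FALSE; msg <<- conditionMessage(e)
    })
    data.frame(f = f, exchange_s = ex, t_rise_s = t_rise, tau_deact_s = tau,
               fit_ok = ok, note = msg, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# deactivation time constant of a brief-pulse trace: monoexponential fit
# from the post-peak sample to the end of the recording
deactivation_tau <- function(trace) {
  ipk <- which.max(trace$response)
  fit <- fit_monoexp(trace, window = c(trace$time_s[ipk],
                                       trace$time_s[nrow(trace)]))
  fit$tau
}
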