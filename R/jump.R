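#' Specify a realistic agonist concentration jump
#'
#' Parameterizes the agonist waveform delivered by a fast perfusion
#' system: a pulse of given duration (full width at half maximum) whose
#' rising and falling edges have a stated 10--90\% solution-exchange
#' time.  Edges are complementary Gaussian-CDF ramps with
#' sigma = exchange_10_90 / 2.5631 (the 10--90 width of a normal CDF is
#' \code{qnorm(0.9) - qnorm(0.1) = 2.5631} sigma); a logistic edge is
#' available as an alternative since sub-10\% rise-time comparisons can
#' depend on the edge shape.
#'
#' @param peak peak concentration (molar).
#' @param baseline pre- and post-pulse concentration (molar).
#' @param onset_time time of the rising edge's half-maximum (s).
#' @param pulse_duration full width at half maximum of the pulse (s).
#' @param exchange_10_90 10--90\% rise time of each edge (s); 0 gives an
#'   ideal step.
#' @param sample_interval waveform sampling interval (s).
#' @param shape edge shape, \code{"gaussian"} (default) or \code{"logistic"}.
#' @return A \code{jump_spec} object.
#' @export
jump_spec <- function(peak = 0.01, baseline = 0,
                      onset_time = 1e-3, pulse_duration = 800e-6,
                      exchange_10_90 = 300e-6,
                      sample_interval = 5e-6,
                      shape = c("gaussian", "logistic")) {
  shape <- match.arg(shape)
  if (peak < baseline || baseline < 0)
    stop("need peak >= baseline >= 0", call. = FALSE)
  if (pulse_duration <= 0) stop("pulse_duration must be > 0", call. = FALSE)
  if (exchange_10_90 < 0) stop("exchange_10_90 must be >= 0", call. = FALSE)
  if (sample_interval <= 0) stop("sample_interval must be > 0", call. = FALSE)
  structure(list(peak = peak, baseline = baseline, onset_time = onset_time,
                 pulse_duration = pulse_duration,
                 exchange_10_90 = exchange_10_90,
                 sample_interval = sample_interval, shape = shape),
            class = "jump_spec")
}

# 10-90 width of the standard normal CDF, qnorm(.9) - qnorm(.1)
RISE_1090_SIGMA <- 2.5631031310892007

# unit edge rising from 0 to 1 with half-maximum at t = 0 and
# a 10-90 width of `exchange`
jump_edge <- function(t, exchange, shape) {
  if (exchange <= 0) return(as.numeric(t >= 0))
  if (shape == "gaussian") {
    stats::pnorm(t / (exchange / RISE_1090_SIGMA))
  } else {
    stats::plogis(t / (exchange / (2 * log(9))))
  }
}

#' Evaluate a jump waveform on a time grid
#'
#' @param spec a \code{\link{jump_spec}}.
#' @param times optional time grid (s); by default a grid at the spec's
#'   sampling interval covering the pulse plus generous margins.
#' @param t_end optional end of the default grid (s).
#' @return A \code{concentration_profile}: data.frame with columns
#'   \code{time_s} and \code{conc_M}, carrying the spec as an attribute.
#' @examples
#' prof <- make_jump(jump_spec())
#' measure_exchange(prof)  # ~300e-6
#' @export
make_jump <- function(spec, times = NULL, t_end = NULL) {
  stopifnot(inherits(spec, "jump_spec"))
  margin <- 4 * spec$exchange_10_90
  if (is.null(times)) {
    if (is.null(t_end))
      t_end <- spec$onset_time + spec$pulse_duration + margin + 2e-3
    times <- seq(0, t_end, by = spec$sample_interval)
  }
  if (spec$exchange_10_90 > 0 &&
      spec$sample_interval >= spec$exchange_10_90 / 5)
    warning("sample_interval too coarse to resolve the solution exchange",
            call. = FALSE)
  t_off <- spec$onset_time + spec$pulse_duration
  up <- jump_edge(times - spec$onset_time, spec$exchange_10_90, spec$shape)
  dn <- jump_edge(times - t_off, spec$exchange_10_90, spec$shape)
  conc <- spec$baseline + (spec$peak - spec$baseline) * (up - dn)
  structure(data.frame(time_s = times, conc_M = pmax(conc, 0)),
            spec = spec, class = c("concentration_profile", "data.frame"))
}

#' Constant-concentration profile
#' @param concentration molar.
#' @param t_end end time (s).
#' @param sample_interval grid spacing (s).
#' @return A \code{concentration_profile}.
#' @export
constant_profile <- function(concentration, t_end, sample_interval = 1e-5) {
  times <- seq(0, t_end, by = sample_interval)
  structure(data.frame(time_s = times, conc_M = rep(concentration,
                                                    length(times))),
            spec = NULL, class = c("concentration_profile", "data.frame"))
}

#' Measure the 10--90\% rise time of a concentration profile
#'
#' Locates the rising edge and linearly interpolates the times at which
#' the waveform crosses 10\% and 90\% of (peak - baseline).
#'
#' @param profile a \code{concentration_profile} (or any data.frame with
#'   time and value in the first two columns).
#' @return 10--90\% rise time (s).
#' @export
measure_exchange <- function(profile) {
  t <- profile[[1]]
  y <- profile[[2]]
  ipk <- which.max(y)
  if (ipk == 1) stop("profile has no rising edge", call. = FALSE)
  base <- y[1]
  amp <- y[ipk] - base
  if (amp <= 0) stop("profile has no rising edge", call. = FALSE)
  rise_t <- t[1:ipk]
  rise_y <- y[1:ipk]
  cross <- function(frac) {
    lev <- base + frac * amp
    i <- which(rise_y >= lev)[1]
    if (i == 1) return(rise_t[1])
    t0 <- rise_t[i - 1]; t1 <- rise_t[i]
    y0 <- rise_y[i - 1]; y1 <- rise_y[i]
    if (y1 == y0) return(t1)
    t0 + (lev - y0) / (y1 - y0) * (t1 - t0)
  }
  t10 <- cross(0.10)
  t90 <- cross(0.90)
  # guard against a non-monotonic edge (beyond interpolation jitter)
  seg <- rise_y[rise_t >= t10 & rise_t <= t90]
  if (length(seg) > 2 && any(diff(seg) < -0.02 * amp))
    stop("rising edge is not monotonic", call. = FALSE)
  t90 - t10
}

#' Write / read concentration profiles and current traces as TSV
#'
#' Two-column tab-separated files: time in seconds, then concentration
#' (molar) or normalized response.
#'
#' @param x a \code{concentration_profile} or \code{current_trace}.
#' @param path file path.
#' @return Readers return the corresponding object; writers return
#'   \code{path} invisibly.
#' @export
write_profile_tsv <- function(x, path) {
  utils::write.table(data.frame(time_s = x[[1]], value = x[[2]]), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(data.frame(time_s = d[[1]], conc_M = d[[2]]),
            class = c("concentration_profile", "data.frame"))
}
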