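#' 10--90\% rise time by sigmoid interpolation
#'
#' Fits a monotone sigmoid from the baseline to the peak of a current
#' trace and interpolates the times at which the fitted curve crosses
#' 10\% and 90\% of the baseline-to-peak amplitude.  The sigmoid is a
#' Richards (generalized logistic) curve,
#' \deqn{y = base + amp (1 + \nu e^{-(t-t_{50})/k})^{-1/\nu},}
#' whose shape parameter \eqn{\nu} nests the symmetric logistic
#' (\eqn{\nu = 1}) and the saturating exponential \eqn{1 - e^{-t/\tau}}
#' (\eqn{\nu = -1}), so both channel-like sigmoidal onsets and
#' first-order relaxations are fitted without bias.  Crossing times are
#' computed from the fitted curve, not from raw samples.
#'
#' @param trace a \code{current_trace} (columns time, response).
#' @param baseline_end optional end of the pre-pulse baseline window (s);
#'   default: everything before the last 1\%-amplitude crossing that
#'   precedes the peak.
#' @return A \code{rise_time_result}: list with \code{t10}, \code{t90},
#'   \code{t_rise}, the fitted \code{pars} (base, amp, t50, k, nu) and
#'   the root-mean-square \code{residual}.
#' @export
rise_time_10_90 <- function(trace, baseline_end = NULL) {
  t <- trace[[1]]; y <- trace[[2]]
  ipk <- which.max(y)
  if (ipk < 4) stop("trace has no rising phase", call. = FALSE)
  t <- t[1:ipk]; y <- y[1:ipk]
  base0 <- stats::median(y[1:3])
  amp0 <- y[ipk] - base0
  # point-noise estimate from first differences (robust to the trend)
  noise <- stats::mad(diff(y)) / sqrt(2)
  if (amp0 <= 5 * max(noise, .Machine$double.eps))
    stop("no peak above baseline + 5x noise", call. = FALSE)

  # raw crossings for starting values
  raw_cross <- function(frac) {
    lev <- base0 + frac * amp0
    i <- which(y >= lev)[1]
    if (i == 1) return(t[1])
    t[i - 1] + (lev - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  }
  t10r <- raw_cross(0.1); t50r <- raw_cross(0.5); t90r <- raw_cross(0.9)
  k0 <- max((t90r - t10r) / (2 * log(9)), diff(range(t)) * 1e-4)

  richards <- function(t, base, amp, t50, k, nu) {
    z <- exp(-(t - t50) / k)
    if (abs(nu) < 1e-8) return(base + amp * exp(-z))     # Gompertz limit
    u <- 1 + nu * z
    # nu < 0: u^(-1/nu) -> 0 as u -> 0+, so clip the u <= 0 branch to the
    # baseline; this makes nu = -1 reproduce a flat start followed by
    # 1 - exp(-t/tau) exactly
    base + amp * ifelse(u > 0, u^(-1 / nu), 0)
  }
  fit1 <- function(nu0) {
    minpack.lm::nlsLM(
      y ~ richards(t, base, amp, t50, k, nu),
      start = list(base = base0, amp = amp0, t50 = t50r, k = k0, nu = nu0),
      lower = c(-Inf, 0, -Inf, k0 * 1e-3, -5),
      upper = c(Inf, Inf, Inf, Inf, 50),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- NULL
  for (nu0 in c(1, -1, -0.5, 0.2, 5)) {
    f <- tryCatch(fit1(nu0), error = function(e) NULL)
    if (!is.null(f) &&
        (is.null(fit) || stats::deviance(f) < stats::deviance(fit)))
      fit <- f
  }
  if (is.null(fit)) stop("sigmoid fit did not converge", call. = FALSE)
  p <- as.list(stats::coef(fit))

  # closed-form crossing of the fitted curve at fraction `frac` of amp
  crossing <- function(frac) {
    if (abs(p$nu) < 1e-8) {
      z <- -log(frac)
    } else {
      z <- (frac^(-p$nu) - 1) / p$nu
      if (z <= 0) return(NA_real_)
    }
    p$t50 - p$k * log(z)
  }
  t10 <- crossing(0.1); t90 <- crossing(0.9)
  if (!is.finite(t10) || !is.finite(t90) || t90 <= t10)
    stop("fitted sigmoid has no valid 10/90 crossings", call. = FALSE)
  structure(list(t10 = t10, t90 = t90, t_rise = t90 - t10,
                 pars = unlist(p),
                 residual = sqrt(mean(stats::residuals(fit)^2))),
            class = "rise_time_result")
}

#' Monoexponential decay fit
#'
#' Least-squares fit of \eqn{A e^{-t/\tau} + C} over a window of a
#' current trace, used for both deactivation (after agonist washout) and
#' desensitization (after the peak during sustained agonist).
#'
#' @param trace a \code{current_trace}.
#' @param window numeric length-2: start and end times (s) of the fit
#'   window; default the post-peak sample to the end of the trace.
#' @return An \code{exp_fit_result}: list with \code{tau} (s),
#'   \code{amplitude}, \code{offset}, \code{window}, \code{residual}.
#' @export
fit_monoexp <- function(trace, window = NULL) {
  t <- trace[[1]]; y <- trace[[2]]
  if (is.null(window)) {
    ipk <- which.max(y)
    window <- c(t[ipk], t[length(t)])
  }
  sel <- t >= window[1] & t <= window[2]
  if (sum(sel) < 4) stop("fit window contains too few samples", call. = FALSE)
  tw <- t[sel] - window[1]
  yw <- y[sel]
  if (yw[length(yw)] >= yw[1])
    stop("window is not a decaying segment", call. = FALSE)
  C0 <- min(yw)
  A0 <- yw[1] - C0
  # crude tau from the 1/e point
  ie <- which(yw - C0 <= A0 / exp(1))[1]
  tau0 <- if (!is.na(ie) && ie > 1) tw[ie] else diff(range(tw)) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(yw ~ A * exp(-tw / tau) + C,
                      start = list(A = A0, tau = tau0, C = C0),
                      lower = c(0, tau0 * 1e-4, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("monoexponential fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  p <- stats::coef(fit)
  structure(list(tau = unname(p["tau"]), amplitude = unname(p["A"]),
                 offset = unname(p["C"]), window = window,
                 residual = sqrt(mean(stats::residuals(fit)^2))),
            class = "exp_fit_result")
}

#' Effective decay constant from a 90--10\% decay time
#'
#' Back-calculates the time constant of a single-exponential decay from
#' its 90\%-to-10\% time: \eqn{\tau = \Delta t / \ln 9}.
#'
#' @param delta_t 90--10\% decay time (s), > 0.
#' @return Effective time constant (s).
#' @examples
#' effective_tau_from_90_10(log(9) * 1e-3)  # 1 ms
#' @export
effective_tau_from_90_10 <- function(delta_t) {
  if (any(!is.finite(delta_t)) || any(delta_t <= 0))
    stop("delta_t must be > 0", call. = FALSE)
  delta_t / log(9)
}

#' Hill fit of a concentration--response curve
#'
#' Nonlinear least-squares fit of
#' \eqn{I/I_{max} = [A]^n / ([A]^n + EC_{50}^n)}.
#'
#' @param concentrations agonist concentrations (molar), >= 3 distinct.
#' @param responses peak responses at each concentration.
#' @return A \code{hill_fit_result}: list with \code{EC50} (molar),
#'   \code{n}, \code{Imax}, standard errors \code{se}, the fitted curve
#'   function \code{predict}, and \code{flagged} if the EC50 left the
#'   tested range by more than 100-fold.
#' @export
fit_hill <- function(concentrations, responses) {
  if (length(unique(concentrations)) < 3)
    stop("need at least 3 distinct concentrations", call. = FALSE)
  x <- concentrations; y <- responses
  Imax0 <- max(y)
  half <- Imax0 / 2
  ec0 <- exp(stats::approx(y, log(x), xout = half, ties = mean)$y)
  if (!is.finite(ec0)) ec0 <- exp(mean(log(range(x[x > 0]))))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Imax * x^n / (x^n + EC50^n),
                      start = list(Imax = Imax0, n = 1.2, EC50 = ec0),
                      lower = c(0, 0.05, min(x[x > 0]) * 1e-4),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("Hill fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  p <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  flagged <- p["EC50"] < min(x[x > 0]) * 0.01 || p["EC50"] > max(x) * 100
  structure(list(EC50 = unname(p["EC50"]), n = unname(p["n"]),
                 Imax = unname(p["Imax"]), se = se, flagged = flagged,
                 predict = function(conc)
                   unname(p["Imax"] * conc^p["n"] /
                            (conc^p["n"] + p["EC50"]^p["n"]))),
            class = "hill_fit_result")
}

#' Hodgkin-Huxley-type fit of recovery from desensitization
#'
#' Fits \eqn{N(t) = N_0 + (1 - N_0)(1 - e^{-k_{rec} t})^n} to
#' test/conditioning peak-response fractions from a two-pulse protocol,
#' where \eqn{N_0} is the active fraction at the end of the conditioning
#' pulse and \eqn{k_{rec}} the recovery rate.
#'
#' @param intervals interpulse intervals (s), >= 4 points.
#' @param fractions recovered peak-response fractions.
#' @return A \code{recovery_fit_result}: list with \code{N0},
#'   \code{k_rec} (s^-1), \code{n}, standard errors \code{se},
#'   \code{predict}, and \code{degenerate} if there is no recovery signal.
#' @export
fit_recovery <- function(intervals, fractions) {
  if (length(intervals) < 4)
    stop("need at least 4 interval points", call. = FALSE)
  if (diff(range(fractions)) < 1e-3)
    return(structure(list(N0 = mean(fractions), k_rec = NA_real_,
                          n = NA_real_, se = NULL, degenerate = TRUE,
                          predict = function(t) rep(mean(fractions),
                                                    length(t))),
                     class = "recovery_fit_result"))
  t <- intervals; y <- fractions
  N00 <- max(min(y), 0)
  thalf <- stats::approx(y, t, xout = (N00 + 1) / 2, ties = mean)$y
  k0 <- if (is.finite(thalf) && thalf > 0) log(2) / thalf else 1 / mean(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ N0 + (1 - N0) * (1 - exp(-k_rec * t))^n,
                      start = list(N0 = N00, k_rec = k0, n = 2),
                      lower = c(0, 1e-12, 1), upper = c(1, Inf, 20),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("recovery fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  p <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(N0 = unname(p["N0"]), k_rec = unname(p["k_rec"]),
                 n = unname(p["n"]), se = se, degenerate = FALSE,
                 predict = function(t)
                   unname(p["N0"] + (1 - p["N0"]) *
                            (1 - exp(-p["k_rec"] * t))^p["n"])),
            class = "recovery_fit_result")
}

#' Errors-in-variables straight-line fit (York regression)
#'
#' Orthogonal-distance fit of \eqn{y = a + b x} to points with known
#' standard errors on both axes, minimizing
#' \eqn{\sum_i [(\Delta x_i/\sigma_{x,i})^2 + (\Delta y_i/\sigma_{y,i})^2]}.
#' Uses the exact iterative solution of York (unified least-squares
#' line), which reduces to ordinary least squares when the x-errors
#' vanish and all y-errors are equal.
#'
#' @param x,y coordinates (e.g. activation rise time and deactivation
#'   time constant, same units).
#' @param sx,sy per-point standard errors, > 0 (scalars are recycled).
#' @return An \code{eiv_line_fit}: list with \code{slope},
#'   \code{intercept}, their standard errors, \code{chisq_red} (reduced
#'   chi-square), \code{cov} (2x2 parameter covariance) and
#'   \code{conf_band(xnew, level)} giving the confidence band of the
#'   fitted line.
#' @examples
#' f <- fit_line_eiv(0:2, c(0, 8, 16), sx = 0.1, sy = 0.1)
#' f$slope
#' @export
fit_line_eiv <- function(x, y, sx, sy) {
  n <- length(x)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  sx <- rep_len(sx, n); sy <- rep_len(sy, n)
  if (any(sx <= 0) || any(sy <= 0))
    stop("uncertainties must be > 0", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("degenerate geometry: all x equal", call. = FALSE)
  wx <- 1 / sx^2; wy <- 1 / sy^2
  b <- stats::coef(stats::lm(y ~ x))[2]   # OLS start
  for (it in 1:200) {
    W <- wx * wy / (wx + b^2 * wy)
    xbar <- sum(W * x) / sum(W)
    ybar <- sum(W * y) / sum(W)
    U <- x - xbar; V <- y - ybar
    beta <- W * (U / wy + b * V / wx)
    b_new <- sum(W * beta * V) / sum(W * beta * U)
    if (!is.finite(b_new)) stop("York iteration diverged", call. = FALSE)
    if (abs(b_new - b) < 1e-14 * max(1, abs(b))) { b <- b_new; break }
    b <- b_new
  }
  W <- wx * wy / (wx + b^2 * wy)
  xbar <- sum(W * x) / sum(W)
  ybar <- sum(W * y) / sum(W)
  a <- ybar - b * xbar
  U <- x - xbar; V <- y - ybar
  beta <- W * (U / wy + b * V / wx)
  # adjusted points and parameter uncertainties (York 2004 recipe)
  xa <- xbar + beta
  xabar <- sum(W * xa) / sum(W)
  u <- xa - xabar
  sb2 <- 1 / sum(W * u^2)
  sa2 <- 1 / sum(W) + xabar^2 * sb2
  cov_ab <- -xabar * sb2
  S <- sum(W * (y - b * x - a)^2)
  chisq_red <- if (n > 2) S / (n - 2) else 0
  structure(list(
    slope = unname(b), intercept = unname(a),
    slope_se = sqrt(sb2), intercept_se = sqrt(sa2),
    chisq_red = chisq_red, n = n,
    cov = matrix(c(sa2, cov_ab, cov_ab, sb2), 2, 2,
                 dimnames = list(c("intercept", "slope"),
                                 c("intercept", "slope"))),
    conf_band = function(xnew, level = 0.95) {
      tq <- stats::qt(1 - (1 - level) / 2, df = n - 2)
      se <- sqrt(sa2 + 2 * cov_ab * xnew + sb2 * xnew^2)
      data.frame(x = xnew, fit = a + b * xnew,
                 lower = a + b * xnew - tq * se,
                 upper = a + b * xnew + tq * se)
    }),
    class = "eiv_line_fit")
}

#' @export
print.eiv_line_fit <- function(x, ...) {
  cat(sprintf("EIV line fit: slope %.4g +/- %.2g, intercept %.4g +/- %.2g, reduced chi-square %.3g (n = %d)\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se,
              x$chisq_red, x$n))
  invisible(x)
}
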