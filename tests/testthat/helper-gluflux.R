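# shared fixtures built in code

default_rates <- function() rate_constants()

# raw linear-interpolation 10-90 rise time of a trace (independent of the
# sigmoid-fit path; used as a cross-check oracle)
raw_rise_1090 <- function(trace) {
  t <- trace[[1]]; y <- trace[[2]]
  ipk <- which.max(y)
  base <- y[1]; amp <- y[ipk] - base
  cross <- function(frac) {
    lev <- base + frac * amp
    i <- which(y[1:ipk] >= lev)[1]
    t[i - 1] + (lev - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  }
  cross(0.9) - cross(0.1)
}

# two-state C <-> O toy scheme with rates beta (open) / alpha (close)
toy_two_state <- function(rates = rate_constants()) {
  st <- data.frame(label = c("C", "O"), occupancy = 0L,
                   klass = c("closed", "open"), conductance = c(0, 1))
  tr <- data.frame(from = c("C", "O"), to = c("O", "C"),
                   base_rate = c("beta", "alpha"), multiplicity = 1L,
                   conc_order = 0L, f_scaled = FALSE)
  gating_scheme(st, tr, rates)
}

# small two-well synthetic landscape shared by PMF recovery tests
two_well_potential <- function() {
  potential_spec(box = c(40, 24, 24),
                 wells = list(list(center = c(12, 12, 12), depth = 2.5,
                                   width = 5),
                              list(center = c(28, 12, 12), depth = 1.5,
                                   width = 5)))
}
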