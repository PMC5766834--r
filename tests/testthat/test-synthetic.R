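test_that("generators are reproducible from the seed", {
  pot <- potential_spec(box = c(50, 50, 50),
                        wells = list(list(center = c(25, 25, 25),
                                          depth = 2, width = 3)))
  par <- bd_params(n_steps = 500, save_interval = 10, seed = 7,
                   n_ligands = 3)
  t1 <- bd_simulate(pot, par)
  t2 <- bd_simulate(pot, par)
  expect_identical(t1$coords, t2$coords)
  par2 <- par; par2$seed <- 8L
  t3 <- bd_simulate(pot, par2)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("free diffusion reproduces the Einstein relation", {
  pot <- potential_spec(box = c(1e4, 1e4, 1e4))
  par <- bd_params(D = 76, dt = 1e-3, n_steps = 1e4, save_interval = 10,
                   seed = 42, n_ligands = 20)
  tr <- bd_simulate(pot, par, start = matrix(5000, 20, 3))
  co <- tr$coords
  msd <- mean(vapply(split(co, co$ligand), function(d) {
    d <- d[order(d$frame), ]
    mean(diff(d$x)^2 + diff(d$y)^2 + diff(d$z)^2)
  }, numeric(1)))
  expect_equal(msd, 6 * 76 * 1e-2, tolerance = 0.05)
})

test_that("a stiff Gaussian well matches its Boltzmann positional
           variance", {
  # depth/width^2 = 1 kcal/mol/A^2 near the bottom: harmonic equipartition
  # gives kBT/k = 0.596 A^2 per axis; the Gaussian well is slightly softer
  # than harmonic, so the exact Boltzmann variance (radial quadrature
  # oracle) is a little larger
  depth <- 25; width <- 5; kBT <- 1.9872e-3 * 300
  pot <- potential_spec(box = c(60, 60, 60),
                        wells = list(list(center = c(30, 30, 30),
                                          depth = depth, width = width)))
  wfun <- function(r) r^2 * exp(depth * exp(-r^2 / (2 * width^2)) / kBT)
  norm <- stats::integrate(wfun, 0, 10)$value
  vref <- stats::integrate(function(r) r^2 * wfun(r), 0, 10)$value /
    norm / 3
  expect_equal(vref, 0.596, tolerance = 0.25)   # near the harmonic value
  par <- bd_params(D = 76, dt = 1e-3, n_steps = 2e4, save_interval = 5,
                   seed = 9, n_ligands = 5)
  tr <- bd_simulate(pot, par, start = matrix(30, 5, 3))
  co <- tr$coords
  v <- mean(c(var(co$x), var(co$y), var(co$z)))
  expect_equal(v, vref, tolerance = 0.1)
})

test_that("two-well occupancy densities follow the Boltzmann ratio", {
  pot <- two_well_potential()         # referenced depth difference 1
  par <- bd_params(D = 76, dt = 1e-3, n_steps = 6e4, save_interval = 30,
                   seed = 101, n_ligands = 10)
  traj <- bd_simulate(pot, par)
  pos <- as.matrix(traj$coords[, c("x", "y", "z")])
  # compare point densities near the two minima (within 1.5 A)
  nA <- sum(sqrt(rowSums(sweep(pos, 2, c(12, 12, 12))^2)) <= 1.5)
  nB <- sum(sqrt(rowSums(sweep(pos, 2, c(28, 12, 12))^2)) <= 1.5)
  ratio <- nB / nA
  expect_equal(ratio, exp(-1 / (1.9872e-3 * 300)), tolerance = 0.25)
})

test_that("timestep stability guards trigger", {
  pot <- potential_spec(box = c(20, 20, 20),
                        wells = list(list(center = c(10, 10, 10),
                                          depth = 2, width = 0.5)))
  expect_error(bd_simulate(pot, bd_params(n_steps = 10)), "timestep")
})

test_that("analytic truth PMF matches Boltzmann inversion exactly", {
  g <- grid_spec(c(5, 5, 5), 1, c(10, 10, 10))
  # zero potential: flat zero grid
  flat <- truth_pmf(potential_spec(box = c(20, 20, 20)), g)
  expect_true(all(flat$W == 0))
  # single well centred on a voxel center: zero there, +depth far away
  pot <- potential_spec(box = c(20, 20, 20),
                        wells = list(list(center = c(9.5, 9.5, 9.5),
                                          depth = 3, width = 1.5)))
  tp <- truth_pmf(pot, g)
  expect_equal(min(tp$W), 0)
  expect_equal(tp$W[5, 5, 5], 0)               # voxel at the well bottom
  expect_equal(tp$W[1, 1, 1], 3, tolerance = 1e-3)
  # numerical inversion of the analytic density exp(-U/kBT)
  ctr <- as.matrix(expand.grid(x = 5 + (1:10) - 0.5, y = 5 + (1:10) - 0.5,
                               z = 5 + (1:10) - 0.5))
  rho <- exp(-potential_energy(pot, ctr) / (1.9872e-3 * 300))
  dens <- structure(list(grid = g, counts = array(rho, dim = g$shape),
                         frames = 1, atoms_outside = 0L),
                    class = "density_grid")
  expect_lt(max(abs(boltzmann_invert(dens, 300)$W - tp$W)), 1e-10)
})

test_that("absorbing-sphere runs count events and expose the reference", {
  pot <- potential_spec(box = c(60, 60, 60),
                        absorbing = list(center = c(30, 30, 30),
                                         radius = 5))
  par <- bd_params(D = 76, dt = 1e-3, n_steps = 2e5, seed = 3,
                   n_ligands = 4)
  res <- bd_association(pot, par)
  expect_gt(nrow(res$events), 5)
  expect_s3_class(res$input, "kon_input")
  expect_equal(sum(res$input$Nb), nrow(res$events))
  expect_equal(res$reference, 4 * pi * 76 * 5 * 1e9 * 6.02214076e-4)
  expect_equal(res$conc_M, 1 / (60^3 * 6.02214076e-4))
  # an attractive well around the sphere funnels ligands: more events
  pot_w <- potential_spec(box = c(60, 60, 60),
                          wells = list(list(center = c(30, 30, 30),
                                            depth = 2, width = 8)),
                          absorbing = list(center = c(30, 30, 30),
                                           radius = 5))
  res_w <- bd_association(pot_w, par)
  expect_gt(estimate_kon(res_w$input), estimate_kon(res$input))
  # errors: sphere at the boundary, missing sphere
  expect_error(potential_spec(box = c(20, 20, 20),
                              absorbing = list(center = c(2, 10, 10),
                                               radius = 5)),
               "overlaps")
  expect_error(bd_association(potential_spec(box = c(20, 20, 20)), par),
               "absorbing")
})

test_that("synthetic traces carry their noiseless kinetic truth", {
  s0 <- synth_current("brief_pulse", noise_sd = 0, seed = 5, dt = 2e-5)
  clean <- run_protocol("brief_pulse", dt = 2e-5)
  expect_equal(s0$trace$response, clean$response)
  s1 <- synth_current("brief_pulse", noise_sd = 0.02, seed = 5, dt = 2e-5)
  s2 <- synth_current("brief_pulse", noise_sd = 0.02, seed = 6, dt = 2e-5)
  expect_false(identical(s1$trace$response, s2$trace$response))
  expect_identical(s1$truth, s2$truth)
  # fitted deactivation on the noisy trace within 5% of the truth
  ipk <- which.max(s1$trace$response)
  fit <- fit_monoexp(s1$trace, window = c(s1$trace$time_s[ipk],
                                          max(s1$trace$time_s)))
  expect_equal(fit$tau, s1$truth$tau_deact, tolerance = 0.05)
})
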