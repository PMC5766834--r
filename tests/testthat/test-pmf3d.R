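make_rigid_traj <- function(xyz_prot, xyz_lig, transform = identity) {
  nfr <- 2L
  prot <- do.call(rbind, lapply(seq_len(nfr), function(fr) {
    P <- transform(xyz_prot)
    data.frame(frame = fr, atom = seq_len(nrow(P)),
               x = P[, 1], y = P[, 2], z = P[, 3])
  }))
  lig <- do.call(rbind, lapply(seq_len(nfr), function(fr) {
    L <- transform(xyz_lig)
    data.frame(frame = fr, atom = 1L, ligand = 1L,
               x = L[, 1], y = L[, 2], z = L[, 3], radius = 1.7)
  }))
  ligand_trajectory(lig, frame_interval = 0.12, protein = prot)
}

test_that("frame alignment removes rigid-body motion", {
  set.seed(21)
  ref <- matrix(rnorm(30, sd = 5), 10, 3)
  lig <- matrix(c(3, 4, 5), 1, 3)
  # already aligned: idempotent
  tr <- make_rigid_traj(ref, lig)
  al <- align_frames(tr, ref, 1:10)
  expect_lt(max(abs(as.matrix(al$coords[, c("x", "y", "z")]) -
                      lig[rep(1, 2), ])), 1e-8)
  # pure translation is removed
  tr2 <- make_rigid_traj(ref, lig, function(X) sweep(X, 2, c(5, 5, 5), "+"))
  al2 <- align_frames(tr2, ref, 1:10)
  expect_lt(max(abs(as.matrix(al2$coords[, c("x", "y", "z")]) -
                      lig[rep(1, 2), ])), 1e-8)
  # random rotation: RMSD to reference after alignment is numerically zero
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr3 <- make_rigid_traj(ref, lig, function(X) X %*% R + 2)
  al3 <- align_frames(tr3, ref, 1:10)
  prot_al <- as.matrix(al3$protein[al3$protein$frame == 1, c("x", "y", "z")])
  expect_lt(sqrt(mean((prot_al - ref)^2)), 1e-6)
  expect_lt(max(abs(as.matrix(al3$coords[, c("x", "y", "z")]) -
                      lig[rep(1, 2), ])), 1e-6)
  expect_error(align_frames(tr3, ref, 1:11), "missing|n_selection")
})

test_that("alignment agrees with the bio3d superposition", {
  skip_if_not_installed("bio3d")
  set.seed(22)
  ref <- matrix(rnorm(24, sd = 4), 8, 3)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  mob <- ref %*% R + 3
  tr <- make_rigid_traj(ref, matrix(c(1, 2, 3), 1, 3),
                        function(X) if (nrow(X) == 8) mob else X %*% R + 3)
  al <- align_frames(tr, ref, 1:8)
  fit <- bio3d::fit.xyz(fixed = as.vector(t(ref)),
                        mobile = as.vector(t(mob)),
                        fixed.inds = 1:24, mobile.inds = 1:24)
  ours <- as.matrix(al$protein[al$protein$frame == 1, c("x", "y", "z")])
  expect_lt(max(abs(ours - matrix(fit, ncol = 3, byrow = TRUE))), 1e-6)
})

test_that("hard-sphere binning matches brute-force voxel scans", {
  g <- grid_spec(c(5, 5, 5), 0.5, c(20, 20, 20))
  ctrs <- as.matrix(expand.grid(x = 5 + (1:20 - 0.5) * 0.5,
                                y = 5 + (1:20 - 0.5) * 0.5,
                                z = 5 + (1:20 - 0.5) * 0.5))
  brute <- function(p, r) rowSums(sweep(ctrs, 2, p)^2) <= r^2
  # one atom of radius 1.7 at a voxel center
  t1 <- ligand_trajectory(data.frame(frame = 1, atom = 1, x = 10.25,
                                     y = 10.25, z = 10.25, radius = 1.7))
  d1 <- bin_density(t1, g)
  expect_equal(as.vector(d1$counts) == 1,
               unname(brute(c(10.25, 10.25, 10.25), 1.7)))
  # two identical frames double every count
  t2 <- t1; t2$coords <- rbind(t1$coords,
                               transform(t1$coords, frame = 2))
  expect_equal(bin_density(t2, g)$counts, 2 * d1$counts)
  # two frames with the atom displaced 1 A: overlap 2, symmetric diff 1
  t3 <- t1
  t3$coords <- rbind(t1$coords, transform(t1$coords, frame = 2, x = 11.25))
  d3 <- bin_density(t3, g)
  occ1 <- brute(c(10.25, 10.25, 10.25), 1.7)
  occ2 <- brute(c(11.25, 10.25, 10.25), 1.7)
  expect_equal(as.vector(d3$counts), unname(occ1 + occ2))
  # several atoms covering a voxel in the same frame count once
  t4 <- t1
  t4$coords <- rbind(t1$coords, transform(t1$coords, atom = 2, x = 10.75))
  expect_true(all(bin_density(t4, g)$counts <= 1))
  # atoms wholly outside the grid are reported, not counted
  t5 <- t1
  t5$coords$x <- 100
  d5 <- bin_density(t5, g)
  expect_equal(sum(d5$counts), 0)
  expect_equal(d5$atoms_outside, 1L)
})

test_that("Boltzmann inversion is exact and properly referenced", {
  g <- grid_spec(c(0, 0, 0), 1, c(3, 3, 3))
  mk <- function(counts) structure(
    list(grid = g, counts = array(counts, dim = c(3, 3, 3)),
         frames = 10, atoms_outside = 0L), class = "density_grid")
  # uniform density: W identically zero
  expect_true(all(boltzmann_invert(mk(rep(7, 27)))$W == 0))
  # density ratio e gives a kB T step
  d <- rep(10, 27); d[1] <- 10 * exp(1)
  W <- boltzmann_invert(mk(d), 300)$W
  expect_equal(max(W) - min(W), 1.9872e-3 * 300, tolerance = 1e-12)
  # the published site-1 depth: density ratio 0.6148 -> 0.29 kcal/mol
  d2 <- rep(1, 27); d2[1] <- 1 / 0.6148
  W2 <- boltzmann_invert(mk(d2), 300)$W
  expect_equal(max(W2), 0.29, tolerance = 0.01)
  # multiplicative rescaling of the density leaves the referenced map
  # unchanged (frame-count normalization invariance)
  W3 <- boltzmann_invert(mk(5 * d))$W
  expect_lt(max(abs(W3 - boltzmann_invert(mk(d))$W)), 1e-10)
  # zero-density voxels are masked; all-zero is an error
  d4 <- rep(0, 27); d4[5] <- 3
  expect_equal(sum(!is.na(boltzmann_invert(mk(d4))$W)), 1L)
  expect_error(boltzmann_invert(mk(rep(0, 27))), "zero")
})

test_that("block errors follow the declared population convention", {
  # trajectory made of two identical halves: zero error with 2 blocks
  set.seed(23)
  half <- data.frame(frame = rep(1:50, each = 1), atom = 1L, ligand = 1L,
                     x = runif(50, 2, 8), y = runif(50, 2, 8),
                     z = runif(50, 2, 8), radius = 1.7)
  both <- rbind(half, transform(half, frame = frame + 50))
  traj <- ligand_trajectory(both, 0.12)
  g <- grid_spec(c(0, 0, 0), 1, c(10, 10, 10))
  be <- block_error(traj, g, n_blocks = 2)
  expect_true(all(be$sd[!is.na(be$sd)] == 0))
  # two blocks with known per-voxel maps: sd = |W1 - W2| / 2
  W1 <- boltzmann_invert(bin_density(
    ligand_trajectory(half, 0.12), g))$W
  shifted <- transform(half, x = pmin(x + 0.6, 9.9), frame = frame + 50)
  traj2 <- ligand_trajectory(rbind(half, shifted), 0.12)
  be2 <- block_error(traj2, g, n_blocks = 2)
  W2 <- boltzmann_invert(bin_density(
    ligand_trajectory(transform(shifted, frame = frame - 50), 0.12), g))$W
  ref <- abs(W1 - W2) / 2
  both_mapped <- !is.na(ref) & !is.na(be2$sd)
  expect_true(any(both_mapped))
  expect_lt(max(abs(be2$sd[both_mapped] - ref[both_mapped])), 1e-10)
  expect_error(block_error(traj, g, n_blocks = 1), "2 blocks")
  # block-count sensitivity: 5, 10 and 15 blocks give error estimates of
  # the same magnitude on commonly mapped voxels
  set.seed(26)
  long <- data.frame(frame = 1:600, atom = 1L, ligand = 1L,
                     x = runif(600, 2, 8), y = runif(600, 2, 8),
                     z = runif(600, 2, 8), radius = 1.7)
  tl <- ligand_trajectory(long, 0.12)
  med <- vapply(c(5, 10, 15), function(nb)
    stats::median(block_error(tl, g, n_blocks = nb)$sd, na.rm = TRUE),
    numeric(1))
  expect_true(all(med > 0))
  expect_lt(max(med) / min(med), 3)
})

test_that("site extraction counts connected components exactly", {
  # constructed two-well field with referenced minima 0 and 2.0 kcal/mol
  g <- grid_spec(c(0, 0, 0), 1, c(30, 12, 12))
  ctr <- as.matrix(expand.grid(x = (1:30) - 0.5, y = (1:12) - 0.5,
                               z = (1:12) - 0.5))
  U <- 6 - 6 * exp(-rowSums(sweep(ctr, 2, c(7, 6, 6))^2) / 18) -
    4 * exp(-rowSums(sweep(ctr, 2, c(22, 6, 6))^2) / 18)
  W <- array(U - min(U), dim = g$shape)
  pmf <- structure(list(grid = g, W = W, temperature = 300),
                   class = "pmf_grid")
  expect_length(extract_sites(pmf, 1.0), 1L)
  sites <- extract_sites(pmf, 2.5)
  expect_length(sites, 2L)
  expect_equal(sites[[1]]$id, 0L)
  expect_equal(sites[[1]]$min_energy, 0)
  expect_equal(sites[[2]]$min_energy, 2.0, tolerance = 0.05)
  # the stored minimum location is the argmin voxel center of the field
  expect_equal(sites[[1]]$min_position, unname(ctr[which.min(U), ]))
  expect_equal(sites[[1]]$volume,
               nrow(sites[[1]]$voxels) * g$spacing^3)
  # contour just above zero: a single site containing the argmin voxel
  # (degenerate symmetric minima share the component)
  tiny <- extract_sites(pmf, 1e-6)
  expect_length(tiny, 1L)
  amin <- arrayInd(which.min(W), dim(W))
  expect_true(any(apply(tiny[[1]]$voxels, 1, function(v)
    all(v == amin))))
  # empty when nothing lies below the contour is impossible here (min = 0),
  # but a shifted map gives an empty list
  pmf2 <- pmf; pmf2$W <- pmf$W + 1; pmf2$W[1] <- NA
  expect_length(extract_sites(pmf2, 0.5), 0L)
  # site minima are invariant to whole-voxel grid translation
  g2 <- grid_spec(c(3, -2, 5), 1, c(30, 12, 12))
  pmf3 <- structure(list(grid = g2, W = W, temperature = 300),
                    class = "pmf_grid")
  s3 <- extract_sites(pmf3, 2.5)
  expect_equal(vapply(s3, `[[`, numeric(1), "min_energy"),
               vapply(sites, `[[`, numeric(1), "min_energy"))
})

test_that("1D flattening runs z fastest from the grid origin corner", {
  W <- array(0, dim = c(2, 2, 2))
  for (i in 0:1) for (j in 0:1) for (k in 0:1)
    W[i + 1, j + 1, k + 1] <- 100 * i + 10 * j + k
  v <- flatten_1d(W)
  expect_equal(v, c(0, 1, 10, 11, 100, 101, 110, 111))
  expect_equal(unflatten_1d(v, c(2, 2, 2)), W)
  # argmin position consistency
  set.seed(24)
  W2 <- array(runif(60), dim = c(3, 4, 5))
  v2 <- flatten_1d(W2)
  expect_equal(min(v2), min(W2))
  ijk <- arrayInd(which.min(W2), dim(W2))
  expect_equal(which.min(v2),
               (ijk[1] - 1) * 20 + (ijk[2] - 1) * 5 + ijk[3])
})

test_that("cleft-closure order parameters are center-of-mass distances", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 7.8), c(2, 0, 0), c(-2, 0, 0),
               c(2, 0, 7.8), c(-2, 0, 7.8))
  spec <- cluster_spec(1, 2, c(3, 4), c(5, 6))
  xi <- xi_values(xyz, spec)
  expect_equal(unname(xi["xi1"]), 7.8)
  expect_equal(unname(xi["xi2"]), 7.8)   # symmetric pairs: COMs on the axis
  # mass weighting moves the COM
  xi_m <- xi_values(rbind(c(0, 0, 0), c(0, 0, 4), c(0, 0, 10)),
                    cluster_spec(c(1, 2), 3, c(1, 2), 3),
                    masses = c(3, 1, 1))
  expect_equal(unname(xi_m["xi1"]), 9)   # COM of pair at z = 1
  expect_error(xi_values(xyz, cluster_spec(1, 2, c(3, 4), 99)),
               "outside")
  expect_error(cluster_spec(1, 1, 2, 3), "disjoint")
})

test_that("OpenDX export round-trips grid values", {
  g <- grid_spec(c(1, 2, 3), 0.5, c(3, 4, 5))
  set.seed(25)
  W <- array(round(runif(60), 4), dim = g$shape)
  W[2, 2, 2] <- NA
  pmf <- structure(list(grid = g, W = W, temperature = 300),
                   class = "pmf_grid")
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(pmf, path, na = 999)
  lines <- readLines(path)
  i0 <- grep("data follows", lines) + 1
  i1 <- grep("attribute", lines)[1] - 1
  vals <- as.numeric(unlist(strsplit(paste(lines[i0:i1], collapse = " "),
                                     " +")))
  W_na <- W; W_na[is.na(W_na)] <- 999
  expect_equal(vals, as.vector(aperm(W_na, c(3, 2, 1))))
  expect_match(lines[2], "origin 1.25 2.25 3.25")
})
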