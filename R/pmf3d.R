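#' Ligand-coordinate trajectory
#'
#' Container for per-frame ligand heavy-atom coordinates in a
#' protein-aligned reference frame, the raw material for occupancy
#' densities and binding-event detection.
#'
#' @param coords data.frame with columns \code{frame} (integer, 1-based),
#'   \code{x}, \code{y}, \code{z} (Angstrom) and \code{radius} (van der
#'   Waals radius, Angstrom); optional \code{atom} and \code{ligand}
#'   identifiers (a single ligand is assumed when absent).
#' @param frame_interval time between saved frames (ns); default 0.12.
#' @param protein optional data.frame of protein coordinates with columns
#'   \code{frame}, \code{atom}, \code{x}, \code{y}, \code{z}, used for
#'   alignment and distance queries.
#' @return A \code{ligand_trajectory}.
#' @export
ligand_trajectory <- function(coords, frame_interval = 0.12, protein = NULL) {
  need <- c("frame", "x", "y", "z", "radius")
  if (!all(need %in% names(coords)))
    stop("coords needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(coords)) stop("trajectory has no frames", call. = FALSE)
  if (!all(is.finite(as.matrix(coords[c("x", "y", "z", "radius")]))))
    stop("coordinates must be finite", call. = FALSE)
  if (any(coords$radius <= 0)) stop("radii must be > 0", call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  if (is.null(coords$ligand)) coords$ligand <- 1L
  structure(list(coords = coords, frame_interval = frame_interval,
                 protein = protein),
            class = "ligand_trajectory")
}

#' @export
print.ligand_trajectory <- function(x, ...) {
  cat(sprintf("Ligand trajectory: %d frames x %d ligand(s), %g ns/frame\n",
              length(unique(x$coords$frame)),
              length(unique(x$coords$ligand)), x$frame_interval))
  invisible(x)
}

#' Read / write ligand trajectories as TSV
#' @param path file path; columns frame, atom, ligand, x, y, z, radius.
#' @param traj a \code{ligand_trajectory}.
#' @param frame_interval frame interval (ns) for the reader.
#' @return Reader returns a \code{ligand_trajectory}.
#' @export
read_trajectory_tsv <- function(path, frame_interval = 0.12) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  ligand_trajectory(d, frame_interval = frame_interval)
}

#' @rdname read_trajectory_tsv
#' @export
write_trajectory_tsv <- function(traj, path) {
  utils::write.table(traj$coords, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Regular 3D grid specification
#'
#' @param origin corner of the grid (Angstrom); voxel i,j,k (1-based) has
#'   its center at \code{origin + (c(i,j,k) - 0.5) * spacing}.
#' @param spacing isotropic voxel edge length (Angstrom); default 0.5.
#' @param shape integer vector (nx, ny, nz).
#' @return A \code{grid_spec}.
#' @export
grid_spec <- function(origin, spacing = 0.5, shape) {
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1))
    stop("shape must be three positive integers", call. = FALSE)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 shape = shape), class = "grid_spec")
}

# voxel centers along one axis
axis_centers <- function(grid, ax) {
  grid$origin[ax] + (seq_len(grid$shape[ax]) - 0.5) * grid$spacing
}

#' Rigid-body superposition of trajectory frames onto a reference
#'
#' Least-squares (Kabsch) superposition of each frame's backbone
#' selection onto reference coordinates; the rotation and translation are
#' applied to the ligand (and protein) coordinates of that frame.
#'
#' @param traj a \code{ligand_trajectory} carrying protein coordinates.
#' @param reference matrix (n_sel x 3) of reference positions for the
#'   selected backbone atoms, in selection order.
#' @param backbone_selection atom identifiers (matched against the
#'   protein's \code{atom} column) defining the superposition set.
#' @return The aligned \code{ligand_trajectory}.
#' @export
align_frames <- function(traj, reference, backbone_selection) {
  stopifnot(inherits(traj, "ligand_trajectory"))
  if (is.null(traj$protein))
    stop("trajectory carries no protein coordinates", call. = FALSE)
  ref <- as.matrix(reference)
  if (ncol(ref) != 3 || nrow(ref) != length(backbone_selection))
    stop("reference must be n_selection x 3", call. = FALSE)
  ref_c <- colMeans(ref)
  ref0 <- sweep(ref, 2, ref_c)
  frames <- sort(unique(traj$coords$frame))
  lig <- traj$coords
  prot <- traj$protein
  for (fr in frames) {
    psel <- prot$frame == fr
    mob <- prot[psel, ]
    m <- match(backbone_selection, mob$atom)
    if (anyNA(m))
      stop("backbone selection missing in frame ", fr, call. = FALSE)
    X <- as.matrix(mob[m, c("x", "y", "z")])
    mob_c <- colMeans(X)
    X0 <- sweep(X, 2, mob_c)
    R <- kabsch_rotation(X0, ref0)
    rot <- function(df, sel) {
      P <- as.matrix(df[sel, c("x", "y", "z")])
      P <- sweep(P, 2, mob_c) %*% R
      df[sel, c("x", "y", "z")] <- sweep(P, 2, ref_c, "+")
      df
    }
    lig <- rot(lig, lig$frame == fr)
    prot <- rot(prot, psel)
  }
  traj$coords <- lig
  traj$protein <- prot
  traj
}

# optimal rotation matrix mapping centred mobile X0 onto centred
# reference Y0 (rows are atoms): X0 %*% R ~ Y0
kabsch_rotation <- function(X0, Y0) {
  H <- crossprod(X0, Y0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Hard-sphere occupancy density on a 3D grid
#'
#' For every frame, a voxel is counted as occupied if its center lies
#' within the van der Waals radius of any ligand heavy atom in that frame
#' (binary per frame: several atoms covering one voxel still count once).
#' Counts accumulate over frames.  With \code{weighted = TRUE} each
#' covering atom contributes one count instead (atom-count weighting).
#'
#' @param traj a \code{ligand_trajectory}.
#' @param grid a \code{grid_spec} covering the region of interest.
#' @param weighted logical; default FALSE (binary per-frame occupancy).
#' @return A \code{density_grid}: list with \code{grid}, \code{counts}
#'   (3D array), \code{frames}, and \code{atoms_outside} (number of
#'   atom-frames wholly outside the grid, reported not counted).
#' @export
bin_density <- function(traj, grid, weighted = FALSE) {
  stopifnot(inherits(traj, "ligand_trajectory"), inherits(grid, "grid_spec"))
  co <- traj$coords
  sp <- grid$spacing
  org <- grid$origin
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  counts <- numeric(nx * ny * nz)
  outside <- 0L
  # voxel index range touched by a sphere along one axis
  idx_range <- function(p, r, ax) {
    lo <- max(1L, as.integer(ceiling((p - r - org[ax]) / sp + 0.5)))
    hi <- min(grid$shape[ax], as.integer(floor((p + r - org[ax]) / sp + 0.5)))
    if (lo > hi) integer(0) else lo:hi
  }
  cx <- axis_centers(grid, 1); cy <- axis_centers(grid, 2)
  cz <- axis_centers(grid, 3)
  frames <- unique(co$frame)
  for (fr in frames) {
    rows <- which(co$frame == fr)
    vox <- integer(0)
    for (a in rows) {
      p <- c(co$x[a], co$y[a], co$z[a]); r <- co$radius[a]
      ix <- idx_range(p[1], r, 1); iy <- idx_range(p[2], r, 2)
      iz <- idx_range(p[3], r, 3)
      if (!length(ix) || !length(iy) || !length(iz)) { outside <- outside + 1L; next }
      dx2 <- (cx[ix] - p[1])^2; dy2 <- (cy[iy] - p[2])^2
      dz2 <- (cz[iz] - p[3])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      keep <- which(d2 <= r^2)
      if (!length(keep)) { outside <- outside + 1L; next }
      ijk <- arrayInd(keep, c(length(ix), length(iy), length(iz)))
      lin <- ix[ijk[, 1]] + nx * (iy[ijk[, 2]] - 1L) +
        nx * ny * (iz[ijk[, 3]] - 1L)
      vox <- c(vox, lin)
    }
    if (!weighted) vox <- unique(vox)
    if (length(vox)) {
      tb <- tabulate(vox, nbins = nx * ny * nz)
      counts <- counts + tb
    }
  }
  structure(list(grid = grid,
                 counts = array(counts, dim = grid$shape),
                 frames = length(frames),
                 atoms_outside = outside),
            class = "density_grid")
}

#' Boltzmann constant in kcal mol^-1 K^-1
#' @export
KB_KCAL <- 1.9872e-3

#' Boltzmann inversion of an occupancy density
#'
#' Converts a ligand occupancy density into a free-energy map,
#' \eqn{W(r) = -k_B T \ln \rho(r)}, referenced so the mapped minimum is
#' exactly zero.  Voxels with zero density are masked (NA) rather than
#' capped: \eqn{-\ln 0} is undefined and capping would bias site volumes.
#'
#' @param density a \code{density_grid}.
#' @param temperature simulation temperature (K); default 300 (use 310
#'   for runs thermostatted there).
#' @return A \code{pmf_grid}: list with \code{grid}, \code{W} (3D array,
#'   kcal/mol, NA where unmapped), \code{temperature}.
#' @export
boltzmann_invert <- function(density, temperature = 300) {
  stopifnot(inherits(density, "density_grid"))
  rho <- density$counts
  if (all(rho == 0)) stop("density is identically zero", call. = FALSE)
  W <- array(NA_real_, dim = dim(rho))
  pos <- rho > 0
  W[pos] <- -KB_KCAL * temperature * log(rho[pos])
  W <- W - min(W, na.rm = TRUE)
  structure(list(grid = density$grid, W = W, temperature = temperature),
            class = "pmf_grid")
}

#' Block-averaged statistical uncertainty of a PMF
#'
#' Splits the trajectory into contiguous equal-length blocks (serial
#' correlation motivates contiguity; trailing remainder frames are
#' dropped), computes a PMF per block, and returns the per-voxel standard
#' deviation of the block free energies (population convention,
#' denominator n_blocks, so two blocks give |W1 - W2| / 2).  Voxels
#' unmapped in any block are masked.
#'
#' @param traj a \code{ligand_trajectory}.
#' @param grid a \code{grid_spec}.
#' @param n_blocks number of blocks (default 10).
#' @param temperature K.
#' @param weighted passed to \code{\link{bin_density}}.
#' @return A \code{block_error_grid}: list with \code{grid}, \code{sd}
#'   (3D array, kcal/mol), \code{n_blocks}, and \code{block_pmfs}.
#' @export
block_error <- function(traj, grid, n_blocks = 10, temperature = 300,
                        weighted = FALSE) {
  if (n_blocks < 2) stop("need at least 2 blocks", call. = FALSE)
  frames <- sort(unique(traj$coords$frame))
  nf <- length(frames)
  if (nf < n_blocks) stop("fewer frames than blocks", call. = FALSE)
  per <- nf %/% n_blocks
  Ws <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    fsel <- frames[((b - 1) * per + 1):(b * per)]
    sub <- traj
    sub$coords <- traj$coords[traj$coords$frame %in% fsel, , drop = FALSE]
    Ws[[b]] <- boltzmann_invert(bin_density(sub, grid, weighted = weighted),
                                temperature = temperature)$W
  }
  stack <- simplify2array(Ws)                     # nx x ny x nz x B
  any_na <- apply(stack, 1:3, function(v) any(is.na(v)))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  sdW <- apply(stack, 1:3, pop_sd)
  sdW[any_na] <- NA_real_
  structure(list(grid = grid, sd = sdW, n_blocks = n_blocks,
                 block_pmfs = Ws),
            class = "block_error_grid")
}

#' Extract metastable sites from a PMF by contouring
#'
#' Connected components (26-connectivity) of mapped voxels with free
#' energy below the contour, sorted by their minimum free energy
#' ascending, so site 1 in the returned list is the component containing
#' the global minimum (conventionally "site 0").  The contour presets
#' used for display in this kind of analysis are 0.32, 1.16, 1.89 and
#' 2.62 kcal/mol.
#'
#' @param pmf a \code{pmf_grid}.
#' @param contour free-energy threshold (kcal/mol), > 0.
#' @return List of \code{metastable_site}s: each has \code{id} (0-based,
#'   by depth), \code{voxels} (n x 3 index matrix), \code{min_energy}
#'   (kcal/mol), \code{min_position} (Angstrom), \code{volume}
#'   (Angstrom^3).
#' @export
extract_sites <- function(pmf, contour) {
  stopifnot(inherits(pmf, "pmf_grid"))
  if (contour <= 0) stop("contour must be > 0", call. = FALSE)
  W <- pmf$W
  dims <- dim(W)
  below <- which(!is.na(W) & W < contour)
  if (!length(below)) return(list())
  lab <- array(0L, dim = dims)
  lab[below] <- -1L                                # candidate, unlabelled
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  ncomp <- 0L
  comps <- list()
  for (seed in below) {
    if (lab[seed] != -1L) next
    ncomp <- ncomp + 1L
    stack <- seed
    lab[seed] <- ncomp
    members <- seed
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      ijk <- arrayInd(v, dims)
      nb <- sweep(offs, 2, as.integer(ijk), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + dims[1] * (nb[, 2] - 1L) +
        dims[1] * dims[2] * (nb[, 3] - 1L)
      new <- lin[lab[lin] == -1L]
      if (length(new)) {
        lab[new] <- ncomp
        stack <- c(stack, new)
        members <- c(members, new)
      }
    }
    comps[[ncomp]] <- members
  }
  mins <- vapply(comps, function(m) min(W[m]), numeric(1))
  ord <- order(mins)
  vol1 <- pmf$grid$spacing^3
  sites <- lapply(seq_along(ord), function(k) {
    m <- comps[[ord[k]]]
    ijk <- arrayInd(m, dims)
    imin <- m[which.min(W[m])]
    pmin <- arrayInd(imin, dims)
    pos <- pmf$grid$origin + (as.numeric(pmin) - 0.5) * pmf$grid$spacing
    structure(list(id = k - 1L, voxels = ijk,
                   min_energy = min(W[m]), min_position = pos,
                   volume = length(m) * vol1),
              class = "metastable_site")
  })
  sites
}

#' Flatten a 3D PMF to the canonical 1D profile
#'
#' Emits the grid values as a single sequence indexed increasing in z,
#' then y, then x, starting from the (x_min, y_min, z_min) corner, so
#' that z varies fastest.  Unmapped voxels are emitted as NA.
#'
#' @param pmf a \code{pmf_grid} (or any object with a 3D array in
#'   \code{$W}).
#' @return Numeric vector of length prod(shape).
#' @export
flatten_1d <- function(pmf) {
  W <- if (is.array(pmf)) pmf else pmf$W
  as.vector(aperm(W, c(3, 2, 1)))
}

#' Restore a flattened profile to its 3D grid
#' @param v vector from \code{\link{flatten_1d}}.
#' @param shape grid shape (nx, ny, nz).
#' @return 3D array.
#' @export
unflatten_1d <- function(v, shape) {
  aperm(array(v, dim = rev(shape)), c(3, 2, 1))
}

#' Cluster specification for cleft-closure order parameters
#'
#' Defines the two pairs of atom clusters whose center-of-mass distances
#' (xi1, xi2) quantify closure of the clamshell-shaped ligand-binding
#' domain: one pair spanning the cleft mouth, one deeper pair.
#'
#' @param xi1_a,xi1_b,xi2_a,xi2_b atom index vectors (rows of the
#'   coordinate matrix handed to \code{\link{xi_values}}).
#' @return A \code{cluster_spec}.
#' @export
cluster_spec <- function(xi1_a, xi1_b, xi2_a, xi2_b) {
  sets <- list(xi1_a = xi1_a, xi1_b = xi1_b, xi2_a = xi2_a, xi2_b = xi2_b)
  if (any(vapply(sets, length, integer(1)) == 0))
    stop("cluster atom sets must be non-empty", call. = FALSE)
  if (length(intersect(xi1_a, xi1_b)) || length(intersect(xi2_a, xi2_b)))
    stop("cluster sets within a pair must be disjoint", call. = FALSE)
  structure(sets, class = "cluster_spec")
}

#' Cleft-closure order parameters of one frame
#'
#' @param xyz matrix (n_atoms x 3) of coordinates (Angstrom).
#' @param spec a \code{\link{cluster_spec}}.
#' @param masses per-atom masses for the center-of-mass weighting;
#'   default unit masses.
#' @return Named numeric c(xi1, xi2) in Angstrom.
#' @export
xi_values <- function(xyz, spec, masses = NULL) {
  stopifnot(inherits(spec, "cluster_spec"))
  xyz <- as.matrix(xyz)
  if (is.null(masses)) masses <- rep(1, nrow(xyz))
  idx <- unlist(spec)
  if (any(idx < 1 | idx > nrow(xyz)))
    stop("cluster atom index outside coordinate set", call. = FALSE)
  com <- function(i) colSums(xyz[i, , drop = FALSE] * masses[i]) /
    sum(masses[i])
  c(xi1 = sqrt(sum((com(spec$xi1_a) - com(spec$xi1_b))^2)),
    xi2 = sqrt(sum((com(spec$xi2_a) - com(spec$xi2_b))^2)))
}

#' Export a grid in OpenDX volumetric format
#'
#' Writes a density, PMF or block-error grid as an OpenDX scalar field
#' readable by standard molecular viewers.  Unmapped voxels are written
#' as the value given by \code{na}.
#'
#' @param x a \code{density_grid}, \code{pmf_grid} or
#'   \code{block_error_grid}.
#' @param path output file.
#' @param na replacement value for unmapped voxels (default 999).
#' @return \code{path}, invisibly.
#' @export
write_dx <- function(x, path, na = 999) {
  g <- x$grid
  vals <- if (!is.null(x$W)) x$W else if (!is.null(x$sd)) x$sd else x$counts
  vals[is.na(vals)] <- na
  # OpenDX stores with z fastest
  v <- as.vector(aperm(vals, c(3, 2, 1)))
  con <- file(path, "w")
  on.exit(close(con))
  nx <- g$shape[1]; ny <- g$shape[2]; nz <- g$shape[3]
  ctr0 <- g$origin + 0.5 * g$spacing
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", nx, ny, nz),
    sprintf("origin %g %g %g", ctr0[1], ctr0[2], ctr0[3]),
    sprintf("delta %g 0 0", g$spacing),
    sprintf("delta 0 %g 0", g$spacing),
    sprintf("delta 0 0 %g", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", nx, ny, nz),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(v))), con)
  full <- length(v) %/% 3
  if (full > 0) {
    m <- matrix(v[seq_len(3 * full)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%g %g %g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (3 * full < length(v))
    writeLines(paste(sprintf("%g", v[(3 * full + 1):length(v)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
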