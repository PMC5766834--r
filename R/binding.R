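#' Criteria for binding-event detection and bulk-time bookkeeping
#'
#' @param bound_cutoff distance (Angstrom) between the ligand reference
#'   atom and the pocket reference below which the ligand counts as
#'   bound; default 6.
#' @param min_dwell minimum continuous time (ns) below/above the cutoff
#'   before a state change is accepted (hysteresis against flicker);
#'   default 1.
#' @param bulk_cutoff minimum ligand-protein heavy-atom distance
#'   (Angstrom) defining bulk solvent; default 8, mirroring the
#'   "at least 8 A from any non-water molecule" placement criterion.
#' @return A \code{binding_criteria} object.
#' @export
binding_criteria <- function(bound_cutoff = 6, min_dwell = 1,
                             bulk_cutoff = 8) {
  if (bound_cutoff <= 0 || bulk_cutoff <= 0)
    stop("cutoffs must be > 0", call. = FALSE)
  if (min_dwell < 0) stop("min_dwell must be >= 0", call. = FALSE)
  structure(list(bound_cutoff = bound_cutoff, min_dwell = min_dwell,
                 bulk_cutoff = bulk_cutoff), class = "binding_criteria")
}

#' Detect binding and unbinding events from a distance series
#'
#' An event opens when the ligand-pocket reference distance stays below
#' \code{bound_cutoff} for at least \code{min_dwell}, and closes when the
#' distance stays above the cutoff for at least \code{min_dwell}
#' (sub-dwell excursions in either direction are ignored).  Entry and
#' exit times are the start of the qualifying runs; an event still open
#' at the end of the series has \code{NA} exit.
#'
#' @param times frame times (ns), strictly increasing.
#' @param dist reference distances (Angstrom), same length.
#' @param criteria a \code{\link{binding_criteria}}.
#' @return data.frame with columns \code{entry_ns}, \code{exit_ns}.
#' @export
events_from_distance <- function(times, dist, criteria) {
  stopifnot(inherits(criteria, "binding_criteria"))
  if (length(times) != length(dist))
    stop("times and dist lengths differ", call. = FALSE)
  if (anyNA(dist)) stop("missing reference distances", call. = FALSE)
  below <- dist < criteria$bound_cutoff
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  run_dur <- times[ends] - times[starts] +
    (if (length(times) > 1) stats::median(diff(times)) else 0)
  entry <- numeric(0); exit <- numeric(0)
  open <- FALSE
  for (k in seq_along(r$lengths)) {
    if (run_dur[k] < criteria$min_dwell) next    # flicker, no state change
    if (r$values[k] && !open) {
      open <- TRUE
      entry <- c(entry, times[starts[k]])
    } else if (!r$values[k] && open) {
      open <- FALSE
      exit <- c(exit, times[starts[k]])
    }
  }
  if (open) exit <- c(exit, NA_real_)
  data.frame(entry_ns = entry, exit_ns = exit)
}

#' Detect binding events in a ligand trajectory
#'
#' Computes, per ligand, the distance from its reference atom (by
#' default the first atom of each ligand, e.g. the alpha-carbon) to the
#' pocket reference point, and applies \code{\link{events_from_distance}}.
#'
#' @param traj a \code{ligand_trajectory}.
#' @param criteria a \code{\link{binding_criteria}}.
#' @param pocket_center numeric length-3 pocket reference point
#'   (Angstrom) in the aligned frame.
#' @param system,subunit identifiers copied into the output.
#' @return data.frame with columns system, subunit, ligand, entry_ns,
#'   exit_ns.
#' @export
detect_events <- function(traj, criteria, pocket_center,
                          system = "sys1", subunit = 1L) {
  stopifnot(inherits(traj, "ligand_trajectory"))
  if (length(pocket_center) != 3)
    stop("pocket_center must be length 3", call. = FALSE)
  co <- traj$coords
  out <- lapply(split(co, co$ligand), function(d) {
    ref <- d[!duplicated(d$frame), ]              # first atom per frame
    ref <- ref[order(ref$frame), ]
    dist <- sqrt((ref$x - pocket_center[1])^2 +
                 (ref$y - pocket_center[2])^2 +
                 (ref$z - pocket_center[3])^2)
    ev <- events_from_distance((ref$frame - 1) * traj$frame_interval,
                               dist, criteria)
    if (nrow(ev))
      cbind(data.frame(system = system, subunit = subunit,
                       ligand = d$ligand[1]), ev)
    else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(system = character(0), subunit = integer(0),
                      ligand = integer(0), entry_ns = numeric(0),
                      exit_ns = numeric(0))
  rownames(out) <- NULL
  out
}

#' Anchor definition for bound-pose classification
#'
#' The crystallographic glutamate pose anchors the alpha-carboxylate to
#' a Lobe-1 residue (the arginine guanidinium) and the gamma-carboxylate
#' to a Lobe-2 backbone amine; the inverted pose swaps the two.
#'
#' @param lobe1,lobe2 row indices of the two anchor atom groups in the
#'   frame's coordinate matrix.
#' @param alpha_carboxylate,gamma_carboxylate row indices of the two
#'   ligand carboxylate groups.
#' @param contact_cutoff heavy-atom contact distance (Angstrom);
#'   default 4.
#' @return A \code{pose_anchors} object.
#' @export
pose_anchors <- function(lobe1, lobe2, alpha_carboxylate,
                         gamma_carboxylate, contact_cutoff = 4) {
  sets <- list(lobe1 = lobe1, lobe2 = lobe2,
               alpha_carboxylate = alpha_carboxylate,
               gamma_carboxylate = gamma_carboxylate)
  if (any(vapply(sets, length, integer(1)) == 0))
    stop("anchor atom sets must be non-empty", call. = FALSE)
  structure(c(sets, list(contact_cutoff = contact_cutoff)),
            class = "pose_anchors")
}

#' Classify the bound ligand pose in one frame
#'
#' \code{"crystallographic"} when the alpha-carboxylate contacts Lobe 1
#' and the gamma-carboxylate contacts Lobe 2 (any heavy-atom pair within
#' the contact cutoff), \code{"inverted"} when the contacts are swapped,
#' \code{"undetermined"} otherwise (including when both patterns hold).
#'
#' @param xyz matrix (n_atoms x 3) of the frame's coordinates (Angstrom).
#' @param anchors a \code{\link{pose_anchors}}.
#' @return One of "crystallographic", "inverted", "undetermined".
#' @export
classify_pose <- function(xyz, anchors) {
  stopifnot(inherits(anchors, "pose_anchors"))
  xyz <- as.matrix(xyz)
  mind <- function(i, j) {
    A <- xyz[i, , drop = FALSE]; B <- xyz[j, , drop = FALSE]
    min(sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)))
  }
  cut <- anchors$contact_cutoff
  a1 <- mind(anchors$alpha_carboxylate, anchors$lobe1) <= cut
  g2 <- mind(anchors$gamma_carboxylate, anchors$lobe2) <= cut
  g1 <- mind(anchors$gamma_carboxylate, anchors$lobe1) <= cut
  a2 <- mind(anchors$alpha_carboxylate, anchors$lobe2) <= cut
  cryst <- a1 && g2
  inv <- g1 && a2
  if (cryst && !inv) "crystallographic"
  else if (inv && !cryst) "inverted"
  else "undetermined"
}

#' Time a ligand spends in bulk solvent
#'
#' Total trajectory time during which the minimum ligand-protein
#' heavy-atom distance exceeds \code{bulk_cutoff}, as a
#' frame-interval-weighted frame count.  With \code{exclude_bound} the
#' alternative bookkeeping "bulk = not bound" is used instead
#' (everything outside \code{bound_cutoff} of the pocket counts as bulk),
#' since the precise definition of bulk is a convention.
#'
#' @param min_dist per-frame minimum ligand-protein distance (Angstrom).
#' @param frame_interval ns per frame.
#' @param criteria a \code{\link{binding_criteria}}.
#' @param exclude_bound logical, default FALSE.
#' @param bound_dist per-frame ligand-pocket reference distance, needed
#'   when \code{exclude_bound = TRUE}.
#' @return Bulk time in seconds.
#' @export
bulk_time <- function(min_dist, frame_interval, criteria,
                      exclude_bound = FALSE, bound_dist = NULL) {
  stopifnot(inherits(criteria, "binding_criteria"))
  sel <- if (exclude_bound) {
    if (is.null(bound_dist))
      stop("exclude_bound needs bound_dist", call. = FALSE)
    bound_dist >= criteria$bound_cutoff
  } else min_dist > criteria$bulk_cutoff
  sum(sel) * frame_interval * 1e-9
}

#' Per-system inputs for the association-rate estimator
#'
#' @param data data.frame with columns \code{system}, \code{Nb}
#'   (binding-event count), \code{t_s} (bulk time, s), \code{conc_M}
#'   (free ligand concentration, M), \code{subunits}.
#' @return A validated \code{kon_input}.
#' @export
kon_input <- function(data) {
  need <- c("system", "Nb", "t_s", "conc_M", "subunits")
  if (!all(need %in% names(data)))
    stop("kon_input needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(data$Nb < 0) || any(data$t_s < 0) || any(data$conc_M < 0))
    stop("Nb, t_s, conc_M must be non-negative", call. = FALSE)
  if (any(data$subunits < 1))
    stop("subunit counts must be >= 1", call. = FALSE)
  structure(as.data.frame(data), class = c("kon_input", "data.frame"))
}

#' @rdname kon_input
#' @param path TSV path with the \code{kon_input} columns.
#' @export
read_kon_input_tsv <- function(path) {
  kon_input(utils::read.table(path, header = TRUE, sep = "\t"))
}

#' Association rate constant from pooled binding events
#'
#' \deqn{k_{on} = \frac{\sum_i N_{b,i}}{\sum_i t_i [L_i] s_i}}
#' where for each simulation system i, \eqn{N_b} is the number of
#' binding events, \eqn{t_i} the time the ligand spends in bulk solvent,
#' \eqn{[L_i]} the free ligand concentration and \eqn{s_i} the number of
#' protein subunits.  The estimate is invariant to splitting a system's
#' row into rows with the same totals.
#'
#' @param input a \code{\link{kon_input}}.
#' @return k_on in M^-1 s^-1 (0 with a warning when no events).
#' @examples
#' estimate_kon(kon_input(data.frame(system = "a", Nb = 3, t_s = 1e-5,
#'                                   conc_M = 0.01, subunits = 1)))
#' @export
estimate_kon <- function(input) {
  stopifnot(inherits(input, "kon_input"))
  denom <- sum(input$t_s * input$conc_M * input$subunits)
  if (denom <= 0) stop("zero exposure: sum(t * [L] * s) is 0", call. = FALSE)
  nb <- sum(input$Nb)
  if (nb == 0) {
    warning("no binding events; k_on estimate is 0", call. = FALSE)
    return(0)
  }
  nb / denom
}

#' Restrict pooled events to one pose label and re-estimate k_on
#'
#' @param events data.frame with a \code{system} column and a \code{pose}
#'   label per event.
#' @param input a \code{\link{kon_input}} whose \code{Nb} column is
#'   replaced by the per-system count of events with the given pose.
#' @param pose label to keep (e.g. "crystallographic").
#' @return k_on in M^-1 s^-1.
#' @export
estimate_kon_pose <- function(events, input, pose) {
  stopifnot(inherits(input, "kon_input"))
  keep <- events[events$pose == pose, , drop = FALSE]
  cnt <- table(factor(keep$system, levels = input$system))
  input$Nb <- as.integer(cnt)
  estimate_kon(input)
}

#' Write detected events as TSV
#' @param events event data.frame.
#' @param path file path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
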