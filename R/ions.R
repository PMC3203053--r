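#' Describe an ion-binding site
#'
#' @param ion_id atom serial of the ion in the topology.
#' @param partners list of \code{c(res_id, atom_name)} pairs (or a
#'   data.frame with columns \code{res_id}, \code{atom_name}) giving the
#'   coordinating atoms, in reporting order.
#' @param hydration_cutoff water-oxygen cutoff for hydration counts
#'   (Angstrom, default 3).
#' @param contact_cutoff protein heavy-atom cutoff for "in contact"
#'   (Angstrom, default 4).
#' @export
coordination_site <- function(ion_id, partners, hydration_cutoff = 3.0,
                              contact_cutoff = 4.0) {
  stopifnot(hydration_cutoff > 0, contact_cutoff > 0)
  if (is.data.frame(partners))
    partners <- lapply(seq_len(nrow(partners)), function(i)
      list(res_id = partners$res_id[i], atom_name = partners$atom_name[i]))
  else
    partners <- lapply(partners, function(p)
      list(res_id = as.integer(p[[1]]), atom_name = as.character(p[[2]])))
  structure(list(ion_id = ion_id, partners = partners,
                 hydration_cutoff = hydration_cutoff,
                 contact_cutoff = contact_cutoff),
            class = "coordination_site")
}

.ion_index <- function(topology, ion_id) {
  i <- which(topology$serial == ion_id)
  if (length(i) != 1L)
    stop("unknown selection: ion serial ", ion_id, " not found")
  i
}

.partner_indices <- function(topology, site) {
  vapply(site$partners, function(p) {
    i <- which(topology$res_id == p$res_id & topology$name == p$atom_name)
    if (length(i) != 1L)
      stop("unknown selection: partner atom ", p$atom_name,
           " of residue ", p$res_id, " not found")
    i
  }, integer(1))
}

#' Ion-to-partner distances in one frame
#'
#' @param coords frame coordinates.
#' @param topology matching \code{topology}.
#' @param site a \code{\link{coordination_site}}.
#' @return named numeric vector of distances (Angstrom), in partner order.
#' @export
coordination_distances <- function(coords, topology, site) {
  ii <- .ion_index(topology, site$ion_id)
  pi_ <- .partner_indices(topology, site)
  d <- sqrt(rowSums(sweep(coords[pi_, , drop = FALSE], 2, coords[ii, ])^2))
  names(d) <- vapply(site$partners, function(p)
    paste0(p$res_id, ":", p$atom_name), "")
  d
}

#' Per-frame ion-to-partner distance traces
#'
#' @param traj a \code{trajectory}.
#' @param site a \code{\link{coordination_site}}.
#' @return list of \code{metric_series}, one per partner.
#' @export
coordination_series <- function(traj, site) {
  nf <- n_frames(traj)
  mat <- vapply(seq_len(nf), function(k)
    coordination_distances(frame_coords(traj, k), traj$topology, site),
    numeric(length(site$partners)))
  mat <- matrix(mat, ncol = nf)
  nm <- vapply(site$partners, function(p)
    paste0(p$res_id, ":", p$atom_name), "")
  stats::setNames(lapply(seq_along(site$partners), function(j)
    metric_series(nm[j], "Angstrom", traj$times, mat[j, ])), nm)
}

#' Per-frame count of first-shell waters around the ion
#'
#' @param traj a \code{trajectory}.
#' @param site a \code{\link{coordination_site}} (uses
#'   \code{hydration_cutoff}).
#' @return a \code{metric_series} of counts.
#' @export
ion_hydration_series <- function(traj, site) {
  top <- traj$topology
  ii <- .ion_index(top, site$ion_id)
  wo <- .water_oxygens(top)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    if (length(wo) == 0L) return(0)
    fr <- frame_coords(traj, k)
    d2 <- rowSums(sweep(fr[wo, , drop = FALSE], 2, fr[ii, ])^2)
    sum(d2 < site$hydration_cutoff^2)
  }, numeric(1))
  metric_series("ion_hydration", "count", traj$times, vals)
}

# signed dihedral (degrees, (-180, 180]) from four points
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Side-chain chi1 torsion trace (N-CA-CB-CG)
#'
#' @param traj a \code{trajectory}.
#' @param res_id residue id carrying N, CA, CB and CG atoms.
#' @param chain optional chain restriction.
#' @return a \code{metric_series} in degrees, signed, in (-180, 180].
#' @export
chi1_dihedral_series <- function(traj, res_id, chain = NULL) {
  top <- traj$topology
  idx <- vapply(c("N", "CA", "CB", "CG"), function(a) {
    m <- top$res_id == res_id & top$name == a
    if (!is.null(chain)) m <- m & top$chain == chain
    i <- which(m)
    if (length(i) != 1L)
      stop("missing atom: residue ", res_id, " lacks a unique ", a,
           " atom (chi1 undefined, e.g. Gly/Ala)")
    i
  }, integer(1))
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    fr <- frame_coords(traj, k)
    .dihedral(fr[idx[1], ], fr[idx[2], ], fr[idx[3], ], fr[idx[4], ])
  }, numeric(1))
  metric_series(paste0("chi1_", res_id), "degrees", traj$times, vals)
}

#' Release criteria for an ion
#'
#' @param contact_cutoff no protein heavy atom within this distance
#'   (Angstrom, default 4).
#' @param min_hydration minimum first-shell water count (default 4,
#'   matching a fully solvated monovalent cation's 4-5 first-shell waters).
#' @param min_dwell minimum consecutive frames satisfying both conditions
#'   (default 10).
#' @export
release_criteria <- function(contact_cutoff = 4.0, min_hydration = 4L,
                             min_dwell = 10L) {
  stopifnot(min_dwell >= 1L)
  structure(list(contact_cutoff = contact_cutoff,
                 min_hydration = min_hydration, min_dwell = min_dwell),
            class = "release_criteria")
}

#' Detect the frame at which an ion is released into bulk
#'
#' The ion counts as released at the first frame starting a run of at least
#' \code{min_dwell} frames in which no protein heavy atom lies within
#' \code{contact_cutoff} of the ion and the first-shell hydration is at
#' least \code{min_hydration}.
#'
#' @param traj a \code{trajectory}.
#' @param site a \code{\link{coordination_site}}.
#' @param criteria a \code{\link{release_criteria}}.
#' @return 1-based frame index, or \code{NA_integer_} when never satisfied.
#' @export
detect_ion_release <- function(traj, site, criteria = release_criteria()) {
  top <- traj$topology
  ii <- .ion_index(top, site$ion_id)
  prot <- which(top$role == "protein" & top$element != "H")
  wo <- .water_oxygens(top)
  nf <- n_frames(traj)
  ok <- logical(nf)
  for (k in seq_len(nf)) {
    fr <- frame_coords(traj, k)
    free <- if (criteria$contact_cutoff <= 0 || length(prot) == 0L) TRUE
            else min(rowSums(sweep(fr[prot, , drop = FALSE], 2,
                                   fr[ii, ])^2)) >= criteria$contact_cutoff^2
    hyd <- if (length(wo) == 0L) 0L
           else sum(rowSums(sweep(fr[wo, , drop = FALSE], 2,
                                  fr[ii, ])^2) < site$hydration_cutoff^2)
    ok[k] <- free && hyd >= criteria$min_hydration
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= criteria$min_dwell)
  if (length(hit) == 0L) return(NA_integer_)
  starts[hit[1]]
}

#' Ion positions in the scaffold-aligned reference frame
#'
#' Every sampled frame is first superposed onto frame 1 via the scaffold
#' C-alpha selection, so global tumbling of the protein is removed from the
#' trace.
#'
#' @param traj a \code{trajectory}.
#' @param ion_id ion atom serial.
#' @param scaffold_sel scaffold C-alpha selection used for alignment.
#' @param stride sample every \code{stride} frames (>= 1).
#' @return data.frame with \code{frame}, \code{time_ns}, \code{x}, \code{y},
#'   \code{z} (Angstrom).
#' @export
ion_pathway_trace <- function(traj, ion_id, scaffold_sel, stride = 1L) {
  stopifnot(stride >= 1L)
  top <- traj$topology
  ii <- .ion_index(top, ion_id)
  ai <- .ca_indices(top, resolve_selection(top, scaffold_sel))
  ref <- frame_coords(traj, 1L)
  ks <- seq(1L, n_frames(traj), by = stride)
  pos <- t(vapply(ks, function(k) {
    fr <- frame_coords(traj, k)
    tf <- kabsch_superpose(fr[ai, , drop = FALSE], ref[ai, , drop = FALSE])
    as.vector(apply_transform(rbind(fr[ii, ]), tf))
  }, numeric(3)))
  data.frame(frame = ks, time_ns = traj$times[ks],
             x = pos[, 1], y = pos[, 2], z = pos[, 3])
}
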