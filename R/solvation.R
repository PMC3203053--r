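# deterministic quasi-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * (seq_len(n) - 1)
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, test points are placed quasi-uniformly (golden-spiral
#' placement, deterministic) on the sphere of radius \code{r + probe}; the
#' accessible fraction is the share of points not inside any neighbour's
#' probe-inflated sphere, and the per-atom area is that fraction times
#' \code{4 pi (r + probe)^2}.
#'
#' @param coords \code{n x 3} matrix of atom centres (Angstrom).
#' @param radii per-atom van der Waals radii (positive).
#' @param probe probe radius, default 1.4 Angstrom (water).
#' @param n_sphere_points test points per atom (>= 96), default 960.
#' @param subset optional indices: compute areas only for these atoms (all
#'   atoms still occlude).  Default all.
#' @return list with \code{per_atom_area} (Angstrom^2, NA outside
#'   \code{subset}) and \code{group_total} (sum over \code{subset}).
#' @export
sasa <- function(coords, radii, probe = 1.4, n_sphere_points = 960L,
                 subset = NULL) {
  coords <- rbind(as.matrix(coords))
  n <- nrow(coords)
  if (n == 0L) stop("empty input: no atoms for SASA")
  if (length(radii) != n) stop("radii must match atom count")
  if (any(radii <= 0)) stop("radii must be positive")
  if (n_sphere_points < 96L) stop("need n_sphere_points >= 96")
  if (is.null(subset)) subset <- seq_len(n)
  pts <- .sphere_points(n_sphere_points)
  R <- radii + probe
  area <- rep(NA_real_, n)
  for (i in subset) {
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    sp <- sweep(pts * R[i], 2, coords[i, ], `+`)
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(sp, 2, coords[j, ])^2)
      acc <- acc & dj2 >= R[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * R[i]^2 * sum(acc) / n_sphere_points
  }
  list(per_atom_area = area, group_total = sum(area[subset]))
}

#' Per-frame SASA of an atom group within a context
#'
#' Occlusion is computed against all atoms of \code{context_sel} (by default
#' protein plus substrate heavy atoms; waters and ions never occlude).  The
#' group must be a subset of the context.
#'
#' @param traj a \code{trajectory}.
#' @param group_sel selection for the atoms whose area is reported.
#' @param context_sel occluding-atom selection; default all protein and
#'   substrate non-hydrogen atoms.
#' @param probe probe radius (Angstrom).
#' @param n_sphere_points test points per atom.
#' @return a \code{metric_series} in Angstrom^2.
#' @export
group_sasa_series <- function(traj, group_sel, context_sel = NULL,
                              probe = 1.4, n_sphere_points = 960L) {
  top <- traj$topology
  gi <- resolve_selection(top, group_sel)
  ci <- if (is.null(context_sel)) {
    which(top$role %in% c("protein", "substrate") & top$element != "H")
  } else resolve_selection(top, context_sel)
  if (!all(gi %in% ci))
    stop("configuration error: group selection must be within the context")
  sub <- match(gi, ci)
  radii <- top$vdw_radius[ci]
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    fr <- frame_coords(traj, k)
    sasa(fr[ci, , drop = FALSE], radii, probe, n_sphere_points,
         subset = sub)$group_total
  }, numeric(1))
  metric_series("sasa", "Angstrom^2", traj$times, vals)
}

#' Count water molecules near a selection
#'
#' A water counts when its oxygen lies within \code{cutoff} of any atom of
#' the target selection.  Returns 0 when the topology has no waters.
#'
#' @param coords frame coordinates (\code{n_atoms x 3}).
#' @param topology the matching \code{topology}.
#' @param target_sel selection string or list.
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @return integer count of distinct water molecules.
#' @export
count_waters_near <- function(coords, topology, target_sel, cutoff) {
  stopifnot(cutoff > 0)
  wo <- .water_oxygens(topology)
  if (length(wo) == 0L) return(0L)
  ti <- resolve_selection(topology, target_sel)
  W <- coords[wo, , drop = FALSE]
  Tm <- coords[ti, , drop = FALSE]
  d2 <- outer(rowSums(W^2), rowSums(Tm^2), `+`) - 2 * tcrossprod(W, Tm)
  sum(apply(d2, 1, min) < cutoff^2)
}

#' Define an extracellular or intracellular cavity
#'
#' A water belongs to the cavity when its oxygen satisfies all of: the z
#' bounds (strict inequalities, measured relative to a caller-supplied z
#' origin), distance below \code{cutoff} from the reference residue, and
#' distance below \code{cutoff} from the listed TMs (every TM when
#' \code{tm_logic = "all"}, any one when \code{"any"}).
#'
#' @param side "EC" or "IC".
#' @param reference_residue residue id of the reference residue.
#' @param tm_list character TM names (resolved via the selection config).
#' @param cutoff distance cutoff in Angstrom, default 10.
#' @param z_min,z_max z bounds in Angstrom relative to the z origin;
#'   \code{-Inf}/\code{Inf} for unbounded.
#' @param tm_logic "all" (conjunctive, default) or "any".
#' @export
cavity_definition <- function(side, reference_residue, tm_list, cutoff = 10,
                              z_min = -Inf, z_max = Inf, tm_logic = "all") {
  stopifnot(side %in% c("EC", "IC"), cutoff > 0,
            tm_logic %in% c("all", "any"))
  if (is.finite(z_min) && is.finite(z_max) && z_min >= z_max)
    stop("need z_min < z_max")
  structure(list(side = side, reference_residue = reference_residue,
                 tm_list = tm_list, cutoff = cutoff,
                 z_min = z_min, z_max = z_max, tm_logic = tm_logic),
            class = "cavity_definition")
}

#' Count waters occupying a cavity in one frame
#'
#' @param coords frame coordinates.
#' @param topology matching \code{topology}.
#' @param cavity a \code{\link{cavity_definition}}.
#' @param sel_cfg a \code{\link{selection_config}} supplying TM ranges.
#' @param z_origin z (Angstrom) of the reference plane; by convention the
#'   z of the substrate centre of mass.
#' @return integer count.
#' @export
cavity_water_count <- function(coords, topology, cavity, sel_cfg,
                               z_origin = 0) {
  wo <- .water_oxygens(topology)
  if (length(wo) == 0L) return(0L)
  W <- coords[wo, , drop = FALSE]
  ok <- (W[, 3] - z_origin) > cavity$z_min &
        (W[, 3] - z_origin) < cavity$z_max
  ri <- resolve_selection(topology, list(res_id = cavity$reference_residue))
  ok <- ok & .min_dist_to(W, coords[ri, , drop = FALSE]) < cavity$cutoff
  tm_hits <- lapply(cavity$tm_list, function(tm) {
    rng <- sel_cfg$tm_ranges[[tm]]
    if (is.null(rng)) stop("unknown selection: TM '", tm, "' not in config")
    ti <- .tm_indices(topology, rng)
    .min_dist_to(W, coords[ti, , drop = FALSE]) < cavity$cutoff
  })
  tm_ok <- Reduce(if (cavity$tm_logic == "all") `&` else `|`, tm_hits)
  sum(ok & tm_ok)
}

# per-row minimum distance from points P to point set Q
.min_dist_to <- function(P, Q) {
  d2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * tcrossprod(P, Q)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Split the substrate water shell at the substrate's z plane
#'
#' Waters within each cutoff of any substrate atom are partitioned by the z
#' of their oxygen relative to the substrate centre of mass: above (z > 0)
#' counts as extracellular, below as intracellular; a water exactly on the
#' plane is assigned EC.
#'
#' @param coords frame coordinates.
#' @param topology matching \code{topology}.
#' @param substrate_sel substrate selection (non-empty).
#' @param cutoffs numeric vector of shell cutoffs in Angstrom (e.g.
#'   \code{c(3, 4)}).
#' @return data.frame with \code{cutoff}, \code{ec_count}, \code{ic_count}.
#' @export
substrate_shell_split <- function(coords, topology, substrate_sel,
                                  cutoffs = c(3, 4)) {
  si <- resolve_selection(topology, substrate_sel)
  S <- coords[si, , drop = FALSE]
  com <- colSums(S * topology$mass[si]) / sum(topology$mass[si])
  wo <- .water_oxygens(topology)
  if (length(wo) == 0L)
    return(data.frame(cutoff = cutoffs, ec_count = 0L, ic_count = 0L))
  W <- coords[wo, , drop = FALSE]
  dmin <- .min_dist_to(W, S)
  above <- W[, 3] >= com[3]
  data.frame(
    cutoff = cutoffs,
    ec_count = vapply(cutoffs, function(ct) sum(dmin < ct & above), 0L),
    ic_count = vapply(cutoffs, function(ct) sum(dmin < ct & !above), 0L)
  )
}

#' Substrate centre-of-mass z for use as cavity z origin
#' @param coords frame coordinates.
#' @param topology matching \code{topology}.
#' @param substrate_sel substrate selection; default role-based.
#' @export
substrate_com_z <- function(coords, topology,
                            substrate_sel = list(role = "substrate")) {
  si <- resolve_selection(topology, substrate_sel)
  sum(coords[si, 3] * topology$mass[si]) / sum(topology$mass[si])
}
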