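# Sliding 4-point weighted centroids that exactly cancel the C-alpha spiral
# of a canonical 100-degree-per-residue helix, leaving points on the axis.
# Weights w = (1, a, b, 0.75) solve sum_k w_k exp(i k twist) = 0; they are
# fixed, so the filter is linear and rigid-motion equivariant.
.helix_smooth_weights <- function(twist = 100) {
  th <- twist * pi / 180
  A <- rbind(c(cos(th), cos(2 * th)), c(sin(th), sin(2 * th)))
  ab <- solve(A, -c(1 + 0.75 * cos(3 * th), 0.75 * sin(3 * th)))
  c(1, ab[1], ab[2], 0.75)
}

.smooth_ca <- function(X) {
  n <- nrow(X)
  if (n < 5L) return(X)
  w <- .helix_smooth_weights()
  t(vapply(seq_len(n - 3L), function(i)
    colSums(X[i:(i + 3L), ] * w) / sum(w), numeric(3)))
}

#' Fit the axis of a helix from ordered C-alpha coordinates
#'
#' The C-alpha spiral is first collapsed onto the helix axis by a sliding
#' one-turn weighted centroid (exact for the canonical 100-degree twist);
#' the direction is then the principal axis (largest-variance direction) of
#' the centered smoothed points, sign-fixed toward the N-to-C vector (last
#' point minus first) so that the orientation is equivariant under rigid
#' motion.  The smoothing removes the principal-axis bias that plain
#' C-alpha PCA suffers on helices spanning a non-integer number of turns.
#'
#' @param ca_coords ordered \code{n x 3} matrix of C-alpha positions,
#'   \code{n >= 4}.
#' @param polarity +1 to orient along N-to-C (default), -1 to flip (for
#'   helices that run EC-to-IC in sequence order, so all axes can share the
#'   IC-to-EC convention).
#' @return a \code{helix_axis}: list with \code{centroid}, \code{direction}
#'   (unit vector) and \code{n_points}.
#' @export
fit_helix_axis <- function(ca_coords, polarity = 1) {
  X <- rbind(as.matrix(ca_coords))
  if (nrow(X) < 4L)
    stop("degenerate geometry: helix axis needs >= 4 points")
  ctr <- colMeans(X)
  Xs <- .smooth_ca(X)
  s <- svd(sweep(Xs, 2, colMeans(Xs)), nu = 0, nv = 3)
  dir <- s$v[, 1]
  nc <- X[nrow(X), ] - X[1, ]
  ref <- polarity * nc
  if (sum(ref^2) > 0 && sum(dir * ref) < 0) dir <- -dir
  structure(list(centroid = ctr, direction = dir / sqrt(sum(dir^2)),
                 n_points = nrow(X)),
            class = "helix_axis")
}

#' Angle between two helix axes
#'
#' Unsigned angle between the oriented direction vectors, in [0, 180]
#' degrees (dot product clamped to [-1, 1] before acos).
#'
#' @param a,b \code{helix_axis} objects.
#' @return angle in degrees.
#' @export
tilt_angle <- function(a, b) {
  d <- sum(a$direction * b$direction)
  acos(max(-1, min(1, d))) * 180 / pi
}

#' Composite axis of a TM group
#'
#' Principal axis of the pooled spiral-smoothed C-alpha coordinates of all
#' member TMs (not the mean of per-helix axes), sign-fixed against the
#' polarity-weighted sum of the member N-to-C vectors so antiparallel
#' helices vote consistently.
#'
#' @param coords frame coordinates.
#' @param topology matching \code{topology}.
#' @param tm_names character vector of TM names in \code{sel_cfg$tm_ranges}.
#' @param sel_cfg a \code{\link{selection_config}}.
#' @return a \code{helix_axis}.
#' @export
group_axis <- function(coords, topology, tm_names, sel_cfg) {
  pooled <- NULL
  ref <- c(0, 0, 0)
  for (tm in tm_names) {
    rng <- sel_cfg$tm_ranges[[tm]]
    if (is.null(rng)) stop("unknown selection: TM '", tm, "' not in config")
    ca <- .ca_indices(topology, .tm_indices(topology, rng))
    if (length(ca) < 4L)
      stop("degenerate geometry: TM ", tm, " has fewer than 4 C-alphas")
    X <- coords[ca, , drop = FALSE]
    pooled <- rbind(pooled, .smooth_ca(X))
    pol <- sel_cfg$tm_polarity[tm]
    if (is.na(pol) || is.null(pol)) pol <- 1
    ref <- ref + pol * (X[nrow(X), ] - X[1, ])
  }
  ctr <- colMeans(pooled)
  s <- svd(sweep(pooled, 2, ctr), nu = 0, nv = 3)
  dir <- s$v[, 1]
  if (sum(ref^2) > 0 && sum(dir * ref) < 0) dir <- -dir
  structure(list(centroid = ctr, direction = dir / sqrt(sum(dir^2)),
                 n_points = nrow(pooled)),
            class = "helix_axis")
}

#' Per-frame tilt angles for a list of TM-group pairs
#'
#' Angles are frame-internal (no global alignment needed: they are
#' invariant under rigid motion of the frame).  Pairs may mix composite
#' groups (e.g. the scaffold) and single or sub-range TMs (e.g. TM1a).
#'
#' @param traj a \code{trajectory}.
#' @param pairs named list; each element a list of two character vectors
#'   \code{(groupA tm_names, groupB tm_names)}.  Unnamed pairs are labelled
#'   "A/B" from their first members.
#' @param sel_cfg a \code{\link{selection_config}}.
#' @return named list of \code{metric_series} (degrees).
#' @export
tilt_angle_series <- function(traj, pairs, sel_cfg) {
  top <- traj$topology
  labs <- names(pairs)
  if (is.null(labs)) labs <- rep("", length(pairs))
  labs <- ifelse(nzchar(labs), labs,
                 vapply(pairs, function(p)
                   paste(p[[1]][1], p[[2]][1], sep = "/"), ""))
  nf <- n_frames(traj)
  out <- lapply(seq_along(pairs), function(j) {
    ga <- pairs[[j]][[1]]; gb <- pairs[[j]][[2]]
    vals <- vapply(seq_len(nf), function(k) {
      fr <- frame_coords(traj, k)
      tilt_angle(group_axis(fr, top, ga, sel_cfg),
                 group_axis(fr, top, gb, sel_cfg))
    }, numeric(1))
    metric_series(labs[j], "degrees", traj$times, vals)
  })
  stats::setNames(out, labs)
}

#' Classify a frame's bundle orientation against reference structures
#'
#' The frame's scaffold C-alphas are superposed onto each reference's
#' scaffold; the bundle axis is then expressed in that common frame and
#' compared with the reference's bundle axis.  The nearest reference (the
#' smallest angle) labels the frame's conformational state.
#'
#' @param coords frame coordinates.
#' @param topology matching \code{topology}.
#' @param sel_cfg a \code{\link{selection_config}} with scaffold and bundle
#'   TM lists.
#' @param references named list; each element a list with \code{coords} and
#'   optionally \code{topology} (defaults to the frame's topology).  Every
#'   reference must share the scaffold C-alpha count.
#' @return list with \code{axis} (frame bundle axis, frame coordinates),
#'   \code{angle_to_each} (named degrees) and \code{nearest_label}.
#' @export
bundle_state_vector <- function(coords, topology, sel_cfg, references) {
  stopifnot(length(references) >= 1L, !is.null(names(references)))
  sc_sel <- list(res_id = unlist(lapply(sel_cfg$scaffold_tms, function(tm)
    seq(sel_cfg$tm_ranges[[tm]][1], sel_cfg$tm_ranges[[tm]][2]))))
  ca <- .ca_indices(topology, resolve_selection(topology, sc_sel))
  ax <- group_axis(coords, topology, sel_cfg$bundle_tms, sel_cfg)
  angles <- vapply(names(references), function(lb) {
    ref <- references[[lb]]
    rtop <- ref$topology %||% topology
    rca <- .ca_indices(rtop, resolve_selection(rtop, sc_sel))
    if (length(rca) != length(ca))
      stop("topology mismatch: reference '", lb, "' scaffold has ",
           length(rca), " C-alphas, frame has ", length(ca))
    tf <- kabsch_superpose(coords[ca, , drop = FALSE],
                           ref$coords[rca, , drop = FALSE])
    dir_common <- as.vector(tf$rotation %*% ax$direction)
    rax <- group_axis(ref$coords, rtop, sel_cfg$bundle_tms, sel_cfg)
    acos(max(-1, min(1, sum(dir_common * rax$direction)))) * 180 / pi
  }, numeric(1))
  list(axis = ax, angle_to_each = angles,
       nearest_label = names(which.min(angles)))
}
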