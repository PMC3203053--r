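#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the least-squares
#' deviation of \code{mobile} onto \code{reference}.  If the optimal
#' orthogonal matrix is a reflection (determinant -1) the axis of smallest
#' singular value is flipped so a proper rotation is always returned.
#'
#' @param mobile,reference numeric \code{n x 3} matrices, equal \code{n >= 3},
#'   not collinear.
#' @return list with \code{rotation} (3x3, det +1), \code{translation}
#'   (length-3), and \code{rmsd} (Angstrom) after the transform.  The fitted
#'   position of a point x is \code{rotation \%*\% x + translation}.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be equal-sized n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop("degenerate geometry: need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); R0 <- sweep(reference, 2, cr)
  # collinearity check on both point sets
  if (svd(M)$d[2] < 1e-8 * max(svd(M)$d[1], 1) ||
      svd(R0)$d[2] < 1e-8 * max(svd(R0)$d[1], 1))
    stop("degenerate geometry: points are collinear")
  H <- crossprod(M, R0)              # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  rot <- s$v %*% D %*% t(s$u)
  trans <- cr - as.vector(rot %*% cm)
  fitted <- M %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - R0)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords \code{n x 3} matrix.
#' @param tf transform from \code{\link{kabsch_superpose}}.
#' @export
apply_transform <- function(coords, tf) {
  sweep(as.matrix(coords) %*% t(tf$rotation), 2, tf$translation, `+`)
}

#' Per-frame RMSD after superposition
#'
#' Each frame is superposed onto the reference frame using the C-alpha atoms
#' of \code{align_sel}; the RMSD is then measured over the C-alpha atoms of
#' \code{measure_sel}.
#'
#' @param traj a \code{trajectory}.
#' @param reference_frame reference frame index (default 1, the first frame).
#' @param align_sel,measure_sel selection strings or lists
#'   (\code{\link{resolve_selection}}).
#' @param ca_only restrict both selections to C-alpha atoms (default TRUE).
#' @return a \code{metric_series} in Angstrom.
#' @export
rmsd_series <- function(traj, reference_frame = 1L, align_sel, measure_sel,
                        ca_only = TRUE) {
  top <- traj$topology
  ai <- resolve_selection(top, align_sel)
  mi <- resolve_selection(top, measure_sel)
  if (ca_only) { ai <- .ca_indices(top, ai); mi <- .ca_indices(top, mi) }
  if (length(ai) == 0L || length(mi) == 0L)
    stop("unknown selection: no C-alpha atoms in align/measure selection")
  ref <- frame_coords(traj, reference_frame)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    fr <- frame_coords(traj, k)
    tf <- kabsch_superpose(fr[ai, , drop = FALSE], ref[ai, , drop = FALSE])
    moved <- apply_transform(fr[mi, , drop = FALSE], tf)
    sqrt(mean(rowSums((moved - ref[mi, , drop = FALSE])^2)))
  }, numeric(1))
  metric_series("rmsd", "Angstrom", traj$times, vals)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are first superposed onto the first frame via the C-alpha atoms of
#' \code{align_sel}; the RMSF of each C-alpha of \code{measure_sel} is then
#' computed about the mean structure (single pass, no iterative mean
#' refinement).
#'
#' @param traj a \code{trajectory} with at least 2 frames.
#' @param align_sel,measure_sel selections.
#' @return data.frame with \code{res_id}, \code{chain}, \code{rmsf}
#'   (Angstrom).
#' @export
rmsf <- function(traj, align_sel, measure_sel) {
  if (n_frames(traj) < 2L)
    stop("insufficient frames: RMSF needs at least 2 frames")
  top <- traj$topology
  ai <- .ca_indices(top, resolve_selection(top, align_sel))
  mi <- .ca_indices(top, resolve_selection(top, measure_sel))
  if (length(ai) < 3L) stop("unknown selection: alignment needs >= 3 C-alphas")
  if (length(mi) == 0L) stop("unknown selection: empty measure selection")
  ref <- frame_coords(traj, 1L)
  nf <- n_frames(traj)
  aligned <- array(0, dim = c(length(mi), 3L, nf))
  for (k in seq_len(nf)) {
    fr <- frame_coords(traj, k)
    tf <- kabsch_superpose(fr[ai, , drop = FALSE], ref[ai, , drop = FALSE])
    aligned[, , k] <- apply_transform(fr[mi, , drop = FALSE], tf)
  }
  mean_str <- apply(aligned, c(1, 2), mean)
  dev2 <- vapply(seq_len(nf), function(k)
    rowSums((aligned[, , k, drop = TRUE] - mean_str)^2), numeric(length(mi)))
  dev2 <- matrix(dev2, nrow = length(mi))
  data.frame(res_id = top$res_id[mi], chain = top$chain[mi],
             rmsf = sqrt(rowMeans(dev2)))
}
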