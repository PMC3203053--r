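#' Read trajectory frames into a Trajectory object
#'
#' Accepts multi-model PDB files and binary CHARMM/NAMD DCD files (format
#' chosen by file extension); several files are concatenated in the order
#' given.  Frame times are assigned from a fixed spacing.
#'
#' @param paths character vector of trajectory file paths.
#' @param topology a \code{topology} from \code{\link{load_topology}}; every
#'   frame must carry exactly this atom count.
#' @param dt frame spacing in ns (default 0.1 ns, i.e. 1000 snapshots per
#'   100 ns).
#' @param t0 time of the first frame in ns.
#' @return a \code{trajectory} object: list with \code{topology},
#'   \code{coords} (array \code{n_atoms x 3 x n_frames}, Angstrom) and
#'   \code{times} (ns, strictly increasing).
#' @export
load_trajectory <- function(paths, topology, dt = 0.1, t0 = 0) {
  if (length(paths) == 0L) stop("empty input: no trajectory files given")
  stopifnot(inherits(topology, "topology"))
  xyz_list <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("trajectory file not found: ", p)
    if (grepl("\\.dcd$", p, ignore.case = TRUE)) {
      m <- tryCatch(bio3d::read.dcd(p, verbose = FALSE),
                    error = function(e) stop("I/O error reading DCD '", p,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
      if (is.null(dim(m))) m <- matrix(m, nrow = 1)
      m
    } else {
      pdb <- suppressWarnings(bio3d::read.pdb(p, multi = TRUE,
                                              verbose = FALSE))
      m <- pdb$xyz
      if (is.null(dim(m))) m <- matrix(m, nrow = 1)
      m
    }
  })
  xyz <- do.call(rbind, xyz_list)
  n_fr <- nrow(xyz)
  if (n_fr == 0L) stop("empty input: trajectory contains no frames")
  na <- nrow(topology)
  if (ncol(xyz) != 3L * na)
    stop("topology mismatch: trajectory frames have ", ncol(xyz) / 3,
         " atoms, topology has ", na)
  coords <- array(0, dim = c(na, 3L, n_fr))
  for (k in seq_len(n_fr))
    coords[, , k] <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
  new_trajectory(topology, coords, t0 + dt * (seq_len(n_fr) - 1))
}

#' Construct a trajectory from in-memory coordinates
#'
#' @param topology a \code{topology}.
#' @param coords array \code{n_atoms x 3 x n_frames} in Angstrom.
#' @param times frame times in ns, strictly increasing.
#' @export
new_trajectory <- function(topology, coords, times) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(topology))
    stop("topology mismatch: coords have ", dim(coords)[1],
         " atoms, topology has ", nrow(topology))
  if (dim(coords)[3] != length(times))
    stop("times length must equal the number of frames")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, coords = coords, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames x", dim(x$coords)[1], "atoms, t =",
      x$times[1], "..", x$times[n_frames(x)], "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{trajectory}.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj a \code{trajectory}.
#' @param i frame index (1-based).
#' @return numeric \code{n_atoms x 3} matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}
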