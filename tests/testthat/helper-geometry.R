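# shared geometry helpers and brute-force oracles

rot_mat <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rot_mat(ax, stats::runif(1, 0, 360))
}

apply_rigid <- function(X, R, t) sweep(as.matrix(X) %*% t(R), 2, t, `+`)

# exhaustive minimum cross-pair distance
brute_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

# best superposition RMSD by Euler-angle grid search with shrinking
# refinement; independent of the SVD route
grid_rmsd <- function(mobile, reference) {
  M <- sweep(mobile, 2, colMeans(mobile))
  R0 <- sweep(reference, 2, colMeans(reference))
  euler <- function(a, b, c) rot_mat(c(0, 0, 1), a) %*%
    rot_mat(c(0, 1, 0), b) %*% rot_mat(c(0, 0, 1), c)
  f <- function(p) {
    D <- M %*% t(euler(p[1], p[2], p[3])) - R0
    sqrt(mean(rowSums(D^2)))
  }
  best <- c(0, 0, 0); bf <- f(best)
  for (a in seq(0, 345, by = 15)) for (b in seq(0, 180, by = 15))
    for (c in seq(0, 345, by = 15)) {
      v <- f(c(a, b, c))
      if (v < bf) { bf <- v; best <- c(a, b, c) }
    }
  step <- 7.5
  while (step > 0.002) {
    off <- expand.grid(a = -2:2, b = -2:2, c = -2:2)
    for (i in seq_len(nrow(off))) {
      p <- best + step * as.numeric(off[i, ])
      v <- f(p)
      if (v < bf) { bf <- v; best <- p }
    }
    step <- step / 2
  }
  bf
}

# place a fourth atom at prescribed bond length, angle and torsion (NeRF)
place_dihedral_atom <- function(a, b, c, length, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180; tor <- torsion_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- pracma::cross(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- pracma::cross(n, bc)
  d2 <- c(-length * cos(ang), length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# minimal hand-built topology for constructed-geometry tests
make_topology <- function(n, name = "CA", res_name = "ALA",
                          res_id = seq_len(n), role = "protein",
                          element = NULL) {
  name <- rep_len(name, n); res_name <- rep_len(res_name, n)
  res_id <- rep_len(res_id, n); role <- rep_len(role, n)
  if (is.null(element)) element <- substr(name, 1, 1)
  element <- rep_len(element, n)
  top <- data.frame(serial = seq_len(n), name = name, element = element,
                    res_name = res_name, res_id = res_id, chain = "A",
                    role = role, vdw_radius = vdw_radius(element),
                    mass = transportscope:::.atomic_mass(element),
                    stringsAsFactors = FALSE)
  class(top) <- c("topology", "data.frame")
  top
}

make_traj <- function(top, frames, dt = 0.1) {
  coords <- array(0, dim = c(nrow(top), 3, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
  new_trajectory(top, coords, dt * (seq_along(frames) - 1))
}

# small toy-transporter runs shared between test files (cached)
small_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_toy_trajectory(
        toy_transporter_spec(n_frames = 30L,
                             hinge_profile = list(start_deg = 0,
                                                  end_deg = 25,
                                                  ramp_start = 5L,
                                                  ramp_end = 25L),
                             ion_release_frame = NA_integer_,
                             gate_rupture_frame = 12L, seed = 42L))
    cache
  }
})
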