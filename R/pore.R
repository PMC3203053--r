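#' Pore radius profile along a channel axis
#'
#' For each slice along the axis, reports the radius of the largest sphere
#' centred in that plane that does not overlap any van der Waals sphere:
#' \code{radius(c) = min over atoms (|c - atom| - vdw)}, maximized over
#' candidate centres within \code{search_radius} of the axis.  The search
#' is a deterministic coarse grid followed by a shrinking-grid local
#' descent refined to a step of \code{grid_step / 16}; this replaces the
#' Monte Carlo annealing of classic pore programs while preserving their
#' objective, so profiles are exactly reproducible.
#'
#' By default only protein and substrate heavy atoms block the pore; waters
#' and ions are excluded.
#'
#' @param coords frame coordinates (\code{n_atoms x 3}).
#' @param topology matching \code{topology}, or NULL when \code{radii} and
#'   \code{block_idx} are given explicitly.
#' @param axis_point a point on the channel axis (Angstrom).
#' @param axis_dir axis direction (normalized internally); default +z, the
#'   membrane normal.
#' @param z_range \code{c(z_min, z_max)} along the axis relative to
#'   \code{axis_point}.
#' @param z_step slice spacing (Angstrom), default 0.5.
#' @param search_radius in-plane search extent around the axis, default 10.
#' @param grid_step coarse grid spacing, default 0.5.
#' @param radii,block_idx optional explicit per-atom radii and blocking-atom
#'   indices (override the topology-based default).
#' @return a \code{pore_profile}: data.frame with \code{z}, \code{radius}
#'   (clamped at 0, capped at \code{search_radius}), \code{cx}, \code{cy},
#'   \code{cz} (sphere centre) and \code{unbounded} (TRUE when no atom was
#'   near enough to bound the slice).
#' @export
pore_radius_profile <- function(coords, topology = NULL,
                                axis_point = c(0, 0, 0),
                                axis_dir = c(0, 0, 1),
                                z_range = c(-15, 15), z_step = 0.5,
                                search_radius = 10, grid_step = 0.5,
                                radii = NULL, block_idx = NULL) {
  stopifnot(z_step > 0, grid_step > 0, search_radius > 0)
  coords <- as.matrix(coords)
  if (is.null(block_idx)) {
    if (is.null(topology)) stop("need a topology or explicit block_idx")
    block_idx <- which(topology$role %in% c("protein", "substrate") &
                       topology$element != "H")
  }
  if (is.null(radii)) radii <- topology$vdw_radius
  if (length(block_idx) == 0L) stop("no blocking atoms for pore profile")
  A <- coords[block_idx, , drop = FALSE]
  r <- radii[block_idx]
  u <- axis_dir / sqrt(sum(axis_dir^2))
  # orthonormal in-plane basis
  tmp <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- tmp - sum(tmp * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  # coarse candidate grid in the plane (disk of search_radius)
  g <- seq(-search_radius, search_radius, by = grid_step)
  cand <- as.matrix(expand.grid(a = g, b = g))
  cand <- cand[rowSums(cand^2) <= search_radius^2, , drop = FALSE]
  zs <- seq(z_range[1], z_range[2], by = z_step)
  max_r <- max(r)
  f_at <- function(P, Asub, rsub) {
    # P: m x 3 candidate centres; returns min_i |P - A_i| - r_i per row
    d2 <- outer(rowSums(P^2), rowSums(Asub^2), `+`) - 2 * tcrossprod(P, Asub)
    apply(sweep(sqrt(pmax(d2, 0)), 2, rsub), 1, min)
  }
  res <- data.frame(z = zs, radius = NA_real_, cx = NA_real_, cy = NA_real_,
                    cz = NA_real_, unbounded = FALSE)
  for (si in seq_along(zs)) {
    p0 <- axis_point + zs[si] * u
    # atoms able to bound any candidate below the search_radius cap
    d0 <- sqrt(rowSums(sweep(A, 2, p0)^2))
    near <- d0 <= 2 * search_radius + max_r
    if (!any(d0 <= search_radius + max_r + 20)) {
      res$radius[si] <- search_radius
      res[si, c("cx", "cy", "cz")] <- p0
      res$unbounded[si] <- TRUE
      next
    }
    Asub <- A[near, , drop = FALSE]; rsub <- r[near]
    if (nrow(Asub) == 0L) {  # bounded only by distant atoms: cap
      res$radius[si] <- search_radius
      res[si, c("cx", "cy", "cz")] <- p0
      res$unbounded[si] <- TRUE
      next
    }
    P <- sweep(cand[, 1, drop = FALSE] %*% rbind(e1) +
               cand[, 2, drop = FALSE] %*% rbind(e2), 2, p0, `+`)
    fv <- f_at(P, Asub, rsub)
    best <- which.max(fv)
    bc <- P[best, ]; bf <- fv[best]
    # shrinking-grid descent around the best coarse point
    step <- grid_step / 2
    off <- as.matrix(expand.grid(a = -2:2, b = -2:2))
    while (step > grid_step / 16) {
      L <- sweep(off[, 1, drop = FALSE] %*% rbind(e1) * step +
                 off[, 2, drop = FALSE] %*% rbind(e2) * step, 2, bc, `+`)
      # keep candidates inside the search disk
      rel <- sweep(L, 2, p0)
      inplane2 <- (rel %*% e1)^2 + (rel %*% e2)^2
      keep <- inplane2 <= search_radius^2
      L <- L[keep, , drop = FALSE]
      fl <- f_at(L, Asub, rsub)
      w <- which.max(fl)
      if (fl[w] > bf) { bf <- fl[w]; bc <- L[w, ] } else step <- step / 2
    }
    res$radius[si] <- min(max(bf, 0), search_radius)
    res$unbounded[si] <- bf >= search_radius
    res[si, c("cx", "cy", "cz")] <- bc
  }
  class(res) <- c("pore_profile", "data.frame")
  attr(res, "axis_point") <- axis_point
  attr(res, "axis_dir") <- u
  res
}

#' Align several pore profiles on a common z grid
#'
#' Profiles are linearly interpolated onto the z grid of their overlap
#' region; per-region means (EC: z > 0, IC: z < 0) are reported per
#' profile.
#'
#' @param profiles named list of \code{pore_profile} objects (>= 2, with
#'   overlapping z ranges).
#' @return list with \code{table} (data.frame: z plus one radius column per
#'   label) and \code{region_means} (data.frame: label, ec_mean, ic_mean).
#' @export
compare_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 2L, !is.null(names(profiles)))
  lo <- max(vapply(profiles, function(p) min(p$z), numeric(1)))
  hi <- min(vapply(profiles, function(p) max(p$z), numeric(1)))
  if (lo >= hi) stop("no overlap between profile z ranges")
  step <- min(vapply(profiles, function(p) min(diff(p$z)), numeric(1)))
  zg <- seq(lo, hi, by = step)
  tab <- data.frame(z = zg)
  for (lb in names(profiles)) {
    p <- profiles[[lb]]
    tab[[lb]] <- stats::approx(p$z, p$radius, xout = zg)$y
  }
  rm_ <- do.call(rbind, lapply(names(profiles), function(lb) {
    v <- tab[[lb]]
    data.frame(label = lb,
               ec_mean = mean(v[zg > 0]),
               ic_mean = mean(v[zg < 0]))
  }))
  list(table = tab, region_means = rm_)
}
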