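# --- small geometry helpers -------------------------------------------------

# Rodrigues rotation matrix: angle (radians) about unit axis
.axis_angle <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# rotation taking +z onto 'direction'
.rotation_to <- function(direction) {
  b <- direction / sqrt(sum(direction^2))
  a <- c(0, 0, 1)
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (sum(v^2) < 1e-14) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))   # 180 degrees about x
  }
  .axis_angle(v, acos(max(-1, min(1, c_))))
}

# run code with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# --- ideal helix ------------------------------------------------------------

# canonical alpha-helix parameters: 1.5 A rise and 100 degree twist per
# residue, C-alpha at 2.3 A from the axis; backbone partners on nearby
# concentric helices
.helix_atoms <- data.frame(
  name = c("N", "CA", "CB", "C", "O"),
  radius = c(1.60, 2.30, 3.30, 1.70, 1.90),
  phase = c(-28, 0, 8, 27, 40),       # degrees relative to the CA
  dz = c(-0.90, 0, 0.20, 1.05, 1.30),
  stringsAsFactors = FALSE
)

#' Build an ideal alpha-helix
#'
#' Canonical geometry: 1.5 Angstrom rise and 100 degree twist per residue,
#' C-alpha radius 2.3 Angstrom, with N, CB, C and O placed on nearby
#' concentric helices.  Deterministic.
#'
#' @param n_res number of residues (>= 4).
#' @param origin position of the helix axis at the first residue's z.
#' @param direction helix axis direction (normalized internally).
#' @return list with \code{coords} (\code{5*n_res x 3}), \code{atom_name},
#'   \code{res_index} (1..n_res per atom) and \code{ca_rows}.
#' @export
build_ideal_helix <- function(n_res, origin = c(0, 0, 0),
                              direction = c(0, 0, 1)) {
  if (n_res < 4L) stop("need n_res >= 4 for a helix")
  per <- .helix_atoms
  rows <- n_res * nrow(per)
  coords <- matrix(0, rows, 3)
  atom_name <- character(rows); res_index <- integer(rows)
  k <- 0L
  for (i in seq_len(n_res)) {
    for (j in seq_len(nrow(per))) {
      k <- k + 1L
      ang <- (100 * (i - 1) + per$phase[j]) * pi / 180
      coords[k, ] <- c(per$radius[j] * cos(ang), per$radius[j] * sin(ang),
                       1.5 * (i - 1) + per$dz[j])
      atom_name[k] <- per$name[j]; res_index[k] <- i
    }
  }
  R <- .rotation_to(direction)
  coords <- sweep(coords %*% t(R), 2, origin, `+`)
  list(coords = coords, atom_name = atom_name, res_index = res_index,
       ca_rows = which(atom_name == "CA"))
}

# --- toy transporter spec ---------------------------------------------------

#' Specification of a synthetic toy transporter trajectory
#'
#' The toy emulates the geometry and bookkeeping of an alternating-access
#' transition, not physics: a static scaffold of helices on a ring, a
#' four-helix bundle whose intracellular halves of the hinge TMs swing
#' outward following a programmed angle schedule, cavity waters whose
#' occupancy tracks the opening, a bound ion that leaves along -z at a
#' scripted frame into a mobile first hydration shell, a central substrate
#' pseudo-residue, and two salt-bridge gates (the intracellular one rupturing
#' at a scripted frame).  All randomness is fixed by \code{seed}.
#'
#' @param n_tms number of TM helices (default 10, on a 36-degree ring).
#' @param residues_per_tm residues per helix (default 22).
#' @param ring_radius radius of the helix ring (Angstrom, default 8).
#' @param bundle_tms,scaffold_tms TM name partitions.
#' @param hinge_tms TMs whose intracellular halves hinge (default TM1, TM6).
#' @param hinge_split residue index separating the a (IC) and b (EC)
#'   sub-helices; default half of \code{residues_per_tm}.
#' @param hinge_profile list \code{(start_deg, end_deg, ramp_start,
#'   ramp_end)}: hinge angle is \code{start_deg} through frame
#'   \code{ramp_start}, ramps linearly to \code{end_deg} at frame
#'   \code{ramp_end}, then stays (1-based frames).
#' @param cavity_water_rate expected IC cavity waters per frame per degree
#'   of opening (default 0.6; at the default 25 degree plateau the mean
#'   occupancy is 15).
#' @param ec_water_rate constant expected EC cavity water count (default 3).
#' @param ion_release_frame frame at which the ion unbinds, or NA.
#' @param gate_rupture_frame frame at which the IC gate distance steps from
#'   3 to 8 Angstrom, or NA.
#' @param n_frames,frame_dt trajectory length and spacing (ns).
#' @param n_waters size of the water pool (single-oxygen waters, <= 500).
#' @param seed RNG seed fixing all randomness.
#' @export
toy_transporter_spec <- function(n_tms = 10L, residues_per_tm = 22L,
                                 ring_radius = 8,
                                 bundle_tms = c("TM1", "TM2", "TM6", "TM7"),
                                 scaffold_tms = c("TM3", "TM4", "TM5",
                                                  "TM8", "TM9", "TM10"),
                                 hinge_tms = c("TM1", "TM6"),
                                 hinge_split = NULL,
                                 hinge_profile = list(start_deg = 0,
                                                      end_deg = 25,
                                                      ramp_start = 20L,
                                                      ramp_end = 60L),
                                 cavity_water_rate = 0.6,
                                 ec_water_rate = 3,
                                 ion_release_frame = 70L,
                                 gate_rupture_frame = 40L,
                                 n_frames = 100L, frame_dt = 0.1,
                                 n_waters = 80L, seed = 1L) {
  if (is.null(hinge_split)) hinge_split <- residues_per_tm %/% 2L
  if (hinge_split < 4L || hinge_split > residues_per_tm - 4L)
    stop("spec error: hinge split must leave >= 4 residues on each side")
  if (hinge_profile$end_deg < 0 || hinge_profile$end_deg > 90 ||
      hinge_profile$start_deg < 0 || hinge_profile$start_deg > 90)
    stop("spec error: hinge angles must lie in [0, 90] degrees")
  if (n_frames < 2L) stop("spec error: need >= 2 frames")
  if (n_waters > 500L) stop("spec error: water pool capped at 500")
  if (!all(hinge_tms %in% bundle_tms))
    stop("spec error: hinge TMs must belong to the bundle")
  structure(list(n_tms = n_tms, residues_per_tm = residues_per_tm,
                 ring_radius = ring_radius, bundle_tms = bundle_tms,
                 scaffold_tms = scaffold_tms, hinge_tms = hinge_tms,
                 hinge_split = hinge_split, hinge_profile = hinge_profile,
                 cavity_water_rate = cavity_water_rate,
                 ec_water_rate = ec_water_rate,
                 ion_release_frame = ion_release_frame,
                 gate_rupture_frame = gate_rupture_frame,
                 n_frames = n_frames, frame_dt = frame_dt,
                 n_waters = n_waters, seed = seed),
            class = "toy_transporter_spec")
}

#' Programmed hinge angle per frame
#' @param spec a \code{toy_transporter_spec}.
#' @return numeric vector (degrees), one value per frame.
#' @export
hinge_schedule <- function(spec) {
  p <- spec$hinge_profile
  t <- seq_len(spec$n_frames)
  frac <- (t - p$ramp_start) / (p$ramp_end - p$ramp_start)
  frac <- pmin(pmax(frac, 0), 1)
  p$start_deg + frac * (p$end_deg - p$start_deg)
}

# --- generator --------------------------------------------------------------

#' Generate a toy transporter trajectory with exact ground truth
#'
#' Writes \code{traj.pdb} (multi-model), \code{ground_truth.json} and
#' \code{config.yaml} (a matching \code{\link{selection_config}}) into
#' \code{dir}, optionally also \code{traj.dcd}, and returns the in-memory
#' trajectory plus ground truth.  Identical spec (including seed) gives
#' byte-identical output.
#'
#' @param spec a \code{\link{toy_transporter_spec}}.
#' @param dir output directory (created if absent).
#' @param dcd also write a DCD copy of the coordinates.
#' @return list with \code{trajectory}, \code{ground_truth},
#'   \code{config} (selection_config), \code{site}
#'   (\code{\link{coordination_site}} of the toy Na2 site) and \code{paths}.
#' @export
generate_toy_trajectory <- function(spec, dir = tempfile("toytraj"),
                                    dcd = FALSE) {
  stopifnot(inherits(spec, "toy_transporter_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nres <- spec$residues_per_tm
  rise <- 1.5
  z0 <- -(nres - 1) * rise / 2
  tm_names <- paste0("TM", seq_len(spec$n_tms))

  ## ---- static base structure
  atom_name <- character(); res_name <- character()
  res_id <- integer(); base <- NULL
  add <- function(names, resnm, rid, coords) {
    atom_name <<- c(atom_name, names)
    res_name <<- c(res_name, rep(resnm, length(names)))
    res_id <<- c(res_id, rep(rid, length(names)))
    base <<- rbind(base, coords)
  }
  tm_rows <- list()    # row indices per TM
  tm_res_rows <- list() # row indices per TM per residue index
  for (m in seq_len(spec$n_tms)) {
    phi <- 2 * pi * (m - 1) / spec$n_tms
    org <- c(spec$ring_radius * cos(phi), spec$ring_radius * sin(phi), z0)
    hx <- build_ideal_helix(nres, origin = org)
    first <- length(res_id) + 1L
    for (i in seq_len(nres)) {
      rows <- which(hx$res_index == i)
      add(hx$atom_name[rows], "ALA", 1000L + 100L * m + i, hx$coords[rows, ])
    }
    tm_rows[[tm_names[m]]] <- seq(first, length(res_id))
    tm_res_rows[[tm_names[m]]] <- lapply(seq_len(nres), function(i)
      first - 1L + which(hx$res_index == i))
  }
  ## substrate (5HT pseudo-residue), centre of mass exactly at the origin
  add(c("C1", "C2", "C3", "C4", "N1"), "5HT", 900L,
      rbind(c(1.2, 0, 0.4), c(0, 1.2, -0.4), c(-1.2, 0, 0.4),
            c(0, -1.2, -0.4), c(0, 0, 0)))
  ## Na2-like site below the substrate, with its two coordination partners
  site <- c(0, 0, -2)
  add(c("N", "CA", "CB", "CG", "OD1", "OD2"), "ASP", 437L,
      rbind(c(0, 0.8, 2.9), c(0, 1.5, 1.9), c(0, 1.5, 0.4),
            c(0, 0.8, -0.6), site + c(0, 0, 2.3), c(1.1, 0.8, -0.4)))
  add(c("N", "CA", "C", "O"), "GLY", 94L,
      rbind(c(3.3, 0, -1.2), site + c(2.5, 0, 0), c(3.3, 0, -2.8),
            c(4.2, 0, -3.2)))
  ## cavity reference residues (EC: 335, IC: 341), off the hinge azimuth
  add(c("CA", "CB", "CG"), "PHE", 335L,
      rbind(c(0, 4.5, 5), c(0, 5.2, 5.8), c(0, 6.0, 6.4)))
  add(c("CA", "CB", "CG"), "PHE", 341L,
      rbind(c(0, 4.5, -5), c(0, 5.2, -5.8), c(0, 6.0, -6.4)))
  ## EC gate (static, formed at 3.0 A) on the +y side
  add(c("CA", "OE1", "OE2"), "GLU", 493L,
      rbind(c(0, 14.8, 6.8), c(0, 15, 6), c(-0.8, 14.6, 6.5)))
  add(c("CA", "NH1", "NH2"), "ARG", 104L,
      rbind(c(0, 18.5, 6.5), c(0, 18, 6), c(0.8, 18.4, 6.5)))
  ## IC gate (ruptures) on the -y side; NH positions move per frame
  add(c("CA", "OD1", "OD2"), "ASP", 452L,
      rbind(c(0, -14.8, -6.8), c(0, -15, -6), c(-0.8, -14.6, -6.5)))
  arg79_first <- length(res_id) + 1L
  add(c("CA", "NH1", "NH2"), "ARG", 79L,
      rbind(c(0, -18.5, -6.5), c(0, -18, -6), c(0.8, -18.4, -6.5)))
  ion_row <- length(res_id) + 1L
  add("NA", "NA", 901L, rbind(site))
  water_first <- length(res_id) + 1L
  for (w in seq_len(spec$n_waters))
    add("O", "HOH", 3000L + w, rbind(c(26 + 3 * ((w - 1) %% 8),
                                       30 + 3 * ((w - 1) %/% 8), -28)))
  n_at <- length(res_id)

  ## ---- hinge bookkeeping
  theta <- hinge_schedule(spec)
  zsplit <- z0 + rise * (spec$hinge_split - 0.5)
  hinges <- lapply(spec$hinge_tms, function(tm) {
    m <- match(tm, tm_names)
    phi <- 2 * pi * (m - 1) / spec$n_tms
    pivot <- c(spec$ring_radius * cos(phi), spec$ring_radius * sin(phi),
               zsplit)
    taxis <- c(-sin(phi), cos(phi), 0)
    rows <- unlist(tm_res_rows[[tm]][seq_len(spec$hinge_split)])
    # pick the rotation sign that swings the IC end radially outward
    probe <- base[rows[which.min(base[rows, 3])], ]
    sgn <- 1
    for (s in c(1, -1)) {
      p2 <- .axis_angle(taxis, s * 10 * pi / 180) %*% (probe - pivot) + pivot
      if (sqrt(sum(p2[1:2]^2)) > sqrt(sum(probe[1:2]^2))) { sgn <- s; break }
    }
    list(pivot = pivot, axis = taxis, rows = rows, sign = sgn)
  })

  ## ---- water pools
  n_shell <- 6L
  shell_ids <- seq_len(n_shell)
  ec_pool <- seq(n_shell + 1L, n_shell + min(15L, spec$n_waters - n_shell))
  ic_pool <- seq(max(ec_pool) + 1L, spec$n_waters)
  release <- spec$ion_release_frame
  rupture <- spec$gate_rupture_frame
  release_step <- 14

  nf <- spec$n_frames
  coords <- array(0, dim = c(n_at, 3, nf))
  gt_ion <- matrix(NA_real_, nf, 3)
  gt_gate <- numeric(nf)
  gt_cavity <- vector("list", nf)

  .with_seed(spec$seed, {
    for (t in seq_len(nf)) {
      fr <- base
      ## hinge opening
      for (h in hinges) {
        R <- .axis_angle(h$axis, h$sign * theta[t] * pi / 180)
        fr[h$rows, ] <- sweep(sweep(fr[h$rows, , drop = FALSE], 2, h$pivot)
                              %*% t(R), 2, h$pivot, `+`)
      }
      ## IC gate distance (exactly 3 before rupture, 8 from rupture on)
      d <- if (!is.na(rupture) && t >= rupture) 8 else 3
      fr[arg79_first + 1L, ] <- c(0, -15 - d, -6)        # NH1
      fr[arg79_first + 2L, ] <- c(0.8, -15.4 - d, -6.5)  # NH2
      gt_gate[t] <- d
      ## ion
      released <- !is.na(release) && t >= release
      ion <- if (released) site + c(0, 0, -release_step * (t - release + 1))
             else site
      fr[ion_row, ] <- ion
      gt_ion[t, ] <- ion
      ## waters: first-shell ring follows the released ion
      if (released) {
        for (j in seq_len(n_shell)) {
          a <- 2 * pi * (j - 1) / n_shell
          fr[water_first - 1L + shell_ids[j], ] <-
            ion + c(2.4 * cos(a), 2.4 * sin(a), 0)
        }
      }
      ## EC cavity waters: constant low Poisson rate
      n_ec <- min(stats::rpois(1, spec$ec_water_rate), length(ec_pool))
      if (n_ec > 0) for (j in seq_len(n_ec)) {
        r <- 1.5 * sqrt(stats::runif(1)); a <- 2 * pi * stats::runif(1)
        fr[water_first - 1L + ec_pool[j], ] <-
          c(r * cos(a), r * sin(a), stats::runif(1, 2.5, 7.5))
      }
      ## IC cavity waters: rate tracks the current opening; never placed
      ## within 3.2 A of the ion binding site
      n_ic <- min(stats::rpois(1, spec$cavity_water_rate * theta[t]),
                  length(ic_pool))
      if (n_ic > 0) for (j in seq_len(n_ic)) {
        repeat {
          r <- 2.0 * sqrt(stats::runif(1)); a <- 2 * pi * stats::runif(1)
          p <- c(r * cos(a), r * sin(a), stats::runif(1, -7.5, -3.5))
          if (sum((p - site)^2) > 3.2^2) break
        }
        fr[water_first - 1L + ic_pool[j], ] <- p
      }
      gt_cavity[[t]] <- if (n_ic > 0) 3000L + ic_pool[seq_len(n_ic)]
                        else integer(0)
      coords[, , t] <- fr
    }
  })

  ## ---- topology + trajectory objects
  element <- .guess_element(rep(NA_character_, n_at), atom_name, res_name)
  top <- data.frame(serial = seq_len(n_at), name = atom_name,
                    element = element, res_name = res_name, res_id = res_id,
                    chain = "A", role = "protein",
                    vdw_radius = vdw_radius(element),
                    mass = .atomic_mass(element), stringsAsFactors = FALSE)
  top$role[res_name == "HOH"] <- "water"
  top$role[res_name == "NA"] <- "ion"
  top$role[res_name == "5HT"] <- "substrate"
  class(top) <- c("topology", "data.frame")
  traj <- new_trajectory(top, coords,
                         spec$frame_dt * (seq_len(nf) - 1))

  ## ---- selection config
  tm_ranges <- stats::setNames(lapply(seq_len(spec$n_tms), function(m)
    c(1000L + 100L * m + 1L, 1000L + 100L * m + nres)), tm_names)
  for (tm in spec$hinge_tms) {
    lo <- tm_ranges[[tm]][1]
    tm_ranges[[paste0(tm, "a")]] <- c(lo, lo + spec$hinge_split - 1L)
    tm_ranges[[paste0(tm, "b")]] <- c(lo + spec$hinge_split,
                                      tm_ranges[[tm]][2])
  }
  pathway <- unlist(lapply(c("TM1", "TM5", "TM6", "TM8"), function(tm)
    seq(tm_ranges[[tm]][1], tm_ranges[[tm]][1] + 2L)))
  cfg <- selection_config(
    tm_ranges = tm_ranges,
    gates = list(
      gate_definition("EC_gate", "res 493 atoms OE1 OE2",
                      "res 104 atoms NH1 NH2"),
      gate_definition("IC_gate", "res 452 atoms OD1 OD2",
                      "res 79 atoms NH1 NH2")),
    pathway_residues = pathway,
    cavity_defs = list(
      cavity_definition("EC", 335L, c("TM1", "TM6", "TM8", "TM10"),
                        cutoff = 10, z_min = 2, z_max = 15),
      cavity_definition("IC", 341L, c("TM1", "TM6", "TM8", "TM5"),
                        cutoff = 10, z_min = -15, z_max = -2)),
    scaffold_tms = spec$scaffold_tms, bundle_tms = spec$bundle_tms,
    ion_ids = top$serial[ion_row], substrate_res = "5HT",
    tm_polarity = stats::setNames(rep(1, length(tm_ranges)),
                                  names(tm_ranges)),
    frame_dt = spec$frame_dt
  )
  na2 <- coordination_site(top$serial[ion_row],
                           list(c(437L, "OD1"), c(94L, "CA")),
                           hydration_cutoff = 3.0, contact_cutoff = 4.0)

  ## ---- files
  paths <- list(pdb = file.path(dir, "traj.pdb"),
                ground_truth = file.path(dir, "ground_truth.json"),
                config = file.path(dir, "config.yaml"))
  write_multimodel_pdb(traj, paths$pdb)
  if (dcd) {
    paths$dcd <- file.path(dir, "traj.dcd")
    write_dcd(traj, paths$dcd)
  }
  gt <- list(theta_per_frame = theta,
             ion_position_per_frame = gt_ion,
             gate_distance_per_frame = gt_gate,
             water_ids_in_cavity_per_frame = gt_cavity,
             release_frame = release, rupture_frame = rupture)
  jsonlite::write_json(
    list(theta_per_frame = theta,
         ion_position_per_frame = as.data.frame(gt_ion),
         gate_distance_per_frame = gt_gate,
         water_ids_in_cavity_per_frame = gt_cavity,
         release_frame = release, rupture_frame = rupture),
    paths$ground_truth, digits = NA, auto_unbox = TRUE, null = "null")
  write_selection_config(cfg, paths$config)
  list(trajectory = traj, ground_truth = gt, config = cfg, site = na2,
       paths = paths, spec = spec)
}

# --- file writers -----------------------------------------------------------

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a \code{trajectory}.
#' @param path output file.
#' @export
write_multimodel_pdb <- function(traj, path) {
  top <- traj$topology
  het <- top$role %in% c("water", "ion")
  con <- file(path, "w")
  on.exit(close(con))
  chunks <- vector("list", n_frames(traj))
  for (k in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, k)
    rec <- sprintf(
      "%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(het, "HETATM", "ATOM"),
      top$serial %% 100000L,
      ifelse(nchar(top$name) < 4, paste0(" ", top$name), top$name),
      substr(top$res_name, 1, 4), top$chain, top$res_id %% 10000L,
      fr[, 1], fr[, 2], fr[, 3], 1, 0,
      formatC(substr(top$element, 1, 2), width = 2))
    chunks[[k]] <- c(sprintf("MODEL     %4d", k), rec, "ENDMDL")
  }
  writeLines(c(unlist(chunks), "END"), con)
  invisible(path)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Minimal single-precision CHARMM/NAMD DCD writer (no unit cell, no fixed
#' atoms), round-trippable with standard DCD readers.
#'
#' @param traj a \code{trajectory}.
#' @param path output file.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj); na <- dim(traj$coords)[1]
  rec <- function(writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L                      # CHARMM version flag
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl[1:9], con, size = 4, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")   # delta as float bits ~ 1
    writeBin(icntrl[11:20], con, size = 4, endian = "little")
  }, 84)
  title <- formatC("synthetic toy transporter trajectory", width = -80)
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(substr(title, 1, 80), con, nchars = 80, eos = NULL)
  }, 4 + 80)
  rec(function() writeBin(as.integer(na), con, size = 4, endian = "little"),
      4)
  for (k in seq_len(nf)) {
    fr <- frame_coords(traj, k)
    for (d in 1:3)
      rec(function() writeBin(as.numeric(fr[, d]), con, size = 4,
                              endian = "little"), 4 * na)
  }
  invisible(path)
}

# --- uptake data ------------------------------------------------------------

#' Simulate Michaelis-Menten uptake data with multiplicative noise
#'
#' Rates are \code{Vmax * S / (KM + S) * (1 + e)} with
#' \code{e ~ N(0, noise_cv)}, drawn independently per concentration and
#' replicate; deterministic under \code{seed}.
#'
#' @param K_M,V_max true parameters (concentration / rate units).
#' @param concentrations tested concentrations (>= 0).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param n_replicates replicates per concentration.
#' @param seed RNG seed.
#' @param label dataset label.
#' @return data.frame with \code{label}, \code{concentration}, \code{rate},
#'   \code{replicate}.
#' @export
generate_uptake_data <- function(K_M, V_max, concentrations,
                                 noise_cv = 0.05, n_replicates = 1L,
                                 seed = 1L, label = "synthetic") {
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  .with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      v <- V_max * concentrations / (K_M + concentrations)
      data.frame(label = label, concentration = concentrations,
                 rate = v * (1 + stats::rnorm(length(v), 0, noise_cv)),
                 replicate = r)
    }))
    rownames(out) <- NULL
    out
  })
}
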