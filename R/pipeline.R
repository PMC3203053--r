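#' Bundle everything one analysis run needs
#'
#' @param trajectory_paths character vector of trajectory files (PDB/DCD).
#' @param selection a \code{\link{selection_config}} or path to its YAML.
#' @param out_dir output directory (created on run).
#' @param topology_path PDB defining the topology; default the first
#'   trajectory file.
#' @param site optional \code{\link{coordination_site}} for the ion
#'   analyses; when NULL a partner-less site is built from the config's
#'   first \code{ion_ids} entry.
#' @param params named list overriding analysis parameters:
#'   \code{water_cutoffs} (default c(3, 4)), \code{probe} (1.4),
#'   \code{n_sphere_points} (960), \code{min_dwell} (5),
#'   \code{release} (a \code{\link{release_criteria}}),
#'   \code{pore} (list: z_range, z_step, search_radius, grid_step),
#'   \code{pore_frames} (frames profiled; default first and last).
#' @param seed seed for any stochastic step (the analyses are
#'   deterministic; kept for the manifest).
#' @export
run_config <- function(trajectory_paths, selection, out_dir,
                       topology_path = trajectory_paths[1], site = NULL,
                       params = list(), seed = 1L) {
  for (p in unique(c(trajectory_paths, topology_path)))
    if (!file.exists(p)) stop("input file not found: ", p)
  cfg <- if (is.character(selection)) read_selection_config(selection)
         else selection
  defaults <- list(water_cutoffs = c(3, 4), probe = 1.4,
                   n_sphere_points = 960L, min_dwell = 5L,
                   release = release_criteria(),
                   pore = list(z_range = c(-15, 15), z_step = 0.5,
                               search_radius = 10, grid_step = 0.5),
                   pore_frames = NULL)
  for (nm in names(params)) defaults[[nm]] <- params[[nm]]
  structure(list(trajectory_paths = trajectory_paths,
                 topology_path = topology_path, config = cfg,
                 out_dir = out_dir, site = site, params = defaults,
                 seed = seed),
            class = "run_config")
}

#' Run the full analysis battery over one trajectory
#'
#' Executes the stages stability, gates, solvation, ions, helices and pore
#' in order, writing per-metric CSVs, a JSON run manifest (input checksums,
#' parameters, per-stage status) and the exported "most inward-facing"
#' snapshot: the frame maximizing the cytoplasmic-pathway SASA (ties broken
#' by the earliest frame).  A failing stage is logged and recorded; later
#' stages still run.
#'
#' @param rc a \code{\link{run_config}}.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with per-stage results, the manifest and
#'   \code{ok} (TRUE when every stage succeeded).
#' @export
run_all <- function(rc, quiet = FALSE) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- rc$config; pm <- rc$params
  say <- function(...) if (!quiet) message(...)

  # config problems surface inside the stage that needs the selection, so
  # one bad selection cannot take down unrelated stages
  top <- load_topology(rc$topology_path, substrate_name = cfg$substrate_res)
  traj <- load_trajectory(rc$trajectory_paths, top, dt = cfg$frame_dt)
  nf <- n_frames(traj)

  res <- list(); status <- list()
  run_stage <- function(name, fun) {
    say("stage: ", name)
    out <- tryCatch(fun(), error = function(e) {
      say("  stage ", name, " FAILED: ", conditionMessage(e))
      structure(list(message = conditionMessage(e)), class = "stage_error")
    })
    status[[name]] <<- if (inherits(out, "stage_error"))
      paste("error:", out$message) else "ok"
    res[[name]] <<- out
  }
  tm_res <- function(tms) unlist(lapply(tms, function(tm)
    seq(cfg$tm_ranges[[tm]][1], cfg$tm_ranges[[tm]][2])))
  all_tm_sel <- list(res_id = tm_res(setdiff(names(cfg$tm_ranges),
    grep("a$|b$", names(cfg$tm_ranges), value = TRUE))))
  scaffold_sel <- list(res_id = tm_res(cfg$scaffold_tms))

  run_stage("stability", function() {
    rs <- rmsd_series(traj, 1L, scaffold_sel, all_tm_sel)
    write_metric_csv(rs, file.path(rc$out_dir, "rmsd.csv"))
    rf <- rmsf(traj, scaffold_sel, all_tm_sel)
    utils::write.csv(rf, file.path(rc$out_dir, "rmsf.csv"),
                     row.names = FALSE)
    list(rmsd = rs, rmsf = rf)
  })

  run_stage("gates", function() {
    out <- list()
    tab <- data.frame(time_ns = traj$times)
    for (g in cfg$gates) {
      s <- gate_distance_series(traj, g)
      tab[[g$name]] <- s$values
      ev <- detect_state_change(s, g, min_dwell = pm$min_dwell)
      out[[g$name]] <- list(series = s, events = ev)
    }
    utils::write.csv(tab, file.path(rc$out_dir, "gates.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(out, function(x) x$events),
                         file.path(rc$out_dir, "events.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  run_stage("solvation", function() {
    pathway_sel <- list(res_id = cfg$pathway_residues)
    sasa_s <- group_sasa_series(traj, pathway_sel, probe = pm$probe,
                                n_sphere_points = pm$n_sphere_points)
    write_metric_csv(sasa_s, file.path(rc$out_dir, "sasa_pathway.csv"))
    wat <- data.frame(time_ns = traj$times)
    for (ct in pm$water_cutoffs)
      wat[[paste0("within_", ct, "A")]] <-
        vapply(seq_len(nf), function(k)
          count_waters_near(frame_coords(traj, k), top, pathway_sel, ct),
          numeric(1))
    utils::write.csv(wat, file.path(rc$out_dir, "pathway_waters.csv"),
                     row.names = FALSE)
    cav <- data.frame(time_ns = traj$times)
    shell <- NULL
    have_substrate <- any(top$role == "substrate")
    for (k in seq_len(nf)) {
      fr <- frame_coords(traj, k)
      z0 <- if (have_substrate) substrate_com_z(fr, top) else 0
      for (cv in cfg$cavity_defs)
        cav[k, cv$side] <- cavity_water_count(fr, top, cv, cfg, z0)
      if (have_substrate) {
        sp <- substrate_shell_split(fr, top, list(role = "substrate"),
                                    pm$water_cutoffs)
        sp$time_ns <- traj$times[k]
        shell <- rbind(shell, sp)
      }
    }
    utils::write.csv(cav, file.path(rc$out_dir, "cavity_waters.csv"),
                     row.names = FALSE)
    if (!is.null(shell))
      utils::write.csv(shell, file.path(rc$out_dir, "shell_split.csv"),
                       row.names = FALSE)
    list(sasa_pathway = sasa_s, pathway_waters = wat, cavity_waters = cav,
         shell_split = shell)
  })

  run_stage("ions", function() {
    if (length(cfg$ion_ids) == 0L) return(list(skipped = "no ions in config"))
    site <- rc$site %||% coordination_site(cfg$ion_ids[1], list())
    out <- list()
    if (length(site$partners) > 0L) {
      cs <- coordination_series(traj, site)
      tab <- data.frame(time_ns = traj$times)
      for (nm in names(cs)) tab[[nm]] <- cs[[nm]]$values
      utils::write.csv(tab, file.path(rc$out_dir, "coordination.csv"),
                       row.names = FALSE)
      out$coordination <- cs
    }
    hyd <- ion_hydration_series(traj, site)
    write_metric_csv(hyd, file.path(rc$out_dir, "hydration.csv"))
    rel <- detect_ion_release(traj, site, pm$release)
    jsonlite::write_json(list(release_frame = rel,
                              release_time_ns = if (is.na(rel)) NULL
                                                else traj$times[rel]),
                         file.path(rc$out_dir, "release.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    trace <- ion_pathway_trace(traj, site$ion_id, scaffold_sel)
    utils::write.csv(trace, file.path(rc$out_dir, "pathway_trace.csv"),
                     row.names = FALSE)
    c(out, list(hydration = hyd, release_frame = rel, trace = trace))
  })

  run_stage("helices", function() {
    pairs <- list(`scaffold/bundle` = list(cfg$scaffold_tms, cfg$bundle_tms))
    for (tm in cfg$bundle_tms) {
      subs <- intersect(paste0(tm, c("a", "b")), names(cfg$tm_ranges))
      members <- if (length(subs)) subs else tm
      for (mm in members)
        pairs[[paste0("scaffold/", mm)]] <- list(cfg$scaffold_tms, mm)
      if (length(subs) == 2L)
        pairs[[paste(subs, collapse = "/")]] <- list(subs[1], subs[2])
    }
    angs <- tilt_angle_series(traj, pairs, cfg)
    tab <- data.frame(time_ns = traj$times)
    for (nm in names(angs)) tab[[nm]] <- angs[[nm]]$values
    utils::write.csv(tab, file.path(rc$out_dir, "angles.csv"),
                     row.names = FALSE)
    angs
  })

  run_stage("pore", function() {
    kf <- pm$pore_frames %||% unique(c(1L, nf))
    profs <- lapply(kf, function(k)
      pore_radius_profile(frame_coords(traj, k), top,
                          z_range = pm$pore$z_range,
                          z_step = pm$pore$z_step,
                          search_radius = pm$pore$search_radius,
                          grid_step = pm$pore$grid_step))
    names(profs) <- paste0("frame_", kf)
    tab <- do.call(rbind, lapply(names(profs), function(nm)
      cbind(frame = nm, as.data.frame(profs[[nm]]))))
    utils::write.csv(tab, file.path(rc$out_dir, "pore_profile.csv"),
                     row.names = FALSE)
    cmp <- if (length(profs) >= 2L) compare_profiles(profs) else NULL
    list(profiles = profs, comparison = cmp)
  })

  ## most inward-facing snapshot: argmax of the pathway SASA series
  snapshot_frame <- NA_integer_
  if (identical(status$solvation, "ok")) {
    sv <- res$solvation$sasa_pathway$values
    snapshot_frame <- which.max(sv)   # which.max takes the earliest tie
    snap <- new_trajectory(top,
                           traj$coords[, , snapshot_frame, drop = FALSE],
                           traj$times[snapshot_frame])
    write_multimodel_pdb(snap, file.path(rc$out_dir, "inward_snapshot.pdb"))
  }

  manifest <- list(
    inputs = as.list(tools::md5sum(unique(c(rc$trajectory_paths,
                                            rc$topology_path)))),
    n_frames = nf, n_atoms = nrow(top), seed = rc$seed,
    parameters = list(water_cutoffs = pm$water_cutoffs, probe = pm$probe,
                      n_sphere_points = pm$n_sphere_points,
                      min_dwell = pm$min_dwell, pore = pm$pore),
    stages = status,
    inward_snapshot_frame = snapshot_frame,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(rc$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  ok <- all(vapply(status, identical, TRUE, "ok"))
  invisible(list(results = res, manifest = manifest, status = status,
                 snapshot_frame = snapshot_frame, ok = ok,
                 trajectory = traj))
}
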