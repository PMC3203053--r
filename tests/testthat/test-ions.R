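# a 30-frame toy with the ion scripted to unbind at frame 15
release_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_toy_trajectory(
        toy_transporter_spec(n_frames = 30L,
                             hinge_profile = list(start_deg = 0,
                                                  end_deg = 25,
                                                  ramp_start = 5L,
                                                  ramp_end = 25L),
                             ion_release_frame = 15L,
                             gate_rupture_frame = NA_integer_,
                             seed = 11L))
    cache
  }
})

test_that("coordination distances match per-pair brute force", {
  # ion at origin, partners on unit axes
  top <- make_topology(4, name = c("NA", "OD1", "CA", "CG"),
                       res_name = c("NA", "ASP", "GLY", "ASP"),
                       res_id = c(901, 437, 94, 437),
                       role = c("ion", rep("protein", 3)),
                       element = c("NA", "O", "C", "C"))
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  site <- coordination_site(1, list(c(437, "OD1"), c(94, "CA"),
                                    c(437, "CG")))
  d <- coordination_distances(X, top, site)
  expect_equal(unname(d), c(1, 1, 1))
  # coincident partner -> zero
  X2 <- X; X2[2, ] <- 0
  expect_equal(unname(coordination_distances(X2, top, site)[1]), 0)
  # random frame vs brute force
  set.seed(30)
  X3 <- matrix(rnorm(12), 4)
  d3 <- coordination_distances(X3, top, site)
  brute <- sqrt(colSums((t(X3[c(2, 3, 4), ]) - X3[1, ])^2))
  expect_equal(unname(d3), unname(brute), tolerance = 1e-12)
  # missing partner atom errors
  bad <- coordination_site(1, list(c(437, "OD2")))
  expect_error(coordination_distances(X, top, bad), "unknown selection")
})

test_that("ion hydration counts constructed first shells", {
  n <- 6
  top <- make_topology(n, name = c("NA", rep("O", 4), "CA"),
                       res_name = c("NA", rep("HOH", 4), "ALA"),
                       res_id = c(901, 2:5, 6),
                       role = c("ion", rep("water", 4), "protein"),
                       element = c("NA", rep("O", 4), "C"))
  shell <- rbind(c(0, 0, 0), c(2.4, 0, 0), c(-2.4, 0, 0), c(0, 2.4, 0),
                 c(0, -2.4, 0), c(10, 0, 0))
  site <- coordination_site(1, list(), hydration_cutoff = 3)
  s <- ion_hydration_series(make_traj(top, list(shell, shell)), site)
  expect_equal(s$values, c(4, 4))
  # vacuum (no waters) -> zero
  top2 <- make_topology(2, name = c("NA", "CA"),
                        res_name = c("NA", "ALA"), res_id = 1:2,
                        role = c("ion", "protein"),
                        element = c("NA", "C"))
  s2 <- ion_hydration_series(make_traj(top2,
                                       list(rbind(c(0, 0, 0), c(8, 0, 0)))),
                             coordination_site(1, list()))
  expect_equal(s2$values, 0)
})

test_that("chi1 recovers constructed torsions to 1e-6 degrees", {
  topa <- make_topology(4, name = c("N", "CA", "CB", "CG"),
                        res_name = "ASP", res_id = 437)
  N <- c(0, 1.2, 0.5); CA <- c(0, 0, 0); CB <- c(1.5, 0, 0)
  for (target in c(0, 60, 180, -120)) {
    CG <- place_dihedral_atom(N, CA, CB, 1.52, 111, target)
    s <- chi1_dihedral_series(make_traj(topa, list(rbind(N, CA, CB, CG))),
                              437)
    d <- (s$values - target + 180) %% 360 - 180
    expect_lt(abs(d), 1e-6)
  }
})

test_that("chi1 on a residue lacking CG names the residue in the error", {
  g <- release_toy()
  expect_error(chi1_dihedral_series(g$trajectory, 94), "94")
})

test_that("scripted ion release is recovered exactly", {
  g <- release_toy()
  rel <- detect_ion_release(g$trajectory, g$site)
  expect_equal(rel, g$ground_truth$release_frame)
  # hydration jumps to the full first shell at release
  hy <- ion_hydration_series(g$trajectory, g$site)
  pre <- hy$values[seq_len(g$ground_truth$release_frame - 1L)]
  post <- hy$values[seq(g$ground_truth$release_frame, n_frames(g$trajectory))]
  expect_gte(min(post), max(pre))
  expect_gte(min(post), 4)
})

test_that("a permanently coordinated ion is never reported released", {
  g <- small_toy()   # ion_release_frame = NA in this toy
  expect_true(is.na(detect_ion_release(g$trajectory, g$site)))
})

test_that("degenerate criteria release at the first frame", {
  g <- small_toy()
  crit <- release_criteria(contact_cutoff = 0, min_hydration = 0L,
                           min_dwell = 1L)
  expect_equal(detect_ion_release(g$trajectory, g$site, crit), 1L)
})

test_that("loosening release criteria never delays the release frame", {
  g <- release_toy()
  base <- detect_ion_release(g$trajectory, g$site,
                             release_criteria(4, 4L, 5L))
  looser_contact <- detect_ion_release(g$trajectory, g$site,
                                       release_criteria(2, 4L, 5L))
  looser_hyd <- detect_ion_release(g$trajectory, g$site,
                                   release_criteria(4, 2L, 5L))
  expect_lte(looser_contact, base)
  expect_lte(looser_hyd, base)
})

test_that("the pathway trace removes global tumbling", {
  g <- release_toy()
  tr <- g$trajectory
  cfg <- g$config
  sc <- list(res_id = unlist(lapply(cfg$scaffold_tms, function(tm)
    seq(cfg$tm_ranges[[tm]][1], cfg$tm_ranges[[tm]][2]))))
  t1 <- ion_pathway_trace(tr, g$site$ion_id, sc, stride = 3)
  # rigidly tumble every frame after the shared reference frame
  set.seed(31)
  coords2 <- tr$coords
  for (k in seq(2L, n_frames(tr))) {
    R <- random_rotation(); tt <- rnorm(3, sd = 5)
    coords2[, , k] <- apply_rigid(tr$coords[, , k], R, tt)
  }
  tr2 <- new_trajectory(tr$topology, coords2, tr$times)
  t2 <- ion_pathway_trace(tr2, g$site$ion_id, sc, stride = 3)
  expect_lt(max(abs(as.matrix(t2[, c("x", "y", "z")]) -
                    as.matrix(t1[, c("x", "y", "z")]))), 1e-6)
  # the released ion leaves along -z: trace z is non-increasing
  expect_true(all(diff(t1$z) <= 1e-9))
})

test_that("coordination and chi1 are invariant under global rigid motion", {
  g <- release_toy()
  tr <- g$trajectory
  fr <- frame_coords(tr, 10)
  d1 <- coordination_distances(fr, tr$topology, g$site)
  set.seed(32)
  R <- random_rotation(); tt <- rnorm(3)
  d2 <- coordination_distances(apply_rigid(fr, R, tt), tr$topology, g$site)
  expect_equal(d2, d1, tolerance = 1e-9)
  s1 <- chi1_dihedral_series(tr, 437)
  coords2 <- tr$coords
  for (k in seq_len(n_frames(tr)))
    coords2[, , k] <- apply_rigid(tr$coords[, , k], R, tt)
  s2 <- chi1_dihedral_series(new_trajectory(tr$topology, coords2, tr$times),
                             437)
  expect_equal(s2$values, s1$values, tolerance = 1e-6)
})
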