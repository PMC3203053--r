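test_that("isolated and well-separated atoms match the sphere area", {
  exact <- 4 * pi * (1.7 + 1.4)^2
  s1 <- sasa(rbind(c(0, 0, 0)), 1.7, probe = 1.4, n_sphere_points = 960)
  expect_lt(abs(s1$group_total - exact) / exact, 0.02)
  s2 <- sasa(rbind(c(0, 0, 0), c(10, 0, 0)), c(1.7, 1.7), 1.4, 960)
  expect_lt(abs(s2$per_atom_area[1] - exact) / exact, 0.02)
  expect_lt(abs(s2$per_atom_area[2] - exact) / exact, 0.02)
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  r <- 1.7; probe <- 1.4; R <- r + probe
  for (d in c(2.0, 3.0, 4.5)) {
    s <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c(r, r), probe, 960)
    h <- R - d / 2
    exact <- 2 * (4 * pi * R^2 - 2 * pi * R * h)
    expect_lt(abs(s$group_total - exact) / exact, 0.02)
  }
})

test_that("SASA converges between 960 and 3840 sphere points", {
  set.seed(20)
  for (rep in 1:3) {
    X <- matrix(rnorm(60, sd = 3), 20)
    r <- runif(20, 1.2, 2.0)
    a1 <- sasa(X, r, 1.4, 960)$group_total
    a2 <- sasa(X, r, 1.4, 3840)$group_total
    expect_lt(abs(a1 - a2) / a2, 0.01)
  }
})

test_that("SASA input contract is enforced", {
  expect_error(sasa(matrix(0, 0, 3), numeric(0)), "empty input")
  expect_error(sasa(rbind(c(0, 0, 0)), 1.7, n_sphere_points = 50),
               "n_sphere_points")
  expect_error(sasa(rbind(c(0, 0, 0)), -1), "positive")
})

test_that("water shell counts equal the brute-force double loop", {
  set.seed(21)
  n_prot <- 10; n_wat <- 50
  top <- make_topology(n_prot + n_wat,
                       name = c(rep("CA", n_prot), rep("O", n_wat)),
                       res_name = c(rep("ALA", n_prot), rep("HOH", n_wat)),
                       res_id = seq_len(n_prot + n_wat),
                       role = c(rep("protein", n_prot), rep("water", n_wat)))
  for (rep in 1:5) {
    X <- rbind(matrix(rnorm(n_prot * 3, sd = 3), n_prot),
               matrix(rnorm(n_wat * 3, sd = 6), n_wat))
    for (ct in c(3, 4, 6)) {
      brute <- sum(vapply(seq_len(n_wat), function(w) {
        any(sqrt(rowSums(sweep(X[1:n_prot, , drop = FALSE], 2,
                               X[n_prot + w, ])^2)) < ct)
      }, logical(1)))
      expect_equal(count_waters_near(X, top, list(res_id = 1:n_prot), ct),
                   brute)
    }
    # monotone in cutoff
    cnt <- vapply(c(2, 3, 4, 5, 8), function(ct)
      count_waters_near(X, top, list(res_id = 1:n_prot), ct), numeric(1))
    expect_true(all(diff(cnt) >= 0))
  }
})

test_that("shell boundary is strict: inside counts, outside does not", {
  top <- make_topology(2, name = c("CA", "O"), res_name = c("ALA", "HOH"),
                       res_id = 1:2, role = c("protein", "water"))
  eps <- 1e-6
  inside <- rbind(c(0, 0, 0), c(3 - eps, 0, 0))
  outside <- rbind(c(0, 0, 0), c(3 + eps, 0, 0))
  expect_equal(count_waters_near(inside, top, list(res_id = 1), 3), 1L)
  expect_equal(count_waters_near(outside, top, list(res_id = 1), 3), 0L)
})

test_that("cavity counts equal brute-force evaluation of all predicates", {
  g <- small_toy()
  top <- g$trajectory$topology
  cfg <- g$config
  wo <- which(top$role == "water")
  for (k in c(1L, 15L, 30L)) {
    fr <- frame_coords(g$trajectory, k)
    z0 <- substrate_com_z(fr, top)
    for (cv in cfg$cavity_defs) {
      ref_idx <- which(top$res_id == cv$reference_residue)
      tm_idx <- lapply(cv$tm_list, function(tm) {
        rng <- cfg$tm_ranges[[tm]]
        which(top$res_id >= rng[1] & top$res_id <= rng[2])
      })
      brute <- 0L
      for (w in wo) {
        z <- fr[w, 3] - z0
        if (!(z > cv$z_min && z < cv$z_max)) next
        dref <- min(sqrt(rowSums(sweep(fr[ref_idx, , drop = FALSE], 2,
                                       fr[w, ])^2)))
        if (dref >= cv$cutoff) next
        tm_ok <- vapply(tm_idx, function(ti)
          min(sqrt(rowSums(sweep(fr[ti, , drop = FALSE], 2,
                                 fr[w, ])^2))) < cv$cutoff, logical(1))
        if (all(tm_ok)) brute <- brute + 1L
      }
      expect_equal(cavity_water_count(fr, top, cv, cfg, z0), brute)
    }
  }
})

test_that("cavity z bounds are strict and counts track the ground truth", {
  g <- small_toy()
  top <- g$trajectory$topology
  ic <- g$config$cavity_defs[[2]]
  counts <- vapply(seq_len(n_frames(g$trajectory)), function(k) {
    fr <- frame_coords(g$trajectory, k)
    cavity_water_count(fr, top, ic, g$config, substrate_com_z(fr, top))
  }, numeric(1))
  truth <- lengths(g$ground_truth$water_ids_in_cavity_per_frame)
  expect_equal(counts, as.numeric(truth))
  # strict bound: a water exactly below z_min is excluded
  top2 <- make_topology(2, name = c("CA", "O"),
                        res_name = c("PHE", "HOH"), res_id = c(341, 400),
                        role = c("protein", "water"))
  cfg2 <- selection_config(tm_ranges = list(TM1 = c(341, 341)),
                           cavity_defs = list())
  cv <- cavity_definition("EC", 341, "TM1", cutoff = 10, z_min = 2,
                          z_max = 15)
  at_bound <- rbind(c(0, 0, 3), c(0, 1, 1.9))
  expect_equal(cavity_water_count(at_bound, top2, cv, cfg2, 0), 0L)
  above <- rbind(c(0, 0, 3), c(0, 1, 8))
  expect_equal(cavity_water_count(above, top2, cv, cfg2, 0), 1L)
})

test_that("substrate shell split partitions at the substrate plane", {
  n_w <- 6
  top <- make_topology(1 + n_w, name = c("C1", rep("O", n_w)),
                       res_name = c("5HT", rep("HOH", n_w)),
                       res_id = c(900, 1000 + seq_len(n_w)),
                       role = c("substrate", rep("water", n_w)))
  # symmetric about the substrate plane -> equal counts
  sym <- rbind(c(0, 0, 0),
               c(1, 0, 1), c(0, 1, 2), c(1, 1, 2.5),
               c(1, 0, -1), c(0, 1, -2), c(1, 1, -2.5))
  sp <- substrate_shell_split(sym, top, list(role = "substrate"), c(3, 4))
  expect_equal(sp$ec_count, sp$ic_count)
  # all waters below -> no EC waters
  below <- sym; below[2:7, 3] <- -abs(below[2:7, 3]) - 0.1
  sp2 <- substrate_shell_split(below, top, list(role = "substrate"), c(4))
  expect_equal(sp2$ec_count, 0L)
  expect_gt(sp2$ic_count, 0L)
  # random configuration matches brute force
  set.seed(22)
  X <- rbind(c(0, 0, 0), matrix(rnorm(n_w * 3, sd = 3), n_w))
  for (ct in c(3, 4)) {
    d <- sqrt(rowSums(sweep(X[-1, , drop = FALSE], 2, X[1, ])^2))
    brute_ec <- sum(d < ct & X[-1, 3] >= 0)
    brute_ic <- sum(d < ct & X[-1, 3] < 0)
    sp3 <- substrate_shell_split(X, top, list(role = "substrate"), ct)
    expect_equal(sp3$ec_count, brute_ec)
    expect_equal(sp3$ic_count, brute_ic)
  }
})

test_that("group SASA: isolated atoms keep the sphere value, buried drop", {
  # one atom far from a 4x4 slab of context atoms
  slab <- as.matrix(expand.grid(x = seq(0, 6, 2), y = seq(0, 6, 2), z = 0))
  lone <- c(30, 0, 0)
  X <- rbind(lone, slab)
  n <- nrow(X)
  top <- make_topology(n, name = "CA", res_id = seq_len(n))
  tr <- make_traj(top, list(X, X))
  s <- group_sasa_series(tr, list(res_id = 1), list(res_id = 1:n),
                         n_sphere_points = 960)
  exact <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(max(abs(s$values - exact)) / exact, 0.02)
  # translating the slab onto the atom buries it
  buried <- rbind(lone, sweep(slab, 2, c(27, -3, 0), `+`),
                  sweep(slab, 2, c(27, -3, 2.5), `+`),
                  sweep(slab, 2, c(27, -3, -2.5), `+`))
  nb <- nrow(buried)
  topb <- make_topology(nb, name = "CA", res_id = seq_len(nb))
  sb <- group_sasa_series(make_traj(topb, list(buried)), list(res_id = 1),
                          list(res_id = 1:nb), n_sphere_points = 960)
  expect_lt(sb$values[1], 0.10 * exact)
})

test_that("pathway SASA tracks the programmed opening", {
  g <- small_toy()
  s <- group_sasa_series(g$trajectory,
                         list(res_id = g$config$pathway_residues),
                         n_sphere_points = 240)
  rho <- cor(s$values, g$ground_truth$theta_per_frame, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("group must lie within its occlusion context", {
  top <- make_topology(4)
  tr <- make_traj(top, list(matrix(rnorm(12), 4)))
  expect_error(group_sasa_series(tr, list(res_id = 1:4),
                                 list(res_id = 1:2)),
               "within the context")
})
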