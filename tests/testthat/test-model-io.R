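# hand-written PDB text so the reader is tested independently of the
# package's own writer
pdb_line <- function(serial, name, resn, resi, x, y, z, el,
                     rec = "ATOM") {
  sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          resn, "A", resi, x, y, z, 1, 0, el)
}

write_tiny_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

test_that("topology roles are assigned from residue names", {
  f <- write_tiny_pdb(tempfile(fileext = ".pdb"), c(
    pdb_line(1, "CA", "GLY", 1, 0, 0, 0, "C"),
    pdb_line(2, "O", "HOH", 2, 3, 0, 0, "O", rec = "HETATM"),
    pdb_line(3, "N", "GLY", 1, 1, 1, 0, "N")))
  top <- load_topology(f)
  expect_s3_class(top, "topology")
  expect_equal(nrow(top), 3L)
  expect_equal(top$role[top$res_name == "HOH"], "water")
  expect_equal(sum(top$role == "protein"), 2L)
})

test_that("configured substrate residue name is tagged as substrate", {
  f <- write_tiny_pdb(tempfile(fileext = ".pdb"), c(
    pdb_line(1, "C1", "5HT", 10, 0, 0, 0, "C", rec = "HETATM"),
    pdb_line(2, "N1", "5HT", 10, 1.4, 0, 0, "N", rec = "HETATM"),
    pdb_line(3, "CA", "ALA", 1, 5, 0, 0, "C")))
  top <- load_topology(f, substrate_name = "5HT")
  expect_equal(top$role[top$res_name == "5HT"], rep("substrate", 2))
  top2 <- load_topology(f)   # without the substrate tag -> protein
  expect_equal(top2$role[top2$res_name == "5HT"], rep("protein", 2))
})

test_that("sodium gets the bundled radius and re-reading is identical", {
  f <- write_tiny_pdb(tempfile(fileext = ".pdb"), c(
    pdb_line(1, "NA", "NA", 1, 0, 0, 0, "NA", rec = "HETATM"),
    pdb_line(2, "CA", "ALA", 2, 4, 0, 0, "C"),
    pdb_line(3, "XX", "UNK", 3, 8, 0, 0, "")))
  top <- load_topology(f)
  expect_equal(top$vdw_radius[1], vdw_radius("NA"))
  expect_equal(top$vdw_radius[1], 2.27)
  expect_equal(top$role[1], "ion")
  # unknown element falls back to the documented default
  expect_equal(top$vdw_radius[3], 1.70)
  top2 <- load_topology(f)
  expect_identical(as.data.frame(top), as.data.frame(top2))
})

test_that("empty or missing PDB input fails fast", {
  f <- tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(load_topology(f))
  expect_error(load_topology(tempfile(fileext = ".pdb")), "not found")
})

test_that("multi-model PDB becomes an ordered trajectory", {
  lines <- c("MODEL     1",
             pdb_line(1, "CA", "ALA", 1, 0, 0, 0, "C"),
             pdb_line(2, "CA", "ALA", 2, 1, 0, 0, "C"),
             pdb_line(3, "CA", "ALA", 3, 0, 1, 0, "C"),
             pdb_line(4, "CA", "ALA", 4, 0, 0, 1, "C"),
             pdb_line(5, "CA", "ALA", 5, 1, 1, 1, "C"),
             "ENDMDL", "MODEL     2",
             pdb_line(1, "CA", "ALA", 1, 0, 0, 2, "C"),
             pdb_line(2, "CA", "ALA", 2, 1, 0, 2, "C"),
             pdb_line(3, "CA", "ALA", 3, 0, 1, 2, "C"),
             pdb_line(4, "CA", "ALA", 4, 0, 0, 3, "C"),
             pdb_line(5, "CA", "ALA", 5, 1, 1, 3, "C"),
             "ENDMDL")
  f <- write_tiny_pdb(tempfile(fileext = ".pdb"), lines)
  top <- load_topology(f)
  traj <- load_trajectory(f, top, dt = 0.1)
  expect_equal(n_frames(traj), 2L)
  expect_equal(dim(traj$coords)[1], 5L)
  expect_equal(frame_coords(traj, 2)[1, 3], 2)
  expect_equal(traj$times, c(0, 0.1))
})

test_that("PDB and DCD routes deliver the same coordinates", {
  g <- small_toy()
  dcd <- file.path(tempdir(), "roundtrip.dcd")
  write_dcd(g$trajectory, dcd)
  top <- g$trajectory$topology
  t_pdb <- load_trajectory(g$paths$pdb, top)
  t_dcd <- load_trajectory(dcd, top)
  expect_equal(n_frames(t_pdb), n_frames(t_dcd))
  expect_lt(max(abs(t_pdb$coords - t_dcd$coords)), 1e-3)
})

test_that("trajectory loading fails fast on bad input", {
  g <- small_toy()
  top_small <- make_topology(3)
  expect_error(load_trajectory(g$paths$pdb, top_small), "mismatch")
  expect_error(load_trajectory(character(), g$trajectory$topology),
               "empty input")
})

test_that("selections resolve to sorted unique indices", {
  g <- small_toy()
  top <- g$trajectory$topology
  idx <- resolve_selection(top, "res 493, atoms OE1 OE2")
  expect_length(idx, 2L)
  expect_setequal(top$name[idx], c("OE1", "OE2"))
  # residue range equals the brute-force filter
  rng <- resolve_selection(top, "res 1101-1110")
  brute <- which(top$res_id >= 1101 & top$res_id <= 1110)
  expect_identical(idx_sorted <- rng, sort(unique(brute)))
  # idempotent and order-independent
  expect_identical(resolve_selection(top, list(res_id = c(1105, 1101))),
                   resolve_selection(top, list(res_id = c(1101, 1105))))
})

test_that("empty selections are an error, not an empty vector", {
  g <- small_toy()
  expect_error(resolve_selection(g$trajectory$topology, "res 9999"),
               "unknown selection")
})

test_that("metric series survive a CSV round trip to 1e-9", {
  s <- metric_series("gate", "Angstrom", seq(0, 0.9, by = 0.1),
                     c(pi, exp(1), 1 / 3, 1e-7, 123456.789,
                       sqrt(2), 2 / 7, 0, -1.5, 42))
  f <- tempfile(fileext = ".csv")
  write_metric_csv(s, f)
  s2 <- read_metric_csv(f)
  expect_lt(max(abs(s2$values - s$values)), 1e-9)
  expect_lt(max(abs(s2$times - s$times)), 1e-9)
})

test_that("selection config survives a YAML round trip", {
  g <- small_toy()
  cfg <- g$config
  f <- tempfile(fileext = ".yaml")
  write_selection_config(cfg, f)
  cfg2 <- read_selection_config(f)
  expect_equal(cfg2$tm_ranges, cfg$tm_ranges)
  expect_equal(cfg2$scaffold_tms, cfg$scaffold_tms)
  expect_equal(cfg2$pathway_residues, cfg$pathway_residues)
  expect_equal(cfg2$cavity_defs[[1]]$z_min, cfg$cavity_defs[[1]]$z_min)
  expect_equal(cfg2$gates[[2]]$name, cfg$gates[[2]]$name)
  expect_true(validate_config(cfg2, g$trajectory$topology))
})

test_that("scaffold and bundle TM sets must be disjoint", {
  expect_error(selection_config(scaffold_tms = c("TM3", "TM4"),
                                bundle_tms = c("TM4", "TM1")),
               "disjoint")
})
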