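test_that("membrane PDB files parse with DUM planes and overrides", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(path, ring_atoms(24, 10, 14.5), dum_z = c(15, -15))
  st <- read_membrane_pdb(path)
  expect_equal(st$z_outer, 15)
  expect_equal(st$z_inner, -15)
  expect_equal(nrow(st$atoms), 24L)
  # explicit overrides beat the DUM layers
  st2 <- read_membrane_pdb(path, z_outer = 16, z_inner = -16)
  expect_equal(c(st2$z_outer, st2$z_inner), c(16, -16))
  # hydrogens and waters dropped
  hoh <- rbind(ring_atoms(4, 5, 14.5),
               data.frame(x = 0, y = 0, z = 14.5, element = "H"))
  hoh$residue <- c(rep("ALA", 4), "HOH")
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(path2, hoh, dum_z = c(15, -15))
  expect_equal(nrow(read_membrane_pdb(path2)$atoms), 4L)
  # no planes from either source is an error
  path3 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(path3, ring_atoms(4, 5, 14.5))
  expect_error(read_membrane_pdb(path3), "DUM")
  expect_error(read_membrane_pdb("/no/such/file.pdb"), "cannot read")
})

test_that("wedge integration reproduces a circle to the analytic factor", {
  # in-memory structure keeps coordinates at full precision
  st <- structure(list(atoms = ring_atoms(720, 15, 15),
                       z_outer = 15, z_inner = -15, conformation = "ring"),
                  class = "membrane_structure")
  fp <- leaflet_cross_section(st, "outer")
  # n = 80 fan over a uniform circle: area = pi r^2 x (80/pi) tan(pi/80)
  expect_equal(fp$area, pi * 15^2 * (80 / pi) * tan(pi / 80),
               tolerance = 1e-9)
  expect_equal(fp$area, 707.22, tolerance = 1e-4)
  expect_equal(fp$area / (pi * 15^2), 1.000514, tolerance = 1e-6)
  # convergence: the overshoot factor shrinks toward 1 as n grows
  f <- vapply(c(16L, 80L, 400L), function(n) {
    leaflet_cross_section(st, "outer",
                          geometry_params(n_wedges = n))$area / (pi * 225)
  }, numeric(1))
  expect_equal(f, (c(16, 80, 400) / pi) * tan(pi / c(16, 80, 400)),
               tolerance = 1e-9)
  expect_true(all(diff(f) < 0))
  # through the PDB round-trip, 0.001 A coordinate quantization still
  # leaves the analytic factor intact to 0.01%
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(path, ring_atoms(720, 15, 15), dum_z = c(15, -15))
  fp2 <- leaflet_cross_section(read_membrane_pdb(path), "outer")
  expect_equal(fp2$area, pi * 15^2 * 1.000514, tolerance = 1e-4)
})

test_that("wedge radii use the most distant atom; empty wedges give 0", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(path, data.frame(x = 10, y = 0, z = 15, element = "C"),
                    dum_z = c(15, -15))
  st <- read_membrane_pdb(path)
  # single atom 10 A from a fixed center: one wedge of r = 10
  fp <- leaflet_cross_section(st, "outer", center = c(0, 0))
  expect_equal(fp$area, 100 * tan(pi / 80), tolerance = 1e-9)
  expect_equal(fp$area, 3.93, tolerance = 1e-2)
  expect_equal(sum(fp$radii > 0), 1L)
})

test_that("area is monotone in atoms and rotation-stable", {
  ring <- ring_atoms(360, 12, 15)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(p1, ring, dum_z = c(15, -15))
  a1 <- leaflet_cross_section(read_membrane_pdb(p1), "outer",
                              center = c(0, 0))$area
  # adding an atom never decreases the area (fixed center)
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(p2, rbind(ring, data.frame(x = 20, y = 3, z = 15,
                                               element = "C")),
                    dum_z = c(15, -15))
  a2 <- leaflet_cross_section(read_membrane_pdb(p2), "outer",
                              center = c(0, 0))$area
  expect_gte(a2, a1)
  # rotating about the membrane normal changes the area by < 1%
  th <- 17 * pi / 180
  rot <- data.frame(x = ring$x * cos(th) - ring$y * sin(th),
                    y = ring$x * sin(th) + ring$y * cos(th),
                    z = ring$z, element = "C")
  p3 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(p3, rot, dum_z = c(15, -15))
  a3 <- leaflet_cross_section(read_membrane_pdb(p3), "outer",
                              center = c(0, 0))$area
  expect_lt(abs(a3 - a1) / a1, 0.01)
})

test_that("lipid counts in the 35 A circle follow the free-area rule", {
  expect_equal(lipid_count_in_circle(1900), 41L)
  expect_equal(lipid_count_in_circle(0), 82L)
  expect_equal(lipid_count_in_circle(pi * 35^2), 0L)
  expect_equal(lipid_count_in_circle(5000), 0L)
  # monotone non-increasing in the protein area
  counts <- vapply(seq(0, 4000, by = 250), lipid_count_in_circle,
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(lipid_count_in_circle(-1), "negative")
})

test_that("conformational deltas subtract per-leaflet lipid counts", {
  mk <- function(outer, inner, label) {
    data.frame(leaflet = c("outer", "inner"), area_A2 = c(0, 0),
               lipid_count = c(outer, inner), conformation = label)
  }
  d <- conformational_lipid_delta(mk(50, 46, "inward"),
                                  mk(47, 49, "outward"))
  expect_equal(d$delta[d$leaflet == "inner"], 3)
  expect_equal(d$delta[d$leaflet == "outer"], -3)
  same <- conformational_lipid_delta(mk(44, 44, "a"), mk(44, 44, "b"))
  expect_true(all(same$delta == 0))
})

test_that("footprint wrapper integrates both leaflets of a structure", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(path, rbind(ring_atoms(360, 20, 15),
                                ring_atoms(360, 10, -15)),
                    dum_z = c(15, -15))
  fp <- conformation_footprints(read_membrane_pdb(path))
  expect_setequal(fp$leaflet, c("outer", "inner"))
  expect_equal(fp$area_A2[fp$leaflet == "outer"], pi * 400 * 1.000514,
               tolerance = 1e-4)
  expect_equal(fp$lipid_count[fp$leaflet == "inner"],
               round((pi * 35^2 - pi * 100 * 1.000514) / 47.1))
})

test_that("SMALP capacity lands in the predicted stoichiometry window", {
  expect_equal(smalp_lipid_capacity(), 78L)
  # hand check: (pi (4.5 - 1)^2 - 20) * 2 / 0.471
  expect_equal(smalp_lipid_capacity(),
               as.integer(round((pi * 3.5^2 - 20) * 2 / 0.471)))
  expect_equal(smalp_lipid_capacity(geometry_params(smalp_diameter_nm = 10)),
               as.integer(round((pi * 4^2 - 20) * 2 / 0.471)))
  # degenerate cases
  full <- geometry_params(protein_area_nm2 = pi * 3.5^2)
  expect_equal(smalp_lipid_capacity(full), 0L)
  expect_error(smalp_lipid_capacity(geometry_params(sma_rim_nm = 5)),
               "rim exceeds")
})
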