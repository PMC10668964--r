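test_that("superposition is exact on identical and rigidly moved sets", {
  set.seed(101)
  a <- matrix(rnorm(24), ncol = 3)
  expect_lt(kabsch_superpose(a, a)$rmsd, 1e-12)
  # random proper rotation + translation
  q <- rnorm(4); rot <- quat_to_rot(q)
  b <- a %*% t(rot) + matrix(rep(c(3, -1, 2), each = 8), ncol = 3)
  s <- kabsch_superpose(a, b)
  expect_lt(s$rmsd, 1e-8)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(a[1:2, ], a[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(a, a[1:4, ]), "N x 3")
})

test_that("RMSD is symmetric and invariant under rigid motion of either side", {
  set.seed(102)
  for (rep in 1:10) {
    a <- matrix(rnorm(15), ncol = 3)
    b <- a + matrix(rnorm(15, sd = 0.5), ncol = 3)
    r_ab <- kabsch_superpose(a, b)$rmsd
    expect_equal(kabsch_superpose(b, a)$rmsd, r_ab, tolerance = 1e-9)
    rot <- quat_to_rot(rnorm(4))
    b_moved <- b %*% t(rot) + matrix(rep(rnorm(3), each = 5), ncol = 3)
    expect_equal(kabsch_superpose(a, b_moved)$rmsd, r_ab, tolerance = 1e-9)
    a_moved <- a %*% t(rot) + matrix(rep(rnorm(3), each = 5), ncol = 3)
    expect_equal(kabsch_superpose(a_moved, b)$rmsd, r_ab, tolerance = 1e-9)
  }
})

test_that("weighted superposition honours the weights", {
  set.seed(103)
  a <- matrix(rnorm(12), ncol = 3)
  b <- a; b[4, ] <- b[4, ] + 2
  # zero weight on the displaced point: perfect fit of the rest
  s <- kabsch_superpose(a, b, weights = c(1, 1, 1, 0))
  expect_lt(s$rmsd, 1e-9)
})

test_that("displacement profile is zero on identical pairs and localized for bumps", {
  rec <- identical_record()
  prof <- ca_displacement_profile(rec)
  expect_true(all(prof$displacement < 1e-9, na.rm = TRUE))

  scn <- scenario("local", seed = 12, amplitude = 3, perturb_halfwidth = 6L)
  pr <- make_pair(scn)
  rec2 <- build_pair_record(candidate_pair(pr$intact, pr$modified, "X"))
  prof2 <- ca_displacement_profile(rec2)
  peak <- which.max(prof2$displacement)
  expect_lte(abs(peak - scn$site_index), scn$perturb_halfwidth)
})

test_that("radius of gyration matches closed forms and scales linearly", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  two <- matrix(c(0, 0, 0, 4, 0, 0), 2, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 2)
  square <- matrix(c(0, 0, 0, 2, 0, 0, 0, 2, 0, 2, 2, 0), 4, byrow = TRUE)
  expect_equal(radius_of_gyration(square), sqrt(2))
  set.seed(104)
  pts <- matrix(rnorm(30), ncol = 3)
  expect_equal(radius_of_gyration(pts * 2.5), 2.5 * radius_of_gyration(pts),
               tolerance = 1e-12)
  expect_equal(radius_of_gyration(two, unit = "nm"), 0.2)
  expect_error(radius_of_gyration(matrix(numeric(0), ncol = 3)), "empty")
})

test_that("mass weighting shifts Rg toward heavy atoms", {
  atoms <- data.frame(x = c(0, 10), y = 0, z = 0, element = c("C", "P"))
  rg_m <- radius_of_gyration(atoms, mass_weighted = TRUE)
  rg_u <- radius_of_gyration(atoms, mass_weighted = FALSE)
  expect_lt(abs(rg_u - 5), 1e-12)
  expect_lt(rg_m, 5)  # centroid pulled toward phosphorus
})

test_that("SASA matches the analytic sphere for isolated and distant atoms", {
  one <- data.frame(x = 0, y = 0, z = 0, element = "C")
  a1 <- shrake_rupley_sasa(one)$total
  expect_equal(a1, 4 * pi * 3.1^2, tolerance = 0.02 * 4 * pi * 3.1^2)
  # two atoms beyond occlusion range are both fully exposed
  two <- data.frame(x = c(0, 10), y = 0, z = 0, element = "C")
  a2 <- shrake_rupley_sasa(two)$atom_area
  expect_equal(a2, rep(a1, 2), tolerance = 1e-9)
})

test_that("a fully caged atom has zero accessible area", {
  shell <- ptmlocal:::fibonacci_sphere(26) * 2.0
  atoms <- data.frame(x = c(0, shell[, 1]), y = c(0, shell[, 2]),
                      z = c(0, shell[, 3]),
                      element = "C")
  area <- shrake_rupley_sasa(atoms)$atom_area
  expect_equal(area[1], 0)
})

test_that("adding atoms never increases any existing atom's SASA", {
  pr <- make_backbone(6, "helix")
  at <- pr$atoms
  base <- shrake_rupley_sasa(at)$atom_area
  grown <- rbind(at[, c("x", "y", "z", "element")],
                 data.frame(x = at$x + 2, y = at$y, z = at$z, element = "C"))
  more <- shrake_rupley_sasa(grown)$atom_area
  expect_true(all(more[seq_along(base)] <= base + 1e-9))
})

test_that("SASA converges with mesh refinement", {
  ch <- make_backbone(10, "mixed")
  s960 <- shrake_rupley_sasa(ch$atoms, sasa_params(mesh_points = 960))$total
  s4000 <- shrake_rupley_sasa(ch$atoms, sasa_params(mesh_points = 4000))$total
  expect_lt(abs(s960 - s4000) / s4000, 0.01)
})

test_that("unknown elements fall back with a warning, or error without fallback", {
  odd <- data.frame(x = 0, y = 0, z = 0, element = "XX")
  expect_warning(res <- shrake_rupley_sasa(odd), "fallback")
  expect_equal(res$total, 4 * pi * (1.8 + 1.4)^2, tolerance = 1e-6)
  expect_error(
    shrake_rupley_sasa(odd, sasa_params(fallback_radius = NULL)),
    "no van der Waals radius")
})
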