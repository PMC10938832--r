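# MD trajectory descriptors against analytic oracles, unit conversions and
# invariances.

test_that("mass density matches the hand unit conversion", {
  fr <- list(coordinates = matrix(5, 100, 3), box_lengths = c(10, 10, 10),
             time = 0)
  topo <- system_topology(rep(18, 100), 0:99, vdw_radii = rep(1.5, 100))
  expect_equal(mass_density(fr, topo), 1800 * 1.66053906660e-3,
               tolerance = 1e-12)
  expect_equal(mass_density(fr, topo), 2.989, tolerance = 1e-3)
  # doubling the box divides density by 8
  fr2 <- fr; fr2$box_lengths <- c(20, 20, 20)
  expect_equal(mass_density(fr2, topo), mass_density(fr, topo) / 8)
  expect_error(mass_density(fr, system_topology(numeric(0), integer(0))),
               "empty")
})

test_that("radius of gyration reproduces analytic cases exactly", {
  single <- generate_toy_trajectory("single_sphere")
  expect_equal(radius_of_gyration(single$trajectory[[1]], single$topology), 0)
  dimer <- generate_toy_trajectory("dimer", list(d = 2))
  expect_equal(radius_of_gyration(dimer$trajectory[[1]], dimer$topology), 1,
               tolerance = 1e-9)
  sq <- generate_toy_trajectory("square", list(a = 2))
  expect_equal(radius_of_gyration(sq$trajectory[[1]], sq$topology),
               2 / sqrt(2), tolerance = 1e-9)
})

test_that("Rg unwraps molecules split across the periodic boundary", {
  # atoms 1 A apart through the box edge (9.5 -> 10 -> 0.5), so Rg = 0.5
  L <- 10
  xyz <- rbind(c(9.5, 5, 5), c(0.5, 5, 5))
  topo <- system_topology(c(12, 12), c(0L, 0L), vdw_radii = c(1.7, 1.7))
  fr <- list(coordinates = xyz, box_lengths = rep(L, 3), time = 0)
  expect_equal(radius_of_gyration(fr, topo), 0.5, tolerance = 1e-9)
  # the naive wrapped computation would have given 4.5
})

test_that("RMS displacement tracks rigid translations without alignment", {
  tt <- generate_toy_trajectory("translate", list(step = 1, n_frames = 3))
  expect_equal(rms_displacement(tt$trajectory, tt$topology), c(0, 1, 2),
               tolerance = 1e-9)
  # mixed displacements: atoms moved by 3 and 4 A give sqrt(12.5)
  f1 <- list(coordinates = rbind(c(5, 5, 5), c(10, 10, 10)),
             box_lengths = c(50, 50, 50), time = 0)
  f2 <- list(coordinates = rbind(c(8, 5, 5), c(10, 14, 10)),
             box_lengths = c(50, 50, 50), time = 1)
  topo <- system_topology(c(1, 1), c(0L, 1L))
  traj <- structure(list(f1, f2), class = "trajectory")
  expect_equal(rms_displacement(traj, topo)[2], sqrt(12.5), tolerance = 1e-9)
  expect_error(rms_displacement(traj, topo, reference_index = 5),
               "out of range")
})

test_that("free volume matches the single-sphere closed form and an MC oracle", {
  ts <- generate_toy_trajectory("single_sphere", list(L = 10, r = 1.7))
  fv <- percent_free_volume(ts$trajectory[[1]], ts$topology,
                            grid_spacing = 0.1)
  expect_equal(fv, ts$expected$MD_FV, tolerance = 0.05)

  lat <- generate_toy_trajectory("lattice", list(m_side = 3, s = 4, r = 1.5))
  fv_lat <- percent_free_volume(lat$trajectory[[1]], lat$topology,
                                grid_spacing = 0.1)
  expect_equal(fv_lat, lat$expected$MD_FV, tolerance = 0.1)

  # Monte-Carlo point-sampling oracle on a random fixture
  set.seed(12)
  L <- 8; n <- 5
  xyz <- matrix(runif(n * 3, 0, L), n, 3)
  radii <- runif(n, 1, 2)
  topo <- system_topology(rep(10, n), 0:(n - 1), vdw_radii = radii)
  fr <- list(coordinates = xyz, box_lengths = rep(L, 3), time = 0)
  pts <- matrix(runif(3e5, 0, L), ncol = 3)
  free <- rep(TRUE, nrow(pts))
  for (a in seq_len(n)) {
    d <- sweep(pts, 2, xyz[a, ], "-")
    d <- d - round(d / L) * L
    free <- free & (rowSums(d^2) > radii[a]^2)
  }
  mc <- 100 * mean(free)
  grid <- percent_free_volume(fr, topo, grid_spacing = 0.1)
  expect_equal(grid, mc, tolerance = 1)
  # an empty box is all free volume
  empty_fr <- list(coordinates = matrix(numeric(0), 0, 3),
                   box_lengths = rep(L, 3), time = 0)
  expect_equal(percent_free_volume(empty_fr, topo), 100)
  expect_error(percent_free_volume(fr, topo, grid_spacing = 0), "positive")
})

test_that("cohesive energy density converts units correctly", {
  tc <- generate_toy_trajectory("constant_energy",
                                list(L = 46.42, n_molecules = 100,
                                     e_inter = -1000, T_K = 300))
  sol <- cohesive_energy_and_solubility(tc$trajectory, tc$topology)
  # independent conversion: kcal/mol/A^3 -> Pa via Avogadro and 4184 J/kcal
  conv <- 4184 / (6.02214076e23 * 1e-30) / 1e6
  expect_equal(sol$CED, 1000 / 46.42^3 * conv, tolerance = 1e-9)
  expect_equal(sol$MD_SP, sqrt(sol$CED))
  # component parameters add in quadrature when the shares sum to the total
  expect_equal(sol$MD_SP_E^2 + sol$MD_SP_V^2, sol$MD_SP^2, tolerance = 1e-9)
  # zero energy -> all parameters zero
  tz <- generate_toy_trajectory("constant_energy",
                                list(e_inter = 0, e_elst = 0, e_vdw = 0))
  solz <- cohesive_energy_and_solubility(tz$trajectory, tz$topology)
  expect_equal(solz$MD_SP, 0)
  # non-cohesive energies clamp with a warning
  tp <- generate_toy_trajectory("constant_energy", list(e_inter = 50))
  expect_warning(solp <- cohesive_energy_and_solubility(tp$trajectory,
                                                        tp$topology),
                 "clamped")
  expect_equal(solp$MD_SP, 0)
})

test_that("heat of vaporization is -E/n + RT", {
  topo <- system_topology(rep(30, 100), 0:99)
  frames <- list(list(energies = c(total = 0, inter = 0, elst = 0, vdw = 0),
                      box_lengths = c(10, 10, 10)))
  expect_equal(heat_of_vaporization(frames, topo, 300),
               1.98720425864083e-3 * 300, tolerance = 1e-9)
  expect_equal(heat_of_vaporization(frames, topo, 300), 0.5962,
               tolerance = 1e-4)
  frames2 <- list(list(energies = c(total = -4000, inter = -4000,
                                    elst = -1000, vdw = -3000),
                       box_lengths = c(10, 10, 10)))
  expect_equal(heat_of_vaporization(frames2, topo, 0), 40)
  # monotone in temperature
  expect_lt(heat_of_vaporization(frames2, topo, 250),
            heat_of_vaporization(frames2, topo, 350))
  expect_error(heat_of_vaporization(list(list(energies = NULL,
                                              box_lengths = rep(10, 3))),
                                    topo, 300), "lack")
})

test_that("ensemble averaging uses the trailing window", {
  # density ramp via shrinking boxes: per-frame densities known analytically
  topo <- system_topology(rep(18, 10), 0:9, vdw_radii = rep(1.5, 10))
  boxes <- seq(10, 9, length.out = 10)
  frames <- lapply(seq_along(boxes), function(i) {
    list(coordinates = matrix(runif(30, 0, 9), 10, 3),
         box_lengths = rep(boxes[i], 3), time = i,
         energies = c(total = -100, inter = -100, elst = -40, vdw = -60))
  })
  traj <- structure(frames, class = "trajectory")
  dens_per_frame <- vapply(frames, mass_density, numeric(1), topology = topo)
  ed <- ensemble_descriptors(traj, topo, T_K = 300, trailing_fraction = 0.5,
                             grid_spacing = 0.5)
  expect_equal(ed$MD_density, mean(dens_per_frame[6:10]), tolerance = 1e-12)
  ed_all <- ensemble_descriptors(traj, topo, T_K = 300,
                                 trailing_fraction = 1.0, grid_spacing = 0.5)
  expect_equal(ed_all$MD_density, mean(dens_per_frame), tolerance = 1e-12)
  expect_true(ed$MD_FV >= 0 && ed$MD_FV <= 100)
})

test_that("descriptors are invariant under rigid translation", {
  tc <- generate_toy_trajectory("lattice", list(m_side = 2, s = 5, r = 1.5))
  fr <- tc$trajectory[[1]]
  shifted <- fr
  shifted$coordinates <- fr$coordinates + matrix(c(3.3, -2.1, 7.7),
                                                 nrow(fr$coordinates), 3,
                                                 byrow = TRUE)
  expect_equal(mass_density(shifted, tc$topology),
               mass_density(fr, tc$topology))
  expect_equal(radius_of_gyration(shifted, tc$topology),
               radius_of_gyration(fr, tc$topology), tolerance = 1e-9)
  expect_equal(percent_free_volume(shifted, tc$topology, grid_spacing = 0.25),
               percent_free_volume(fr, tc$topology, grid_spacing = 0.25),
               tolerance = 0.3)
})

test_that("trajectory IO round-trips and validates its contracts", {
  dir <- withr::local_tempdir()
  tt <- generate_toy_trajectory("translate", list(step = 1, n_frames = 3))
  tt$topology$elements <- c("C", "C")
  xyz <- file.path(dir, "traj.xyz")
  topo_js <- file.path(dir, "topo.json")
  write_trajectory(tt$trajectory, tt$topology, xyz)
  jsonlite::write_json(list(
    atom_masses = tt$topology$atom_masses,
    molecule_membership = tt$topology$molecule_membership,
    elements = tt$topology$elements), topo_js, auto_unbox = FALSE)
  rt <- read_trajectory(xyz, topo_js)
  expect_length(rt$trajectory, 3)
  expect_equal(rt$trajectory[[3]]$coordinates, tt$trajectory[[3]]$coordinates,
               tolerance = 1e-6)
  expect_true(all(diff(vapply(rt$trajectory, `[[`, numeric(1), "time")) > 0))
  # vdW radii default from the bundled element table
  expect_equal(rt$topology$vdw_radii, c(1.70, 1.70))

  # atom-count mismatch errors
  jsonlite::write_json(list(atom_masses = c(12, 12, 12),
                            molecule_membership = c(0, 0, 1)),
                       topo_js, auto_unbox = FALSE)
  expect_error(read_trajectory(xyz, topo_js), "topology has 3")

  # frames without energies are kept, energies marked absent
  topo2 <- file.path(dir, "topo2.json")
  jsonlite::write_json(list(atom_masses = c(12, 12),
                            molecule_membership = c(0, 1)),
                       topo2, auto_unbox = FALSE)
  rt2 <- read_trajectory(xyz, topo2)
  expect_null(rt2$trajectory[[1]]$energies)
})
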