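# Occupancy density grids: whole-lipid selection, voxel fractions,
# thresholding, state differences and five-fold symmetry.

test_that("proximal selection uses whole-lipid semantics and is monotone", {
  sim <- fx_small()
  tr <- sim$trajectory
  sel3 <- select_proximal_lipids(tr, sim$topology, 0, cutoff = 3)
  sel4 <- select_proximal_lipids(tr, sim$topology, 0, cutoff = 4)
  expect_true(all(sel3 %in% sel4))
  # ring lipids hug the protein: a nonempty first selection by construction
  expect_gt(length(sel4), 0)

  # whole-lipid rule: one atom within cutoff selects the whole molecule
  sys <- toy_system(protein = c(25, 25, 15),
                    lipids = c(25, 27.5, 15), box = c(50, 50, 60))
  # add two far tail beads to the same lipid molecule
  a <- sys$topology$atoms
  tails <- a[a$kind == "lipid", ][c(1, 1), ]
  tails$elety <- c("T1", "T2"); tails$eleno <- 3:4
  topo <- sl_topology(rbind(a, tails))
  coords <- array(0, c(4, 3, 1))
  coords[1, , 1] <- c(25, 25, 15)
  coords[2, , 1] <- c(25, 27.5, 15)   # head 2.5 A from protein
  coords[3, , 1] <- c(25, 27.5, 3)    # tails 12 A away in z
  coords[4, , 1] <- c(25, 27.5, 7)
  tr2 <- sl_trajectory(coords, c(50, 50, 60), 1)
  expect_equal(select_proximal_lipids(tr2, topo, 0, cutoff = 3), 1L)
  # nearest atom at 3.5 A -> excluded
  coords[2, , 1] <- c(25, 28.5, 15)
  coords[3, , 1] <- c(25, 28.5, 3)
  coords[4, , 1] <- c(25, 28.5, 7)
  tr3 <- sl_trajectory(coords, c(50, 50, 60), 1)
  expect_length(select_proximal_lipids(tr3, topo, 0, cutoff = 3), 0)
})

test_that("occupancy values are frame fractions in [0, 1]", {
  # one lipid atom fixed at a voxel centre for 4 of 10 frames
  sys <- toy_system(protein = c(10, 10, 10), lipids = c(12, 10, 10),
                    box = c(20, 20, 20), n_frames = 10)
  tr <- sys$trajectory
  for (f in 5:10) tr$coords[2, 1, f] <- 100  # outside box/cutoff afterwards
  geom <- sl_grid(array(0, c(21, 21, 21)), c(0, 0, 0), 1)
  g <- occupancy_grid(tr, sys$topology, 0:9, geom, cutoff = 3)
  expect_true(all(g$values >= 0 & g$values <= 1))
  expect_equal(g$values[13, 11, 11], 0.4)   # voxel at (12, 10, 10)
  # all-frames occupancy at the atom's own voxel over the first 4 frames
  g4 <- occupancy_grid(tr, sys$topology, 0:3, geom, cutoff = 3)
  expect_equal(g4$values[13, 11, 11], 1.0)
  expect_error(occupancy_grid(tr, sys$topology, integer(), geom),
               "empty frame set")
})

test_that("occupancy grids combine as frame-count-weighted averages", {
  sim <- fx_small()
  geom <- grid_geometry(sim$trajectory, sim$topology, spacing = 2)
  g_all <- occupancy_grid(sim$trajectory, sim$topology, 0:29, geom)
  g_a <- occupancy_grid(sim$trajectory, sim$topology, 0:9, geom)
  g_b <- occupancy_grid(sim$trajectory, sim$topology, 10:29, geom)
  expect_equal(g_all$values, (10 * g_a$values + 20 * g_b$values) / 30,
               tolerance = 1e-12)
  # frame order is irrelevant
  g_perm <- occupancy_grid(sim$trajectory, sim$topology,
                           sample(0:29), geom)
  expect_equal(g_all$values, g_perm$values)
})

test_that("thresholding is inclusive and monotone in the level", {
  v <- array(c(0.39, 0.40, 0.41, 0.1, 0.95, 0, 0.3, 0.5), c(2, 2, 2))
  g <- sl_grid(v, c(0, 0, 0), 1)
  t40 <- threshold_grid(g, 0.4)
  expect_equal(as.vector(t40$values), as.numeric(v >= 0.4))
  t30 <- threshold_grid(g, 0.3)
  expect_true(all(t30$values >= t40$values))   # 30% reveals a superset
  expect_error(threshold_grid(g, 1.4), "\\[0, 1\\]")
})

test_that("state differences subtract voxelwise and antisymmetrically", {
  set.seed(1)
  a <- sl_grid(array(runif(27), c(3, 3, 3)), c(0, 0, 0), 1)
  b <- sl_grid(array(runif(27), c(3, 3, 3)), c(0, 0, 0), 1)
  zero <- sl_grid(array(0, c(3, 3, 3)), c(0, 0, 0), 1)
  expect_true(all(state_difference(a, a)$values == 0))
  expect_equal(state_difference(a, zero)$values, a$values)
  expect_equal(state_difference(a, b)$values, -state_difference(b, a)$values)
  shifted <- sl_grid(a$values, c(1, 0, 0), 1)
  expect_error(state_difference(a, shifted), "geometry|origin|differ")
})

test_that("the open-minus-closed grid peaks at the gated binding sites", {
  sim <- fx_gated()
  geom <- grid_geometry(sim$trajectory, sim$topology, spacing = 1.5)
  fo <- state_frames(sim$labels, "synthetic", "open")
  fc <- state_frames(sim$labels, "synthetic", "closed")
  go <- occupancy_grid(sim$trajectory, sim$topology, fo, geom, state = "open")
  gc <- occupancy_grid(sim$trajectory, sim$topology, fc, geom,
                       state = "closed")
  dg <- state_difference(go, gc)
  ix <- which(dg$values == max(dg$values), arr.ind = TRUE)[1, ]
  peak <- dg$origin + (ix - 1) * dg$spacing
  # capture radius is lateral: the peak must lie within it of some anchor
  lat <- sqrt((sim$sites$anchor_x - peak[1])^2 +
                (sim$sites$anchor_y - peak[2])^2)
  expect_lt(min(lat), sim$sites$capture_radius[1])
  # and the peak sits in the gated (outer) leaflet
  expect_gt(peak[3], 0)
})

test_that("exact five-fold grids correlate >= 0.98 under 72-degree rotation", {
  g <- c5_test_grid()
  sym <- c5_symmetry_correlation(g, center = c(25, 25))
  expect_length(sym$correlations, 4)
  expect_true(all(sym$correlations >= 0.98))
  # symmetrisation is idempotent within resampling tolerance
  s1 <- sym$symmetrized
  s2 <- c5_symmetry_correlation(s1, center = c(25, 25))$symmetrized
  expect_lt(max(abs(s2$values - s1$values)) / max(s1$values), 0.02)
})

test_that("random grids decorrelate under rotation", {
  set.seed(7)
  n <- 48
  g <- sl_grid(array(runif(n * n * n), c(n, n, n)), c(0, 0, 0), 1)
  sym <- c5_symmetry_correlation(g, center = c((n - 1) / 2, (n - 1) / 2))
  expect_true(all(abs(sym$correlations) < 0.1))
  expect_error(c5_symmetry_correlation(g, center = c(NA, NA)), "degenerate")
})
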