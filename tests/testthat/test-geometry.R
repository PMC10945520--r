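# Pore-axis geometry, penetration statistics, residue-lipid distances,
# landscape projection and the geometric state classifier.

test_that("the pore axis passes through the symmetry centre", {
  sim <- fx_small()
  axis <- define_pore_axis(sim$topology, sim$trajectory$coords[, , 1])
  expect_lt(sqrt(sum((axis$origin[1:2] - sim$center[1:2])^2)), 0.1)
  expect_equal(sqrt(sum(axis$axis^2)), 1)
  # translating the system translates the origin identically
  shifted <- sim$trajectory$coords[, , 1]
  shifted <- sweep(shifted, 2, c(3, -2, 5), "+")
  axis2 <- define_pore_axis(sim$topology, shifted)
  expect_equal(axis2$origin, axis$origin + c(3, -2, 5), tolerance = 1e-10)
})

test_that("radial minima report the closest slab lipid or a missing value", {
  sys <- toy_system(protein = rbind(matrix(c(25, 25, 0), 1),
                                    matrix(c(25, 25, 5), 1),
                                    matrix(c(25, 25, -5), 1),
                                    matrix(c(25, 25, 10), 1),
                                    matrix(c(25, 25, -10), 1)),
                    lipids = c(45, 25, 15,    # radius 20, in outer slab
                               50, 25, 18),   # radius 25
                    box = c(100, 100, 60))
  axis <- define_pore_axis(sys$topology, sys$trajectory$coords[, , 1],
                           slabs = list(outer = c(12, 20),
                                        inner = c(-20, -12)))
  expect_equal(radial_min_distance(sys$trajectory, sys$topology, 0, axis,
                                   "outer"), 20)
  expect_true(is.na(radial_min_distance(sys$trajectory, sys$topology, 0,
                                        axis, "inner")))
  expect_error(radial_min_distance(sys$trajectory, sys$topology, 0, axis,
                                   "middle"), "unknown slab")
  # sector variant: both lipids lie in the +x wedge
  sec <- radial_min_distance(sys$trajectory, sys$topology, 0, axis,
                             "outer", n_sectors = 5)
  expect_equal(sec[1], 20)
  expect_true(all(is.na(sec[2:5])))
})

test_that("penetration fractions count frames below the radial threshold", {
  sim <- fx_gated()
  axis <- define_pore_axis(sim$topology, sim$trajectory$coords[, , 1])
  fo <- state_frames(sim$labels, "synthetic", "open")
  fc <- state_frames(sim$labels, "synthetic", "closed")
  r_site <- 15   # protein radius: bound lipids sit inside it
  po <- penetration_fraction(sim$trajectory, sim$topology, fo, axis,
                             "outer", r_threshold = r_site)
  pc <- penetration_fraction(sim$trajectory, sim$topology, fc, axis,
                             "outer", r_threshold = r_site)
  expect_gt(po, pc)    # gated sites admit lipids only in open frames
  # monotone in the threshold, and 1 at infinity
  p_lo <- penetration_fraction(sim$trajectory, sim$topology, fo, axis,
                               "outer", r_threshold = 10)
  p_inf <- penetration_fraction(sim$trajectory, sim$topology, fo, axis,
                                "outer", r_threshold = Inf)
  expect_lte(p_lo, po)
  expect_equal(p_inf, 1)
})

test_that("residue-lipid minimum distances honour the minimum image", {
  sys <- toy_system(protein = c(1, 10, 10),
                    lipids = c(3.9, 10, 10,
                               19.5, 10, 10),  # 1.5 A through the boundary
                    box = c(20, 20, 20))
  d <- residue_lipid_min_distance(sys$trajectory, sys$topology, 0, "A", 1)
  expect_equal(d, 1.5, tolerance = 1e-10)
  expect_error(residue_lipid_min_distance(sys$trajectory, sys$topology, 0,
                                          "Z", 9), "no residue")
})

test_that("state-resolved contact fractions separate gated states", {
  sim <- fx_gated()
  site <- sim$sites[1, ]
  d <- residue_lipid_min_distance(sim$trajectory, sim$topology, 0:599,
                                  site$chain, site$resid)
  scf <- state_contact_fraction(d, sim$schedule, threshold = 3)
  open_f <- scf$fraction[scf$state == "open"]
  closed_f <- scf$fraction[scf$state == "closed"]
  expect_gt(open_f, closed_f)
  expect_equal(scf$n_frames, c(300L, 300L))
  # plain arithmetic on a hand series
  scf2 <- state_contact_fraction(c(2.5, 2.8, 3.5), rep("open", 3), 3)
  expect_equal(scf2$fraction, 2 / 3)
  expect_error(state_contact_fraction(1:3, c("a", "b")), "align")
})

test_that("landscape projection bins means and conserves frame counts", {
  cv1 <- c(0.1, 0.2, 0.8, 0.9, 0.6)
  cv2 <- c(0.1, 0.1, 0.9, 0.9, 0.6)
  scalar <- c(3, 5, 7, 9, 11)
  lp <- landscape_projection(cv1, cv2, scalar, breaks1 = c(0, 0.5, 1),
                             breaks2 = c(0, 0.5, 1))
  expect_equal(sum(lp$count), 5)
  expect_equal(lp$mean[1, 1], 4)        # frames 1, 2
  expect_equal(lp$mean[2, 2], 9)        # frames 3, 4, 5
  expect_true(lp$empty[1, 2] && lp$empty[2, 1])
  # constant scalar propagates to every nonempty bin
  lpc <- landscape_projection(cv1, cv2, rep(2.5, 5), c(0, 0.5, 1),
                              c(0, 0.5, 1))
  expect_true(all(lpc$mean[!lpc$empty] == 2.5))
  expect_error(landscape_projection(cv1, cv2, scalar, c(0, 0), c(0, 1)),
               "increasing")
})

test_that("the geometric classifier recovers the generating schedule", {
  sim <- fx_gated()
  axis <- define_pore_axis(sim$topology, sim$trajectory$coords[, , 1])
  lab <- geometric_state_classifier(sim$trajectory, sim$topology, 0:599,
                                    sim$gate_idx, axis, open_radius = 4.5)
  expect_identical(lab, sim$schedule)
  # threshold is inclusive: a gate radius exactly at the threshold is open
  r0 <- mean(sqrt((sim$trajectory$coords[sim$gate_idx, 1, 1] -
                     axis$origin[1])^2 +
                  (sim$trajectory$coords[sim$gate_idx, 2, 1] -
                     axis$origin[2])^2))
  at <- geometric_state_classifier(sim$trajectory, sim$topology, 0,
                                   sim$gate_idx, axis, open_radius = r0)
  expect_equal(at, "open")
  above <- geometric_state_classifier(sim$trajectory, sim$topology, 0,
                                      sim$gate_idx, axis,
                                      open_radius = r0 + 0.01)
  expect_equal(above, "closed")
})

test_that("distance analyses are invariant under a rigid in-plane rotation", {
  sim <- fx_small()
  site <- sim$sites[1, ]
  d1 <- residue_lipid_min_distance(sim$trajectory, sim$topology, 0:9,
                                   site$chain, site$resid)
  rot <- sim$trajectory
  ang <- 2 * pi / 5   # the lattice has no symmetry; any angle works with
  cx <- sim$center[1]; cy <- sim$center[2]
  x <- rot$coords[, 1, ] - cx; y <- rot$coords[, 2, ] - cy
  rot$coords[, 1, ] <- cx + cos(ang) * x - sin(ang) * y
  rot$coords[, 2, ] <- cy + sin(ang) * x + cos(ang) * y
  d2 <- residue_lipid_min_distance(rot, sim$topology, 0:9,
                                   site$chain, site$resid)
  expect_equal(d1, d2, tolerance = 1e-8)
})
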