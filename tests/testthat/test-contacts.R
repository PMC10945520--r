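# Residue-lipid contacts: cutoff behaviour, minimum image, run statistics,
# exchange counts, ensemble aggregation.

test_that("contact detection respects the 4 A cutoff and minimum image", {
  sys <- toy_system(protein = c(0, 0, 0),
                    lipids = c(3.9, 0, 0,
                               4.1, 0, 0), box = c(50, 50, 50))
  cs <- contact_series(sys$trajectory, sys$topology)
  expect_true(cs$contacts[1, 1, 1])
  expect_false(cs$contacts[1, 2, 1])

  # wrapped neighbour: box 10, lipid at 9.5 is 0.5 away through the boundary
  sys2 <- toy_system(protein = c(0, 0, 0), lipids = c(9.5, 0, 0),
                     box = c(10, 10, 10))
  cs2 <- contact_series(sys2$trajectory, sys2$topology)
  expect_true(cs2$contacts[1, 1, 1])
  # brute force over the 27 periodic images agrees
  imgs <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1)) * 10
  d <- min(sqrt(rowSums((sweep(imgs, 2, c(9.5, 0, 0), "+"))^2)))
  expect_equal(d, 0.5)
})

test_that("contact_series errors without lipids and with a bad selection", {
  sys <- toy_system(protein = c(0, 0, 0), lipids = c(3, 0, 0))
  nolip <- sys$topology
  nolip$atoms$kind <- "protein"
  nolip$atoms$lipid_id <- NA_integer_
  expect_error(contact_series(sys$trajectory, sl_topology(nolip$atoms)),
               "no lipid")
  expect_error(contact_series(sys$trajectory, sys$topology,
                              residues = data.frame(chain = "Z", resid = 99)),
               "no protein atoms")
})

test_that("duration statistics follow run and gap-merge rules", {
  make_series <- function(x) {
    nf <- length(x)
    structure(list(
      contacts = array(x, c(1, 1, nf), dimnames = list("A:1", "1", NULL)),
      dt = 1, cutoff = 4, traj_id = "toy",
      residues = data.frame(chain = "A", resid = 1, resname = "ALA")),
      class = "sl_contact_series")
  }
  s <- make_series(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  d0 <- duration_stats(s, gap_tolerance = 0)
  expect_equal(d0$mean_duration_ns, 2.5)   # runs of 3 and 2 ns
  expect_equal(d0$n_runs, 2L)
  expect_true(d0$censored)                 # both runs touch an end
  d1 <- duration_stats(s, gap_tolerance = 1)
  expect_equal(d1$mean_duration_ns, 6)     # merged into one 6 ns run
  expect_equal(d1$n_runs, 1L)
  z <- duration_stats(make_series(rep(FALSE, 6)))
  expect_equal(z$mean_duration_ns, 0)
  expect_equal(z$n_runs, 0L)
  # interior run is not censored
  s2 <- make_series(c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_false(duration_stats(s2)$censored)
  # total contact time never exceeds the trajectory length
  expect_lte(d0$mean_duration_ns * d0$n_runs, 6)
})

test_that("exchange counts equal brute-force distinct-lipid counts", {
  set.seed(42)
  nf <- 50; nres <- 6; nlip <- 12
  arr <- array(runif(nres * nlip * nf) < 0.05, c(nres, nlip, nf),
               dimnames = list(paste0("A:", 1:nres), 1:nlip, NULL))
  s <- structure(list(contacts = arr, dt = 1, cutoff = 4, traj_id = "rand",
                      residues = data.frame(chain = "A", resid = 1:nres,
                                            resname = "ALA")),
                 class = "sl_contact_series")
  got <- exchange_counts(s)$n_lipids
  want <- vapply(seq_len(nres), function(r) {
    length(unique(which(apply(arr[r, , , drop = FALSE], 2, any))))
  }, integer(1))
  expect_equal(got, want)
  # no contacts -> zero lipids
  arr0 <- arr; arr0[] <- FALSE
  s0 <- s; s0$contacts <- arr0
  expect_true(all(exchange_counts(s0)$n_lipids == 0))
})

test_that("duration statistics are invariant to lipid id relabelling", {
  sim <- fx_gated()
  cs <- contact_series(sim$trajectory, sim$topology,
                       residues = sim$sites[c("chain", "resid")])
  ds1 <- duration_stats(cs)
  perm <- sample(dim(cs$contacts)[2])
  cs2 <- cs
  cs2$contacts <- cs$contacts[, perm, , drop = FALSE]
  ds2 <- duration_stats(cs2)
  expect_equal(ds1$mean_duration_ns, ds2$mean_duration_ns)
  expect_equal(ds1$n_runs, ds2$n_runs)
})

test_that("site-residue contact durations converge to 1/k_off", {
  sim <- fx_residence()
  cs <- contact_series(sim$trajectory, sim$topology,
                       residues = sim$sites[c("chain", "resid")])
  ds <- duration_stats(cs)
  truth <- 10   # 1/k_off ns
  pooled <- sum(ds$mean_duration_ns * ds$n_runs) / sum(ds$n_runs)
  expect_lt(abs(pooled - truth) / truth, 0.15)
  # and the contact runs track the generator's own event log closely
  # (site jitter can very occasionally break one interaction into two runs)
  ev <- sim$events
  expect_lt(abs(sum(ds$n_runs) - nrow(ev)) / nrow(ev), 0.05)
})

test_that("ensemble aggregation averages trajectories and pools subunits", {
  a <- data.frame(traj_id = "t1", chain = "A", resid = 1, resname = "SIT",
                  mean_duration_ns = 2, n_runs = 1L, n_lipids = 1L,
                  censored = FALSE)
  b <- a; b$traj_id <- "t2"; b$mean_duration_ns <- 4
  agg <- aggregate_ensemble(list(a, b))
  expect_equal(agg$ensemble$mean_duration_ns, 3)
  expect_equal(nrow(agg$points), 2)
  single <- aggregate_ensemble(list(a))
  expect_equal(single$ensemble$mean_duration_ns, 2)
  expect_error(aggregate_ensemble(list()), "empty")
})

test_that("pooling five subunits shrinks the standard error about sqrt(5)-fold", {
  specs <- lapply(1:5, function(s) sl_site(s, capture_radius = 6, k_on = 2,
                                           k_off = 0.1))
  stats_list <- lapply(1:6, function(sd) {
    cfg <- sl_synthetic_config(
      n_lipids_per_leaflet = 40, n_frames = 1500, dt = 0.5,
      site_specs = specs, box = c(110, 110),
      state_schedule = data.frame(from = 0, to = 1500, state = "closed"),
      seed = 100 + sd)
    sim <- simulate_bilayer(cfg)
    cs <- contact_series(sim$trajectory, sim$topology,
                         residues = sim$sites[c("chain", "resid")])
    duration_stats(cs)
  })
  pooled <- aggregate_ensemble(stats_list, pool_subunits = TRUE)$ensemble
  unpooled <- aggregate_ensemble(stats_list)$ensemble
  expect_equal(pooled$n, 30)          # 6 trajectories x 5 subunits
  ratio <- pooled$se / mean(unpooled$se)
  expect_gt(ratio, 1 / sqrt(5) * 0.5)
  expect_lt(ratio, 1 / sqrt(5) * 2.0)
  expect_lt(pooled$se, mean(unpooled$se))
})

test_that("raising k_off at one site shortens that residue's mean duration", {
  base_specs <- lapply(1:5, function(s) sl_site(s, capture_radius = 6,
                                                k_on = 2, k_off = 0.05))
  mut_specs <- base_specs
  mut_specs[[1]] <- sl_site(1, capture_radius = 6, k_on = 2, k_off = 0.5)
  run <- function(specs, seed) {
    cfg <- sl_synthetic_config(
      n_lipids_per_leaflet = 40, n_frames = 1500, dt = 0.5,
      site_specs = specs, box = c(110, 110),
      state_schedule = data.frame(from = 0, to = 1500, state = "closed"),
      seed = seed)
    sim <- simulate_bilayer(cfg)
    cs <- contact_series(sim$trajectory, sim$topology,
                         residues = sim$sites[c("chain", "resid")])
    duration_stats(cs)
  }
  wt <- aggregate_ensemble(lapply(c(31, 32), function(s) run(base_specs, s)))
  mut <- aggregate_ensemble(lapply(c(31, 32), function(s) run(mut_specs, s)))
  wt_site <- wt$ensemble$mean_duration_ns[wt$ensemble$chain == "A"]
  mut_site <- mut$ensemble$mean_duration_ns[mut$ensemble$chain == "A"]
  expect_lt(mut_site, wt_site)
  # untouched subunits keep comparable kinetics
  wt_other <- mean(wt$ensemble$mean_duration_ns[wt$ensemble$chain != "A"])
  mut_other <- mean(mut$ensemble$mean_duration_ns[mut$ensemble$chain != "A"])
  expect_lt(abs(mut_other - wt_other) / wt_other, 0.5)
})
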