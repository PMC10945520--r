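# Shared fixtures, built once per test run and memoised.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- build()
  .fx_cache[[name]]
}

# Gated-binding system: one site per subunit, active only in "open",
# alternating closed/open schedule.
fx_gated <- function() fx("gated", function() {
  specs <- lapply(1:5, function(s) {
    sl_site(s, capture_radius = 6, k_on = 3, k_off = 0.05,
            states_active = "open")
  })
  sch <- data.frame(from = c(0, 150, 300, 450), to = c(150, 300, 450, 600),
                    state = c("closed", "open", "closed", "open"))
  cfg <- sl_synthetic_config(n_lipids_per_leaflet = 60, n_frames = 600,
                             dt = 1, site_specs = specs,
                             state_schedule = sch, box = c(120, 120),
                             seed = 5)
  sim <- simulate_bilayer(cfg)
  sim$schedule <- rep(c("closed", "open", "closed", "open"), each = 150)
  sim
})

# Always-active sites with 10 ns residence, long run: many binding events.
fx_residence <- function() fx("residence", function() {
  specs <- lapply(1:5, function(s) {
    sl_site(s, capture_radius = 6, k_on = 2, k_off = 0.1)
  })
  cfg <- sl_synthetic_config(
    n_lipids_per_leaflet = 80, n_frames = 4000, dt = 0.5,
    site_specs = specs,
    state_schedule = data.frame(from = 0, to = 4000, state = "closed"),
    seed = 11)
  simulate_bilayer(cfg)
})

# Site-free bilayer for clean diffusion recovery (400 lipids, 1200 frames).
fx_diffusion <- function() fx("diffusion", function() {
  cfg <- sl_synthetic_config(n_lipids_per_leaflet = 200, n_frames = 1200,
                             dt = 1, D_free = 1.0, site_specs = list(),
                             box = c(180, 180), seed = 2)
  simulate_bilayer(cfg)
})

# Small default-style simulation for io / pipeline round-trips.
fx_small <- function() fx("small", function() {
  cfg <- sl_synthetic_config(n_lipids_per_leaflet = 30, n_frames = 60,
                             dt = 1, box = c(100, 100), seed = 3)
  simulate_bilayer(cfg)
})

# Hand-built point system: each protein "residue" and each lipid is a
# single bead at a stated position.
toy_system <- function(protein, lipids, box = c(50, 50, 50), dt = 1,
                       n_frames = 1, radius = 1.7) {
  if (!is.matrix(protein)) protein <- matrix(protein, ncol = 3, byrow = TRUE)
  if (!is.matrix(lipids)) lipids <- matrix(lipids, ncol = 3, byrow = TRUE)
  np <- nrow(protein); nl <- nrow(lipids)
  atoms <- data.frame(
    eleno = seq_len(np + nl),
    elety = c(rep("CA", np), rep("HD", nl)),
    resid = c(seq_len(np), seq_len(nl)),
    resname = c(rep("ALA", np), rep("LIP", nl)),
    chain = c(rep("A", np), rep("L", nl)),
    kind = c(rep("protein", np), rep("lipid", nl)),
    lipid_id = c(rep(NA_integer_, np), seq_len(nl)),
    radius = radius, stringsAsFactors = FALSE)
  topo <- sl_topology(atoms)
  xyz <- rbind(protein, lipids)
  coords <- array(rep(xyz, n_frames), c(np + nl, 3, n_frames))
  list(topology = topo,
       trajectory = sl_trajectory(coords, box, dt, id = "toy"))
}

# Exactly C5-symmetric smooth grid: Gaussian blobs at five rotated anchors.
c5_test_grid <- function(center = c(25, 25), radius = 12, z0 = 10,
                         spacing = 1, n = 51, sigma = 3) {
  vals <- array(0, c(n, n, 21))
  ax <- (seq_len(n) - 1) * spacing
  az <- (seq_len(21) - 1) * spacing
  for (k in 0:4) {
    ang <- 2 * pi * k / 5
    cx <- center[1] + radius * cos(ang)
    cy <- center[2] + radius * sin(ang)
    gx <- exp(-(ax - cx)^2 / (2 * sigma^2))
    gy <- exp(-(ax - cy)^2 / (2 * sigma^2))
    gz <- exp(-(az - z0)^2 / (2 * sigma^2))
    vals <- vals + outer(outer(gx, gy), gz)
  }
  sl_grid(vals, c(0, 0, 0), spacing)
}

# Continuous residence times from frame-quantised bound intervals: the
# within-frame event offset is drawn from its exact truncated-exponential
# conditional, so intervals generated by per-frame unbinding at rate k_off
# become exactly Exponential(k_off).
dejitter_durations <- function(frames_bound, dt, rate, seed = 99) {
  set.seed(seed)
  u <- stats::runif(length(frames_bound))
  v <- log(1 + u * (exp(rate * dt) - 1)) / (rate * dt)
  (frames_bound - v) * dt
}
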