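# Synthetic bilayer-trajectory generator with known ground truth.
#
# The model is deliberately minimal: a C-symmetric pentameric pseudo-protein
# spanning a two-leaflet bilayer, rigid three-bead lipids performing lateral
# Brownian motion, and discrete binding sites with Markovian (telegraph)
# on/off kinetics whose availability can be gated by a closed/open state
# schedule.  Every downstream estimator (contacts, diffusion, occupancy,
# frame selection, geometry) has an exact analytic counterpart here.

#' Describe a lipid binding site for the synthetic generator
#'
#' Each site belongs to one subunit and one leaflet.  A free lipid whose
#' head bead enters the site's capture radius may bind with per-frame
#' probability `1 - exp(-k_on * dt)`; a bound lipid is held at the site
#' anchor (plus small jitter) and unbinds with probability
#' `1 - exp(-k_off * dt)`.  Sites are exclusive: one lipid at a time, which
#' makes the residence-time distribution exactly exponential with mean
#' `1/k_off`.  A site is only able to bind when the current state label is
#' in `states_active`; when the state leaves that set, a bound lipid is
#' released immediately (gated release, flagged separately from stochastic
#' unbinding).
#'
#' @param subunit subunit index (1-based).
#' @param leaflet `"outer"` (positive z) or `"inner"`.
#' @param capture_radius lateral capture radius around the anchor, Angstrom.
#' @param k_on,k_off binding/unbinding rates, 1/ns (non-negative).
#' @param states_active character vector of state labels in which the site
#'   can bind.
#' @return a `sl_site` list.
#' @export
sl_site <- function(subunit, leaflet = c("outer", "inner"),
                    capture_radius = 6, k_on = 1, k_off = 0.02,
                    states_active = c("closed", "open")) {
  leaflet <- match.arg(leaflet)
  if (capture_radius <= 0) stopf("capture_radius must be positive")
  if (k_on < 0 || k_off < 0) stopf("k_on and k_off must be non-negative")
  structure(list(subunit = as.integer(subunit), leaflet = leaflet,
                 capture_radius = capture_radius, k_on = k_on, k_off = k_off,
                 states_active = states_active), class = "sl_site")
}

#' Configuration for the synthetic bilayer generator
#'
#' Defaults emulate the simulated pentameric channel system: a five-fold
#' symmetric protein of ~15 Angstrom radius in a square patch of bilayer,
#' lipids diffusing at the bulk POPC-like rate of 1.47 nm^2/us, and one
#' outer-leaflet binding site per subunit with a 50 ns mean residence time.
#' Internal units are Angstrom and nanoseconds; `D_free` is given in
#' nm^2/us and converted via 1 nm^2/us = 0.1 A^2/ns.
#'
#' @param n_subunits number of protein subunits (default 5).
#' @param protein_radius radius of the protein surface bead ring, Angstrom.
#' @param bilayer_halfwidth leaflet head-plane height |z|, Angstrom.
#' @param n_lipids_per_leaflet lipid count per leaflet.
#' @param D_free lateral diffusion coefficient of free lipids, nm^2/us.
#' @param site_specs list of [sl_site()] descriptions; `NULL` gives one
#'   always-active outer-leaflet site per subunit.
#' @param state_schedule data.frame with columns `from`, `to`, `state`:
#'   half-open 0-based frame ranges `[from, to)` that must tile
#'   `[0, n_frames)`.  Default: first half `"closed"`, second half `"open"`.
#' @param n_frames number of frames (including frame 0).
#' @param dt time per frame, ns.
#' @param box lateral box lengths (x, y), Angstrom.
#' @param gate_radius_closed,gate_radius_open radial position of the
#'   pore-lining gate beads in each state, Angstrom.
#' @param seed integer RNG seed stored with the configuration.
#' @return object of class `sl_synthetic_config`.
#' @export
sl_synthetic_config <- function(n_subunits = 5L,
                                protein_radius = 15,
                                bilayer_halfwidth = 15,
                                n_lipids_per_leaflet = 100L,
                                D_free = 1.47,
                                site_specs = NULL,
                                state_schedule = NULL,
                                n_frames = 1000L,
                                dt = 1,
                                box = c(140, 140),
                                gate_radius_closed = 3,
                                gate_radius_open = 6,
                                seed = 1L) {
  if (is.null(site_specs)) {
    site_specs <- lapply(seq_len(n_subunits), function(s) sl_site(s))
  }
  if (is.null(state_schedule)) {
    h <- n_frames %/% 2L
    state_schedule <- data.frame(
      from = c(0L, h), to = c(h, n_frames),
      state = c("closed", "open"), stringsAsFactors = FALSE)
  }
  cfg <- structure(list(
    n_subunits = as.integer(n_subunits), protein_radius = protein_radius,
    bilayer_halfwidth = bilayer_halfwidth,
    n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
    beads_per_lipid = 3L, D_free = D_free, site_specs = site_specs,
    state_schedule = state_schedule, n_frames = as.integer(n_frames),
    dt = dt, box = as.numeric(box),
    gate_radius_closed = gate_radius_closed,
    gate_radius_open = gate_radius_open,
    lipid_exclusion = 1.5, bind_jitter = 0.5, bead_radius = 1.7,
    seed = as.integer(seed)), class = "sl_synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$D_free < 0) stopf("D_free must be non-negative")
  if (cfg$n_subunits < 1L) stopf("need at least one subunit")
  if (cfg$dt <= 0) stopf("dt must be positive")
  if (length(cfg$box) != 2 || any(cfg$box <= 0)) {
    stopf("box must be two positive lateral lengths")
  }
  for (s in cfg$site_specs) {
    if (!inherits(s, "sl_site")) stopf("site_specs must be sl_site objects")
    if (s$subunit < 1L || s$subunit > cfg$n_subunits) {
      stopf("site subunit %d outside 1..%d", s$subunit, cfg$n_subunits)
    }
    if (cfg$protein_radius + s$capture_radius >= min(cfg$box) / 2) {
      stopf("protein_radius + capture_radius must be < box/2")
    }
  }
  if (cfg$protein_radius >= min(cfg$box) / 2) {
    stopf("protein_radius must be smaller than half the box")
  }
  sch <- cfg$state_schedule
  if (!all(c("from", "to", "state") %in% names(sch))) {
    stopf("state_schedule needs columns from, to, state")
  }
  sch <- sch[order(sch$from), ]
  if (sch$from[1] != 0L || sch$to[nrow(sch)] != cfg$n_frames ||
      (nrow(sch) > 1 && any(sch$to[-nrow(sch)] != sch$from[-1]))) {
    stopf("state_schedule must tile [0, n_frames) without gaps or overlap")
  }
  invisible(cfg)
}

#' Per-frame state labels implied by a schedule
#' @noRd
schedule_labels <- function(cfg) {
  lab <- character(cfg$n_frames)
  for (i in seq_len(nrow(cfg$state_schedule))) {
    r <- cfg$state_schedule[i, ]
    lab[(r$from + 1L):r$to] <- r$state
  }
  lab
}

# z of the head-bead plane of a leaflet
leaflet_z <- function(cfg, leaflet) {
  if (leaflet == "outer") cfg$bilayer_halfwidth else -cfg$bilayer_halfwidth
}

#' Build the synthetic system: topology and initial coordinates
#'
#' Places a C-symmetric arrangement of protein pseudo-residues — surface
#' bead rings at four membrane depths, one pore-lining gate bead per
#' subunit, and one designated site residue per binding site — and lays
#' lipids on a square lattice in each leaflet outside the protein
#' footprint.  Rotating the protein coordinates by 360/n_subunits degrees
#' about the pore axis maps each subunit onto the next.
#'
#' @param cfg an [sl_synthetic_config()].
#' @return list with `topology` ([sl_topology()]), `coords` (n x 3 matrix,
#'   Angstrom), `center` (protein centre), `box` (length-3 box vector),
#'   `sites` (data.frame of site anchors and kinetics) and `gate_idx`
#'   (atom indices of the gate beads).
#' @export
build_system <- function(cfg) {
  validate_synthetic_config(cfg)
  R <- cfg$protein_radius
  H <- cfg$bilayer_halfwidth
  cx <- cfg$box[1] / 2
  cy <- cfg$box[2] / 2
  box3 <- c(cfg$box, 6 * H + 40)

  atoms <- list()
  xyz <- list()
  add <- function(x, y, z, elety, resid, resname, chain, kind, lipid_id,
                  radius) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      elety = elety, resid = resid, resname = resname, chain = chain,
      kind = kind, lipid_id = lipid_id, radius = radius,
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- c(x, y, z)
  }

  chains <- LETTERS[seq_len(cfg$n_subunits)]
  z_levels <- c(-H, -H / 3, H / 3, H)
  ring_offsets <- pi / 180 * c(-24, 0, 24)

  # sites grouped by subunit so residue layouts stay identical across
  # subunits whenever every subunit carries the same number of sites
  site_by_subunit <- split(seq_along(cfg$site_specs),
                           vapply(cfg$site_specs, `[[`, 1L, "subunit"))

  ns <- length(cfg$site_specs)
  sites <- data.frame(site = seq_len(ns),
                      subunit = rep(NA_integer_, ns),
                      leaflet = rep(NA_character_, ns),
                      anchor_x = rep(NA_real_, ns),
                      anchor_y = rep(NA_real_, ns),
                      anchor_z = rep(NA_real_, ns),
                      capture_radius = rep(NA_real_, ns),
                      k_on = rep(NA_real_, ns), k_off = rep(NA_real_, ns),
                      chain = rep(NA_character_, ns),
                      resid = rep(NA_integer_, ns))
  sites$states_active <- vector("list", ns)

  for (s in seq_len(cfg$n_subunits)) {
    phi <- 2 * pi * (s - 1) / cfg$n_subunits
    resid <- 0L
    for (zl in z_levels) {                       # surface bead rings
      resid <- resid + 1L
      for (off in ring_offsets) {
        add(cx + R * cos(phi + off), cy + R * sin(phi + off), zl,
            "SUR", resid, "SUR", chains[s], "protein", NA_integer_,
            cfg$bead_radius)
      }
    }
    resid <- resid + 1L                           # pore-lining gate bead
    r0 <- cfg$gate_radius_closed
    add(cx + r0 * cos(phi), cy + r0 * sin(phi), 0,
        "GAT", resid, "GAT", chains[s], "protein", NA_integer_,
        cfg$bead_radius)
    for (si in site_by_subunit[[as.character(s)]]) { # recessed site residues
      spec <- cfg$site_specs[[si]]
      resid <- resid + 1L
      zs <- leaflet_z(cfg, spec$leaflet)
      rr <- R - 3                                  # recessed into the wall
      add(cx + rr * cos(phi), cy + rr * sin(phi), zs,
          "SIT", resid, "SIT", chains[s], "protein", NA_integer_,
          cfg$bead_radius)
      sites$subunit[si] <- s
      sites$leaflet[si] <- spec$leaflet
      sites$anchor_x[si] <- cx + (R - 1) * cos(phi)
      sites$anchor_y[si] <- cy + (R - 1) * sin(phi)
      sites$anchor_z[si] <- zs
      sites$capture_radius[si] <- spec$capture_radius
      sites$k_on[si] <- spec$k_on
      sites$k_off[si] <- spec$k_off
      sites$chain[si] <- chains[s]
      sites$resid[si] <- resid
      sites$states_active[[si]] <- spec$states_active
    }
  }

  # lipids per leaflet: an annular ring hugging the protein (the initial
  # first shell) plus a lattice spread over the rest of the box
  excl <- R + cfg$lipid_exclusion + 1
  n_per <- cfg$n_lipids_per_leaflet
  free_area <- cfg$box[1] * cfg$box[2] - pi * excl^2
  min_area <- (2 * cfg$bead_radius + 1)^2    # beads must not overlap
  if (free_area / n_per < min_area) {
    stopf("cannot place %d lipids per leaflet in a %g x %g box",
          n_per, cfg$box[1], cfg$box[2])
  }
  r_ring <- R + cfg$lipid_exclusion + 0.5
  n_ring <- min(n_per %/% 5, floor(2 * pi * r_ring / 8))
  ring_phi <- 2 * pi * (seq_len(n_ring) - 1) / max(n_ring, 1L)
  ring <- data.frame(x = cx + r_ring * cos(ring_phi),
                     y = cy + r_ring * sin(ring_phi))
  n_lat <- n_per - n_ring
  n_side <- ceiling(sqrt(n_lat * cfg$box[1] * cfg$box[2] /
                           max(cfg$box[1] * cfg$box[2] - pi * excl^2, 1)) *
                      1.3) + 1L
  gx <- (seq_len(n_side) - 0.5) * cfg$box[1] / n_side
  gy <- (seq_len(n_side) - 0.5) * cfg$box[2] / n_side
  lattice <- expand.grid(x = gx, y = gy)
  keep <- (lattice$x - cx)^2 + (lattice$y - cy)^2 > excl^2
  lattice <- lattice[keep, ]
  if (nrow(lattice) < n_lat) {
    stopf("cannot place %d lipids per leaflet in a %g x %g box",
          n_per, cfg$box[1], cfg$box[2])
  }
  # evenly strided subset so the occupied lattice covers the whole box
  lattice <- lattice[round(seq(1, nrow(lattice), length.out = n_lat)), ]
  lattice <- rbind(ring, lattice)

  lip_id <- 0L
  for (leaflet in c("outer", "inner")) {
    zh <- leaflet_z(cfg, leaflet)
    sgn <- if (leaflet == "outer") 1 else -1
    for (i in seq_len(n_per)) {
      lip_id <- lip_id + 1L
      x <- lattice$x[i]; y <- lattice$y[i]
      add(x, y, zh, "HD", lip_id, "LIP", "L", "lipid", lip_id,
          cfg$bead_radius)
      add(x, y, zh - sgn * 4, "T1", lip_id, "LIP", "L", "lipid", lip_id,
          cfg$bead_radius)
      add(x, y, zh - sgn * 8, "T2", lip_id, "LIP", "L", "lipid", lip_id,
          cfg$bead_radius)
    }
  }

  atoms <- do.call(rbind, atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  coords <- do.call(rbind, xyz)
  colnames(coords) <- c("x", "y", "z")

  min_sep <- min(stats::dist(coords[atoms$kind == "protein", ]))
  if (min_sep < 0.8) stopf("degenerate geometry: bead separation %.2f A", min_sep)

  topo <- sl_topology(atoms[c("eleno", "elety", "resid", "resname", "chain",
                              "kind", "lipid_id", "radius")])
  list(topology = topo, coords = coords, center = c(cx, cy, 0), box = box3,
       sites = sites, gate_idx = which(atoms$elety == "GAT"))
}

#' Analytic ground truth implied by a configuration
#'
#' @param cfg an [sl_synthetic_config()].
#' @return list with `D_free` (nm^2/us, echoed), and per site
#'   `mean_residence_ns` (`1/k_off`) and `bound_fraction`
#'   (`k_on/(k_on + k_off)` for the two-state gate).
#' @export
analytic_ground_truth <- function(cfg) {
  validate_synthetic_config(cfg)
  k_on <- vapply(cfg$site_specs, `[[`, 0, "k_on")
  k_off <- vapply(cfg$site_specs, `[[`, 0, "k_off")
  list(
    D_free = cfg$D_free,
    sites = data.frame(
      site = seq_along(cfg$site_specs),
      mean_residence_ns = ifelse(k_off > 0, 1 / k_off, Inf),
      bound_fraction = ifelse(k_on + k_off > 0, k_on / (k_on + k_off), 0)))
}

#' Simulate a synthetic bilayer trajectory
#'
#' Free lipids take lateral Brownian steps with per-axis variance
#' `2 * D_free * dt` (after unit conversion) and are reflected off a
#' cylindrical exclusion zone around the protein; positions are wrapped
#' into the periodic box laterally while an unwrapped copy is retained for
#' displacement analysis.  Site binding follows the telegraph kinetics of
#' [sl_site()], gated by the state schedule.  Gate beads move radially
#' outward in `"open"` frames so a geometric classifier can recover the
#' schedule.  The run is exactly reproducible for a fixed seed.
#'
#' @param cfg an [sl_synthetic_config()].
#' @param seed overrides `cfg$seed` when given.
#' @param traj_id trajectory identifier for the output objects.
#' @param condition condition tag carried on the trajectory.
#' @return list with `trajectory` ([sl_trajectory()], including unwrapped
#'   coordinates), `topology`, `labels` ([sl_state_labels()]), `sites`
#'   (anchor table from [build_system()]), `events` (one row per binding
#'   event: site, lipid, start/end frame, frames bound, `release` one of
#'   `"stochastic"`, `"gated"`, `"end"`), `ground_truth`
#'   ([analytic_ground_truth()]) and `config`.
#' @export
simulate_bilayer <- function(cfg, seed = NULL, traj_id = "synthetic",
                             condition = NA_character_) {
  validate_synthetic_config(cfg)
  seed <- seed %||% cfg$seed
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  sys <- build_system(cfg)
  topo <- sys$topology
  atoms <- topo$atoms
  nat <- nrow(atoms)
  nf <- cfg$n_frames
  labels <- schedule_labels(cfg)
  box3 <- sys$box
  cx <- sys$center[1]; cy <- sys$center[2]

  D_a2 <- cfg$D_free * NM2_PER_US_TO_A2_PER_NS        # A^2/ns
  step_sd <- sqrt(2 * D_a2 * cfg$dt)
  r_excl <- cfg$protein_radius + cfg$lipid_exclusion

  lip_head <- which(atoms$elety == "HD")
  nlip <- length(lip_head)
  lip_of_head <- atoms$lipid_id[lip_head]
  # per-lipid bead row indices (head, tail1, tail2) — contiguous by build
  bead_rows <- lapply(lip_head, function(i) i + 0:2)
  bead_dz <- lapply(bead_rows, function(r) sys$coords[r, 3] - sys$coords[r[1], 3])

  # lateral head positions drive the dynamics
  pos <- sys$coords[lip_head, 1:2, drop = FALSE]       # wrapped
  upos <- pos                                          # unwrapped
  leaflet <- ifelse(sys$coords[lip_head, 3] > 0, "outer", "inner")

  sites <- sys$sites
  nsite <- nrow(sites)
  occupant <- rep(NA_integer_, nsite)                  # lipid index per site
  bound_site <- rep(NA_integer_, nlip)                 # site per lipid
  start_frame <- rep(NA_integer_, nsite)
  p_on <- 1 - exp(-sites$k_on * cfg$dt)
  p_off <- 1 - exp(-sites$k_off * cfg$dt)

  events <- list()
  push_event <- function(si, frame_end, release) {
    events[[length(events) + 1L]] <<- data.frame(
      site = si, lipid = lip_of_head[occupant[si]],
      start_frame = start_frame[si], end_frame = frame_end,
      frames_bound = frame_end - start_frame[si] + 1L,
      release = release, stringsAsFactors = FALSE)
  }

  coords <- array(NA_real_, c(nat, 3, nf))
  ucoords <- array(NA_real_, c(nat, 3, nf))

  site_active <- function(lab) {
    vapply(seq_len(nsite), function(si) {
      lab %in% sites$states_active[[si]]
    }, TRUE)
  }

  all_lip_rows <- unlist(bead_rows)                  # 3 beads per lipid
  place_frame <- function(f) {
    fr <- sys$coords                   # protein static except gate beads
    r_gate <- if (labels[f] == "open") cfg$gate_radius_open else
      cfg$gate_radius_closed
    phi <- 2 * pi * (seq_len(cfg$n_subunits) - 1) / cfg$n_subunits
    fr[sys$gate_idx, 1] <- cx + r_gate * cos(phi)
    fr[sys$gate_idx, 2] <- cy + r_gate * sin(phi)
    # lipid z is fixed per leaflet (set at build); beads share the head's x,y
    fr[all_lip_rows, 1] <- rep(pos[, 1], each = 3L)
    fr[all_lip_rows, 2] <- rep(pos[, 2], each = 3L)
    coords[, , f] <<- fr
    fr[all_lip_rows, 1] <- rep(upos[, 1], each = 3L)
    fr[all_lip_rows, 2] <- rep(upos[, 2], each = 3L)
    ucoords[, , f] <<- fr
  }

  place_frame(1L)

  for (f in 2L:nf) {
    lab <- labels[f]
    active <- site_active(lab)
    released_now <- integer(0)   # no same-step rebinding: keeps intervals
                                 # and contact runs in 1:1 correspondence

    # --- gated release: site no longer available in this state
    for (si in which(!active & !is.na(occupant))) {
      li <- occupant[si]
      push_event(si, f - 2L, "gated")
      # eject radially to just outside the exclusion zone
      ang <- atan2(pos[li, 2] - cy, pos[li, 1] - cx)
      new <- c(cx + (r_excl + 0.1) * cos(ang), cy + (r_excl + 0.1) * sin(ang))
      upos[li, ] <- upos[li, ] + (new - pos[li, ])
      pos[li, ] <- new
      occupant[si] <- NA_integer_
      bound_site[li] <- NA_integer_
      released_now <- c(released_now, li)
    }

    # --- stochastic unbinding
    for (si in which(!is.na(occupant))) {
      if (p_off[si] > 0 && stats::runif(1) < p_off[si]) {
        li <- occupant[si]
        push_event(si, f - 2L, "stochastic")
        ang <- atan2(pos[li, 2] - cy, pos[li, 1] - cx)
        new <- c(cx + (r_excl + 0.1) * cos(ang), cy + (r_excl + 0.1) * sin(ang))
        upos[li, ] <- upos[li, ] + (new - pos[li, ])
        pos[li, ] <- new
        occupant[si] <- NA_integer_
        bound_site[li] <- NA_integer_
        released_now <- c(released_now, li)
      }
    }

    # --- free diffusion with reflection off the protein footprint
    free <- which(is.na(bound_site))
    if (length(free) && step_sd > 0) {
      stp <- matrix(stats::rnorm(2 * length(free), sd = step_sd), ncol = 2)
      cand <- pos[free, , drop = FALSE] + stp
      dxl <- cand[, 1] - cx
      dyl <- cand[, 2] - cy
      rr <- sqrt(dxl^2 + dyl^2)
      inside <- rr < r_excl & rr > 0
      if (any(inside)) {               # radial reflection
        scl <- (2 * r_excl - rr[inside]) / rr[inside]
        cand[inside, 1] <- cx + dxl[inside] * scl
        cand[inside, 2] <- cy + dyl[inside] * scl
      }
      disp <- cand - pos[free, , drop = FALSE]
      upos[free, ] <- upos[free, , drop = FALSE] + disp
      pos[free, ] <- wrap_coords(cbind(cand, 0), box3)[, 1:2, drop = FALSE]
    }

    # --- binding attempts at active, unoccupied sites
    for (si in which(active & is.na(occupant))) {
      if (p_on[si] <= 0) next
      dx <- pos[, 1] - sites$anchor_x[si]
      dy <- pos[, 2] - sites$anchor_y[si]
      dx <- dx - box3[1] * round(dx / box3[1])
      dy <- dy - box3[2] * round(dy / box3[2])
      near <- which(is.na(bound_site) & leaflet == sites$leaflet[si] &
                      dx^2 + dy^2 <= sites$capture_radius[si]^2)
      near <- setdiff(near, released_now)
      if (!length(near)) next
      for (li in near[sample.int(length(near))]) {
        if (stats::runif(1) < p_on[si]) {
          occupant[si] <- li
          bound_site[li] <- si
          start_frame[si] <- f - 1L      # 0-based frame index
          break
        }
      }
    }

    # --- bound lipids sit at the anchor plus jitter
    for (si in which(!is.na(occupant))) {
      li <- occupant[si]
      new <- c(sites$anchor_x[si], sites$anchor_y[si]) +
        stats::rnorm(2, sd = cfg$bind_jitter)
      upos[li, ] <- upos[li, ] + (new - pos[li, ])
      pos[li, ] <- new
    }

    place_frame(f)
  }

  # close out events still bound at the trajectory end
  for (si in which(!is.na(occupant))) push_event(si, nf - 1L, "end")

  events <- if (length(events)) do.call(rbind, events) else
    data.frame(site = integer(), lipid = integer(), start_frame = integer(),
               end_frame = integer(), frames_bound = integer(),
               release = character())

  traj <- sl_trajectory(coords, box3, cfg$dt, id = traj_id,
                        condition = condition, unwrapped = ucoords)
  lab_tab <- sl_state_labels(
    data.frame(traj_id = traj_id, frame = 0:(nf - 1L), state = labels,
               stringsAsFactors = FALSE),
    vocabulary = unique(c("closed", "open", labels)))

  list(trajectory = traj, topology = topo, labels = lab_tab,
       sites = sites, events = events,
       ground_truth = analytic_ground_truth(cfg), config = cfg,
       gate_idx = sys$gate_idx, center = sys$center)
}
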