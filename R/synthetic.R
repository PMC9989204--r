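#' Specification for a synthetic planar bilayer with known ground truth
#'
#' The generator emulates the geometry and kinematics of a planar,
#' two-leaflet bilayer so that every analysis in the package has a
#' closed-form expectation: lipids on a square lateral grid at a
#' prescribed area per lipid, phosphate planes at a prescribed
#' separation, straight acyl chains tilted according to a prescribed
#' distribution, lateral Brownian motion with a prescribed diffusion
#' coefficient, scripted leaflet translocations, and optional guest
#' amphiphiles planted at a prescribed depth below the phosphate plane.
#' Dynamics are kinematic (per-frame resampled geometry plus a Brownian
#' walk), not physical: there are no forces and no thermostat — the point
#' is known ground truth, not realism.
#'
#' Each lipid is built as an amine headgroup bead (`NH3`, charge +1),
#' a phosphate bead (`PO4`, charge -1) on the phosphate plane, and
#' `chain_sites` chain beads (`C1` ... ) extending toward the midplane at
#' `bond_length` spacing, the whole chain rigidly tilted. Guests carry a
#' carboxylate (`COO`) and a hydroxyl (`ROH`) headgroup site at
#' `depth_below_phosphate` under the upper phosphate plane plus two
#' chains (`D1...`/`E1...`). Electron counts are synthetic placeholders
#' chosen at plausible heavy-atom magnitudes; the carboxylate is modelled
#' protonated (charge 0) so default systems are net-neutral.
#'
#' @param n_per_leaflet lipids per leaflet; must be a perfect square.
#' @param apl area per lipid, nm^2 (sets the lateral box edge
#'   `sqrt(n_per_leaflet * apl)`).
#' @param phosphate_plane_sep inter-leaflet phosphate-plane distance, nm.
#' @param chain_sites beads per acyl chain.
#' @param bond_length chain bead spacing, nm.
#' @param headgroup_offset amine bead offset outward of the phosphate
#'   plane, nm.
#' @param tilt_mode chain-tilt distribution: `fixed_angle` (all chains at
#'   `tilt_param` degrees from the inward normal), `isotropic` (uniform
#'   on the sphere), or `wrapped_gaussian` (tilt angle ~ N(0,
#'   `tilt_param` degrees)).
#' @param tilt_param degrees: the fixed angle, or the Gaussian sigma.
#' @param d_lat lateral diffusion coefficient, nm^2/ps; per-axis Brownian
#'   step variance is `2 * d_lat * dt`.
#' @param z_noise_sd per-site, per-frame Gaussian z noise, nm.
#' @param flip_script optional data.frame with columns `molecule_id`,
#'   `start_ps`, `residency_ps`: the molecule is mirrored into the other
#'   leaflet at `start_ps` and returns after `residency_ps` (or stays if
#'   the residency extends past the trajectory end).
#' @param guest_spec optional `list(n_guests, depth_below_phosphate)`.
#' @param water_spec optional `list(n, mass, charge, electrons)`: a
#'   uniform water slab outside the phosphate planes, resampled per frame.
#' @param box_z_margin water/vacuum margin beyond each phosphate plane, nm.
#' @param seed integer RNG seed; the generator is bit-reproducible.
#' @return a validated `bilayer_spec` list.
#' @export
bilayer_spec <- function(n_per_leaflet = 64, apl = 0.5625,
                         phosphate_plane_sep = 4.0, chain_sites = 4,
                         bond_length = 0.3, headgroup_offset = 0.3,
                         tilt_mode = c("fixed_angle", "isotropic",
                                       "wrapped_gaussian"),
                         tilt_param = 0, d_lat = 1e-3, z_noise_sd = 0,
                         flip_script = NULL, guest_spec = NULL,
                         water_spec = NULL, box_z_margin = 2.0, seed = 1) {
  tilt_mode <- match.arg(tilt_mode)
  stopifnot(n_per_leaflet >= 1, apl > 0, phosphate_plane_sep > 0,
            chain_sites >= 1, bond_length > 0, d_lat >= 0,
            z_noise_sd >= 0, box_z_margin > 0, tilt_param >= 0)
  if (!is.null(flip_script)) {
    flip_script <- as.data.frame(flip_script)
    need <- c("molecule_id", "start_ps", "residency_ps")
    if (!all(need %in% names(flip_script)))
      stop("flip_script needs columns ", paste(need, collapse = ", "))
  }
  if (!is.null(guest_spec)) {
    stopifnot(is.list(guest_spec), guest_spec$n_guests >= 1,
              guest_spec$depth_below_phosphate > 0)
    if (guest_spec$depth_below_phosphate >= phosphate_plane_sep / 2)
      stop("guest depth_below_phosphate (",
           guest_spec$depth_below_phosphate,
           " nm) exceeds the monolayer thickness (",
           phosphate_plane_sep / 2, " nm)")
  }
  if (!is.null(water_spec)) {
    water_spec <- utils::modifyList(
      list(n = 0L, mass = 18, charge = 0, electrons = 10), water_spec)
  }
  structure(list(n_per_leaflet = as.integer(n_per_leaflet), apl = apl,
                 phosphate_plane_sep = phosphate_plane_sep,
                 chain_sites = as.integer(chain_sites),
                 bond_length = bond_length,
                 headgroup_offset = headgroup_offset,
                 tilt_mode = tilt_mode, tilt_param = tilt_param,
                 d_lat = d_lat, z_noise_sd = z_noise_sd,
                 flip_script = flip_script, guest_spec = guest_spec,
                 water_spec = water_spec, box_z_margin = box_z_margin,
                 seed = as.integer(seed)),
            class = "bilayer_spec")
}

# synthetic per-bead metadata (placeholder electron counts at heavy-atom
# magnitude; only conservation properties depend on them)
BEAD_META <- list(
  NH3 = list(mass = 45, charge = +1, electrons = 30,
             class = "headgroup_amine"),
  PO4 = list(mass = 94, charge = -1, electrons = 47, class = "phosphate"),
  CHN = list(mass = 56, charge = 0, electrons = 32, class = "apolar"),
  COO = list(mass = 45, charge = 0, electrons = 23,
             class = "headgroup_carboxylate"),
  ROH = list(mass = 31, charge = 0, electrons = 17, class = "hydroxyl"),
  W   = list(mass = 18, charge = 0, electrons = 10, class = "water")
)

#' Build the initial configuration of a synthetic bilayer
#'
#' Lays `n_per_leaflet` lipids per leaflet on a square grid in a box with
#' `box_x = box_y = sqrt(n_per_leaflet * apl)`, phosphate planes at
#' `z_mid +/- phosphate_plane_sep/2`, chains tilted per `tilt_mode`, and
#' optional guests and water. Uses `spec$seed` for all randomness.
#'
#' @param spec a `bilayer_spec`.
#' @return `list(sites = site_table, frame = md_frame)`.
#' @export
build_bilayer <- function(spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  m <- sqrt(spec$n_per_leaflet)
  if (m != floor(m))
    stop("n_per_leaflet must be a perfect square for the lateral grid (got ",
         spec$n_per_leaflet, ")")
  if (spec$chain_sites * spec$bond_length >= spec$phosphate_plane_sep / 2 +
      spec$box_z_margin)
    stop("chains longer than the available z extent")
  set.seed(spec$seed)
  geo <- bilayer_geometry(spec)
  sites <- bilayer_site_table(spec)
  anchors <- bilayer_anchors(spec, geo)
  coords <- place_sites(spec, sites, geo, anchors,
                        signs = anchors$sign0,
                        tilt = sample_tilts(spec, nrow(anchors)))
  list(sites = sites,
       frame = md_frame(coords, geo$box, time = 0,
                        title = "bilayr synthetic bilayer"))
}

bilayer_geometry <- function(spec) {
  L <- sqrt(spec$n_per_leaflet * spec$apl)
  box_z <- spec$phosphate_plane_sep + 2 * spec$box_z_margin
  list(box = c(L, L, box_z), z_mid = box_z / 2,
       z_plane = spec$phosphate_plane_sep / 2)
}

# one row per molecule: anchor lateral position and initial leaflet sign
bilayer_anchors <- function(spec, geo) {
  m <- as.integer(sqrt(spec$n_per_leaflet))
  a <- geo$box[1] / m
  gx <- (rep(seq_len(m), each = m) - 0.5) * a
  gy <- (rep(seq_len(m), times = m) - 0.5) * a
  df <- data.frame(
    x = c(gx, gx), y = c(gy, gy),
    sign0 = rep(c(1, -1), each = spec$n_per_leaflet),
    kind = "lipid", stringsAsFactors = FALSE)
  if (!is.null(spec$guest_spec)) {
    ng <- spec$guest_spec$n_guests
    df <- rbind(df, data.frame(
      x = runif(ng, 0, geo$box[1]), y = runif(ng, 0, geo$box[2]),
      sign0 = rep(1, ng), kind = "guest", stringsAsFactors = FALSE))
  }
  df$molecule_id <- seq_len(nrow(df))
  df
}

bilayer_site_table <- function(spec) {
  cs <- spec$chain_sites
  lipid_names <- c("NH3", "PO4", paste0("C", seq_len(cs)))
  lipid_kinds <- c("NH3", "PO4", rep("CHN", cs))
  lipid_chain <- c(NA, NA, rep("sn1", cs))
  lipid_pos <- c(NA, NA, seq_len(cs))
  n_lip <- 2L * spec$n_per_leaflet
  name <- rep(lipid_names, n_lip)
  kind <- rep(lipid_kinds, n_lip)
  resn <- rep("PL", length(name))
  mol <- rep(seq_len(n_lip), each = length(lipid_names))
  chl <- rep(lipid_chain, n_lip)
  chp <- rep(lipid_pos, n_lip)
  if (!is.null(spec$guest_spec)) {
    ng <- spec$guest_spec$n_guests
    g_names <- c("COO", "ROH", paste0("D", seq_len(cs)),
                 paste0("E", seq_len(cs)))
    g_kinds <- c("COO", "ROH", rep("CHN", 2 * cs))
    g_chain <- c(NA, NA, rep("guest_chain1", cs), rep("guest_chain2", cs))
    g_pos <- c(NA, NA, seq_len(cs), seq_len(cs))
    name <- c(name, rep(g_names, ng))
    kind <- c(kind, rep(g_kinds, ng))
    resn <- c(resn, rep("RL", length(g_names) * ng))
    mol <- c(mol, rep(n_lip + seq_len(ng), each = length(g_names)))
    chl <- c(chl, rep(g_chain, ng))
    chp <- c(chp, rep(g_pos, ng))
  }
  if (!is.null(spec$water_spec) && spec$water_spec$n > 0) {
    nw <- spec$water_spec$n
    name <- c(name, rep("W", nw))
    kind <- c(kind, rep("W", nw))
    resn <- c(resn, rep("SOL", nw))
    mol <- c(mol, max(mol) + seq_len(nw))
    chl <- c(chl, rep(NA, nw))
    chp <- c(chp, rep(NA, nw))
  }
  meta <- BEAD_META[kind]
  tab <- site_table(
    site_name = name, residue_name = resn, molecule_id = mol,
    mass = vapply(meta, `[[`, numeric(1), "mass"),
    charge = vapply(meta, `[[`, numeric(1), "charge"),
    electrons = vapply(meta, `[[`, numeric(1), "electrons"),
    polarity_class = vapply(meta, `[[`, character(1), "class"),
    chain_label = chl, chain_position = chp)
  if (!is.null(spec$water_spec)) {
    w <- tab$polarity_class == "water"
    tab$mass[w] <- spec$water_spec$mass
    tab$charge[w] <- spec$water_spec$charge
    tab$electrons[w] <- spec$water_spec$electrons
  }
  tab
}

# tilt unit polar angles (radians) per molecule: list(theta, phi)
sample_tilts <- function(spec, n_mol) {
  th <- switch(spec$tilt_mode,
    fixed_angle = rep(spec$tilt_param * pi / 180, n_mol),
    wrapped_gaussian = rnorm(n_mol, 0, spec$tilt_param * pi / 180),
    isotropic = acos(runif(n_mol, -1, 1)))
  list(theta = th, phi = runif(n_mol, 0, 2 * pi))
}

# assemble coordinates for all sites given per-molecule anchors/signs/tilts
place_sites <- function(spec, sites, geo, anchors, signs, tilt,
                        water_xyz = NULL) {
  n <- nrow(sites)
  coords <- matrix(0, n, 3)
  cs <- spec$chain_sites
  b <- spec$bond_length
  ux <- sin(tilt$theta) * cos(tilt$phi)
  uy <- sin(tilt$theta) * sin(tilt$phi)
  uz <- cos(tilt$theta)
  is_lip <- anchors$kind == "lipid"
  lip <- which(is_lip)
  # lipid block layout: NH3, PO4, C1..Ccs per molecule, molecules in order
  npl <- 2L + cs
  base <- (seq_along(lip) - 1L) * npl
  zP <- geo$z_mid + signs[lip] * geo$z_plane
  coords[base + 1L, ] <- cbind(anchors$x[lip], anchors$y[lip],
                               zP + signs[lip] * spec$headgroup_offset)
  coords[base + 2L, ] <- cbind(anchors$x[lip], anchors$y[lip], zP)
  for (k in seq_len(cs)) {
    coords[base + 2L + k, ] <- cbind(
      anchors$x[lip] + k * b * ux[lip],
      anchors$y[lip] + k * b * uy[lip],
      zP - signs[lip] * k * b * uz[lip])
  }
  gst <- which(anchors$kind == "guest")
  if (length(gst)) {
    npg <- 2L + 2L * cs
    gbase <- length(lip) * npl + (seq_along(gst) - 1L) * npg
    depth <- spec$guest_spec$depth_below_phosphate
    zH <- geo$z_mid + signs[gst] * (geo$z_plane - depth)
    coords[gbase + 1L, ] <- cbind(anchors$x[gst], anchors$y[gst], zH)
    coords[gbase + 2L, ] <- cbind(anchors$x[gst] + 0.12, anchors$y[gst], zH)
    for (k in seq_len(cs)) {
      coords[gbase + 2L + k, ] <- cbind(
        anchors$x[gst] + k * b * ux[gst],
        anchors$y[gst] + k * b * uy[gst],
        zH - signs[gst] * k * b * uz[gst])
      coords[gbase + 2L + cs + k, ] <- cbind(
        anchors$x[gst] + 0.12 - k * b * ux[gst],
        anchors$y[gst] - k * b * uy[gst],
        zH - signs[gst] * k * b * uz[gst])
    }
  }
  wat <- which(sites$polarity_class == "water")
  if (length(wat)) {
    if (is.null(water_xyz)) water_xyz <- sample_water(spec, geo, length(wat))
    coords[wat, ] <- water_xyz
  }
  if (spec$z_noise_sd > 0) {
    notw <- setdiff(seq_len(n), wat)
    coords[notw, 3] <- coords[notw, 3] + rnorm(length(notw), 0,
                                               spec$z_noise_sd)
  }
  coords
}

# uniform water in the two slabs outside the phosphate planes (+0.1 nm gap)
sample_water <- function(spec, geo, nw) {
  lo_top <- geo$z_mid - geo$z_plane - 0.1
  hi_bot <- geo$z_mid + geo$z_plane + 0.1
  widths <- c(lo_top, geo$box[3] - hi_bot)
  pick <- runif(nw) < widths[1] / sum(widths)
  z <- ifelse(pick, runif(nw, 0, lo_top), runif(nw, hi_bot, geo$box[3]))
  cbind(runif(nw, 0, geo$box[1]), runif(nw, 0, geo$box[2]), z)
}

#' Generate a kinematic bilayer trajectory
#'
#' Evolves the synthetic bilayer for `n_frames` frames at spacing `dt`:
#' molecule anchors take independent Gaussian lateral steps with variance
#' `2 * d_lat * dt` per axis (x, y; unwrapped), chain tilts are resampled
#' per frame from `tilt_mode`, scripted flips mirror the molecule's
#' z-template into the other leaflet for the scripted residency, water is
#' resampled uniformly, and optional Gaussian z noise is applied. Seeded
#' from `spec$seed + 1`; bit-reproducible.
#'
#' @param sites `site_table` from [build_bilayer()].
#' @param frame0 initial `md_frame` from [build_bilayer()].
#' @param n_frames number of frames (>= 2), the first at `frame0$time`.
#' @param dt frame spacing, ps (> 0).
#' @param spec the `bilayer_spec` used to build the system.
#' @return a `md_trajectory` with unwrapped coordinates.
#' @export
simulate_dynamics <- function(sites, frame0, n_frames, dt, spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  if (dt <= 0) stop("dt must be > 0")
  if (n_frames < 2) stop("n_frames must be >= 2")
  set.seed(spec$seed + 1L)
  geo <- bilayer_geometry(spec)
  anchors <- bilayer_anchors(spec, geo)
  n_mol <- nrow(anchors)
  times <- frame0$time + (seq_len(n_frames) - 1) * dt
  arr <- array(0, c(nrow(sites), 3, n_frames))
  step_sd <- sqrt(2 * spec$d_lat * dt)
  fs <- spec$flip_script
  ax <- anchors$x
  ay <- anchors$y
  for (f in seq_len(n_frames)) {
    if (f > 1L && step_sd > 0) {
      ax <- ax + rnorm(n_mol, 0, step_sd)
      ay <- ay + rnorm(n_mol, 0, step_sd)
    }
    a <- anchors; a$x <- ax; a$y <- ay
    signs <- anchors$sign0
    if (!is.null(fs)) {
      t <- times[f]
      fl <- fs$molecule_id[t >= fs$start_ps &
                             t < fs$start_ps + fs$residency_ps]
      if (length(fl)) {
        i <- match(fl, anchors$molecule_id)
        signs[i] <- -signs[i]
      }
    }
    arr[, , f] <- place_sites(spec, sites, geo, a, signs,
                              sample_tilts(spec, n_mol))
  }
  md_trajectory(sites, arr, times, matrix(geo$box, n_frames, 3,
                                          byrow = TRUE), dt = dt)
}

#' Generate a complete synthetic bilayer trajectory in one call
#'
#' Convenience wrapper: [build_bilayer()] then [simulate_dynamics()].
#'
#' @inheritParams simulate_dynamics
#' @param spec a `bilayer_spec`.
#' @return `list(sites, trajectory)`.
#' @export
generate_bilayer_trajectory <- function(spec, n_frames, dt) {
  built <- build_bilayer(spec)
  list(sites = built$sites,
       trajectory = simulate_dynamics(built$sites, built$frame,
                                      n_frames, dt, spec))
}
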