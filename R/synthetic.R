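# Synthetic channel systems and trajectories with planted ground truth.
#
# The toy system is a cylinder-with-constriction of pseudo-protein atoms in
# a planar pseudo-bilayer: a dimeric channel reduced to the features the
# analysis measures.  Hydration of the constriction follows a discrete-time
# telegraph process (wet/dry); each frame plants a Poisson number of water
# oxygens uniformly inside the water counting box and, per lipid, a
# state-dependent number of tail carbons inside the carbon counting box.
# Planted counts are moved-in/moved-out designated atoms, so the occupancy
# pipeline must recover them exactly: the defining contract of the
# generator, and the strongest oracle the pipeline can be tested against.

#' Specify a toy channel system
#'
#' @param pore_radius cylinder wall radius (Angstrom).
#' @param constriction_radius wall radius across the hydrophobic
#'   constriction (< `pore_radius`).
#' @param channel_half_length half-length of the cylinder (Angstrom).
#' @param anchor_z laboratory z of the pseudo-filter anchor (the S4-like
#'   site; pore-frame z = 0).
#' @param n_lipids_per_leaflet pseudo-lipids per leaflet; the lower-leaflet
#'   lipids are the ones eligible to insert tail carbons into the pore.
#' @param n_cavity_waters size of the relocatable water pool used to plant
#'   constriction counts.
#' @param n_bulk_waters waters kept in bulk.
#' @param box orthorhombic box edges (Angstrom).
#' @return Object of class `toy_system_spec`.
#' @export
toy_system_spec <- function(pore_radius = 8, constriction_radius = 4,
                            channel_half_length = 16, anchor_z = 48,
                            n_lipids_per_leaflet = 6, n_cavity_waters = 30,
                            n_bulk_waters = 60, box = c(60, 60, 80)) {
  if (constriction_radius >= pore_radius)
    stop("toy_system_spec: constriction_radius must be < pore_radius",
         call. = FALSE)
  if (any(c(pore_radius, constriction_radius, channel_half_length,
            n_cavity_waters, n_bulk_waters) <= 0) || any(box <= 0))
    stop("toy_system_spec: all extents and counts must be positive",
         call. = FALSE)
  if (anchor_z + 30 > box[3] || anchor_z - 2 * channel_half_length < 0)
    stop("toy_system_spec: geometry does not fit inside the box",
         call. = FALSE)
  structure(list(pore_radius = pore_radius,
                 constriction_radius = constriction_radius,
                 channel_half_length = channel_half_length,
                 anchor_z = anchor_z,
                 n_lipids_per_leaflet = n_lipids_per_leaflet,
                 n_cavity_waters = n_cavity_waters,
                 n_bulk_waters = n_bulk_waters, box = box),
            class = "toy_system_spec")
}

# Pseudo-POPC heavy-atom topology: 1 N, 1 P, 8 O, 40 C (head to tail).
popc_atom_names <- function() {
  c("N", "C1", "C2", "C3", "P", paste0("O", 1:8),
    paste0("C", 4:40))
}

#' Build a toy channel system
#'
#' Deterministic geometry: wall rings (residue WAL) forming a cylinder with
#' a constriction; four pseudo-threonine anchor atoms (residue THR, atom
#' CA) at `anchor_z`; four orientation atoms (residue ORI) above them; two
#' leaflets of pseudo-lipids (residue POPC, 40 carbons each) standing clear
#' of the counting boxes; a relocatable cavity-water pool and bulk waters
#' (residue SOL: OW, HW1, HW2).
#'
#' @param spec a [toy_system_spec].
#' @param path optional output path; when given, the structure is written
#'   there (format from the extension: `.gro` or `.pdb`).
#' @return List of class `toy_system` with `system` ([molecular_system]),
#'   `frame` ([md_frame]) and `meta` (planting bookkeeping used by
#'   [simulate_trajectory]).
#' @export
build_toy_system <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "toy_system_spec"))
  cx <- spec$box[1] / 2; cy <- spec$box[2] / 2; za <- spec$anchor_z
  atoms <- list(); coords <- list()
  rid <- 0L
  add <- function(names, resname, xyz) {
    rid <<- rid + 1L
    atoms[[length(atoms) + 1L]] <<- data.frame(
      atom_name = names, residue_name = resname, residue_id = rid,
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
  }
  # cylinder wall: rings every 2 A; constriction across the water-box zone
  ring_z <- seq(za - 8 - spec$channel_half_length,
                za - 8 + spec$channel_half_length, by = 2)
  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  for (z in ring_z) {
    r <- if (z > za - 12 && z < za - 4) spec$constriction_radius
         else spec$pore_radius
    add(paste0("C", seq_along(theta)), "WAL",
        cbind(cx + r * cos(theta), cy + r * sin(theta), z))
  }
  # anchor threonines (4-fold symmetric CA ring => centroid on the axis)
  th <- c(0, pi / 2, pi, 3 * pi / 2)
  for (k in 1:4) add("CA", "THR",
                     cbind(cx + 5 * cos(th[k]), cy + 5 * sin(th[k]), za))
  for (k in 1:4) add("OR1", "ORI",
                     cbind(cx + 5 * cos(th[k]), cy + 5 * sin(th[k]), za + 8))
  # lipids on a circle of radius 20 from the axis (max(|x|,|y|) >= 14.1 A,
  # always clear of the 20 x 20 A counting boxes)
  nl <- spec$n_lipids_per_leaflet
  lip_names <- popc_atom_names()
  n_la <- length(lip_names)
  lipid_rows <- list(); first_row <- 1L +
    length(ring_z) * length(theta) + 8L
  row_cursor <- first_row
  for (leaflet in c("upper", "lower")) {
    zhead <- if (leaflet == "upper") za + 2 else za - 24
    dirz <- if (leaflet == "upper") -1 else 1
    for (j in seq_len(nl)) {
      ang <- 2 * pi * (j - 1) / nl + (leaflet == "lower") * pi / nl
      bx <- cx + 20 * cos(ang); by <- cy + 20 * sin(ang)
      zz <- zhead + dirz * 0.35 * (seq_len(n_la) - 1)
      xx <- bx + 0.8 * cos(seq_len(n_la))
      yy <- by + 0.8 * sin(seq_len(n_la))
      add(lip_names, "POPC", cbind(xx, yy, zz))
      lipid_rows[[length(lipid_rows) + 1L]] <- list(
        leaflet = leaflet,
        carbon_rows = row_cursor - 1L + which(startsWith(lip_names, "C")))
      row_cursor <- row_cursor + n_la
    }
  }
  # relocatable cavity-water pool, parked at lateral radius 24
  pool_O_rows <- integer(spec$n_cavity_waters)
  for (j in seq_len(spec$n_cavity_waters)) {
    ang <- 2 * pi * (j - 1) / spec$n_cavity_waters
    ox <- cx + 24 * cos(ang); oy <- cy + 24 * sin(ang)
    oz <- za + 14 + 2 * ((j - 1) %% 5)
    pool_O_rows[j] <- row_cursor
    add(c("OW", "HW1", "HW2"), "SOL",
        rbind(c(ox, oy, oz), c(ox + 0.8, oy + 0.6, oz),
              c(ox - 0.8, oy + 0.6, oz)))
    row_cursor <- row_cursor + 3L
  }
  # bulk waters above the channel mouth
  nb <- spec$n_bulk_waters
  side <- ceiling(sqrt(nb))
  for (j in seq_len(nb)) {
    gx <- 6 + 48 * (((j - 1) %% side) + 0.5) / side
    gy <- 6 + 48 * ((((j - 1) %/% side) %% side) + 0.5) / side
    gz <- za + 12 + 14 * ((j - 1) %% 7) / 7
    add(c("OW", "HW1", "HW2"), "SOL",
        rbind(c(gx, gy, gz), c(gx + 0.8, gy + 0.6, gz),
              c(gx - 0.8, gy + 0.6, gz)))
    row_cursor <- row_cursor + 3L
  }
  sys <- molecular_system(do.call(rbind, atoms))
  xyz <- do.call(rbind, coords)
  if (max(xyz[, 1]) > spec$box[1] || max(xyz[, 2]) > spec$box[2] ||
      max(xyz[, 3]) > spec$box[3] || min(xyz) < 0)
    stop("build_toy_system: geometry overflows the box", call. = FALSE)
  frame <- md_frame(xyz, box = spec$box, time = 0)
  eligible <- which(vapply(lipid_rows, function(l) l$leaflet == "lower",
                           logical(1)))
  meta <- list(center = c(cx, cy), anchor_z = za,
               pool_O_rows = pool_O_rows,
               lipid_rows = lipid_rows, eligible_lipids = eligible,
               spec = spec)
  toy <- structure(list(system = sys, frame = frame, meta = meta),
                   class = "toy_system")
  if (!is.null(path)) {
    fmt <- guess_format(path)
    if (fmt == "gro") write_gro(sys, frame, path)
    else if (fmt == "pdb") write_pdb(sys, frame, path)
    else stop("build_toy_system: unsupported structure format for ", path,
              call. = FALSE)
  }
  toy
}

#' @export
print.toy_system <- function(x, ...) {
  cat("<toy_system> ", x$system$n_atoms, " atoms; anchor at z = ",
      x$meta$anchor_z, " A; ", length(x$meta$eligible_lipids),
      " insertion-eligible lipids\n", sep = "")
  invisible(x)
}

#' Specify synthetic wetting/insertion dynamics
#'
#' @param k_wet_to_dry,k_dry_to_wet telegraph switching rates (1/ns); the
#'   discrete-time switch probability per frame is `k * dt` and must stay
#'   below 0.5 for the discretization to be valid.
#' @param lambda_wet,lambda_dry mean planted water count in the constriction
#'   box per state (Poisson emissions; `lambda_dry < lambda_wet`).
#' @param p_wet,p_dry per-lipid, per-frame probability of inserting tail
#'   carbons in the wet and dry state.
#' @param max_insert maximum carbons a lipid inserts at once.
#' @param dt frame spacing (ns).
#' @param n_frames number of frames.
#' @param seed RNG seed (integer).
#' @param init initial hydration state.
#' @return Object of class `dynamics_spec`.
#' @export
dynamics_spec <- function(k_wet_to_dry = 0.5, k_dry_to_wet = 1.0,
                          lambda_wet = 8, lambda_dry = 0.3,
                          p_wet = 0.08, p_dry = 0.27, max_insert = 4L,
                          dt = 0.1, n_frames = 2000L, seed = 1L,
                          init = c("wet", "dry")) {
  init <- match.arg(init)
  if (k_wet_to_dry < 0 || k_dry_to_wet < 0)
    stop("dynamics_spec: rates must be >= 0", call. = FALSE)
  if (max(k_wet_to_dry, k_dry_to_wet) * dt >= 0.5)
    stop("dynamics_spec: need k * dt < 0.5 (discretization validity)",
         call. = FALSE)
  if (p_wet < 0 || p_wet > 1 || p_dry < 0 || p_dry > 1)
    stop("dynamics_spec: insertion probabilities must be in [0, 1]",
         call. = FALSE)
  if (lambda_dry >= lambda_wet)
    stop("dynamics_spec: need lambda_dry < lambda_wet", call. = FALSE)
  if (n_frames < 1L) stop("dynamics_spec: n_frames must be >= 1",
                          call. = FALSE)
  structure(list(k_wet_to_dry = k_wet_to_dry, k_dry_to_wet = k_dry_to_wet,
                 lambda_wet = lambda_wet, lambda_dry = lambda_dry,
                 p_wet = p_wet, p_dry = p_dry,
                 max_insert = as.integer(max_insert), dt = dt,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 init = init),
            class = "dynamics_spec")
}

#' Preset dynamics matching the two study conditions
#'
#' Parameter sets whose closed-form expected lipid-carbon percent occupancy
#' (see [ground_truth_stats]) equals the two reported design points: a
#' wild-type-like pore that dewets readily and carries lipid 55% of the
#' time, and an L146N-like polar mutant that stays hydrated and carries
#' lipid 35% of the time.  In both, insertion is more likely while the
#' cavity is dry (`p_dry > p_wet`), the coupling behind the inverse
#' water-lipid correlation.
#'
#' @param condition `"WT"` or `"L146N"`.
#' @param n_frames,seed,dt passed to [dynamics_spec] (defaults: 2000 frames
#'   at 0.1 ns = one 200 ns trajectory).
#' @param n_eligible number of insertion-eligible lipids of the paired toy
#'   system (default 6, the lower leaflet of [toy_system_spec] defaults).
#' @return A [dynamics_spec].
#' @export
dynamics_preset <- function(condition = c("WT", "L146N"), n_frames = 2000L,
                            seed = 1L, dt = 0.1, n_eligible = 6L) {
  condition <- match.arg(condition)
  p_from_q <- function(q) 1 - (1 - q)^(1 / n_eligible)
  if (condition == "WT") {
    # pi_wet = 2/3: 2/3 * 0.40 + 1/3 * 0.85 = 0.55
    dynamics_spec(k_wet_to_dry = 0.5, k_dry_to_wet = 1.0,
                  p_wet = p_from_q(0.40), p_dry = p_from_q(0.85),
                  dt = dt, n_frames = n_frames, seed = seed)
  } else {
    # pi_wet = 0.9: 0.9 * 0.30 + 0.1 * 0.80 = 0.35
    dynamics_spec(k_wet_to_dry = 0.1, k_dry_to_wet = 0.9,
                  p_wet = p_from_q(0.30), p_dry = p_from_q(0.80),
                  dt = dt, n_frames = n_frames, seed = seed)
  }
}

# Deterministic per-frame substream seed (exact in double arithmetic).
frame_seed <- function(seed, i, lane = 0L) {
  ((seed %% 2147483647) * 69069 + i * 1234567 + lane * 97) %% 2147483647
}

#' Simulate the planted dynamics (states and counts)
#'
#' The stochastic core of the generator, independent of geometry: the
#' telegraph hydration state, the Poisson water count, and the per-lipid
#' carbon insertions of every frame.  [simulate_trajectory] realizes these
#' counts geometrically; statistical tests can consume them directly.
#'
#' @param dyn a [dynamics_spec].
#' @param n_eligible number of insertion-eligible lipids.
#' @return List with `state` (character per frame), `n_water`, `n_carbon`
#'   (integer per frame), `insertions` (n_frames x n_eligible matrix of
#'   per-lipid inserted carbon counts) and `times` (ns).
#' @export
simulate_dynamics <- function(dyn, n_eligible = 6L) {
  stopifnot(inherits(dyn, "dynamics_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  n <- dyn$n_frames
  state <- character(n)
  n_water <- integer(n)
  ins <- matrix(0L, n, n_eligible)
  s <- dyn$init
  for (i in seq_len(n)) {
    set.seed(frame_seed(dyn$seed, i))
    if (i > 1L) {
      p_switch <- if (s == "wet") dyn$k_wet_to_dry * dyn$dt
                  else dyn$k_dry_to_wet * dyn$dt
      if (stats::runif(1) < p_switch) s <- if (s == "wet") "dry" else "wet"
    }
    state[i] <- s
    lam <- if (s == "wet") dyn$lambda_wet else dyn$lambda_dry
    n_water[i] <- stats::rpois(1, lam)
    p_ins <- if (s == "wet") dyn$p_wet else dyn$p_dry
    if (n_eligible > 0L) {
      inserts <- stats::runif(n_eligible) < p_ins
      if (any(inserts))
        ins[i, inserts] <- sample.int(dyn$max_insert, sum(inserts),
                                      replace = TRUE)
    }
  }
  list(state = state, n_water = n_water, n_carbon = as.integer(rowSums(ins)),
       insertions = ins, times = (seq_len(n) - 1L) * dyn$dt)
}

#' Simulate a trajectory with planted ground truth
#'
#' Evolves the hydration state as a discrete-time telegraph process and
#' realizes each frame geometrically: the planted number of pool waters is
#' moved uniformly into the water counting box (the rest stay parked in
#' bulk), each inserting lipid moves tail carbons uniformly into the carbon
#' counting box, and bulk atoms jitter slightly.  Fully reproducible from
#' the seed; the same seed gives byte-identical ground truth and files.
#'
#' @param toy a [toy_system][build_toy_system].
#' @param dyn a [dynamics_spec].
#' @param traj_path output trajectory path (`.pdb` for multi-model PDB or
#'   `.dcd`).
#' @return List of class `synthetic_trajectory`: `ground_truth` (data.frame:
#'   frame, time_ns, state, n_water, n_carbon), `expectations`
#'   ([ground_truth_stats]), `traj_path`, `n_eligible`.
#' @export
simulate_trajectory <- function(toy, dyn, traj_path) {
  stopifnot(inherits(toy, "toy_system"), inherits(dyn, "dynamics_spec"))
  meta <- toy$meta
  L <- length(meta$eligible_lipids)
  dynres <- simulate_dynamics(dyn, n_eligible = L)
  if (any(dynres$n_water > length(meta$pool_O_rows)))
    stop("simulate_trajectory: planted water count ",
         max(dynres$n_water), " exceeds the cavity pool of ",
         length(meta$pool_O_rows), " waters; enlarge n_cavity_waters",
         call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  base <- toy$frame$coordinates
  cx <- meta$center[1]; cy <- meta$center[2]; za <- meta$anchor_z
  wb <- water_box(); cb <- carbon_box()
  m <- 0.3  # placement margin against box faces (A)
  jitter_rows <- sort(unique(c(
    unlist(lapply(meta$pool_O_rows, function(r) r:(r + 2L))),
    unlist(lapply(meta$lipid_rows, `[[`, "carbon_rows")))))
  frames <- vector("list", dyn$n_frames)
  for (i in seq_len(dyn$n_frames)) {
    set.seed(frame_seed(dyn$seed, i, lane = 1L))
    co <- base
    # small bulk jitter on relocatable atoms (parked pool, lipid tails)
    co[jitter_rows, ] <- co[jitter_rows, ] +
      matrix(stats::runif(3 * length(jitter_rows), -0.05, 0.05),
             ncol = 3)
    # plant waters inside the water box
    nw <- dynres$n_water[i]
    if (nw > 0L) {
      orows <- meta$pool_O_rows[seq_len(nw)]
      px <- cx + stats::runif(nw, -wb$lx / 2 + m, wb$lx / 2 - m)
      py <- cy + stats::runif(nw, -wb$ly / 2 + m, wb$ly / 2 - m)
      pz <- za + stats::runif(nw, wb$zmin + m, wb$zmax - m)
      co[orows, ] <- cbind(px, py, pz)
      co[orows + 1L, ] <- cbind(px + 0.8, py + 0.6, pz)
      co[orows + 2L, ] <- cbind(px - 0.8, py + 0.6, pz)
    }
    # plant lipid carbons inside the carbon box
    for (j in seq_len(L)) {
      mi <- dynres$insertions[i, j]
      if (mi > 0L) {
        crows <- meta$lipid_rows[[meta$eligible_lipids[j]]]$carbon_rows
        tail_rows <- crows[(length(crows) - mi + 1L):length(crows)]
        co[tail_rows, ] <- cbind(
          cx + stats::runif(mi, -cb$lx / 2 + m, cb$lx / 2 - m),
          cy + stats::runif(mi, -cb$ly / 2 + m, cb$ly / 2 - m),
          za + stats::runif(mi, cb$zmin + m, cb$zmax - m))
      }
    }
    frames[[i]] <- md_frame(co, box = toy$frame$box,
                            time = (i - 1L) * dyn$dt)
  }
  fmt <- guess_format(traj_path)
  if (fmt == "pdb") write_pdb(toy$system, frames, traj_path)
  else if (fmt == "dcd") write_dcd(toy$system, frames, traj_path)
  else stop("simulate_trajectory: unsupported trajectory format for ",
            traj_path, call. = FALSE)
  structure(list(
    ground_truth = data.frame(frame = seq_len(dyn$n_frames) - 1L,
                              time_ns = dynres$times, state = dynres$state,
                              n_water = dynres$n_water,
                              n_carbon = dynres$n_carbon,
                              stringsAsFactors = FALSE),
    expectations = ground_truth_stats(dyn, n_eligible = L),
    traj_path = traj_path, n_eligible = L),
    class = "synthetic_trajectory")
}

#' @export
print.synthetic_trajectory <- function(x, ...) {
  cat("<synthetic_trajectory> ", nrow(x$ground_truth), " frames -> ",
      x$traj_path, "\n  realized wet fraction ",
      format(mean(x$ground_truth$state == "wet"), digits = 3),
      " (expected ", format(x$expectations$wet_fraction, digits = 3),
      ")\n", sep = "")
  invisible(x)
}

#' Closed-form expectations of the synthetic dynamics
#'
#' @param dyn a [dynamics_spec].
#' @param n_eligible number of insertion-eligible lipids.
#' @return List with `wet_fraction` (stationary
#'   `k_dw / (k_dw + k_wd)`; the initial state when both rates are 0),
#'   `expected_percent_carbon`
#'   (`100 * [pi_wet (1 - (1-p_wet)^L) + pi_dry (1 - (1-p_dry)^L)]`) and
#'   `expected_mean_water` (`pi_wet lambda_wet + pi_dry lambda_dry`).
#' @export
ground_truth_stats <- function(dyn, n_eligible = 6L) {
  stopifnot(inherits(dyn, "dynamics_spec"))
  ksum <- dyn$k_wet_to_dry + dyn$k_dry_to_wet
  pi_wet <- if (ksum > 0) dyn$k_dry_to_wet / ksum
            else as.numeric(dyn$init == "wet")
  q_wet <- 1 - (1 - dyn$p_wet)^n_eligible
  q_dry <- 1 - (1 - dyn$p_dry)^n_eligible
  list(wet_fraction = pi_wet,
       expected_percent_carbon = 100 * (pi_wet * q_wet + (1 - pi_wet) * q_dry),
       expected_mean_water = pi_wet * dyn$lambda_wet +
         (1 - pi_wet) * dyn$lambda_dry)
}
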