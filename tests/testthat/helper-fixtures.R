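# Fixture builders shared across the suite.  Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# n_waters SOL residues (O, H, H) at given oxygen positions.
water_system <- function(o_positions, resname = "SOL",
                         names = c("OW", "HW1", "HW2")) {
  n <- nrow(o_positions)
  atoms <- data.frame(
    atom_name = rep(names, n),
    residue_name = resname,
    residue_id = rep(seq_len(n), each = 3))
  co <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    o <- o_positions[i, ]
    co[3 * i - 2, ] <- o
    co[3 * i - 1, ] <- o + c(0.8, 0.6, 0)
    co[3 * i, ] <- o + c(-0.8, 0.6, 0)
  }
  list(system = molecular_system(atoms), frame = md_frame(co))
}

# Minimal anchored system: 4 THR CA at z = 0 on a radius-5 ring, 4 ORI at
# z = +8, plus optional extra atoms appended.
anchored_system <- function(extra_atoms = NULL, extra_coords = NULL) {
  th <- c(0, pi / 2, pi, 3 * pi / 2)
  atoms <- data.frame(
    atom_name = c(rep("CA", 4), rep("OR1", 4)),
    residue_name = c(rep("THR", 4), rep("ORI", 4)),
    residue_id = 1:8)
  co <- rbind(cbind(5 * cos(th), 5 * sin(th), 0),
              cbind(5 * cos(th), 5 * sin(th), 8))
  if (!is.null(extra_atoms)) {
    atoms <- rbind(atoms, extra_atoms)
    co <- rbind(co, extra_coords)
  }
  atoms$residue_id <- seq_len(nrow(atoms))
  list(system = molecular_system(atoms), frame = md_frame(co))
}

# Ring(s) of pseudo-atoms for pore-profile tests: rings of residue RNG with
# the anchored frame attached.  `rings` is a list of lists(z, r, n).
ring_system <- function(rings, atom_name = "C1") {
  extra <- NULL; co <- NULL
  for (rg in rings) {
    th <- seq(0, 2 * pi, length.out = rg$n + 1)[-(rg$n + 1)]
    cxy <- if (is.null(rg$center)) c(0, 0) else rg$center
    extra <- rbind(extra, data.frame(
      atom_name = atom_name, residue_name = "RNG", residue_id = 1L))
    co <- rbind(co, cbind(cxy[1] + rg$r * cos(th), cxy[2] + rg$r * sin(th),
                          rg$z))
  }
  extra <- extra[rep(1, nrow(co)), , drop = FALSE]
  anchored_system(extra, co)
}

# Reference frame of the anchored fixtures (axis +z, origin at the origin).
anchored_ref <- function(sys) {
  build_reference_frame(sys$frame,
                        select_atoms(sys$system, "resname THR and name CA"),
                        select_atoms(sys$system, "resname ORI"))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# occupancy_ts from bare counts (times implied by dt)
ts_from_counts <- function(n_water, n_carbon = rep(0L, length(n_water)),
                           dt = 0.1, label = "") {
  occupancy_ts((seq_along(n_water) - 1) * dt, n_water, n_carbon,
               dt = dt, label = label)
}
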