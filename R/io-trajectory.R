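# Trajectory reading: multi-model PDB (vectorised text splitter, supporting
# truncated tails and CRYST1 boxes) and CHARMM/NAMD DCD (read via bio3d,
# written natively).  GROMACS compressed formats (XTC/TRR) are rejected with
# a pointer to conversion; see the methods vignette.

#' Read trajectory frames
#'
#' Reads every `stride`-th frame of a trajectory.  Supported dialects:
#' multi-model PDB (`.pdb`) and DCD (`.dcd`).  A GRO file is accepted as a
#' single-frame trajectory.
#'
#' @param system the [molecular_system] the trajectory belongs to; the atom
#'   count must match every frame.
#' @param traj_path path to the trajectory file.
#' @param stride keep every `stride`-th frame (>= 1), starting at the first.
#' @param dt nominal time between *stored* frames in ns, used when the file
#'   carries no time information (default 0.1 ns, the sampling interval the
#'   occupancy analysis assumes).
#' @return A list of [md_frame] objects, in file order.
#' @export
iterate_frames <- function(system, traj_path, stride = 1L, dt = 0.1) {
  stopifnot(inherits(system, "molecular_system"))
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L)
    stop("iterate_frames: stride must be a positive integer", call. = FALSE)
  if (!file.exists(traj_path))
    stop("iterate_frames: file not found: ", traj_path, call. = FALSE)
  fmt <- guess_format(traj_path)
  frames <- switch(fmt,
    pdb = read_pdb_frames(traj_path),
    gro = list(read_structure_gro(traj_path)$frame),
    dcd = read_dcd_frames(traj_path),
    xtc = ,
    trr = stop("iterate_frames: GROMACS ", toupper(fmt), " trajectories are ",
               "not supported; convert to multi-model PDB or DCD first ",
               "(e.g. `gmx trjconv` or `mdconvert`)", call. = FALSE),
    stop("iterate_frames: unsupported trajectory format '", fmt, "'",
         call. = FALSE))
  n_at <- vapply(frames, function(f) nrow(f$coordinates), integer(1))
  if (any(n_at != system$n_atoms))
    stop("iterate_frames: trajectory frames have ", n_at[n_at != system$n_atoms][1],
         " atoms but system has ", system$n_atoms, call. = FALSE)
  keep <- seq(1L, length(frames), by = stride)
  frames <- frames[keep]
  for (i in seq_along(frames)) {
    if (is.na(frames[[i]]$time)) frames[[i]]$time <- (keep[i] - 1L) * dt
  }
  frames
}

# Vectorised multi-model PDB splitter.  Frames are delimited by MODEL/ENDMDL;
# a file without MODEL records is one frame.  A truncated final model (fewer
# atom records than the first) is dropped with a warning.
read_pdb_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom))
    stop("read_pdb_frames: no ATOM/HETATM records in ", path, call. = FALSE)
  box <- pdb_cryst1_box(path)
  model_line <- startsWith(lines, "MODEL")
  frame_of_line <- cumsum(model_line)
  al <- lines[is_atom]
  fid <- frame_of_line[is_atom]
  if (all(fid == 0L)) fid <- rep(1L, length(al))
  x <- as.numeric(substr(al, 31, 38))
  y <- as.numeric(substr(al, 39, 46))
  z <- as.numeric(substr(al, 47, 54))
  counts <- tabulate(fid)
  counts <- counts[counts > 0L]
  ufid <- sort(unique(fid))
  n0 <- counts[1]
  good <- counts == n0
  if (!all(good)) {
    warning("read_pdb_frames: dropping ", sum(!good),
            " incomplete model(s) in ", path)
  }
  starts <- c(0L, cumsum(counts))
  out <- vector("list", sum(good))
  j <- 0L
  for (k in seq_along(ufid)) {
    if (!good[k]) next
    j <- j + 1L
    idx <- (starts[k] + 1L):starts[k + 1L]
    out[[j]] <- md_frame(cbind(x[idx], y[idx], z[idx]), box = box)
  }
  out
}

read_dcd_frames <- function(path) {
  xyz <- suppressWarnings(bio3d::read.dcd(path, verbose = FALSE))
  cell <- tryCatch(
    suppressWarnings(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE)),
    error = function(e) NULL)
  n_fr <- nrow(xyz)
  lapply(seq_len(n_fr), function(i) {
    co <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    box <- NULL
    if (!is.null(cell) && ncol(cell) >= 6) {
      edges <- cell[i, 1:3]
      angles <- cell[i, 4:6]
      if (all(edges > 0)) {
        if (isTRUE(any(abs(angles - 90) > 1e-3)))
          stop("triclinic DCD unit cell not supported", call. = FALSE)
        box <- as.numeric(edges)
      }
    }
    md_frame(co, box = box)
  })
}

#' Write a DCD trajectory
#'
#' Writes a CHARMM-style binary DCD (native endianness, crystal records when
#' frames carry a box).  The written file is readable by `bio3d::read.dcd`
#' and common MD viewers.
#'
#' @param system a [molecular_system].
#' @param frames list of [md_frame] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(system, frames, path) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  if (!length(frames)) stop("write_dcd: no frames to write", call. = FALSE)
  for (fr in frames) check_frame_system(fr, system)
  has_box <- !is.null(frames[[1]]$box)
  n_fr <- length(frames)
  n_at <- system$n_atoms
  con <- file(path, open = "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L)
  # header block: "CORD" + 20 control integers (icntrl[11] flags crystal,
  # icntrl[20] is the CHARMM version stamp)
  icntrl <- integer(20)
  icntrl[1] <- n_fr; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- n_fr
  icntrl[11] <- as.integer(has_box); icntrl[20] <- 24L
  wi(84L); writeChar("CORD", con, nchars = 4, eos = NULL); wi(icntrl); wi(84L)
  title <- formatC("Created by hydropore::write_dcd", width = -80)
  wi(80L + 4L); wi(1L); writeChar(title, con, nchars = 80, eos = NULL); wi(84L)
  wi(4L); wi(n_at); wi(4L)
  for (fr in frames) {
    if (has_box) {
      b <- fr$box
      # XTLABC order a, gamma, b, beta, alpha, c with angles stored as
      # cosines (CHARMM >= 22 convention); cos 90 deg = 0
      wi(48L)
      writeBin(as.double(c(b[1], 0, b[2], 0, 0, b[3])), con, size = 8L)
      wi(48L)
    }
    for (d in 1:3) {
      wi(4L * n_at)
      writeBin(as.double(fr$coordinates[, d]), con, size = 4L)
      wi(4L * n_at)
    }
  }
  invisible(path)
}
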