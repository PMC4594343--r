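# Structure file input/output: PDB (via bio3d) and GRO (fixed-width text).
# Coordinates are Angstrom internally; GRO files are nm on disk.

#' Read a molecular structure file
#'
#' Reads a PDB or GRO structure and returns the system topology together with
#' the first (or only) coordinate frame.
#'
#' @param path path to the structure file.
#' @param format `"pdb"`, `"gro"`, or `"auto"` (by file extension).
#' @return A list with components `system` ([molecular_system]) and `frame`
#'   ([md_frame]).  The frame's `box` is taken from CRYST1 (PDB) or the box
#'   line (GRO) when present; triclinic cells are rejected.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("read_structure: file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  if (file.size(path) == 0L)
    stop("read_structure: empty file: ", path, call. = FALSE)
  switch(format,
         pdb = read_structure_pdb(path),
         gro = read_structure_gro(path),
         stop("read_structure: unsupported structure format '", format, "'",
              call. = FALSE))
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdb = "pdb", ent = "pdb", gro = "gro",
         dcd = "dcd", xtc = "xtc", trr = "trr",
         stop("cannot guess file format from extension '.", ext, "'",
              call. = FALSE))
}

read_structure_pdb <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("read_structure: failed to parse PDB '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L)
    stop("read_structure: no atoms in PDB file: ", path, call. = FALSE)
  elem <- a$elesy
  if (is.null(elem)) elem <- ""
  sys <- molecular_system(data.frame(
    atom_name = a$elety, residue_name = a$resid, residue_id = a$resno,
    chain_id = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    element = ifelse(is.na(elem), "", elem),
    stringsAsFactors = FALSE))
  coords <- cbind(a$x, a$y, a$z)
  box <- pdb_cryst1_box(path)
  list(system = sys, frame = md_frame(coords, box = box, time = 0))
}

# Scan the head of a PDB file for an orthorhombic CRYST1 record.
pdb_cryst1_box <- function(path, n_scan = 1000L) {
  head_lines <- readLines(path, n = n_scan, warn = FALSE)
  cl <- head_lines[startsWith(head_lines, "CRYST1")]
  if (!length(cl)) return(NULL)
  cl <- cl[1]
  edges <- as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33)))
  angles <- suppressWarnings(
    as.numeric(c(substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54))))
  if (any(is.na(edges)) || any(edges <= 0)) return(NULL)
  if (!any(is.na(angles)) && any(abs(angles - 90) > 1e-3))
    stop("triclinic unit cell not supported (CRYST1 angles ",
         paste(angles, collapse = ", "), ")", call. = FALSE)
  edges
}

read_structure_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop("read_structure: malformed GRO file (fewer than 3 lines): ", path,
         call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n <= 0L)
    stop("read_structure: bad atom count in GRO file: ", path, call. = FALSE)
  if (length(lines) < 2L + n + 1L)
    stop("read_structure: GRO file truncated (expected ", n, " atom lines): ",
         path, call. = FALSE)
  al <- lines[3:(2 + n)]
  resid <- as.integer(substr(al, 1, 5))
  resnm <- trimws(substr(al, 6, 10))
  atnm <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28)) * 10
  y <- as.numeric(substr(al, 29, 36)) * 10
  z <- as.numeric(substr(al, 37, 44)) * 10
  if (any(is.na(x)) || any(is.na(y)) || any(is.na(z)))
    stop("read_structure: unparseable coordinates in GRO file: ", path,
         call. = FALSE)
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]),
                                               "\\s+")[[1]]))
  box <- NULL
  if (length(boxv) >= 3 && !any(is.na(boxv[1:3]))) {
    if (length(boxv) > 3 && any(abs(boxv[-(1:3)]) > 1e-9))
      stop("triclinic GRO box not supported", call. = FALSE)
    box <- boxv[1:3] * 10
  }
  sys <- molecular_system(data.frame(
    atom_name = atnm, residue_name = resnm, residue_id = resid,
    stringsAsFactors = FALSE))
  list(system = sys, frame = md_frame(cbind(x, y, z), box = box, time = 0))
}

#' Write a structure in GRO format
#'
#' @param system a [molecular_system].
#' @param frame an [md_frame] with coordinates for every atom (Angstrom;
#'   written as nm).
#' @param path output path.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(system, frame, path, title = "hydropore system") {
  check_frame_system(frame, system)
  a <- system$atoms
  xyz <- frame$coordinates / 10
  # 4 decimals (0.0001 nm = 0.001 A) within the fixed 8-char columns, so
  # coordinates round-trip to better than 0.001 A
  lines <- sprintf("%5d%-5s%5s%5d%8.4f%8.4f%8.4f",
                   a$residue_id %% 100000L, substr(a$residue_name, 1, 5),
                   substr(a$atom_name, 1, 5),
                   seq_len(nrow(a)) %% 100000L,
                   xyz[, 1], xyz[, 2], xyz[, 3])
  box <- if (is.null(frame$box)) c(0, 0, 0) else frame$box / 10
  out <- c(title, sprintf("%5d", system$n_atoms), lines,
           sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(out, path)
  invisible(path)
}

# Format one frame as PDB ATOM records (no MODEL wrapper).
format_pdb_atoms <- function(system, coords) {
  a <- system$atoms
  nm <- a$atom_name
  nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4),
                paste0(" ", formatC(nm, width = -3)))
  sprintf("ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(a)) %% 100000L, nm4, substr(a$residue_name, 1, 4),
          substr(a$chain_id, 1, 1), a$residue_id %% 10000L,
          coords[, 1], coords[, 2], coords[, 3], 1, 0,
          formatC(a$element, width = 2))
}

pdb_cryst1_line <- function(box) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
          box[1], box[2], box[3], 90, 90, 90)
}

#' Write a structure or trajectory in PDB format
#'
#' A single frame produces a plain PDB; a list of frames produces a
#' multi-model PDB (one MODEL per frame) that [iterate_frames] reads back as
#' a trajectory.
#'
#' @param system a [molecular_system].
#' @param frames an [md_frame] or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(system, frames, path) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  if (!length(frames)) stop("write_pdb: no frames to write", call. = FALSE)
  con <- file(path, open = "w")
  on.exit(close(con))
  if (!is.null(frames[[1]]$box))
    writeLines(pdb_cryst1_line(frames[[1]]$box), con)
  multi <- length(frames) > 1L
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    check_frame_system(fr, system)
    if (multi) writeLines(sprintf("MODEL %8d", i), con)
    writeLines(format_pdb_atoms(system, fr$coordinates), con)
    writeLines(if (multi) "ENDMDL" else "END", con)
  }
  if (multi) writeLines("END", con)
  invisible(path)
}
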