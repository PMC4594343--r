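# Core containers: molecular system, frame, atom selection.

#' Construct a molecular system
#'
#' A `molecular_system` holds the static atom identities of a simulation
#' system: names, residues, chains and elements.  Per-frame coordinates live
#' in [md_frame] objects so that a single system can be paired with any
#' number of trajectory frames.
#'
#' @param atoms data.frame with columns `atom_name`, `residue_name`,
#'   `residue_id`, and optionally `chain_id` and `element`.  Elements are
#'   inferred from atom names where absent (see [infer_element]).
#' @return An object of class `molecular_system` with fields `atoms`
#'   (data.frame, with a 0-based `index` column) and `n_atoms`.
#' @examples
#' s <- molecular_system(data.frame(
#'   atom_name = c("OW", "HW1", "HW2"),
#'   residue_name = "SOL", residue_id = 1L))
#' s$n_atoms
#' @export
molecular_system <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) == 0L)
    stop("molecular_system: system must contain at least one atom", call. = FALSE)
  need <- c("atom_name", "residue_name", "residue_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("molecular_system: missing atom columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  atoms$atom_name <- trimws(as.character(atoms$atom_name))
  atoms$residue_name <- trimws(as.character(atoms$residue_name))
  atoms$residue_id <- as.integer(atoms$residue_id)
  if (any(!nzchar(atoms$atom_name)) || any(!nzchar(atoms$residue_name)))
    stop("molecular_system: empty atom or residue name", call. = FALSE)
  if (is.null(atoms$chain_id)) atoms$chain_id <- "A"
  atoms$chain_id <- as.character(atoms$chain_id)
  if (is.null(atoms$element) || all(!nzchar(trimws(atoms$element)))) {
    atoms$element <- infer_element(atoms$atom_name)
  } else {
    atoms$element <- trimws(as.character(atoms$element))
    blank <- !nzchar(atoms$element)
    atoms$element[blank] <- infer_element(atoms$atom_name[blank])
  }
  bad <- !grepl("^([A-Z][a-z]?|X)$", atoms$element)
  if (any(bad)) atoms$element[bad] <- "X"
  atoms$index <- seq_len(nrow(atoms)) - 1L
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, n_atoms = nrow(atoms)),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("<molecular_system> ", x$n_atoms, " atoms, ",
      length(unique(x$atoms$residue_name)), " residue types (",
      paste(utils::head(sort(unique(x$atoms$residue_name)), 6), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# Two-letter element symbols recognised when the whole atom name matches.
# CA is deliberately absent: in protein context CA is an alpha-carbon.
.two_letter_elements <- c("CL", "BR", "NA", "MG", "FE", "ZN", "MN",
                          "LI", "RB", "CS", "SE", "CU", "NI", "CD")

#' Infer chemical elements from atom names
#'
#' Uses the first alphabetic character of the atom name, with a two-letter
#' override when the full name is itself a two-letter element symbol
#' (CL, NA, MG, ...).  Names with no alphabetic character map to "X".
#'
#' @param atom_names character vector of atom names.
#' @return Character vector of element symbols ("O", "C", "Cl", ..., or "X").
#' @export
infer_element <- function(atom_names) {
  nm <- toupper(trimws(atom_names))
  out <- rep("X", length(nm))
  two <- nm %in% .two_letter_elements
  out[two] <- paste0(substr(nm[two], 1, 1), tolower(substr(nm[two], 2, 2)))
  rest <- !two
  first <- sub("^[^A-Z]*([A-Z]).*$", "\\1", nm[rest])
  ok <- grepl("^[A-Z]$", first)
  out[rest][ok] <- first[ok]
  out
}

#' Construct a trajectory frame
#'
#' @param coordinates numeric matrix, one row per atom, columns x, y, z in
#'   Angstrom.
#' @param box orthorhombic box edge lengths in Angstrom (length-3 numeric),
#'   or `NULL` for a non-periodic frame.
#' @param time frame time in ns.
#' @return Object of class `md_frame`.
#' @export
md_frame <- function(coordinates, box = NULL, time = NA_real_) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L)
    stop("md_frame: coordinates must be an n x 3 matrix", call. = FALSE)
  storage.mode(coordinates) <- "double"
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L)
      stop("md_frame: box must be three orthorhombic edge lengths", call. = FALSE)
  }
  structure(list(coordinates = coordinates, box = box, time = as.numeric(time)),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat("<md_frame> ", nrow(x$coordinates), " atoms, t = ",
      format(x$time), " ns", sep = "")
  if (!is.null(x$box))
    cat(", box ", paste(format(x$box, digits = 4), collapse = " x "), " A", sep = "")
  cat("\n")
  invisible(x)
}

check_frame_system <- function(frame, system) {
  if (nrow(frame$coordinates) != system$n_atoms)
    stop("frame has ", nrow(frame$coordinates), " atoms but system has ",
         system$n_atoms, call. = FALSE)
  invisible(TRUE)
}

#' Construct an atom index set
#'
#' @param indices 0-based atom indices (ordered, unique).
#' @param selection_spec the textual query that produced the set.
#' @param n_atoms system size the indices refer to (for validation).
#' @return Object of class `atom_set`; `rows(x)` gives 1-based row positions.
#' @export
atom_set <- function(indices, selection_spec = "", n_atoms = NULL) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices))
    stop("atom_set: duplicate indices", call. = FALSE)
  if (length(indices) && any(indices < 0L))
    stop("atom_set: negative index", call. = FALSE)
  if (!is.null(n_atoms) && length(indices) && any(indices >= n_atoms))
    stop("atom_set: index out of range for system of ", n_atoms, " atoms",
         call. = FALSE)
  structure(list(indices = indices, selection_spec = selection_spec),
            class = "atom_set")
}

#' @export
print.atom_set <- function(x, ...) {
  cat("<atom_set> ", length(x$indices), " atoms",
      if (nzchar(x$selection_spec)) paste0(" [", x$selection_spec, "]"), "\n",
      sep = "")
  invisible(x)
}

#' 1-based row positions of an atom set
#' @param x an `atom_set`.
#' @return integer vector of row positions into `system$atoms`.
#' @export
rows <- function(x) {
  stopifnot(inherits(x, "atom_set"))
  x$indices + 1L
}
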