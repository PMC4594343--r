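# Pore-centered coordinate system.  z = 0 at the anchor centroid (the S4
# ion-binding site of the selectivity filter: the threonine pair that defines
# the 0 A position), positive z toward the extracellular side.  The frame is
# recomputed every trajectory frame so the analysis is valid for restrained
# and unrestrained runs alike.

#' Build the pore-centered reference frame
#'
#' Origin is the centroid of the anchor atoms; the pore axis is the unit
#' vector from that centroid toward the centroid of the orientation
#' selection (an extracellular reference, e.g. the filter's outer
#' carbonyls).  The lateral axes complete a right-handed orthonormal basis,
#' seeded by Gram-Schmidt from a direction fixed in the molecule (the first
#' anchor atom's offset from the centroid) so that all pore-frame
#' coordinates are invariant under rigid-body motion of the whole system;
#' if that offset is degenerate or near-parallel to the axis, the laboratory
#' x axis (then y) is used instead.
#'
#' @param frame an [md_frame].
#' @param anchor [atom_set] of anchor atoms (nonempty).
#' @param orient [atom_set] whose centroid marks the extracellular direction.
#' @return Object of class `reference_frame` with fields `origin` (3-vector,
#'   Angstrom) and `basis` (3 x 3 matrix, columns = lateral e1, lateral e2,
#'   pore axis).
#' @export
build_reference_frame <- function(frame, anchor, orient) {
  stopifnot(inherits(frame, "md_frame"))
  if (!length(anchor$indices))
    stop("build_reference_frame: empty anchor selection", call. = FALSE)
  if (!length(orient$indices))
    stop("build_reference_frame: empty orientation selection", call. = FALSE)
  co <- frame$coordinates
  origin <- colMeans(co[rows(anchor), , drop = FALSE])
  ocent <- colMeans(co[rows(orient), , drop = FALSE])
  axisv <- ocent - origin
  nrm <- sqrt(sum(axisv^2))
  if (nrm < 1e-6)
    stop("build_reference_frame: degenerate pore axis (anchor and ",
         "orientation centroids coincide)", call. = FALSE)
  axisv <- axisv / nrm
  seed <- co[rows(anchor)[1], ] - origin
  e1 <- gram_schmidt_seed(seed, axisv)
  e2 <- cross3(axisv, e1)
  structure(list(origin = origin, basis = cbind(e1, e2, axisv)),
            class = "reference_frame")
}

# Orthonormalise `seed` against `axis`; fall back to lab x then y axes when
# the seed is (near-)parallel to the axis or too short.
gram_schmidt_seed <- function(seed, axisv) {
  candidates <- list(seed, c(1, 0, 0), c(0, 1, 0))
  for (v in candidates) {
    w <- v - sum(v * axisv) * axisv
    nw <- sqrt(sum(w^2))
    if (nw > 1e-6) return(w / nw)
  }
  stop("build_reference_frame: could not construct lateral axis", call. = FALSE)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("<reference_frame> origin (",
      paste(format(x$origin, digits = 4), collapse = ", "),
      ") A, axis (", paste(format(x$basis[, 3], digits = 3), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Transform coordinates into the pore frame
#'
#' @param frame an [md_frame].
#' @param ref a [reference_frame][build_reference_frame].
#' @param subset optional [atom_set]; default all atoms.
#' @return n x 3 matrix of pore-frame coordinates (Angstrom); the third
#'   column is the position along the pore axis, 0 at the anchor.
#' @export
to_pore_coords <- function(frame, ref, subset = NULL) {
  stopifnot(inherits(ref, "reference_frame"))
  co <- frame$coordinates
  if (!is.null(subset)) co <- co[rows(subset), , drop = FALSE]
  sweep(co, 2, ref$origin) %*% ref$basis
}

#' Wrap coordinates into the primary periodic cell
#'
#' Shifts every atom by integer multiples of the orthorhombic box edges so
#' it lies in the half-open cell `[center - edge/2, center + edge/2)`.
#' Needed so that bilayer lipids broken across the periodic boundary are
#' counted on the correct side of the pore.
#'
#' @param frame an [md_frame] with a positive orthorhombic box.
#' @param center 3-vector cell center (Angstrom).
#' @return A new [md_frame] with wrapped coordinates.
#' @export
wrap_to_primary_cell <- function(frame, center) {
  stopifnot(inherits(frame, "md_frame"))
  if (is.null(frame$box) || any(frame$box <= 0))
    stop("wrap_to_primary_cell: frame needs a positive orthorhombic box",
         call. = FALSE)
  co <- frame$coordinates
  for (d in 1:3) {
    co[, d] <- co[, d] - frame$box[d] *
      floor((co[, d] - center[d]) / frame$box[d] + 0.5)
  }
  md_frame(co, box = frame$box, time = frame$time)
}

#' Define a counting box in the pore frame
#'
#' The box is axis-aligned in the pore frame and centered laterally on the
#' pore axis; only its edge lengths and z interval are free.  Defaults
#' correspond to the two boxes of the analysis: `water_box()` is the
#' 20 x 20 x 5 A region spanning -10 A < z <= -5 A below the S4 site where
#' water oxygens are counted, `carbon_box()` the 20 x 20 x 20 A region
#' (-20 A < z <= 0 A) where lipid carbons are counted.
#'
#' @param lx,ly lateral edge lengths (Angstrom, > 0).
#' @param zmin,zmax pore-frame z bounds (Angstrom, `zmin < zmax`); the z
#'   interval is half-open, `(zmin, zmax]`, so stacked boxes never double
#'   count.
#' @return Object of class `counting_box`.
#' @export
counting_box <- function(lx, ly, zmin, zmax) {
  if (lx <= 0 || ly <= 0) stop("counting_box: edges must be > 0", call. = FALSE)
  if (zmin >= zmax) stop("counting_box: need zmin < zmax", call. = FALSE)
  structure(list(lx = lx, ly = ly, zmin = zmin, zmax = zmax),
            class = "counting_box")
}

#' @rdname counting_box
#' @export
water_box <- function() counting_box(20, 20, -10, -5)

#' @rdname counting_box
#' @export
carbon_box <- function() counting_box(20, 20, -20, 0)

#' @export
print.counting_box <- function(x, ...) {
  cat("<counting_box> ", x$lx, " x ", x$ly, " A lateral, ",
      x$zmin, " < z <= ", x$zmax, " A\n", sep = "")
  invisible(x)
}
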