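# Pore-radius-versus-z profile of the conduction pathway.  At each z slice
# the accessible radius at a point (x, y) is the smallest 3-D distance to
# any protein heavy atom minus that atom's van der Waals radius; the slice
# center maximizes this radius by a Nelder-Mead search in the plane, seeded
# from the neighbouring slice and walked from the middle of the range
# outward.  A deliberate divergence from the classic Monte-Carlo
# sphere-squeeze along a bendable path: the straight-axis variant is
# deterministic and adequate for channels with an essentially straight pore.

#' Bondi-style van der Waals radii (Angstrom)
#'
#' Default radii used by [pore_radius_profile]; unlisted elements fall back
#' to `default`.
#'
#' @param default radius for elements missing from the table.
#' @return Named numeric vector.
#' @export
vdw_radii <- function(default = 1.70) {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20, X = default)
}

#' Pore radius profile along the pore axis
#'
#' @param frame an [md_frame].
#' @param system the matching [molecular_system].
#' @param ref a [reference_frame][build_reference_frame]; slices are taken
#'   perpendicular to its pore axis.
#' @param z_range `c(zlo, zhi)` pore-frame heights to profile (Angstrom).
#' @param dz slice spacing (Angstrom, default 0.5).
#' @param radii_table named element -> vdW radius map (see [vdw_radii]).
#' @param selection [atom_set] of pore-lining atoms, or `NULL` for the
#'   default: all heavy atoms that are neither water nor lipid.
#' @param lipid_resnames residue names excluded as lipids by the default
#'   selection.
#' @return Object of class `pore_profile`: data.frame-like list with `z`,
#'   `radius`, `cx`, `cy` (optimized center per slice) and `flag`
#'   (`"ok"` or `"fallback"` when the local search failed to improve on the
#'   on-axis radius).
#' @export
pore_radius_profile <- function(frame, system, ref, z_range, dz = 0.5,
                                radii_table = vdw_radii(), selection = NULL,
                                lipid_resnames = "POPC") {
  stopifnot(inherits(frame, "md_frame"), inherits(ref, "reference_frame"))
  if (length(z_range) != 2L || z_range[1] >= z_range[2])
    stop("pore_radius_profile: z_range must be c(zlo, zhi) with zlo < zhi",
         call. = FALSE)
  if (is.null(selection)) {
    spec <- paste0("not resname ", paste(.water_resnames, collapse = " "),
                   " ", paste(lipid_resnames, collapse = " "),
                   " and not element H")
    selection <- select_atoms(system, spec)
  }
  if (!length(selection$indices))
    stop("pore_radius_profile: empty pore-lining selection", call. = FALSE)
  co <- to_pore_coords(frame, ref, selection)
  rv <- radii_table[system$atoms$element[rows(selection)]]
  rv[is.na(rv)] <- if ("X" %in% names(radii_table)) radii_table[["X"]] else 1.70
  zs <- seq(z_range[1], z_range[2], by = dz)
  n <- length(zs)
  radius <- cx <- cy <- numeric(n)
  flag <- character(n)
  # walk from the middle slice outward, seeding each center from the
  # nearest already-solved slice
  order_idx <- order(abs(zs - mean(z_range)), zs)
  center_of <- matrix(NA_real_, n, 2)
  for (i in order_idx) {
    solved <- which(!is.na(center_of[, 1]))
    seedc <- if (length(solved)) {
      center_of[solved[which.min(abs(zs[solved] - zs[i]))], ]
    } else c(0, 0)
    res <- slice_radius(co, rv, zs[i], seedc)
    radius[i] <- res$radius; cx[i] <- res$center[1]; cy[i] <- res$center[2]
    flag[i] <- res$flag
    center_of[i, ] <- res$center
  }
  structure(list(z = zs, radius = radius, cx = cx, cy = cy, flag = flag),
            class = "pore_profile")
}

# Accessible radius at (x, y, z): min over atoms of 3-D distance minus vdW.
point_radius <- function(xy, z, co, rv) {
  min(sqrt((co[, 1] - xy[1])^2 + (co[, 2] - xy[2])^2 + (co[, 3] - z)^2) - rv)
}

slice_radius <- function(co, rv, z, seedc) {
  lat <- sqrt((co[, 1] - seedc[1])^2 + (co[, 2] - seedc[2])^2)
  if (!any(lat <= 15))
    stop("pore_radius_profile: no pore-lining atom within 15 A of the axis ",
         "at z = ", z, call. = FALSE)
  f <- function(xy) -point_radius(xy, z, co, rv)
  seed_val <- point_radius(seedc, z, co, rv)
  opt <- tryCatch(
    stats::optim(seedc, f, method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 500)),
    error = function(e) NULL)
  if (is.null(opt) || -opt$value < seed_val - 1e-9) {
    return(list(radius = seed_val, center = seedc, flag = "fallback"))
  }
  list(radius = -opt$value, center = opt$par, flag = "ok")
}

#' @export
print.pore_profile <- function(x, ...) {
  m <- min_radius(x)
  cat("<pore_profile> ", length(x$z), " slices, z in [",
      min(x$z), ", ", max(x$z), "] A; constriction: r = ",
      format(m$radius, digits = 3), " A at z = ", m$z, " A\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.pore_profile <- function(x, ...) {
  data.frame(z = x$z, radius = x$radius, cx = x$cx, cy = x$cy, flag = x$flag)
}

#' Locate the narrowest constriction of a pore profile
#'
#' @param profile a [pore_profile].
#' @return List with `z` and `radius` of the tightest slice (first slice on
#'   ties).
#' @export
min_radius <- function(profile) {
  stopifnot(inherits(profile, "pore_profile"))
  i <- which.min(profile$radius)
  list(z = profile$z[i], radius = profile$radius[i])
}
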