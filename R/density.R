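# Time-averaged 3-D density grids, bulk-water normalization and isovalue
# thresholding.  Grids use nearest-voxel (floor) binning so that voxel sums
# conserve counts exactly.

#' Construct a density grid
#'
#' @param values 3-D numeric array of per-voxel mean counts (or dimensionless
#'   relative density after normalization).
#' @param origin 3-vector: lower corner of the grid (Angstrom).
#' @param spacing voxel edge length (Angstrom).
#' @param n_frames number of frames accumulated.
#' @param normalized whether values are relative to bulk density.
#' @param bulk_stats list with `mean`, `sd`, `n_voxels` of the bulk region
#'   used for normalization (or `NULL`).
#' @return Object of class `density_grid`.
#' @export
density_grid <- function(values, origin, spacing, n_frames = 1L,
                         normalized = FALSE, bulk_stats = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (any(values < 0)) stop("density_grid: negative values", call. = FALSE)
  if (spacing <= 0) stop("density_grid: spacing must be > 0", call. = FALSE)
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = spacing, dims = dim(values),
                 n_frames = as.integer(n_frames), normalized = normalized,
                 bulk_stats = bulk_stats),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid> ", paste(x$dims, collapse = " x "), " voxels @ ",
      x$spacing, " A, ", x$n_frames, " frames",
      if (x$normalized) ", bulk-normalized", "\n", sep = "")
  invisible(x)
}

check_region <- function(region) {
  region <- as.numeric(region)
  if (length(region) != 6L)
    stop("region must be c(xmin, xmax, ymin, ymax, zmin, zmax)", call. = FALSE)
  lo <- region[c(1, 3, 5)]; hi <- region[c(2, 4, 6)]
  if (any(hi <= lo)) stop("region must have positive extent", call. = FALSE)
  list(lo = lo, hi = hi)
}

#' Accumulate a time-averaged density grid
#'
#' Selected atoms of each frame are binned to voxels by floor binning; the
#' grid holds total counts divided by the number of frames, so the voxel sum
#' equals the mean number of selected atoms inside the region per frame.
#' With a `config`, coordinates are first transformed into the pore frame
#' (wrap, rebuild reference frame per frame); without one, laboratory
#' coordinates are binned directly.
#'
#' @param frames list of [md_frame] objects.
#' @param system the matching [molecular_system].
#' @param selection an [atom_set] (e.g. from
#'   `select_atoms(system, "water_oxygen")`).
#' @param region `c(xmin, xmax, ymin, ymax, zmin, zmax)` bounds in Angstrom
#'   (pore-frame when `config` is given).
#' @param spacing voxel edge length in Angstrom (default 0.5).
#' @param config optional [occupancy_config] providing the pore frame.
#' @return A [density_grid] of per-voxel mean counts.
#' @export
accumulate_density <- function(frames, system, selection, region,
                               spacing = 0.5, config = NULL) {
  if (!length(frames)) stop("accumulate_density: no frames", call. = FALSE)
  stopifnot(inherits(selection, "atom_set"))
  if (spacing <= 0) stop("accumulate_density: spacing must be > 0",
                         call. = FALSE)
  reg <- check_region(region)
  dims <- pmax(1L, as.integer(ceiling((reg$hi - reg$lo) / spacing - 1e-9)))
  anchor <- orient <- NULL
  if (!is.null(config)) {
    stopifnot(inherits(config, "occupancy_config"))
    anchor <- select_atoms(system, config$anchor_selection)
    orient <- select_atoms(system, config$orient_selection)
    if (!length(anchor$indices))
      stop("accumulate_density: empty anchor selection", call. = FALSE)
  }
  counts <- numeric(prod(dims))
  nvox <- prod(dims)
  for (fr in frames) {
    check_frame_system(fr, system)
    if (!is.null(config)) {
      cent <- colMeans(fr$coordinates[rows(anchor), , drop = FALSE])
      if (!is.null(fr$box)) fr <- wrap_to_primary_cell(fr, cent)
      ref <- build_reference_frame(fr, anchor, orient)
      co <- to_pore_coords(fr, ref, selection)
    } else {
      co <- fr$coordinates[rows(selection), , drop = FALSE]
    }
    ii <- floor((co[, 1] - reg$lo[1]) / spacing)
    jj <- floor((co[, 2] - reg$lo[2]) / spacing)
    kk <- floor((co[, 3] - reg$lo[3]) / spacing)
    ok <- ii >= 0 & ii < dims[1] & jj >= 0 & jj < dims[2] &
          kk >= 0 & kk < dims[3]
    if (any(ok)) {
      lin <- 1L + ii[ok] + dims[1] * (jj[ok] + dims[2] * kk[ok])
      counts <- counts + tabulate(lin, nbins = nvox)
    }
  }
  density_grid(array(counts / length(frames), dim = dims),
               origin = reg$lo, spacing = spacing, n_frames = length(frames))
}

# Voxel-center coordinates along each axis.
voxel_centers <- function(grid) {
  lapply(1:3, function(d)
    grid$origin[d] + (seq_len(grid$dims[d]) - 0.5) * grid$spacing)
}

# Logical 3-D mask of voxels whose centers lie inside `region`; with
# region = NULL, the default bulk: lateral distance from the pore axis
# > 15 A and |z| > 15 A.
region_mask <- function(grid, region = NULL,
                        lateral_min = 15, z_min = 15) {
  ctr <- voxel_centers(grid)
  if (is.null(region)) {
    lat <- sqrt(outer(ctr[[1]]^2, ctr[[2]]^2, `+`))
    m2d <- lat > lateral_min
    mz <- abs(ctr[[3]]) > z_min
    return(outer(m2d, mz, `&`))
  }
  reg <- check_region(region)
  mx <- ctr[[1]] >= reg$lo[1] & ctr[[1]] <= reg$hi[1]
  my <- ctr[[2]] >= reg$lo[2] & ctr[[2]] <= reg$hi[2]
  mz <- ctr[[3]] >= reg$lo[3] & ctr[[3]] <= reg$hi[3]
  outer(outer(mx, my, `&`), mz, `&`)
}

#' Normalize a density grid to bulk water density
#'
#' Divides every voxel by the mean value over the bulk region, so that
#' bulk water has relative density 1 and an isovalue of 0.5 marks
#' half-bulk density.
#'
#' @param grid an unnormalized [density_grid].
#' @param bulk_region `c(xmin, xmax, ymin, ymax, zmin, zmax)` defining bulk,
#'   or `NULL` for the default (voxel centers with lateral distance > 15 A
#'   from the pore axis and |z| > 15 A).
#' @return A normalized [density_grid]; `$bulk_stats` reports the bulk mean,
#'   its standard deviation across bulk voxels, and the voxel count.
#' @export
normalize_to_bulk <- function(grid, bulk_region = NULL) {
  stopifnot(inherits(grid, "density_grid"))
  mask <- region_mask(grid, bulk_region)
  nb <- sum(mask)
  if (nb < 100L)
    stop("normalize_to_bulk: bulk region covers only ", nb,
         " voxels (need >= 100)", call. = FALSE)
  bulk_vals <- grid$values[mask]
  mu <- mean(bulk_vals)
  if (mu <= 0)
    stop("normalize_to_bulk: bulk mean density is ", mu,
         " (no atoms in bulk region?)", call. = FALSE)
  density_grid(grid$values / mu, grid$origin, grid$spacing,
               n_frames = grid$n_frames, normalized = TRUE,
               bulk_stats = list(mean = mu, sd = stats::sd(bulk_vals),
                                 n_voxels = nb))
}

#' Threshold a normalized density grid at an isovalue
#'
#' @param grid a normalized [density_grid].
#' @param isovalue relative-density threshold (default 0.5, half bulk).
#' @param cavity_region optional `c(xmin, xmax, ...)` bounds of a cavity of
#'   interest; the dewetted volume fraction (fraction of sub-isovalue
#'   voxels) is reported for it, or for the whole grid when `NULL`.
#' @return List with `mask` (3-D logical array, `TRUE` where density >=
#'   isovalue), `dewetted_fraction`, and `isovalue`.
#' @export
binarize <- function(grid, isovalue = 0.5, cavity_region = NULL) {
  stopifnot(inherits(grid, "density_grid"))
  if (!grid$normalized)
    stop("binarize: grid must be bulk-normalized first", call. = FALSE)
  mask <- grid$values >= isovalue
  cav <- if (is.null(cavity_region)) array(TRUE, grid$dims)
         else region_mask(grid, cavity_region)
  if (!sum(cav))
    stop("binarize: cavity region contains no voxels", call. = FALSE)
  list(mask = mask, dewetted_fraction = mean(!mask[cav]), isovalue = isovalue)
}
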