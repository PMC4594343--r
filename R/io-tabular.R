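# Tabular and volumetric output: occupancy CSV and OpenDX scalar grids.

#' Write an occupancy time series as CSV
#'
#' Columns `time_ns, n_water, n_carbon`, RFC 4180 with a header row.
#'
#' @param ts a nonempty [occupancy_ts].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(ts, path) {
  stopifnot(inherits(ts, "occupancy_ts"))
  if (!length(ts$times))
    stop("write_series_csv: empty series", call. = FALSE)
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an occupancy time series from CSV
#'
#' @param path CSV written by [write_series_csv].
#' @param label condition label to attach.
#' @return An [occupancy_ts].
#' @export
read_series_csv <- function(path, label = "") {
  d <- utils::read.csv(path)
  need <- c("time_ns", "n_water", "n_carbon")
  if (!all(need %in% names(d)))
    stop("read_series_csv: expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  occupancy_ts(d$time_ns, d$n_water, d$n_carbon, label = label)
}

#' Write a density grid in OpenDX format
#'
#' Scalar-field dialect readable by common molecular viewers (origin at the
#' first voxel center, uniform deltas, z-fastest data order, three values
#' per line).  Grid metadata (frame count, normalization flag) is carried in
#' a comment so that [read_grid_dx] round-trips the object.
#'
#' @param grid a [density_grid].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_dx <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  d <- grid$dims
  if (!prod(d)) stop("write_grid_dx: empty grid", call. = FALSE)
  orig <- grid$origin + grid$spacing / 2
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest
  n <- length(vals)
  pad <- (-n) %% 3L
  vm <- matrix(c(sprintf("%.7e", vals), rep("", pad)), nrow = 3)
  data_lines <- trimws(apply(vm, 2, paste, collapse = " "))
  header <- c(
    sprintf("# hydropore density grid; n_frames=%d; normalized=%d",
            grid$n_frames, as.integer(grid$normalized)),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.7e %.7e %.7e", orig[1], orig[2], orig[3]),
    sprintf("delta %.7e 0 0", grid$spacing),
    sprintf("delta 0 %.7e 0", grid$spacing),
    sprintf("delta 0 0 %.7e", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n))
  writeLines(c(header, data_lines,
               'attribute "dep" string "positions"'), path)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' @param path DX file (uniform orthogonal deltas required).
#' @return A [density_grid].
#' @export
read_grid_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^# hydropore density grid", lines, value = TRUE)
  n_frames <- 1L; normalized <- FALSE
  if (length(meta)) {
    n_frames <- as.integer(sub(".*n_frames=([0-9]+).*", "\\1", meta[1]))
    normalized <- sub(".*normalized=([01]).*", "\\1", meta[1]) == "1"
  }
  gp <- grep("gridpositions", lines, value = TRUE)
  if (!length(gp)) stop("read_grid_dx: no gridpositions object", call. = FALSE)
  dims <- as.integer(strsplit(trimws(sub(".*counts", "", gp[1])),
                              "\\s+")[[1]])
  ol <- grep("^origin", lines, value = TRUE)
  orig <- as.numeric(strsplit(trimws(sub("^origin", "", ol[1])), "\\s+")[[1]])
  dl <- grep("^delta", lines, value = TRUE)
  deltas <- t(vapply(dl[1:3], function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]]),
    numeric(3)))
  diag_d <- diag(deltas)
  if (any(abs(deltas - diag(diag_d, 3)) > 1e-9) ||
      max(abs(diff(diag_d))) > 1e-9)
    stop("read_grid_dx: only uniform orthogonal grids supported",
         call. = FALSE)
  spacing <- diag_d[1]
  start <- grep("data follows", lines)[1] + 1L
  end <- length(lines)
  data_lines <- lines[start:end]
  data_lines <- data_lines[!startsWith(data_lines, "attribute") &
                           !startsWith(data_lines, "object") &
                           nzchar(trimws(data_lines))]
  vals <- as.numeric(unlist(strsplit(trimws(data_lines), "\\s+")))
  n <- prod(dims)
  if (length(vals) < n)
    stop("read_grid_dx: expected ", n, " values, found ", length(vals),
         call. = FALSE)
  arr <- aperm(array(vals[seq_len(n)], dim = rev(dims)), c(3, 2, 1))
  density_grid(arr, origin = orig - spacing / 2, spacing = spacing,
               n_frames = n_frames, normalized = normalized)
}
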