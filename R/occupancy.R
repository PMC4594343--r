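# Box occupancy time series, percent occupancy, wet/dry segmentation and
# transition-rate estimation.

#' Count points inside a counting box
#'
#' A point is inside when `|x| <= lx/2`, `|y| <= ly/2` and
#' `zmin < z <= zmax` (half-open in z so vertically stacked boxes never
#' double count a boundary atom).
#'
#' @param pore_coords n x 3 matrix of pore-frame coordinates (Angstrom).
#' @param box a [counting_box].
#' @return Integer count.
#' @export
count_in_box <- function(pore_coords, box) {
  stopifnot(inherits(box, "counting_box"))
  if (is.null(pore_coords) || NROW(pore_coords) == 0L) return(0L)
  pore_coords <- matrix(as.numeric(pore_coords), ncol = 3)
  sum(abs(pore_coords[, 1]) <= box$lx / 2 &
      abs(pore_coords[, 2]) <= box$ly / 2 &
      pore_coords[, 3] > box$zmin & pore_coords[, 3] <= box$zmax)
}

#' Configuration for the occupancy pipeline
#'
#' Bundles the selections and counting boxes the per-frame analysis needs.
#'
#' @param anchor_selection selection string for the z = 0 anchor atoms (the
#'   S4-site threonines in the real channel).
#' @param orient_selection selection string whose centroid marks the
#'   extracellular direction.
#' @param water_box,carbon_box [counting_box] objects for water oxygens and
#'   lipid carbons.
#' @param water_selection,lipid_selection selection strings for the counted
#'   species.
#' @param lipid_resnames residue names expanded by the `lipid_carbon` named
#'   selection.
#' @param dt nominal frame spacing in ns.
#' @param label condition label carried into the time series (e.g. "WT").
#' @return Object of class `occupancy_config`.
#' @export
occupancy_config <- function(anchor_selection = "resname THR and name CA",
                             orient_selection = "resname ORI",
                             water_box = hydropore::water_box(),
                             carbon_box = hydropore::carbon_box(),
                             water_selection = "water_oxygen",
                             lipid_selection = "lipid_carbon",
                             lipid_resnames = "POPC",
                             dt = 0.1,
                             label = "") {
  stopifnot(inherits(water_box, "counting_box"),
            inherits(carbon_box, "counting_box"))
  structure(list(anchor_selection = anchor_selection,
                 orient_selection = orient_selection,
                 water_box = water_box, carbon_box = carbon_box,
                 water_selection = water_selection,
                 lipid_selection = lipid_selection,
                 lipid_resnames = lipid_resnames, dt = dt, label = label),
            class = "occupancy_config")
}

#' Construct an occupancy time series
#'
#' @param times frame times in ns (ascending).
#' @param n_water,n_carbon non-negative integer counts per frame.
#' @param dt nominal frame spacing in ns.
#' @param label condition label (e.g. "WT", "L146N").
#' @return Object of class `occupancy_ts`.
#' @export
occupancy_ts <- function(times, n_water, n_carbon, dt = NA_real_, label = "") {
  n <- length(times)
  if (length(n_water) != n || length(n_carbon) != n)
    stop("occupancy_ts: times, n_water, n_carbon must have equal length",
         call. = FALSE)
  if (n && is.unsorted(times))
    stop("occupancy_ts: times must be ascending", call. = FALSE)
  n_water <- as.integer(n_water); n_carbon <- as.integer(n_carbon)
  if (any(n_water < 0L) || any(n_carbon < 0L))
    stop("occupancy_ts: counts must be non-negative", call. = FALSE)
  if (is.na(dt) && n > 1L) dt <- stats::median(diff(times))
  structure(list(times = as.numeric(times), n_water = n_water,
                 n_carbon = n_carbon, dt = dt, label = label),
            class = "occupancy_ts")
}

#' @export
print.occupancy_ts <- function(x, ...) {
  cat("<occupancy_ts", if (nzchar(x$label)) paste0(" '", x$label, "'"), "> ",
      length(x$times), " frames, dt = ", format(x$dt), " ns; mean n_water = ",
      format(mean(x$n_water), digits = 3), ", mean n_carbon = ",
      format(mean(x$n_carbon), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.occupancy_ts <- function(x, ...) {
  data.frame(time_ns = x$times, n_water = x$n_water, n_carbon = x$n_carbon)
}

# Pool a ts or list of ts into one list of count vectors.
pool_series <- function(ts) {
  if (inherits(ts, "occupancy_ts")) ts <- list(ts)
  if (!length(ts) || !all(vapply(ts, inherits, logical(1), "occupancy_ts")))
    stop("expected an occupancy_ts or a nonempty list of them", call. = FALSE)
  if (!sum(vapply(ts, function(s) length(s$times), integer(1))))
    stop("empty occupancy series", call. = FALSE)
  list(n_water = unlist(lapply(ts, `[[`, "n_water")),
       n_carbon = unlist(lapply(ts, `[[`, "n_carbon")))
}

#' Compute the water/lipid-carbon occupancy time series of a trajectory
#'
#' Per frame: wrap into the primary cell centered on the anchor, rebuild the
#' pore reference frame, transform the water-oxygen and lipid-carbon
#' selections into it, and count each inside its box.
#'
#' @param frames list of [md_frame] objects (e.g. from [iterate_frames]).
#' @param system the matching [molecular_system].
#' @param config an [occupancy_config].
#' @return An [occupancy_ts].
#' @export
occupancy_series <- function(frames, system, config = occupancy_config()) {
  stopifnot(inherits(config, "occupancy_config"))
  if (!length(frames)) stop("occupancy_series: no frames", call. = FALSE)
  anchor <- select_atoms(system, config$anchor_selection)
  if (!length(anchor$indices))
    stop("occupancy_series: anchor selection '", config$anchor_selection,
         "' matched no atoms", call. = FALSE)
  orient <- select_atoms(system, config$orient_selection)
  wat <- select_atoms(system, config$water_selection,
                      lipid_resnames = config$lipid_resnames)
  lip <- select_atoms(system, config$lipid_selection,
                      lipid_resnames = config$lipid_resnames)
  n <- length(frames)
  n_water <- integer(n); n_carbon <- integer(n); times <- numeric(n)
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    check_frame_system(fr, system)
    anchor_cent <- colMeans(fr$coordinates[rows(anchor), , drop = FALSE])
    if (!is.null(fr$box)) fr <- wrap_to_primary_cell(fr, anchor_cent)
    ref <- build_reference_frame(fr, anchor, orient)
    n_water[i] <- count_in_box(to_pore_coords(fr, ref, wat), config$water_box)
    n_carbon[i] <- count_in_box(to_pore_coords(fr, ref, lip), config$carbon_box)
    times[i] <- if (is.na(fr$time)) (i - 1) * config$dt else fr$time
  }
  occupancy_ts(times, n_water, n_carbon, dt = config$dt, label = config$label)
}

#' Percent occupancy of a box
#'
#' Percentage of frames in which the counted species is present, i.e. in
#' which the count is at least `min_count`.  Multiple series (replicate
#' simulations) are pooled at the frame level before taking the ratio.
#'
#' @param ts an [occupancy_ts] or list of them.
#' @param channel `"carbon"` or `"water"`.
#' @param min_count presence threshold (default 1: at least one atom).
#' @return Percentage in `[0, 100]`.
#' @export
percent_occupancy <- function(ts, channel = c("carbon", "water"),
                              min_count = 1L) {
  channel <- match.arg(channel)
  if (min_count < 1L) stop("percent_occupancy: min_count must be >= 1",
                           call. = FALSE)
  pooled <- pool_series(ts)
  counts <- if (channel == "carbon") pooled$n_carbon else pooled$n_water
  100 * mean(counts >= min_count)
}

#' Segment a hydration trace into wet and dry states
#'
#' Two-threshold hysteresis: the state switches to dry when the water count
#' drops to `dry_max` or below, to wet when it reaches `wet_min` or above,
#' and holds in between.  Frames before the first resolved state take that
#' first state.  Segments shorter than `min_dwell` frames are merged into
#' the longer neighbouring segment (ties go to the preceding one), shortest
#' segment first.
#'
#' @param ts an [occupancy_ts] (the water channel is segmented).
#' @param dry_max,wet_min hysteresis thresholds (`dry_max < wet_min`).
#' @param min_dwell minimum segment length in frames.
#' @return Object of class `wetting_segmentation` with fields `state`
#'   (character per frame), `segments` (data.frame: start, end, state,
#'   1-based inclusive frame indices) and `n_transitions`.
#' @export
classify_wetting <- function(ts, dry_max = 1L, wet_min = 4L, min_dwell = 5L) {
  stopifnot(inherits(ts, "occupancy_ts"))
  if (dry_max >= wet_min)
    stop("classify_wetting: need dry_max < wet_min (hysteresis band)",
         call. = FALSE)
  n <- length(ts$times)
  if (n < 2L)
    stop("classify_wetting: series must have at least 2 frames", call. = FALSE)
  w <- ts$n_water
  raw <- ifelse(w <= dry_max, "dry", ifelse(w >= wet_min, "wet", NA))
  # hold previous state through the hysteresis band
  state <- raw
  for (i in 2:n) if (is.na(state[i])) state[i] <- state[i - 1]
  # leading in-band frames take the first resolved state
  if (anyNA(state)) {
    first_resolved <- state[!is.na(state)][1]
    if (is.na(first_resolved))
      stop("classify_wetting: no frame outside the hysteresis band",
           call. = FALSE)
    state[is.na(state)] <- first_resolved
  }
  seg <- rle_segments(state)
  seg <- merge_short_segments(seg, min_dwell)
  state <- rep(seg$state, seg$end - seg$start + 1L)
  structure(list(state = state, segments = seg,
                 n_transitions = nrow(seg) - 1L),
            class = "wetting_segmentation")
}

rle_segments <- function(state) {
  r <- rle(state)
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1L, end = end, state = r$values,
             stringsAsFactors = FALSE)
}

merge_short_segments <- function(seg, min_dwell) {
  if (min_dwell <= 1L) return(seg)
  repeat {
    len <- seg$end - seg$start + 1L
    short <- which(len < min_dwell)
    if (!length(short) || nrow(seg) == 1L) return(seg)
    k <- short[which.min(len[short])]
    # relabel to the longer neighbour's state (tie -> preceding neighbour)
    left_len <- if (k > 1L) len[k - 1L] else -1L
    right_len <- if (k < nrow(seg)) len[k + 1L] else -1L
    seg$state[k] <- if (left_len >= right_len) seg$state[k - 1L]
                    else seg$state[k + 1L]
    # coalesce equal-state runs
    seg <- coalesce_segments(seg)
  }
}

coalesce_segments <- function(seg) {
  r <- rle(seg$state)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  data.frame(start = seg$start[first], end = seg$end[last], state = r$values,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.wetting_segmentation <- function(x, ...) {
  tot <- length(x$state)
  cat("<wetting_segmentation> ", tot, " frames, ", nrow(x$segments),
      " segments, ", x$n_transitions, " transitions; wet fraction ",
      format(mean(x$state == "wet"), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Estimate wetting/dewetting transition rates
#'
#' Maximum-likelihood rates of a two-state (telegraph) process observed at
#' fixed stride: each rate is the number of exits from a state divided by
#' the total time spent in it.  Standard errors are `rate / sqrt(n)` with
#' `n` the number of transitions of that kind; a rate with no observed
#' transition is reported as 0 with `NA` standard error and flagged.
#'
#' @param seg a [wetting_segmentation][classify_wetting].
#' @param dt frame spacing in ns.
#' @return Object of class `rate_estimate` with fields `k_wet_to_dry`,
#'   `k_dry_to_wet` (1/ns), `wet_fraction`, `se_wet_to_dry`,
#'   `se_dry_to_wet`, and `flags`.
#' @export
estimate_rates <- function(seg, dt) {
  stopifnot(inherits(seg, "wetting_segmentation"))
  if (length(seg$state) < 2L)
    stop("estimate_rates: segmentation must cover >= 2 frames", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0)
    stop("estimate_rates: dt must be > 0", call. = FALSE)
  st <- seg$state
  n <- length(st)
  wet_frames <- sum(st == "wet")
  dry_frames <- n - wet_frames
  from <- st[-n]; to <- st[-1]
  n_wd <- sum(from == "wet" & to == "dry")
  n_dw <- sum(from == "dry" & to == "wet")
  t_wet <- wet_frames * dt
  t_dry <- dry_frames * dt
  k_wd <- if (t_wet > 0) n_wd / t_wet else 0
  k_dw <- if (t_dry > 0) n_dw / t_dry else 0
  flags <- character(0)
  if (n_wd == 0L) flags <- c(flags, "no wet->dry transitions")
  if (n_dw == 0L) flags <- c(flags, "no dry->wet transitions")
  structure(list(
    k_wet_to_dry = k_wd, k_dry_to_wet = k_dw,
    se_wet_to_dry = if (n_wd > 0L) k_wd / sqrt(n_wd) else NA_real_,
    se_dry_to_wet = if (n_dw > 0L) k_dw / sqrt(n_dw) else NA_real_,
    wet_fraction = wet_frames / n,
    n_wet_to_dry = n_wd, n_dry_to_wet = n_dw,
    flags = flags), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("<rate_estimate> k(wet->dry) = ", format(x$k_wet_to_dry, digits = 3),
      " /ns (se ", format(x$se_wet_to_dry, digits = 2), "), k(dry->wet) = ",
      format(x$k_dry_to_wet, digits = 3), " /ns (se ",
      format(x$se_dry_to_wet, digits = 2), "), wet fraction ",
      format(x$wet_fraction, digits = 3), "\n", sep = "")
  if (length(x$flags)) cat("  flags: ", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
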