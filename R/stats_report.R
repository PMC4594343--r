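# Joint water-lipid occupancy statistics, rank correlation with permutation
# inference, and condition comparison with bootstrap intervals.

#' Joint water-carbon occupancy heat map
#'
#' 2-D integer-bin histogram of per-frame (n_water, n_carbon) pairs over one
#' or more (pooled) series, expressed as percent of pooled frames.  Also
#' reports the modal carbon count among dry frames (`n_water <= dry_max`).
#'
#' @param ts an [occupancy_ts] or list of them (replicates are pooled).
#' @param dry_max water-count threshold defining a dry frame for the modal
#'   carbon summary.
#' @return Object of class `joint_occupancy`: `water_bins`, `carbon_bins`
#'   (integer bin labels starting at 0), `percent` (matrix water x carbon
#'   summing to 100), `modal_dry_carbon` (NA when no dry frames), `n_frames`.
#' @export
joint_heatmap <- function(ts, dry_max = 1L) {
  pooled <- pool_series(ts)
  w <- pooled$n_water; cc <- pooled$n_carbon
  wb <- 0:max(w); cb <- 0:max(cc)
  tab <- table(factor(w, levels = wb), factor(cc, levels = cb))
  percent <- 100 * unclass(tab) / length(w)
  dimnames(percent) <- list(water = wb, carbon = cb)
  dry <- w <= dry_max
  modal <- if (any(dry)) {
    dc <- table(cc[dry])
    as.integer(names(dc)[which.max(dc)])
  } else NA_integer_
  structure(list(water_bins = wb, carbon_bins = cb, percent = percent,
                 modal_dry_carbon = modal, n_frames = length(w)),
            class = "joint_occupancy")
}

#' @export
print.joint_occupancy <- function(x, ...) {
  cat("<joint_occupancy> ", x$n_frames, " frames, water 0..",
      max(x$water_bins), " x carbon 0..", max(x$carbon_bins),
      "; modal carbon count in dry frames: ", x$modal_dry_carbon,
      "\n", sep = "")
  invisible(x)
}

#' Write a joint occupancy map as CSV
#'
#' Matrix layout: one row per water count, one column per carbon count,
#' cells in percent of frames.
#'
#' @param map a [joint_occupancy][joint_heatmap].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(map, path) {
  stopifnot(inherits(map, "joint_occupancy"))
  d <- as.data.frame(map$percent)
  d <- cbind(n_water = map$water_bins, d)
  names(d)[-1] <- paste0("carbon_", map$carbon_bins)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Spearman rho via Pearson on mid-ranks (handles ties).
spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Water-lipid rank correlation with permutation inference
#'
#' Spearman rank correlation between the water and carbon counts of a
#' series, with a two-sided permutation p-value obtained by permuting one
#' series: `p = (1 + #{|rho_perm| >= |rho|}) / (1 + n_permutations)`.  A
#' hydrophobic pore in which lipid tails enter preferentially while the
#' cavity is dry shows rho < 0.
#'
#' @param ts an [occupancy_ts] (or list; pooled), length >= 10.
#' @param method correlation type; only `"spearman"`.
#' @param n_permutations number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return List with `rho`, `p`, `n`, and `flag` (`"constant series"` when
#'   either channel is constant, in which case `rho = 0`).
#' @export
inverse_correlation <- function(ts, method = "spearman",
                                n_permutations = 10000L, seed = 1L) {
  method <- match.arg(method, "spearman")
  pooled <- pool_series(ts)
  w <- pooled$n_water; cc <- pooled$n_carbon
  n <- length(w)
  if (n < 10L)
    stop("inverse_correlation: need at least 10 frames", call. = FALSE)
  rho <- spearman_rho(w, cc)
  if (is.na(rho)) {
    return(list(rho = 0, p = 1, n = n, flag = "constant series"))
  }
  rw <- rank(w); rc <- rank(cc)
  # center once; permutation rho is then a normalized cross product
  rwc <- rw - mean(rw); rcc <- rc - mean(rc)
  denom <- sqrt(sum(rwc^2) * sum(rcc^2))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  perm_rho <- vapply(seq_len(n_permutations), function(i) {
    sum(rwc * rcc[sample.int(n)]) / denom
  }, numeric(1))
  p <- (1 + sum(abs(perm_rho) >= abs(rho) - 1e-12)) / (1 + n_permutations)
  list(rho = rho, p = p, n = n, flag = "")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

condition_summary <- function(series, label) {
  pooled <- pool_series(series)
  list(label = label,
       n_frames = length(pooled$n_water),
       percent_occupancy_carbon = percent_occupancy(series, "carbon"),
       percent_occupancy_water = percent_occupancy(series, "water"),
       mean_n_water = mean(pooled$n_water),
       mean_n_carbon = mean(pooled$n_carbon))
}

# Bootstrap resample of frame indices: plain iid frames, or moving blocks of
# `block_length` frames when set (MD frames are autocorrelated).
boot_indices <- function(n, block_length = NULL) {
  if (is.null(block_length) || block_length <= 1L) return(sample.int(n, n, replace = TRUE))
  nb <- ceiling(n / block_length)
  starts <- sample.int(n - block_length + 1L, nb, replace = TRUE)
  idx <- as.vector(outer(0:(block_length - 1L), starts, `+`))
  idx[seq_len(n)]
}

#' Compare two simulation conditions
#'
#' Pools the replicate series of each condition (e.g. two 200 ns runs of
#' wild type vs mutant), summarizes each, and reports the difference in
#' lipid-carbon percent occupancy with a frame-level bootstrap percentile
#' interval, plus the within-condition water-carbon rank correlation.
#'
#' @param series_a,series_b an [occupancy_ts] or list of replicates per
#'   condition.
#' @param labels length-2 character, condition names.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @param conf interval coverage (default 0.95).
#' @param block_length optional moving-block length in frames (default
#'   `NULL`: iid frame bootstrap; use ~10 to respect MD autocorrelation).
#' @param n_permutations permutations for the per-condition correlation
#'   p-values.
#' @return Object of class `comparison_report`.
#' @export
compare_conditions <- function(series_a, series_b,
                               labels = c("A", "B"), n_boot = 1000L,
                               seed = 1L, conf = 0.95, block_length = NULL,
                               n_permutations = 1000L) {
  sa <- pool_series(series_a); sb <- pool_series(series_b)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  summ_a <- condition_summary(series_a, labels[1])
  summ_b <- condition_summary(series_b, labels[2])
  diff_obs <- summ_a$percent_occupancy_carbon - summ_b$percent_occupancy_carbon
  na <- length(sa$n_carbon); nb <- length(sb$n_carbon)
  set.seed(seed)
  diffs <- vapply(seq_len(n_boot), function(i) {
    ia <- boot_indices(na, block_length)
    ib <- boot_indices(nb, block_length)
    100 * (mean(sa$n_carbon[ia] >= 1L) - mean(sb$n_carbon[ib] >= 1L))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(diffs, c(alpha, 1 - alpha)))
  cor_a <- inverse_correlation(series_a, n_permutations = n_permutations,
                               seed = seed)
  cor_b <- inverse_correlation(series_b, n_permutations = n_permutations,
                               seed = seed + 1L)
  structure(list(conditions = list(summ_a, summ_b),
                 difference_percent_occupancy = diff_obs,
                 ci = ci, conf = conf, n_boot = n_boot,
                 block_length = block_length,
                 correlation = list(cor_a, cor_b)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  a <- x$conditions[[1]]; b <- x$conditions[[2]]
  cat("<comparison_report> ", a$label, " vs ", b$label, "\n", sep = "")
  for (s in x$conditions) {
    cat(sprintf("  %-8s carbon occupancy %5.1f%%  water occupancy %5.1f%%  mean n_water %5.2f  mean n_carbon %5.2f\n",
                s$label, s$percent_occupancy_carbon,
                s$percent_occupancy_water, s$mean_n_water, s$mean_n_carbon))
  }
  cat(sprintf("  difference (carbon occupancy) %.1f points, %d%% CI [%.1f, %.1f]\n",
              x$difference_percent_occupancy, round(100 * x$conf),
              x$ci[1], x$ci[2]))
  for (co in x$correlation) {
    cat(sprintf("  water-carbon Spearman rho = %.3f (p = %.3g)\n",
                co$rho, co$p))
  }
  invisible(x)
}
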