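# Box counting, occupancy series, percent occupancy, wet/dry segmentation
# and rate estimation.

brute_count <- function(pts, box) {
  n <- 0L
  for (i in seq_len(nrow(pts))) {
    if (abs(pts[i, 1]) <= box$lx / 2 && abs(pts[i, 2]) <= box$ly / 2 &&
        pts[i, 3] > box$zmin && pts[i, 3] <= box$zmax)
      n <- n + 1L
  }
  n
}

test_that("count_in_box equals the brute-force loop and handles edges", {
  wb <- water_box()
  expect_identical(count_in_box(matrix(numeric(0), 0, 3), wb), 0L)
  expect_identical(count_in_box(matrix(c(0, 0, 0), 1, 3), wb), 0L)
  # half-open z: zmax inside, zmin outside; lateral faces inclusive
  expect_identical(count_in_box(matrix(c(0, 0, -5), 1, 3), wb), 1L)
  expect_identical(count_in_box(matrix(c(0, 0, -10), 1, 3), wb), 0L)
  expect_identical(count_in_box(matrix(c(10, 10, -7), 1, 3), wb), 1L)
  set.seed(21)
  for (rep in 1:5) {
    pts <- matrix(stats::runif(1500, -20, 20), 500, 3)
    expect_identical(count_in_box(pts, wb), brute_count(pts, wb))
  }
})

test_that("occupancy_series counts planted waters in a minimal system", {
  extra <- data.frame(atom_name = rep(c("OW", "HW1", "HW2"), 3),
                      residue_name = "SOL", residue_id = rep(1:3, each = 3))
  os <- rbind(c(0, 0, -7), c(3, -2, -6), c(-5, 5, -9.5))
  co <- NULL
  for (i in 1:3) co <- rbind(co, os[i, ], os[i, ] + c(0.8, 0.6, 0),
                             os[i, ] + c(-0.8, 0.6, 0))
  sysfr <- anchored_system(extra, co)
  ts <- occupancy_series(list(sysfr$frame), sysfr$system, occupancy_config())
  expect_identical(ts$n_water, 3L)
  expect_identical(ts$n_carbon, 0L)
})

test_that("striding an emitted trajectory halves the series", {
  toy <- build_toy_system(toy_system_spec())
  p <- withr::local_tempfile(fileext = ".pdb")
  simulate_trajectory(toy, dynamics_spec(n_frames = 10L, seed = 4L), p)
  fr <- iterate_frames(toy$system, p, stride = 2)
  ts <- occupancy_series(fr, toy$system)
  expect_length(ts$n_water, 5L)
})

test_that("percent occupancy matches direct ratios and pools replicates", {
  expect_equal(percent_occupancy(ts_from_counts(0:3, c(0L, 0L, 0L, 0L)),
                                 "carbon"), 0)
  expect_equal(percent_occupancy(ts_from_counts(0:3, c(0L, 1L, 2L, 0L)),
                                 "carbon"), 50)
  expect_equal(percent_occupancy(ts_from_counts(c(0L, 5L, 2L, 0L)), "water",
                                 min_count = 2L), 50)
  expect_error(percent_occupancy(list(), "carbon"), "nonempty|empty")
  # complement identity and frame-weighted pooling
  set.seed(13)
  a <- ts_from_counts(rpois(40, 2), rpois(40, 1))
  b <- ts_from_counts(rpois(10, 2), rpois(10, 1))
  pct <- percent_occupancy(list(a, b), "carbon")
  expect_equal(pct + 100 * mean(c(a$n_carbon, b$n_carbon) == 0L), 100)
  expect_equal(pct, (40 * percent_occupancy(a, "carbon") +
                       10 * percent_occupancy(b, "carbon")) / 50)
})

test_that("hysteresis segmentation follows the two-threshold rule", {
  seg <- classify_wetting(ts_from_counts(rep(10L, 6)))
  expect_identical(seg$n_transitions, 0L)
  expect_identical(seg$segments$state, "wet")
  seg <- classify_wetting(ts_from_counts(c(10L, 10L, 0L, 0L, 0L, 10L, 10L)),
                          min_dwell = 1L)
  expect_identical(seg$segments$state, c("wet", "dry", "wet"))
  expect_identical(seg$segments$start, c(1L, 3L, 6L))
  expect_identical(seg$segments$end, c(2L, 5L, 7L))
  expect_identical(seg$n_transitions, 2L)
  # in-band counts (2..3) hold the previous state; leading band frames take
  # the first resolved state
  seg <- classify_wetting(ts_from_counts(c(2L, 3L, 8L, 2L, 2L, 1L, 3L, 9L)),
                          min_dwell = 1L)
  expect_identical(seg$state,
                   c("wet", "wet", "wet", "wet", "wet", "dry", "dry", "wet"))
  expect_error(classify_wetting(ts_from_counts(c(5L, 5L)), dry_max = 4L,
                                wet_min = 4L), "dry_max < wet_min")
  expect_error(classify_wetting(ts_from_counts(7L)), "2 frames")
})

test_that("short segments merge into the longer neighbour", {
  w <- c(rep(10L, 6), 0L, rep(10L, 6))
  seg <- classify_wetting(ts_from_counts(w), min_dwell = 5L)
  expect_identical(seg$segments$state, "wet")
  expect_identical(seg$n_transitions, 0L)
  # tie between neighbours goes to the preceding segment
  w <- c(rep(10L, 4), 0L, 0L, rep(10L, 4))
  seg <- classify_wetting(ts_from_counts(w), min_dwell = 3L)
  expect_identical(seg$segments$state, "wet")
  # a long dry block survives
  w <- c(rep(10L, 8), rep(0L, 8), rep(10L, 8))
  seg <- classify_wetting(ts_from_counts(w), min_dwell = 5L)
  expect_identical(seg$segments$state, c("wet", "dry", "wet"))
})

test_that("raising wet_min never increases total wet time", {
  set.seed(31)
  for (rep in 1:10) {
    w <- rpois(200, 3)
    wet_prev <- Inf
    for (wm in 2:6) {
      seg <- classify_wetting(ts_from_counts(w), dry_max = 1L,
                              wet_min = wm, min_dwell = 1L)
      wet_now <- sum(seg$state == "wet")
      expect_lte(wet_now, wet_prev)
      wet_prev <- wet_now
    }
  }
})

test_that("rate estimates follow the transitions-over-exposure closed form", {
  seg <- classify_wetting(ts_from_counts(rep(10L, 20)))
  r <- estimate_rates(seg, dt = 0.1)
  expect_equal(r$k_wet_to_dry, 0)
  expect_equal(r$wet_fraction, 1)
  expect_true("no wet->dry transitions" %in% r$flags)
  expect_true(is.na(r$se_wet_to_dry))
  # strict alternation: every wet frame exits, so k_wd = 1/dt exactly
  n <- 2000L
  w <- rep(c(10L, 0L), n / 2)
  seg <- classify_wetting(ts_from_counts(w), min_dwell = 1L)
  r <- estimate_rates(seg, dt = 0.1)
  expect_equal(r$k_wet_to_dry, 10)
  expect_equal(r$k_dry_to_wet, 10 * (n / 2 - 1) / (n / 2))
  expect_equal(r$se_wet_to_dry, 10 / sqrt(n / 2))
})

test_that("telegraph rates are recovered from emitted counts", {
  errs_wd <- errs_dw <- numeric(3)
  for (s in 1:3) {
    dyn <- dynamics_spec(k_wet_to_dry = 0.5, k_dry_to_wet = 1.0,
                         n_frames = 10000L, seed = 100L + s)
    sim <- simulate_dynamics(dyn)
    ts <- ts_from_counts(sim$n_water, sim$n_carbon)
    seg <- classify_wetting(ts, min_dwell = 1L)
    r <- estimate_rates(seg, dt = 0.1)
    errs_wd[s] <- r$k_wet_to_dry / 0.5 - 1
    errs_dw[s] <- r$k_dry_to_wet / 1.0 - 1
    # stationary wet fraction within 3 asymptotic standard errors of 2/3
    sd_f <- sqrt(2 * (2 / 3) * (1 / 3) * (1 / 1.5) / 1000)
    expect_lt(abs(r$wet_fraction - 2 / 3), 3 * sd_f)
  }
  expect_lt(abs(mean(errs_wd)), 0.2)
  expect_lt(abs(mean(errs_dw)), 0.2)
})

test_that("segmentation recovers planted states at >= 95% of frames", {
  agree <- numeric(10)
  for (s in 1:10) {
    dyn <- dynamics_spec(k_wet_to_dry = 0.5, k_dry_to_wet = 1.0,
                         lambda_wet = 8, lambda_dry = 0.3,
                         n_frames = 2000L, seed = 500L + s)
    sim <- simulate_dynamics(dyn)
    seg <- classify_wetting(ts_from_counts(sim$n_water, sim$n_carbon),
                            min_dwell = 1L)
    agree[s] <- mean(seg$state == sim$state)
  }
  expect_true(all(agree >= 0.95))
})
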