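# Structure/trajectory readers and writers and their round-trips.

test_that("a minimal PDB water parses with names, residue and count", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  O   HOH A   1       1.000   2.000   3.000  1.00  0.00           O",
    "ATOM      2  H1  HOH A   1       1.800   2.600   3.000  1.00  0.00           H",
    "ATOM      3  H2  HOH A   1       0.200   2.600   3.000  1.00  0.00           H",
    "END"), p)
  st <- read_structure(p)
  expect_equal(st$system$n_atoms, 3L)
  expect_equal(unique(st$system$atoms$residue_name), "HOH")
  expect_equal(st$system$atoms$element, c("O", "H", "H"))
  expect_equal(st$frame$coordinates[1, ], c(1, 2, 3))
})

test_that("empty and missing files raise clear errors", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), p)
  expect_error(read_structure(p), "empty")
  expect_error(read_structure("no/such/file.gro"), "not found")
})

test_that("GRO files written by the generator round-trip", {
  p <- withr::local_tempfile(fileext = ".gro")
  toy <- build_toy_system(toy_system_spec(), path = p)
  rt <- read_structure(p)
  expect_identical(rt$system$atoms$atom_name, toy$system$atoms$atom_name)
  expect_identical(rt$system$atoms$residue_name, toy$system$atoms$residue_name)
  expect_lt(max(abs(rt$frame$coordinates - toy$frame$coordinates)), 0.001)
  expect_equal(rt$frame$box, toy$frame$box)
})

test_that("iterate_frames strides correctly and assigns default times", {
  toy <- build_toy_system(toy_system_spec())
  dyn <- dynamics_spec(n_frames = 10L, seed = 5L)
  p <- withr::local_tempfile(fileext = ".pdb")
  simulate_trajectory(toy, dyn, p)
  f1 <- iterate_frames(toy$system, p, stride = 1)
  expect_length(f1, 10L)
  f3 <- iterate_frames(toy$system, p, stride = 3)
  expect_length(f3, 4L)  # frames 0, 3, 6, 9
  expect_equal(vapply(f3, `[[`, numeric(1), "time"), c(0, 0.3, 0.6, 0.9))
  for (s in 1:7)
    expect_length(iterate_frames(toy$system, p, stride = s),
                  ceiling(10 / s))
})

test_that("atom-count mismatches and GROMACS binary formats are rejected", {
  toy <- build_toy_system(toy_system_spec())
  p <- withr::local_tempfile(fileext = ".pdb")
  simulate_trajectory(toy, dynamics_spec(n_frames = 2L), p)
  small <- water_system(matrix(0, 1, 3))
  expect_error(iterate_frames(small$system, p), "atoms")
  expect_error(iterate_frames(toy$system, "x.xtc"), "not found")
  xtc <- withr::local_tempfile(fileext = ".xtc")
  writeLines("x", xtc)
  expect_error(iterate_frames(toy$system, xtc), "XTC")
})

test_that("a truncated multi-model PDB yields complete frames plus warning", {
  toy <- build_toy_system(toy_system_spec())
  p <- withr::local_tempfile(fileext = ".pdb")
  simulate_trajectory(toy, dynamics_spec(n_frames = 4L), p)
  lines <- readLines(p)
  cut <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[1:(length(lines) - 500)], cut)  # cut into the 4th model
  expect_warning(fr <- iterate_frames(toy$system, cut), "incomplete")
  expect_length(fr, 3L)
})

test_that("the multi-model splitter agrees with bio3d's multi-model reader", {
  toy <- build_toy_system(toy_system_spec())
  p <- withr::local_tempfile(fileext = ".pdb")
  simulate_trajectory(toy, dynamics_spec(n_frames = 5L, seed = 11L), p)
  fr <- iterate_frames(toy$system, p)
  ref <- suppressWarnings(bio3d::read.pdb(p, multi = TRUE, verbose = FALSE))
  for (i in 1:5) {
    expect_equal(fr[[i]]$coordinates,
                 matrix(ref$xyz[i, ], ncol = 3, byrow = TRUE),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("DCD round-trips through bio3d's reader with box intact", {
  toy <- build_toy_system(toy_system_spec())
  dyn <- dynamics_spec(n_frames = 6L, seed = 2L)
  pd <- withr::local_tempfile(fileext = ".dcd")
  pp <- withr::local_tempfile(fileext = ".pdb")
  simulate_trajectory(toy, dyn, pd)
  simulate_trajectory(toy, dyn, pp)
  fd <- iterate_frames(toy$system, pd)
  fp <- iterate_frames(toy$system, pp)
  expect_length(fd, 6L)
  expect_equal(fd[[1]]$box, c(60, 60, 80))
  for (i in 1:6)  # float32 storage vs 3-decimal text
    expect_lt(max(abs(fd[[i]]$coordinates - fp[[i]]$coordinates)), 2e-3)
})

test_that("occupancy CSV round-trips and rejects empty series", {
  ts <- ts_from_counts(c(3L, 0L, 5L), c(0L, 2L, 1L))
  p <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(ts, p)
  expect_identical(readLines(p)[1], "time_ns,n_water,n_carbon")
  rt <- read_series_csv(p)
  expect_identical(rt$n_water, ts$n_water)
  expect_identical(rt$n_carbon, ts$n_carbon)
  expect_equal(rt$times, ts$times)
  empty <- structure(list(times = numeric(0), n_water = integer(0),
                          n_carbon = integer(0), dt = NA_real_, label = ""),
                     class = "occupancy_ts")
  expect_error(write_series_csv(empty, p), "empty")
})

test_that("OpenDX grids round-trip losslessly within float precision", {
  set.seed(42)
  vals <- array(stats::runif(6 * 5 * 4), dim = c(6, 5, 4))
  g <- density_grid(vals, origin = c(-1, 0, 2.5), spacing = 0.5,
                    n_frames = 7L, normalized = TRUE)
  p <- withr::local_tempfile(fileext = ".dx")
  write_grid_dx(g, p)
  g2 <- read_grid_dx(p)
  expect_identical(g2$dims, g$dims)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$spacing, g$spacing)
  expect_identical(g2$n_frames, 7L)
  expect_true(g2$normalized)
  expect_lt(max(abs(g2$values - g$values)), 1e-6)
})
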