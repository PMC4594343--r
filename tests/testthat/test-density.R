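# Density accumulation, bulk normalization, isovalue thresholding.

# frames of bare points as a 1-atom-per-point pseudo water system
point_frames <- function(pts_list) {
  n <- nrow(pts_list[[1]])
  sys <- molecular_system(data.frame(
    atom_name = "OW", residue_name = "SOL", residue_id = seq_len(n)))
  frames <- lapply(pts_list, md_frame)
  list(system = sys, frames = frames,
       sel = select_atoms(sys, "water_oxygen"))
}

test_that("single atoms bin to their voxel with frame averaging", {
  pf <- point_frames(list(matrix(c(0.25, 0.25, 0.25), 1, 3)))
  g <- accumulate_density(pf$frames, pf$system, pf$sel,
                          region = c(0, 2, 0, 2, 0, 2), spacing = 0.5)
  expect_equal(g$values[1, 1, 1], 1)
  expect_equal(sum(g$values), 1)
  pf2 <- point_frames(list(matrix(c(0.25, 0.25, 0.25), 1, 3),
                           matrix(c(10, 10, 10), 1, 3)))
  g2 <- accumulate_density(pf2$frames, pf2$system, pf2$sel,
                           region = c(0, 2, 0, 2, 0, 2), spacing = 0.5)
  expect_equal(g2$values[1, 1, 1], 0.5)
})

test_that("binned density equals a literal per-point histogram", {
  set.seed(5)
  pts <- lapply(1:4, function(i) matrix(stats::runif(1500, 0, 5), 500, 3))
  pf <- point_frames(pts)
  g <- accumulate_density(pf$frames, pf$system, pf$sel,
                          region = c(0, 5, 0, 5, 0, 5), spacing = 0.5)
  oracle <- array(0, dim = c(10, 10, 10))
  for (m in pts) {
    for (i in seq_len(nrow(m))) {
      ii <- floor(m[i, ] / 0.5) + 1
      if (all(ii >= 1) && all(ii <= 10))
        oracle[ii[1], ii[2], ii[3]] <- oracle[ii[1], ii[2], ii[3]] + 1
    }
  }
  expect_equal(g$values, oracle / 4)
  # count conservation: voxel sum = mean in-region points per frame
  inside <- mean(vapply(pts, function(m)
    sum(apply(m, 1, function(p) all(p >= 0 & p < 5))), numeric(1)))
  expect_equal(sum(g$values), inside)
})

test_that("bulk normalization rescales to mean 1 and validates inputs", {
  g <- density_grid(array(3, dim = c(6, 6, 6)), c(0, 0, 0), 0.5)
  gn <- normalize_to_bulk(g, bulk_region = c(0, 3, 0, 3, 0, 3))
  expect_true(all(gn$values == 1))
  expect_true(gn$normalized)
  expect_equal(gn$bulk_stats$mean, 3)
  vals <- array(2, dim = c(6, 6, 6)); vals[1, 1, 1] <- 0.5
  gn <- normalize_to_bulk(density_grid(vals, c(0, 0, 0), 0.5),
                          bulk_region = c(1, 3, 0, 3, 0, 3))
  expect_equal(gn$values[1, 1, 1], 0.25)
  # idempotence up to the bulk tolerance
  gn2 <- normalize_to_bulk(gn, bulk_region = c(1, 3, 0, 3, 0, 3))
  expect_equal(gn2$values, gn$values)
  expect_error(normalize_to_bulk(g, bulk_region = c(0, 1, 0, 1, 0, 1)),
               "100")
  zero <- density_grid(array(0, dim = c(6, 6, 6)), c(0, 0, 0), 0.5)
  expect_error(normalize_to_bulk(zero, c(0, 3, 0, 3, 0, 3)), "bulk mean")
  expect_error(accumulate_density(list(), point_frames(
    list(matrix(0, 1, 3)))$system, atom_set(0L), c(0, 1, 0, 1, 0, 1)),
    "no frames")
})

test_that("binarize thresholds at the isovalue and reports dewetting", {
  ones <- density_grid(array(1, dim = c(4, 4, 4)), c(0, 0, 0), 0.5,
                       normalized = TRUE)
  b <- binarize(ones)
  expect_true(all(b$mask))
  expect_equal(b$dewetted_fraction, 0)
  zeros <- density_grid(array(0, dim = c(4, 4, 4)), c(0, 0, 0), 0.5,
                        normalized = TRUE)
  b <- binarize(zeros)
  expect_false(any(b$mask))
  expect_equal(b$dewetted_fraction, 1)
  expect_error(binarize(density_grid(array(1, dim = c(4, 4, 4)),
                                     c(0, 0, 0), 0.5)), "normalized")
})

test_that("pore-frame grids are invariant under rigid-body motion", {
  toy <- build_toy_system(toy_system_spec())
  p <- withr::local_tempfile(fileext = ".pdb")
  simulate_trajectory(toy, dynamics_spec(n_frames = 5L, seed = 8L), p)
  frames <- iterate_frames(toy$system, p)
  cfg <- occupancy_config()
  sel <- select_atoms(toy$system, "water_oxygen")
  region <- c(-12, 12, -12, 12, -15, 5)
  g0 <- accumulate_density(frames, toy$system, sel, region, 0.5, cfg)
  set.seed(17)
  R <- random_rotation(); tr <- c(5, -8, 12)
  moved <- lapply(frames, function(fr) {
    md_frame(fr$coordinates %*% t(R) +
               matrix(tr, nrow(fr$coordinates), 3, byrow = TRUE))
  })
  g1 <- accumulate_density(moved, toy$system, sel, region, 0.5, cfg)
  expect_equal(g1$values, g0$values)
})

test_that("a planted dry cavity falls below the isovalue after normalization", {
  # bulk-like uniform points everywhere except an empty cavity cube
  set.seed(23)
  pts <- lapply(1:20, function(i) {
    m <- matrix(stats::runif(3 * 16000, 0, 20), ncol = 3)
    cav <- m[, 1] > 8 & m[, 1] < 12 & m[, 2] > 8 & m[, 2] < 12 &
      m[, 3] > 8 & m[, 3] < 12
    m[!cav, , drop = FALSE]
  })
  sys <- molecular_system(data.frame(
    atom_name = "OW", residue_name = "SOL",
    residue_id = seq_len(max(vapply(pts, nrow, integer(1))))))
  frames <- lapply(pts, function(m)
    md_frame(rbind(m, matrix(1e6, nrow(sys$atoms) - nrow(m), 3))))
  sel <- select_atoms(sys, "water_oxygen")
  g <- accumulate_density(frames, sys, sel, region = c(0, 20, 0, 20, 0, 20),
                          spacing = 1)
  gn <- normalize_to_bulk(g, bulk_region = c(0, 20, 0, 20, 0, 6))
  b <- binarize(gn, isovalue = 0.5, cavity_region = c(9, 11, 9, 11, 9, 11))
  expect_equal(b$dewetted_fraction, 1)
  bulk_b <- binarize(gn, isovalue = 0.5, cavity_region = c(1, 19, 1, 19, 1, 5))
  expect_lt(bulk_b$dewetted_fraction, 0.01)
})
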