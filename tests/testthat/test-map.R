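test_that("MRC mode-2 round trip preserves values and header", {
  set.seed(3)
  m <- density_map(array(rnorm(24^3), dim = c(24, 24, 24)),
                   spacing = c(1.1, 0.9, 1.3), origin = c(-4, 2, 7))
  tf <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, tf)
  m2 <- read_map(tf)
  expect_lt(max(abs(m$grid - m2$grid)), 1e-6)   # float32 storage
  expect_equal(m2$origin, m$origin)
  expect_equal(m2$spacing, m$spacing, tolerance = 1e-6)
})

test_that("corrupt and non-orthogonal maps are rejected", {
  tf <- withr::local_tempfile(fileext = ".mrc")
  writeBin(as.raw(rep(0, 600)), tf)
  expect_error(read_map(tf), "corrupt|format|mode")
  # valid map, then poison the cell angles in the header (words 17-19)
  m <- density_map(array(0, dim = c(4, 4, 4)), spacing = c(1, 1, 1))
  write_map(m, tf)
  con <- file(tf, "r+b"); seek(con, 4 * 13, rw = "write")
  writeBin(c(90, 90, 120), con, size = 4, endian = "little"); close(con)
  expect_error(read_map(tf), "orthogonal|unsupported")
})

test_that("blurring a point source gives the analytic Gaussian width", {
  d <- c(64, 64, 64); sp <- 0.5
  g <- array(0, dim = d); g[33, 33, 33] <- 1
  m <- density_map(g, spacing = rep(sp, 3))
  mb <- sharpen_blur(m, 200)
  idx <- which(mb$grid > max(mb$grid) * 1e-4, arr.ind = TRUE)
  r2 <- rowSums((sweep(idx, 2, c(33, 33, 33)) * sp)^2)
  fit <- stats::lm(log(mb$grid[idx]) ~ r2)
  sigma_fit <- sqrt(-1 / (2 * coef(fit)[[2]]))
  expect_equal(sigma_fit, sqrt(200 / (8 * pi^2)), tolerance = 0.02)
})

test_that("blur factors compose, invert, and preserve the mean", {
  set.seed(5)
  m <- density_map(array(rnorm(20^3), dim = c(20, 20, 20)),
                   spacing = c(0.8, 0.8, 0.8))
  expect_lt(max(abs(sharpen_blur(m, 0)$grid - m$grid)), 1e-10)
  twice <- sharpen_blur(sharpen_blur(m, 100), 100)
  expect_rms_close(twice$grid, sharpen_blur(m, 200)$grid, 1e-5)
  undone <- sharpen_blur(sharpen_blur(m, 50), -50)
  expect_rms_close(undone$grid, m$grid, 1e-5)
  expect_equal(mean(sharpen_blur(m, 150)$grid), mean(m$grid))
  expect_error(sharpen_blur(m, NaN), "finite")
})

test_that("reciprocal-space resampling leaves original nodes unchanged", {
  d <- c(32, 32, 32)
  g <- array(0, dim = d); g[17, 17, 17] <- 1
  m <- density_map(g, spacing = rep(0.5, 3))
  ref <- sharpen_blur(m, 200)
  fine <- sharpen_blur(m, 200, resample_factor = 2)
  expect_equal(dim(fine$grid), d * 2)
  expect_equal(fine$cell, m$cell)
  at_nodes <- fine$grid[seq(1, 64, 2), seq(1, 64, 2), seq(1, 64, 2)]
  expect_lt(max(abs(at_nodes - ref$grid)), 1e-5)
})

test_that("multi_sharpen matches per-call sharpen_blur", {
  set.seed(6)
  m <- density_map(array(rnorm(16^3), dim = c(16, 16, 16)),
                   spacing = c(1, 1, 1))
  maps <- multi_sharpen(m, c(-50, 0, 50, 100))
  expect_length(maps, 4)
  expect_lt(max(abs(maps[[2]]$grid - m$grid)), 1e-10)
  for (k in c(1, 3, 4))
    expect_lt(max(abs(maps[[k]]$grid -
                        sharpen_blur(m, c(-50, 0, 50, 100)[k])$grid)), 1e-6)
  expect_error(multi_sharpen(m, numeric(0)), "non-empty")
})

test_that("trilinear interpolation: nodes, midpoints, out of bounds", {
  m <- density_map(array(0:7, dim = c(2, 2, 2)), spacing = c(1, 1, 1))
  expect_equal(interpolate_density(m, c(1, 0, 0)), 1, ignore_attr = TRUE)
  expect_equal(interpolate_density(m, c(0.5, 0, 0)), 0.5, ignore_attr = TRUE)
  v <- interpolate_density(m, c(99, 0, 0))
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "out_of_bounds"))
})

test_that("density_fit_score is occupancy-linear and prefers the truth pose", {
  one <- make_ideal_polypeptide(1)
  one$atoms <- one$atoms[one$atoms$atom == "CA", , drop = FALSE]
  m <- synthesize_map(one, spacing = 0.4)
  s1 <- density_fit_score(m, one)
  half <- one; half$atoms$occ <- 0.5
  expect_equal(density_fit_score(m, half), s1 / 2)
  zero <- density_map(array(0, dim = c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_equal(density_fit_score(zero, one), 0)
  expect_error(density_fit_score(m, one$atoms[0, ]), "empty")
  truth <- helix20
  expect_gt(density_fit_score(helix20_map, truth),
            density_fit_score(helix20_map,
                              perturb_structure(truth,
                                                translation = c(5, 0, 0))))
})

test_that("blob search finds the centre, honours first-transition and step halving", {
  one <- make_ideal_polypeptide(1)
  one$atoms <- one$atoms[one$atoms$atom == "CA", , drop = FALSE]
  m <- synthesize_map(one, spacing = 0.4)
  ap <- c(one$atoms$x, one$atoms$y, one$atoms$z)
  hit <- find_blob_along_segment(m, ap + c(-8, 0.1, 0), ap + c(8, 0.1, 0), 1)
  expect_lt(vnorm_test(hit$centre - ap), max(m$spacing))
  expect_gte(hit$peak, 1)
  expect_null(find_blob_along_segment(m, ap + c(-8, 0, 0), ap + c(8, 0, 0),
                                      99))
  # half-step invariance
  hit2 <- find_blob_along_segment(m, ap + c(-8, 0.1, 0), ap + c(8, 0.1, 0),
                                  1, step = min(m$spacing) / 4)
  expect_lt(vnorm_test(hit2$centre - hit$centre), max(m$spacing) / 2)
  # two blobs: the one nearer the front point wins
  two <- one; two$atoms <- rbind(two$atoms, two$atoms)
  two$atoms[2, c("x", "y", "z")] <- two$atoms[1, c("x", "y", "z")] + c(6, 0, 0)
  m2 <- synthesize_map(two, spacing = 0.4)
  hfront <- find_blob_along_segment(m2, ap + c(-8, 0.1, 0),
                                    ap + c(12, 0.1, 0), 1)
  expect_lt(vnorm_test(hfront$centre - ap), 1)
  hback <- find_blob_along_segment(m2, ap + c(12, 0.1, 0),
                                   ap + c(-8, 0.1, 0), 1)
  expect_lt(vnorm_test(hback$centre - (ap + c(6, 0, 0))), 1)
})
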