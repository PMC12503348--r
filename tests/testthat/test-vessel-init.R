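test_that("distance transform matches the brute-force oracle", {
  set.seed(7)
  for (rep in 1:3) {
    px <- matrix(as.numeric(stats::runif(30 * 24) < 0.4), 30, 24)
    expect_equal(distance_transform(px), edt_brute(px), tolerance = 1e-12)
  }
  # empty mask -> all zeros
  expect_true(all(distance_transform(matrix(0, 10, 10)) == 0))
  # single isolated vessel pixel: radius ~ one pixel
  px1 <- matrix(0, 9, 9); px1[5, 5] <- 1
  m1 <- vessel_mask(px1, pixel_size = 3)
  expect_equal(max(local_radius(m1)), 3)   # 1 px * 3 um
})

test_that("stripe skeleton carries the local half-width", {
  r <- 3                       # stripe of width 2r+1 = 7 px
  px <- matrix(0, 40, 20)
  px[, 7 + seq_len(2 * r + 1)] <- 1
  m <- vessel_mask(px, pixel_size = 2)
  rad <- local_radius(m)
  skel_vals <- rad[rad > 0]
  expect_gt(length(skel_vals), 0)
  # EDT convention: distance to the nearest background pixel = (r+1) px;
  # within one pixel of r * pixel_size
  expect_true(all(abs(skel_vals - r * 2) <= 2 + 1e-12))
  # the skeleton lies on the stripe centerline away from the ends
  ctr <- which(rad > 0, arr.ind = TRUE)
  mid <- ctr[ctr[, 1] > 5 & ctr[, 1] < 35, ]
  expect_true(all(mid[, 2] == 7 + r + 1))
})

test_that("2D reconstruction maps vessel pixels to +1 and the rest to -1", {
  u <- unit_system()
  d <- sim_domain(c(100 / 800, 100 / 800), h = 2 / 800)
  # all-zero and all-one masks
  m0 <- vessel_mask(matrix(0, 60, 60), pixel_size = 2)
  expect_true(all(reconstruct_field_2d(m0, d, u) == -1))
  m1 <- suppressWarnings(vessel_mask(matrix(1, 60, 60), pixel_size = 2))
  expect_true(all(reconstruct_field_2d(m1, d, u) == 1))
  # 10-px stripe at 1 um/px -> 10 um band
  px <- matrix(0, 120, 120)
  px[51:60, ] <- 1
  ms <- vessel_mask(px, pixel_size = 1)
  cf <- reconstruct_field_2d(ms, d, u)
  ax_um <- grid_axes(d)[[1]] * 800
  in_band <- ax_um > 50 & ax_um < 60
  expect_true(all(cf[in_band, ] == 1))
  out_band <- ax_um < 49 | ax_um > 61
  expect_true(all(cf[out_band, ] == -1))
  # a mask smaller than the domain is rejected
  expect_error(reconstruct_field_2d(vessel_mask(matrix(0, 10, 10), 1), d, u),
               "cover")
})

test_that("3D reconstruction builds a tube of the local radius", {
  u <- unit_system()
  d <- sim_domain(c(60, 60, 40) / 800, h = 2 / 800)
  px <- matrix(0, 40, 40)
  px[, 16:20] <- 1            # straight stripe, width 10 um at 2 um/px
  m <- vessel_mask(px, pixel_size = 2)
  z0 <- 20 / 800
  cf <- reconstruct_field_3d(m, d, z0 = z0, units = u)
  # oracle: union of balls = distance to the center line <= 5 um
  ax <- lapply(grid_axes(d), function(a) a * 800)
  axis_y <- 17.5 * 2          # stripe center in um (pixel-center convention)
  for (probe in list(c(30, axis_y, 20, TRUE),      # on the axis
                     c(30, axis_y + 8, 20, FALSE), # 8 um off-axis
                     c(30, axis_y, 28, FALSE))) {  # 8 um along z
    i <- round(probe[1:3] / (2)) + 1
    expect_equal(cf[i[1], i[2], i[3]] == 1, as.logical(probe[4]),
                 info = paste(probe, collapse = ","))
  }
  # empty mask -> all -1
  cf0 <- reconstruct_field_3d(vessel_mask(matrix(0, 40, 40), 2), d,
                              z0 = z0, units = u)
  expect_true(all(cf0 == -1))
  expect_error(reconstruct_field_3d(m, d, z0 = 10, units = u), "z0")
})

test_that("projected 3D reconstruction conservatively recovers the 2D region", {
  u <- unit_system()
  mask <- synth_plexus(n_vessels = 3, width_range = c(8, 16), size_px = 64,
                       pixel_size = 2, avascular_radius = 30, seed = 5)
  ext <- dim(mask$pixels) * 2 / 800
  d2 <- sim_domain(ext, h = 2 / 800)
  d3 <- sim_domain(c(ext, 40 / 800), h = 2 / 800)
  c2 <- reconstruct_field_2d(mask, d2, u)
  c3 <- reconstruct_field_3d(mask, d3, units = u)
  proj <- apply(c3 == 1, c(1, 2), any)
  # every projected vessel node is within one grid cell of a 2D vessel node
  near2 <- c2 == 1
  grown <- near2
  n1 <- nrow(near2); n2 <- ncol(near2)
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                  c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    g <- matrix(FALSE, n1, n2)
    si <- max(1, 1 + sh[1]):min(n1, n1 + sh[1])
    sj <- max(1, 1 + sh[2]):min(n2, n2 + sh[2])
    g[si, sj] <- near2[si - sh[1], sj - sh[2]]
    grown <- grown | g
  }
  expect_true(all(!proj | grown))
  # and the projection covers most of the 2D region (skeleton carries the
  # radius, so thin features may shrink by up to a cell)
  expect_gt(sum(proj & near2) / sum(near2), 0.7)
})

test_that("synthetic plexus is deterministic and honours its constraints", {
  m1 <- synth_plexus(n_vessels = 3, width_range = c(5, 20), size_px = 128,
                     pixel_size = 2, avascular_radius = 60, seed = 1)
  m2 <- synth_plexus(n_vessels = 3, width_range = c(5, 20), size_px = 128,
                     pixel_size = 2, avascular_radius = 60, seed = 1)
  expect_identical(m1$pixels, m2$pixels)
  m3 <- synth_plexus(n_vessels = 3, width_range = c(5, 20), size_px = 128,
                     pixel_size = 2, avascular_radius = 60, seed = 2)
  expect_false(identical(m1$pixels, m3$pixels))
  # no vessel pixel inside the avascular disk
  idx <- which(m1$pixels == 1, arr.ind = TRUE)
  ctr_um <- 128 * 2 / 2
  dist_um <- sqrt(((idx[, 1] - 0.5) * 2 - ctr_um)^2 +
                    ((idx[, 2] - 0.5) * 2 - ctr_um)^2)
  expect_true(all(dist_um >= 60))
  # width audit: per-component max EDT within [w_min/2, w_max/2] +- 1 px
  # (pad with background so vessels clipped at the image border are not
  # credited with inflated radii)
  padded <- matrix(0, 132, 132)
  padded[3:130, 3:130] <- m1$pixels
  comp <- label_components(padded)
  edt <- distance_transform(padded) * 2   # um
  for (k in seq_len(max(comp))) {
    mx <- max(edt[comp == k])
    expect_gte(mx, 5 / 2 - 2)
    expect_lte(mx, 20 / 2 + 2)
  }
  # infeasible spec errors after bounded retries
  expect_error(synth_plexus(n_vessels = 8, width_range = c(30, 40),
                            size_px = 32, pixel_size = 2,
                            avascular_radius = 30, seed = 1,
                            max_retries = 3),
               "infeasible|could not place")
})
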