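test_that("circle init is a signed distance with a closed zero level", {
  st <- init_level_set(c(64, 64), gac_config(radius_frac = 20 / 64))
  expect_equal(st$phi[33, 33], 20, tolerance = 0.8)  # near-center pixel
  expect_lt(st$phi[1, 1], 0)

  # boundary-length oracle: count sign-change interfaces ~ perimeter;
  # the L1 interface count of a digital circle is 8r (4/pi times 2*pi*r)
  flips <- sum(diff(sign(st$phi)) != 0) + sum(apply(st$phi, 1, function(r) sum(diff(sign(r)) != 0)))
  expect_equal(flips, 8 * 20, tolerance = 0.15)

  chk <- init_level_set(c(32, 32), gac_config(init = "checkerboard", checker_period = 8))
  expect_equal(sign(chk$phi[4, 4]), -sign(chk$phi[12, 4]))

  expect_error(init_level_set(c(16, 16), gac_config(radius_frac = 0.9)), "exceeds")
  expect_error(init_level_set(c(4, 4), gac_config()), "8 x 8")
})

test_that("region_means splits means by the sign of phi", {
  st <- init_level_set(c(16, 16), gac_config())
  two <- raster_image(matrix(as.numeric(st$phi > 0), 16, 16))
  m <- region_means(two, st)
  expect_equal(unname(m), c(0, 1))

  const <- raster_image(matrix(0.4, 16, 16))
  expect_equal(unname(region_means(const, st)), c(0.4, 0.4))

  img <- random_gray(8, 16)
  phi <- withr::with_seed(9, matrix(stats::rnorm(256), 16, 16))
  m <- region_means(img, phi)
  expect_equal(m[["m2"]], mean(img$pixels[phi > 0]))
  expect_equal(m[["m1"]], mean(img$pixels[phi <= 0]))

  expect_error(region_means(img, matrix(1, 16, 16)), "degenerate")
})

test_that("chan_vese_energy matches direct summation and is linear in beta", {
  st <- init_level_set(c(16, 16), gac_config())
  piecewise <- raster_image(matrix(as.numeric(st$phi > 0), 16, 16))
  expect_equal(chan_vese_energy(piecewise, st, beta = 0), 0)

  len <- contour_length(st$phi)
  expect_equal(chan_vese_energy(piecewise, st, beta = 2), 2 * len, tolerance = 1e-12)

  # random instance against an independent accumulation oracle
  img <- random_gray(21, 8)
  phi <- withr::with_seed(22, matrix(stats::rnorm(64), 8, 8))
  m1 <- mean(img$pixels[phi <= 0]); m2 <- mean(img$pixels[phi > 0])
  acc <- 0
  for (i in 1:8) for (j in 1:8) {
    acc <- acc + if (phi[i, j] > 0) (img$pixels[i, j] - m2)^2 else (img$pixels[i, j] - m1)^2
  }
  beta <- 0.7
  expect_equal(chan_vese_energy(img, phi, beta), acc + beta * contour_length(phi),
               tolerance = 1e-10)
})

test_that("evolve_step forces move the contour toward bright objects", {
  # perfectly partitioned image, beta 0: sign pattern is a fixed point
  st <- init_level_set(c(16, 16), gac_config())
  img <- raster_image(matrix(as.numeric(st$phi > 0), 16, 16))
  st2 <- evolve_step(img, st, gac_config(beta = 0, reinit_every = 0))
  expect_identical(st2$phi > 0, st$phi > 0)
  expect_equal(st2$iteration, 1L)
  expect_length(st2$energy_trace, 1L)

  # 1-D-style profile: bright band on the right, contour initialized short
  # of it; the data force must be positive (grow) on bright outside pixels
  prof <- raster_image(matrix(rep(c(rep(0.2, 8), rep(0.9, 8)), each = 16), 16, 16))
  phi0 <- matrix(-1, 16, 16); phi0[, 11:16] <- 1  # inside = right part of band
  m <- region_means(prof, phi0)
  force <- (prof$pixels - m[["m1"]])^2 - (prof$pixels - m[["m2"]])^2
  expect_true(all(force[, 9:10] > 0))   # bright outside columns pulled in
  expect_true(all(force[, 1:8] < 0))    # dark outside columns pushed out
})

test_that("energy trace is non-increasing on seeded noisy disks", {
  for (seed in c(2, 9, 17)) {
    d <- make_noisy_disk(seed)
    seg <- gac_segment(d$img, gac_config())
    rel <- diff(seg$energy_trace) / pmax(abs(utils::head(seg$energy_trace, -1)), 1)
    expect_lte(max(rel), 1e-6)
    expect_lte(seg$final_energy, seg$energy_trace[1])
  }
})

test_that("gac_segment recovers disks in either polarity and flags degenerates", {
  d <- make_noisy_disk(41)
  seg <- gac_segment(d$img, gac_config())
  expect_gte(dice_coefficient(seg$mask, d$truth), 0.95)
  # m1/m2 exactness against the returned mask
  expect_equal(seg$m2, mean(to_grayscale(d$img)$pixels[seg$mask]))
  expect_equal(seg$m1, mean(to_grayscale(d$img)$pixels[!seg$mask]))

  inv <- d
  inv$img$pixels <- 1 - inv$img$pixels
  seg_inv <- gac_segment(inv$img, gac_config())
  expect_gte(dice_coefficient(seg_inv$mask, d$truth), 0.95)

  expect_error(gac_segment(raster_image(matrix(0.5, 32, 32)), gac_config()),
               "degenerate")
})

test_that("length penalty smooths boundaries (beta = 0 never smoother than 0.5)", {
  perim_ratio <- function(mask) {
    flips <- sum(abs(diff(mask))) + sum(apply(mask, 1, function(r) sum(abs(diff(r)))))
    flips / sum(mask)
  }
  worse <- 0
  for (seed in 1:5) {
    d <- make_noisy_disk(seed, sd = 0.15)  # rough noise so smoothing matters
    m0 <- gac_segment(d$img, gac_config(beta = 0))$mask
    m5 <- gac_segment(d$img, gac_config(beta = 0.5))$mask
    worse <- worse + (perim_ratio(m5) > perim_ratio(m0))
  }
  expect_lte(worse, 0)
})

test_that("postprocess_mask removes specks, fills holes, keeps idempotence", {
  mask <- matrix(FALSE, 32, 32)
  mask[8:24, 8:24] <- TRUE    # large blob
  mask[14:17, 14:17] <- FALSE # interior hole
  mask[2, 2] <- TRUE          # tiny speck
  out <- postprocess_mask(mask, min_area_fraction = 0.01)
  expect_false(out[2, 2])
  expect_true(all(out[14:17, 14:17]))          # hole filled
  expect_equal(sum(out), 17L * 17L)
  expect_identical(postprocess_mask(out, 0.01), out)  # idempotent on clean mask

  expect_error(postprocess_mask(matrix(FALSE, 8, 8), 0.01), "empty")
})

test_that("extract_roi masks pixels and validates shapes", {
  img <- random_rgb(5, 12)
  full <- matrix(TRUE, 12, 12)
  expect_equal(extract_roi(img, full)$pixels, img$pixels)

  half <- matrix(rep(c(TRUE, FALSE), each = 6), 12, 12)
  out <- extract_roi(img, half)
  expect_true(all(out$pixels[!half] == 0))
  expect_equal(out$pixels[, , 2][half], img$pixels[, , 2][half])

  # support equality on a random mask
  rmask <- withr::with_seed(6, matrix(stats::runif(144) > 0.5, 12, 12))
  out <- extract_roi(img, rmask)
  sup <- apply(out$pixels, c(1, 2), function(v) any(v != 0))
  expect_true(all(sup[!rmask] == FALSE))

  expect_error(extract_roi(img, matrix(TRUE, 4, 4)), "does not match")
})
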