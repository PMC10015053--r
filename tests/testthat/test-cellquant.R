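# cell_quant: N/C ratio, dot density, FA counts, coherency, spreading

test_that("nc_ratio: construction arithmetic, identity, recovery sweep", {
  ci <- synth_cell_image(nuc_intensity = 100, cyto_intensity = 50, noise_sd = 0,
                         seed = 1)
  expect_equal(nc_ratio(stack_plane(ci$stack, 2), ci$nucleus_mask, ci$cell_mask),
               2.0, tolerance = 1e-12)
  # uniform image: ratio 1 (background taken outside the cell)
  msk_n <- ci$nucleus_mask$labels > 0; msk_c <- ci$cell_mask$labels > 0
  uni <- matrix(80, nrow(msk_n), ncol(msk_n))
  expect_equal(nc_ratio(uni, msk_n, msk_c, background = 0), 1.0)
  # sweep of true ratios recovered within 2% at mild noise
  for (tr in c(0.5, 1, 2, 4)) {
    cs <- synth_cell_image(nuc_intensity = 100 * tr, cyto_intensity = 100,
                           noise_sd = 5, seed = 40 + round(10 * tr))
    got <- nc_ratio(stack_plane(cs$stack, 2), cs$nucleus_mask, cs$cell_mask)
    expect_lt(abs(got / tr - 1), 0.02)
  }
  expect_error(nc_ratio(uni, msk_c, msk_c), "cytoplasm")
})

test_that("nc_ratio invariances: positive scaling; subtracted offset", {
  ci <- synth_cell_image(nuc_intensity = 120, cyto_intensity = 60, noise_sd = 3,
                         seed = 2)
  img <- stack_plane(ci$stack, 2)
  base <- nc_ratio(img, ci$nucleus_mask, ci$cell_mask, background = 0)
  expect_equal(nc_ratio(img * 2.5, ci$nucleus_mask, ci$cell_mask, background = 0),
               base, tolerance = 1e-12)
  expect_equal(nc_ratio(img + 30, ci$nucleus_mask, ci$cell_mask, background = 30),
               base, tolerance = 1e-12)
})

test_that("dot_density: construction arithmetic and intensity linearity", {
  img <- matrix(0, 40, 40)
  msk <- matrix(FALSE, 40, 40); msk[11:30, 16:35] <- TRUE  # 400 px = 100 um^2
  rows <- c(15, 25); cols <- c(18, 22, 26, 30, 33)
  for (r in rows) for (c in cols) img[r, c] <- 100
  d <- dot_density(img, msk, pixel_size_um = 0.5, threshold_mode = "absolute",
                   threshold = 0)
  expect_equal(d$n_dots, 10)
  expect_equal(d$total_dot_intensity, 1000)
  expect_equal(d$density_per_um2, 10.0)
  # doubling dot intensity doubles density at fixed geometry
  d2 <- dot_density(img * 2, msk, pixel_size_um = 0.5,
                    threshold_mode = "absolute", threshold = 0)
  expect_equal(d2$density_per_um2, 20.0)
  # empty nucleus signal: zero density
  d0 <- dot_density(matrix(0, 40, 40), msk, pixel_size_um = 0.5,
                    threshold_mode = "absolute", threshold = 0)
  expect_equal(d0$n_dots, 0)
  expect_equal(d0$density_per_um2, 0)
  expect_error(dot_density(img, matrix(FALSE, 40, 40), pixel_size_um = 0.5),
               "zero-area")
  # two conditions at densities d and d/2: medians ordered
  hi <- sapply(1:5, function(s) {
    im <- matrix(0, 40, 40)
    set.seed(s); pos <- sample(which(msk), 12)
    im[pos] <- 100
    dot_density(im, msk, 0.5, "absolute", threshold = 0)$density_per_um2
  })
  lo <- sapply(1:5, function(s) {
    im <- matrix(0, 40, 40)
    set.seed(100 + s); pos <- sample(which(msk), 6)
    im[pos] <- 100
    dot_density(im, msk, 0.5, "absolute", threshold = 0)$density_per_um2
  })
  expect_gt(median(hi), median(lo))
})

test_that("count_focal_adhesions equals flood-fill oracle; inclusive area rule", {
  set.seed(14)
  for (rep in 1:4) {
    bin <- matrix(runif(64 * 64) < 0.12, 64, 64)
    img <- bin * 100
    got <- count_focal_adhesions(img, matrix(TRUE, 64, 64), min_area_um2 = 0,
                                 pixel_size_um = 1, threshold_mode = "absolute",
                                 threshold = 50)
    expect_equal(got, flood_count(bin))
  }
  # blank image: zero
  expect_equal(count_focal_adhesions(matrix(0, 32, 32), matrix(TRUE, 32, 32),
                                     pixel_size_um = 1), 0L)
  # components at exactly min_area are counted (inclusive)
  img <- matrix(0, 20, 20); img[5, 5] <- 100; img[10, 10:11] <- 100
  n1 <- count_focal_adhesions(img, matrix(TRUE, 20, 20), min_area_um2 = 1,
                              pixel_size_um = 1, threshold_mode = "absolute",
                              threshold = 50)
  expect_equal(n1, 2L)   # 1-px and 2-px components, min area 1 px^2
  n2 <- count_focal_adhesions(img, matrix(TRUE, 20, 20), min_area_um2 = 2,
                              pixel_size_um = 1, threshold_mode = "absolute",
                              threshold = 50)
  expect_equal(n2, 1L)   # 2-px component area == min_area -> counted
  # synthetic fixture: 20 high-contrast blobs
  ci <- synth_cell_image(n_fa_blobs = 20, seed = 3)
  expect_equal(count_focal_adhesions(stack_plane(ci$stack, 3), ci$cell_mask), 20L)
})

test_that("coherency: stripes ~1, noise ~0, rotation- and scale-invariant", {
  cs <- synth_cell_image(actin_pattern = "stripes", seed = 4)
  co_stripe <- actin_coherency(stack_plane(cs$stack, 4), cs$cell_mask)
  expect_gt(co_stripe, 0.95)
  cn <- synth_cell_image(actin_pattern = "isotropic", seed = 4)
  co_noise <- actin_coherency(stack_plane(cn$stack, 4), cn$cell_mask)
  expect_lt(co_noise, 0.2)
  # stripes at 37 degrees: same coherency within 1% (up to resampling)
  cr <- synth_cell_image(actin_pattern = "stripes", stripe_angle = 37 * pi / 180,
                         seed = 4)
  co_rot <- actin_coherency(stack_plane(cr$stack, 4), cr$cell_mask)
  expect_lt(abs(co_rot - co_stripe), 0.01)
  # intensity scaling leaves coherency fixed
  expect_equal(actin_coherency(stack_plane(cs$stack, 4) * 4.2, cs$cell_mask),
               co_stripe, tolerance = 1e-12)
  expect_error(actin_coherency(matrix(1, 48, 48), matrix(TRUE, 48, 48)), "flat")
})

test_that("spreading_ratio is plain area arithmetic", {
  m0 <- matrix(FALSE, 30, 30); m0[1:10, 1:10] <- TRUE
  m1 <- matrix(FALSE, 30, 30); m1[1:20, 1:20] <- TRUE
  expect_equal(spreading_ratio(m0, m1), 4.0)
  expect_equal(spreading_ratio(m0, m0), 1.0)
  m2 <- matrix(FALSE, 30, 30); m2[1:10, 1:15] <- TRUE
  expect_equal(spreading_ratio(m2, m0), 100 / 150)
  expect_error(spreading_ratio(matrix(FALSE, 5, 5), m0), "empty t0")
})
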