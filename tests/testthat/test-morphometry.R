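# nuclear_morphometry: EOP (polygon + skeleton), orientation, polarity
# maps, front/rear and condition tests

test_that("EOP: convex shapes score exactly 1; slit square matches closed form", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- cbind(5 + 3 * cos(th), 5 + 3 * sin(th))
  g <- compute_eop(circ)
  expect_identical(g$eop, 1)
  expect_identical(g$excess, 0)
  # unit square with a zero-width slit of depth 0.25 traversed twice:
  # eop = (4 + 0.5) / 4 = 1.125
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0.5, 1), c(0.5, 0.75),
              c(0.5, 1), c(0, 1))
  g2 <- compute_eop(sq)
  expect_equal(g2$eop, 1.125, tolerance = 1e-12)
  # same geometry via the internal-segments route (single-count convention)
  g3 <- compute_eop(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                    internal_segments = list(rbind(c(0.5, 1), c(0.5, 0.75))))
  expect_equal(g3$eop, (4 + 0.25) / 4, tolerance = 1e-12)
  expect_error(compute_eop(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
  expect_error(compute_eop(rbind(c(0, 0), c(1, 1))), ">= 3 vertices")
})

test_that("polygon EOP equals the arc-length oracle and is invariant/monotone", {
  set.seed(8)
  for (rep in 1:5) {
    nv <- sample(10:100, 1)
    th <- sort(runif(nv, 0, 2 * pi))
    r <- 3 + runif(nv, -0.5, 0.5)
    poly <- cbind(r * cos(th), r * sin(th))
    segs <- list(rbind(c(0, 0), c(1, 0.3)), rbind(c(-1, 0), c(-0.2, -0.8)))
    g <- compute_eop(poly, segs)
    hull <- poly[grDevices::chull(poly), ]
    oracle <- (arc_length(poly) + arc_length(segs[[1]], closed = FALSE) +
                 arc_length(segs[[2]], closed = FALSE)) / arc_length(hull)
    expect_equal(g$eop, oracle, tolerance = 1e-12)
    # rigid motion + uniform scaling invariance
    phi <- runif(1, 0, 2 * pi); sc <- runif(1, 0.5, 3)
    rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    move <- function(p) sweep(sc * p %*% rot, 2, c(10, -4), `+`)
    g2 <- compute_eop(move(poly), lapply(segs, move))
    expect_equal(g2$eop, g$eop, tolerance = 1e-9)
    # longer internal segments never decrease EOP
    g3 <- compute_eop(poly, c(segs, list(rbind(c(0, 0), c(0, 1)))))
    expect_gte(g3$eop, g$eop)
  }
})

test_that("skeleton EOP recovers generator truth within 3% at 0.1 um/px", {
  for (d in c(0, 1, 2, 3)) {
    inv <- if (d > 0) data.frame(angle = 1.1, depth_um = d, width_um = 0.2)
           else NULL
    nu <- synth_nucleus(a_um = 8, b_um = 5, invaginations = inv,
                        pixel_size_um = 0.1)
    g <- compute_eop_skeleton(nu$skeleton, nu$mask)
    expect_lt(abs(g$eop / nu$truth$eop_skeleton - 1), 0.03)
  }
  # skeleton without a ring: warning + mask-boundary fallback
  nu <- synth_nucleus(a_um = 5, b_um = 5, pixel_size_um = 0.2)
  empty_skel <- matrix(FALSE, nrow(nu$skeleton), ncol(nu$skeleton))
  expect_warning(g2 <- compute_eop_skeleton(empty_skel, nu$mask), "ring")
  expect_gt(g2$eop, 0.9)
})

test_that("orient_front maps the Golgi direction to +x", {
  msk <- matrix(FALSE, 21, 21); msk[6:16, 6:16] <- TRUE   # centroid (10, 10)
  # golgi due east: identity
  expect_equal(orient_front(msk, c(20, 10))$theta, 0)
  # golgi due north (larger y): theta pi/2, so rotating by -theta maps to +x
  expect_equal(orient_front(msk, c(10, 20))$theta, pi / 2)
  # explicit pattern axis with golgi choosing the sign
  o <- orient_front(msk, golgi_centroid = c(0, 10), pattern_axis = 0)
  expect_equal(cos(o$theta), -1, tolerance = 1e-12)
  expect_error(orient_front(msk, c(10, 10)), "coincides")
  expect_error(orient_front(msk), "golgi_centroid or pattern_axis")
})

test_that("polarity_map selects exactly ceil(0.2 n) pixels, deterministic ties", {
  set.seed(12)
  msk <- matrix(FALSE, 30, 30); msk[8:22, 8:22] <- TRUE
  n <- sum(msk)
  sig <- matrix(0, 30, 30); sig[msk] <- sample(1:5, n, TRUE)  # heavy ties
  pm <- polarity_map(list(list(signal = sig, mask = msk, theta = 0)),
                     quantile = 0.80)
  expect_equal(length(pm$per_cell_axis_samples[[1]]), ceiling(0.2 * n))
  # rerun: identical selection (ties broken by intensity then raster order)
  pm2 <- polarity_map(list(list(signal = sig, mask = msk, theta = 0)))
  expect_identical(pm$per_cell_axis_samples, pm2$per_cell_axis_samples)
  expect_true(all(abs(unlist(pm$per_cell_axis_samples)) <= 1))
  # tiny mask is skipped
  tiny <- matrix(FALSE, 30, 30); tiny[1:2, 1:2] <- TRUE
  expect_message(
    pm3 <- polarity_map(list(list(signal = sig, mask = msk, theta = 0),
                             list(signal = sig, mask = tiny, theta = 0))),
    "skipped")
  expect_equal(pm3$n_cells, 1)
})

test_that("front_rear_test: mirror symmetry, extremes, label swap", {
  # perfectly symmetric sample: statistic 0, p = 1
  x <- c(-(1:20) / 20, (1:20) / 20)
  r <- front_rear_test(x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # all samples positive: statistic 1
  r2 <- front_rear_test(runif(50, 0.1, 1))
  expect_equal(r2$statistic, 1)
  expect_lt(r2$p_value, 1e-6)
  # exact front/rear symmetry: mirroring the data leaves p unchanged
  set.seed(3)
  y <- rnorm(200, 0.1)
  expect_equal(front_rear_test(-y)$p_value, front_rear_test(y)$p_value,
               tolerance = 1e-12)
  expect_error(front_rear_test(1:5), ">= 10")
})

test_that("condition_test matches the frozen reference and behaves at extremes", {
  # frozen two-sample CvM reference computed with an independent
  # implementation: statistic is exact, p to series accuracy
  set.seed(42)
  x <- rnorm(30); y <- rnorm(40, 0.5)
  r <- condition_test(x, y)
  expect_equal(r$statistic, 0.4446428571, tolerance = 1e-9)
  expect_equal(r$p_value, 0.0552903421, tolerance = 2e-3)
  # identical samples: minimal statistic, p near 1
  z <- runif(25)
  ri <- condition_test(z, z)
  expect_lt(ri$statistic, 0.05)
  expect_gt(ri$p_value, 0.95)
  # disjoint supports: near-maximal statistic, tiny p
  rd <- condition_test(runif(40), runif(40) + 5)
  expect_gt(rd$statistic, 5)
  expect_lt(rd$p_value, 1e-6)
  expect_error(condition_test(1:5, 1:20), ">= 10")
})

test_that("condition test separates biased from null fixtures", {
  # front_fraction 0.7 vs 0.5 with 50 cells each: p < 0.05 in >= 90% of reps
  hits <- 0; B <- 20
  for (b in 1:B) {
    sa <- synth_polarized_cell(0.7, n_cells = 50, seed = 6000 + b)
    sb <- synth_polarized_cell(0.5, n_cells = 50, seed = 7000 + b)
    pa <- polarity_map(polar_cells(sa))
    pb <- polarity_map(polar_cells(sb))
    if (condition_test(pa, pb)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / B, 0.9)
})

test_that("null occupancy maps are front/rear balanced", {
  s <- synth_polarized_cell(0.5, n_cells = 100, seed = 77)
  pm <- polarity_map(polar_cells(s, use_golgi = FALSE))
  gr <- pm$grid
  front <- mean(gr[, (ncol(gr) / 2 + 1):ncol(gr)])
  rear <- mean(gr[, 1:(ncol(gr) / 2)])
  # |front - rear| below 2 SE of the occupancy difference at 100 cells
  se <- sd(as.vector(gr)) / sqrt(pm$n_cells)
  expect_lt(abs(front - rear), 2 * se + 0.01)
})
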