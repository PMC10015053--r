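# synthetic_data: generators match their stated distributions and record
# ground truth sufficient to regenerate each fixture bit-identically

test_that("Brownian generator: defaults, step variance, validation", {
  sim <- simulate_brownian_tracks(D = 0.1, seed = 1)
  expect_equal(sum(sim$tracks$particle_id == 1), 500)  # 100 fps x 5 s
  expect_equal(sim$truth$dt, 0.01)
  # empirical per-axis step variance ~ 2 D dt within 5% (n = 49,900 steps)
  sim2 <- simulate_brownian_tracks(D = 0.1, n_particles = 100, n_frames = 500,
                                   dt = 0.01, seed = 42)
  steps <- do.call(rbind, lapply(split(sim2$tracks, sim2$tracks$particle_id),
                                 function(tr) cbind(diff(tr$x_um), diff(tr$y_um))))
  expect_equal(nrow(steps), 49900)
  expect_lt(abs(var(steps[, 1]) / (2 * 0.1 * 0.01) - 1), 0.05)
  expect_lt(abs(var(steps[, 2]) / (2 * 0.1 * 0.01) - 1), 0.05)
  # D = 0, no noise: stationary
  sim0 <- simulate_brownian_tracks(D = 0, loc_noise_um = 0, n_particles = 3,
                                   n_frames = 10, seed = 1)
  expect_equal(diff(range(sim0$tracks$x_um[sim0$tracks$particle_id == 1])), 0)
  expect_error(simulate_brownian_tracks(D = -1), "invalid")
  expect_error(simulate_brownian_tracks(n_frames = 1), "invalid")
})

test_that("generators regenerate bit-identically from seed", {
  expect_identical(simulate_brownian_tracks(seed = 7, n_particles = 5, n_frames = 20),
                   simulate_brownian_tracks(seed = 7, n_particles = 5, n_frames = 20))
  expect_identical(synth_spectral_stack(noise_sd = 3, seed = 5),
                   synth_spectral_stack(noise_sd = 3, seed = 5))
  expect_identical(synth_photon_decay(seed = 9, n_photons = 1000),
                   synth_photon_decay(seed = 9, n_photons = 1000))
  expect_identical(synth_polarized_cell(0.7, n_cells = 3, seed = 11),
                   synth_polarized_cell(0.7, n_cells = 3, seed = 11))
  expect_identical(simulate_cell_trajectories(n_cells = 4, seed = 13),
                   simulate_cell_trajectories(n_cells = 4, seed = 13))
})

test_that("rendered movies place symmetric spots at true subpixel positions", {
  tr <- data.frame(frame = 0, t_s = 0, x_um = 17.30 * 0.2, y_um = 41.80 * 0.2)
  mv <- render_particle_movie(tr, image_size = c(64, 64), pixel_size_um = 0.2,
                              background = 0, noise_sd = 0, seed = 1)
  fr <- stack_plane(mv, 1)
  w <- fr / sum(fr)
  cx <- sum(w * (col(fr) - 1))
  cy <- sum(w * (row(fr) - 1))
  expect_lt(abs(cx - 17.30), 1e-6)
  expect_lt(abs(cy - 41.80), 1e-6)
  # two particles 20 px apart give two local maxima
  tr2 <- data.frame(frame = c(0, 0), t_s = 0, x_um = c(20, 40) * 0.2,
                    y_um = c(32, 32) * 0.2)
  mv2 <- render_particle_movie(tr2, image_size = c(64, 64), pixel_size_um = 0.2,
                               background = 0, noise_sd = 0, seed = 1)
  d <- detect_particles(stack_plane(mv2, 1), "absolute", threshold = 1)
  expect_equal(nrow(d), 2)
  expect_warning(
    render_particle_movie(data.frame(frame = 0, t_s = 0, x_um = -5, y_um = 2),
                          image_size = c(16, 16), pixel_size_um = 1, seed = 1),
    "clipped")
})

test_that("spectral stacks peak at the configured band centres", {
  s <- synth_spectral_stack(donor_amp = 200, acceptor_amp = 100, noise_sd = 0)
  wl <- s$stack$channel_wavelengths_nm
  spec <- sapply(seq_along(wl), function(ci) mean(stack_plane(s$stack, ci)[s$mask$labels == 1]))
  win <- wl >= 470 & wl <= 490
  expect_true(all(spec[wl == 480] >= spec[win]))
  expect_equal(wl[which.max(spec)], 480)
  expect_error(synth_spectral_stack(donor_peak_nm = 450), "range")
  expect_error(synth_spectral_stack(donor_amp = -1), ">= 0")
})

test_that("photon decays follow the truncated exponential", {
  # wide window: sample mean approaches tau
  d <- synth_photon_decay(tau_ns = 2.5, n_photons = 2e5, window_ns = 100,
                          n_bins = 4000, seed = 3)
  expect_lt(abs(d$truth$mean_arrival_ns - 2.5), 0.02)
  # single photon histogram
  d1 <- synth_photon_decay(tau_ns = 2.5, n_photons = 1, seed = 1)
  expect_equal(sum(d1$hist$counts), 1)
  expect_error(synth_photon_decay(tau_ns = -1), "invalid")
})

test_that("nucleus generator records closed-form EOP truth", {
  circ <- synth_nucleus(a_um = 6, b_um = 6, pixel_size_um = 0.1)
  expect_equal(circ$truth$eop, 1.0, tolerance = 1e-9)
  # one radial slit of depth d and width w on a circle of radius R:
  # outline = circle - gap + 2 d + w; the generator's polygon arithmetic
  # must agree with direct arc-length summation of its own outline
  nu <- synth_nucleus(a_um = 6, b_um = 6,
                      invaginations = data.frame(angle = 1, depth_um = 2,
                                                 width_um = 0.2),
                      pixel_size_um = 0.1)
  hull <- nu$outline[grDevices::chull(nu$outline), ]
  expect_equal(nu$truth$eop, arc_length(nu$outline) / arc_length(hull),
               tolerance = 1e-12)
  expect_gt(nu$truth$eop, 1)
  expect_gt(nu$truth$eop, nu$truth$eop_skeleton)  # two walls vs one polyline
  expect_error(synth_nucleus(invaginations = data.frame(angle = 0, depth_um = 10,
                                                        width_um = 0.2)),
               "semi-axis")
  expect_error(synth_nucleus(invaginations = data.frame(angle = c(0, 0.1),
                                                        depth_um = 1, width_um = 0.2)),
               "overlapping")
})

test_that("polarised fixtures control the front share of top-quantile pixels", {
  # front_fraction = 1: every hot pixel is in the designated front half
  s1 <- synth_polarized_cell(1.0, n_cells = 4, seed = 2)
  pm <- polarity_map(polar_cells(s1))
  expect_gt(min(unlist(pm$per_cell_axis_samples)), 0)
  # front_fraction = 0.7: pooled front share near 0.7
  s7 <- synth_polarized_cell(0.7, n_cells = 40, seed = 3)
  ax <- unlist(polarity_map(polar_cells(s7))$per_cell_axis_samples)
  expect_lt(abs(mean(ax > 0) - 0.7), 0.05)
  # golgi sits on the front side in every cell
  or <- vapply(s7$cells, function(cc) {
    o <- orient_front(cc$mask, cc$golgi_centroid)
    cos(o$theta - cc$front_angle)
  }, numeric(1))
  expect_true(all(or > 0.99))
  expect_error(synth_polarized_cell(1.5), "front_fraction")
})

test_that("trajectory generator: sampling grid and persistence ordering", {
  tr <- simulate_cell_trajectories(n_cells = 3, seed = 1)
  expect_equal(tr$truth$n_samples, 109)   # every 10 min for 18 h
  expect_equal(sum(tr$trajectories$cell_id == 2), 109)
  # speed 0: stationary
  tr0 <- simulate_cell_trajectories(speed_um_min = 0, n_cells = 2, seed = 1)
  m0 <- motility_metrics(tr0$trajectories)
  expect_equal(m0$mean_speed_um_min, c(0, 0))
  # persistence decreases monotonically with rotational diffusion
  med_pers <- sapply(c(0.01, 0.1, 1), function(rd) {
    p <- sapply(1:20, function(s) {
      t2 <- simulate_cell_trajectories(speed_um_min = 0.5, rot_diffusion = rd,
                                       n_cells = 5, seed = 100 + s)
      median(motility_metrics(t2$trajectories)$persistence)
    })
    median(p)
  })
  expect_true(all(diff(med_pers) < 0))
})
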