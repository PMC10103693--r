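test_that("assignment matches brute-force enumeration on random costs", {
  set.seed(31)
  for (r in 1:30) {
    n <- sample(1:5, 1); m <- n + sample.int(5 - n + 1, 1) - 1L
    cost <- matrix(runif(n * m), n, m)
    a <- cvmbarrier:::hungarian_assign(cost)
    expect_false(anyNA(a))
    expect_equal(sum(cost[cbind(seq_len(n), a)]),
                 brute_force_assignment(cost), tolerance = 1e-12)
  }
  # more rows than columns: unmatched rows allowed, optimum preserved
  cost <- matrix(runif(12), 4, 3)
  a <- cvmbarrier:::hungarian_assign(cost)
  rows <- which(!is.na(a))
  expect_equal(length(rows), 3)
  expect_equal(sum(cost[cbind(rows, a[rows])]),
               brute_force_assignment(t(cost)), tolerance = 1e-12)
})

test_that("a noiseless off-grid spot is localized within 0.1 px", {
  opt <- optics_config(image_shape = c(200, 200), duration = 2,
                       frame_rate = 15, photon_scale = 5000, background = 0)
  df <- data.frame(particle_id = 1, frame = 0,
                   x_um = 100.4 * opt$pixel_size,
                   y_um = 50.2 * opt$pixel_size)
  sp <- detect_spots(render_video(df, opt, noise = FALSE), opt)
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$x_um / opt$pixel_size - 100.4), 0.1)
  expect_lt(abs(sp$y_um / opt$pixel_size - 50.2), 0.1)
  expect_gt(sp$mass, 0)
})

test_that("flat frames yield zero spots", {
  opt <- test_optics()
  expect_equal(nrow(detect_spots(matrix(0, 64, 64), opt)), 0)
  expect_equal(nrow(detect_spots(matrix(7, 64, 64), opt)), 0)
})

test_that("detection is equivariant under integer pixel shifts", {
  opt <- optics_config(image_shape = c(128, 128), duration = 2,
                       frame_rate = 15, photon_scale = 5000, background = 0)
  df <- data.frame(particle_id = 1, frame = 0,
                   x_um = 60.3 * opt$pixel_size, y_um = 58.7 * opt$pixel_size)
  img <- render_video(df, opt, noise = FALSE)[[1]]
  s0 <- detect_spots(img, opt)
  shifted <- matrix(0L, 128, 128)
  shifted[4:128, 6:128] <- img[1:125, 1:123]   # shift +3 rows, +5 cols
  s1 <- detect_spots(shifted, opt)
  expect_equal((s1$x_um - s0$x_um) / opt$pixel_size, 5, tolerance = 1e-6)
  expect_equal((s1$y_um - s0$y_um) / opt$pixel_size, 3, tolerance = 1e-6)
})

test_that("spots closer than the window are merged and flagged ambiguous", {
  opt <- optics_config(image_shape = c(64, 64), duration = 2,
                       frame_rate = 15, photon_scale = 5000, background = 0,
                       psf_sigma = 1.5)
  df <- data.frame(particle_id = 1:2, frame = 0,
                   x_um = c(28, 36) * opt$pixel_size,
                   y_um = c(30, 30) * opt$pixel_size)
  sp <- detect_spots(render_video(df, opt, noise = FALSE), opt, window = 11)
  expect_true(all(sp$ambiguous))
  expect_lte(nrow(sp), 1)   # reported once
  # and ambiguous spots never enter linking
  expect_equal(nrow(link_trajectories(sp, link_params(0.5, 0, 2))), 0)
})

test_that("well-separated parallel tracks keep their identities", {
  spots <- do.call(rbind, lapply(0:19, function(f)
    data.frame(frame = f, x_um = 0.05 * f + c(0, 0),
               y_um = c(0, 10), mass = 1, sigma_px = 1, ambiguous = FALSE)))
  lt <- link_trajectories(spots, link_params(0.5, 0, 10))
  expect_equal(length(unique(lt$particle_id)), 2)
  ys <- tapply(lt$y_um, lt$particle_id, function(v) length(unique(v)))
  expect_true(all(ys == 1))   # no identity swaps across the two lines
})

test_that("a particle vanishing within memory is bridged into one track", {
  frames <- setdiff(0:14, c(6, 7))
  spots <- data.frame(frame = frames, x_um = 0.02 * frames, y_um = 1,
                      mass = 1, sigma_px = 1, ambiguous = FALSE)
  lt <- link_trajectories(spots, link_params(0.5, memory = 2,
                                             min_track_length = 10))
  expect_equal(length(unique(lt$particle_id)), 1)
  expect_equal(sort(lt$frame), frames)
  # without memory the gap splits the track and both halves are too short
  lt0 <- link_trajectories(spots, link_params(0.5, memory = 0,
                                              min_track_length = 10))
  expect_equal(nrow(lt0), 0)
})

test_that("min_track_length keeps only full-length tracks", {
  full <- data.frame(frame = 0:29, x_um = 0, y_um = 1)
  part <- data.frame(frame = 0:19, x_um = 0, y_um = 5)
  spots <- rbind(full, part)
  spots$mass <- 1; spots$sigma_px <- 1; spots$ambiguous <- FALSE
  lt <- link_trajectories(spots, link_params(0.5, 0, min_track_length = 30))
  expect_equal(length(unique(lt$particle_id)), 1)
  expect_equal(unique(lt$y_um), 1)
})

test_that("rendered videos re-track to ground truth within 0.1 px RMS", {
  opt <- test_optics()
  trajs <- grid_trajectories(opt)
  stack <- render_video(trajs, opt, noise = FALSE)
  sp <- detect_spots(stack, opt)
  lt <- link_trajectories(sp, link_params(0.5, 2, 30))
  expect_equal(length(unique(lt$particle_id)), 5)
  # match each recovered track to its generating particle and measure error
  errs <- vapply(unique(lt$particle_id), function(pid) {
    g <- lt[lt$particle_id == pid, ]
    min(vapply(unique(trajs$particle_id), function(tid) {
      t2 <- trajs[trajs$particle_id == tid, ]
      m <- merge(g, t2, by = "frame")
      sqrt(mean((m$x_um.x - m$x_um.y)^2 + (m$y_um.x - m$y_um.y)^2))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(max(errs) / opt$pixel_size, 0.1)
})

test_that("linked displacements never exceed the gate and spots are unique", {
  opt <- test_optics()
  set.seed(33)
  s <- simulate_sample(population_spec(1, 0.005), 5, opt, seed = 34)
  stack <- render_video(s, noise = FALSE)
  lt <- link_trajectories(detect_spots(stack, opt), link_params(0.5, 2, 10))
  expect_false(any(duplicated(lt[c("frame", "x_um", "y_um")])))
  for (pid in unique(lt$particle_id)) {
    g <- lt[lt$particle_id == pid, ]
    g <- g[order(g$frame), ]
    d <- sqrt(diff(g$x_um)^2 + diff(g$y_um)^2)
    expect_true(all(d <= 0.5 + 1e-12))
  }
})
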