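test_that("hand-computed MSD over overlapping windows", {
  tr <- data.frame(frame = 0:3, x_um = c(0, 1, 2, 3), y_um = 0)
  r <- time_averaged_msd(tr, tau = 1, dt = 1)
  expect_equal(r$msd, 1.0)
  expect_equal(r$n_pairs, 3L)
  # lag 2: pairs (0,2),(1,3), each displacement 2 um
  r2 <- time_averaged_msd(tr, tau = 2, dt = 1)
  expect_equal(r2$msd, 4.0)
  expect_equal(r2$n_pairs, 2L)
})

test_that("a stationary particle has zero MSD and the log floor applies", {
  tr <- data.frame(frame = 0:9, x_um = 2, y_um = 3)
  r <- time_averaged_msd(tr, tau = 2, dt = 1)
  expect_equal(r$msd, 0)
  expect_equal(r$log10_msd, log10(1e-6))
})

test_that("MSD is invariant under translation and rotation", {
  set.seed(41)
  tr <- simulate_trajectory(0.2, 1, 60, 1 / 15)
  base <- time_averaged_msd(tr, 1)$msd
  shifted <- tr; shifted$x_um <- tr$x_um + 5; shifted$y_um <- tr$y_um - 3
  attr(shifted, "dt") <- attr(tr, "dt")
  expect_equal(time_averaged_msd(shifted, 1)$msd, base, tolerance = 1e-12)
  th <- 0.7
  rotated <- tr
  rotated$x_um <- cos(th) * tr$x_um - sin(th) * tr$y_um
  rotated$y_um <- sin(th) * tr$x_um + cos(th) * tr$y_um
  attr(rotated, "dt") <- attr(tr, "dt")
  expect_equal(time_averaged_msd(rotated, 1)$msd, base, tolerance = 1e-12)
})

test_that("gaps contribute no pairs; gap-free pairs count n - lag", {
  tr <- data.frame(frame = c(0, 1, 2, 4), x_um = c(0, 1, 2, 4), y_um = 0)
  r <- time_averaged_msd(tr, tau = 1, dt = 1)
  expect_equal(r$n_pairs, 2L)       # (0,1) and (1,2) only
  set.seed(42)
  tr2 <- simulate_trajectory(0.1, 1, 80, 1 / 15)
  expect_equal(time_averaged_msd(tr2, 1)$n_pairs, 80L - 15L)
})

test_that("the non-overlapping estimator uses spaced starts", {
  tr <- data.frame(frame = 0:5, x_um = 0:5, y_um = 0)
  expect_equal(time_averaged_msd(tr, 2, dt = 1)$n_pairs, 4L)
  expect_equal(time_averaged_msd(tr, 2, dt = 1, overlap = FALSE)$n_pairs, 2L)
})

test_that("a trajectory shorter than tau is an explicit insufficient result", {
  tr <- data.frame(frame = 0:5, x_um = 0:5, y_um = 0)
  r <- time_averaged_msd(tr, tau = 10, dt = 1)
  expect_true(is.na(r$msd))
  expect_equal(r$n_pairs, 0L)
  expect_false(r$eligible)
  expect_error(time_averaged_msd(tr, tau = 1.5, dt = 1), "integer multiple")
})

test_that("per-particle records are conserved and eligibility enforced", {
  opt <- test_optics()
  s <- simulate_sample(population_spec(1, 0.05), 40, opt, seed = 43)
  rec <- msd_at_one_second(s)
  expect_equal(nrow(rec), 40)
  expect_true(all(rec$eligible))
  expect_true(all(rec$n_pairs == opt$n_frames - 15))
  # ten-frame tracks at 15 Hz cannot span tau = 1 s
  short <- s$trajectories[s$trajectories$frame < 10, ]
  rec2 <- msd_at_one_second(short, dt = opt$dt)
  expect_equal(nrow(rec2), 40)
  expect_true(all(!rec2$eligible))
  expect_warning(msd_at_one_second(short[0, ], dt = opt$dt),
                 "no trajectories")
})

test_that("a mixed population produces a clearly bimodal log-MSD histogram", {
  opt <- optics_config(duration = 10)
  pops <- list(population_spec(0.5, 10^(-2.5) / 4, 0.5, "trapped"),
               population_spec(0.5, 0.5, 1, "mobile"))
  s <- simulate_sample(pops, 200, opt, seed = 44)
  rec <- msd_at_one_second(s)
  x <- rec$log10_msd[rec$eligible]
  # two-component mixture must beat one Gaussian on BIC
  fit2 <- fit_mixture(x)
  ll1 <- sum(dnorm(x, mean(x), sd(x) * sqrt((length(x) - 1) / length(x)),
                   log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(length(x))
  bic2 <- -2 * fit2$loglik + 5 * log(length(x))
  expect_lt(bic2, bic1)
})
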