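test_that("EM recovers planted mixture parameters and matches mclust", {
  set.seed(51)
  x <- c(rnorm(700, -2.5, 0.3), rnorm(300, 0, 0.3))
  fit <- fit_mixture(x)
  expect_true(fit$converged)
  expect_equal(fit$weights, c(0.7, 0.3), tolerance = 0.05)
  expect_equal(fit$means, c(-2.5, 0), tolerance = 0.1)
  # independent cross-check: mclust on the same data (attach needed for
  # its internal model-name lookup)
  suppressPackageStartupMessages(library(mclust))
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(mc$parameters$mean), fit$means, tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 0.01)
})

test_that("EM log-likelihood never decreases across iterations", {
  set.seed(52)
  for (r in 1:5) {
    x <- c(rnorm(100, -2, 0.5), rnorm(100, runif(1, -1, 1), 0.5))
    fit <- fit_mixture(x)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
  }
})

test_that("components are always ordered by ascending mean", {
  set.seed(53)
  for (r in 1:5) {
    x <- rnorm(60, sample(c(-3, 0, 2), 1), runif(1, 0.2, 1))
    fit <- fit_mixture(x)
    expect_true(fit$means[1] <= fit$means[2])
  }
})

test_that("degenerate identical input triggers the variance floor", {
  fit <- fit_mixture(rep(-2, 50))
  expect_true(fit$floored)
  expect_false(cvmbarrier:::is_bimodal(fit))
  est <- mobile_fraction(fit, rep(-2, 50))
  expect_equal(est$method, "cutoff")
  expect_equal(est$mobile_fraction, 0)
})

test_that("fewer than 10 particles is an insufficient marker", {
  fit <- fit_mixture(rnorm(5))
  expect_true(fit$insufficient)
  est <- mobile_fraction(fit, rnorm(5))
  expect_equal(est$method, "insufficient")
  expect_true(is.na(est$mobile_fraction))
})

test_that("single-peak samples fall back to the -1.3 cutoff exactly", {
  set.seed(58)
  lo <- rnorm(200, -3, 0.05)
  est <- mobile_fraction(fit_mixture(lo), lo)
  expect_equal(est$method, "cutoff")
  expect_equal(est$mobile_fraction, 0)
  hi <- rnorm(200, 0, 0.05)
  est2 <- mobile_fraction(fit_mixture(hi), hi)
  expect_equal(est2$method, "cutoff")
  expect_equal(est2$mobile_fraction, 1)
})

test_that("mixture weight and cutoff count agree for well-split components", {
  set.seed(54)
  x <- c(rnorm(400, -2.8, 0.3), rnorm(600, 0.2, 0.3))  # straddle -1.3
  fit <- fit_mixture(x)
  w <- mobile_fraction(fit, x)
  expect_equal(w$method, "mixture")
  expect_lt(abs(w$mobile_fraction - mean(x > -1.3)), 0.05)
  post <- mobile_fraction(fit, x, fraction = "posterior")
  expect_lt(abs(post$mobile_fraction - w$mobile_fraction), 0.05)
})

test_that("mobile fraction is monotone under upward shifts of the data", {
  set.seed(55)
  x <- c(rnorm(300, -2.5, 0.4), rnorm(200, -0.5, 0.4))
  prev <- -Inf
  for (shift in seq(0, 2, by = 0.5)) {
    xs <- x + shift
    est <- mobile_fraction(fit_mixture(xs), xs)
    expect_gte(est$mobile_fraction, prev - 0.02)
    prev <- est$mobile_fraction
  }
})

test_that("per-sample mobility table pools groups and flags sparse cells", {
  set.seed(56)
  rec <- rbind(
    data.frame(sample_id = "s1", probe = "MPP100",
               log10_msd = c(rnorm(60, -2.5, 0.3), rnorm(40, 0, 0.3)),
               eligible = TRUE),
    data.frame(sample_id = "s1", probe = "MPP200",
               log10_msd = rnorm(4, 0, 0.3), eligible = TRUE),
    data.frame(sample_id = "s2", probe = "MPP100",
               log10_msd = rnorm(50, -3, 0.2), eligible = TRUE))
  tab <- sample_mobility_table(rec)
  expect_equal(nrow(tab), 3)
  s1 <- tab[tab$sample_id == "s1" & tab$probe == "MPP100", ]
  expect_equal(s1$method, "mixture")
  expect_equal(s1$mobile_fraction, 0.4, tolerance = 0.08)
  expect_equal(tab$method[tab$probe == "MPP200"], "insufficient")
  expect_equal(tab$mobile_fraction[tab$sample_id == "s2"], 0)
})

test_that("estimated sample mobility tracks the generating fraction", {
  opt <- optics_config(duration = 10)
  true_f <- c(0.2, 0.5, 0.8)
  set.seed(57)
  rec <- do.call(rbind, lapply(seq_along(true_f), function(i) {
    pops <- list(
      population_spec(1 - true_f[i], 10^(-2.5) / 4, 0.5, "trapped"),
      population_spec(true_f[i], 0.5, 1, "mobile"))
    s <- simulate_sample(pops, 150, opt, seed = 570 + i)
    cbind(sample_id = paste0("s", i), probe = "MPP100",
          msd_at_one_second(s))
  }))
  tab <- sample_mobility_table(rec)
  expect_equal(tab$mobile_fraction[order(tab$sample_id)], true_f,
               tolerance = 0.06)
})
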