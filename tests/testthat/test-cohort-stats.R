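test_that("exclusion rules retain unflagged samples with a per-reason log", {
  md <- data.frame(sample_id = letters[1:5],
                   blood_flag = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                   intercourse_flag = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  out <- apply_exclusions(md)
  expect_equal(nrow(out$samples), 3)
  expect_equal(unname(out$log["n_blood"]), 1)
  expect_equal(unname(out$log["n_intercourse"]), 1)
  # no flags: identity
  clean <- data.frame(blood_flag = rep(FALSE, 4),
                      intercourse_flag = rep(FALSE, 4))
  expect_equal(nrow(apply_exclusions(clean)$samples), 4)
  # a doubly flagged row is removed once but logged under both reasons
  both <- data.frame(blood_flag = c(TRUE, FALSE),
                     intercourse_flag = c(TRUE, FALSE))
  ob <- apply_exclusions(both)
  expect_equal(unname(ob$log["n_excluded"]), 1)
  expect_equal(unname(ob$log["n_blood"] + ob$log["n_intercourse"]), 2)
  expect_equal(unname(ob$log["n_both"]), 1)
  expect_error(apply_exclusions(data.frame(x = 1)), "blood_flag")
})

test_that("risk ratios and odds ratios follow the 2x2 formulas", {
  r <- contingency_stats(7, 18, 3, 64)
  expect_equal(r$rr, (7 / 25) / (3 / 67))
  expect_equal(r$or_, (7 * 64) / (18 * 3))
  z <- contingency_stats(0, 9, 10, 73)       # zero numerator prints as 0
  expect_equal(z$rr, 0)
  expect_equal(z$or_, 0)
  expect_true(z$haldane)
  expect_error(contingency_stats(-1, 2, 3, 4), "non-negative")
})

test_that("odds ratios obey exposure-relabelling reciprocity", {
  set.seed(71)
  for (r in 1:10) {
    cells <- sample(1:40, 4)
    o1 <- contingency_stats(cells[1], cells[2], cells[3], cells[4])$or_
    o2 <- contingency_stats(cells[2], cells[1], cells[4], cells[3])$or_
    expect_equal(o1 * o2, 1, tolerance = 1e-12)
  }
})

test_that("Fisher p is invariant under transposing the table", {
  set.seed(72)
  for (r in 1:10) {
    cells <- sample(0:30, 4)
    if (sum(cells) == 0) next
    p1 <- contingency_stats(cells[1], cells[2], cells[3], cells[4])$fisher_p
    p2 <- contingency_stats(cells[1], cells[3], cells[2], cells[4])$fisher_p
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("Welch t matches hand computation and base conventions", {
  w <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3.674, tolerance = 1e-3)
  expect_equal(w$df, 4)
  expect_equal(w$p, 0.0214, tolerance = 5e-3)
  # identical constant groups: t = 0, p = 1 by convention
  same <- welch_t(rep(2, 5), rep(2, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # scaling both groups leaves t unchanged
  w2 <- welch_t(10 * c(1, 2, 3), 10 * c(4, 5, 6))
  expect_equal(w2$t, w$t, tolerance = 1e-12)
  # equal variances and sizes: Welch equals the classic t test
  x <- c(1.2, 2.1, 2.9, 4.3); y <- x + 1.7
  expect_equal(welch_t(x, y)$p,
               t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA with Tukey flags only the shifted group", {
  # all groups the same constant: F = 0
  const <- list(a = rep(1, 3), b = rep(1, 3), c = rep(1, 3))
  a0 <- anova_tukey(const)
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)
  set.seed(73)
  groups <- lapply(setNames(1:5, paste0("g", 1:5)),
                   function(i) rnorm(30, 0, 1))
  groups$g3 <- groups$g3 + 5
  res <- anova_tukey(groups)
  expect_lt(res$p, 0.05)
  hit <- grepl("g3", res$pairwise$comparison)
  expect_true(all(res$pairwise$p_adj[hit] < 0.05))
  expect_true(all(res$pairwise$p_adj[!hit] > 0.05))
})

test_that("permuting group order permutes but preserves pairwise p-values", {
  set.seed(74)
  groups <- list(a = rnorm(10), b = rnorm(10, 2), c = rnorm(10, 4))
  r1 <- anova_tukey(groups)
  r2 <- anova_tukey(groups[c("c", "a", "b")])
  expect_equal(r1$F, r2$F, tolerance = 1e-12)
  canon <- function(pw) {
    key <- vapply(strsplit(pw$comparison, "-"), function(s)
      paste(sort(s), collapse = "-"), character(1))
    setNames(pw$p_adj, key)[order(key)]
  }
  expect_equal(canon(r1$pairwise), canon(r2$pairwise), tolerance = 1e-12)
})

test_that("slope regression handles exact lines and rejects constant x", {
  x <- 1:10
  r <- suppressWarnings(slope_regression(x, 2 * x))
  expect_equal(r$slope, 2)
  expect_equal(r$r_squared, 1)
  r2 <- suppressWarnings(slope_regression(x, 2 * x + 7))
  expect_equal(r2$slope, 2)
  expect_equal(r2$intercept, 7)
  expect_error(slope_regression(rep(1, 5), rnorm(5)), "constant")
  expect_error(slope_regression(1:2, 1:2), "3 points")
})

test_that("published-count risk table reproduces the headline rows", {
  tab <- published_risk_table()
  row <- function(l) tab[tab$label == l, ]
  expect_equal(row("Black or African American")$rr, 6.25, tolerance = 1e-3)
  expect_equal(row("Black or African American")$or_, 8.296, tolerance = 1e-3)
  expect_equal(row("Gonorrhea")$rr, 7.42, tolerance = 5e-3)
  expect_equal(row("Gonorrhea")$or_, 20.25, tolerance = 5e-3)
  expect_equal(row("Previous pregnancy")$rr, 0.127, tolerance = 5e-3)
  expect_equal(row("Previous pregnancy")$or_, 0.088, tolerance = 5e-3)
})
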