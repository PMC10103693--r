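#' Apply the study's sample exclusion rules
#'
#' Removes samples that contained blood, or where the participant reported
#' unprotected vaginal intercourse in the three days before collection.
#' A sample carrying both flags is removed once but counted under both
#' reasons in the log.
#'
#' @param samples data.frame with logical (or 0/1) columns `blood_flag`
#'   and `intercourse_flag`.
#' @return List with `samples` (retained rows) and `log` (named counts:
#'   `n_input, n_retained, n_excluded, n_blood, n_intercourse, n_both`).
#' @export
apply_exclusions <- function(samples) {
  need <- c("blood_flag", "intercourse_flag")
  if (!all(need %in% names(samples)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  blood <- as.logical(samples$blood_flag)
  sex <- as.logical(samples$intercourse_flag)
  if (anyNA(blood) || anyNA(sex)) stop("exclusion flags must not be NA")
  drop <- blood | sex
  list(samples = samples[!drop, , drop = FALSE],
       log = c(n_input = nrow(samples), n_retained = sum(!drop),
               n_excluded = sum(drop), n_blood = sum(blood),
               n_intercourse = sum(sex), n_both = sum(blood & sex)))
}

#' Relative risk, odds ratio, CIs and Fisher p for a 2x2 table
#'
#' For the exposure-by-outcome table with `a` exposed cases, `b` exposed
#' non-cases, `c` unexposed cases and `d` unexposed non-cases:
#' `RR = (a/(a+b)) / (c/(c+d))` and `OR = (a*d)/(b*c)`. A zero numerator
#' gives a point estimate of 0; a zero denominator gives `Inf` (flagged
#' `undefined`). Confidence intervals use the Katz log method (RR) and the
#' Woolf log method (OR); when any cell is zero the 0.5 Haldane-Anscombe
#' correction is applied inside the CI computation only (flagged
#' `haldane`), never to the point estimates. The p-value is the two-sided
#' Fisher exact test (hypergeometric point-probability rule).
#'
#' @param a,b,c,d Non-negative integer cell counts; alternatively pass a
#'   2x2 matrix `rbind(c(a, b), c(c, d))` as `a`.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `contingency_result`: list with `a,b,c,d`,
#'   `rr`, `or_`, `rr_ci`, `or_ci`, `fisher_p`, `haldane`, `conf_level`.
#' @export
contingency_stats <- function(a, b = NULL, c = NULL, d = NULL,
                              conf_level = 0.95) {
  if (is.matrix(a)) { b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1] }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) < 1) stop("the table must contain at least one count")
  risk1 <- if (a + b > 0) a / (a + b) else NaN
  risk0 <- if (c + d > 0) c / (c + d) else NaN
  rr <- if (is.nan(risk1) || is.nan(risk0)) NaN
        else if (risk0 == 0) { if (risk1 == 0) NaN else Inf }
        else risk1 / risk0
  or_ <- if (b * c == 0) { if (a * d == 0) NaN else Inf } else (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  haldane <- any(cells == 0)
  h <- if (haldane) cells + 0.5 else cells
  rr_h <- (h["a"] / (h["a"] + h["b"])) / (h["c"] / (h["c"] + h["d"]))
  se_log_rr <- sqrt(1 / h["a"] - 1 / (h["a"] + h["b"]) +
                      1 / h["c"] - 1 / (h["c"] + h["d"]))
  rr_ci <- unname(exp(log(rr_h) + c(-1, 1) * z * se_log_rr))
  or_h <- (h["a"] * h["d"]) / (h["b"] * h["c"])
  se_log_or <- sqrt(sum(1 / h))
  or_ci <- unname(exp(log(or_h) + c(-1, 1) * z * se_log_or))
  p <- fisher.test(matrix(c(a, c, b, d), 2))$p.value
  structure(list(a = a, b = b, c = c, d = d, rr = rr, or_ = or_,
                 rr_ci = rr_ci, or_ci = or_ci, fisher_p = p,
                 haldane = haldane, conf_level = conf_level),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  fmt <- function(v) if (is.nan(v)) "undefined" else
    if (is.infinite(v)) "Inf" else sprintf("%.4g", v)
  cat(sprintf("2x2 [%d %d / %d %d]: RR = %s (%s-%s), OR = %s (%s-%s), %s\n",
              x$a, x$b, x$c, x$d, fmt(x$rr), fmt(x$rr_ci[1]),
              fmt(x$rr_ci[2]), fmt(x$or_), fmt(x$or_ci[1]),
              fmt(x$or_ci[2]), sprintf("Fisher p = %.4g", x$fisher_p)))
  if (x$haldane) cat("  (0.5 continuity correction inside CIs only)\n")
  invisible(x)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and
#' a two-sided p-value. Two groups that are both constant and equal return
#' `t = 0, p = 1` by convention (the pooled variance is 0).
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @return List with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  mean_x = mean(x), mean_y = mean(y)))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0,
                mean_x = mean(x), mean_y = mean(y)))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' One-way ANOVA with Tukey's multiple-comparison correction
#'
#' Standard one-way F test across named groups; for three or more groups,
#' all pairwise comparisons are adjusted by Tukey's HSD on the studentized
#' range, with Tukey-Kramer standard errors under unequal group sizes.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @return List with `F`, `df`, `p`, and `pairwise` (data.frame
#'   `comparison, diff, lwr, upr, p_adj`; NULL for 2 groups).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2) stop("at least 2 groups are required")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  if (var(df$value) == 0) {   # degenerate: all observations identical
    pw <- NULL
    if (length(groups) >= 3) {
      nm <- names(groups)
      pairs <- utils::combn(rev(nm), 2)
      pw <- data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = "-"),
                       diff = 0, lwr = 0, upr = 0, p_adj = 1)
    }
    return(list(F = 0, df = c(length(groups) - 1,
                              nrow(df) - length(groups)),
                p = 1, pairwise = pw))
  }
  fit <- aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  res <- list(F = s[1, "F value"], df = c(s[1, "Df"], s[2, "Df"]),
              p = s[1, "Pr(>F)"], pairwise = NULL)
  if (length(groups) >= 3) {
    tk <- TukeyHSD(fit)$group
    res$pairwise <- data.frame(comparison = rownames(tk),
                               diff = tk[, "diff"], lwr = tk[, "lwr"],
                               upr = tk[, "upr"], p_adj = tk[, "p adj"],
                               row.names = NULL)
  }
  res
}

#' Simple linear regression with a slope test
#'
#' Ordinary least squares of `y` on `x` with the t test of a non-zero
#' slope; reports both R-squared and the p-value, the summaries used for
#' trend scatter plots (e.g. particle mobility versus gestational week).
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must vary.
#' @return List with `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
slope_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 points are required")
  if (sd(x) == 0) stop("'x' must not be constant")
  fit <- lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared,
       p = s$coefficients["x", "Pr(>|t|)"], n = length(x))
}
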