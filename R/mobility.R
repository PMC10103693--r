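#' Two-component Gaussian mixture on log10 MSD by EM
#'
#' Fits, by expectation-maximization, the two-normal mixture used to
#' separate a trapped (low-MSD) from a mobile (high-MSD) particle
#' population in the per-sample histogram of log10(MSD at tau = 1 s).
#' Initialization is deterministic — component means at the 25th and 75th
#' percentiles, equal weights, the pooled SD for both components — so the
#' fit is reproducible without randomness; `seed` only matters when
#' `n_starts > 1` adds randomized restarts. Component variances are
#' floored at `var_floor` to prevent singular collapse. Components are
#' always returned ordered by ascending mean.
#'
#' @param log_msds Numeric vector of log10(MSD in um^2) values; at least
#'   10 finite values are required for a fit.
#' @param tol EM stops when the log-likelihood improves by less than this.
#' @param max_iter Maximum EM iterations (default 500).
#' @param var_floor Variance floor in (log10 um^2)^2 (default 1e-4).
#' @param seed Optional seed for randomized restarts.
#' @param n_starts Number of starts; 1 (default) is fully deterministic.
#'
#' @return An object of class `mixture_fit`: list with `means`, `sds`,
#'   `weights` (ascending-mean order), `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `floored`, `n`, `insufficient`. With fewer than 10
#'   values, a marker fit with `insufficient = TRUE` is returned.
#' @export
fit_mixture <- function(log_msds, tol = 1e-8, max_iter = 500,
                        var_floor = 1e-4, seed = NULL, n_starts = 1) {
  x <- log_msds[is.finite(log_msds)]
  if (length(x) < 10) {
    return(structure(list(means = c(NA_real_, NA_real_),
                          sds = c(NA_real_, NA_real_),
                          weights = c(NA_real_, NA_real_),
                          loglik = NA_real_, loglik_trace = numeric(),
                          n_iter = 0L, converged = FALSE, floored = FALSE,
                          n = length(x), insufficient = TRUE),
                     class = "mixture_fit"))
  }
  s0 <- max(sd(x), sqrt(var_floor))
  starts <- list(list(mu = as.numeric(quantile(x, c(0.25, 0.75))),
                      sd = c(s0, s0), w = c(0.5, 0.5)))
  if (n_starts > 1) {
    extra <- with_seed(seed, lapply(seq_len(n_starts - 1), function(k)
      list(mu = sort(sample(x, 2)), sd = c(s0, s0), w = c(0.5, 0.5))))
    starts <- c(starts, extra)
  }
  best <- NULL
  for (st in starts) {
    fit <- em_two_normal(x, st$mu, st$sd, st$w, tol, max_iter, var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  o <- order(best$means)
  structure(list(means = best$means[o], sds = best$sds[o],
                 weights = best$weights[o], loglik = best$loglik,
                 loglik_trace = best$loglik_trace, n_iter = best$n_iter,
                 converged = best$converged, floored = best$floored,
                 n = length(x), insufficient = FALSE),
            class = "mixture_fit")
}

em_two_normal <- function(x, mu, s, w, tol, max_iter, var_floor) {
  n <- length(x)
  ll_old <- -Inf; trace <- numeric(0); converged <- FALSE
  floored <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    g <- d1 / tot                    # responsibility of component 1
    n1 <- sum(g); n2 <- n - n1
    if (n1 < 1e-10 || n2 < 1e-10) { converged <- TRUE; break }
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    v <- c(sum(g * (x - mu[1])^2) / n1, sum((1 - g) * (x - mu[2])^2) / n2)
    if (any(v < var_floor)) { floored <- TRUE; v <- pmax(v, var_floor) }
    s <- sqrt(v)
    w <- c(n1, n2) / n
  }
  list(means = mu, sds = s, weights = w, loglik = trace[length(trace)],
       loglik_trace = trace, n_iter = it, converged = converged,
       floored = floored)
}

#' @export
print.mixture_fit <- function(x, ...) {
  if (x$insufficient) {
    cat("mixture_fit: insufficient particles (n =", x$n, ")\n")
  } else {
    cat(sprintf(
      "mixture_fit: mu = (%.3f, %.3f), sd = (%.3f, %.3f), w = (%.3f, %.3f)\n",
      x$means[1], x$means[2], x$sds[1], x$sds[2], x$weights[1], x$weights[2]))
    cat(sprintf("  loglik %.3f after %d iter (%s)\n", x$loglik, x$n_iter,
                if (x$converged) "converged" else "not converged"))
  }
  invisible(x)
}

# Bimodality rule: the fitted mixture counts as two peaks only when
# (i) EM converged, (ii) both weights reach `min_weight`, (iii) the means
# are separated by at least `sep` mixture-implied pooled SDs, and (iv) the
# two-component model beats a single Gaussian on BIC. The BIC condition is
# essential: on genuinely unimodal data EM can converge to a "split
# halves" optimum whose component separation passes any threshold, but
# whose likelihood gain over one Gaussian is negligible.
is_bimodal <- function(fit, x = NULL, sep = 1.0, min_weight = 0.02) {
  if (fit$insufficient || !fit$converged) return(FALSE)
  mbar <- sum(fit$weights * fit$means)
  pooled <- sqrt(sum(fit$weights * (fit$sds^2 + fit$means^2)) - mbar^2)
  if (abs(diff(fit$means)) < sep * pooled ||
      min(fit$weights) < min_weight) return(FALSE)
  if (!is.null(x)) {
    x <- x[is.finite(x)]
    n <- length(x)
    s_mle <- sqrt(sum((x - mean(x))^2) / n)
    ll1 <- sum(dnorm(x, mean(x), max(s_mle, 1e-4), log = TRUE))
    bic1 <- -2 * ll1 + 2 * log(n)
    bic2 <- -2 * fit$loglik + 5 * log(n)
    if (bic2 >= bic1) return(FALSE)
  }
  TRUE
}

#' Mobile fraction of a particle population
#'
#' If the mixture fit is bimodal under the separation rule, the mobile
#' fraction is the mixing weight of the higher-mean component
#' (`method = "mixture"`; a posterior-count variant is available via
#' `fraction = "posterior"`). When the fit reveals only one peak, the
#' fixed cutoff of log10(MSD) = -1.3 (MSD in um^2) is used instead: the
#' mobile fraction is the proportion of particles above the cutoff
#' (`method = "cutoff"`).
#'
#' @param fit A `mixture_fit` from [fit_mixture()].
#' @param log_msds The log10 MSD values the fit was computed on.
#' @param cutoff Fallback threshold in log10(um^2) (default -1.3).
#' @param sep,min_weight Bimodality rule: minimum separation of the means
#'   in pooled SDs, and minimum component weight.
#' @param fraction `"weight"` (default) or `"posterior"` for the
#'   posterior-classification count.
#'
#' @return An object of class `mobility_estimate`: list with
#'   `mobile_fraction`, `method` (`"mixture"`, `"cutoff"` or
#'   `"insufficient"`), `cutoff`, `n_particles`, and the `fit`.
#' @export
mobile_fraction <- function(fit, log_msds, cutoff = -1.3, sep = 1.0,
                            min_weight = 0.02,
                            fraction = c("weight", "posterior")) {
  fraction <- match.arg(fraction)
  x <- log_msds[is.finite(log_msds)]
  if (fit$insufficient) {
    res <- list(mobile_fraction = NA_real_, method = "insufficient")
  } else if (is_bimodal(fit, x, sep, min_weight)) {
    mf <- if (fraction == "weight") fit$weights[2] else {
      d1 <- fit$weights[1] * dnorm(x, fit$means[1], fit$sds[1])
      d2 <- fit$weights[2] * dnorm(x, fit$means[2], fit$sds[2])
      mean(d2 > d1)
    }
    res <- list(mobile_fraction = unname(mf), method = "mixture")
  } else {
    res <- list(mobile_fraction = mean(x > cutoff), method = "cutoff")
  }
  structure(c(res, list(cutoff = cutoff, n_particles = length(x),
                        fit = fit)), class = "mobility_estimate")
}

#' Per-sample, per-probe mobile-fraction table
#'
#' Pools all particles of each (sample, probe) group — across the several
#' videos taken per probe per sample — fits the log10 MSD mixture, and
#' applies the cutoff fallback where the fit is single-peaked. Groups with
#' fewer than `min_particles` eligible particles are marked insufficient
#' rather than dropped.
#'
#' @param msd_records data.frame from [msd_at_one_second()] with columns
#'   `sample_id, probe, log10_msd, eligible`.
#' @param min_particles Minimum eligible particles per group (default 10).
#' @param ... Passed to [mobile_fraction()] (e.g. `cutoff`, `fraction`).
#'
#' @return data.frame `sample_id, probe, n_particles, mobile_fraction,
#'   method, mu_trapped, mu_mobile, w_mobile`.
#' @export
sample_mobility_table <- function(msd_records, min_particles = 10, ...) {
  need <- c("sample_id", "probe", "log10_msd", "eligible")
  if (!all(need %in% names(msd_records)))
    stop("msd_records must have columns ", paste(need, collapse = ", "))
  rec <- msd_records[msd_records$eligible, , drop = FALSE]
  groups <- unique(msd_records[c("sample_id", "probe")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- rec[rec$sample_id == groups$sample_id[i] &
               rec$probe == groups$probe[i], ]
    x <- g$log10_msd[is.finite(g$log10_msd)]
    if (length(x) < min_particles) {
      return(data.frame(sample_id = groups$sample_id[i],
                        probe = groups$probe[i], n_particles = length(x),
                        mobile_fraction = NA_real_, method = "insufficient",
                        mu_trapped = NA_real_, mu_mobile = NA_real_,
                        w_mobile = NA_real_))
    }
    fit <- fit_mixture(x)
    est <- mobile_fraction(fit, x, ...)
    data.frame(sample_id = groups$sample_id[i], probe = groups$probe[i],
               n_particles = length(x),
               mobile_fraction = est$mobile_fraction, method = est$method,
               mu_trapped = fit$means[1], mu_mobile = fit$means[2],
               w_mobile = fit$weights[2])
  })
  do.call(rbind, rows)
}
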