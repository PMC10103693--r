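#' Declarative configuration of an end-to-end pipeline run
#'
#' One object carrying every stage's settings; together with its seed it
#' fully determines every output of [run_pipeline()].
#'
#' @param seed Root seed; every stochastic stage draws from a child stream
#'   derived from it.
#' @param cohort A [cohort_config()].
#' @param optics An [optics_config()].
#' @param link A [link_params()].
#' @param use_video If TRUE, trajectories are rendered to video stacks and
#'   re-tracked (detect + link) before MSD analysis; if FALSE (default)
#'   the simulated trajectories feed the MSD stage directly. Only
#'   practical for small fields/cohorts when TRUE.
#' @param n_particles Particles simulated per sample per probe (pooling
#'   the several videos taken per probe; default 60).
#' @param tau MSD lag in seconds (default 1).
#' @param min_pairs Minimum displacement pairs for MSD eligibility.
#' @param min_particles Minimum particles per (sample, probe) mobility fit.
#' @param cutoff Single-peak fallback threshold, log10(um^2).
#' @param trapped_log10_msd Target log10 MSD (um^2 at tau = 1 s) of the
#'   trapped population (default -2.5).
#' @param trapped_alpha Anomalous exponent of the trapped population
#'   (default 0.5; subdiffusive stand-in for caged particles).
#' @param temperature,viscosity,d_fiber_nm Pore-model constants.
#' @param k Number of CST clusters (default 5).
#' @param out_dir Optional directory; when set, every stage table is
#'   written there as CSV.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, cohort = cohort_config(seed = seed),
                       optics = optics_config(), link = link_params(),
                       use_video = FALSE, n_particles = 60, tau = 1,
                       min_pairs = 15, min_particles = 10, cutoff = -1.3,
                       trapped_log10_msd = -2.5, trapped_alpha = 0.5,
                       temperature = 298.15, viscosity = 8.9e-4,
                       d_fiber_nm = 7, k = 5, out_dir = NULL) {
  structure(list(seed = as.integer(seed), cohort = cohort, optics = optics,
                 link = link, use_video = use_video,
                 n_particles = as.integer(n_particles), tau = tau,
                 min_pairs = min_pairs, min_particles = min_particles,
                 cutoff = cutoff, trapped_log10_msd = trapped_log10_msd,
                 trapped_alpha = trapped_alpha, temperature = temperature,
                 viscosity = viscosity, d_fiber_nm = d_fiber_nm, k = k,
                 out_dir = out_dir), class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in dependency order: cohort simulation, sample exclusions,
#' per-sample particle simulation (optionally rendered to video and
#' re-tracked), MSD at tau = 1 s, trapped/mobile mixture classification,
#' obstruction-model pore-size estimation, Bray-Curtis + PAM community
#' state typing with carry-forward, and the cohort statistics (CST
#' distribution by outcome, mobility by CST, trend regressions, CST IV
#' exposure risk). Identical config + seed reproduce every table exactly.
#'
#' @param config A [run_config()].
#' @return Object of class `report_bundle`: list of stage tables
#'   (`cohort`, `exclusions`, `msd`, `mobility`, `pore`,
#'   `cst_assignments`, `cst_distribution`, `mobility_by_cst`,
#'   `mobility_cst_tests`, `pore_test`, `regressions`, `risk`,
#'   `provenance`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- seed_streams(config$seed, 3L)
  cohort <- simulate_cohort(config$cohort)
  excl <- apply_exclusions(cohort$metadata)
  included <- excl$samples$sample_id

  msd_records <- pipeline_particles(cohort, config, included, seeds[2])
  mobility <- sample_mobility_table(msd_records,
                                    min_particles = config$min_particles,
                                    cutoff = config$cutoff)
  pore <- pipeline_pore(msd_records, cohort, config)

  dmat <- bray_curtis_matrix(cohort$compositions)
  assignments <- assign_cst_labels(pam_cluster(dmat, k = config$k),
                                   cohort$compositions)
  timelines <- pipeline_timelines(assignments, cohort$metadata)

  stats <- pipeline_stats(cohort, excl, mobility, pore, assignments,
                          timelines, config)

  bundle <- structure(c(
    list(cohort = cohort$metadata, exclusions = excl$log,
         msd = msd_records, mobility = mobility, pore = pore,
         cst_assignments = assignments, timelines = timelines),
    stats,
    list(provenance = list(
      seed = config$seed,
      n_participants = config$cohort$n_participants,
      n_samples = nrow(cohort$metadata),
      n_included = length(included),
      use_video = config$use_video,
      package_version = as.character(utils::packageVersion("cvmbarrier")),
      r_version = R.version.string),
      truth = cohort$truth)), class = "report_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# Simulate (or render + re-track) every included sample's particles and
# return the tau = 1 s MSD records, stamped with sample and probe ids.
pipeline_particles <- function(cohort, config, included, seed) {
  probes <- config$cohort$probes
  grid <- expand.grid(sample_id = included, probe = probes$probe,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$sample_id, grid$probe), , drop = FALSE]
  sub_seeds <- seed_streams(seed, nrow(grid))
  d_trapped <- 10^config$trapped_log10_msd / 4
  truth_mob <- cohort$truth$mobility
  truth_pore <- cohort$truth$pore
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sid <- grid$sample_id[i]; pr <- grid$probe[i]
    diam <- probes$diameter_nm[probes$probe == pr]
    f <- truth_mob$mobile_fraction[truth_mob$sample_id == sid &
                                     truth_mob$probe == pr]
    xi <- truth_pore$xi_nm[truth_pore$sample_id == sid]
    d0 <- stokes_einstein_d0(diam, config$temperature, config$viscosity)
    d_mob <- d0 * obstruction_hindrance(xi, diam, config$d_fiber_nm)
    pops <- list(
      population_spec(1 - f, d_trapped, config$trapped_alpha, "trapped"),
      population_spec(f, d_mob, 1, "mobile"))
    set <- simulate_sample(pops, config$n_particles, config$optics,
                           seed = sub_seeds[i])
    traj <- if (config$use_video) {
      stack <- render_video(set, seed = sub_seeds[i])
      link_trajectories(detect_spots(stack, config$optics), config$link)
    } else set$trajectories
    rec <- msd_at_one_second(traj, dt = config$optics$dt, tau = config$tau,
                             min_pairs = config$min_pairs)
    if (nrow(rec)) out[[i]] <- cbind(sample_id = sid, probe = pr, rec)
  }
  do.call(rbind, out)
}

# Ensemble-average MSD per sample per MPP probe -> pore-size estimates.
pipeline_pore <- function(msd_records, cohort, config) {
  probes <- config$cohort$probes
  mpp <- probes[probes$surface == "MPP", , drop = FALSE]
  rec <- msd_records[msd_records$eligible &
                       msd_records$probe %in% mpp$probe, , drop = FALSE]
  if (nrow(rec) == 0) return(NULL)
  avg <- aggregate(msd ~ sample_id + probe, data = rec, FUN = mean)
  rows <- lapply(split(avg, avg$sample_id), function(g) {
    msd_by_probe <- setNames(
      g$msd, mpp$diameter_nm[match(g$probe, mpp$probe)])
    est <- sample_pore_size(msd_by_probe, tau = config$tau,
                            temperature = config$temperature,
                            viscosity = config$viscosity,
                            d_fiber_nm = config$d_fiber_nm,
                            sample_id = g$sample_id[1])
    xi <- est$per_probe_xi[as.character(mpp$diameter_nm)]
    data.frame(sample_id = g$sample_id[1],
               setNames(as.list(unname(xi)),
                        paste0("xi_", mpp$diameter_nm)),
               xi_mean_nm = est$xi_mean,
               flags = paste(est$flags, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Carry each participant's CST timeline forward to delivery.
pipeline_timelines <- function(assignments, metadata) {
  m <- merge(assignments[c("sample_id", "cst")],
             metadata[c("sample_id", "participant_id", "week",
                        "delivery_week")], by = "sample_id")
  rows <- lapply(split(m, m$participant_id), function(g) {
    tl <- carry_forward_cst(g[order(g$week), c("week", "cst")],
                            g$delivery_week[1])
    cbind(participant_id = g$participant_id[1], tl)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pipeline_stats <- function(cohort, excl, mobility, pore, assignments,
                           timelines, config) {
  meta <- cohort$metadata
  dist_tab <- cst_distribution_by_outcome(assignments, meta)
  mob_by_cst <- participant_cst_mobility_average(mobility, assignments, meta)

  # per-probe ANOVA across CSTs + Welch t of CST I vs CST IV
  tests <- lapply(split(mob_by_cst, mob_by_cst$probe), function(g) {
    groups <- split(g$mobile_fraction, g$cst)
    groups <- groups[lengths(groups) >= 2]
    an <- if (length(groups) >= 2) anova_tukey(groups) else NULL
    wt <- if (all(c("I", "IV") %in% names(groups)))
      welch_t(groups[["I"]], groups[["IV"]]) else NULL
    list(probe = g$probe[1], anova = an, welch_I_vs_IV = wt)
  })

  pore_test <- NULL
  if (!is.null(pore)) {
    pm <- merge(pore, assignments[c("sample_id", "cst")], by = "sample_id")
    gi <- pm$xi_mean_nm[pm$cst == "I" & is.finite(pm$xi_mean_nm)]
    gv <- pm$xi_mean_nm[pm$cst == "IV" & is.finite(pm$xi_mean_nm)]
    if (length(gi) >= 2 && length(gv) >= 2) pore_test <- welch_t(gi, gv)
  }

  # mobility vs gestational week, per probe
  mw <- merge(mobility, meta[c("sample_id", "week")], by = "sample_id")
  regressions <- do.call(rbind, lapply(split(mw, mw$probe), function(g) {
    g <- g[is.finite(g$mobile_fraction), ]
    if (nrow(g) < 3 || sd(g$week) == 0) return(NULL)
    r <- slope_regression(g$week, g$mobile_fraction)
    data.frame(probe = g$probe[1], slope = r$slope,
               r_squared = r$r_squared, p = r$p, n = r$n)
  }))
  if (!is.null(regressions)) rownames(regressions) <- NULL

  # CST IV exposure (ever assigned or carried) vs preterm delivery
  parts <- unique(meta[c("participant_id", "outcome")])
  ever_iv <- tapply(timelines$cst == "IV", timelines$participant_id, any)
  parts$exposed_iv <- as.logical(ever_iv[parts$participant_id])
  risk <- with(parts, contingency_stats(
    a = sum(exposed_iv & outcome == "preterm"),
    b = sum(exposed_iv & outcome == "term"),
    c = sum(!exposed_iv & outcome == "preterm"),
    d = sum(!exposed_iv & outcome == "term")))

  list(cst_distribution = dist_tab, mobility_by_cst = mob_by_cst,
       mobility_cst_tests = tests, pore_test = pore_test,
       regressions = regressions, risk = risk)
}

#' Percentage of samples in each CST, split by delivery outcome
#'
#' @param assignments data.frame `sample_id, cst`.
#' @param metadata data.frame `sample_id, outcome` (outcome `"term"` /
#'   `"preterm"`).
#' @return data.frame `outcome, cst, n, pct`; percentages sum to 100
#'   within each outcome group. Empty outcome groups are omitted with a
#'   warning.
#' @export
cst_distribution_by_outcome <- function(assignments, metadata) {
  m <- merge(assignments[c("sample_id", "cst")],
             metadata[c("sample_id", "outcome")], by = "sample_id")
  out <- lapply(split(m, m$outcome), function(g) {
    n <- table(factor(g$cst, levels = .cst_levels))
    data.frame(outcome = g$outcome[1], cst = names(n),
               n = as.integer(n), pct = 100 * as.integer(n) / nrow(g))
  })
  missing <- setdiff(unique(metadata$outcome), names(out))
  if (length(missing))
    warning("no samples for outcome group(s): ",
            paste(missing, collapse = ", "))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Demographics table with risk columns
#'
#' For each logical attribute column, counts and integer-rounded
#' percentages per outcome group in the `"n (pct)"` style, plus RR, OR and
#' Fisher p from [contingency_stats()] with preterm as the case column.
#'
#' @param participants One row per participant with an `outcome` column
#'   (`"term"` / `"preterm"`).
#' @param attributes Character vector of logical columns to tabulate
#'   (defaults to every logical column). Unknown columns are skipped with
#'   a warning.
#' @return data.frame `label, total, term, preterm, rr, or_, fisher_p`
#'   where the first three are `"n (pct)"` strings.
#' @export
demographics_table <- function(participants, attributes = NULL) {
  if (nrow(participants) == 0 || !"outcome" %in% names(participants)) {
    return(data.frame(label = character(), total = character(),
                      term = character(), preterm = character(),
                      rr = numeric(), or_ = numeric(),
                      fisher_p = numeric()))
  }
  is_logical <- vapply(participants, is.logical, logical(1))
  attributes <- attributes %||% names(participants)[is_logical]
  unknown <- setdiff(attributes, names(participants))
  if (length(unknown)) {
    warning("skipping unknown attribute column(s): ",
            paste(unknown, collapse = ", "))
    attributes <- setdiff(attributes, unknown)
  }
  term <- participants$outcome == "term"
  cell <- function(k, n) sprintf("%d (%.0f)", k, ifelse(n > 0, 100 * k / n, 0))
  rows <- lapply(attributes, function(at) {
    flag <- as.logical(participants[[at]])
    a <- sum(flag & !term); b <- sum(flag & term)
    c_ <- sum(!flag & !term); d <- sum(!flag & term)
    cs <- contingency_stats(a, b, c_, d)
    data.frame(label = at,
               total = cell(sum(flag), nrow(participants)),
               term = cell(b, sum(term)),
               preterm = cell(a, sum(!term)),
               rr = cs$rr, or_ = cs$or_, fisher_p = cs$fisher_p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published cohort 2x2 counts and the risk table computed from them
#'
#' `table1_counts()` loads the demographic attribute counts of the
#' 92-participant pregnancy cohort (82 term, 10 preterm deliveries)
#' shipped with the package; `published_risk_table()` recomputes relative
#' risk, odds ratio, confidence intervals and Fisher p for every attribute
#' from those counts.
#'
#' @param term_total,preterm_total Cohort outcome-group sizes.
#' @return `table1_counts()`: data.frame `label, n_total, n_term,
#'   n_preterm`. `published_risk_table()`: data.frame `label, n_total,
#'   n_term, n_preterm, rr, or_, rr_ci_low, rr_ci_high, or_ci_low,
#'   or_ci_high, fisher_p`.
#' @export
table1_counts <- function() {
  read.csv(system.file("extdata", "cohort_demographic_counts.csv",
                       package = "cvmbarrier"), stringsAsFactors = FALSE)
}

#' @rdname table1_counts
#' @param counts A counts data.frame as returned by [table1_counts()].
#' @export
published_risk_table <- function(counts = table1_counts(),
                                 term_total = 82, preterm_total = 10) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    a <- counts$n_preterm[i]; b <- counts$n_term[i]
    cs <- contingency_stats(a, b, preterm_total - a, term_total - b)
    data.frame(label = counts$label[i], n_total = counts$n_total[i],
               n_term = b, n_preterm = a, rr = cs$rr, or_ = cs$or_,
               rr_ci_low = cs$rr_ci[1], rr_ci_high = cs$rr_ci[2],
               or_ci_low = cs$or_ci[1], or_ci_high = cs$or_ci[2],
               fisher_p = cs$fisher_p)
  })
  do.call(rbind, rows)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) if (!is.null(x) && is.data.frame(x))
    write.csv(x, file.path(out_dir, paste0(name, ".csv")),
              row.names = FALSE)
  wr(bundle$cohort, "cohort_metadata")
  wr(data.frame(reason = names(bundle$exclusions),
                n = as.integer(bundle$exclusions)), "exclusion_log")
  wr(bundle$mobility, "mobility")
  wr(bundle$pore, "pore_size")
  wr(bundle$cst_assignments, "cst_assignments")
  wr(bundle$timelines, "cst_timelines")
  wr(bundle$cst_distribution, "cst_distribution")
  wr(bundle$mobility_by_cst, "mobility_by_cst")
  wr(bundle$regressions, "regressions")
  risk <- bundle$risk
  wr(data.frame(a = risk$a, b = risk$b, c = risk$c, d = risk$d,
                rr = risk$rr, or_ = risk$or_, fisher_p = risk$fisher_p),
     "risk_cst_iv")
  writeLines(paste(names(unlist(bundle$provenance)),
                   unlist(bundle$provenance), sep = "="),
             file.path(out_dir, "provenance.txt"))
  invisible(out_dir)
}
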