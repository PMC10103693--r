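#' Default probe panel: PEG-coated mucus-penetrating particles
#'
#' @return data.frame with columns `probe`, `diameter_nm`, `surface`.
#' @export
default_probes <- function() {
  data.frame(probe = c("MPP100", "MPP200", "MPP500"),
             diameter_nm = c(100, 200, 500),
             surface = "MPP", stringsAsFactors = FALSE)
}

# Mean mobile fraction per CST per probe. Lactobacillus crispatus-dominated
# samples (CST I) show the tightest barrier and polymicrobial samples
# (CST IV) a markedly leakier one; larger probes are more hindered.
default_cst_mobility_means <- function() {
  m <- rbind(I   = c(0.725, 0.628, 0.526),
             II  = c(0.937, 0.974, 0.877),
             III = c(0.840, 0.800, 0.680),
             IV  = c(0.871, 0.850, 0.750),
             V   = c(0.800, 0.700, 0.600))
  colnames(m) <- default_probes()$probe
  m
}

# Mean effective pore size (nm) per CST; CST I tighter than CST IV.
default_cst_pore_means <- function() {
  c(I = 250, II = 450, III = 330, IV = 420, V = 300)
}

# First-order Markov transitions between CSTs across ~4-week visits:
# strongly persistent, with III -> I and III -> IV the most common moves.
default_cst_transitions <- function() {
  m <- rbind(
    I   = c(0.85, 0.01, 0.08, 0.05, 0.01),
    II  = c(0.05, 0.85, 0.05, 0.03, 0.02),
    III = c(0.15, 0.01, 0.70, 0.12, 0.02),
    IV  = c(0.05, 0.01, 0.12, 0.80, 0.02),
    V   = c(0.05, 0.01, 0.07, 0.02, 0.85))
  colnames(m) <- .cst_levels
  m
}

#' Configuration of the synthetic longitudinal pregnancy cohort
#'
#' Defines the study conditions the cohort generator emulates: participants
#' enrol in early-mid pregnancy and self-collect samples approximately
#' every 4 weeks; each sample carries a vaginal microbiome community state
#' type (CST) evolving as a first-order Markov chain, a CST-structured
#' taxon composition, per-probe ground-truth particle mobility, a
#' ground-truth effective pore size, and blood / recent-intercourse
#' exclusion flags; the delivery outcome (term vs preterm) is drawn from a
#' CST-dependent risk.
#'
#' @param n_participants Number of participants (default 20).
#' @param visit_interval Weeks between visits (default 4).
#' @param enrollment_weeks Range of gestational weeks at enrolment.
#' @param last_visit_week No scheduled visits after this gestational week.
#' @param cst_transition_matrix 5x5 row-stochastic matrix over CSTs I-V.
#' @param initial_cst_probs Initial CST distribution.
#' @param per_cst_mobility_means CST x probe matrix of mean mobile fractions.
#' @param mobility_sd Between-sample SD of the true mobile fraction.
#' @param per_cst_pore_means Named vector, mean pore size (nm) per CST.
#' @param pore_sd Between-sample SD of the true pore size (nm).
#' @param preterm_risk_by_cst Named vector of preterm-birth probabilities;
#'   a participant's risk is that of the highest-risk CST they visit.
#' @param exclusion_rates Named vector `c(blood = , intercourse = )` of
#'   per-sample flag probabilities.
#' @param attrition_rate Probability a participant drops out early (their
#'   visit schedule is truncated).
#' @param probes Probe panel data.frame (see [default_probes()]).
#' @param n_taxa Taxa in the composition table.
#' @param seed Integer seed; fixed seed gives a bit-reproducible cohort.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 20,
                          visit_interval = 4,
                          enrollment_weeks = c(8, 16),
                          last_visit_week = 36,
                          cst_transition_matrix = default_cst_transitions(),
                          initial_cst_probs = c(I = 0.29, II = 0.04,
                                                III = 0.32, IV = 0.28,
                                                V = 0.07),
                          per_cst_mobility_means = default_cst_mobility_means(),
                          mobility_sd = 0.06,
                          per_cst_pore_means = default_cst_pore_means(),
                          pore_sd = 40,
                          preterm_risk_by_cst = c(I = 0.04, II = 0.05,
                                                  III = 0.12, IV = 0.35,
                                                  V = 0.05),
                          exclusion_rates = c(blood = 0.05,
                                              intercourse = 0.05),
                          attrition_rate = 0.12,
                          probes = default_probes(),
                          n_taxa = 12,
                          seed = 1L) {
  if (n_participants < 1) stop("'n_participants' must be >= 1")
  tm <- as.matrix(cst_transition_matrix)
  if (!all(dim(tm) == c(5L, 5L)) || any(tm < 0) ||
      any(abs(rowSums(tm) - 1) > 1e-9))
    stop("'cst_transition_matrix' must be 5x5 row-stochastic")
  dimnames(tm) <- list(.cst_levels, .cst_levels)
  if (any(initial_cst_probs < 0) || abs(sum(initial_cst_probs) - 1) > 1e-9)
    stop("'initial_cst_probs' must be a probability vector over I-V")
  for (p in list(preterm_risk_by_cst, exclusion_rates, attrition_rate))
    if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  if (any(per_cst_mobility_means < 0 | per_cst_mobility_means > 1))
    stop("'per_cst_mobility_means' must be in [0, 1]")
  structure(list(
    n_participants = as.integer(n_participants),
    visit_interval = visit_interval,
    enrollment_weeks = enrollment_weeks,
    last_visit_week = last_visit_week,
    cst_transition_matrix = tm,
    initial_cst_probs = initial_cst_probs,
    per_cst_mobility_means = per_cst_mobility_means,
    mobility_sd = mobility_sd,
    per_cst_pore_means = per_cst_pore_means,
    pore_sd = pore_sd,
    preterm_risk_by_cst = preterm_risk_by_cst,
    exclusion_rates = exclusion_rates,
    attrition_rate = attrition_rate,
    probes = probes, n_taxa = n_taxa,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Simulate a longitudinal pregnancy cohort with ground truth
#'
#' Draws, per participant: an enrolment week and visit schedule, a Markov
#' CST path over visits, a delivery outcome from the CST-dependent preterm
#' risk (the participant's risk is that of the highest-risk CST they ever
#' occupy) and a delivery week consistent with the outcome; per visit: a
#' taxon composition drawn from the CST archetype, per-probe true mobile
#' fractions around the CST means, a true pore size around the CST mean,
#' and exclusion flags. All ground truth is retained for recovery tests.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: list with `metadata`
#'   (one row per sample: `participant_id, sample_id, week, probe_set,
#'   blood_flag, intercourse_flag, delivery_week, outcome`), `compositions`
#'   (samples x taxa matrix), `truth` (list with `cst`, `mobility`, `pore`,
#'   `participants` data.frames), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    meta <- list(); cst_truth <- list(); mob_truth <- list()
    pore_truth <- list(); part_truth <- list(); comp_labels <- list()
    sid <- 0L
    for (i in seq_len(config$n_participants)) {
      pid <- sprintf("P%03d", i)
      w0 <- sample(seq(config$enrollment_weeks[1],
                       config$enrollment_weeks[2]), 1)
      weeks <- seq(w0, config$last_visit_week, by = config$visit_interval)
      if (length(weeks) > 1 && runif(1) < config$attrition_rate)
        weeks <- weeks[seq_len(sample(length(weeks) - 1L, 1))]
      path <- character(length(weeks))
      path[1] <- sample(.cst_levels, 1, prob = config$initial_cst_probs)
      for (v in seq_along(weeks)[-1])
        path[v] <- sample(.cst_levels, 1,
                          prob = config$cst_transition_matrix[path[v - 1], ])
      risk <- max(config$preterm_risk_by_cst[unique(path)])
      preterm <- runif(1) < risk
      delivery <- if (preterm) {
        min(max(rnorm(1, 34.5, 2), 27), 36.9)
      } else min(max(rnorm(1, 39.3, 1.2), 37), 42.5)
      # visits cannot postdate delivery
      keep <- weeks < delivery
      if (!any(keep)) keep[1] <- TRUE
      weeks <- weeks[keep]; path <- path[keep]
      part_truth[[i]] <- data.frame(
        participant_id = pid, risk = unname(risk),
        outcome = if (preterm) "preterm" else "term",
        delivery_week = delivery)
      for (v in seq_along(weeks)) {
        sid <- sid + 1L
        sample_id <- sprintf("%s_w%02d", pid, weeks[v])
        meta[[sid]] <- data.frame(
          participant_id = pid, sample_id = sample_id, week = weeks[v],
          probe_set = paste(config$probes$probe, collapse = ";"),
          blood_flag = runif(1) < config$exclusion_rates[["blood"]],
          intercourse_flag = runif(1) < config$exclusion_rates[["intercourse"]],
          delivery_week = delivery,
          outcome = if (preterm) "preterm" else "term")
        cst_truth[[sid]] <- data.frame(sample_id = sample_id, cst = path[v])
        mob_truth[[sid]] <- data.frame(
          sample_id = sample_id, probe = config$probes$probe,
          mobile_fraction = pmin(pmax(
            rnorm(nrow(config$probes),
                  config$per_cst_mobility_means[path[v], config$probes$probe],
                  config$mobility_sd), 0.02), 0.98))
        pore_truth[[sid]] <- data.frame(
          sample_id = sample_id,
          xi_nm = max(rnorm(1, config$per_cst_pore_means[[path[v]]],
                            config$pore_sd), 80))
        comp_labels[[sid]] <- path[v]
      }
    }
    cst_truth <- do.call(rbind, cst_truth)
    compositions <- simulate_composition_table(
      unlist(comp_labels), n_taxa = config$n_taxa,
      sample_ids = cst_truth$sample_id)
    structure(list(
      metadata = do.call(rbind, meta),
      compositions = compositions,
      truth = list(cst = cst_truth,
                   mobility = do.call(rbind, mob_truth),
                   pore = do.call(rbind, pore_truth),
                   participants = do.call(rbind, part_truth)),
      config = config), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d participants, %d samples, %d preterm\n",
              nrow(x$truth$participants), nrow(x$metadata),
              sum(x$truth$participants$outcome == "preterm")))
  invisible(x)
}
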