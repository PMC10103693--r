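#' Bray-Curtis dissimilarity matrix of a composition table
#'
#' `BC(a, b) = 1 - 2 * sum_i min(a_i, b_i) / (sum_i a_i + sum_i b_i)`,
#' computed over all sample pairs. Input rows must be relative abundances
#' summing to 1 (within 1e-6).
#'
#' @param table Numeric matrix, rows = samples (named), columns = taxa.
#' @return A `dist` object with sample labels.
#' @export
bray_curtis_matrix <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2) stop("at least 2 samples are required")
  if (any(table < 0)) stop("relative abundances must be non-negative")
  if (any(abs(rowSums(table) - 1) > 1e-6))
    stop("composition rows must sum to 1 (within 1e-6)")
  vegan::vegdist(table, method = "bray")
}

#' Partitioning around medoids on a precomputed distance matrix
#'
#' Classic PAM: deterministic BUILD initialization followed by SWAP to a
#' local optimum of the total within-cluster distance to medoid. Because
#' BUILD is deterministic the clustering is reproducible; `seed` is
#' accepted for interface symmetry but unused.
#'
#' @param distances A `dist` object (e.g. from [bray_curtis_matrix()]).
#' @param k Number of clusters (default 5, the five community state
#'   types); must not exceed the number of samples.
#' @param seed Ignored (PAM here is deterministic); present so callers can
#'   treat all cluster steps uniformly.
#' @return List with `clustering` (named integer vector),
#'   `medoids` (sample ids, one per cluster), `objective`
#'   (`build`/`swap` objective values), and the underlying `cluster::pam`
#'   object as `fit`.
#' @export
pam_cluster <- function(distances, k = 5, seed = NULL) {
  n <- attr(distances, "Size")
  if (k > n) stop("'k' must not exceed the number of samples")
  if (k == n) {   # degenerate: every sample is its own medoid
    ids <- attr(distances, "Labels") %||% as.character(seq_len(n))
    return(list(clustering = setNames(seq_len(n), ids), medoids = ids,
                objective = c(build = 0, swap = 0), fit = NULL))
  }
  fit <- cluster::pam(distances, k = k, diss = TRUE)
  list(clustering = fit$clustering, medoids = fit$medoids,
       objective = fit$objective, fit = fit)
}

#' Name PAM clusters as community state types I-V
#'
#' Each cluster is named by its medoid sample's dominant taxon:
#' L. crispatus maps to CST I, L. gasseri to II, L. iners to III and
#' L. jensenii to V, provided the medoid's dominant Lactobacillus reaches
#' the `dominance` threshold (default 0.5 relative abundance); clusters
#' whose medoid has no dominant Lactobacillus are the polymicrobial CST
#' IV. If two clusters map to the same Lactobacillus CST, the one with the
#' higher medoid dominant abundance keeps the name and the other falls
#' through to IV with a warning.
#'
#' @param clusters Result of [pam_cluster()].
#' @param table The composition matrix the clustering was computed on.
#' @param dominance Minimum medoid relative abundance for a Lactobacillus
#'   CST name (default 0.5).
#' @return data.frame `sample_id, cst, cluster, medoid_sample_id,
#'   dominant_taxon, dominant_abundance` (the dominant taxon/abundance of
#'   each sample itself).
#' @export
assign_cst_labels <- function(clusters, table, dominance = 0.5) {
  table <- as.matrix(table)
  medoids <- clusters$medoids
  k <- length(medoids)
  lacto_to_cst <- setNames(names(.cst_archetype), unname(.cst_archetype))
  cl_name <- character(k); cl_dom <- numeric(k)
  for (cl in seq_len(k)) {
    med <- table[medoids[cl], ]
    top <- which.max(med)
    cl_dom[cl] <- med[top]
    taxon <- colnames(table)[top]
    cl_name[cl] <- if (taxon %in% names(lacto_to_cst) && med[top] >= dominance)
      lacto_to_cst[[taxon]] else "IV"
  }
  # tie-break duplicated Lactobacillus names
  for (nm in setdiff(unique(cl_name), "IV")) {
    which_nm <- which(cl_name == nm)
    if (length(which_nm) > 1) {
      loser <- which_nm[-which.max(cl_dom[which_nm])]
      warning(sprintf(
        "clusters %s all map to CST %s; keeping the most dominant medoid, %s",
        paste(which_nm, collapse = ","), nm,
        "reassigning the rest to CST IV"))
      cl_name[loser] <- "IV"
    }
  }
  cl <- clusters$clustering
  top_i <- max.col(table)
  data.frame(sample_id = rownames(table),
             cst = cl_name[cl],
             cluster = as.integer(cl),
             medoid_sample_id = medoids[cl],
             dominant_taxon = colnames(table)[top_i],
             dominant_abundance = table[cbind(seq_len(nrow(table)), top_i)],
             row.names = NULL)
}

#' Carry the last observed CST forward to delivery
#'
#' Longitudinal bookkeeping for participants lost to follow-up: the last
#' sampled CST is assumed to persist until delivery. If the last visit
#' precedes the delivery week, a carried row at the delivery week is
#' appended with `carried = TRUE`; a fully sampled timeline is returned
#' unchanged (all `carried = FALSE`).
#'
#' @param timeline data.frame with columns `week`, `cst` for one
#'   participant (any extra columns are preserved on observed rows).
#' @param delivery_week Gestational week of delivery.
#' @return data.frame `week, cst, carried`, sorted by week.
#' @export
carry_forward_cst <- function(timeline, delivery_week) {
  if (nrow(timeline) == 0)
    stop("participant has no CST assignments; excluded")
  timeline <- timeline[order(timeline$week), , drop = FALSE]
  out <- data.frame(week = timeline$week, cst = timeline$cst,
                    carried = FALSE)
  last <- nrow(out)
  if (out$week[last] < delivery_week) {
    out <- rbind(out, data.frame(week = delivery_week,
                                 cst = out$cst[last], carried = TRUE))
  }
  out
}

#' Average particle mobility per participant per CST
#'
#' Adjusts for unequal sampling across participants: for each participant,
#' each CST and each probe, the unweighted arithmetic mean of the
#' mobile fractions of that participant's samples assigned to that CST.
#' Samples with no CST assignment are dropped with a message.
#'
#' @param mobility data.frame `sample_id, probe, mobile_fraction` (e.g.
#'   from [sample_mobility_table()]).
#' @param assignments data.frame `sample_id, cst` (e.g. from
#'   [assign_cst_labels()]).
#' @param metadata data.frame `sample_id, participant_id`.
#' @return data.frame `participant_id, cst, probe, mobile_fraction,
#'   n_samples`.
#' @export
participant_cst_mobility_average <- function(mobility, assignments,
                                             metadata) {
  m <- merge(mobility, assignments[c("sample_id", "cst")], by = "sample_id",
             all.x = TRUE)
  m <- merge(m, unique(metadata[c("sample_id", "participant_id")]),
             by = "sample_id", all.x = TRUE)
  orphan <- is.na(m$cst) | is.na(m$participant_id)
  if (any(orphan)) {
    message(sum(orphan), " mobility rows without a CST assignment dropped")
    m <- m[!orphan, , drop = FALSE]
  }
  m <- m[!is.na(m$mobile_fraction), , drop = FALSE]
  if (nrow(m) == 0)
    return(data.frame(participant_id = character(), cst = character(),
                      probe = character(), mobile_fraction = numeric(),
                      n_samples = integer()))
  agg <- aggregate(mobile_fraction ~ participant_id + cst + probe, data = m,
                   FUN = mean)
  cnt <- aggregate(mobile_fraction ~ participant_id + cst + probe, data = m,
                   FUN = length)
  agg$n_samples <- cnt$mobile_fraction
  agg[order(agg$participant_id, agg$cst, agg$probe), , drop = FALSE]
}
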