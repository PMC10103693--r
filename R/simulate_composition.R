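#' Default taxon panel for synthetic vaginal microbiome compositions
#'
#' The first four taxa are the Lactobacillus archetypes that define
#' community state types I, II, III and V; the remainder are common
#' BV-associated anaerobes that dominate polymicrobial (CST IV) samples.
#'
#' @param n_taxa Number of taxa (>= 5; default 12).
#' @return Character vector of taxon names.
#' @export
default_taxa <- function(n_taxa = 12) {
  pool <- c("Lactobacillus crispatus", "Lactobacillus gasseri",
            "Lactobacillus iners", "Lactobacillus jensenii",
            "Gardnerella vaginalis", "Atopobium vaginae",
            "Prevotella bivia", "Megasphaera sp.", "Sneathia amnii",
            "Mobiluncus mulieris", "Dialister micraerophilus",
            "Finegoldia magna", "Anaerococcus tetradius",
            "Peptoniphilus lacrimalis", "Aerococcus christensenii",
            "Veillonella montpellierensis")
  if (n_taxa < 5) stop("'n_taxa' must be >= 5")
  if (n_taxa > length(pool)) stop("at most ", length(pool), " taxa available")
  pool[seq_len(n_taxa)]
}

.cst_archetype <- c(I = "Lactobacillus crispatus",
                    II = "Lactobacillus gasseri",
                    III = "Lactobacillus iners",
                    V = "Lactobacillus jensenii")

.cst_levels <- c("I", "II", "III", "IV", "V")

# Dirichlet concentration vector for one CST.
# Lactobacillus-dominated CSTs put a large weight on one archetype taxon
# (expected relative abundance ~0.88 at defaults); CST IV spreads moderate
# weight over the anaerobes so no taxon exceeds 0.3 in expectation.
cst_concentration <- function(cst_label, taxa,
                              dominance = 25, minor = 0.3,
                              poly_anaerobe = 2, poly_lacto = 0.5) {
  if (!cst_label %in% .cst_levels)
    stop("unknown CST label: ", cst_label)
  alpha <- rep(minor, length(taxa))
  names(alpha) <- taxa
  lactos <- intersect(unname(.cst_archetype), taxa)
  if (cst_label == "IV") {
    alpha[] <- poly_anaerobe
    alpha[lactos] <- poly_lacto
  } else {
    alpha[.cst_archetype[[cst_label]]] <- dominance
  }
  alpha
}

#' Simulate one sample's taxon relative-abundance vector for a given CST
#'
#' Draws a composition from a Dirichlet distribution whose concentration
#' parameters encode the CST archetype: CSTs I, II, III and V are dominated
#' by L. crispatus, L. gasseri, L. iners and L. jensenii respectively
#' (expected archetype abundance >= 0.7 at defaults), while CST IV is
#' polymicrobial with no taxon expected above 0.3.
#'
#' @param cst_label One of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @param n_taxa Number of taxa (>= 5); ignored when `taxa` is given.
#' @param seed Optional integer seed.
#' @param taxa Taxon names; must contain the four Lactobacillus archetypes.
#' @param ... Concentration overrides passed to the archetype model:
#'   `dominance`, `minor`, `poly_anaerobe`, `poly_lacto`.
#'
#' @return Named non-negative numeric vector summing to 1.
#' @export
simulate_composition <- function(cst_label, n_taxa = 12, seed = NULL,
                                 taxa = default_taxa(n_taxa), ...) {
  if (!all(unname(.cst_archetype) %in% taxa))
    stop("'taxa' must contain the four Lactobacillus archetype species")
  alpha <- cst_concentration(cst_label, taxa, ...)
  with_seed(seed, {
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    setNames(g / sum(g), names(alpha))
  })
}

#' Simulate a CST-labelled composition table
#'
#' @param cst_labels Character vector of CST labels, one per sample.
#' @param n_taxa Number of taxa.
#' @param seed Optional integer seed.
#' @param sample_ids Row names; defaults to `s0001`-style ids.
#' @param ... Passed to [simulate_composition()].
#' @return Numeric matrix, rows = samples (named), columns = taxa; each row
#'   sums to 1.
#' @export
simulate_composition_table <- function(cst_labels, n_taxa = 12, seed = NULL,
                                       sample_ids = NULL, ...) {
  taxa <- default_taxa(n_taxa)
  sample_ids <- sample_ids %||% sprintf("s%04d", seq_along(cst_labels))
  with_seed(seed, {
    m <- t(vapply(cst_labels, function(l)
      simulate_composition(l, taxa = taxa, ...), numeric(length(taxa))))
    dimnames(m) <- list(sample_ids, taxa)
    m
  })
}

#' Write / read relative-abundance tables (samples x taxa TSV)
#'
#' @param mat Matrix, rows = samples, columns = taxa.
#' @param path File path.
#' @return `read_composition_tsv` returns the matrix;
#'   `write_composition_tsv` returns `path` invisibly.
#' @export
write_composition_tsv <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_composition_tsv
#' @export
read_composition_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
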