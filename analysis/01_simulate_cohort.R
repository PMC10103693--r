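#!/usr/bin/env Rscript
# Stage 1: generate the synthetic longitudinal pregnancy cohort that the
# rest of the workflow analyses, and apply the sample exclusion rules.
# Writes the cohort metadata, the per-sample taxon composition table and
# the exclusion log under results/.

suppressMessages(library(cvmbarrier))

seed <- 20260901L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- cohort_config(n_participants = 30, seed = seed)
cohort <- simulate_cohort(cfg)
print(cohort)

excl <- apply_exclusions(cohort$metadata)
cat(sprintf("exclusions: %d of %d samples removed (%d blood, %d intercourse)\n",
            excl$log[["n_excluded"]], excl$log[["n_input"]],
            excl$log[["n_blood"]], excl$log[["n_intercourse"]]))

write.csv(cohort$metadata, file.path(out, "cohort_metadata.csv"),
          row.names = FALSE)
write_composition_tsv(cohort$compositions,
                      file.path(out, "compositions.tsv"))
write.csv(data.frame(reason = names(excl$log), n = as.integer(excl$log)),
          file.path(out, "exclusion_log.csv"), row.names = FALSE)
write.csv(cohort$truth$cst, file.path(out, "truth_cst.csv"),
          row.names = FALSE)

tab <- table(cohort$truth$cst$cst)
cat("ground-truth CST sample counts:\n")
print(tab)
cat(sprintf("preterm deliveries: %d / %d participants\n",
            sum(cohort$truth$participants$outcome == "preterm"),
            nrow(cohort$truth$participants)))
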