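test_that("Bray-Curtis hand cases are exact", {
  m <- rbind(a = c(0.5, 0.5, 0), b = c(0.5, 0.5, 0), c = c(0, 0, 1),
             d = c(0.8, 0.2, 0), e = c(0.2, 0.8, 0))
  bc <- as.matrix(bray_curtis_matrix(m))
  expect_equal(bc["a", "b"], 0)
  expect_equal(bc["a", "c"], 1)     # disjoint supports
  expect_equal(bc["d", "e"], 0.6)   # 1 - 2*0.4/2
})

test_that("Bray-Curtis matrices are symmetric with zero diagonal in [0,1]", {
  set.seed(61)
  tab <- simulate_composition_table(sample(c("I", "III", "IV"), 12,
                                           replace = TRUE))
  bc <- as.matrix(bray_curtis_matrix(tab))
  expect_equal(bc, t(bc))
  expect_true(all(diag(bc) == 0))
  expect_true(all(bc >= 0 & bc <= 1))
  expect_error(bray_curtis_matrix(tab * 2), "sum to 1")
  expect_error(bray_curtis_matrix(tab[1, , drop = FALSE]), "2 samples")
})

test_that("PAM recovers planted well-separated clusters exactly", {
  set.seed(62)
  centers <- rbind(c(0.9, 0.05, 0.05), c(0.05, 0.9, 0.05),
                   c(0.05, 0.05, 0.9))
  tab <- do.call(rbind, lapply(1:3, function(k) {
    t(vapply(1:8, function(i) {
      v <- centers[k, ] + runif(3, 0, 0.02); v / sum(v)
    }, numeric(3)))
  }))
  rownames(tab) <- sprintf("s%02d", 1:24)
  cl <- pam_cluster(bray_curtis_matrix(tab), k = 3)
  planted <- rep(1:3, each = 8)
  expect_equal(length(unique(paste(cl$clustering, planted))), 3)
  expect_true(all(cl$medoids %in% rownames(tab)))
  # SWAP can only improve on BUILD
  expect_lte(cl$objective[["swap"]], cl$objective[["build"]] + 1e-12)
})

test_that("k = n makes every sample its own medoid with zero objective", {
  set.seed(63)
  tab <- simulate_composition_table(c("I", "II", "III", "IV", "V"))
  cl <- pam_cluster(bray_curtis_matrix(tab), k = 5)
  expect_equal(cl$objective[["swap"]], 0)
  expect_setequal(cl$medoids, rownames(tab))
  expect_error(pam_cluster(bray_curtis_matrix(tab), k = 6), "exceed")
})

test_that("clustering is invariant to row permutation up to relabelling", {
  set.seed(64)
  co <- labelled_compositions(c(6, 4, 6, 6, 4), seed = 65)
  cl1 <- assign_cst_labels(pam_cluster(bray_curtis_matrix(co$table), 5),
                           co$table)
  perm <- sample(nrow(co$table))
  tab2 <- co$table[perm, ]
  cl2 <- assign_cst_labels(pam_cluster(bray_curtis_matrix(tab2), 5), tab2)
  m <- merge(cl1[c("sample_id", "cst")], cl2[c("sample_id", "cst")],
             by = "sample_id")
  expect_true(all(m$cst.x == m$cst.y))
})

test_that("clusters are named by medoid dominance with IV as fallback", {
  taxa <- default_taxa(6)
  tab <- rbind(
    s1 = c(0.90, 0.02, 0.02, 0.02, 0.02, 0.02),   # crispatus-dominated
    s2 = c(0.88, 0.03, 0.03, 0.02, 0.02, 0.02),
    s3 = c(0.05, 0.05, 0.05, 0.10, 0.25, 0.50),   # anaerobe-dominated
    s4 = c(0.25, 0.05, 0.05, 0.15, 0.25, 0.25))   # polymicrobial
  colnames(tab) <- taxa
  cl <- list(clustering = c(s1 = 1, s2 = 1, s3 = 2, s4 = 2),
             medoids = c("s1", "s4"))
  out <- assign_cst_labels(cl, tab)
  expect_equal(out$cst, c("I", "I", "IV", "IV"))
  expect_equal(out$dominant_taxon[1], "Lactobacillus crispatus")
  expect_equal(out$dominant_abundance[1], 0.90)
})

test_that("duplicate Lactobacillus clusters tie-break to CST IV", {
  taxa <- default_taxa(5)
  tab <- rbind(s1 = c(0.95, 0.01, 0.01, 0.01, 0.02),
               s2 = c(0.60, 0.10, 0.10, 0.10, 0.10))
  colnames(tab) <- taxa
  cl <- list(clustering = c(s1 = 1, s2 = 2), medoids = c("s1", "s2"))
  expect_warning(out <- assign_cst_labels(cl, tab), "CST I")
  expect_equal(out$cst, c("I", "IV"))
})

test_that("the last sampled CST carries forward to delivery", {
  tl <- data.frame(week = c(12, 20), cst = c("III", "I"))
  out <- carry_forward_cst(tl, delivery_week = 39)
  expect_equal(nrow(out), 3)
  expect_equal(out$cst[3], "I")
  expect_equal(out$week[3], 39)
  expect_equal(out$carried, c(FALSE, FALSE, TRUE))
  # fully sampled timelines are unchanged
  full <- data.frame(week = c(12, 39), cst = c("III", "I"))
  expect_equal(carry_forward_cst(full, 39)$carried, c(FALSE, FALSE))
  # a single sample spans the whole pregnancy
  one <- carry_forward_cst(data.frame(week = 10, cst = "IV"), 38)
  expect_equal(one$cst, c("IV", "IV"))
  expect_error(carry_forward_cst(data.frame(week = numeric(),
                                            cst = character()), 38),
               "no CST assignments")
})

test_that("participant mobility averages within CST are arithmetic means", {
  mob <- data.frame(sample_id = c("a", "b", "c", "d"),
                    probe = "MPP100",
                    mobile_fraction = c(0.1, 0.2, 0.3, 0.9))
  asg <- data.frame(sample_id = c("a", "b", "c", "d"),
                    cst = c("I", "I", "I", "IV"))
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     participant_id = "P1")
  out <- participant_cst_mobility_average(mob, asg, meta)
  expect_equal(nrow(out), 2)            # one row per CST visited
  expect_equal(out$mobile_fraction[out$cst == "I"], 0.2)
  expect_equal(out$n_samples[out$cst == "I"], 3)
  # orphan samples are dropped with a message; empty join yields empty table
  expect_message(
    out2 <- participant_cst_mobility_average(mob, asg[1:2, ], meta),
    "dropped")
  expect_equal(nrow(out2), 1)
  expect_equal(nrow(participant_cst_mobility_average(mob[0, ], asg, meta)),
               0)
})

test_that("synthetic CST labels are recovered end to end", {
  co <- labelled_compositions(c(15, 6, 15, 15, 9), seed = 66)
  cl <- pam_cluster(bray_curtis_matrix(co$table), k = 5)
  out <- assign_cst_labels(cl, co$table)
  expect_gte(mean(out$cst == co$labels), 0.95)
})
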