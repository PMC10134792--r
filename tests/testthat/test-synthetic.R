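test_that("case-control generator is seed-deterministic with exact depths", {
  a <- generate_case_control_study(10, 10, n_features = 50, seed = 7)
  b <- generate_case_control_study(10, 10, n_features = 50, seed = 7)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$metadata, b$metadata)
  c <- generate_case_control_study(10, 10, n_features = 50, seed = 8)
  expect_false(identical(a$table$values, c$table$values))

  # column sums equal the drawn depths exactly
  expect_equal(unname(colSums(a$table$values)), unname(a$truth$depths))

  expect_error(
    generate_case_control_study(5, 5, n_features = 20,
                                effects = data.frame(feature_id = "nope",
                                                     log_fold = 1), seed = 1),
    "unknown feature_id")
})

test_that("a planted ln(4) effect raises mean relative abundance in R", {
  eff <- data.frame(feature_id = "sp001", log_fold = log(4))
  g <- generate_case_control_study(100, 100, n_features = 50, effects = eff,
                                   seed = 11)
  rel <- sweep(g$table$values, 2, colSums(g$table$values), "/")
  is_R <- g$metadata$response == "R"
  mean_R <- mean(rel["sp001", is_R])
  mean_NR <- mean(rel["sp001", !is_R])
  expect_gt(mean_R, mean_NR)

  # oracle: expected abundances from the generating parameters themselves
  logits <- g$truth$baseline_logits + g$truth$study_bias[[1]]
  soft <- function(z) exp(z - max(z)) / sum(exp(z - max(z)))
  p_NR <- soft(logits)["sp001"]
  shifted <- logits; shifted["sp001"] <- shifted["sp001"] + log(4)
  p_R <- soft(shifted)["sp001"]
  expect_gt(p_R, p_NR)
  # sampled means sit near the noise-free expectations
  expect_lt(abs(mean_NR - p_NR) / p_NR, 0.5)
  expect_lt(abs(mean_R - p_R) / p_R, 0.5)
})

test_that("null generation yields differentials within the permutation spread", {
  g <- generate_case_control_study(20, 20, n_features = 80, seed = 3)
  fit <- fit_differentials(g$table, g$metadata)
  # permutation null: refit with shuffled labels
  spreads <- sapply(1:3, function(i) {
    md <- g$metadata
    set.seed(100 + i)
    md$response <- sample(md$response)
    sd(fit_differentials(g$table, md)$differentials)
  })
  frac_within <- mean(abs(fit$differentials) < 3 * max(spreads))
  expect_gte(frac_within, 0.95)
})

test_that("multi-study truth encodes the consolidation ground rules", {
  studies <- data.frame(name = c("a", "b", "c"), n_R = 10, n_NR = 10)
  ms <- generate_multi_study(studies, n_features = 40,
                             consistent_positive = c("sp001", "sp002"),
                             inconsistent = "sp003", seed = 5)
  expect_setequal(ms$truth$consolidated_truth, c("sp001", "sp002"))
  # inconsistent feature: positive in first two, negative in third
  lf <- sapply(ms$truth$effects, function(e) e$log_fold[e$feature_id == "sp003"])
  expect_true(all(lf[1:2] > 0) && lf[3] < 0)
  # shared ids across studies
  expect_identical(rownames(ms$bundles$a$table$values),
                   rownames(ms$bundles$c$table$values))

  expect_error(generate_multi_study(studies, consistent_positive = "sp001",
                                    inconsistent = "sp001", seed = 1),
               "overlap")
  null_ms <- generate_multi_study(studies, n_features = 40, seed = 6)
  expect_length(null_ms$truth$consolidated_truth, 0)
})

test_that("FMT generator honours engraftment probability limits", {
  # p = 1: every donor-specific species observed in the donor sample shows up
  # in every post-FMT sample of its recipients
  fmt <- generate_fmt_cohort(n_donors = 3, n_recipients = 6,
                             engraftment_prob_R = 1, engraftment_prob_NR = 1,
                             n_features = 60, seed = 2)
  v <- fmt$table$values
  md <- fmt$metadata
  for (r in names(fmt$truth$donor_of)) {
    d <- fmt$truth$donor_of[[r]]
    donor_col <- v[, md$sample_id[md$subject_id == d & md$role == "donor"][1]]
    base_col <- v[, md$sample_id[md$subject_id == r & md$timepoint_days <= 0 &
                                   !is.na(md$timepoint_days)][1]]
    donor_specific <- donor_col > 0 &
      fmt$truth$baseline_communities[[r]] == 0 & base_col == 0
    posts <- md$sample_id[md$subject_id == r & !is.na(md$timepoint_days) &
                            md$timepoint_days > 0]
    for (p in posts) {
      expect_true(all(v[donor_specific, p] > 0))
    }
  }

  # p = 0: no donor_derived truth labels anywhere
  fmt0 <- generate_fmt_cohort(n_donors = 3, n_recipients = 6,
                              engraftment_prob_R = 0, engraftment_prob_NR = 0,
                              n_features = 60, seed = 2, prob_new = 0)
  labels <- unlist(fmt0$truth$engraftment_truth)
  expect_false(any(labels == "donor_derived"))

  expect_error(generate_fmt_cohort(timepoints = c(14, 30), seed = 1),
               "baseline")
})

test_that("engraftment truth labels agree with generated table presence", {
  fmt <- generate_fmt_cohort(n_donors = 4, n_recipients = 8, seed = 9)
  v <- fmt$table$values
  md <- fmt$metadata
  for (r in names(fmt$truth$engraftment_truth)) {
    lab <- fmt$truth$engraftment_truth[[r]]
    d <- fmt$truth$donor_of[[r]]
    donor_col <- v[, md$sample_id[md$subject_id == d & md$role == "donor"][1]]
    # a donor_derived label requires donor carriage in truth
    dd <- names(lab)[lab == "donor_derived"]
    expect_true(all(fmt$truth$donor_communities[[d]][dd] > 0))
  }
})

test_that("functional profiles are copy-weighted sums over linked taxa", {
  tab <- tiny_table(rbind(c(2, 4), c(3, 1)), feature_ids = c("tA", "tB"))
  links <- data.frame(taxon_id = c("tA", "tB"), gene_group_id = "k1")
  # weights 1 and 2: k1 = 2*1 + 3*2 = 8 in sample 1
  fp <- derive_functional_profiles(tab, links, copy_weights = c(1, 2))
  expect_equal(unname(fp$values["k1", ]), c(8, 6))
  expect_equal(fp$feature_kind, "gene_group")

  # unlinked gene group is an all-zero row
  fp2 <- derive_functional_profiles(tab, links, gene_groups = c("k1", "k2"))
  expect_equal(unname(fp2$values["k2", ]), c(0, 0))

  # single taxon, unit weights: profile replicates the taxon abundance
  solo <- tiny_table(matrix(c(5, 7), 1), feature_ids = "tA")
  links2 <- data.frame(taxon_id = "tA", gene_group_id = c("k1", "k2"))
  fp3 <- derive_functional_profiles(solo, links2)
  expect_equal(unname(fp3$values["k1", ]), c(5, 7))
  expect_equal(unname(fp3$values["k2", ]), c(5, 7))

  expect_error(derive_functional_profiles(tab, links, copy_weights = c(-1, 1)),
               "negative copy weight")
  expect_error(derive_functional_profiles(
    tab, data.frame(taxon_id = "ghost", gene_group_id = "k1")), "unknown taxa")
})

test_that("link table generator is deterministic and well-formed", {
  l1 <- generate_link_table(sprintf("t%02d", 1:10), n_gene_groups = 20, seed = 4)
  l2 <- generate_link_table(sprintf("t%02d", 1:10), n_gene_groups = 20, seed = 4)
  expect_identical(l1, l2)
  expect_false(any(duplicated(l1)))
  expect_setequal(unique(l1$gene_group_id), sprintf("K%05d", 1:20))
})
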