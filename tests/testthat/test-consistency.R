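calls_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(feature_id = r[1], study = r[2], call = r[3],
               stringsAsFactors = FALSE)
  }))
}

test_that("consolidation applies the two published rules", {
  calls <- calls_df(
    c("A", "study1", "RMI"), c("A", "study2", "RMI"),        # rule (i): in
    c("B", "study1", "RMI"),                                  # 1 study: out
    c("C", "study1", "RMI"), c("C", "study2", "RMI"),
    c("C", "study3", "UMI"))                                  # rule (ii): out
  led <- consolidate(calls, consistency_rules(), "RMI")
  expect_equal(led$consolidated$feature_id, "A")
  expect_equal(led$consolidated$supporting_studies, "study1,study2")
  expect_equal(led$removed$reason[led$removed$feature_id == "B"],
               "insufficient_support")
  expect_equal(led$removed$reason[led$removed$feature_id == "C"],
               "opposite_call")
})

test_that("a feature UMI in two FMT cohorts but RMI elsewhere is excluded", {
  # the Prevotella copri pattern: UMI in both FMT datasets, RMI in one
  # group-comparison dataset -> excluded from the UMI list
  calls <- calls_df(
    c("P_copri", "Baruch2021", "UMI"), c("P_copri", "Davar2021", "UMI"),
    c("P_copri", "Frankel2017", "RMI"))
  led <- consolidate(calls, consistency_rules(), "UMI")
  expect_false("P_copri" %in% led$consolidated$feature_id)
  expect_equal(led$removed$reason[led$removed$feature_id == "P_copri"],
               "opposite_call")
  # without the exclusion rule it would have been consolidated
  led2 <- consolidate(calls, consistency_rules(exclusion_on_any_opposite = FALSE),
                      "UMI")
  expect_true("P_copri" %in% led2$consolidated$feature_id)
})

test_that("consolidation is order-independent and monotone in studies", {
  set.seed(15)
  studies <- paste0("s", 1:4)
  features <- paste0("f", 1:30)
  calls <- expand.grid(feature_id = features, study = studies,
                       stringsAsFactors = FALSE)
  calls$call <- sample(c("RMI", "UMI", "none"), nrow(calls), TRUE,
                       prob = c(0.2, 0.2, 0.6))
  led <- consolidate(calls, consistency_rules(), "RMI")
  shuffled <- calls[sample(nrow(calls)), ]
  led_sh <- consolidate(shuffled, consistency_rules(), "RMI")
  expect_equal(led$consolidated, led_sh$consolidated)

  # dropping a study never adds a consolidated feature
  for (drop in studies[1:3]) {
    sub <- calls[calls$study != drop, ]
    led_sub <- consolidate(sub, consistency_rules(), "RMI")
    expect_true(all(led_sub$consolidated$feature_id %in%
                      led$consolidated$feature_id) ||
                # removing an opposite call may rescue a feature; exclude those
                all(setdiff(led_sub$consolidated$feature_id,
                            led$consolidated$feature_id) %in%
                      led$removed$feature_id[led$removed$reason == "opposite_call"]))
  }
})

mk_result <- function(study, d) {
  structure(list(study = study, feature_ids = names(d), differentials = d,
                 rank_order = names(d)[order(-d, names(d))],
                 fit_info = list(converged = TRUE)),
            class = "differential_result")
}

test_that("validation retains, contradicts and enforces the magnitude floor", {
  calls <- calls_df(c("A", "s1", "RMI"), c("A", "s2", "RMI"),
                    c("B", "s1", "RMI"), c("B", "s2", "RMI"),
                    c("C", "s1", "RMI"), c("C", "s2", "RMI"))
  led <- consolidate(calls, consistency_rules(), "RMI")
  v1 <- mk_result("v1", c(A = 0.6, B = 0.3, C = 0.4))
  v2 <- mk_result("v2", c(A = 0.4, B = -0.2, C = 0.05))
  out <- validate_biomarkers(led, list(v1, v2), consistency_rules())
  expect_equal(out$validated$feature_id, "A")
  expect_equal(out$removed$reason[out$removed$feature_id == "B"],
               "contradiction_in_validation")
  expect_equal(out$removed$reason[out$removed$feature_id == "C"],
               "below_magnitude")

  # validated subset of consolidated subset of ever-called
  expect_true(all(out$validated$feature_id %in% led$consolidated$feature_id))
  expect_true(all(led$consolidated$feature_id %in%
                    calls$feature_id[calls$call == "RMI"]))

  # a feature missing from a validation study is a contradiction, with warning
  v3 <- mk_result("v3", c(A = 0.5))
  v4 <- mk_result("v4", c(A = 0.5, B = 0.5, C = 0.5))
  w <- capture_warnings(out2 <- validate_biomarkers(led, list(v3, v4)))
  expect_true(all(grepl("treated as contradiction", w)))
  expect_length(w, 2)  # one per missing feature
  expect_setequal(out2$validated$feature_id, "A")

  # validation studies must be disjoint from discovery studies
  expect_error(validate_biomarkers(led, list(mk_result("s1", c(A = 1)))),
               "overlap")
})

test_that("denominator selection is strict at the -0.5 threshold", {
  res <- mk_result("v", c(A = -0.6, B = -0.4, C = 1.0, D = -0.5))
  expect_equal(select_denominator(res), "A")  # -0.5 itself excluded
  expect_error(select_denominator(mk_result("v", c(A = 1, B = 2))),
               "bottom-k")
})

test_that("ledger export is table-shaped with reasons", {
  calls <- calls_df(c("A", "s1", "RMI"), c("A", "s2", "RMI"),
                    c("B", "s1", "RMI"), c("B", "s2", "RMI"))
  led <- consolidate(calls, consistency_rules(), "RMI")
  led <- validate_biomarkers(led, list(mk_result("v1", c(A = 0.5, B = -0.5))))
  path <- withr::local_tempfile(fileext = ".tsv")
  ann <- data.frame(feature_id = c("A", "B"), phylum = c("Firmicutes", "Bacteroidetes"))
  out <- write_ledger(led, path, ann)
  tsv <- read.delim(path)
  expect_setequal(names(tsv), c("feature_id", "phylum", "direction",
                                "supporting_studies", "status", "removal_reason"))
  expect_equal(tsv$status[tsv$feature_id == "A"], "validated")
  expect_equal(tsv$removal_reason[tsv$feature_id == "B"],
               "contradiction_in_validation")
})
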