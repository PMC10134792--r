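test_that("log-ratio values, zero handling and scale invariance", {
  tab <- tiny_table(rbind(c(3, 10, 0), c(5, 0, 2), c(2, 5, 0), c(2, 5, 1)),
                    feature_ids = c("n1", "n2", "d1", "d2"))
  lr <- log_ratio(tab, c("n1", "n2"), c("d1", "d2"))
  expect_equal(unname(lr$per_sample_log_ratio[1]), log(8 / 4))
  expect_equal(unname(lr$per_sample_log_ratio[2]), 0)  # 10/10
  # sample 3 has denominator 0+1 > 0, numerator 0+2 > 0 -> kept
  expect_equal(lr$n_dropped, 0)

  # a zero sum on either side drops the sample and counts it
  tab0 <- tiny_table(rbind(c(3, 0), c(2, 5)), feature_ids = c("n1", "d1"))
  lr0 <- log_ratio(tab0, "n1", "d1")
  expect_true(is.na(lr0$per_sample_log_ratio[2]))
  expect_equal(lr0$n_dropped, 1)

  # per-sample scale invariance
  tab7 <- tiny_table(tab$values %*% diag(c(7, 1, 1)),
                     feature_ids = rownames(tab$values),
                     sample_ids = colnames(tab$values))
  lr7 <- log_ratio(tab7, c("n1", "n2"), c("d1", "d2"))
  expect_equal(lr7$per_sample_log_ratio[1], lr$per_sample_log_ratio[1])

  expect_error(log_ratio(tab, c("n1"), c("n1", "d1")), "disjoint")
  expect_error(log_ratio(tab, "ghost", "d1"), "no numerator feature")
})

test_that("wilcoxon exact mode matches brute-force enumeration", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6), 0.1)
  expect_equal(wilcoxon_rank_sum(c(5, 5), c(5, 5)), 1)

  # property sweep over all group sizes with n_a + n_b <= 10
  set.seed(42)
  for (n1 in 1:5) {
    for (n2 in n1:(10 - n1)) {
      for (rep in 1:3) {
        x <- sample(seq_len(50), n1 + n2)  # untied
        a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
        expect_equal(wilcoxon_rank_sum(a, b, mode = "exact"),
                     brute_force_wilcoxon(a, b),
                     info = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
      }
    }
  }
  expect_error(wilcoxon_rank_sum(c(1, 2, 2), c(3, 4), mode = "exact"), "untied")
})

test_that("wilcoxon normal approximation tracks the exact test", {
  set.seed(7)
  for (rep in 1:10) {
    a <- rnorm(10); b <- rnorm(10, 0.3)
    p_e <- wilcoxon_rank_sum(a, b, mode = "exact")
    p_n <- wilcoxon_rank_sum(a, b, mode = "normal")
    expect_lt(abs(p_e - p_n), 0.02)
  }
  # agreement with the standard implementation on tied data
  a <- c(1, 2, 2, 3, 5, 5); b <- c(2, 4, 4, 6, 6, 7)
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))$p.value
  expect_equal(wilcoxon_rank_sum(a, b, mode = "normal"), ref, tolerance = 1e-10)
})

test_that("Benjamini-Hochberg step-up matches the hand example and p.adjust", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  set.seed(3)
  for (rep in 1:5) {
    p <- runif(25)^2
    q <- benjamini_hochberg(p)
    expect_equal(q, stats::p.adjust(p, "BH"))
    expect_true(all(q >= p) && all(q <= 1))
  }
})

test_that("Aitchison distance matches clr geometry and the oracle", {
  expect_equal(aitchison_distance(c(2, 8), c(8, 2)), 2 * sqrt(2) * log(2))
  x <- c(1, 2, 3, 4)
  expect_equal(aitchison_distance(x, x), 0)
  expect_equal(aitchison_distance(x, 2 * x), 0)  # clr scale invariance
  expect_error(aitchison_distance(c(0, 1), c(1, 1)), "pseudocount")
  set.seed(5)
  for (rep in 1:100) {
    a <- stats::rgamma(8, 1) + 0.01
    b <- stats::rgamma(8, 1) + 0.01
    expect_equal(aitchison_distance(a, b), oracle_aitchison(a, b))
  }
})

test_that("Bray-Curtis values and oracle agreement", {
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(2, 2), c(1, 3)), 0.25)
  expect_equal(bray_curtis(c(1, 2), c(1, 2)), 0)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  skip_if_not_installed("vegan")
  set.seed(6)
  for (rep in 1:20) {
    m <- matrix(stats::rpois(16, 5), 2)
    expect_equal(bray_curtis(m[1, ], m[2, ]),
                 as.numeric(vegan::vegdist(m, "bray")))
  }
})

test_that("permanova matches exhaustive enumeration on the separated toy", {
  D <- matrix(1, 6, 6); D[1:3, 1:3] <- 0; D[4:6, 4:6] <- 0; diag(D) <- 0
  labels <- rep(c("a", "b"), each = 3)
  p_exact <- brute_force_permanova_p(D, labels)
  expect_equal(p_exact, 0.1)
  res <- permanova(D, labels, n_permutations = 20000, seed = 1)
  expect_true(is.infinite(res$pseudo_F))  # observed F maximal (SS_within = 0)
  expect_lt(abs(res$p_value - p_exact), 0.01)
  expect_equal(res$r_squared, 1)
})

test_that("permanova permutation distribution matches brute force at n <= 8", {
  set.seed(8)
  pts <- matrix(rnorm(16), 8, 2)
  D <- as.matrix(dist(pts))
  labels <- rep(c("a", "b"), each = 4)
  p_exact <- brute_force_permanova_p(D, labels)
  res <- permanova(D, labels, n_permutations = 20000, seed = 2)
  # Monte-Carlo agreement: 4 sd of the binomial error
  tol <- 4 * sqrt(p_exact * (1 - p_exact) / 20000) + 1e-4
  expect_lt(abs(res$p_value - p_exact), tol)
  expect_true(res$r_squared >= 0 && res$r_squared <= 1)
  expect_gte(res$p_value, 1 / (res$n_permutations + 1))
  expect_error(permanova(D, c(rep("a", 7), "b"), 100, 1), "singleton")
})

test_that("permanova F and R2 agree with the vegan reference", {
  skip_if_not_installed("vegan")
  set.seed(9)
  pts <- matrix(rnorm(60), 20, 3)
  pts[11:20, ] <- pts[11:20, ] + 0.8
  D <- dist(pts)
  labels <- rep(c("g1", "g2"), each = 10)
  res <- permanova(as.matrix(D), labels, n_permutations = 999, seed = 3)
  ref <- vegan::adonis2(D ~ labels, permutations = 999)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(res$r_squared, ref$R2[1], tolerance = 1e-10)
})

test_that("log-ratio group test separates planted groups", {
  eff <- data.frame(feature_id = c("sp001", "sp002"), log_fold = log(4))
  g <- generate_case_control_study(40, 40, n_features = 50, effects = eff,
                                   seed = 13)
  res <- fit_differentials(g$table, g$metadata)
  den <- utils::tail(res$rank_order, 5)
  lr <- log_ratio_group_test(g$table, c("sp001", "sp002"), den, g$metadata)
  expect_lt(lr$group_p_value, 0.05)
  # stochastically smaller than under label permutation
  set.seed(14)
  md_perm <- g$metadata
  md_perm$response <- sample(md_perm$response)
  lr_perm <- log_ratio_group_test(g$table, c("sp001", "sp002"), den, md_perm)
  expect_lt(lr$group_p_value, lr_perm$group_p_value)
})
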