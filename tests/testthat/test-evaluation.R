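test_that("the KS statistic behaves analytically in degenerate cases", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  expect_equal(ks_two_sample(c(0, 1), c(2, 3))$D, 1)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("exact small-sample KS p-values match exhaustive enumeration", {
  set.seed(8)
  for (rep in 1:5) {
    a <- runif(4); b <- runif(4) + runif(1, -0.5, 0.5)
    res <- ks_two_sample(a, b)
    expect_equal(res$p, ks_exact_enum(a, b), tolerance = 1e-12)
  }
  # and at unequal sizes within the exact regime
  a <- runif(3); b <- runif(5)
  expect_equal(ks_two_sample(a, b)$p, ks_exact_enum(a, b), tolerance = 1e-12)
})

test_that("the KS statistic is invariant under common monotone transforms", {
  set.seed(9)
  a <- rnorm(20); b <- rnorm(25, 0.4)
  d0 <- ks_two_sample(a, b)$D
  for (f in list(function(x) exp(x), function(x) x^3, function(x) atan(x))) {
    expect_equal(ks_two_sample(f(a), f(b))$D, d0)
  }
})

test_that("roc_auc matches the pairwise oracle, pROC, and its reflection identity", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(10)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    s <- sample(1:6, n, replace = TRUE)      # ties on purpose
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l), auc_pair_oracle(s, l))
    expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(11)
    s <- rnorm(40); l <- runif(40) < 0.4
    expect_equal(roc_auc(s, l),
                 as.numeric(suppressMessages(pROC::auc(pROC::roc(
                   l, s, quiet = TRUE, direction = "<",
                   levels = c(FALSE, TRUE))))))
  }
})

test_that("identical cohorts compare as indistinguishable across all features", {
  set.seed(12)
  cohort <- purrr::map(1:4, function(i) {
    img <- matrix(runif(256, 0, 100), 16, 16)
    extract_features(img, matrix(TRUE, 16, 16), radiomics_config(bin_width = 10))
  })
  rep_ <- compare_cohorts(cohort, cohort, alpha = 0.05)
  expect_equal(attr(rep_, "n_total"), 93)
  expect_true(all(rep_$D == 0))
  expect_true(all(rep_$p == 1))
  expect_equal(attr(rep_, "n_nonsignificant"), 93)
  expect_error(compare_cohorts(cohort[1], cohort, alpha = 0.05), "two feature")
})

test_that("the KS report counts non-significant features as p >= alpha", {
  tbl <- tibble::tibble(family = "f", feature = paste0("x", 1:5),
                        p = c(0.9, 0.06, 0.05, 0.049, 0.001))
  rep_ <- ks_report(tbl, alpha = 0.05)
  expect_equal(attr(rep_, "n_nonsignificant"), 3)   # 0.05 itself is not significant
  expect_equal(rep_$p, sort(tbl$p, decreasing = TRUE))
  g <- glance(rep_)
  expect_equal(g$n_nonsignificant, 3)
  expect_equal(g$pct_nonsignificant, 60)
})

test_that("null cohorts trigger significance at about the nominal rate", {
  set.seed(13)
  n_rep <- 200
  pvals <- vapply(seq_len(n_rep), function(i) {
    ks_two_sample(rnorm(100), rnorm(100))$p
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  band <- 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(frac, 0.05 - band - 0.01)
  expect_lt(frac, 0.05 + band + 0.01)
})

test_that("cross-validated classification behaves at both signal extremes", {
  set.seed(14)
  # no signal: identical feature values, random labels -> AUC 0.5 exactly
  X <- matrix(1, nrow = 40, ncol = 3)
  colnames(X) <- paste0("f", 1:3)
  y <- rep(c("real", "synthetic"), 20)
  cv <- real_vs_fake_auc(X, y, k = 4, seed = 2)
  expect_equal(cv$pooled_auc, 0.5)

  # a perfectly separating feature -> pooled AUC 1
  X2 <- cbind(f1 = c(rnorm(20, -3), rnorm(20, 3)), f2 = rnorm(40))
  y2 <- rep(c("synthetic", "real"), each = 20)
  cv2 <- real_vs_fake_auc(X2, y2, k = 4, seed = 3)
  expect_equal(cv2$pooled_auc, 1)
  expect_gt(cv2$pooled_accuracy, 0.9)

  # fold partition: disjoint, exhaustive, balanced within one case
  expect_equal(sort(unique(cv2$folds)), 1:4)
  expect_true(max(table(cv2$folds)) - min(table(cv2$folds)) <= 1)
  expect_equal(length(cv2$folds), 40)
})

test_that("cross-validated AUC tracks the analytic binormal prediction", {
  # two Gaussian cohorts at effect size d: theoretical AUC = pnorm(d / sqrt(2))
  set.seed(15)
  d <- 1.5
  n <- 400
  X <- cbind(f1 = c(rnorm(n / 2), rnorm(n / 2, d)))
  y <- rep(c("synthetic", "real"), each = n / 2)
  cv <- real_vs_fake_auc(X, y, k = 4, seed = 4)
  # band: about three standard errors of the empirical AUC at this n
  expect_lt(abs(cv$pooled_auc - pnorm(d / sqrt(2))), 0.06)
})

test_that("VTT summaries reproduce reader-study arithmetic", {
  records <- vtt_reference_records()
  vs <- vtt_summary(records)
  expect_equal(vs$n, 100)
  expect_equal(as.integer(vs$confusion["synthetic", "called real"]), 19)
  g <- glance(vs)
  expect_equal(g$synthetic_called_real, 19L)
  expect_equal(g$frac_synthetic_called_real, 19 / 51)
  # per-truth proportions sum to one
  props <- tidy(vs)
  sums <- tapply(props$n, props$truth, sum)
  expect_equal(unname(sums), c(1, 1), ignore_attr = TRUE)

  # one-class degenerate: AUC flagged as not computable
  one <- records[records$truth == "real", ]
  vs1 <- vtt_summary(one)
  expect_false(vs1$auc_computable)
  expect_true(is.na(vs1$auc))

  bad <- records; bad$rating[1] <- "maybe"
  expect_error(vtt_summary(bad), "unknown rating")
})

test_that("the VTT reader AUC equals the Mann-Whitney pairwise count", {
  records <- tibble::tibble(
    case_id = paste0("c", 1:10),
    truth = rep(c("real", "synthetic"), each = 5),
    rating = c("confidently real", "leaning real", "leaning real",
               "leaning fake", "confidently real",
               "confidently fake", "leaning fake", "leaning real",
               "confidently fake", "leaning fake"),
    reader_id = "r1"
  )
  vs <- vtt_summary(records)
  score <- match(records$rating,
                 c("confidently fake", "leaning fake", "leaning real",
                   "confidently real")) - 1
  expect_equal(vs$auc, auc_pair_oracle(score, records$truth == "real"))
})

test_that("the packaged reference p-value table is complete and well-formed", {
  tbl <- table1_ks_pvalues()
  expect_equal(nrow(tbl), 93)
  counts <- table(tbl$family)
  expect_equal(unname(counts[c("First order", "GLCM", "GLDM", "GLRLM",
                               "GLSZM", "NGTDM")]),
               c(18L, 24L, 14L, 16L, 16L, 5L), ignore_attr = TRUE)
  expect_true(all(tbl$p_value >= 0 & tbl$p_value <= 1))
})
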