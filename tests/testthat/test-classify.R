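# Staged splits, cross-validated ensemble classification, vote shares,
# AUC conventions, and permutation nulls.

stage_counts <- function(plan, meta, grp) {
  s <- plan$assignment$stage[meta$group == grp]
  table(factor(s, levels = c("discovery", "demonstration", "generalization")))
}

test_that("the staged split reproduces the 25/25/52 case allocation", {
  meta <- generate_cohort(cohort_config(
    n_cases = 102L, n_controls_per_batch = c(300L, 300L, 25L, 25L),
    n_parcels = 4L, n_subcortical = 2L, seed = 18L))$meta
  stopifnot(sum(meta$n_types >= 3, na.rm = TRUE) >= 50)
  plan <- staged_split(meta, seed = 1)
  cc <- stage_counts(plan, meta, "case")
  expect_identical(as.integer(cc), c(25L, 25L, 52L))
  # discovery/demonstration cases all have 3+ types
  picked <- plan$assignment$subject_id[plan$assignment$stage != "generalization" &
                                         meta$group == "case"]
  expect_true(all(meta$n_types[match(picked, meta$subject_id)] >= 3))
  # large-batch controls halved, local controls discovery-only
  for (b in 1:2) {
    s <- plan$assignment$stage[meta$group == "control" & meta$batch == b]
    expect_identical(as.integer(table(s)[c("discovery", "demonstration")]),
                     c(150L, 150L))
  }
  s34 <- plan$assignment$stage[meta$group == "control" & meta$batch %in% 3:4]
  expect_true(all(s34 == "discovery"))
  # deterministic given the seed, distinct across seeds
  expect_identical(staged_split(meta, seed = 1)$assignment, plan$assignment)
  expect_false(identical(staged_split(meta, seed = 2)$assignment,
                         plan$assignment))
})

test_that("too few multi-type cases triggers the proportional fallback", {
  meta <- data.frame(
    subject_id = sprintf("S%03d", 1:40),
    group = rep(c("case", "control"), c(20, 20)),
    batch = rep(c(4L, 1L), c(20, 20)),
    n_types = c(rep(c(1L, 3L), 10), rep(NA_integer_, 20)))
  expect_warning(plan <- staged_split(meta, seed = 3), "scaling")
  expect_true(any(grepl("fallback", plan$rule_trace)))
  cc <- stage_counts(plan, meta, "case")
  expect_identical(sum(cc), 20L)
  expect_identical(as.integer(cc[1]), as.integer(cc[2]))
})

test_that("AUC uses the Mann-Whitney half-credit-tie convention", {
  labels <- c("case", "control", "control")
  expect_equal(auc_score(c(0.6, 0.6, 0.2), labels), 0.75)
  expect_equal(auc_score(c(1, 0, 0), labels), 1)
  expect_equal(auc_score(c(0, 1, 1), labels), 0)
  # matches exhaustive pair counting on random score sets with ties
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    lab <- sample(c("case", "control"), n, replace = TRUE,
                  prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
    expect_equal(auc_score(sc, lab), auc_by_pair_counting(sc, lab))
  }
})

test_that("AUC agrees with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  lab <- sample(c("case", "control"), 60, replace = TRUE)
  sc <- rnorm(60) + (lab == "case")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = sc, levels = c("control", "case"),
    direction = "<", quiet = TRUE)))
  expect_equal(auc_score(sc, lab), ref, tolerance = 1e-12)
})

test_that("perfectly separated clusters classify perfectly", {
  set.seed(21)
  n <- 60
  lab <- rep(c("case", "control"), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5)
  x[lab == "case", 1] <- x[lab == "case", 1] + 20
  res <- evaluate_biomarker(x, lab, k = 5, num_trees = 100, seed = 1)
  expect_equal(res$auc, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_identical(length(res$vote_share), as.integer(n))
})

test_that("evaluation is deterministic given the seed and validates inputs", {
  set.seed(22)
  x <- matrix(rnorm(40 * 6), 40, 6)
  lab <- rep(c("case", "control"), 20)
  a <- evaluate_biomarker(x, lab, k = 4, num_trees = 50, seed = 9)
  b <- evaluate_biomarker(x, lab, k = 4, num_trees = 50, seed = 9)
  expect_identical(a$vote_share, b$vote_share)
  expect_error(evaluate_biomarker(x, lab, k = 25), "minority")
  expect_error(evaluate_biomarker(x, rep("case", 40), k = 2), "both classes")
  xc <- cbind(x, constant = 1)
  expect_message(evaluate_biomarker(xc, lab, k = 4, num_trees = 50, seed = 9),
                 "constant")
})

test_that("down-sampling balances training folds but not held-out data", {
  # structural check: held-out vote shares exist for every subject, so the
  # test folds keep the original imbalance
  set.seed(23)
  n_case <- 15
  n_ctrl <- 60
  x <- matrix(rnorm((n_case + n_ctrl) * 8), n_case + n_ctrl, 8)
  lab <- rep(c("case", "control"), c(n_case, n_ctrl))
  res <- evaluate_biomarker(x, lab, k = 5, downsample = TRUE,
                            num_trees = 50, seed = 2)
  expect_false(anyNA(res$vote_share))
  expect_identical(sum(res$labels == "case"), as.integer(n_case))
  idx <- synmark:::.downsample_idx(factor(rep(c("a", "b"), c(5, 17))))
  expect_identical(as.integer(table(rep(c("a", "b"), c(5, 17))[idx])),
                   c(5L, 5L))
})

test_that("pure-noise features with memorizable structure stay at chance", {
  # a subject-unique feature invites memorization; fold-safe training keeps
  # held-out performance at chance (no leakage from test labels)
  set.seed(24)
  n <- 80
  lab <- rep(c("case", "control"), n / 2)  # interleaved with subject index
  x <- cbind(id_like = seq_len(n), matrix(rnorm(n * 4), n, 4))
  res <- evaluate_biomarker(x, lab, k = 5, num_trees = 100, seed = 3)
  expect_lt(abs(res$auc - 0.5), 0.25)
})

test_that("PCA reduction inside folds handles wide feature sets", {
  set.seed(25)
  n <- 40
  lab <- rep(c("case", "control"), each = n / 2)
  wide <- matrix(rnorm(n * 300), n, 300)
  wide[lab == "case", 1:50] <- wide[lab == "case", 1:50] + 1.2
  fm <- structure(list(biomarker = "myelin_pairwise", values = wide,
                       reduce = TRUE), class = "feature_matrix")
  res <- evaluate_biomarker(fm, lab, k = 4, num_trees = 100, seed = 4)
  expect_gt(res$auc, 0.7)
})

test_that("hyper-parameter tuning selects from the grid", {
  set.seed(26)
  n <- 60
  lab <- rep(c("case", "control"), each = n / 2)
  x <- matrix(rnorm(n * 12), n, 12)
  x[lab == "case", 1:3] <- x[lab == "case", 1:3] + 1
  res <- evaluate_biomarker(x, lab, k = 3, tune_grid = 3:10,
                            num_trees = 50, seed = 5)
  expect_true(all(res$tuned_params$mtry %in% 3:10))
})

test_that("the permutation null is centered at chance and scores tails", {
  set.seed(27)
  n <- 60
  lab <- rep(c("case", "control"), each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10)
  pn <- permutation_null(x, lab, n_perm = 100, k = 3, num_trees = 50,
                         observed_auc = 0.9, seed = 6)
  expect_equal(mean(pn$null_aucs), 0.5, tolerance = 0.05)
  expect_true(pn$null_ci95[1] >= 0 && pn$null_ci95[2] <= 1)
  expect_equal(permutation_null(x, lab, n_perm = 100, k = 3, num_trees = 50,
                                observed_auc = max(pn$null_aucs) + 1e-9,
                                seed = 6)$p_value, 1 / 101)
  expect_error(permutation_null(x, lab, n_perm = 10), "n_perm")
})

test_that("vote shares correlate with the covariate that drives the effect", {
  set.seed(28)
  res <- structure(list(
    vote_share = c(0.9, 0.8, 0.3, 0.2, 0.7, 0.1),
    labels = factor(rep("case", 6), levels = c("control", "case"))),
    class = "biomarker_result")
  v <- res$vote_share
  expect_equal(vote_share_correlates(res, v)$r, 1)
  expect_error(vote_share_correlates(res, rep(1, 6)), "zero-variance")

  # generator ties the planted effect to n_types: more types, higher votes
  n <- 128
  n_types <- sample(1:6, n, replace = TRUE)
  votes <- plogis(0.4 * n_types - 1 + rnorm(n))
  res2 <- structure(list(
    vote_share = votes,
    labels = factor(rep("case", n), levels = c("control", "case"))),
    class = "biomarker_result")
  out <- vote_share_correlates(res2, n_types)
  expect_gt(out$r, 0)
  expect_lt(out$p, 0.05)
  # independent covariate: near-zero correlation
  out0 <- vote_share_correlates(res2, rnorm(n))
  expect_lt(abs(out0$r), 0.25)
})

test_that("multi-type cases are easier to classify when effects scale with types", {
  bt <- behavioral_table(128, 109, effects = rep(0.4, 35),
                         types_scale_effects = TRUE, seed = 44)
  res <- evaluate_biomarker(bt$values, bt$labels, k = 10, downsample = TRUE,
                            num_trees = 200, seed = 8)
  out <- vote_share_correlates(res, bt$meta$n_types[bt$meta$group == "case"])
  expect_gt(out$r, 0)
  expect_lt(out$p, 0.05)
})

test_that("staged evaluation tunes on discovery and scores later stages", {
  cfg <- cohort_config(n_cases = 60L, n_controls_per_batch = c(40L, 40L, 10L, 10L),
                       n_parcels = 30L, n_subcortical = 5L,
                       effect_map = list(list(measure = "myelin",
                                              parcels = 1:10, d = 1.0)),
                       seed = 29L)
  coh <- generate_cohort(cfg)
  plan <- staged_split(coh$meta, seed = 2, quota = 15L)
  res <- evaluate_staged(coh$myelin, coh$meta$group, plan,
                         tune_grid = c(3, 5), num_trees = 100, seed = 7)
  expect_true(res$mtry %in% c(3, 5))
  expect_gt(res$demonstration, 0.6)
  expect_gt(res$generalization, 0.6)
})
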