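# Biomarker validation protocol: staged splits, stratified cross-validated
# random-forest classification with training-fold down-sampling, per-subject
# vote shares, AUC/sensitivity/specificity, and permutation nulls.

#' Staged discovery / demonstration / generalization split
#'
#' Cases with three or more types of synesthesia fill the discovery then the
#' demonstration stage (25 each, seeded random tie-break); the remaining
#' cases (one or more types) form the generalization stage. Controls from
#' the two large public batches (batch 1 and 2) are randomly halved between
#' discovery and demonstration; controls from the small local batches (3
#' and 4) go to discovery alone. With fewer than 50 eligible multi-type
#' cases the 25/25 quota is scaled proportionally (with a warning) and the
#' fallback is recorded in the rule trace.
#'
#' @param metadata data.frame with subject_id, group, batch, n_types.
#' @param seed Integer seed for the random assignments.
#' @param quota Target discovery/demonstration case counts (default 25).
#' @return An object of class `split_plan`: `assignment` (data.frame
#'   subject_id, stage), `rule_trace` (character), `seed`.
#' @export
staged_split <- function(metadata, seed = 1L, quota = 25L) {
  stopifnot(all(c("subject_id", "group", "batch") %in% names(metadata)))
  set.seed(seed)
  trace <- character()
  stage <- stats::setNames(rep(NA_character_, nrow(metadata)),
                           metadata$subject_id)

  is_case <- metadata$group == "case"
  cases <- metadata[is_case, ]
  if (!"n_types" %in% names(metadata) || anyNA(cases$n_types))
    stop("metadata must provide n_types for every case")
  eligible <- cases$subject_id[cases$n_types >= 3]
  q <- quota
  if (length(eligible) < 2 * quota) {
    q <- floor(length(eligible) / 2)
    warning("only ", length(eligible), " cases with 3+ types; ",
            "scaling discovery/demonstration quota to ", q)
    trace <- c(trace, sprintf(
      "fallback: %d eligible multi-type cases < %d, quota scaled to %d",
      length(eligible), 2 * quota, q))
  }
  picked <- sample(eligible, 2 * q)
  stage[picked[seq_len(q)]] <- "discovery"
  stage[picked[q + seq_len(q)]] <- "demonstration"
  stage[cases$subject_id[is.na(stage[cases$subject_id])]] <- "generalization"
  trace <- c(trace, sprintf(
    "cases: %d discovery / %d demonstration from %d with 3+ types; %d to generalization",
    q, q, length(eligible), sum(stage[cases$subject_id] == "generalization")))

  ctrls <- metadata[!is_case, ]
  for (b in unique(ctrls$batch)) {
    ids <- ctrls$subject_id[ctrls$batch == b]
    if (b %in% c(1, 2)) {
      half <- sample(ids, floor(length(ids) / 2))
      stage[half] <- "discovery"
      stage[setdiff(ids, half)] <- "demonstration"
      trace <- c(trace, sprintf(
        "controls batch %s: %d/%d halved discovery/demonstration",
        b, length(half), length(ids) - length(half)))
    } else {
      stage[ids] <- "discovery"
      trace <- c(trace, sprintf(
        "controls batch %s (local): %d to discovery", b, length(ids)))
    }
  }

  structure(list(
    assignment = data.frame(subject_id = metadata$subject_id,
                            stage = unname(stage[metadata$subject_id]),
                            stringsAsFactors = FALSE),
    rule_trace = trace,
    seed = seed
  ), class = "split_plan")
}

#' Rank-based AUC with half-credit ties
#'
#' Mann-Whitney convention: the probability a random case scores above a
#' random control, with ties counted as half.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels Factor or character; the positive class is `"case"`.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  pos <- labels == "case"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated biomarker evaluation
#'
#' Stratified k-fold cross-validation of a bagged-tree ensemble (500 trees
#' by default) on one biomarker feature set. Within each training fold the
#' majority class is randomly down-sampled to the minority count (seeded)
#' when `downsample` is set; any PCA reduction (`var_target`) is fitted on
#' the training fold only and applied frozen to the held-out fold; the
#' features-per-tree parameter is tuned by inner 3-fold cross-validation
#' over `tune_grid` when supplied. Held-out per-subject vote shares (the
#' fraction of trees voting "case") are pooled across folds; AUC uses the
#' rank statistic with half-credit ties; sensitivity and specificity use a
#' 0.5 vote threshold.
#'
#' @param features A `feature_matrix` from [build_biomarker()], or a plain
#'   subjects x p numeric matrix.
#' @param labels Factor with levels control/case (or coercible).
#' @param k Number of folds (default 5; must not exceed the minority count).
#' @param downsample Balance training folds by down-sampling (default TRUE).
#' @param tune_grid Candidate features-per-tree (mtry) values, e.g. `3:10`
#'   for the behavioral protocol; NULL uses `floor(sqrt(p))`.
#' @param var_target PCA variance target for fold-safe reduction; NULL (or a
#'   `feature_matrix` with `reduce = FALSE`) skips reduction.
#' @param num_trees Trees per forest (default 500).
#' @param combat Optional fold-safe harmonization: `list(batch = <labels>,
#'   covariates = <matrix or NULL>)`. Within each fold a ComBat model is
#'   fitted on the training subjects only ([combat_fit()]) and applied
#'   frozen to the held-out fold, so no information about test subjects
#'   enters the batch adjustment. The outcome label must never appear in
#'   `covariates` here (that would leak it through the adjustment).
#' @param seed Integer seed controlling folds, down-sampling, tuning, and
#'   the forests.
#' @return An object of class `biomarker_result`: auc, sensitivity,
#'   specificity, vote_share (per subject, held-out), folds, tuned_params,
#'   labels, seed. Permutation fields are filled by [permutation_null()].
#' @export
evaluate_biomarker <- function(features, labels, k = 5L, downsample = TRUE,
                               tune_grid = NULL, var_target = NULL,
                               num_trees = 500L, combat = NULL, seed = 1L) {
  fm <- .as_feature_values(features, var_target)
  x <- fm$values
  if (!is.null(fm$var_target)) var_target <- fm$var_target
  labels <- .as_labels(labels)
  stopifnot(nrow(x) == length(labels))
  n_min <- min(table(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (k > n_min) stop("k = ", k, " exceeds minority class count ", n_min)

  keep <- which(apply(x, 2, function(col) stats::sd(col) > 0))
  if (length(keep) < ncol(x)) {
    message("dropping ", ncol(x) - length(keep), " constant feature column(s)")
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0) stop("no informative feature columns")

  set.seed(seed)
  folds <- .stratified_folds(labels, k)
  vote <- rep(NA_real_, length(labels))
  names(vote) <- rownames(x)
  tuned <- integer(k)

  for (f in seq_len(k)) {
    tr <- folds != f
    xtr <- x[tr, , drop = FALSE]
    ytr <- labels[tr]
    xte <- x[!tr, , drop = FALSE]
    if (!is.null(combat)) {
      ctr <- if (is.null(combat$covariates)) NULL else
        as.matrix(combat$covariates)[tr, , drop = FALSE]
      cte <- if (is.null(combat$covariates)) NULL else
        as.matrix(combat$covariates)[!tr, , drop = FALSE]
      cm <- combat_fit(xtr, combat$batch[tr], ctr)
      xtr <- cm$adjusted
      xte <- combat_apply(cm, xte, combat$batch[!tr], cte)
    }
    if (!is.null(var_target)) {
      red <- fit_reducer(xtr, var_target)
      xtr <- apply_reducer(red, xtr)
      xte <- apply_reducer(red, xte)
    }
    if (downsample) {
      idx <- .downsample_idx(ytr)
      xtr <- xtr[idx, , drop = FALSE]
      ytr <- ytr[idx]
    }
    mtry <- if (is.null(tune_grid)) max(1L, floor(sqrt(ncol(xtr)))) else
      .tune_mtry(xtr, ytr, tune_grid, num_trees,
                 seed = seed * 1000L + f)
    mtry <- min(mtry, ncol(xtr))
    tuned[f] <- mtry
    fit <- ranger::ranger(x = xtr, y = ytr, num.trees = num_trees,
                          mtry = mtry, num.threads = 1,
                          seed = seed * 100L + f)
    vote[!tr] <- .case_vote_share(fit, xte)
  }

  pred_case <- vote > 0.5
  structure(list(
    auc = auc_score(vote, labels),
    sensitivity = mean(pred_case[labels == "case"]),
    specificity = mean(!pred_case[labels == "control"]),
    vote_share = vote,
    labels = labels,
    folds = k,
    tuned_params = list(mtry = tuned, num_trees = num_trees,
                        downsample = downsample, var_target = var_target,
                        combat = !is.null(combat)),
    null_aucs = NULL, null_ci95 = NULL, p_value = NULL,
    seed = seed
  ), class = "biomarker_result")
}

.as_feature_values <- function(features, var_target) {
  if (inherits(features, "feature_matrix")) {
    vt <- if (isTRUE(features$reduce) && is.null(var_target)) 0.95 else var_target
    x <- as.matrix(features$values)
  } else {
    vt <- var_target
    x <- as.matrix(features)
  }
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%05d", seq_len(ncol(x)))
  list(values = x, var_target = vt)
}

.as_labels <- function(labels) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("control", "case")))
  factor(labels, levels = c("control", "case"))
}

.stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cls in levels(labels)) {
    idx <- which(labels == cls)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

.downsample_idx <- function(y) {
  tab <- table(y)
  n_min <- min(tab)
  idx <- unlist(lapply(names(tab), function(cls) {
    cls_idx <- which(y == cls)
    if (length(cls_idx) > n_min) sample(cls_idx, n_min) else cls_idx
  }))
  sort(idx)
}

.case_vote_share <- function(fit, x) {
  pr <- stats::predict(fit, data = x, predict.all = TRUE, num.threads = 1)
  case_code <- which(fit$forest$levels == "case")
  rowMeans(pr$predictions == case_code)
}

.tune_mtry <- function(x, y, grid, num_trees, seed) {
  grid <- pmin(as.integer(grid), ncol(x))
  grid <- unique(grid)
  if (length(grid) == 1) return(grid)
  set.seed(seed)
  inner <- .stratified_folds(y, 3L)
  perf <- vapply(grid, function(m) {
    aucs <- vapply(1:3, function(f) {
      tr <- inner != f
      if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2)
        return(NA_real_)
      fit <- ranger::ranger(x = x[tr, , drop = FALSE], y = y[tr],
                            num.trees = num_trees, mtry = m,
                            num.threads = 1, seed = seed + f)
      auc_score(.case_vote_share(fit, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  grid[which.max(perf)]
}

#' Permutation-null distribution for a biomarker
#'
#' Re-runs the full cross-validated protocol of [evaluate_biomarker()] on
#' label shufflings, giving the chance-performance distribution against
#' which an observed AUC is judged. The empirical p-value of an observed
#' AUC uses the add-one tail correction `(1 + #{null >= obs}) / (n_perm + 1)`.
#'
#' @param features,labels,k,downsample,tune_grid,var_target,num_trees,combat
#'   As in [evaluate_biomarker()].
#' @param n_perm Number of permutations (>= 100 for CI reporting).
#' @param observed_auc Optional observed AUC to score against the null.
#' @param seed Integer seed.
#' @return List of class `permutation_null`: `null_aucs`, `null_ci95`
#'   (2.5/97.5 percentiles), `mean_null`, and `p_value` when an observed
#'   AUC was given.
#' @export
permutation_null <- function(features, labels, n_perm = 1000L, k = 5L,
                             downsample = TRUE, tune_grid = NULL,
                             var_target = NULL, num_trees = 500L,
                             combat = NULL, observed_auc = NULL, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100 for CI reporting")
  labels <- .as_labels(labels)
  null_aucs <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(seed + 7919L * b)
    perm <- sample(labels)
    res <- evaluate_biomarker(features, perm, k = k, downsample = downsample,
                              tune_grid = tune_grid, var_target = var_target,
                              num_trees = num_trees, combat = combat,
                              seed = seed + b)
    null_aucs[b] <- res$auc
  }
  out <- list(null_aucs = null_aucs,
              null_ci95 = unname(stats::quantile(null_aucs, c(0.025, 0.975))),
              mean_null = mean(null_aucs))
  if (!is.null(observed_auc))
    out$p_value <- (1 + sum(null_aucs >= observed_auc)) / (n_perm + 1)
  structure(out, class = "permutation_null")
}

#' Correlate case vote shares with a covariate
#'
#' Tests whether classifiability (a case's vote share) tracks a per-case
#' covariate such as the number of types of synesthesia.
#'
#' @param result A `biomarker_result`.
#' @param covariate Numeric covariate, one value per case (in case order).
#' @return List with `r`, `p`, `n` from a two-sided Pearson test.
#' @export
vote_share_correlates <- function(result, covariate) {
  stopifnot(inherits(result, "biomarker_result"))
  v <- result$vote_share[result$labels == "case"]
  stopifnot(length(covariate) == length(v))
  if (stats::sd(covariate) == 0) stop("zero-variance covariate")
  ct <- stats::cor.test(v, covariate)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(v))
}

#' Staged evaluation of a biomarker
#'
#' The staged counterpart of the single-step protocol: the features-per-tree
#' parameter is tuned by cross-validation within the discovery sample and
#' frozen; a forest trained on discovery is scored on the demonstration
#' sample, and a forest trained on discovery + demonstration is scored on
#' the generalization cases (against the demonstration controls, which are
#' the held-out controls available at that stage).
#'
#' @param features A `feature_matrix` or matrix (all subjects).
#' @param labels Factor control/case for all subjects.
#' @param plan A `split_plan` from [staged_split()].
#' @param tune_grid,var_target,num_trees,downsample,seed As in
#'   [evaluate_biomarker()].
#' @return List with per-stage AUCs (`demonstration`, `generalization`) and
#'   the frozen `mtry`.
#' @export
evaluate_staged <- function(features, labels, plan, tune_grid = 3:10,
                            var_target = NULL, num_trees = 500L,
                            downsample = TRUE, seed = 1L) {
  stopifnot(inherits(plan, "split_plan"))
  fm <- .as_feature_values(features, var_target)
  x <- fm$values
  if (!is.null(fm$var_target)) var_target <- fm$var_target
  labels <- .as_labels(labels)
  stage <- plan$assignment$stage

  fit_score <- function(train_idx, test_idx, mtry, seed) {
    xtr <- x[train_idx, , drop = FALSE]
    ytr <- labels[train_idx]
    xte <- x[test_idx, , drop = FALSE]
    if (!is.null(var_target)) {
      red <- fit_reducer(xtr, var_target)
      xtr <- apply_reducer(red, xtr)
      xte <- apply_reducer(red, xte)
    }
    if (downsample) {
      set.seed(seed)
      idx <- .downsample_idx(ytr)
      xtr <- xtr[idx, , drop = FALSE]
      ytr <- ytr[idx]
    }
    fit <- ranger::ranger(x = xtr, y = ytr, num.trees = num_trees,
                          mtry = min(mtry, ncol(xtr)), num.threads = 1,
                          seed = seed)
    .case_vote_share(fit, xte)
  }

  disc <- which(stage == "discovery")
  demo <- which(stage == "demonstration")
  gen <- which(stage == "generalization")
  set.seed(seed)
  xd <- x[disc, , drop = FALSE]
  if (!is.null(var_target)) xd <- apply_reducer(fit_reducer(xd, var_target), xd)
  mtry <- .tune_mtry(xd, labels[disc], tune_grid, num_trees, seed)

  v_demo <- fit_score(disc, demo, mtry, seed + 1L)
  auc_demo <- auc_score(v_demo, labels[demo])
  auc_gen <- NA_real_
  if (length(gen)) {
    demo_ctrl <- demo[labels[demo] == "control"]
    test_gen <- c(gen, demo_ctrl)
    v_gen <- fit_score(c(disc, setdiff(demo, demo_ctrl)), test_gen,
                       mtry, seed + 2L)
    auc_gen <- auc_score(v_gen, labels[test_gen])
  }
  list(demonstration = auc_demo, generalization = auc_gen, mtry = mtry)
}
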