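# Structural biomarker feature sets: global surface area / eTIV, regional
# maps, inter-regional difference features with PCA reduction, and
# structural covariance summaries.

#' Registry of the thirteen biomarkers
#'
#' Enumerates every biomarker the pipeline evaluates with its dimensionality
#' before any data reduction. Pairwise difference features and the partial
#' correlation connectome have `n * (n - 1) / 2` variables and are reduced
#' by PCA inside the classification folds.
#'
#' @param n_parcels Cortical parcel count (default 360).
#' @param n_subcortical Subcortical volume count (default 34).
#' @return data.frame with columns `id`, `k` (raw variable count),
#'   `reduced` (whether PCA reduction applies) and `description`.
#' @export
biomarker_registry <- function(n_parcels = 360L, n_subcortical = 34L) {
  np <- as.integer(n_parcels)
  npair <- as.integer(np * (np - 1L) / 2L)
  data.frame(
    id = c("global_sa_etiv", "regional_area", "subcortical",
           "thickness", "thickness_pairwise", "thickness_summed",
           "myelin", "myelin_pairwise", "myelin_summed",
           "fc_partial", "fc_centrality", "gradient1", "gradient2"),
    k = as.integer(c(4L, np, n_subcortical, np, npair, np, np, npair, np,
          npair, np, np, np)),
    reduced = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE,
                TRUE, FALSE, FALSE, FALSE),
    description = c(
      "global surface area, eTIV, sex, age",
      "regional surface area as % of total",
      "subcortical/other volumes as % of eTIV",
      "regional cortical thickness (mm)",
      "absolute pairwise thickness differences (PCA-reduced)",
      "summed absolute thickness differences per region",
      "regional intracortical myelin (T1w/T2w)",
      "absolute pairwise myelin differences (PCA-reduced)",
      "summed absolute myelin differences per region",
      "partial-correlation functional connectome edges (PCA-reduced)",
      "functional degree centrality (sum |partial r|)",
      "first connectivity gradient score per region",
      "second connectivity gradient score per region"),
    stringsAsFactors = FALSE
  )
}

#' Global surface area / eTIV feature set
#'
#' The four-variable biomarker: global surface area (mm^2), estimated total
#' intracranial volume (mm^3), sex (F = 0, M = 1) and age. The derived
#' surface-area-per-volume ratio (cm^2 / cm^3), the quantity that separates
#' groups when cases have smaller skulls but non-scaled cortex, is attached
#' as attribute `"sa_per_vol"` for univariate statistics.
#'
#' @param cohort A `syn_cohort`.
#' @return subjects x 4 matrix, columns global_area, etiv, sex_coded, age.
#' @export
global_sa_etiv_features <- function(cohort) {
  stopifnot(all(cohort$etiv > 0))
  out <- cbind(global_area = unname(cohort$global_area),
               etiv = unname(cohort$etiv),
               sex_coded = as.numeric(cohort$meta$sex == "M"),
               age = cohort$meta$age)
  rownames(out) <- cohort$meta$subject_id
  attr(out, "sa_per_vol") <- (out[, "global_area"] / 100) / (out[, "etiv"] / 1000)
  out
}

#' Regional surface area as percentage of total
#'
#' Scale-invariant: each subject's parcel areas are rescaled to sum to 100.
#'
#' @param area Non-negative parcel-area vector, or subjects x parcels matrix.
#' @return Same shape, rows summing to 100.
#' @export
regional_area_percent <- function(area) {
  if (is.matrix(area)) {
    tot <- rowSums(area)
    if (any(tot <= 0)) stop("subject with all-zero surface area")
    return(sweep(area, 1, tot / 100, `/`))
  }
  if (any(area < 0)) stop("surface area must be non-negative")
  tot <- sum(area)
  if (tot <= 0) stop("all-zero surface area")
  100 * area / tot
}

#' Volumes as percentage of eTIV
#'
#' @param volumes Volume vector (mm^3), or subjects x structures matrix.
#' @param etiv eTIV (mm^3), scalar or per-subject vector.
#' @return `100 * volumes / etiv`, elementwise by subject.
#' @export
volumes_percent_etiv <- function(volumes, etiv) {
  if (any(etiv <= 0)) stop("etiv must be > 0")
  if (any(volumes < 0)) stop("negative volume")
  if (is.matrix(volumes)) return(sweep(volumes, 1, etiv / 100, `/`))
  100 * volumes / etiv
}

#' Upper-triangle pair index for n regions
#'
#' Fixed row-major ordering (1,2), (1,3), ..., (1,n), (2,3), ...: the
#' serialization order for every pairwise feature.
#'
#' @param n Region count.
#' @return list with integer vectors `i`, `j` (i < j) of length n(n-1)/2.
#' @export
pair_index <- function(n) {
  stopifnot(n >= 2)
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  list(i = as.integer(i), j = as.integer(j))
}

#' Absolute pairwise differences of a regional map
#'
#' For each region pair (i < j, row-major order, see [pair_index()]) the
#' absolute difference of the map values: the subject-level construction
#' behind the pairwise thickness and myelin biomarkers.
#'
#' @param x Regional vector of length n, or subjects x n matrix.
#' @return Vector (or subjects x n(n-1)/2 matrix) of absolute differences,
#'   named `<label_i>|<label_j>` when labels exist.
#' @export
pairwise_abs_diff <- function(x) {
  if (is.matrix(x)) {
    idx <- pair_index(ncol(x))
    out <- abs(x[, idx$i, drop = FALSE] - x[, idx$j, drop = FALSE])
    labs <- colnames(x)
    if (!is.null(labs)) colnames(out) <- paste(labs[idx$i], labs[idx$j], sep = "|")
    rownames(out) <- rownames(x)
    return(out)
  }
  idx <- pair_index(length(x))
  out <- abs(x[idx$i] - x[idx$j])
  labs <- names(x)
  if (!is.null(labs)) names(out) <- paste(labs[idx$i], labs[idx$j], sep = "|")
  out
}

#' Summed absolute differences per region
#'
#' Entry r is the sum over all other regions s of |x_r - x_s|; twice the
#' total of [pairwise_abs_diff()] when summed over regions.
#'
#' @param x Regional vector, or subjects x n matrix.
#' @return Vector of length n (or subjects x n matrix).
#' @export
summed_abs_diff <- function(x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, function(row) colSums(abs(outer(row, row, `-`)))))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  stats::setNames(colSums(abs(outer(x, x, `-`))), names(x))
}

#' Fit a PCA reducer on training data
#'
#' Centered principal-component projection retaining the smallest number of
#' components whose cumulative variance reaches `var_target`, capped at
#' n_train - 1. Fitting on training folds only and applying the frozen state
#' to held-out folds is the leakage contract the classification protocol
#' enforces.
#'
#' @param train Training subjects x p matrix (>= 3 subjects).
#' @param var_target Cumulative variance fraction in (0, 1] (default 0.95).
#' @return An object of class `pca_reducer` (center, rotation, k,
#'   explained).
#' @export
fit_reducer <- function(train, var_target = 0.95) {
  if (var_target <= 0 || var_target > 1)
    stop("var_target must lie in (0, 1]")
  train <- as.matrix(train)
  if (nrow(train) < 3) stop("need >= 3 training subjects")
  pc <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  v <- v / sum(v)
  k <- which(cumsum(v) >= var_target - 1e-12)[1]
  k <- min(k, nrow(train) - 1L)
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 k = k,
                 explained = cumsum(v)[k]),
            class = "pca_reducer")
}

#' Apply a fitted PCA reducer
#'
#' @param state A `pca_reducer` from [fit_reducer()].
#' @param x Subjects x p matrix with the same columns as at fit time.
#' @return Subjects x k score matrix.
#' @export
apply_reducer <- function(state, x) {
  stopifnot(inherits(state, "pca_reducer"))
  x <- as.matrix(x)
  out <- sweep(x, 2, state$center) %*% state$rotation
  rownames(out) <- rownames(x)
  out
}

#' Structural covariance of a regional measure within one group
#'
#' Across-subject Pearson correlation between every pair of regions -- the
#' inter-regional coupling summary whose pooled distribution is compared
#' between groups. With a resample specification, returns the mean
#' correlation matrix over seeded subsamples of a fixed size, which balances
#' group sizes before comparison.
#'
#' @param x Subjects x regions matrix for one group (>= 3 subjects).
#' @param resample_spec Optional `list(n_per_resample, n_resamples, seed)`.
#' @return List of class `covariance_summary`: `r_matrix` (regions x
#'   regions, unit diagonal), `n_subjects`, `resample_spec`.
#' @export
structural_covariance <- function(x, resample_spec = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need >= 3 subjects")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region: ", colnames(x)[which(sds == 0)[1]])
  if (is.null(resample_spec)) {
    r <- stats::cor(x)
  } else {
    stopifnot(resample_spec$n_per_resample <= nrow(x),
              resample_spec$n_per_resample >= 3)
    set.seed(resample_spec$seed)
    r <- matrix(0, ncol(x), ncol(x))
    for (b in seq_len(resample_spec$n_resamples)) {
      idx <- sample(nrow(x), resample_spec$n_per_resample)
      r <- r + stats::cor(x[idx, , drop = FALSE])
    }
    r <- r / resample_spec$n_resamples
    dimnames(r) <- list(colnames(x), colnames(x))
  }
  structure(list(r_matrix = r, n_subjects = nrow(x),
                 resample_spec = resample_spec),
            class = "covariance_summary")
}

#' Build a biomarker feature matrix from a (harmonized) cohort
#'
#' Dispatches on the registry id and returns the raw feature matrix for the
#' biomarker; PCA-reduced biomarkers return their full pairwise matrix with
#' `reduce = TRUE` recorded, and the reduction itself happens fold-safely
#' inside [evaluate_biomarker()].
#'
#' @param cohort A `syn_cohort`; functional biomarkers require time series.
#' @param id One registry id, see [biomarker_registry()].
#' @param shrinkage Shrinkage for [partial_connectome()] (default "auto").
#' @return An object of class `feature_matrix`: list with `biomarker`,
#'   `values` (subjects x k), `reduce` flag.
#' @export
build_biomarker <- function(cohort, id, shrinkage = "auto") {
  reg <- biomarker_registry(ncol(cohort$area), ncol(cohort$subcortical))
  if (!id %in% reg$id) stop("unknown biomarker id: ", id)
  needs_ts <- id %in% c("fc_partial", "fc_centrality", "gradient1", "gradient2")
  if (needs_ts && is.null(cohort$timeseries))
    stop("biomarker '", id, "' requires resting-state time series")
  vals <- switch(id,
    global_sa_etiv = global_sa_etiv_features(cohort),
    regional_area = regional_area_percent(cohort$area),
    subcortical = volumes_percent_etiv(cohort$subcortical, cohort$etiv),
    thickness = cohort$thickness,
    thickness_pairwise = pairwise_abs_diff(cohort$thickness),
    thickness_summed = summed_abs_diff(cohort$thickness),
    myelin = cohort$myelin,
    myelin_pairwise = pairwise_abs_diff(cohort$myelin),
    myelin_summed = summed_abs_diff(cohort$myelin),
    fc_partial = .fc_edge_features(cohort, shrinkage),
    fc_centrality = .fc_centrality_features(cohort, shrinkage),
    gradient1 = .gradient_features(cohort, 1L),
    gradient2 = .gradient_features(cohort, 2L)
  )
  structure(list(biomarker = id, values = vals,
                 reduce = reg$reduced[reg$id == id]),
            class = "feature_matrix")
}

.subject_partials <- function(cohort, shrinkage) {
  lapply(cohort$timeseries, function(ts) partial_connectome(ts, shrinkage))
}

.fc_edge_features <- function(cohort, shrinkage) {
  pcs <- .subject_partials(cohort, shrinkage)
  idx <- pair_index(nrow(pcs[[1]]$weights))
  labs <- pcs[[1]]$parcel_labels
  out <- t(vapply(pcs, function(pc)
    pc$weights[cbind(idx$i, idx$j)], numeric(length(idx$i))))
  dimnames(out) <- list(names(pcs), paste(labs[idx$i], labs[idx$j], sep = "|"))
  out
}

.fc_centrality_features <- function(cohort, shrinkage) {
  pcs <- .subject_partials(cohort, shrinkage)
  out <- t(vapply(pcs, function(pc) degree_centrality(pc),
                  numeric(nrow(pcs[[1]]$weights))))
  rownames(out) <- names(pcs)
  out
}

.gradient_features <- function(cohort, which_gradient) {
  conns <- lapply(cohort$timeseries, pearson_connectome)
  ctrl <- conns[cohort$meta$group == "control"]
  ref <- gradient_reference(ctrl)
  out <- t(vapply(conns, function(cn) {
    gr <- gradients(cn, ref)
    gr$scores[, which_gradient]
  }, numeric(nrow(conns[[1]]$weights))))
  dimnames(out) <- list(names(conns), conns[[1]]$parcel_labels)
  out
}
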