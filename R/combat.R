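# Empirical-Bayes batch harmonization (parametric ComBat), with a separated
# fit/apply so a model frozen on training subjects can adjust held-out ones.
#
# Model per feature g and batch i:
#   y_ijg = alpha_g + x_ij' beta_g + gamma_ig + delta_ig e_ijg
# Additive effects gamma get a Normal prior, multiplicative effects delta^2
# an Inverse-Gamma prior; prior hyper-parameters are estimated across
# features by method of moments and posteriors solved by the standard
# iterative fixed-point update.

#' Fit a ComBat harmonization model
#'
#' Estimates per-batch additive and multiplicative effects on every feature
#' after adjusting for covariates of interest (typically age, sex and --
#' optionally -- group status, so the group signal is preserved rather than
#' absorbed into batch means), shrinks them across features by empirical
#' Bayes, and returns a model that [combat_apply()] can use on the fitting
#' data (reproducing the adjusted output exactly) or on new subjects.
#'
#' @param features Subjects x p numeric matrix.
#' @param batch Batch labels, one per subject (>= 2 subjects per batch).
#' @param covariates Optional subjects x c numeric design columns (no
#'   intercept; e.g. age, sex code, group code). Must be full rank together
#'   with the batch indicators.
#' @param tol,max_iter Fixed-point convergence tolerance (default 1e-6) and
#'   iteration cap for the EB posterior updates.
#' @return An object of class `combat_model` with elements `alpha` (grand
#'   intercept per feature), `beta` (covariate coefficients), `gamma_star`
#'   and `delta_star` (EB-shrunken additive effects and multiplicative
#'   variances, one row per batch level), `pooled_var`, `batch_levels`,
#'   `covariate_names`, and `adjusted` (the harmonized fitting data).
#' @references Johnson, Li & Rabinovic (2007) Biostatistics 8(1):118-127.
#' @export
combat_fit <- function(features, batch, covariates = NULL,
                       tol = 1e-6, max_iter = 500L) {
  features <- as.matrix(features)
  n <- nrow(features)
  p <- ncol(features)
  batch <- factor(batch)
  levs <- levels(batch)
  ni <- table(batch)
  if (any(ni < 2))
    stop("batch '", names(ni)[ni < 2][1],
         "' has fewer than 2 subjects; batch variance undefined")
  B <- if (length(levs) == 1) matrix(1, n, 1, dimnames = list(NULL, levs))
       else stats::model.matrix(~ 0 + batch)
  X <- B
  cov_names <- NULL
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    cov_names <- colnames(covariates)
    if (is.null(cov_names)) cov_names <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(B, covariates)
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix (batch indicators + covariates) is rank deficient")

  bhat <- solve(crossprod(X), crossprod(X, features))  # (nb + c) x p
  nb <- length(levs)
  gamma_hat_ls <- bhat[seq_len(nb), , drop = FALSE]    # per-batch means
  beta <- if (nb < nrow(bhat)) bhat[-seq_len(nb), , drop = FALSE] else
    matrix(0, 0, p)
  alpha <- as.numeric(ni / n) %*% gamma_hat_ls          # 1 x p grand intercept

  resid <- features - X %*% bhat
  pooled_var <- colMeans(resid^2)                       # MLE (1/n) pooled
  if (any(pooled_var <= 0))
    stop("feature '", colnames(features)[which(pooled_var <= 0)[1]],
         "' has zero residual variance")

  stand_mean <- matrix(alpha, n, p, byrow = TRUE)
  if (ncol(beta) == p && nrow(beta) > 0)
    stand_mean <- stand_mean + covariates %*% beta
  z <- (features - stand_mean) / matrix(sqrt(pooled_var), n, p, byrow = TRUE)

  gamma_hat <- matrix(0, nb, p, dimnames = list(levs, colnames(features)))
  delta_hat <- matrix(0, nb, p, dimnames = list(levs, colnames(features)))
  for (i in seq_len(nb)) {
    zi <- z[batch == levs[i], , drop = FALSE]
    gamma_hat[i, ] <- colMeans(zi)
    # MLE denominator so a single-batch fit leaves the data untouched
    delta_hat[i, ] <- colMeans(sweep(zi, 2, gamma_hat[i, ])^2)
  }
  zero_var <- which(delta_hat <= 0, arr.ind = TRUE)
  if (nrow(zero_var) > 0)
    stop("feature '", colnames(delta_hat)[zero_var[1, 2]],
         "' has zero variance within batch '", levs[zero_var[1, 1]], "'")

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_len(nb)) {
    eb <- .combat_eb_batch(z[batch == levs[i], , drop = FALSE],
                           gamma_hat[i, ], delta_hat[i, ], tol, max_iter)
    gamma_star[i, ] <- eb$gamma
    delta_star[i, ] <- eb$delta2
  }

  model <- structure(list(
    alpha = drop(alpha),
    beta = beta,
    gamma_star = gamma_star,
    delta_star = delta_star,
    pooled_var = pooled_var,
    batch_levels = levs,
    covariate_names = cov_names,
    feature_names = colnames(features)
  ), class = "combat_model")
  model$adjusted <- combat_apply(model, features, batch, covariates)
  model
}

# EB shrinkage for one batch: Normal prior on gamma, Inverse-Gamma on
# delta^2, hyper-parameters by method of moments across features, posterior
# by the canonical fixed-point iteration.
.combat_eb_batch <- function(zi, g_hat, d_hat, tol, max_iter) {
  ni <- nrow(zi)
  p <- length(g_hat)
  g_bar <- mean(g_hat)
  tau2 <- stats::var(g_hat)
  m <- mean(d_hat)
  s2 <- stats::var(d_hat)
  if (p < 2 || !is.finite(tau2) || tau2 <= 0 || !is.finite(s2) || s2 <= 0) {
    # degenerate prior (e.g. single feature, or identical moments across
    # features): no information to shrink with; keep raw estimates
    return(list(gamma = g_hat, delta2 = d_hat))
  }
  lambda <- (2 * s2 + m^2) / s2
  theta <- (m * s2 + m^3) / s2
  g_new <- g_hat
  d_new <- d_hat
  for (it in seq_len(max_iter)) {
    g_old <- g_new
    d_old <- d_new
    g_new <- (ni * tau2 * g_hat + d_new * g_bar) / (ni * tau2 + d_new)
    sse <- colSums(sweep(zi, 2, g_new)^2)
    d_new <- (theta + 0.5 * sse) / (ni / 2 + lambda - 1)
    if (max(abs(g_new - g_old), abs(d_new - d_old)) < tol) break
  }
  list(gamma = g_new, delta2 = d_new)
}

#' Apply a fitted ComBat model
#'
#' Removes the model's batch location/scale effects from `features` and
#' restores the covariate signal. Applied to the data [combat_fit()] was
#' fitted on, it reproduces the model's `adjusted` output exactly; applied
#' to new subjects, batch levels must be among those seen at fit time.
#'
#' @param model A `combat_model`.
#' @param features Subjects x p matrix (same features as at fit time).
#' @param batch Batch labels (subset of `model$batch_levels`).
#' @param covariates Covariate columns matching the fit design (or NULL).
#' @return Adjusted subjects x p matrix.
#' @export
combat_apply <- function(model, features, batch, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  features <- as.matrix(features)
  n <- nrow(features)
  p <- ncol(features)
  if (p != length(model$pooled_var))
    stop("feature count does not match the fitted model")
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$batch_levels)
  if (length(unseen))
    stop("unseen batch level '", unseen[1], "'")
  has_cov <- nrow(model$beta) > 0
  if (has_cov && is.null(covariates))
    stop("model was fitted with covariates; provide them")
  stand_mean <- matrix(model$alpha, n, p, byrow = TRUE)
  if (has_cov)
    stand_mean <- stand_mean + as.matrix(covariates) %*% model$beta
  sdv <- matrix(sqrt(model$pooled_var), n, p, byrow = TRUE)
  z <- (features - stand_mean) / sdv
  bi <- match(batch, model$batch_levels)
  z_adj <- (z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star[bi, , drop = FALSE])
  out <- z_adj * sdv + stand_mean
  dimnames(out) <- dimnames(features)
  out
}

#' Harmonize a cohort's structural measures
#'
#' Convenience wrapper running [combat_fit()]/[combat_apply()] over the
#' measures the pipeline harmonizes (subcortical volumes + eTIV, parcellated
#' myelin, thickness and surface area), with age, sex and -- when
#' `preserve_group` -- group status as covariates. Derived biomarkers are
#' computed from these harmonized inputs and never re-harmonized.
#'
#' @param cohort A `syn_cohort`.
#' @param preserve_group Include group status in the design so the group
#'   signal is protected from the batch adjustment (default TRUE).
#' @param measures Which structural measures to harmonize.
#' @return The cohort with harmonized measures and an added
#'   `combat_models` element.
#' @export
harmonize_cohort <- function(cohort,
                             preserve_group = TRUE,
                             measures = c("area", "thickness", "myelin",
                                          "subcortical", "etiv")) {
  covs <- cbind(age = cohort$meta$age,
                sex = as.numeric(cohort$meta$sex == "M"))
  if (preserve_group)
    covs <- cbind(covs, group = as.numeric(cohort$meta$group == "case"))
  models <- list()
  for (m in measures) {
    x <- if (m == "etiv") matrix(cohort$etiv, ncol = 1,
                                 dimnames = list(cohort$meta$subject_id, "etiv"))
         else cohort[[m]]
    fit <- combat_fit(x, cohort$meta$batch, covs)
    if (m == "etiv") cohort$etiv <- stats::setNames(drop(fit$adjusted),
                                                    cohort$meta$subject_id)
    else cohort[[m]] <- fit$adjusted
    models[[m]] <- fit
  }
  cohort$global_area <- rowSums(cohort$area)
  cohort$combat_models <- models
  cohort
}
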