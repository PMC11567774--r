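# Mass-univariate group comparisons, FDR control, and the effect-size
# calculus: AUC <-> Cohen's d, bias-corrected Mahalanobis D, noncentral-t
# power analysis.

#' Per-region two-sample t-tests with FDR control
#'
#' Pooled-variance (Student) two-sample t per region, Cohen's d with pooled
#' SD, and Benjamini-Hochberg q-values across regions. Positive t and d
#' mean group A above group B.
#'
#' @param groupA,groupB Subjects x regions matrices (same columns).
#' @param alpha Significance threshold used for the direction counts.
#' @return An object of class `region_stats`: data.frame with columns
#'   region, t, df, p, q, cohens_d, direction; attributes `n_sig_up` /
#'   `n_sig_down` count FDR-significant regions by direction.
#' @export
region_ttests <- function(groupA, groupB, alpha = 0.05) {
  groupA <- as.matrix(groupA)
  groupB <- as.matrix(groupB)
  stopifnot(ncol(groupA) == ncol(groupB))
  nA <- nrow(groupA)
  nB <- nrow(groupB)
  stopifnot(nA >= 2, nB >= 2)
  mA <- colMeans(groupA)
  mB <- colMeans(groupB)
  vA <- apply(groupA, 2, stats::var)
  vB <- apply(groupB, 2, stats::var)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  if (any(sp2 == 0)) {
    labs <- colnames(groupA)
    if (is.null(labs)) labs <- as.character(seq_along(sp2))
    stop("zero pooled variance in region: ", labs[which(sp2 == 0)[1]])
  }
  d <- (mA - mB) / sqrt(sp2)
  tval <- (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
  df <- nA + nB - 2
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  q <- bh_fdr(p)
  labs <- colnames(groupA)
  if (is.null(labs)) labs <- sprintf("region_%04d", seq_along(p))
  out <- data.frame(region = labs, t = tval, df = df, p = p, q = q,
                    cohens_d = d,
                    direction = ifelse(d > 0, "up", ifelse(d < 0, "down", "none")),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_sig_up") <- sum(out$q < alpha & out$cohens_d > 0)
  attr(out, "n_sig_down") <- sum(out$q < alpha & out$cohens_d < 0)
  class(out) <- c("region_stats", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforced; idempotent on already
#' adjusted inputs and never below the raw p-value.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Convert an AUC to Cohen's d (binormal equal-variance model)
#'
#' Under equal-variance normal score distributions, AUC = Phi(d / sqrt(2)),
#' so d = sqrt(2) * qnorm(AUC): an AUC of 0.8 corresponds to d = 1.19 and
#' 0.9 to d = 1.81.
#'
#' @param auc AUC in (0, 1), exclusive.
#' @return Cohen's d (negative for AUC below chance).
#' @seealso [d_to_auc()]
#' @export
auc_to_d <- function(auc) {
  if (any(auc <= 0 | auc >= 1))
    stop("auc must lie strictly inside (0, 1); d is infinite at the bounds")
  sqrt(2) * stats::qnorm(auc)
}

#' Convert Cohen's d to AUC (inverse of [auc_to_d()])
#'
#' @param d Cohen's d.
#' @return AUC in (0, 1).
#' @export
d_to_auc <- function(d) {
  stats::pnorm(d / sqrt(2))
}

#' Mahalanobis D between two groups
#'
#' Multivariate analogue of Cohen's d: `D = sqrt((mA - mB)' S^-1 (mA - mB))`
#' with pooled covariance S. With `bias_correct`, the squared distance is
#' replaced by the standard unbiased estimator
#' `D_u^2 = ((N - p - 3) / (N - 2)) D^2 - p N / (nA nB)` (floored at zero),
#' which removes the small-sample inflation that makes raw D positive even
#' under the null.
#'
#' @param groupA,groupB Subjects x p matrices.
#' @param bias_correct Apply the small-sample correction (default TRUE).
#' @param floor_at_zero Floor the corrected squared distance at zero before
#'   taking the root (default TRUE); set FALSE to obtain the signed squared
#'   distance in attribute `"d2"`, e.g. to check unbiasedness by simulation.
#' @return Scalar D (bias-corrected when requested), with the (possibly
#'   negative) squared distance in attribute `"d2"`.
#' @export
mahalanobis_D <- function(groupA, groupB, bias_correct = TRUE,
                          floor_at_zero = TRUE) {
  groupA <- as.matrix(groupA)
  groupB <- as.matrix(groupB)
  p <- ncol(groupA)
  stopifnot(ncol(groupB) == p)
  nA <- nrow(groupA)
  nB <- nrow(groupB)
  n <- nA + nB
  if (p >= n - 2)
    stop("p >= N - 2: pooled covariance singular; reduce dimensionality first")
  s <- (stats::cov(groupA) * (nA - 1) + stats::cov(groupB) * (nB - 1)) / (n - 2)
  dm <- colMeans(groupA) - colMeans(groupB)
  d2 <- drop(crossprod(dm, solve(s, dm)))
  if (bias_correct)
    d2 <- (n - p - 3) / (n - 2) * d2 - p * n / (nA * nB)
  d2_floored <- if (floor_at_zero) max(d2, 0) else max(d2, 0)
  out <- sqrt(d2_floored)
  attr(out, "d2") <- if (floor_at_zero) d2_floored else d2
  out
}

# two-sided two-sample t power at effect size d, n per group
.t_power <- function(d, alpha, n) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}

#' Smallest detectable effect size for a two-sample t-test
#'
#' Solves the noncentral-t power function by bisection (tolerance 1e-6) for
#' the smallest Cohen's d reaching the requested power at the given
#' per-group sample size with a two-sided test. At alpha = 0.05 and power
#' 0.8, n = 100 per group detects d = 0.40 and above.
#'
#' @param alpha Two-sided significance level in (0, 1).
#' @param power Target power in (alpha, 1).
#' @param n_per_group Per-group sample size (>= 2).
#' @return The minimal detectable Cohen's d.
#' @export
detectable_d <- function(alpha = 0.05, power = 0.8, n_per_group = 100) {
  stopifnot(alpha > 0, alpha < 1, power > alpha, power < 1, n_per_group >= 2)
  lo <- 0
  hi <- 1
  while (.t_power(hi, alpha, n_per_group) < power) hi <- hi * 2
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (.t_power(mid, alpha, n_per_group) < power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Correlation between control centrality and group difference
#'
#' The hub-flattening summary: the Pearson correlation across parcels
#' between control-group mean degree centrality and the per-parcel group
#' difference (Cohen's d, cases minus controls). A negative correlation
#' says hubs are less central in cases and spokes more so -- a flatter
#' connectome.
#'
#' @param control_centrality Per-parcel mean centrality in controls.
#' @param group_d Per-parcel group difference (Cohen's d).
#' @return List with `r`, `p` (two-sided), `n`.
#' @export
flattening_correlation <- function(control_centrality, group_d) {
  stopifnot(length(control_centrality) == length(group_d))
  if (stats::sd(control_centrality) == 0 || stats::sd(group_d) == 0)
    stop("constant input")
  ct <- stats::cor.test(control_centrality, group_d)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(group_d))
}
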