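# Functional connectome derivations: Pearson and shrinkage-regularized
# partial correlations, degree centrality, and connectivity gradients with
# Procrustes alignment to a control-derived reference.

#' Pearson correlation connectome
#'
#' @param ts Parcels x timepoints matrix (a subject's resting-state series),
#'   or a `RestingTimeseries`-style list with element `data`.
#' @return An object of class `connectome`: `weights` (parcels x parcels,
#'   zero diagonal), `kind = "pearson"`, `parcel_labels`.
#' @export
pearson_connectome <- function(ts) {
  x <- .ts_matrix(ts)
  v <- apply(x, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance parcel: ", rownames(x)[which(v == 0)[1]])
  w <- stats::cor(t(x))
  diag(w) <- 0
  .connectome(w, "pearson", rownames(x))
}

#' Partial correlation connectome with shrinkage regularization
#'
#' Computes partial correlations from the inverse of a regularized
#' correlation matrix: `R_lambda = (1 - lambda) R + lambda I`, then
#' `pr_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)` with `Omega = R_lambda^-1`.
#' With hundreds of parcels and modest scan lengths the sample correlation
#' is ill-conditioned or singular; shrinkage toward the identity is the
#' standard remedy. `"auto"` uses the analytic (Schafer-Strimmer style)
#' optimal intensity `sum(Var(r_ij)) / sum(r_ij^2)` over off-diagonal
#' entries, clipped to \[0.01, 1\].
#'
#' @param ts Parcels x timepoints matrix (T >= 30), or list with `data`.
#' @param shrinkage `"auto"` or a fixed lambda in \[0, 1\].
#' @return A `connectome` with `kind = "partial"` and attribute
#'   `shrinkage` recording the intensity used.
#' @export
partial_connectome <- function(ts, shrinkage = "auto") {
  x <- .ts_matrix(ts)
  tt <- ncol(x)
  if (tt < 30) stop("need at least 30 timepoints")
  v <- apply(x, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance parcel: ", rownames(x)[which(v == 0)[1]])
  xs <- t(scale(t(x)))  # parcel-standardized
  r <- tcrossprod(xs) / (tt - 1)
  if (identical(shrinkage, "auto")) {
    lambda <- .optimal_shrinkage(xs, r, tt)
  } else {
    lambda <- as.numeric(shrinkage)
    if (lambda < 0 || lambda > 1) stop("shrinkage must lie in [0, 1]")
  }
  p <- nrow(r)
  r_shrunk <- (1 - lambda) * r
  diag(r_shrunk) <- diag(r_shrunk) + lambda
  omega <- tryCatch(solve(r_shrunk), error = function(e)
    stop("regularized correlation matrix not invertible (lambda = ",
         signif(lambda, 3), ")"))
  d <- sqrt(diag(omega))
  w <- -omega / tcrossprod(d)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  out <- .connectome(w, "partial", rownames(x))
  attr(out, "shrinkage") <- lambda
  out
}

# analytic shrinkage intensity toward the identity target:
# lambda* = sum_{i!=j} Var(r_ij) / sum_{i!=j} r_ij^2
.optimal_shrinkage <- function(xs, r, tt) {
  # w_kij = xs_ik * xs_jk; Var(r_ij) ~ n/(n-1)^3 * sum_k (w_kij - wbar_ij)^2
  xs2 <- xs^2
  sw2 <- tcrossprod(xs2)              # sum_k w_kij^2
  wbar <- r * (tt - 1) / tt
  varr <- tt / (tt - 1)^3 * (sw2 - tt * wbar^2)
  off <- upper.tri(r)
  lam <- sum(varr[off]) / sum(r[off]^2)
  min(max(lam, 0.01), 1)
}

#' Degree centrality of a connectome
#'
#' Per region, the sum of absolute edge weights to all other regions: high
#' values mark hubs whose influence spans the network. Intended for partial
#' correlation connectomes; a Pearson input is accepted with the kind
#' recorded in the result's `"kind"` attribute so provenance is auditable.
#'
#' @param c A `connectome`.
#' @return Named numeric vector of length n_parcels with attribute `"kind"`.
#' @export
degree_centrality <- function(c) {
  stopifnot(inherits(c, "connectome"))
  out <- rowSums(abs(c$weights))
  names(out) <- c$parcel_labels
  attr(out, "kind") <- c$kind
  if (c$kind != "partial")
    warning("degree centrality computed from a ", c$kind, " connectome")
  out
}

#' Reference gradient set from control connectomes
#'
#' Averages the supplied (Pearson) connectomes and extracts the first two
#' principal components over regions: each region's row of connectivity
#' weights is one observation, so regions with similar connectivity
#' profiles receive similar gradient scores. Subject gradients are aligned
#' to this reference by orthogonal Procrustes, resolving the sign/rotation
#' indeterminacy of per-subject PCA.
#'
#' @param connectomes List of >= 10 `connectome` objects (control group).
#' @return A `gradient_set`: `scores` (regions x 2, zero column means),
#'   `explained_variance` (length 2), `reference_aligned = TRUE`.
#' @export
gradient_reference <- function(connectomes) {
  if (length(connectomes) < 10)
    stop("reference requires >= 10 connectomes")
  w <- Reduce(`+`, lapply(connectomes, function(cn) cn$weights)) /
    length(connectomes)
  gs <- .gradient_pca(w)
  gs$reference_aligned <- TRUE
  rownames(gs$scores) <- connectomes[[1]]$parcel_labels
  gs
}

#' Gradient scores for one connectome, aligned to a reference
#'
#' @param c A `connectome` (Pearson by construction of the pipeline).
#' @param reference Output of [gradient_reference()].
#' @return A `gradient_set` with Procrustes-aligned scores.
#' @export
gradients <- function(c, reference) {
  stopifnot(inherits(c, "connectome"))
  gs <- .gradient_pca(c$weights)
  # orthogonal Procrustes: rotate subject scores onto the reference frame
  m <- crossprod(gs$scores, reference$scores)
  sv <- svd(m)
  q <- sv$u %*% t(sv$v)
  gs$scores <- gs$scores %*% q
  colnames(gs$scores) <- c("gradient1", "gradient2")
  rownames(gs$scores) <- c$parcel_labels
  gs$reference_aligned <- TRUE
  gs
}

.gradient_pca <- function(w) {
  if (max(apply(w, 2, stats::sd)) < 1e-12)
    stop("degenerate connectome: all rows equal")
  pc <- stats::prcomp(w, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, 1:2, drop = FALSE]
  colnames(scores) <- c("gradient1", "gradient2")
  structure(list(scores = scores, explained_variance = v[1:2],
                 reference_aligned = FALSE),
            class = "gradient_set")
}

.ts_matrix <- function(ts) {
  x <- if (is.list(ts) && !is.null(ts$data)) ts$data else ts
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("P_%03d", seq_len(nrow(x)))
  x
}

.connectome <- function(w, kind, labels) {
  if (max(abs(w - t(w))) > 1e-8) stop("connectome weights not symmetric")
  dimnames(w) <- list(labels, labels)
  structure(list(weights = w, kind = kind, parcel_labels = labels),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome>", x$kind, ":", nrow(x$weights), "x", ncol(x$weights), "\n")
  invisible(x)
}
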