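# Functional connectome derivations: Pearson/partial correlations, degree
# centrality, gradients, and the hub-flattening signatures.

test_that("Pearson connectome reproduces exact and null correlations", {
  set.seed(1)
  ts <- matrix(rnorm(5 * 200), 5, 200)
  ts[2, ] <- ts[1, ]  # duplicated parcel
  cn <- pearson_connectome(ts)
  expect_equal(cn$weights[1, 2], 1)
  expect_equal(diag(cn$weights), rep(0, 5), ignore_attr = TRUE)

  expect_equal(pearson_connectome(rbind(c(1, 2, 3), c(3, 2, 1)))$weights[1, 2], -1)

  white <- matrix(rnorm(30 * 2000), 30, 2000)
  cw <- pearson_connectome(white)$weights
  expect_lt(quantile(abs(cw[upper.tri(cw)]), 0.95), 0.06)

  bad <- matrix(rnorm(3 * 50), 3, 50)
  bad[2, ] <- 4
  rownames(bad) <- c("L_001", "L_002", "L_003")
  expect_error(pearson_connectome(bad), "L_002")
})

test_that("partial correlation reduces to Pearson for two parcels", {
  set.seed(2)
  ts <- matrix(rnorm(2 * 500), 2, 500)
  ts[2, ] <- 0.6 * ts[1, ] + 0.8 * ts[2, ]
  pe <- pearson_connectome(ts)$weights[1, 2]
  pa <- partial_connectome(ts, shrinkage = 0)$weights[1, 2]
  expect_equal(pa, pe, tolerance = 1e-6)
})

test_that("partial correlation recovers chain conditional independence", {
  # X -> Y -> Z: Pearson r(X,Z) is large but partial r(X,Z) ~ 0
  set.seed(3)
  n <- 5000
  x <- rnorm(n)
  y <- x + rnorm(n)
  z <- y + rnorm(n)
  ts <- rbind(x, y, z)
  pearson_xz <- pearson_connectome(ts)$weights[1, 3]
  partial <- partial_connectome(ts, shrinkage = 1e-4)$weights
  expect_gt(pearson_xz, 0.4)
  expect_lt(abs(partial[1, 3]), 0.05)
  # closed-form oracle from the population covariance of the chain
  sigma <- rbind(c(1, 1, 1), c(1, 2, 2), c(1, 2, 3))
  omega <- solve(sigma)
  oracle_xy <- -omega[1, 2] / sqrt(omega[1, 1] * omega[2, 2])
  expect_equal(partial[1, 2], oracle_xy, tolerance = 0.05)
})

test_that("full shrinkage zeroes all partials and auto stays in range", {
  set.seed(4)
  ts <- matrix(rnorm(10 * 100), 10, 100)
  p1 <- partial_connectome(ts, shrinkage = 1)
  expect_true(all(abs(p1$weights) < 1e-12))
  pa <- partial_connectome(ts, shrinkage = "auto")
  lam <- attr(pa, "shrinkage")
  expect_gte(lam, 0.01)
  expect_lte(lam, 1)
  expect_error(partial_connectome(ts[, 1:20]), "30 timepoints")
})

test_that("degree centrality sums absolute weights and flags provenance", {
  w <- matrix(0.2, 6, 6)
  diag(w) <- 0
  cn <- structure(list(weights = w, kind = "partial",
                       parcel_labels = letters[1:6]), class = "connectome")
  expect_equal(degree_centrality(cn), rep(5 * 0.2, 6), ignore_attr = TRUE)
  cn$weights <- matrix(0, 6, 6)
  expect_equal(degree_centrality(cn), rep(0, 6), ignore_attr = TRUE)
  cn$kind <- "pearson"
  expect_warning(dc <- degree_centrality(cn), "pearson")
  expect_identical(attr(dc, "kind"), "pearson")
})

test_that("template hubs attain the top centrality ranks", {
  tmpl <- connectome_template(60)
  hubs <- attr(tmpl, "hubs")
  w <- tmpl
  diag(w) <- 0
  cn <- structure(list(weights = w, kind = "partial",
                       parcel_labels = parcel_labels(60)), class = "connectome")
  dc <- degree_centrality(cn)
  top <- order(dc, decreasing = TRUE)[seq_along(hubs)]
  expect_setequal(top, hubs)
})

test_that("gradient 1 separates the blocks of a two-block connectome", {
  p <- 40
  blk <- rep(1:2, each = p / 2)
  w <- ifelse(outer(blk, blk, `==`), 0.6, 0.05)
  diag(w) <- 0
  cn <- structure(list(weights = w, kind = "pearson",
                       parcel_labels = parcel_labels(p)), class = "connectome")
  gs <- synmark:::.gradient_pca(w)
  g1 <- gs$scores[, 1]
  expect_true(all(sign(g1[blk == 1]) == sign(g1[blk == 1])[1]))
  expect_true(sign(g1[blk == 1][1]) != sign(g1[blk == 2][1]))
  expect_equal(mean(g1), 0, tolerance = 1e-10)
  # oracle: the dominant eigenvector of the ideal two-block matrix is the
  # block contrast, so within-block scores are near-constant
  expect_lt(sd(g1[blk == 1]) / sd(g1), 0.2)
})

test_that("gradients align to the reference up to sign flips", {
  set.seed(5)
  cfg <- small_config(n_cases = 6L, n_controls_per_batch = c(4L, 4L, 2L, 2L),
                      n_timepoints = 80L, seed = 16L)
  coh <- generate_cohort(cfg)
  conns <- lapply(coh$timeseries, pearson_connectome)
  ref <- gradient_reference(conns[1:12])
  expect_equal(colMeans(ref$scores), c(0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)

  # a subject whose connectome equals the reference mean reproduces the
  # reference scores
  wbar <- Reduce(`+`, lapply(conns[1:12], function(cn) cn$weights)) / 12
  cn_mean <- structure(list(weights = wbar, kind = "pearson",
                            parcel_labels = conns[[1]]$parcel_labels),
                       class = "connectome")
  gs <- gradients(cn_mean, ref)
  expect_equal(unname(gs$scores), unname(ref$scores), tolerance = 1e-6)

  # sign-flipped PCA solutions are undone by the Procrustes alignment
  flipped <- ref
  flipped$scores <- ref$scores %*% diag(c(-1, 1))
  gs2 <- gradients(cn_mean, structure(flipped, class = "gradient_set"))
  expect_equal(unname(gs2$scores %*% diag(c(-1, 1))), unname(ref$scores),
               tolerance = 1e-6)

  expect_error(gradient_reference(conns[1:3]), ">= 10")
  degenerate <- structure(list(weights = matrix(0.5, 40, 40), kind = "pearson",
                               parcel_labels = parcel_labels(40)),
                          class = "connectome")
  expect_error(gradients(degenerate, ref), "degenerate")
})

test_that("hub flattening produces the negative centrality-difference coupling", {
  cfg <- cohort_config(n_cases = 100L, n_controls_per_batch = c(25L, 25L, 25L, 25L),
                       n_parcels = 360L, n_subcortical = 10L,
                       n_timepoints = 120L, hub_flattening = 0.5, seed = 17L)
  coh <- generate_cohort(cfg)
  case <- coh$meta$group == "case"
  cent <- t(vapply(coh$timeseries, function(ts)
    unname(degree_centrality(partial_connectome(ts, "auto"))), numeric(360)))
  ctrl_mean <- colMeans(cent[!case, ])
  sp <- sqrt(((sum(case) - 1) * apply(cent[case, ], 2, var) +
              (sum(!case) - 1) * apply(cent[!case, ], 2, var)) /
             (nrow(cent) - 2))
  d <- (colMeans(cent[case, ]) - colMeans(cent[!case, ])) / sp
  fc <- flattening_correlation(ctrl_mean, d)
  expect_lt(fc$r, -0.2)

  # controls show more extreme partial correlations than flattened cases
  edge_var <- function(ids) {
    v <- vapply(coh$timeseries[ids], function(ts) {
      w <- partial_connectome(ts, "auto")$weights
      var(w[upper.tri(w)])
    }, numeric(1))
    mean(v)
  }
  expect_gt(edge_var(which(!case)[1:30]) / edge_var(which(case)[1:30]), 1)
})
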