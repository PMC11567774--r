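# Shared fixture builders: small cohorts generated in code at test time.

small_config <- function(..., seed = 11L) {
  defaults <- list(n_cases = 20L, n_controls_per_batch = c(10L, 10L, 5L, 5L),
                   n_parcels = 40L, n_subcortical = 10L, n_timepoints = 0L,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# a two-group measure matrix pair with planted shifts on the first parcels
planted_groups <- function(n_per = 150, p = 360, d = 0.8, n_affected = 10,
                           seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(n_per * p), n_per, p)
  b <- matrix(rnorm(n_per * p), n_per, p)
  a[, seq_len(n_affected)] <- a[, seq_len(n_affected)] + d
  list(case = a, control = b, affected = seq_len(n_affected))
}

# exhaustive pairwise AUC oracle: half credit for ties
auc_by_pair_counting <- function(scores, labels) {
  pos <- which(labels == "case")
  neg <- which(labels == "control")
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + if (scores[i] > scores[j]) 1
      else if (scores[i] == scores[j]) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
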