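# Synthetic cohort generation: structural parcel maps, volumes, metadata and
# hub-structured resting-state time series, with planted group effects and
# per-batch location/scale site effects.

#' Generate a synthetic cohort
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes: per-parcel Gaussian structural measures with planted case-control
#' mean shifts (in units of within-group SD), a latent-factor cortical
#' thickness model whose inter-regional correlation can be raised in cases,
#' an eTIV shift decoupled from global surface area, resting-state time
#' series drawn from group connectome templates (hub-structured; the case
#' template optionally shrunk toward uniform connectivity), and per-batch
#' additive/multiplicative site effects applied last.
#'
#' @param config A [cohort_config()].
#' @return An object of class `syn_cohort`: a list with
#'   \describe{
#'     \item{meta}{data.frame with subject_id, group ("case"/"control"),
#'       batch (1..4), sex ("F"/"M"), age, n_types (NA for controls).}
#'     \item{area, thickness, myelin}{subjects x n_parcels matrices (mm^2,
#'       mm, T1w/T2w ratio).}
#'     \item{subcortical}{subjects x n_subcortical matrix (mm^3).}
#'     \item{etiv}{named vector (mm^3).}
#'     \item{global_area}{named vector (mm^2), exactly `rowSums(area)`.}
#'     \item{timeseries}{named list of parcels x timepoints matrices, or
#'       NULL when `n_timepoints = 0`.}
#'   }
#' @seealso [behavioral_table()], [save_cohort()]
#' @examples
#' cfg <- cohort_config(n_cases = 10, n_controls_per_batch = c(5, 5, 2, 2),
#'                      n_parcels = 20, n_timepoints = 0, seed = 7)
#' coh <- generate_cohort(cfg)
#' table(coh$meta$group)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  p <- config$n_parcels
  q <- config$n_subcortical
  plabs <- parcel_labels(p)
  slabs <- if (q == 34L) subcortical_labels() else sprintf("structure_%02d", seq_len(q))

  meta <- .cohort_metadata(config)
  n <- nrow(meta)
  case <- meta$group == "case"

  # per-parcel baseline means drawn once per cohort (part of the template)
  mu <- list(
    area        = stats::runif(p, 300, 700),
    thickness   = stats::runif(p, 2.0, 3.0),
    myelin      = stats::runif(p, 1.3, 1.7),
    subcortical = exp(stats::runif(q, log(500), log(60000)))
  )
  sdv <- lapply(names(mu), function(m) mu[[m]] * config$noise_sd[[m]])
  names(sdv) <- names(mu)

  draw_measure <- function(measure, dim2, labs) {
    x <- matrix(stats::rnorm(n * dim2), n, dim2)
    x <- sweep(x, 2, sdv[[measure]], `*`)
    x <- sweep(x, 2, mu[[measure]], `+`)
    dimnames(x) <- list(meta$subject_id, labs)
    x
  }

  area <- draw_measure("area", p, plabs)
  myelin <- draw_measure("myelin", p, plabs)
  subcortical <- draw_measure("subcortical", q, slabs)

  # thickness: one-factor model so inter-parcel correlation is base_coupling
  # (+ coupling_boost in cases)
  rho <- ifelse(case, config$base_coupling + config$coupling_boost,
                config$base_coupling)
  f <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * p), n, p)
  z <- sqrt(rho) * f + sqrt(1 - rho) * eps
  thickness <- sweep(sweep(z, 2, sdv$thickness, `*`), 2, mu$thickness, `+`)
  dimnames(thickness) <- list(meta$subject_id, plabs)

  # planted group mean shifts: case mean = control mean + d * within-group SD
  measures <- list(area = area, thickness = thickness, myelin = myelin,
                   subcortical = subcortical)
  case_mult <- if (config$types_scale_effects)
    meta$n_types[case] / 3 else rep(1, sum(case))
  for (ef in config$effect_map) {
    shift <- outer(case_mult, ef$d * sdv[[ef$measure]][ef$parcels])
    measures[[ef$measure]][case, ef$parcels] <-
      measures[[ef$measure]][case, ef$parcels, drop = FALSE] + shift
  }

  # eTIV shifted by etiv_effect_d in cases; global area stays the parcel sum,
  # so cases with smaller eTIV keep non-scaled-down cortex
  mu_etiv <- 1.5e6
  sd_etiv <- mu_etiv * config$noise_sd[["etiv"]]
  etiv <- mu_etiv + sd_etiv * (stats::rnorm(n) + config$etiv_effect_d * case)
  names(etiv) <- meta$subject_id

  # resting-state series from group connectome templates
  timeseries <- NULL
  if (config$n_timepoints > 0) {
    tmpl <- connectome_template(p)
    tmpl_case <- flatten_template(tmpl, config$hub_flattening)
    u_ctrl <- chol(tmpl)
    u_case <- chol(tmpl_case)
    timeseries <- vector("list", n)
    names(timeseries) <- meta$subject_id
    for (i in seq_len(n)) {
      zmat <- matrix(stats::rnorm(config$n_timepoints * p), config$n_timepoints, p)
      x <- zmat %*% (if (case[i]) u_case else u_ctrl)
      ts <- t(x)
      dimnames(ts) <- list(plabs, NULL)
      timeseries[[i]] <- ts
    }
  }

  # site effects last: pure location/scale per measure per batch
  b <- meta$batch
  for (m in names(measures)) {
    sc <- config$batch_scale[[m]][b]
    sh <- config$batch_shift[[m]][b]
    measures[[m]] <- measures[[m]] * sc + sh
  }
  etiv <- etiv * config$batch_scale[["etiv"]][b] + config$batch_shift[["etiv"]][b]

  global_area <- rowSums(measures$area)

  structure(list(
    meta = meta,
    area = measures$area,
    thickness = measures$thickness,
    myelin = measures$myelin,
    subcortical = measures$subcortical,
    etiv = etiv,
    global_area = global_area,
    timeseries = timeseries,
    config = config
  ), class = "syn_cohort")
}

#' @keywords internal
.cohort_metadata <- function(config) {
  n_ctrl <- sum(config$n_controls_per_batch)
  n <- config$n_cases + n_ctrl
  group <- c(rep("case", config$n_cases), rep("control", n_ctrl))
  case_batches <- if (identical(config$case_batch, "spread"))
    rep(1:4, length.out = config$n_cases) else
    rep(config$case_batch, config$n_cases)
  batch <- c(case_batches, rep(1:4, config$n_controls_per_batch))
  # multi-type synesthesia is the norm in verified cohorts: P(3+ types) ~ 0.65
  type_probs <- c(0.17, 0.18, 0.25, 0.18, 0.12, 0.10)
  n_types <- ifelse(group == "case",
                    sample(seq_along(type_probs), n, replace = TRUE,
                           prob = type_probs), NA_integer_)
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = group,
    batch = as.integer(batch),
    sex = ifelse(stats::runif(n) < config$sex_ratio_f, "F", "M"),
    age = round(stats::runif(n, 18, 65), 1),
    n_types = as.integer(n_types),
    stringsAsFactors = FALSE
  )
}

#' Control-group connectome template
#'
#' Builds the correlation-scale template the time-series generator samples
#' from: a stochastic-block structure (5 blocks, within-block coupling above
#' between-block), with 10% of parcels designated hubs whose couplings are
#' doubled. A small ridge keeps the matrix positive definite.
#'
#' @param n_parcels Number of parcels.
#' @param n_blocks Number of blocks (default 5).
#' @param hub_frac Fraction of hub parcels (default 0.1).
#' @param r_within,r_between Within/between block baseline couplings.
#' @return `n_parcels` x `n_parcels` positive-definite correlation matrix
#'   with attribute `"hubs"` (hub parcel indices).
#' @export
connectome_template <- function(n_parcels, n_blocks = 5L, hub_frac = 0.1,
                                r_within = 0.30, r_between = 0.05) {
  blk <- rep(seq_len(n_blocks), length.out = n_parcels)
  blk <- sort(blk)
  w <- ifelse(outer(blk, blk, `==`), r_within, r_between)
  hubs <- seq(1L, n_parcels, by = max(1L, round(1 / hub_frac)))
  w[hubs, ] <- 2 * w[hubs, ]
  w[, hubs] <- pmax(w[, hubs], t(w[hubs, , drop = FALSE]))
  w <- (w + t(w)) / 2
  w <- pmin(w, 0.85)
  diag(w) <- 1
  # ridge toward identity to guarantee positive definiteness
  ev_min <- min(eigen(w, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 0.05) {
    lam <- (0.05 - ev_min) / (1 - ev_min)
    w <- (1 - lam) * w
    diag(w) <- 1
  }
  attr(w, "hubs") <- hubs
  w
}

#' Shrink a connectome template toward uniform connectivity
#'
#' @param template Output of [connectome_template()].
#' @param strength Flattening strength in \[0, 1\]; 0 returns the template,
#'   1 replaces every off-diagonal weight with the template's mean weight.
#' @return Flattened template (hubs attribute preserved).
#' @export
flatten_template <- function(template, strength) {
  stopifnot(strength >= 0, strength <= 1)
  off <- template[upper.tri(template)]
  flat <- matrix(mean(off), nrow(template), ncol(template))
  diag(flat) <- 1
  out <- (1 - strength) * template + strength * flat
  attr(out, "hubs") <- attr(template, "hubs")
  out
}

#' Synthetic behavioral assessment table
#'
#' Stand-in for the 35 behavioral dependent variables (autistic traits,
#' sensory sensitivity, anxiety, mood, PTSD-like symptoms, hypermobility,
#' personality, imagery, memory, intelligence, creativity): independent
#' standard-normal scores for controls with case means shifted by the
#' requested Cohen's d per variable.
#'
#' @param n_cases,n_controls Group sizes.
#' @param effects Numeric vector of 35 Cohen's d values (case minus control).
#' @param types_scale_effects When TRUE, each case's shift is scaled by
#'   `n_types / 3`, linking classifiability to the number of types.
#' @param seed Integer seed.
#' @return List with `values` (subjects x 35 matrix, named columns),
#'   `labels` (factor, levels control/case) and `meta` (subject_id, group,
#'   n_types for cases).
#' @export
behavioral_table <- function(n_cases, n_controls, effects,
                             types_scale_effects = FALSE, seed = 1L) {
  vars <- behavioral_variables()
  if (length(effects) != length(vars))
    stop("effects must have length ", length(vars))
  set.seed(seed)
  n <- n_cases + n_controls
  labels <- factor(rep(c("case", "control"), c(n_cases, n_controls)),
                   levels = c("control", "case"))
  x <- matrix(stats::rnorm(n * length(vars)), n, length(vars))
  ids <- sprintf("B%04d", seq_len(n))
  dimnames(x) <- list(ids, vars)
  type_probs <- c(0.17, 0.18, 0.25, 0.18, 0.12, 0.10)
  meta <- data.frame(
    subject_id = ids, group = as.character(labels),
    n_types = ifelse(labels == "case",
                     sample(6L, n, replace = TRUE, prob = type_probs),
                     NA_integer_),
    stringsAsFactors = FALSE
  )
  mult <- if (types_scale_effects) meta$n_types[labels == "case"] / 3 else
    rep(1, n_cases)
  x[labels == "case", ] <- x[labels == "case", , drop = FALSE] +
    outer(mult, effects)
  list(values = x, labels = labels, meta = meta)
}

#' Names of the 35 behavioral dependent variables
#' @return Character vector of length 35.
#' @export
behavioral_variables <- function() {
  c(paste0("AQ_", c("social_skills", "imagination", "communication",
                    "attention_detail", "attention_switch")),
    "GSQ_sensory",
    paste0("ASI_", c("social", "physical", "cognitive")),
    paste0("DASS_", c("depression", "stress", "anxiety")),
    paste0("IES_", c("intrusions", "hyperarousal", "avoidance")),
    "hypermobility",
    paste0("BFI_", c("openness", "negative_emotion", "conscientiousness",
                     "agreeableness", "extraversion")),
    paste0("imagery_", c("smell", "vision", "touch", "taste", "sound",
                         "emotion", "body_sensation")),
    paste0("memory_", c("acc_conf_r", "auc", "familiarity", "recollection")),
    "ravens_matrices",
    paste0("AUT_", c("creativity", "novelty")))
}

#' @export
print.syn_cohort <- function(x, ...) {
  cat("<syn_cohort>", nrow(x$meta), "subjects (",
      sum(x$meta$group == "case"), "cases /",
      sum(x$meta$group == "control"), "controls ),",
      ncol(x$area), "parcels,",
      if (is.null(x$timeseries)) "no time series" else
        paste(ncol(x$timeseries[[1]]), "timepoints"), "\n")
  invisible(x)
}
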