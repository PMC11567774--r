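# Cohort configuration and validation for the synthetic generator.

#' Measures handled by the structural generator
#' @keywords internal
.structural_measures <- c("area", "thickness", "myelin", "subcortical", "etiv")

#' Labels for the 34 subcortical / non-cortical structures
#'
#' Bilateral grey-matter structures, corpus callosum segments, cerebellar
#' white matter, brainstem, optic chiasm and the ventricular system --
#' the volume set carried as a biomarker alongside eTIV.
#'
#' @return Character vector of length 34.
#' @export
subcortical_labels <- function() {
  bilat <- c("amygdala", "hippocampus", "thalamus", "ventral_DC", "caudate",
             "cerebellum_cortex", "pallidum", "putamen", "accumbens_area",
             "cerebellum_WM", "lateral_ventricle", "inferior_lateral_ventricle")
  c(paste0("left_", bilat), paste0("right_", bilat),
    paste0("CC_", c("anterior", "mid_anterior", "central", "mid_posterior",
                    "posterior")),
    "optic_chiasm", "brainstem", "CSF", "third_ventricle", "fourth_ventricle")
}

#' Default parcel labels (180 per hemisphere)
#'
#' @param n_parcels Total parcel count (must be even; half per hemisphere).
#' @return Character vector `L_001..L_k, R_001..R_k`.
#' @export
parcel_labels <- function(n_parcels = 360L) {
  stopifnot(n_parcels >= 2, n_parcels %% 2 == 0)
  k <- n_parcels / 2
  c(sprintf("L_%03d", seq_len(k)), sprintf("R_%03d", seq_len(k)))
}

#' Configure a synthetic cohort
#'
#' Defines the generative conditions for [generate_cohort()]: group sizes
#' across the four acquisition batches, planted group effects per measure,
#' intracranial-volume shift, inter-regional thickness coupling, functional
#' hub flattening, and per-batch location/scale site effects. Sample-size
#' defaults follow the study design this pipeline validates (102 cases and
#' 650 controls from two large public batches plus two small local ones);
#' all effect dials default to zero, i.e. a null cohort unless effects are
#' requested.
#'
#' @param n_cases Number of cases (synesthetes).
#' @param n_controls_per_batch Integer vector of length 4: controls per batch.
#'   Batches 1 and 2 are the "large public" sources that the staged split
#'   halves between discovery and demonstration; batches 3 and 4 are the
#'   small local sources used in discovery only.
#' @param case_batch Batch label (1..4) assigned to cases; default 4, the
#'   local site that scanned the case group. `"spread"` distributes cases
#'   round-robin over all four batches, which removes the group-batch
#'   confound when a test needs site effects orthogonal to group.
#' @param n_parcels Number of cortical parcels (default 360).
#' @param n_subcortical Number of subcortical volumes (default 34).
#' @param n_timepoints Resting-state timepoints per subject; 0 skips time
#'   series generation. When positive, must be at least `n_parcels / 4`.
#' @param effect_map List of planted mean shifts; each element is
#'   `list(measure = <name>, parcels = <indices>, d = <Cohen's d>)`, where
#'   `measure` is one of area, thickness, myelin, subcortical. Case means on
#'   the listed parcels are shifted by `d` within-group SDs.
#' @param etiv_effect_d Standardized shift of case eTIV (negative = smaller
#'   intracranial volume in cases).
#' @param coupling_boost Increment of the inter-regional thickness
#'   correlation in cases (added to `base_coupling`).
#' @param base_coupling Baseline inter-regional thickness correlation shared
#'   by both groups (latent-factor model; default 0.2).
#' @param hub_flattening Strength in \[0, 1\] shrinking the case connectome
#'   template toward uniform connectivity (0 = same hubs as controls,
#'   1 = fully flattened).
#' @param batch_shift,batch_scale Named lists (by measure) of length-4
#'   numeric vectors: additive / multiplicative site effects per batch,
#'   applied last in raw measurement units. Defaults: no shift, unit scale.
#' @param noise_sd Named numeric vector of per-measure residual SDs expressed
#'   as a fraction of the measure's parcel mean.
#' @param types_scale_effects When TRUE, each case's planted structural
#'   shifts are scaled by `n_types / 3`, so multi-type cases carry larger
#'   effects and are easier to classify (the vote-share-vs-types relation
#'   seen in real cohorts). Default FALSE: all cases share the nominal d.
#' @param sex_ratio_f Probability a subject is female (study cohorts are
#'   female-dominated; default 0.75).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 102L,
                          n_controls_per_batch = c(300L, 300L, 25L, 25L),
                          case_batch = 4L,
                          n_parcels = 360L,
                          n_subcortical = 34L,
                          n_timepoints = 0L,
                          effect_map = list(),
                          etiv_effect_d = 0,
                          coupling_boost = 0,
                          base_coupling = 0.2,
                          hub_flattening = 0,
                          batch_shift = NULL,
                          batch_scale = NULL,
                          noise_sd = NULL,
                          types_scale_effects = FALSE,
                          sex_ratio_f = 0.75,
                          seed = 1L) {
  default_noise <- c(area = 0.10, thickness = 0.05, myelin = 0.06,
                     subcortical = 0.12, etiv = 0.10)
  if (is.null(noise_sd)) noise_sd <- default_noise
  noise_sd <- replace(default_noise, names(noise_sd), noise_sd)

  zero4 <- stats::setNames(
    rep(list(rep(0, 4)), length(.structural_measures)), .structural_measures)
  one4 <- stats::setNames(
    rep(list(rep(1, 4)), length(.structural_measures)), .structural_measures)
  if (!is.null(batch_shift)) zero4 <- replace(zero4, names(batch_shift), batch_shift)
  if (!is.null(batch_scale)) one4 <- replace(one4, names(batch_scale), batch_scale)

  cfg <- structure(list(
    n_cases = as.integer(n_cases),
    n_controls_per_batch = as.integer(n_controls_per_batch),
    case_batch = if (identical(case_batch, "spread")) "spread"
                 else as.integer(case_batch),
    n_parcels = as.integer(n_parcels),
    n_subcortical = as.integer(n_subcortical),
    n_timepoints = as.integer(n_timepoints),
    effect_map = effect_map,
    etiv_effect_d = etiv_effect_d,
    coupling_boost = coupling_boost,
    base_coupling = base_coupling,
    hub_flattening = hub_flattening,
    batch_shift = zero4,
    batch_scale = one4,
    noise_sd = noise_sd,
    types_scale_effects = isTRUE(types_scale_effects),
    sex_ratio_f = sex_ratio_f,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @keywords internal
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_cases <= 0) stop("n_cases must be > 0")
  if (length(cfg$n_controls_per_batch) != 4 || any(cfg$n_controls_per_batch < 0))
    stop("n_controls_per_batch must be 4 non-negative counts")
  if (sum(cfg$n_controls_per_batch) == 0) stop("at least one control required")
  if (!identical(cfg$case_batch, "spread") && !cfg$case_batch %in% 1:4)
    stop("case_batch must be in 1..4 or \"spread\"")
  if (cfg$n_parcels <= 0 || cfg$n_parcels %% 2 != 0)
    stop("n_parcels must be a positive even count")
  if (cfg$n_subcortical <= 0) stop("n_subcortical must be > 0")
  if (cfg$n_timepoints < 0) stop("n_timepoints must be >= 0")
  if (cfg$n_timepoints > 0 && cfg$n_timepoints < cfg$n_parcels / 4)
    stop("n_timepoints must be at least n_parcels / 4")
  if (cfg$hub_flattening < 0 || cfg$hub_flattening > 1)
    stop("hub_flattening must lie in [0, 1]")
  if (cfg$base_coupling < 0 || cfg$base_coupling + max(cfg$coupling_boost, 0) >= 1)
    stop("thickness coupling (base_coupling + coupling_boost) must lie in [0, 1)")
  if (any(unlist(cfg$batch_scale) <= 0)) stop("batch_scale must be > 0")
  if (any(cfg$noise_sd <= 0)) stop("noise_sd must be > 0 for every measure")
  for (ef in cfg$effect_map) {
    if (!is.list(ef) || is.null(ef$measure) || is.null(ef$parcels) || is.null(ef$d))
      stop("each effect_map entry needs measure, parcels, d")
    if (!ef$measure %in% c("area", "thickness", "myelin", "subcortical"))
      stop("effect_map measure must be one of area/thickness/myelin/subcortical")
    n_max <- if (ef$measure == "subcortical") cfg$n_subcortical else cfg$n_parcels
    if (any(ef$parcels < 1L) || any(ef$parcels > n_max))
      stop("effect_map parcel indices out of range for ", ef$measure)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  cases:", x$n_cases, " controls/batch:",
      paste(x$n_controls_per_batch, collapse = "/"), "\n")
  cat("  parcels:", x$n_parcels, " subcortical:", x$n_subcortical,
      " timepoints:", x$n_timepoints, "\n")
  cat("  planted effects:", length(x$effect_map),
      " eTIV d:", x$etiv_effect_d,
      " coupling boost:", x$coupling_boost,
      " hub flattening:", x$hub_flattening, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
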