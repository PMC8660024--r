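# Automated methods reporting: a deterministic, manuscript-style paragraph
# describing exactly the processing steps a configuration executes.

#' Stages executed by a configuration
#'
#' The canonical stage list of [run_pipeline()] restricted to the steps the
#' configuration actually runs (disabled steps are omitted).
#'
#' @param config A [pipeline_config()].
#' @return Character vector of stage names, in execution order.
#' @export
executed_stages <- function(config) {
  stages <- character(0)
  if (config$reannotate) stages <- c(stages, "reannotation")
  if (!is.null(config$intensity_threshold)) {
    stages <- c(stages, "intensity_filter")
  }
  stages <- c(stages, "probe_selection")
  if (config$use_corrected_coords) {
    stages <- c(stages, "coordinate_correction")
  }
  if (config$mirror != "none") stages <- c(stages, "mirroring")
  if (!is.null(config$similarity_threshold)) {
    stages <- c(stages, "similarity_filter")
  }
  stages <- c(stages, "assignment")
  if (config$sample_norm != "none") {
    stages <- c(stages, "sample_normalization")
  }
  if (config$gene_norm != "none") stages <- c(stages, "gene_normalization")
  stages <- c(stages, "aggregation")
  if (config$missing == "nearest") stages <- c(stages, "missing_data")
  stages
}

#' Report context
#'
#' @param config A [pipeline_config()].
#' @param dataset_summary Named list: `n_donors`, `n_probes`,
#'   `n_samples` (total tissue samples), optionally `n_regions`.
#' @param version Software version string interpolated into the report.
#' @return A `report_context`.
#' @export
report_context <- function(config, dataset_summary = list(),
                           version = as.character(
                             utils::packageVersion("multigex"))) {
  stopifnot(inherits(config, "pipeline_config"))
  structure(list(config = config, dataset_summary = dataset_summary,
                 version = version),
            class = "report_context")
}

percent <- function(x) sprintf("%g%%", 100 * x)

norm_phrase <- function(method) {
  switch(method, zscore = "a z-score transform",
         srs = "a scaled robust sigmoid transform", method)
}

probe_phrase <- function(method) {
  switch(method,
         max_intensity = "the probe with the highest mean intensity across samples",
         corr_intensity = "the probe most correlated with the gene's other probes (falling back to the highest mean intensity for two-probe genes)",
         corr_variance = "the probe most correlated with the gene's other probes (falling back to the highest variance for two-probe genes)",
         diff_stability = "the probe with the highest differential stability across donors",
         rnaseq = "the probe most consistent with matched RNAseq data",
         average = "the mean across all of the gene's probes")
}

# One sentence per executed stage, keyed by stage name.
stage_sentences <- function(context) {
  cfg <- context$config
  ds <- context$dataset_summary
  sentences <- c(
    reannotation = "Probe-to-gene annotations were updated using the supplied reannotation table; probes without a current gene assignment were discarded.",
    intensity_filter = if (!is.null(cfg$intensity_threshold)) sprintf(
      "Probes were retained only if their expression exceeded background noise in more than %s of tissue samples, pooled across donors.",
      percent(cfg$intensity_threshold)),
    probe_selection = sprintf(
      "Redundant probes indexing the same gene were collapsed by selecting %s (donor mode: %s).",
      probe_phrase(cfg$probe_method), cfg$donor_mode),
    coordinate_correction = "Tissue sample MNI coordinates were replaced with the corrected coordinates derived from nonlinear registration.",
    mirroring = switch(cfg$mirror,
      bidirectional = "Tissue samples were mirrored bilaterally across the left-right hemisphere boundary to improve spatial coverage.",
      left_to_right = "Left-hemisphere tissue samples were mirrored into the right hemisphere to improve spatial coverage.",
      right_to_left = "Right-hemisphere tissue samples were mirrored into the left hemisphere.",
      NULL),
    similarity_filter = if (!is.null(cfg$similarity_threshold)) sprintf(
      "Tissue samples whose mean inter-areal Spearman correlation with the donor's other samples fell below %g were discarded.",
      cfg$similarity_threshold),
    assignment = if (cfg$atlas_space == "volume") sprintf(
      "Samples were matched to regions of the volumetric atlas; samples not directly within a region were assigned to the nearest compatible region within %g mm, or discarded.",
      cfg$tolerance) else sprintf(
      "Samples were matched to the nearest labeled surface vertex of their hemisphere; samples farther from the surface than %g standard deviation(s) above the donor mean were discarded.",
      cfg$tolerance),
    sample_normalization = sprintf(
      "Expression values were normalized across genes within each tissue sample using %s.",
      norm_phrase(cfg$sample_norm)),
    gene_normalization = sprintf(
      "Expression values of each gene were normalized across %s%s within donors using %s%s.",
      if (cfg$norm_matched_only) "region-matched tissue samples" else
        "all tissue samples",
      if (cfg$norm_within_structures) ", separately within structural classes,"
      else "",
      norm_phrase(cfg$gene_norm),
      ""),
    aggregation = if (cfg$combine == "donors_first") sprintf(
      "Samples assigned to the same region were aggregated with the %s within each donor and then across donors.",
      cfg$metric) else sprintf(
      "Samples assigned to the same region were aggregated with the %s simultaneously across all donors.",
      cfg$metric),
    missing_data = "Regions to which no sample was assigned were filled by nearest-neighbor interpolation from the closest tissue sample of each donor.")
  sentences[executed_stages(cfg)]
}

#' Generate a methods-style processing report
#'
#' Produces a deterministic paragraph with one sentence per executed
#' processing step, parameter values interpolated; steps a configuration
#' disables are omitted. The text ends with a reference-placeholder list.
#'
#' @param context A [report_context()] (a bare [pipeline_config()] is also
#'   accepted).
#' @return Character scalar; the stage sentences are available via
#'   `attr(, "sentences")` (named by stage).
#' @export
generate_report <- function(context) {
  if (inherits(context, "pipeline_config")) {
    context <- report_context(context)
  }
  stopifnot(inherits(context, "report_context"))
  ds <- context$dataset_summary
  intro <- sprintf(
    "Regional microarray expression data were processed with multigex (version %s) to generate a %s-atlas region-by-gene expression matrix.",
    context$version, context$config$atlas_space)
  if (!is.null(ds$n_donors)) {
    intro <- paste(intro, sprintf(
      "Data comprised %d donor(s)%s%s.", ds$n_donors,
      if (!is.null(ds$n_probes)) sprintf(", %d probes", ds$n_probes) else "",
      if (!is.null(ds$n_samples)) sprintf(" and %d tissue samples",
                                          ds$n_samples) else ""))
  }
  sentences <- stage_sentences(context)
  refs <- paste0("[", seq_len(3), "] REFERENCE PLACEHOLDER")
  text <- paste(c(intro, unname(sentences), "", "References:", refs),
                collapse = "\n")
  attr(text, "sentences") <- sentences
  text
}
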