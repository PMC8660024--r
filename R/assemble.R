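# Pipeline configuration, sample aggregation, missing-region handling, and
# the end-to-end orchestrator.

ATLAS_SPACES <- c("volume", "surface")
MISSING_METHODS <- c("omit", "nearest")
COMBINE_METHODS <- c("donors_first", "pooled")
METRICS <- c("mean", "median")

# The 17 processing options, in canonical key order. atlas_type has a single
# admissible value here (group-level atlas); it is carried so that config
# files enumerate every option explicitly.
CONFIG_KEYS <- c("atlas_space", "atlas_type", "use_corrected_coords",
                 "mirror", "reannotate", "intensity_threshold",
                 "similarity_threshold", "probe_method", "donor_mode",
                 "missing", "tolerance", "sample_norm", "gene_norm",
                 "norm_matched_only", "norm_within_structures", "combine",
                 "metric")

#' Pipeline configuration
#'
#' Validates the 17 processing options into one record. Disabled thresholds
#' are represented as `NULL` (the string `"disabled"` is also accepted). The
#' donor mode is coerced to `"aggregate"` for probe selection methods that
#' make it redundant (see [probe_selection_spec()]).
#'
#' @param atlas_space `"volume"` or `"surface"`.
#' @param atlas_type Only `"group"` is supported.
#' @param use_corrected_coords Replace MNI coordinates with the corrected
#'   table.
#' @param mirror `"none"`, `"left_to_right"`, `"right_to_left"` or
#'   `"bidirectional"`.
#' @param reannotate Apply the probe-reannotation table.
#' @param intensity_threshold Fraction in `[0, 1)` or `NULL`/`"disabled"`.
#' @param similarity_threshold Number in `[-1, 1]` or `NULL`/`"disabled"`.
#' @param probe_method,donor_mode See [probe_selection_spec()].
#' @param missing `"omit"` or `"nearest"`.
#' @param tolerance Non-negative matching tolerance (mm for volumetric,
#'   standard deviations for surface atlases).
#' @param sample_norm,gene_norm `"none"`, `"zscore"` or `"srs"`.
#' @param norm_matched_only,norm_within_structures Gene-normalization
#'   variants (see [normalize_genes()]).
#' @param combine `"donors_first"` or `"pooled"`.
#' @param metric `"mean"` or `"median"`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(atlas_space = "volume", atlas_type = "group",
                            use_corrected_coords = TRUE, mirror = "none",
                            reannotate = TRUE, intensity_threshold = 0.5,
                            similarity_threshold = NULL,
                            probe_method = "diff_stability",
                            donor_mode = "aggregate", missing = "omit",
                            tolerance = 2, sample_norm = "srs",
                            gene_norm = "srs", norm_matched_only = TRUE,
                            norm_within_structures = FALSE,
                            combine = "donors_first", metric = "mean") {
  as_disabled <- function(x) {
    if (is.null(x) || (is.character(x) && identical(x, "disabled"))) NULL
    else x
  }
  intensity_threshold <- as_disabled(intensity_threshold)
  similarity_threshold <- as_disabled(similarity_threshold)
  check_choice <- function(value, choices, name) {
    if (length(value) != 1L || !value %in% choices) {
      mg_config_error(sprintf("invalid %s: %s (must be one of %s)", name,
                              paste(value, collapse = ","),
                              paste(choices, collapse = ", ")))
    }
  }
  check_choice(atlas_space, ATLAS_SPACES, "atlas_space")
  check_choice(atlas_type, "group", "atlas_type")
  check_choice(mirror, MIRROR_MODES, "mirror")
  check_choice(probe_method, PROBE_METHODS, "probe_method")
  check_choice(donor_mode, DONOR_MODES, "donor_mode")
  check_choice(missing, MISSING_METHODS, "missing")
  check_choice(sample_norm, NORM_METHODS, "sample_norm")
  check_choice(gene_norm, NORM_METHODS, "gene_norm")
  check_choice(combine, COMBINE_METHODS, "combine")
  check_choice(metric, METRICS, "metric")
  for (flag in list(use_corrected_coords = use_corrected_coords,
                    reannotate = reannotate,
                    norm_matched_only = norm_matched_only,
                    norm_within_structures = norm_within_structures)) {
    if (!is.logical(flag) || length(flag) != 1L || is.na(flag)) {
      mg_config_error("flags must be TRUE or FALSE")
    }
  }
  if (!is.null(intensity_threshold) &&
      (!is.numeric(intensity_threshold) || intensity_threshold < 0 ||
         intensity_threshold >= 1)) {
    mg_config_error("intensity_threshold must be in [0, 1) or disabled")
  }
  if (!is.null(similarity_threshold) &&
      (!is.numeric(similarity_threshold) ||
         abs(similarity_threshold) > 1)) {
    mg_config_error("similarity_threshold must be in [-1, 1] or disabled")
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0) {
    mg_config_error("tolerance must be a non-negative number")
  }
  if (probe_method %in% DONOR_INDEPENDENT_METHODS) donor_mode <- "aggregate"
  structure(list(atlas_space = atlas_space, atlas_type = atlas_type,
                 use_corrected_coords = use_corrected_coords,
                 mirror = mirror, reannotate = reannotate,
                 intensity_threshold = intensity_threshold,
                 similarity_threshold = similarity_threshold,
                 probe_method = probe_method, donor_mode = donor_mode,
                 missing = missing, tolerance = tolerance,
                 sample_norm = sample_norm, gene_norm = gene_norm,
                 norm_matched_only = norm_matched_only,
                 norm_within_structures = norm_within_structures,
                 combine = combine, metric = metric),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in CONFIG_KEYS) {
    cat(sprintf("  %-24s %s\n", k, format(x[[k]] %||% "disabled")))
  }
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' Flat YAML key/value file over the 17 option keys. Unknown keys are
#' rejected; omitted keys take the package defaults; disabled thresholds are
#' written as the string `"disabled"`.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) mg_file_missing(sprintf("no such file: %s", path))
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), CONFIG_KEYS)
  if (length(unknown)) {
    mg_config_error(sprintf("unknown configuration key(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration file
#' @param config A [pipeline_config()].
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  vals <- lapply(CONFIG_KEYS, function(k) config[[k]] %||% "disabled")
  names(vals) <- CONFIG_KEYS
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' A stable single-line identifier for a configuration
#' @param config A [pipeline_config()].
#' @return Character scalar `key=value|key=value|...` in canonical key
#'   order.
#' @export
config_id <- function(config) {
  paste(vapply(CONFIG_KEYS, function(k) {
    v <- config[[k]] %||% "disabled"
    sprintf("%s=%s", k, format(v, trim = TRUE))
  }, character(1)), collapse = "|")
}

metric_fun <- function(metric) {
  switch(metric, mean = mean, median = stats::median,
         mg_parameter_error(sprintf("unknown metric: %s", metric)))
}

#' Aggregate assigned samples into regions
#'
#' `combine = "donors_first"` applies the metric over each donor's samples
#' in a region and then across the donors that have at least one sample
#' there; `"pooled"` applies the metric once over all donors' samples in the
#' region (so donors with more samples weigh more). Regions receiving no
#' samples are flagged missing.
#'
#' @param mats Named list of gene x sample matrices, one per donor
#'   (identical gene rows; columns named by well_id).
#' @param assignments Named list of assignment tables (see
#'   [assign_volumetric()]), aligned with `mats`.
#' @param region_ids Regions of the output matrix (row order).
#' @param combine `"donors_first"` or `"pooled"`.
#' @param metric `"mean"` or `"median"`.
#' @return An [expression_matrix()].
#' @export
aggregate_expression <- function(mats, assignments, region_ids,
                                 combine = "donors_first", metric = "mean") {
  if (!combine %in% COMBINE_METHODS) {
    mg_parameter_error(sprintf("unknown combine method: %s", combine))
  }
  f <- metric_fun(metric)
  genes <- rownames(mats[[1]])
  n_g <- length(genes)
  region_ids <- as.integer(region_ids)
  values <- matrix(NA_real_, length(region_ids), n_g,
                   dimnames = list(as.character(region_ids), genes))
  # per-donor region membership of sample columns
  donor_regions <- lapply(names(mats), function(d) {
    a <- assignments[[d]]
    idx <- match(colnames(mats[[d]]), as.character(a$well_id))
    a$region_id[idx]
  })
  names(donor_regions) <- names(mats)
  any_sample <- FALSE
  for (r in seq_along(region_ids)) {
    rid <- region_ids[r]
    if (combine == "pooled") {
      cols <- lapply(names(mats), function(d) {
        mats[[d]][, which(donor_regions[[d]] == rid), drop = FALSE]
      })
      pooled <- do.call(cbind, cols)
      if (is.null(pooled) || ncol(pooled) == 0L) next
      values[r, ] <- apply(pooled, 1, f)
    } else {
      per_donor <- lapply(names(mats), function(d) {
        m <- mats[[d]][, which(donor_regions[[d]] == rid), drop = FALSE]
        if (ncol(m) == 0L) NULL else apply(m, 1, f)
      })
      per_donor <- per_donor[!vapply(per_donor, is.null, logical(1))]
      if (!length(per_donor)) next
      values[r, ] <- apply(do.call(cbind, per_donor), 1, f)
    }
    any_sample <- TRUE
  }
  if (!any_sample) {
    mg_empty_error("no atlas region received any tissue sample")
  }
  expression_matrix(values, region_ids, genes)
}

#' Fill regions with no assigned samples
#'
#' `strategy = "omit"` leaves the matrix unchanged (missing rows stay
#' flagged and are dropped by the analyses). `strategy = "nearest"` fills
#' each missing region from the tissue sample nearest (Euclidean mm) to the
#' region's centroid in each donor, aggregating those per-donor values with
#' the pipeline's metric; filled rows are unflagged.
#'
#' @param em An [expression_matrix()].
#' @param donor_data Named list per donor of `list(expression, samples)` as
#'   produced inside [run_pipeline()] (expression gene x sample; samples
#'   with current coordinates).
#' @param centroids Data frame from [region_centroids()].
#' @param strategy `"omit"` or `"nearest"`.
#' @param metric `"mean"` or `"median"`.
#' @return The (possibly filled) [expression_matrix()].
#' @export
fill_missing <- function(em, donor_data, centroids, strategy = "omit",
                         metric = "mean") {
  if (!strategy %in% MISSING_METHODS) {
    mg_parameter_error(sprintf("unknown missing-data strategy: %s",
                               strategy))
  }
  if (strategy == "omit" || !any(em$missing_mask)) return(em)
  f <- metric_fun(metric)
  total_samples <- sum(vapply(donor_data, function(d) ncol(d$expression),
                              integer(1)))
  if (total_samples == 0L) {
    mg_empty_error("nearest-neighbor fill requires at least one sample")
  }
  values <- em$values
  for (r in which(em$missing_mask)) {
    rid <- em$region_ids[r]
    cent <- unlist(centroids[centroids$region_id == rid, c("x", "y", "z")])
    per_donor <- lapply(donor_data, function(d) {
      if (ncol(d$expression) == 0L) return(NULL)
      pts <- as.matrix(d$samples[, c("mni_x", "mni_y", "mni_z")])
      dists <- sqrt(colSums((t(pts) - cent)^2))
      d$expression[, which.min(dists)]
    })
    per_donor <- per_donor[!vapply(per_donor, is.null, logical(1))]
    values[r, ] <- apply(do.call(cbind, per_donor), 1, f)
  }
  filled <- expression_matrix(values, em$region_ids, em$gene_symbols,
                              missing_mask = rep(FALSE, length(em$region_ids)))
  mg_log("missing_data", sum(em$missing_mask), " region(s) filled")
  filled
}

# Re-raise any package error with the failing stage named in the message.
with_stage <- function(stage, expr) {
  tryCatch(expr, multigex_error = function(e) {
    stop(errorCondition(sprintf("stage %s: %s", stage, conditionMessage(e)),
                        class = class(e)))
  })
}

#' Run the full processing pipeline
#'
#' Canonical stage order: reannotation, intensity filtering, probe
#' selection, coordinate update, mirroring, similarity filtering,
#' sample-to-region assignment, sample normalization, gene normalization,
#' aggregation, missing-data handling. Intensity filtering always precedes
#' probe selection; sample normalization always precedes gene
#' normalization. The result carries the executed stage names in its
#' `"stages"` attribute and the chosen-probe report in `"probe_report"`.
#'
#' @param config A [pipeline_config()].
#' @param bundles Named list of [donor_bundle()]s.
#' @param atlas A `brain_atlas` matching `config$atlas_space`.
#' @param correction_table Corrected-coordinates table (required when
#'   `use_corrected_coords`).
#' @param reannotation Probe-reannotation mapping (required when
#'   `reannotate`).
#' @return An [expression_matrix()].
#' @export
run_pipeline <- function(config, bundles, atlas, correction_table = NULL,
                         reannotation = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (atlas$space != config$atlas_space) {
    mg_config_error(sprintf(
      "config requests a %s atlas but the atlas is %s", config$atlas_space,
      atlas$space))
  }
  stages <- character(0)

  ## probes ------------------------------------------------------------------
  if (config$reannotate) {
    with_stage("reannotation", {
      if (is.null(reannotation)) {
        mg_config_error("reannotation requested but no mapping table given")
      }
      bundles <- lapply(bundles, function(b) {
        b$probes <- reannotate_probes(b$probes, reannotation)
        b
      })
    })
    stages <- c(stages, "reannotation")
  }
  kept <- with_stage("intensity_filter",
                     filter_probes_by_intensity(bundles,
                                                config$intensity_threshold))
  if (!is.null(config$intensity_threshold)) {
    stages <- c(stages, "intensity_filter")
  }
  spec <- with_stage("probe_selection",
                     probe_selection_spec(config$probe_method,
                                          config$donor_mode))
  sel <- with_stage("probe_selection", select_probes(bundles, spec, kept))
  stages <- c(stages, "probe_selection")
  donor_data <- lapply(names(sel$matrices), function(d) {
    list(expression = sel$matrices[[d]], samples = bundles[[d]]$samples,
         donor_id = d)
  })
  names(donor_data) <- names(sel$matrices)

  ## samples -----------------------------------------------------------------
  if (config$use_corrected_coords) {
    donor_data <- lapply(donor_data, function(d) {
      d$samples <- with_stage("coordinate_correction",
                              apply_corrected_coordinates(
                                d$samples, TRUE, correction_table,
                                d$donor_id))
      d
    })
    stages <- c(stages, "coordinate_correction")
  }
  if (config$mirror != "none") {
    donor_data <- lapply(donor_data, function(d) {
      m <- with_stage("mirroring",
                      mirror_samples(d$samples, d$expression, config$mirror))
      d$samples <- m$samples
      d$expression <- m$expression
      d
    })
    stages <- c(stages, "mirroring")
  }
  if (!is.null(config$similarity_threshold)) {
    donor_data <- lapply(donor_data, function(d) {
      kept_wells <- with_stage("similarity_filter",
                               filter_samples_by_similarity(
                                 d$expression, config$similarity_threshold))
      keep <- as.character(d$samples$well_id) %in% kept_wells
      d$samples <- d$samples[keep, , drop = FALSE]
      d$expression <- d$expression[, keep, drop = FALSE]
      d
    })
    stages <- c(stages, "similarity_filter")
  }
  assignments <- lapply(donor_data, function(d) {
    with_stage("assignment", {
      if (config$atlas_space == "volume") {
        assign_volumetric(d$samples, atlas, config$tolerance, d$donor_id)
      } else {
        assign_surface(d$samples, atlas, config$tolerance, d$donor_id)
      }
    })
  })
  stages <- c(stages, "assignment")

  ## normalization -----------------------------------------------------------
  if (config$sample_norm != "none") {
    donor_data <- lapply(donor_data, function(d) {
      d$expression <- with_stage("sample_normalization",
                                 normalize_samples(d$expression,
                                                   config$sample_norm))
      d
    })
    stages <- c(stages, "sample_normalization")
  }
  if (config$gene_norm != "none") {
    donor_data <- lapply(donor_data, function(d) {
      res <- with_stage("gene_normalization",
                        normalize_genes(d$expression, d$samples,
                                        config$gene_norm,
                                        config$norm_matched_only,
                                        config$norm_within_structures,
                                        assignments[[d$donor_id]]))
      d$expression <- res$expression
      d$samples <- res$samples
      d
    })
    stages <- c(stages, "gene_normalization")
  }

  ## aggregation and missing data -------------------------------------------
  mats <- lapply(donor_data, `[[`, "expression")
  em <- with_stage("aggregation",
                   aggregate_expression(mats, assignments,
                                        sort(atlas$regions$region_id),
                                        config$combine, config$metric))
  stages <- c(stages, "aggregation")
  if (config$missing == "nearest") {
    em <- with_stage("missing_data",
                     fill_missing(em, donor_data, region_centroids(atlas),
                                  "nearest", config$metric))
    stages <- c(stages, "missing_data")
  }
  attr(em, "stages") <- stages
  attr(em, "probe_report") <- sel$report
  attr(em, "assignments") <- assignments
  em
}
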