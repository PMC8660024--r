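# Parameter-grid declaration, pipeline enumeration/counting with redundancy
# rules, and batch execution of pipelines over a grid.

# Canonical single-string key for one option choice (used in enumeration
# tables and config identifiers).
value_key <- function(v) {
  if (is.null(v)) return("disabled")
  if (is.logical(v)) return(if (v) "TRUE" else "FALSE")
  format(v, trim = TRUE)
}

#' Declare one processing option of a parameter grid
#'
#' @param name Option name; must match a [pipeline_config()] key.
#' @param choices List of admissible values, in declaration order (`NULL`
#'   denotes a disabled threshold).
#' @param scale `"binary"` (exactly 2 choices), `"ordinal"` (ordered) or
#'   `"categorical"`. The scale decides how impact scores average choice
#'   differences.
#' @return An `option_spec`.
#' @export
option_spec <- function(name, choices, scale) {
  if (!is.list(choices)) choices <- as.list(choices)
  if (!length(choices)) mg_parameter_error("option needs at least 1 choice")
  if (!scale %in% c("binary", "ordinal", "categorical")) {
    mg_parameter_error(sprintf("unknown scale: %s", scale))
  }
  if ((scale == "binary") != (length(choices) == 2L)) {
    mg_parameter_error("binary options must have exactly 2 choices")
  }
  keys <- vapply(choices, value_key, character(1))
  if (anyDuplicated(keys)) mg_parameter_error("duplicate choices")
  structure(list(name = name, choices = choices, keys = keys,
                 scale = scale),
            class = "option_spec")
}

#' Declare a redundancy rule
#'
#' States that `option` is redundant -- collapsed to `collapse_to` --
#' whenever `when_option` takes one of `when_choices`. Configurations
#' differing only in a collapsed option are the same pipeline and are
#' enumerated (and counted) once.
#'
#' @param option Option made redundant.
#' @param when_option Conditioning option.
#' @param when_choices Values of `when_option` that trigger the collapse.
#' @param collapse_to The single value `option` takes when collapsed.
#' @return A `redundancy_rule`.
#' @export
redundancy_rule <- function(option, when_option, when_choices, collapse_to) {
  structure(list(option = option, when_option = when_option,
                 when_keys = vapply(as.list(when_choices), value_key,
                                    character(1)),
                 collapse_key = value_key(collapse_to)),
            class = "redundancy_rule")
}

#' Assemble a parameter grid
#'
#' @param options List of [option_spec()]s (declaration order fixes
#'   column/rank tie order).
#' @param redundancies List of [redundancy_rule()]s.
#' @return A `parameter_grid`.
#' @export
parameter_grid <- function(options, redundancies = list()) {
  names(options) <- vapply(options, `[[`, character(1), "name")
  if (anyDuplicated(names(options))) {
    mg_parameter_error("duplicate option names")
  }
  for (r in redundancies) {
    if (!r$option %in% names(options) ||
        !r$when_option %in% names(options)) {
      mg_parameter_error("redundancy rule references an unknown option")
    }
    if (!r$collapse_key %in% options[[r$option]]$keys) {
      mg_parameter_error("collapse_to is not a choice of the option")
    }
    if (!all(r$when_keys %in% options[[r$when_option]]$keys)) {
      mg_parameter_error("when_choices are not choices of when_option")
    }
  }
  structure(list(options = options, redundancies = redundancies),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("<parameter_grid: %d options, %s pipelines>\n",
              length(x$options), format(count_grid(x), big.mark = ",")))
  invisible(x)
}

# Apply redundancy collapses to a key table (data.frame of choice keys) and
# return it with a logical attribute marking rows that were canonical
# already (i.e. the deduplicated enumeration keeps exactly those rows).
collapse_keys <- function(grid, tab) {
  canonical <- rep(TRUE, nrow(tab))
  for (r in grid$redundancies) {
    active <- tab[[r$when_option]] %in% r$when_keys
    canonical <- canonical & (!active | tab[[r$option]] == r$collapse_key)
    tab[[r$option]][active] <- r$collapse_key
  }
  attr(tab, "canonical") <- canonical
  tab
}

#' Enumerate every distinct pipeline configuration of a grid
#'
#' Yields each effective (redundancy-collapsed) configuration exactly once,
#' as a data frame of choice keys in deterministic order (first declared
#' option varies fastest).
#'
#' @param grid A [parameter_grid()].
#' @return Data frame with one column per option and one row per distinct
#'   configuration.
#' @export
enumerate_grid <- function(grid) {
  raw <- expand.grid(lapply(grid$options, `[[`, "keys"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  collapsed <- collapse_keys(grid, raw)
  out <- raw[attr(collapsed, "canonical"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count the distinct pipelines of a grid without enumerating it
#'
#' Closed-form count: options untouched by redundancy rules contribute a
#' plain product; the (small) sub-grid of options involved in rules is
#' enumerated explicitly and its canonical rows counted.
#'
#' @param grid A [parameter_grid()].
#' @return Integer-valued count (as double, counts can exceed .Machine
#'   integer range).
#' @export
count_grid <- function(grid) {
  involved <- unique(unlist(lapply(grid$redundancies, function(r) {
    c(r$option, r$when_option)
  })))
  free <- setdiff(names(grid$options), involved)
  free_product <- prod(vapply(grid$options[free], function(o) {
    length(o$keys)
  }, numeric(1)))
  if (!length(involved)) return(free_product)
  sub <- parameter_grid(grid$options[involved], grid$redundancies)
  free_product * nrow(enumerate_grid(sub))
}

#' Number of matched tuples behind one option's impact score
#'
#' For an option untouched by redundancy rules this is the total pipeline
#' count divided by the option's number of choices (e.g. the matched-pair
#' count of a binary option). For an option collapsed by a rule, only
#' conditioning choices under which the option actually varies yield
#' tuples.
#'
#' @param grid A [parameter_grid()].
#' @param option Option name.
#' @return Number of matched tuples.
#' @export
impact_pair_count <- function(grid, option) {
  opt <- grid$options[[option]]
  if (is.null(opt)) mg_parameter_error(sprintf("unknown option: %s", option))
  involved <- unique(unlist(lapply(grid$redundancies, function(r) {
    c(r$option, r$when_option)
  })))
  if (!option %in% involved) {
    return(count_grid(grid) / length(opt$keys))
  }
  # replicate the matched-tuple construction of impact_scores() on the
  # (small) sub-grid of rule-involved options: a tuple is valid when the
  # option's choices map to distinct effective configurations, and
  # duplicate effective tuples count once
  sub_grid <- parameter_grid(grid$options[involved], grid$redundancies)
  others <- setdiff(involved, option)
  combos <- if (length(others)) {
    expand.grid(lapply(sub_grid$options[others], `[[`, "keys"),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame(row.names = 1)
  }
  k <- length(opt$keys)
  seen <- character(0)
  for (i in seq_len(nrow(combos))) {
    tuple <- combos[rep(i, k), , drop = FALSE]
    tuple[[option]] <- opt$keys
    eff <- collapse_keys(sub_grid, tuple)
    keys <- row_key(eff, involved)
    if (length(unique(keys)) < k) next
    seen <- union(seen, paste(sort(keys), collapse = "&"))
  }
  free <- setdiff(names(grid$options), involved)
  length(seen) * prod(vapply(grid$options[free], function(o) length(o$keys),
                             numeric(1)))
}

# Decode one enumeration row (choice keys) into the corresponding
# pipeline_config, with unlisted options taking `base` (then default)
# values.
config_from_keys <- function(grid, row, base = list()) {
  args <- base
  for (nm in names(grid$options)) {
    opt <- grid$options[[nm]]
    val <- opt$choices[[match(row[[nm]], opt$keys)]]
    args[[nm]] <- val
  }
  # NULL values (disabled thresholds) drop out of lists; reinsert explicitly
  cfg <- do.call(pipeline_config, args)
  for (nm in names(grid$options)) {
    opt <- grid$options[[nm]]
    if (is.null(opt$choices[[match(row[[nm]], opt$keys)]])) {
      cfg[nm] <- list(NULL)
    }
  }
  cfg
}

#' The full 17-option parameter grid
#'
#' The grid of processing choices explored by the multiverse analysis:
#' volumetric/surface atlas; group atlas (single admissible choice);
#' original versus corrected MNI coordinates; no / left-to-right / bilateral
#' mirroring; original versus updated probe annotations; intensity filtering
#' disabled / 0.25 / 0.5; inter-areal similarity filtering disabled (single
#' choice); six probe selection methods by three donor modes, with the donor
#' mode redundant (collapsed to aggregate) for the three donor-independent
#' methods; missing regions omitted or nearest-neighbor filled; matching
#' tolerance 0 / 1 / 2; sample and gene normalization none / z-score /
#' scaled robust sigmoid; matched-only and within-structure gene
#' normalization variants; donors-first versus pooled aggregation; mean
#' versus median metric.
#'
#' @return A [parameter_grid()] with 746,496 distinct pipelines.
#' @export
default_parameter_grid <- function() {
  parameter_grid(
    list(
      option_spec("atlas_space", list("volume", "surface"), "binary"),
      option_spec("atlas_type", list("group"), "categorical"),
      option_spec("use_corrected_coords", list(FALSE, TRUE), "binary"),
      option_spec("mirror", list("none", "left_to_right", "bidirectional"),
                  "categorical"),
      option_spec("reannotate", list(FALSE, TRUE), "binary"),
      option_spec("intensity_threshold", list(NULL, 0.25, 0.5), "ordinal"),
      option_spec("similarity_threshold", list(NULL), "categorical"),
      option_spec("probe_method", as.list(PROBE_METHODS), "categorical"),
      option_spec("donor_mode", as.list(DONOR_MODES), "categorical"),
      option_spec("missing", list("omit", "nearest"), "binary"),
      option_spec("tolerance", list(0, 1, 2), "ordinal"),
      option_spec("sample_norm", as.list(NORM_METHODS), "categorical"),
      option_spec("gene_norm", as.list(NORM_METHODS), "categorical"),
      option_spec("norm_matched_only", list(FALSE, TRUE), "binary"),
      option_spec("norm_within_structures", list(FALSE, TRUE), "binary"),
      option_spec("combine", list("donors_first", "pooled"), "binary"),
      option_spec("metric", list("mean", "median"), "binary")),
    list(redundancy_rule("donor_mode", "probe_method",
                         DONOR_INDEPENDENT_METHODS, "aggregate")))
}

#' Reduced grid for parameter-recovery checks
#'
#' 16 configurations varying gene normalization, sample normalization,
#' aggregation metric and mirroring around the default pipeline.
#'
#' @return A [parameter_grid()].
#' @export
reduced_recovery_grid <- function() {
  parameter_grid(list(
    option_spec("gene_norm", list("none", "zscore"), "binary"),
    option_spec("sample_norm", list("none", "zscore"), "binary"),
    option_spec("metric", list("mean", "median"), "binary"),
    option_spec("mirror", list("none", "bidirectional"), "binary")))
}

#' Reduced grid for the scaled-down impact analysis
#'
#' 96 configurations over five options: gene normalization (3 choices),
#' sample normalization (2), aggregation metric (2), mirroring (2) and
#' matching tolerance (4 ordinal values).
#'
#' @return A [parameter_grid()].
#' @export
reduced_impact_grid <- function() {
  parameter_grid(list(
    option_spec("gene_norm", as.list(NORM_METHODS), "categorical"),
    option_spec("sample_norm", list("none", "zscore"), "binary"),
    option_spec("metric", list("mean", "median"), "binary"),
    option_spec("mirror", list("none", "bidirectional"), "binary"),
    option_spec("tolerance", list(0, 1, 2, 3), "ordinal")))
}

#' Read a parameter grid from a YAML file
#'
#' Layout: a top-level `options` list of `{name, choices, scale}` maps and
#' an optional `redundancies` list of `{option, when_option, when_choices,
#' collapse_to}` maps; the string `disabled` denotes a disabled threshold.
#'
#' @param path YAML file.
#' @return A [parameter_grid()].
#' @export
read_parameter_grid <- function(path) {
  if (!file.exists(path)) mg_file_missing(sprintf("no such file: %s", path))
  spec <- yaml::read_yaml(path)
  decode <- function(v) if (identical(v, "disabled")) NULL else v
  options <- lapply(spec$options, function(o) {
    option_spec(o$name, lapply(o$choices, decode), o$scale)
  })
  redundancies <- lapply(spec$redundancies %||% list(), function(r) {
    redundancy_rule(r$option, r$when_option, r$when_choices, r$collapse_to)
  })
  parameter_grid(options, redundancies)
}

#' Run every pipeline of a grid and collect analysis estimates
#'
#' Executes [run_pipeline()] plus the three analyses for each distinct
#' configuration of the grid. Failing configurations are recorded with
#' their error message rather than dropped. Results do not depend on
#' execution order.
#'
#' @param grid A [parameter_grid()].
#' @param data List with elements `bundles`, `atlas` (volumetric),
#'   `surface_atlas` (required when the grid varies atlas_space),
#'   `correction_table`, `reannotation`, `module_labels`, `phenotype` (e.g.
#'   the result of [simulate_dataset()]).
#' @param base Named list of config values for options the grid does not
#'   vary (defaults otherwise).
#' @param jobs Number of worker processes (forked; 1 = sequential).
#' @return Data frame: one row per configuration with the choice-key
#'   columns, `config_id`, the three estimates (NA on failure) and `error`.
#' @export
run_multiverse <- function(grid, data, base = list(), jobs = 1L) {
  enum <- enumerate_grid(grid)
  centroids_vol <- region_centroids(data$atlas)
  centroids_surf <- if (!is.null(data$surface_atlas)) {
    region_centroids(data$surface_atlas)
  }
  run_one <- function(i) {
    row <- enum[i, , drop = FALSE]
    cfg <- tryCatch(config_from_keys(grid, row, base), error = identity)
    if (inherits(cfg, "error")) {
      return(data.frame(config_id = NA_character_, cge_rho = NA_real_,
                        gce_silhouette = NA_real_, rge_rho = NA_real_,
                        error = conditionMessage(cfg)))
    }
    atlas <- if (cfg$atlas_space == "surface") data$surface_atlas
             else data$atlas
    centroids <- if (cfg$atlas_space == "surface") centroids_surf
                 else centroids_vol
    est <- tryCatch({
      em <- run_pipeline(cfg, data$bundles, atlas,
                         correction_table = data$correction_table,
                         reannotation = data$reannotation)
      analysis_estimates(em, centroids, data$module_labels, data$phenotype)
    }, error = identity)
    if (inherits(est, "error")) {
      data.frame(config_id = config_id(cfg), cge_rho = NA_real_,
                 gce_silhouette = NA_real_, rge_rho = NA_real_,
                 error = conditionMessage(est))
    } else {
      data.frame(config_id = config_id(cfg), est, error = NA_character_)
    }
  }
  results <- if (jobs > 1L) {
    parallel::mclapply(seq_len(nrow(enum)), run_one, mc.cores = jobs)
  } else {
    lapply(seq_len(nrow(enum)), run_one)
  }
  out <- cbind(enum, do.call(rbind, results))
  rownames(out) <- NULL
  out
}
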