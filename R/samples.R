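# Sample handling: coordinate correction, hemispheric mirroring, inter-areal
# similarity filtering, and sample-to-region assignment (volume/surface).

#' Replace sample coordinates with corrected values
#'
#' @param samples Sample annotation data frame of one donor.
#' @param use_corrected If `FALSE`, samples are returned unchanged.
#' @param correction_table Data frame `well_id, donor_id, x, y, z` (see
#'   [read_correction_table()]); must cover every well_id of the donor when
#'   `use_corrected` is set.
#' @param donor_id Donor whose rows of the table apply.
#' @return The sample data frame, coordinates updated.
#' @export
apply_corrected_coordinates <- function(samples, use_corrected,
                                        correction_table = NULL,
                                        donor_id = NULL) {
  if (!isTRUE(use_corrected)) return(samples)
  if (is.null(correction_table)) {
    mg_mapping_error("corrected coordinates requested but no table given")
  }
  tab <- correction_table
  if (!is.null(donor_id) && "donor_id" %in% names(tab)) {
    tab <- tab[tab$donor_id == donor_id, , drop = FALSE]
  }
  idx <- match(samples$well_id, tab$well_id)
  if (anyNA(idx)) {
    mg_mapping_error(sprintf(
      "correction table missing well_id(s): %s",
      paste(samples$well_id[is.na(idx)], collapse = ", ")))
  }
  samples$mni_x <- tab$x[idx]
  samples$mni_y <- tab$y[idx]
  samples$mni_z <- tab$z[idx]
  samples
}

MIRROR_MODES <- c("none", "bidirectional", "left_to_right", "right_to_left")

#' Mirror tissue samples across the midsagittal plane
#'
#' Mirrored copies have the x coordinate negated, the hemisphere flipped,
#' identical expression values, and fresh synthetic well_ids. Samples lying
#' exactly on the midline (x = 0) are flagged and excluded from mirroring.
#'
#' @param samples Sample annotation data frame of one donor.
#' @param expression Gene x sample matrix with one column per row of
#'   `samples`.
#' @param mode `"none"`, `"left_to_right"`, `"right_to_left"` or
#'   `"bidirectional"` (every off-midline sample mirrored once).
#' @return List with the augmented `samples` and `expression`.
#' @export
mirror_samples <- function(samples, expression, mode) {
  if (!mode %in% MIRROR_MODES) {
    mg_parameter_error(sprintf("unknown mirror mode: %s", mode))
  }
  if (mode == "none") {
    return(list(samples = samples, expression = expression))
  }
  on_midline <- samples$mni_x == 0
  if (any(on_midline)) {
    mg_log("mirror", sum(on_midline), " sample(s) at x = 0 not mirrored")
  }
  src <- switch(mode,
                bidirectional = which(!on_midline),
                left_to_right = which(samples$mni_x < 0),
                right_to_left = which(samples$mni_x > 0))
  if (!length(src)) {
    return(list(samples = samples, expression = expression))
  }
  mirrored <- samples[src, , drop = FALSE]
  mirrored$mni_x <- -mirrored$mni_x
  mirrored$hemisphere <- ifelse(mirrored$hemisphere == "L", "R", "L")
  mirrored$well_id <- max(samples$well_id) + seq_along(src)
  out_samples <- rbind(samples, mirrored)
  rownames(out_samples) <- NULL
  out_expr <- cbind(expression, expression[, src, drop = FALSE])
  colnames(out_expr) <- as.character(out_samples$well_id)
  list(samples = out_samples, expression = out_expr)
}

#' Filter samples by inter-areal similarity
#'
#' Each sample's score is its mean Spearman correlation with all other
#' samples of the same donor (across genes); samples scoring below
#' `threshold` are dropped. `threshold = NULL` disables the filter.
#'
#' @param expression Gene x sample matrix of one donor.
#' @param threshold Numeric in `[-1, 1]`, or `NULL` to disable.
#' @return Integer/character vector of kept sample columns (well_ids).
#' @export
filter_samples_by_similarity <- function(expression, threshold) {
  if (is.null(threshold)) return(colnames(expression))
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < -1 || threshold > 1) {
    mg_parameter_error("similarity threshold must be in [-1, 1] or NULL")
  }
  if (ncol(expression) < 3L) {
    mg_parameter_error(
      "similarity filtering needs at least 3 samples per donor")
  }
  cc <- suppressWarnings(stats::cor(expression, method = "spearman"))
  diag(cc) <- NA
  score <- rowMeans(cc, na.rm = TRUE)
  kept <- colnames(expression)[score >= threshold]
  mg_log("similarity_filter", sprintf("kept %d/%d samples", length(kept),
                                      ncol(expression)))
  kept
}

# Region compatibility gate: a sample may only be matched to regions of its
# own hemisphere and structure class (NA metadata acts as a wildcard).
compatible_regions <- function(regions, hemisphere, structure_class) {
  hemi_ok <- is.na(regions$hemisphere) | regions$hemisphere == hemisphere
  class_ok <- is.na(regions$structure_class) |
    regions$structure_class == structure_class
  regions$region_id[hemi_ok & class_ok]
}

#' Assign samples to regions of a volumetric atlas
#'
#' Each sample's mm coordinate is mapped through the inverse affine to its
#' nearest voxel; if that voxel carries a label whose region matches the
#' sample's hemisphere and structure class, the sample is assigned at
#' distance 0. Otherwise the nearest compatible labeled voxel (Euclidean mm)
#' within `tolerance_mm` is used; if none exists the sample is unassigned.
#' Equidistant-voxel ties resolve to the most frequent label among the tied
#' voxels, then to the lowest region_id.
#'
#' @param samples Sample annotation data frame of one donor.
#' @param atlas Volumetric `brain_atlas`.
#' @param tolerance_mm Non-negative matching tolerance in mm.
#' @param donor_id Donor id recorded in the table.
#' @return Assignment data frame `well_id, donor_id, region_id,
#'   distance_mm` (`region_id` `NA` when unassigned).
#' @export
assign_volumetric <- function(samples, atlas, tolerance_mm,
                              donor_id = NA_character_) {
  stopifnot(inherits(atlas, "brain_atlas"), atlas$space == "volume")
  if (!is.numeric(tolerance_mm) || tolerance_mm < 0) {
    mg_parameter_error("tolerance_mm must be a non-negative number")
  }
  inv <- solve(atlas$affine)
  dims <- dim(atlas$labels)
  vox <- which(atlas$labels != 0, arr.ind = TRUE)    # 1-based
  vox_labels <- atlas$labels[atlas$labels != 0]
  vox_mm <- apply_affine(atlas$affine, vox - 1)
  reg_meta <- atlas$regions
  pts <- as.matrix(samples[, c("mni_x", "mni_y", "mni_z")])
  n <- nrow(samples)
  region <- rep(NA_integer_, n)
  dist_mm <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    comp <- compatible_regions(reg_meta, samples$hemisphere[i],
                               samples$structure_class[i])
    ijk <- round(apply_affine(inv, matrix(pts[i, ], 1))) + 1  # 1-based
    inside <- all(ijk >= 1) && all(ijk <= dims)
    if (inside) {
      lab <- atlas$labels[ijk[1], ijk[2], ijk[3]]
      if (lab != 0 && lab %in% comp) {
        region[i] <- lab
        dist_mm[i] <- 0
        next
      }
    }
    ok <- vox_labels %in% comp
    if (!any(ok)) next
    d <- sqrt(colSums((t(vox_mm[ok, , drop = FALSE]) - pts[i, ])^2))
    dmin <- min(d)
    if (dmin <= tolerance_mm) {
      tied <- vox_labels[ok][d <= dmin + 1e-9]
      tab <- table(tied)
      best <- as.integer(names(tab)[tab == max(tab)])
      region[i] <- min(best)
      dist_mm[i] <- dmin
    }
  }
  mg_log("assign", sprintf("%d/%d samples assigned (volume, tol %.1f mm)",
                           sum(!is.na(region)), n, tolerance_mm))
  data.frame(well_id = samples$well_id, donor_id = donor_id,
             region_id = region, distance_mm = dist_mm)
}

#' Assign samples to regions of a surface atlas
#'
#' Each sample is matched to the nearest labeled vertex of its hemisphere;
#' with d the vector of those distances over the donor's samples, samples
#' with d greater than mean(d) + k * sd(d) (k = `tolerance_sd`, sd with the
#' n - 1 denominator) are left unassigned, the rest take the nearest
#' vertex's label.
#'
#' @param samples Sample annotation data frame of one donor.
#' @param atlas Surface `brain_atlas`.
#' @param tolerance_sd Non-negative number of standard deviations.
#' @param donor_id Donor id recorded in the table.
#' @return Assignment data frame as in [assign_volumetric()].
#' @export
assign_surface <- function(samples, atlas, tolerance_sd,
                           donor_id = NA_character_) {
  stopifnot(inherits(atlas, "brain_atlas"), atlas$space == "surface")
  if (!is.numeric(tolerance_sd) || tolerance_sd < 0) {
    mg_parameter_error("tolerance_sd must be a non-negative number")
  }
  for (h in c("L", "R")) {
    if (!any(atlas$hemispheres[[h]]$labels != 0)) {
      mg_config_error(sprintf(
        "surface atlas has no labeled vertices in hemisphere %s", h))
    }
  }
  n <- nrow(samples)
  pts <- as.matrix(samples[, c("mni_x", "mni_y", "mni_z")])
  nearest_label <- integer(n)
  d <- numeric(n)
  for (i in seq_len(n)) {
    hemi <- atlas$hemispheres[[samples$hemisphere[i]]]
    ok <- hemi$labels != 0
    dv <- sqrt(colSums((t(hemi$coords[ok, , drop = FALSE]) - pts[i, ])^2))
    j <- which.min(dv)
    nearest_label[i] <- hemi$labels[ok][j]
    d[i] <- dv[j]
  }
  cutoff <- mean(d) + tolerance_sd * mg_sd(d)
  if (is.na(cutoff)) cutoff <- Inf   # single sample: sd undefined, keep it
  excluded <- d > cutoff
  region <- ifelse(excluded, NA_integer_, nearest_label)
  mg_log("assign", sprintf("%d/%d samples assigned (surface, tol %g sd)",
                           sum(!excluded), n, tolerance_sd))
  data.frame(well_id = samples$well_id, donor_id = donor_id,
             region_id = region, distance_mm = ifelse(excluded, NA_real_, d))
}
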