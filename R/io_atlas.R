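# Atlas readers/writers. Two interchangeable on-disk forms are supported:
#   * volumetric: a NIfTI label image (via the RNifti package) or the
#     plain-text fallback written by write_atlas() -- a header with the grid
#     dimensions and affine followed by "i j k label" rows (0-based voxel
#     indices) for nonzero voxels;
#   * surface: one vertex-table CSV per hemisphere with columns
#     x, y, z, label.
# Region metadata is always a CSV with columns region_id, label, hemisphere,
# structure_class.

#' Read region metadata
#' @param path CSV with columns `region_id, label, hemisphere,
#'   structure_class`.
#' @return Data frame.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) mg_file_missing(sprintf("no such file: %s", path))
  utils::read.csv(path)
}

#' Load an atlas from a directory
#'
#' The directory must contain `regions.csv` plus either `volume.txt` (or a
#' `volume.nii`/`volume.nii.gz` label image) for a volumetric atlas, or
#' `surface_L.csv` and `surface_R.csv` for a surface atlas. If both forms
#' are present, `space` selects which to read.
#'
#' @param path Atlas directory.
#' @param space `"volume"` or `"surface"`; defaults to whichever form is
#'   present.
#' @return A `brain_atlas`.
#' @export
load_atlas <- function(path, space = NULL) {
  regions <- read_regions(file.path(path, "regions.csv"))
  has_vol <- any(file.exists(file.path(path, c("volume.txt", "volume.nii",
                                               "volume.nii.gz"))))
  has_surf <- file.exists(file.path(path, "surface_L.csv"))
  if (is.null(space)) {
    space <- if (has_vol) "volume" else "surface"
  }
  if (space == "volume") {
    if (!has_vol) mg_file_missing(sprintf("no volume atlas under %s", path))
    txt <- file.path(path, "volume.txt")
    if (file.exists(txt)) {
      read_atlas_volume_text(txt, regions)
    } else {
      nii <- file.path(path, c("volume.nii", "volume.nii.gz"))
      read_atlas_volume_nifti(nii[file.exists(nii)][1], regions)
    }
  } else {
    left <- file.path(path, "surface_L.csv")
    right <- file.path(path, "surface_R.csv")
    if (!file.exists(left) || !file.exists(right)) {
      mg_format_error(sprintf(
        "surface atlas under %s must provide both hemispheres", path))
    }
    read_atlas_surface(left, right, regions)
  }
}

#' Read a plain-text volumetric label atlas
#'
#' Format: line 1 `dim nx ny nz`; lines 2-5 the rows of the 4x4
#' voxel-to-world affine; remaining lines `i j k label` (0-based indices,
#' nonzero voxels only).
#'
#' @param path Text file.
#' @param regions Region metadata data frame (see [read_regions()]).
#' @return A volumetric `brain_atlas`.
#' @export
read_atlas_volume_text <- function(path, regions) {
  lines <- readLines(path)
  if (length(lines) < 5L || !startsWith(lines[1], "dim ")) {
    mg_format_error(sprintf("%s: not a volume atlas text file", path))
  }
  dims <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][2:4])
  affine <- unname(t(vapply(lines[2:5], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }, numeric(4))))
  labels <- array(0L, dim = dims)
  if (length(lines) > 5L) {
    body <- utils::read.table(text = lines[-(1:5)],
                              col.names = c("i", "j", "k", "label"))
    labels[cbind(body$i + 1L, body$j + 1L, body$k + 1L)] <-
      as.integer(body$label)
  }
  atlas_volume(labels, affine, regions)
}

# NIfTI path: optional, used only when RNifti is available.
read_atlas_volume_nifti <- function(path, regions) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    mg_format_error("reading NIfTI atlases requires the RNifti package")
  }
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), class = NULL)
  atlas_volume(array(as.integer(round(img)), dim = dim(img)),
               matrix(affine, 4, 4), regions)
}

#' Read a surface atlas from per-hemisphere vertex tables
#'
#' @param left,right CSV files with columns `x, y, z, label` (one row per
#'   vertex; label 0 = unlabeled).
#' @param regions Region metadata data frame.
#' @return A surface `brain_atlas`.
#' @export
read_atlas_surface <- function(left, right, regions) {
  lt <- utils::read.csv(left)
  rt <- utils::read.csv(right)
  for (tab in list(lt, rt)) {
    if (!all(c("x", "y", "z", "label") %in% names(tab))) {
      mg_format_error("surface vertex table must have columns x, y, z, label")
    }
  }
  atlas_surface(as.matrix(lt[, c("x", "y", "z")]), lt$label,
                as.matrix(rt[, c("x", "y", "z")]), rt$label, regions)
}

#' Write an atlas directory
#'
#' Writes `regions.csv` plus the plain-text volume file or the per-hemisphere
#' vertex tables, depending on atlas space.
#'
#' @param atlas A `brain_atlas`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  mg_write_table(atlas$regions, file.path(path, "regions.csv"))
  if (atlas$space == "volume") {
    vox <- which(atlas$labels != 0, arr.ind = TRUE) - 1L
    labs <- atlas$labels[atlas$labels != 0]
    con <- file(file.path(path, "volume.txt"), "w")
    on.exit(close(con))
    writeLines(paste("dim", paste(dim(atlas$labels), collapse = " ")), con)
    writeLines(apply(atlas$affine, 1, function(r)
      paste(mg_num(r), collapse = " ")), con)
    if (nrow(vox)) {
      writeLines(paste(vox[, 1], vox[, 2], vox[, 3], labs), con)
    }
  } else {
    for (h in c("L", "R")) {
      hemi <- atlas$hemispheres[[h]]
      df <- data.frame(x = hemi$coords[, 1], y = hemi$coords[, 2],
                       z = hemi$coords[, 3], label = hemi$labels)
      mg_write_table(df, file.path(path, sprintf("surface_%s.csv", h)))
    }
  }
  invisible(path)
}
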