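# Domain containers: donor bundles, atlases, region-by-gene matrices.

STRUCTURE_CLASSES <- c("cortex", "subcortex_brainstem", "cerebellum",
                       "white_matter")

#' Construct a donor bundle
#'
#' A donor bundle holds one donor's probe-level microarray data: a
#' probe-by-sample matrix of log2 expression intensities, the matching binary
#' above-background ("PA call") matrix, probe annotations, sample annotations
#' with MNI coordinates, and (for donors that have it) a gene-level RNAseq
#' matrix over the same samples.
#'
#' @param donor_id Character scalar identifying the donor.
#' @param expression Numeric probe-by-sample matrix of log2 intensities.
#' @param pacall Binary matrix of the same shape as `expression`; 1 means the
#'   probe exceeded background in that sample.
#' @param probes Data frame with columns `probe_id` (integer, unique),
#'   `probe_name`, `gene_symbol`, `entrez_id`. A probe that maps to no gene
#'   has `NA` in both `gene_symbol` and `entrez_id`.
#' @param samples Data frame with columns `well_id` (integer, unique within
#'   donor), `structure_acronym`, `hemisphere` ("L"/"R"), `mni_x`, `mni_y`,
#'   `mni_z`, `structure_class`.
#' @param rnaseq Optional gene-by-sample numeric matrix (rownames = gene
#'   symbols) over the same sample columns.
#' @return An object of class `donor_bundle`.
#' @export
donor_bundle <- function(donor_id, expression, pacall, probes, samples,
                         rnaseq = NULL) {
  expression <- as.matrix(expression)
  pacall <- as.matrix(pacall)
  if (!identical(dim(expression), dim(pacall))) {
    mg_format_error(sprintf(
      "donor %s: expression (%d x %d) and pacall (%d x %d) differ in shape",
      donor_id, nrow(expression), ncol(expression),
      nrow(pacall), ncol(pacall)))
  }
  if (nrow(probes) != nrow(expression)) {
    mg_format_error(sprintf(
      "donor %s: %d probe annotations but %d expression rows",
      donor_id, nrow(probes), nrow(expression)))
  }
  if (nrow(samples) != ncol(expression)) {
    mg_format_error(sprintf(
      "donor %s: %d sample annotations but %d expression columns",
      donor_id, nrow(samples), ncol(expression)))
  }
  if (anyDuplicated(probes$probe_id)) {
    mg_format_error(sprintf("donor %s: duplicate probe_id", donor_id))
  }
  if (anyDuplicated(samples$well_id)) {
    mg_format_error(sprintf("donor %s: duplicate well_id", donor_id))
  }
  bad_gene <- xor(is.na(probes$gene_symbol), is.na(probes$entrez_id))
  if (any(bad_gene)) {
    mg_format_error(sprintf(
      "donor %s: probes with gene_symbol/entrez_id only partially annotated: %s",
      donor_id, paste(probes$probe_id[bad_gene], collapse = ", ")))
  }
  if (!all(samples$structure_class %in% STRUCTURE_CLASSES)) {
    mg_format_error(sprintf("donor %s: unknown structure_class", donor_id))
  }
  if (!all(samples$hemisphere %in% c("L", "R"))) {
    mg_format_error(sprintf("donor %s: hemisphere must be L or R", donor_id))
  }
  if (!is.null(rnaseq)) {
    rnaseq <- as.matrix(rnaseq)
    if (ncol(rnaseq) != nrow(samples)) {
      mg_format_error(sprintf(
        "donor %s: RNAseq has %d sample columns, annotations have %d",
        donor_id, ncol(rnaseq), nrow(samples)))
    }
  }
  dimnames(expression) <- list(as.character(probes$probe_id),
                               as.character(samples$well_id))
  dimnames(pacall) <- dimnames(expression)
  if (!is.null(rnaseq)) colnames(rnaseq) <- as.character(samples$well_id)
  structure(list(donor_id = donor_id, expression = expression,
                 pacall = pacall, probes = probes, samples = samples,
                 rnaseq = rnaseq),
            class = "donor_bundle")
}

#' @export
print.donor_bundle <- function(x, ...) {
  cat(sprintf("<donor_bundle %s: %d probes x %d samples%s>\n", x$donor_id,
              nrow(x$expression), ncol(x$expression),
              if (is.null(x$rnaseq)) "" else ", with RNAseq"))
  invisible(x)
}

#' Construct a volumetric atlas
#'
#' @param labels 3-D integer array; 0 marks unlabeled voxels.
#' @param affine 4x4 matrix mapping 0-based voxel indices (at voxel centers)
#'   to mm world coordinates (MNI convention: left hemisphere x < 0).
#' @param regions Data frame with columns `region_id` (unique, matching the
#'   nonzero labels), `label` (region name), `hemisphere` ("L"/"R"),
#'   `structure_class`.
#' @return An object of class `brain_atlas` with `space = "volume"`.
#' @export
atlas_volume <- function(labels, affine, regions) {
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) {
    mg_format_error("affine must be a 4x4 matrix")
  }
  if (length(dim(labels)) != 3L) {
    mg_format_error("labels must be a 3-D array")
  }
  if (any(labels < 0)) mg_format_error("labels must be non-negative")
  present <- sort(unique(as.integer(labels[labels != 0])))
  validate_regions(regions, present)
  structure(list(space = "volume", labels = labels, affine = affine,
                 regions = regions),
            class = "brain_atlas")
}

#' Construct a surface atlas
#'
#' @param coords_left,coords_right Vertex coordinate matrices (n x 3, mm) for
#'   the left and right hemisphere.
#' @param labels_left,labels_right Integer label per vertex; 0 = unlabeled.
#' @param regions Region metadata as in [atlas_volume()].
#' @return An object of class `brain_atlas` with `space = "surface"`.
#' @export
atlas_surface <- function(coords_left, labels_left, coords_right,
                          labels_right, regions) {
  if (is.null(coords_left) || is.null(coords_right)) {
    mg_format_error("surface atlas requires both hemispheres")
  }
  coords_left <- as.matrix(coords_left)
  coords_right <- as.matrix(coords_right)
  if (ncol(coords_left) != 3L || ncol(coords_right) != 3L) {
    mg_format_error("vertex coordinates must be n x 3")
  }
  if (nrow(coords_left) != length(labels_left) ||
      nrow(coords_right) != length(labels_right)) {
    mg_format_error("vertex labels and coordinates differ in length")
  }
  if (any(labels_left < 0) || any(labels_right < 0)) {
    mg_format_error("labels must be non-negative")
  }
  present <- sort(unique(c(labels_left[labels_left != 0],
                           labels_right[labels_right != 0])))
  validate_regions(regions, as.integer(present))
  structure(list(space = "surface",
                 hemispheres = list(
                   L = list(coords = coords_left,
                            labels = as.integer(labels_left)),
                   R = list(coords = coords_right,
                            labels = as.integer(labels_right))),
                 regions = regions),
            class = "brain_atlas")
}

validate_regions <- function(regions, present_labels) {
  needed <- c("region_id", "hemisphere", "structure_class")
  if (!all(needed %in% names(regions))) {
    mg_metadata_error(paste("region metadata must contain columns:",
                            paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(regions$region_id)) {
    mg_metadata_error("duplicate region_id in region metadata")
  }
  missing <- setdiff(present_labels, regions$region_id)
  if (length(missing)) {
    mg_metadata_error(sprintf(
      "labels present in atlas but absent from metadata: %s",
      paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat(sprintf("<brain_atlas (%s): %d regions>\n", x$space, nrow(x$regions)))
  invisible(x)
}

#' Region centroids in world (mm) coordinates
#'
#' For a volumetric atlas the centroid of a region is the mean of the world
#' coordinates (affine applied at voxel centers) of its voxels; for a surface
#' atlas it is the mean of the region's vertex coordinates. Regions with no
#' voxels/vertices are excluded (and logged).
#'
#' @param atlas A [atlas_volume()] / [atlas_surface()] object.
#' @return Data frame with columns `region_id`, `x`, `y`, `z`.
#' @export
region_centroids <- function(atlas) {
  stopifnot(inherits(atlas, "brain_atlas"))
  if (atlas$space == "volume") {
    vox <- which(atlas$labels != 0, arr.ind = TRUE) - 1  # 0-based indices
    labs <- atlas$labels[atlas$labels != 0]
    mm <- apply_affine(atlas$affine, vox)
    cent <- rowsum(mm, group = labs) / as.vector(table(labs))
    ids <- as.integer(rownames(cent))
  } else {
    pts <- rbind(atlas$hemispheres$L$coords, atlas$hemispheres$R$coords)
    labs <- c(atlas$hemispheres$L$labels, atlas$hemispheres$R$labels)
    keep <- labs != 0
    cent <- rowsum(pts[keep, , drop = FALSE], group = labs[keep]) /
      as.vector(table(labs[keep]))
    ids <- as.integer(rownames(cent))
  }
  empty <- setdiff(atlas$regions$region_id, ids)
  if (length(empty)) {
    mg_log("centroids", "regions with no voxels/vertices excluded: ",
           paste(empty, collapse = ", "))
  }
  out <- data.frame(region_id = ids, x = cent[, 1], y = cent[, 2],
                    z = cent[, 3], row.names = NULL)
  out[order(out$region_id), , drop = FALSE]
}

# Apply a 4x4 voxel-to-world affine to an n x 3 matrix of 0-based indices.
apply_affine <- function(affine, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  hom <- cbind(ijk, 1)
  out <- hom %*% t(affine)
  out[, 1:3, drop = FALSE]
}

#' Construct a region-by-gene expression matrix
#'
#' @param values Numeric region-by-gene matrix.
#' @param region_ids Integer vector of region ids (row order).
#' @param gene_symbols Character vector of unique gene symbols (column order).
#' @param missing_mask Logical per region; `TRUE` rows are all-`NA` and mark
#'   regions to which no tissue sample was assigned.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, region_ids, gene_symbols,
                              missing_mask = NULL) {
  values <- as.matrix(values)
  if (anyDuplicated(gene_symbols)) {
    mg_format_error("duplicate gene symbols")
  }
  if (nrow(values) != length(region_ids) ||
      ncol(values) != length(gene_symbols)) {
    mg_format_error("values shape does not match region/gene lists")
  }
  if (is.null(missing_mask)) {
    missing_mask <- apply(values, 1, function(r) all(is.na(r)))
  }
  values[missing_mask, ] <- NA_real_
  dimnames(values) <- list(as.character(region_ids), gene_symbols)
  structure(list(values = values,
                 region_ids = as.integer(region_ids),
                 gene_symbols = as.character(gene_symbols),
                 missing_mask = as.logical(missing_mask)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix: %d regions x %d genes (%d missing)>\n",
              length(x$region_ids), length(x$gene_symbols),
              sum(x$missing_mask)))
  invisible(x)
}

#' @export
as.matrix.expression_matrix <- function(x, ...) x$values
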