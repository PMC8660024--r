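# Readers/writers for the donor-directory dialect (the layout of the public
# AHBA microarray releases): one directory per donor containing
# MicroarrayExpression.csv, PACall.csv, Probes.csv, SampleAnnot.csv and,
# for donors with RNAseq, RNAseq.csv.

donor_files <- c(expression = "MicroarrayExpression.csv",
                 pacall = "PACall.csv",
                 probes = "Probes.csv",
                 samples = "SampleAnnot.csv")

#' Load one donor directory
#'
#' Reads the donor-directory dialect: `MicroarrayExpression.csv` (no header;
#' first column probe_id, remaining columns one per sample), `PACall.csv`
#' (same shape, binary), `Probes.csv` (header: probe_id, probe_name,
#' gene_symbol, entrez_id; empty gene fields allowed), `SampleAnnot.csv`
#' (header: well_id, structure_acronym, slab_type, hemisphere, mni_x, mni_y,
#' mni_z, structure_class) and optionally `RNAseq.csv` (header: gene_symbol
#' then one column per sample).
#'
#' @param path Donor directory.
#' @param donor_id Donor identifier; defaults to the directory name.
#' @return A [donor_bundle()].
#' @export
load_donor <- function(path, donor_id = basename(normalizePath(path))) {
  for (f in donor_files) {
    if (!file.exists(file.path(path, f))) {
      mg_file_missing(sprintf("donor directory %s is missing %s", path, f))
    }
  }
  expr_raw <- utils::read.csv(file.path(path, donor_files["expression"]),
                              header = FALSE)
  pa_raw <- utils::read.csv(file.path(path, donor_files["pacall"]),
                            header = FALSE)
  if (!identical(dim(expr_raw), dim(pa_raw))) {
    mg_format_error(sprintf(
      "%s: MicroarrayExpression.csv and PACall.csv differ in shape", path))
  }
  probes <- utils::read.csv(file.path(path, donor_files["probes"]),
                            colClasses = c(probe_id = "integer",
                                           probe_name = "character",
                                           gene_symbol = "character",
                                           entrez_id = "integer"))
  probes$gene_symbol[!is.na(probes$gene_symbol) &
                       probes$gene_symbol == ""] <- NA_character_
  samples <- utils::read.csv(file.path(path, donor_files["samples"]))
  required <- c("well_id", "structure_acronym", "hemisphere",
                "mni_x", "mni_y", "mni_z", "structure_class")
  if (!all(required %in% names(samples))) {
    mg_format_error(sprintf("%s: SampleAnnot.csv lacks required columns",
                            path))
  }
  expr_ids <- as.integer(expr_raw[[1]])
  pa_ids <- as.integer(pa_raw[[1]])
  if (!identical(expr_ids, pa_ids)) {
    mg_format_error(sprintf(
      "%s: probe order differs between expression and PACall", path))
  }
  if (!identical(expr_ids, probes$probe_id)) {
    mg_format_error(sprintf(
      "%s: probe order differs between expression and Probes.csv", path))
  }
  expression <- as.matrix(expr_raw[, -1, drop = FALSE])
  pacall <- as.matrix(pa_raw[, -1, drop = FALSE])
  rnaseq <- NULL
  rna_path <- file.path(path, "RNAseq.csv")
  if (file.exists(rna_path)) {
    rna_raw <- utils::read.csv(rna_path)
    rnaseq <- as.matrix(rna_raw[, -1, drop = FALSE])
    rownames(rnaseq) <- rna_raw[[1]]
  }
  donor_bundle(donor_id, expression, pacall, probes, samples, rnaseq)
}

#' Write one donor bundle to a directory
#'
#' Emits the same dialect that [load_donor()] consumes; a write/load
#' round-trip reproduces the bundle.
#'
#' @param bundle A [donor_bundle()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_donor <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  expr_df <- data.frame(probe_id = bundle$probes$probe_id,
                        bundle$expression, check.names = FALSE)
  mg_write_table(expr_df, file.path(path, donor_files["expression"]),
                 col.names = FALSE)
  pa_df <- data.frame(probe_id = bundle$probes$probe_id,
                      bundle$pacall, check.names = FALSE)
  mg_write_table(pa_df, file.path(path, donor_files["pacall"]),
                 col.names = FALSE)
  probes <- bundle$probes
  probes$gene_symbol[is.na(probes$gene_symbol)] <- ""
  utils::write.table(probes, file.path(path, donor_files["probes"]),
                     sep = ",", quote = FALSE, row.names = FALSE, na = "")
  mg_write_table(bundle$samples, file.path(path, donor_files["samples"]))
  if (!is.null(bundle$rnaseq)) {
    rna_df <- data.frame(gene_symbol = rownames(bundle$rnaseq),
                         bundle$rnaseq, check.names = FALSE)
    mg_write_table(rna_df, file.path(path, "RNAseq.csv"))
  }
  invisible(path)
}

#' Load all donor directories under a root
#'
#' @param root Directory whose subdirectories are donor directories.
#' @return Named list of [donor_bundle()]s, ordered by donor id.
#' @export
load_donors <- function(root) {
  dirs <- list.dirs(root, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, donor_files["expression"]))]
  if (!length(dirs)) {
    mg_file_missing(sprintf("no donor directories found under %s", root))
  }
  dirs <- sort(dirs)
  bundles <- lapply(dirs, load_donor)
  names(bundles) <- vapply(bundles, `[[`, character(1), "donor_id")
  bundles
}

#' Read a corrected-coordinates table
#'
#' CSV with header columns `well_id, donor_id, x, y, z` giving updated MNI
#' coordinates (e.g. from a nonlinear registration) per tissue sample.
#'
#' @param path CSV file.
#' @return Data frame with those columns.
#' @export
read_correction_table <- function(path) {
  if (!file.exists(path)) mg_file_missing(sprintf("no such file: %s", path))
  tab <- utils::read.csv(path)
  needed <- c("well_id", "donor_id", "x", "y", "z")
  if (!all(needed %in% names(tab))) {
    mg_format_error(sprintf("%s: correction table lacks columns %s", path,
                            paste(setdiff(needed, names(tab)),
                                  collapse = ", ")))
  }
  tab
}

#' Read a probe-reannotation table
#'
#' CSV with header columns `probe_name, gene_symbol, entrez_id`; probes
#' absent from the table are treated as mapping to no gene.
#'
#' @param path CSV file.
#' @return Data frame usable as the mapping in [reannotate_probes()].
#' @export
read_reannotation_table <- function(path) {
  if (!file.exists(path)) mg_file_missing(sprintf("no such file: %s", path))
  tab <- utils::read.csv(path, colClasses = c(probe_name = "character",
                                              gene_symbol = "character",
                                              entrez_id = "integer"))
  tab$gene_symbol[!is.na(tab$gene_symbol) & tab$gene_symbol == ""] <-
    NA_character_
  tab
}
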