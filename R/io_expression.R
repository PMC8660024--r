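# Region-by-gene matrix TSV dialect: first column region_id, remaining
# columns one per gene symbol; missing regions serialized as all-NA rows.
# Values are written with 6 significant decimals, so a write/read round-trip
# is exact to that precision.

#' Write a region-by-gene expression matrix as TSV
#'
#' @param em An [expression_matrix()].
#' @param path Output file.
#' @param digits Significant decimals retained (default 6).
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, digits = 6L) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(region_id = em$region_ids, em$values,
                   check.names = FALSE)
  mg_write_table(df, path, sep = "\t", digits = digits)
  invisible(path)
}

#' Read a region-by-gene expression matrix TSV
#'
#' @param path File written by [write_expression()].
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) mg_file_missing(sprintf("no such file: %s", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  genes <- header[-1]
  if (anyDuplicated(genes)) {
    mg_format_error(sprintf("%s: duplicate gene columns: %s", path,
                            paste(unique(genes[duplicated(genes)]),
                                  collapse = ", ")))
  }
  tab <- utils::read.delim(path, check.names = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  expression_matrix(values, region_ids = as.integer(tab[[1]]),
                    gene_symbols = genes)
}
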