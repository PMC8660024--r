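# Internal helpers shared across modules.

# Classed condition constructor. Every user-facing error in the package goes
# through this so callers can test on condition class rather than message.
mg_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "multigex_error"),
                      call = call))
}

mg_file_missing      <- function(msg) mg_stop(msg, "mg_file_missing")
mg_format_error      <- function(msg) mg_stop(msg, "mg_format_error")
mg_metadata_error    <- function(msg) mg_stop(msg, "mg_metadata_error")
mg_parameter_error   <- function(msg) mg_stop(msg, "mg_parameter_error")
mg_mapping_error     <- function(msg) mg_stop(msg, "mg_mapping_error")
mg_config_error      <- function(msg) mg_stop(msg, "mg_configuration_error")
mg_degenerate_error  <- function(msg) mg_stop(msg, "mg_degenerate_input_error")
mg_empty_error       <- function(msg) mg_stop(msg, "mg_empty_result_error")
mg_incomplete_error  <- function(msg) mg_stop(msg, "mg_incomplete_grid_error")

# Structured log line. Quiet by default; enable with
# options(multigex.verbose = TRUE).
mg_log <- function(stage, ...) {
  if (isTRUE(getOption("multigex.verbose", FALSE))) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  invisible(NULL)
}

# The repo-wide standard deviation convention is the (n - 1) denominator,
# i.e. base stats::sd. Alias kept so the convention is greppable.
mg_sd <- function(x) stats::sd(x)

# Spearman correlation tolerant of NA pairs.
mg_spearman <- function(x, y) {
  suppressWarnings(stats::cor(x, y, method = "spearman",
                              use = "pairwise.complete.obs"))
}

# Fixed-format numeric rendering used by all writers so identical inputs
# produce byte-identical files.
mg_num <- function(x, digits = 15L) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf(paste0("%.", digits, "g"), v)
  }, character(1))
  out
}

# Write a data.frame as CSV/TSV with deterministic formatting (no quoting,
# no row names); numeric columns rendered through mg_num.
mg_write_table <- function(df, path, sep = ",", digits = 15L,
                           col.names = TRUE) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]])) df2[[j]] <- mg_num(df2[[j]], digits)
  }
  utils::write.table(df2, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = col.names, na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
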