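# Sample-wise (row) and gene-wise (column) normalization. All normalization
# is performed per donor -- its purpose is to remove donor-specific offsets
# and scale differences, so pooling donors before normalizing would defeat
# it.

NORM_METHODS <- c("none", "zscore", "srs")

#' Normalize a numeric vector
#'
#' `"zscore"` is (x - mean) / sd with the (n - 1) denominator (a constant
#' vector maps to all zeros). `"srs"` is the scaled robust sigmoid:
#' y = 1 / (1 + exp(-(x - median) / (IQR / 1.35))), rescaled to the unit
#' interval as (y - min) / (max - min). The 1.35 factor makes the IQR an
#' estimate of the s.d. under normality; when the IQR is 0 the s.d. is used
#' in the denominator instead, and a fully constant vector maps to all 0.5.
#'
#' @param x Numeric vector.
#' @param method `"none"`, `"zscore"` or `"srs"`.
#' @return Normalized vector of the same length.
#' @export
normalize_vector <- function(x, method) {
  if (!method %in% NORM_METHODS) {
    mg_parameter_error(sprintf("unknown normalization method: %s", method))
  }
  if (!length(x)) mg_parameter_error("cannot normalize an empty vector")
  if (method == "none") return(x)
  if (method == "zscore") {
    s <- mg_sd(x)
    if (is.na(s) || s == 0) return(rep(0, length(x)))
    return((x - mean(x)) / s)
  }
  # scaled robust sigmoid
  med <- stats::median(x)
  scale <- stats::IQR(x) / 1.35
  if (scale == 0) scale <- mg_sd(x)
  if (is.na(scale) || scale == 0) return(rep(0.5, length(x)))
  y <- 1 / (1 + exp(-(x - med) / scale))
  rng <- range(y)
  if (rng[2] == rng[1]) return(rep(0.5, length(x)))
  (y - rng[1]) / (rng[2] - rng[1])
}

#' Row-wise (per-sample) normalization
#'
#' Applies [normalize_vector()] to each sample's gene vector of one donor's
#' gene x sample matrix.
#'
#' @param expression Gene x sample matrix of one donor.
#' @param method `"none"`, `"zscore"` or `"srs"`.
#' @return Matrix of the same shape.
#' @export
normalize_samples <- function(expression, method) {
  if (method == "none") return(expression)
  out <- apply(expression, 2, normalize_vector, method = method)
  dimnames(out) <- dimnames(expression)
  out
}

#' Column-wise (per-gene) normalization
#'
#' Transforms each gene's values across one donor's samples. With
#' `matched_only`, normalization statistics are computed on -- and the output
#' restricted to -- samples assigned to an atlas region. With
#' `within_structures`, the transform is applied separately within each
#' structure class present among the (retained) samples; a class with fewer
#' than 2 samples is passed through unchanged.
#'
#' @param expression Gene x sample matrix of one donor (columns named by
#'   well_id).
#' @param samples Sample annotation data frame aligned with the columns.
#' @param method `"none"`, `"zscore"` or `"srs"`.
#' @param matched_only Restrict to region-matched samples.
#' @param within_structures Normalize within structure classes.
#' @param assignment Assignment table for the donor (required when
#'   `matched_only` is set).
#' @return List with the normalized `expression` and the corresponding
#'   `samples` (restricted when `matched_only` is set).
#' @export
normalize_genes <- function(expression, samples, method,
                            matched_only = FALSE, within_structures = FALSE,
                            assignment = NULL) {
  if (matched_only) {
    if (is.null(assignment)) {
      mg_parameter_error("matched_only normalization requires assignments")
    }
    matched <- assignment$well_id[!is.na(assignment$region_id)]
    keep <- samples$well_id %in% matched
    expression <- expression[, keep, drop = FALSE]
    samples <- samples[keep, , drop = FALSE]
  }
  if (method == "none" || ncol(expression) == 0L) {
    return(list(expression = expression, samples = samples))
  }
  norm_block <- function(block) {
    t(apply(block, 1, normalize_vector, method = method))
  }
  if (within_structures) {
    out <- expression
    for (cls in unique(samples$structure_class)) {
      cols <- which(samples$structure_class == cls)
      if (length(cols) < 2L) {
        mg_log("normalize", "structure class ", cls,
               " has < 2 samples; passed through unchanged")
        next
      }
      out[, cols] <- norm_block(expression[, cols, drop = FALSE])
    }
  } else {
    out <- norm_block(expression)
    dimnames(out) <- dimnames(expression)
  }
  list(expression = out, samples = samples)
}
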