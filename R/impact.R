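# Impact scoring: how much does varying one option -- all others held fixed
# -- change each analysis estimate; plus PCA of the estimate table.

ESTIMATE_COLUMNS <- c("cge_rho", "gce_silhouette", "rge_rho")

# Key used to look up a row of an estimates table from its choice keys.
row_key <- function(tab, option_names) {
  do.call(paste, c(lapply(option_names, function(nm) {
    paste0(nm, "=", tab[[nm]])
  }), sep = "|"))
}

#' Per-option impact scores and ranks
#'
#' For every option, pipelines are grouped into matched tuples that differ
#' only in that option (matching on effective, redundancy-collapsed
#' configurations, so collapsed cells are never double counted; tuples in
#' which the option has no effective variation are skipped). Each tuple
#' contributes, per analysis, the absolute estimate difference -- for binary
#' options the single pair difference, for ordinal options the mean over
#' adjacent choice pairs, for categorical options the mean over all
#' unordered choice pairs. The impact score is the mean over tuples; ranks
#' are assigned per analysis with 1 = most impactful (ties break by option
#' declaration order).
#'
#' @param estimates Result of [run_multiverse()] (must cover the full
#'   factorial grid).
#' @param grid The [parameter_grid()] that produced it.
#' @param measures Estimate columns to score (default the three analyses).
#' @return Data frame `option, analysis, impact, rank`.
#' @export
impact_scores <- function(estimates, grid,
                          measures = ESTIMATE_COLUMNS) {
  option_names <- names(grid$options)
  keys <- row_key(estimates, option_names)
  if (anyDuplicated(keys)) {
    mg_parameter_error("estimates table has duplicated configurations")
  }
  lookup <- lapply(measures, function(m) {
    stats::setNames(estimates[[m]], keys)
  })
  names(lookup) <- measures
  scored <- list()
  for (opt_name in option_names) {
    opt <- grid$options[[opt_name]]
    k <- length(opt$keys)
    if (k < 2L) {
      scored[[opt_name]] <- stats::setNames(rep(0, length(measures)),
                                            measures)
      next
    }
    others <- setdiff(option_names, opt_name)
    combos <- expand.grid(lapply(grid$options[others], `[[`, "keys"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    if (!nrow(combos)) combos <- data.frame(row.names = 1)
    sums <- stats::setNames(numeric(length(measures)), measures)
    n_tuples <- 0L
    seen <- new.env(hash = TRUE)
    missing_cells <- character(0)
    for (i in seq_len(nrow(combos))) {
      tuple <- combos[rep(i, k), , drop = FALSE]
      tuple[[opt_name]] <- opt$keys
      eff <- collapse_keys(grid, tuple)
      eff_keys <- row_key(eff, option_names)
      if (length(unique(eff_keys)) < k) next   # option collapsed away here
      tuple_id <- paste(sort(eff_keys), collapse = "&")
      if (!is.null(seen[[tuple_id]])) next     # effective tuple already seen
      seen[[tuple_id]] <- TRUE
      absent <- eff_keys[!eff_keys %in% names(lookup[[1]])]
      if (length(absent)) {
        missing_cells <- unique(c(missing_cells, absent))
        next
      }
      for (m in measures) {
        vals <- lookup[[m]][eff_keys]
        sums[m] <- sums[m] + tuple_difference(vals, opt$scale)
      }
      n_tuples <- n_tuples + 1L
    }
    if (length(missing_cells)) {
      mg_incomplete_error(sprintf(
        "estimates table is not a full factorial; missing cells: %s",
        paste(utils::head(missing_cells, 5), collapse = "; ")))
    }
    scored[[opt_name]] <- if (n_tuples > 0L) sums / n_tuples else
      stats::setNames(rep(NA_real_, length(measures)), measures)
  }
  out <- do.call(rbind, lapply(names(scored), function(o) {
    data.frame(option = o, analysis = measures,
               impact = as.numeric(scored[[o]][measures]))
  }))
  out$rank <- NA_integer_
  for (m in measures) {
    rows <- which(out$analysis == m)
    decl <- match(out$option[rows], option_names)
    ord <- order(-out$impact[rows], decl)
    out$rank[rows[ord]] <- seq_along(rows)
  }
  rownames(out) <- NULL
  out
}

# Mean absolute difference over the pairs dictated by the option scale,
# applied to the estimates of one matched tuple (in choice order).
tuple_difference <- function(vals, scale) {
  if (anyNA(vals)) return(NA_real_)
  if (length(vals) == 2L) return(abs(vals[1] - vals[2]))
  if (scale == "ordinal") {
    mean(abs(diff(vals)))
  } else {
    mean(abs(as.numeric(stats::dist(matrix(vals, ncol = 1)))))
  }
}

#' PCA of a pipeline-by-estimate table
#'
#' Mean-centers the estimate columns and extracts the first two principal
#' components by singular value decomposition.
#'
#' @param estimates Data frame or matrix whose columns are the analysis
#'   estimates (e.g. the three-statistic table from [run_multiverse()]).
#' @param measures Columns to use when `estimates` is a data frame.
#' @return List with `scores` (n x 2 matrix), `variance_explained`
#'   (fractions for the first two components, non-increasing) and
#'   `rotation` (loadings).
#' @export
pca_estimates <- function(estimates, measures = ESTIMATE_COLUMNS) {
  x <- if (is.data.frame(estimates)) {
    as.matrix(estimates[, intersect(measures, names(estimates)),
                        drop = FALSE])
  } else {
    as.matrix(estimates)
  }
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3L) {
    mg_parameter_error("PCA needs at least 3 complete pipelines")
  }
  centered <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) {
    mg_degenerate_error("all estimate columns are constant")
  }
  sv <- svd(centered)
  var_frac <- sv$d^2 / sum(sv$d^2)
  n_pc <- min(2L, length(sv$d))
  scores <- sv$u[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)], n_pc)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  list(scores = scores, variance_explained = var_frac[seq_len(n_pc)],
       rotation = sv$v[, seq_len(n_pc), drop = FALSE])
}
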