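# Probe handling: reannotation, intensity-based filtering, and collapse of
# redundant probes to one expression row per gene.

PROBE_METHODS <- c("max_intensity", "corr_intensity", "corr_variance",
                   "diff_stability", "rnaseq", "average")
DONOR_MODES <- c("aggregate", "independent", "common")
# Methods whose selection criterion is defined jointly across donors (or
# needs no selection at all); for these the donor mode is redundant and is
# fixed to "aggregate".
DONOR_INDEPENDENT_METHODS <- c("diff_stability", "rnaseq", "average")

#' Probe selection specification
#'
#' @param method One of `"max_intensity"`, `"corr_intensity"`,
#'   `"corr_variance"`, `"diff_stability"`, `"rnaseq"`, `"average"`.
#' @param donor_mode `"aggregate"` (criterion on samples pooled across
#'   donors, one probe per gene for all donors), `"independent"` (criterion
#'   per donor; donors may use different probes) or `"common"` (per-donor
#'   selection, then the modal probe applied to all donors). For
#'   `diff_stability`, `rnaseq` and `average` the donor mode is redundant and
#'   is coerced to `"aggregate"`.
#' @return A `probe_selection_spec` list.
#' @export
probe_selection_spec <- function(method, donor_mode = "aggregate") {
  if (!method %in% PROBE_METHODS) {
    mg_parameter_error(sprintf("unknown probe selection method: %s", method))
  }
  if (!donor_mode %in% DONOR_MODES) {
    mg_parameter_error(sprintf("unknown donor mode: %s", donor_mode))
  }
  if (method %in% DONOR_INDEPENDENT_METHODS && donor_mode != "aggregate") {
    mg_log("probes", "donor_mode is redundant for method ", method,
           "; using aggregate")
    donor_mode <- "aggregate"
  }
  structure(list(method = method, donor_mode = donor_mode),
            class = "probe_selection_spec")
}

#' Reannotate probes against a mapping table
#'
#' Replaces each probe's gene annotation by the mapping's entry for its
#' `probe_name`. Probes absent from the mapping (or mapped to an empty gene)
#' are retained with null gene fields, which drops them at probe selection.
#' A `NULL` mapping returns the probes unchanged.
#'
#' @param probes Probe annotation data frame (`probe_id, probe_name,
#'   gene_symbol, entrez_id`).
#' @param mapping Data frame with columns `probe_name, gene_symbol,
#'   entrez_id`, or `NULL`.
#' @return The reannotated probe data frame.
#' @export
reannotate_probes <- function(probes, mapping = NULL) {
  if (is.null(mapping)) return(probes)
  if (anyDuplicated(mapping$probe_name)) {
    mg_format_error("reannotation mapping has duplicate probe_name entries")
  }
  idx <- match(probes$probe_name, mapping$probe_name)
  probes$gene_symbol <- mapping$gene_symbol[idx]
  probes$entrez_id <- mapping$entrez_id[idx]
  probes$gene_symbol[!is.na(probes$gene_symbol) &
                       probes$gene_symbol == ""] <- NA_character_
  probes$entrez_id[is.na(probes$gene_symbol)] <- NA_integer_
  probes
}

#' Intensity-based probe filtering
#'
#' A probe is kept iff it is flagged above background in strictly more than
#' `threshold` of all tissue samples, pooled across donors. `threshold =
#' NULL` disables filtering (all probes kept) -- this is a distinct state,
#' not `threshold = 0`.
#'
#' @param bundles List of [donor_bundle()]s sharing one probe list.
#' @param threshold Fraction in `[0, 1)`, or `NULL` to disable.
#' @return Integer vector of kept `probe_id`s.
#' @export
filter_probes_by_intensity <- function(bundles, threshold) {
  probes <- shared_probes(bundles)
  if (is.null(threshold)) return(probes$probe_id)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold >= 1) {
    mg_parameter_error("intensity threshold must be in [0, 1) or NULL")
  }
  flagged <- Reduce(`+`, lapply(bundles, function(b) rowSums(b$pacall)))
  total <- sum(vapply(bundles, function(b) ncol(b$pacall), integer(1)))
  kept <- probes$probe_id[flagged / total > threshold]
  mg_log("intensity_filter", sprintf("kept %d/%d probes at threshold %.2f",
                                     length(kept), nrow(probes), threshold))
  kept
}

shared_probes <- function(bundles) {
  probes <- bundles[[1]]$probes
  for (b in bundles[-1]) {
    if (!identical(b$probes$probe_id, probes$probe_id)) {
      mg_format_error("donor bundles do not share a probe list")
    }
  }
  probes
}

#' Collapse probes to one expression row per gene
#'
#' Applies the selection criterion of `spec` to the probes surviving
#' intensity filtering (which must run first) after dropping probes with no
#' gene annotation. Criteria: `max_intensity` picks the probe with the
#' highest mean expression over the evaluation samples; `corr_intensity`
#' (`corr_variance`) picks, for genes with at least three probes, the probe
#' most correlated on average with the gene's other probes, falling back to
#' max intensity (max variance) for two-probe genes; `diff_stability` picks
#' the probe with the highest mean between-donor Spearman correlation of
#' structure-averaged expression profiles (structures matched by acronym);
#' `rnaseq` picks the probe whose expression best matches the gene's RNAseq
#' values across the RNAseq donors' samples (genes absent from RNAseq are
#' dropped); `average` takes the mean across the gene's probes. All argmax
#' ties break to the lowest probe_id.
#'
#' @param bundles List of [donor_bundle()]s sharing one probe list.
#' @param spec A [probe_selection_spec()].
#' @param kept_probes Integer vector of probe_ids surviving intensity
#'   filtering; `NULL` means all probes.
#' @return List with `matrices` (named list of gene x sample matrices, one
#'   per donor, identical gene row order) and `report` (data frame
#'   `gene_symbol, donor_id, probe` where probe is a probe_id or
#'   `"average"`).
#' @export
select_probes <- function(bundles, spec, kept_probes = NULL) {
  stopifnot(inherits(spec, "probe_selection_spec"))
  probes <- shared_probes(bundles)
  keep <- !is.na(probes$gene_symbol)
  if (!is.null(kept_probes)) keep <- keep & probes$probe_id %in% kept_probes
  if (spec$method == "rnaseq") {
    rna <- lapply(bundles, `[[`, "rnaseq")
    rna <- rna[!vapply(rna, is.null, logical(1))]
    if (!length(rna)) {
      mg_config_error("probe selection method 'rnaseq' requires at least one donor with RNAseq data")
    }
    rna_genes <- Reduce(union, lapply(rna, rownames))
    keep <- keep & probes$gene_symbol %in% rna_genes
  }
  idx <- which(keep)
  if (!length(idx)) mg_empty_error("no probes survive filtering")
  sub <- probes[idx, , drop = FALSE]
  ord <- order(sub$gene_symbol, sub$probe_id)
  sub <- sub[ord, , drop = FALSE]
  idx <- idx[ord]
  gene_of <- sub$gene_symbol
  genes <- sort(unique(gene_of))
  by_gene <- split(seq_along(idx), gene_of)  # positions into idx/sub

  expr_list <- lapply(bundles, function(b) b$expression[idx, , drop = FALSE])
  donor_ids <- vapply(bundles, `[[`, character(1), "donor_id")

  if (spec$method == "average") {
    mats <- lapply(expr_list, function(e) {
      rows <- t(vapply(by_gene, function(p) {
        colMeans(e[p, , drop = FALSE])
      }, numeric(ncol(e))))
      rownames(rows) <- names(by_gene)
      rows[genes, , drop = FALSE]
    })
    names(mats) <- donor_ids
    report <- data.frame(gene_symbol = genes, donor_id = "all",
                         probe = "average")
    return(list(matrices = mats, report = report))
  }

  pick_per_gene <- function(scores) {
    # scores: numeric over rows of sub (ordered by gene, then probe_id);
    # which.max takes the first maximum, i.e. the lowest probe_id on ties
    vapply(by_gene, function(p) p[which.max(scores[p])], integer(1))[genes]
  }

  chosen_all <- NULL   # per-gene position into idx (shared across donors)
  chosen_by_donor <- NULL
  if (spec$method %in% c("max_intensity", "corr_intensity",
                         "corr_variance")) {
    score_fun <- function(e) intensity_scores(e, by_gene, spec$method)
    if (spec$donor_mode == "aggregate") {
      pooled <- do.call(cbind, expr_list)
      chosen_all <- pick_per_gene(score_fun(pooled))
    } else {
      chosen_by_donor <- lapply(expr_list,
                                function(e) pick_per_gene(score_fun(e)))
      if (spec$donor_mode == "common") {
        chosen_all <- modal_choice(chosen_by_donor, sub$probe_id)
        chosen_by_donor <- NULL
      }
    }
  } else if (spec$method == "diff_stability") {
    chosen_all <- pick_per_gene(
      diff_stability_scores(expr_list, bundles))
  } else { # rnaseq
    chosen_all <- pick_per_gene(
      rnaseq_scores(expr_list, bundles, gene_of))
  }

  if (!is.null(chosen_all)) {
    mats <- lapply(expr_list, function(e) {
      m <- e[chosen_all, , drop = FALSE]
      rownames(m) <- genes
      m
    })
    names(mats) <- donor_ids
    report <- data.frame(gene_symbol = genes, donor_id = "all",
                         probe = as.character(sub$probe_id[chosen_all]))
  } else {
    mats <- Map(function(e, ch) {
      m <- e[ch, , drop = FALSE]
      rownames(m) <- genes
      m
    }, expr_list, chosen_by_donor)
    names(mats) <- donor_ids
    report <- do.call(rbind, Map(function(d, ch) {
      data.frame(gene_symbol = genes, donor_id = d,
                 probe = as.character(sub$probe_id[ch]))
    }, donor_ids, chosen_by_donor))
    rownames(report) <- NULL
  }
  list(matrices = mats, report = report)
}

# Scores for the intensity-family criteria over one (possibly pooled)
# probe x sample expression matrix.
intensity_scores <- function(e, by_gene, method) {
  scores <- numeric(nrow(e))
  mean_int <- rowMeans(e)
  if (method == "max_intensity") return(mean_int)
  row_var <- apply(e, 1, stats::var)
  for (p in by_gene) {
    if (length(p) >= 3L) {
      cc <- suppressWarnings(stats::cor(t(e[p, , drop = FALSE])))
      cc[!is.finite(cc)] <- 0
      diag(cc) <- NA
      scores[p] <- rowMeans(cc, na.rm = TRUE)
    } else if (length(p) == 2L) {
      scores[p] <- if (method == "corr_intensity") mean_int[p] else row_var[p]
    } else {
      scores[p] <- 0
    }
  }
  scores
}

# Mean over donor pairs of the Spearman correlation between a probe's
# structure-averaged expression profiles (structures matched by acronym).
diff_stability_scores <- function(expr_list, bundles) {
  n_d <- length(bundles)
  profiles <- lapply(seq_len(n_d), function(d) {
    acro <- bundles[[d]]$samples$structure_acronym
    e <- expr_list[[d]]
    groups <- split(seq_len(ncol(e)), acro)
    prof <- vapply(groups, function(cols) {
      rowMeans(e[, cols, drop = FALSE])
    }, numeric(nrow(e)))
    prof  # probe x structure
  })
  n_p <- nrow(expr_list[[1]])
  total <- matrix(0, n_p, 1)
  count <- matrix(0, n_p, 1)
  for (a in seq_len(n_d - 1L)) {
    for (b in seq((a + 1L), n_d)) {
      common <- intersect(colnames(profiles[[a]]), colnames(profiles[[b]]))
      if (length(common) < 3L) next
      pa <- profiles[[a]][, common, drop = FALSE]
      pb <- profiles[[b]][, common, drop = FALSE]
      rho <- vapply(seq_len(n_p), function(i) mg_spearman(pa[i, ], pb[i, ]),
                    numeric(1))
      ok <- !is.na(rho)
      total[ok] <- total[ok] + rho[ok]
      count[ok] <- count[ok] + 1
    }
  }
  score <- ifelse(count > 0, total / count, -Inf)
  as.numeric(score)
}

# Mean over RNAseq donors of the Spearman correlation between each probe's
# expression and its gene's RNAseq values across that donor's samples.
rnaseq_scores <- function(expr_list, bundles, gene_of) {
  n_p <- length(gene_of)
  total <- numeric(n_p)
  count <- numeric(n_p)
  for (d in seq_along(bundles)) {
    rna <- bundles[[d]]$rnaseq
    if (is.null(rna)) next
    gi <- match(gene_of, rownames(rna))
    e <- expr_list[[d]]
    for (i in which(!is.na(gi))) {
      rho <- mg_spearman(e[i, ], rna[gi[i], ])
      if (!is.na(rho)) {
        total[i] <- total[i] + rho
        count[i] <- count[i] + 1
      }
    }
  }
  ifelse(count > 0, total / count, -Inf)
}

# Modal probe across donors' selections; ties break to lowest probe_id.
modal_choice <- function(chosen_by_donor, probe_ids) {
  n_g <- length(chosen_by_donor[[1]])
  vapply(seq_len(n_g), function(g) {
    picks <- vapply(chosen_by_donor, `[[`, integer(1), g)
    ids <- probe_ids[picks]
    tab <- table(ids)
    best <- as.integer(names(tab)[tab == max(tab)])
    picks[match(min(best), ids)]
  }, integer(1))
}
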