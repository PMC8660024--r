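# The three prototypical statistics computed from a region-by-gene matrix:
#   CGE: Spearman correlation between inter-region distance and correlated
#        gene expression (region-region Pearson correlation across genes);
#   GCE: silhouette score of gene-module labels on Euclidean distances
#        between gene expression profiles;
#   RGE: absolute Spearman correlation between the matrix's first principal
#        component and a regional phenotype.

#' Correlated gene expression versus distance
#'
#' Builds the region x region correlated-gene-expression (CGE) matrix as the
#' Pearson correlation between region rows across genes, then returns the
#' Spearman correlation between the strictly-upper triangles of the
#' inter-region Euclidean distance matrix and the CGE matrix. Missing
#' regions are excluded. Region pairs with a constant expression row are
#' undefined; if more than 10% of pairs are undefined the input is rejected.
#'
#' @param em An [expression_matrix()].
#' @param centroids Data frame from [region_centroids()] covering the
#'   non-missing regions.
#' @return Spearman rho (scalar in `[-1, 1]`).
#' @export
cge_distance_correlation <- function(em, centroids) {
  keep <- !em$missing_mask
  if (sum(keep) < 3L) {
    mg_parameter_error("CGE needs at least 3 non-missing regions")
  }
  ids <- em$region_ids[keep]
  idx <- match(ids, centroids$region_id)
  if (anyNA(idx)) {
    mg_parameter_error("centroids do not cover all non-missing regions")
  }
  pts <- as.matrix(centroids[idx, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(pts))
  cge <- suppressWarnings(stats::cor(t(em$values[keep, , drop = FALSE])))
  ut <- upper.tri(cge)
  undefined <- sum(is.na(cge[ut]))
  if (undefined > 0.1 * sum(ut)) {
    mg_degenerate_error(sprintf(
      "%d of %d region pairs have undefined correlations", undefined,
      sum(ut)))
  }
  mg_spearman(dmat[ut], cge[ut])
}

#' Gene co-expression silhouette
#'
#' Computes pairwise Euclidean distances between gene columns over the
#' non-missing regions and evaluates the silhouette of the supplied gene
#' modules: for each gene i, a(i) is its mean distance to the other genes of
#' its module, b(i) the mean distance to the nearest other module, and
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)). Genes in singleton modules (and
#' the degenerate a = b = 0 case) contribute s(i) = 0. The score is the
#' mean of s(i); positive values indicate assortative modules.
#'
#' @param em An [expression_matrix()].
#' @param module_labels Data frame `gene_symbol, module_id`; genes of the
#'   matrix absent from the table are ignored.
#' @return List with `score` and `terms` (data frame `gene_symbol,
#'   module_id, a, b, s`).
#' @export
gce_silhouette <- function(em, module_labels) {
  keep <- !em$missing_mask
  vals <- em$values[keep, , drop = FALSE]
  idx <- match(em$gene_symbols, module_labels$gene_symbol)
  genes <- which(!is.na(idx))
  if (!length(genes)) mg_parameter_error("no labeled genes in the matrix")
  labels <- module_labels$module_id[idx[genes]]
  if (length(unique(labels)) < 2L) {
    mg_parameter_error("silhouette needs at least 2 modules")
  }
  d <- as.matrix(stats::dist(t(vals[, genes, drop = FALSE])))
  n <- length(genes)
  a <- b <- s <- numeric(n)
  mods <- unique(labels)
  members <- lapply(mods, function(m) which(labels == m))
  names(members) <- as.character(mods)
  for (i in seq_len(n)) {
    own <- members[[as.character(labels[i])]]
    own_others <- setdiff(own, i)
    if (!length(own_others)) {       # singleton module
      a[i] <- 0; b[i] <- 0; s[i] <- 0
      next
    }
    a[i] <- mean(d[i, own_others])
    b[i] <- min(vapply(mods[mods != labels[i]], function(m) {
      mean(d[i, members[[as.character(m)]]])
    }, numeric(1)))
    denom <- max(a[i], b[i])
    s[i] <- if (denom == 0) 0 else (b[i] - a[i]) / denom
  }
  list(score = mean(s),
       terms = data.frame(gene_symbol = em$gene_symbols[genes],
                          module_id = labels, a = a, b = b, s = s))
}

# PC1 region scores of a column-mean-centered matrix, via SVD.
pc1_scores <- function(values) {
  centered <- scale(values, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) {
    mg_degenerate_error("matrix has zero variance; no principal component")
  }
  sv <- svd(centered, nu = 1, nv = 0)
  sv$u[, 1] * sv$d[1]
}

#' Regional expression PC1 versus a phenotype
#'
#' Mean-centers the gene columns over non-missing regions, extracts the
#' first principal component's region scores by singular value
#' decomposition, and returns the absolute Spearman correlation with the
#' phenotype (absolute because the component's sign is arbitrary).
#'
#' @param em An [expression_matrix()].
#' @param phenotype Data frame `region_id, value` covering the non-missing
#'   regions.
#' @return `|rho|` in `[0, 1]`.
#' @export
rge_pc1_correlation <- function(em, phenotype) {
  keep <- !em$missing_mask
  if (sum(keep) < 3L) {
    mg_parameter_error("RGE needs at least 3 non-missing regions")
  }
  ids <- em$region_ids[keep]
  idx <- match(ids, phenotype$region_id)
  if (anyNA(idx)) {
    mg_parameter_error("phenotype does not cover all non-missing regions")
  }
  scores <- pc1_scores(em$values[keep, , drop = FALSE])
  abs(mg_spearman(scores, phenotype$value[idx]))
}

#' Compute all three analysis estimates
#'
#' @param em An [expression_matrix()].
#' @param centroids Region centroids (for CGE).
#' @param module_labels Gene-module table (for GCE).
#' @param phenotype Regional phenotype (for RGE).
#' @return One-row data frame `cge_rho, gce_silhouette, rge_rho`.
#' @export
analysis_estimates <- function(em, centroids, module_labels, phenotype) {
  data.frame(cge_rho = cge_distance_correlation(em, centroids),
             gce_silhouette = gce_silhouette(em, module_labels)$score,
             rge_rho = rge_pc1_correlation(em, phenotype))
}
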