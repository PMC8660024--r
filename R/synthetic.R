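# Seeded generator of donor-directory fixtures with known ground truth.
#
# The generator plants the structures the processing pipeline is supposed to
# recover: a smooth regional expression field whose inter-region covariance
# decays exponentially with Euclidean distance, gene modules sharing spatial
# patterns, per-donor batch effects (offsets/scales per gene), redundant
# probes per gene with probe-level biases and probe-biased above-background
# failures, hemispherically asymmetric sampling (only the first
# n_bilateral_donors have right-hemisphere samples; those donors also carry
# gene-level RNAseq), and a regional phenotype built as an affine function of
# PC1 of the true regional expression.

#' Simulation parameters
#'
#' @param n_donors Number of donors (default 6).
#' @param n_bilateral_donors Donors sampled in both hemispheres; these also
#'   carry RNAseq (default 2). All other donors are sampled only on the left.
#' @param n_genes Number of genes.
#' @param probes_per_gene_range Integer range (min, max) of redundant probes
#'   per gene.
#' @param n_samples_per_donor Tissue samples per donor.
#' @param n_regions Number of atlas regions; must be even (split L/R into
#'   mirror-symmetric halves).
#' @param n_modules Number of planted gene modules.
#' @param decay_length Spatial correlation length lambda in mm: inter-region
#'   expression covariance is exp(-d / lambda).
#' @param donor_offset_sd,donor_scale_sd Per-donor per-gene batch-effect
#'   magnitudes (additive offset s.d.; multiplicative scale s.d. around 1).
#' @param probe_bias_sd S.d. of the per-probe additive intensity bias.
#' @param noise_sd Measurement noise s.d. (scaled per probe so that probes
#'   with a high background-failure propensity are also noisier).
#' @param background_fail_rate Mean fraction of probe x sample
#'   above-background flags set to 0; probe-biased so some probes fail often.
#' @param n_outlier_samples Samples of the first donor placed far outside the
#'   atlas (beyond any matching tolerance), exercising unassigned-sample
#'   handling.
#' @param seed Integer RNG seed.
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(n_donors = 6L, n_bilateral_donors = 2L,
                              n_genes = 150L,
                              probes_per_gene_range = c(1L, 4L),
                              n_samples_per_donor = 100L, n_regions = 30L,
                              n_modules = 5L, decay_length = 40,
                              donor_offset_sd = 1.0, donor_scale_sd = 0.1,
                              probe_bias_sd = 0.3, noise_sd = 0.5,
                              background_fail_rate = 0.1,
                              n_outlier_samples = 1L, seed = 42L) {
  p <- list(n_donors = as.integer(n_donors),
            n_bilateral_donors = as.integer(n_bilateral_donors),
            n_genes = as.integer(n_genes),
            probes_per_gene_range = as.integer(probes_per_gene_range),
            n_samples_per_donor = as.integer(n_samples_per_donor),
            n_regions = as.integer(n_regions),
            n_modules = as.integer(n_modules),
            decay_length = decay_length,
            donor_offset_sd = donor_offset_sd,
            donor_scale_sd = donor_scale_sd,
            probe_bias_sd = probe_bias_sd, noise_sd = noise_sd,
            background_fail_rate = background_fail_rate,
            n_outlier_samples = as.integer(n_outlier_samples),
            seed = as.integer(seed))
  counts <- c(p$n_donors, p$n_bilateral_donors, p$n_genes,
              p$n_samples_per_donor, p$n_regions, p$n_modules)
  if (any(counts < 1L)) mg_parameter_error("all counts must be >= 1")
  if (p$n_regions %% 2L != 0L) {
    mg_parameter_error("n_regions must be even (regions are split L/R)")
  }
  if (background_fail_rate < 0 || background_fail_rate > 1) {
    mg_parameter_error("background_fail_rate must be in [0, 1]")
  }
  if (decay_length <= 0) mg_parameter_error("decay_length must be > 0")
  if (p$probes_per_gene_range[1] < 1L ||
      p$probes_per_gene_range[2] < p$probes_per_gene_range[1]) {
    mg_parameter_error("invalid probes_per_gene_range")
  }
  if (p$n_bilateral_donors > p$n_donors) {
    mg_parameter_error("n_bilateral_donors cannot exceed n_donors")
  }
  structure(p, class = "simulation_params")
}

# Fixed geometry/scale constants of the generator (documented in the
# methods vignette): sampling box, voxel grid, and signal composition.
SIM_CONST <- list(
  box_x = c(8, 60),          # |x| range of region centroids, mm
  box_y = c(-70, 60), box_z = c(-40, 60),
  min_separation = 14,       # min distance between same-side centroids, mm
  voxel_size = 4,            # mm
  grid_half = 72,            # grid spans [-72, 72] mm per axis
  region_radius = 8,         # voxels within this distance of a centroid
                             # take its label
  vertices_per_region = 8,
  vertex_jitter = 2.5,       # mm, uniform
  sample_jitter_sd = 1.5,    # mm, sample placement around centroid
  coord_error_sd = 0.5,      # mm, error of the uncorrected MNI coordinates
  baseline_mean = 8,         # log2 intensity baseline
  gene_baseline_sd = 0.5,    # per-gene baseline spread
  gene_amplitude_sdlog = 1,  # lognormal spread of per-gene spatial
                              # signal amplitude (genes differ widely in
                              # how strongly they are brain-patterned)
  donor_coverage_sdlog = 1,  # lognormal spread of per-donor region
                             # sampling weights (donors cover regions
                             # unevenly, as in irregular post-mortem
                             # sampling)
  offset_heterogeneity_sdlog = 1, # lognormal spread, across genes, of the
                             # between-donor offset magnitude
  donor_coverage_frac = 0.6, # fraction of its admissible regions each
                             # donor (after the first) actually samples;
                             # regional donor composition therefore varies
                             # across the brain
  module_weight = 0.6,       # fraction of spatial variance shared in-module
  gradient_loading_sd = 0.8, # s.d. of per-gene loadings on the global
                             # expression gradient; gives the truth matrix
                             # a dominant, well-separated first principal
                             # component, as observed in cortical
                             # transcriptomes
  symmetry_weight = 0.9,     # fraction of spatial variance that is
                             # bilaterally symmetric (decays with
                             # midline-folded distance); the rest decays
                             # with true 3-D distance
  asymmetry_sd = 0.05,        # residual iid left/right expression asymmetry
  phenotype_noise_frac = 0.05,
  rnaseq_coverage = 0.9,     # fraction of genes present in RNAseq tables
  rnaseq_noise_sd = 0.2,     # lognormal noise on RNAseq values
  reannotation_drop_every = 50L, # every k-th probe loses its gene under
                                 # the emitted reannotation table
  outlier_position = c(150, 150, 150))

# Draw a Gaussian field over regions with covariance exp(-D / lambda).
draw_spatial_field <- function(chol_cov, n_fields) {
  n <- nrow(chol_cov)
  t(chol_cov) %*% matrix(stats::rnorm(n * n_fields), n, n_fields)
}

#' Generate a synthetic dataset with known ground truth
#'
#' Builds donor bundles, a mirror-symmetric volumetric and surface atlas, a
#' regional phenotype, coordinate-correction and probe-reannotation tables,
#' and the ground truth behind them. If `path` is given, everything is also
#' written to disk in the formats consumed by [load_donors()], [load_atlas()]
#' and friends, plus a `ground_truth/` directory.
#'
#' @param params A [simulation_params()] object.
#' @param path Optional output directory.
#' @return List with elements `bundles` (named list of [donor_bundle()]),
#'   `atlas` (volumetric), `surface_atlas`, `phenotype` (data frame
#'   region_id, value), `correction_table`, `reannotation`, `ground_truth`
#'   (list: `true_regional_expression` as an [expression_matrix()],
#'   `module_labels`, `phenotype`, `region_centroids`), and `params`.
#' @export
simulate_dataset <- function(params, path = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(params$seed)
  k <- SIM_CONST

  ## --- regions: mirror-symmetric centroids --------------------------------
  n_half <- params$n_regions %/% 2L
  left <- matrix(NA_real_, n_half, 3)
  placed <- 0L
  while (placed < n_half) {
    cand <- c(-stats::runif(1, k$box_x[1], k$box_x[2]),
              stats::runif(1, k$box_y[1], k$box_y[2]),
              stats::runif(1, k$box_z[1], k$box_z[2]))
    ok <- placed == 0L ||
      min(sqrt(colSums((t(left[seq_len(placed), , drop = FALSE]) -
                          cand)^2))) >= k$min_separation
    if (ok) {
      placed <- placed + 1L
      left[placed, ] <- cand
    }
  }
  right <- left
  right[, 1] <- -right[, 1]
  centroids <- rbind(left, right)
  region_ids <- seq_len(params$n_regions)
  acronyms <- sprintf("A%02d", rep(seq_len(n_half), 2L))
  hemis <- rep(c("L", "R"), each = n_half)
  regions <- data.frame(region_id = region_ids,
                        label = paste0(acronyms, "-", tolower(hemis)),
                        hemisphere = hemis,
                        structure_class = "cortex")

  ## --- latent regional signal --------------------------------------------
  # Spatial covariance is a mixture of two exponential kernels: one decaying
  # with true 3-D distance (distance-dependent transcriptional similarity)
  # and one decaying with midline-folded (|x|, y, z) distance, which makes
  # homologous left/right regions strongly correlated -- the near-absence of
  # expression lateralization that motivates sample mirroring. A small iid
  # term keeps the hemispheres from being exactly identical.
  folded <- centroids
  folded[, 1] <- abs(folded[, 1])
  sw <- k$symmetry_weight
  D <- as.matrix(stats::dist(centroids))
  cov <- sw * exp(-as.matrix(stats::dist(folded)) / params$decay_length) +
    (1 - sw) * exp(-D / params$decay_length)
  ch <- chol(cov + diag(1e-8, nrow(cov)))
  genes <- sprintf("GENE%04d", seq_len(params$n_genes))
  module_labels <- rep(seq_len(params$n_modules),
                       length.out = params$n_genes)
  M <- draw_spatial_field(ch, params$n_modules)
  F_g <- draw_spatial_field(ch, params$n_genes)
  P <- draw_spatial_field(ch, 1L)    # global expression gradient
  ell <- stats::rnorm(params$n_genes, 0, k$gradient_loading_sd)
  b_g <- stats::rnorm(params$n_genes, 0, k$gene_baseline_sd)
  s_g <- exp(stats::rnorm(params$n_genes, 0, k$gene_amplitude_sdlog))
  w <- k$module_weight
  # Per-gene amplitude scales the module/idiosyncratic signal only; the
  # global gradient enters with loadings independent of amplitude. Genes
  # with a large raw dynamic range are therefore not more gradient-rich --
  # without gene normalization, analyses become driven by a small subset
  # of high-amplitude genes whose patterns are idiosyncratic.
  G <- sqrt(w) * M[, module_labels, drop = FALSE] + sqrt(1 - w) * F_g
  G <- G + matrix(stats::rnorm(length(G), 0, k$asymmetry_sd), nrow(G))
  G <- sweep(G, 2, s_g, `*`)
  G <- G + P %*% t(ell)
  G <- sweep(G, 2, k$baseline_mean + b_g, `+`)
  dimnames(G) <- list(as.character(region_ids), genes)

  ## --- phenotype: affine in PC1 of the true regional expression -----------
  # columns are standardized first so the phenotype tracks the dominant
  # spatial expression gradient rather than the units of high-amplitude
  # genes (mirroring how imaging phenotypes are compared against
  # normalized expression)
  standardized <- scale(G)
  sv <- svd(standardized)
  pc1 <- sv$u[, 1] * sv$d[1]
  phenotype_values <- pc1 +
    stats::rnorm(params$n_regions, 0, k$phenotype_noise_frac * stats::sd(pc1))
  phenotype <- data.frame(region_id = region_ids, value = phenotype_values)

  ## --- volumetric atlas: nearest same-side centroid within a radius -------
  ax <- seq(-k$grid_half, k$grid_half, by = k$voxel_size)
  dims <- rep(length(ax), 3L)
  affine <- rbind(cbind(diag(k$voxel_size, 3), -k$grid_half), c(0, 0, 0, 1))
  vox_mm <- as.matrix(expand.grid(x = ax, y = ax, z = ax,
                                  KEEP.OUT.ATTRS = FALSE))
  labels_flat <- integer(nrow(vox_mm))
  for (side in c("L", "R")) {
    side_regions <- which(hemis == side)
    sel <- if (side == "L") vox_mm[, 1] < 0 else vox_mm[, 1] > 0
    if (!any(sel)) next
    dmat <- outer_dist(vox_mm[sel, , drop = FALSE],
                       centroids[side_regions, , drop = FALSE])
    nearest <- max.col(-dmat, ties.method = "first")
    dmin <- dmat[cbind(seq_len(nrow(dmat)), nearest)]
    lab <- ifelse(dmin <= k$region_radius, side_regions[nearest], 0L)
    labels_flat[sel] <- lab
  }
  # expand.grid varies x fastest: matches array(dim = dims) linear order
  labels <- array(as.integer(labels_flat), dim = dims)
  atlas <- atlas_volume(labels, affine, regions)

  ## --- surface atlas: mirrored jittered vertex clouds ---------------------
  vl <- do.call(rbind, lapply(seq_len(n_half), function(i) {
    jit <- matrix(stats::runif(3 * k$vertices_per_region, -k$vertex_jitter,
                               k$vertex_jitter), ncol = 3)
    sweep(jit, 2, left[i, ], `+`)
  }))
  labs_l <- rep(seq_len(n_half), each = k$vertices_per_region)
  vr <- vl
  vr[, 1] <- -vr[, 1]
  labs_r <- labs_l + n_half
  surface_atlas <- atlas_surface(vl, labs_l, vr, labs_r, regions)

  ## --- probes --------------------------------------------------------------
  ppg <- params$probes_per_gene_range
  n_probes_per_gene <- if (ppg[1] == ppg[2]) {
    rep(ppg[1], params$n_genes)
  } else {
    sample(seq(ppg[1], ppg[2]), params$n_genes, replace = TRUE)
  }
  probe_gene <- rep(seq_len(params$n_genes), n_probes_per_gene)
  n_probes <- length(probe_gene)
  probes <- data.frame(probe_id = 1000L + seq_len(n_probes),
                       probe_name = sprintf("probe_%05d", seq_len(n_probes)),
                       gene_symbol = genes[probe_gene],
                       entrez_id = probe_gene)
  probe_bias <- stats::rnorm(n_probes, 0, params$probe_bias_sd)
  # Above-background failures are probe-biased: a background_fail_rate
  # fraction of probes are unreliable and fail in most samples (so the
  # 25%/50% intensity filters actually discriminate), the rest fail rarely.
  unreliable <- stats::runif(n_probes) < params$background_fail_rate
  probe_fail_rate <- ifelse(unreliable,
                            stats::runif(n_probes, 0.5, 0.95),
                            stats::runif(n_probes, 0,
                                         min(params$background_fail_rate,
                                             0.99)))
  probe_noise_mult <- 1 + 2 * probe_fail_rate  # failing probes are noisier

  ## --- donors --------------------------------------------------------------
  donor_ids <- sprintf("donor%02d", seq_len(params$n_donors))
  # Between-donor offsets have two parts: a shared batch axis -- one
  # gene-loading profile (heavy-tailed across genes, independent of spatial
  # signal amplitude) expressed by every donor with donor-specific severity,
  # emulating global post-mortem batch differences -- plus iid per-donor
  # per-gene residuals at half the magnitude.
  u_g <- sample(c(-1, 1), params$n_genes, replace = TRUE) *
    exp(stats::rnorm(params$n_genes, 0, k$offset_heterogeneity_sdlog))
  delta_d <- stats::rnorm(params$n_donors, 0, params$donor_offset_sd)
  donor_offset <- delta_d %*% t(u_g) +
    0.5 * params$donor_offset_sd *
    matrix(stats::rnorm(params$n_donors * params$n_genes),
           params$n_donors, params$n_genes)
  donor_scale <- matrix(pmax(stats::rnorm(params$n_donors * params$n_genes,
                                          1, params$donor_scale_sd), 0.1),
                        params$n_donors, params$n_genes)
  rna_genes <- genes[seq_len(round(k$rnaseq_coverage * params$n_genes))]
  bundles <- vector("list", params$n_donors)
  correction_rows <- list()
  for (d in seq_len(params$n_donors)) {
    bilateral <- d <= params$n_bilateral_donors
    allowed <- if (bilateral) region_ids else region_ids[hemis == "L"]
    n_s <- params$n_samples_per_donor
    if (d == 1L) {
      # the first donor cycles through every region, guaranteeing that
      # each region is sampled by at least one donor
      reg <- sample(rep(allowed, length.out = n_s))
    } else {
      # remaining donors sample only a subset of regions, unevenly
      n_cov <- max(3L, round(k$donor_coverage_frac * length(allowed)))
      covered <- sort(sample(allowed, n_cov))
      wts <- exp(stats::rnorm(n_cov, 0, k$donor_coverage_sdlog))
      reg <- sample(covered, n_s, replace = TRUE, prob = wts)
    }
    true_pos <- centroids[reg, , drop = FALSE] +
      matrix(stats::rnorm(3 * n_s, 0, k$sample_jitter_sd), ncol = 3)
    # keep samples on their hemisphere's side of the midline
    sgn <- sign(centroids[reg, 1])
    true_pos[, 1] <- sgn * pmax(abs(true_pos[, 1]), 0.5)
    out_idx <- integer(0)
    if (d == 1L && params$n_outlier_samples > 0L) {
      out_idx <- seq(n_s - params$n_outlier_samples + 1L, n_s)
      true_pos[out_idx, ] <- matrix(rep(k$outlier_position,
                                        each = length(out_idx)), ncol = 3)
    }
    mni <- true_pos + matrix(stats::rnorm(3 * n_s, 0, k$coord_error_sd),
                             ncol = 3)
    mni[, 1] <- sign(true_pos[, 1]) * pmax(abs(mni[, 1]), 0.5)
    hemi_s <- ifelse(true_pos[, 1] < 0, "L", "R")
    acro_s <- acronyms[reg]
    acro_s[out_idx] <- "OUT"
    well_ids <- d * 10000L + seq_len(n_s)
    samp <- data.frame(well_id = well_ids,
                       structure_acronym = acro_s,
                       slab_type = "cx",
                       hemisphere = hemi_s,
                       mni_x = mni[, 1], mni_y = mni[, 2], mni_z = mni[, 3],
                       structure_class = "cortex")
    # expression: scale * G + offset + probe bias + probe-scaled noise
    g_sample <- t(G[reg, , drop = FALSE])            # gene x sample
    sig <- donor_scale[d, ] * g_sample + donor_offset[d, ]
    expr <- sig[probe_gene, , drop = FALSE] + probe_bias
    noise <- matrix(stats::rnorm(n_probes * n_s), n_probes, n_s) *
      (params$noise_sd * probe_noise_mult)
    expr <- expr + noise
    pacall <- matrix(1L, n_probes, n_s)
    if (params$background_fail_rate > 0) {
      fails <- matrix(stats::runif(n_probes * n_s), n_probes, n_s) <
        probe_fail_rate
      pacall[fails] <- 0L
    }
    rnaseq <- NULL
    if (bilateral) {
      base <- 2^(t(g_sample[match(rna_genes, genes), , drop = FALSE]) / 2)
      lognoise <- exp(matrix(stats::rnorm(length(base), 0,
                                          k$rnaseq_noise_sd), nrow(base)))
      rnaseq <- t(base * lognoise)
      rownames(rnaseq) <- rna_genes
    }
    bundles[[d]] <- donor_bundle(donor_ids[d], expr, pacall, probes, samp,
                                 rnaseq)
    correction_rows[[d]] <- data.frame(well_id = well_ids,
                                       donor_id = donor_ids[d],
                                       x = true_pos[, 1], y = true_pos[, 2],
                                       z = true_pos[, 3])
  }
  names(bundles) <- donor_ids
  correction_table <- do.call(rbind, correction_rows)

  ## --- reannotation table: identity except every k-th probe loses its gene
  reann <- probes[, c("probe_name", "gene_symbol", "entrez_id")]
  drop <- seq_len(n_probes) %% k$reannotation_drop_every == 0L
  reann$gene_symbol[drop] <- NA_character_
  reann$entrez_id[drop] <- NA_integer_

  truth <- list(
    true_regional_expression = expression_matrix(G, region_ids, genes),
    module_labels = data.frame(gene_symbol = genes,
                               module_id = module_labels),
    phenotype = phenotype,
    region_centroids = data.frame(region_id = region_ids,
                                  x = centroids[, 1], y = centroids[, 2],
                                  z = centroids[, 3]))

  result <- list(bundles = bundles, atlas = atlas,
                 surface_atlas = surface_atlas, phenotype = phenotype,
                 correction_table = correction_table, reannotation = reann,
                 ground_truth = truth, params = params)

  if (!is.null(path)) {
    write_simulation(result, path)
    result$path <- path
  }
  result
}

# Pairwise Euclidean distances between the rows of two matrices.
outer_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# Write every component of a simulation to disk in the package's dialects.
write_simulation <- function(sim, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (b in sim$bundles) {
    write_donor(b, file.path(path, "donors", b$donor_id))
  }
  write_atlas(sim$atlas, file.path(path, "atlas"))
  # surface tables live alongside the volume in the same atlas directory
  for (h in c("L", "R")) {
    hemi <- sim$surface_atlas$hemispheres[[h]]
    df <- data.frame(x = hemi$coords[, 1], y = hemi$coords[, 2],
                     z = hemi$coords[, 3], label = hemi$labels)
    mg_write_table(df, file.path(path, "atlas",
                                 sprintf("surface_%s.csv", h)))
  }
  mg_write_table(sim$correction_table,
                 file.path(path, "corrected_coordinates.csv"))
  reann <- sim$reannotation
  reann$gene_symbol[is.na(reann$gene_symbol)] <- ""
  utils::write.table(reann, file.path(path, "reannotation.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE, na = "")
  gt_dir <- file.path(path, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  write_expression(sim$ground_truth$true_regional_expression,
                   file.path(gt_dir, "expression.tsv"), digits = 10L)
  mg_write_table(sim$ground_truth$module_labels,
                 file.path(gt_dir, "modules.csv"))
  mg_write_table(sim$ground_truth$phenotype,
                 file.path(gt_dir, "phenotype.csv"))
  mg_write_table(sim$ground_truth$region_centroids,
                 file.path(gt_dir, "centroids.csv"))
  invisible(path)
}

#' Read a phenotype table
#' @param path CSV with columns `region_id, value`.
#' @return Data frame.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) mg_file_missing(sprintf("no such file: %s", path))
  utils::read.csv(path)
}

#' Read a gene-module label table
#' @param path CSV with columns `gene_symbol, module_id`.
#' @return Data frame.
#' @export
read_modules <- function(path) {
  if (!file.exists(path)) mg_file_missing(sprintf("no such file: %s", path))
  utils::read.csv(path)
}
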