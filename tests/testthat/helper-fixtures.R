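# Shared fixtures, built in code. Small simulations are cached per test run
# so several test files can reuse the same dataset without regenerating it.

small_params <- function(...) {
  simulation_params(n_donors = 4L, n_bilateral_donors = 2L, n_genes = 60L,
                    probes_per_gene_range = c(1L, 3L),
                    n_samples_per_donor = 60L, n_regions = 16L,
                    n_modules = 4L, seed = 101L, ...)
}

# Noise-free parameters: one probe per gene, no batch effects, no failures;
# the pipeline should reconstruct the truth exactly.
noisefree_params <- function(...) {
  simulation_params(n_donors = 3L, n_bilateral_donors = 3L, n_genes = 30L,
                    probes_per_gene_range = c(1L, 1L),
                    n_samples_per_donor = 48L, n_regions = 12L,
                    n_modules = 3L, donor_offset_sd = 0,
                    donor_scale_sd = 0, probe_bias_sd = 0, noise_sd = 0,
                    background_fail_rate = 0, n_outlier_samples = 0L,
                    seed = 202L, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, params) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- simulate_dataset(params)
  }
  .fixture_cache[[name]]
}

small_sim <- function() cached_sim("small", small_params())
noisefree_sim <- function() cached_sim("noisefree", noisefree_params())

# A tiny hand-built volumetric atlas: labeled voxels given as a data frame
# i, j, k, label (0-based indices).
tiny_volume_atlas <- function(voxels, dims = c(10L, 10L, 10L),
                              affine = diag(4), regions = NULL) {
  labels <- array(0L, dim = dims)
  labels[as.matrix(voxels[, c("i", "j", "k")]) + 1L] <-
    as.integer(voxels$label)
  if (is.null(regions)) {
    ids <- sort(unique(voxels$label))
    regions <- data.frame(region_id = ids, label = paste0("R", ids),
                          hemisphere = NA_character_,
                          structure_class = NA_character_)
  }
  atlas_volume(labels, affine, regions)
}

# A minimal donor bundle wrapping explicit matrices.
tiny_bundle <- function(donor_id, expression, gene_per_probe = NULL,
                        pacall = NULL, samples = NULL, rnaseq = NULL,
                        acronyms = NULL) {
  n_p <- nrow(expression)
  n_s <- ncol(expression)
  if (is.null(pacall)) pacall <- matrix(1L, n_p, n_s)
  if (is.null(gene_per_probe)) gene_per_probe <- paste0("G", seq_len(n_p))
  probes <- data.frame(probe_id = seq_len(n_p),
                       probe_name = paste0("p", seq_len(n_p)),
                       gene_symbol = gene_per_probe,
                       entrez_id = ifelse(is.na(gene_per_probe), NA_integer_,
                                          as.integer(factor(gene_per_probe))))
  if (is.null(samples)) {
    samples <- data.frame(well_id = seq_len(n_s),
                          structure_acronym = acronyms %||%
                            paste0("S", seq_len(n_s)),
                          slab_type = "cx", hemisphere = "L",
                          mni_x = -seq_len(n_s), mni_y = 0, mni_z = 0,
                          structure_class = "cortex")
  }
  donor_bundle(donor_id, expression, pacall, probes, samples, rnaseq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
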