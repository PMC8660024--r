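# Configuration validation, aggregation, missing-region handling, and the
# end-to-end orchestrator.

test_that("configuration validation rejects unknown values and coerces donor mode", {
  cfg <- pipeline_config()
  expect_s3_class(cfg, "pipeline_config")
  expect_error(pipeline_config(metric = "mode"),
               class = "mg_configuration_error")
  expect_error(pipeline_config(intensity_threshold = 1.2),
               class = "mg_configuration_error")
  expect_error(pipeline_config(tolerance = -1),
               class = "mg_configuration_error")
  expect_error(pipeline_config(atlas_type = "individualized"),
               class = "mg_configuration_error")
  # donor mode is redundant for donor-independent probe methods
  cfg2 <- pipeline_config(probe_method = "average", donor_mode = "common")
  expect_identical(cfg2$donor_mode, "aggregate")
  # the string "disabled" and NULL both disable thresholds
  cfg3 <- pipeline_config(intensity_threshold = "disabled")
  expect_null(cfg3$intensity_threshold)
})

test_that("config files round-trip and unknown keys are rejected", {
  cfg <- pipeline_config(mirror = "bidirectional", gene_norm = "zscore",
                         intensity_threshold = NULL, tolerance = 1)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_pipeline_config(cfg, path)
  back <- read_pipeline_config(path)
  expect_equal(back, cfg)
  writeLines(c(readLines(path), "frobnicate: yes"), path)
  expect_error(read_pipeline_config(path),
               class = "mg_configuration_error")
})

test_that("aggregation matches hand-computed donor weighting", {
  # region 1: donor1 samples {1,3}, donor2 {5}
  mats <- list(d1 = matrix(c(1, 3), 1, 2, dimnames = list("G1", c("1", "2"))),
               d2 = matrix(5, 1, 1, dimnames = list("G1", "3")))
  assignments <- list(
    d1 = data.frame(well_id = 1:2, donor_id = "d1", region_id = 1L,
                    distance_mm = 0),
    d2 = data.frame(well_id = 3, donor_id = "d2", region_id = 1L,
                    distance_mm = 0))
  df <- aggregate_expression(mats, assignments, region_ids = 1:2,
                             combine = "donors_first", metric = "mean")
  expect_equal(df$values["1", "G1"], 3.5)   # mean(mean(1,3), 5)
  pooled <- aggregate_expression(mats, assignments, region_ids = 1:2,
                                 combine = "pooled", metric = "mean")
  expect_equal(pooled$values["1", "G1"], 3)  # mean(1,3,5)
  expect_true(pooled$missing_mask[2])        # region 2 got nothing
  med <- aggregate_expression(
    list(d1 = matrix(c(1, 2, 100), 1, 3,
                     dimnames = list("G1", c("1", "2", "3")))),
    list(d1 = data.frame(well_id = 1:3, donor_id = "d1", region_id = 1L,
                         distance_mm = 0)),
    region_ids = 1L, combine = "pooled", metric = "median")
  expect_equal(med$values["1", "G1"], 2)
  # nothing assigned anywhere is an empty result
  none <- list(d1 = data.frame(well_id = 1:2, donor_id = "d1",
                               region_id = NA_integer_, distance_mm = NA))
  expect_error(aggregate_expression(mats["d1"], none, 1:2,
                                    "pooled", "mean"),
               class = "mg_empty_result_error")
})

test_that("aggregation agrees with a brute-force oracle on random data", {
  set.seed(11)
  for (metric in c("mean", "median")) {
    n_g <- 4
    mats <- list()
    assignments <- list()
    for (d in 1:3) {
      n_s <- sample(3:7, 1)
      m <- matrix(rnorm(n_g * n_s), n_g, n_s,
                  dimnames = list(paste0("G", 1:n_g), seq_len(n_s)))
      mats[[paste0("d", d)]] <- m
      assignments[[paste0("d", d)]] <-
        data.frame(well_id = seq_len(n_s), donor_id = paste0("d", d),
                   region_id = sample(c(1L, 2L, NA), n_s, TRUE),
                   distance_mm = 0)
    }
    f <- match.fun(metric)
    for (combine in c("donors_first", "pooled")) {
      em <- aggregate_expression(mats, assignments, 1:2, combine, metric)
      for (r in 1:2) for (g in 1:n_g) {
        per_donor <- lapply(names(mats), function(d) {
          cols <- which(assignments[[d]]$region_id %in% r)
          mats[[d]][g, cols]
        })
        per_donor <- per_donor[lengths(per_donor) > 0]
        expected <- if (!length(per_donor)) NA_real_ else if
          (combine == "pooled") f(unlist(per_donor)) else
            f(vapply(per_donor, f, numeric(1)))
        expect_equal(em$values[as.character(r), g], unname(expected),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("missing regions are filled from each donor's nearest sample", {
  mats <- list(d1 = matrix(c(1, 5), 1, 2,
                           dimnames = list("G1", c("1", "2"))))
  samples <- data.frame(well_id = 1:2, structure_acronym = "S",
                        slab_type = "cx", hemisphere = "L",
                        mni_x = c(-1, -20), mni_y = 0, mni_z = 0,
                        structure_class = "cortex")
  donor_data <- list(d1 = list(expression = mats$d1, samples = samples))
  centroids <- data.frame(region_id = 1:2, x = c(-1, -19), y = 0, z = 0)
  vals <- matrix(c(1, NA), 2, 1, dimnames = list(1:2, "G1"))
  em <- expression_matrix(vals, 1:2, "G1")
  expect_true(em$missing_mask[2])
  # omit leaves the matrix untouched
  expect_identical(fill_missing(em, donor_data, centroids, "omit"), em)
  filled <- fill_missing(em, donor_data, centroids, "nearest", "mean")
  expect_false(any(filled$missing_mask))
  expect_equal(filled$values["2", "G1"], 5)  # sample 2 is nearest
  expect_equal(filled$values["1", "G1"], 1)  # untouched row
})

test_that("the orchestrator is deterministic and invariant to donor order", {
  sim <- small_sim()
  cfg <- pipeline_config(gene_norm = "zscore", mirror = "bidirectional",
                         probe_method = "max_intensity", tolerance = 1)
  em1 <- run_pipeline(cfg, sim$bundles, sim$atlas,
                      correction_table = sim$correction_table,
                      reannotation = sim$reannotation)
  em2 <- run_pipeline(cfg, sim$bundles, sim$atlas,
                      correction_table = sim$correction_table,
                      reannotation = sim$reannotation)
  expect_equal(em1$values, em2$values, tolerance = 1e-15)
  em3 <- run_pipeline(cfg, rev(sim$bundles), sim$atlas,
                      correction_table = sim$correction_table,
                      reannotation = sim$reannotation)
  expect_equal(em3$values, em1$values, tolerance = 1e-12)
})

test_that("pipeline errors name their stage", {
  sim <- noisefree_sim()  # bilateral donors only, but no RNAseq needed here
  bundles <- lapply(sim$bundles, function(b) { b$rnaseq <- NULL; b })
  cfg <- pipeline_config(probe_method = "rnaseq", reannotate = FALSE)
  err <- tryCatch(run_pipeline(cfg, bundles, sim$atlas,
                               correction_table = sim$correction_table),
                  error = identity)
  expect_s3_class(err, "mg_configuration_error")
  expect_match(conditionMessage(err), "probe_selection")
  # requesting reannotation without a mapping fails in that stage
  err2 <- tryCatch(run_pipeline(pipeline_config(), sim$bundles, sim$atlas,
                                correction_table = sim$correction_table),
                   error = identity)
  expect_match(conditionMessage(err2), "reannotation")
  # atlas space mismatch
  expect_error(run_pipeline(pipeline_config(atlas_space = "surface"),
                            sim$bundles, sim$atlas,
                            correction_table = sim$correction_table),
               class = "mg_configuration_error")
})

test_that("metric choice changes values but not the matrix contract", {
  sim <- small_sim()
  base <- list(reannotate = FALSE, probe_method = "max_intensity")
  em_mean <- run_pipeline(do.call(pipeline_config, c(base, metric = "mean")),
                          sim$bundles, sim$atlas,
                          correction_table = sim$correction_table)
  em_med <- run_pipeline(do.call(pipeline_config, c(base, metric = "median")),
                         sim$bundles, sim$atlas,
                         correction_table = sim$correction_table)
  expect_identical(em_mean$region_ids, em_med$region_ids)
  expect_identical(em_mean$gene_symbols, em_med$gene_symbols)
  expect_gt(max(abs(em_mean$values - em_med$values), na.rm = TRUE), 0)
})

test_that("mirrored-only data fills homologous regions symmetrically", {
  sim <- noisefree_sim()
  # keep only left-hemisphere samples, then mirror bidirectionally: right
  # regions are built purely from mirrored copies of their homologs
  bundles <- lapply(sim$bundles, function(b) {
    keep <- b$samples$hemisphere == "L"
    donor_bundle(b$donor_id, b$expression[, keep], b$pacall[, keep],
                 b$probes, b$samples[keep, ], NULL)
  })
  cfg <- pipeline_config(mirror = "bidirectional", reannotate = FALSE,
                         probe_method = "max_intensity",
                         sample_norm = "none", gene_norm = "none",
                         intensity_threshold = NULL)
  em <- run_pipeline(cfg, bundles, sim$atlas,
                     correction_table = sim$correction_table)
  n_half <- length(em$region_ids) / 2
  left_rows <- em$values[seq_len(n_half), , drop = FALSE]
  right_rows <- em$values[n_half + seq_len(n_half), , drop = FALSE]
  # atlas regions are mirror-symmetric and the expression is noise-free, so
  # homologous rows agree exactly
  expect_equal(unname(right_rows), unname(left_rows), tolerance = 1e-10)
})
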