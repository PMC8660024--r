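# Reannotation, intensity filtering, and probe-to-gene collapse.

test_that("reannotation replaces, nulls, or preserves probe annotations", {
  probes <- data.frame(probe_id = 1:3,
                       probe_name = c("P1", "P2", "P3"),
                       gene_symbol = c("GENE1", "GENE2", "GENE3"),
                       entrez_id = 1:3)
  # null mapping is the identity
  expect_identical(reannotate_probes(probes, NULL), probes)
  # remap P1, omit P2 (-> null gene), keep P3
  mapping <- data.frame(probe_name = c("P1", "P3"),
                        gene_symbol = c("GENE9", "GENE3"),
                        entrez_id = c(9L, 3L))
  out <- reannotate_probes(probes, mapping)
  expect_identical(out$gene_symbol, c("GENE9", NA, "GENE3"))
  expect_identical(out$entrez_id, c(9L, NA, 3L))
  # duplicate probe_name in the mapping is rejected
  dup <- rbind(mapping, mapping[1, ])
  expect_error(reannotate_probes(probes, dup), class = "mg_format_error")
})

test_that("intensity filtering applies a strict pooled threshold", {
  # probe 1 flagged in 40% of pooled samples, probe 2 in exactly 50%,
  # probe 3 in 100%
  pa1 <- rbind(c(1, 1, 0, 0, 0), c(1, 1, 1, 0, 0), c(1, 1, 1, 1, 1))
  pa2 <- rbind(c(1, 1, 0, 0, 0), c(1, 1, 0, 0, 0), c(1, 1, 1, 1, 1))
  mk <- function(id, pa) tiny_bundle(id, matrix(rnorm(15), 3, 5), pacall = pa)
  bundles <- list(mk("d1", pa1), mk("d2", pa2))
  expect_identical(filter_probes_by_intensity(bundles, 0.25), c(1L, 2L, 3L))
  expect_identical(filter_probes_by_intensity(bundles, 0.5), 3L)
  # disabled keeps everything, even never-flagged probes
  pa_zero <- matrix(0L, 3, 5)
  bz <- list(mk("d1", pa_zero))
  expect_identical(filter_probes_by_intensity(bz, NULL), c(1L, 2L, 3L))
  expect_identical(filter_probes_by_intensity(bz, 0), integer(0))
  expect_error(filter_probes_by_intensity(bundles, 1),
               class = "mg_parameter_error")
})

test_that("filtering is monotone in the threshold", {
  sim <- small_sim()
  k_dis <- filter_probes_by_intensity(sim$bundles, NULL)
  k25 <- filter_probes_by_intensity(sim$bundles, 0.25)
  k50 <- filter_probes_by_intensity(sim$bundles, 0.5)
  expect_true(all(k50 %in% k25))
  expect_true(all(k25 %in% k_dis))
  expect_lt(length(k50), length(k_dis))
})

test_that("max_intensity picks the brightest probe; average matches a mean oracle", {
  e <- rbind(rep(5, 4), rep(7, 4), c(1, 2, 3, 4))
  b <- tiny_bundle("d1", e, gene_per_probe = c("G1", "G1", "G2"))
  sel <- select_probes(list(b), probe_selection_spec("max_intensity"))
  expect_identical(sel$report$probe[sel$report$gene_symbol == "G1"], "2")
  expect_equal(sel$matrices$d1["G1", ], e[2, ], ignore_attr = TRUE)
  avg <- select_probes(list(b), probe_selection_spec("average"))
  expect_equal(avg$matrices$d1["G1", ], colMeans(e[1:2, ]),
               ignore_attr = TRUE)
  expect_equal(avg$matrices$d1["G2", ], e[3, ], ignore_attr = TRUE)
})

test_that("differential stability prefers the probe consistent across donors", {
  # 2 donors, 3 shared structures; probe A reproduces the profile (1,2,3)
  # in both donors (Spearman 1), probe B reverses it (Spearman -1)
  eA1 <- c(1, 2, 3); eA2 <- c(1, 2, 3)
  eB1 <- c(1, 2, 3); eB2 <- c(3, 2, 1)
  acro <- c("S1", "S2", "S3")
  b1 <- tiny_bundle("d1", rbind(eA1, eB1), gene_per_probe = c("G1", "G1"),
                    acronyms = acro)
  b2 <- tiny_bundle("d2", rbind(eA2, eB2), gene_per_probe = c("G1", "G1"),
                    acronyms = acro)
  sel <- select_probes(list(b1, b2), probe_selection_spec("diff_stability"))
  expect_identical(sel$report$probe, "1")
  # invariant to donor order
  sel2 <- select_probes(list(b2, b1), probe_selection_spec("diff_stability"))
  expect_identical(sel2$report$probe, "1")
})

test_that("correlation-based selection falls back as specified", {
  set.seed(1)
  base <- rnorm(10)
  # three probes: two track each other, one is inverted; highest mean
  # pairwise correlation wins
  e <- rbind(base, base + rnorm(10, 0, 0.01), -base,
             c(rep(0, 9), 1), rep(c(0, 1), 5))
  b <- tiny_bundle("d1", e, gene_per_probe = c("G1", "G1", "G1", "G2", "G2"))
  sel <- select_probes(list(b), probe_selection_spec("corr_intensity"))
  expect_true(sel$report$probe[sel$report$gene_symbol == "G1"] %in%
                c("1", "2"))
  # two-probe gene falls back to max intensity
  expect_identical(sel$report$probe[sel$report$gene_symbol == "G2"], "5")
  # ... or to max variance under corr_variance
  selv <- select_probes(list(b), probe_selection_spec("corr_variance"))
  expect_identical(selv$report$probe[selv$report$gene_symbol == "G2"], "5")
})

test_that("rnaseq selection follows RNAseq fidelity and drops absent genes", {
  set.seed(2)
  g1 <- rnorm(12)
  e <- rbind(g1 + rnorm(12, 0, 0.05),   # tracks RNAseq
             rnorm(12),                 # unrelated
             rnorm(12))                 # gene absent from RNAseq
  b <- tiny_bundle("d1", e, gene_per_probe = c("G1", "G1", "G2"),
                   rnaseq = matrix(exp(g1), 1, 12,
                                   dimnames = list("G1", NULL)))
  sel <- select_probes(list(b), probe_selection_spec("rnaseq"))
  expect_identical(sel$report$gene_symbol, "G1")
  expect_identical(sel$report$probe, "1")
  # no RNAseq anywhere is a configuration error
  b2 <- tiny_bundle("d1", e, gene_per_probe = c("G1", "G1", "G2"))
  expect_error(select_probes(list(b2), probe_selection_spec("rnaseq")),
               class = "mg_configuration_error")
})

test_that("donor modes pool, separate, or take the modal probe", {
  # probe 1 brighter in donor 1, probe 2 brighter in donors 2 and 3
  mk <- function(id, v1, v2) {
    tiny_bundle(id, rbind(rep(v1, 4), rep(v2, 4)),
                gene_per_probe = c("G1", "G1"))
  }
  bundles <- list(mk("d1", 8, 1), mk("d2", 1, 5), mk("d3", 1, 5))
  ind <- select_probes(bundles,
                       probe_selection_spec("max_intensity", "independent"))
  probes_by_donor <- ind$report$probe[match(c("d1", "d2", "d3"),
                                            ind$report$donor_id)]
  expect_identical(probes_by_donor, c("1", "2", "2"))
  com <- select_probes(bundles,
                       probe_selection_spec("max_intensity", "common"))
  expect_identical(unique(com$report$probe), "2")  # modal choice
  agg <- select_probes(bundles,
                       probe_selection_spec("max_intensity", "aggregate"))
  # pooled means: probe 1 = (8+1+1)/3, probe 2 = (1+5+5)/3
  expect_identical(unique(agg$report$probe), "2")
  # donor-independent methods silently coerce the donor mode
  spec <- probe_selection_spec("average", "independent")
  expect_identical(spec$donor_mode, "aggregate")
})

test_that("single-probe genes are identical under every method", {
  sim <- cached_sim("single_probe", simulation_params(
    n_donors = 3L, n_bilateral_donors = 2L, n_genes = 25L,
    probes_per_gene_range = c(1L, 1L), n_samples_per_donor = 40L,
    n_regions = 10L, n_modules = 3L, seed = 77L))
  kept <- filter_probes_by_intensity(sim$bundles, NULL)
  mats <- lapply(c("max_intensity", "corr_intensity", "corr_variance",
                   "diff_stability", "average"), function(m) {
    select_probes(sim$bundles, probe_selection_spec(m), kept)$matrices
  })
  for (i in seq_along(mats)[-1]) {
    expect_equal(mats[[i]], mats[[1]], tolerance = 1e-12)
  }
})

test_that("ties in the selection criterion break to the lowest probe id", {
  e <- rbind(rep(4, 4), rep(4, 4))  # identical mean intensity
  b <- tiny_bundle("d1", e, gene_per_probe = c("G1", "G1"))
  sel <- select_probes(list(b), probe_selection_spec("max_intensity"))
  expect_identical(sel$report$probe, "1")
})
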