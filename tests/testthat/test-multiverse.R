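# Grid declaration, enumeration/counting with redundancy, impact scoring,
# and PCA of estimate tables.

test_that("plain grids enumerate the full product", {
  g <- parameter_grid(list(option_spec("a", list("x", "y"), "binary"),
                           option_spec("b", list(1, 2, 3), "ordinal")))
  enum <- enumerate_grid(g)
  expect_equal(nrow(enum), 6)
  expect_equal(count_grid(g), 6)
  expect_equal(anyDuplicated(enum), 0)
})

test_that("redundancy collapses configurations as declared", {
  # B is redundant under choice x of A: (x,p), (y,p), (y,q) remain
  g <- parameter_grid(
    list(option_spec("A", list("x", "y"), "binary"),
         option_spec("B", list("p", "q"), "binary")),
    list(redundancy_rule("B", "A", "x", "p")))
  enum <- enumerate_grid(g)
  expect_equal(nrow(enum), 3)
  expect_equal(count_grid(g), 3)
  expect_identical(sort(paste(enum$A, enum$B)), c("x p", "y p", "y q"))
})

test_that("count_grid equals enumeration length on randomized rule grids", {
  set.seed(18)
  for (rep in 1:30) {
    n_opt <- sample(2:5, 1)
    options <- lapply(seq_len(n_opt), function(i) {
      k <- sample(2:4, 1)
      option_spec(paste0("o", i), as.list(paste0("c", seq_len(k))),
                  if (k == 2) "binary" else "categorical")
    })
    rules <- list()
    if (runif(1) < 0.7) {
      ij <- sample(n_opt, 2)
      tgt <- options[[ij[1]]]
      cond <- options[[ij[2]]]
      when <- sample(unlist(cond$choices),
                     sample(length(cond$choices) - 1, 1))
      rules <- list(redundancy_rule(tgt$name, cond$name, as.list(when),
                                    tgt$choices[[1]]))
    }
    g <- parameter_grid(options, rules)
    enum <- enumerate_grid(g)
    expect_equal(count_grid(g), nrow(enum))
    expect_equal(anyDuplicated(enum), 0)
  }
})

test_that("the full processing grid counts 746,496 pipelines", {
  g <- default_parameter_grid()
  expect_equal(count_grid(g), 746496)
})

test_that("impact scores reproduce the worked examples", {
  # binary option, two matched pairs: |0.2-0.5| and |0.1-0.1| -> 0.15
  g <- parameter_grid(list(option_spec("a", list("u", "v"), "binary"),
                           option_spec("b", list("p", "q"), "binary")))
  est <- expand.grid(a = c("u", "v"), b = c("p", "q"),
                     stringsAsFactors = FALSE)
  est$cge_rho <- c(0.2, 0.5, 0.1, 0.1)
  imp <- impact_scores(est, g, measures = "cge_rho")
  expect_equal(imp$impact[imp$option == "a"], 0.15)
  # ordinal 3-choice tuple (0.1, 0.2, 0.4): mean(|0.1-0.2|, |0.2-0.4|)
  g_ord <- parameter_grid(list(option_spec("t", list(0, 1, 2), "ordinal")))
  est_ord <- data.frame(t = c("0", "1", "2"),
                        cge_rho = c(0.1, 0.2, 0.4))
  imp_ord <- impact_scores(est_ord, g_ord, measures = "cge_rho")
  expect_equal(imp_ord$impact, 0.15)
  # categorical 3-choice tuple (1, 2, 4): mean(1, 3, 2) = 2
  g_cat <- parameter_grid(list(option_spec("m", list("a", "b", "c"),
                                           "categorical")))
  est_cat <- data.frame(m = c("a", "b", "c"), cge_rho = c(1, 2, 4))
  imp_cat <- impact_scores(est_cat, g_cat, measures = "cge_rho")
  expect_equal(imp_cat$impact, 2)
})

test_that("impact scores shift-invariant, scale-equivariant, zero for null options", {
  g <- parameter_grid(list(option_spec("a", list("u", "v"), "binary"),
                           option_spec("b", list("p", "q", "r"),
                                       "categorical")))
  est <- expand.grid(a = c("u", "v"), b = c("p", "q", "r"),
                     stringsAsFactors = FALSE)
  set.seed(19)
  est$cge_rho <- rnorm(6)
  base <- impact_scores(est, g, measures = "cge_rho")
  est_shift <- est; est_shift$cge_rho <- est$cge_rho + 10
  expect_equal(impact_scores(est_shift, g, measures = "cge_rho")$impact,
               base$impact, tolerance = 1e-12)
  est_scaled <- est; est_scaled$cge_rho <- -3 * est$cge_rho
  expect_equal(impact_scores(est_scaled, g, measures = "cge_rho")$impact,
               3 * base$impact, tolerance = 1e-12)
  # an option whose choices never change the estimate has impact exactly 0
  est_null <- est
  est_null$cge_rho <- rep(c(1, 2, 3), each = 2)  # depends on b only
  imp_null <- impact_scores(est_null, g, measures = "cge_rho")
  expect_identical(imp_null$impact[imp_null$option == "a"], 0)
  # ranks are a permutation per analysis
  expect_setequal(base$rank, 1:2)
  # incomplete factorial tables are rejected
  expect_error(impact_scores(est[-1, ], g, measures = "cge_rho"),
               class = "mg_incomplete_grid_error")
})

test_that("matched pair counts follow the redundancy-collapsed grid", {
  g <- default_parameter_grid()
  for (opt in c("metric", "combine", "norm_matched_only", "missing")) {
    expect_equal(impact_pair_count(g, opt), 373248)
  }
  expect_equal(impact_pair_count(g, "tolerance"), 746496 / 3)
  # donor mode only varies for the three donor-dependent methods
  expect_equal(impact_pair_count(g, "donor_mode"), 3 * 746496 / 12)
  # probe-method tuples exist for each (possibly collapsed) donor-mode cell
  expect_equal(impact_pair_count(g, "probe_method"), 746496 / 12 * 3)
})

test_that("estimate-space PCA matches its contracts", {
  set.seed(20)
  x <- cbind(a = rnorm(50))
  tab <- data.frame(cge_rho = x[, 1], gce_silhouette = x[, 1],
                    rge_rho = x[, 1])
  res <- pca_estimates(tab)
  expect_equal(res$variance_explained[1], 1, tolerance = 1e-12)
  # row order does not change the variance split
  res2 <- pca_estimates(tab[sample(50), ])
  expect_equal(res2$variance_explained, res$variance_explained,
               tolerance = 1e-12)
  # orthogonal noise columns split variance roughly evenly
  big <- data.frame(cge_rho = rnorm(4000), gce_silhouette = rnorm(4000),
                    rge_rho = rnorm(4000))
  res3 <- pca_estimates(big)
  expect_true(all(abs(res3$variance_explained - 1 / 3) < 0.05))
  expect_true(res3$variance_explained[1] >= res3$variance_explained[2])
  # PCA leading component against the eigen oracle
  y <- matrix(rnorm(60), 20, 3) %*% diag(c(3, 1, 0.2))
  centered <- scale(y, center = TRUE, scale = FALSE)
  ev1 <- eigen(crossprod(centered))$values[1]
  res4 <- pca_estimates(as.data.frame(`colnames<-`(
    y, c("cge_rho", "gce_silhouette", "rge_rho"))))
  expect_equal(res4$variance_explained[1],
               ev1 / sum(eigen(crossprod(centered))$values),
               tolerance = 1e-12)
  expect_error(pca_estimates(data.frame(cge_rho = rep(1, 5),
                                        gce_silhouette = 1, rge_rho = 1)),
               class = "mg_degenerate_input_error")
})

test_that("a one-config grid reproduces run_pipeline plus the analyses", {
  sim <- small_sim()
  data <- list(bundles = sim$bundles, atlas = sim$atlas,
               surface_atlas = sim$surface_atlas,
               correction_table = sim$correction_table,
               reannotation = sim$reannotation,
               module_labels = sim$ground_truth$module_labels,
               phenotype = sim$ground_truth$phenotype)
  g <- parameter_grid(list(option_spec("metric", list("median"),
                                       "categorical")))
  est <- run_multiverse(g, data)
  expect_equal(nrow(est), 1)
  em <- run_pipeline(pipeline_config(metric = "median"), sim$bundles,
                     sim$atlas, correction_table = sim$correction_table,
                     reannotation = sim$reannotation)
  direct <- analysis_estimates(em, region_centroids(sim$atlas),
                               sim$ground_truth$module_labels,
                               sim$ground_truth$phenotype)
  expect_equal(est$cge_rho, direct$cge_rho, tolerance = 1e-12)
  expect_equal(est$gce_silhouette, direct$gce_silhouette,
               tolerance = 1e-12)
  expect_equal(est$rge_rho, direct$rge_rho, tolerance = 1e-12)
  expect_true(is.na(est$error))
})
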