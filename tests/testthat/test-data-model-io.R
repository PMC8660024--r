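# Domain containers and the on-disk dialects.

test_that("donor write/load round-trips the generator's bundles", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  for (b in sim$bundles) write_donor(b, file.path(dir, b$donor_id))
  loaded <- load_donors(dir)
  expect_identical(names(loaded), names(sim$bundles))
  for (id in names(loaded)) {
    orig <- sim$bundles[[id]]
    got <- loaded[[id]]
    expect_equal(got$expression, orig$expression, tolerance = 1e-12)
    expect_identical(got$pacall, orig$pacall)
    expect_equal(got$probes, orig$probes)
    expect_equal(got$samples, orig$samples, tolerance = 1e-12)
    if (is.null(orig$rnaseq)) {
      expect_null(got$rnaseq)
    } else {
      expect_equal(got$rnaseq, orig$rnaseq, tolerance = 1e-12)
    }
  }
})

test_that("bundle invariants are enforced on construction and load", {
  b <- small_sim()$bundles[[1]]
  # shape mismatch between expression and above-background flags
  expect_error(
    donor_bundle("x", b$expression, b$pacall[, -1], b$probes, b$samples),
    class = "mg_format_error")
  # duplicate well ids
  s2 <- b$samples
  s2$well_id[2] <- s2$well_id[1]
  expect_error(donor_bundle("x", b$expression, b$pacall, b$probes, s2),
               class = "mg_format_error")
  # half-annotated probe (gene_symbol without entrez)
  p2 <- b$probes
  p2$gene_symbol[1] <- NA
  expect_error(donor_bundle("x", b$expression, b$pacall, p2, b$samples),
               class = "mg_format_error")
  # missing file on load
  dir <- withr::local_tempdir()
  write_donor(b, file.path(dir, "d"))
  file.remove(file.path(dir, "d", "PACall.csv"))
  expect_error(load_donor(file.path(dir, "d")), class = "mg_file_missing")
})

test_that("probes with empty gene fields survive the round trip as NA", {
  b <- tiny_bundle("d1", matrix(1:12, 3, 4),
                   gene_per_probe = c("G1", NA, "G2"))
  dir <- withr::local_tempdir()
  write_donor(b, file.path(dir, "d1"))
  got <- load_donor(file.path(dir, "d1"))
  expect_identical(got$probes$gene_symbol, c("G1", NA, "G2"))
  expect_true(is.na(got$probes$entrez_id[2]))
})

test_that("atlas constructors validate labels against metadata", {
  vox <- data.frame(i = c(1, 2), j = c(1, 2), k = c(1, 2), label = c(1, 2))
  atlas <- tiny_volume_atlas(vox)
  expect_s3_class(atlas, "brain_atlas")
  expect_equal(nrow(atlas$regions), 2)
  # label present in the array but absent from metadata
  expect_error(
    tiny_volume_atlas(data.frame(i = 1, j = 1, k = 1, label = 3),
                      regions = data.frame(region_id = 1:2, label = "x",
                                           hemisphere = NA,
                                           structure_class = NA)),
    class = "mg_metadata_error")
  # surface atlases need both hemispheres
  expect_error(
    atlas_surface(NULL, NULL, matrix(0, 1, 3), 1,
                  data.frame(region_id = 1, hemisphere = "R",
                             structure_class = "cortex")),
    class = "mg_format_error")
})

test_that("region centroids agree with a brute-force voxel loop", {
  # single voxel at (2,3,4) with identity affine sits at (2,3,4)
  a1 <- tiny_volume_atlas(data.frame(i = 2, j = 3, k = 4, label = 1))
  expect_equal(unlist(region_centroids(a1)[1, c("x", "y", "z")]),
               c(x = 2, y = 3, z = 4))
  # two voxels average
  a2 <- tiny_volume_atlas(data.frame(i = c(0, 2), j = 0, k = 0, label = 1))
  expect_equal(unlist(region_centroids(a2)[1, c("x", "y", "z")]),
               c(x = 1, y = 0, z = 0))
  # scaling affine (2 mm voxels): voxel (1,1,1) maps to (2,2,2)
  aff <- diag(c(2, 2, 2, 1))
  a3 <- tiny_volume_atlas(data.frame(i = 1, j = 1, k = 1, label = 1),
                          affine = aff)
  expect_equal(unlist(region_centroids(a3)[1, c("x", "y", "z")]),
               c(x = 2, y = 2, z = 2))
  # random atlases against an explicit per-voxel loop
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    vox <- data.frame(i = sample(0:7, n, TRUE), j = sample(0:7, n, TRUE),
                      k = sample(0:7, n, TRUE),
                      label = sample(1:3, n, TRUE))
    vox <- vox[!duplicated(vox[, 1:3]), , drop = FALSE]
    aff <- diag(4)
    aff[1:3, 4] <- runif(3, -5, 5)
    aff[1:3, 1:3] <- diag(runif(3, 0.5, 3))
    atlas <- tiny_volume_atlas(vox, dims = c(8L, 8L, 8L), affine = aff)
    got <- region_centroids(atlas)
    for (lab in sort(unique(vox$label))) {
      rows <- vox[vox$label == lab, , drop = FALSE]
      mm <- t(apply(rows[, 1:3], 1, function(ijk) {
        (aff %*% c(ijk, 1))[1:3]
      }))
      expect_equal(unlist(got[got$region_id == lab, c("x", "y", "z")]),
                   c(x = mean(mm[, 1]), y = mean(mm[, 2]),
                     z = mean(mm[, 3])),
                   tolerance = 1e-12)
    }
  }
})

test_that("translating the affine translates all centroids equally", {
  sim <- small_sim()
  base <- region_centroids(sim$atlas)
  shift <- c(5, -3, 7)
  aff2 <- sim$atlas$affine
  aff2[1:3, 4] <- aff2[1:3, 4] + shift
  moved <- region_centroids(atlas_volume(sim$atlas$labels, aff2,
                                         sim$atlas$regions))
  expect_equal(moved$x, base$x + shift[1], tolerance = 1e-9)
  expect_equal(moved$y, base$y + shift[2], tolerance = 1e-9)
  expect_equal(moved$z, base$z + shift[3], tolerance = 1e-9)
})

test_that("surface centroids are vertex means and atlas IO round-trips", {
  sim <- small_sim()
  surf <- sim$surface_atlas
  cent <- region_centroids(surf)
  lab1 <- surf$hemispheres$L$labels
  r1 <- lab1[1]
  manual <- colMeans(surf$hemispheres$L$coords[lab1 == r1, , drop = FALSE])
  expect_equal(unlist(cent[cent$region_id == r1, c("x", "y", "z")]),
               c(x = manual[1], y = manual[2], z = manual[3]),
               tolerance = 1e-12)
  dir <- withr::local_tempdir()
  write_atlas(sim$atlas, dir)
  write_atlas(surf, dir)  # adds the surface tables alongside
  vol2 <- load_atlas(dir, space = "volume")
  expect_identical(vol2$labels, sim$atlas$labels)
  expect_equal(vol2$affine, sim$atlas$affine, tolerance = 1e-12)
  surf2 <- load_atlas(dir, space = "surface")
  expect_equal(surf2$hemispheres$L$coords, surf$hemispheres$L$coords,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(surf2$hemispheres$R$labels, surf$hemispheres$R$labels)
})

test_that("expression TSV round-trips and rejects duplicate gene columns", {
  set.seed(7)
  vals <- matrix(rnorm(20), 5, 4)
  vals[3, ] <- NA  # one missing region
  em <- expression_matrix(vals, region_ids = 1:5,
                          gene_symbols = paste0("G", 1:4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(em, path)
  got <- read_expression(path)
  expect_equal(got$values, em$values, tolerance = 1e-5)
  expect_identical(got$missing_mask, em$missing_mask)
  expect_identical(got$gene_symbols, em$gene_symbols)
  # one all-NA line in the file
  expect_length(grep("\tNA\tNA\tNA\tNA$", readLines(path)), 1L)
  # duplicate gene header rejected
  lines <- readLines(path)
  lines[1] <- "region_id\tG1\tG1\tG3\tG4"
  writeLines(lines, path)
  expect_error(read_expression(path), class = "mg_format_error")
  # duplicate genes rejected at construction too
  expect_error(expression_matrix(vals, 1:5, c("G1", "G1", "G3", "G4")),
               class = "mg_format_error")
})
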