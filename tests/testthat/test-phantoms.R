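# Synthetic vessel phantom generator.

test_that("a straight tube rasterizes to approximately its cylinder volume", {
  mask <- array(FALSE, c(48, 16, 16))
  pts <- cbind(c(4, 44), c(8, 8), c(8, 8))  # axis-aligned, length 40
  mask <- rasterize_tube(mask, pts, c(3, 3))
  count <- sum(mask)
  expect_lt(abs(count - pi * 9 * 40) / (pi * 9 * 40), 0.10)
})

test_that("an unbranched tube is one 26-connected component", {
  spec <- phantom_spec(extent = 32L, n_branches = 1L, radius_range = c(1.5, 2.5),
                       distractor_count = 0L, seed = 11L)
  ph <- generate_phantom(spec)
  expect_identical(count_components_26(ph$label), 1L)
})

test_that("generation is bit-identical for a repeated seed", {
  spec <- desk_phantom_spec(seed = 7L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$label, b$label)
  spec2 <- desk_phantom_spec(seed = 8L)
  expect_false(identical(generate_phantom(spec2)$label, a$label))
})

test_that("labels are binary and foreground stays sparse", {
  for (sd in 21:24) {
    ph <- generate_phantom(desk_phantom_spec(seed = sd))
    expect_true(all(ph$label %in% c(0L, 1L)))
    f <- mean(ph$label)
    expect_gt(f, 0)
    expect_lt(f, 0.05)
  }
})

test_that("noiseless lumen voxels sit above background by at least one sigma", {
  spec <- phantom_spec(extent = 32L, n_branches = 2L, noise_sd = 0,
                       lumen_sd = 0, background_sd = 0, distractor_count = 0L,
                       seed = 31L)
  ph <- generate_phantom(spec)
  expect_true(all(ph$image[ph$label == 1L] >=
                    spec$background_mean + spec$background_sd))
})

test_that("distance transform maximum inside the label matches the max radius", {
  spec <- phantom_spec(extent = 24L, n_branches = 1L, radius_range = c(2.5, 2.5),
                       taper = 1, curvature = 0, distractor_count = 0L,
                       noise_sd = 0, seed = 41L)
  ph <- generate_phantom(spec)
  fg <- which(ph$label == 1L, arr.ind = TRUE)
  bg <- which(ph$label == 0L, arr.ind = TRUE)
  dt <- min_dists_oracle(fg, bg)
  expect_lt(abs(max(dt) - 2.5), 1.0 + 1e-9)
})

test_that("CT-like intensity mode rescales the image only", {
  spec <- desk_phantom_spec(seed = 51L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec, hu = TRUE, hu_scale = 400, hu_offset = -100)
  expect_equal(b$image, a$image * 400 - 100)
  expect_identical(a$label, b$label)
})

test_that("infeasible specs are rejected", {
  expect_error(phantom_spec(extent = 16L, radius_range = c(1, 8)), "quarter")
  expect_error(phantom_spec(radius_range = c(0.4, 2)), ">= 1 voxel")
})

test_that("fold assignment is disjoint, exhaustive and balanced", {
  ids <- sprintf("c%02d", 1:60)
  f <- assign_folds(ids, folds = 3L, seed = 2L)
  expect_identical(sort(unique(f)), 1:3)
  expect_identical(as.integer(table(f)), c(20L, 20L, 20L))
  expect_identical(sort(names(f)), sort(ids))

  f4 <- assign_folds(1:4, folds = 3L, seed = 2L)
  expect_identical(sort(as.integer(table(f4)), decreasing = TRUE), c(2L, 1L, 1L))
  expect_error(assign_folds(1:2, folds = 3L), "cannot fill")

  f2 <- assign_folds(ids, folds = 3L, seed = 2L)
  expect_identical(f, f2)  # deterministic
})

test_that("datasets write paired NIfTI volumes with a manifest", {
  dir <- file.path(tempdir(), "phantom-ds")
  unlink(dir, recursive = TRUE)
  spec <- phantom_spec(extent = 16L, n_branches = 1L, radius_range = c(1.5, 2),
                       distractor_count = 0L, seed = 61L)
  ds <- make_dataset(spec, n_cases = 4L, folds = 3L, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, pattern = "image\\.nii\\.gz$"), 4L)
  img <- read_volume(file.path(dir, "case-001_image.nii.gz"))
  lab <- read_volume(file.path(dir, "case-001_label.nii.gz"))
  expect_equal(dim(img), c(16L, 16L, 16L))
  ref <- generate_phantom({ s <- spec; s$seed <- ds$manifest$seed[1]; s })
  expect_equal(as.vector(img), as.vector(ref$image), tolerance = 1e-6)
  expect_equal(as.vector(lab), as.vector(ref$label))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_identical(sort(unique(man$fold)), 1:3)
  unlink(dir, recursive = TRUE)
})
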