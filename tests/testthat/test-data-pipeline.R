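# Paired image/mask IO, preprocessing, splitting and patch slicing.

make_disk_dataset <- function(n = 3L, size = 32L, seed = 1L, dir = tempfile()) {
  samples <- generate_dataset(synthetic_spec(n, size = size,
                                             modality_preset = "ultrasound_blob",
                                             seed = seed))
  write_dataset(samples, dir)
  list(dir = dir, samples = samples)
}

test_that("paired PNG layout round-trips through the loader", {
  dd <- make_disk_dataset(3L)
  loaded <- load_samples(dataset_spec(dd$dir, resize_target = NA))
  expect_length(loaded, 3L)
  byid <- setNames(loaded, vapply(loaded, `[[`, "", "id"))
  for (s in dd$samples) {
    expect_identical(byid[[s$id]]$mask, s$mask)               # masks exact
    expect_lt(max(abs(byid[[s$id]]$image - s$image)), 1 / 254) # 8-bit quantised
  }
})

test_that("class folders are honoured by the filter", {
  root <- tempfile()
  for (cls in c("benign", "malignant", "normal")) {
    sub <- file.path(root, cls)
    samples <- generate_dataset(synthetic_spec(2L, size = 16L,
                                               modality_preset = "ultrasound_blob",
                                               seed = nchar(cls)))
    write_dataset(samples, sub)
  }
  all_s <- load_samples(dataset_spec(root, resize_target = NA))
  expect_length(all_s, 6L)
  kept <- load_samples(dataset_spec(root, resize_target = NA,
                                    class_filter = c("benign", "malignant")))
  expect_length(kept, 4L)
  expect_true(all(vapply(kept, `[[`, "", "class") %in% c("benign", "malignant")))
})

test_that("multiple masks merge by pixelwise union; missing masks warn", {
  dir <- tempfile(); dir.create(dir)
  img <- matrix(runif(16 * 16), 16)
  m1 <- matrix(0, 16, 16); m1[1:4, 1:4] <- 1
  m2 <- matrix(0, 16, 16); m2[10:12, 10:12] <- 1
  png::writePNG(img, file.path(dir, "case1.png"))
  png::writePNG(m1, file.path(dir, "case1_mask.png"))
  png::writePNG(m2, file.path(dir, "case1_mask_1.png"))
  png::writePNG(img, file.path(dir, "orphan.png"))
  expect_warning(loaded <- load_samples(dataset_spec(dir, resize_target = NA)),
                 "without mask")
  expect_length(loaded, 1L)
  expect_identical(loaded[[1]]$mask, pmax(m1, m2))
})

test_that("resizing keeps masks binary and records the distortion", {
  samples <- generate_dataset(synthetic_spec(1L, size = 100L,
                                             modality_preset = "ultrasound_blob",
                                             seed = 2L))
  r <- resize_sample(samples[[1]], 64L)
  expect_equal(dim(r$image), c(64L, 64L))
  expect_true(all(r$mask %in% c(0, 1)))
  expect_equal(r$native_size, c(100L, 100L))

  # anisotropic input: per-axis scales recorded
  s <- segmentation_sample(matrix(runif(400 * 600), 400, 600),
                           matrix(0, 400, 600), id = "aniso")
  r2 <- resize_sample(s, 256L)
  expect_equal(attr(r2, "scale"), c(256 / 400, 256 / 600), tolerance = 1e-12)

  # already at target: identity on pixels
  t0 <- segmentation_sample(matrix(runif(64 * 64), 64), matrix(0, 64, 64),
                            id = "same")
  expect_identical(resize_sample(t0, 64L)$image, t0$image)
})

test_that("seeded splits are deterministic, disjoint and exhaustive", {
  samples <- lapply(1:10, function(i)
    segmentation_sample(matrix(0, 4, 4), matrix(0, 4, 4), id = paste0("s", i)))
  sp <- split_samples(samples, 0.8, seed = 42L)
  expect_length(sp$train, 8L); expect_length(sp$test, 2L)
  sp2 <- split_samples(samples, 0.8, seed = 42L)
  expect_identical(vapply(sp$train, `[[`, "", "id"),
                   vapply(sp2$train, `[[`, "", "id"))
  ids <- sort(c(vapply(sp$train, `[[`, "", "id"),
                vapply(sp$test, `[[`, "", "id")))
  expect_identical(ids, sort(vapply(samples, `[[`, "", "id")))

  # 647 samples at 8:2 -> 518 / 129 under round-half-up
  big <- lapply(1:647, function(i)
    segmentation_sample(matrix(0, 2, 2), matrix(0, 2, 2), id = paste0("b", i)))
  spb <- split_samples(big, 0.8, seed = 1L)
  expect_length(spb$train, 518L); expect_length(spb$test, 129L)

  expect_error(split_samples(samples[1], 0.8, 1L), "at least 2")
})

test_that("patch slicing follows the uniform grid arithmetic", {
  tile <- segmentation_sample(matrix(runif(1000 * 1000), 1000),
                              matrix(rbinom(1e6, 1, 0.1), 1000), id = "tile")
  patches <- patchify(tile, 256L, 128L)
  expect_length(patches, 36L)
  expect_true(all(vapply(patches, function(p) all(dim(p$image) == 256L),
                         logical(1))))

  one <- patchify(segmentation_sample(matrix(0, 256, 256), matrix(0, 256, 256),
                                      id = "x"), 256L, 64L)
  expect_length(one, 1L)

  # every patch mask equals the corresponding crop of the full mask
  p <- patches[[14]]
  coords <- as.integer(sub(".*_r(\\d+)c(\\d+)$", "\\1", p$id))
  c0 <- as.integer(sub(".*_r(\\d+)c(\\d+)$", "\\2", p$id))
  expect_identical(p$mask,
                   tile$mask[(coords + 1):(coords + 256), (c0 + 1):(c0 + 256)])
  expect_identical(p$image,
                   tile$image[(coords + 1):(coords + 256), (c0 + 1):(c0 + 256)])

  expect_error(patchify(one[[1]], 512L, 128L), "exceeds")
})

test_that("prepare_dataset splits patchified tiles per tile", {
  dd <- make_disk_dataset(5L, size = 32L, seed = 9L)
  spec <- dataset_spec(dd$dir, resize_target = NA, split_ratio = 0.8,
                       seed = 3L, patch_window = 16L, patch_stride = 8L)
  parts <- prepare_dataset(spec)
  # 4 tiles x 9 patches train, 1 tile x 9 patches test
  expect_length(parts$train, 36L)
  expect_length(parts$test, 9L)
  tile_of <- function(s) sub("_r\\d+c\\d+$", "", s$id)
  expect_length(intersect(unique(vapply(parts$train, tile_of, "")),
                          unique(vapply(parts$test, tile_of, ""))), 0L)
})

test_that("manifest CSV input is accepted", {
  dd <- make_disk_dataset(2L, size = 16L, seed = 4L)
  files <- list.files(dd$dir, full.names = TRUE)
  imgs <- files[!grepl("_mask", files)]
  manifest <- data.frame(id = c("a", "b"), image_path = imgs,
                         mask_paths = sub("\\.png$", "_mask.png", imgs),
                         class = c("benign", "benign"))
  mpath <- tempfile(fileext = ".csv")
  write.csv(manifest, mpath, row.names = FALSE)
  loaded <- load_samples(dataset_spec(mpath, resize_target = NA))
  expect_length(loaded, 2L)
  expect_identical(vapply(loaded, `[[`, "", "id"), c("a", "b"))
})
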