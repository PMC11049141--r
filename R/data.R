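# Paired image/mask data pipeline: loading, preprocessing, patch slicing
# and seeded splitting.

#' Dataset specification
#'
#' Describes where a paired image/mask dataset lives and how it is
#' preprocessed: resize target, train fraction of the seeded split, patch
#' slicing geometry for large tiles and an optional class filter applied
#' to the class (parent-folder or manifest) labels.
#'
#' @param root Directory containing the image/mask pairs, or a manifest
#'   CSV (columns `id, image_path, mask_paths, class`; multiple mask
#'   paths separated by `;`).
#' @param resize_target Square resize target in pixels (divisible by 16),
#'   or `NA` to keep native sizes.
#' @param split_ratio Train fraction in (0, 1); default 0.8 (an 8:2
#'   split).
#' @param seed Integer seed fixing the randomised split.
#' @param patch_window,patch_stride Patch slicing geometry in pixels
#'   (`stride <= window`); `NA` disables slicing.
#' @param class_filter Character vector of class names to keep, or `NULL`
#'   to keep everything.
#' @return A list of class `"dataset_spec"`.
#' @export
dataset_spec <- function(root, resize_target = 256L, split_ratio = 0.8,
                         seed = 1L, patch_window = NA_integer_,
                         patch_stride = NA_integer_, class_filter = NULL) {
  if (split_ratio <= 0 || split_ratio >= 1)
    stop("split_ratio must be in (0, 1)", call. = FALSE)
  if (!is.na(resize_target) && resize_target %% 16L != 0L)
    stop("resize_target must be divisible by 16", call. = FALSE)
  if (!is.na(patch_window) && !is.na(patch_stride) &&
      patch_stride > patch_window)
    stop("patch_stride must not exceed patch_window", call. = FALSE)
  structure(list(root = root, resize_target = resize_target,
                 split_ratio = split_ratio, seed = as.integer(seed),
                 patch_window = patch_window, patch_stride = patch_stride,
                 class_filter = class_filter),
            class = "dataset_spec")
}

#' Construct a segmentation sample
#'
#' One image/mask pair: a `(H, W)` (grayscale) or `(C, H, W)` image in
#' [0, 1], a binary `(H, W)` mask of the same spatial size, the native
#' size and a string id.
#'
#' @param image Numeric image array.
#' @param mask Binary mask matrix.
#' @param id Sample identifier.
#' @param class Optional class label.
#' @param native_size Original `(H, W)` before any resize.
#' @return A list of class `"segmentation_sample"`.
#' @export
segmentation_sample <- function(image, mask, id, class = NA_character_,
                                native_size = NULL) {
  img_hw <- spatial_dims(image)
  if (!identical(as.integer(img_hw), as.integer(dim(mask))))
    stop("image and mask sizes differ for sample ", id, call. = FALSE)
  if (any(mask != 0 & mask != 1))
    stop("mask must be binary for sample ", id, call. = FALSE)
  if (is.null(native_size)) native_size <- img_hw
  structure(list(image = image, mask = mask, id = id, class = class,
                 native_size = as.integer(native_size)),
            class = "segmentation_sample")
}

spatial_dims <- function(image) {
  d <- dim(image)
  if (length(d) == 2L) d else d[2:3]
}

# ---- file IO --------------------------------------------------------------

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("reading JPEG requires the 'EBImage' package", call. = FALSE)
      img <- EBImage::imageData(EBImage::readImage(path))
      # EBImage stores (x, y[, c]); transpose to (row, col)
      if (length(dim(img)) == 2L) t(img) else aperm(img, c(2L, 1L, 3L))
    },
    stop("unsupported image format: ", path, call. = FALSE))
  if (is.null(img)) stop("unreadable image: ", path, call. = FALSE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
    else img <- aperm(img[, , 1:min(3L, dim(img)[3L]), drop = FALSE],
                      c(3L, 1L, 2L))  # (C, H, W), alpha dropped
  }
  img
}

read_mask_file <- function(path) {
  m <- read_image_file(path)
  if (length(dim(m)) == 3L) m <- m[1L, , ]  # first channel of RGB masks
  (m >= 0.5) * 1
}

#' Load paired image/mask samples
#'
#' Scans `spec$root` for images whose mask files share the image stem
#' plus a `_mask` suffix (`stem_mask.png`, `stem_mask_1.png`, ...);
#' multiple masks for one image are merged by pixelwise union. Class
#' labels are taken from the parent directory name (or the manifest
#' `class` column) and filtered by `spec$class_filter`. Images without
#' any mask are skipped with a warning; unreadable files are an error.
#' PNG and TIFF are read natively; JPEG requires the `EBImage` package.
#'
#' @param spec A [dataset_spec()].
#' @return List of [segmentation_sample()] objects.
#' @export
load_samples <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  if (file.exists(spec$root) && !dir.exists(spec$root)) {
    manifest <- utils::read.csv(spec$root, stringsAsFactors = FALSE)
    entries <- lapply(seq_len(nrow(manifest)), function(i) {
      list(id = as.character(manifest$id[i]), image = manifest$image_path[i],
           masks = strsplit(manifest$mask_paths[i], ";", fixed = TRUE)[[1L]],
           class = if ("class" %in% names(manifest))
             as.character(manifest$class[i]) else NA_character_)
    })
  } else if (dir.exists(spec$root)) {
    files <- list.files(spec$root, recursive = TRUE, full.names = TRUE,
                        pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                        ignore.case = TRUE)
    imgs <- files[!grepl("_mask", basename(files))]
    entries <- lapply(imgs, function(f) {
      stem <- tools::file_path_sans_ext(basename(f))
      dirn <- dirname(f)
      masks <- list.files(dirn, full.names = TRUE,
                          pattern = paste0("^", gsub("([^[:alnum:]])", "\\\\\\1",
                                                     stem),
                                           "_mask(_[0-9]+)?\\."))
      cls <- basename(dirn)
      if (normalizePath(dirn) == normalizePath(spec$root)) cls <- NA_character_
      list(id = stem, image = f, masks = masks, class = cls)
    })
  } else {
    stop("dataset root not found: ", spec$root, call. = FALSE)
  }
  if (!is.null(spec$class_filter)) {
    entries <- Filter(function(e) is.na(e$class) ||
                        e$class %in% spec$class_filter, entries)
    entries <- Filter(function(e) !is.na(e$class), entries)
  }
  samples <- list()
  for (e in entries) {
    if (length(e$masks) == 0L) {
      warning("image without mask skipped: ", e$image, call. = FALSE)
      next
    }
    img <- read_image_file(e$image)
    mask <- NULL
    for (mp in e$masks) {
      m <- read_mask_file(mp)
      mask <- if (is.null(mask)) m else pmax(mask, m)  # pixelwise union
    }
    samples[[length(samples) + 1L]] <-
      segmentation_sample(img, mask, id = e$id, class = e$class)
  }
  samples
}

# ---- preprocessing --------------------------------------------------------

#' Resize a sample
#'
#' Bilinear resize for the image, nearest neighbour for the mask (which
#' therefore stays binary). The native size is preserved in the sample
#' metadata so the anisotropic distortion ratio remains recoverable.
#'
#' @param s A [segmentation_sample()].
#' @param target Target square size in pixels (divisible by 16), or a
#'   `(H, W)` pair.
#' @return The resized sample; attribute `"scale"` holds the per-axis
#'   scale factors.
#' @export
resize_sample <- function(s, target) {
  stopifnot(inherits(s, "segmentation_sample"))
  if (length(target) == 1L) target <- c(target, target)
  hw <- spatial_dims(s$image)
  if (all(hw == target)) {
    attr(s, "scale") <- c(1, 1)
    return(s)
  }
  img <- s$image
  if (length(dim(img)) == 2L) {
    dim(img) <- c(dim(img), 1L, 1L)
    img <- bilinear_resize(img, target[1L], target[2L])[, , 1L, 1L]
  } else {
    arr <- aperm(img, c(2L, 3L, 1L))          # (H, W, C)
    C <- dim(arr)[3L]
    dim(arr) <- c(dim(arr)[1:2], 1L, C)
    arr <- bilinear_resize(arr, target[1L], target[2L])
    dim(arr) <- c(target[1L], target[2L], C)
    img <- aperm(arr, c(3L, 1L, 2L))
  }
  ridx <- nn_index(target[1L], hw[1L])
  cidx <- nn_index(target[2L], hw[2L])
  mask <- s$mask[ridx, cidx, drop = FALSE]
  out <- segmentation_sample(img, mask, id = s$id, class = s$class,
                             native_size = s$native_size)
  attr(out, "scale") <- c(target[1L] / hw[1L], target[2L] / hw[2L])
  out
}

# nearest-neighbour source indices, half-pixel convention
nn_index <- function(n_out, n_in) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  pmin(pmax(floor(src), 1L), n_in)
}

#' Seeded train/test split
#'
#' Shuffles the samples with a fixed seed and assigns the first
#' `round(ratio * n)` to the training set. The partition is disjoint,
#' exhaustive and identical for identical seeds.
#'
#' @param samples List of samples (length >= 2).
#' @param ratio Train fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with `train` and `test` sample lists.
#' @export
split_samples <- function(samples, ratio = 0.8, seed = 1L) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples to split", call. = FALSE)
  n_train <- floor(ratio * n + 0.5)  # round half up
  n_train <- min(max(n_train, 1L), n - 1L)
  perm <- with_local_seed(seed, sample.int(n))
  list(train = samples[perm[seq_len(n_train)]],
       test = samples[perm[(n_train + 1L):n]])
}

# run code under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Slice a sample into overlapping patches
#'
#' Extracts the uniform grid of `window x window` patches with the given
#' stride: `floor((H - window)/stride) + 1` rows of patches by the
#' analogous number of columns, each with its mask crop. With window 256
#' and stride 128, a 1000x1000 tile yields 36 patches. Crops use 0-based,
#' row-major, half-open coordinate conventions in the patch ids.
#'
#' @param s A [segmentation_sample()].
#' @param window Patch edge in pixels (at most the image size).
#' @param stride Grid stride in pixels (at most `window`).
#' @return List of patch samples with ids `<id>_r<row>c<col>`.
#' @export
patchify <- function(s, window, stride) {
  stopifnot(inherits(s, "segmentation_sample"))
  hw <- spatial_dims(s$image)
  if (window > min(hw)) stop("window exceeds image size", call. = FALSE)
  nr <- (hw[1L] - window) %/% stride + 1L
  nc <- (hw[2L] - window) %/% stride + 1L
  gray <- length(dim(s$image)) == 2L
  out <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      r0 <- (i - 1L) * stride
      c0 <- (j - 1L) * stride
      rows <- (r0 + 1L):(r0 + window)
      cols <- (c0 + 1L):(c0 + window)
      img <- if (gray) s$image[rows, cols] else s$image[, rows, cols]
      k <- k + 1L
      out[[k]] <- segmentation_sample(
        img, s$mask[rows, cols], id = sprintf("%s_r%dc%d", s$id, r0, c0),
        class = s$class, native_size = s$native_size)
    }
  }
  out
}

#' Apply a dataset spec end to end
#'
#' Loads, optionally resizes or patch-slices, and splits a dataset in one
#' call. For patch-sliced datasets the split is performed per tile (all
#' patches of a tile stay on one side) to prevent leakage.
#'
#' @param spec A [dataset_spec()].
#' @return List with `train` and `test` sample lists.
#' @export
prepare_dataset <- function(spec) {
  samples <- load_samples(spec)
  if (!is.na(spec$patch_window)) {
    parts <- split_samples(samples, spec$split_ratio, spec$seed)
    expand <- function(ss) do.call(c, lapply(ss, patchify,
                                             window = spec$patch_window,
                                             stride = spec$patch_stride))
    return(list(train = expand(parts$train), test = expand(parts$test)))
  }
  if (!is.na(spec$resize_target))
    samples <- lapply(samples, resize_sample, target = spec$resize_target)
  split_samples(samples, spec$split_ratio, spec$seed)
}
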