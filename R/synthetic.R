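#' Specification of the synthetic pattern generator
#'
#' The generator emulates the structure the WTA network exploits in digit
#' images: each class has a fixed sparse prototype of bright blobs on a
#' dark background, samples are the prototype plus per-pixel Gaussian
#' noise clipped to `[0, 255]`, and pixel intensity is proportional to
#' the Poisson firing rate.  Blob locations are drawn without replacement
#' from a non-overlapping block partition of the grid, so prototypes of
#' different classes are disjoint and classes are well separated.
#'
#' @param n_classes Number of classes (>= 2).
#' @param grid_h,grid_w Image dimensions.
#' @param blobs_per_class Number of bright blobs per prototype.
#' @param blob_size Side of each square blob (pixels).
#' @param intensity Blob intensity (0-255).
#' @param noise_sd Per-pixel Gaussian noise standard deviation.
#' @param seed RNG seed; the generator is fully reproducible from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 3, grid_h = 16, grid_w = 16,
                           blobs_per_class = 3, blob_size = 3,
                           intensity = 255, noise_sd = 20, seed = 1) {
  if (n_classes < 2) stop("synthetic_spec: n_classes must be >= 2")
  if (noise_sd < 0) stop("synthetic_spec: noise_sd must be >= 0")
  if (intensity < 1 || intensity > 255)
    stop("synthetic_spec: intensity must be in [1, 255]")
  slots <- floor(grid_h / blob_size) * floor(grid_w / blob_size)
  if (slots < n_classes * blobs_per_class)
    stop("synthetic_spec: grid too small for disjoint class prototypes")
  structure(list(n_classes = as.integer(n_classes),
                 grid_h = as.integer(grid_h), grid_w = as.integer(grid_w),
                 blobs_per_class = as.integer(blobs_per_class),
                 blob_size = as.integer(blob_size),
                 intensity = intensity, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

synthetic_prototypes <- function(spec) {
  bh <- floor(spec$grid_h / spec$blob_size)
  bw <- floor(spec$grid_w / spec$blob_size)
  slots <- sample.int(bh * bw, spec$n_classes * spec$blobs_per_class)
  protos <- vector("list", spec$n_classes)
  for (k in seq_len(spec$n_classes)) {
    proto <- matrix(0, spec$grid_h, spec$grid_w)
    mine <- slots[((k - 1) * spec$blobs_per_class + 1):(k * spec$blobs_per_class)]
    for (s in mine) {
      r0 <- ((s - 1) %% bh) * spec$blob_size
      c0 <- ((s - 1) %/% bh) * spec$blob_size
      proto[r0 + seq_len(spec$blob_size), c0 + seq_len(spec$blob_size)] <-
        spec$intensity
    }
    protos[[k]] <- proto
  }
  protos
}

sample_split <- function(spec, protos, n) {
  labels <- rep(seq_len(spec$n_classes) - 1L, length.out = n)
  images <- array(0, dim = c(n, spec$grid_h, spec$grid_w))
  npix <- spec$grid_h * spec$grid_w
  for (m in seq_len(n)) {
    img <- protos[[labels[m] + 1L]]
    if (spec$noise_sd > 0)
      img <- img + rnorm(npix, sd = spec$noise_sd)
    images[m, , ] <- pmin(255, pmax(0, img))
  }
  structure(list(images = images, labels = labels, split = NA_character_),
            class = "image_dataset")
}

#' Generate a synthetic train/test dataset pair
#'
#' Reproducible from `spec$seed`: the caller's RNG state is saved and
#' restored, so calling this function does not perturb an experiment's
#' random stream.
#'
#' @param spec A [synthetic_spec()].
#' @param n_train,n_test Split sizes (classes are balanced by cycling).
#' @return List with `train` and `test` [image datasets][read_idx] and
#'   the class `prototypes`.
#' @export
#' @examples
#' d <- make_synthetic(synthetic_spec(noise_sd = 0), 6, 3)
#' all(d$train$images[1, , ] == d$prototypes[[1]])
make_synthetic <- function(spec, n_train, n_test) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  protos <- synthetic_prototypes(spec)
  train <- sample_split(spec, protos, n_train)
  train$split <- "train"
  test <- sample_split(spec, protos, n_test)
  test$split <- "test"
  list(train = train, test = test, prototypes = protos)
}

#' Flatten dataset images to an n x n_input matrix
#'
#' @param dataset An `image_dataset`.
#' @return Numeric matrix, one image per row (pixels in row-major order
#'   matching the input grid).
#' @export
as_image_matrix <- function(dataset) {
  d <- dim(dataset$images)
  matrix(dataset$images, d[1], d[2] * d[3])
}
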