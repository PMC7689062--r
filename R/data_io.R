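#' Read an IDX/ubyte image file
#'
#' Parses the standard big-endian IDX3 layout used by the MNIST family:
#' magic number 2051, then the number of images, rows, and columns as
#' 4-byte integers, then one unsigned byte per pixel.
#'
#' @param path Path to an `*-images-idx3-ubyte` file.
#' @return Integer array `n x rows x cols` with values in `[0, 255]`.
#' @export
read_idx_images <- function(path) {
  if (!file.exists(path)) stop("read_idx_images: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (length(magic) == 0)
    stop("read_idx_images: truncated file at offset 0 (missing magic)")
  if (magic != 2051L)
    stop("read_idx_images: wrong magic number ", magic,
         " at offset 0 (expected 2051)")
  dims <- readBin(con, "integer", 3, size = 4, endian = "big")
  if (length(dims) < 3)
    stop("read_idx_images: truncated header at offset 4")
  n <- dims[1]; h <- dims[2]; w <- dims[3]
  payload <- readBin(con, "raw", n * h * w)
  if (length(payload) < n * h * w)
    stop("read_idx_images: truncated payload at offset ",
         16 + length(payload), " (expected ", n * h * w, " bytes)")
  # pixels are stored row-major per image
  a <- array(as.integer(payload), dim = c(w, h, n))
  aperm(a, c(3, 2, 1))
}

#' Read an IDX/ubyte label file
#'
#' Magic number 2049, then the label count as a 4-byte integer, then one
#' unsigned byte per label.
#'
#' @param path Path to a `*-labels-idx1-ubyte` file.
#' @return Integer vector of labels.
#' @export
read_idx_labels <- function(path) {
  if (!file.exists(path)) stop("read_idx_labels: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (length(magic) == 0)
    stop("read_idx_labels: truncated file at offset 0 (missing magic)")
  if (magic != 2049L)
    stop("read_idx_labels: wrong magic number ", magic,
         " at offset 0 (expected 2049)")
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (length(n) == 0) stop("read_idx_labels: truncated header at offset 4")
  payload <- readBin(con, "raw", n)
  if (length(payload) < n)
    stop("read_idx_labels: truncated payload at offset ",
         8 + length(payload), " (expected ", n, " bytes)")
  as.integer(payload)
}

#' Read an image/label pair into a dataset
#'
#' @param images_path,labels_path Paths to the IDX image and label files.
#' @param split Optional split tag (`"train"` or `"test"`).
#' @return A list of class `image_dataset` with `images` (n x h x w
#'   array), `labels`, and `split`.
#' @export
read_idx <- function(images_path, labels_path, split = NA_character_) {
  images <- read_idx_images(images_path)
  labels <- read_idx_labels(labels_path)
  if (dim(images)[1] != length(labels))
    stop("read_idx: image and label counts differ")
  structure(list(images = images, labels = labels, split = split),
            class = "image_dataset")
}

#' Write images to an IDX/ubyte file
#'
#' Counterpart of [read_idx_images()], used for round-trip tests and for
#' exporting synthetic datasets.
#'
#' @param images Integer array `n x h x w`, values in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_idx_images <- function(images, path) {
  d <- dim(images)
  if (length(d) != 3) stop("write_idx_images: images must be n x h x w")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(2051L, con, size = 4, endian = "big")
  writeBin(as.integer(d), con, size = 4, endian = "big")
  writeBin(as.raw(as.integer(aperm(images, c(3, 2, 1)))), con)
  invisible(path)
}

#' Write labels to an IDX/ubyte file
#'
#' @param labels Integer vector in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_idx_labels <- function(labels, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(2049L, con, size = 4, endian = "big")
  writeBin(length(labels), con, size = 4, endian = "big")
  writeBin(as.raw(as.integer(labels)), con)
  invisible(path)
}

#' Write and read sweep result tables
#'
#' CSV serialization with a fixed header; numeric columns round-trip to
#' full double precision.
#'
#' @param reports A data frame (e.g. stacked [fom_report()] rows).
#' @param path CSV path.
#' @return `write_results` returns `path` invisibly; `read_results`
#'   returns the data frame.
#' @export
write_results <- function(reports, path) {
  utils::write.csv(as.data.frame(reports), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
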