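# Radiograph preprocessing: pluggable lung segmentation, tight bounding-box
# crop, bilinear resize to the backbone's 224x224 input, grayscale
# replication to 3 channels and [-1, 1] scaling.

#' Read an 8-bit grayscale radiograph
#'
#' Supports PNG and TIFF. Pixels are returned as a numeric matrix of
#' intensities in `[0, 255]` (row = image row). Multi-channel files are
#' accepted only when all channels are identical (grayscale stored as RGB).
#'
#' @param path Image file path.
#' @return Numeric matrix with values in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (use 8-bit PNG or TIFF): ",
         path)
  )
  if (length(dim(px)) == 3) {
    ch1 <- px[, , 1]
    for (k in seq_len(dim(px)[3])[-1]) {
      if (max(abs(px[, , k] - ch1)) > 1e-9) {
        stop("multi-channel image with differing channels is not grayscale: ",
             path)
      }
    }
    px <- ch1
  }
  round(px * 255)
}

#' Segmentation backends for the lung-field mask
#'
#' Lung segmentation is a pluggable contract: a backend is a function of
#' the image (and, for file-based backends, its path) returning a logical
#' mask of identical shape. Two backends ship with the package:
#'
#' * `oracle_backend()` reads a pre-computed binary mask stored next to the
#'   image (`<image>_mask.png` by default, nonzero = lung) — the hook for
#'   masks produced by any external pretrained segmentation model, and the
#'   deterministic backend used by the test fixtures.
#' * `threshold_backend()` applies Otsu thresholding and keeps the two
#'   largest bright connected components; adequate for the synthetic
#'   two-ellipse fixtures, not for clinical radiographs.
#'
#' @param mask_suffix Suffix replacing the image extension to locate the
#'   mask file.
#' @return A `seg_backend` object for [segment_lungs()].
#' @export
oracle_backend <- function(mask_suffix = "_mask.png") {
  structure(list(
    name = "oracle",
    segment = function(image, image_path = NULL) {
      if (is.null(image_path)) stop("oracle backend needs the image path")
      mask_path <- paste0(tools::file_path_sans_ext(image_path), mask_suffix)
      if (!file.exists(mask_path)) stop("mask file not found: ", mask_path)
      m <- png::readPNG(mask_path)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m > 0
    }
  ), class = "seg_backend")
}

#' @rdname oracle_backend
#' @export
threshold_backend <- function() {
  structure(list(
    name = "threshold",
    segment = function(image, image_path = NULL) {
      img01 <- image / 255
      th <- EBImage::otsu(EBImage::Image(img01), range = c(0, 1))
      bw <- img01 > th
      lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
      if (max(lab) == 0) return(matrix(FALSE, nrow(image), ncol(image)))
      sizes <- tabulate(lab[lab > 0])
      keep <- order(sizes, decreasing = TRUE)[seq_len(min(2, length(sizes)))]
      matrix(lab %in% keep, nrow(image), ncol(image))
    }
  ), class = "seg_backend")
}

#' Segment the lung fields of a radiograph
#'
#' Dispatches to the registered backend and validates its contract: the
#' mask must be logical, match the image shape, and be non-empty.
#'
#' @param image Grayscale matrix from [read_gray_image()].
#' @param backend A `seg_backend` (see [oracle_backend()]).
#' @param image_path Original file path, needed by file-based backends.
#' @return Logical matrix, `TRUE` = lung.
#' @export
segment_lungs <- function(image, backend, image_path = NULL) {
  if (!inherits(backend, "seg_backend")) stop("backend must be a seg_backend")
  mask <- backend$segment(image, image_path)
  if (!is.matrix(mask) || !is.logical(c(mask)[1])) {
    mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  }
  if (!identical(dim(mask), dim(image))) {
    stop("segmentation backend '", backend$name, "' returned a mask of shape ",
         paste(dim(mask), collapse = "x"), " for an image of shape ",
         paste(dim(image), collapse = "x"))
  }
  if (!any(mask)) {
    stop("segmentation produced an empty lung mask",
         if (!is.null(image_path)) paste0(" for ", image_path) else "")
  }
  mask
}

#' Tightest axis-aligned box around the lung mask
#'
#' Returns the smallest rectangle containing every `TRUE` pixel of the
#' mask — both lung fields jointly, with no margin. Coordinates are 0-based
#' and inclusive (pixel-index convention of the imaging toolkits the masks
#' come from).
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @return A `bounding_box` list: `row_min`, `row_max`, `col_min`,
#'   `col_max`.
#' @export
lung_bounding_box <- function(mask) {
  if (!any(mask)) stop("cannot bound an empty mask")
  idx <- which(mask, arr.ind = TRUE)
  structure(list(
    row_min = min(idx[, 1]) - 1L, row_max = max(idx[, 1]) - 1L,
    col_min = min(idx[, 2]) - 1L, col_max = max(idx[, 2]) - 1L
  ), class = "bounding_box")
}

#' Crop, resize and scale a radiograph to the backbone input contract
#'
#' Crops the image to the (inclusive) bounding box, resizes to
#' `size` x `size` with bilinear interpolation (no antialiasing),
#' replicates the grayscale plane to 3 identical channels, and maps 8-bit
#' intensities to `[-1, 1]` as `x / 127.5 - 1`.
#'
#' @param image Grayscale matrix in `[0, 255]`.
#' @param box A `bounding_box` within the image bounds.
#' @param size Output side length (default 224).
#' @return `size` x `size` x 3 array with values in `[-1, 1]`, all three
#'   channels identical.
#' @export
crop_resize_normalize <- function(image, box, size = 224) {
  stopifnot(inherits(box, "bounding_box"))
  nr <- nrow(image); nc <- ncol(image)
  if (box$row_min < 0 || box$col_min < 0 ||
      box$row_max >= nr || box$col_max >= nc ||
      box$row_min > box$row_max || box$col_min > box$col_max) {
    stop("bounding box out of image bounds")
  }
  crop <- image[(box$row_min + 1):(box$row_max + 1),
                (box$col_min + 1):(box$col_max + 1), drop = FALSE]
  resized <- EBImage::imageData(EBImage::resize(
    EBImage::Image(crop), w = size, h = size, antialias = FALSE))
  chan <- pmin(1, pmax(-1, resized / 127.5 - 1))
  array(chan, dim = c(size, size, 3))
}

#' Full radiograph preprocessing pipeline
#'
#' Composition of [segment_lungs()], [lung_bounding_box()] and
#' [crop_resize_normalize()]; deterministic for fixed inputs and backend.
#'
#' @inheritParams segment_lungs
#' @inheritParams crop_resize_normalize
#' @return Preprocessed `size` x `size` x 3 array in `[-1, 1]`.
#' @export
preprocess <- function(image, backend, image_path = NULL, size = 224) {
  mask <- segment_lungs(image, backend, image_path)
  box <- lung_bounding_box(mask)
  crop_resize_normalize(image, box, size = size)
}
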