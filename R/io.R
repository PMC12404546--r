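# Patch image IO and manifest loading.

#' Read an 8-bit RGB patch image
#'
#' PNG is read natively; TIFF via the `tiff` package and JPEG via `EBImage`
#' when installed. Grayscale input is replicated to three channels; an alpha
#' channel is dropped.
#'
#' @param path image path.
#' @return `H x W x 3` numeric array in `[0, 255]`.
#' @export
read_patch <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    jpg = , jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("reading JPEG requires the 'EBImage' package")
      # EBImage images are x-y ordered; transpose back to row-major
      aperm(as.array(EBImage::readImage(path)), c(2, 1, 3))
    },
    stop("unsupported image format: .", ext))
  if (is.null(dim(img)) || length(dim(img)) == 2)
    img <- array(rep(img, 3), c(dim(img) %||% c(1, length(img)), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1) img <- array(rep(img, 3), c(dim(img)[1:2], 3))
  img * 255
}

#' Load a dataset manifest and its images as patch records
#'
#' Reads a `manifest.csv` written by [generate_dataset()] (columns `id`,
#' `path`, `label`, truth fields) and the referenced images.
#'
#' @param manifest_csv path to the manifest.
#' @param base_dir directory to resolve relative image paths against
#'   (default: the manifest's directory).
#' @return list of `patch_record`.
#' @export
load_manifest <- function(manifest_csv, base_dir = dirname(manifest_csv)) {
  m <- read.csv(manifest_csv, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(m)), function(i) {
    p <- m$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, basename(p))
    structure(list(image = read_patch(p), label = m$label[i],
                   truth = list(intensity_score = m$intensity_score[i],
                                proportion_score = m$proportion_score[i],
                                dab_area_fraction = m$dab_area_fraction[i],
                                dab_mean_od = m$dab_mean_od[i]),
                   seed = m$seed[i], id = m$id[i]),
              class = "patch_record")
  })
}
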