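#' Read an image file as a raster image
#'
#' Supports PNG, JPEG and TIFF. Pixel values are normalized to the
#' canonical `[0, 1]` range (8-bit images are divided by 255 by the
#' decoders); color mode is preserved. Gray+alpha / RGBA channels are
#' dropped to gray / RGB.
#'
#' @param path Path to a `.png`, `.jpg`/`.jpeg`, `.tif`/`.tiff` file.
#' @return A [raster_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file does not exist: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = read_jpeg(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported image format '.", ext, "': ", path, call. = FALSE)
    ),
    error = function(e) stop("failed to read image ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  px <- drop_alpha(px)
  raster_image(px)
}

# EBImage stores pixels x-major; transpose back to row = image row
read_jpeg <- function(path) {
  im <- EBImage::readImage(path)
  px <- EBImage::imageData(im)
  if (length(dim(px)) == 2L) t(px) else aperm(px, c(2, 1, 3))
}

drop_alpha <- function(px) {
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 2L) px <- px[, , 1]              # gray + alpha
    else if (dim(px)[3] == 4L) px <- px[, , 1:3]       # RGBA
    else if (dim(px)[3] == 1L) px <- px[, , 1]
  }
  px
}

#' Write a raster image to a PNG or TIFF file
#'
#' Values are clipped to `[0, 1]`; PNG output is quantized to 8 bits.
#'
#' @param img A [raster_image()].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_raster(img)
  px <- pmin(pmax(img$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stop("unsupported output format '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}

image_extensions <- c("png", "jpg", "jpeg", "tif", "tiff")

#' Scan a class-per-folder image dataset
#'
#' Expects the layout `<root>/<class_name>/<image>` (the LC25000-style
#' layout). Class names and files are ordered lexicographically with a
#' fixed collation so two scans of the same tree always yield the same
#' ordered records. When a sibling `<root>-masks/<class_name>/<image>.png`
#' exists it is recorded as the truth mask for that tile.
#'
#' @param root Dataset root directory.
#' @return A `labeled_image_set`: a tibble with columns `sample_id`,
#'   `path`, `label`, `mask_path`, carrying `class_names` as an attribute.
#' @export
scan_dataset <- function(root) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root, call. = FALSE)
  classes <- sort_c(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) stop("dataset root contains no class folders: ", root, call. = FALSE)
  mask_root <- paste0(sub("/+$", "", root), "-masks")
  records <- purrr::map_dfr(classes, function(cl) {
    files <- sort_c(list.files(file.path(root, cl),
                               pattern = paste0("\\.(", paste(image_extensions, collapse = "|"), ")$"),
                               ignore.case = TRUE))
    if (length(files) == 0L) {
      stop("class folder contains no images: ", file.path(root, cl), call. = FALSE)
    }
    mp <- file.path(mask_root, cl, paste0(tools::file_path_sans_ext(files), ".png"))
    tibble::tibble(
      sample_id = paste0(cl, "/", tools::file_path_sans_ext(files)),
      path      = file.path(root, cl, files),
      label     = cl,
      mask_path = ifelse(file.exists(mp), mp, NA_character_)
    )
  })
  stopifnot(!anyDuplicated(records$path))
  labeled_image_set(records, classes)
}

labeled_image_set <- function(records, class_names) {
  stopifnot(all(records$label %in% class_names))
  structure(records, class = c("labeled_image_set", class(tibble::tibble())),
            class_names = class_names)
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("<labeled_image_set> %d records, %d classes: %s\n",
              nrow(x), length(attr(x, "class_names")),
              paste(attr(x, "class_names"), collapse = ", ")))
  NextMethod()
}

# locale-independent lexicographic sort
sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(x)
}

#' Fetch a record's image, reading from disk if needed
#' @param set A `labeled_image_set`.
#' @param i Record index.
#' @return A [raster_image()].
#' @export
record_image <- function(set, i) {
  if ("image" %in% names(set) && !is.null(set$image[[i]])) return(set$image[[i]])
  read_image(set$path[i])
}
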