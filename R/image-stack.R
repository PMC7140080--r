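#' Two-channel 3D image stack
#'
#' Container for a confocal z-stack with a cell-dye channel (`DiO`) and a
#' nuclear-stain channel (`DAPI`). Each channel is a numeric 3D array with
#' dimensions `(z, y, x)` holding non-negative (by default 8-bit integer)
#' intensities; both channels share a shape and a physical voxel size.
#'
#' @param channels named list of 3D arrays, typically `DiO` and `DAPI`,
#'   all with identical dimensions and non-negative values.
#' @param voxel_size_zyx numeric length-3, micrometres per voxel along
#'   (z, y, x).
#' @return An object of class `image_stack`: a list with elements
#'   `channels` and `voxel_size_zyx`.
#' @examples
#' a <- array(0, c(4, 8, 8))
#' s <- image_stack(list(DiO = a, DAPI = a), voxel_size_zyx = c(2, 1, 1))
#' dim(s$channels$DiO)
#' @export
image_stack <- function(channels, voxel_size_zyx = c(1, 1, 1)) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), length(voxel_size_zyx) == 3)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("each channel must be a 3D array (z, y, x)")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share the same shape")
  if (any(vapply(channels, function(a) any(a < 0), TRUE)))
    stop("intensities must be non-negative")
  structure(list(channels = channels,
                 voxel_size_zyx = as.numeric(voxel_size_zyx)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d slices of %d x %d, channels [%s], voxel %s um\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", "),
              paste(signif(x$voxel_size_zyx, 3), collapse = " x ")))
  invisible(x)
}

#' Number of z slices in a stack
#' @param stack an [image_stack()].
#' @return integer slice count.
#' @export
n_slices <- function(stack) dim(stack$channels[[1]])[1]

#' Voxel volume of a stack in cubic micrometres
#' @param stack an [image_stack()].
#' @return scalar volume of one voxel.
#' @export
voxel_volume <- function(stack) prod(stack$voxel_size_zyx)

#' Read / write a single channel as a multi-page TIFF
#'
#' Slices are stored as TIFF pages (page i = z slice i) with 8 bits per
#' sample; integer intensities in `[0, 255]` round-trip exactly.
#'
#' @param path TIFF file path.
#' @param voxels 3D array `(z, y, x)` of intensities in `[0, 255]`.
#' @return `read_channel_tiff()` returns a 3D array; `write_channel_tiff()`
#'   returns `path` invisibly.
#' @export
write_channel_tiff <- function(voxels, path) {
  stopifnot(length(dim(voxels)) == 3L)
  if (any(voxels < 0 | voxels > 255)) stop("intensities must lie in [0, 255]")
  pages <- lapply(seq_len(dim(voxels)[1]), function(z) voxels[z, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_channel_tiff
#' @export
read_channel_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr
}

#' Write / read a two-channel stack as per-channel TIFF files
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param voxel_size_zyx voxel size to attach on reading.
#' @return `write_stack_tiff()` returns the written paths invisibly;
#'   `read_stack_tiff()` returns an [image_stack()].
#' @export
write_stack_tiff <- function(stack, dir, prefix = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(stack$channels)) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    write_channel_tiff(stack$channels[[ch]], p)
    paths[ch] <- p
  }
  invisible(paths)
}

#' @rdname write_stack_tiff
#' @param paths named character vector of channel TIFF paths (names become
#'   channel names).
#' @export
read_stack_tiff <- function(paths, voxel_size_zyx = c(1, 1, 1)) {
  chans <- lapply(paths, read_channel_tiff)
  names(chans) <- names(paths)
  image_stack(chans, voxel_size_zyx)
}
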