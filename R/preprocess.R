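#' Per-slice summed intensities of a stack
#'
#' Sums every slice of every channel into one value, the first step of the
#' glass/scaffold cropping rule.
#'
#' @param stack an [image_stack()].
#' @return A data.frame with one row per slice: `slice` (1-based z index)
#'   and one column per channel holding the slice's total intensity.
#' @examples
#' a <- array(0, c(4, 5, 5)); a[3, 1, 1] <- 7
#' sum_slice_intensities(image_stack(list(DiO = a, DAPI = a * 0)))
#' @export
sum_slice_intensities <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (n_slices(stack) < 1) stop("empty stack")
  sums <- lapply(stack$channels, function(a) rowSums(a, dims = 1))
  cbind(data.frame(slice = seq_len(n_slices(stack))),
        as.data.frame(sums))
}

#' Tukey inner fences of a sample
#'
#' Computes the outlier bounds `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7). A value is outlying iff it falls strictly
#' outside the closed interval `[lower, upper]`.
#'
#' @param values numeric vector of at least 4 values.
#' @return named numeric `c(lower = , upper = )`.
#' @examples
#' tukey_inner_fences(c(1, 2, 3, 4, 5))   # (-1, 7)
#' @export
tukey_inner_fences <- function(values) {
  if (length(values) < 4) stop("insufficient slices: need at least 4 values")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
}

#' Highest slice attaining a channel's absolute maximum intensity
#'
#' For each channel, finds the largest z index containing a voxel equal to
#' the channel's global maximum ("the highest slice with absolute maximum
#' intensity"); the cross-channel reference index used by [crop_stack()]
#' is the maximum over channels.
#'
#' @param stack an [image_stack()].
#' @return named integer vector of per-channel slice indices, with the
#'   cross-channel reference as `attr(, "reference")`.
#' @export
max_intensity_slice <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (n_slices(stack) < 1) stop("empty stack")
  idx <- vapply(stack$channels, function(a) {
    m <- max(a)
    slice_max <- apply(a, 1, max)
    max(which(slice_max == m))
  }, 1L)
  attr(idx, "reference") <- max(idx)
  idx
}

#' Crop high-index outlying slices from a stack
#'
#' Implements the rule separating coverslip-adherent 2D signal from 3D
#' scaffold signal: a slice is removed iff (a) its z index is greater than
#' the reference index (the highest slice attaining either channel's
#' absolute maximum intensity) and (b) its summed intensity is outlying
#' (outside the Tukey inner fences, computed once from all slices) in
#' either channel. The lowest removed index is recorded as the dividing
#' line between the glass layer and the scaffold region.
#'
#' @param stack an [image_stack()] with at least 4 slices.
#' @return `list(stack = cropped image_stack, profile = slice_profile)`.
#'   The `slice_profile` lists per-slice sums, per-channel fences and
#'   max-intensity indices, the reference index, the removed slice indices
#'   and `dividing_slice` (lowest removed index, or `NA` when nothing is
#'   removed).
#' @examples
#' sim <- simulate_stack(stack_spec(shape_zyx = c(20, 48, 48),
#'   n_singletons = 4, n_clusters = 0,
#'   glass_layer = list(z_range = c(16, 20), density = 0.3), seed = 2))
#' crop_stack(sim$stack)$profile$removed
#' @export
crop_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- n_slices(stack)
  if (nz < 4) stop("insufficient slices: need at least 4")
  sums <- sum_slice_intensities(stack)
  chans <- names(stack$channels)
  fences <- lapply(chans, function(ch) tukey_inner_fences(sums[[ch]]))
  names(fences) <- chans
  outlying <- rep(FALSE, nz)
  for (ch in chans)
    outlying <- outlying | sums[[ch]] < fences[[ch]]["lower"] |
      sums[[ch]] > fences[[ch]]["upper"]
  ref <- max_intensity_slice(stack)
  reference <- attr(ref, "reference")
  removed <- which(outlying & seq_len(nz) > reference)
  keep <- setdiff(seq_len(nz), removed)
  if (length(keep) == 0) stop("no scaffold region: all slices removed")
  cropped <- image_stack(
    lapply(stack$channels, function(a) a[keep, , , drop = FALSE]),
    stack$voxel_size_zyx)
  profile <- structure(list(
    sums = sums, fences = fences, max_slice = ref,
    reference = reference, removed = removed,
    dividing_slice = if (length(removed)) min(removed) else NA_integer_),
    class = "slice_profile")
  list(stack = cropped, profile = profile)
}

#' @export
print.slice_profile <- function(x, ...) {
  cat(sprintf("slice_profile: %d slices, reference %d, removed %s, dividing %s\n",
              nrow(x$sums), x$reference,
              if (length(x$removed)) paste(range(x$removed), collapse = "-")
              else "none",
              x$dividing_slice))
  invisible(x)
}

#' Write a slice profile as TSV plus a JSON sidecar
#'
#' @param profile a `slice_profile` from [crop_stack()].
#' @param path_tsv,path_json output paths.
#' @return invisibly, the two paths.
#' @export
write_slice_profile <- function(profile, path_tsv, path_json) {
  utils::write.table(profile$sums, path_tsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  side <- list(fences = profile$fences,
               max_slice = as.list(profile$max_slice),
               reference = profile$reference,
               removed = profile$removed,
               dividing_slice = profile$dividing_slice)
  jsonlite::write_json(side, path_json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(path_tsv, path_json))
}
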