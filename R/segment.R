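#' Otsu threshold of an intensity volume
#'
#' Builds an intensity histogram (integer levels 0..255 for 8-bit data;
#' otherwise `n_bins` equal-width bins over the observed range) and returns
#' the threshold maximizing the between-class variance
#' `w0 w1 (mu0 - mu1)^2`. Foreground is defined as intensity strictly
#' greater than the threshold; ties in the variance curve are broken
#' toward the lowest threshold.
#'
#' @param x numeric array or vector of intensities.
#' @param n_bins bins used for non-8-bit data.
#' @return scalar threshold, with the candidate thresholds and their
#'   between-class variances attached as `attr(, "curve")`.
#' @examples
#' otsu_threshold(c(rep(0, 50), rep(200, 50)))
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("degenerate histogram: constant image")
  eightbit <- all(v == floor(v)) && lo >= 0 && hi <= 255
  if (eightbit) {
    counts <- tabulate(v + 1L, nbins = 256L)
    levels <- 0:255
  } else {
    br <- seq(lo, hi, length.out = n_bins + 1L)
    counts <- tabulate(findInterval(v, br, rightmost.closed = TRUE),
                       nbins = n_bins)
    levels <- br[-1]            # threshold = bin upper edge
  }
  n <- length(v)
  w0 <- cumsum(counts) / n
  mu_cum <- cumsum(counts * levels) / n
  mu_t <- mu_cum[length(mu_cum)]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, length(levels))
  sigma_b[ok] <- (mu_t * w0[ok] - mu_cum[ok])^2 / (w0[ok] * w1[ok])
  best <- which.max(sigma_b)    # which.max takes the first (lowest) tie
  structure(levels[best], curve = data.frame(threshold = levels,
                                             variance = sigma_b))
}

# half neighbourhood offsets (z, y, x) for 6- and 26-connectivity
half_offsets <- function(connectivity) {
  if (connectivity == 6)
    return(matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  if (connectivity != 26) stop("connectivity must be 6 or 26")
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  # keep one of each +/- pair: lexicographically positive offsets
  pos <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  g[pos, , drop = FALSE]
}

#' Label 3D connected components of a binary mask
#'
#' Finds connected components of the foreground (non-zero) voxels under
#' 26-connectivity (face, edge and vertex neighbours; the default) or
#' 6-connectivity, and tabulates per-object statistics.
#'
#' @param mask 3D array `(z, y, x)`; non-zero voxels are foreground.
#' @param connectivity 26 (default) or 6.
#' @param voxel_size_zyx micrometres per voxel, used for object volumes.
#' @return `list(labels = integer 3D array (0 = background), table =
#'   object_table)`. The `object_table` data.frame has one row per object:
#'   `id`, `voxels`, `volume_um3`, centroid `z`, `y`, `x`, bounding box
#'   `z0 z1 y0 y1 x0 x1`, and `on_edge` (touches any face of the volume).
#' @examples
#' m <- array(0L, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- 1L
#' label_components_3d(m)$table$voxels
#' @export
label_components_3d <- function(mask, connectivity = 26,
                                voxel_size_zyx = c(1, 1, 1)) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  fg <- which(mask != 0)
  empty <- data.frame(id = integer(0), voxels = integer(0),
                      volume_um3 = numeric(0), z = numeric(0),
                      y = numeric(0), x = numeric(0),
                      z0 = integer(0), z1 = integer(0),
                      y0 = integer(0), y1 = integer(0),
                      x0 = integer(0), x1 = integer(0),
                      on_edge = logical(0))
  if (length(fg) == 0)
    return(list(labels = array(0L, d), table = empty))

  rank <- array(0L, d)          # foreground voxel -> 1..n
  rank[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)
  offs <- half_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    z2 <- co[, 1] + offs[k, 1]
    y2 <- co[, 2] + offs[k, 2]
    x2 <- co[, 3] + offs[k, 3]
    inb <- z2 >= 1 & z2 <= d[1] & y2 >= 1 & y2 <= d[2] &
      x2 >= 1 & x2 <= d[3]
    lin2 <- z2[inb] + (y2[inb] - 1) * d[1] + (x2[inb] - 1) * d[1] * d[2]
    nb <- rank[lin2]
    hit <- nb > 0L
    from <- c(from, which(inb)[hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(fg),
                          directed = FALSE)
  memb <- igraph::components(g)$membership

  vox <- tabulate(memb)
  sums <- rowsum(cbind(co, 1), memb)
  cz <- sums[, 1] / vox; cy <- sums[, 2] / vox; cx <- sums[, 3] / vox
  bb <- function(f, col) as.integer(tapply(co[, col], memb, f))
  z0 <- bb(min, 1); z1 <- bb(max, 1)
  y0 <- bb(min, 2); y1 <- bb(max, 2)
  x0 <- bb(min, 3); x1 <- bb(max, 3)
  on_edge <- z0 == 1L | z1 == d[1] | y0 == 1L | y1 == d[2] |
    x0 == 1L | x1 == d[3]

  labels <- array(0L, d)
  labels[fg] <- memb
  tab <- data.frame(id = seq_along(vox), voxels = vox,
                    volume_um3 = vox * prod(voxel_size_zyx),
                    z = cz, y = cy, x = cx,
                    z0 = z0, z1 = z1, y0 = y0, y1 = y1,
                    x0 = x0, x1 = x1, on_edge = on_edge)
  list(labels = labels, table = tab)
}

#' Filter an object table by size and edge contact
#'
#' Removes objects smaller than `min_voxels` voxels (default 10, i.e.
#' objects from ten voxels up to the maximum volume are retained) and,
#' when `exclude_edges`, objects touching any face of the volume.
#'
#' @param table an `object_table` from [label_components_3d()].
#' @param min_voxels minimum retained object size in voxels.
#' @param exclude_edges drop objects with `on_edge = TRUE`.
#' @return the filtered `object_table`.
#' @export
filter_objects <- function(table, min_voxels = 10L, exclude_edges = TRUE) {
  keep <- table$voxels >= min_voxels
  if (exclude_edges) keep <- keep & !table$on_edge
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label volume restricted to retained objects
#'
#' Zeroes every voxel whose object was filtered out, producing the masked
#' stack of object labels; relabelling the result reproduces the same
#' voxel counts.
#'
#' @param labels integer label array from [label_components_3d()].
#' @param table the (possibly filtered) `object_table` whose ids survive.
#' @return integer 3D array of object ids (0 = background).
#' @export
masked_stack <- function(labels, table) {
  keep <- array(labels %in% table$id, dim(labels))
  labels * keep
}

#' Segment one channel of a stack end to end
#'
#' Applies [otsu_threshold()], labels the resulting foreground mask in 3D
#' and filters objects by size and edge contact.
#'
#' @param stack an [image_stack()] (typically already cropped).
#' @param channel channel name to segment.
#' @param min_voxels,exclude_edges,connectivity see
#'   [label_components_3d()] and [filter_objects()].
#' @return `list(threshold, table, labels, masked)`: the Otsu threshold,
#'   the filtered `object_table` (with a `channel` column), the full label
#'   volume and the filtered label volume.
#' @export
segment_stack <- function(stack, channel = "DiO", min_voxels = 10L,
                          exclude_edges = TRUE, connectivity = 26) {
  stopifnot(inherits(stack, "image_stack"),
            channel %in% names(stack$channels))
  vox <- stack$channels[[channel]]
  thr <- otsu_threshold(vox)
  lab <- label_components_3d(vox > thr, connectivity = connectivity,
                             voxel_size_zyx = stack$voxel_size_zyx)
  tab <- filter_objects(lab$table, min_voxels, exclude_edges)
  if (nrow(tab)) tab$channel <- channel else
    tab$channel <- character(0)
  list(threshold = as.numeric(thr), table = tab, labels = lab$labels,
       masked = masked_stack(lab$labels, tab))
}

#' Write / read an object table as CSV
#'
#' @param table an `object_table`.
#' @param path CSV path.
#' @return the path / the table.
#' @export
write_object_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_object_table
#' @export
read_object_table <- function(path) read.csv(path)
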