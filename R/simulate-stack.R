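#' Specification for a synthetic two-channel confocal stack
#'
#' Describes a ground-truthed z-stack emulating cells growing in a 3D
#' scaffold: isolated cells ("singletons"), cell clusters (a seed centre
#' plus members displaced by an isotropic Gaussian), and optionally a dense
#' layer of coverslip-adherent cells ("glass layer") occupying a contiguous
#' z range at one end of the stack. Cells are rendered as filled digital
#' spheres (a voxel belongs to a cell iff its centre lies within
#' `cell_radius_vox` of the cell centre) in the cell-dye channel, with a
#' smaller nuclear spot in the nuclear channel.
#'
#' @param shape_zyx integer length-3, voxel counts along (z, y, x).
#' @param voxel_size_zyx numeric length-3, micrometres per voxel; the
#'   default matches 2 um z steps with 1 um in-plane pixels.
#' @param n_singletons number of isolated cells.
#' @param n_clusters number of cell clusters.
#' @param cells_per_cluster integer length-2 inclusive range for the number
#'   of cells per cluster.
#' @param cell_radius_vox cell radius in voxels (>= 1).
#' @param cluster_spread_vox standard deviation (voxels) of member
#'   displacement around the cluster seed; members may overlap, in which
#'   case the rendered objects merge.
#' @param glass_layer `NULL` or `list(z_range = c(lo, hi), density = d,
#'   gain_scale = s)`: a contiguous slice range filled with cells until
#'   roughly a fraction `d` of its volume is foreground. Rendering is
#'   clipped to the range so glass signal never bleeds into scaffold
#'   slices. `gain_scale` (default 0.85) dims glass cells relative to
#'   scaffold cells: the layer dominates the per-slice summed intensity
#'   while the per-voxel absolute maximum stays in the scaffold, as when
#'   the in-focus scaffold signal is brightest but the adherent layer is
#'   densest.
#' @param noise `list(sd = , background = )`: Gaussian additive noise and a
#'   constant background level, clipped to the 8-bit range.
#' @param channel_gains named numeric, rendered intensity for `DiO` and
#'   `DAPI` foreground.
#' @param seed RNG seed; one global stream per generator call.
#' @return A validated list of class `stack_spec`.
#' @seealso [simulate_stack()]
#' @export
stack_spec <- function(shape_zyx = c(32, 96, 96),
                       voxel_size_zyx = c(2, 1, 1),
                       n_singletons = 10,
                       n_clusters = 4,
                       cells_per_cluster = c(3, 6),
                       cell_radius_vox = 2,
                       cluster_spread_vox = 2,
                       glass_layer = NULL,
                       noise = list(sd = 2, background = 8),
                       channel_gains = c(DiO = 180, DAPI = 220),
                       seed = 1L) {
  spec <- list(shape_zyx = as.integer(shape_zyx),
               voxel_size_zyx = as.numeric(voxel_size_zyx),
               n_singletons = as.integer(n_singletons),
               n_clusters = as.integer(n_clusters),
               cells_per_cluster = as.integer(cells_per_cluster),
               cell_radius_vox = as.integer(cell_radius_vox),
               cluster_spread_vox = as.numeric(cluster_spread_vox),
               glass_layer = glass_layer,
               noise = noise,
               channel_gains = channel_gains,
               seed = as.integer(seed))
  if (length(spec$shape_zyx) != 3 || any(spec$shape_zyx < 1))
    stop("shape_zyx must be three positive voxel counts")
  if (spec$n_singletons < 0 || spec$n_clusters < 0)
    stop("counts must be >= 0")
  if (spec$cell_radius_vox < 1) stop("cell_radius_vox must be >= 1")
  if (length(spec$cells_per_cluster) != 2 ||
      any(spec$cells_per_cluster < 1) ||
      spec$cells_per_cluster[1] > spec$cells_per_cluster[2])
    stop("cells_per_cluster must be an increasing positive range")
  if (!is.null(glass_layer)) {
    zr <- glass_layer$z_range
    if (length(zr) != 2 || zr[1] > zr[2] || zr[1] < 1 ||
        zr[2] > spec$shape_zyx[1])
      stop("glass z_range must lie within the stack")
    if (is.null(glass_layer$density) || glass_layer$density <= 0 ||
        glass_layer$density > 1)
      stop("glass density must be in (0, 1]")
    if (is.null(glass_layer$gain_scale))
      spec$glass_layer$gain_scale <- 0.85
  }
  structure(spec, class = "stack_spec")
}

# integer offsets of a filled digital sphere of radius r (voxel units)
sphere_offsets <- function(r) {
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  as.matrix(g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, ])
}

# paint spheres into `arr` at integer centres, value = gain, overlap via max;
# voxels outside bounds (and outside zclip, if given) are dropped.
# Returns per-centre rendered voxel counts.
paint_spheres <- function(arr, centers, r, gain, zclip = NULL) {
  d <- dim(arr)
  off <- sphere_offsets(r)
  counts <- integer(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    z <- centers[i, 1] + off[, 1]
    y <- centers[i, 2] + off[, 2]
    x <- centers[i, 3] + off[, 3]
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    if (!is.null(zclip)) ok <- ok & z >= zclip[1] & z <= zclip[2]
    counts[i] <- sum(ok)
    lin <- z[ok] + (y[ok] - 1) * d[1] + (x[ok] - 1) * d[1] * d[2]
    arr[lin] <- pmax(arr[lin], gain)
  }
  list(arr = arr, counts = counts)
}

#' Simulate a two-channel confocal stack with known ground truth
#'
#' Renders the cells described by a [stack_spec()] into an 8-bit
#' [image_stack()] and returns, alongside it, a truth table listing every
#' generated cell with its centre, intended group membership and rendered
#' voxel volume. Identical spec + seed gives bit-identical output.
#'
#' @param spec a [stack_spec()].
#' @return `list(stack = image_stack, truth = data.frame)`. The truth table
#'   has columns `object_id`, `kind` (`"singleton"`, `"cluster"`,
#'   `"glass"`), `group_id` (cluster index or `NA`), centre coordinates
#'   `z`, `y`, `x`, `radius` and `voxels` (rendered digital-sphere voxel
#'   count, before any overlap merging); the glass slice range is attached
#'   as `attr(truth, "glass_slices")`.
#' @examples
#' sim <- simulate_stack(stack_spec(shape_zyx = c(16, 48, 48),
#'                                  n_singletons = 3, n_clusters = 1,
#'                                  noise = list(sd = 0, background = 0)))
#' nrow(sim$truth)
#' @export
simulate_stack <- function(spec) {
  stopifnot(inherits(spec, "stack_spec"))
  withr::with_seed(spec$seed, simulate_stack_impl(spec))
}

simulate_stack_impl <- function(spec) {
  d <- spec$shape_zyx
  r <- spec$cell_radius_vox
  sp <- spec$cluster_spread_vox
  n_sph <- nrow(sphere_offsets(r))

  # z slices available for scaffold placement (glass range, padded by the
  # cell radius, is excluded so scaffold cells never touch the glass layer)
  glass <- spec$glass_layer
  zmin <- r + 2; zmax <- d[1] - r - 1   # one clear voxel inside each face
  # scaffold spheres stop one slice short of the glass layer, so that
  # cropping at the glass boundary never creates edge-touching objects
  forbid <- if (is.null(glass)) c(0, 0) else
    c(glass$z_range[1] - r - 1, glass$z_range[2] + r + 1)
  z_ok <- setdiff(seq(zmin, max(zmin, zmax)),
                  seq(forbid[1], forbid[2]))
  if (zmax < zmin || ((spec$n_singletons + spec$n_clusters) > 0 &&
                      length(z_ok) == 0))
    stop("overfull stack: no room for scaffold cells")

  # capacity pre-check: intended foreground must fit loosely in the volume
  max_cells <- spec$n_singletons + spec$n_clusters * spec$cells_per_cluster[2]
  if (max_cells * n_sph > 0.4 * length(z_ok) * d[2] * d[3])
    stop("overfull stack: requested cell volume exceeds capacity")

  # group seed centres by rejection sampling with a minimum separation so
  # that distinct intended objects do not merge after rendering
  ext_single <- r
  ext_cluster <- r + ceiling(3 * sp)
  n_groups <- spec$n_singletons + spec$n_clusters
  ext <- c(rep(ext_single, spec$n_singletons),
           rep(ext_cluster, spec$n_clusters))
  centers <- matrix(0L, n_groups, 3)
  placed <- 0
  for (i in seq_len(n_groups)) {
    pad <- ext[i] - r           # extra margin beyond the sphere radius
    ok_z <- z_ok[z_ok >= zmin + pad & z_ok <= zmax - pad]
    lo_yx <- ext[i] + 2; hi_yx <- d[2:3] - ext[i] - 1
    if (length(ok_z) == 0 || any(hi_yx < lo_yx))
      stop("overfull stack: group does not fit inside the volume")
    for (try in seq_len(2000)) {
      cand <- c(ok_z[sample.int(length(ok_z), 1)],
                sample(seq(lo_yx, hi_yx[1]), 1),
                sample(seq(lo_yx, hi_yx[2]), 1))
      if (placed == 0) { okc <- TRUE } else {
        dd <- sweep(centers[seq_len(placed), , drop = FALSE], 2, cand)
        okc <- all(sqrt(rowSums(dd^2)) >= ext[i] +
                     ext[seq_len(placed)] + 2)
      }
      if (okc) { centers[i, ] <- cand; placed <- placed + 1; break }
    }
    if (placed < i) stop("overfull stack: could not place all cells")
  }

  # expand clusters into member centres
  truth <- list()
  all_centers <- NULL
  if (spec$n_singletons > 0) {
    cs <- centers[seq_len(spec$n_singletons), , drop = FALSE]
    truth[[1]] <- data.frame(kind = "singleton", group_id = NA_integer_,
                             z = cs[, 1], y = cs[, 2], x = cs[, 3])
    all_centers <- cs
  }
  if (spec$n_clusters > 0) {
    for (ci in seq_len(spec$n_clusters)) {
      seedc <- centers[spec$n_singletons + ci, ]
      k <- spec$cells_per_cluster[1] +
        sample.int(spec$cells_per_cluster[2] -
                     spec$cells_per_cluster[1] + 1, 1) - 1L
      # members grow as a chain: each is displaced from the previous one
      # in an isotropic direction with a Gaussian-scale magnitude clamped
      # into [r, 2r - 1], so consecutive spheres overlap (the cluster
      # renders as one connected object) while still adding volume
      mem <- matrix(0, k, 3)
      mem[1, ] <- seedc
      for (mi in seq_len(k - 1)) {
        for (try in seq_len(40)) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          mag <- min(max(abs(rnorm(1, 0, max(sp, r))), r), 2 * r - 1)
          cand <- mem[mi, ] + round(u * mag)
          # reject candidates folding back onto non-adjacent members so
          # every cell contributes volume to the merged object
          dd <- sweep(mem[seq_len(mi - 1), , drop = FALSE], 2, cand)
          if (mi == 1 || all(rowSums(dd^2) >= r^2)) break
        }
        mem[mi + 1, ] <- cand
      }
      # project members onto the cluster's placement box (non-expansive,
      # so connectivity survives) and the volume interior
      box <- ext_cluster - r
      for (ax in 1:3) {
        mem[, ax] <- pmin(pmax(mem[, ax], seedc[ax] - box),
                          seedc[ax] + box)
      }
      zlo_m <- zmin; zhi_m <- zmax
      if (!is.null(glass)) {
        if (seedc[1] < forbid[1]) zhi_m <- min(zmax, forbid[1] - 1)
        else zlo_m <- max(zmin, forbid[2] + 1)
      }
      mem[, 1] <- pmin(pmax(mem[, 1], zlo_m), zhi_m)
      mem[, 2] <- pmin(pmax(mem[, 2], r + 2), d[2] - r - 1)
      mem[, 3] <- pmin(pmax(mem[, 3], r + 2), d[3] - r - 1)
      truth[[length(truth) + 1]] <-
        data.frame(kind = "cluster", group_id = ci,
                   z = mem[, 1], y = mem[, 2], x = mem[, 3])
      all_centers <- rbind(all_centers, mem)
    }
  }

  # glass layer: cells clipped to the glass z range
  glass_centers <- NULL
  if (!is.null(glass)) {
    zr <- glass$z_range
    n_glass_vox <- (zr[2] - zr[1] + 1) * d[2] * d[3]
    n_glass <- max(1L, round(glass$density * n_glass_vox / n_sph *
                               (zr[2] - zr[1] + 1 + 2 * r) /
                               (zr[2] - zr[1] + 1)))
    # centres drawn from a radius-extended range (rendering is clipped to
    # the layer) so coverage is uniform across every glass slice
    glass_centers <- cbind(
      z = sample(seq(zr[1] - r, zr[2] + r), n_glass, replace = TRUE),
      y = sample(seq_len(d[2]), n_glass, replace = TRUE),
      x = sample(seq_len(d[3]), n_glass, replace = TRUE))
    truth[[length(truth) + 1]] <-
      data.frame(kind = "glass", group_id = NA_integer_,
                 z = glass_centers[, 1], y = glass_centers[, 2],
                 x = glass_centers[, 3])
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(0), group_id = integer(0),
               z = integer(0), y = integer(0), x = integer(0))

  dio <- array(0, d); dapi <- array(0, d)
  voxn <- integer(nrow(truth))
  scaff_n <- nrow(truth) - if (is.null(glass_centers)) 0 else
    nrow(glass_centers)
  rn <- max(1L, floor(r / 2))
  if (scaff_n > 0) {
    sc <- as.matrix(truth[seq_len(scaff_n), c("z", "y", "x")])
    p <- paint_spheres(dio, sc, r, spec$channel_gains[["DiO"]])
    dio <- p$arr; voxn[seq_len(scaff_n)] <- p$counts
    dapi <- paint_spheres(dapi, sc, rn, spec$channel_gains[["DAPI"]])$arr
  }
  if (!is.null(glass_centers)) {
    zr <- glass$z_range
    gs <- glass$gain_scale
    p <- paint_spheres(dio, glass_centers, r,
                       round(gs * spec$channel_gains[["DiO"]]),
                       zclip = zr)
    dio <- p$arr; voxn[seq(scaff_n + 1, nrow(truth))] <- p$counts
    dapi <- paint_spheres(dapi, glass_centers, rn,
                          round(gs * spec$channel_gains[["DAPI"]]),
                          zclip = zr)$arr
  }

  add_noise <- function(a) {
    a <- a + spec$noise$background
    if (spec$noise$sd > 0)
      a <- a + array(rnorm(length(a), 0, spec$noise$sd), dim(a))
    array(round(pmin(pmax(a, 0), 255)), dim(a))
  }
  dio <- add_noise(dio); dapi <- add_noise(dapi)

  truth <- cbind(object_id = seq_len(nrow(truth)), truth)
  truth$radius <- if (nrow(truth)) r else integer(0)
  truth$voxels <- voxn
  attr(truth, "glass_slices") <-
    if (is.null(glass)) integer(0) else seq(glass$z_range[1], glass$z_range[2])

  list(stack = image_stack(list(DiO = dio, DAPI = dapi),
                           spec$voxel_size_zyx),
       truth = truth)
}
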