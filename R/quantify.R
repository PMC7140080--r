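#' Freedman-Diaconis bin width
#'
#' Default histogram bin width: `2 IQR / n^(1/3)`, falling back to a single
#' bin spanning the data when the IQR is zero.
#'
#' @param x numeric sample.
#' @return positive scalar bin width.
#' @export
fd_bin_width <- function(x) {
  iqr <- diff(quantile(x, c(0.25, 0.75), names = FALSE, type = 7))
  w <- 2 * iqr / length(x)^(1 / 3)
  if (w <= 0) w <- max(diff(range(x)), 1)
  w
}

#' Object-volume density histogram
#'
#' Bins object volumes into a density histogram (bar areas sum to 1). With
#' `peak_region = TRUE` the domain is restricted to `[0, mean + 2 sd]`,
#' with the mean and standard deviation taken from the full input sample;
#' densities are renormalized over the restricted domain so they again
#' integrate to 1.
#'
#' @param volumes numeric vector of object volumes (um^3).
#' @param bin_width bin width in um^3; defaults to Freedman-Diaconis on
#'   the input.
#' @param peak_region restrict the domain to `[0, mean + 2 sd]`.
#' @param condition,day optional labels carried through to the output.
#' @return A `volume_histogram`: list with `breaks`, `density`, `counts`,
#'   `mean`, `sd`, `peak_region_domain` (`c(0, mean + 2 sd)`, or `NULL`
#'   when not restricted), `n`, `condition`, `day`.
#' @examples
#' h <- volume_density_histogram(c(10, 12, 14, 100), bin_width = 5)
#' sum(h$density * diff(h$breaks))   # 1
#' @export
volume_density_histogram <- function(volumes, bin_width = NULL,
                                     peak_region = FALSE,
                                     condition = NA_character_,
                                     day = NA_character_) {
  if (length(volumes) < 1) stop("no volumes to histogram")
  if (is.null(bin_width)) bin_width <- fd_bin_width(volumes)
  if (bin_width <= 0) stop("bin_width must be > 0")
  m <- mean(volumes)
  s <- if (length(volumes) > 1) sd(volumes) else 0
  dom <- c(0, m + 2 * s)
  v <- volumes
  if (peak_region) v <- v[v >= 0 & v <= dom[2]]
  if (length(v) == 0) stop("no volumes inside the peak-region domain")
  top <- if (peak_region) dom[2] else max(v)
  breaks <- seq(0, top + bin_width, by = bin_width)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  density <- counts / (sum(counts) * bin_width)
  structure(list(breaks = breaks, density = density, counts = counts,
                 mean = m, sd = s,
                 peak_region_domain = if (peak_region) dom else NULL,
                 n = length(v), condition = condition, day = day),
            class = "volume_histogram")
}

#' @export
print.volume_histogram <- function(x, ...) {
  cat(sprintf("volume_histogram: %d objects in %d bins, mean %.1f um^3%s\n",
              x$n, length(x$counts), x$mean,
              if (!is.null(x$peak_region_domain))
                sprintf(", peak region [0, %.1f]", x$peak_region_domain[2])
              else ""))
  invisible(x)
}

#' Scalar clustering metrics from an object table
#'
#' Operationalizes "clustered vs non-clustered" with a declared cutoff: an
#' object is a singleton if its volume is below twice the calibrated
#' single-cell volume, otherwise a cluster. This scalar summary is an
#' artifact-defined reading of a histogram-shape comparison, and the
#' outputs flag it as such via the recorded `unit_volume`.
#'
#' @param table an `object_table` (needs a `volume_um3` column), or a
#'   numeric vector of volumes.
#' @param unit_volume calibrated single-cell volume in um^3; default is
#'   the mode of the Freedman-Diaconis volume histogram (the most common
#'   object size, taken to approximate a single cell).
#' @return A `clustering_metrics` list: `unit_volume`,
#'   `singleton_fraction`, `cluster_fraction` (`1 - singleton_fraction`),
#'   `n_objects`, `n_clusters`, `mean_cluster_volume`, and
#'   `cells_per_object` (volumes divided by `unit_volume`, rounded, at
#'   least 1).
#' @examples
#' clustering_metrics(c(100, 100, 500), unit_volume = 100)$cluster_fraction
#' @export
clustering_metrics <- function(table, unit_volume = NULL) {
  volumes <- if (is.data.frame(table)) table$volume_um3 else table
  if (length(volumes) == 0) stop("no objects")
  if (is.null(unit_volume)) {
    h <- volume_density_histogram(volumes)
    i <- which.max(h$counts)
    unit_volume <- (h$breaks[i] + h$breaks[i + 1]) / 2
  }
  if (unit_volume <= 0) stop("unit_volume must be > 0")
  is_cluster <- volumes >= 2 * unit_volume
  structure(list(
    unit_volume = unit_volume,
    singleton_fraction = mean(!is_cluster),
    cluster_fraction = mean(is_cluster),
    n_objects = length(volumes),
    n_clusters = sum(is_cluster),
    mean_cluster_volume = if (any(is_cluster)) mean(volumes[is_cluster])
      else NA_real_,
    cells_per_object = pmax(1, round(volumes / unit_volume))),
    class = "clustering_metrics")
}

#' @export
print.clustering_metrics <- function(x, ...) {
  cat(sprintf(
    "clustering_metrics: %d objects, unit %.1f um^3, cluster fraction %.3f\n",
    x$n_objects, x$unit_volume, x$cluster_fraction))
  invisible(x)
}

#' Compare clustering metrics across conditions
#'
#' Tabulates per-condition (and optionally per-day) metrics side by side
#' with differences relative to the first condition. No inferential
#' statistics are attached: the comparison is a descriptive ordering.
#'
#' @param metrics named list of `clustering_metrics` (names = condition
#'   labels), or, for multi-day designs, a named list per condition of
#'   named lists per day; every condition must then carry the same day
#'   labels.
#' @return A data.frame with one row per condition (and day): `condition`,
#'   `day`, `n_objects`, `unit_volume`, `singleton_fraction`,
#'   `cluster_fraction`, `mean_cluster_volume` and
#'   `cluster_fraction_diff` (relative to the first condition within each
#'   day).
#' @export
compare_conditions <- function(metrics) {
  if (length(metrics) < 2) stop("need at least 2 conditions to compare")
  if (is.null(names(metrics))) stop("metrics must be named by condition")
  nested <- !inherits(metrics[[1]], "clustering_metrics")
  if (nested) {
    days <- lapply(metrics, names)
    if (length(unique(lapply(days, sort))) != 1)
      stop("mismatched day labels across conditions")
  } else {
    metrics <- lapply(metrics, function(m) list(all = m))
  }
  rows <- list()
  for (cc in names(metrics)) for (dd in names(metrics[[cc]])) {
    m <- metrics[[cc]][[dd]]
    stopifnot(inherits(m, "clustering_metrics"))
    rows[[length(rows) + 1]] <-
      data.frame(condition = cc, day = dd, n_objects = m$n_objects,
                 unit_volume = m$unit_volume,
                 singleton_fraction = m$singleton_fraction,
                 cluster_fraction = m$cluster_fraction,
                 mean_cluster_volume = m$mean_cluster_volume)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$day, match(out$condition, names(metrics))), ]
  rownames(out) <- NULL
  ref <- out$cluster_fraction[match(paste(out$day, names(metrics)[1]),
                                    paste(out$day, out$condition))]
  out$cluster_fraction_diff <- out$cluster_fraction - ref
  out
}

#' Write a volume histogram as TSV
#'
#' @param hist a `volume_histogram`.
#' @param path TSV path.
#' @return the path, invisibly.
#' @export
write_volume_histogram <- function(hist, path) {
  df <- data.frame(bin_lo = head(hist$breaks, -1),
                   bin_hi = hist$breaks[-1],
                   count = hist$counts, density = hist$density,
                   condition = hist$condition, day = hist$day)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
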