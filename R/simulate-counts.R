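#' Specification for a synthetic gene-by-cell count matrix
#'
#' Describes negative-binomial counts for a set of experimental conditions,
#' with a block of mitochondrial genes whose expected share of each cell's
#' counts is set per condition, a small "stem-like" subpopulation
#' overexpressing a panel of marker genes by a fixed fold, and an optional
#' tail of cells whose totals exceed a molecule-count trim threshold.
#'
#' @param n_genes number of genes (mitochondrial block included).
#' @param n_cells_per_condition named integer vector: cells per condition,
#'   e.g. `c(control = 500, treated = 500)`.
#' @param nb_mean negative-binomial mean per gene per cell (non-mito
#'   baseline).
#' @param nb_dispersion negative-binomial `size` parameter (> 0; large
#'   values approach Poisson).
#' @param mito_gene_count number of mitochondrial genes (named `MT-1`,
#'   `MT-2`, ...); must be < `n_genes`.
#' @param mito_fraction_by_condition named numeric in `[0, 1)`: target
#'   expected fraction of each cell's counts coming from mitochondrial
#'   genes, per condition. A fraction of exactly 0 zeroes the mito block.
#' @param stem_subpop `list(fraction = , markers = , fold = )`: fraction of
#'   cells (within the first condition) labelled stem-like, the marker
#'   genes elevated, and the fold elevation of their mean.
#' @param max_molecules_tail fraction of cells whose counts are scaled up
#'   until their total exceeds `trim_threshold` (emulating droplets that a
#'   molecule-count QC rule should remove).
#' @param trim_threshold molecule-count threshold the tail is pushed past.
#' @param seed RNG seed.
#' @return A validated list of class `counts_spec`.
#' @seealso [simulate_counts()]
#' @export
counts_spec <- function(n_genes = 500,
                        n_cells_per_condition = c(control = 400,
                                                  treated = 400),
                        nb_mean = 2,
                        nb_dispersion = 1,
                        mito_gene_count = 10,
                        mito_fraction_by_condition = c(control = 0.05,
                                                       treated = 0.30),
                        stem_subpop = list(fraction = 0.1,
                                           markers = c("SOX2", "FOXM1",
                                                       "CD44", "SOX4"),
                                           fold = 4),
                        max_molecules_tail = 0,
                        trim_threshold = 40000,
                        seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_cells_per_condition = n_cells_per_condition,
               nb_mean = nb_mean, nb_dispersion = nb_dispersion,
               mito_gene_count = as.integer(mito_gene_count),
               mito_fraction_by_condition = mito_fraction_by_condition,
               stem_subpop = stem_subpop,
               max_molecules_tail = max_molecules_tail,
               trim_threshold = trim_threshold,
               seed = as.integer(seed))
  if (is.null(names(spec$n_cells_per_condition)))
    stop("n_cells_per_condition must be named by condition")
  if (spec$mito_gene_count >= spec$n_genes)
    stop("mito_gene_count must be smaller than n_genes")
  if (spec$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  f <- spec$mito_fraction_by_condition
  if (any(f < 0 | f >= 1)) stop("mito fractions must lie in [0, 1)")
  if (!setequal(names(f), names(spec$n_cells_per_condition)))
    stop("mito fractions and cell counts must name the same conditions")
  s <- spec$stem_subpop
  if (s$fraction < 0 || s$fraction > 1) stop("stem fraction must be in [0, 1]")
  if (spec$max_molecules_tail < 0 || spec$max_molecules_tail > 1)
    stop("max_molecules_tail must be in [0, 1]")
  structure(spec, class = "counts_spec")
}

#' Simulate a sparse gene-by-cell count matrix with truth labels
#'
#' Draws counts per the [counts_spec()]: baseline negative-binomial counts;
#' mitochondrial genes whose mean is scaled so their expected share of each
#' cell's counts matches the per-condition target (`mu_mt = f/(1-f) *
#' total_non_mito_mu / n_mito`); stem-like cells with marker means elevated
#' `fold`-fold; and tail cells integer-scaled until their total strictly
#' exceeds the trim threshold.
#'
#' @param spec a [counts_spec()].
#' @return A `count_matrix`: `list(counts = dgCMatrix genes x cells,
#'   gene_meta = data.frame(gene, mito), cell_meta = data.frame(barcode,
#'   condition, cluster, is_stem, is_tail, total))`. Cluster labels encode
#'   the generating population (condition, with stem cells as their own
#'   cluster) for use by downstream dot-plot / DE statistics.
#' @examples
#' cm <- simulate_counts(counts_spec(n_genes = 50,
#'   n_cells_per_condition = c(control = 30, treated = 30),
#'   mito_gene_count = 5, seed = 7))
#' dim(cm$counts)
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "counts_spec"))
  withr::with_seed(spec$seed, simulate_counts_impl(spec))
}

simulate_counts_impl <- function(spec) {
  conds <- names(spec$n_cells_per_condition)
  n_cells <- sum(spec$n_cells_per_condition)
  n_mt <- spec$mito_gene_count
  markers <- spec$stem_subpop$markers
  n_marker <- length(markers)
  n_plain <- spec$n_genes - n_mt - n_marker
  if (n_plain < 0) stop("n_genes too small for mito block plus markers")
  genes <- c(if (n_mt) paste0("MT-", seq_len(n_mt)),
             markers,
             if (n_plain) paste0("GENE", seq_len(n_plain)))
  mito <- genes %in% (if (n_mt) paste0("MT-", seq_len(n_mt)) else character(0))

  condition <- rep(conds, spec$n_cells_per_condition)
  barcode <- sprintf("CELL%05d", seq_len(n_cells))

  # stem subpopulation: an exact count of cells within the first condition
  is_stem <- rep(FALSE, n_cells)
  n_stem <- round(spec$stem_subpop$fraction *
                    spec$n_cells_per_condition[[1]])
  if (n_stem > 0) {
    idx1 <- which(condition == conds[1])
    is_stem[sample(idx1, n_stem)] <- TRUE
  }

  # per-gene, per-cell mean matrix assembled column-block-wise by condition
  mu_base <- spec$nb_mean
  non_mito_total_mu <- (spec$n_genes - n_mt) * mu_base
  counts <- matrix(0L, spec$n_genes, n_cells)
  for (cc in conds) {
    cells <- which(condition == cc)
    f <- spec$mito_fraction_by_condition[[cc]]
    mu <- matrix(mu_base, spec$n_genes, length(cells))
    mu[mito, ] <- if (f == 0) 0 else
      f / (1 - f) * non_mito_total_mu / n_mt
    stem_here <- is_stem[cells]
    if (any(stem_here) && n_marker > 0)
      mu[match(markers, genes), stem_here] <-
        mu_base * spec$stem_subpop$fold
    draw <- rnbinom(length(mu), mu = mu, size = spec$nb_dispersion)
    counts[, cells] <- matrix(draw, nrow = spec$n_genes)
  }

  # high-total tail: scale whole cells by the smallest integer factor that
  # pushes the total strictly past the trim threshold
  is_tail <- rep(FALSE, n_cells)
  n_tail <- round(spec$max_molecules_tail * n_cells)
  if (n_tail > 0) {
    tl <- sample(n_cells, n_tail)
    is_tail[tl] <- TRUE
    for (j in tl) {
      tot <- sum(counts[, j])
      if (tot == 0) { counts[1, j] <- spec$trim_threshold + 1; next }
      counts[, j] <- counts[, j] * ceiling((spec$trim_threshold + 1) / tot)
    }
  }

  cluster <- ifelse(is_stem, "stem", condition)
  cm <- Matrix::Matrix(counts, sparse = TRUE)
  dimnames(cm) <- list(genes, barcode)
  structure(list(
    counts = cm,
    gene_meta = data.frame(gene = genes, mito = mito),
    cell_meta = data.frame(barcode = barcode, condition = condition,
                           cluster = cluster, is_stem = is_stem,
                           is_tail = is_tail,
                           total = Matrix::colSums(cm))),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%d mito genes, %d conditions)\n",
              nrow(x$counts), ncol(x$counts), sum(x$gene_meta$mito),
              length(unique(x$cell_meta$condition))))
  invisible(x)
}
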