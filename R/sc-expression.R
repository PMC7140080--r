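#' Trim cells by total molecule count
#'
#' Removes cells whose total count strictly exceeds `max_molecules`
#' (default 40,000): a cell with exactly the threshold total is retained.
#'
#' @param cm a `count_matrix` (see [simulate_counts()] /
#'   [read_count_matrix()]).
#' @param max_molecules molecule-count threshold.
#' @return the trimmed `count_matrix`, with `n_removed` attached as an
#'   attribute.
#' @export
qc_trim <- function(cm, max_molecules = 40000) {
  totals <- Matrix::colSums(cm$counts)
  keep <- totals <= max_molecules
  if (!any(keep)) stop("all cells removed by the molecule-count trim")
  out <- cm
  out$counts <- cm$counts[, keep, drop = FALSE]
  out$cell_meta <- cm$cell_meta[keep, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  out$cell_meta$total <- Matrix::colSums(out$counts)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Percent mitochondrial RNA per cell
#'
#' `100 * (counts on mitochondrial genes) / (total counts)` per cell,
#' computed from the count matrix. (When applied to a matrix of counted
#' molecules this approximates read-level percentages.)
#'
#' @param cm a `count_matrix` with a `mito` flag in `gene_meta`.
#' @return named numeric vector of percentages in `[0, 100]`; also written
#'   into `cm$cell_meta$percent_mt` when assigned via
#'   `add_percent_mtrna()`.
#' @export
percent_mtrna <- function(cm) {
  totals <- Matrix::colSums(cm$counts)
  if (any(totals == 0)) stop("empty cell: zero total counts")
  mito <- cm$gene_meta$mito
  mt <- if (any(mito))
    Matrix::colSums(cm$counts[mito, , drop = FALSE]) else
      numeric(ncol(cm$counts))
  setNames(100 * mt / totals, colnames(cm$counts))
}

#' @rdname percent_mtrna
#' @return `add_percent_mtrna()` returns `cm` with a `percent_mt` column
#'   in `cell_meta`.
#' @export
add_percent_mtrna <- function(cm) {
  cm$cell_meta$percent_mt <- as.numeric(percent_mtrna(cm))
  cm
}

#' Median size-factor normalization
#'
#' Each cell's counts are divided by its size factor, defined as the
#' cell's total count divided by the median total over all cells. Every
#' normalized cell total therefore equals the median raw total.
#'
#' @param cm a `count_matrix`.
#' @return `cm` with `counts` replaced by the normalized (dense-value
#'   sparse) matrix and `size_factor` recorded in `cell_meta`.
#' @examples
#' cm <- simulate_counts(counts_spec(n_genes = 40,
#'   n_cells_per_condition = c(control = 20, treated = 20),
#'   mito_gene_count = 4, seed = 1))
#' norm <- size_factor_normalize(cm)
#' range(Matrix::colSums(norm$counts))  # both equal the median raw total
#' @export
size_factor_normalize <- function(cm) {
  totals <- Matrix::colSums(cm$counts)
  if (any(totals == 0)) stop("empty cell: zero total counts")
  sf <- totals / median(totals)
  out <- cm
  out$counts <- cm$counts %*% Matrix::Diagonal(x = 1 / sf)
  dimnames(out$counts) <- dimnames(cm$counts)
  out$cell_meta$size_factor <- sf
  attr(out, "normalized") <- TRUE
  out
}

# two-sided rank-sum p value; exact by enumeration of rank assignments
# when both groups are small, otherwise tie-corrected normal approximation
rank_sum_p <- function(x, y, exact_max = 10L) {
  na <- length(x); nb <- length(y); n <- na + nb
  r <- rank(c(x, y))
  w <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (na <= exact_max && nb <= exact_max) {
    sums <- colSums(matrix(r[combn(n, na)], nrow = na))
    return(min(1, mean(abs(sums - mu) >= abs(w - mu) - 1e-9)))
  }
  ties <- table(r)
  sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(1)
  min(1, 2 * pnorm(-abs(w - mu) / sqrt(sig2)))
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-group differential expression on a normalized count
#' matrix. The log fold change is the natural log of the ratio of group
#' means after adding a pseudocount of 1: `ln((mean_a + 1)/(mean_b + 1))`.
#' Genes are pre-filtered to `|LFC| > lfc_threshold` before testing, so
#' the Bonferroni factor `m` counts only tested genes. P values come from
#' a two-sided rank-sum test: exact enumeration of rank assignments when
#' both groups have at most 10 cells, otherwise a tie-corrected normal
#' approximation. A gene is reported significant when `|LFC| >
#' lfc_threshold` and its (by default Bonferroni-adjusted) p value is
#' below `alpha`.
#'
#' @param cm a normalized `count_matrix` (see [size_factor_normalize()]).
#' @param cells_a,cells_b disjoint barcode vectors (or column indices) of
#'   the two groups, each with at least 3 cells.
#' @param lfc_threshold natural-log fold-change pre-filter (default 0.25).
#' @param alpha significance level on the chosen p value (default 0.01).
#' @param p_use which p value the significance flag uses: `"adjusted"`
#'   (default) or `"raw"`; both are always reported.
#' @return data.frame with one row per tested gene: `gene`, `lfc`,
#'   `mean_a`, `mean_b`, `pct_a`, `pct_b`, `p`, `p_adj` (Bonferroni,
#'   `min(1, p * m)`), `significant`. The number of genes tested is
#'   attached as `attr(, "m")`.
#' @export
wilcoxon_de <- function(cm, cells_a, cells_b, lfc_threshold = 0.25,
                        alpha = 0.01, p_use = c("adjusted", "raw")) {
  p_use <- match.arg(p_use)
  mat <- cm$counts
  if (is.character(cells_a)) cells_a <- match(cells_a, colnames(mat))
  if (is.character(cells_b)) cells_b <- match(cells_b, colnames(mat))
  if (anyNA(cells_a) || anyNA(cells_b)) stop("unknown cell barcodes")
  if (length(intersect(cells_a, cells_b)) > 0)
    stop("groups overlap")
  if (length(cells_a) < 3 || length(cells_b) < 3)
    stop("each group needs at least 3 cells")
  a <- mat[, cells_a, drop = FALSE]
  b <- mat[, cells_b, drop = FALSE]
  mean_a <- Matrix::rowMeans(a); mean_b <- Matrix::rowMeans(b)
  lfc <- log((mean_a + 1) / (mean_b + 1))
  tested <- which(abs(lfc) > lfc_threshold)
  m <- length(tested)
  res <- data.frame(gene = rownames(mat)[tested],
                    lfc = lfc[tested],
                    mean_a = mean_a[tested], mean_b = mean_b[tested],
                    pct_a = Matrix::rowSums(a[tested, , drop = FALSE] > 0) /
                      ncol(a) * 100,
                    pct_b = Matrix::rowSums(b[tested, , drop = FALSE] > 0) /
                      ncol(b) * 100,
                    row.names = NULL)
  res$p <- vapply(tested, function(g)
    rank_sum_p(as.numeric(a[g, ]), as.numeric(b[g, ])), 1.0)
  res$p_adj <- pmin(1, res$p * m)
  res$significant <- (if (p_use == "adjusted") res$p_adj else res$p) < alpha
  res <- res[order(res$p, -abs(res$lfc)), ]
  rownames(res) <- NULL
  attr(res, "m") <- m
  res
}

#' Dot-plot statistics: mean expression and percent expressing
#'
#' For each requested gene and each cluster, the mean normalized
#' expression and the percentage of cells with a non-zero count.
#'
#' @param cm a (normalized) `count_matrix` with a `cluster` column in
#'   `cell_meta`.
#' @param genes gene panel; unknown genes are reported in
#'   `attr(, "skipped")` rather than raising an error.
#' @param clusters optional subset of cluster labels (default: all).
#' @return data.frame with columns `cluster`, `gene`, `mean_expr`,
#'   `pct_expr`.
#' @export
dotplot_stats <- function(cm, genes, clusters = NULL) {
  known <- intersect(genes, rownames(cm$counts))
  skipped <- setdiff(genes, known)
  if (is.null(clusters)) clusters <- unique(cm$cell_meta$cluster)
  rows <- list()
  for (cl in clusters) {
    cells <- which(cm$cell_meta$cluster == cl)
    if (length(cells) == 0) stop("empty cluster: ", cl)
    sub <- cm$counts[known, cells, drop = FALSE]
    rows[[cl]] <- data.frame(
      cluster = cl, gene = known,
      mean_expr = as.numeric(Matrix::rowMeans(sub)),
      pct_expr = as.numeric(Matrix::rowSums(sub > 0)) /
        length(cells) * 100)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Per-group fraction of cells below a metric threshold
#'
#' E.g. the fraction of cells per condition with percent mitochondrial
#' RNA under 10. The comparison is strict (`metric < threshold`).
#'
#' @param cell_meta data.frame of per-cell metadata.
#' @param metric metadata column name.
#' @param threshold numeric threshold.
#' @param group_by grouping column name (default `"condition"`).
#' @return data.frame with `group`, `n`, `n_below`, `fraction`.
#' @export
population_fraction <- function(cell_meta, metric, threshold,
                                group_by = "condition") {
  stopifnot(metric %in% names(cell_meta), group_by %in% names(cell_meta))
  groups <- unique(cell_meta[[group_by]])
  rows <- lapply(groups, function(g) {
    v <- cell_meta[[metric]][cell_meta[[group_by]] == g]
    if (length(v) == 0) stop("empty group: ", g)
    data.frame(group = g, n = length(v), n_below = sum(v < threshold),
               fraction = mean(v < threshold))
  })
  do.call(rbind, rows)
}

#' Cluster composition per sample
#'
#' Counts cells by cluster and sample/condition, the table behind
#' per-sample cluster-occupancy summaries.
#'
#' @param cell_meta per-cell metadata.
#' @param sample_col,cluster_col column names.
#' @return data.frame `cluster`, `sample`, `n`, `fraction_of_sample`.
#' @export
cluster_composition <- function(cell_meta, sample_col = "condition",
                                cluster_col = "cluster") {
  tab <- as.data.frame(table(cluster = cell_meta[[cluster_col]],
                             sample = cell_meta[[sample_col]]))
  names(tab)[3] <- "n"
  totals <- tapply(tab$n, tab$sample, sum)
  tab$fraction_of_sample <- tab$n / as.numeric(totals[tab$sample])
  tab
}
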