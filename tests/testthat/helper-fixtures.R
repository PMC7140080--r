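# Shared fixture recipes. All fixtures are generated in code at test time.

fixture_glass_spec <- function(seed = 1) {
  stack_spec(shape_zyx = c(28, 96, 96), n_singletons = 10, n_clusters = 5,
             cells_per_cluster = c(4, 4),
             glass_layer = list(z_range = c(24, 28), density = 0.3),
             noise = list(sd = 2, background = 8), seed = seed)
}

fixture_singleton_spec <- function(n = 8, seed = 1, noise_sd = 2) {
  stack_spec(shape_zyx = c(20, 64, 64), n_singletons = n, n_clusters = 0,
             noise = list(sd = noise_sd, background = 8), seed = seed)
}

# tiny count matrix with hand-set totals, for exactness checks
manual_count_matrix <- function(counts, mito = NULL, condition = NULL) {
  genes <- rownames(counts)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(counts)))
  cells <- colnames(counts)
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(counts)))
  cm <- Matrix::Matrix(counts, sparse = TRUE)
  dimnames(cm) <- list(genes, cells)
  if (is.null(mito)) mito <- rep(FALSE, nrow(counts))
  if (is.null(condition)) condition <- rep("a", ncol(counts))
  structure(list(counts = cm,
                 gene_meta = data.frame(gene = genes, mito = mito),
                 cell_meta = data.frame(barcode = cells,
                                        condition = condition,
                                        cluster = condition,
                                        total = Matrix::colSums(cm))),
            class = "count_matrix")
}
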