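#' Specification for synthetic interaction networks, gene sets and DEGs
#'
#' Describes edge tables at several systems-biology levels over a common
#' gene universe, a differential-expression table whose significant rows
#' define the seed genes, one planted dense clique among the DEGs at a
#' designated level, and a gene-set collection containing one planted term
#' strongly enriched in the DEG list among uniformly drawn background
#' terms.
#'
#' @param n_genes size of the gene universe (`G00001`, ...).
#' @param n_deg number of significant genes in the DEG table (the table
#'   additionally carries the same number of non-significant rows).
#' @param edges_per_level named integer vector: random background edges per
#'   level, e.g. `c(ppi = 400, tf = 300, mirna = 300, coexpression = 400)`.
#'   Levels `tf` and `mirna` connect genes to regulator nodes (`TF...`,
#'   `MIR...`); other levels connect genes to genes.
#' @param planted_clique_size size (>= 3) of the clique planted among DEGs.
#' @param planted_clique_level level receiving the clique.
#' @param planted_term `list(id = , size = , deg_fraction = )`: the planted
#'   gene set; `round(size * deg_fraction)` members are drawn from the DEG
#'   list, the rest from non-DEG genes.
#' @param n_terms number of background terms.
#' @param term_size_range inclusive size range for background terms.
#' @param seed RNG seed.
#' @return A validated list of class `network_spec`.
#' @seealso [simulate_networks()]
#' @export
network_spec <- function(n_genes = 1000,
                         n_deg = 60,
                         edges_per_level = c(ppi = 500, tf = 400,
                                             mirna = 400,
                                             coexpression = 500),
                         planted_clique_size = 8,
                         planted_clique_level = "ppi",
                         planted_term = list(id = "TERM_PLANTED",
                                             size = 25,
                                             deg_fraction = 0.8),
                         n_terms = 40,
                         term_size_range = c(10, 40),
                         seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_deg = as.integer(n_deg),
               edges_per_level = edges_per_level,
               planted_clique_size = as.integer(planted_clique_size),
               planted_clique_level = planted_clique_level,
               planted_term = planted_term,
               n_terms = as.integer(n_terms),
               term_size_range = as.integer(term_size_range),
               seed = as.integer(seed))
  if (is.null(names(spec$edges_per_level)))
    stop("edges_per_level must be named by level")
  if (spec$planted_clique_size < 3)
    stop("planted_clique_size must be >= 3")
  if (!planted_clique_level %in% names(edges_per_level))
    stop("planted_clique_level must be one of the levels")
  if (spec$n_deg > 0 && spec$planted_clique_size > spec$n_deg)
    stop("planted clique cannot exceed the DEG list")
  if (max(spec$term_size_range) > spec$n_genes ||
      spec$planted_term$size > spec$n_genes)
    stop("term sizes exceed the gene universe")
  if (spec$n_deg > spec$n_genes) stop("n_deg exceeds the universe")
  structure(spec, class = "network_spec")
}

#' Simulate multi-level edge tables, a gene-set collection and a DEG table
#'
#' @param spec a [network_spec()].
#' @return `list(edges = data.frame(source, target, level), gene_sets =
#'   named list of character vectors, de_table = data.frame(gene, logFC,
#'   adj_p), truth = list(degs, clique, clique_level, planted_term))`.
#'   Each level's edge set is simple: no self-loops, no duplicate
#'   (unordered) pairs within a level.
#' @examples
#' nets <- simulate_networks(network_spec(n_genes = 200, n_deg = 20,
#'   edges_per_level = c(ppi = 80, coexpression = 80),
#'   planted_clique_size = 5, n_terms = 10, seed = 3))
#' table(nets$edges$level)
#' @export
simulate_networks <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  withr::with_seed(spec$seed, simulate_networks_impl(spec))
}

simulate_networks_impl <- function(spec) {
  genes <- sprintf("G%05d", seq_len(spec$n_genes))

  # DEG table: n_deg significant rows plus as many non-significant ones
  degs <- if (spec$n_deg > 0) sample(genes, spec$n_deg) else character(0)
  nondeg_rows <- sample(setdiff(genes, degs),
                        min(spec$n_deg, spec$n_genes - spec$n_deg))
  de_table <- data.frame(
    gene = c(degs, nondeg_rows),
    logFC = round(c(sample(c(-1, 1), spec$n_deg, TRUE) *
                      runif(spec$n_deg, 0.3, 2.5),
                    runif(length(nondeg_rows), -0.2, 0.2)), 4),
    adj_p = round(c(runif(spec$n_deg, 1e-6, 0.049),
                    runif(length(nondeg_rows), 0.05, 1)), 6))

  # edge tables: each level gets random simple edges; every DEG is given at
  # least one incident edge so first-order networks cover the seed list
  levels <- names(spec$edges_per_level)
  partner_pool <- function(level, n) {
    switch(level,
           tf = sprintf("TF%03d", sample.int(80, n, replace = TRUE)),
           mirna = sprintf("MIR%03d", sample.int(80, n, replace = TRUE)),
           sample(genes, n, replace = TRUE))
  }
  edge_blocks <- list()
  for (lv in levels) {
    n_e <- spec$edges_per_level[[lv]]
    a <- c(sample(genes, n_e, replace = TRUE), degs)
    b <- c(partner_pool(lv, n_e), partner_pool(lv, length(degs)))
    keep <- a != b
    e <- data.frame(source = a[keep], target = b[keep], level = lv)
    edge_blocks[[lv]] <- e
  }
  # planted clique among DEGs at the designated level
  clique <- character(0)
  if (spec$n_deg >= spec$planted_clique_size) {
    clique <- sample(degs, spec$planted_clique_size)
    pairs <- combn(clique, 2)
    edge_blocks[[length(edge_blocks) + 1]] <-
      data.frame(source = pairs[1, ], target = pairs[2, ],
                 level = spec$planted_clique_level)
  }
  edges <- do.call(rbind, edge_blocks)
  key <- paste(pmin(edges$source, edges$target),
               pmax(edges$source, edges$target), edges$level)
  edges <- edges[!duplicated(key), ]
  rownames(edges) <- NULL

  # gene sets: planted term biased to DEGs, background terms uniform
  pt <- spec$planted_term
  n_from_deg <- min(round(pt$size * pt$deg_fraction), length(degs))
  planted <- c(sample(degs, n_from_deg),
               sample(setdiff(genes, degs), pt$size - n_from_deg))
  gene_sets <- list()
  gene_sets[[pt$id]] <- sort(planted)
  for (i in seq_len(spec$n_terms)) {
    sz <- sample(seq(spec$term_size_range[1], spec$term_size_range[2]), 1)
    gene_sets[[sprintf("TERM_%03d", i)]] <- sort(sample(genes, sz))
  }

  list(edges = edges, gene_sets = gene_sets, de_table = de_table,
       truth = list(degs = degs, clique = sort(clique),
                    clique_level = spec$planted_clique_level,
                    planted_term = pt$id, universe = genes))
}
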