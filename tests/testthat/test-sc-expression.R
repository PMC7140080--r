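test_that("the molecule-count trim boundary is strict", {
  counts <- matrix(0, 2, 3)
  counts[1, ] <- c(40000, 40001, 100)
  cm <- manual_count_matrix(counts)
  trimmed <- qc_trim(cm)
  expect_equal(colnames(trimmed$counts), c("c1", "c3"))
  expect_equal(attr(trimmed, "n_removed"), 1)
  untouched <- qc_trim(manual_count_matrix(matrix(1, 2, 2)))
  expect_equal(ncol(untouched$counts), 2)
  expect_error(qc_trim(cm, max_molecules = 50), "all cells")
})

test_that("percent mitochondrial RNA is an exact per-cell ratio", {
  counts <- rbind(mt = c(5, 0), other = c(45, 10))
  cm <- manual_count_matrix(counts, mito = c(TRUE, FALSE))
  expect_equal(unname(percent_mtrna(cm)), c(10, 0))
  no_mt <- manual_count_matrix(counts, mito = c(FALSE, FALSE))
  expect_equal(unname(percent_mtrna(no_mt)), c(0, 0))
  zero <- manual_count_matrix(matrix(c(1, 0), 1, 2))
  expect_error(percent_mtrna(zero), "empty cell")
})

test_that("size factors equal total over median and conserve totals", {
  counts <- matrix(0, 2, 3)
  counts[1, ] <- c(100, 200, 400)
  cm <- manual_count_matrix(counts)
  norm <- size_factor_normalize(cm)
  expect_equal(unname(norm$cell_meta$size_factor), c(0.5, 1, 2))
  expect_equal(unname(Matrix::colSums(norm$counts)), rep(200, 3),
               tolerance = 1e-9)
  # the median-total cell is unchanged
  expect_equal(as.numeric(norm$counts[, 2]), as.numeric(cm$counts[, 2]))
  single <- size_factor_normalize(manual_count_matrix(matrix(7, 1, 1)))
  expect_equal(unname(single$cell_meta$size_factor), 1)
})

test_that("rank-sum p values match exhaustive enumeration for small groups", {
  withr::with_seed(11, {
    for (sizes in list(c(3, 3), c(4, 4), c(5, 6))) {
      x <- rnorm(sizes[1]); y <- rnorm(sizes[2]) + 0.8
      got <- scaffoldomics:::rank_sum_p(x, y)
      expect_equal(got, oracle_ranksum_enum(x, y))
      # tie-free small samples also agree with the classical exact test
      expect_equal(got, wilcox.test(x, y, exact = TRUE)$p.value)
    }
    # tied data: enumeration under the permutation null
    x <- c(1, 1, 2, 3); y <- c(2, 2, 3, 5)
    expect_equal(scaffoldomics:::rank_sum_p(x, y),
                 oracle_ranksum_enum(x, y))
  })
})

test_that("differential expression applies the fold-change and Bonferroni rules", {
  cm <- simulate_counts(counts_spec(
    n_genes = 120, n_cells_per_condition = c(control = 200),
    mito_gene_count = 5, mito_fraction_by_condition = c(control = 0.05),
    stem_subpop = list(fraction = 0.15, markers = c("SOX2", "FOXM1"),
                       fold = 5),
    seed = 21))
  cm <- size_factor_normalize(cm)
  stem <- cm$cell_meta$barcode[cm$cell_meta$is_stem]
  rest <- cm$cell_meta$barcode[!cm$cell_meta$is_stem]
  de <- wilcoxon_de(cm, stem, rest)
  expect_true(all(abs(de$lfc) > 0.25))
  expect_equal(de$p_adj, pmin(1, de$p * attr(de, "m")))
  expect_true(all(de$p_adj >= de$p))
  expect_true(all(c("SOX2", "FOXM1") %in% de$gene[de$significant]))
  # identical groups: every LFC is zero, nothing is tested
  half <- cm$cell_meta$barcode[1:50]
  dup <- cm
  dup$counts <- cbind(cm$counts[, half], cm$counts[, half])
  colnames(dup$counts) <- paste0("d", seq_len(100))
  same <- wilcoxon_de(dup, paste0("d", 1:50), paste0("d", 51:100))
  expect_equal(nrow(same), 0)
  expect_error(wilcoxon_de(cm, stem, c(stem[1], rest[1:5])), "overlap")
})

test_that("swapping groups negates the fold change and keeps p", {
  cm <- simulate_counts(counts_spec(
    n_genes = 40, n_cells_per_condition = c(control = 60),
    mito_gene_count = 4, mito_fraction_by_condition = c(control = 0.1),
    stem_subpop = list(fraction = 0.3, markers = c("SOX2"), fold = 4),
    seed = 8))
  cm <- size_factor_normalize(cm)
  stem <- cm$cell_meta$barcode[cm$cell_meta$is_stem]
  rest <- cm$cell_meta$barcode[!cm$cell_meta$is_stem]
  ab <- wilcoxon_de(cm, stem, rest, lfc_threshold = 0)
  ba <- wilcoxon_de(cm, rest, stem, lfc_threshold = 0)
  ord <- match(ab$gene, ba$gene)
  expect_equal(ab$lfc, -ba$lfc[ord])
  expect_equal(ab$p, ba$p[ord])
})

test_that("dot-plot statistics summarise expression per cluster", {
  counts <- rbind(SOX2 = c(4, 4, 0, 0), GAPDH = c(2, 2, 2, 2))
  cm <- manual_count_matrix(counts,
                            condition = c("a", "a", "b", "b"))
  d <- dotplot_stats(cm, c("SOX2", "GAPDH", "MISSING"))
  expect_equal(attr(d, "skipped"), "MISSING")
  sox_b <- d[d$cluster == "b" & d$gene == "SOX2", ]
  expect_equal(sox_b$mean_expr, 0)
  expect_equal(sox_b$pct_expr, 0)
  gap_a <- d[d$cluster == "a" & d$gene == "GAPDH", ]
  expect_equal(gap_a$mean_expr, 2)
  expect_equal(gap_a$pct_expr, 100)
})

test_that("population fractions use a strict threshold per group", {
  meta <- data.frame(condition = rep("a", 4),
                     percent_mt = c(5, 8, 12, 20))
  f <- population_fraction(meta, "percent_mt", 10)
  expect_equal(f$fraction, 0.5)
  expect_equal(population_fraction(meta, "percent_mt", 1)$fraction, 0)
  comp <- cluster_composition(data.frame(condition = c("a", "a", "b"),
                                         cluster = c("c1", "c2", "c1")))
  expect_equal(sum(comp$n), 3)
  expect_equal(comp$fraction_of_sample[comp$sample == "b" &
                                         comp$cluster == "c1"], 1)
})

test_that("null data yields a calibrated p-value distribution", {
  fracs <- sapply(1:10, function(rep) {
    withr::with_seed(100 + rep, {
      mat <- matrix(rnbinom(80 * 60, mu = 4, size = 2), 80, 60)
      ps <- apply(mat, 1, function(g)
        scaffoldomics:::rank_sum_p(g[1:30], g[31:60]))
      mean(ps < 0.05)
    })
  })
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.05), 3 * se + 1e-9)
})
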