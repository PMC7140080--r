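test_that("ORA p values are exact hypergeometric tails", {
  # full overlap of a 5-gene term in a 5-gene study: p = 1/C(20,5)
  uni <- paste0("g", 1:20)
  res <- hypergeom_ora(uni[1:5], list(T1 = uni[1:5]), uni)
  expect_equal(res$p, 1 / choose(20, 5))
  # zero overlap: p = 1
  res0 <- hypergeom_ora(uni[1:5], list(T2 = uni[10:14]), uni)
  expect_equal(res0$k, 0)
  expect_equal(res0$p, 1)
  expect_error(hypergeom_ora(character(0), list(T1 = uni[1:3]), uni),
               "empty study")
  expect_error(hypergeom_ora(uni[1], list(T1 = uni[1]), character(0)),
               "empty universe")
})

test_that("ORA matches subset enumeration and the choose-sum tail", {
  # literal enumeration for small universes
  for (case in list(c(8, 3, 4, 2), c(10, 4, 5, 3), c(12, 6, 6, 4))) {
    N <- case[1]; K <- case[2]; n <- case[3]; k <- case[4]
    uni <- paste0("g", 1:N)
    res <- hypergeom_ora(uni[1:n], list(T1 = uni[1:K]), uni)
    expect_equal(res$k, length(intersect(1:n, 1:K)))
    p_at <- function(kk) oracle_hyper_enum(N, K, n, kk)
    expect_equal(res$p, p_at(res$k))
  }
  # the explicit choose() sum across every (N <= 30, K, n, k)
  for (N in c(5, 9, 14, 21, 30)) {
    for (K in seq(0, N, by = 3)) for (n in seq(1, N, by = 4)) {
      kmax <- min(n, K)
      for (k in unique(c(0, 1, kmax %/% 2, kmax))) {
        got <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        expect_equal(got, oracle_hyper_choose(N, K, n, k),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # hand step-up: sorted p * m / i with running minima from the top
  p <- c(0.001, 0.02, 0.04, 0.9)
  hand <- rev(cummin(rev(p * 4 / 1:4)))
  expect_equal(bh_fdr(p), hand)
  q <- bh_fdr(c(0.5, 0.001, 0.04, 0.04, 0.9))
  expect_true(all(diff(q[order(c(0.5, 0.001, 0.04, 0.04, 0.9))]) >= 0))
})

test_that("consensus keeps terms significant in enough levels", {
  mk <- function(q) {
    data.frame(term = paste0("T", seq_along(q)), k = 1, n = 5, K = 5,
               N = 50, p = q, q = q, level = NA, hits = "")
  }
  ora <- list(a = mk(c(0.01, 0.5, 0.01)), b = mk(c(0.02, 0.01, 0.5)),
              c = mk(c(0.03, 0.5, 0.01)), d = mk(c(0.04, 0.5, 0.5)),
              e = mk(c(0.5, 0.5, 0.01)))
  cons <- consensus_terms(ora, q_threshold = 0.1, min_networks = 3)
  expect_equal(cons$term, c("T1", "T3"))
  expect_equal(cons$n_networks, c(4, 3))
  strict <- consensus_terms(ora, min_networks = 5)
  expect_equal(nrow(strict), 0)
  # raising min_networks never adds terms
  sizes <- sapply(1:5, function(m)
    nrow(consensus_terms(ora, min_networks = m)))
  expect_true(all(diff(sizes) <= 0))
  fam <- consensus_terms(ora, min_networks = 3,
                         families = c(T1 = "mRNA processing"))
  expect_equal(fam$family[fam$term == "T1"], "mRNA processing")
  expect_equal(attr(fam, "isolated_terms"), "T3")
})

test_that("region enrichment annotates regions independently", {
  uni <- paste0("g", 1:40)
  sets <- list(TA = uni[1:10], TB = uni[11:20])
  regions <- list(region_1 = uni[1:8], region_2 = uni[11:18])
  enr <- region_enrichment(regions, sets, uni, degs = uni[1:5])
  expect_equal(enr$region_1$term[1], "TA")
  expect_equal(enr$region_2$term[1], "TB")
  expect_equal(enr$region_1$deg_hits[enr$region_1$term == "TA"], 5L)
  expect_warning(
    out <- region_enrichment(list(r = c("zz1", "zz2")), sets, uni),
    "no annotated")
  expect_equal(nrow(out$r), 0)
})

test_that("gene-list overlap is case-normalized", {
  ov <- gene_list_overlap(c("A", "B", "C"), c("b", "c", "d"))
  expect_equal(ov$n_a, 3)
  expect_equal(ov$n_overlap, 2)
  expect_equal(ov$jaccard, 0.5)
  expect_equal(gene_list_overlap(c("x"), c("y"))$n_overlap, 0)
  expect_equal(gene_list_overlap(c("x", "y"), c("X", "Y"))$jaccard, 1)
})

test_that("random study sets keep the hypergeometric type-I rate", {
  uni <- paste0("g", 1:200)
  fracs <- sapply(1:10, function(rep) withr::with_seed(300 + rep, {
    sets <- lapply(1:50, function(i) sample(uni, 20))
    names(sets) <- paste0("T", 1:50)
    res <- hypergeom_ora(sample(uni, 30), sets, uni)
    mean(res$p < 0.05)
  }))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.05), 3 * se + 0.02)
})
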