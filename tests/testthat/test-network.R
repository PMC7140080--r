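test_that("DEG selection is strict at the alpha boundary", {
  de <- data.frame(gene = c("a", "b", "c"), logFC = c(1, -1, 2),
                   adj_p = c(0.049, 0.05, 0.2))
  sel <- select_degs(de)
  expect_equal(sel$gene, "a")
  expect_equal(nrow(select_degs(de[0, ])), 0)
  expect_equal(nrow(select_degs(transform(de, adj_p = 0.001))), 3)
})

test_that("network construction is first-order around the seeds", {
  edges <- data.frame(source = c("A", "B"), target = c("B", "C"),
                      level = "ppi")
  net <- build_network(data.frame(gene = "A", logFC = 1, adj_p = 0.01),
                       edges, "ppi")
  expect_setequal(igraph::V(net$graph)$name, c("A", "B"))
  expect_equal(igraph::ecount(net$graph), 1)
  lone <- build_network(data.frame(gene = "Z", logFC = 1, adj_p = 0.01),
                        edges, "ppi")
  expect_equal(igraph::vcount(lone$graph), 1)
  expect_equal(igraph::ecount(lone$graph), 0)
  # planted-clique fixture: all clique genes land in one component
  nets <- simulate_networks(network_spec(n_genes = 300, n_deg = 30,
                                         edges_per_level = c(ppi = 120),
                                         planted_clique_size = 6,
                                         n_terms = 5, seed = 6))
  built <- build_network(select_degs(nets$de_table), nets$edges, "ppi")
  memb <- igraph::components(built$graph)$membership
  cl_memb <- memb[nets$truth$clique]
  expect_equal(length(unique(cl_memb)), 1)
})

test_that("trimming protects seeds and respects thresholds", {
  star <- data.frame(source = "H", target = paste0("L", 1:5),
                     level = "ppi")
  net <- build_network(data.frame(gene = "H", logFC = 1, adj_p = 0.01),
                       star, "ppi")
  trimmed <- suppressMessages(trim_network(net, degree_min = 2))
  expect_equal(igraph::V(trimmed$graph)$name, "H")
  unchanged <- suppressMessages(trim_network(net, degree_min = 0))
  expect_equal(igraph::vcount(unchanged$graph), 6)
  # seeds survive even when they fail the threshold
  net2 <- build_network(data.frame(gene = c("H", "L1"),
                                   logFC = c(1, 1), adj_p = 0.01),
                        star, "ppi")
  trimmed2 <- suppressMessages(trim_network(net2, degree_min = 3))
  expect_true(all(c("H", "L1") %in% igraph::V(trimmed2$graph)$name))
})

test_that("raising the degree threshold never grows the network", {
  for (s in 1:10) {
    g <- withr::with_seed(s, igraph::sample_gnp(60, 0.08))
    igraph::V(g)$name <- paste0("n", 1:60)
    igraph::V(g)$seed <- FALSE
    igraph::V(g)$seed[1:3] <- TRUE
    net <- structure(list(graph = g, level = "ppi"),
                     class = "interaction_network")
    sizes <- sapply(0:5, function(dm)
      igraph::vcount(suppressMessages(
        trim_network(net, degree_min = dm))$graph))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("merging reports replicate nodes and edges", {
  mk <- function(edges, level) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::V(g)$seed <- FALSE
    igraph::V(g)$logFC <- NA_real_
    structure(list(graph = g, level = level),
              class = "interaction_network")
  }
  n1 <- mk(data.frame(from = "A", to = "B"), "ppi")
  n2 <- mk(data.frame(from = "A", to = "C"), "tf")
  m <- merge_networks(list(n1, n2))
  expect_equal(igraph::vcount(m$network$graph), 3)
  expect_equal(igraph::ecount(m$network$graph), 2)
  expect_equal(m$replicate_nodes, "A")
  expect_equal(m$n_replicate_edges, 0)
  ident <- merge_networks(list(n1, mk(data.frame(from = "A", to = "B"),
                                      "tf")))
  expect_equal(ident$n_replicate_nodes, 2)
  expect_equal(ident$n_replicate_edges, 1)
  disj <- merge_networks(list(n1, mk(data.frame(from = "X", to = "Y"),
                                     "tf")))
  expect_equal(disj$n_replicate_nodes, 0)
  expect_equal(disj$n_replicate_edges, 0)
})

test_that("dense-region detection finds planted cliques", {
  # 6-clique attached to a sparse chain
  g <- igraph::graph_from_data_frame(rbind(
    t(combn(paste0("c", 1:6), 2)),
    cbind(paste0("t", 1:6), paste0("t", 2:7)),
    c("c1", "t1")), directed = FALSE)
  res <- mcode_dense_regions(g)
  expect_equal(sort(res$membership$region_1), paste0("c", 1:6))
  # a tree has no 2-core, hence no regions
  tree <- igraph::make_tree(12, children = 2, mode = "undirected")
  expect_equal(nrow(mcode_dense_regions(tree)$regions), 0)
  # two disjoint cliques rank by score: the 8-clique first
  g2 <- igraph::graph_from_data_frame(rbind(
    t(combn(paste0("a", 1:8), 2)),
    t(combn(paste0("b", 1:5), 2))), directed = FALSE)
  res2 <- mcode_dense_regions(g2)
  expect_equal(nrow(res2$regions), 2)
  expect_equal(sort(res2$membership$region_1), paste0("a", 1:8))
  expect_equal(sort(res2$membership$region_2), paste0("b", 1:5))
  # regions satisfy the k-core cutoff after the haircut
  sub <- igraph::induced_subgraph(g2, res2$membership$region_1)
  expect_true(min(igraph::coreness(sub)) >= 2)
})

test_that("networks serialize as edge-list TSV", {
  edges <- data.frame(source = c("A", "B"), target = c("B", "C"),
                      level = "ppi")
  net <- build_network(data.frame(gene = c("A", "C"), logFC = 1,
                                  adj_p = 0.01), edges, "ppi")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_edge_table(path)
  expect_equal(nrow(back), 2)
  expect_setequal(back$level, "ppi")
})
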