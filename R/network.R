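#' Select differentially expressed seed genes
#'
#' Genes with adjusted p strictly below `alpha` (default 0.05), carrying
#' their log fold changes.
#'
#' @param de_table data.frame with `gene`, `logFC`, `adj_p`.
#' @param alpha adjusted-p cutoff.
#' @return data.frame of seed genes (`gene`, `logFC`, `adj_p`); may be
#'   empty.
#' @export
select_degs <- function(de_table, alpha = 0.05) {
  stopifnot(all(c("gene", "adj_p") %in% names(de_table)))
  out <- de_table[de_table$adj_p < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# infer a node type from its id prefix (regulator nodes carry TF/MIR ids)
node_type <- function(ids) {
  ifelse(grepl("^TF", ids), "tf",
         ifelse(grepl("^MIR|^hsa-miR", ids, ignore.case = TRUE), "mirna",
                ifelse(grepl("^DRUG", ids), "drug", "gene")))
}

#' Build a first-order DEG-seeded interaction network
#'
#' The network contains the seed genes plus their direct interactors from
#' one level's edge table; edges among any pair of included nodes are
#' retained (the induced subgraph on the first-order neighbourhood). The
#' graph is undirected and simple. Seeds with no edges remain as isolated
#' vertices. Connected components are computed and the largest is flagged.
#'
#' @param seeds data.frame from [select_degs()] (or a character vector of
#'   gene ids).
#' @param edge_table data.frame `source`, `target` (a `level` column, if
#'   present, is filtered to `level`).
#' @param level level tag for the network.
#' @return An `interaction_network`: `list(graph = igraph, level = )`.
#'   Vertices carry `seed` (logical), `logFC` (NA for non-seeds), `type`,
#'   and `in_largest_component`.
#' @export
build_network <- function(seeds, edge_table, level = "ppi") {
  if (is.character(seeds)) seeds <- data.frame(gene = seeds,
                                               logFC = NA_real_)
  if (nrow(seeds) == 0) stop("empty seed set: no genes to build from")
  et <- edge_table
  if ("level" %in% names(et)) et <- et[et$level == level, , drop = FALSE]
  touch <- et$source %in% seeds$gene | et$target %in% seeds$gene
  first <- et[touch, , drop = FALSE]
  nodes <- unique(c(seeds$gene, first$source, first$target))
  induced <- et[et$source %in% nodes & et$target %in% nodes, ,
                drop = FALSE]
  g <- igraph::graph_from_data_frame(
    induced[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = nodes))
  g <- igraph::simplify(g)
  ids <- igraph::V(g)$name
  igraph::V(g)$seed <- ids %in% seeds$gene
  igraph::V(g)$logFC <- seeds$logFC[match(ids, seeds$gene)]
  igraph::V(g)$type <- node_type(ids)
  comp <- igraph::components(g)
  igraph::V(g)$in_largest_component <-
    comp$membership == which.max(comp$csize)
  structure(list(graph = g, level = level),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network [%s]: %d nodes (%d seeds), %d edges\n",
              x$level, igraph::vcount(x$graph),
              sum(igraph::V(x$graph)$seed), igraph::ecount(x$graph)))
  invisible(x)
}

#' Trim a network by degree and betweenness thresholds
#'
#' Removes non-seed nodes failing the thresholds; seed genes are always
#' protected. Degree and (exact, unnormalized, shortest-path) betweenness
#' are computed once on the untrimmed network. With `rule = "both"` (the
#' default) a non-seed node is kept only if it meets every threshold that
#' is set; with `rule = "either"` meeting one suffices. A message warns,
#' without erroring, when the trimmed size falls outside the target node
#' budget.
#'
#' @param net an `interaction_network`.
#' @param degree_min minimum degree (0 disables).
#' @param betweenness_min minimum betweenness (`NULL` disables).
#' @param node_budget length-2 target node range; default `c(200, 600)`.
#' @param rule `"both"` (thresholds conjunctive) or `"either"`.
#' @return the trimmed `interaction_network`.
#' @export
trim_network <- function(net, degree_min = 0, betweenness_min = NULL,
                         node_budget = c(200, 600),
                         rule = c("both", "either")) {
  rule <- match.arg(rule)
  stopifnot(inherits(net, "interaction_network"),
            degree_min >= 0,
            is.null(betweenness_min) || betweenness_min >= 0)
  g <- net$graph
  deg_ok <- igraph::degree(g) >= degree_min
  btw_ok <- if (is.null(betweenness_min)) NULL else
    igraph::betweenness(g, normalized = FALSE) >= betweenness_min
  pass <- if (is.null(btw_ok)) deg_ok else
    if (rule == "both") deg_ok & btw_ok else deg_ok | btw_ok
  keep <- igraph::V(g)$seed | pass
  if (!any(keep)) stop("trimming removed all nodes")
  g2 <- igraph::induced_subgraph(g, which(keep))
  n <- igraph::vcount(g2)
  if (n < node_budget[1] || n > node_budget[2])
    message(sprintf(
      "trimmed network has %d nodes, outside the target budget [%d, %d]",
      n, node_budget[1], node_budget[2]))
  structure(list(graph = g2, level = net$level),
            class = "interaction_network")
}

#' Merge networks with replicate accounting
#'
#' Union of node and edge sets across input networks. The replicate report
#' counts node ids appearing in more than one input and (unordered,
#' level-agnostic) edges appearing in more than one input. Merged edges
#' keep their level provenance as an edge attribute.
#'
#' @param networks list of at least two `interaction_network`s.
#' @return `list(network = merged interaction_network (level "merged"),
#'   replicate_nodes = character, replicate_edges = character "a|b",
#'   n_replicate_nodes, n_replicate_edges)`.
#' @export
merge_networks <- function(networks) {
  stopifnot(length(networks) >= 2,
            all(vapply(networks, inherits, TRUE, "interaction_network")))
  node_sets <- lapply(networks, function(n) igraph::V(n$graph)$name)
  edge_sets <- lapply(networks, function(n) {
    e <- igraph::as_edgelist(n$graph)
    unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "|"))
  })
  node_tab <- table(unlist(lapply(node_sets, unique)))
  edge_tab <- table(unlist(edge_sets))
  rep_nodes <- names(node_tab)[node_tab > 1]
  rep_edges <- names(edge_tab)[edge_tab > 1]

  edges <- do.call(rbind, lapply(networks, function(n) {
    e <- igraph::as_edgelist(n$graph)
    if (nrow(e) == 0)
      return(data.frame(source = character(0), target = character(0),
                        level = character(0)))
    data.frame(source = e[, 1], target = e[, 2], level = n$level)
  }))
  key <- paste(pmin(edges$source, edges$target),
               pmax(edges$source, edges$target), edges$level)
  edges <- edges[!duplicated(key), , drop = FALSE]

  verts <- do.call(rbind, lapply(networks, function(n)
    data.frame(name = igraph::V(n$graph)$name,
               seed = igraph::V(n$graph)$seed,
               logFC = igraph::V(n$graph)$logFC)))
  verts <- do.call(rbind, lapply(split(verts, verts$name), function(d)
    data.frame(name = d$name[1], seed = any(d$seed),
               logFC = d$logFC[which(!is.na(d$logFC))[1]][1])))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  igraph::V(g)$type <- node_type(igraph::V(g)$name)
  merged <- structure(list(graph = g, level = "merged"),
                      class = "interaction_network")
  list(network = merged,
       replicate_nodes = rep_nodes, replicate_edges = rep_edges,
       n_replicate_nodes = length(rep_nodes),
       n_replicate_edges = length(rep_edges))
}

#' Write a network as an edge-list TSV (and optionally GraphML)
#'
#' @param net an `interaction_network`.
#' @param path TSV path.
#' @param graphml optional GraphML path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, graphml = NULL) {
  e <- igraph::as_edgelist(net$graph)
  df <- data.frame(source = e[, 1], target = e[, 2],
                   level = if (igraph::ecount(net$graph) &&
                               "level" %in%
                               igraph::edge_attr_names(net$graph))
                     igraph::E(net$graph)$level else net$level)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(net$graph, graphml, format = "graphml")
  invisible(path)
}
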