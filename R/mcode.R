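#' MCODE-style dense-region detection
#'
#' Implements the published MCODE scheme on an undirected simple graph.
#'
#' Stage 1 (vertex weighting): each vertex with degree at least
#' `degree_cutoff` is weighted by the highest k-core of its closed
#' neighbourhood: the weight is `k_max * density` where `k_max` is the
#' maximum coreness in the neighbourhood subgraph and `density` is the
#' edge density of that highest k-core (the "core-clustering
#' coefficient"). Vertices below the degree cutoff get weight 0.
#'
#' Stage 2 (complex prediction): vertices are visited in decreasing weight
#' order; from each unvisited seed, neighbours whose weight is at least
#' `(1 - node_score_cutoff)` times the seed weight are added breadth-first
#' up to `max_depth`. Added vertices are marked visited, so regions are
#' disjoint.
#'
#' Stage 3 (post-processing): with `haircut`, each complex is reduced to
#' its 2-core (iteratively removing singly connected vertices); complexes
#' whose members do not form at least a `k_core`-core are discarded.
#' `fluff` is accepted for interface completeness but off by default, as
#' in the original defaults.
#'
#' Complexes are scored by `density * n_nodes` and ranked by decreasing
#' score.
#'
#' @param net an `interaction_network` or an igraph graph.
#' @param degree_cutoff minimum degree for a non-zero vertex weight
#'   (default 2).
#' @param node_score_cutoff fraction of the seed weight a neighbour may
#'   fall below and still join (default 0.2).
#' @param k_core minimum core a reported complex must contain (default 2).
#' @param max_depth maximum breadth-first depth from the seed
#'   (default 100).
#' @param haircut reduce complexes to their 2-core (default TRUE).
#' @param fluff unused placeholder matching the original parameter list
#'   (default FALSE).
#' @return `list(regions = data.frame(rank, score, n_nodes, seed,
#'   members), membership = named list of member vectors)`; empty when
#'   the graph has no qualifying region.
#' @examples
#' g <- igraph::make_full_graph(6) + igraph::make_ring(10)
#' mcode_dense_regions(g)$regions$n_nodes
#' @export
mcode_dense_regions <- function(net, degree_cutoff = 2,
                                node_score_cutoff = 0.2, k_core = 2,
                                max_depth = 100, haircut = TRUE,
                                fluff = FALSE) {
  g <- if (inherits(net, "interaction_network")) net$graph else net
  stopifnot(igraph::is_igraph(g))
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  n <- igraph::vcount(g)
  empty <- list(regions = data.frame(rank = integer(0),
                                     score = numeric(0),
                                     n_nodes = integer(0),
                                     seed = character(0),
                                     members = character(0)),
                membership = list())
  if (n == 0) return(empty)
  if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- as.character(seq_len(n))

  deg <- igraph::degree(g)
  w <- numeric(n)
  for (v in which(deg >= degree_cutoff)) {
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0) next
    core_sub <- igraph::induced_subgraph(sub, which(core == kmax))
    dens <- igraph::edge_density(core_sub)
    if (is.nan(dens)) dens <- 0
    w[v] <- kmax * dens
  }

  visited <- rep(FALSE, n)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  regions <- list()
  for (s in order(w, decreasing = TRUE)) {
    if (visited[s] || w[s] <= 0) next
    cutoff <- w[s] * (1 - node_score_cutoff)
    members <- s
    visited[s] <- TRUE
    frontier <- s
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- unique(unlist(lapply(adj[frontier], as.integer)))
      nxt <- nxt[!visited[nxt] & w[nxt] >= cutoff]
      if (length(nxt) == 0) break
      visited[nxt] <- TRUE
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1
    }
    sub <- igraph::induced_subgraph(g, members)
    if (haircut) {
      core <- igraph::coreness(sub)
      sub <- igraph::induced_subgraph(sub, which(core >= 2))
    }
    if (igraph::vcount(sub) < 2 || max(igraph::coreness(sub)) < k_core)
      next
    dens <- igraph::edge_density(sub)
    regions[[length(regions) + 1]] <-
      list(seed = igraph::V(g)$name[s],
           members = igraph::V(sub)$name,
           score = dens * igraph::vcount(sub))
  }
  if (length(regions) == 0) return(empty)
  ord <- order(vapply(regions, `[[`, 1.0, "score"), decreasing = TRUE)
  regions <- regions[ord]
  df <- data.frame(
    rank = seq_along(regions),
    score = vapply(regions, `[[`, 1.0, "score"),
    n_nodes = vapply(regions, function(r) length(r$members), 1L),
    seed = vapply(regions, `[[`, "", "seed"),
    members = vapply(regions, function(r)
      paste(sort(r$members), collapse = ","), ""))
  list(regions = df,
       membership = setNames(lapply(regions, `[[`, "members"),
                             paste0("region_", seq_along(regions))))
}
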