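#' Hypergeometric over-representation analysis
#'
#' For each term, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the study set and the term, within
#' the stated universe: `p = P(X >= k)` with `X ~ Hypergeom(N, K, n)`
#' where `N` is the universe size, `K` the term size and `n` the study
#' size (all after intersection with the universe). Benjamini-Hochberg
#' FDR is computed across the terms of one run.
#'
#' @param study character vector of study genes (a subset of the
#'   universe; genes outside it are dropped with a warning).
#' @param gene_sets named list of character vectors.
#' @param universe character vector defining the background.
#' @param level optional level tag carried into the result.
#' @return An `ora_result` data.frame: `term`, `k` (overlap), `n` (study
#'   size), `K` (term size in universe), `N` (universe size), `p`, `q`
#'   (BH-FDR), `level`, `hits` (comma-joined overlap genes), ordered by
#'   increasing p.
#' @examples
#' hypergeom_ora(c("a", "b"), list(T1 = c("a", "b", "c")),
#'               universe = letters[1:20])
#' @export
hypergeom_ora <- function(study, gene_sets, universe,
                          level = NA_character_) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty universe")
  outside <- setdiff(study, universe)
  if (length(outside) > 0)
    warning(length(outside), " study genes outside the universe dropped")
  study <- unique(intersect(study, universe))
  n <- length(study)
  if (n == 0) stop("empty study set")
  rows <- lapply(names(gene_sets), function(tm) {
    set <- intersect(unique(gene_sets[[tm]]), universe)
    K <- length(set)
    hits <- intersect(study, set)
    k <- length(hits)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p = p,
               hits = paste(sort(hits), collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$level <- level
  out <- out[order(out$p), c("term", "k", "n", "K", "N", "p", "q",
                             "level", "hits")]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR
#'
#' Step-up adjustment with monotonicity enforcement:
#' `q_(i) = min_{j >= i} p_(j) * m / j` over the sorted p values.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return numeric vector of q values, same order as the input.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Cross-network consensus of enriched terms
#'
#' A term is significant in a level iff its FDR q is below `q_threshold`
#' (default 0.1); the consensus table keeps terms significant in at least
#' `min_networks` levels (default 3) and reports each retained term's
#' per-level q values. Terms without an entry in the optional `families`
#' mapping are surfaced as candidates for manual dismissal (the isolated
#' terms), not removed automatically.
#'
#' @param ora_by_level named list of `ora_result`s (names = levels).
#' @param q_threshold per-level significance cutoff on q.
#' @param min_networks minimum number of levels a consensus term must be
#'   significant in (inclusive).
#' @param families optional named character vector mapping term -> family
#'   label (manually curated; never inferred).
#' @return A data.frame `term`, `n_networks`, one `q_<level>` column per
#'   level, `family`; ordered by decreasing `n_networks` then increasing
#'   minimum q. Terms lacking a family label are listed in
#'   `attr(, "isolated_terms")`.
#' @export
consensus_terms <- function(ora_by_level, q_threshold = 0.1,
                            min_networks = 3, families = NULL) {
  stopifnot(length(ora_by_level) >= 2,
            !is.null(names(ora_by_level)))
  levels <- names(ora_by_level)
  terms <- unique(unlist(lapply(ora_by_level, `[[`, "term")))
  qmat <- sapply(ora_by_level, function(o)
    o$q[match(terms, o$term)])
  qmat <- matrix(qmat, nrow = length(terms),
                 dimnames = list(terms, levels))
  sig <- !is.na(qmat) & qmat < q_threshold
  n_networks <- rowSums(sig)
  keep <- n_networks >= min_networks
  if (min_networks > length(levels))
    warning("min_networks exceeds the number of levels analysed; ",
            "consensus is empty")
  out <- data.frame(term = terms[keep],
                    n_networks = n_networks[keep])
  for (lv in levels) out[[paste0("q_", lv)]] <- qmat[keep, lv]
  out$family <- if (is.null(families)) rep(NA_character_, nrow(out))
    else unname(families[out$term])
  minq <- apply(qmat[keep, , drop = FALSE], 1, min, na.rm = TRUE)
  out <- out[order(-out$n_networks, minq), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "isolated_terms") <- out$term[is.na(out$family)]
  out
}

#' Gene-set enrichment of dense network regions
#'
#' One over-representation run per dense region (study = the region's
#' genes intersected with the universe), with per-term counts of how many
#' differentially expressed genes map to each term within the region.
#'
#' @param regions `membership` list from [mcode_dense_regions()] (or any
#'   named list of gene vectors).
#' @param gene_sets named list of gene sets.
#' @param universe background gene vector.
#' @param degs optional DEG id vector for the mapped-DEG counts.
#' @return named list of `ora_result`s (one per region, possibly empty
#'   with a warning when a region has no annotated genes), each with an
#'   extra `deg_hits` column when `degs` is given.
#' @export
region_enrichment <- function(regions, gene_sets, universe,
                              degs = NULL) {
  out <- list()
  for (rn in names(regions)) {
    genes <- intersect(regions[[rn]], universe)
    if (length(genes) == 0) {
      warning("region ", rn, " has no annotated genes")
      out[[rn]] <- data.frame()
      next
    }
    o <- hypergeom_ora(genes, gene_sets, universe, level = rn)
    if (!is.null(degs))
      o$deg_hits <- vapply(strsplit(o$hits, ","), function(h)
        sum(h %in% degs), 1L)
    out[[rn]] <- o
  }
  out
}

#' Overlap statistics of two gene lists
#'
#' Case-normalized intersection counts and Jaccard index.
#'
#' @param list_a,list_b character vectors of gene ids.
#' @return `list(n_a, n_b, n_overlap, jaccard, overlap)`.
#' @examples
#' gene_list_overlap(c("A", "B", "C"), c("b", "c", "d"))$n_overlap
#' @export
gene_list_overlap <- function(list_a, list_b) {
  a <- unique(toupper(list_a)); b <- unique(toupper(list_b))
  ov <- intersect(a, b)
  un <- union(a, b)
  list(n_a = length(a), n_b = length(b), n_overlap = length(ov),
       jaccard = if (length(un)) length(ov) / length(un) else NA_real_,
       overlap = sort(ov))
}
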