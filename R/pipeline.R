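#' Default run configuration
#'
#' Assembles a full pipeline configuration with every threshold pre-filled
#' at its documented default: imaging (min object size 10 voxels,
#' 26-connectivity, edge exclusion on, peak-region histograms), expression
#' (molecule trim 40,000, natural-log fold-change filter 0.25, alpha 0.01
#' on adjusted p, percent-mito threshold 10), network (DEG alpha 0.05,
#' FDR threshold 0.1, consensus over >= 3 levels, per-level trim
#' thresholds: ppi degree 10, tf degree 25, mirna degree 25, coexpression
#' degree 2 with betweenness 4, node budget 200-600, MCODE defaults).
#' User values override defaults recursively. A configuration written
#' with [write_run_config()] and read back with [read_run_config()]
#' round-trips losslessly.
#'
#' @param ... named overrides, nested lists merged over the defaults.
#' @return a nested list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = "scaffoldomics_run",
    imaging = list(inputs = list(), voxel_size_zyx = c(2, 1, 1),
                   min_voxels = 10L, connectivity = 26L,
                   exclude_edges = TRUE, peak_region = TRUE,
                   bin_width = NULL, unit_volume = NULL),
    expression = list(counts_dir = NULL, max_molecules = 40000,
                      lfc = 0.25, alpha = 0.01, p_use = "adjusted",
                      group_col = "cluster", group_a = NULL,
                      group_b = NULL, dotplot_genes = character(0),
                      mito_threshold = 10),
    network = list(de_table = NULL, edges = NULL, gmt = NULL,
                   alpha_deg = 0.05, q_threshold = 0.1,
                   min_networks = 3L,
                   node_budget = c(200L, 600L),
                   trim = list(ppi = list(degree = 10),
                               tf = list(degree = 25),
                               mirna = list(degree = 25),
                               coexpression = list(degree = 2,
                                                   betweenness = 4)),
                   mcode = list(degree_cutoff = 2,
                                node_score_cutoff = 0.2, k_core = 2,
                                max_depth = 100, haircut = TRUE)))
  cfg <- merge_config(defaults, list(...))
  structure(cfg, class = "run_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML path.
#' @param config a `run_config`.
#' @return `read_run_config()` returns a `run_config` (defaults filled for
#'   missing entries); `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# manifest: parameter echo plus md5 checksums of written files; no
# wall-clock fields so reruns on identical inputs are byte-identical
write_manifest <- function(dir, arm, params, files) {
  files <- files[file.exists(files)]
  man <- list(arm = arm, params = params,
              r_version = paste(R.version$major, R.version$minor,
                                sep = "."),
              files = lapply(setNames(nm = basename(files)), function(f)
                unname(tools::md5sum(file.path(dir, f)))))
  jsonlite::write_json(man, file.path(dir, paste0("manifest_", arm,
                                                  ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

#' Run the imaging arm end to end
#'
#' For each configured input (condition, day, per-channel TIFF paths):
#' crop glass-layer slices ([crop_stack()]), segment the cell-dye channel
#' ([segment_stack()]), and write the object table. Volumes are then
#' pooled per condition/day into density histograms and clustering
#' metrics, and a cross-condition comparison table is written.
#'
#' @param config a `run_config` whose `imaging$inputs` is a list of
#'   `list(condition = , day = , dio = , dapi = )` entries.
#' @return invisibly, a list with the per-input object tables, the
#'   metrics, the comparison table, and the output directory.
#' @export
run_imaging_arm <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$imaging
  if (length(p$inputs) == 0) stop("imaging: no inputs configured")
  dir <- file.path(config$out_dir, "imaging")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  volumes <- list(); tables <- list(); files <- character(0)
  for (inp in p$inputs) {
    for (ch in c("dio", "dapi"))
      if (is.null(inp[[ch]]) || !file.exists(inp[[ch]]))
        stop("imaging: missing ", toupper(ch), " file for condition ",
             inp$condition)
    stack <- read_stack_tiff(c(DiO = inp$dio, DAPI = inp$dapi),
                             voxel_size_zyx = p$voxel_size_zyx)
    cr <- crop_stack(stack)
    seg <- segment_stack(cr$stack, "DiO", min_voxels = p$min_voxels,
                         exclude_edges = p$exclude_edges,
                         connectivity = p$connectivity)
    key <- paste(inp$condition, inp$day, sep = "_")
    f_obj <- file.path(dir, paste0("objects_", key, ".csv"))
    write_object_table(seg$table, f_obj)
    f_prof <- file.path(dir, paste0("slices_", key, ".tsv"))
    write_slice_profile(cr$profile, f_prof,
                        sub("tsv$", "json", f_prof))
    files <- c(files, f_obj, f_prof)
    tables[[key]] <- seg$table
    volumes[[key]] <- list(condition = inp$condition, day = inp$day,
                           volumes = seg$table$volume_um3)
  }
  metrics <- list(); hist_files <- character(0)
  for (key in names(volumes)) {
    v <- volumes[[key]]
    h <- volume_density_histogram(v$volumes, bin_width = p$bin_width,
                                  peak_region = p$peak_region,
                                  condition = v$condition, day = v$day)
    f_h <- file.path(dir, paste0("histogram_", key, ".tsv"))
    write_volume_histogram(h, f_h)
    hist_files <- c(hist_files, f_h)
    metrics[[v$condition]] <- clustering_metrics(
      v$volumes, unit_volume = p$unit_volume)
  }
  comparison <- if (length(metrics) >= 2) compare_conditions(metrics)
    else NULL
  if (!is.null(comparison)) {
    f_c <- file.path(dir, "clustering_comparison.tsv")
    utils::write.table(comparison, f_c, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, f_c)
  }
  write_manifest(dir, "imaging", p[setdiff(names(p), "inputs")],
                 c(files, hist_files))
  invisible(list(tables = tables, metrics = metrics,
                 comparison = comparison, dir = dir))
}

#' Run the expression arm end to end
#'
#' Reads the count-matrix directory, trims cells on total molecule count,
#' computes percent mitochondrial RNA, normalizes by median size factors,
#' runs Wilcoxon differential expression between the two configured
#' groups, and writes DE, dot-plot, population-fraction and
#' cluster-composition tables.
#'
#' @param config a `run_config` with `expression$counts_dir`,
#'   `expression$group_a` and `expression$group_b` set.
#' @return invisibly, a list with the processed matrix, DE table,
#'   dot-plot table, fraction tables and output directory.
#' @export
run_expression_arm <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$expression
  if (is.null(p$counts_dir)) stop("expression: counts_dir not set")
  dir <- file.path(config$out_dir, "expression")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- read_count_matrix(p$counts_dir)
  cm <- qc_trim(cm, max_molecules = p$max_molecules)
  cm <- add_percent_mtrna(cm)
  cm <- size_factor_normalize(cm)
  meta <- cm$cell_meta
  de <- NULL
  if (!is.null(p$group_a) && !is.null(p$group_b)) {
    cells_a <- meta$barcode[meta[[p$group_col]] == p$group_a]
    cells_b <- meta$barcode[meta[[p$group_col]] == p$group_b]
    de <- wilcoxon_de(cm, cells_a, cells_b, lfc_threshold = p$lfc,
                      alpha = p$alpha, p_use = p$p_use)
    utils::write.table(de, file.path(dir, "de_table.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  dots <- NULL
  if (length(p$dotplot_genes) > 0) {
    dots <- dotplot_stats(cm, p$dotplot_genes)
    utils::write.table(dots, file.path(dir, "dotplot.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  frac <- population_fraction(meta, "percent_mt", p$mito_threshold,
                              group_by = "condition")
  utils::write.table(frac, file.path(dir, "mito_fraction.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  comp <- cluster_composition(meta)
  utils::write.table(comp, file.path(dir, "cluster_composition.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_manifest(dir, "expression", p,
                 file.path(dir, c("de_table.tsv", "dotplot.tsv",
                                  "mito_fraction.tsv",
                                  "cluster_composition.tsv")))
  invisible(list(matrix = cm, de = de, dotplot = dots, fractions = frac,
                 composition = comp, dir = dir))
}

#' Run the network arm end to end
#'
#' Selects DEG seeds, builds one first-order network per level from the
#' edge table, runs per-level over-representation (plus one run on the
#' DEG list itself) and the cross-network consensus, trims each network
#' with its configured thresholds, merges the trimmed networks with
#' replicate accounting, detects dense regions with the MCODE scheme, and
#' runs region-level enrichment. The over-representation universe is the
#' set of genes in the annotation collection.
#'
#' @param config a `run_config` with `network$de_table`, `network$edges`
#'   and `network$gmt` paths set.
#' @return invisibly, a list with the per-level networks and ORA results,
#'   the consensus table, the merge report, the dense regions and their
#'   enrichment, and the output directory.
#' @export
run_network_arm <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$network
  for (f in c("de_table", "edges", "gmt"))
    if (is.null(p[[f]]) || !file.exists(p[[f]]))
      stop("network: missing input ", f)
  dir <- file.path(config$out_dir, "network")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  de <- read_de_table(p$de_table)
  seeds <- select_degs(de, alpha = p$alpha_deg)
  if (nrow(seeds) == 0)
    stop("no differentially expressed genes at adjusted p < ",
         p$alpha_deg)
  edges <- read_edge_table(p$edges)
  gene_sets <- read_gmt(p$gmt)
  universe <- unique(unlist(gene_sets))
  levels <- unique(edges$level)

  nets <- list(); ora <- list()
  ora[["degs"]] <- hypergeom_ora(intersect(seeds$gene, universe),
                                 gene_sets, universe, level = "degs")
  for (lv in levels) {
    nets[[lv]] <- build_network(seeds, edges, level = lv)
    study <- intersect(igraph::V(nets[[lv]]$graph)$name, universe)
    ora[[lv]] <- hypergeom_ora(study, gene_sets, universe, level = lv)
    utils::write.table(ora[[lv]],
                       file.path(dir, paste0("ora_", lv, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  consensus <- consensus_terms(ora, q_threshold = p$q_threshold,
                               min_networks = p$min_networks)
  utils::write.table(consensus, file.path(dir, "consensus.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  trimmed <- lapply(levels, function(lv) {
    tp <- p$trim[[lv]]
    if (is.null(tp)) return(nets[[lv]])
    trim_network(nets[[lv]], degree_min = tp$degree %||% 0,
                 betweenness_min = tp$betweenness,
                 node_budget = p$node_budget)
  })
  merged <- merge_networks(trimmed)
  write_network(merged$network, file.path(dir, "merged_network.tsv"))
  dense <- do.call(mcode_dense_regions,
                   c(list(net = merged$network), p$mcode))
  utils::write.table(dense$regions, file.path(dir, "dense_regions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  reg_enr <- region_enrichment(dense$membership, gene_sets, universe,
                               degs = seeds$gene)
  for (rn in names(reg_enr))
    if (nrow(reg_enr[[rn]]))
      utils::write.table(reg_enr[[rn]],
                         file.path(dir, paste0("enrichment_", rn,
                                               ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  rep_df <- data.frame(kind = c("nodes", "edges"),
                       replicates = c(merged$n_replicate_nodes,
                                      merged$n_replicate_edges))
  utils::write.table(rep_df, file.path(dir, "merge_replicates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_manifest(dir, "network", p[setdiff(names(p), c())],
                 list.files(dir, pattern = "\\.tsv$",
                            full.names = TRUE))
  invisible(list(networks = nets, ora = ora, consensus = consensus,
                 merge = merged, regions = dense,
                 region_enrichment = reg_enr, dir = dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
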