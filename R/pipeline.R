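#' Pipeline run configuration
#'
#' Collects every input path and module parameter for [run_pipeline()].
#' Serializes to/from a flat `key = value` file with [write_run_config()]
#' / [read_run_config()]; the round trip is identity.
#'
#' @param abundance path to the abundance TSV.
#' @param groups path to a two-column TSV (`sample_id`, `group`).
#' @param traits optional path to a trait TSV.
#' @param out_dir output directory.
#' @param orientation abundance table orientation.
#' @param prevalence_filter apply the prevalence filter (default FALSE;
#'   whether published networks used a filtered taxon subset is not
#'   determinable, so the filter defaults off).
#' @param min_rel_abund,min_sample_frac prevalence-filter thresholds.
#' @param rho_threshold,alpha,p_kind network thresholds: |rho| > 0.7,
#'   P < 0.05 on `"adjusted"` (default) or `"raw"` P.
#' @param null_model `"rewire"` or `"gnm"`.
#' @param n_replicates null-ensemble size (default 1000).
#' @param zi_cut,pi_cut role-classification thresholds.
#' @param assoc_r_cut association screen magnitude criterion (default 0.35).
#' @param seed master integer seed; stage sub-seeds derive from it.
#' @return A `run_config` list, validated.
#' @export
run_config <- function(abundance, groups, traits = NA_character_,
                       out_dir = "coocnet_out", orientation = "rows-are-samples",
                       prevalence_filter = FALSE, min_rel_abund = 0.001,
                       min_sample_frac = 0.5, rho_threshold = 0.7, alpha = 0.05,
                       p_kind = "adjusted", null_model = "rewire",
                       n_replicates = 1000, zi_cut = 2.5, pi_cut = 0.62,
                       assoc_r_cut = 0.35, seed = 1L) {
  if (length(traits) != 1 || is.na(traits) || traits %in% c("NA", ""))
    traits <- NA_character_
  cfg <- list(abundance = abundance, groups = groups, traits = traits,
              out_dir = out_dir, orientation = orientation,
              prevalence_filter = as.logical(prevalence_filter),
              min_rel_abund = as.numeric(min_rel_abund),
              min_sample_frac = as.numeric(min_sample_frac),
              rho_threshold = as.numeric(rho_threshold),
              alpha = as.numeric(alpha), p_kind = p_kind,
              null_model = null_model, n_replicates = as.integer(n_replicates),
              zi_cut = as.numeric(zi_cut), pi_cut = as.numeric(pi_cut),
              assoc_r_cut = as.numeric(assoc_r_cut), seed = as.integer(seed))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must be in (0, 1)")
  if (!(cfg$rho_threshold > 0 && cfg$rho_threshold <= 1))
    stop("rho_threshold must be in (0, 1]")
  if (!cfg$p_kind %in% c("adjusted", "raw")) stop("p_kind must be adjusted|raw")
  if (!cfg$null_model %in% c("rewire", "gnm")) stop("null_model must be rewire|gnm")
  if (!cfg$orientation %in% c("rows-are-samples", "rows-are-taxa"))
    stop("bad orientation")
  if (cfg$n_replicates < 10) stop("n_replicates must be >= 10")
  invisible(cfg)
}

#' Write a run configuration as a flat key = value file
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", format(config[[k]], scientific = FALSE)), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration from a flat key = value file
#' @param path config file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  cfg <- stats::setNames(as.list(vals), keys)
  do.call(run_config, cfg)
}

stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage) %% 2147483647)
}

#' Run the full co-occurrence pipeline
#'
#' Per group: Spearman correlation set, thresholded signed network,
#' topology with null ensemble, Louvain partition, Zi-Pi roles. Globally:
#' alpha diversity, Bray-Curtis matrix, Wilcoxon differential abundance,
#' and (when traits are supplied) the association screen. Every
#' intermediate artifact is written under `config$out_dir` and a single
#' machine-readable JSON report collects all parameters, seeds and
#' metrics. Deterministic: identical config + seed gives a byte-identical
#' report.
#'
#' @param config a [run_config()].
#' @return The report, invisibly (also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  gdf <- stage("read_groups", utils::read.table(config$groups, header = TRUE,
               sep = "\t", colClasses = "character"))
  groups <- stats::setNames(gdf[[2]], gdf[[1]])
  tab <- stage("read_abundance",
               read_abundance_table(config$abundance, orientation = config$orientation,
                                    groups = groups))
  tab <- stage("normalize", suppressMessages(normalize_relative(tab)))
  if (isTRUE(config$prevalence_filter))
    tab <- stage("prevalence_filter",
                 prevalence_filter(tab, config$min_rel_abund, config$min_sample_frac))
  ncfg <- network_config(config$rho_threshold, config$alpha,
                         use_adjusted_p = config$p_kind == "adjusted")
  glabels <- sort(unique(tab$groups))
  per_group <- list()
  for (gi in seq_along(glabels)) {
    gl <- glabels[gi]
    sub <- tab
    keep <- tab$groups == gl
    sub$values <- tab$values[keep, , drop = FALSE]
    sub$groups <- tab$groups[keep]
    corr <- stage(paste0("spearman[", gl, "]"),
                  suppressMessages(spearman_matrix(sub)))
    net <- stage(paste0("network[", gl, "]"),
                 build_network(corr, ncfg, group_label = gl, lineages = tab$lineages))
    write_network(net, file.path(config$out_dir, paste0("network_", gl, ".graphml")))
    write_network(net, file.path(config$out_dir, paste0("edges_", gl, ".tsv")),
                  format = "edgelist")
    if (igraph::ecount(net$graph) > 0) {
      topo <- stage(paste0("topology[", gl, "]"),
                    null_ensemble_summary(net, model = config$null_model,
                                          n_replicates = config$n_replicates,
                                          seed = stage_seed(config$seed, gi)))
      part <- topo$partition
      roles <- stage(paste0("roles[", gl, "]"),
                     node_roles(net, part, zi_cut = config$zi_cut,
                                pi_cut = config$pi_cut))
      utils::write.table(
        data.frame(node = names(part$membership), module = unname(part$membership)),
        file.path(config$out_dir, paste0("partition_", gl, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(as.data.frame(roles),
        file.path(config$out_dir, paste0("roles_", gl, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      topo <- topology_summary(net)
      roles <- NULL
    }
    per_group[[gl]] <- list(
      n_nodes = topo$n_nodes, n_edges = topo$n_edges,
      edges_per_node_E_over_N = round(topo$edges_per_node_E_over_N, 10),
      mean_degree_2E_over_N = round(topo$mean_degree_2E_over_N, 10),
      acc = round(topo$acc, 10), apl = round(topo$apl, 10),
      diameter = topo$diameter, Q = round(topo$Q, 10),
      n_modules = topo$n_modules, modular = isTRUE(topo$Q > 0.4),
      positive_edge_fraction = round(topo$positive_edge_fraction, 10),
      null_stats = if (!is.null(topo$null_stats))
        lapply(topo$null_stats, function(s) lapply(s, function(v) round(v, 10)))
        else NULL,
      role_counts = if (is.null(roles)) NULL else attr(roles, "counts"))
  }
  div <- stage("alpha_diversity", suppressMessages(alpha_diversity(tab)))
  utils::write.table(div, file.path(config$out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bc <- stage("bray_curtis", bray_curtis(tab))
  utils::write.table(data.frame(sample_id = rownames(bc), bc, check.names = FALSE),
                     file.path(config$out_dir, "bray_curtis.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  da <- if (length(glabels) == 2)
    stage("differential_abundance", differential_abundance(tab, alpha = config$alpha))
    else NULL
  if (!is.null(da))
    utils::write.table(da, file.path(config$out_dir, "differential_abundance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  assoc <- NULL
  if (!is.na(config$traits) && nzchar(config$traits)) {
    traits <- stage("read_traits", read_trait_table(config$traits))
    assoc <- stage("associations",
                   trait_correlations(tab, traits, r_cut = config$assoc_r_cut,
                                      alpha = config$alpha,
                                      use_adjusted_p = config$p_kind == "adjusted"))
    correlation_panel_export(assoc, file.path(config$out_dir, "associations.tsv"))
  }
  report <- list(
    schema = "coocnet-report/1",
    parameters = unclass(config),
    n_samples = nrow(tab$values), n_taxa = ncol(tab$values),
    groups = as.list(stats::setNames(as.integer(table(tab$groups)),
                                     names(table(tab$groups)))),
    networks = per_group,
    diversity_means = lapply(split(div$shannon, div$group), function(x) round(mean(x), 10)),
    n_significant_taxa = if (is.null(da)) NULL else sum(da$significant),
    n_passing_associations = if (is.null(assoc)) NULL else sum(assoc$passes_screen))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(report)
}

#' Side-by-side group contrast table from a pipeline report
#'
#' @param report a report list from [run_pipeline()] (or read back from
#'   `report.json`).
#' @return data.frame with one metric per row and one column per group.
#' @export
compare_groups <- function(report) {
  nets <- report$networks
  if (length(nets) < 2) stop("report contains fewer than 2 groups")
  metrics <- c("n_nodes", "n_edges", "edges_per_node_E_over_N",
               "mean_degree_2E_over_N", "acc", "apl", "diameter", "Q",
               "n_modules", "positive_edge_fraction")
  rows <- lapply(metrics, function(m)
    stats::setNames(lapply(nets, function(g) if (is.null(g[[m]])) NA else g[[m]]),
                    names(nets)))
  out <- data.frame(metric = metrics,
                    do.call(rbind, lapply(rows, function(r) as.data.frame(r))),
                    check.names = FALSE)
  role_levels <- c("peripheral", "connector", "module_hub", "network_hub")
  for (rl in role_levels) {
    vals <- vapply(nets, function(g)
      if (is.null(g$role_counts)) NA_real_ else as.numeric(g$role_counts[[rl]]), 0)
    out <- rbind(out, data.frame(metric = paste0("n_", rl),
                                 as.data.frame(as.list(vals), check.names = FALSE),
                                 check.names = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Shipped JSON report schema
#'
#' Returns the path of the versioned report schema bundled with the
#' package, and `validate_report()` checks a report against it.
#'
#' @return Path to the schema JSON.
#' @export
report_schema <- function() {
  system.file("extdata", "report-schema.json", package = "coocnet")
}

#' Validate a pipeline report against the shipped schema
#' @param report a report list.
#' @return TRUE invisibly; errors on missing required fields.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(report_schema())
  need <- unlist(schema$required)
  miss <- setdiff(need, names(report))
  if (length(miss) > 0) stop("report missing required fields: ",
                             paste(miss, collapse = ", "))
  if (!identical(report$schema, schema$id))
    stop("report schema id mismatch: ", report$schema)
  net_need <- unlist(schema$network_required)
  for (g in names(report$networks)) {
    miss <- setdiff(net_need, names(report$networks[[g]]))
    if (length(miss) > 0)
      stop("network summary '", g, "' missing: ", paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
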