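#' Midranks of a numeric vector
#'
#' Tied values receive the mean of the ranks they span, so ranks always sum
#' to n(n+1)/2. This is the rank transform underlying Spearman correlation.
#'
#' @param x numeric vector, length >= 2, finite.
#' @return Numeric vector of midranks.
#' @export
midrank <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  if (!all(is.finite(x))) stop("values must be finite")
  rank(x, ties.method = "average")
}

#' Pairwise Spearman correlation matrix with P-values
#'
#' Computes tie-aware Spearman rho for every taxon pair as the Pearson
#' correlation of midranks, two-sided P-values from the t approximation
#' with n - 2 degrees of freedom, and Benjamini-Hochberg adjusted P-values
#' over the strictly upper triangle (the full taxon-pair family), mirrored
#' to a symmetric matrix. Pairs involving a constant taxon get rho = 0,
#' P = 1, and are flagged.
#'
#' @param table an `abundance_table`, or a plain samples x taxa numeric
#'   matrix with dimnames.
#' @return An object of class `correlation_set` with elements `rho`,
#'   `p_raw`, `p_adj` (symmetric matrices), `n_samples`, `taxon_ids`, and
#'   `constant_taxa`.
#' @export
spearman_matrix <- function(table) {
  m <- if (inherits(table, "abundance_table")) table$values else table
  if (!is.matrix(m) || !is.numeric(m)) stop("input must be an abundance_table or numeric matrix")
  n <- nrow(m)
  if (n < 4) stop("need at least 4 samples for the t-approximation P-value")
  if (ncol(m) < 2) stop("need at least 2 taxa")
  ranks <- apply(m, 2, midrank)
  const <- apply(m, 2, function(x) length(unique(x)) == 1)
  if (any(const))
    message("constant taxa (rho set to 0, P to 1 for their pairs): ",
            paste(colnames(m)[const], collapse = ", "))
  # guard: cor() of a constant column is NA; patch below
  suppressWarnings(rho <- stats::cor(ranks, method = "pearson"))
  rho[const, ] <- 0
  rho[, const] <- 0
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p_raw <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p_raw[abs(r) >= 1] <- 0
  p_raw[const, ] <- 1
  p_raw[, const] <- 1
  diag(p_raw) <- 0
  p_adj <- p_raw
  ut <- upper.tri(p_raw)
  p_adj[ut] <- bh_adjust(p_raw[ut])
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  structure(list(rho = rho, p_raw = p_raw, p_adj = p_adj, n_samples = n,
                 taxon_ids = colnames(m), constant_taxa = colnames(m)[const]),
            class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, ...) {
  cat("correlation_set:", length(x$taxon_ids), "taxa,", x$n_samples, "samples\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Delegates to [stats::p.adjust()] with `method = "BH"` after validating
#' the input range. Order-preserving; output is elementwise >= input.
#'
#' @param p vector of raw P-values in \[0,1\].
#' @return Vector of BH-adjusted P-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("P-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Network construction configuration
#'
#' Defaults encode the robust-correlation rule: an edge requires
#' |rho| > 0.7 (strict) and significance at P < 0.05 (strict), with the
#' BH-adjusted P used by default.
#'
#' @param rho_threshold correlation magnitude threshold in (0, 1\].
#' @param alpha significance level in (0, 1).
#' @param use_adjusted_p use BH-adjusted (default) or raw P-values.
#' @param drop_isolated_nodes exclude taxa with no surviving edge (default
#'   TRUE; this is why published node counts fall below taxon counts).
#' @return A `network_config` list.
#' @export
network_config <- function(rho_threshold = 0.7, alpha = 0.05,
                           use_adjusted_p = TRUE, drop_isolated_nodes = TRUE) {
  if (!(rho_threshold > 0 && rho_threshold <= 1)) stop("rho_threshold must be in (0, 1]")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  structure(list(rho_threshold = rho_threshold, alpha = alpha,
                 use_adjusted_p = isTRUE(use_adjusted_p),
                 drop_isolated_nodes = isTRUE(drop_isolated_nodes)),
            class = "network_config")
}

#' Build a signed co-occurrence network from a correlation set
#'
#' Edge (i, j) is included iff |rho_ij| strictly exceeds the threshold AND
#' the selected P-value is strictly below alpha. Edge sign is the sign of
#' rho. Isolated taxa are dropped by default.
#'
#' @param corr a `correlation_set` from [spearman_matrix()].
#' @param config a [network_config()].
#' @param group_label optional label (e.g. `"CON"` or `"AOS"`).
#' @param lineages optional named lineage vector; genus is attached as a
#'   node attribute when available.
#' @return An object of class `cooc_network` wrapping an undirected simple
#'   igraph graph with edge attributes `rho` and `sign` (`"+"`/`"-"`).
#' @export
build_network <- function(corr, config = network_config(), group_label = NA_character_,
                          lineages = NULL) {
  stopifnot(inherits(corr, "correlation_set"))
  if (!identical(rownames(corr$rho), rownames(corr$p_raw)) &&
      !is.null(rownames(corr$rho)))
    stop("taxon ordering mismatch between rho and P matrices")
  p <- if (config$use_adjusted_p) corr$p_adj else corr$p_raw
  sel <- abs(corr$rho) > config$rho_threshold & p < config$alpha
  sel[lower.tri(sel, diag = TRUE)] <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  ids <- corr$taxon_ids
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(idx) > 0) {
    ev <- rbind(ids[idx[, 1]], ids[idx[, 2]])
    g <- igraph::add_edges(g, as.vector(ev))
    rho_e <- corr$rho[idx]
    g <- igraph::set_edge_attr(g, "rho", value = rho_e)
    g <- igraph::set_edge_attr(g, "sign", value = ifelse(rho_e > 0, "+", "-"))
  }
  if (!is.null(lineages)) {
    gen <- parse_lineage(lineages[ids])[, "genus"]
    g <- igraph::set_vertex_attr(g, "genus", value = unname(gen))
  }
  if (config$drop_isolated_nodes)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  cooc_network(g, group_label = group_label)
}

#' Wrap an igraph graph as a co-occurrence network
#'
#' @param graph an undirected simple igraph graph; edges may carry `rho`
#'   and `sign` attributes.
#' @param group_label optional group label.
#' @return A `cooc_network`.
#' @export
cooc_network <- function(graph, group_label = NA_character_) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) stop("co-occurrence networks are undirected")
  if (igraph::any_loop(graph) || igraph::any_multiple(graph))
    stop("co-occurrence networks must be simple (no loops or multi-edges)")
  if (is.null(igraph::vertex_attr(graph, "name")))
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = paste0("n", seq_len(igraph::vcount(graph))))
  structure(list(graph = graph, group_label = group_label), class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("cooc_network", if (!is.na(x$group_label)) paste0("[", x$group_label, "]") else "",
      ": ", igraph::vcount(x$graph), " nodes, ", igraph::ecount(x$graph), " edges\n",
      sep = "")
  invisible(x)
}

#' Export a co-occurrence network to GraphML or edge-list TSV
#'
#' GraphML carries node attributes (taxon id, genus, degree, module, role
#' where present) and edge attributes (rho, sign); it round-trips through
#' [read_network()]. The edge list is a 4-column TSV (source, target, rho,
#' sign) consumable by Gephi or Cytoscape.
#'
#' @param network a `cooc_network`.
#' @param path output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly. An empty network writes a valid file with a
#'   warning.
#' @export
write_network <- function(network, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(network, "cooc_network"))
  format <- match.arg(format)
  g <- network$graph
  if (igraph::ecount(g) == 0) warning("writing network with 0 edges")
  g <- igraph::set_vertex_attr(g, "degree", value = igraph::degree(g))
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    rho <- igraph::edge_attr(g, "rho")
    sgn <- igraph::edge_attr(g, "sign")
    df <- data.frame(source = el[, 1], target = el[, 2],
                     rho = if (is.null(rho)) rep(NA_real_, nrow(el)) else rho,
                     sign = if (is.null(sgn)) rep(NA_character_, nrow(el)) else sgn)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#'
#' @param path GraphML file.
#' @param group_label optional group label to attach.
#' @return A `cooc_network`.
#' @export
read_network <- function(path, group_label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  g <- igraph::as_undirected(g, mode = "collapse")
  cooc_network(g, group_label = group_label)
}
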