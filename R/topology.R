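#' Per-node degree and clustering, and the average clustering coefficient
#'
#' Node clustering is 2 * triangles / (k (k - 1)) for degree k >= 2 and 0
#' otherwise; ACC is the mean over all nodes. Edge signs are ignored:
#' topology is computed on the unweighted, sign-collapsed graph.
#'
#' @param network a `cooc_network`.
#' @return List with `degree` (named vector), `clustering` (named vector),
#'   and `acc`.
#' @export
degree_and_clustering <- function(network) {
  g <- as_topology_graph(network)
  deg <- igraph::degree(g)
  if (igraph::vcount(g) == 0) {
    warning("empty graph: ACC is 0")
    return(list(degree = deg, clustering = deg, acc = 0))
  }
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  list(degree = deg, clustering = cc, acc = mean(cc))
}

#' Shortest-path metrics
#'
#' Breadth-first shortest paths on the unweighted graph. APL is the mean
#' over reachable ordered pairs (self-pairs excluded); unreachable pairs
#' are excluded rather than restricting to the largest component, so the
#' metric stays defined on fragmented, high-module-count networks.
#' Diameter is the largest finite eccentricity.
#'
#' @param network a `cooc_network`.
#' @return List with `apl`, `diameter`, and `component_sizes`. A graph
#'   with no edges returns `apl = NA` flagged missing, never 0.
#' @export
path_metrics <- function(network) {
  g <- as_topology_graph(network)
  comp <- igraph::components(g)
  if (igraph::ecount(g) == 0)
    return(list(apl = NA_real_, diameter = NA_real_,
                component_sizes = sort(comp$csize, decreasing = TRUE)))
  d <- igraph::distances(g, weights = NA)
  finite <- is.finite(d) & d > 0
  list(apl = mean(d[finite]),
       diameter = max(d[finite]),
       component_sizes = sort(comp$csize, decreasing = TRUE))
}

#' Newman modularity of a partition
#'
#' Q = sum_c \[ e_c / m - (d_c / 2m)^2 \] where e_c counts within-module
#' edges, d_c is the total degree of module c, and m the edge count.
#' Unweighted and sign-agnostic.
#'
#' @param network a `cooc_network`.
#' @param membership named vector (or `cooc_partition`) assigning every
#'   node to a module.
#' @return Modularity Q in \[-0.5, 1\].
#' @export
modularity_q <- function(network, membership) {
  g <- as_topology_graph(network)
  mem <- as_membership_vector(membership, g)
  m <- igraph::ecount(g)
  if (m == 0) return(0)
  el <- igraph::as_edgelist(g, names = TRUE)
  within <- mem[el[, 1]] == mem[el[, 2]]
  deg <- igraph::degree(g)
  e_c <- tapply(rep(1L, m)[within], mem[el[within, 1]], sum)
  d_c <- tapply(deg, mem, sum)
  e_c_full <- stats::setNames(numeric(length(d_c)), names(d_c))
  e_c_full[names(e_c)] <- e_c
  sum(e_c_full / m - (d_c / (2 * m))^2)
}

#' Detect modules with seeded Louvain community detection
#'
#' Runs Louvain on the unweighted, sign-collapsed graph under a fixed
#' seed. Singleton components form their own modules and count as
#' modules. The partition is labeled modular iff Q > 0.4, the conventional
#' criterion for calling a network modular.
#'
#' @param network a `cooc_network` with at least one edge.
#' @param seed integer RNG seed.
#' @param method `"louvain"` (default) or `"greedy"` (fast-greedy
#'   agglomeration).
#' @return A `cooc_partition`: list with `membership` (named, 0-based
#'   contiguous ids), `Q`, `n_modules`, `modular` flag.
#' @export
detect_modules <- function(network, seed = 1L, method = c("louvain", "greedy")) {
  method <- match.arg(method)
  g <- as_topology_graph(network)
  if (igraph::ecount(g) == 0) stop("cannot detect modules in a graph with no edges")
  cl <- withr_seed(seed, {
    if (method == "louvain") igraph::cluster_louvain(g, weights = NA)
    else igraph::cluster_fast_greedy(g, weights = NULL)
  })
  mem <- igraph::membership(cl)
  mem <- stats::setNames(as.integer(factor(as.integer(mem))) - 1L, igraph::V(g)$name)
  q <- modularity_q(cooc_network(g), mem)
  structure(list(membership = mem, Q = q, n_modules = length(unique(mem)),
                 modular = q > 0.4),
            class = "cooc_partition")
}

#' @export
print.cooc_partition <- function(x, ...) {
  cat("cooc_partition:", x$n_modules, "modules, Q =", round(x$Q, 4),
      if (x$modular) "(modular, Q > 0.4)" else "", "\n")
  invisible(x)
}

#' Randomize a network under a null model
#'
#' `"gnm"` draws a uniform random graph with the same node and edge
#' counts; `"rewire"` applies Maslov-Sneppen double-edge swaps
#' (`n_swaps_factor` x m attempted swaps), preserving the degree sequence
#' exactly with no self-loops or multi-edges.
#'
#' @param network a `cooc_network`.
#' @param model `"rewire"` (default) or `"gnm"`.
#' @param n_swaps_factor swaps per edge for rewiring (>= 1).
#' @param seed integer RNG seed.
#' @return A randomized `cooc_network` (edge signs are not carried over).
#' @export
randomize_network <- function(network, model = c("rewire", "gnm"),
                              n_swaps_factor = 100, seed = 1L) {
  model <- match.arg(model)
  g <- as_topology_graph(network)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  out <- withr_seed(seed, {
    if (model == "gnm") {
      igraph::sample_gnm(n, m, directed = FALSE)
    } else {
      if (n_swaps_factor < 1) stop("n_swaps_factor must be >= 1")
      if (m < 2) {
        warning("no legal swap exists; returning input unchanged")
        g
      } else {
        igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = ceiling(n_swaps_factor * m)))
      }
    }
  })
  if (is.null(igraph::vertex_attr(out, "name")))
    out <- igraph::set_vertex_attr(out, "name", value = igraph::V(g)$name)
  cooc_network(out, group_label = network$group_label)
}

#' Fraction of positive edges
#'
#' @param network a `cooc_network` whose edges carry a `sign` attribute.
#' @return `count(sign == "+") / count(edges)`; `NA` with a warning on an
#'   empty edge set.
#' @export
positive_edge_fraction <- function(network) {
  stopifnot(inherits(network, "cooc_network"))
  m <- igraph::ecount(network$graph)
  if (m == 0) {
    warning("empty edge set: positive edge fraction undefined")
    return(NA_real_)
  }
  sgn <- igraph::edge_attr(network$graph, "sign")
  if (is.null(sgn)) stop("edges carry no sign attribute")
  mean(sgn == "+")
}

#' Topology summary against a randomized-network null ensemble
#'
#' Computes ACC, APL and modularity Q (of a seeded Louvain partition) on
#' the observed network and on `n_replicates` null randomizations, and
#' reports per-metric null mean, sd and z = (observed - null mean) /
#' null sd. The network is flagged "modular/small-world-like" when the
#' observed ACC and Q both exceed their null means.
#'
#' @param network a `cooc_network`.
#' @param model null model, `"rewire"` (default) or `"gnm"`.
#' @param n_replicates number of null replicates (>= 10; default 1000).
#' @param seed integer RNG seed; per-replicate sub-seeds are derived
#'   deterministically.
#' @return A `topology_summary` list: observed metrics (n_nodes, n_edges,
#'   both edges-per-node conventions, ACC, APL, diameter, Q, n_modules,
#'   positive_edge_fraction) plus `null_stats` per metric.
#' @export
null_ensemble_summary <- function(network, model = c("rewire", "gnm"),
                                  n_replicates = 1000, seed = 1L) {
  model <- match.arg(model)
  if (n_replicates < 10) stop("need at least 10 null replicates")
  obs <- topology_summary(network, seed = seed)
  metrics <- matrix(NA_real_, nrow = n_replicates, ncol = 3,
                    dimnames = list(NULL, c("acc", "apl", "Q")))
  for (i in seq_len(n_replicates)) {
    sub <- as.integer((as.numeric(seed) * 1000003 + i) %% 2147483647)
    nullnet <- randomize_network(network, model = model, seed = sub)
    metrics[i, "acc"] <- degree_and_clustering(nullnet)$acc
    metrics[i, "apl"] <- path_metrics(nullnet)$apl
    metrics[i, "Q"] <- if (igraph::ecount(nullnet$graph) > 0)
      detect_modules(nullnet, seed = sub)$Q else NA_real_
  }
  null_stats <- lapply(colnames(metrics), function(k) {
    v <- metrics[, k]
    mu <- mean(v, na.rm = TRUE); sdv <- stats::sd(v, na.rm = TRUE)
    o <- switch(k, acc = obs$acc, apl = obs$apl, Q = obs$Q)
    z <- if (is.na(sdv) || sdv == 0) NA_real_ else (o - mu) / sdv
    list(observed = o, null_mean = mu, null_sd = sdv, z = z)
  })
  names(null_stats) <- colnames(metrics)
  obs$null_model <- model
  obs$n_replicates <- n_replicates
  obs$null_stats <- null_stats
  obs$null_replicates <- metrics
  obs$modular_small_world <- isTRUE(obs$acc > null_stats$acc$null_mean &&
                                    obs$Q > null_stats$Q$null_mean)
  class(obs) <- "topology_summary"
  obs
}

#' Observed topological summary of a network
#'
#' @param network a `cooc_network`.
#' @param seed seed for the Louvain module detection.
#' @return A `topology_summary` list (no null ensemble).
#' @export
topology_summary <- function(network, seed = 1L) {
  g <- as_topology_graph(network)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  dc <- degree_and_clustering(network)
  pm <- path_metrics(network)
  part <- if (m > 0) detect_modules(network, seed = seed) else NULL
  pef <- if (!is.null(igraph::edge_attr(g, "sign")) && m > 0)
    positive_edge_fraction(network) else NA_real_
  structure(list(group_label = network$group_label,
                 n_nodes = n, n_edges = m,
                 mean_degree_2E_over_N = if (n > 0) 2 * m / n else NA_real_,
                 edges_per_node_E_over_N = if (n > 0) m / n else NA_real_,
                 acc = dc$acc, apl = pm$apl, diameter = pm$diameter,
                 Q = if (is.null(part)) NA_real_ else part$Q,
                 n_modules = if (is.null(part)) NA_integer_ else part$n_modules,
                 positive_edge_fraction = pef,
                 component_sizes = pm$component_sizes,
                 partition = part),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("topology_summary",
      if (!is.na(x$group_label)) paste0("[", x$group_label, "]"), "\n")
  cat(sprintf("  nodes %d, edges %d (E/N %.2f, 2E/N %.2f)\n", x$n_nodes, x$n_edges,
              x$edges_per_node_E_over_N, x$mean_degree_2E_over_N))
  cat(sprintf("  ACC %.3f, APL %s, diameter %s\n", x$acc,
              format(round(x$apl, 3)), format(x$diameter)))
  cat(sprintf("  Q %.3f over %s modules, positive edges %s\n",
              x$Q, format(x$n_modules),
              if (is.na(x$positive_edge_fraction)) "NA"
              else sprintf("%.1f%%", 100 * x$positive_edge_fraction)))
  if (!is.null(x$null_stats)) {
    for (k in names(x$null_stats)) {
      s <- x$null_stats[[k]]
      cat(sprintf("  null %s: mean %.3f sd %.3f z %s\n", k, s$null_mean, s$null_sd,
                  if (is.na(s$z)) "undefined" else sprintf("%.2f", s$z)))
    }
  }
  invisible(x)
}

# internal: unweighted sign-collapsed simple graph for topology
as_topology_graph <- function(network) {
  if (inherits(network, "cooc_network")) return(network$graph)
  if (igraph::is_igraph(network)) return(network)
  stop("expected a cooc_network or igraph graph")
}

# internal: membership as named integer vector aligned to graph vertices
as_membership_vector <- function(membership, g) {
  if (inherits(membership, "cooc_partition")) membership <- membership$membership
  nm <- igraph::V(g)$name
  if (is.null(names(membership))) {
    if (length(membership) != length(nm)) stop("membership length mismatch")
    names(membership) <- nm
  }
  if (!all(nm %in% names(membership)))
    stop("nodes missing from partition: ",
         paste(utils::head(setdiff(nm, names(membership))), collapse = ", "))
  membership[nm]
}

# internal: evaluate expr under a temporary RNG seed, restoring state after
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
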