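#' Specification for a synthetic microbial community
#'
#' Defines the study-design emulation: two groups of 16 cecal samples,
#' a few hundred taxa (a desk-scale stand-in for a MAG catalogue),
#' log-normal base abundances, planted correlated taxon blocks driven by
#' latent Gaussian factors, optional keystone taxa bridging several
#' blocks, and traits linearly coupled to designated taxa.
#'
#' @param n_groups number of sample groups (default 2).
#' @param n_samples_per_group samples per group (default 16).
#' @param n_taxa total taxa (default 200).
#' @param module_sizes integer vector, taxa per planted block; remaining
#'   taxa are independent. Default five blocks of 10.
#' @param latent_corr target within-block latent correlation in \[0, 1)
#'   (default 0.9).
#' @param lognormal_mu,lognormal_sigma mean and sd of per-taxon base
#'   log-abundance (defaults 0 and 2; the sigma spreads taxa over orders
#'   of magnitude as in real relative-abundance data).
#' @param noise_sigma sd of a per-sample multiplicative (log-scale) depth
#'   factor (default 0; compositional closure cancels it, it exists to
#'   emulate pre-closure depth variation).
#' @param keystone_spec named list: keystone taxon index -> integer vector
#'   of block ids it bridges (default empty).
#' @param trait_spec data.frame with columns `trait`, `taxon`, `slope`,
#'   `noise_sd` (default `NULL`, no traits).
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_groups = 2, n_samples_per_group = 16, n_taxa = 200,
                           module_sizes = rep(10L, 5), latent_corr = 0.9,
                           lognormal_mu = 0, lognormal_sigma = 2,
                           noise_sigma = 0, keystone_spec = list(),
                           trait_spec = NULL, seed = 1L) {
  if (sum(module_sizes) > n_taxa)
    stop("module_sizes sum exceeds n_taxa")
  if (latent_corr < 0 || latent_corr >= 1)
    stop("latent_corr must lie in [0, 1)")
  structure(list(n_groups = as.integer(n_groups),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 n_taxa = as.integer(n_taxa),
                 module_sizes = as.integer(module_sizes),
                 latent_corr = latent_corr,
                 lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
                 noise_sigma = noise_sigma,
                 keystone_spec = keystone_spec, trait_spec = trait_spec,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic community with planted correlation blocks
#'
#' Latent-Gaussian copula construction: each planted block b has one
#' standard-normal factor per sample; taxon j in block b draws
#' log-abundance deviation `sqrt(latent_corr) * factor_b +
#' sqrt(1 - latent_corr) * idiosyncratic`, independent taxa are pure
#' noise, and keystone taxa load equally on every block they bridge
#' (loadings rescaled to unit variance). Deviations are shifted by
#' per-taxon log-normal base abundances, exponentiated, and closed to
#' relative abundances, which introduces the mild negative-correlation
#' artifact real compositional data carry.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `table` (an `abundance_table`, rows sum to 1, group
#'   labels attached) and `truth` (a `ground_truth` list:
#'   `block_membership`, `keystone_nodes`, `trait_links`).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr_seed(spec$seed, {
    n <- spec$n_groups * spec$n_samples_per_group
    p <- spec$n_taxa
    taxa <- sprintf("taxon_%03d", seq_len(p))
    samples <- paste0(rep(paste0("G", seq_len(spec$n_groups)), each = spec$n_samples_per_group),
                      "_S", sprintf("%02d", sequence(rep(spec$n_samples_per_group, spec$n_groups))))
    groups <- rep(paste0("G", seq_len(spec$n_groups)), each = spec$n_samples_per_group)
    nb <- length(spec$module_sizes)
    block_of <- rep(NA_integer_, p)
    pos <- 1L
    for (b in seq_len(nb)) {
      block_of[pos:(pos + spec$module_sizes[b] - 1L)] <- b
      pos <- pos + spec$module_sizes[b]
    }
    factors <- matrix(stats::rnorm(n * nb), nrow = n)      # sample x block
    eps <- matrix(stats::rnorm(n * p), nrow = n)           # idiosyncratic
    lc <- spec$latent_corr
    z <- matrix(0, nrow = n, ncol = p, dimnames = list(samples, taxa))
    for (j in seq_len(p)) {
      z[, j] <- if (is.na(block_of[j])) eps[, j]
        else sqrt(lc) * factors[, block_of[j]] + sqrt(1 - lc) * eps[, j]
    }
    keystones <- character(0)
    if (length(spec$keystone_spec) > 0) {
      for (k in seq_along(spec$keystone_spec)) {
        j <- as.integer(names(spec$keystone_spec)[k])
        blocks <- as.integer(spec$keystone_spec[[k]])
        if (j < 1 || j > p) stop("keystone index out of range: ", j)
        load <- sqrt(lc / length(blocks))
        z[, j] <- rowSums(factors[, blocks, drop = FALSE]) * load +
          sqrt(1 - lc) * eps[, j]
        block_of[j] <- NA_integer_
        keystones <- c(keystones, taxa[j])
      }
    }
    base <- stats::rnorm(p, spec$lognormal_mu, spec$lognormal_sigma)
    depth <- stats::rnorm(n, 0, spec$noise_sigma)
    logx <- sweep(z, 2, base, "+") + depth
    x <- exp(logx)
    x <- x / rowSums(x)
    tab <- abundance_table(x, groups = groups)
    truth <- structure(list(
      block_membership = stats::setNames(block_of, taxa),
      keystone_nodes = keystones,
      trait_links = if (is.null(spec$trait_spec)) NULL
        else stats::setNames(as.character(spec$trait_spec$taxon), spec$trait_spec$trait)),
      class = "ground_truth")
    list(table = tab, truth = truth)
  })
}

#' Generate traits linearly coupled to designated taxa
#'
#' Each trait is `slope * linked-taxon relative abundance + N(0, noise_sd)`
#' per sample; deterministic under the spec seed (offset so trait noise is
#' independent of the community draw).
#'
#' @param table an `abundance_table` from [generate_community()].
#' @param spec the generating [synthetic_spec()]; `trait_spec` must name
#'   taxa present in `table`.
#' @return A `trait_table` aligned to `table`'s samples.
#' @export
generate_traits <- function(table, spec) {
  stopifnot(inherits(table, "abundance_table"), inherits(spec, "synthetic_spec"))
  ts <- spec$trait_spec
  if (is.null(ts) || nrow(ts) == 0) stop("spec carries no trait_spec")
  missing <- setdiff(as.character(ts$taxon), taxon_ids(table))
  if (length(missing) > 0)
    stop("linked taxa not in table: ", paste(missing, collapse = ", "))
  withr_seed(spec$seed + 7919L, {
    n <- nrow(table$values)
    vals <- sapply(seq_len(nrow(ts)), function(i) {
      ts$slope[i] * table$values[, as.character(ts$taxon[i])] +
        stats::rnorm(n, 0, ts$noise_sd[i])
    })
    dimnames(vals) <- list(rownames(table$values), as.character(ts$trait))
    trait_table(vals)
  })
}

#' Generate a benchmark graph with known partition and roles
#'
#' Oracle fixtures for module detection and Zi-Pi role classification:
#' \describe{
#'   \item{two-cliques}{two disjoint complete graphs K_`clique_size`;
#'     the clique partition is optimal (Q = 0.5 for equal cliques).}
#'   \item{ring-of-cliques}{`k` cliques of size `clique_size` arranged in
#'     a ring; between consecutive cliques sits a dedicated bridge node
#'     linked to one member of each of the three nearest cliques, so
#'     bridge nodes are connectors (Pi = 2/3) and clique members are
#'     peripherals.}
#'   \item{planted-partition}{stochastic block model with `k` blocks of
#'     `block_size` nodes, within-probability `p_in`, between `p_out`.}
#' }
#'
#' @param kind `"two-cliques"`, `"ring-of-cliques"` or `"planted-partition"`.
#' @param k number of cliques/blocks (>= 2).
#' @param clique_size nodes per clique (two-cliques, ring-of-cliques).
#' @param block_size nodes per block (planted-partition).
#' @param p_in,p_out edge probabilities (planted-partition).
#' @param seed RNG seed (planted-partition only; the clique kinds are
#'   deterministic).
#' @return List with `network` (a `cooc_network`, all edges signed "+"),
#'   `membership` (true module of every node) and `roles` (true role of
#'   every node, where analytically known).
#' @export
generate_benchmark_graph <- function(kind = c("two-cliques", "ring-of-cliques",
                                              "planted-partition"),
                                     k = 2, clique_size = 4, block_size = 20,
                                     p_in = 0.9, p_out = 0.01, seed = 1L) {
  kind <- match.arg(kind)
  if (k < 2) stop("need at least 2 cliques/blocks")
  if (kind == "two-cliques") k <- 2
  if (kind %in% c("two-cliques", "ring-of-cliques")) {
    nodes <- paste0("c", rep(seq_len(k), each = clique_size), "_",
                    sequence(rep(clique_size, k)))
    edges <- character(0)
    for (b in seq_len(k)) {
      mem <- nodes[((b - 1) * clique_size + 1):(b * clique_size)]
      pr <- utils::combn(mem, 2)
      edges <- c(edges, as.vector(pr))
    }
    membership <- stats::setNames(rep(seq_len(k), each = clique_size), nodes)
    roles <- stats::setNames(rep("peripheral", length(nodes)), nodes)
    if (kind == "ring-of-cliques") {
      bridges <- paste0("bridge_", seq_len(k))
      for (b in seq_len(k)) {
        touched <- (c(b, b + 1, b + 2) - 1) %% k + 1
        anchor <- nodes[(touched - 1) * clique_size + 1]
        edges <- c(edges, as.vector(rbind(bridges[b], anchor)))
      }
      nodes <- c(nodes, bridges)
      membership <- c(membership, stats::setNames(seq_len(k), bridges))
      roles <- c(roles, stats::setNames(rep("connector", k), bridges))
    }
    g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = nodes)
    g <- igraph::add_edges(g, edges)
  } else {
    if (k < 2 || block_size < 2) stop("need k >= 2 blocks of >= 2 nodes")
    g <- withr_seed(seed, igraph::sample_sbm(k * block_size,
      pref.matrix = matrix(p_out, k, k) + diag(p_in - p_out, k),
      block.sizes = rep(block_size, k)))
    nodes <- sprintf("v%03d", seq_len(k * block_size))
    g <- igraph::set_vertex_attr(g, "name", value = nodes)
    membership <- stats::setNames(rep(seq_len(k), each = block_size), nodes)
    roles <- NULL
  }
  g <- igraph::set_edge_attr(g, "rho", value = rep(1, igraph::ecount(g)))
  g <- igraph::set_edge_attr(g, "sign", value = rep("+", igraph::ecount(g)))
  list(network = cooc_network(g), membership = membership, roles = roles)
}

#' Write ground truth to JSON
#'
#' @param truth a `ground_truth` from [generate_community()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(list(
    block_membership = as.list(truth$block_membership),
    keystone_nodes = truth$keystone_nodes,
    trait_links = as.list(truth$trait_links)),
    path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}
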