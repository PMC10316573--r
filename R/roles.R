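#' Within-module degree z-score (Zi)
#'
#' For node i in module s, Zi = (k_is - mean_s) / sd_s where k_is counts
#' links from i to other members of s and mean/sd are taken over the
#' members of s (population sd, the Guimera-Amaral convention). Modules
#' whose within-degrees have zero spread give Zi = 0 by convention.
#'
#' @param network a `cooc_network`.
#' @param partition a `cooc_partition` or named membership vector covering
#'   all nodes.
#' @return Named numeric vector of Zi values.
#' @export
within_module_degree_z <- function(network, partition) {
  g <- as_topology_graph(network)
  mem <- as_membership_vector(partition, g)
  kis <- within_module_links(g, mem)
  z <- numeric(length(kis))
  names(z) <- names(kis)
  for (mod in unique(mem)) {
    members <- names(mem)[mem == mod]
    k <- kis[members]
    sdv <- sqrt(mean((k - mean(k))^2))  # population sd; 0 for singletons
    z[members] <- if (sdv == 0) 0 else (k - mean(k)) / sdv
  }
  z
}

#' Participation coefficient (Pi)
#'
#' Pi = 1 - sum_s (k_is / k_i)^2 over modules s, where k_is counts node
#' i's links into module s and k_i is its total degree. Pi = 0 means all
#' links stay inside one module; isolated nodes get Pi = 0.
#'
#' @inheritParams within_module_degree_z
#' @return Named numeric vector of Pi values in \[0, 1\].
#' @export
participation_coefficient <- function(network, partition) {
  g <- as_topology_graph(network)
  mem <- as_membership_vector(partition, g)
  nm <- igraph::V(g)$name
  pi <- stats::setNames(numeric(length(nm)), nm)
  el <- igraph::as_edgelist(g, names = TRUE)
  deg <- igraph::degree(g)
  if (nrow(el) == 0) return(pi)
  # per-node counts of links into each module
  ends_long <- data.frame(node = c(el[, 1], el[, 2]),
                          mod = c(mem[el[, 2]], mem[el[, 1]]))
  tab <- table(ends_long$node, ends_long$mod)
  for (v in rownames(tab)) {
    k <- deg[v]
    if (k == 0) next
    pi[v] <- 1 - sum((tab[v, ] / k)^2)
  }
  pi
}

#' Classify nodes into Zi-Pi topological roles
#'
#' Four-way Guimera-Amaral classification: module hubs (Zi >= zi_cut,
#' Pi < pi_cut), network hubs (Zi >= zi_cut, Pi >= pi_cut), connectors
#' (Zi < zi_cut, Pi >= pi_cut), peripherals otherwise. Boundary ties go
#' to the hub/connector side. Module hubs and connectors are the
#' candidate keystone taxa.
#'
#' @param zi named vector of within-module degree z-scores.
#' @param pi named vector of participation coefficients, same nodes.
#' @param zi_cut Zi threshold (default 2.5).
#' @param pi_cut Pi threshold (default 0.62).
#' @return A `role_table` data.frame with columns `node`, `zi`, `pi`,
#'   `role`; attribute `counts` holds per-category totals.
#' @export
classify_roles <- function(zi, pi, zi_cut = 2.5, pi_cut = 0.62) {
  if (length(zi) != length(pi)) stop("zi and pi length mismatch")
  if (!is.finite(zi_cut) || !is.finite(pi_cut)) stop("thresholds must be finite")
  if (!is.null(names(zi)) && !is.null(names(pi))) pi <- pi[names(zi)]
  role <- ifelse(zi >= zi_cut & pi >= pi_cut, "network_hub",
          ifelse(zi >= zi_cut,               "module_hub",
          ifelse(pi >= pi_cut,               "connector", "peripheral")))
  out <- data.frame(node = if (is.null(names(zi))) as.character(seq_along(zi)) else names(zi),
                    zi = unname(zi), pi = unname(pi), role = unname(role),
                    stringsAsFactors = FALSE)
  counts <- table(factor(out$role, levels = c("peripheral", "connector",
                                              "module_hub", "network_hub")))
  structure(out, counts = as.list(counts), zi_cut = zi_cut, pi_cut = pi_cut,
            class = c("role_table", "data.frame"))
}

#' Compute Zi, Pi and role categories for a partitioned network
#'
#' Convenience wrapper running [within_module_degree_z()],
#' [participation_coefficient()] and [classify_roles()].
#'
#' @inheritParams within_module_degree_z
#' @param zi_cut,pi_cut role thresholds (defaults 2.5 and 0.62).
#' @return A `role_table`.
#' @export
node_roles <- function(network, partition, zi_cut = 2.5, pi_cut = 0.62) {
  zi <- within_module_degree_z(network, partition)
  pi <- participation_coefficient(network, partition)
  classify_roles(zi, pi, zi_cut = zi_cut, pi_cut = pi_cut)
}

# internal: links from each node into its own module
within_module_links <- function(g, mem) {
  nm <- igraph::V(g)$name
  kis <- stats::setNames(numeric(length(nm)), nm)
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0) return(kis)
  same <- mem[el[, 1]] == mem[el[, 2]]
  if (any(same)) {
    inc <- table(c(el[same, 1], el[same, 2]))
    kis[names(inc)] <- as.numeric(inc)
  }
  kis
}
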