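# Shared fixtures and independent oracles, built in code.

make_table <- function(values, lineages = NULL, groups = NULL) {
  if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("t", seq_len(ncol(values)))
  abundance_table(values, lineages = lineages, groups = groups)
}

random_table <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(n * p), nrow = n,
              dimnames = list(paste0("s", 1:n), paste0("t", 1:p)))
  abundance_table(m / rowSums(m))
}

# oracle: midranks without rank() — average positions of tied values
oracle_midrank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# oracle: textbook Pearson on oracle midranks
oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# oracle: BH step-up by explicit sort / cummin
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# oracle: exact two-sided Wilcoxon P by full enumeration of rank assignments
oracle_wilcoxon_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(n + m, n)
  u_all <- apply(sets, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}

# oracle: modularity by direct double loop over the formula's terms
oracle_modularity <- function(graph, mem) {
  m <- igraph::ecount(graph)
  el <- igraph::as_edgelist(graph, names = TRUE)
  deg <- igraph::degree(graph)
  q <- 0
  for (mod in unique(mem)) {
    members <- names(mem)[mem == mod]
    e_c <- sum(el[, 1] %in% members & el[, 2] %in% members)
    d_c <- sum(deg[members])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

triangle_graph <- function() {
  g <- igraph::make_ring(3)
  g <- igraph::set_vertex_attr(g, "name", value = c("a", "b", "c"))
  g <- igraph::set_edge_attr(g, "sign", value = rep("+", 3))
  cooc_network(g)
}

path_graph <- function(n = 3) {
  g <- igraph::make_ring(n, circular = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("n", seq_len(n)))
  cooc_network(g)
}
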