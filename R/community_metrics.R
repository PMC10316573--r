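#' Per-sample alpha diversity
#'
#' Shannon (natural log), Simpson (1 - sum p^2), inverse Simpson
#' (1 / sum p^2) and richness (taxa with p > 0). Rows not summing to ~1
#' are auto-normalized with a notice.
#'
#' @param table an `abundance_table`.
#' @return data.frame with one row per sample: `shannon`, `simpson`,
#'   `invsimpson`, `richness`, plus `group` when labels are present.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  tot <- rowSums(v)
  if (any(abs(tot - 1) > 1e-9)) {
    message("rows do not sum to 1; normalizing to relative abundances")
    v <- normalize_relative(table)$values
  }
  shannon <- apply(v, 1, function(p) { p <- p[p > 0]; -sum(p * log(p)) })
  sump2 <- rowSums(v^2)
  out <- data.frame(sample_id = rownames(v), shannon = shannon,
                    simpson = 1 - sump2, invsimpson = 1 / sump2,
                    richness = rowSums(v > 0), row.names = NULL)
  if (!is.null(table$groups)) out$group <- unname(table$groups[out$sample_id])
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(a, b) = 1 - 2 sum min(a_t, b_t) / sum (a_t + b_t), computed with
#' [vegan::vegdist()]. Symmetric with zero diagonal; a pair of all-zero
#' samples is undefined and returned as `NA` with a warning.
#'
#' @param table an `abundance_table` with non-negative rows.
#' @return A symmetric sample x sample dissimilarity matrix.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  zero <- rowSums(table$values) == 0
  if (sum(zero) >= 2) warning("all-zero sample pair(s): dissimilarity undefined (NA)")
  d <- as.matrix(vegan::vegdist(table$values, method = "bray"))
  if (any(zero)) {
    d[zero, zero] <- NA_real_
    diag(d) <- 0
  }
  d
}

#' Family-level abundance ratio per sample
#'
#' Ratio of two family-level abundances (e.g. Lactobacillaceae to
#' Enterobacteriaceae, an intestinal-health indicator). A zero
#' denominator yields `Inf` with a flag unless a pseudocount is set.
#'
#' @param table an `abundance_table` with lineages.
#' @param numerator_family,denominator_family family labels (with or
#'   without the `f__` prefix).
#' @param pseudocount optional value added to both terms (default `NULL`,
#'   zero denominators flagged infinite instead).
#' @return data.frame with per-sample `ratio` and `denominator_zero`
#'   flag, plus `group`; attribute `group_summary` holds per-group means
#'   and medians when groups are present.
#' @export
family_ratio <- function(table, numerator_family, denominator_family,
                         pseudocount = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  fam <- aggregate_at_rank(table, "family")
  strip <- function(x) sub("^f__", "", x)
  num <- strip(numerator_family); den <- strip(denominator_family)
  for (f in c(num, den)) {
    if (!f %in% taxon_ids(fam))
      stop("family absent from every sample: ", f)
  }
  a <- fam$values[, num]; b <- fam$values[, den]
  if (!is.null(pseudocount)) { a <- a + pseudocount; b <- b + pseudocount }
  out <- data.frame(sample_id = rownames(fam$values), ratio = a / b,
                    denominator_zero = b == 0, row.names = NULL)
  if (!is.null(table$groups)) {
    out$group <- unname(table$groups[out$sample_id])
    gs <- do.call(rbind, lapply(split(out$ratio, out$group), function(r)
      data.frame(mean = mean(r[is.finite(r)]), median = stats::median(r[is.finite(r)]))))
    attr(out, "group_summary") <- gs
  }
  out
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Wraps [stats::wilcox.test()]: exact two-sided P by enumeration when
#' the combined sample is small (<= 20) and tie-free, otherwise the
#' tie-corrected normal approximation with continuity correction. The
#' statistic is the Mann-Whitney U of `x`.
#'
#' @param x,y numeric vectors, each of length >= 3.
#' @param mode `"auto"` (default), `"exact"` or `"normal-approx"`.
#' @return List with `statistic` (U) and `p_value` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal-approx")) {
  mode <- match.arg(mode)
  if (length(x) < 3 || length(y) < 3) stop("both groups need >= 3 observations")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
    auto = length(x) + length(y) <= 20 && !ties,
    exact = {
      if (length(x) + length(y) > 20) stop("exact mode requires combined n <= 20")
      if (ties) stop("exact mode requires tie-free data")
      TRUE
    },
    `normal-approx` = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = unname(wt$p.value))
}

#' Wilcoxon differential abundance between two groups
#'
#' Per-taxon two-sided Wilcoxon rank-sum test across the two sample
#' groups, BH correction over all tested taxa, significance at
#' `alpha` on the adjusted P. Constant taxa get P = 1 and are never
#' flagged.
#'
#' @param table an `abundance_table` with exactly two group labels.
#' @param alpha significance level on adjusted P (default 0.05).
#' @return data.frame per taxon: group medians, U statistic, `p_raw`,
#'   `p_adj`, `significant`.
#' @export
differential_abundance <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$groups)) stop("abundance table carries no group labels")
  gl <- unique(table$groups)
  if (length(gl) != 2) stop("need exactly two groups, found: ",
                            paste(gl, collapse = ", "))
  i1 <- table$groups == gl[1]; i2 <- table$groups == gl[2]
  if (sum(i1) == 0 || sum(i2) == 0) stop("a group has no samples")
  res <- lapply(taxon_ids(table), function(tx) {
    a <- table$values[i1, tx]; b <- table$values[i2, tx]
    if (length(unique(c(a, b))) == 1)
      return(data.frame(taxon = tx, median_1 = stats::median(a),
                        median_2 = stats::median(b), statistic = NA_real_,
                        p_raw = 1))
    w <- wilcoxon_rank_sum(a, b, mode = "auto")
    data.frame(taxon = tx, median_1 = stats::median(a), median_2 = stats::median(b),
               statistic = w$statistic, p_raw = w$p_value)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("median_", gl)
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
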