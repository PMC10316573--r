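#' Screen taxon-trait and trait-trait Spearman correlations
#'
#' Computes tie-aware Spearman rho across the taxon x trait rectangle and
#' the trait x trait triangle with pairwise-complete handling of missing
#' trait values, t-approximation P-values, and BH correction within each
#' panel family (taxon-trait and trait-trait corrected separately,
#' mirroring the two panels of a correlation figure). A pair passes the
#' screen iff |rho| strictly exceeds `r_cut` AND the selected P is
#' strictly below `alpha`. Pairs with fewer than 4 complete observations
#' are flagged untestable, not dropped.
#'
#' @param table an `abundance_table`.
#' @param traits a `trait_table` whose samples all appear in `table`.
#' @param taxa optional character vector restricting the taxon panel
#'   (e.g. differentially abundant taxa only).
#' @param r_cut correlation magnitude criterion (default 0.35).
#' @param alpha significance level (default 0.05).
#' @param use_adjusted_p screen on BH-adjusted (default) or raw P.
#' @return An `association_result` data.frame: `entity1`, `entity2`,
#'   `panel` (`"taxon-trait"`/`"trait-trait"`), `n`, `rho`, `p_raw`,
#'   `p_adj`, `testable`, `passes_screen`; screen parameters as
#'   attributes.
#' @export
trait_correlations <- function(table, traits, taxa = NULL, r_cut = 0.35,
                               alpha = 0.05, use_adjusted_p = TRUE) {
  stopifnot(inherits(table, "abundance_table"), inherits(traits, "trait_table"))
  ts <- rownames(traits$values)
  missing <- setdiff(ts, sample_ids(table))
  if (length(missing) > 0)
    stop("trait samples absent from abundance table: ",
         paste(utils::head(missing), collapse = ", "))
  if (is.null(taxa)) taxa <- taxon_ids(table)
  bad <- setdiff(taxa, taxon_ids(table))
  if (length(bad) > 0) stop("unknown taxa: ", paste(utils::head(bad), collapse = ", "))
  ab <- table$values[ts, taxa, drop = FALSE]
  tv <- traits$values
  one_pair <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 4) return(c(n = n, rho = NA_real_, p = NA_real_))
    x <- x[ok]; y <- y[ok]
    if (length(unique(x)) == 1 || length(unique(y)) == 1)
      return(c(n = n, rho = 0, p = 1))
    r <- stats::cor(midrank(x), midrank(y))
    r <- min(max(r, -1), 1)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- if (abs(r) >= 1) 0 else 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    c(n = n, rho = r, p = p)
  }
  rows <- list()
  for (tx in taxa) for (tr in colnames(tv)) {
    s <- one_pair(ab[, tx], tv[, tr])
    rows[[length(rows) + 1]] <- data.frame(entity1 = tx, entity2 = tr,
      panel = "taxon-trait", n = s["n"], rho = s["rho"], p_raw = s["p"])
  }
  trn <- colnames(tv)
  if (length(trn) >= 2) {
    for (i in seq_len(length(trn) - 1)) for (j in (i + 1):length(trn)) {
      s <- one_pair(tv[, trn[i]], tv[, trn[j]])
      rows[[length(rows) + 1]] <- data.frame(entity1 = trn[i], entity2 = trn[j],
        panel = "trait-trait", n = s["n"], rho = s["rho"], p_raw = s["p"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- NA_real_
  for (pn in unique(out$panel)) {
    sel <- out$panel == pn & !is.na(out$p_raw)
    out$p_adj[sel] <- bh_adjust(out$p_raw[sel])
  }
  out$testable <- !is.na(out$rho)
  p_sel <- if (use_adjusted_p) out$p_adj else out$p_raw
  out$passes_screen <- out$testable & abs(out$rho) > r_cut & p_sel < alpha
  structure(out, r_cut = r_cut, alpha = alpha,
            p_kind = if (use_adjusted_p) "adjusted" else "raw",
            class = c("association_result", "data.frame"))
}

#' Export an association screen as a plot-ready long TSV
#'
#' Writes `entity1, entity2, panel, n, rho, p, p_adj, passes` rows in a
#' deterministic order (panel, then entity1, then entity2), suitable for
#' heatmap/correlogram rendering. All tested pairs are exported, passing
#' or not.
#'
#' @param result an `association_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
correlation_panel_export <- function(result, path) {
  stopifnot(inherits(result, "association_result"))
  if (nrow(result) == 0) stop("empty association result")
  df <- as.data.frame(result)
  df <- df[order(df$panel, df$entity1, df$entity2), ]
  df <- data.frame(entity1 = df$entity1, entity2 = df$entity2, panel = df$panel,
                   n = df$n, rho = signif(df$rho, 12), p = signif(df$p_raw, 12),
                   p_adj = signif(df$p_adj, 12), passes = df$passes_screen)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
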