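#' Construct an abundance table
#'
#' An `abundance_table` holds a samples x taxa matrix of non-negative
#' abundances plus optional per-taxon lineage strings and per-sample group
#' labels. It is the root input of the co-occurrence pipeline.
#'
#' @param values numeric matrix, samples in rows, taxa in columns; dimnames
#'   supply sample and taxon identifiers.
#' @param lineages optional character vector of GTDB-style lineage strings
#'   (`"d__...;p__...;...;s__..."`), one per taxon.
#' @param groups optional per-sample categorical labels (character or factor).
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, lineages = NULL, groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample row names and taxon column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-numeric abundance at sample '",
         rownames(values)[bad[1, 1]], "', taxon '", colnames(values)[bad[1, 2]], "'")
  if (!is.null(lineages)) {
    if (length(lineages) != ncol(values))
      stop("'lineages' must have one entry per taxon")
    names(lineages) <- colnames(values)
  }
  if (!is.null(groups)) {
    if (length(groups) != nrow(values))
      stop("'groups' must have one entry per sample")
    groups <- as.character(groups)
    names(groups) <- rownames(values)
  }
  structure(list(values = values, lineages = lineages, groups = groups),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$values), "samples x", ncol(x$values), "taxa\n")
  if (!is.null(x$groups))
    cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$groups)), table(x$groups)),
                         collapse = ", "), "\n")
  if (!is.null(x$lineages)) cat("lineages: present\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Sample identifiers of an abundance or trait table
#' @param x an `abundance_table` or `trait_table`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) rownames(x$values)

#' Taxon identifiers of an abundance table
#' @param x an `abundance_table`.
#' @return Character vector of taxon ids.
#' @export
taxon_ids <- function(x) colnames(x$values)

#' Read a taxon abundance table from TSV
#'
#' Reads a tab-delimited table with a header row; the first column holds
#' identifiers. Orientation is explicit and never guessed: silent
#' transposition is the classic microbiome-pipeline bug.
#'
#' @param path path to a TSV file.
#' @param orientation `"rows-are-samples"` (default) or `"rows-are-taxa"`.
#' @param lineages optional named character vector of lineage strings keyed
#'   by taxon id.
#' @param groups optional named character vector of group labels keyed by
#'   sample id.
#' @return An `abundance_table`. Rows that do not sum to ~1 are accepted
#'   as counts and left for [normalize_relative()].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("rows-are-samples", "rows-are-taxa"),
                                 lineages = NULL, groups = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate identifiers in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(ids, colnames(body))))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric cell at row '", ids[bad[1, 1]], "', column '",
         colnames(body)[bad[1, 2]], "'")
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop("missing value at row '", ids[bad[1, 1]], "', column '",
         colnames(num)[bad[1, 2]], "'")
  }
  if (orientation == "rows-are-taxa") num <- t(num)
  if (!is.null(groups)) groups <- unname(groups[rownames(num)])
  if (!is.null(lineages)) lineages <- unname(lineages[colnames(num)])
  abundance_table(num, lineages = lineages, groups = groups)
}

#' Write an abundance table to TSV
#'
#' @param table an `abundance_table`.
#' @param path output path.
#' @param digits significant digits for printing (default 12, round-trip safe).
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, digits = 12) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(sample_id = rownames(table$values),
                   signif(table$values, digits), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Close each sample to relative abundances
#'
#' Divides every sample row by its total so rows sum to 1. Idempotent;
#' zeros stay zero.
#'
#' @param table an `abundance_table`.
#' @return A normalized `abundance_table`.
#' @export
normalize_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  tot <- rowSums(table$values)
  zero <- which(tot == 0)
  if (length(zero) > 0)
    stop("all-zero sample(s): ", paste(rownames(table$values)[zero], collapse = ", "))
  table$values <- table$values / tot
  table
}

#' Filter taxa by prevalence at a minimum relative abundance
#'
#' Retains exactly the taxa whose relative abundance exceeds
#' `min_rel_abund` (strictly) in strictly more than `min_sample_frac` of
#' samples. The default thresholds mirror the "> 0.1% in more than 50% of
#' samples" convention for major-taxon screens. The sample set is unchanged.
#'
#' @param table an `abundance_table`.
#' @param min_rel_abund abundance threshold in \[0,1\] (default 0.001).
#' @param min_sample_frac sample-fraction threshold in \[0,1\] (default 0.5).
#' @return A filtered `abundance_table`.
#' @export
prevalence_filter <- function(table, min_rel_abund = 0.001, min_sample_frac = 0.5) {
  stopifnot(inherits(table, "abundance_table"))
  if (min_rel_abund < 0 || min_rel_abund > 1 || min_sample_frac < 0 || min_sample_frac > 1)
    stop("thresholds must lie in [0, 1]")
  frac <- colMeans(table$values > min_rel_abund)
  keep <- frac > min_sample_frac
  table$values <- table$values[, keep, drop = FALSE]
  if (!is.null(table$lineages)) table$lineages <- table$lineages[keep]
  table
}

.LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
.LINEAGE_PREFIX <- c(domain = "d__", phylum = "p__", class = "c__", order = "o__",
                     family = "f__", genus = "g__", species = "s__")

#' Parse a GTDB-style lineage string
#'
#' Splits `"d__Bacteria;p__Firmicutes;...;s__"` into the seven canonical
#' ranks. Missing levels come back as empty strings; parsing then
#' re-serializing a well-formed string is the identity.
#'
#' @param lineage character vector of lineage strings.
#' @return A character matrix with one row per lineage and the seven rank
#'   columns `domain` ... `species`.
#' @export
parse_lineage <- function(lineage) {
  out <- matrix("", nrow = length(lineage), ncol = 7,
                dimnames = list(names(lineage), .LINEAGE_RANKS))
  for (i in seq_along(lineage)) {
    if (is.na(lineage[i]) || !nzchar(lineage[i])) next
    parts <- trimws(strsplit(lineage[i], ";", fixed = TRUE)[[1]])
    for (p in parts) {
      hit <- which(startsWith(p, .LINEAGE_PREFIX))
      if (length(hit) == 1) out[i, hit] <- substring(p, 4)
    }
  }
  out
}

#' Serialize rank labels back into a GTDB-style lineage string
#'
#' @param ranks character matrix as returned by [parse_lineage()].
#' @return Character vector of lineage strings with empty rank prefixes kept.
#' @export
format_lineage <- function(ranks) {
  apply(ranks, 1, function(r) paste0(.LINEAGE_PREFIX, r, collapse = ";"))
}

#' Aggregate an abundance table at a taxonomic rank
#'
#' Sums the abundances of taxa sharing the same label at `rank`; taxa with
#' an empty label at that rank are pooled as `"Unassigned"`. Per-sample
#' totals are conserved.
#'
#' @param table an `abundance_table` with lineages.
#' @param rank one of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return An `abundance_table` whose taxa are the rank labels.
#' @export
aggregate_at_rank <- function(table, rank) {
  stopifnot(inherits(table, "abundance_table"))
  if (!rank %in% .LINEAGE_RANKS)
    stop("unknown rank '", rank, "'; must be one of ",
         paste(.LINEAGE_RANKS, collapse = ", "))
  if (is.null(table$lineages)) stop("abundance table carries no lineages")
  labels <- parse_lineage(table$lineages)[, rank]
  labels[!nzchar(labels)] <- "Unassigned"
  agg <- t(rowsum(t(table$values), group = labels))
  abundance_table(agg, groups = unname(table$groups))
}

#' Construct a per-sample trait table
#'
#' Continuous phenotypes (SCFA concentrations, hormone levels, body weight)
#' aligned to an abundance table by sample id. Missing values are allowed.
#'
#' @param values numeric matrix, samples in rows, traits in columns, with
#'   dimnames; `NA` marks missing measurements.
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x traits)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample row names and trait column names")
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (any(is.infinite(values)))
    stop("trait values must be finite where not missing")
  structure(list(values = values), class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", nrow(x$values), "samples x", ncol(x$values), "traits\n")
  invisible(x)
}

#' Read a trait table from TSV
#'
#' @param path TSV with a header row; first column sample ids; empty cells
#'   or `NA` mark missing values.
#' @return A `trait_table`.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  trait_table(m)
}

#' Write a trait table to TSV
#' @param traits a `trait_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  stopifnot(inherits(traits, "trait_table"))
  df <- data.frame(sample_id = rownames(traits$values), traits$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
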