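#' Feature-count table
#'
#' Container for an annotated metagenomic count table: a non-negative integer
#' matrix with features as rows and samples as columns, a feature kind
#' describing the annotation source, and an optional taxonomic lineage for
#' taxon features.
#'
#' @param counts numeric matrix of non-negative whole numbers, features in
#'   rows and samples in columns; both dimensions must be named with unique
#'   identifiers.
#' @param kind character scalar describing the annotation, e.g.
#'   `"taxon@Species"`, `"KEGG-pathway"`, `"CARD-type"`, `"VFDB-factor"`,
#'   `"PHI-ID"` or `"BacMet-gene"`.
#' @param lineage optional data frame giving a seven-rank lineage per taxon
#'   feature (columns `Kingdom`, `Phylum`, `Class`, `Order`, `Family`,
#'   `Genus`, `Species`); row order must match `counts`.
#'
#' @return An object of class `feature_table`.
#' @export
#' @examples
#' m <- matrix(c(4L, 0L, 2L, 6L), 2, 2,
#'             dimnames = list(c("fA", "fB"), c("s1", "s2")))
#' feature_table(m, kind = "KEGG-pathway")
feature_table <- function(counts, kind = "taxon@Species", lineage = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop2("'counts' must be a numeric matrix (features x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop2("'counts' must have feature row names and sample column names")
  if (anyNA(counts))
    stop2("'counts' contains missing values")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop2("negative count at feature '", rownames(counts)[bad[1, 1]],
          "', sample '", colnames(counts)[bad[1, 2]], "'")
  if (!is_whole(counts))
    stop2("'counts' must contain whole numbers")
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup))
    stop2("duplicated feature ids: ", paste(dup, collapse = ", "))
  dup <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup))
    stop2("duplicated sample ids: ", paste(dup, collapse = ", "))
  if (!is.null(lineage)) {
    lineage <- as.data.frame(lineage)
    if (nrow(lineage) != nrow(counts))
      stop2("'lineage' must have one row per feature")
    missing_cols <- setdiff(taxonomic_ranks(), names(lineage))
    if (length(missing_cols))
      stop2("'lineage' lacks rank columns: ", paste(missing_cols, collapse = ", "))
  }
  structure(
    list(counts = counts, kind = kind, lineage = lineage),
    class = "feature_table"
  )
}

#' The seven taxonomic ranks used throughout the package
#'
#' @return Character vector `Kingdom` through `Species`.
#' @export
taxonomic_ranks <- function() {
  c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus", "Species")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$counts), " features x ", ncol(x$counts),
      " samples (", x$kind, ")\n", sep = "")
  cat("  total counts: ", format(sum(x$counts), big.mark = ","),
      "; sparsity: ", round(100 * mean(x$counts == 0), 1), "% zero cells\n",
      sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

feature_ids <- function(x) rownames(x$counts)
sample_ids <- function(x) colnames(x$counts)

metadata_columns <- function() {
  c("sample_id", "occupation", "gender", "sample_type", "smoking", "drinking")
}

validate_metadata <- function(metadata) {
  metadata <- as.data.frame(metadata)
  missing_cols <- setdiff(metadata_columns(), names(metadata))
  if (length(missing_cols))
    stop2("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  chk <- function(col, allowed) {
    bad <- setdiff(unique(as.character(metadata[[col]])), allowed)
    if (length(bad))
      stop2("metadata column '", col, "' has invalid values: ",
            paste(bad, collapse = ", "))
  }
  chk("occupation", c("student", "laborer"))
  chk("gender", c("M", "F"))
  chk("sample_type", c("saliva", "feces"))
  chk("smoking", c("yes", "no"))
  chk("drinking", c("yes", "no"))
  dup <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
  if (length(dup))
    stop2("duplicated sample ids in metadata: ", paste(dup, collapse = ", "))
  metadata
}

#' Derive the six-level cohort group code for each sample
#'
#' Samples are grouped from three dimensions: gender (M/F), occupation
#' (St for students, La for laborers), and sample type (S for saliva, F for
#' feces). A saliva sample from a female student is thus coded `"FStS"`.
#'
#' @param metadata a sample metadata data frame (see [load_feature_table()]).
#' @return Character vector of group codes, one per metadata row.
#' @export
group_code <- function(metadata) {
  metadata <- validate_metadata(metadata)
  paste0(ifelse(metadata$gender == "F", "F", "M"),
         ifelse(metadata$occupation == "student", "St", "La"),
         ifelse(metadata$sample_type == "saliva", "S", "F"))
}

#' Load a feature table and its sample metadata from TSV files
#'
#' The feature table file holds one feature per row: the first column is the
#' feature identifier, the remaining columns are integer counts named by
#' sample id. The metadata file has columns `sample_id`, `occupation`
#' (`student`/`laborer`), `gender` (`M`/`F`), `sample_type`
#' (`saliva`/`feces`), `smoking` and `drinking` (`yes`/`no`).
#'
#' @param path path to the feature-count TSV.
#' @param metadata_path path to the sample-metadata TSV.
#' @param kind feature kind label, see [feature_table()].
#' @return A list with elements `table` (a [feature_table()]) and `metadata`
#'   (a data frame).
#' @export
load_feature_table <- function(path, metadata_path, kind = "taxon@Species") {
  if (!file.exists(path)) stop2("feature table file not found: ", path)
  if (!file.exists(metadata_path))
    stop2("metadata file not found: ", metadata_path)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop2("feature table must have a feature id column plus sample columns")
  ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1L, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    col <- colnames(raw)[-1L][bad[1, 2]]
    stop2("malformed number in column '", col, "', row ", bad[1, 1])
  }
  rownames(mat) <- ids
  metadata <- validate_metadata(
    read.delim(metadata_path, stringsAsFactors = FALSE))
  missing_meta <- setdiff(colnames(mat), metadata$sample_id)
  if (length(missing_meta))
    stop2("samples absent from metadata: ", paste(missing_meta, collapse = ", "))
  extra_meta <- setdiff(metadata$sample_id, colnames(mat))
  if (length(extra_meta))
    stop2("metadata samples absent from table: ",
          paste(extra_meta, collapse = ", "))
  metadata <- metadata[match(colnames(mat), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  list(table = feature_table(mat, kind = kind), metadata = metadata)
}

#' Write a feature table (and optionally metadata) to TSV
#'
#' @param x a [feature_table()].
#' @param path output path for the count TSV.
#' @param id_column name of the leading feature-id column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, id_column = "feature_id") {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(feature_id = feature_ids(x), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param metadata a sample metadata data frame.
#' @export
write_sample_metadata <- function(metadata, path) {
  metadata <- validate_metadata(metadata)
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove undetermined features
#'
#' Drops features whose identifier or lineage matches any of the given label
#' patterns (case-insensitive substrings). Used to discard unassigned or
#' uncultured annotations before computing relative abundances.
#'
#' @param x a [feature_table()].
#' @param patterns character vector of case-insensitive substrings.
#' @return A [feature_table()] with matching features removed; counts of the
#'   retained features are unchanged.
#' @export
drop_undetermined <- function(x, patterns = c("unassigned", "uncultured")) {
  stopifnot(inherits(x, "feature_table"))
  if (length(patterns) == 0L) stop2("'patterns' must be non-empty")
  hit <- rep(FALSE, nrow(x$counts))
  for (p in patterns)
    hit <- hit | grepl(p, feature_ids(x), ignore.case = TRUE, fixed = FALSE)
  if (!is.null(x$lineage)) {
    lin <- apply(x$lineage[, taxonomic_ranks(), drop = FALSE], 1,
                 paste, collapse = ";")
    for (p in patterns) hit <- hit | grepl(p, lin, ignore.case = TRUE)
  }
  if (all(hit))
    stop2("all features match the undetermined patterns; nothing retained")
  keep <- which(!hit)
  feature_table(x$counts[keep, , drop = FALSE], kind = x$kind,
                lineage = if (!is.null(x$lineage))
                  x$lineage[keep, , drop = FALSE])
}

#' Convert counts to per-sample relative abundances
#'
#' Relative abundance of a feature is its count divided by the sample's total
#' count over all (determined) features, so each sample column sums to one.
#'
#' @param x a [feature_table()] or a non-negative numeric matrix
#'   (features x samples).
#' @return A numeric matrix of the same shape whose columns sum to 1.
#' @export
relative_abundance <- function(x) {
  counts <- if (inherits(x, "feature_table")) x$counts else x
  if (!is.matrix(counts) || !is.numeric(counts))
    stop2("'x' must be a feature_table or numeric matrix")
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero))
    stop2("sample(s) with zero total count: ", paste(zero, collapse = ", "))
  sweep(counts, 2L, totals, "/")
}

#' Filter features by detection prevalence
#'
#' Retains features detected (count > 0) in at least `min_samples` samples.
#' Feature order is preserved and the operation is idempotent for a fixed
#' threshold.
#'
#' @param x a [feature_table()].
#' @param min_samples minimum number of samples a feature must be detected in.
#' @return A filtered [feature_table()].
#' @export
prevalence_filter <- function(x, min_samples) {
  stopifnot(inherits(x, "feature_table"))
  n <- ncol(x$counts)
  if (!is.numeric(min_samples) || length(min_samples) != 1L ||
      min_samples < 0 || min_samples > n)
    stop2("'min_samples' must lie in [0, ", n, "]")
  prev <- rowSums(x$counts > 0)
  keep <- which(prev >= min_samples)
  if (length(keep) == 0L)
    stop2("no features detected in at least ", min_samples, " samples")
  feature_table(x$counts[keep, , drop = FALSE], kind = x$kind,
                lineage = if (!is.null(x$lineage))
                  x$lineage[keep, , drop = FALSE])
}

#' Aggregate a species-level table to a higher taxonomic rank
#'
#' Counts of species sharing the same ancestor at `rank` are summed, so
#' per-sample totals are conserved exactly.
#'
#' @param x a species-level [feature_table()].
#' @param taxonomy a taxonomy table as returned by [simulate_taxonomy()]: a
#'   data frame with the seven rank columns, one row per species.
#' @param rank one of the seven ranks, see [taxonomic_ranks()].
#' @return A [feature_table()] at the requested rank.
#' @export
aggregate_taxonomy <- function(x, taxonomy, rank) {
  stopifnot(inherits(x, "feature_table"))
  rank <- match.arg(rank, taxonomic_ranks())
  taxonomy <- as.data.frame(taxonomy)
  idx <- match(feature_ids(x), taxonomy$Species)
  if (anyNA(idx))
    stop2("species missing from taxonomy: ",
          paste(feature_ids(x)[is.na(idx)], collapse = ", "))
  if (rank == "Species") {
    out <- x
    out$kind <- "taxon@Species"
    return(out)
  }
  group <- as.character(taxonomy[[rank]][idx])
  # rowsum() sorts groups; restore first-appearance order
  agg <- rowsum(x$counts, group = group, reorder = FALSE)
  feature_table(agg, kind = paste0("taxon@", rank))
}
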