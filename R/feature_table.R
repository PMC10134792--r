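#' Construct a feature table
#'
#' A feature table holds a features-by-samples matrix of non-negative counts
#' or relative abundances, together with the kind of feature it contains
#' (microbial species or functional gene groups such as KEGG orthology
#' groups) and optional per-feature annotations.
#'
#' @param values Numeric matrix, rows = features, columns = samples. Row and
#'   column names are required and must be unique.
#' @param feature_kind Either `"taxon"` or `"gene_group"`.
#' @param annotations Optional data frame with columns `feature_id`,
#'   `phylum`, `display_name`. Missing annotations default to the feature id
#'   as display name and `NA` phylum.
#' @return An object of class `feature_table` with elements `values`,
#'   `feature_kind` and `annotations`.
#' @export
feature_table <- function(values, feature_kind = c("taxon", "gene_group"),
                          annotations = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have row names (feature ids) and column names (sample ids)")
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at feature '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at feature '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  ann <- data.frame(feature_id = rownames(values),
                    phylum = NA_character_,
                    display_name = rownames(values),
                    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    if (!all(c("feature_id") %in% names(annotations))) {
      stop("`annotations` needs a feature_id column")
    }
    idx <- match(ann$feature_id, annotations$feature_id)
    if ("phylum" %in% names(annotations)) {
      ann$phylum <- as.character(annotations$phylum[idx])
    }
    if ("display_name" %in% names(annotations)) {
      dn <- as.character(annotations$display_name[idx])
      ann$display_name <- ifelse(is.na(dn), ann$display_name, dn)
    }
  }
  structure(list(values = values, feature_kind = feature_kind,
                 annotations = ann),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d %s features x %d samples\n",
              nrow(x$values), x$feature_kind, ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

feature_ids <- function(table) rownames(table$values)
sample_ids <- function(table) colnames(table$values)

#' Subset a feature table
#'
#' @param table A [feature_table()].
#' @param features,samples Character vectors of ids to keep (`NULL` keeps all).
#' @return A `feature_table` restricted to the requested ids, in the
#'   requested order.
#' @export
subset_feature_table <- function(table, features = NULL, samples = NULL) {
  stopifnot(inherits(table, "feature_table"))
  f <- if (is.null(features)) rownames(table$values) else features
  s <- if (is.null(samples)) colnames(table$values) else samples
  missing_f <- setdiff(f, rownames(table$values))
  missing_s <- setdiff(s, colnames(table$values))
  if (length(missing_f)) stop("unknown features: ", paste(missing_f, collapse = ", "))
  if (length(missing_s)) stop("unknown samples: ", paste(missing_s, collapse = ", "))
  feature_table(table$values[f, s, drop = FALSE], table$feature_kind,
                table$annotations)
}

#' Read a feature table from TSV
#'
#' Two dialects are supported. `generic_tsv` expects feature ids in the first
#' column and sample ids in the header. `metaphlan_merged` expects
#' MetaPhlAn-style merged tables whose first column carries full taxonomy
#' strings with rank prefixes (`k__...|p__...|...|s__...`); only species-level
#' rows are retained, the feature id is the `s__` name and the `p__` rank is
#' recorded as the phylum annotation. Leading comment lines starting with `#`
#' are tolerated in the metaphlan dialect (the last one, if tab-separated, is
#' taken as the header).
#'
#' @param path Path to a tab-separated file.
#' @param dialect `"generic_tsv"` (default) or `"metaphlan_merged"`.
#' @param feature_kind Passed to [feature_table()].
#' @param annotations_path Optional TSV of feature annotations
#'   (`feature_id`, `phylum`, `display_name`). For the generic dialect,
#'   `<path>.annotations.tsv` is picked up automatically when present.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path,
                               dialect = c("generic_tsv", "metaphlan_merged"),
                               feature_kind = "taxon",
                               annotations_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "generic_tsv") {
    raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
    ids <- raw[[1]]
    mat <- .numeric_matrix(raw[-1], ids, path)
    ann <- NULL
    sidecar <- if (is.null(annotations_path)) paste0(path, ".annotations.tsv") else annotations_path
    if (file.exists(sidecar)) {
      ann <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    }
    feature_table(mat, feature_kind, ann)
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    is_comment <- startsWith(lines, "#")
    header_line <- lines[!is_comment][1]
    comment_headers <- lines[is_comment & grepl("\t", lines)]
    if (length(comment_headers)) {
      header_line <- sub("^#", "", comment_headers[length(comment_headers)])
      body <- lines[!is_comment]
    } else {
      body <- lines[!is_comment][-1]
    }
    header <- strsplit(header_line, "\t", fixed = TRUE)[[1]]
    fields <- strsplit(body, "\t", fixed = TRUE)
    clade <- vapply(fields, `[[`, character(1), 1)
    # species-level rows: lineage terminates at the s__ rank
    last_rank <- sub(".*\\|", "", clade)
    keep <- startsWith(last_rank, "s__")
    fields <- fields[keep]
    clade <- clade[keep]
    species <- sub("^s__", "", sub(".*\\|s__", "s__", clade))
    phylum <- ifelse(grepl("\\|p__", paste0("|", clade)),
                     sub("\\|.*", "", sub(".*?p__", "", clade)), NA_character_)
    vals <- lapply(fields, function(f) f[-1])
    # tolerate an NCBI_tax_id-style extra column between clade and samples
    n_samples <- length(header) - 1
    vals <- lapply(vals, function(v) utils::tail(v, n_samples))
    df <- as.data.frame(do.call(rbind, vals), stringsAsFactors = FALSE)
    names(df) <- utils::tail(header, n_samples)
    mat <- .numeric_matrix(df, species, path)
    ann <- data.frame(feature_id = species, phylum = phylum,
                      display_name = species, stringsAsFactors = FALSE)
    feature_table(mat, "taxon", ann)
  }
}

.numeric_matrix <- function(df, ids, path) {
  mat <- matrix(NA_real_, nrow = length(ids), ncol = ncol(df),
                dimnames = list(ids, names(df)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell in %s at row '%s', column '%s'",
                   path, ids[i], names(df)[j]))
    }
    mat[, j] <- v
  }
  mat
}

#' Write a feature table to generic TSV
#'
#' Writes the matrix with a `feature_id` first column; when the table carries
#' non-trivial annotations these go to a `<path>.annotations.tsv` sidecar so
#' that [read_feature_table()] round-trips the object.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(feature_id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  ann <- table$annotations
  trivial <- all(is.na(ann$phylum)) && all(ann$display_name == ann$feature_id)
  if (!trivial) {
    utils::write.table(ann, paste0(path, ".annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Per-feature prevalence
#'
#' Fraction of samples in which each feature has a value greater than zero,
#' mirroring the "% of samples with nonzero relative abundance" statistic
#' commonly reported for metagenomic biomarkers.
#'
#' @param table A [feature_table()].
#' @return Data frame with columns `feature_id`, `fraction_nonzero`.
#' @export
compute_prevalence <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (ncol(table$values) == 0) stop("table has no samples")
  data.frame(feature_id = rownames(table$values),
             fraction_nonzero = rowMeans(table$values > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter features by prevalence
#'
#' Retains features observed (value > 0) in at least `min_fraction` of
#' samples. Low-prevalence features destabilise multinomial fits, so the
#' pipeline applies this filter before differential ranking (default 0.1).
#'
#' @param table A [feature_table()].
#' @param min_fraction Minimum fraction of nonzero samples, in \[0, 1\].
#' @return A filtered `feature_table`; the sample set is unchanged.
#' @export
filter_by_prevalence <- function(table, min_fraction = 0.1) {
  stopifnot(inherits(table, "feature_table"))
  if (min_fraction < 0 || min_fraction > 1) stop("`min_fraction` must be in [0, 1]")
  prev <- compute_prevalence(table)
  keep <- prev$feature_id[prev$fraction_nonzero >= min_fraction]
  if (length(keep) == 0) {
    stop("prevalence filter removed every feature; lower `min_fraction`")
  }
  subset_feature_table(table, features = keep)
}

#' Convert a table to model-scale counts
#'
#' The multinomial likelihood needs totals on a count scale. A table whose
#' columns each sum to 1 (within 1e-6) is treated as relative abundances and
#' rescaled to `pseudo_depth`; count tables pass through unchanged.
#'
#' @param table A [feature_table()].
#' @param pseudo_depth Total assigned to each relative-abundance column.
#' @return A `feature_table` on the count scale.
#' @export
as_model_counts <- function(table, pseudo_depth = 10000) {
  stopifnot(inherits(table, "feature_table"))
  cs <- colSums(table$values)
  if (all(abs(cs - 1) <= 1e-6)) {
    v <- table$values * pseudo_depth
    return(feature_table(v, table$feature_kind, table$annotations))
  }
  table
}
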