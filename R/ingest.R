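#' Read a wide protein abundance table
#'
#' Parses a Spectronaut-style wide export: one row per protein group, an
#' accession column, optional symbol/description columns, and one numeric
#' column per sample. Cells that are empty, non-numeric, the literal
#' `"NaN"`/`"Filtered"`, or exactly zero are treated as missing — a DIA
#' intensity of zero encodes non-detection, not a measured abundance.
#'
#' @param path Path to a TSV/CSV file.
#' @param id_col Name of the accession column.
#' @param symbol_col,description_col Optional metadata column names.
#' @param sample_cols Character vector of sample column names; defaults to
#'   every column that is not an id/metadata column.
#' @param sep Field separator (tab by default).
#'
#' @return An [abundance_matrix()] with `scale = "raw"`.
#' @export
read_abundance_table <- function(path, id_col = "accession",
                                 symbol_col = "symbol",
                                 description_col = "description",
                                 sample_cols = NULL, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (!id_col %in% names(df)) stop("missing id column: ", id_col)
  ids <- df[[id_col]]
  if (anyDuplicated(ids)) stop("duplicate protein ids in ", path)
  meta <- intersect(c(id_col, symbol_col, description_col), names(df))
  if (is.null(sample_cols)) sample_cols <- setdiff(names(df), meta)
  if (length(sample_cols) == 0) stop("no sample columns found")
  vals <- suppressWarnings(
    vapply(df[sample_cols], function(col) {
      col[col %in% c("", "NaN", "NA", "Filtered")] <- NA
      as.numeric(col)
    }, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, sample_cols))
  vals[!is.na(vals) & vals == 0] <- NA
  abundance_matrix(vals,
                   symbols = if (symbol_col %in% names(df))
                     df[[symbol_col]] else NULL,
                   descriptions = if (description_col %in% names(df))
                     df[[description_col]] else NULL,
                   scale = "raw")
}

#' Write an abundance matrix as a wide TSV
#'
#' Inverse of [read_abundance_table()]; values are written with full
#' precision so that a write/read round trip is lossless.
#'
#' @param x An `AbundanceMatrix`.
#' @param path Output path.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  df <- data.frame(accession = protein_ids(x),
                   symbol = unname(x$symbols),
                   description = unname(x$descriptions),
                   check.names = FALSE, stringsAsFactors = FALSE)
  vals <- format(x$values, digits = 17, trim = TRUE, scientific = TRUE)
  vals[is.na(x$values)] <- ""
  df <- cbind(df, as.data.frame(vals, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter proteins by within-group presence
#'
#' Retains a protein when, for at least one sample group, the fraction of
#' non-missing values within that group reaches `threshold`. This is the
#' standard DIA protein-group filter: a protein quantified consistently in a
#' single histotype is kept even if undetected everywhere else. Row order is
#' preserved and the operation is idempotent.
#'
#' Proteins sitting exactly on the threshold in their best group are
#' reported via a message, since "at least 70%" and "over 70%" differ only
#' for these boundary rows; the inclusive rule is applied.
#'
#' @param x An `AbundanceMatrix`.
#' @param annotation Sample annotation data frame with `sample_id` and
#'   `group` columns covering every sample of `x`.
#' @param threshold Presence fraction in (0, 1]; default 0.70.
#'
#' @return Filtered `AbundanceMatrix`.
#' @export
filter_by_group_presence <- function(x, annotation, threshold = 0.70) {
  stopifnot(inherits(x, "AbundanceMatrix"),
            threshold > 0, threshold <= 1)
  groups <- group_lookup(annotation, sample_ids(x))
  best <- best_group_presence(x, groups)
  keep <- best >= threshold
  at_boundary <- keep & abs(best - threshold) < 1e-12
  if (any(at_boundary)) {
    message(sum(at_boundary),
            " protein(s) retained exactly at the presence threshold")
  }
  subset_abundance(x, proteins = protein_ids(x)[keep])
}

# Best per-group non-missing fraction for every protein.
best_group_presence <- function(x, groups) {
  obs <- !is.na(x$values)
  fractions <- vapply(split(seq_along(groups), groups), function(idx) {
    rowMeans(obs[, idx, drop = FALSE])
  }, numeric(nrow(x$values)))
  fractions <- matrix(fractions, nrow = nrow(x$values))
  apply(fractions, 1, max)
}

group_lookup <- function(annotation, samples) {
  stopifnot(all(c("sample_id", "group") %in% names(annotation)))
  idx <- match(samples, annotation$sample_id)
  if (anyNA(idx)) stop("samples missing from annotation: ",
                       paste(samples[is.na(idx)], collapse = ", "))
  g <- as.character(annotation$group[idx])
  if (any(table(g) == 0)) stop("empty group")
  g
}

#' Log2-transform raw intensities
#'
#' @param x An `AbundanceMatrix` on the raw scale; all present values must
#'   be strictly positive. Applying the transform twice is an error.
#' @return The matrix with `scale = "log2"`; missingness is unchanged.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  if (x$scale != "raw") stop("matrix is already log2-transformed")
  v <- x$values
  if (any(v[!is.na(v)] <= 0)) stop("non-positive intensity present")
  abundance_matrix(log2(v), symbols = x$symbols,
                   descriptions = x$descriptions, scale = "log2")
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: each line holds a set name, a description,
#' then the member symbols. Duplicate members within a set are removed.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (class `GeneSetCollection`);
#'   descriptions are kept in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields: line ",
                     paste(which(bad), collapse = ", "))
  names_ <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(names_)) stop("duplicate set names in GMT")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (any(lengths(sets) == 0)) stop("empty gene set in GMT")
  names(sets) <- names_
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, "", 2), names_)
  class(sets) <- "GeneSetCollection"
  sets
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions; defaults to `"na"`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
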