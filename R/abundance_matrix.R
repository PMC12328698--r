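#' Construct a protein abundance matrix
#'
#' Wide proteins-by-samples intensity grid with explicit missingness, the
#' central data container of the package. Raw MS2 intensities must be
#' strictly positive where present; missing cells are `NA`. The object keeps
#' track of whether values are on the raw or the log2 scale so that
#' transformations cannot be applied twice.
#'
#' @param values Numeric matrix, proteins in rows, samples in columns.
#'   Dimnames are taken as protein and sample identifiers when
#'   `protein_ids`/`sample_ids` are not given.
#' @param protein_ids Character vector of unique protein accessions.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param symbols Optional character vector of gene symbols parallel to
#'   `protein_ids`. Defaults to the accessions themselves.
#' @param descriptions Optional character vector of protein descriptions.
#' @param scale Either `"raw"` or `"log2"`.
#'
#' @return An object of class `AbundanceMatrix`: a list with elements
#'   `values`, `symbols`, `descriptions` and `scale`.
#' @export
abundance_matrix <- function(values,
                             protein_ids = rownames(values),
                             sample_ids = colnames(values),
                             symbols = NULL,
                             descriptions = NULL,
                             scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(protein_ids) || is.null(sample_ids)) {
    stop("protein and sample identifiers are required")
  }
  protein_ids <- as.character(protein_ids)
  sample_ids <- as.character(sample_ids)
  if (length(protein_ids) != nrow(values) ||
      length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(protein_ids)) stop("duplicate protein ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  present <- values[!is.na(values)]
  if (scale == "raw" && any(present <= 0)) {
    stop("raw intensities must be strictly positive where present")
  }
  dimnames(values) <- list(protein_ids, sample_ids)
  if (is.null(symbols)) symbols <- protein_ids
  if (is.null(descriptions)) descriptions <- rep(NA_character_,
                                                 length(protein_ids))
  stopifnot(length(symbols) == length(protein_ids),
            length(descriptions) == length(protein_ids))
  structure(
    list(values = values,
         symbols = stats::setNames(as.character(symbols), protein_ids),
         descriptions = stats::setNames(as.character(descriptions),
                                        protein_ids),
         scale = scale),
    class = "AbundanceMatrix"
  )
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("AbundanceMatrix: %d proteins x %d samples (%s scale)\n",
              nrow(v), ncol(v), x$scale))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(v)),
              100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)

protein_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Subset an abundance matrix by proteins and/or samples
#'
#' Metadata and the requested order are preserved.
#'
#' @param x An `AbundanceMatrix`.
#' @param proteins,samples Identifier vectors; `NULL` keeps all.
#' @return The subsetted `AbundanceMatrix`.
#' @export
subset_abundance <- function(x, proteins = NULL, samples = NULL) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  p <- if (is.null(proteins)) protein_ids(x) else proteins
  s <- if (is.null(samples)) sample_ids(x) else samples
  if (!all(p %in% protein_ids(x))) stop("unknown protein id in subset")
  if (!all(s %in% sample_ids(x))) stop("unknown sample id in subset")
  abundance_matrix(x$values[p, s, drop = FALSE],
                   protein_ids = p, sample_ids = s,
                   symbols = x$symbols[p],
                   descriptions = x$descriptions[p],
                   scale = x$scale)
}
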