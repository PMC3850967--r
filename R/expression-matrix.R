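#' Expression matrix container
#'
#' A light container for a probes-by-samples expression matrix together with
#' the bookkeeping the downstream signature machinery needs: the measurement
#' scale (linear intensities versus log2), whether columns have been quantile
#' normalized, and per-sample annotations (class labels, batch, subtype,
#' replicate group, GAPDH 3'/5' control intensities).
#'
#' @param values numeric matrix, probes in rows, samples in columns; both
#'   dimnames must be present and free of duplicates.
#' @param scale measurement scale of `values`: `"linear"` (e.g. MAS5-style
#'   intensities) or `"log2"`.
#' @param annotations optional data.frame of per-sample annotations; row names
#'   (or a `sample_id` column) must match the column names of `values`.
#'   Recognised columns used elsewhere: `class` (0/1 training label), `batch`,
#'   `subtype`, `replicate`, `gapdh3`, `gapdh5`.
#' @param quantile_normalized logical flag carried on the object.
#'
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, scale = c("linear", "log2"),
                              annotations = NULL, quantile_normalized = FALSE) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("'values' must have probe row names and sample column names")
  if (anyDuplicated(rownames(values)))
    .stopf("duplicated probe ids: %s",
           paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    .stopf("duplicated sample ids: %s",
           paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) .stopf("missing values are not allowed in an expression matrix")
  if (scale == "log2" && any(!is.finite(values)))
    .stopf("log2-scale values must all be finite")
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if ("sample_id" %in% names(annotations) && !identical(rownames(annotations), colnames(values)))
      rownames(annotations) <- annotations$sample_id
    if (!setequal(rownames(annotations), colnames(values)))
      .stopf("annotation row names do not match sample ids")
    annotations <- annotations[colnames(values), , drop = FALSE]
  }
  structure(list(values = values, scale = scale,
                 quantile_normalized = isTRUE(quantile_normalized),
                 annotations = annotations),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples (%s scale%s)\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (x$quantile_normalized) ", quantile normalized" else ""))
  if (!is.null(x$annotations))
    cat("annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

# internal: pull an annotation column or fail informatively
.get_annotation <- function(m, key) {
  if (is.null(m$annotations) || !key %in% names(m$annotations))
    .stopf("sample annotation '%s' is required but absent", key)
  m$annotations[[key]]
}

# internal: subset samples, keeping annotations aligned
.subset_samples <- function(m, keep) {
  m$values <- m$values[, keep, drop = FALSE]
  if (!is.null(m$annotations)) m$annotations <- m$annotations[keep, , drop = FALSE]
  m
}

#' Read an expression table
#'
#' Reads a tab-delimited expression table into an [expression_matrix()].
#' The plain dialect expects a header row of sample ids and a first column of
#' probe ids. The GCT-like dialect additionally allows two leading metadata
#' lines (version and dimensions) and a `Description` column after the probe
#' ids, both of which are skipped.
#'
#' @param path path to a tab-delimited file.
#' @param dialect `"tsv"` (plain) or `"gct"` (GCT-compatible).
#' @param scale declared measurement scale of the stored values.
#' @param annotations optional per-sample annotation data.frame, passed on.
#' @return An `expr_matrix`.
#' @export
read_expression_table <- function(path, dialect = c("tsv", "gct"),
                                  scale = c("linear", "log2"), annotations = NULL) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  skip <- if (dialect == "gct") 2L else 0L
  tab <- read.delim(path, header = TRUE, sep = "\t", skip = skip,
                    check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) .stopf("malformed header in %s: need probe id column plus samples", path)
  ids <- tab[[1]]
  tab <- tab[, -1, drop = FALSE]
  if (dialect == "gct" && tolower(names(tab)[1]) == "description")
    tab <- tab[, -1, drop = FALSE]
  if (anyDuplicated(ids))
    .stopf("duplicated probe id(s) in %s: %s", path,
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(tab), ncol(tab), dimnames = list(ids, names(tab)))
  for (j in seq_len(ncol(tab))) {
    col <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(is.na(col))
    if (length(bad))
      .stopf("non-numeric or missing cell at probe '%s', sample '%s'",
             ids[bad[1]], names(tab)[j])
    vals[, j] <- col
  }
  expression_matrix(vals, scale = scale, annotations = annotations)
}

#' Write an expression table
#'
#' Writes the values of an `expr_matrix` (or a plain matrix) as a tab-delimited
#' table with a `probe_id` first column, using a shortest-round-trip numeric
#' representation so that reading the file back reproduces the values exactly.
#'
#' @param m an `expr_matrix` or numeric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path) {
  vals <- if (inherits(m, "expr_matrix")) m$values else m
  txt <- matrix(sprintf("%.17g", vals), nrow(vals), dimnames = dimnames(vals))
  out <- cbind(probe_id = rownames(vals), txt)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
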