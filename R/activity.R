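#' Rescale activation probabilities within a dataset
#'
#' Log-transforms raw activation probabilities and linearly maps them onto
#' `[0, 1]` within the dataset: `score = (log p - min log p) / (max - min)`.
#' The log base is immaterial (any base yields identical scores); natural log
#' is used. If all probabilities are equal the rescaling is degenerate and all
#' scores are set to 0.5, flagged via the `degenerate` attribute.
#'
#' @param raw numeric vector of probabilities, all strictly inside (0, 1).
#' @return Numeric vector of rescaled scores in `[0, 1]` (min maps to 0, max
#'   to 1), same names as `raw`.
#' @export
rescale_activity <- function(raw) {
  if (length(raw) < 1) .stopf("need at least one probability")
  if (any(!is.finite(raw)) || any(raw <= 0) || any(raw >= 1))
    .stopf("raw probabilities must lie strictly inside (0, 1)")
  y <- log(raw)
  rng <- range(y)
  if (rng[1] == rng[2]) {
    out <- rep(0.5, length(raw))
    names(out) <- names(raw)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (y - rng[1]) / (rng[2] - rng[1])
}

#' Activity table: samples by pathways
#'
#' Bundles raw activation probabilities with their within-dataset rescaled
#' `[0, 1]` scores. Rescaling is always derived from the current raw matrix,
#' so operations that change the raw values (such as replicate averaging)
#' produce scores consistent with the fixed pipeline order: predict, then
#' average replicates, then rescale.
#'
#' @param raw numeric matrix of raw probabilities, samples in rows, pathways
#'   in columns, values strictly inside (0, 1); dimnames required.
#' @param dataset_id provenance tag carried on the object.
#' @return Object of class `activity_table` with elements `raw`, `rescaled`,
#'   `sample_ids`, `pathways`, `dataset_id`.
#' @export
activity_table <- function(raw, dataset_id = "") {
  if (!is.matrix(raw) || !is.numeric(raw)) .stopf("'raw' must be a numeric matrix")
  if (is.null(rownames(raw)) || is.null(colnames(raw)))
    .stopf("'raw' needs sample row names and pathway column names")
  rescaled <- apply(raw, 2, rescale_activity)
  rescaled <- matrix(rescaled, nrow(raw), dimnames = dimnames(raw))
  structure(list(raw = raw, rescaled = rescaled,
                 sample_ids = rownames(raw), pathways = colnames(raw),
                 dataset_id = dataset_id),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("activity_table: %d samples x %d pathways%s\n",
              nrow(x$raw), ncol(x$raw),
              if (nzchar(x$dataset_id)) paste0(" [", x$dataset_id, "]") else ""))
  cat("pathways:", paste(x$pathways, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.activity_table <- function(x) dim(x$raw)

#' Predict activities for several signatures at once
#'
#' Applies a list of trained signatures to one target dataset and assembles
#' the resulting raw probabilities into an [activity_table()] (one column per
#' pathway). Replicate averaging, if required, should be applied to the
#' returned table before using the rescaled scores.
#'
#' @param models named list of `pathway_signature` fits.
#' @param m target `expr_matrix`.
#' @param dataset_id provenance tag for the table.
#' @param ... passed to [predict.pathway_signature()].
#' @return An `activity_table`.
#' @export
predict_activity <- function(models, m, dataset_id = "", ...) {
  stopifnot(is.list(models), length(models) >= 1)
  if (is.null(names(models)))
    names(models) <- vapply(models, function(f) f$pathway, character(1))
  raw <- vapply(models, function(f) as.numeric(predict(f, m, ...)),
                numeric(ncol(m$values)))
  raw <- matrix(raw, ncol(m$values),
                dimnames = list(colnames(m$values), names(models)))
  activity_table(raw, dataset_id = dataset_id)
}

#' Write an activity table to TSV
#'
#' @param a an `activity_table`.
#' @param path output path; raw and rescaled scores are written side by side
#'   (`<pathway>.raw`, `<pathway>.score` columns).
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(a, path) {
  stopifnot(inherits(a, "activity_table"))
  out <- data.frame(sample_id = a$sample_ids, check.names = FALSE)
  for (p in a$pathways) {
    out[[paste0(p, ".raw")]] <- sprintf("%.17g", a$raw[, p])
    out[[paste0(p, ".score")]] <- sprintf("%.17g", a$rescaled[, p])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
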