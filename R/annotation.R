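#' Parcel-by-feature annotation matrices
#'
#' The predictor side of the latent-component analyses: a real matrix
#' with one row per parcel of a parcellation and one column per feature —
#' gene symbols (regional microarray expression) or cognitive terms
#' (meta-analytic activation likelihood). Columns are standardized inside
#' the model fit, not here.
#'
#' @param parcellation a [spherical_parcellation()] whose parcels index
#'   the rows.
#' @param values numeric matrix, parcels x features. Row names, if
#'   present, must match the parcellation's parcel_ids.
#' @param feature_id character vector of column labels (defaults to
#'   existing column names).
#' @param source tag describing the feature family, `"gene"` or `"term"`.
#' @return object of class `annotation_matrix`: fields `values`,
#'   `parcellation`, `feature_id`, `source`.
#' @export
annotation_matrix <- function(parcellation, values,
                              feature_id = colnames(values),
                              source = c("gene", "term")) {
  stopifnot(inherits(parcellation, "spherical_parcellation"))
  source <- match.arg(source)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != n_parcels(parcellation)) {
    stop("row count (", nrow(values), ") != parcel count (",
         n_parcels(parcellation), ")")
  }
  if (!is.null(rownames(values)) &&
      !identical(rownames(values), parcellation$parcel_id)) {
    stop("row names do not match the parcellation's parcel_ids")
  }
  if (is.null(feature_id)) feature_id <- paste0("f", seq_len(ncol(values)))
  if (anyDuplicated(feature_id)) stop("duplicate feature_id")
  dimnames(values) <- list(parcellation$parcel_id, feature_id)
  structure(list(values = values, parcellation = parcellation,
                 feature_id = as.character(feature_id), source = source),
            class = "annotation_matrix")
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat("annotation_matrix (", x$source, "): ", nrow(x$values), " parcels x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

#' Read / write an annotation TSV
#'
#' First column `parcel_id`, remaining columns features. Left-only (31
#' parcels) and reduced region sets are supported: rows must simply match
#' the supplied parcellation.
#'
#' @inheritParams annotation_matrix
#' @param path file path.
#' @return an `annotation_matrix`.
#' @export
read_annotation_matrix <- function(parcellation, path,
                                   source = c("gene", "term")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1L] != "parcel_id") stop("first column must be parcel_id")
  if (!identical(tab$parcel_id, parcellation$parcel_id)) {
    stop("parcel_id rows do not match the parcellation")
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$parcel_id
  annotation_matrix(parcellation, m, source = match.arg(source))
}

#' @rdname read_annotation_matrix
#' @param x an `annotation_matrix` to write.
#' @export
write_annotation_matrix <- function(x, path) {
  write_tsv(data.frame(parcel_id = rownames(x$values), x$values,
                       check.names = FALSE), path)
}
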