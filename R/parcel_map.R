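#' Parcel-wise map
#'
#' One real value per parcel of a [spherical_parcellation()] — a t-map,
#' a receptor density map, a gene-score map. Missing parcels are carried
#' as NA and masked, never imputed.
#'
#' @param parcellation a `spherical_parcellation`.
#' @param value numeric vector, one value per parcel (NA = missing). If
#'   named, names must match `parcellation$parcel_id` and are used to
#'   align.
#' @return object of class `parcel_map` with fields `parcellation`,
#'   `value` (named numeric) and `missing` (logical mask).
#' @export
parcel_map <- function(parcellation, value) {
  stopifnot(inherits(parcellation, "spherical_parcellation"))
  ids <- parcellation$parcel_id
  if (!is.null(names(value))) {
    if (!setequal(names(value), ids)) {
      stop("named value vector does not match the parcellation's parcel_ids")
    }
    value <- value[ids]
  }
  value <- as.numeric(value)
  if (length(value) != length(ids)) {
    stop("value length (", length(value), ") != parcel count (",
         length(ids), ")")
  }
  names(value) <- ids
  structure(list(parcellation = parcellation, value = value,
                 missing = is.na(value)),
            class = "parcel_map")
}

#' @export
print.parcel_map <- function(x, ...) {
  cat("parcel_map:", length(x$value), "parcels,",
      sum(x$missing), "missing\n")
  print(utils::head(x$value, 5L))
  invisible(x)
}

same_parcellation <- function(a, b) {
  identical(a$parcellation$parcel_id, b$parcellation$parcel_id)
}

#' Read / write parcel-map TSV
#'
#' The canonical on-disk form is a two-column tab-separated table
#' `parcel_id  value` with a header row.
#'
#' @param parcellation parcellation the values belong to.
#' @param path file path.
#' @return `read_parcel_map` returns a `parcel_map`; `write_parcel_map`
#'   returns the path invisibly.
#' @export
read_parcel_map <- function(parcellation, path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("parcel_id", "value") %in% names(tab))) {
    stop("parcel-map table needs columns parcel_id, value")
  }
  v <- stats::setNames(rep(NA_real_, n_parcels(parcellation)),
                       parcellation$parcel_id)
  known <- intersect(tab$parcel_id, names(v))
  v[known] <- tab$value[match(known, tab$parcel_id)]
  parcel_map(parcellation, v)
}

#' @rdname read_parcel_map
#' @param map a `parcel_map` to write.
#' @export
write_parcel_map <- function(map, path) {
  write_tsv(data.frame(parcel_id = names(map$value), value = map$value),
            path)
}

#' Read a battery of maps from a wide TSV
#'
#' First column `parcel_id`, one further column per map.
#'
#' @inheritParams read_parcel_map
#' @return named list of `parcel_map`s.
#' @export
read_map_battery <- function(parcellation, path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (names(tab)[1L] != "parcel_id") stop("first column must be parcel_id")
  maps <- lapply(names(tab)[-1L], function(nm) {
    v <- stats::setNames(tab[[nm]], tab$parcel_id)
    parcel_map(parcellation, v)
  })
  stats::setNames(maps, names(tab)[-1L])
}
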