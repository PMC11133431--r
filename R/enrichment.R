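#' Gene-set overrepresentation analysis
#'
#' Hypergeometric (one-sided, enrichment) test of whether a feature list
#' — for example the genes a PLS component flags at |BR| > 3 — overlaps
#' each named gene set more than expected given a reference universe
#' (all genes considered in the analysis). P-values are
#' Benjamini-Hochberg adjusted across the tested sets; positive and
#' negative feature lists are analysed in separate runs.
#'
#' @name enrichment
NULL

#' Read a GMT gene-set file
#'
#' One set per line: set name, description, then tab-separated members.
#' Duplicate members within a set are counted once.
#'
#' @param path GMT file path.
#' @return object of class `gene_set_collection`: `sets` is a named list
#'   of unique member vectors; `source` records the path.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, ": expected name, description and ",
           "at least one member")
    }
    nms[i] <- fields[1L]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(nms)) {
    stop("duplicate set names: ", paste(unique(nms[duplicated(nms)]),
                                        collapse = ", "))
  }
  structure(list(sets = stats::setNames(sets, nms), source = path),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets from", x$source, "\n")
  invisible(x)
}

#' Hypergeometric overrepresentation test
#'
#' For each set, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap when `length(interest)` features are drawn
#' from the universe without replacement. Sets are intersected with the
#' universe first; empty-after-intersection sets and sets outside the
#' size filters are dropped with a notice. Interest features outside the
#' universe are dropped with a notice.
#'
#' @param interest character vector of features of interest (e.g. the
#'   positive BR-selected genes).
#' @param collection a [read_gmt()] collection (or a named list of
#'   sets).
#' @param universe character vector: the reference feature list.
#' @param min_size,max_size set-size filters applied after intersection
#'   with the universe (defaults 5 and 2000).
#' @return data.frame of class `ora_result` with columns `set_name`,
#'   `overlap`, `set_size`, `hits`, `universe`, `expected`, `ratio`,
#'   `p`, `q`, sorted by q then p.
#' @export
overrepresentation_test <- function(interest, collection, universe,
                                    min_size = 5L, max_size = 2000L) {
  sets <- if (inherits(collection, "gene_set_collection")) {
    collection$sets
  } else as.list(collection)
  if (length(interest) == 0L) stop("empty interest list")
  universe <- unique(as.character(universe))
  N <- length(universe)
  outside <- setdiff(interest, universe)
  if (length(outside)) {
    message("dropping ", length(outside),
            " interest features outside the universe")
  }
  interest <- unique(intersect(interest, universe))
  if (length(interest) == 0L) stop("no interest features inside the universe")
  if (N < length(interest)) stop("universe smaller than the interest list")
  sets_u <- lapply(sets, intersect, universe)
  sizes <- lengths(sets_u)
  drop_empty <- sizes == 0L
  if (any(drop_empty)) {
    message("dropping sets empty after intersection with the universe: ",
            paste(names(sets_u)[drop_empty], collapse = ", "))
  }
  keep <- !drop_empty & sizes >= min_size & sizes <= max_size
  if (any(!keep & !drop_empty)) {
    message("dropping ", sum(!keep & !drop_empty),
            " sets outside size filters [", min_size, ", ", max_size, "]")
  }
  sets_u <- sets_u[keep]
  if (length(sets_u) == 0L) stop("no sets left to test")
  k <- length(interest)
  res <- lapply(names(sets_u), function(nm) {
    m <- length(sets_u[[nm]])
    ov <- length(intersect(interest, sets_u[[nm]]))
    data.frame(set_name = nm, overlap = ov, set_size = m, hits = k,
               universe = N, expected = k * m / N,
               ratio = if (m > 0) (ov / k) / (m / N) else NA_real_,
               p = stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE))
  })
  res <- do.call(rbind, res)
  res$q <- bh_fdr(res$p)
  res <- res[order(res$q, res$p), ]
  rownames(res) <- NULL
  class(res) <- c("ora_result", "data.frame")
  res
}

#' Top of an overrepresentation table
#'
#' Convenience view of the `n` most significantly associated sets
#' (default 10, the reporting depth used for pathway summaries).
#'
#' @param res an `ora_result`.
#' @param n number of rows.
#' @return the first `n` rows.
#' @export
ora_top <- function(res, n = 10L) {
  utils::head(res, n)
}
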