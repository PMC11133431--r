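#' Spherical parcellation objects
#'
#' A `spherical_parcellation` holds parcel identities, hemisphere labels and
#' unit-sphere centroid directions for a cortical parcellation (for example
#' the 62-parcel Desikan-Killiany-Tourville scheme, 31 parcels per
#' hemisphere). It is the geometric substrate on which spin permutations are
#' generated: rotating centroid directions on the sphere and reassigning
#' each parcel to its nearest rotated neighbour yields spatially constrained
#' null permutations of any parcel-wise map.
#'
#' @param parcel_id character vector of unique parcel labels
#'   (DKT-style, e.g. `"lh.superiorfrontal"`).
#' @param hemisphere character vector, one of `"left"`/`"right"` per parcel
#'   (also accepts `lh`/`rh`/`l`/`r`, case-insensitively).
#' @param centroids numeric matrix, one row per parcel, columns x, y, z.
#'   Rows are normalized to unit length; the x axis is the left-right axis
#'   (sagittal plane x = 0).
#' @return An object of class `spherical_parcellation` with fields
#'   `parcel_id`, `hemisphere` (factor with levels left/right) and
#'   `centroids` (n x 3 unit-row matrix).
#' @export
spherical_parcellation <- function(parcel_id, hemisphere, centroids) {
  parcel_id <- as.character(parcel_id)
  n <- length(parcel_id)
  if (n < 2L) stop("a parcellation needs at least 2 parcels")
  dup <- unique(parcel_id[duplicated(parcel_id)])
  if (length(dup)) {
    stop("duplicate parcel_id: ", paste(dup, collapse = ", "))
  }
  hemisphere <- parse_hemisphere(hemisphere)
  centroids <- as.matrix(centroids)
  storage.mode(centroids) <- "double"
  if (nrow(centroids) != n || ncol(centroids) != 3L) {
    stop("centroids must be an n x 3 matrix matching parcel_id")
  }
  nrm <- sqrt(rowSums(centroids^2))
  if (any(nrm < 1e-12)) {
    stop("zero-length centroid vector for parcel: ",
         paste(parcel_id[nrm < 1e-12], collapse = ", "))
  }
  centroids <- centroids / nrm
  dimnames(centroids) <- list(parcel_id, c("x", "y", "z"))
  structure(
    list(parcel_id = parcel_id, hemisphere = hemisphere,
         centroids = centroids),
    class = "spherical_parcellation")
}

parse_hemisphere <- function(h) {
  h <- tolower(as.character(h))
  out <- rep(NA_character_, length(h))
  out[h %in% c("left", "lh", "l")] <- "left"
  out[h %in% c("right", "rh", "r")] <- "right"
  if (anyNA(out)) {
    stop("unknown hemisphere label: ",
         paste(unique(h[is.na(out)]), collapse = ", "))
  }
  factor(out, levels = c("left", "right"))
}

#' @export
print.spherical_parcellation <- function(x, ...) {
  tab <- table(x$hemisphere)
  cat("spherical_parcellation:", length(x$parcel_id), "parcels (",
      tab[["left"]], "left /", tab[["right"]], "right )\n")
  invisible(x)
}

n_parcels <- function(parcellation) length(parcellation$parcel_id)

#' Load a parcellation from a centroid table
#'
#' Reads a tab-separated table with header columns `parcel_id`,
#' `hemisphere`, `x`, `y`, `z` and returns a [spherical_parcellation()].
#' Centroid vectors are normalized to unit length; parcels keep file order.
#'
#' @param path path to the centroid TSV.
#' @return a `spherical_parcellation`.
#' @examples
#' tsv <- system.file("extdata", "dkt62_centroids_synthetic.tsv",
#'                    package = "spinpls")
#' parc <- load_parcellation(tsv)
#' @export
load_parcellation <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("parcel_id", "hemisphere", "x", "y", "z")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("centroid table lacks columns: ",
                         paste(miss, collapse = ", "))
  spherical_parcellation(tab$parcel_id, tab$hemisphere,
                         cbind(tab$x, tab$y, tab$z))
}

#' Sample uniform random rotations
#'
#' Draws proper rotation matrices uniformly over SO(3) by orthonormalizing
#' a matrix of independent standard-normal draws (QR with sign correction)
#' and flipping one column when the determinant is negative. The draw is a
#' pure function of `seed`.
#'
#' @param n_perm number of rotations (>= 1).
#' @param seed integer RNG seed; mandatory so ensembles are reproducible.
#' @return object of class `rotation_set`: fields `n_perm`, `seed` and
#'   `rotations`, a 3 x 3 x n_perm array of proper rotation matrices.
#' @export
sample_rotations <- function(n_perm, seed) {
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1")
  rot <- array(0, dim = c(3L, 3L, n_perm))
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      qr_m <- qr(matrix(stats::rnorm(9L), 3L, 3L))
      Q <- qr.Q(qr_m) %*% diag(sign(diag(qr.R(qr_m))))
      if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
      rot[, , i] <- Q
    }
  })
  structure(list(n_perm = n_perm, rotations = rot, seed = seed),
            class = "rotation_set")
}

#' Build a spin-permutation null ensemble
#'
#' For each rotation, each hemisphere's centroids are rotated (the right
#' hemisphere receives the sagittally mirrored rotation, so contralateral
#' structure is preserved) and every target parcel is assigned the source
#' parcel whose rotated centroid lies nearest by great-circle distance.
#' Assignments never cross hemispheres; a source parcel may serve several
#' targets (nearest-neighbour reassignment, not a bijection). Exact
#' distance ties resolve to the lowest source index.
#'
#' @param parcellation a [spherical_parcellation()].
#' @param rotations a [sample_rotations()] result.
#' @return object of class `spin_ensemble`: `assignment` is an
#'   n_perm x n_parcels integer matrix mapping each target parcel index to
#'   a source parcel index.
#' @export
build_spin_ensemble <- function(parcellation, rotations) {
  stopifnot(inherits(parcellation, "spherical_parcellation"),
            inherits(rotations, "rotation_set"))
  hemi <- parcellation$hemisphere
  if (any(table(hemi)[unique(as.character(hemi))] < 1L)) {
    stop("each represented hemisphere needs at least 1 parcel")
  }
  C <- parcellation$centroids
  n <- nrow(C)
  n_perm <- rotations$n_perm
  mirror <- diag(c(-1, 1, 1))
  assignment <- matrix(0L, n_perm, n,
                       dimnames = list(NULL, parcellation$parcel_id))
  idx_by_hemi <- split(seq_len(n), hemi, drop = TRUE)
  for (i in seq_len(n_perm)) {
    R <- rotations$rotations[, , i]
    for (h in names(idx_by_hemi)) {
      idx <- idx_by_hemi[[h]]
      Rh <- if (h == "left") R else mirror %*% R %*% mirror
      rotated <- C[idx, , drop = FALSE] %*% t(Rh)   # rotated source centroids
      # cosine of great-circle distance target x source; nearest = max,
      # which.max takes the first (lowest-index) maximum on ties
      cosine <- C[idx, , drop = FALSE] %*% t(rotated)
      assignment[i, idx] <- idx[max.col(cosine, ties.method = "first")]
    }
  }
  structure(list(n_perm = n_perm, assignment = assignment,
                 parcellation = parcellation, seed = rotations$seed),
            class = "spin_ensemble")
}

#' Convenience: rotations + ensemble in one call
#'
#' @inheritParams build_spin_ensemble
#' @inheritParams sample_rotations
#' @return a `spin_ensemble`.
#' @export
spin_ensemble <- function(parcellation, n_perm, seed) {
  build_spin_ensemble(parcellation, sample_rotations(n_perm, seed))
}

#' Permute a parcel map through one ensemble member
#'
#' @param map a [parcel_map()] (or bare numeric vector).
#' @param ensemble a `spin_ensemble` on the map's parcellation.
#' @param i permutation index in `1:n_perm`.
#' @return numeric vector of permuted values (NA where the assigned source
#'   parcel is missing).
#' @export
permute_map <- function(map, ensemble, i) {
  v <- if (inherits(map, "parcel_map")) map$value else as.numeric(map)
  if (length(v) != ncol(ensemble$assignment)) {
    stop("map length does not match ensemble parcellation")
  }
  unname(v[ensemble$assignment[i, ]])
}
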