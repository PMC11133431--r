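#' Spatial correspondence of parcel maps with spin-test inference
#'
#' Pearson correlation between parcel-wise maps, with significance from a
#' spatially constrained spin permutation null: one map is permuted
#' through a [build_spin_ensemble()] member, the correlation recomputed,
#' and the observed coefficient compared to the null distribution of
#' permuted coefficients. Spatial autocorrelation — nearby parcels having
#' similar values — inflates naive permutation tests; the spin null keeps
#' it intact and so restores calibration.
#'
#' @name spatial_correspondence
NULL

map_values <- function(map) {
  if (inherits(map, "parcel_map")) map$value else as.numeric(map)
}

#' Pearson correlation of two parcel maps
#'
#' Computed over jointly non-missing parcels; requires at least 3 of them
#' and nonzero variance in both maps.
#'
#' @param map_a,map_b parcel maps (or bare numeric vectors of equal
#'   length).
#' @return Pearson r.
#' @export
pearson_corr <- function(map_a, map_b) {
  a <- map_values(map_a); b <- map_values(map_b)
  if (inherits(map_a, "parcel_map") && inherits(map_b, "parcel_map") &&
      !same_parcellation(map_a, map_b)) {
    stop("maps are on different parcellations")
  }
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("fewer than 3 jointly non-missing parcels")
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in one of the maps")
  }
  stats::cor(a, b)
}

# Correlations of each row of the permuted-value matrix A (n_perm x n)
# with the fixed vector b, over jointly non-missing entries.
null_correlations <- function(A, b) {
  if (!anyNA(A) && !anyNA(b)) {
    Ac <- A - rowMeans(A)
    bc <- b - mean(b)
    num <- Ac %*% bc
    den <- sqrt(rowSums(Ac^2) * sum(bc^2))
    return(as.numeric(num / den))
  }
  apply(A, 1L, function(row) {
    ok <- !is.na(row) & !is.na(b)
    if (sum(ok) < 3L) return(NA_real_)
    suppressWarnings(stats::cor(row[ok], b[ok]))
  })
}

#' Spin-test p-value for a map pair
#'
#' `map_a` is permuted through every ensemble assignment and the Pearson
#' correlation against the fixed `map_b` recomputed, giving the null
#' distribution. The empirical two-sided p-value is
#' `(1 + #\{|r_null| >= |r_obs|\}) / (n_perm + 1)`, so p is never 0 and
#' never below `1/(n_perm + 1)`.
#'
#' @param map_a the map that is spun (by convention the phenotype map).
#' @param map_b the fixed annotation map.
#' @param ensemble a `spin_ensemble` on the maps' parcellation.
#' @param return_null if TRUE, attach the null correlations as attribute
#'   `"null"`.
#' @return the empirical p-value, with attribute `r_obs`.
#' @export
spin_pvalue <- function(map_a, map_b, ensemble, return_null = FALSE) {
  stopifnot(inherits(ensemble, "spin_ensemble"))
  a <- map_values(map_a); b <- map_values(map_b)
  if (length(a) != ncol(ensemble$assignment)) {
    stop("ensemble parcellation does not match the maps")
  }
  if (inherits(map_a, "parcel_map") &&
      !identical(map_a$parcellation$parcel_id,
                 ensemble$parcellation$parcel_id)) {
    stop("ensemble was built on a different parcellation")
  }
  r_obs <- pearson_corr(a, b)
  A <- matrix(a[ensemble$assignment], nrow = ensemble$n_perm)
  r_null <- null_correlations(A, b)
  r_null <- r_null[!is.na(r_null)]
  # tolerant comparison: a null recomputation of the observed statistic
  # (identity assignment) must count as an exceedance
  p <- (1 + sum(abs(r_null) >= abs(r_obs) - 1e-10)) /
    (length(r_null) + 1)
  attr(p, "r_obs") <- r_obs
  if (return_null) attr(p, "null") <- r_null
  p
}

#' Correlate a target map against a battery of annotation maps
#'
#' One spin-tested Pearson correlation per battery member (for example the
#' 19 PET neurotransmitter receptor/transporter maps), with
#' Benjamini-Hochberg adjustment across the battery as the
#' multiple-comparison family. The target map is spun; annotation maps are
#' held fixed.
#'
#' @param target the phenotype map (spun side).
#' @param battery named list of parcel maps.
#' @param ensemble spin ensemble on the shared parcellation.
#' @return data.frame with columns `map_id`, `r`, `p_spin`, `q`,
#'   `n_parcels_used`, sorted by q then |r| (descending).
#' @export
correlate_battery <- function(target, battery, ensemble) {
  if (length(battery) == 0L) stop("empty battery")
  ids <- names(battery) %||% paste0("map", seq_along(battery))
  tv <- map_values(target)
  res <- lapply(seq_along(battery), function(i) {
    bv <- map_values(battery[[i]])
    p <- spin_pvalue(target, battery[[i]], ensemble)
    data.frame(map_id = ids[i], r = attr(p, "r_obs"), p_spin = as.numeric(p),
               n_parcels_used = sum(!is.na(tv) & !is.na(bv)))
  })
  res <- do.call(rbind, res)
  res$q <- bh_fdr(res$p_spin)
  res <- res[order(res$q, -abs(res$r)), c("map_id", "r", "p_spin", "q",
                                          "n_parcels_used")]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment across one family of tests.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values (q), same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
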