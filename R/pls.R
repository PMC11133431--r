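#' Single-response partial least squares with spin-permutation inference
#'
#' PLS finds latent components — weighted combinations of annotation
#' features — that maximize covariance with a parcel-wise response map.
#' This module implements the single-response (PLS1) variant with
#' X-deflation: after column-wise z-scoring of the annotation matrix and
#' the response, the first weight vector is the normalized
#' cross-covariance `X'y`, scores are the projection of the (deflated)
#' matrix onto the weights, and X is deflated between components.
#' Components are sign-oriented so the score-response correlation is
#' nonnegative. Inference:
#' \itemize{
#'   \item component significance by spin permutation of the response —
#'     the k-th observed captured covariance is compared against the null
#'     distribution of k-th-component covariances from refits on spun
#'     responses;
#'   \item feature reliability by bootstrap over parcels — rows of X and
#'     y resampled jointly with replacement, refit, resampled weights
#'     sign-aligned to the original, and the bootstrap ratio
#'     `BR = weight / SD_boot(weight)` thresholded at |BR| > 3.
#' }
#'
#' @name pls_correspondence
NULL

zscore <- function(v) {
  s <- stats::sd(v)
  if (is.na(s) || s == 0) return(rep(NA_real_, length(v)))
  (v - mean(v)) / s
}

# column z-score; constant columns become zero (flagged via attr)
zscore_cols <- function(M) {
  mu <- colMeans(M)
  s <- sqrt(colMeans(M^2) - mu^2) * sqrt(nrow(M) / (nrow(M) - 1))
  const <- s < .Machine$double.eps^0.5 * (abs(mu) + 1)
  s[const] <- 1
  Z <- sweep(sweep(M, 2L, mu), 2L, s, "/")
  Z[, const] <- 0
  attr(Z, "constant") <- const
  Z
}

# Fast PLS1 core on pre-standardized inputs. Returns weights (p x k),
# orthogonal scores (n x k) and captured covariance t'y (= ||Xk'y||,
# nonnegative by construction) per component.
pls1_fit <- function(X, y, k, covariances_only = FALSE) {
  p <- ncol(X)
  W <- if (covariances_only) NULL else matrix(0, p, k)
  Tm <- if (covariances_only) NULL else matrix(0, nrow(X), k)
  cv <- numeric(k)
  Xk <- X
  for (j in seq_len(k)) {
    w <- crossprod(Xk, y)
    nw <- sqrt(sum(w * w))
    if (nw < 1e-12) break
    w <- w / nw
    t <- Xk %*% w
    cv[j] <- nw
    loading <- crossprod(Xk, t) / sum(t * t)
    Xk <- Xk - tcrossprod(t, loading)
    if (!covariances_only) { W[, j] <- w; Tm[, j] <- t }
  }
  list(weights = W, scores = Tm, cov = cv)
}

#' Fit a PLS model of an annotation matrix against a response map
#'
#' @param X an [annotation_matrix()] (or bare numeric matrix).
#' @param y a [parcel_map()] (or bare numeric vector) aligned to the rows
#'   of `X`.
#' @param n_components number of latent components (default 5).
#' @return object of class `pls_model` with per-component entries
#'   (`weights` — unit-norm, named by feature; `scores` — parcel scores
#'   with NA at masked parcels; `r_obs`; `variance_explained` in percent;
#'   `cov`; `flipped`), plus `parcels_used`, `feature_id`,
#'   `dropped_features`, and a preprocessing record.
#' @export
fit_pls <- function(X, y, n_components = 5L) {
  is_am <- inherits(X, "annotation_matrix")
  Xv <- if (is_am) X$values else as.matrix(X)
  if (is.null(colnames(Xv))) colnames(Xv) <- paste0("f", seq_len(ncol(Xv)))
  yv <- map_values(y)
  if (nrow(Xv) != length(yv)) stop("X rows do not align with y parcels")
  if (all(is.na(yv))) stop("response map is entirely missing")
  ok <- !is.na(yv) & stats::complete.cases(Xv)
  n_components <- as.integer(n_components)
  if (sum(ok) < n_components + 2L) {
    stop("need at least n_components + 2 jointly non-missing parcels")
  }
  Xs <- zscore_cols(Xv[ok, , drop = FALSE])
  const <- attr(Xs, "constant")
  if (any(const)) {
    message("dropping all-constant feature columns: ",
            paste(colnames(Xv)[const], collapse = ", "))
    Xs <- Xs[, !const, drop = FALSE]
  }
  ys <- zscore(yv[ok])
  rank_x <- qr(Xs)$rank
  max_k <- min(sum(ok) - 1L, ncol(Xs), rank_x)
  if (n_components > max_k) {
    stop("n_components (", n_components, ") exceeds usable rank (",
         max_k, ")")
  }
  fit <- pls1_fit(Xs, ys, n_components)
  comps <- vector("list", n_components)
  for (j in seq_len(n_components)) {
    w <- fit$weights[, j]
    sc <- fit$scores[, j]
    r <- suppressWarnings(stats::cor(sc, ys))
    flipped <- isTRUE(r < 0)
    if (flipped) { w <- -w; sc <- -sc; r <- -r }
    full_scores <- rep(NA_real_, length(yv))
    full_scores[ok] <- sc
    names(w) <- colnames(Xs)
    comps[[j]] <- structure(list(
      index = j, weights = w,
      scores = if (inherits(y, "parcel_map")) {
        parcel_map(y$parcellation, full_scores)
      } else full_scores,
      r_obs = r, variance_explained = 100 * r^2,
      cov = fit$cov[j], flipped = flipped), class = "pls_component")
  }
  structure(list(
    components = comps, n_components = n_components,
    parcels_used = which(ok), feature_id = colnames(Xs),
    dropped_features = if (any(const)) colnames(Xv)[const] else character(0),
    preprocessing = list(x_zscored = TRUE, y_zscored = TRUE),
    cov = fit$cov), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model:", x$n_components, "components,",
      length(x$feature_id), "features,",
      length(x$parcels_used), "parcels\n")
  for (cmp in x$components) {
    cat(sprintf("  comp %d: r = %.3f, var expl = %.2f%%, cov = %.3f%s\n",
                cmp$index, cmp$r_obs, cmp$variance_explained, cmp$cov,
                if (cmp$flipped) " (sign-flipped)" else ""))
  }
  invisible(x)
}

#' Spin-permutation significance of PLS components
#'
#' The response map is permuted through each spin-ensemble member, the
#' model refit on the spun response, and the k-th observed captured
#' covariance compared to the null distribution of k-th-component
#' covariances: `p_k = (1 + #\{null_k >= obs_k\}) / (n_perm + 1)`.
#'
#' @param model a fitted [fit_pls()] model.
#' @param X,y the inputs the model was fit on.
#' @param ensemble spin ensemble on `y`'s parcellation.
#' @return numeric vector of empirical p-values, one per component, with
#'   the null covariance matrix attached as attribute `"null"`.
#' @export
component_significance <- function(model, X, y, ensemble) {
  stopifnot(inherits(model, "pls_model"), inherits(ensemble, "spin_ensemble"))
  Xv <- if (inherits(X, "annotation_matrix")) X$values else as.matrix(X)
  yv <- map_values(y)
  if (length(yv) != ncol(ensemble$assignment)) {
    stop("ensemble parcellation does not match the response map")
  }
  k <- model$n_components
  ok0 <- !is.na(yv) & stats::complete.cases(Xv)
  n_perm <- ensemble$n_perm
  null_cov <- matrix(NA_real_, n_perm, k)
  Xs0 <- zscore_cols(Xv[ok0, , drop = FALSE])   # hot path: no missing parcels
  for (i in seq_len(n_perm)) {
    yp <- yv[ensemble$assignment[i, ]]
    ok <- ok0 & !is.na(yp)
    if (sum(ok) < k + 2L) next
    Xs <- if (identical(ok, ok0)) Xs0 else zscore_cols(Xv[ok, , drop = FALSE])
    ys <- zscore(yp[ok])
    null_cov[i, ] <- pls1_fit(Xs, ys, k, covariances_only = TRUE)$cov
  }
  obs <- model$cov
  p <- vapply(seq_len(k), function(j) {
    nc <- null_cov[, j]
    nc <- nc[!is.na(nc)]
    # tolerant comparison so an identity null recomputation counts
    (1 + sum(nc >= obs[j] * (1 - 1e-10) - 1e-12)) / (length(nc) + 1)
  }, numeric(1))
  attr(p, "null") <- null_cov
  p
}

#' Bootstrap ratios for PLS feature reliability
#'
#' Parcel rows of (X, y) are resampled jointly with replacement; the
#' model is refit per resample; each resampled weight vector is
#' sign-aligned to the original (flipped when its dot product with the
#' original weights is negative); and `BR = original weight /
#' SD_boot(weight)`. A zero bootstrap SD yields a signed infinite ratio
#' (flagged), never an error. Resamples with fewer than 3 distinct
#' parcels are redrawn (bounded retries).
#'
#' @inheritParams component_significance
#' @param n_boot number of bootstrap resamples (study default 20000;
#'   must be >= 100).
#' @param seed integer RNG seed.
#' @return numeric matrix, features x components, of bootstrap ratios;
#'   attributes `n_boot`, `seed` and `boot_sd`.
#' @export
bootstrap_ratios <- function(X, y, model, n_boot, seed) {
  stopifnot(inherits(model, "pls_model"))
  n_boot <- as.integer(n_boot)
  if (n_boot < 100L) stop("n_boot must be >= 100")
  Xv <- if (inherits(X, "annotation_matrix")) X$values else as.matrix(X)
  yv <- map_values(y)
  ok <- !is.na(yv) & stats::complete.cases(Xv)
  Xu <- Xv[ok, , drop = FALSE]
  yu <- yv[ok]
  n <- nrow(Xu)
  k <- model$n_components
  p <- length(model$feature_id)
  W0 <- matrix(0, p, k)
  for (j in seq_len(k)) W0[, j] <- model$components[[j]]$weights
  keep <- match(model$feature_id, colnames(Xu))
  s1 <- matrix(0, p, k)   # running sum of aligned bootstrap weights
  s2 <- matrix(0, p, k)   # running sum of squares
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) >= 3L) break
        n_redrawn <- n_redrawn + 1L
      }
      Xb <- zscore_cols(Xu[idx, keep, drop = FALSE])
      yb <- zscore(yu[idx])
      if (anyNA(yb)) next   # degenerate resample (constant response)
      fb <- pls1_fit(Xb, yb, k)
      Wb <- fb$weights
      # sign-align each component to the original weights
      flip <- colSums(Wb * W0) < 0
      Wb[, flip] <- -Wb[, flip, drop = FALSE]
      s1 <- s1 + Wb
      s2 <- s2 + Wb^2
    }
  })
  m <- s1 / n_boot
  sd_b <- sqrt(pmax(s2 / n_boot - m^2, 0) * n_boot / (n_boot - 1))
  br <- W0 / sd_b
  br[sd_b == 0] <- sign(W0[sd_b == 0]) * Inf
  dimnames(br) <- list(model$feature_id, paste0("comp", seq_len(k)))
  if (n_redrawn > 0L) message(n_redrawn, " degenerate resamples redrawn")
  structure(br, n_boot = n_boot, seed = seed, boot_sd = sd_b)
}

#' Select reliable features by bootstrap ratio
#'
#' Features with |BR| strictly greater than the threshold (default 3,
#' comparable to p < 0.001 when BRs behave like z-scores) are split by
#' sign. Flagged infinite ratios are included with their sign.
#'
#' @param br numeric vector of bootstrap ratios for one component (e.g. a
#'   column of [bootstrap_ratios()]), named by feature.
#' @param threshold positive cutoff (default 3).
#' @return list with `positive` and `negative` character vectors of
#'   feature names (disjoint).
#' @export
select_features <- function(br, threshold = 3) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a positive number")
  }
  br <- drop(br)
  nm <- names(br) %||% as.character(seq_along(br))
  list(positive = nm[!is.na(br) & br > threshold],
       negative = nm[!is.na(br) & br < -threshold])
}

#' Gene-score map of a component
#'
#' The per-parcel projection of the annotation matrix onto a component's
#' weights — a brain map of the component's expression (or term) pattern.
#'
#' @param component a `pls_component` from a fitted model.
#' @return the component scores as a [parcel_map()] (or numeric vector
#'   when the model was fit on bare vectors).
#' @export
gene_score_map <- function(component) {
  stopifnot(inherits(component, "pls_component"))
  component$scores
}

#' Variance in the response explained by a component
#'
#' Defined as `100 * r^2` where r is the Pearson correlation between the
#' component scores and the response map.
#'
#' @param scores a `pls_component`, `parcel_map` or numeric score vector.
#' @param y the response map (parcel_map or numeric).
#' @return percent of response variance, in [0, 100].
#' @export
variance_explained <- function(scores, y) {
  sv <- if (inherits(scores, "pls_component")) {
    map_values(scores$scores)
  } else map_values(scores)
  yv <- map_values(y)
  ok <- !is.na(sv) & !is.na(yv)
  if (sum(ok) < 3L) stop("fewer than 3 jointly non-missing parcels")
  if (stats::sd(sv[ok]) == 0) stop("zero-variance scores")
  100 * stats::cor(sv[ok], yv[ok])^2
}
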