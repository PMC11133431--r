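test_that("a single column equal to the response gives a perfect component", {
  parc <- dkt_parc()
  y <- make_autocorrelated_map(parc, 0.5, 1)
  X <- matrix(y$value, ncol = 1, dimnames = list(NULL, "g1"))
  m <- fit_pls(annotation_matrix(parc, X), y, 1)
  expect_equal(m$components[[1]]$r_obs, 1, tolerance = 1e-12)
  expect_equal(m$components[[1]]$variance_explained, 100, tolerance = 1e-10)
})

test_that("first-component weights equal the normalized cross-covariance", {
  set.seed(4)
  for (rep in 1:5) {
    X <- matrix(rnorm(31 * 200), 31, 200)
    y <- rnorm(31)
    m <- fit_pls(X, y, 2)
    # independent closed form: z-score, then X'y normalized
    Xs <- scale(X); ys <- as.numeric(scale(y))
    w_ref <- crossprod(Xs, ys)
    w_ref <- w_ref / sqrt(sum(w_ref^2))
    w <- m$components[[1]]$weights
    cosine <- abs(sum(w * w_ref))
    expect_gt(cosine, 0.999)
  }
})

test_that("weights are unit norm and captured covariance is nonincreasing", {
  set.seed(8)
  X <- matrix(rnorm(31 * 60), 31, 60)
  y <- rnorm(31)
  m <- fit_pls(X, y, 5)
  for (cmp in m$components) {
    expect_equal(sum(cmp$weights^2), 1, tolerance = 1e-10)
    expect_gte(cmp$r_obs, 0)
    expect_true(cmp$variance_explained >= 0 && cmp$variance_explained <= 100)
  }
  expect_true(all(diff(m$cov) <= 1e-8))
})

test_that("an independent PLS implementation agrees on the first component", {
  skip_if_not_installed("mixOmics")
  set.seed(12)
  X <- matrix(rnorm(31 * 40), 31, 40)
  y <- rnorm(31)
  m <- fit_pls(X, y, 2)
  ref <- mixOmics::pls(X, y, ncomp = 2, mode = "regression",
                       scale = TRUE)
  w_ref <- ref$loadings$X[, 1]
  cosine <- abs(sum(m$components[[1]]$weights * w_ref) /
                  sqrt(sum(w_ref^2)))
  expect_gt(cosine, 0.999)
})

test_that("rank and missingness preconditions are enforced", {
  set.seed(2)
  X <- matrix(rnorm(10 * 4), 10, 4)
  expect_error(fit_pls(X, rnorm(10), 8), "rank")
  expect_error(fit_pls(X, rep(NA_real_, 10), 1), "missing")
  expect_error(fit_pls(X[1:3, ], rnorm(3), 2), "non-missing parcels")
  # constant columns are dropped with a message
  Xc <- cbind(X, const = 1)
  expect_message(m <- fit_pls(Xc, rnorm(10), 2), "constant")
  expect_false("const" %in% names(m$components[[1]]$weights))
})

test_that("X residualized against y yields a null first component", {
  parc <- dkt_parc()
  y <- make_autocorrelated_map(parc, 0.5, 21)
  set.seed(22)
  X <- matrix(rnorm(62 * 80), 62, 80)
  ys <- as.numeric(scale(y$value))
  X <- X - ys %*% t(crossprod(X, ys)) / sum(ys^2)   # columns orthogonal to y
  X <- X + matrix(rnorm(length(X), sd = 0.01), nrow(X))  # break exactness
  m <- fit_pls(X, y, 1)
  expect_lt(abs(m$components[[1]]$r_obs), 0.15)
  ens <- spin_ensemble(parc, 199, seed = 23)
  p <- component_significance(m, X, y, ens)
  expect_gt(p[1], 0.05)
})

test_that("identity ensemble makes every component non-significant at p = 1", {
  parc <- dkt_parc()
  y <- make_autocorrelated_map(parc, 0.5, 31)
  sc <- synth_config(seed = 32)
  am <- make_annotation_matrix(parc, y, sc)
  m <- fit_pls(am, y, 3)
  p <- component_significance(m, am, y, identity_ensemble(parc, 20L))
  expect_equal(as.numeric(p), rep(1, 3))
})

test_that("a planted component is detected with small spin p", {
  parc <- dkt_parc()
  y <- make_autocorrelated_map(parc, 0.5, 41)
  # rank-1 correspondence with weak annotation noise
  sc <- synth_config(seed = 42, annotation_noise_sd = 0.3)
  am <- make_annotation_matrix(parc, y, sc)
  m <- fit_pls(am, y, 2)
  ens <- spin_ensemble(parc, 999, seed = 43)
  p <- component_significance(m, am, y, ens)
  expect_lte(p[1], 0.01)
})

test_that("bootstrap ratios flag a noiseless informative column as infinite", {
  parc <- dkt_parc()
  y <- make_autocorrelated_map(parc, 0.5, 51)
  sc <- synth_config(seed = 52, n_features = 1L, n_informative = 1L,
                     annotation_noise_sd = 0)
  am <- make_annotation_matrix(parc, y, sc)
  m <- fit_pls(am, y, 1)
  br <- bootstrap_ratios(am, y, m, 100, seed = 53)
  expect_true(is.infinite(br[1, 1]))
  expect_error(bootstrap_ratios(am, y, m, 50, seed = 1), "n_boot")
})

test_that("bootstrap ratios separate informative from null features", {
  # white-noise target isolates estimator reliability from chance
  # smooth-map correlations; loadings at the stated unit magnitude.
  # Pooled over a few planted instances: per-instance false-positive
  # rates are heavy-tailed because the bootstrap measures stability of
  # in-sample chance correlations, not distance from zero.
  parc <- make_sphere_parcellation(62, seed = 60)
  lh <- subset_hemisphere(parc, "left")
  sens <- fpr <- numeric(3)
  for (s in 1:3) {
    y <- make_autocorrelated_map(lh, 0, 60 + s)
    sc <- synth_config(seed = 61 + s, n_features = 100L,
                       n_informative = 10L, loadings = rep(c(1, -1), 5))
    am <- make_annotation_matrix(lh, y, sc)
    truth <- attr(am, "loadings")
    m <- fit_pls(am, y, 1)
    br <- bootstrap_ratios(am, y, m, 500, seed = 63)
    sel <- select_features(br[, 1], 3)
    flagged <- c(sel$positive, sel$negative)
    informative <- names(truth)[truth != 0]
    sens[s] <- mean(informative %in% flagged)
    fpr[s] <- length(setdiff(flagged, informative)) /
      (length(truth) - length(informative))
  }
  expect_gt(mean(sens), 0.8)
  expect_lt(mean(fpr), 0.15)
})

test_that("feature selection applies a strict signed threshold", {
  br <- c(f1 = 3.5, f2 = -4.0, f3 = 2.9)
  sel <- select_features(br, 3)
  expect_equal(sel$positive, "f1")
  expect_equal(sel$negative, "f2")
  sel0 <- select_features(c(a = 1, b = -2), 3)
  expect_length(sel0$positive, 0)
  expect_length(sel0$negative, 0)
  expect_error(select_features(br, 0), "positive")
  sel_inf <- select_features(c(g = Inf, h = -Inf, i = 3), 3)
  expect_equal(sel_inf$positive, "g")
  expect_equal(sel_inf$negative, "h")
})

test_that("gene-score maps align with the parcellation and the response", {
  parc <- dkt_parc()
  lh <- subset_hemisphere(parc, "left")
  y <- make_autocorrelated_map(lh, 0.5, 71)
  sc <- synth_config(seed = 72, n_features = 50L, n_informative = 5L)
  am <- make_annotation_matrix(lh, y, sc)
  m <- fit_pls(am, y, 1)
  smap <- gene_score_map(m$components[[1]])
  expect_s3_class(smap, "parcel_map")
  expect_length(smap$value, 31L)
  expect_equal(pearson_corr(smap, y), m$components[[1]]$r_obs,
               tolerance = 1e-10)
})

test_that("variance explained is the squared score-response correlation", {
  set.seed(81)
  y <- rnorm(62)
  expect_equal(variance_explained(y, y), 100)
  e <- rnorm(62)
  e <- e - mean(e)
  yc <- y - mean(y)
  e_perp <- e - yc * sum(e * yc) / sum(yc^2)
  expect_equal(variance_explained(e_perp, y), 0, tolerance = 1e-10)
  expect_error(variance_explained(rep(1, 62), y), "zero-variance")
  s <- scores_with_correlation(y, 0.654)
  expect_equal(variance_explained(s, y), 100 * 0.654^2, tolerance = 1e-10)
})

test_that("sign orientation is recorded and idempotent", {
  parc <- dkt_parc()
  y <- make_autocorrelated_map(parc, 0.5, 91)
  sc <- synth_config(seed = 92, n_features = 30L, n_informative = 5L,
                     loading_sd = 2)
  am <- make_annotation_matrix(parc, y, sc)
  m <- fit_pls(am, y, 2)
  for (cmp in m$components) expect_gte(cmp$r_obs, 0)
  # refitting (orientation already applied) changes nothing
  m2 <- fit_pls(am, y, 2)
  expect_equal(m$components[[1]]$weights, m2$components[[1]]$weights)
})

test_that("planted loadings are recovered by the first weight vector", {
  # recovery is assessed over the informative features: with p - k null
  # features the full-vector correlation is bounded by parcel-sampling
  # noise (about 1/sqrt(n_parcels) per null weight) regardless of signal
  # strength, while the informative subvector approaches 1
  parc <- make_sphere_parcellation(62, seed = 100)
  lh <- subset_hemisphere(parc, "left")
  y <- make_autocorrelated_map(lh, 0, 101)
  sc <- synth_config(seed = 102, loadings = rep(c(1, -1), 10))
  am <- make_annotation_matrix(lh, y, sc)
  truth <- attr(am, "loadings")
  m <- fit_pls(am, y, 1)
  inf <- truth != 0
  expect_gt(abs(cor(m$components[[1]]$weights[inf], truth[inf])), 0.9)
})
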