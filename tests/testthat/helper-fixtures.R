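# shared fixtures and independent oracles, built in code at test time

dkt_path <- function() {
  system.file("extdata", "dkt62_centroids_synthetic.tsv", package = "spinpls")
}

dkt_parc <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_parcellation(dkt_path())
    cache
  }
})

# an ensemble whose every member is the identity assignment
identity_ensemble <- function(parc, n_perm = 5L) {
  n <- length(parc$parcel_id)
  structure(list(
    n_perm = n_perm,
    assignment = matrix(rep(seq_len(n), each = n_perm), n_perm, n,
                        dimnames = list(NULL, parc$parcel_id)),
    parcellation = parc, seed = 0L), class = "spin_ensemble")
}

identity_rotations <- function(n_perm = 1L) {
  structure(list(n_perm = n_perm,
                 rotations = array(rep(diag(3), n_perm), c(3, 3, n_perm)),
                 seed = 0L), class = "rotation_set")
}

# Moran's I with inverse-squared-distance weights: spatial-autocorrelation
# oracle, independent of the generator under test
morans_i <- function(v, centroids) {
  D <- acos(pmin(pmax(tcrossprod(centroids), -1), 1))
  diag(D) <- Inf
  W <- 1 / D^2
  z <- v - mean(v)
  n <- length(v)
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

# brute-force BH step-up: q_i = min_{j >= i} p_(j) * m / j, mapped back
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, ps * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# brute-force hypergeometric upper tail by enumeration (universe <= 25)
hyper_tail_brute <- function(overlap, set_size, universe, hits) {
  js <- overlap:min(set_size, hits)
  sum(choose(set_size, js) * choose(universe - set_size, hits - js)) /
    choose(universe, hits)
}

# closed-form OLS oracle via normal equations (independent of the qr path)
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  t <- as.numeric(b) / se
  list(beta = as.numeric(b), se = se, t = t,
       p = 2 * pt(abs(t), df, lower.tail = FALSE), df = df)
}

# construct a score vector with an exact sample Pearson correlation r to y
scores_with_correlation <- function(y, r, seed = 987654 + round(1000 * r)) {
  set.seed(seed)   # must differ from the seed that generated y
  e <- rnorm(length(y))
  ys <- (y - mean(y)) / sd(y)
  e <- e - mean(e)
  e <- e - ys * sum(e * ys) / sum(ys^2)   # orthogonalize to y
  e <- e / sd(e)
  r * ys + sqrt(1 - r^2) * e
}
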