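#' Calibration and recovery experiments
#'
#' Simulation experiments that characterize the pipeline's inferential
#' behaviour on synthetic data: type-I error of the spin test against an
#' unconstrained shuffle, calibration of PLS component significance under
#' an independent autocorrelated null, agreement of the first PLS
#' direction with its closed form, and recovery of planted loadings with
#' bootstrap-ratio selection. The analysis scripts and the acceptance
#' checks are thin drivers over these functions.
#'
#' @name experiments
NULL

#' Type-I error of the spin test vs an unconstrained shuffle
#'
#' Generates independent pairs of spatially autocorrelated null maps and
#' tests each pair twice: with the spin permutation null and with
#' a naive unconstrained value shuffle. On autocorrelated maps the naive
#' test rejects far too often; the spin test stays near the nominal
#' level.
#'
#' @param parcellation substrate for the maps and the ensemble.
#' @param n_pairs number of independent null map pairs (default 500).
#' @param n_perm permutations per test (default 1000).
#' @param lengthscale autocorrelation lengthscale of the null maps
#'   (default 0.5 rad).
#' @param alpha nominal level (default 0.05).
#' @param pairs_per_ensemble rebuild the spin ensemble every this many
#'   pairs (default 20), averaging over ensemble-conditional bias at a
#'   fraction of the cost of one ensemble per pair.
#' @param seed integer seed.
#' @return list with `spin_rejection`, `naive_rejection` (empirical
#'   rates), `n_pairs`, `n_perm`.
#' @export
spin_type1_experiment <- function(parcellation, n_pairs = 500L,
                                  n_perm = 1000L, lengthscale = 0.5,
                                  alpha = 0.05, pairs_per_ensemble = 20L,
                                  seed = 1L) {
  ens <- NULL
  rej_spin <- rej_naive <- logical(n_pairs)
  for (i in seq_len(n_pairs)) {
    if (i %% pairs_per_ensemble == 1L || is.null(ens)) {
      ens <- spin_ensemble(parcellation, n_perm,
                           derive_seed(seed, 1L + i %/% pairs_per_ensemble))
    }
    a <- make_autocorrelated_map(parcellation, lengthscale,
                                 derive_seed(seed, 1000L + i))
    b <- make_autocorrelated_map(parcellation, lengthscale,
                                 derive_seed(seed, 900000L + i))
    rej_spin[i] <- spin_pvalue(a, b, ens) < alpha
    # naive null: unconstrained shuffles of map a
    r_obs <- pearson_corr(a, b)
    av <- a$value
    r_null <- with_seed(derive_seed(seed, 1800000L + i), {
      vapply(seq_len(n_perm),
             function(j) stats::cor(av[sample.int(length(av))], b$value),
             numeric(1))
    })
    p_naive <- (1 + sum(abs(r_null) >= abs(r_obs) - 1e-10)) / (n_perm + 1)
    rej_naive[i] <- p_naive < alpha
  }
  list(spin_rejection = mean(rej_spin), naive_rejection = mean(rej_naive),
       n_pairs = n_pairs, n_perm = n_perm)
}

#' First-direction closed-form agreement
#'
#' On random standardized instances the covariance-maximizing first PLS
#' direction equals the normalized cross-covariance vector `X'y`; this
#' experiment reports the worst cosine similarity between the fitted
#' first-component weights and that closed form.
#'
#' @param n_instances random instances (default 50).
#' @param n_parcels,n_features instance shape (defaults 31 x 200).
#' @param seed integer seed.
#' @return list with `min_cosine`, `mean_cosine`, `n_instances`.
#' @export
pls_oracle_experiment <- function(n_instances = 50L, n_parcels = 31L,
                                  n_features = 200L, seed = 1L) {
  cosine <- with_seed(seed, {
    vapply(seq_len(n_instances), function(i) {
      X <- matrix(stats::rnorm(n_parcels * n_features), n_parcels)
      y <- stats::rnorm(n_parcels)
      m <- fit_pls(X, y, 1L)
      Xs <- scale(X)
      w_ref <- crossprod(Xs, as.numeric(scale(y)))
      w_ref <- w_ref / sqrt(sum(w_ref^2))
      abs(sum(m$components[[1L]]$weights * w_ref))
    }, numeric(1))
  })
  list(min_cosine = min(cosine), mean_cosine = mean(cosine),
       n_instances = n_instances)
}

#' Recovery of planted loadings and bootstrap-ratio selection
#'
#' Plants a single latent component (fixed unit-magnitude loadings on
#' `n_informative` of `n_features` columns, signal SD equal to the unit
#' annotation noise SD) against a white-noise target map on a left
#' hemisphere, fits one PLS component, and runs the parcel bootstrap.
#' Reported per instance and averaged: correlation between planted and
#' recovered loadings over the informative features, the fraction of
#' informative features reaching |BR| > `br_threshold` (sensitivity), and
#' the fraction of null features doing so (false-positive rate). A white
#' target isolates estimator recovery: with a smooth target the smooth
#' null annotation columns correlate with it by chance and the bootstrap
#' reliably flags those real in-sample correlations.
#'
#' @param n_instances planted instances to average over (default 20).
#' @param n_parcels,n_features,n_informative instance shape (defaults
#'   31 x 200, 20 informative).
#' @param n_boot bootstrap resamples (default 2000).
#' @param br_threshold selection cutoff (default 3).
#' @param seed integer seed.
#' @return list with `weight_recovery_cor`, `br_sensitivity`, `br_fpr`
#'   (averages), per-instance vectors, and the settings.
#' @export
pls_recovery_experiment <- function(n_instances = 20L, n_parcels = 31L,
                                    n_features = 200L, n_informative = 20L,
                                    n_boot = 2000L, br_threshold = 3,
                                    seed = 1L) {
  parc <- make_sphere_parcellation(n_parcels, derive_seed(seed, 1L),
                                   hemisphere = "left")
  loadings <- rep(c(1, -1), length.out = n_informative)
  rec <- sens <- fpr <- numeric(n_instances)
  for (i in seq_len(n_instances)) {
    y <- make_autocorrelated_map(parc, 0, derive_seed(seed, 100L + i))
    sc <- synth_config(seed = derive_seed(seed, 200L + i),
                       n_features = n_features,
                       n_informative = n_informative, loadings = loadings)
    am <- make_annotation_matrix(parc, y, sc)
    truth <- attr(am, "loadings")
    inf <- truth != 0
    m <- fit_pls(am, y, 1L)
    rec[i] <- abs(stats::cor(m$components[[1L]]$weights[inf], truth[inf]))
    br <- bootstrap_ratios(am, y, m, n_boot,
                           seed = derive_seed(seed, 300L + i))
    sel <- select_features(br[, 1L], br_threshold)
    flagged <- names(truth) %in% c(sel$positive, sel$negative)
    sens[i] <- mean(flagged[inf])
    fpr[i] <- mean(flagged[!inf])
  }
  list(weight_recovery_cor = mean(rec), br_sensitivity = mean(sens),
       br_fpr = mean(fpr), per_instance = list(recovery = rec,
                                               sensitivity = sens,
                                               fpr = fpr),
       n_instances = n_instances, n_boot = n_boot)
}

#' Calibration of PLS component significance under the null
#'
#' Generates replicates in which the response map is independent of the
#' annotation matrix (both spatially autocorrelated), fits the first
#' component and computes its spin-permutation p-value, and reports the
#' rejection rate at `alpha`.
#'
#' @param parcellation substrate (two-hemisphere recommended; see the
#'   methods vignette on single-hemisphere spins).
#' @param n_reps replicates (default 500).
#' @param n_perm spins per replicate (default 1000).
#' @param n_features annotation width (default 200).
#' @param lengthscale autocorrelation of maps and annotation columns
#'   (default 0.5 rad).
#' @param alpha nominal level (default 0.05).
#' @param reps_per_ensemble rebuild the spin ensemble every this many
#'   replicates (default 20).
#' @param seed integer seed.
#' @return list with `rejection`, `p_values`, `n_reps`, `n_perm`.
#' @export
pls_calibration_experiment <- function(parcellation, n_reps = 500L,
                                       n_perm = 1000L, n_features = 200L,
                                       lengthscale = 0.5, alpha = 0.05,
                                       reps_per_ensemble = 20L,
                                       seed = 1L) {
  ens <- NULL
  pv <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    if (i %% reps_per_ensemble == 1L || is.null(ens)) {
      ens <- spin_ensemble(parcellation, n_perm,
                           derive_seed(seed, 1L + i %/% reps_per_ensemble))
    }
    y <- make_autocorrelated_map(parcellation, lengthscale,
                                 derive_seed(seed, 5000L + i))
    sc <- synth_config(seed = derive_seed(seed, 6000L + i),
                       lengthscale = lengthscale,
                       n_features = n_features, n_informative = 0L)
    am <- make_annotation_matrix(parcellation, y, sc)
    m <- fit_pls(am, y, 1L)
    pv[i] <- component_significance(m, am, y, ens)[1L]
  }
  list(rejection = mean(pv < alpha), p_values = pv,
       n_reps = n_reps, n_perm = n_perm)
}
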