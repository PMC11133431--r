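#' Synthetic study inputs
#'
#' Generators for every input the pipeline consumes, so the whole
#' workflow runs and is testable without restricted cohort or atlas data:
#' spherical parcellations, spatially autocorrelated parcel maps, subject
#' cohorts with a planted regional BMI effect, and parcel-by-feature
#' annotation matrices with planted latent structure. Each generator is a
#' pure function of its arguments and seed, and emits its ground truth
#' (planted coefficients, loadings) alongside the data.
#'
#' @name synthetic_data
NULL

#' Synthetic-cohort configuration
#'
#' Bundles the generator parameters with their defaults. The defaults
#' emulate a single-scanner adolescent cohort: BMI log-normal with mean
#' about 19 kg/m^2 and SD about 4.2 (clipped to the inclusion range
#' [10, 50]); age about 10 +/- 0.5 years; balanced sex; a handful of
#' sites with small additive offsets; baseline thickness 2.5 mm with
#' residual SD 0.1 mm.
#'
#' @param n_parcels parcel count (default 62, two hemispheres of 31).
#' @param lengthscale spatial-autocorrelation lengthscale in radians of
#'   great-circle distance (default 0.5).
#' @param n_subjects cohort size (default 500).
#' @param beta_map planted BMI effect per parcel, mm per kg/m^2 (default
#'   all zero; named vector or scalar recycled).
#' @param covariate_effects named list of slopes: `age` (mm/year), `sex`
#'   (mm, effect of being in the second sex level), `site_sd` (SD of
#'   additive site offsets, mm), `education` (mm/year), `ses` (mm/SD).
#' @param noise_sd residual thickness SD in mm (default 0.1).
#' @param n_sites number of imaging sites (default 4).
#' @param n_features annotation width (default 200; the study-scale
#'   15,633-gene matrix is emulated at reduced width).
#' @param n_informative number of annotation columns carrying the target
#'   map (default 20).
#' @param loading_sd SD of the informative loadings (default 1).
#' @param loadings optional explicit loadings for the informative
#'   columns (length `n_informative`), e.g. a stated fixed magnitude;
#'   when NULL (default) loadings are drawn from
#'   Normal(0, `loading_sd`).
#' @param annotation_noise_sd SD of the additive noise on informative
#'   annotation columns (default 1; 0 gives noiseless rank-1 columns).
#' @param seed mandatory integer seed; every generator is deterministic
#'   given it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_parcels = 62L, lengthscale = 0.5,
                         n_subjects = 500L, beta_map = 0,
                         covariate_effects = list(age = -0.01, sex = 0.02,
                                                  site_sd = 0.02,
                                                  education = 0.002,
                                                  ses = 0.005),
                         noise_sd = 0.1, n_sites = 4L,
                         n_features = 200L, n_informative = 20L,
                         loading_sd = 1, loadings = NULL,
                         annotation_noise_sd = 1, seed) {
  if (missing(seed)) stop("seed is mandatory (no silent nondeterminism)")
  if (noise_sd < 0 || loading_sd < 0 || annotation_noise_sd < 0) {
    stop("SDs must be >= 0")
  }
  if (n_informative > n_features) stop("n_informative > n_features")
  if (!is.null(loadings) && length(loadings) != n_informative) {
    stop("loadings must have length n_informative")
  }
  structure(list(n_parcels = as.integer(n_parcels),
                 lengthscale = lengthscale,
                 n_subjects = as.integer(n_subjects), beta_map = beta_map,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd, n_sites = as.integer(n_sites),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 loading_sd = loading_sd, loadings = loadings,
                 annotation_noise_sd = annotation_noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a spherical parcellation
#'
#' Centroids are laid out as an evenly spread spherical spiral per
#' hemisphere (golden-angle lattice restricted to one side of the
#' sagittal plane x = 0), jittered slightly under the seed, and mirrored
#' to the other hemisphere for two-hemisphere output.
#'
#' @param n_parcels total parcel count; must be even for two-hemisphere
#'   output.
#' @param seed integer seed.
#' @param hemisphere `"both"` (default), `"left"` or `"right"`.
#' @return a [spherical_parcellation()].
#' @export
make_sphere_parcellation <- function(n_parcels, seed,
                                     hemisphere = c("both", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  n_parcels <- as.integer(n_parcels)
  if (n_parcels < 2L) stop("n_parcels must be >= 2")
  if (hemisphere == "both" && n_parcels %% 2L != 0L) {
    stop("n_parcels must be even for two-hemisphere output")
  }
  m <- if (hemisphere == "both") n_parcels %/% 2L else n_parcels
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(m)
  z <- (2 * i - 1) / m - 1
  phi <- pi / 2 + ((i * golden) %% pi)     # azimuth in (pi/2, 3pi/2): x < 0
  r <- sqrt(pmax(1 - z^2, 0))
  left <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  left <- with_seed(seed, left + matrix(stats::rnorm(3 * m, sd = 0.02), m, 3))
  left[, 1] <- -abs(left[, 1])             # keep on the left of x = 0
  left <- left / sqrt(rowSums(left^2))
  right <- left; right[, 1] <- -right[, 1]
  lab <- function(h, k) sprintf("%s.parcel%02d", h, k)
  if (hemisphere == "both") {
    spherical_parcellation(c(lab("lh", i), lab("rh", i)),
                           rep(c("left", "right"), each = m),
                           rbind(left, right))
  } else if (hemisphere == "left") {
    spherical_parcellation(lab("lh", i), rep("left", m), left)
  } else {
    spherical_parcellation(lab("rh", i), rep("right", m), right)
  }
}

great_circle_distance <- function(centroids) {
  cosine <- tcrossprod(centroids)
  acos(pmin(pmax(cosine, -1), 1))
}

#' Generate a spatially autocorrelated parcel map
#'
#' White standard-normal values per parcel are smoothed with a Gaussian
#' kernel `exp(-d^2 / (2 * lengthscale^2))` over great-circle distances
#' d, then re-standardized to mean 0 and SD 1. Smoothing is restricted
#' within hemisphere: cortical hemispheres are disjoint surfaces, so
#' surface-based smoothing never crosses the midline. `lengthscale = 0`
#' gives re-standardized white noise.
#'
#' @param parcellation a [spherical_parcellation()].
#' @param lengthscale kernel lengthscale in radians (>= 0).
#' @param seed integer seed.
#' @return a [parcel_map()] with mean 0 and SD 1.
#' @export
make_autocorrelated_map <- function(parcellation, lengthscale, seed) {
  if (lengthscale < 0) stop("lengthscale must be >= 0")
  n <- n_parcels(parcellation)
  z <- with_seed(seed, stats::rnorm(n))
  v <- if (lengthscale == 0) z else {
    D <- great_circle_distance(parcellation$centroids)
    K <- exp(-D^2 / (2 * lengthscale^2))
    h <- as.integer(parcellation$hemisphere)
    K[outer(h, h, "!=")] <- 0   # hemispheres are disjoint surfaces
    as.numeric(K %*% z)
  }
  v <- (v - mean(v)) / stats::sd(v)
  parcel_map(parcellation, v)
}

#' Generate a subject cohort with a planted BMI effect
#'
#' Per-parcel thickness is `2.5 mm + beta_map * BMI + covariate effects +
#' Normal(0, noise_sd)`. BMI is log-normal (mean about 19 kg/m^2, SD
#' about 4.2, the profile of a large adolescent cohort) clipped to
#' [10, 50] with clip events reported; age ~ Normal(10, 0.5) years; sex
#' balanced; sites uniform with additive Normal(0, site_sd) offsets;
#' education ~ 8..20 years; ses ~ Normal(0, 1).
#'
#' @param parcellation a [spherical_parcellation()].
#' @param config a [synth_config()].
#' @return subject table data.frame (see [read_subject_table()]) with
#'   attributes `bmi_units = "kgm2"` and `beta_map` (the planted ground
#'   truth, one value per parcel).
#' @export
make_cohort <- function(parcellation, config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_subjects
  ids <- parcellation$parcel_id
  np <- length(ids)
  if (n < 10L) stop("n_subjects too small for the model terms")
  beta <- rep(config$beta_map, length.out = np)
  if (!is.null(names(config$beta_map))) {
    beta <- rep(0, np)
    names(beta) <- ids
    beta[names(config$beta_map)] <- config$beta_map
  }
  names(beta) <- ids
  ce <- config$covariate_effects
  with_seed(derive_seed(config$seed, 101L), {
    bmi_raw <- stats::rlnorm(n, meanlog = 2.916, sdlog = 0.2205)
    clipped <- bmi_raw < 10 | bmi_raw > 50
    if (any(clipped)) message(sum(clipped), " BMI draws clipped to [10, 50]")
    bmi <- pmin(pmax(bmi_raw, 10), 50)
    age <- stats::rnorm(n, 10, 0.5)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    site <- sample(paste0("site", seq_len(config$n_sites)), n, replace = TRUE)
    site_offset <- stats::setNames(
      stats::rnorm(config$n_sites, 0, ce$site_sd %||% 0),
      paste0("site", seq_len(config$n_sites)))
    education <- sample(8:20, n, replace = TRUE)
    ses <- stats::rnorm(n)
    lin <- (ce$age %||% 0) * (age - 10) +
      (ce$sex %||% 0) * (sex == "M") +
      site_offset[site] +
      (ce$education %||% 0) * (education - 14) +
      (ce$ses %||% 0) * ses
    thick <- 2.5 + outer(bmi, beta) + lin +
      matrix(stats::rnorm(n * np, 0, config$noise_sd), n, np)
    colnames(thick) <- ids
    out <- data.frame(subject_id = sprintf("sub%05d", seq_len(n)),
                      bmi = bmi, age = age, sex = sex, site = site,
                      education = education, ses = ses,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(thick, check.names = FALSE))
    attr(out, "bmi_units") <- "kgm2"
    attr(out, "beta_map") <- beta
    out
  })
}

#' Generate an annotation matrix with planted latent structure
#'
#' `n_informative` columns carry the target map at loadings drawn from
#' Normal(0, loading_sd) plus unit Gaussian noise; the remaining columns
#' are independent spatially autocorrelated maps. Column order is
#' shuffled under the seed. The planted loadings (zero for null columns)
#' are returned as the `"loadings"` attribute so recovery tests never
#' re-derive them.
#'
#' @param parcellation a [spherical_parcellation()].
#' @param target_map a [parcel_map()] on the parcellation.
#' @param config a [synth_config()] (fields `n_features`,
#'   `n_informative`, `loading_sd`, `lengthscale`, `seed`).
#' @return an [annotation_matrix()] with attribute `loadings`.
#' @export
make_annotation_matrix <- function(parcellation, target_map, config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_informative > config$n_features) {
    stop("n_informative > n_features")
  }
  np <- n_parcels(parcellation)
  tv <- map_values(target_map)
  p <- config$n_features
  k <- config$n_informative
  K <- if (config$lengthscale > 0) {
    D <- great_circle_distance(parcellation$centroids)
    Km <- exp(-D^2 / (2 * config$lengthscale^2))
    h <- as.integer(parcellation$hemisphere)
    Km[outer(h, h, "!=")] <- 0   # hemispheres are disjoint surfaces
    Km
  } else diag(np)
  with_seed(derive_seed(config$seed, 202L), {
    M <- matrix(0, np, p)
    load <- numeric(p)
    if (k > 0L) {
      load[seq_len(k)] <- config$loadings %||%
        stats::rnorm(k, 0, config$loading_sd)
      M[, seq_len(k)] <- outer(tv, load[seq_len(k)]) +
        matrix(stats::rnorm(np * k, 0, config$annotation_noise_sd), np, k)
    }
    if (p > k) {
      # null columns: independent autocorrelated maps, standardized
      Z <- K %*% matrix(stats::rnorm(np * (p - k)), np, p - k)
      Z <- scale(Z)
      M[, (k + 1L):p] <- Z
    }
    ord <- sample.int(p)
    M <- M[, ord, drop = FALSE]
    load <- load[ord]
    colnames(M) <- sprintf("gene%04d", seq_len(p))
    am <- annotation_matrix(parcellation, M, source = "gene")
    attr(am, "loadings") <- stats::setNames(load, colnames(M))
    am
  })
}
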