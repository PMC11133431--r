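#' Run configuration
#'
#' Bundles the inference settings of a full pipeline run. Study-scale
#' defaults: 10,000 spin permutations, 20,000 bootstrap resamples, 5
#' latent components, bootstrap-ratio threshold 3, alpha 0.05. Tests and
#' the bundled analysis scripts use reduced settings (1,000 spins, 2,000
#' bootstraps) for desk-scale runtime.
#'
#' @param seed mandatory integer seed; all stage seeds derive from it.
#' @param n_perm spin permutations (default 10000).
#' @param n_boot bootstrap resamples (default 20000).
#' @param n_components PLS components tested (default 5).
#' @param br_threshold bootstrap-ratio selection cutoff (default 3).
#' @param alpha significance threshold (default 0.05).
#' @param spun_side which map is spun in correlation tests: `"target"`
#'   (default) or `"annotation"`.
#' @param synth a [synth_config()] describing the simulated inputs
#'   (defaults to `synth_config(seed = seed)`).
#' @param n_receptor_maps size of the simulated annotation-map battery
#'   (default 19, the neurotransmitter-system roster size).
#' @param n_terms width of the simulated cognitive-term matrix (default
#'   123).
#' @param gmt optional path to a GMT file for the overrepresentation
#'   stage; when NULL, a deterministic synthetic collection is built from
#'   the simulated gene universe.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed, n_perm = 10000L, n_boot = 20000L,
                       n_components = 5L, br_threshold = 3,
                       alpha = 0.05, spun_side = c("target", "annotation"),
                       synth = NULL, n_receptor_maps = 19L,
                       n_terms = 123L, gmt = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  spun_side <- match.arg(spun_side)
  counts <- c(n_perm = n_perm, n_boot = n_boot, n_components = n_components,
              n_receptor_maps = n_receptor_maps, n_terms = n_terms)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (br_threshold <= 0) stop("br_threshold must be positive")
  structure(list(seed = as.integer(seed), n_perm = as.integer(n_perm),
                 n_boot = as.integer(n_boot),
                 n_components = as.integer(n_components),
                 br_threshold = br_threshold, alpha = alpha,
                 spun_side = spun_side,
                 synth = synth %||% synth_config(seed = seed),
                 n_receptor_maps = as.integer(n_receptor_maps),
                 n_terms = as.integer(n_terms), gmt = gmt),
            class = "run_config")
}

#' Restrict a parcellation to one hemisphere
#'
#' Used when an annotation source covers only one hemisphere (donor
#' expression atlases are typically analysed left-only).
#'
#' @param parcellation a [spherical_parcellation()].
#' @param hemisphere `"left"` or `"right"`.
#' @return the single-hemisphere `spherical_parcellation`.
#' @export
subset_hemisphere <- function(parcellation, hemisphere) {
  keep <- parcellation$hemisphere == hemisphere
  spherical_parcellation(parcellation$parcel_id[keep],
                         as.character(parcellation$hemisphere[keep]),
                         parcellation$centroids[keep, , drop = FALSE])
}

config_record <- function(config) {
  rec <- unclass(config)
  rec$synth <- unclass(rec$synth)
  rec
}

# deterministic synthetic gene-set collection over a feature universe:
# one set concentrated on the planted informative genes plus random sets
synthetic_gene_sets <- function(universe, informative, seed, n_random = 12L) {
  with_seed(seed, {
    sets <- list(planted_program = unique(c(
      informative, sample(universe, max(3L, length(informative) %/% 2L)))))
    for (i in seq_len(n_random)) {
      sets[[sprintf("random_set_%02d", i)]] <-
        sample(universe, sample(8:40, 1L))
    }
    sets
  })
}

#' Run the full synthetic pipeline
#'
#' Executes the whole workflow on simulated inputs: cohort simulation,
#' inclusion filtering, obesity-map construction, spin-tested battery
#' correlation, gene and cognitive-term PLS with component significance
#' and bootstrap-ratio selection, and overrepresentation analysis of the
#' selected gene lists. Every tabular artifact is written as TSV with a
#' JSON sidecar recording settings and seed; a rerun with an identical
#' config is byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  sc <- config$synth

  # -- simulate ----------------------------------------------------------
  sim <- stage("simulate", {
    parc <- make_sphere_parcellation(sc$n_parcels, derive_seed(config$seed, 1L))
    # plant a negative BMI effect in a fronto-temporal-like cluster:
    # the first 5 parcels of each hemisphere
    m <- sc$n_parcels %/% 2L
    beta <- stats::setNames(rep(0, sc$n_parcels), parc$parcel_id)
    planted <- c(seq_len(5L), m + seq_len(5L))
    beta[planted] <- -0.005
    sc_cohort <- sc; sc_cohort$beta_map <- beta
    class(sc_cohort) <- "synth_config"
    cohort <- make_cohort(parc, sc_cohort)
    battery <- lapply(seq_len(config$n_receptor_maps), function(i) {
      make_autocorrelated_map(parc, sc$lengthscale,
                              derive_seed(config$seed, 1000L + i))
    })
    names(battery) <- sprintf("receptor%02d", seq_len(config$n_receptor_maps))
    list(parc = parc, cohort = cohort, battery = battery, beta = beta)
  })
  write_tsv(data.frame(parcel_id = sim$parc$parcel_id,
                       hemisphere = as.character(sim$parc$hemisphere),
                       sim$parc$centroids),
            file.path(out_dir, "parcellation.tsv"))
  utils::write.csv(sim$cohort, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE, quote = FALSE)
  note("simulate: ", nrow(sim$cohort), " subjects, ",
       length(sim$parc$parcel_id), " parcels, ",
       length(sim$battery), " battery maps")

  # -- obesity map -------------------------------------------------------
  omap <- stage("mapfit", {
    kept <- apply_inclusion_filters(sim$cohort)
    note("mapfit: ", attr(kept, "n_excluded"), " subjects excluded by BMI filter")
    build_obesity_map(kept, sim$parc,
                      covariates = c("age", "sex", "site", "education", "ses"))
  })
  write_obesity_map(omap, file.path(out_dir, "obesity_map.tsv"))
  note("mapfit: t range [",
       sprintf("%.2f", min(omap$tmap$value, na.rm = TRUE)), ", ",
       sprintf("%.2f", max(omap$tmap$value, na.rm = TRUE)), "], ",
       sum(omap$q < config$alpha, na.rm = TRUE), " parcels q < ", config$alpha)

  # -- battery spin correlation -----------------------------------------
  spin <- stage("spincorr", {
    ens <- spin_ensemble(sim$parc, config$n_perm, derive_seed(config$seed, 2L))
    correlate_battery(omap$tmap, sim$battery, ens)
  })
  write_tsv(spin, file.path(out_dir, "spincorr.tsv"))
  write_sidecar(list(n_perm = config$n_perm, seed = config$seed,
                     spun_side = config$spun_side,
                     settings = config_record(config)),
                file.path(out_dir, "spincorr.tsv.json"))
  note("spincorr: ", sum(spin$q < config$alpha), " of ", nrow(spin),
       " battery maps q < ", config$alpha)

  # -- gene PLS (left hemisphere, as for donor expression data) ---------
  gene <- stage("pls_genes", {
    parc_lh <- subset_hemisphere(sim$parc, "left")
    y_lh <- parcel_map(parc_lh,
                       omap$tmap$value[parc_lh$parcel_id])
    sc_genes <- sc; sc_genes$seed <- derive_seed(config$seed, 3L)
    class(sc_genes) <- "synth_config"
    am <- make_annotation_matrix(parc_lh, y_lh, sc_genes)
    model <- fit_pls(am, y_lh, config$n_components)
    ens_lh <- spin_ensemble(parc_lh, config$n_perm,
                            derive_seed(config$seed, 4L))
    p_perm <- component_significance(model, am, y_lh, ens_lh)
    br <- bootstrap_ratios(am, y_lh, model, config$n_boot,
                           derive_seed(config$seed, 5L))
    sel <- select_features(br[, 1L], config$br_threshold)
    list(parc = parc_lh, y = y_lh, am = am, model = model,
         p_perm = p_perm, br = br, sel = sel)
  })
  write_annotation_matrix(gene$am, file.path(out_dir, "gene_annotation.tsv"))
  write_tsv(data.frame(feature_id = rownames(gene$br),
                       weight = gene$model$components[[1L]]$weights,
                       br = gene$br[, 1L]),
            file.path(out_dir, "gene_weights.tsv"))
  write_parcel_map(gene_score_map(gene$model$components[[1L]]),
                   file.path(out_dir, "gene_scores.tsv"))
  write_sidecar(list(
    components = lapply(gene$model$components, function(cmp) list(
      index = cmp$index, r_obs = cmp$r_obs,
      variance_explained = cmp$variance_explained,
      p_perm = gene$p_perm[cmp$index], flipped = cmp$flipped)),
    n_perm = config$n_perm, n_boot = config$n_boot,
    br_threshold = config$br_threshold, seed = config$seed,
    positive_features = gene$sel$positive,
    negative_features = gene$sel$negative,
    settings = config_record(config)),
    file.path(out_dir, "gene_pls.json"))
  note("pls_genes: comp1 r = ", sprintf("%.3f", gene$model$components[[1L]]$r_obs),
       ", p = ", sprintf("%.4g", gene$p_perm[1L]), ", ",
       length(gene$sel$positive), " positive / ",
       length(gene$sel$negative), " negative features at |BR| > ",
       config$br_threshold)

  # -- overrepresentation of selected genes -----------------------------
  ora <- stage("ora", {
    universe <- gene$model$feature_id
    collection <- if (!is.null(config$gmt)) {
      read_gmt(config$gmt)
    } else {
      truth <- attr(gene$am, "loadings")
      synthetic_gene_sets(universe, names(truth)[truth != 0],
                          derive_seed(config$seed, 6L))
    }
    run_one <- function(interest) {
      if (length(interest) == 0L) return(NULL)
      overrepresentation_test(interest, collection, universe, min_size = 3L)
    }
    list(positive = run_one(gene$sel$positive),
         negative = run_one(gene$sel$negative))
  })
  for (side in c("positive", "negative")) {
    if (!is.null(ora[[side]])) {
      write_tsv(ora[[side]], file.path(out_dir, paste0("ora_", side, ".tsv")))
      note("ora ", side, ": top set ", ora[[side]]$set_name[1L],
           " (q = ", sprintf("%.3g", ora[[side]]$q[1L]), ")")
    } else {
      note("ora ", side, ": no selected features, stage skipped")
    }
  }

  # -- cognitive-term PLS (full parcellation) ---------------------------
  term <- stage("pls_terms", {
    sc_terms <- sc
    sc_terms$n_features <- config$n_terms
    sc_terms$n_informative <- max(1L, config$n_terms %/% 10L)
    sc_terms$seed <- derive_seed(config$seed, 7L)
    class(sc_terms) <- "synth_config"
    am <- make_annotation_matrix(sim$parc, omap$tmap, sc_terms)
    am$source <- "term"
    colnames(am$values) <- sprintf("term%03d", seq_len(config$n_terms))
    am$feature_id <- colnames(am$values)
    model <- fit_pls(am, omap$tmap, config$n_components)
    ens <- spin_ensemble(sim$parc, config$n_perm, derive_seed(config$seed, 8L))
    p_perm <- component_significance(model, am, omap$tmap, ens)
    list(am = am, model = model, p_perm = p_perm)
  })
  write_sidecar(list(
    components = lapply(term$model$components, function(cmp) list(
      index = cmp$index, r_obs = cmp$r_obs,
      variance_explained = cmp$variance_explained,
      p_perm = term$p_perm[cmp$index], flipped = cmp$flipped)),
    n_perm = config$n_perm, seed = config$seed,
    settings = config_record(config)),
    file.path(out_dir, "term_pls.json"))
  note("pls_terms: comp1 r = ",
       sprintf("%.3f", term$model$components[[1L]]$r_obs),
       ", p = ", sprintf("%.4g", term$p_perm[1L]))

  writeLines(log_lines, logf)
  write_sidecar(config_record(config), file.path(out_dir, "run.json"))
  invisible(list(sim = sim, obesity_map = omap, spincorr = spin,
                 gene = gene, ora = ora, term = term))
}
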