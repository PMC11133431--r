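#!/usr/bin/env Rscript
# Stage 4: PLS correspondence with gene expression and cognitive terms.
#
# Left-hemisphere gene matrix (donor expression atlases cover the left
# hemisphere) against the left half of the obesity map; whole-cortex
# term matrix against the full map. For each: 5 latent components,
# spin-permutation component significance (1,000 spins), parcel
# bootstrap (2,000 resamples) for bootstrap ratios, and |BR| > 3 feature
# selection on component 1. Both annotation matrices were planted on
# targets independent of the cohort, so component significance is
# expected to be null; the selected-feature machinery is exercised
# regardless and feeds stage 5.

suppressMessages(library(spinpls))

parc <- load_parcellation(system.file("extdata",
                                      "dkt62_centroids_synthetic.tsv",
                                      package = "spinpls"))
omap <- read_parcel_map(parc, "results/obesity_map.tsv")

run_pls <- function(am, y, ens, n_boot, seed, label) {
  model <- fit_pls(am, y, 5)
  p_perm <- component_significance(model, am, y, ens)
  br <- bootstrap_ratios(am, y, model, n_boot, seed = seed)
  sel <- select_features(br[, 1], 3)
  message(label, ": comp1 r = ",
          sprintf("%.3f", model$components[[1]]$r_obs),
          " (", sprintf("%.1f", model$components[[1]]$variance_explained),
          "% variance), p_perm = ", sprintf("%.3g", p_perm[1]), "; ",
          length(sel$positive), " positive / ", length(sel$negative),
          " negative features at |BR| > 3")
  list(model = model, p_perm = p_perm, br = br, sel = sel)
}

# genes: left hemisphere only
lh <- subset_hemisphere(parc, "left")
genes <- read_annotation_matrix(lh, "results/data/gene_expression.tsv")
y_lh <- parcel_map(lh, omap$value[lh$parcel_id])
ens_lh <- spin_ensemble(lh, 1000, seed = 44)
g <- run_pls(genes, y_lh, ens_lh, 2000, 45, "genes (lh)")

utils::write.table(
  data.frame(feature_id = rownames(g$br),
             weight = g$model$components[[1]]$weights,
             br = g$br[, 1]),
  "results/gene_weights.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write_parcel_map(gene_score_map(g$model$components[[1]]),
                 "results/gene_scores.tsv")
jsonlite::write_json(
  list(components = lapply(g$model$components, function(cmp) list(
         index = cmp$index, r_obs = cmp$r_obs,
         variance_explained = cmp$variance_explained,
         p_perm = g$p_perm[cmp$index], flipped = cmp$flipped)),
       n_perm = 1000, n_boot = 2000, seed = 44,
       positive = g$sel$positive, negative = g$sel$negative),
  "results/gene_pls.json", auto_unbox = TRUE, digits = NA)

# cognitive terms: whole cortex
terms <- read_annotation_matrix(parc, "results/data/cognitive_terms.tsv",
                                source = "term")
ens <- spin_ensemble(parc, 1000, seed = 46)
tr <- run_pls(terms, omap, ens, 2000, 47, "terms")
jsonlite::write_json(
  list(components = lapply(tr$model$components, function(cmp) list(
         index = cmp$index, r_obs = cmp$r_obs,
         variance_explained = cmp$variance_explained,
         p_perm = tr$p_perm[cmp$index], flipped = cmp$flipped)),
       n_perm = 1000, n_boot = 2000, seed = 46,
       positive = tr$sel$positive, negative = tr$sel$negative),
  "results/term_pls.json", auto_unbox = TRUE, digits = NA)
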