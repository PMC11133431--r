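#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
#
# Builds everything the downstream stages consume, on the bundled
# 62-parcel DKT-style parcellation: a subject cohort (n = 500) with a
# planted fronto-temporal-like negative BMI effect, a 19-map battery of
# receptor-density-like annotation maps, and left-hemisphere gene and
# whole-cortex cognitive-term annotation matrices with planted latent
# structure. Ground truth is saved alongside so later stages can be
# checked against it.

suppressMessages(library(spinpls))

seed <- 42L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

parc <- load_parcellation(system.file("extdata",
                                      "dkt62_centroids_synthetic.tsv",
                                      package = "spinpls"))
write_tsv <- function(x, f) utils::write.table(
  x, file.path(out, f), sep = "\t", quote = FALSE, row.names = FALSE)

# cohort with a planted regional deficit: -0.005 mm per kg/m^2 in the
# first five parcels of each hemisphere
beta <- stats::setNames(rep(0, 62), parc$parcel_id)
beta[c(1:5, 32:36)] <- -0.005
sc <- synth_config(seed = seed, n_subjects = 500, beta_map = beta)
cohort <- make_cohort(parc, sc)
utils::write.csv(cohort, file.path(out, "subjects.csv"), row.names = FALSE,
                 quote = FALSE)

# receptor-like battery: 19 independent autocorrelated maps
battery <- sapply(1:19, function(i) {
  make_autocorrelated_map(parc, 0.5, seed + 1000L + i)$value
})
colnames(battery) <- sprintf("receptor%02d", 1:19)
write_tsv(data.frame(parcel_id = parc$parcel_id, battery), "receptor_maps.tsv")

# left-hemisphere gene matrix planted on an autocorrelated target and a
# whole-cortex term matrix; ground truth loadings go to JSON
lh <- subset_hemisphere(parc, "left")
gene_target <- make_autocorrelated_map(lh, 0.5, seed + 7L)
sc_gene <- synth_config(seed = seed + 8L, n_features = 200L,
                        n_informative = 20L, loading_sd = 2)
genes <- make_annotation_matrix(lh, gene_target, sc_gene)
write_annotation_matrix(genes, file.path(out, "gene_expression.tsv"))

term_target <- make_autocorrelated_map(parc, 0.5, seed + 9L)
sc_term <- synth_config(seed = seed + 10L, n_features = 123L,
                        n_informative = 12L, loading_sd = 2)
terms <- make_annotation_matrix(parc, term_target, sc_term)
colnames(terms$values) <- sprintf("term%03d", 1:123)
terms$feature_id <- colnames(terms$values)
terms$source <- "term"
write_annotation_matrix(terms, file.path(out, "cognitive_terms.tsv"))

jsonlite::write_json(
  list(seed = seed, planted_beta = as.list(beta),
       gene_loadings = as.list(attr(genes, "loadings")),
       term_loadings = as.list(attr(terms, "loadings"))),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

message("simulated: ", nrow(cohort), " subjects, 19 receptor maps, ",
        "200 genes (lh), 123 terms; planted deficit in ",
        sum(beta != 0), " parcels")
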