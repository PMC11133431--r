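#!/usr/bin/env Rscript
# Stage 5: overrepresentation analysis of the selected gene lists.
#
# Positive and negative |BR| > 3 gene lists from stage 4 are tested
# separately against a gene-set collection (GMT). No curated pathway
# database ships with the package; this driver builds a small synthetic
# GMT over the simulated gene universe — one set concentrated on the
# planted informative genes plus random sets — so the stage demonstrates
# the full WebGestalt-style flow: hypergeometric enrichment against the
# analysis universe, BH-FDR across sets, top-10 reporting.

suppressMessages(library(spinpls))

pls <- jsonlite::read_json("results/gene_pls.json", simplifyVector = TRUE)
truth <- jsonlite::read_json("results/data/ground_truth.json",
                             simplifyVector = TRUE)
loadings <- unlist(truth$gene_loadings)
universe <- names(loadings)
informative <- names(loadings)[loadings != 0]

# synthetic GMT over the simulated universe
gmt_path <- "results/data/synthetic_sets.gmt"
set.seed(48)
sets <- c(list(planted_program = unique(c(informative,
                                          sample(universe, 10)))),
          stats::setNames(lapply(1:12, function(i) sample(universe,
                                                          sample(8:40, 1))),
                          sprintf("random_set_%02d", 1:12)))
writeLines(vapply(names(sets), function(nm) {
  paste(c(nm, "synthetic gene set", sets[[nm]]), collapse = "\t")
}, character(1)), gmt_path)
collection <- read_gmt(gmt_path)

for (side in c("positive", "negative")) {
  interest <- unlist(pls[[side]])
  if (length(interest) == 0) {
    message(side, " list empty; stage skipped for this side")
    next
  }
  res <- overrepresentation_test(interest, collection, universe,
                                 min_size = 3L)
  utils::write.table(res, sprintf("results/ora_%s.tsv", side), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message("top sets for the ", side, " gene list (", length(interest),
          " genes):")
  print(ora_top(res, 5)[, c("set_name", "overlap", "set_size", "expected",
                            "p", "q")])
}
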