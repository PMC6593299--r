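#!/usr/bin/env Rscript
# Generate the synthetic serum miRNA study: a 756-miRNA x 21-sample count
# matrix (10 DR cases vs 11 NDR controls, age-confounded), a 2588-feature
# abundance-mixture variant, and the miRNA-target/pathway fixture.
# Writes TSV/GMT inputs for the downstream steps under results/data/.

suppressPackageStartupMessages(library(mirisk))

seed <- 20260101
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_dataset(sim_params(), seed = seed)
write_count_matrix(sim$counts, file.path(out, "counts.tsv"))
write.table(sim$samples, file.path(out, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$sample_truth, file.path(out, "sample_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d miRNAs x %d samples; %d planted DE (LFC %s)\n",
            nrow(sim$counts), ncol(sim$counts), sum(sim$truth$de),
            paste(round(sim$truth$beta[sim$truth$de], 2), collapse = ", ")))
cat(sprintf("age: DR %.1f +/- %.1f vs NDR %.1f +/- %.1f years (confounded)\n",
            mean(sim$samples$age[sim$samples$group == "DR"]),
            sd(sim$samples$age[sim$samples$group == "DR"]),
            mean(sim$samples$age[sim$samples$group == "NDR"]),
            sd(sim$samples$age[sim$samples$group == "NDR"])))

# abundance-mixture scenario: 2588 features, ~70% below the 200-count filter
mix <- simulate_low_abundance_mix(sim_params(n_features = 2588),
                                  seed = seed + 1L, fraction = 0.7)
write_count_matrix(mix$counts, file.path(out, "counts_mixture.tsv"))
kept <- nrow(filter_low_abundance(mix$counts))
cat(sprintf("mixture scenario: %d of 2588 features pass the total>=200 filter\n",
            kept))

# target-gene and pathway fixture for the enrichment step (panel filled in
# with the DE calls of step 02; the structure is panel-size invariant)
panel <- c("miR-9-5p", "miR-4448", "miR-338-3p", "miR-190a-5p", "miR-485-5p")
fx <- make_target_fixture(panel, seed = seed)
write.table(fx$targets, file.path(out, "targets.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
gmt <- vapply(names(fx$collection$sets), function(nm) {
  paste(c(nm, "synthetic", fx$collection$sets[[nm]]), collapse = "\t")
}, character(1))
writeLines(gmt, file.path(out, "gene_sets.gmt"))
cat(sprintf("fixture: %d target rows, %d gene sets (focal pathway '%s')\n",
            nrow(fx$targets), length(fx$collection$sets), fx$pathway))
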