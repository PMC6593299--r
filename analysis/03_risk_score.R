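#!/usr/bin/env Rscript
# LFC-weighted polygenic risk score over the DE miRNA panel, evaluated with
# ROC/AUC (DeLong CI) and the Youden-optimal cutoff. The evaluation reuses
# the discovery samples, so the AUC is optimistically biased; that reuse is
# deliberate and flagged.

suppressPackageStartupMessages(library(mirisk))

counts <- read_count_matrix("results/data/counts.tsv")
samples <- read_sample_metadata("results/data/samples.tsv")
de <- read.delim("results/de_results.tsv")

filtered <- filter_low_abundance(counts, 200)
sf <- estimate_size_factors(filtered)
lf <- log_fpm(fpm(filtered, sf))

panel <- de[de$de, ]
stopifnot(nrow(panel) > 0)
weights <- setNames(panel$lfc, panel$mirna)
rs <- polygenic_score(lf, weights)

labels <- as.character(samples$group[match(names(rs$score), samples$sample)])
roc <- roc_curve(rs$score, labels, "DR", direction = "auto")
ci <- auc_confidence_interval(
  if (roc$direction == "case_low") -rs$score else rs$score, labels, "DR")
yj <- youden_cutoff(roc)

write.table(data.frame(sample = names(rs$score), score = rs$score,
                       group = labels),
            "results/risk_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(roc$points, "results/roc_points.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("panel of %d miRNAs, weights = their LFCs (%s)\n",
            length(weights), paste(round(weights, 2), collapse = ", ")))
cat(sprintf("AUC = %.3f, 95%% DeLong CI [%.3f, %.3f] (direction %s; in-sample, optimistic)\n",
            roc$auc, ci$lower, ci$upper, roc$direction))
cat(sprintf("Youden-optimal cutoff %.3f: sensitivity %.3f, specificity %.3f\n",
            yj$cutoff, yj$sensitivity, yj$specificity))
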