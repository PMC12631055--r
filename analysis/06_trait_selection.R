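#!/usr/bin/env Rscript
# Stage 6: traits predicting genetic-group membership — correlation
# prefilter (|r| > 0.9) then shadow-feature (Boruta) selection around a
# random forest, groups with fewer than 3 accessions dropped.

suppressPackageStartupMessages(library(alfadiv))
seed <- 6024L

tab <- utils::read.delim("results/accession_traits.tsv", check.names = FALSE)
X <- as.matrix(tab[, -1]); rownames(X) <- tab[[1]]
groups <- utils::read.delim("results/data/genetic_groups.tsv")
group_of <- stats::setNames(groups$group, groups$accession)[rownames(X)]

keep <- names(which(table(group_of) >= 3))
sel <- group_of %in% keep
cat(sprintf("dropping %d accession(s) in groups below 3 members\n", sum(!sel)))

pf <- prefilter_correlated(X[sel, ], threshold = 0.9)
cat(sprintf("prefilter kept %d of %d traits\n", length(pf$kept), ncol(X)))

br <- boruta_select(pf$x, factor(group_of[sel]), alpha = 0.05,
                    max_runs = 200, seed = seed)
print(br)
tabi <- importance_table(br)
print(utils::head(tabi, 6))
utils::write.table(tabi, "results/trait_importance.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
if (nrow(pf$dropped))
  utils::write.table(pf$dropped, "results/traits_dropped_prefilter.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
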