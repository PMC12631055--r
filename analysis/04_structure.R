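#!/usr/bin/env Rscript
# Stage 4: phenotypic structure without priors — PCA, k-means with BIC,
# and DAPC trait loadings; genetic groups overlaid on the scores.

suppressPackageStartupMessages(library(alfadiv))
seed <- 4024L

tab <- utils::read.delim("results/accession_traits.tsv", check.names = FALSE)
X <- as.matrix(tab[, -1]); rownames(X) <- tab[[1]]
groups <- utils::read.delim("results/data/genetic_groups.tsv")
group_of <- stats::setNames(groups$group, groups$accession)

pca <- run_pca(X)
d <- which(cumsum(pca$variance_fractions) >= 0.9)[1]
cat(sprintf("retained %d PCs (%.1f%% of variance)\n", d,
            100 * sum(pca$variance_fractions[1:d])))

sol <- kmeans_bic_scan(pca$scores[, 1:d, drop = FALSE], k_range = 1:12,
                       n_restarts = 20, seed = seed)
print(sol)
dapc <- run_dapc(X, sol$assignment, retained_pcs = d)
print(dapc)
cat("top traits on axis 1:\n")
print(top_traits(dapc, 1, 5))

utils::write.table(data.frame(accession = names(sol$assignment),
                              cluster = unname(sol$assignment)),
                   "results/pheno_clusters.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(data.frame(k = names(sol$bic_by_k), bic = unname(sol$bic_by_k)),
                   "results/bic_curve.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(overlay_groups(dapc$scores, group_of),
                   "results/dapc_scores_genetic_overlay.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(trait = rownames(dapc$trait_loadings),
                              dapc$trait_loadings, check.names = FALSE),
                   "results/dapc_trait_loadings.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
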