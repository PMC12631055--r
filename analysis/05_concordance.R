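#!/usr/bin/env Rscript
# Stage 5: concordance between genetic and phenotypic structure —
# Euclidean distance on allele-frequency profiles vs Mahalanobis
# distance on standardized traits, compared by a Spearman Mantel test
# with 999 permutations.

suppressPackageStartupMessages(library(alfadiv))
seed <- 5024L

geno <- read_frequency_table("results/data/frequencies_imputed.tsv",
                             "results/data/marker_map.tsv")
tab <- utils::read.delim("results/accession_traits.tsv", check.names = FALSE)
X <- as.matrix(tab[, -1]); rownames(X) <- tab[[1]]

common <- intersect(rownames(geno$values), rownames(X))
geno <- afm(geno$values[common, ], geno$marker_map)
X <- X[common, , drop = FALSE]

gd <- genetic_distance(geno)
pd <- phenotypic_distance(X, shrinkage = "auto")
cat(sprintf("phenotypic covariance shrinkage used: %.3f\n", pd$shrinkage))

mt <- mantel_test(gd, pd, n_permutations = 999, seed = seed)
print(mt)

write_distance(gd, "results/genetic_distance.tsv")
write_distance(pd, "results/phenotypic_distance.tsv")
jsonlite::write_json(list(r = mt$r_obs, p_value = mt$p_value,
                          n_permutations = mt$n_permutations,
                          method = mt$method, n_accessions = length(common)),
                     "results/mantel.json", auto_unbox = TRUE, digits = NA)
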