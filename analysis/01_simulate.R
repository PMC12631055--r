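#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study panel.
#
# Emulates a cultivated alfalfa diversity panel: 395 accessions in 7
# genetic groups (one deliberately tiny, mirroring a relict subspecies
# group), pooled-GBS allele frequencies at 4000 biallelic markers
# (pool of 100 tetraploid plants = 400 chromosomes), neutral group
# differentiation F = 0.05 with 2% strongly divergent loci (F = 0.4),
# and mild within-group cultivar drift.

suppressPackageStartupMessages(library(alfadiv))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 2024L

group_sizes <- c(G1_Falcata = 2, G2_North_America = 45,
                 G3_France_North_Europe = 100, G4_East_Europe = 111,
                 G5_USA = 60, G6_China = 17, G7_Mediterranean = 60)

truth <- simulate_group_frequencies(
  n_groups = length(group_sizes), n_markers = 4000,
  fst_neutral = 0.05, outlier_fraction = 0.02, fst_outlier = 0.4,
  seed = seed)
rownames(truth$group_freq) <- names(group_sizes)

panel <- simulate_panel(group_sizes, truth, pool_chromosomes = 400,
                        accession_fst = 0.05, seed = seed + 1)

write_frequency_table(panel$afm, "results/data/frequencies.tsv",
                      "results/data/marker_map.tsv")
utils::write.table(
  data.frame(accession = names(panel$group_of), group = unname(panel$group_of)),
  "results/data/genetic_groups.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(outlier_markers = colnames(truth$group_freq)[truth$outlier_index],
       fst_neutral = truth$fst_neutral, fst_outlier = truth$fst_outlier,
       group_sizes = as.list(group_sizes)),
  "results/data/truth.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("panel: %d accessions x %d markers, %d groups, %d planted outlier loci\n",
            nrow(panel$afm$values), ncol(panel$afm$values),
            length(group_sizes), length(truth$outlier_index)))
print(panel$afm)
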