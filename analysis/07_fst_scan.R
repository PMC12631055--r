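#!/usr/bin/env Rscript
# Stage 7: per-SNP Nei FST for every pair of genetic groups, empirical
# neutral null (one shared random marker sample), BH q-values, outlier
# calls at q < 0.05, and gene-window annotation (synthetic gene models
# tiled over the marker map; 500 bp window).

suppressPackageStartupMessages(library(alfadiv))
seed <- 7024L

geno <- read_frequency_table("results/data/frequencies_imputed.tsv",
                             "results/data/marker_map.tsv")
groups <- utils::read.delim("results/data/genetic_groups.tsv")
group_of <- stats::setNames(groups$group, groups$accession)

# synthetic gene annotation: 300 genes of 1-2 kb tiled over the 8
# chromosomes spanned by the marker map
set.seed(seed)
map <- geno$marker_map
genes <- do.call(rbind, lapply(split(map$pos, map$chrom), range))
genes <- data.frame(chrom = rownames(genes),
                    lo = genes[, 1], hi = genes[, 2])
ann <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
  starts <- sort(sample(seq(genes$lo[i], genes$hi[i]), 40))
  data.frame(chrom = genes$chrom[i], start = starts,
             end = starts + sample(1000:2000, 40, replace = TRUE),
             gene_id = sprintf("synth_gene_%s_%02d", genes$chrom[i], 1:40))
}))

scan <- fst_outlier_scan(geno, group_of, neutral = 2000L,
                         q_threshold = 0.05, annotation = ann,
                         window = 500L, min_group_size = 3L, seed = seed)
print(scan)

truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)
called <- unique(unlist(lapply(scan$pairs, function(t) t$marker[!is.na(t$outlier) & t$outlier])))
cat(sprintf("outliers called in >=1 comparison: %d; planted outliers recovered: %d of %d\n",
            length(called), sum(truth$outlier_markers %in% called),
            length(truth$outlier_markers)))

# The q < 0.05 call is conservative at desk scale (the empirical p cannot
# go below 1/(|null|+1), so BH needs dozens of loci at that floor before
# anything is called). The ranking itself is informative: check how
# strongly the planted divergent loci are enriched in the FST tail.
max_fst <- apply(sapply(scan$pairs, `[[`, "fst"), 1, max, na.rm = TRUE)
names(max_fst) <- scan$pairs[[1]]$marker
top1pct <- names(sort(max_fst, decreasing = TRUE))[1:ceiling(0.01 * length(max_fst))]
n_planted_top <- sum(truth$outlier_markers %in% top1pct)
cat(sprintf("top 1%% of max pairwise FST (%d loci): %d planted outliers (%.0fx enrichment)\n",
            length(top1pct), n_planted_top,
            (n_planted_top / length(top1pct)) /
              (length(truth$outlier_markers) / length(max_fst))))

# annotate the top-ranked loci as candidate regions (rank-based, the
# q-threshold call stays as reported above)
top_snps <- geno$marker_map[match(top1pct, geno$marker_map$marker), ]
names(top_snps)[1] <- "marker"
rank_hits <- annotate_outliers(top_snps, ann, window = 500L)
utils::write.table(rank_hits, "results/fst/top_rank_candidate_genes.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("rank-based candidate gene hits for top 1%% loci: %d\n", nrow(rank_hits)))

dir.create("results/fst", showWarnings = FALSE)
for (pr in names(scan$pairs))
  utils::write.table(scan$pairs[[pr]],
                     sprintf("results/fst/fst_%s.tsv", gsub("[^A-Za-z0-9]", "_", pr)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
write_outlier_bed(scan, "results/fst/outliers.bed")
if (!is.null(scan$hits)) {
  utils::write.table(scan$hits, "results/fst/candidate_gene_hits.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("candidate gene hits: %d (%d genes)\n", nrow(scan$hits),
              length(unique(scan$hits$gene_id))))
}
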