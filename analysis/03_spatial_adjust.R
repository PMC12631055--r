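#!/usr/bin/env Rscript
# Stage 3: field trials and spatial phenotype adjustment.
#
# Two augmented trials on a 10 x 44 grid (440 plots each): 5 checks
# replicated 6x, 15 entries duplicated, remainder unreplicated. Twelve
# traits: half purely polygenic, half with additive group shifts of
# varying size (these are the traits the structure/selection stages
# should later pick up). Each trait x trial is fitted with the
# tensor-product B-spline genomic mixed model, knots chosen by AIC; the
# fitted surface is removed, accession means taken across trials, then
# traits standardized.

suppressPackageStartupMessages(library(alfadiv))
seed <- 3024L

grm_tab <- utils::read.delim("results/grm.tsv", check.names = FALSE)
G <- as.matrix(grm_tab[, -1]); rownames(G) <- grm_tab[[1]]
grm <- structure(list(G = G, n_scale = 16), class = "grm")
groups <- utils::read.delim("results/data/genetic_groups.tsv")
group_of <- stats::setNames(groups$group, groups$accession)
acc <- rownames(G)

n_traits <- 12
shift_sizes <- c(rep(0, 6), seq(0.4, 1.4, length.out = 6))
set.seed(seed)
group_effects <- sapply(shift_sizes, function(s)
  if (s == 0) rep(0, length(unique(group_of)))
  else rnorm(length(unique(group_of)), 0, s))
rownames(group_effects) <- sort(unique(group_of))
colnames(group_effects) <- paste0("trait", seq_len(n_traits))

all_means <- list()
fit_summaries <- list()
for (trial in c("Lusignan", "NoviSad")) {
  toff <- if (trial == "Lusignan") 0L else 500L
  lay <- simulate_trial(10, 44, acc,
                        checks_replication = stats::setNames(
                          c(rep(6, 5), rep(2, 15)), acc[1:20]),
                        trial_id = trial, seed = seed + 1L + toff)
  surf <- simulate_spatial_surface(10, 44, length_scale = 10, variance = 1,
                                   seed = seed + 2L + toff)
  ph <- simulate_phenotypes(grm, lay, surf, sigma2_a = 1, sigma2_e = 1,
                            n_traits = n_traits, mu = 10,
                            group_effects = group_effects,
                            group_of = group_of, seed = seed + 3L + toff)
  res <- suppressMessages(adjust_trial_traits(
    ph$plots, grm, paste0("trait", seq_len(n_traits)),
    knot_grid = list(c(4L, 6L), c(6L, 10L))))
  all_means[[trial]] <- res$accession_means
  fit_summaries[[trial]] <- lapply(res$fits, function(f)
    list(knots = f$knots, aic = f$aic, var_additive = f$var_additive,
         var_spatial = f$var_spatial, var_residual = f$var_residual))
  utils::write.table(res$adjusted,
                     sprintf("results/adjusted_plots_%s.tsv", trial),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: fitted %d traits; median var_spatial = %.2f\n", trial,
              n_traits, median(sapply(res$fits, `[[`, "var_spatial"))))
}

# accession means across trials, then standardization
mean_mat <- (all_means$Lusignan + all_means$NoviSad) / 2
# accessions present in only one trial keep that trial's mean
only <- is.na(mean_mat)
mean_mat[only] <- all_means$Lusignan[only]
mean_mat[is.na(mean_mat)] <- all_means$NoviSad[is.na(mean_mat)]
std <- standardize_traits(mean_mat[rowSums(is.na(mean_mat)) == 0, , drop = FALSE])
utils::write.table(data.frame(accession = rownames(std), std, check.names = FALSE),
                   "results/accession_traits.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
jsonlite::write_json(fit_summaries, "results/spatial_fits.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("standardized trait matrix: %d accessions x %d traits\n",
            nrow(std), ncol(std)))
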