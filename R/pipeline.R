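# Config-driven orchestration of the analysis stages. Each stage's seed
# is derived from the global seed as seed * 100 + stage position (kept
# well below 2^31), so stages can be re-run in isolation reproducibly.

.stage_order <- c("simulate", "grm", "adjust", "structure", "mantel",
                  "select", "fst_scan")

.config_defaults <- list(
  seed = 1L,
  outdir = "alfadiv_out",
  stages = character(0),
  simulate = list(n_groups = 6L, n_markers = 2000L, fst_neutral = 0.05,
                  outlier_fraction = 0.02, fst_outlier = 0.4,
                  group_size = 30L, pool_chromosomes = 400L,
                  n_rows = 10L, n_cols = 44L,
                  surface_variance = 1, length_scale = 10,
                  sigma2_a = 1, sigma2_e = 1, n_traits = 4L, mu = 10),
  grm = list(n_scale = 16, auto_scale = FALSE, max_missing = 0.05,
             maf_min = 0.01, drop_unmapped = FALSE),
  adjust = list(knot_grid = list(c(4L, 6L), c(6L, 8L)), S_structure = "identity"),
  structure = list(k_range = 1:10, n_restarts = 20L),
  mantel = list(n_permutations = 999L, shrinkage = "auto"),
  select = list(alpha = 0.05, max_runs = 100L, cor_threshold = 0.9),
  fst_scan = list(neutral_size = 1000L, q_threshold = 0.05, window = 500L,
                  min_group_size = 3L)
)

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), checks every key against the
#' documented schema, rejects unknown keys, fills in defaults, and
#' checks stage dependencies (every requested stage must be able to get
#' its inputs from an earlier stage or from configured files).
#'
#' @param config Path to a YAML config file, or a named list.
#' @return Normalized config list of class `run_config`.
#' @export
validate_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(.config_defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (stage in .stage_order) {
    if (!is.null(cfg[[stage]])) {
      bad <- setdiff(names(cfg[[stage]]), names(.config_defaults[[stage]]))
      if (length(bad))
        stop("unknown key(s) in '", stage, "': ", paste(bad, collapse = ", "))
    }
  }
  out <- utils::modifyList(.config_defaults, cfg)
  out$stages <- as.character(out$stages)
  bad_stage <- setdiff(out$stages, .stage_order)
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  # dependency check: everything downstream needs the simulated inputs here
  downstream <- setdiff(out$stages, "simulate")
  if (length(downstream) && !("simulate" %in% out$stages))
    stop("stage(s) ", paste(downstream, collapse = ", "),
         " require the 'simulate' stage to provide inputs")
  if ("fst_scan" %in% out$stages && out$simulate$n_groups < 2)
    stop("fst_scan requires at least 2 groups")
  out$adjust$knot_grid <- lapply(out$adjust$knot_grid,
                                 function(k) as.integer(unlist(k)))
  out$stages <- .stage_order[.stage_order %in% out$stages]
  class(out) <- "run_config"
  out
}

# per-stage seed derivation (documented counter scheme)
stage_seed <- function(global_seed, stage) {
  (as.integer(global_seed) %% 20000000L) * 100L +
    match(stage, .stage_order)
}

#' Run the configured analysis stages
#'
#' Executes the requested stages in dependency order on a synthetic
#' panel, writing each stage's tables under `outdir` and recording every
#' output file with an md5 hash in a JSON run report. A stage failure
#' aborts its dependents; the report then marks the run as partial.
#'
#' @param config A `run_config` from [validate_config()] (or anything it
#'   accepts).
#' @return The run report (list), invisibly; written to
#'   `<outdir>/run_report.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, stages = list(), outputs = character(0),
                 status = "complete", started = format(Sys.time(), tz = "UTC"))
  state <- new.env(parent = emptyenv())
  record <- function(path) {
    report$outputs[basename(path)] <<- unname(tools::md5sum(path))
  }
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({ fun(); "ok" },
                    error = function(e) paste("error:", conditionMessage(e)))
    report$stages[[name]] <<- list(status = res,
                                   seed = stage_seed(cfg$seed, name),
                                   seconds = round(proc.time()[["elapsed"]] - t0, 2))
    if (!identical(res, "ok")) {
      report$status <<- "partial"
      FALSE
    } else TRUE
  }
  ok <- TRUE
  for (stage in cfg$stages) {
    if (!ok) break  # abort dependents after a failure
    sd <- stage_seed(cfg$seed, stage)
    ok <- switch(stage,
      simulate = run_stage("simulate", function() {
        p <- cfg$simulate
        truth <- simulate_group_frequencies(p$n_groups, p$n_markers,
                                            p$fst_neutral, p$outlier_fraction,
                                            p$fst_outlier, seed = sd)
        panel <- simulate_panel(stats::setNames(rep(p$group_size, p$n_groups),
                                                rownames(truth$group_freq)),
                                truth, p$pool_chromosomes, seed = sd + 1L)
        state$truth <- truth; state$afm <- panel$afm
        state$group_of <- panel$group_of
        layout <- simulate_trial(p$n_rows, p$n_cols,
                                 rownames(panel$afm$values), seed = sd + 2L)
        surface <- simulate_spatial_surface(p$n_rows, p$n_cols, p$length_scale,
                                            p$surface_variance, seed = sd + 3L)
        g0 <- compute_relationship(impute_missing(panel$afm))
        ph <- simulate_phenotypes(g0, layout, surface, p$sigma2_a, p$sigma2_e,
                                  p$n_traits, mu = p$mu, seed = sd + 4L)
        state$layout <- layout; state$surface <- surface
        state$plots <- ph$plots; state$pheno_truth <- ph$truth
        f1 <- file.path(cfg$outdir, "frequencies.tsv")
        f2 <- file.path(cfg$outdir, "marker_map.tsv")
        write_frequency_table(panel$afm, f1, f2)
        f3 <- file.path(cfg$outdir, "plots.tsv")
        utils::write.table(ph$plots, f3, sep = "\t", quote = FALSE, row.names = FALSE)
        f4 <- file.path(cfg$outdir, "groups.tsv")
        utils::write.table(data.frame(accession = names(panel$group_of),
                                      group = unname(panel$group_of)),
                           f4, sep = "\t", quote = FALSE, row.names = FALSE)
        f5 <- file.path(cfg$outdir, "truth.json")
        jsonlite::write_json(list(outlier_markers =
                                    colnames(truth$group_freq)[truth$outlier_index],
                                  fst_neutral = truth$fst_neutral,
                                  fst_outlier = truth$fst_outlier,
                                  variance_components =
                                    as.list(ph$truth$variance_components)),
                             f5, auto_unbox = TRUE, digits = NA)
        for (f in c(f1, f2, f3, f4, f5)) record(f)
      }),
      grm = run_stage("grm", function() {
        p <- cfg$grm
        filt <- filter_markers(state$afm, p$max_missing, p$maf_min, p$drop_unmapped)
        state$grm <- compute_relationship(impute_missing(filt),
                                          n_scale = p$n_scale,
                                          auto_scale = p$auto_scale)
        f <- file.path(cfg$outdir, "grm.tsv")
        write_relationship(state$grm, f); record(f)
      }),
      adjust = run_stage("adjust", function() {
        p <- cfg$adjust
        traits <- grep("^trait", names(state$plots), value = TRUE)
        res <- adjust_trial_traits(state$plots, state$grm, traits,
                                   knot_grid = p$knot_grid,
                                   S_structure = p$S_structure)
        state$accession_means <- res$accession_means
        state$std_traits <- standardize_traits(res$accession_means)
        f1 <- file.path(cfg$outdir, "adjusted_plots.tsv")
        utils::write.table(res$adjusted, f1, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        f2 <- file.path(cfg$outdir, "accession_traits.tsv")
        utils::write.table(data.frame(accession = rownames(state$std_traits),
                                      state$std_traits, check.names = FALSE),
                           f2, sep = "\t", quote = FALSE, row.names = FALSE)
        f3 <- file.path(cfg$outdir, "spatial_fits.json")
        jsonlite::write_json(lapply(res$fits, function(ft)
          list(mu = ft$mu, var_additive = ft$var_additive,
               var_spatial = ft$var_spatial, var_residual = ft$var_residual,
               knots = ft$knots, aic = ft$aic)),
          f3, auto_unbox = TRUE, digits = NA)
        for (f in c(f1, f2, f3)) record(f)
      }),
      structure = run_stage("structure", function() {
        p <- cfg$structure
        pca <- run_pca(state$std_traits)
        d <- pcs_for_variance(pca$variance_fractions)
        sol <- kmeans_bic_scan(pca$scores[, seq_len(d), drop = FALSE],
                               p$k_range, p$n_restarts, seed = sd)
        state$clusters <- sol
        dapc <- run_dapc(state$std_traits, sol$assignment, retained_pcs = d)
        f1 <- file.path(cfg$outdir, "cluster_assignment.tsv")
        utils::write.table(data.frame(accession = names(sol$assignment),
                                      cluster = unname(sol$assignment)),
                           f1, sep = "\t", quote = FALSE, row.names = FALSE)
        f2 <- file.path(cfg$outdir, "bic_curve.tsv")
        utils::write.table(data.frame(k = names(sol$bic_by_k),
                                      bic = unname(sol$bic_by_k)),
                           f2, sep = "\t", quote = FALSE, row.names = FALSE)
        f3 <- file.path(cfg$outdir, "dapc_scores.tsv")
        utils::write.table(overlay_groups(dapc$scores, state$group_of),
                           f3, sep = "\t", quote = FALSE, row.names = FALSE)
        f4 <- file.path(cfg$outdir, "dapc_trait_loadings.tsv")
        utils::write.table(data.frame(trait = rownames(dapc$trait_loadings),
                                      dapc$trait_loadings, check.names = FALSE),
                           f4, sep = "\t", quote = FALSE, row.names = FALSE)
        for (f in c(f1, f2, f3, f4)) record(f)
      }),
      mantel = run_stage("mantel", function() {
        p <- cfg$mantel
        gd <- genetic_distance(impute_missing(state$afm))
        pd <- phenotypic_distance(state$std_traits, shrinkage = p$shrinkage)
        mt <- mantel_test(gd, pd, p$n_permutations, seed = sd)
        f <- file.path(cfg$outdir, "mantel.json")
        jsonlite::write_json(list(r = mt$r_obs, p_value = mt$p_value,
                                  n_permutations = mt$n_permutations,
                                  method = mt$method),
                             f, auto_unbox = TRUE, digits = NA)
        record(f)
      }),
      select = run_stage("select", function() {
        p <- cfg$select
        pf <- prefilter_correlated(state$std_traits, p$cor_threshold)
        br <- boruta_select(pf$x, state$group_of[rownames(pf$x)],
                            alpha = p$alpha, max_runs = p$max_runs, seed = sd)
        f <- file.path(cfg$outdir, "trait_importance.tsv")
        utils::write.table(importance_table(br), f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        record(f)
      }),
      fst_scan = run_stage("fst_scan", function() {
        p <- cfg$fst_scan
        scan <- fst_outlier_scan(impute_missing(state$afm), state$group_of,
                                 neutral = p$neutral_size,
                                 q_threshold = p$q_threshold,
                                 window = p$window,
                                 min_group_size = p$min_group_size, seed = sd)
        for (pr in names(scan$pairs)) {
          f <- file.path(cfg$outdir,
                         paste0("fst_", gsub("[^A-Za-z0-9]", "_", pr), ".tsv"))
          utils::write.table(scan$pairs[[pr]], f, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          record(f)
        }
        fb <- file.path(cfg$outdir, "fst_outliers.bed")
        write_outlier_bed(scan, fb); record(fb)
      }))
  }
  report$finished <- format(Sys.time(), tz = "UTC")
  rp <- file.path(cfg$outdir, "run_report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
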