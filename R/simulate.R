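#' Simulate group allele frequencies under a Balding-Nichols model
#'
#' Draws an ancestral allele frequency per marker and, for each genetic
#' group, a group frequency from the Balding-Nichols Beta distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose variance around the ancestral
#' frequency `p` matches a target differentiation `F`. A designated
#' minority of markers uses a larger divergence parameter, emulating loci
#' under divergent selection on top of a neutral background.
#'
#' @param n_groups Number of genetic groups.
#' @param n_markers Number of biallelic markers.
#' @param fst_neutral Target FST for neutral markers, in (0, 1).
#' @param outlier_fraction Fraction of markers drawn with the elevated
#'   divergence parameter; `ceiling(outlier_fraction * n_markers)` markers
#'   are designated outliers.
#' @param fst_outlier Target FST for outlier markers; must exceed
#'   `fst_neutral`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `group_freq_truth`: a list with
#'   `ancestral_freq` (length `n_markers`), `group_freq`
#'   (`n_groups x n_markers` matrix, rows named `G1..`), `fst_neutral`,
#'   `fst_outlier` and `outlier_index` (integer vector).
#' @export
simulate_group_frequencies <- function(n_groups, n_markers, fst_neutral,
                                       outlier_fraction = 0, fst_outlier = fst_neutral,
                                       seed = 1L) {
  if (n_groups < 1L || n_markers < 1L)
    stop("n_groups and n_markers must be positive")
  if (!(fst_neutral > 0 && fst_neutral < 1))
    stop("fst_neutral must lie in (0, 1)")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must lie in [0, 1)")
  if (outlier_fraction > 0 && !(fst_outlier > fst_neutral && fst_outlier < 1))
    stop("fst_outlier must lie in (fst_neutral, 1)")
  set.seed(seed)
  p <- stats::runif(n_markers, 0.05, 0.95)
  n_out <- ceiling(outlier_fraction * n_markers)
  outlier_index <- if (n_out > 0) sort(sample.int(n_markers, n_out)) else integer(0)
  f <- rep(fst_neutral, n_markers)
  f[outlier_index] <- fst_outlier
  shape1 <- p * (1 - f) / f
  shape2 <- (1 - p) * (1 - f) / f
  gf <- matrix(stats::rbeta(n_groups * n_markers,
                            rep(shape1, each = n_groups),
                            rep(shape2, each = n_groups)),
               nrow = n_groups, ncol = n_markers)
  rownames(gf) <- paste0("G", seq_len(n_groups))
  colnames(gf) <- paste0("m", seq_len(n_markers))
  structure(list(ancestral_freq = p, group_freq = gf,
                 fst_neutral = fst_neutral, fst_outlier = fst_outlier,
                 outlier_index = outlier_index),
            class = "group_freq_truth")
}

#' Simulate a pooled-sample allele-frequency panel
#'
#' Each accession is a pool of plants from one group; its observed
#' frequency at a marker is a binomial draw of `pool_chromosomes`
#' chromosomes at the group frequency, divided by `pool_chromosomes`.
#' The default of 400 corresponds to pools of 100 autotetraploid plants.
#'
#' @param group_sizes Named integer vector: accessions per group. Names
#'   must match rows of `truth$group_freq`.
#' @param truth A `group_freq_truth` object.
#' @param pool_chromosomes Chromosomes sampled per pool (>= 1).
#' @param accession_fst Optional within-group drift: when > 0, each
#'   accession's own frequency is first drawn from a Balding-Nichols Beta
#'   around its group frequency with this divergence parameter (cultivars
#'   within a gene pool differ from one another), then pool-sampled.
#'   Default 0: accessions differ only by pool sampling noise.
#' @param seed Integer seed.
#' @return A list with `afm` (an [afm] allele-frequency matrix with a
#'   synthetic marker map over 8 chromosomes) and `group_of`, a named
#'   character vector mapping accession id to group.
#' @export
simulate_panel <- function(group_sizes, truth, pool_chromosomes = 400L,
                           accession_fst = 0, seed = 1L) {
  stopifnot(inherits(truth, "group_freq_truth"))
  if (pool_chromosomes < 1L) stop("pool_chromosomes must be >= 1")
  if (accession_fst < 0 || accession_fst >= 1)
    stop("accession_fst must lie in [0, 1)")
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% rownames(truth$group_freq)))
    stop("all groups in group_sizes must be present in truth")
  set.seed(seed)
  m <- ncol(truth$group_freq)
  n <- sum(group_sizes)
  values <- matrix(NA_real_, nrow = n, ncol = m)
  group_of <- character(n)
  acc <- character(n)
  i <- 0L
  for (g in names(group_sizes)) {
    gf <- truth$group_freq[g, ]
    for (k in seq_len(group_sizes[[g]])) {
      i <- i + 1L
      af <- gf
      if (accession_fst > 0) {
        poly <- gf > 0 & gf < 1   # Beta undefined at fixed frequencies
        ratio <- (1 - accession_fst) / accession_fst
        af[poly] <- stats::rbeta(sum(poly), gf[poly] * ratio,
                                 (1 - gf[poly]) * ratio)
      }
      values[i, ] <- stats::rbinom(m, pool_chromosomes, af) / pool_chromosomes
      group_of[i] <- g
      acc[i] <- sprintf("%s_acc%03d", g, k)
    }
  }
  rownames(values) <- acc
  colnames(values) <- colnames(truth$group_freq)
  names(group_of) <- acc
  map <- data.frame(marker = colnames(values),
                    chrom = paste0("chr", ((seq_len(m) - 1L) %% 8L) + 1L),
                    pos = ((seq_len(m) - 1L) %/% 8L + 1L) * 1000L,
                    stringsAsFactors = FALSE)
  list(afm = afm(values, marker_map = map), group_of = group_of)
}

#' Simulate an augmented-design field trial layout
#'
#' Places accessions on a rows-by-columns grid. Unreplicated entries get
#' one plot each; entries listed in `checks_replication` are replicated
#' the stated number of times, spread over incomplete blocks formed by
#' splitting the columns into `n_blocks` contiguous strips. Plot
#' assignment is randomized by `seed`.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param accessions Character vector of entry ids (one plot each unless
#'   replicated).
#' @param checks_replication Named integer vector: replicate counts for
#'   check entries (may name accessions already in `accessions`).
#' @param n_blocks Number of incomplete blocks (column strips).
#' @param trial_id Trial label.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `plot_id`, `trial_id`, `row`,
#'   `column`, `block`, `accession`; `(trial, row, column)` unique.
#' @export
simulate_trial <- function(n_rows, n_cols, accessions,
                           checks_replication = NULL, n_blocks = 4L,
                           trial_id = "T1", seed = 1L) {
  if (anyNA(accessions)) stop("accessions contains NA")
  reps <- stats::setNames(rep(1L, length(accessions)), accessions)
  if (!is.null(checks_replication)) {
    for (a in names(checks_replication)) reps[a] <- checks_replication[[a]]
  }
  entries <- rep(names(reps), reps)
  if (length(entries) > n_rows * n_cols)
    stop(sprintf("grid too small: %d plots needed, %d available",
                 length(entries), n_rows * n_cols))
  set.seed(seed)
  cells <- expand.grid(row = seq_len(n_rows), column = seq_len(n_cols))
  cells <- cells[sample.int(nrow(cells), length(entries)), , drop = FALSE]
  ord <- sample.int(length(entries))
  block_of <- cut(cells$column, breaks = n_blocks, labels = paste0("B", seq_len(n_blocks)))
  data.frame(plot_id = sprintf("%s_p%04d", trial_id, seq_along(entries)),
             trial_id = trial_id,
             row = cells$row, column = cells$column,
             block = as.character(block_of),
             accession = entries[ord],
             stringsAsFactors = FALSE)
}

#' Simulate a smooth spatial field surface
#'
#' Deterministic (seeded) mixture of low-frequency sinusoids over the
#' grid, rescaled so that the empirical variance over all cells equals
#' `variance`. Wavelengths are drawn between one and two times
#' `length_scale`, so cells closer than the length scale are strongly
#' correlated.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param length_scale Smoothness scale in plot units (default 10).
#' @param variance Target empirical variance of the surface (>= 0).
#' @param n_components Number of sinusoid components.
#' @param seed Integer seed.
#' @return `n_rows x n_cols` numeric matrix; entry `[r, c]` is the field
#'   effect of the plot in row `r`, column `c`.
#' @export
simulate_spatial_surface <- function(n_rows, n_cols, length_scale = 10,
                                     variance = 1, n_components = 6L, seed = 1L) {
  if (variance < 0) stop("variance must be >= 0")
  s <- matrix(0, n_rows, n_cols)
  if (variance == 0) return(s)
  set.seed(seed)
  r <- matrix(seq_len(n_rows), n_rows, n_cols)
  c_ <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  for (k in seq_len(n_components)) {
    wavelength <- stats::runif(1, length_scale, 2 * length_scale)
    theta <- stats::runif(1, 0, 2 * pi)
    phase <- stats::runif(1, 0, 2 * pi)
    amp <- stats::rnorm(1)
    s <- s + amp * sin(2 * pi * (cos(theta) * r + sin(theta) * c_) / wavelength + phase)
  }
  s <- s - mean(s)
  v <- mean(s^2)
  if (v == 0) return(s)  # degenerate flat draw
  s * sqrt(variance / v)
}

#' Simulate plot-level phenotypes from the spatial genomic mixed model
#'
#' Generates traits as `y = mu + u(accession) + s(plot) + e` with
#' breeding values `u ~ N(0, G * sigma2_a)` (jointly over accessions),
#' a fixed spatial surface `s` evaluated at each plot's coordinates, and
#' i.i.d. residuals `e ~ N(0, sigma2_e)`. Optional additive group shifts
#' create group-differentiated traits.
#'
#' @param G Genomic relationship object from [compute_relationship()] or a
#'   symmetric accession matrix with dimnames.
#' @param layout Trial layout as from [simulate_trial()].
#' @param surface Matrix from [simulate_spatial_surface()] (or NULL for no
#'   spatial effect).
#' @param sigma2_a,sigma2_e Additive and residual variances (>= 0).
#' @param n_traits Number of traits to generate.
#' @param mu Global mean (recycled over traits).
#' @param group_effects Optional `group x trait` matrix of additive shifts;
#'   requires `group_of`.
#' @param group_of Named vector accession -> group (only used with
#'   `group_effects`).
#' @param seed Integer seed.
#' @return A list with `plots` (the layout plus one column per trait,
#'   named `trait1..`) and `truth` (class `synthetic_truth`: `mu`,
#'   `breeding_value` accession x trait matrix, `spatial_surface`,
#'   `variance_components`).
#' @export
simulate_phenotypes <- function(G, layout, surface = NULL,
                                sigma2_a = 1, sigma2_e = 1, n_traits = 1L,
                                mu = 10, group_effects = NULL, group_of = NULL,
                                seed = 1L) {
  Gm <- if (inherits(G, "grm")) G$G else G
  if (!isSymmetric(unname(Gm), tol = 1e-8)) stop("G must be symmetric")
  if (sigma2_a < 0 || sigma2_e < 0) stop("variances must be >= 0")
  acc <- rownames(Gm)
  if (!all(layout$accession %in% acc))
    stop("layout contains accessions absent from G")
  set.seed(seed)
  n <- length(acc)
  mu <- rep_len(mu, n_traits)
  u <- matrix(0, n, n_traits, dimnames = list(acc, paste0("trait", seq_len(n_traits))))
  if (sigma2_a > 0) {
    L <- chol_psd(Gm * sigma2_a)
    u <- crossprod(L, matrix(stats::rnorm(n * n_traits), n, n_traits))
    dimnames(u) <- list(acc, paste0("trait", seq_len(n_traits)))
  }
  if (!is.null(group_effects)) {
    if (is.null(group_of)) stop("group_effects requires group_of")
    u <- u + group_effects[group_of[acc], , drop = FALSE]
    rownames(u) <- acc
  }
  s_plot <- if (is.null(surface)) rep(0, nrow(layout)) else
    surface[cbind(layout$row, layout$column)]
  plots <- layout
  for (t in seq_len(n_traits)) {
    e <- if (sigma2_e > 0) stats::rnorm(nrow(layout), 0, sqrt(sigma2_e)) else 0
    plots[[paste0("trait", t)]] <- mu[t] + u[layout$accession, t] + s_plot + e
  }
  truth <- structure(list(mu = mu, breeding_value = u,
                          spatial_surface = surface,
                          variance_components = c(sigma2_a = sigma2_a,
                                                  sigma2_e = sigma2_e)),
                     class = "synthetic_truth")
  list(plots = plots, truth = truth)
}

# Upper Cholesky factor of a PSD matrix, tolerating zero/negative
# numerical eigenvalues via pivoting-free eigen fallback.
chol_psd <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))  # returns factor R with R'R = S
}
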