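#' Principal component analysis of a standardized trait matrix
#'
#' Thin wrapper over the singular value decomposition with canonicalized
#' axis signs (the largest-magnitude loading of each component is made
#' positive), so results are reproducible across platforms and row
#' orders.
#'
#' @param x Standardized accession x trait matrix.
#' @param n_components Number of components to return (default
#'   `min(n - 1, p)`).
#' @return List with `scores` (n x k), `loadings` (p x k, orthonormal)
#'   and `variance_fractions` (length k, fractions of *total* variance,
#'   non-increasing).
#' @export
run_pca <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  kmax <- min(n - 1L, p)
  if (is.null(n_components)) n_components <- kmax
  if (n_components > kmax) stop("n_components exceeds min(n - 1, p)")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # canonical signs
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = load,
       variance_fractions = vf[seq_len(k)], center = pc$center)
}

#' Choose the number of phenotypic clusters by k-means and BIC
#'
#' For each candidate `k`, runs k-means with `n_restarts` random starts
#' on the retained PC scores and computes a spherical-Gaussian BIC,
#' `BIC(k) = n d ln(WSS_k / (n d)) + k d ln(n)`, with `d` the number of
#' score dimensions and `WSS_k` the total within-cluster sum of squares.
#' The solution with the lowest BIC is returned; ties break toward
#' smaller `k`.
#'
#' @param scores Accession x dimension score matrix.
#' @param k_range Candidate cluster numbers (all `< nrow(scores)`).
#' @param n_restarts Random restarts per `k` (default 20).
#' @param seed Integer seed.
#' @return Object of class `cluster_solution`: `k`, `assignment` (named
#'   integer vector), `bic_by_k` (named numeric), `n_pcs_used`,
#'   `centers`.
#' @export
kmeans_bic_scan <- function(scores, k_range = 1:10, n_restarts = 20L, seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores); d <- ncol(scores)
  if (max(k_range) >= n) stop("max(k_range) must be < number of accessions")
  set.seed(seed)
  bic <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  sols <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k == 1) {
      wss <- sum(scale(scores, scale = FALSE)^2)
      sols[[i]] <- list(cluster = rep(1L, n),
                        centers = matrix(colMeans(scores), 1))
    } else {
      km <- suppressWarnings(
        stats::kmeans(scores, centers = k, nstart = n_restarts, iter.max = 100))
      wss <- km$tot.withinss
      sols[[i]] <- km
    }
    bic[i] <- n * d * log(wss / (n * d)) + k * d * log(n)
  }
  best <- which(bic == min(bic))[1]  # ties toward smaller k (k_range ordered)
  assignment <- stats::setNames(as.integer(sols[[best]]$cluster), rownames(scores))
  structure(list(k = k_range[best], assignment = assignment, bic_by_k = bic,
                 n_pcs_used = d, centers = sols[[best]]$centers),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("k-means/BIC solution: k = %d (BIC = %.2f) on %d dimensions\n",
              x$k, min(x$bic_by_k), x$n_pcs_used))
  invisible(x)
}

# Number of leading PCs explaining at least `target` of total variance.
pcs_for_variance <- function(variance_fractions, target = 0.9) {
  max(1L, which(cumsum(variance_fractions) >= target)[1])
}

#' Discriminant analysis of principal components
#'
#' Runs PCA on the standardized trait matrix, retains `retained_pcs`
#' components (default: the smallest number explaining >= 90% of the
#' variance), and fits a linear discriminant analysis on the scores:
#' axes are the leading eigenvectors of `solve(W, B)` with `W` the
#' pooled within-group and `B` the between-group scatter of the scores.
#' When `W` is near-singular a ridge of `shrinkage * mean(diag(W))` is
#' added (logged). Discriminant axes are mapped back through the PC
#' loadings to per-trait contributions.
#'
#' @param x Standardized accession x trait matrix.
#' @param assignment Group label per accession (factor or vector, aligned
#'   with rows of `x`).
#' @param retained_pcs Number of PCs to keep (default: 90% variance
#'   rule).
#' @param n_axes Number of discriminant axes (default
#'   `min(retained_pcs, n_groups - 1)`).
#' @param shrinkage Ridge fraction applied to the within scatter when it
#'   is ill-conditioned (default 1e-8, escalated automatically).
#' @return Object of class `dapc_result`: `retained_pcs`,
#'   `discriminant_axes` (PC-space, columns normalized to unit within-
#'   group variance), `trait_loadings` (p x axes), `axis_variance_fraction`
#'   (sums to 1 over retained axes), `scores` (accession coordinates),
#'   `group_means` (axis coordinates of group centroids), `eigenvalues`.
#' @export
run_dapc <- function(x, assignment, retained_pcs = NULL, n_axes = NULL,
                     shrinkage = 1e-8) {
  x <- as.matrix(x)
  g <- factor(assignment)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 members")
  pca <- run_pca(x)
  if (is.null(retained_pcs))
    retained_pcs <- pcs_for_variance(pca$variance_fractions)
  retained_pcs <- min(retained_pcs, ncol(pca$scores))
  S <- pca$scores[, seq_len(retained_pcs), drop = FALSE]
  kmax <- min(retained_pcs, nlevels(g) - 1L)
  if (is.null(n_axes)) n_axes <- kmax
  if (n_axes > kmax) stop("n_axes exceeds min(retained_pcs, n_groups - 1)")

  n <- nrow(S)
  gm <- apply(S, 2, function(col) tapply(col, g, mean))
  gm <- matrix(gm, nrow = nlevels(g))
  cnt <- as.numeric(table(g))
  center <- colMeans(S)
  Bm <- crossprod(sweep(gm, 2, center) * sqrt(cnt)) / n
  Wm <- crossprod(S - gm[as.integer(g), , drop = FALSE]) / n
  lam <- shrinkage
  repeat {
    Wreg <- Wm + lam * mean(diag(Wm)) * diag(retained_pcs)
    ch <- tryCatch(chol(Wreg), error = function(e) NULL)
    if (!is.null(ch) && kappa(Wreg) < 1e12) break
    lam <- max(lam * 100, 1e-6)
    message("within-group covariance ill-conditioned; shrinkage raised to ", lam)
  }
  # generalized eigenproblem B a = lambda W a via symmetric reduction
  Linv <- backsolve(ch, diag(retained_pcs))
  Msym <- crossprod(Linv, Bm %*% Linv)
  e <- eigen((Msym + t(Msym)) / 2, symmetric = TRUE)
  axes <- Linv %*% e$vectors[, seq_len(n_axes), drop = FALSE]
  # normalize: unit within-group variance along each axis
  for (j in seq_len(n_axes)) {
    s2 <- drop(crossprod(axes[, j], Wreg %*% axes[, j]))
    axes[, j] <- axes[, j] / sqrt(s2)
  }
  ev <- pmax(e$values[seq_len(n_axes)], 0)
  trait_load <- pca$loadings[, seq_len(retained_pcs), drop = FALSE] %*% axes
  # canonical signs on trait loadings
  for (j in seq_len(n_axes)) {
    i <- which.max(abs(trait_load[, j]))
    if (trait_load[i, j] < 0) {
      trait_load[, j] <- -trait_load[, j]; axes[, j] <- -axes[, j]
    }
  }
  scores <- S %*% axes
  colnames(scores) <- colnames(axes) <- colnames(trait_load) <-
    paste0("LD", seq_len(n_axes))
  rownames(trait_load) <- colnames(x)
  structure(list(retained_pcs = retained_pcs,
                 discriminant_axes = axes,
                 trait_loadings = trait_load,
                 axis_variance_fraction = if (sum(ev) > 0) ev / sum(ev) else ev,
                 eigenvalues = ev,
                 scores = scores,
                 group_means = apply(scores, 2, function(cc) tapply(cc, g, mean)),
                 groups = g),
            class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("DAPC: %d PCs retained, %d discriminant axes; axis variance fractions: %s\n",
              x$retained_pcs, ncol(x$scores),
              paste(sprintf("%.3f", x$axis_variance_fraction), collapse = ", ")))
  invisible(x)
}

#' Traits contributing most to a discriminant axis
#'
#' @param dapc A `dapc_result`.
#' @param axis Axis index.
#' @param top_n How many traits to return (capped at the trait count).
#' @return `data.frame` with `trait`, `loading` and `contribution`
#'   (squared loading, normalized to sum 1 over all traits), sorted by
#'   contribution, descending.
#' @export
top_traits <- function(dapc, axis = 1L, top_n = 10L) {
  if (axis < 1 || axis > ncol(dapc$trait_loadings)) stop("axis out of range")
  l <- dapc$trait_loadings[, axis]
  contrib <- l^2 / sum(l^2)
  ord <- order(contrib, decreasing = TRUE)
  utils::head(data.frame(trait = names(contrib)[ord], loading = l[ord],
                         contribution = contrib[ord], row.names = NULL,
                         stringsAsFactors = FALSE), top_n)
}

#' Overlay an external grouping onto ordination scores
#'
#' @param scores Accession x axis score matrix with rownames.
#' @param grouping Named vector accession -> label; accessions absent
#'   from it are labeled `"unassigned"`.
#' @return `data.frame`: `accession`, one column per axis, `group`.
#' @export
overlay_groups <- function(scores, grouping) {
  lab <- grouping[rownames(scores)]
  lab[is.na(lab)] <- "unassigned"
  data.frame(accession = rownames(scores), as.data.frame(scores),
             group = unname(lab), row.names = NULL, stringsAsFactors = FALSE)
}
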