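#' Euclidean genetic distance between accessions
#'
#' `D[x, y] = sqrt(sum_i (x_i - y_i)^2)` over allele-frequency profiles.
#'
#' @param afm An [afm] object without missing values.
#' @return Object of class `dist_matrix`: list with `D` (symmetric matrix
#'   with accession dimnames), `labels`, `metric = "euclidean_freq"`.
#' @export
genetic_distance <- function(afm) {
  if (any(afm$missing_mask)) stop("missing values present; impute first")
  D <- as.matrix(stats::dist(afm$values, method = "euclidean"))
  structure(list(D = D, labels = rownames(D), metric = "euclidean_freq"),
            class = "dist_matrix")
}

#' Mahalanobis phenotypic distance between accessions
#'
#' `D[i, j] = sqrt((Z_i - Z_j)' Sigma^-1 (Z_i - Z_j))` with `Sigma` the
#' sample covariance of the standardized trait matrix, optionally shrunk
#' toward the identity: `Sigma(s) = (1 - s) Sigma + s I`. Shrinkage is
#' needed whenever the trait count approaches or exceeds the accession
#' count (the covariance is then singular). The `"auto"` rule uses
#' `s = p / (n + p)`, which grows with the ratio of traits to accessions.
#'
#' @param x Standardized accession x trait matrix (rownames = accession
#'   ids).
#' @param shrinkage Number in `[0, 1]`, or `"auto"`.
#' @return `dist_matrix` with `metric = "mahalanobis_pheno"` and the
#'   shrinkage used in `$shrinkage`.
#' @export
phenotypic_distance <- function(x, shrinkage = "auto") {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n <= 2) stop("need more than 2 accessions")
  if (identical(shrinkage, "auto")) shrinkage <- p / (n + p)
  stopifnot(shrinkage >= 0, shrinkage <= 1)
  Sig <- (1 - shrinkage) * stats::cov(x) + shrinkage * diag(p)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch))
    stop("covariance numerically singular; increase `shrinkage` (e.g. \"auto\")")
  xw <- t(backsolve(ch, t(x), transpose = TRUE))  # rows: L^-1 z_i
  rownames(xw) <- rownames(x)
  D <- as.matrix(stats::dist(xw, method = "euclidean"))
  structure(list(D = D, labels = rownames(D), metric = "mahalanobis_pheno",
                 shrinkage = shrinkage),
            class = "dist_matrix")
}

#' Mantel test between two distance matrices
#'
#' Spearman rank correlation of the strictly-upper-triangle entries; the
#' null distribution is built by jointly permuting rows and columns of
#' the second matrix. One-sided (greater) p-value with the observed
#' statistic included in the null count:
#' `p = (1 + #(r_perm >= r_obs)) / (1 + n_permutations)`, so the smallest
#' attainable p at 999 permutations is 0.001.
#'
#' @param d1,d2 `dist_matrix` objects (or plain symmetric matrices) with
#'   identical labels in identical order.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Object of class `mantel_result`: `r_obs`, `p_value`,
#'   `n_permutations`, `method = "spearman"`, `seed`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 999L, seed = 1L) {
  M1 <- if (inherits(d1, "dist_matrix")) d1$D else as.matrix(d1)
  M2 <- if (inherits(d2, "dist_matrix")) d2$D else as.matrix(d2)
  n <- nrow(M1)
  if (n < 4) stop("need at least 4 accessions")
  l1 <- rownames(M1); l2 <- rownames(M2)
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("distance matrices have mismatched labels")
  up <- upper.tri(M1)
  r1 <- rank(M1[up])
  # ranks of D2 entries, stored as a symmetric matrix so that ranks of a
  # permuted matrix are just permuted ranks (same multiset of entries)
  RK2 <- matrix(0, n, n)
  RK2[up] <- rank(M2[up])
  RK2 <- RK2 + t(RK2)
  r2 <- RK2[up]
  r_obs <- stats::cor(r1, r2)
  set.seed(seed)
  r_perm <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    r_perm[b] <- stats::cor(r1, RK2[perm, perm][up])
  }
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_permutations)
  structure(list(r_obs = r_obs, p_value = p,
                 n_permutations = n_permutations, method = "spearman",
                 seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (Spearman, %d permutations): r = %.4f, p = %.4g\n",
              x$n_permutations, x$r_obs, x$p_value))
  invisible(x)
}

#' Write a labeled distance matrix to TSV
#'
#' @param dm A `dist_matrix`.
#' @param path Output path.
#' @export
write_distance <- function(dm, path) {
  tab <- data.frame(accession = dm$labels, dm$D, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
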