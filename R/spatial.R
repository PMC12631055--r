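#' B-spline basis over field coordinates
#'
#' Open-uniform B-spline basis of the given degree with `n_knots` equally
#' spaced knots spanning `range` (default: the data range). The basis has
#' `n_knots + degree - 1` columns and forms a partition of unity (every
#' row sums to 1) inside the span. Degree 0 gives indicator bins.
#'
#' @param x Numeric coordinates.
#' @param n_knots Number of (distinct) knots, >= 2.
#' @param degree Spline degree (default 3, cubic).
#' @param range Length-2 span; coordinates must lie inside it.
#' @return Matrix, rows = `length(x)`, with attributes `knots`, `degree`,
#'   `range`.
#' @export
bspline_basis <- function(x, n_knots, degree = 3, range = base::range(x)) {
  if (n_knots < 2) stop("n_knots must be >= 2")
  if (any(x < range[1] | x > range[2])) stop("coordinate outside knot span")
  inner <- seq(range[1], range[2], length.out = n_knots)
  if (degree == 0) {
    idx <- findInterval(x, inner, rightmost.closed = TRUE)
    B <- matrix(0, length(x), n_knots - 1)
    B[cbind(seq_along(x), idx)] <- 1
  } else {
    knots <- c(rep(range[1], degree), inner, rep(range[2], degree))
    B <- splines::splineDesign(knots, x, ord = degree + 1, outer.ok = FALSE)
  }
  attr(B, "knots") <- inner
  attr(B, "degree") <- degree
  attr(B, "range") <- range
  B
}

#' Tensor-product design matrix for the spatial surface
#'
#' Builds the plot x knot-effect design `W` from row and column bases:
#' `W[plot, (a,b)] = row_basis[row(plot), a] * col_basis[col(plot), b]`.
#' Bases are indexed by coordinate value, so they must be built over
#' integer coordinates `1..n_rows` / `1..n_cols`.
#'
#' @param row_basis Basis matrix over row coordinates (row `r` = coordinate
#'   `r`).
#' @param col_basis Basis matrix over column coordinates.
#' @param layout Trial layout with `row` and `column` columns.
#' @return Matrix with `nrow(layout)` rows and
#'   `ncol(row_basis) * ncol(col_basis)` columns (row index varying
#'   slowest).
#' @export
tensor_design <- function(row_basis, col_basis, layout) {
  if (any(layout$row < 1 | layout$row > nrow(row_basis)) ||
      any(layout$column < 1 | layout$column > nrow(col_basis)))
    stop("plot coordinates outside basis span")
  A <- ncol(row_basis); B <- ncol(col_basis)
  Rb <- row_basis[layout$row, , drop = FALSE]
  Cb <- col_basis[layout$column, , drop = FALSE]
  W <- Rb[, rep(seq_len(A), each = B), drop = FALSE] *
    Cb[, rep(seq_len(B), times = A), drop = FALSE]
  colnames(W) <- paste0("k", rep(seq_len(A), each = B), "_", rep(seq_len(B), times = A))
  W
}

# First-order autoregressive correlation matrix (internal).
ar1_cor <- function(k, rho) rho^abs(outer(seq_len(k), seq_len(k), "-"))

# REML log-likelihood of y = mu*1 + sum_i random terms with covariance
# V = sum_i sigma2_i K_i + sigma2_e I, profiled over mu (internal).
reml_loglik <- function(sig2, Ks, y) {
  n <- length(y)
  V <- diag(sig2[length(sig2)], n)
  for (i in seq_along(Ks)) V <- V + sig2[i] * Ks[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  xvx <- sum(Vi_1)              # 1' V^-1 1
  if (xvx <= 0) return(-Inf)
  beta <- sum(Vi_y) / xvx
  Py <- Vi_y - Vi_1 * beta
  ll <- -0.5 * (logdetV + log(xvx) + sum(y * Py) + (n - 1) * log(2 * pi))
  attr(ll, "Py") <- Py
  attr(ll, "mu") <- beta
  ll
}

#' Fit the spatial genomic mixed model by REML
#'
#' Fits `y = mu + Z u + W s + e`, with breeding values
#' `u ~ N(0, G sigma2_a)`, tensor-product B-spline knot effects
#' `s ~ N(0, S sigma2_s)`, and residuals `e ~ N(0, I sigma2_e)`. `Z` is
#' the plot-to-accession incidence and `W` the tensor design from
#' [tensor_design()]. Variance components are estimated by restricted
#' maximum likelihood: the global mean is profiled out and the
#' log-variances optimized with bounded L-BFGS-B from moment-based
#' starting values. BLUPs of `u` and `s` come from the mixed-model
#' equations at the optimum.
#'
#' @param y Numeric plot phenotypes (one per layout row; `NA` rows are
#'   dropped).
#' @param layout Trial layout (`row`, `column`, `accession`).
#' @param G A `grm` object or symmetric accession matrix with dimnames
#'   covering the layout's accessions.
#' @param knots Length-2 integer vector `(n_row_knots, n_col_knots)`, or
#'   `NULL` for a model without the spatial term.
#' @param S_structure Knot-effect covariance: `"identity"` (independent
#'   knot effects) or `"ar1"` (separable first-order autoregressive over
#'   the knot grid with correlation `rho`).
#' @param rho AR(1) correlation used when `S_structure = "ar1"`.
#' @param degree B-spline degree.
#' @return Object of class `spatial_fit`: variance components
#'   (`var_additive`, `var_spatial`, `var_residual`), `mu`, `u_hat`
#'   (named by accession), `s_hat`, `W`, `Z_design`, `knots`, `loglik`,
#'   `aic` (= -2 loglik + 2 x number of variance parameters),
#'   `S_structure`, `converged`.
#' @export
fit_spatial_gblup <- function(y, layout, G, knots = c(6L, 8L),
                              S_structure = c("identity", "ar1"), rho = 0.5,
                              degree = 3) {
  S_structure <- match.arg(S_structure)
  Gm <- if (inherits(G, "grm")) G$G else G
  if (!isSymmetric(unname(Gm), tol = 1e-6)) stop("G must be symmetric")
  ok <- !is.na(y)
  y <- y[ok]; layout <- layout[ok, , drop = FALSE]
  if (!all(layout$accession %in% rownames(Gm)))
    stop("layout contains accessions absent from G")
  acc <- intersect(rownames(Gm), unique(layout$accession))
  Gm <- Gm[acc, acc, drop = FALSE]
  n <- length(y)
  Z <- matrix(0, n, length(acc), dimnames = list(NULL, acc))
  Z[cbind(seq_len(n), match(layout$accession, acc))] <- 1

  has_spatial <- !is.null(knots)
  if (has_spatial) {
    if (any(knots < 2)) stop("need at least 2 knots per dimension")
    rb <- bspline_basis(seq_len(max(layout$row)), knots[1], degree,
                        range = c(1, max(layout$row)))
    cb <- bspline_basis(seq_len(max(layout$column)), knots[2], degree,
                        range = c(1, max(layout$column)))
    W <- tensor_design(rb, cb, layout)
    S <- if (S_structure == "ar1")
      kronecker(ar1_cor(ncol(rb), rho), ar1_cor(ncol(cb), rho))
    else diag(ncol(W))
  } else {
    W <- matrix(0, n, 0); S <- matrix(0, 0, 0)
  }

  vy <- stats::var(y)
  if (!is.finite(vy) || vy == 0) {
    u_hat <- stats::setNames(rep(0, length(acc)), acc)
    fit <- structure(list(mu = y[1], var_additive = 0, var_spatial = 0,
                          var_residual = 0, u_hat = u_hat,
                          s_hat = rep(0, ncol(W)), W = W, Z_design = Z,
                          knots = knots, loglik = Inf, aic = -Inf,
                          S_structure = S_structure, converged = TRUE),
                     class = "spatial_fit")
    return(fit)
  }

  # ridge jitter if G is numerically singular
  Ka <- tcrossprod(Z %*% Gm, Z)
  ev_min <- min(eigen(Gm, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-8 * mean(diag(Gm))) {
    Ka <- Ka + 1e-6 * mean(diag(Ka)) * tcrossprod(Z)
    message("G numerically singular; ridge jitter applied")
  }
  Ks <- list(Ka)
  if (has_spatial) Ks <- c(Ks, list(tcrossprod(W %*% S, W)))
  nv <- length(Ks) + 1L  # variance parameters incl. residual

  obj <- function(theta) {
    ll <- reml_loglik(exp(theta), Ks, y)
    if (!is.finite(ll)) return(1e10)
    -as.numeric(ll)
  }
  start <- log(rep(vy / nv, nv))
  opt <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = log(vy) - 25, upper = log(vy) + 10,
                      control = list(maxit = 200, factr = 1e7))
  sig2 <- exp(opt$par)
  ll <- reml_loglik(sig2, Ks, y)
  Py <- attr(ll, "Py")
  u_hat <- drop(sig2[1] * Gm %*% crossprod(Z, Py))
  names(u_hat) <- acc
  s_hat <- if (has_spatial) drop(sig2[2] * S %*% crossprod(W, Py)) else numeric(0)
  if (opt$convergence != 0)
    warning("REML did not report convergence (code ", opt$convergence, ")")
  structure(list(mu = attr(ll, "mu"),
                 var_additive = sig2[1],
                 var_spatial = if (has_spatial) sig2[2] else 0,
                 var_residual = sig2[length(sig2)],
                 u_hat = u_hat, s_hat = s_hat, W = W, Z_design = Z,
                 knots = knots, loglik = as.numeric(ll),
                 aic = -2 * as.numeric(ll) + 2 * nv,
                 S_structure = S_structure, converged = opt$convergence == 0),
            class = "spatial_fit")
}

#' @export
print.spatial_fit <- function(x, ...) {
  cat(sprintf("Spatial GBLUP fit: mu = %.4g, var_a = %.4g, var_s = %.4g, var_e = %.4g\n",
              x$mu, x$var_additive, x$var_spatial, x$var_residual))
  if (!is.null(x$knots))
    cat(sprintf("  knots = (%d, %d), S = %s, AIC = %.2f\n",
                x$knots[1], x$knots[2], x$S_structure, x$aic))
  invisible(x)
}

#' Select knot numbers by AIC grid search
#'
#' Fits [fit_spatial_gblup()] at every knot pair in `knot_grid` and
#' returns the fit with smallest AIC; ties go to fewer total knots.
#'
#' @inheritParams fit_spatial_gblup
#' @param knot_grid List of length-2 integer vectors.
#' @return The winning `spatial_fit`, with attribute `aic_grid` (a
#'   `data.frame` of the whole search).
#' @export
select_knots <- function(y, layout, G, knot_grid, S_structure = "identity",
                         rho = 0.5, degree = 3) {
  if (length(knot_grid) == 0) stop("knot_grid is empty")
  fits <- vector("list", length(knot_grid))
  errs <- character(length(knot_grid))
  for (i in seq_along(knot_grid)) {
    fits[[i]] <- tryCatch(
      fit_spatial_gblup(y, layout, G, knots = knot_grid[[i]],
                        S_structure = S_structure, rho = rho, degree = degree),
      error = function(e) { errs[i] <<- conditionMessage(e); NULL })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all grid points failed; first error: ", errs[which(errs != "")[1]])
  aics <- vapply(fits[ok], `[[`, numeric(1), "aic")
  total <- vapply(knot_grid[ok], sum, numeric(1))
  best <- order(aics, total)[1]
  out <- fits[ok][[best]]
  attr(out, "aic_grid") <- data.frame(
    row_knots = vapply(knot_grid[ok], `[`, numeric(1), 1),
    col_knots = vapply(knot_grid[ok], `[`, numeric(1), 2),
    aic = aics)
  out
}

#' Remove the fitted spatial surface from plot phenotypes
#'
#' The micro-environmental plot effect `W s_hat` is subtracted from the
#' raw phenotype; genetic and residual parts are retained.
#'
#' @param fit A `spatial_fit` produced from `y`.
#' @param y The raw plot phenotypes the fit was computed from (with the
#'   same `NA` pattern).
#' @return Numeric vector of spatially adjusted plot values (`NA` where
#'   `y` is `NA`).
#' @export
adjust_phenotype <- function(fit, y) {
  adj <- y
  ok <- !is.na(y)
  surf <- if (length(fit$s_hat)) drop(fit$W %*% fit$s_hat) else 0
  adj[ok] <- y[ok] - surf
  adj
}

#' Aggregate adjusted plot values to accession means
#'
#' @param values Plot-level values.
#' @param layout Layout with an `accession` column aligned to `values`.
#' @param accessions Optional accession universe; entries with no plot
#'   data get `NA`.
#' @return Named numeric vector of accession means.
#' @export
aggregate_accessions <- function(values, layout, accessions = NULL) {
  means <- tapply(values, layout$accession, mean, na.rm = TRUE)
  out <- stats::setNames(as.numeric(means), names(means))
  out[is.nan(out)] <- NA_real_
  if (!is.null(accessions)) {
    full <- stats::setNames(rep(NA_real_, length(accessions)), accessions)
    full[names(out)] <- out
    out <- full
    if (anyNA(out))
      message(sum(is.na(out)), " accession(s) without plot data: set to NA")
  }
  out
}

#' Standardize an accession x trait matrix
#'
#' Centers each trait to mean 0 and scales to sample standard deviation 1
#' (denominator `n - 1`). Constant traits are dropped with a warning.
#'
#' @param x Numeric matrix (accessions x traits).
#' @return Standardized matrix; columns with zero variance removed.
#' @export
standardize_traits <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  const <- !is.na(sds) & sds == 0
  if (any(const)) {
    warning("dropping constant trait(s): ", paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  scale(x, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Spatially adjust all traits of a plot table
#'
#' Convenience wrapper: for each trait column, selects knots by AIC (or
#' uses fixed knots), adjusts plot values, and aggregates to accession
#' means.
#'
#' @param plots Plot table: layout columns plus trait columns.
#' @param G Relationship matrix (`grm` or matrix).
#' @param traits Character vector of trait column names.
#' @param knot_grid List of knot pairs for [select_knots()], or a single
#'   length-2 vector for a fixed-knot fit.
#' @param ... Passed to the fitter.
#' @return List with `fits` (per trait), `adjusted` (plot table with
#'   adjusted traits) and `accession_means` (accession x trait matrix).
#' @export
adjust_trial_traits <- function(plots, G, traits, knot_grid = list(c(6L, 8L)), ...) {
  if (is.numeric(knot_grid)) knot_grid <- list(knot_grid)
  layout <- plots[, c("plot_id", "trial_id", "row", "column", "accession")]
  fits <- list(); adjusted <- plots
  acc <- rownames(if (inherits(G, "grm")) G$G else G)
  means <- matrix(NA_real_, length(acc), length(traits),
                  dimnames = list(acc, traits))
  for (tr in traits) {
    y <- plots[[tr]]
    fit <- if (length(knot_grid) > 1)
      select_knots(y, layout, G, knot_grid, ...)
    else fit_spatial_gblup(y, layout, G, knots = knot_grid[[1]], ...)
    adj <- adjust_phenotype(fit, y)
    adjusted[[tr]] <- adj
    means[, tr] <- aggregate_accessions(adj, layout, accessions = acc)
    fits[[tr]] <- fit
  }
  list(fits = fits, adjusted = adjusted, accession_means = means)
}
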