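test_that("B-spline basis is a partition of unity and matches Cox-de Boor", {
  x <- seq(1, 10, by = 0.25)
  B <- bspline_basis(x, n_knots = 5, degree = 3, range = c(1, 10))
  expect_equal(ncol(B), 5 + 3 - 1)
  expect_equal(rowSums(B), rep(1, length(x)))
  # degree 0: indicator bins
  B0 <- bspline_basis(c(1, 2.5, 9.9, 10), n_knots = 4, degree = 0, range = c(1, 10))
  expect_equal(ncol(B0), 3)
  expect_equal(rowSums(B0), rep(1, 4))
  expect_equal(B0[2, ], c(1, 0, 0))   # 2.5 in [1, 4)
  expect_equal(B0[4, ], c(0, 0, 1))   # right boundary closed
  # textbook recursion at interior midpoints
  inner <- seq(1, 10, length.out = 5)
  knots <- c(rep(1, 3), inner, rep(10, 3))
  mids <- (inner[-1] + inner[-5]) / 2
  Bm <- bspline_basis(mids, 5, 3, range = c(1, 10))
  for (i in seq_len(ncol(Bm))) {
    oracle <- sapply(mids, coxdeboor, i = i - 1, d = 3, t = knots)
    expect_equal(unname(Bm[, i]), oracle, tolerance = 1e-12)
  }
  expect_error(bspline_basis(11, 5, range = c(1, 10)), "outside")
})

test_that("tensor design multiplies the row and column bases per plot", {
  lay <- expand.grid(row = 1:3, column = 1:3)
  rb <- bspline_basis(1:3, 3, degree = 1, range = c(1, 3))
  cb <- bspline_basis(1:3, 3, degree = 1, range = c(1, 3))
  W <- tensor_design(rb, cb, lay)
  # brute-force double loop
  for (p in seq_len(nrow(lay))) for (a in seq_len(ncol(rb))) for (b in seq_len(ncol(cb)))
    expect_equal(unname(W[p, (a - 1) * ncol(cb) + b]),
                 rb[lay$row[p], a] * cb[lay$column[p], b])
  expect_equal(rowSums(W), rep(1, nrow(lay)))
  # degree-0 bases give a one-hot cell indicator
  rb0 <- bspline_basis(1:4, 5, degree = 0, range = c(1, 5))
  cb0 <- bspline_basis(1:4, 5, degree = 0, range = c(1, 5))
  W0 <- tensor_design(rb0, cb0, expand.grid(row = 1:4, column = 1:4))
  expect_true(all(rowSums(W0 == 1) == 1) && all(rowSums(W0) == 1))
})

test_that("REML matches closed-form one-way ANOVA on balanced data with G = I", {
  set.seed(4)
  n_a <- 30; r <- 4
  acc <- paste0("a", 1:n_a)
  lay <- data.frame(plot_id = paste0("p", 1:(n_a * r)), trial_id = "T",
                    row = rep(1:r, n_a), column = rep(1:n_a, each = r),
                    accession = rep(acc, each = r))
  u <- rnorm(n_a, 0, sqrt(2))
  y <- 5 + u[match(lay$accession, acc)] + rnorm(n_a * r)
  G <- diag(n_a); dimnames(G) <- list(acc, acc)
  fit <- fit_spatial_gblup(y, lay, G, knots = NULL)
  gm <- tapply(y, lay$accession, mean)
  MSA <- r * sum((gm - mean(y))^2) / (n_a - 1)
  MSE <- sum((y - gm[lay$accession])^2) / (n_a * (r - 1))
  expect_equal(fit$var_additive, (MSA - MSE) / r, tolerance = 1e-6)
  expect_equal(fit$var_residual, MSE, tolerance = 1e-6)
  expect_equal(fit$mu, mean(y), tolerance = 1e-6)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 2)
})

test_that("constant phenotypes collapse to the boundary fit", {
  pan <- make_test_panel(n_per_group = 8, n_markers = 100)
  lay <- simulate_trial(6, 8, rownames(pan$grm$G), seed = 1)
  fit <- suppressMessages(fit_spatial_gblup(rep(3.5, nrow(lay)), lay, pan$grm))
  expect_equal(fit$mu, 3.5)
  expect_equal(unname(fit$var_additive + fit$var_spatial + fit$var_residual), 0)
  expect_true(all(fit$u_hat == 0) && all(fit$s_hat == 0))
})

test_that("fit is invariant to plot ordering", {
  pan <- make_test_panel(n_per_group = 8, n_markers = 100)
  lay <- simulate_trial(6, 8, rownames(pan$grm$G), seed = 2)
  surf <- simulate_spatial_surface(6, 8, 6, 0.5, seed = 3)
  ph <- simulate_phenotypes(pan$grm, lay, surf, 1, 0.5, seed = 4)
  y <- ph$plots$trait1
  f1 <- suppressMessages(fit_spatial_gblup(y, lay, pan$grm, knots = c(3, 4)))
  o <- sample(length(y))
  f2 <- suppressMessages(fit_spatial_gblup(y[o], lay[o, ], pan$grm, knots = c(3, 4)))
  expect_equal(f2$var_additive, f1$var_additive, tolerance = 1e-5)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
  expect_equal(f2$u_hat[names(f1$u_hat)], f1$u_hat, tolerance = 1e-5)
})

test_that("spatial variance is shut off when the data carry no spatial signal", {
  # 440-plot augmented trial, phenotypes with genetic + residual variance only
  hits <- sapply(1:20, function(s) {
    tr <- simulate_group_frequencies(6, 300, 0.1, seed = 9000 + s)
    pan <- simulate_panel(stats::setNames(rep(67, 6), paste0("G", 1:6)), tr,
                          seed = 9100 + s)
    acc <- rownames(pan$afm$values)[1:400]
    g <- compute_relationship(impute_missing(afm(pan$afm$values[acc, ],
                                                 pan$afm$marker_map)))
    checks <- stats::setNames(c(rep(6, 5), rep(2, 15)), acc[1:20])
    lay <- simulate_trial(10, 44, acc, checks_replication = checks,
                          seed = 9200 + s)
    ph <- simulate_phenotypes(g, lay, NULL, 1, 1, seed = 9300 + s)
    fit <- suppressMessages(fit_spatial_gblup(ph$plots$trait1, lay, g,
                                              knots = c(4, 6)))
    fit$var_spatial <= 0.05 * var(ph$plots$trait1)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("variance components and the surface are recovered from model-simulated data", {
  # 440 plots as 220 accessions x 2 replicates; within-group accession
  # drift gives G individual-level structure so sigma2_a is identifiable
  reps <- sapply(1:20, function(rep) {
    set.seed(3000 + rep)
    tr <- simulate_group_frequencies(6, 500, 0.1, seed = 3000 + rep)
    pan <- simulate_panel(stats::setNames(rep(37, 6), paste0("G", 1:6)), tr,
                          accession_fst = 0.05, seed = 3050 + rep)
    acc <- rownames(pan$afm$values)[1:220]
    g <- compute_relationship(impute_missing(afm(pan$afm$values[acc, ],
                                                 pan$afm$marker_map)),
                              auto_scale = TRUE)
    lay <- simulate_trial(10, 44, acc,
                          checks_replication = stats::setNames(rep(2, 220), acc),
                          seed = 3100 + rep)
    rb <- bspline_basis(1:10, 4, range = c(1, 10))
    cb <- bspline_basis(1:44, 6, range = c(1, 44))
    W <- tensor_design(rb, cb, lay)
    s <- rnorm(ncol(W))
    surf_true <- drop(W %*% s)
    L <- alfadiv:::chol_psd(g$G)
    u <- drop(crossprod(L, rnorm(length(acc)))); names(u) <- acc
    y <- 10 + u[lay$accession] + surf_true + rnorm(nrow(lay))
    fit <- suppressMessages(fit_spatial_gblup(y, lay, g, knots = c(4, 6)))
    vc <- c(fit$var_additive, fit$var_spatial, fit$var_residual)
    c(within2 = all(vc > 0.5 & vc < 2),
      cor = cor(surf_true, drop(fit$W %*% fit$s_hat)))
  })
  expect_gte(mean(reps["within2", ]), 0.8)
  expect_gte(mean(reps["cor", ] >= 0.8), 0.8)
})

test_that("knot selection returns the AIC argmin with ties toward fewer knots", {
  pan <- make_test_panel(n_per_group = 8, n_markers = 100)
  lay <- simulate_trial(6, 8, rownames(pan$grm$G), seed = 6)
  surf <- simulate_spatial_surface(6, 8, 6, 1, seed = 7)
  ph <- simulate_phenotypes(pan$grm, lay, surf, 0.5, 0.5, seed = 8)
  y <- ph$plots$trait1
  single <- suppressMessages(select_knots(y, lay, pan$grm, list(c(3, 3))))
  expect_equal(single$knots, c(3, 3))
  best <- suppressMessages(select_knots(y, lay, pan$grm,
                                        list(c(3, 3), c(4, 5))))
  grid <- attr(best, "aic_grid")
  expect_equal(best$aic, min(grid$aic))
  expect_error(select_knots(y, lay, pan$grm, list()), "empty")
})

test_that("spatial adjustment removes the surface and helps accession means", {
  pan <- make_test_panel(n_per_group = 10, n_markers = 150)
  acc <- rownames(pan$grm$G)
  lay <- simulate_trial(6, 10, acc,
                        checks_replication = stats::setNames(rep(3, 5), acc[1:5]),
                        seed = 9)
  surf <- simulate_spatial_surface(6, 10, 6, 2, seed = 10)
  improved <- sapply(1:10, function(s) {
    ph <- simulate_phenotypes(pan$grm, lay, surf, 1, 0.5, seed = 700 + s)
    y <- ph$plots$trait1
    fit <- suppressMessages(fit_spatial_gblup(y, lay, pan$grm, knots = c(3, 4)))
    adj <- adjust_phenotype(fit, y)
    truth <- ph$truth$mu + ph$truth$breeding_value[, 1]
    rmse <- function(v) sqrt(mean((v - truth[names(v)])^2, na.rm = TRUE))
    rmse(aggregate_accessions(adj, lay)) < rmse(aggregate_accessions(y, lay))
  })
  expect_gte(mean(improved), 0.9)
  # zero spatial effect leaves phenotypes untouched
  fit0 <- suppressMessages(fit_spatial_gblup(rnorm(nrow(lay)) , lay, pan$grm,
                                             knots = NULL))
  y0 <- rnorm(nrow(lay))
  expect_equal(adjust_phenotype(fit0, y0), y0)
})

test_that("accession aggregation is a plain group-by mean", {
  lay <- data.frame(accession = c("a", "a", "b", "c"))
  expect_equal(aggregate_accessions(c(2, 4, 1, NA), lay),
               c(a = 3, b = 1, c = NA_real_))
  vals <- rnorm(40)
  lay2 <- data.frame(accession = sample(letters[1:8], 40, replace = TRUE))
  brute <- sapply(split(vals, lay2$accession), mean)
  expect_equal(aggregate_accessions(vals, lay2), brute[order(names(brute))])
  expect_message(aggregate_accessions(1, data.frame(accession = "a"),
                                      accessions = c("a", "b")), "without plot data")
})

test_that("trait standardization centers, scales and drops constants", {
  expect_equal(unname(standardize_traits(cbind(t = c(1, 2, 3)))[, 1]),
               c(-1, 0, 1))
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  z <- standardize_traits(x)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(standardize_traits(z)), unname(z), tolerance = 1e-12)
  expect_warning(standardize_traits(cbind(x, K = rep(2, 20))), "constant")
})
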