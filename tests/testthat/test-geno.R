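toy_afm <- function() {
  v <- matrix(c(0.2, 0.4, NA,
                0.0, 1.0, 0.5), nrow = 3,
              dimnames = list(c("x", "y", "z"), c("m1", "m2")))
  map <- data.frame(marker = c("m1", "m2"), chrom = c("chr1", "chr2"),
                    pos = c(100L, 200L))
  afm(v, map)
}

test_that("frequency tables round-trip through TSV and flag bad values", {
  a <- toy_afm()
  f <- tempfile(fileext = ".tsv"); fm <- tempfile(fileext = ".tsv")
  write_frequency_table(a, f, fm)
  b <- read_frequency_table(f, fm)
  expect_equal(b$values, a$values)
  expect_equal(b$missing_mask, a$missing_mask)
  expect_equal(b$marker_map, a$marker_map)
  # NA cells are masked and excluded from marker means
  expect_true(b$missing_mask["z", "m1"])
  expect_equal(mean(b$values[, "m1"], na.rm = TRUE), 0.3)
  # out-of-range value errors with row and column named
  bad <- a$values; bad["x", "m2"] <- 1.2
  expect_error(afm(bad, a$marker_map), "x.*m2")
  # duplicate accession id
  dup <- a$values; rownames(dup) <- c("x", "x", "z")
  expect_error(afm(dup), "duplicate accession")
})

test_that("marker filters apply the missingness, MAF and map rules", {
  # 6 markers with known violations: hand count of survivors = 3
  set.seed(1)
  n <- 100
  v <- cbind(ok1 = runif(n, 0.3, 0.7),
             miss6pct = runif(n, 0.3, 0.7),     # 6% missing -> drop
             rare = rep(0.005, n),              # MAF 0.005 -> drop
             ok2 = runif(n, 0.1, 0.9),
             unmapped = runif(n, 0.3, 0.7),     # no position -> drop if strict
             highfreq = rep(0.995, n))          # MAF 0.005 (1 - p) -> drop
  v[1:6, "miss6pct"] <- NA
  rownames(v) <- paste0("a", 1:n)
  map <- data.frame(marker = c("ok1", "miss6pct", "rare", "ok2", "highfreq"),
                    chrom = "chr1", pos = 1:5 * 100L)
  a <- afm(v, map)
  kept <- filter_markers(a, max_missing = 0.05, maf_min = 0.01,
                         drop_unmapped = FALSE)
  expect_setequal(colnames(kept$values), c("ok1", "ok2", "unmapped"))
  kept2 <- filter_markers(a, drop_unmapped = TRUE)
  expect_setequal(colnames(kept2$values), c("ok1", "ok2"))
  # boundary: exactly 5% missing is kept
  v2 <- v; v2[, "miss6pct"] <- v[, "ok1"]; v2[1:5, "miss6pct"] <- NA
  kept3 <- filter_markers(afm(v2, map))
  expect_true("miss6pct" %in% colnames(kept3$values))
  expect_error(filter_markers(a, maf_min = 0.6), "no markers")
})

test_that("marker sets split into complete and imputable as the mask dictates", {
  a <- toy_afm()
  s <- split_marker_sets(a, max_missing = 0.5, maf_min = 0)
  expect_equal(colnames(s$complete$values), "m2")
  expect_setequal(colnames(s$imputable$values), c("m1", "m2"))
  # without missing data both sets coincide
  full <- impute_missing(a)
  s2 <- split_marker_sets(full, maf_min = 0)
  expect_equal(colnames(s2$complete$values), colnames(s2$imputable$values))
  # counts match brute-force mask column sums
  pan <- make_test_panel()
  v <- pan$afm$values
  v[sample(length(v), 50)] <- NA
  am <- afm(v, pan$afm$marker_map)
  s3 <- split_marker_sets(am, max_missing = 1, maf_min = 0)
  expect_equal(ncol(s3$complete$values), sum(colSums(is.na(v)) == 0))
})

test_that("mean imputation preserves marker means and clears the mask", {
  a <- toy_afm()
  imp <- impute_missing(a)
  expect_false(any(imp$missing_mask))
  expect_equal(imp$values["z", "m1"], 0.3)  # mean of 0.2, 0.4
  expect_equal(colMeans(imp$values), colMeans(a$values, na.rm = TRUE))
  expect_identical(impute_missing(imp)$values, imp$values)
  allna <- a$values; allna[, "m1"] <- NA
  expect_error(impute_missing(afm(allna)), "all values missing")
})

test_that("relationship matrix reproduces the hand-computed example", {
  # M = [[0,0],[1,1]]: pbar = (0.5, 0.5), Z = [[-.5,-.5],[.5,.5]],
  # sum p(1-p) = 0.5, denominator 0.5/16 = 0.03125 -> G = +/-16
  v <- matrix(c(0, 1, 0, 1), 2, dimnames = list(c("a", "b"), c("m1", "m2")))
  g <- compute_relationship(afm(v), n_scale = 16)
  expect_equal(unname(g$G), matrix(c(16, -16, -16, 16), 2))
  # an accession sitting at the marker means has a zero row
  v3 <- rbind(v, c(0.5, 0.5)); rownames(v3) <- c("a", "b", "c")
  g3 <- compute_relationship(afm(v3))
  expect_equal(unname(g3$G["c", ]), c(0, 0, 0))
  expect_error(compute_relationship(afm(matrix(rep(c(0, 0), 2), 2,
    dimnames = list(c("a", "b"), c("m1", "m2"))))), "monomorphic")
})

test_that("relationship matrix is invariant to ordering and marker duplication", {
  pan <- make_test_panel(n_per_group = 10, n_markers = 120)
  a <- impute_missing(pan$afm)
  g <- compute_relationship(a)
  # centering makes G row sums zero (column sums of Z vanish)
  expect_lt(max(abs(rowSums(g$G))), 1e-8 * max(abs(g$G)))
  # permutation invariance
  pm <- sample(ncol(a$values)); pa <- sample(nrow(a$values))
  a_perm <- afm(a$values[pa, pm], a$marker_map)
  g_perm <- compute_relationship(a_perm)
  expect_equal(g_perm$G, g$G[rownames(a_perm$values), rownames(a_perm$values)])
  # duplicating all markers leaves G unchanged
  v2 <- cbind(a$values, a$values)
  colnames(v2) <- make.unique(colnames(v2))
  expect_equal(unname(compute_relationship(afm(v2))$G), unname(g$G))
  # PSD up to numerical tolerance
  ev <- eigen(g$G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(g$G)))
})

test_that("auto-scaling pins the mean diagonal at one", {
  pan <- make_test_panel(n_per_group = 10, n_markers = 150)
  g <- compute_relationship(impute_missing(pan$afm), auto_scale = TRUE)
  expect_equal(mean(diag(g$G)), 1, tolerance = 1e-12)
})

test_that("Balding-Nichols panel at F = 1/16 gives mean diagonal near one at n_scale 16", {
  d <- sapply(1:5, function(s) {
    tr <- simulate_group_frequencies(80, 1500, 1/16, seed = 400 + s)
    v <- tr$group_freq; rownames(v) <- paste0("acc", seq_len(nrow(v)))
    mean(diag(compute_relationship(afm(v), n_scale = 16)$G))
  })
  expect_equal(mean(d), 1, tolerance = 0.1)
})
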