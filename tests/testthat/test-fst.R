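test_that("group frequencies are member means with small groups excluded", {
  v <- rbind(a1 = c(0.2, 0.0), a2 = c(0.4, 1.0), a3 = c(0.3, 0.5),
             b1 = c(0.6, 0.5), b2 = c(0.8, 0.5), b3 = c(1.0, 0.5),
             c1 = c(0.1, 0.1), c2 = c(0.2, 0.2))
  colnames(v) <- c("m1", "m2")
  grp <- stats::setNames(c("A", "A", "A", "B", "B", "B", "C", "C"), rownames(v))
  expect_message(gf <- group_frequencies(afm(v), grp, min_group_size = 3),
                 "excluding group")
  expect_setequal(rownames(gf$freq), c("A", "B"))  # C has only 2 members
  expect_equal(gf$excluded, c(C = 2L))
  expect_equal(unname(gf$freq["A", ]), c(0.3, 0.5))
  # brute-force group-by mean
  expect_equal(unname(gf$freq["B", ]), unname(colMeans(v[4:6, ])))
  expect_error(suppressMessages(group_frequencies(afm(v), grp,
                                                  min_group_size = 4)),
               "fewer than 2 groups")
})

test_that("Nei FST matches the printed formulas and the algebraic identity", {
  expect_equal(nei_fst(0.5, 0.5), data.frame(h_t = 0.5, h_s = 0.5, fst = 0))
  expect_equal(nei_fst(0, 1), data.frame(h_t = 0.5, h_s = 0, fst = 1))
  r <- nei_fst(0.2, 0.4)
  expect_equal(r$h_t, 0.42)
  expect_equal(r$h_s, 0.40)
  expect_equal(r$fst, 0.02 / 0.42)
  expect_equal(r$fst, (0.2 - 0.4)^2 / (2 * r$h_t))
  # undefined when both groups are fixed for the same allele
  expect_true(is.na(nei_fst(0, 0)$fst))
  expect_error(nei_fst(1.2, 0.5), "\\[0, 1\\]")
  # properties over a random grid: identity, symmetry, flip invariance
  set.seed(1)
  p1 <- runif(500); p2 <- runif(500)
  a <- nei_fst(p1, p2)
  expect_equal(a$h_t - a$h_s, (p1 - p2)^2 / 2, tolerance = 1e-14)
  expect_true(all(a$fst >= 0, na.rm = TRUE))
  expect_equal(a, nei_fst(p2, p1))
  expect_equal(a$fst, nei_fst(1 - p1, 1 - p2)$fst, tolerance = 1e-12)
})

test_that("pairwise comparisons enumerate all unordered group pairs", {
  for (g in 2:8) {
    freq <- matrix(runif(g * 10), g, 10,
                   dimnames = list(paste0("G", 1:g), paste0("m", 1:10)))
    gf <- structure(list(freq = freq), class = "group_freq")
    expect_equal(length(fst_all_pairs(gf)), choose(g, 2))
  }
})

test_that("the empirical null is the FST multiset at the shared neutral markers", {
  fst <- stats::setNames(c(0.1, NA, 0.3, 0.2, 0.05), paste0("m", 1:5))
  expect_setequal(build_empirical_null(fst, names(fst)), c(0.1, 0.3, 0.2, 0.05))
  expect_equal(sort(build_empirical_null(fst, c("m1", "m4"))), c(0.1, 0.2))
  expect_error(build_empirical_null(fst, "m2"), "empty")
  # the sample is drawn once and is seed-stable
  s1 <- sample_neutral_markers(paste0("m", 1:100), 20, seed = 5)
  expect_identical(s1, sample_neutral_markers(paste0("m", 1:100), 20, seed = 5))
  expect_length(s1, 20)
})

test_that("empirical p-values follow the +1/+1 counting rule", {
  null <- c(0.1, 0.2, 0.3)
  expect_equal(empirical_pvalues(0.25, null), (1 + 1) / 4)
  expect_equal(empirical_pvalues(0.05, null), 1)
  expect_equal(empirical_pvalues(0.4, null), 1 / 4)
  # beats all 999 null values -> exactly 0.001
  expect_equal(empirical_pvalues(1, runif(999, 0, 0.5)), 1 / 1000)
  # ties count against the marker
  expect_equal(empirical_pvalues(0.2, null), (1 + 2) / 4)
  expect_true(is.na(empirical_pvalues(NA, null)))
  # monotone non-increasing in fst
  set.seed(2)
  nn <- runif(200)
  x <- sort(runif(50))
  expect_true(all(diff(empirical_pvalues(x, nn)) <= 0))
  # neutral p-values are ~uniform when scored against exchangeable nulls
  set.seed(3)
  pool <- rbeta(4000, 0.5, 5)
  p <- empirical_pvalues(pool[1:2000], pool[2001:4000])
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("BH q-values match the hand example and a brute-force oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), bh_bruteforce(p))
  }
})

test_that("outlier calls use a strict threshold", {
  expect_equal(call_outliers(c(0.049, 0.05, 1, NA), 0.05),
               c(TRUE, FALSE, FALSE, NA))
})

test_that("gene annotation matches a brute-force interval scan", {
  genes <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(1000L, 5000L, 2000L),
                      end = c(2000L, 6000L, 3000L),
                      gene_id = c("g1", "g2", "g3"))
  snps <- data.frame(marker = paste0("s", 1:5),
                     chrom = c("chr1", "chr1", "chr1", "chr2", "chr3"),
                     pos = c(1500L, 500L, 499L, 3400L, 100L))
  expect_warning(hits <- annotate_outliers(snps, genes, window = 500),
                 "absent from annotation")
  # s1 inside g1; s2 upstream-of-gene boundary at exactly 500 bp; s3 misses;
  # s4 within 400 bp downstream of g3; s5 unmatched chromosome
  expect_equal(hits$marker, c("s1", "s2", "s4"))
  expect_equal(hits$relation,
               c("inside", "downstream_within_window", "upstream_within_window"))
  expect_equal(hits$distance, c(0L, 500L, 400L))
  brute <- interval_scan_bruteforce(snps, genes, 500)
  expect_equal(hits$marker, brute$marker)
  expect_equal(hits$distance, brute$distance)
  # randomized cross-check
  set.seed(5)
  genes2 <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                       start = sample(1:50000, 30))
  genes2$end <- genes2$start + sample(100:3000, 30)
  genes2$gene_id <- paste0("g", 1:30)
  snps2 <- data.frame(marker = paste0("s", 1:60),
                      chrom = sample(c("chr1", "chr2"), 60, TRUE),
                      pos = sample(1:55000, 60))
  h2 <- annotate_outliers(snps2, genes2, window = 500)
  b2 <- interval_scan_bruteforce(snps2, genes2, 500)
  key <- function(d) sort(paste(d$marker, d$gene_id, d$distance))
  expect_equal(key(h2), key(b2))
})

test_that("annotation reads gene models from GFF3", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=gene1;Name=n1",
    "chr1\tsrc\tmRNA\t1000\t2000\t.\t+\t.\tID=rna1;Parent=gene1",
    "chr2\tsrc\tgene\t300\t700\t.\t-\t.\tID=gene2"), gff)
  snps <- data.frame(marker = c("s1", "s2"), chrom = c("chr1", "chr2"),
                     pos = c(1500L, 800L))
  hits <- annotate_outliers(snps, gff, window = 500)
  expect_equal(hits$gene_id, c("gene1", "gene2"))
  expect_equal(hits$relation, c("inside", "upstream_within_window"))
  expect_equal(hits$distance, c(0L, 100L))
})

test_that("the full scan produces one table per pair and recovers planted outliers", {
  tr <- simulate_group_frequencies(6, 800, 0.05, 0.02, 0.5, seed = 31)
  pan <- simulate_panel(stats::setNames(rep(8, 6), paste0("G", 1:6)), tr, seed = 32)
  scan <- fst_outlier_scan(impute_missing(pan$afm), pan$group_of,
                           neutral = 400L, seed = 33)
  expect_s3_class(scan, "fst_scan")
  expect_length(scan$pairs, 15)   # choose(6, 2)
  expect_named(scan$pairs[[1]],
               c("marker", "chrom", "pos", "h_t", "h_s", "fst",
                 "empirical_p", "q_value", "outlier"))
  # deterministic given the seed
  scan2 <- fst_outlier_scan(impute_missing(pan$afm), pan$group_of,
                            neutral = 400L, seed = 33)
  expect_identical(scan$pairs, scan2$pairs)
  expect_identical(scan$neutral_markers, scan2$neutral_markers)
  # FST values within [0, 1] where defined
  all_fst <- unlist(lapply(scan$pairs, `[[`, "fst"))
  expect_true(all(all_fst >= 0 & all_fst <= 1, na.rm = TRUE))
  # BED export uses 0-based half-open coordinates
  bed <- tempfile(fileext = ".bed")
  write_outlier_bed(scan, bed)
  if (file.size(bed) > 0) {
    b <- utils::read.delim(bed, header = FALSE)
    expect_true(all(b$V3 - b$V2 == 1))
    m <- pan$afm$marker_map
    expect_equal(b$V2, m$pos[match(b$V4, m$marker)] - 1)
  }
})
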