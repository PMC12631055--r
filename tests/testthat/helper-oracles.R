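# Independent oracles used across the test files. These deliberately take
# the dumbest correct route (explicit loops, textbook recursions) so they
# stay independent of the package implementation.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j>=i} m*p_(j)/j,
# capped at 1, mapped back to input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m / (i:m) * ps[i:m]))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Textbook Cox-de Boor recursion for a single B-spline basis function
# B_{i,d}(x) over knot vector t (0-based index i).
coxdeboor <- function(x, i, d, t) {
  if (d == 0) {
    return(as.numeric(t[i + 1] <= x & x < t[i + 2]))
  }
  a <- if (t[i + d + 1] > t[i + 1])
    (x - t[i + 1]) / (t[i + d + 1] - t[i + 1]) * coxdeboor(x, i, d - 1, t)
  else 0
  b <- if (t[i + d + 2] > t[i + 2])
    (t[i + d + 2] - x) / (t[i + d + 2] - t[i + 2]) * coxdeboor(x, i + 1, d - 1, t)
  else 0
  a + b
}

# Brute-force Euclidean distance matrix by explicit double loop.
euclid_bruteforce <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  D
}

# Brute-force SNP-in-gene-window scan.
interval_scan_bruteforce <- function(snps, genes, window) {
  hits <- list()
  for (i in seq_len(nrow(snps))) for (j in seq_len(nrow(genes))) {
    if (snps$chrom[i] != genes$chrom[j]) next
    pos <- snps$pos[i]
    if (pos >= genes$start[j] - window && pos <= genes$end[j] + window) {
      d <- if (pos >= genes$start[j] && pos <= genes$end[j]) 0L
      else if (pos > genes$end[j]) pos - genes$end[j]
      else genes$start[j] - pos
      hits[[length(hits) + 1]] <- data.frame(
        marker = snps$marker[i], gene_id = genes$gene_id[j],
        distance = as.integer(d), stringsAsFactors = FALSE)
    }
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(marker = character(0), gene_id = character(0),
                  distance = integer(0))
}

# Naive re-statement of the correlation prefilter rule: find the worst
# offending pair, drop the member with the larger mean absolute
# correlation to all other remaining traits, repeat.
prefilter_bruteforce <- function(x, threshold) {
  kept <- colnames(x)
  repeat {
    if (length(kept) < 2) break
    cm <- abs(stats::cor(x[, kept, drop = FALSE])); diag(cm) <- 0
    mx <- max(cm)
    if (mx <= threshold) break
    idx <- which(cm == mx, arr.ind = TRUE)
    cand <- unique(t(apply(idx, 1, function(z) sort(kept[z]))))
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    a <- cand[1, 1]; b <- cand[1, 2]
    ma <- mean(cm[a, setdiff(kept, a)]); mb <- mean(cm[b, setdiff(kept, b)])
    victim <- if (ma > mb) a else if (mb > ma) b else sort(c(a, b))[2]
    kept <- setdiff(kept, victim)
  }
  kept
}

# A group_freq_truth built by hand (bypassing the Beta sampler) so panel
# sampling can be tested at exact group frequencies.
manual_truth <- function(group_freq) {
  structure(list(ancestral_freq = colMeans(group_freq),
                 group_freq = group_freq,
                 fst_neutral = 0.05, fst_outlier = 0.5,
                 outlier_index = integer(0)),
            class = "group_freq_truth")
}

# Small standard synthetic panel + relationship matrix for reuse.
make_test_panel <- function(n_groups = 3, n_per_group = 15, n_markers = 300,
                            fst = 0.1, seed = 11) {
  tr <- simulate_group_frequencies(n_groups, n_markers, fst, seed = seed)
  sizes <- stats::setNames(rep(n_per_group, n_groups), rownames(tr$group_freq))
  pan <- simulate_panel(sizes, tr, seed = seed + 1)
  list(truth = tr, afm = pan$afm, group_of = pan$group_of,
       grm = compute_relationship(impute_missing(pan$afm)))
}
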