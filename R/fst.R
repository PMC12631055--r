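#' Per-group allele frequencies
#'
#' Group frequency at each marker is the unweighted mean of the member
#' accessions' pooled frequencies. Groups smaller than `min_group_size`
#' are excluded (and recorded), mirroring the exclusion of groups too
#' small for meaningful differentiation estimates.
#'
#' @param afm An [afm] object without missing values.
#' @param grouping Named vector accession -> group label.
#' @param min_group_size Minimum accessions per group (default 3).
#' @return Object of class `group_freq`: `freq` (group x marker matrix),
#'   `group_sizes`, `excluded` (named sizes of dropped groups).
#' @export
group_frequencies <- function(afm, grouping, min_group_size = 3L) {
  if (any(afm$missing_mask)) stop("missing values present; impute first")
  acc <- rownames(afm$values)
  if (!all(acc %in% names(grouping)))
    stop("grouping does not cover all accessions")
  g <- grouping[acc]
  sizes <- table(g)
  small <- names(sizes)[sizes < min_group_size]
  if (length(small))
    message("excluding group(s) below min_group_size: ",
            paste(sprintf("%s (n=%d)", small, sizes[small]), collapse = ", "))
  keep <- !(g %in% small)
  if (length(unique(g[keep])) < 2) stop("fewer than 2 groups remain")
  v <- afm$values[keep, , drop = FALSE]
  gk <- g[keep]
  sums <- rowsum(v, gk)
  freq <- sums / as.vector(table(gk)[rownames(sums)])
  structure(list(freq = freq,
                 group_sizes = c(table(gk)),
                 excluded = stats::setNames(as.integer(sizes[small]), small),
                 marker_map = afm$marker_map),
            class = "group_freq")
}

#' Nei's two-group FST from allele frequencies
#'
#' With mean frequency `pbar = (p1 + p2)/2`, total heterozygosity
#' `h_t = 2 pbar (1 - pbar)`, mean within-group heterozygosity
#' `h_s = (2 p1 (1 - p1) + 2 p2 (1 - p2)) / 2`, and
#' `fst = (h_t - h_s) / h_t`. Where `h_t = 0` (both groups fixed for the
#' same allele) FST is undefined and returned as `NA`. Vectorized.
#'
#' @param p1,p2 Allele frequencies in the two groups, in `[0, 1]`.
#' @return `data.frame` with columns `h_t`, `h_s`, `fst`.
#' @export
nei_fst <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  pbar <- (p1 + p2) / 2
  h_t <- 2 * pbar * (1 - pbar)
  h_s <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  # (h_t - h_s) equals (p1 - p2)^2 / 2 algebraically; the squared form is
  # used so fst is non-negative at machine precision
  fst <- ifelse(h_t > 0, (p1 - p2)^2 / 2 / h_t, NA_real_)
  data.frame(h_t = h_t, h_s = h_s, fst = fst)
}

#' Per-marker FST for every pair of groups
#'
#' @param gf A `group_freq` object.
#' @return Named list (one element per unordered group pair,
#'   `"A|B"`) of `data.frame`s: `marker`, `h_t`, `h_s`, `fst`.
#' @export
fst_all_pairs <- function(gf) {
  groups <- rownames(gf$freq)
  if (length(groups) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    f <- nei_fst(gf$freq[pr[1], ], gf$freq[pr[2], ])
    cbind(data.frame(marker = colnames(gf$freq), stringsAsFactors = FALSE), f)
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = "|")
  out
}

#' Sample the shared set of putatively neutral markers
#'
#' A single marker set is sampled once (seeded) and reused as the null
#' for every pairwise comparison.
#'
#' @param marker_ids All candidate marker ids.
#' @param size Sample size (capped at the number of markers).
#' @param seed Integer seed.
#' @return Character vector of marker ids.
#' @export
sample_neutral_markers <- function(marker_ids, size, seed = 1L) {
  set.seed(seed)
  sample(marker_ids, min(size, length(marker_ids)))
}

#' Empirical null distribution of FST for one comparison
#'
#' @param fst Named numeric vector of per-marker FST values (names =
#'   marker ids).
#' @param neutral_markers Marker ids of the shared neutral set.
#' @return Numeric vector: the comparison's FST at the neutral markers,
#'   with undefined (NA) values removed.
#' @export
build_empirical_null <- function(fst, neutral_markers) {
  null <- fst[intersect(neutral_markers, names(fst))]
  null <- null[!is.na(null)]
  if (length(null) == 0) stop("neutral set empty after removing undefined FST")
  unname(null)
}

#' Empirical p-values against a null distribution
#'
#' `p = (1 + #(null >= fst)) / (1 + length(null))`; ties count against
#' the marker (conservative), and the +1/+1 correction keeps p > 0.
#' Undefined FST gives `NA`.
#'
#' @param fst Numeric FST values.
#' @param null Numeric null distribution (no NAs).
#' @return Numeric p-values.
#' @export
empirical_pvalues <- function(fst, null) {
  if (length(null) == 0) stop("null distribution is empty")
  ns <- sort(null)
  n_lt <- findInterval(fst, ns, left.open = TRUE)  # #(null < fst)
  p <- (1 + (length(ns) - n_lt)) / (1 + length(ns))
  p[is.na(fst)] <- NA_real_
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; `NA` p-values propagate to
#' `NA` q-values and do not count toward the number of tests.
#'
#' @param p Numeric p-values in `(0, 1]` (NAs allowed).
#' @return Numeric q-values in input order.
#' @export
bh_fdr <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Call FST outliers from q-values
#'
#' @param q Numeric q-values.
#' @param threshold FDR threshold in `(0, 1)`; strict inequality
#'   (`q < threshold`) per the scan's definition of an outlier.
#' @return Logical flags (`NA` where q is `NA`).
#' @export
call_outliers <- function(q, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  q < threshold
}

# Parse gene records out of a GFF3 file (internal): returns data.frame
# chrom, start, end, gene_id (1-based inclusive coordinates).
read_gff_genes <- function(path, feature_type = "gene", id_attribute = "ID") {
  gff <- ape::read.gff(path, GFF3 = TRUE)
  genes <- gff[gff$type == feature_type, , drop = FALSE]
  if (nrow(genes) == 0) stop("no '", feature_type, "' features in ", path)
  pat <- paste0("(^|;)", id_attribute, "=([^;]+)")
  m <- regmatches(genes$attributes, regexec(pat, genes$attributes))
  ids <- vapply(m, function(z) if (length(z) >= 3) z[3] else NA_character_,
                character(1))
  data.frame(chrom = as.character(genes$seqid), start = genes$start,
             end = genes$end, gene_id = ids, stringsAsFactors = FALSE)
}

#' Annotate outlier SNPs against gene models
#'
#' A SNP hits a gene if its position lies inside the gene interval
#' (1-based inclusive, GFF3 convention) or within `window` bp of either
#' gene end. `relation` is `inside` (distance 0), `upstream_within_window`
#' (gene ends before the SNP) or `downstream_within_window` (gene starts
#' after the SNP); `distance` is the bp gap. A SNP inside or near several
#' genes yields several hits.
#'
#' @param snps `data.frame` with columns `marker`, `chrom`, `pos`
#'   (1-based).
#' @param annotation Path to a GFF3 file, or a `data.frame` with `chrom`,
#'   `start`, `end`, `gene_id`.
#' @param window Window in bp (default 500).
#' @param feature_type,id_attribute GFF3 gene feature type and attribute
#'   key for the gene id.
#' @return `data.frame`: `marker`, `chrom`, `pos`, `gene_id`, `relation`,
#'   `distance`.
#' @export
annotate_outliers <- function(snps, annotation, window = 500L,
                              feature_type = "gene", id_attribute = "ID") {
  genes <- if (is.character(annotation))
    read_gff_genes(annotation, feature_type, id_attribute) else annotation
  snps <- snps[!is.na(snps$pos), , drop = FALSE]
  unmatched <- setdiff(unique(snps$chrom), unique(genes$chrom))
  if (length(unmatched))
    warning(length(unmatched), " SNP chromosome(s) absent from annotation: ",
            paste(unmatched, collapse = ", "))
  gr_snp <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  # maxgap counts positions strictly between ranges, so a SNP `window` bp
  # from a gene end has gap window - 1
  ov <- GenomicRanges::findOverlaps(gr_snp, gr_gene, maxgap = window - 1L)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  pos <- snps$pos[qi]
  gstart <- genes$start[si]; gend <- genes$end[si]
  relation <- ifelse(pos >= gstart & pos <= gend, "inside",
                     ifelse(gend < pos, "upstream_within_window",
                            "downstream_within_window"))
  distance <- ifelse(relation == "inside", 0L,
                     ifelse(relation == "upstream_within_window",
                            pos - gend, gstart - pos))
  data.frame(marker = snps$marker[qi], chrom = snps$chrom[qi], pos = pos,
             gene_id = genes$gene_id[si], relation = relation,
             distance = as.integer(distance), stringsAsFactors = FALSE)
}

#' Genome-wide FST outlier scan
#'
#' Orchestrates the full scan: per-group frequencies, per-marker Nei FST
#' for every group pair, a shared empirical neutral null, empirical
#' p-values, Benjamini-Hochberg q-values, outlier calls, and optional
#' gene annotation of the outliers.
#'
#' @param afm An [afm] object without missing values.
#' @param grouping Named vector accession -> group.
#' @param neutral Either a character vector of marker ids (explicit
#'   neutral set) or a single integer: the size of a uniform random
#'   sample of markers drawn once (seeded) and shared by all comparisons.
#' @param q_threshold FDR threshold (default 0.05).
#' @param annotation Optional GFF3 path or gene `data.frame` for
#'   [annotate_outliers()].
#' @param window Annotation window in bp.
#' @param min_group_size Minimum group size (default 3).
#' @param seed Integer seed for the neutral sample.
#' @return Object of class `fst_scan`: `pairs` (named list of per-pair
#'   `data.frame`s with `marker`, `chrom`, `pos`, `h_t`, `h_s`, `fst`,
#'   `empirical_p`, `q_value`, `outlier`), `neutral_markers`, `hits`
#'   (annotation table or NULL), `q_threshold`, `group_sizes`.
#' @export
fst_outlier_scan <- function(afm, grouping, neutral = 5000L,
                             q_threshold = 0.05, annotation = NULL,
                             window = 500L, min_group_size = 3L, seed = 1L) {
  gf <- group_frequencies(afm, grouping, min_group_size)
  pairs <- fst_all_pairs(gf)
  neutral_markers <- if (is.character(neutral)) neutral
  else sample_neutral_markers(colnames(gf$freq), as.integer(neutral), seed)
  map <- afm$marker_map
  res <- lapply(pairs, function(tab) {
    fst <- stats::setNames(tab$fst, tab$marker)
    null <- build_empirical_null(fst, neutral_markers)
    p <- empirical_pvalues(tab$fst, null)
    q <- bh_fdr(p)
    idx <- match(tab$marker, map$marker)
    data.frame(marker = tab$marker, chrom = map$chrom[idx], pos = map$pos[idx],
               h_t = tab$h_t, h_s = tab$h_s, fst = tab$fst,
               empirical_p = p, q_value = q,
               outlier = call_outliers(q, q_threshold),
               stringsAsFactors = FALSE)
  })
  hits <- NULL
  if (!is.null(annotation)) {
    out_snps <- unique(do.call(rbind, lapply(res, function(tab)
      tab[!is.na(tab$outlier) & tab$outlier, c("marker", "chrom", "pos")])))
    hits <- if (nrow(out_snps))
      annotate_outliers(out_snps, annotation, window) else NULL
  }
  structure(list(pairs = res, neutral_markers = neutral_markers, hits = hits,
                 q_threshold = q_threshold, group_sizes = gf$group_sizes,
                 excluded_groups = gf$excluded),
            class = "fst_scan")
}

#' @export
print.fst_scan <- function(x, ...) {
  n_out <- vapply(x$pairs, function(t) sum(t$outlier, na.rm = TRUE), integer(1))
  cat(sprintf("FST outlier scan: %d group pairs, q < %g; outliers per pair: %s\n",
              length(x$pairs), x$q_threshold,
              paste(sprintf("%s=%d", names(n_out), n_out), collapse = ", ")))
  invisible(x)
}

#' Write outlier SNPs as BED
#'
#' BED uses 0-based half-open coordinates; the marker map is 1-based, so
#' a SNP at position `pos` becomes the interval `[pos - 1, pos)`.
#'
#' @param scan_result An `fst_scan` object.
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
write_outlier_bed <- function(scan_result, path) {
  snps <- unique(do.call(rbind, lapply(scan_result$pairs, function(tab)
    tab[!is.na(tab$outlier) & tab$outlier & !is.na(tab$pos),
        c("chrom", "pos", "marker")])))
  bed <- data.frame(chrom = snps$chrom, start = snps$pos - 1L, end = snps$pos,
                    name = snps$marker)
  utils::write.table(bed[order(bed$chrom, bed$start), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
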