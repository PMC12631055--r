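#' Allele-frequency matrix constructor
#'
#' Container for an accession x marker table of pooled allele frequencies
#' in `[0, 1]`, with a missingness mask and a marker map (chromosome and
#' 1-based position). Markers absent from the map are retained but
#' flagged position-less.
#'
#' @param values Numeric matrix, accessions in rows (rownames = accession
#'   ids), markers in columns (colnames = marker ids). `NA` marks missing.
#' @param marker_map `data.frame` with columns `marker`, `chrom`, `pos`.
#' @return Object of class `afm`: list with `values`, `missing_mask`,
#'   `marker_map` (one row per column of `values`, `NA` chrom/pos when
#'   unmapped) and `accession_ids`.
#' @export
afm <- function(values, marker_map = NULL) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have accession rownames and marker colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate accession id: ", rownames(values)[duplicated(rownames(values))][1])
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("frequency outside [0,1] at accession '%s', marker '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  markers <- colnames(values)
  map <- data.frame(marker = markers, chrom = NA_character_, pos = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!is.null(marker_map)) {
    stopifnot(all(c("marker", "chrom", "pos") %in% names(marker_map)))
    idx <- match(markers, marker_map$marker)
    hit <- !is.na(idx)
    map$chrom[hit] <- as.character(marker_map$chrom[idx[hit]])
    map$pos[hit] <- as.integer(marker_map$pos[idx[hit]])
  }
  structure(list(values = values, missing_mask = is.na(values),
                 marker_map = map, accession_ids = rownames(values)),
            class = "afm")
}

#' @export
print.afm <- function(x, ...) {
  cat(sprintf("Allele-frequency matrix: %d accessions x %d markers (%.2f%% missing, %d unmapped)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$missing_mask),
              sum(is.na(x$marker_map$pos))))
  invisible(x)
}

# Subset an afm by marker ids or indices (internal).
subset_markers <- function(afm, keep) {
  v <- afm$values[, keep, drop = FALSE]
  afm(v, afm$marker_map)
}

#' Read an allele-frequency table and marker map from TSV
#'
#' The frequency table has a header row of marker ids and a first column
#' of accession ids; missing cells are encoded `NA`. The map has columns
#' `marker`, `chrom`, `pos` (1-based bp).
#'
#' @param path Frequency table TSV.
#' @param map_path Marker map TSV (optional).
#' @return An [afm] object.
#' @export
read_frequency_table <- function(path, map_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  acc <- as.character(tab[[1]])
  if (anyDuplicated(acc)) stop("duplicate accession id: ", acc[duplicated(acc)][1])
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- acc
  map <- if (!is.null(map_path))
    utils::read.delim(map_path, stringsAsFactors = FALSE) else NULL
  afm(values, map)
}

#' Write an allele-frequency table (and map) to TSV
#'
#' @param afm An [afm] object.
#' @param path Output TSV for the frequency table.
#' @param map_path Optional output TSV for the marker map.
#' @export
write_frequency_table <- function(afm, path, map_path = NULL) {
  tab <- data.frame(accession = rownames(afm$values), afm$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path))
    utils::write.table(afm$marker_map, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Filter markers on missingness, MAF and map position
#'
#' A marker is kept iff its missing fraction is at most `max_missing`,
#' its minor allele frequency `min(p, 1-p)` (with `p` the mean
#' non-missing frequency) is at least `maf_min`, and (when
#' `drop_unmapped`) its genomic position is known.
#'
#' @param afm An [afm] object.
#' @param max_missing Maximum tolerated missing fraction (default 0.05).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param drop_unmapped Drop markers without map positions?
#' @return Filtered [afm].
#' @export
filter_markers <- function(afm, max_missing = 0.05, maf_min = 0.01,
                           drop_unmapped = FALSE) {
  stopifnot(max_missing >= 0, max_missing <= 1, maf_min >= 0, maf_min <= 1)
  miss <- colMeans(afm$missing_mask)
  p <- colMeans(afm$values, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  keep <- miss <= max_missing & !is.na(maf) & maf >= maf_min
  if (drop_unmapped) keep <- keep & !is.na(afm$marker_map$pos)
  if (!any(keep)) stop("no markers pass the filters")
  subset_markers(afm, which(keep))
}

#' Split markers into complete and imputable sets
#'
#' Mirrors the two marker subsets used in practice: a strict set of
#' markers with no missing values at all, and a larger set of markers
#' passing the missingness/MAF filters (to be imputed).
#'
#' @inheritParams filter_markers
#' @return List with `complete` and `imputable`, both [afm] objects.
#' @export
split_marker_sets <- function(afm, max_missing = 0.05, maf_min = 0.01,
                              drop_unmapped = FALSE) {
  nmiss <- colSums(afm$missing_mask)
  imputable <- filter_markers(afm, max_missing, maf_min, drop_unmapped)
  complete_ids <- intersect(colnames(afm$values)[nmiss == 0],
                            colnames(imputable$values))
  list(complete = subset_markers(afm, complete_ids), imputable = imputable)
}

#' Impute missing frequencies by the marker mean
#'
#' Each missing cell is replaced by that marker's mean non-missing
#' frequency, so marker means are unchanged by imputation.
#'
#' @param afm An [afm] object; every marker needs at least one non-missing
#'   value.
#' @return [afm] with no missing values.
#' @export
impute_missing <- function(afm) {
  v <- afm$values
  nmiss <- colSums(afm$missing_mask)
  if (any(nmiss == nrow(v)))
    stop("marker(s) with all values missing: ",
         colnames(v)[which(nmiss == nrow(v))[1]])
  if (any(nmiss > 0)) {
    p <- colMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- p[idx[, 2]]
  }
  afm(v, afm$marker_map)
}

#' Genomic relationship matrix from pooled allele frequencies
#'
#' VanRaden-style relationship adapted to frequency data: with `M` the
#' accession x marker frequency matrix and `P` the per-marker mean
#' frequency, `Z = M - P` and
#' `G = Z Z' / ((1/n_scale) * sum_j p_j (1 - p_j))`. The denominator is
#' the summed expected SNP variance; `n_scale` rescales it so the mean
#' diagonal of `G` is close to 1 (16 is the value recommended for pooled
#' autotetraploid panels). With `auto_scale = TRUE`, `n_scale` is instead
#' set so the mean diagonal equals exactly 1.
#'
#' @param afm An [afm] object without missing values (see
#'   [impute_missing()]).
#' @param n_scale Scaling constant (default 16).
#' @param auto_scale Choose `n_scale` so that `mean(diag(G)) == 1`?
#' @return Object of class `grm`: list with `G` (symmetric, accession
#'   dimnames), `n_scale` (as used), `marker_freqs` and `m` (marker count).
#' @export
compute_relationship <- function(afm, n_scale = 16, auto_scale = FALSE) {
  if (any(afm$missing_mask)) stop("missing values present; impute first")
  M <- afm$values
  if (ncol(M) < 1) stop("need at least one marker")
  p <- colMeans(M)
  spq <- sum(p * (1 - p))
  if (spq == 0) stop("all markers monomorphic: zero expected variance")
  Z <- sweep(M, 2, p)
  ZZt <- tcrossprod(Z)
  if (auto_scale) n_scale <- spq / mean(diag(ZZt))
  G <- ZZt / (spq / n_scale)
  structure(list(G = G, n_scale = n_scale, marker_freqs = p, m = ncol(M)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("Genomic relationship matrix: %d accessions, %d markers, n_scale = %.4g, mean diag = %.4f\n",
              nrow(x$G), x$m, x$n_scale, mean(diag(x$G))))
  invisible(x)
}

#' Write a relationship matrix to TSV with accession header
#'
#' @param grm A `grm` object.
#' @param path Output path.
#' @export
write_relationship <- function(grm, path) {
  tab <- data.frame(accession = rownames(grm$G), grm$G,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
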