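#' Binned cis contact map
#'
#' A `contact_map` holds a symmetric, non-negative n x n matrix of contact
#' counts for a single chromosome, together with its bin table (0-based,
#' half-open intervals of width `resolution`; the last bin may be short).
#' Raw maps hold integer read-pair counts; depth-normalized and balanced
#' maps hold reals. Masked bins (low coverage) have zeroed rows/columns and
#' an `NA` bias.
#'
#' @param counts symmetric numeric matrix, non-negative.
#' @param resolution bin width in bp.
#' @param chrom chromosome label.
#' @param chrom_length chromosome length in bp; defaults to
#'   `nrow(counts) * resolution`.
#' @return An object of class `contact_map` with fields `counts`, `bins`
#'   (data.frame with `start`, `end`), `chrom`, `resolution`, `balanced`,
#'   `depth_normalized`, `bias`, `mask`.
#' @export
contact_map <- function(counts, resolution, chrom = "chrS", chrom_length = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (ncol(counts) != n) stop("contact map must be square")
  if (any(counts < 0)) stop("contact map counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(counts)))
    stop("contact map must be symmetric")
  chrom_length <- chrom_length %||% (n * resolution)
  starts <- (seq_len(n) - 1L) * resolution
  ends <- pmin(starts + resolution, chrom_length)
  structure(list(
    counts = counts,
    bins = data.frame(start = starts, end = ends),
    chrom = chrom,
    resolution = resolution,
    balanced = FALSE,
    depth_normalized = FALSE,
    bias = NULL,
    mask = rep(FALSE, n)
  ), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  n <- nrow(x$counts)
  cat(sprintf("<contact_map> %s: %d bins @ %d bp%s%s, %d masked\n",
              x$chrom, n, x$resolution,
              if (x$balanced) ", balanced" else "",
              if (x$depth_normalized) ", depth-normalized" else "",
              sum(x$mask)))
  invisible(x)
}

n_bins <- function(map) nrow(map$counts)

same_bins <- function(a, b) {
  identical(dim(a$counts), dim(b$counts)) &&
    isTRUE(all.equal(a$bins, b$bins)) && a$resolution == b$resolution
}

#' Read a contact map from a bin-pair triplet file
#'
#' The triplet file is a TSV with columns `bin1_id`, `bin2_id`, `count`
#' (0-based bin ids); the bin table is a 3-column BED (chrom, start, end)
#' defining the bins in order. Entries are mirrored into a symmetric dense
#' matrix; unlisted pairs are zero.
#'
#' @param path triplet TSV path.
#' @param bin_table_path bin BED path.
#' @return A [contact_map].
#' @export
read_triplets <- function(path, bin_table_path) {
  bins <- utils::read.table(bin_table_path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end"),
                            stringsAsFactors = FALSE)
  if (length(unique(bins$chrom)) != 1L) stop("bin table must cover a single chromosome")
  n <- nrow(bins)
  res <- max(bins$end - bins$start)
  counts <- matrix(0, n, n)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (k in seq_along(parts)) {
      p <- parts[[k]]
      if (length(p) != 3L) stop(sprintf("malformed triplet line %d: %s", k, lines[k]))
      i <- suppressWarnings(as.integer(p[1])); j <- suppressWarnings(as.integer(p[2]))
      v <- suppressWarnings(as.numeric(p[3]))
      if (is.na(i) || is.na(j) || is.na(v))
        stop(sprintf("malformed triplet line %d: %s", k, lines[k]))
      if (i < 0 || i >= n || j < 0 || j >= n)
        stop(sprintf("bin id out of range on line %d: %s", k, lines[k]))
      if (v < 0) stop(sprintf("negative count on line %d: %s", k, lines[k]))
      counts[i + 1L, j + 1L] <- counts[i + 1L, j + 1L] + v
      if (i != j) counts[j + 1L, i + 1L] <- counts[j + 1L, i + 1L] + v
    }
  }
  map <- contact_map(counts, resolution = res, chrom = bins$chrom[1],
                     chrom_length = max(bins$end))
  map$bins <- data.frame(start = bins$start, end = bins$end)
  map
}

#' Write a contact map as triplets plus a bin table
#'
#' Only the upper triangle (including the diagonal) of nonzero cells is
#' written, so `write_triplets()` followed by [read_triplets()] is an
#' identity on the counts.
#'
#' @param map a [contact_map].
#' @param path triplet TSV output path.
#' @param bin_table_path bin BED output path.
#' @export
write_triplets <- function(map, path, bin_table_path) {
  n <- n_bins(map)
  ut <- which(upper.tri(map$counts, diag = TRUE) & map$counts != 0, arr.ind = TRUE)
  df <- data.frame(bin1 = ut[, 1] - 1L, bin2 = ut[, 2] - 1L,
                   count = map$counts[ut])
  df <- df[order(df$bin1, df$bin2), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(map$chrom, map$bins$start, map$bins$end),
                     bin_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalize a contact map by sequencing depth
#'
#' Divides every cell by `total` (by default the total read-pair count, the
#' sum over the upper triangle plus diagonal), so that maps sequenced to
#' different depths become comparable.
#'
#' @param map a [contact_map].
#' @param total positive scalar; defaults to the map's read-pair total.
#' @return A depth-normalized [contact_map].
#' @export
normalize_depth <- function(map, total = NULL) {
  total <- total %||% sum(map$counts[upper.tri(map$counts, diag = TRUE)])
  if (!is.numeric(total) || length(total) != 1L || total <= 0)
    stop("total must be a positive scalar")
  map$counts <- map$counts / total
  map$depth_normalized <- TRUE
  map
}

#' Iterative correction (matrix balancing)
#'
#' Removes multiplicative per-bin biases by repeatedly dividing rows and
#' columns by their marginal sums until the marginals are uniform. Bins with
#' zero coverage plus the lowest-coverage `mask_low_coverage_fraction` of
#' nonzero bins are masked (zeroed) before correction. The diagonal is
#' excluded from the marginals. The raw map is exactly recoverable as
#' `balanced[i,j] * bias[i] * bias[j]` over unmasked bins.
#'
#' @param map a raw [contact_map].
#' @param max_iter maximum iterations.
#' @param tol convergence threshold on the maximum relative marginal
#'   deviation from uniformity.
#' @param mask_low_coverage_fraction fraction of lowest-coverage nonzero bins
#'   to mask in addition to zero-coverage bins.
#' @return A balanced [contact_map] with `bias` (NA for masked bins), `mask`,
#'   and a `converged` flag.
#' @export
iterative_correction <- function(map, max_iter = 500L, tol = 1e-8,
                                 mask_low_coverage_fraction = 0.02) {
  W <- map$counts
  n <- nrow(W)
  diag(W) <- 0
  cov <- rowSums(W)
  if (all(cov == 0)) stop("cannot balance an all-zero matrix")
  mask <- cov == 0
  nz <- which(!mask)
  k <- floor(mask_low_coverage_fraction * length(nz))
  if (k > 0) mask[nz[order(cov[nz])[seq_len(k)]]] <- TRUE
  if (sum(!mask) < 2L) stop("fewer than 2 unmasked bins after masking")
  W[mask, ] <- 0
  W[, mask] <- 0
  bias <- rep(1, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m <- rowSums(W)
    dev <- m / mean(m[!mask])
    dev[mask | dev == 0] <- 1
    if (max(abs(dev - 1)) < tol) { converged <- TRUE; break }
    bias <- bias * dev
    W <- W / outer(dev, dev)
    W[mask, ] <- 0
    W[, mask] <- 0
  }
  if (!converged)
    warning(sprintf("iterative correction did not converge in %d iterations", max_iter))
  bias <- bias / mean(bias[!mask])
  out <- map
  # keep exact raw = balanced * bias_i * bias_j on unmasked bins
  full <- map$counts
  diag(full) <- 0
  out$counts <- full / outer(bias, bias)
  out$counts[mask, ] <- 0
  out$counts[, mask] <- 0
  bias[mask] <- NA_real_
  out$bias <- bias
  out$mask <- mask
  out$balanced <- TRUE
  out$converged <- converged
  out
}

#' Observed/expected transform
#'
#' Divides each off-diagonal of a balanced map by its chromosome-wide mean
#' over unmasked cells, removing the distance decay. Diagonals whose mean is
#' zero (or with no unmasked cells) are excluded and reported in
#' `excluded_diagonals`; masked cells stay `NA`.
#'
#' @param map a balanced [contact_map].
#' @return A [contact_map]-shaped object with `oe = TRUE`; cells hold
#'   observed/expected ratios, `NA` where masked or excluded.
#' @export
observed_over_expected <- function(map) {
  if (!isTRUE(map$balanced)) stop("observed_over_expected expects a balanced map")
  n <- n_bins(map)
  W <- map$counts
  mask <- map$mask
  OE <- matrix(NA_real_, n, n)
  excluded <- integer(0)
  for (d in seq_len(n - 1L)) {
    i <- seq_len(n - d)
    j <- i + d
    ok <- !mask[i] & !mask[j]
    if (!any(ok)) { excluded <- c(excluded, d); next }
    m <- mean(W[cbind(i[ok], j[ok])])
    if (!is.finite(m) || m <= 0) { excluded <- c(excluded, d); next }
    OE[cbind(i[ok], j[ok])] <- W[cbind(i[ok], j[ok])] / m
    OE[cbind(j[ok], i[ok])] <- OE[cbind(i[ok], j[ok])]
  }
  out <- map
  out$counts <- OE
  out$oe <- TRUE
  out$excluded_diagonals <- excluded
  out
}

#' Log2 difference map between two conditions
#'
#' `log2((A + p) / (B + p))` cellwise on two depth-normalized maps with
#' identical bin tables; antisymmetric under swapping the conditions.
#'
#' @param mapA,mapB depth-normalized [contact_map]s on the same bins.
#' @param pseudocount small positive stabilizer `p`.
#' @return A signed matrix.
#' @export
difference_map <- function(mapA, mapB, pseudocount = 1e-9) {
  if (!same_bins(mapA, mapB)) stop("bin tables differ between conditions")
  log2((mapA$counts + pseudocount) / (mapB$counts + pseudocount))
}
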