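#' Percent of intersection between two intervals
#'
#' Overlap length divided by the length of the larger interval; 0 when the
#' intervals are disjoint or on different chromosomes. Intervals are
#' 0-based half-open, so abutting intervals do not intersect. Vectorized
#' over pairs.
#'
#' @param a_start,a_end,b_start,b_end interval coordinates (bp).
#' @param a_chrom,b_chrom optional chromosome labels.
#' @return A numeric vector in `[0, 1]`.
#' @export
percent_intersection <- function(a_start, a_end, b_start, b_end,
                                 a_chrom = NULL, b_chrom = NULL) {
  if (any(a_end <= a_start) || any(b_end <= b_start))
    stop("intervals must have end > start")
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  res <- ov / pmax(a_end - a_start, b_end - b_start)
  if (!is.null(a_chrom) && !is.null(b_chrom)) res[a_chrom != b_chrom] <- 0
  res
}

#' Classify peak persistence by the percent-of-intersection rule
#'
#' For each control peak, the best-overlapping treated peak is found and the
#' control peak classified as remaining iff its percent of intersection
#' (overlap over the larger peak length) strictly exceeds `threshold`.
#' Treated peaks whose best percent of intersection against the control set
#' does not exceed `threshold` are novel (the same rule applied in reverse).
#' Ties for best match go to the leftmost treated peak.
#'
#' @param control,treated interval data.frames with `start`, `end` (bp,
#'   0-based half-open), optionally `name`.
#' @param threshold persistence cutoff (default 0.5, strict).
#' @return An object of class `persistence_report`: `n_control`,
#'   `n_treated`, `n_remaining`, `n_lost`, `n_novel`, and `per_peak`
#'   (per-control-peak best `percent_intersection` and status).
#' @export
classify_peaks <- function(control, treated, threshold = 0.5) {
  nc <- nrow(control); nt <- nrow(treated)
  best_pi <- function(query, subject) {
    # best percent-of-intersection of each query interval vs a subject set
    out <- list(pi = rep(0, nrow(query)), match = rep(NA_integer_, nrow(query)))
    if (!nrow(query) || !nrow(subject)) return(out)
    qr <- IRanges::IRanges(start = query$start + 1L, end = query$end)
    sr <- IRanges::IRanges(start = subject$start + 1L, end = subject$end)
    ov <- IRanges::findOverlaps(qr, sr)
    if (!length(ov)) return(out)
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    pi <- percent_intersection(query$start[qi], query$end[qi],
                               subject$start[si], subject$end[si])
    o <- order(qi, -pi, subject$start[si], si)
    qi <- qi[o]; si <- si[o]; pi <- pi[o]
    first <- !duplicated(qi)
    out$pi[qi[first]] <- pi[first]
    out$match[qi[first]] <- si[first]
    out
  }
  fwd <- best_pi(control, treated)
  rev <- best_pi(treated, control)
  remaining <- fwd$pi > threshold
  novel <- !(rev$pi > threshold)
  per_peak <- data.frame(
    name = control$name %||% sprintf("control_%d", seq_len(nc)),
    percent_intersection = fwd$pi,
    best_match = fwd$match,
    remaining = remaining)
  structure(list(n_control = nc, n_treated = nt,
                 n_remaining = sum(remaining), n_lost = sum(!remaining),
                 n_novel = sum(novel), per_peak = per_peak,
                 threshold = threshold),
            class = "persistence_report")
}

#' @export
print.persistence_report <- function(x, ...) {
  cat(sprintf(paste0("<persistence_report> %d control, %d treated: ",
                     "%d remaining, %d lost, %d novel (threshold %g)\n"),
              x$n_control, x$n_treated, x$n_remaining, x$n_lost, x$n_novel,
              x$threshold))
  invisible(x)
}

#' Differential peak counts between conditions
#'
#' Counts of peaks present in only one condition under the
#' percent-of-intersection rule: control-only (lost) and treated-only
#' (novel).
#'
#' @inheritParams classify_peaks
#' @return A named vector `c(control_only, treated_only)`.
#' @export
differential_counts <- function(control, treated, threshold = 0.5) {
  rep <- classify_peaks(control, treated, threshold)
  c(control_only = rep$n_lost, treated_only = rep$n_novel)
}

#' Read / write BED interval files
#'
#' Minimal BED I/O for strandless interval sets (`chrom`, `start`, `end`,
#' and optionally `name`, `score`).
#'
#' @param path file path.
#' @return `read_bed` returns a sorted interval data.frame.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[seq_len(min(5, ncol(df)))] <-
    c("chrom", "start", "end", "name", "score")[seq_len(min(5, ncol(df)))]
  if (any(df$end <= df$start)) stop("BED intervals must have end > start")
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' @param intervals interval data.frame.
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"),
                    names(intervals))
  utils::write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
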